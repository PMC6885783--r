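test_that("net peak area is null on pure flat background", {
  sp <- make_peak_spectrum(bkg = 80, seed = 11)
  pk <- net_peak_area(sp, energy = 500, fwhm = 10)
  expect_lt(abs(pk$net_area), 3 * pk$u_net)
  expect_false(pk$significant)
})

test_that("net peak area recovers a known synthetic peak", {
  for (seed in c(1, 2, 3)) {
    sp <- make_peak_spectrum(bkg = 40, peak_energy = 400, peak_area = 5e4,
                             fwhm = 8, seed = seed)
    pk <- net_peak_area(sp, 400, 8)
    expect_true(pk$significant)
    expect_lt(abs(pk$net_area - 5e4), 3 * pk$u_net + 0.002 * 5e4)
  }
})

test_that("peak overlap and truncation raise errors", {
  sp <- make_peak_spectrum()
  expect_error(net_peak_area(sp, 500, 10, other_lines = c(500, 512)),
               "overlap")
  expect_error(net_peak_area(sp, 5, 10), "truncated")
})

test_that("relative penetration forms the exact rate ratio", {
  mk <- function(net, u = sqrt(net)) {
    structure(list(energy = 662, net_area = net, background = 0,
                   gross = net, u_net = u, rel_uncertainty = u / net,
                   significant = TRUE), class = "peak_result")
  }
  p <- relative_penetration(mk(10000), mk(10000), 300, 300)
  expect_equal(p$penetration, 1)
  expect_equal(p$attenuation, 0)
  p <- relative_penetration(mk(10000), mk(5000), 300, 300)
  expect_equal(p$penetration, 0.5)
  expect_equal(p$attenuation, 0.5)
  # different live times, pure-Poisson uncertainty propagation
  p <- relative_penetration(mk(10000), mk(3000), 300, 600)
  expect_equal(p$penetration, 0.15)
  expect_equal(p$u_penetration, 0.15 * sqrt(1 / 3000 + 1 / 10000),
               tolerance = 1e-12)
  expect_equal(p$attenuation + p$penetration, 1)
})

test_that("penetration uncertainty matches a parametric bootstrap", {
  set.seed(99)
  lam_o <- 20000; lam_s <- 6000
  P <- replicate(4000, (rpois(1, lam_s) / 1) / (rpois(1, lam_o) / 1))
  mk <- function(net) structure(list(energy = 662, net_area = net,
                                     background = 0, gross = net,
                                     u_net = sqrt(net),
                                     rel_uncertainty = 1 / sqrt(net),
                                     significant = TRUE),
                                class = "peak_result")
  p <- relative_penetration(mk(lam_o), mk(lam_s), 1, 1)
  expect_lt(abs(sd(P) / p$u_penetration - 1), 0.1)
})

test_that("degenerate penetration inputs error", {
  mk <- function(net, E = 662, sig = TRUE) {
    structure(list(energy = E, net_area = net, background = 0, gross = net,
                   u_net = sqrt(max(net, 1)),
                   rel_uncertainty = ifelse(net > 0, 1 / sqrt(net), Inf),
                   significant = sig), class = "peak_result")
  }
  expect_error(relative_penetration(mk(0), mk(100), 1, 1), "zero")
  expect_error(relative_penetration(mk(100, E = 662), mk(100, E = 400), 1, 1),
               "different energies")
  expect_error(relative_penetration(mk(100), mk(100), 0, 1), "> 0")
})

test_that("measured mass attenuation inverts Beer-Lambert", {
  mk <- function(P, u = 1e-4) structure(
    list(energy = 661.7, penetration = P, attenuation = 1 - P,
         u_penetration = u, valid = TRUE), class = "attenuation_point")
  expect_equal(mass_attenuation_measured(mk(exp(-1)), 1)$mu_rho, 1,
               tolerance = 1e-12)
  # fixed regression value: P = 0.5 through the 1.25 mm lead sheet
  expect_equal(mass_attenuation_measured(mk(0.5), 1.419)$mu_rho,
               0.4885, tolerance = 1e-3)
  # recovery of the bundled coefficient from an analytic penetration
  w <- material("W", c(W = 1), areal_density = 1.12)
  P <- analytic_penetration(w, 661.7)
  expect_equal(mass_attenuation_measured(mk(P), 1.12)$mu_rho,
               mass_attenuation(w, 661.7), tolerance = 1e-10)
  expect_error(mass_attenuation_measured(mk(1.5, u = 1e-4), 1),
               "not a valid")
})

test_that("per-point lead equivalent matches the paper's tungsten value", {
  mk <- function(P, E, u = 1e-4) structure(
    list(energy = E, penetration = P, attenuation = 1 - P,
         u_penetration = u, valid = TRUE), class = "attenuation_point")
  expect_equal(lead_equivalent_at(mk(1, 662))$t_pb_mm, 0)
  # pure-tungsten shielding layer of the 1 mm vest at the Co-60 line
  w <- material("W", c(W = 1), areal_density = 1.12)
  P <- analytic_penetration(w, 1332.49)
  t <- lead_equivalent_at(mk(P, 1332.49))$t_pb_mm
  expect_lt(abs(t - 0.99), 0.10)
})

test_that("mean lead equivalent applies the edge-exclusion rule", {
  mk <- function(P, E, u = 1e-3) structure(
    list(energy = E, penetration = P, attenuation = 1 - P,
         u_penetration = u, valid = TRUE), class = "attenuation_point")
  pb <- material("Pb", c(Pb = 1), areal_density = 1.419)
  # single point
  one <- mean_lead_equivalent(list(mk(0.5, 400)), pb)
  expect_equal(one$sd, 0)
  expect_equal(one$mean, analytic_lead_equivalent(0.5, 400))
  # a point at 88 keV is excluded for lead-bearing materials
  pts <- list(mk(0.5, 400), mk(0.6, 662), mk(0.05, 88.0))
  res <- mean_lead_equivalent(pts, pb)
  expect_true(88 %in% round(res$excluded_energies$energy_keV))
  kept <- res$per_energy[!res$per_energy$excluded, ]
  expect_equal(res$mean, mean(kept$t_pb_mm))
  expect_equal(res$sd, sd(kept$t_pb_mm))
  expect_error(mean_lead_equivalent(list(mk(0.05, 88.0)), pb), "excluded")
})

test_that("noise-free pipeline recovers the analytic lead equivalent", {
  w <- ppe_fixture("df_vest_w2")
  fit <- simulate_bench(w, nuclides = c("Cs137", "Co60"), seed = 1,
                        poisson = FALSE)
  kept <- fit$points[!fit$points$excluded, ]
  ref <- analytic_lead_equivalent(
    analytic_penetration(w, kept$energy_keV), kept$energy_keV)
  expect_true(all(abs(kept$t_pb_mm / ref - 1) < 1e-3))
})

test_that("penetration uncertainty scales as 1/sqrt(live time)", {
  pb <- ppe_fixture("pb_sheet")
  u_at <- function(lt) {
    fit <- simulate_bench(pb, nuclides = "Cs137", live_time = lt, seed = 21)
    fit$points$u_P[which.min(abs(fit$points$energy_keV - 661.66))]
  }
  r <- u_at(300) / u_at(1200)
  expect_lt(abs(r - 2), 0.6)   # bootstrap-level tolerance
})

test_that("attenuation fit object carries consistent results and methods", {
  pb <- ppe_fixture("pb_sheet")
  fit <- simulate_bench(pb, nuclides = c("Cs137", "Co60"), seed = 4)
  expect_s3_class(fit, "ppe_attenuation")
  expect_true(all(abs(fit$points$A + fit$points$P - 1) < 1e-12))
  expect_equal(unname(coef(fit)["mean_t_pb_mm"]), fit$leadeq$mean)
  pr <- predict(fit)
  expect_equal(length(pr), nrow(fit$points))
  # results CSV round-trips numerically
  tmp <- tempfile(fileext = ".csv")
  write_attenuation_csv(fit, tmp)
  back <- read.csv(tmp, comment.char = "#")
  expect_equal(back$P, fit$points$P, tolerance = 1e-6)
})

test_that("spectrum CSV dialect round-trips", {
  sp <- make_peak_spectrum(seed = 5)
  tmp <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, tmp)
  back <- read_spectrum_csv(tmp)
  expect_equal(back$counts, sp$counts)
  expect_equal(back$live_time, sp$live_time)
  expect_equal(back$gain, sp$gain)
  expect_equal(back$label, sp$label)
})
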
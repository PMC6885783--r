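test_that("Compton samples obey the scattering kinematics", {
  for (E in c(59.54, 364.49, 511, 1332.49)) {
    s <- sample_compton(E, 5000, seed = 2)
    a <- E / 510.99895
    pred <- E / (1 + a * (1 - cos(s$theta_rad)))
    expect_equal(s$energy_keV, pred, tolerance = 1e-10)
    expect_true(all(s$energy_keV >= E / (1 + 2 * a) - 1e-9))
    expect_true(all(s$energy_keV <= E + 1e-9))
  }
  # closed-form backscatter limit at 511 keV
  s <- sample_compton(511, 20000, seed = 3)
  expect_gt(min(s$energy_keV), 511 / 3 - 1e-6)
})

test_that("Klein-Nishina sampler matches the numeric CDF", {
  s <- sample_compton(662, 1e6, seed = 5)
  th <- sort(s$theta_rad)
  grid <- seq_along(th) / length(th)
  probe <- seq(5000, length(th) - 5000, by = 5000)
  cdf <- kn_theta_cdf(662, th[probe])
  ks <- max(abs(cdf - grid[probe]))
  expect_lt(ks, 0.003)
})

test_that("narrow-beam tally reproduces Beer-Lambert limits", {
  empty <- slab_scene(material("void", c(Pb = 1), areal_density = 0), 662)
  t0 <- transport_narrow_beam(empty, fast_cfg(1e4))
  expect_equal(t0$estimate, 1)
  expect_equal(t0$rel_se, 0)
  expect_error(transport_narrow_beam(empty, transport_config(0)), ">= 1")
})

test_that("narrow-beam tally agrees with the analytic oracle over a grid", {
  mats <- c("pb_sheet", "df_vest_w2", "hkx", "demron_suit", "biorubber_e600")
  energies <- c(59.54, 121.78, 356.01, 661.66, 1408.01)
  for (nm in mats) {
    m <- ppe_fixture(nm)
    for (E in energies) {
      tl <- transport_narrow_beam(slab_scene(m, E), fast_cfg(2e5, seed = 9))
      P <- analytic_penetration(m, E)
      se <- max(tl$rel_se * tl$estimate, 1e-12)
      expect_lt(abs(tl$estimate - P), max(3 * se, 3 * sqrt(P * (1 - P) / 2e5)),
                label = paste(nm, E))
    }
  }
})

test_that("stacked layers equal one merged layer of summed optical depth", {
  a <- ppe_fixture("df_vest_w1"); b <- ppe_fixture("opch90")
  two <- transport_narrow_beam(slab_scene(list(a, b), 356.01),
                               fast_cfg(4e5, seed = 2))
  tau <- mass_attenuation(a, 356.01) * a$areal_density +
    mass_attenuation(b, 356.01) * b$areal_density
  expect_lt(abs(two$estimate - exp(-tau)),
            3 * max(two$rel_se * two$estimate, 1e-12) + 3e-3)
})

test_that("identical seeds give bit-identical tallies", {
  sc <- slab_scene(ppe_fixture("pb_sheet"), 661.66)
  t1 <- transport_narrow_beam(sc, fast_cfg(1e5, seed = 77))
  t2 <- transport_narrow_beam(sc, fast_cfg(1e5, seed = 77))
  expect_identical(t1, t2)
  csc <- chamber_scene(garments = list("opch90"))
  c1 <- transport_chamber(csc, 364.49, "air", fast_cfg(5e3, seed = 13))
  c2 <- transport_chamber(csc, 364.49, "air", fast_cfg(5e3, seed = 13))
  expect_identical(c1$deposits, c2$deposits)
})

test_that("relative standard error scales as one over root N", {
  sc <- slab_scene(ppe_fixture("pb_sheet"), 661.66)
  cfg1 <- transport_config(2e5, seed = 101, n_batches = 200)
  cfg4 <- transport_config(8e5, seed = 102, n_batches = 200)
  r <- transport_narrow_beam(sc, cfg1)$rel_se /
    transport_narrow_beam(sc, cfg4)$rel_se
  expect_gt(r, 1.5)
  expect_lt(r, 2.7)
})

test_that("chamber transport conserves energy to the audit tolerance", {
  sc <- chamber_scene(garments = list("opch90", "df_vest_w2"))
  ct <- transport_chamber(sc, 637, "air", fast_cfg(2e4, seed = 4))
  rel <- abs(ct$audit$deposited_keV - ct$audit$emitted_keV) /
    ct$audit$emitted_keV
  expect_lt(max(rel), 1e-6)
  # wall and garment-surface sources audit too
  for (src in c("wall", "ppe")) {
    ct <- transport_chamber(sc, 364.49, src, fast_cfg(1e4, seed = 5))
    rel <- abs(ct$audit$deposited_keV - ct$audit$emitted_keV) /
      ct$audit$emitted_keV
    expect_lt(max(rel), 1e-6)
  }
})

test_that("a sub-cutoff source deposits nothing in the organs", {
  sc <- chamber_scene()
  ct <- transport_chamber(sc, 10.5, "air",
                          transport_config(5e3, seed = 2,
                                           photon_cutoff = 11))
  org <- sc$phantom$organ_names
  expect_true(all(vapply(ct$tallies[org], function(t) t$estimate, 0) == 0))
})

test_that("fluence follows the inverse square law without interactions", {
  sc <- chamber_scene()
  ct <- transport_chamber(sc, 662, "air", fast_cfg(2e4, seed = 6),
                          include_phantom = FALSE,
                          air_density_scale = 1e-12,
                          diag_radii = c(40, 80), point_source = TRUE,
                          wall_albedo = FALSE)
  flu <- ct$diag_counts / (4 * pi * c(40, 80)^2)
  expect_lt(abs(flu[1] / flu[2] - 4), 0.05)
})

test_that("adding areal density to a torso garment never raises torso dose", {
  cfgs <- list(l = list("opch90"),
               m = list("opch90", "df_vest_w1"),
               h = list("opch90", "df_vest_w2"))
  torso_sum <- se_sum <- numeric(3)
  for (i in seq_along(cfgs)) {
    sc <- chamber_scene(garments = cfgs[[i]])
    ct <- transport_chamber(sc, 364.49, "air",
                            fast_cfg(1e5, seed = 21, mode = "track-length"))
    org <- intersect(ppeshield:::.torso_organs, names(ct$tallies))
    est <- vapply(ct$tallies[org], function(t) t$estimate, 0)
    se <- vapply(ct$tallies[org], function(t) t$estimate * t$rel_se, 0)
    torso_sum[i] <- sum(est); se_sum[i] <- sqrt(sum(se^2))
  }
  expect_lt(torso_sum[2], torso_sum[1] + 3 * sqrt(se_sum[1]^2 + se_sum[2]^2))
  expect_lt(torso_sum[3], torso_sum[2] + 3 * sqrt(se_sum[2]^2 + se_sum[3]^2))
})

test_that("lead-bearing layers show the K-edge penetration drop", {
  m <- ppe_fixture("biorubber_e400")
  below <- transport_narrow_beam(slab_scene(m, 86), fast_cfg(2e5, seed = 8))
  above <- transport_narrow_beam(slab_scene(m, 90), fast_cfg(2e5, seed = 9))
  expect_lt(above$estimate, below$estimate)
})

test_that("empirical beta transmission behaves as specified", {
  expect_equal(beta_transmission(1000, 0), 1)
  expect_equal(beta_transmission(1000, 1 / 17), exp(-1), tolerance = 1e-12)
  # hand-computed value for the I-131 main branch through the full-body suit
  expect_equal(beta_transmission(606, 0.13),
               exp(-17 * 0.606^-1.14 * 0.13), tolerance = 1e-12)
  expect_true(beta_transmission(606, 0.2) < beta_transmission(606, 0.1))
  expect_true(beta_transmission(1200, 0.1) > beta_transmission(606, 0.1))
  expect_error(beta_transmission(40, 0.1), "exceed 50")
})

test_that("track-length and analog organ tallies agree", {
  sc <- chamber_scene()
  an <- transport_chamber(sc, 364.49, "air", fast_cfg(2e5, seed = 31))
  tl <- transport_chamber(sc, 364.49, "air",
                          fast_cfg(5e4, seed = 32, mode = "track-length"))
  for (o in c("lungs", "liver", "small_intestine")) {
    a <- an$tallies[[o]]; t <- tl$tallies[[o]]
    comb <- sqrt((a$estimate * a$rel_se)^2 + (t$estimate * t$rel_se)^2)
    expect_lt(abs(a$estimate - t$estimate), 4 * comb, label = o)
  }
})

test_that("phantom organs are pairwise non-overlapping", {
  ph <- stylized_phantom()
  og <- ph$organs
  inside <- function(r, p) {
    if (r["shape"] == 0) {
      sum(((p - r[c("cx", "cy", "cz")]) / r[c("ax", "ay", "az")])^2) <= 1
    } else {
      p[3] >= r["z0"] && p[3] <= r["z1"] &&
        sum(((p[1:2] - r[c("cx", "cy")]) / r[c("ax", "ay")])^2) <= 1
    }
  }
  set.seed(12)
  pts <- cbind(runif(4000, 105, 145), runif(4000, 90, 110),
               runif(4000, 78, 170))
  # paired shapes (lungs, colon, adrenals, kidneys) share one region id, so
  # count distinct organ regions containing each sampled point
  regions_at <- apply(pts, 1, function(p)
    length(unique(og[apply(og, 1, inside, p = p), "region"])))
  expect_lte(max(regions_at), 1)
})
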
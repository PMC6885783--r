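test_that("mixture rule reduces to the table value for a pure element", {
  et <- element_table("Pb")
  pb <- material("lead", c(Pb = 1))
  # probe a handful of interior grid points away from edges
  idx <- c(10, 25, 50, 80, 100)
  for (i in idx) {
    E <- et$grid[i]
    if (abs(E - et$k_edge) < 1e-6 || abs(E - et$l3_edge) < 1e-6) next
    expect_equal(mass_attenuation(pb, E), unname(et$partials[i, "total"]),
                 tolerance = 1e-12)
  }
})

test_that("mixture rule is linear in the weight fractions", {
  mix <- material("PbW", c(Pb = 0.5, W = 0.5))
  pb <- material("Pb", c(Pb = 1)); w <- material("W", c(W = 1))
  expect_equal(mass_attenuation(mix, 500),
               (mass_attenuation(pb, 500) + mass_attenuation(w, 500)) / 2,
               tolerance = 1e-12)
  # random composite, several energies
  set.seed(1)
  for (k in 1:5) {
    fr <- runif(3); fr <- fr / sum(fr)
    names(fr) <- c("Pb", "Sn", "O")
    m <- material("mix", fr)
    for (E in c(40, 200, 662, 1408)) {
      ref <- sum(vapply(names(fr), function(s)
        fr[[s]] * mass_attenuation(material(s, setNames(1, s)), E), 0))
      expect_equal(mass_attenuation(m, E), ref, tolerance = 1e-12)
    }
  }
})

test_that("lead K-edge produces an upward discontinuity near 88 keV", {
  pb <- material("Pb", c(Pb = 1))
  below <- mass_attenuation(pb, 87.9)
  above <- mass_attenuation(pb, 88.1)
  expect_gt(above, 2 * below)
  # evaluation exactly at the edge returns the above-edge branch
  at_edge <- mass_attenuation(pb, element_table("Pb")$k_edge)
  expect_gt(at_edge, above)
})

test_that("every bundled K-edge in range jumps upward", {
  idx <- element_symbols()
  for (s in idx) {
    et <- element_table(s)
    if (et$k_edge < 10.5 || et$k_edge > 2900) next
    m <- material(s, setNames(1, s))
    expect_gt(mass_attenuation(m, et$k_edge * 1.0001),
              mass_attenuation(m, et$k_edge * 0.9999), label = s)
  }
})

test_that("analytic penetration follows Beer-Lambert", {
  expect_equal(analytic_penetration(material("Pb", c(Pb = 1),
                                             areal_density = 0), 662), 1)
  mu <- mass_attenuation(material("Pb", c(Pb = 1)), 661.7)
  m1 <- material("Pb", c(Pb = 1), areal_density = 1 / mu)
  expect_equal(analytic_penetration(m1, 661.7), exp(-1), tolerance = 1e-12)
  # independent table read for the 1.25 mm lead sheet at 661.7 keV
  sheet <- material("Pb sheet", c(Pb = 1), areal_density = 1.419)
  expect_equal(analytic_penetration(sheet, 661.7),
               exp(-read_mu_csv("Pb", 661.7) * 1.419), tolerance = 1e-9)
})

test_that("penetration decreases strictly with areal density", {
  d <- seq(0, 5, by = 0.5)
  P <- vapply(d, function(di)
    analytic_penetration(material("W", c(W = 1), areal_density = di), 356), 0)
  expect_true(all(diff(P) < 0))
})

test_that("high-Z total coefficient decreases with energy away from edges", {
  for (s in c("Pb", "W")) {
    m <- material(s, setNames(1, s))
    E <- seq(100, 1408, by = 50)
    mu <- mass_attenuation(m, E)
    expect_true(all(diff(mu) < 0), label = s)
  }
})

test_that("lead equivalent round-trips a pure lead slab", {
  expect_equal(analytic_lead_equivalent(1, 662), 0)
  for (t_mm in c(0.25, 1.25, 3)) {
    slab <- material("Pb", c(Pb = 1), areal_density = 11.35 * t_mm / 10)
    for (E in c(100, 356, 661.7, 1408)) {
      P <- analytic_penetration(slab, E)
      expect_equal(analytic_lead_equivalent(P, E), t_mm, tolerance = 1e-6)
    }
  }
})

test_that("lead equivalent agrees with a bisection oracle", {
  # thickness solving exp(-mu * rho * t) = 1/e at 661.7 keV
  mu <- read_mu_csv("Pb", 661.7)
  f <- function(t_cm) exp(-mu * 11.35 * t_cm) - exp(-1)
  t_ref <- uniroot(f, c(1e-4, 10), tol = 1e-12)$root * 10
  expect_equal(analytic_lead_equivalent(exp(-1), 661.7), t_ref,
               tolerance = 1e-8)
})

test_that("invalid inputs raise the documented errors", {
  pb <- material("Pb", c(Pb = 1), areal_density = 1)
  expect_error(mass_attenuation(pb, 5), "range")
  expect_error(mass_attenuation(pb, 3500), "range")
  expect_error(material("bad", c(Pb = 0.5)), "sum to 1")
  expect_error(material("bad", c(Xx = 1)), "Xx")
  expect_error(material("bad", c(Pb = 1), areal_density = -1), ">= 0")
  expect_error(analytic_lead_equivalent(0, 662), "\\(0, 1\\]")
  expect_error(analytic_lead_equivalent(1.2, 662), "\\(0, 1\\]")
  expect_error(analytic_penetration(material("Pb", c(Pb = 1)), 662),
               "areal_density")
})

test_that("lead reference carries the conventional density and K-edge", {
  ref <- lead_reference()
  expect_equal(ref$density, 11.35)
  expect_true(ref$table$k_edge >= 87 && ref$table$k_edge <= 89)
})

test_that("element tables satisfy their structural invariants", {
  for (s in element_symbols()) {
    et <- element_table(s)
    g <- et$grid
    expect_true(all(diff(g) >= 0), label = s)
    dup <- which(diff(g) == 0)
    expect_lte(length(dup), 2)            # at most K and L3 duplicated
    expect_true(all(et$partials >= 0), label = s)
    expect_equal(unname(et$partials[, "total"]),
                 unname(rowSums(et$partials[, 1:4])), tolerance = 1e-12)
    expect_true(all(et$partials[g < 1021, "pair"] == 0), label = s)
  }
})
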
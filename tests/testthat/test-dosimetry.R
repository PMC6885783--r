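all_dose_organs <- function(h) {
  orgs <- c(names(tissue_weights())[names(tissue_weights()) != "remainder"],
            ppeshield:::.remainder_members, "testes",
            ppeshield:::.torso_organs)
  setNames(rep(h, length(unique(orgs))), unique(orgs))
}

test_that("tissue weights sum to one and a uniform field is preserved", {
  w <- tissue_weights()
  expect_identical(sum(w), 1)
  per <- all_dose_organs(3.7e-9)
  expect_equal(effective_dose(per), 3.7e-9, tolerance = 1e-12)
})

test_that("a single weighted organ contributes its weight", {
  per <- all_dose_organs(0)
  per["lungs"] <- 2e-8
  expect_equal(effective_dose(per), 0.12 * 2e-8, tolerance = 1e-15)
})

test_that("effective dose equals a brute-force dot product", {
  set.seed(7)
  for (k in 1:10) {
    per <- all_dose_organs(0)
    per[] <- runif(length(per))
    w <- tissue_weights()
    ref <- sum(vapply(setdiff(names(w), "remainder"),
                      function(o) w[[o]] * per[[o]], 0)) +
      w[["remainder"]] * mean(per[ppeshield:::.remainder_members])
    expect_equal(effective_dose(per), ref, tolerance = 1e-14)
  }
})

test_that("torso effective dose restricts the weighted sum", {
  per <- all_dose_organs(0)
  expect_equal(torso_effective_dose(per), 0)
  per <- all_dose_organs(1)
  # torso restriction must stay below the full normalisation bound
  expect_lt(torso_effective_dose(per), 1)
  expect_gt(torso_effective_dose(per), 0)
  set.seed(8)
  for (k in 1:5) {
    per[] <- runif(length(per))
    w <- tissue_weights()
    rem <- setdiff(ppeshield:::.torso_organs,
                   c("lungs", "stomach", "colon", "testes", "liver",
                     "oesophagus", "bladder"))
    ref <- 0.12 * (per[["lungs"]] + per[["stomach"]] + per[["colon"]]) +
      0.08 * per[["testes"]] +
      0.04 * (per[["liver"]] + per[["oesophagus"]] + per[["bladder"]]) +
      0.12 * mean(per[rem])
    expect_equal(torso_effective_dose(per), unname(ref), tolerance = 1e-14)
  }
  expect_error(torso_effective_dose(per[setdiff(names(per), "spleen")]),
               "spleen")
})

test_that("equivalent dose applies the unit conversion and linearity", {
  sc <- chamber_scene()
  st <- source_term(sc)
  expect_equal(sum(st$fractions), 1)
  expect_equal(unname(st$fractions["air"]), 0.9)
  # zero activity
  st0 <- source_term(sc, total_activity = 0)
  expect_equal(unname(equivalent_dose(c(liver = 1), 1, 1, st0,
                                      c(liver = 1))), 0)
  # 1 MeV per photon, yield 1, fraction 1, 1 Bq s, 1 g
  expect_equal(unname(equivalent_dose(c(liver = 1), 1, 1, st,
                                      c(liver = 1))),
               1.602176634e-10, tolerance = 1e-15)
  # two lines equal one run with summed yield-weighted deposits
  d1 <- c(liver = 0.3); d2 <- c(liver = 0.8)
  h12 <- equivalent_dose(d1, 0.4, 0.9, st, c(liver = 1800)) +
    equivalent_dose(d2, 0.1, 0.9, st, c(liver = 1800))
  hsum <- equivalent_dose(d1 * 0.4 + d2 * 0.1, 1, 0.9, st, c(liver = 1800))
  expect_equal(h12, hsum, tolerance = 1e-14)
  expect_error(equivalent_dose(c(nose = 1), 1, 1, st, c(liver = 1)), "nose")
})

test_that("dose decrease reports signed percentages", {
  expect_equal(dose_decrease(1, 1)$percent, 0)
  expect_equal(dose_decrease(0.5, 1)$percent, -50)
  expect_error(dose_decrease(1, 0), "> 0")
})

test_that("doses scale linearly with activity, decreases do not", {
  sc <- chamber_scene(garments = list("opch90"))
  cfg <- fast_cfg(5e3, seed = 41, mode = "track-length")
  d1 <- organ_doses("Tc99m", sc, cfg, source_term(sc, total_activity = 1))
  d2 <- organ_doses("Tc99m", sc, cfg, source_term(sc, total_activity = 2))
  expect_equal(d2$per_organ, 2 * d1$per_organ, tolerance = 1e-12)
  expect_equal(d2$effective, 2 * d1$effective, tolerance = 1e-12)
})

test_that("a zero-areal-density garment is equivalent to the reference", {
  void <- material("void garment", c(C = 1), areal_density = 0)
  attr(void, "coverage") <- "whole_body"
  cfg <- fast_cfg(4e4, seed = 43, mode = "track-length")
  rep <- dose_report("Tc99m", list(void), list(), cfg)
  expect_lt(abs(rep$decreases[["torso_organs"]]),
            3 * rep$se[["torso_organs"]])
})

test_that("dose decrease magnitude follows the emission energy ordering", {
  cfg <- fast_cfg(4e4, seed = 47, mode = "track-length")
  dec <- se <- c(Tc99m = 0, Cs137 = 0, Na24 = 0)
  for (nm in names(dec)) {
    rep <- dose_report(nm, c("opch90", "df_vest_w2"), c("opch90"), cfg)
    dec[nm] <- rep$decreases[["torso_organs"]]
    se[nm] <- rep$se[["torso_organs"]]
  }
  expect_gt(abs(dec["Tc99m"]) + 3 * sqrt(se["Tc99m"]^2 + se["Cs137"]^2),
            abs(dec["Cs137"]))
  expect_gt(abs(dec["Cs137"]) + 3 * sqrt(se["Cs137"]^2 + se["Na24"]^2),
            abs(dec["Na24"]))
  # and the strict ordering of the point estimates
  expect_true(abs(dec["Tc99m"]) > abs(dec["Na24"]))
})

test_that("beta pathway reaches the skin but barely the testes", {
  sc_bare <- chamber_scene()
  nuc <- nuclide_fixture("I131")
  b <- ppeshield:::.beta_doses(nuc, sc_bare, source_term(sc_bare))
  expect_gt(b[["skin"]], 0)
  expect_lt(b[["testes"]], 0.05 * b[["skin"]])
  # a full-body suit attenuates the skin beta dose strongly
  sc_suit <- chamber_scene(garments = list("demron_suit"))
  bs <- ppeshield:::.beta_doses(nuc, sc_suit, source_term(sc_suit))
  expect_lt(bs[["skin"]], 0.05 * b[["skin"]])
})
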
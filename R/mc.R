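#' Monte Carlo transport configuration
#'
#' @param n_histories Number of photon histories (>= 1).
#' @param seed Integer RNG seed; identical (scene, config, seed) runs give
#'   bit-identical tallies.
#' @param photon_cutoff Low-energy photon cutoff (keV, >= 10); photons below
#'   it deposit their energy locally.
#' @param n_batches Number of statistical batches (>= 10) for the standard
#'   error estimate.
#' @param variance_mode `"analog"` collision tallies, or `"track-length"`
#'   expected-value deposition tallies for the phantom organs (lower
#'   variance for small organs; the energy-conservation audit applies to
#'   analog mode).
#' @return Object of class `transport_config`.
#' @export
transport_config <- function(n_histories = 2e6, seed = 1L, photon_cutoff = 10,
                             n_batches = 20L,
                             variance_mode = c("analog", "track-length")) {
  if (photon_cutoff < 10) stop("photon_cutoff must be >= 10 keV", call. = FALSE)
  if (n_histories < 1) stop("n_histories must be >= 1", call. = FALSE)
  if (n_batches < 10) stop("need at least 10 batches", call. = FALSE)
  structure(list(n_histories = n_histories, seed = as.integer(seed),
                 photon_cutoff = photon_cutoff, n_batches = as.integer(n_batches),
                 variance_mode = match.arg(variance_mode)),
            class = "transport_config")
}

#' Monte Carlo tally result
#' @param estimate Tally estimate.
#' @param rel_se Relative standard error from batch statistics.
#' @param n_histories Histories used.
#' @export
tally_result <- function(estimate, rel_se, n_histories) {
  structure(list(estimate = estimate, rel_se = rel_se,
                 n_histories = n_histories), class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat(sprintf("<tally_result> %.6g (rel. SE %.3g%%) from %.3g histories\n",
              x$estimate, 100 * x$rel_se, x$n_histories))
  invisible(x)
}

#' Narrow-beam slab scene
#'
#' Pencil beam of monoenergetic photons at normal incidence on a stack of
#' material layers, as in the bench penetration simulations.
#'
#' @param layers A [material()] or list of materials, each with
#'   `areal_density` set.
#' @param energy Photon energy (keV).
#' @export
slab_scene <- function(layers, energy) {
  if (inherits(layers, "material")) layers <- list(layers)
  if (!length(layers)) stop("at least one layer required", call. = FALSE)
  for (l in layers) {
    stopifnot(inherits(l, "material"))
    if (is.na(l$areal_density) || l$areal_density < 0) {
      stop("every layer needs a non-negative areal_density", call. = FALSE)
    }
  }
  structure(list(layers = layers, energy = energy), class = "slab_scene")
}

#' Uncollided-photon narrow-beam tally
#'
#' Analog Monte Carlo estimate of the fraction of source photons that cross
#' the layer stack without any interaction (the surface-crossing tally
#' restricted to uncollided photons).  Because the tally counts only
#' non-interacting histories, analog transport reduces exactly to Bernoulli
#' trials with survival probability `exp(-sum(mu_i d_i))`; histories are
#' simulated in batches and the relative standard error is taken from the
#' batch spread.
#'
#' @param scene A [slab_scene()].
#' @param config A [transport_config()].
#' @return A [tally_result()]; the estimate is the uncollided fraction.
#' @export
transport_narrow_beam <- function(scene, config) {
  stopifnot(inherits(scene, "slab_scene"), inherits(config, "transport_config"))
  if (scene$energy < config$photon_cutoff) {
    stop("source energy below photon cutoff", call. = FALSE)
  }
  tau <- sum(vapply(scene$layers, function(l)
    mass_attenuation(l, scene$energy, "total") * l$areal_density, 0))
  P <- exp(-tau)
  set.seed(config$seed)
  nb <- config$n_batches
  m <- floor(config$n_histories / nb)
  k <- rbinom(nb, m, P)
  est <- mean(k / m)
  rel <- if (tau == 0) 0 else sd(k / m) / sqrt(nb) / est
  tally_result(est, rel, m * nb)
}

#' Sample Compton scattering events
#'
#' Draws (scattered energy, polar angle) pairs from the free-electron
#' Klein-Nishina differential cross section; scattered energies follow the
#' Compton relation E' = E / (1 + (E / m_e c^2)(1 - cos theta)).
#'
#' @param energy Incident photon energy (keV), >= 10.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return data.frame with `energy_keV` and `theta_rad`.
#' @export
sample_compton <- function(energy, n, seed = 1L) {
  if (energy < 10) stop("energy below supported range", call. = FALSE)
  as.data.frame(cpp_sample_compton(energy, as.integer(n), as.double(seed)))
}

# fine-grid cross-section list consumed by the transport engine
.xs_list <- function(mat, with_fdep = FALSE, n = 220) {
  key <- paste0("xsl_", mat$name, "_",
                paste(sprintf("%s%.6f", names(mat$fractions), mat$fractions),
                      collapse = "_"), "_", with_fdep, "_", n)
  if (!is.null(.ppe[[key]])) return(.ppe[[key]])
  E <- exp(seq(log(10), log(3000), length.out = n))
  tot <- mass_attenuation(mat, E, "total")
  pe <- mass_attenuation(mat, E, "photoelectric")
  inc <- mass_attenuation(mat, E, "incoherent")
  coh <- mass_attenuation(mat, E, "coherent")
  out <- list(loge = log(E), logmu = log(tot),
              fpe = pe / tot, finc = (pe + inc) / tot,
              fcoh = (pe + inc + coh) / tot)
  if (with_fdep) {
    pair <- pmax(tot - pe - inc - coh, 0)
    meps <- vapply(E, .kn_mean_eps, 0)
    out$fdep <- (pe * 1 + inc * (1 - meps) +
                   pair * pmax(E - 1021.998, 0) / E) / tot
  }
  .ppe[[key]] <- out
  out
}

# mean E'/E of a Klein-Nishina scatter at energy E (numeric integral)
.kn_mean_eps <- function(E) {
  a <- E / 510.99895
  f <- function(mu) {
    eps <- 1 / (1 + a * (1 - mu))
    eps^2 * (eps + 1 / eps - (1 - mu^2))
  }
  g <- function(mu) f(mu) / (1 + a * (1 - mu))  # f * eps
  integrate(g, -1, 1, rel.tol = 1e-8)$value /
    integrate(f, -1, 1, rel.tol = 1e-8)$value
}

#' Single-scatter concrete albedo model
#'
#' Precomputes, on a log energy grid, the probability that a photon
#' entering a thick concrete wall returns to the chamber after exactly one
#' incoherent scatter (normal-incidence approximation), together with the
#' discretised distribution of exit angle cosines and the corresponding
#' Compton-shifted exit energies.
#'
#' @param n_energy,n_bins Grid resolutions.
#' @return List consumed by the transport engine.
#' @export
concrete_albedo <- function(n_energy = 30, n_bins = 20) {
  key <- paste0("albedo_", n_energy, "_", n_bins)
  if (!is.null(.ppe[[key]])) return(.ppe[[key]])
  concrete <- material("concrete",
                       c(H = 0.010, C = 0.001, O = 0.529, Na = 0.029,
                         Si = 0.361, Ca = 0.050, Fe = 0.020))
  E <- exp(seq(log(10), log(3000), length.out = n_energy))
  mus <- seq(-1 + 1 / n_bins, 0 - 1 / n_bins, length.out = n_bins) # scatter cos
  prob <- numeric(n_energy)
  cum <- matrix(0, n_energy, n_bins)
  eprime <- matrix(0, n_energy, n_bins)
  for (i in seq_along(E)) {
    a <- E[i] / 510.99895
    epsb <- 1 / (1 + a * (1 - mus))
    Eb <- E[i] * epsb
    kn <- epsb^2 * (epsb + 1 / epsb - (1 - mus^2))
    # normalisation over the full sphere
    f <- function(mu) {
      eps <- 1 / (1 + a * (1 - mu))
      eps^2 * (eps + 1 / eps - (1 - mu^2))
    }
    Z <- integrate(f, -1, 1)$value
    p <- kn / Z * (1 / n_bins)
    mu_in <- mass_attenuation(concrete, E[i], "total")
    mu_inc <- mass_attenuation(concrete, E[i], "incoherent")
    mu_out <- mass_attenuation(concrete, pmax(Eb, 10), "total")
    w <- mu_inc * p / (mu_in + mu_out / abs(mus))
    prob[i] <- sum(w)
    cum[i, ] <- cumsum(w) / sum(w)
    eprime[i, ] <- Eb
  }
  out <- list(loge = log(E), prob = prob, mue = -mus,
              cum = as.numeric(t(cum)), eprime = as.numeric(t(eprime)))
  .ppe[[key]] <- out
  out
}

#' Chamber exposure scene
#'
#' The 250 x 200 x 200 cm gas-tight aerosol test chamber with the stylized
#' phantom standing at its centre, optionally wearing garment layers.
#'
#' @param garments List of garment [material()]s (or fixture names, see
#'   [ppe_fixture()]) ordered outermost first; each must carry an
#'   `areal_density` and a coverage attribute (`"whole_body"`, `"torso"`,
#'   `"head"` or `"legs"`).  Local garments are worn under a covering
#'   contamination suit, so the suit comes first.
#' @param phantom A [stylized_phantom()].
#' @param box Chamber dimensions (cm).
#' @export
chamber_scene <- function(garments = list(), phantom = stylized_phantom(),
                          box = c(250, 200, 200)) {
  garments <- lapply(garments, function(g) {
    if (is.character(g)) g <- ppe_fixture(g)
    stopifnot(inherits(g, "material"))
    if (is.na(g$areal_density)) {
      stop("garment '", g$name, "' has no areal_density", call. = FALSE)
    }
    if (is.null(attr(g, "coverage"))) {
      stop("garment '", g$name, "' has no coverage attribute", call. = FALSE)
    }
    g
  })
  structure(list(garments = garments, phantom = phantom, box = box),
            class = "chamber_scene")
}

.coverage_code <- function(coverage) {
  switch(coverage, whole_body = 0L, torso = 1L, head = 2L, legs = 3L,
         stop("unknown coverage region '", coverage, "'", call. = FALSE))
}

#' Chamber photon transport with per-organ energy deposition
#'
#' Transports monoenergetic photons from one of the three chamber sources -
#' dispersion in the air volume, deposition on the chamber walls, or
#' deposition on the outer garment surface - and tallies the energy
#' deposited in every phantom region (kerma approximation: secondary
#' electrons deposit locally).  Walls return photons through a single
#' backscatter sampled from the precomputed concrete albedo.
#'
#' @param scene A [chamber_scene()].
#' @param energy Photon energy (keV), above the cutoff.
#' @param source `"air"`, `"wall"` or `"ppe"`.
#' @param config A [transport_config()].
#' @param include_phantom Set `FALSE` to remove the phantom (diagnostics).
#' @param air_density_scale Scale factor on air density (diagnostics).
#' @param diag_radii Radii (cm) of diagnostic spheres centred in the
#'   chamber whose crossing counts are returned (fluence checks).
#' @param point_source Collapse the source to the chamber centre
#'   (diagnostics).
#' @param wall_albedo Set `FALSE` to make the walls perfectly absorbing
#'   (diagnostics).
#' @return Object of class `chamber_tallies`: list of [tally_result()] per
#'   region (MeV deposited per source photon), plus `deposits` (region x
#'   batch matrix, keV), `audit` (energy bookkeeping per batch),
#'   `diag_counts`, `masses`, `energy`, `source`.
#' @export
transport_chamber <- function(scene, energy, source = c("air", "wall", "ppe"),
                              config = transport_config(),
                              include_phantom = TRUE, air_density_scale = 1,
                              diag_radii = numeric(), point_source = FALSE,
                              wall_albedo = TRUE) {
  stopifnot(inherits(scene, "chamber_scene"),
            inherits(config, "transport_config"))
  source <- match.arg(source)
  # a source below the cutoff terminates immediately: the engine deposits
  # each photon at its birth place and no organ receives anything
  ph <- scene$phantom
  air <- material("air", c(N = 0.755, O = 0.232, Ar = 0.013))
  tissue <- material("soft tissue",
                     c(H = 0.101, C = 0.111, N = 0.026, O = 0.762))
  gl <- lapply(scene$garments, function(g)
    list(region = .coverage_code(attr(g, "coverage")),
         d = g$areal_density, xs = .xs_list(g)))
  src_code <- c(air = 0L, wall = 1L, ppe = 2L)[[source]]
  alb <- concrete_albedo()
  if (!wall_albedo) alb$prob[] <- 0
  res <- cpp_transport_chamber(
    energy, config$n_histories, config$n_batches, as.double(config$seed),
    src_code, .xs_list(air), .xs_list(tissue, with_fdep = TRUE),
    1.205e-3 * air_density_scale, ph$rho_tissue,
    list(parts = ph$parts, organs = ph$organs,
         skin_thickness = ph$skin_thickness,
         n_organ_regions = ph$n_organ_regions),
    gl, alb, as.numeric(scene$box), config$photon_cutoff,
    include_phantom, config$variance_mode == "track-length",
    as.numeric(diag_radii), point_source)

  dep <- res$deposits
  rownames(dep) <- ph$region_names
  m <- res$histories / config$n_batches
  per_hist <- dep / m / 1000          # MeV per source photon, per batch
  tallies <- lapply(seq_len(nrow(dep)), function(i) {
    x <- per_hist[i, ]
    est <- mean(x)
    rel <- if (est > 0) sd(x) / sqrt(length(x)) / est else 0
    tally_result(est, rel, res$histories)
  })
  names(tallies) <- ph$region_names
  audit <- data.frame(emitted_keV = res$emitted_keV,
                      deposited_keV = colSums(dep))
  structure(list(tallies = tallies, deposits = dep, audit = audit,
                 diag_counts = res$diag_counts, masses = ph$masses,
                 energy = energy, source = source,
                 n_histories = res$histories),
            class = "chamber_tallies")
}

#' @export
print.chamber_tallies <- function(x, ...) {
  cat(sprintf("<chamber_tallies> %.5g keV, %s source, %.3g histories\n",
              x$energy, x$source, x$n_histories))
  org <- vapply(x$tallies, function(t) t$estimate, 0)
  top <- sort(org, decreasing = TRUE)[1:5]
  for (nm in names(top)) {
    cat(sprintf("  %-16s %.4g MeV/photon (rel. SE %.2g%%)\n", nm,
                x$tallies[[nm]]$estimate, 100 * x$tallies[[nm]]$rel_se))
  }
  invisible(x)
}

#' Empirical beta transmission through a layer
#'
#' Transmission fraction exp(-mu_beta d) with the empirical mass absorption
#' coefficient mu_beta = 17 (E_max / MeV)^-1.14 cm^2/g, applicable above a
#' 50 keV endpoint energy.
#'
#' @param e_max Beta spectrum endpoint energy (keV), > 50.
#' @param areal_density Layer areal density (g/cm^2), >= 0.
#' @return Transmitted fraction in (0, 1].
#' @export
beta_transmission <- function(e_max, areal_density) {
  if (any(e_max <= 50)) {
    stop("beta endpoint energy must exceed 50 keV", call. = FALSE)
  }
  if (any(areal_density < 0)) {
    stop("areal_density must be >= 0", call. = FALSE)
  }
  exp(-17 * (e_max / 1000)^-1.14 * areal_density)
}
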
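.fixture_path <- function(...) system.file("extdata", ..., package = "ppeshield")

#' Bundled radionuclide emission data
#'
#' Principal gamma lines (yield >= 1 percent) and beta branches for the nine
#' catalogued nuclides: the five bench sources (Am-241, Ba-133, Eu-152,
#' Cs-137 including the Ba-137m line, Co-60) and the five dispersed-aerosol
#' nuclides (Tc-99m, I-131, Cs-137, La-140, Na-24).  Values are nominal
#' principal-emission data transcribed once into package data.
#'
#' @param name Nuclide name, e.g. `"I131"`, `"Cs137"`, `"Co60"`.
#' @return Object of class `nuclide`: list with `name`, `gamma_lines`
#'   (data.frame energy_keV, yield) and `beta_branches` (data.frame
#'   e_max_keV, e_mean_keV, yield).
#' @export
nuclide_fixture <- function(name) {
  if (is.null(.ppe$gamma_lines)) {
    .ppe$gamma_lines <- read.csv(.fixture_path("nuclides", "gamma_lines.csv"),
                                 stringsAsFactors = FALSE)
    .ppe$beta_branches <- read.csv(.fixture_path("nuclides", "beta_branches.csv"),
                                   stringsAsFactors = FALSE)
  }
  g <- .ppe$gamma_lines[.ppe$gamma_lines$nuclide == name,
                        c("energy_keV", "yield")]
  b <- .ppe$beta_branches[.ppe$beta_branches$nuclide == name,
                          c("e_max_keV", "e_mean_keV", "yield")]
  if (!nrow(g)) {
    stop("unknown nuclide fixture '", name, "'; available: ",
         paste(unique(.ppe$gamma_lines$nuclide), collapse = ", "),
         call. = FALSE)
  }
  g <- g[order(g$energy_keV), ]
  rownames(g) <- rownames(b) <- NULL
  structure(list(name = name, gamma_lines = g, beta_branches = b),
            class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat("<nuclide>", x$name, "-", nrow(x$gamma_lines), "gamma line(s),",
      nrow(x$beta_branches), "beta branch(es)\n")
  invisible(x)
}

.ppe_registry <- function() {
  if (is.null(.ppe$ppe_registry)) {
    .ppe$ppe_registry <- yaml::read_yaml(.fixture_path("materials", "ppe.yaml"))
  }
  .ppe$ppe_registry
}

#' PPE material fixtures
#'
#' Returns the shielding-layer [material()] of a catalogued garment with its
#' experimentally determined areal density.  Compositions of proprietary
#' layers are assumed stand-ins (flagged in the fixture file); the body
#' region the garment covers is attached as attribute `"coverage"` and the
#' assumption flag as attribute `"assumed"`.
#'
#' @param name Fixture key, one of [ppe_names()].
#' @return A [material()] with `areal_density` set.
#' @export
ppe_fixture <- function(name) {
  reg <- .ppe_registry()
  if (!name %in% names(reg)) {
    stop("unknown PPE fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  e <- reg[[name]]
  m <- material(e$label, unlist(e$fractions), density = e$density,
                areal_density = e$areal_density)
  attr(m, "coverage") <- e$coverage
  attr(m, "assumed") <- isTRUE(e$assumed)
  m
}

#' @rdname ppe_fixture
#' @export
ppe_names <- function() names(.ppe_registry())

#' Read a material definition from a structured config file
#'
#' The YAML schema matches the bundled PPE fixture file: `label`,
#' `fractions` (element: weight fraction), optional `density` and
#' `areal_density`.
#'
#' @param path Path to a YAML file describing one material.
#' @return A [material()].
#' @export
read_material_config <- function(path) {
  e <- yaml::read_yaml(path)
  material(if (is.null(e$label)) basename(path) else e$label,
           unlist(e$fractions),
           density = e$density,
           areal_density = if (is.null(e$areal_density)) NA_real_
                           else e$areal_density)
}

#' Detector response models
#'
#' Parametric models of the two handheld spectrometer classes used for
#' narrow-beam bench measurements: a scintillator (`"labr"`, ~3 percent FWHM
#' at 662 keV) and a high-resolution semiconductor (`"hpge"`, ~0.2 percent).
#' FWHM(E) = a sqrt(E) + b; the full-energy-peak efficiency is a smooth
#' log-normal curve in energy; `geometry` is the calibrated solid-angle and
#' collimator-transmission constant; `continuum` is the fraction of detected
#' line events routed to a flat continuum below the peak.
#'
#' @param name `"labr"` or `"hpge"`.
#' @return Object of class `detector_model` with functions `fwhm(E)` and
#'   `efficiency(E)` plus the scalar parameters.
#' @export
detector_model <- function(name = c("hpge", "labr")) {
  name <- match.arg(name)
  if (is.null(.ppe$detectors)) {
    .ppe$detectors <- yaml::read_yaml(.fixture_path("detectors.yaml"))
  }
  p <- .ppe$detectors[[name]]
  fwhm <- function(energy) p$fwhm_a * sqrt(energy) + p$fwhm_b
  efficiency <- function(energy) {
    p$eps_max * exp(-0.5 * (log(energy / p$e_peak_keV) / p$eps_width)^2)
  }
  structure(c(p, list(name = name, fwhm = fwhm, efficiency = efficiency)),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat("<detector_model>", x$label, "\n")
  cat(sprintf("  FWHM at 662 keV: %.2f keV; efficiency at 662 keV: %.3f\n",
              x$fwhm(662), x$efficiency(662)))
  invisible(x)
}
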
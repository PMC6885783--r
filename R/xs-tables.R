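#' @useDynLib ppeshield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rbinom rnorm rpois runif sd setNames integrate
#' @importFrom utils read.csv write.csv
NULL

.ppe <- new.env(parent = emptyenv())

.xs_dir <- function() system.file("extdata", "xs", package = "ppeshield")

#' Symbols of the bundled elements
#'
#' @return Character vector of element symbols for which photon interaction
#'   tables are shipped with the package.
#' @export
element_symbols <- function() {
  idx <- .element_index()
  idx$symbol
}

.element_index <- function() {
  if (is.null(.ppe$element_index)) {
    .ppe$element_index <- read.csv(file.path(.xs_dir(), "elements.csv"),
                                   stringsAsFactors = FALSE)
  }
  .ppe$element_index
}

#' Bundled photon interaction table for one element
#'
#' Loads the packaged cross-section table: photon energy grid (10--3000 keV)
#' with per-grid-point mass interaction coefficients (cm^2/g) for the
#' photoelectric effect, incoherent (Compton) scattering, coherent (Rayleigh)
#' scattering and pair production.  Absorption edges inside the grid are
#' represented as duplicated grid points carrying the below-edge and
#' above-edge values.
#'
#' @param symbol Element symbol, e.g. `"Pb"`.
#' @return An object of class `element_table`: a list with `symbol`, `Z`, `A`
#'   (g/mol), `k_edge` and `l3_edge` energies (keV), the energy `grid` (keV),
#'   and matrix `partials` with columns `photoelectric`, `incoherent`,
#'   `coherent`, `pair` plus the derived `total`.
#' @export
element_table <- function(symbol) {
  key <- paste0("el_", symbol)
  if (!is.null(.ppe[[key]])) return(.ppe[[key]])
  idx <- .element_index()
  row <- idx[idx$symbol == symbol, ]
  if (nrow(row) != 1L) {
    stop("no bundled cross-section table for element '", symbol, "'",
         call. = FALSE)
  }
  fn <- file.path(.xs_dir(), paste0(symbol, ".csv"))
  d <- read.csv(fn, comment.char = "#", stringsAsFactors = FALSE)
  partials <- cbind(photoelectric = d$photoelectric,
                    incoherent = d$incoherent,
                    coherent = d$coherent,
                    pair = d$pair)
  obj <- structure(list(symbol = symbol, Z = row$Z, A = row$A,
                        k_edge = row$k_edge,
                        l3_edge = if (is.na(row$l3_edge)) NA_real_ else row$l3_edge,
                        grid = d$energy_keV,
                        partials = cbind(partials, total = rowSums(partials))),
                   class = "element_table")
  .ppe[[key]] <- obj
  obj
}

# log-log interpolation on a grid that may contain duplicated edge abscissae;
# at an exact duplicate the above-edge (second) row is returned.
.interp_loglog <- function(grid, values, energy) {
  n <- length(grid)
  out <- numeric(length(energy))
  idx <- findInterval(energy, grid)   # rightmost interval start <= energy
  for (k in seq_along(energy)) {
    i <- idx[k]
    e <- energy[k]
    if (i < 1L || e > grid[n]) stop("energy out of table range", call. = FALSE)
    if (i >= n || grid[i] == e) { out[k] <- values[i]; next }
    x0 <- grid[i]; x1 <- grid[i + 1L]
    y0 <- values[i]; y1 <- values[i + 1L]
    if (x1 == x0) { out[k] <- y1; next }
    if (y0 > 0 && y1 > 0) {
      w <- (log(e) - log(x0)) / (log(x1) - log(x0))
      out[k] <- exp((1 - w) * log(y0) + w * log(y1))
    } else {
      w <- (e - x0) / (x1 - x0)
      out[k] <- (1 - w) * y0 + w * y1
    }
  }
  out
}

.element_mu <- function(symbol, energy, which = "total") {
  et <- element_table(symbol)
  cols <- colnames(et$partials)
  if (!which %in% cols) {
    stop("unknown partial '", which, "'; use one of ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  .interp_loglog(et$grid, et$partials[, which], energy)
}

#' Define a material from elemental weight fractions
#'
#' @param name Label for the material.
#' @param fractions Named numeric vector of elemental weight fractions
#'   (must be non-negative and sum to 1 within 1e-6).
#' @param density Optional bulk density (g/cm^3).
#' @param areal_density Areal (density) thickness d (g/cm^2); the mass per
#'   unit area of the layer.
#' @return An object of class `material`.
#' @export
material <- function(name, fractions, density = NULL, areal_density = NA_real_) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("'fractions' must be a named vector of weight fractions", call. = FALSE)
  }
  if (any(fractions < 0)) stop("weight fractions must be >= 0", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("weight fractions must sum to 1 (got ", sum(fractions), ")",
         call. = FALSE)
  }
  unknown <- setdiff(names(fractions), element_symbols())
  if (length(unknown)) {
    stop("no bundled cross-section table for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(density) && !is.na(density) && density <= 0) {
    stop("density must be > 0", call. = FALSE)
  }
  if (!is.na(areal_density) && areal_density < 0) {
    stop("areal_density must be >= 0", call. = FALSE)
  }
  structure(list(name = name, fractions = fractions,
                 density = if (is.null(density)) NA_real_ else density,
                 areal_density = areal_density),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, "\n")
  cat("  fractions:",
      paste(sprintf("%s %.4f", names(x$fractions), x$fractions), collapse = ", "),
      "\n")
  if (!is.na(x$density)) cat("  density:", x$density, "g/cm^3\n")
  if (!is.na(x$areal_density)) {
    cat("  areal density:", x$areal_density, "g/cm^2\n")
  }
  invisible(x)
}

#' Mass attenuation coefficient of a material (mixture rule)
#'
#' Computes the weight-fraction-weighted sum of elemental mass interaction
#' coefficients, log-log interpolated on the bundled grids.  At an absorption
#' edge energy the above-edge value is returned.  The `"total"` coefficient
#' includes coherent scattering (attenuation-with-coherent), matching
#' narrow-beam removal of any interacting photon.
#'
#' @param mat A [material()].
#' @param energy Photon energy (keV), 10--3000; vectorised.
#' @param which One of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`, `"pair"`.
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
mass_attenuation <- function(mat, energy, which = "total") {
  stopifnot(inherits(mat, "material"))
  if (any(energy < 10 | energy > 3000)) {
    stop("energy must lie in the supported range 10--3000 keV", call. = FALSE)
  }
  out <- numeric(length(energy))
  for (sym in names(mat$fractions)) {
    w <- mat$fractions[[sym]]
    if (w > 0) out <- out + w * .element_mu(sym, energy, which)
  }
  out
}

#' Analytic narrow-beam penetration (Beer-Lambert)
#'
#' Relative penetration P = exp(-(mu/rho)_total(E) * d) of an uncollided
#' pencil beam through a layer of the material's areal density.
#'
#' @param mat A [material()] with `areal_density` set.
#' @param energy Photon energy (keV); vectorised.
#' @return Relative penetration in (0, 1].
#' @export
analytic_penetration <- function(mat, energy) {
  stopifnot(inherits(mat, "material"))
  if (is.na(mat$areal_density)) {
    stop("material '", mat$name, "' has no areal_density set", call. = FALSE)
  }
  exp(-mass_attenuation(mat, energy, "total") * mat$areal_density)
}

#' Reference lead data for lead-equivalent conversion
#'
#' @return A list with the conventional lead density `density` (11.35 g/cm^3)
#'   and the bundled lead `table`.
#' @export
lead_reference <- function() {
  list(density = 11.35, table = element_table("Pb"))
}

#' Lead equivalent of a penetration value
#'
#' Thickness of the pure-lead sheet with the same narrow-beam transmission:
#' t_Pb = -ln(P) / ((mu/rho)_Pb(E) * rho_Pb), reported in mm.
#'
#' @param P Relative penetration, in (0, 1]; vectorised (recycled against
#'   `energy`).
#' @param energy Photon energy (keV).
#' @return Lead-equivalent thickness in mm.
#' @export
analytic_lead_equivalent <- function(P, energy) {
  if (any(P <= 0 | P > 1)) {
    stop("penetration must lie in (0, 1]", call. = FALSE)
  }
  ref <- lead_reference()
  mu <- .interp_loglog(ref$table$grid, ref$table$partials[, "total"], energy)
  -log(P) / (mu * ref$density) * 10
}
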
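#' Relative penetration from paired peak areas
#'
#' P = (net_sample / t_sample) / (net_open / t_open); A = 1 - P.  The
#' standard uncertainty of P combines the relative area uncertainties of the
#' two peaks in quadrature.
#'
#' @param open,sample [net_peak_area()] results at the same catalogued
#'   energy.
#' @param live_open,live_sample Live times (s) of the two acquisitions.
#' @return Object of class `attenuation_point`: list with `energy`,
#'   `penetration`, `attenuation`, `u_penetration` and logical `valid`
#'   (FALSE when the sample peak is not significant or P exceeds 1 beyond
#'   3 standard uncertainties).
#' @export
relative_penetration <- function(open, sample, live_open, live_sample) {
  stopifnot(inherits(open, "peak_result"), inherits(sample, "peak_result"))
  if (abs(open$energy - sample$energy) > 1e-6) {
    stop("open and sample peaks are at different energies", call. = FALSE)
  }
  if (live_open <= 0 || live_sample <= 0) {
    stop("live times must be > 0", call. = FALSE)
  }
  if (open$net_area <= 0) {
    stop("open-beam rate is zero at ", open$energy, " keV", call. = FALSE)
  }
  P <- (sample$net_area / live_sample) / (open$net_area / live_open)
  rel_o <- open$u_net / open$net_area
  rel_s <- if (sample$net_area > 0) sample$u_net / sample$net_area else Inf
  u <- if (is.finite(rel_s)) abs(P) * sqrt(rel_o^2 + rel_s^2) else
    (sample$u_net / live_sample) / (open$net_area / live_open)
  valid <- sample$significant && P > 0 && P <= 1 + 3 * u
  structure(list(energy = open$energy, penetration = P, attenuation = 1 - P,
                 u_penetration = u, valid = valid),
            class = "attenuation_point")
}

#' @export
print.attenuation_point <- function(x, ...) {
  cat(sprintf("<attenuation_point> %.2f keV: P = %.4f +/- %.4f (A = %.4f)%s\n",
              x$energy, x$penetration, x$u_penetration, x$attenuation,
              if (x$valid) "" else " [invalid]"))
  invisible(x)
}

# clip noise-driven P slightly above 1 (within 3 sigma) for log-domain use
.clip_penetration <- function(point) {
  P <- point$penetration
  if (P <= 0 || P > 1 + 3 * point$u_penetration) {
    stop("penetration ", signif(P, 4), " at ", point$energy,
         " keV is not a valid measurement", call. = FALSE)
  }
  if (P > 1) {
    warning("penetration ", signif(P, 4), " at ", point$energy,
            " keV clipped to 1 (within statistical noise)", call. = FALSE)
    P <- 1
  }
  P
}

#' Measured mass attenuation coefficient
#'
#' Inverts the Beer-Lambert law for a measured penetration:
#' mu/rho = -ln(P) / d, with propagated uncertainty u_P / (P d).
#'
#' @param point An [relative_penetration()] result.
#' @param areal_density Density thickness d of the sample (g/cm^2), > 0.
#' @return List with `mu_rho` (cm^2/g), `u_mu_rho` and `energy`.
#' @export
mass_attenuation_measured <- function(point, areal_density) {
  stopifnot(inherits(point, "attenuation_point"))
  if (areal_density <= 0) stop("areal_density must be > 0", call. = FALSE)
  P <- .clip_penetration(point)
  list(energy = point$energy,
       mu_rho = -log(P) / areal_density,
       u_mu_rho = point$u_penetration / (max(P, .Machine$double.eps) *
                                           areal_density))
}

#' Lead equivalent of one attenuation point
#'
#' @param point An [relative_penetration()] result.
#' @return List with `energy`, `t_pb_mm` and `u_t_pb_mm`.
#' @export
lead_equivalent_at <- function(point) {
  stopifnot(inherits(point, "attenuation_point"))
  P <- .clip_penetration(point)
  t <- analytic_lead_equivalent(P, point$energy)
  ref <- lead_reference()
  mu <- .interp_loglog(ref$table$grid, ref$table$partials[, "total"],
                       point$energy)
  u <- point$u_penetration / (max(P, .Machine$double.eps) * mu * ref$density) * 10
  list(energy = point$energy, t_pb_mm = t, u_t_pb_mm = u)
}

#' Mean lead equivalent over the significant-peak set
#'
#' Averages per-energy lead equivalents, excluding invalid points and points
#' whose energy lies within the edge-exclusion window (2 FWHM at the edge
#' energy) of any K absorption edge of the sample material's elements or of
#' lead.  The reported spread is the unweighted standard deviation across
#' the retained energies.
#'
#' @param points List of [relative_penetration()] results.
#' @param mat The sample [material()] (for its elements' K-edges).
#' @param detector A [detector_model()] supplying the FWHM scale of the
#'   edge-exclusion window.
#' @return Object of class `lead_equivalent_result`: `per_energy` data.frame
#'   (energy_keV, t_pb_mm, u_t_pb_mm, excluded, reason), `mean`, `sd`,
#'   `excluded_energies`.
#' @export
mean_lead_equivalent <- function(points, mat, detector = detector_model("hpge")) {
  stopifnot(inherits(mat, "material"))
  edges <- vapply(names(mat$fractions),
                  function(s) element_table(s)$k_edge, 0)
  edges <- unique(c(edges, element_table("Pb")$k_edge))
  edges <- edges[edges >= 10 & edges <= 3000]
  rows <- lapply(points, function(pt) {
    reason <- NA_character_
    t <- u <- NA_real_
    if (!pt$valid) {
      reason <- "not a significant/valid measurement"
    } else {
      near <- edges[abs(pt$energy - edges) < 2 * detector$fwhm(edges)]
      if (length(near)) {
        reason <- paste0("within edge-exclusion window of ",
                         paste(round(near, 1), collapse = ", "), " keV")
      }
      le <- lead_equivalent_at(pt)
      t <- le$t_pb_mm; u <- le$u_t_pb_mm
    }
    data.frame(energy_keV = pt$energy, t_pb_mm = t, u_t_pb_mm = u,
               excluded = !is.na(reason),
               reason = reason, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per <- per[order(per$energy_keV), ]
  rownames(per) <- NULL
  kept <- per[!per$excluded, , drop = FALSE]
  if (!nrow(kept)) stop("all attenuation points were excluded", call. = FALSE)
  structure(list(per_energy = per,
                 mean = mean(kept$t_pb_mm),
                 sd = if (nrow(kept) > 1) sd(kept$t_pb_mm) else 0,
                 excluded_energies = per[per$excluded,
                                         c("energy_keV", "reason")]),
            class = "lead_equivalent_result")
}

#' @export
print.lead_equivalent_result <- function(x, ...) {
  cat(sprintf("<lead_equivalent_result> mean t_Pb = %.3f +/- %.3f mm over %d energies (%d excluded)\n",
              x$mean, x$sd, sum(!x$per_energy$excluded),
              sum(x$per_energy$excluded)))
  invisible(x)
}

#' Narrow-beam attenuation analysis of paired spectra
#'
#' The estimator at the core of the bench workflow: for each nuclide pair of
#' open-beam and sample spectra, integrates every significant full-energy
#' peak, forms relative penetration and attenuation, the measured mass
#' attenuation coefficient and the per-energy lead equivalent, and averages
#' the latter into the garment's mean lead equivalent.
#'
#' @param pairs List of `list(nuclide =, open =, sample =)` entries, where
#'   `open` and `sample` are [spectrum()] objects acquired without and with
#'   the sample in the beam.
#' @param mat Sample [material()] with `areal_density` set.
#' @param detector The [detector_model()] the spectra were acquired with.
#' @return Object of class `ppe_attenuation` with components `points`
#'   (data.frame energy_keV, P, u_P, A, mu_rho, u_mu_rho, t_pb_mm,
#'   u_t_pb_mm, excluded, reason), `leadeq` (the
#'   [mean_lead_equivalent()] result), `material`, `detector`.
#' @export
analyze_attenuation <- function(pairs, mat, detector = detector_model("hpge")) {
  stopifnot(inherits(mat, "material"))
  if (is.na(mat$areal_density) || mat$areal_density <= 0) {
    stop("material must carry a positive areal_density", call. = FALSE)
  }
  points <- list()
  for (pr in pairs) {
    nuc <- nuclide_fixture(pr$nuclide)
    lines <- significant_lines(nuc, detector, open = pr$open)
    for (i in seq_len(nrow(lines))) {
      E <- lines$energy_keV[i]; fw <- lines$fwhm_keV[i]
      po <- net_peak_area(pr$open, E, fw)
      ps <- tryCatch(net_peak_area(pr$sample, E, fw),
                     error = function(e) NULL)
      if (is.null(ps)) next
      points[[length(points) + 1L]] <-
        relative_penetration(po, ps, pr$open$live_time, pr$sample$live_time)
    }
  }
  if (!length(points)) stop("no significant peaks found", call. = FALSE)
  leadeq <- mean_lead_equivalent(points, mat, detector)
  tab <- do.call(rbind, lapply(points, function(pt) {
    mu <- if (pt$valid) mass_attenuation_measured(pt, mat$areal_density)
          else list(mu_rho = NA_real_, u_mu_rho = NA_real_)
    data.frame(energy_keV = pt$energy, P = pt$penetration,
               u_P = pt$u_penetration, A = pt$attenuation,
               mu_rho = mu$mu_rho, u_mu_rho = mu$u_mu_rho)
  }))
  tab <- merge(tab, leadeq$per_energy, by = "energy_keV", sort = TRUE)
  structure(list(points = tab, leadeq = leadeq, material = mat,
                 detector = detector$name),
            class = "ppe_attenuation")
}

#' @export
print.ppe_attenuation <- function(x, ...) {
  cat("<ppe_attenuation>", x$material$name,
      sprintf("(d = %.3f g/cm^2, %s detector)\n",
              x$material$areal_density, x$detector))
  cat(sprintf("  %d attenuation points, mean lead equivalent %.3f +/- %.3f mm\n",
              nrow(x$points), x$leadeq$mean, x$leadeq$sd))
  invisible(x)
}

#' @export
summary.ppe_attenuation <- function(object, ...) {
  cat("Narrow-beam attenuation analysis:", object$material$name, "\n")
  cat(sprintf("  areal density: %.3f g/cm^2\n", object$material$areal_density))
  print(object$points[, c("energy_keV", "P", "u_P", "mu_rho", "t_pb_mm",
                          "excluded")], digits = 4)
  cat(sprintf("Mean lead equivalent: %.3f +/- %.3f mm\n",
              object$leadeq$mean, object$leadeq$sd))
  invisible(object)
}

#' @export
coef.ppe_attenuation <- function(object, ...) {
  setNames(c(object$leadeq$mean, object$leadeq$sd),
           c("mean_t_pb_mm", "sd_t_pb_mm"))
}

#' Predicted analytic penetration of the fitted material
#'
#' @param object A [analyze_attenuation()] result.
#' @param energy Energies (keV) at which to evaluate the Beer-Lambert
#'   prediction from the bundled tables; defaults to the measured energies.
#' @param ... Unused.
#' @export
predict.ppe_attenuation <- function(object, energy = NULL, ...) {
  if (is.null(energy)) energy <- object$points$energy_keV
  analytic_penetration(object$material, energy)
}

#' @export
#' @importFrom graphics plot lines arrows legend
plot.ppe_attenuation <- function(x, ...) {
  pts <- x$points
  eg <- exp(seq(log(max(10.5, min(pts$energy_keV) * 0.8)),
                log(min(3000, max(pts$energy_keV) * 1.2)), length.out = 300))
  plot(pts$energy_keV, pts$P, log = "x", xlab = "energy [keV]",
       ylab = "relative penetration P",
       ylim = c(0, max(1, pts$P + pts$u_P)), pch = 19, ...)
  arrows(pts$energy_keV, pts$P - pts$u_P, pts$energy_keV, pts$P + pts$u_P,
         angle = 90, code = 3, length = 0.02)
  lines(eg, analytic_penetration(x$material, eg), col = 2)
  legend("bottomright", c("measured", "analytic"), pch = c(19, NA),
         lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Write attenuation results in the package CSV dialect
#'
#' One row per energy (energy_keV, P, u_P, A, mu_rho, t_pb_mm, u_t_pb_mm,
#' excluded) followed by a summary row carrying the mean lead equivalent.
#'
#' @param fit A [analyze_attenuation()] result.
#' @param path Output file.
#' @export
write_attenuation_csv <- function(fit, path) {
  tab <- fit$points[, c("energy_keV", "P", "u_P", "A", "mu_rho", "t_pb_mm",
                        "u_t_pb_mm", "excluded")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# material=", fit$material$name), con)
  write.csv(format(tab, digits = 8, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  writeLines(sprintf("# mean_t_pb_mm=%.6f,sd_t_pb_mm=%.6f",
                     fit$leadeq$mean, fit$leadeq$sd), con)
  invisible(path)
}
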
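#' Net full-energy-peak area with linear background subtraction
#'
#' Region-of-interest (ROI) peak integration: the ROI spans the catalogued
#' centroid +/- 1.5 FWHM; the background under the peak is a straight line
#' through the average counts of two flanking bands of width 1 FWHM placed
#' directly outside the ROI.  The net-area uncertainty combines the Poisson
#' variance of the gross ROI counts with the variance of the estimated
#' background.
#'
#' @param spec A [spectrum()].
#' @param energy Catalogued line energy (keV).
#' @param fwhm Detector FWHM at `energy` (keV).
#' @param other_lines Optional energies (keV) of other catalogued lines in
#'   the same spectrum; a line closer than 3 FWHM raises an overlap error.
#' @return Object of class `peak_result`: list with `energy`, `net_area`,
#'   `background`, `gross`, `u_net`, `rel_uncertainty` and logical
#'   `significant` (net area exceeding 3 of its uncertainties).
#' @export
net_peak_area <- function(spec, energy, fwhm, other_lines = NULL) {
  if (!is.null(other_lines)) {
    near <- abs(other_lines - energy) < 3 * fwhm & abs(other_lines - energy) > 1e-9
    if (any(near)) {
      stop("peak at ", energy, " keV overlaps catalogued line(s) at ",
           paste(round(other_lines[near], 2), collapse = ", "), " keV",
           call. = FALSE)
    }
  }
  n <- length(spec$counts)
  ch <- function(E) (E - spec$offset) / spec$gain + 1  # 1-based fractional
  half <- 1.5 * fwhm
  band <- 1.0 * fwhm
  lo <- round(ch(energy - half)); hi <- round(ch(energy + half))
  blo <- round(ch(energy - half - band)); bhi <- round(ch(energy + half + band))
  if (blo < 1 || bhi > n) {
    stop("peak region at ", energy, " keV truncated by spectrum bounds",
         call. = FALSE)
  }
  roi <- lo:hi
  left <- blo:(lo - 1)
  right <- (hi + 1):bhi
  mL <- mean(spec$counts[left]); mR <- mean(spec$counts[right])
  w <- (roi - mean(roi)) / (mean(right) - mean(left)) + 0.5
  bkg_ch <- mL * (1 - w) + mR * w
  B <- sum(bkg_ch)
  G <- sum(spec$counts[roi])
  S0 <- sum(1 - w); S1 <- sum(w)
  varB <- S0^2 * sum(spec$counts[left]) / length(left)^2 +
    S1^2 * sum(spec$counts[right]) / length(right)^2
  net <- G - B
  u <- sqrt(G + varB)
  structure(list(energy = energy, net_area = net, background = B, gross = G,
                 u_net = u,
                 rel_uncertainty = if (net > 0) u / net else Inf,
                 significant = net > 3 * u),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak_result> %.2f keV: net %.4g +/- %.3g (%.2f%%)%s\n",
              x$energy, x$net_area, x$u_net, 100 * x$rel_uncertainty,
              if (x$significant) "" else " [not significant]"))
  invisible(x)
}

#' Catalogued significant peaks of a nuclide for a detector
#'
#' Applies the acquisition criterion used on the bench: catalogued lines
#' with emission probability >= 1 percent, no other catalogued line within
#' 3 FWHM (ROI overlap), the full ROI plus flanking bands inside the
#' spectrum, and - when an open-beam spectrum is supplied - an open-beam
#' net-area relative uncertainty below 1 percent.
#'
#' @param nuc A [nuclide_fixture()] or nuclide name.
#' @param detector A [detector_model()].
#' @param open Optional open-beam [spectrum()] used to apply the relative
#'   uncertainty criterion.
#' @return data.frame with columns `energy_keV`, `yield`, `fwhm_keV`.
#' @export
significant_lines <- function(nuc, detector, open = NULL) {
  if (is.character(nuc)) nuc <- nuclide_fixture(nuc)
  lines <- nuc$gamma_lines
  strong <- lines[lines$yield >= 0.01, , drop = FALSE]
  keep <- logical(nrow(strong))
  fw <- detector$fwhm(strong$energy_keV)
  for (i in seq_len(nrow(strong))) {
    others <- lines$energy_keV[abs(lines$energy_keV - strong$energy_keV[i]) > 1e-9]
    keep[i] <- !any(abs(others - strong$energy_keV[i]) < 3 * fw[i]) &&
      strong$energy_keV[i] - 2.5 * fw[i] > 10
  }
  out <- data.frame(energy_keV = strong$energy_keV[keep],
                    yield = strong$yield[keep],
                    fwhm_keV = fw[keep])
  if (!is.null(open)) {
    ok <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      pk <- tryCatch(net_peak_area(open, out$energy_keV[i], out$fwhm_keV[i]),
                     error = function(e) NULL)
      ok[i] <- !is.null(pk) && is.finite(pk$rel_uncertainty) &&
        pk$rel_uncertainty < 0.01
    }
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
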
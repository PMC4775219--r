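#' Ras surface-density calibration
#'
#' Constants for converting bead fluorescence intensity to an apparent bulk
#' concentration and then to a surface density, together with the canonical
#' density bins. The 2-D conversion assumes molecules confined within a
#' length `h` of the surface: `f_2d = n_conv * h` = 602 * 0.055 = 33.11
#' molecules um^-2 per uM at the defaults.
#'
#' This is a crude estimate by construction; relative densities across beads
#' are what matter downstream.
#'
#' @param c_cal intensity calibration, uM per AU.
#' @param h confinement length, um.
#' @param n_conv molecules um^-3 per uM.
#' @param bins canonical density bin centers, molecules um^-2, strictly
#'   increasing.
#' @return An object of class `density_calibration`.
#' @export
density_calibration <- function(c_cal = 4.287, h = 0.055, n_conv = 602,
                                bins = c(150, 300, 600, 1200, 2500, 10000)) {
  if (any(c(c_cal, h, n_conv) <= 0)) stop("calibration constants must be > 0")
  if (any(diff(bins) <= 0)) stop("bins must be strictly increasing")
  structure(list(c_cal = c_cal, h = h, n_conv = n_conv, bins = bins,
                 f_2d = n_conv * h),
            class = "density_calibration")
}

#' Intensity to bulk concentration
#'
#' `Concentration (uM) = c_cal (uM/AU) * Intensity (AU)`.
#'
#' @param intensity fluorescence intensity, AU (>= 0).
#' @param cal a [density_calibration()].
#' @return Concentration in uM.
#' @export
intensity_to_concentration <- function(intensity, cal = density_calibration()) {
  if (any(intensity < 0)) stop("intensity must be non-negative")
  cal$c_cal * intensity
}

#' Bulk concentration to surface density (and back)
#'
#' `density = conc * n_conv * h` (molecules um^-2 from uM);
#' `density_to_concentration` is the exact inverse.
#'
#' @param conc concentration, uM.
#' @param density surface density, molecules um^-2.
#' @param cal a [density_calibration()].
#' @return Surface density (molecules um^-2) or concentration (uM).
#' @export
concentration_to_density <- function(conc, cal = density_calibration()) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  conc * cal$f_2d
}

#' @rdname concentration_to_density
#' @export
density_to_concentration <- function(density, cal = density_calibration()) {
  if (any(density < 0)) stop("density must be non-negative")
  density / cal$f_2d
}

#' Assign a density to the nearest canonical bin
#'
#' Nearest bin in log2 distance (the bins are roughly 2x spaced, so linear
#' distance would misassign the wide shoulders of the top bin); exact ties
#' break to the lower bin.
#'
#' @param density surface density, molecules um^-2 (> 0); vectorized.
#' @param cal a [density_calibration()].
#' @return Bin center value(s) from `cal$bins`.
#' @export
assign_density_bin <- function(density, cal = density_calibration()) {
  if (any(density <= 0)) stop("density must be positive")
  vapply(density, function(d) {
    dist <- abs(log2(d) - log2(cal$bins))
    cal$bins[which(dist <= min(dist) + 1e-12)[1]]
  }, numeric(1))
}
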
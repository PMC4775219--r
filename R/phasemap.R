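#' Factorial GEF x GAP x density scan grid
#'
#' Describes a factorial scan over GEF input strength, GAP level and Ras
#' surface density. The defaults give the canonical 4 x 4 x 6 = 96
#' configurations (four input strengths, four GAP concentrations, six
#' density bins); dropping to a single density gives the 4 x 4 = 16
#' configuration distortion scan.
#'
#' Density is mapped to a total Ras concentration with a fixed
#' bead-geometry factor of 250 molecules um^-2 per nM, tying the typical
#' loading of 2500 molecules um^-2 to the canonical 10 nM Ras of the
#' kinetic models.
#'
#' @param gef_levels GEF concentrations, nM, strictly increasing.
#' @param gap_levels GAP concentrations, nM, strictly increasing (0 allowed;
#'   for the two-state model these act as the lumped deactivation
#'   multiplier).
#' @param density_levels Ras densities, molecules um^-2.
#' @param model which builder to use.
#' @param mutant optional [mutant_spec()] applied to every configuration.
#' @param eff_conc effector concentration, nM.
#' @param k_args further arguments passed to [rate_constants()] for every
#'   configuration (e.g. GAP kinetics).
#' @param density_per_nM bead-geometry conversion factor.
#' @return An object of class `config_grid`.
#' @export
config_grid <- function(gef_levels = c(20, 200, 1000, 2000),
                        gap_levels = c(0, 10, 100, 1000),
                        density_levels = c(150, 300, 600, 1200, 2500, 10000),
                        model = c("three_state", "competition", "two_state"),
                        mutant = NULL, eff_conc = 50, k_args = list(),
                        density_per_nM = 250) {
  model <- match.arg(model)
  if (any(diff(gef_levels) <= 0) || any(diff(gap_levels) <= 0) ||
      any(diff(density_levels) <= 0))
    stop("scan levels must be strictly increasing")
  structure(list(gef_levels = gef_levels, gap_levels = gap_levels,
                 density_levels = density_levels, model = model,
                 mutant = mutant, eff_conc = eff_conc, k_args = k_args,
                 density_per_nM = density_per_nM),
            class = "config_grid")
}

build_config_network <- function(grid, gef, gap) {
  k <- do.call(rate_constants, c(list(gef_conc = gef), grid$k_args))
  net <- switch(grid$model,
    three_state = build_three_state_model(k, eff_conc = grid$eff_conc),
    competition = build_competition_model(k, eff_conc = grid$eff_conc),
    two_state = build_two_state_model(k, gap_level = gap,
                                      eff_conc = grid$eff_conc))
  if (!is.null(grid$mutant)) net <- apply_mutant(net, grid$mutant)
  net
}

#' Run a factorial configuration scan
#'
#' One simulation plus feature extraction per (GEF, GAP, density)
#' configuration; deterministic.
#'
#' @param grid a [config_grid()].
#' @param t_end,sample_dt passed to [simulate()].
#' @return data.frame keyed by `gef_nM`, `gap_nM`, `density`, with one
#'   column per [feature_set()] feature.
#' @export
run_config_grid <- function(grid, t_end = 42000, sample_dt = 900) {
  stopifnot(inherits(grid, "config_grid"))
  configs <- expand.grid(gef_nM = grid$gef_levels, gap_nM = grid$gap_levels,
                         density = grid$density_levels,
                         KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(configs)), function(i) {
    cf <- configs[i, ]
    net <- build_config_network(grid, cf$gef_nM, cf$gap_nM)
    ras_nM <- cf$density / grid$density_per_nM
    ic <- if (identical(grid$model, "two_state"))
      initial_state(net, GD = ras_nM)
    else initial_state(net, gap = cf$gap_nM, GD = ras_nM)
    sim <- tryCatch(simulate(net, ic, t_end = t_end, sample_dt = sample_dt),
                    error = function(e)
                      stop("simulation failed at gef = ", cf$gef_nM,
                           ", gap = ", cf$gap_nM, ", density = ", cf$density,
                           ": ", conditionMessage(e)))
    cbind(cf, feature_set(sim_timecourse(sim)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interpolated phase diagram of one output feature
#'
#' Bilinear interpolation of a scanned feature over the (GEF, GAP) plane in
#' log10 coordinates (GAP is offset by `eps = 0.1 x` the smallest nonzero
#' GAP level so that 0 has a finite coordinate). Exact at the grid nodes.
#'
#' @param rows output of [run_config_grid()].
#' @param feature_name feature column to interpolate.
#' @param density_level which density slice to use (must match a scanned
#'   level; defaults to the single density present).
#' @return An object of class `phase_diagram` with a `surface(gef, gap)`
#'   evaluator.
#' @export
interpolate_phase <- function(rows, feature_name = "integrated_signal",
                              density_level = NULL) {
  stopifnot(feature_name %in% names(rows))
  if (is.null(density_level)) {
    density_level <- unique(rows$density)
    if (length(density_level) != 1)
      stop("rows contain several densities; give density_level")
  }
  rows <- rows[rows$density == density_level, ]
  gef <- sort(unique(rows$gef_nM)); gap <- sort(unique(rows$gap_nM))
  need <- expand.grid(gef_nM = gef, gap_nM = gap)
  key <- paste(rows$gef_nM, rows$gap_nM)
  missing <- need[!paste(need$gef_nM, need$gap_nM) %in% key, ]
  if (nrow(missing))
    stop("incomplete grid; missing nodes: ",
         paste(sprintf("(%g, %g)", missing$gef_nM, missing$gap_nM),
               collapse = ", "))
  eps <- if (any(gap > 0)) 0.1 * min(gap[gap > 0]) else 1
  x <- log10(gef); y <- log10(gap + eps)
  z <- matrix(NA_real_, length(gef), length(gap))
  for (i in seq_along(gef)) for (j in seq_along(gap))
    z[i, j] <- rows[rows$gef_nM == gef[i] & rows$gap_nM == gap[j],
                    feature_name]
  surface <- function(gef_nM, gap_nM) {
    xq <- log10(gef_nM); yq <- log10(gap_nM + eps)
    if (xq < min(x) || xq > max(x) || yq < min(y) || yq > max(y))
      stop("query point outside the scanned hull")
    i <- min(max(findInterval(xq, x), 1), length(x) - 1)
    j <- min(max(findInterval(yq, y), 1), length(y) - 1)
    tx <- (xq - x[i]) / (x[i + 1] - x[i])
    ty <- (yq - y[j]) / (y[j + 1] - y[j])
    (1 - tx) * (1 - ty) * z[i, j] + tx * (1 - ty) * z[i + 1, j] +
      (1 - tx) * ty * z[i, j + 1] + tx * ty * z[i + 1, j + 1]
  }
  structure(list(gef_levels = gef, gap_levels = gap, x = x, y = y, z = z,
                 eps = eps, feature = feature_name,
                 density_level = density_level, surface = surface),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram>", x$feature, "at density", x$density_level,
      "molecules/um^2\n")
  cat("  gef:", paste(x$gef_levels, collapse = ", "), "nM\n")
  cat("  gap:", paste(x$gap_levels, collapse = ", "), "nM\n")
  print(signif(x$z, 4))
  invisible(x)
}

#' Extract iso-output contours (neutral paths)
#'
#' Marching-squares contours of the interpolated surface at a given level.
#' Configurations along a contour produce the same output value and form a
#' neutral path through (GEF, GAP) space.
#'
#' @param pd a [interpolate_phase()] result.
#' @param level contour level; must lie within the range of the grid values
#'   (outside it an empty list is returned). A level exactly equal to a
#'   constant surface yields no paths (degenerate case).
#' @return List of data.frames with columns `gef_nM`, `gap_nM`, `log_gef`,
#'   `log_gap`.
#' @export
extract_isocline <- function(pd, level) {
  stopifnot(inherits(pd, "phase_diagram"))
  if (level < min(pd$z) || level > max(pd$z)) return(list())
  # a constant surface has no level lines: degenerate case, empty result
  if (diff(range(pd$z)) == 0) return(list())
  cl <- grDevices::contourLines(pd$x, pd$y, pd$z, levels = level)
  lapply(cl, function(p)
    data.frame(gef_nM = 10^p$x, gap_nM = pmax(10^p$y - pd$eps, 0),
               log_gef = p$x, log_gap = p$y))
}
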
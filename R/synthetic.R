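#' Noise model for synthetic bead data
#'
#' Observed effector fluorescence on a bead is modeled as a linear gain on
#' the simulated bound-effector occupancy, a per-bead multiplicative factor
#' (lognormal, sd `cv_bead` on the log scale), a constant background and
#' additive per-timepoint Gaussian noise:
#' `AU(t) = gain * occupancy(t) * bead_factor + background + N(0, sigma_add)`.
#'
#' The defaults are calibrated so that bin-averaged traces over 15 beads
#' have a per-timepoint SEM/mean comfortably below the 15% typical of the
#' experimental data. Identical seeds give identical datasets.
#'
#' @param gain AU per nM of bound effector.
#' @param background AU offset.
#' @param sigma_add per-timepoint additive noise sd, AU.
#' @param cv_bead per-bead multiplicative spread (also used as the log-sd of
#'   the density scatter around each bin center in [sample_beads()]).
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gain = 100, background = 50, sigma_add = 5,
                        cv_bead = 0.2, seed = 0L) {
  if (gain <= 0) stop("gain must be positive")
  if (sigma_add < 0 || cv_bead < 0) stop("noise parameters must be >= 0")
  structure(list(gain = gain, background = background, sigma_add = sigma_add,
                 cv_bead = cv_bead, seed = as.integer(seed)),
            class = "noise_model")
}

#' Ground-truth model configuration for the generator
#'
#' @param model builder name.
#' @param gef_conc GEF, nM.
#' @param gap GAP, nM.
#' @param eff_conc effector, nM.
#' @param t_end,sample_dt simulation horizon and imaging interval, s
#'   (15-min frames over ~700 min by default).
#' @param k_args extra [rate_constants()] arguments.
#' @return A list understood by [render_traces()].
#' @export
synth_model_config <- function(model = "three_state", gef_conc = 1000,
                               gap = 0, eff_conc = 50, t_end = 42000,
                               sample_dt = 900, k_args = list()) {
  list(model = model, gef_conc = gef_conc, gap = gap, eff_conc = eff_conc,
       t_end = t_end, sample_dt = sample_dt, k_args = k_args)
}

#' Sample bead geometries and densities
#'
#' Draws `n_per_bin` beads per canonical density bin: densities lognormal
#' around the bin center (log-sd `cv_bead`), radii uniform over `r_range`
#' pixels (areas stay inside the 400-15000 px particle filter). The Ras
#' channel intensity is the value that maps back to the true density
#' through the density calibration.
#'
#' @param n_per_bin beads per bin (>= 1).
#' @param bins density bin centers, molecules um^-2.
#' @param noise a [noise_model()] (supplies `cv_bead` and `seed`).
#' @param r_range bead radius range, px.
#' @param cal a [density_calibration()].
#' @return data.frame with columns `bead_id`, `radius_px`, `area_px`,
#'   `perimeter_px`, `true_density`, `bin`, `ras_intensity`.
#' @export
sample_beads <- function(n_per_bin = 15, bins = density_calibration()$bins,
                         noise = noise_model(), r_range = c(20, 40),
                         cal = density_calibration()) {
  if (n_per_bin < 1) stop("n_per_bin must be >= 1")
  set.seed(noise$seed)
  n <- n_per_bin * length(bins)
  dens <- as.vector(vapply(bins, function(b)
    stats::rlnorm(n_per_bin, meanlog = log(b), sdlog = noise$cv_bead),
    numeric(n_per_bin)))
  r <- stats::runif(n, r_range[1], r_range[2])
  data.frame(bead_id = seq_len(n),
             radius_px = r,
             area_px = pi * r^2,
             perimeter_px = 2 * pi * r,
             true_density = dens,
             bin = rep(bins, each = n_per_bin),
             ras_intensity = dens / (cal$c_cal * cal$f_2d))
}

#' Render effector timecourses for sampled beads
#'
#' Simulates the ground-truth bound-effector occupancy for each bead (total
#' Ras scaled from its true density at 250 molecules um^-2 per nM) and
#' applies the noise model.
#'
#' @param beads output of [sample_beads()].
#' @param model_config a [synth_model_config()].
#' @param noise a [noise_model()].
#' @param density_per_nM bead-geometry conversion factor.
#' @return An object of class `bead_dataset`: `beads` (with the drawn
#'   `bead_factor`), `traces` (beads x timepoints AU matrix), `times` (s),
#'   `ground_truth` (noise-free occupancy, nM), `model_config`, `noise`.
#' @export
render_traces <- function(beads, model_config = synth_model_config(),
                          noise = noise_model(), density_per_nM = 250) {
  set.seed(noise$seed + 1L)
  mc <- model_config
  k <- do.call(rate_constants, c(list(gef_conc = mc$gef_conc), mc$k_args))
  build <- switch(mc$model,
    three_state = function() build_three_state_model(k, eff_conc = mc$eff_conc),
    competition = function() build_competition_model(k, eff_conc = mc$eff_conc),
    two_state = function() build_two_state_model(k, gap_level = mc$gap,
                                                 eff_conc = mc$eff_conc),
    stop("unknown model: ", mc$model))
  net <- build()
  n_t <- length(unique(c(0, seq(mc$sample_dt, mc$t_end, by = mc$sample_dt),
                         mc$t_end)))
  n <- nrow(beads)
  gt <- matrix(NA_real_, n, n_t)
  times <- NULL
  for (i in seq_len(n)) {
    ras_nM <- beads$true_density[i] / density_per_nM
    ic <- if (identical(mc$model, "two_state"))
      initial_state(net, GD = ras_nM)
    else initial_state(net, gap = mc$gap, GD = ras_nM)
    sim <- simulate(net, ic, t_end = mc$t_end, sample_dt = mc$sample_dt)
    gt[i, ] <- sim_timecourse(sim)$values
    times <- sim$times
  }
  bead_factor <- stats::rlnorm(n, meanlog = 0, sdlog = noise$cv_bead)
  traces <- noise$gain * gt * bead_factor + noise$background +
    matrix(stats::rnorm(n * n_t, sd = noise$sigma_add), n, n_t)
  beads$bead_factor <- bead_factor
  structure(list(beads = beads, traces = traces, times = times,
                 ground_truth = gt, model_config = mc, noise = noise),
            class = "bead_dataset")
}

#' @export
print.bead_dataset <- function(x, ...) {
  cat("<bead_dataset>", nrow(x$traces), "beads x", ncol(x$traces),
      "timepoints (", x$model_config$model, "ground truth )\n")
  invisible(x)
}

#' Write a bead dataset in the macro log dialect
#'
#' One block per bead: a header line `area,ras_mean,perim,`, one line per
#' timepoint `value,`, then a stop-marker line `!`. Round-trips through
#' [parse_bead_log()] to numerical identity (values are printed with 15
#' significant digits).
#'
#' @param ds a `bead_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
emit_log_format <- function(ds, path) {
  stopifnot(inherits(ds, "bead_dataset"))
  if (nrow(ds$traces) == 0) stop("empty dataset")
  fmt <- function(x) sprintf("%.15g", x)
  blocks <- vapply(seq_len(nrow(ds$traces)), function(i) {
    b <- ds$beads[i, ]
    paste(c(paste0(fmt(b$area_px), ",", fmt(b$ras_intensity), ",",
                   fmt(b$perimeter_px), ","),
            paste0(fmt(ds$traces[i, ]), ","),
            "!"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Render a synthetic two-channel image series
#'
#' Places each bead as a uniform disk at a random non-overlapping position:
#' the GTPase channel is constant over time (disk value = Ras intensity x
#' gain), the effector channel follows the bead's rendered trace. Pixels
#' get the background plus Gaussian noise and are quantized to 16 bits.
#'
#' @param ds a `bead_dataset`.
#' @param frame_px frame side, px.
#' @param max_attempts rejection-sampling budget for placements.
#' @return List with `gtpase` (frame x frame matrix), `effector`
#'   (frame x frame x timepoints array), and `centers` (data.frame of
#'   placements).
#' @export
render_image_series <- function(ds, frame_px = 512, max_attempts = 1e4) {
  stopifnot(inherits(ds, "bead_dataset"))
  noise <- ds$noise
  set.seed(noise$seed + 2L)
  n <- nrow(ds$beads)
  r <- ds$beads$radius_px
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- stats::runif(1, r[i] + 2, frame_px - r[i] - 2)
      y <- stats::runif(1, r[i] + 2, frame_px - r[i] - 2)
      if (i == 1 || all(sqrt((x - cx[seq_len(i - 1)])^2 +
                             (y - cy[seq_len(i - 1)])^2) >
                        r[i] + r[seq_len(i - 1)] + 2)) {
        cx[i] <- x; cy[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place bead ", i, " without overlap after ",
                  max_attempts, " attempts")
  }
  xg <- matrix(seq_len(frame_px), frame_px, frame_px)
  yg <- t(xg)
  quantize <- function(m) {
    m <- m + noise$background
    if (noise$sigma_add > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = noise$sigma_add),
                      nrow(m), ncol(m))
    matrix(pmin(pmax(round(m), 0), 65535), nrow(m), ncol(m))
  }
  base <- matrix(0, frame_px, frame_px)
  masks <- lapply(seq_len(n), function(i)
    (xg - cx[i])^2 + (yg - cy[i])^2 <= r[i]^2)
  gtpase <- base
  for (i in seq_len(n))
    gtpase[masks[[i]]] <- ds$beads$ras_intensity[i] * noise$gain
  n_t <- ncol(ds$traces)
  effector <- array(0, dim = c(frame_px, frame_px, n_t))
  for (tt in seq_len(n_t)) {
    fr <- base
    for (i in seq_len(n))
      fr[masks[[i]]] <- ds$traces[i, tt] - noise$background
    effector[, , tt] <- quantize(fr)
  }
  list(gtpase = quantize(gtpase), effector = effector,
       centers = data.frame(bead_id = ds$beads$bead_id, cx = cx, cy = cy,
                            radius_px = r))
}

#' Write an image series as multi-page TIFF files
#'
#' Writes the static GTPase channel and the effector timecourse (one page
#' per timepoint) as 16-bit TIFFs. Requires the `tiff` package.
#'
#' @param img a [render_image_series()] result.
#' @param gtpase_path,effector_path output files.
#' @return Invisibly, the two paths.
#' @export
write_tiff_stack <- function(img, gtpase_path, effector_path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  tiff::writeTIFF(img$gtpase / 65535, gtpase_path, bits.per.sample = 16L)
  pages <- lapply(seq_len(dim(img$effector)[3]),
                  function(tt) img$effector[, , tt] / 65535)
  tiff::writeTIFF(pages, effector_path, bits.per.sample = 16L)
  invisible(c(gtpase_path, effector_path))
}
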
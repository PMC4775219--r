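#' Parse a macro-dialect bead log
#'
#' Reads the bead-trace log format: per bead a header line
#' `area,ras_mean,perim,`, one line per timepoint `value,`, then a `!`
#' stop-marker line. All beads must have the same trace length.
#'
#' @param path log file.
#' @param sample_dt imaging interval in seconds assigned to the parsed
#'   traces (the log itself carries no times).
#' @return A `bead_dataset` (without ground truth).
#' @export
parse_bead_log <- function(path, sample_dt = 900) {
  lines <- readLines(path)
  if (!length(lines))
    return(structure(list(
      beads = data.frame(bead_id = integer(), area_px = numeric(),
                         ras_intensity = numeric(), perimeter_px = numeric()),
      traces = matrix(numeric(), 0, 0), times = numeric(),
      ground_truth = NULL, model_config = NULL, noise = NULL),
      class = "bead_dataset"))
  beads <- list(); traces <- list()
  header <- NULL; vals <- numeric(0); header_line <- NA_integer_
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (line == "!") {
      if (is.null(header))
        stop("stop marker without a bead block at line ", ln)
      beads[[length(beads) + 1L]] <- header
      traces[[length(traces) + 1L]] <- vals
      header <- NULL; vals <- numeric(0)
    } else {
      fields <- strsplit(line, ",", fixed = TRUE)[[1]]
      nums <- suppressWarnings(as.numeric(fields))
      if (anyNA(nums))
        stop("malformed numeric field at line ", ln, ": '", line, "'")
      if (is.null(header)) {
        if (length(nums) != 3)
          stop("bead header must have 3 fields (area,ras,perim) at line ", ln)
        header <- nums; header_line <- ln
      } else {
        if (length(nums) != 1)
          stop("expected one measurement per line at line ", ln)
        vals <- c(vals, nums)
      }
    }
  }
  if (!is.null(header))
    stop("bead block starting at line ", header_line,
         " is missing its '!' terminator (EOF reached)")
  lens <- lengths(traces)
  if (length(unique(lens)) > 1)
    stop("inconsistent trace lengths across beads: ",
         paste(sort(unique(lens)), collapse = ", "))
  hdr <- do.call(rbind, beads)
  n_t <- lens[1]
  structure(list(
    beads = data.frame(bead_id = seq_along(beads), area_px = hdr[, 1],
                       ras_intensity = hdr[, 2], perimeter_px = hdr[, 3]),
    traces = do.call(rbind, traces),
    times = (seq_len(n_t) - 1) * sample_dt,
    ground_truth = NULL, model_config = NULL, noise = NULL),
    class = "bead_dataset")
}

#' Normalize a single bead trace
#'
#' Intensity values are normalized to the bead perimeter (the signal lives
#' on a ring in the confocal slice, so a perimeter normalization removes
#' the first-order geometry dependence), then the time-zero value is
#' subtracted so every trace starts at exactly 0 (this also removes any
#' constant background).
#'
#' @param values raw trace, AU.
#' @param perimeter bead perimeter, px (> 0).
#' @param times sample times, s (defaults to a 15-min grid).
#' @return A [timecourse()] with `values[1] == 0`.
#' @export
normalize_trace <- function(values, perimeter,
                            times = (seq_along(values) - 1) * 900) {
  if (perimeter <= 0) stop("perimeter must be positive")
  v <- values / perimeter
  timecourse(times, v - v[1])
}

#' Bin beads by density and average their normalized traces
#'
#' Each bead's Ras intensity is converted to a surface density and assigned
#' to the nearest canonical bin; the perimeter-normalized, baseline-zeroed
#' traces within a bin are averaged pointwise. Bins with no beads are
#' omitted.
#'
#' @param ds a `bead_dataset`.
#' @param cal a [density_calibration()].
#' @return A list of class `binned_responses`; each element has `bin`,
#'   `mean_trace`, `sem_trace` (sample sd / sqrt(n), `NA` for n = 1),
#'   `n_beads`, `times`.
#' @export
bin_and_average <- function(ds, cal = density_calibration()) {
  stopifnot(inherits(ds, "bead_dataset"))
  if (nrow(ds$traces) < 1) stop("dataset has no beads")
  dens <- concentration_to_density(
    intensity_to_concentration(ds$beads$ras_intensity, cal), cal)
  bin <- assign_density_bin(dens, cal)
  norm <- t(vapply(seq_len(nrow(ds$traces)), function(i)
    normalize_trace(ds$traces[i, ], ds$beads$perimeter_px[i],
                    ds$times)$values,
    numeric(ncol(ds$traces))))
  out <- lapply(sort(unique(bin)), function(b) {
    m <- norm[bin == b, , drop = FALSE]
    n <- nrow(m)
    list(bin = b,
         mean_trace = colMeans(m),
         sem_trace = if (n >= 2) apply(m, 2, stats::sd) / sqrt(n)
                     else rep(NA_real_, ncol(m)),
         n_beads = n,
         times = ds$times)
  })
  structure(out, class = "binned_responses")
}

#' @export
print.binned_responses <- function(x, ...) {
  cat("<binned_responses>\n")
  for (b in x)
    cat(sprintf("  bin %6g: n = %2d, peak mean %.4g\n",
                b$bin, b$n_beads, max(b$mean_trace)))
  invisible(x)
}

#' Relative SEM of bin-averaged traces after signal onset
#'
#' For each bin, takes the timepoints after the mean trace first reaches
#' `onset_frac` of its peak and computes SEM/mean per timepoint; returns
#' the median over all bins and retained timepoints, in percent.
#'
#' @param binned a [bin_and_average()] result.
#' @param onset_frac onset threshold as a fraction of the peak mean.
#' @return Median relative SEM, percent.
#' @export
sem_percent <- function(binned, onset_frac = 0.1) {
  stopifnot(inherits(binned, "binned_responses"))
  rel <- unlist(lapply(binned, function(b) {
    if (b$n_beads < 2) return(numeric(0))
    pk <- max(b$mean_trace)
    if (pk <= 0) return(numeric(0))
    from <- which(b$mean_trace >= onset_frac * pk)[1]
    idx <- seq(from, length(b$mean_trace))
    idx <- idx[b$mean_trace[idx] > 0]
    b$sem_trace[idx] / b$mean_trace[idx]
  }))
  100 * stats::median(rel)
}
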
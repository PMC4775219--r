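test_that("bead sampling respects counts, bins and the particle-size filter", {
  beads <- sample_beads(n_per_bin = 15)
  expect_equal(nrow(beads), 15 * 6)
  expect_true(all(beads$area_px >= 400 & beads$area_px <= 15000))
  expect_equal(beads$area_px, pi * beads$radius_px^2)
  expect_equal(beads$perimeter_px, 2 * pi * beads$radius_px)
  # zero spread puts every bead exactly at its bin center
  b0 <- sample_beads(5, noise = noise_model(cv_bead = 0))
  expect_equal(b0$true_density, b0$bin)
})

test_that("the generator is fully deterministic under a seed", {
  nm <- noise_model(seed = 123)
  d1 <- render_traces(sample_beads(4, bins = c(600, 2500), noise = nm),
                      synth_model_config(t_end = 3600), noise = nm)
  d2 <- render_traces(sample_beads(4, bins = c(600, 2500), noise = nm),
                      synth_model_config(t_end = 3600), noise = nm)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$beads, d2$beads)
  d3 <- render_traces(sample_beads(4, bins = c(600, 2500),
                                   noise = noise_model(seed = 124)),
                      synth_model_config(t_end = 3600),
                      noise = noise_model(seed = 124))
  expect_false(identical(d1$traces, d3$traces))
})

test_that("noise-free traces equal the simulated occupancy and scale with gain", {
  nm <- noise_model(gain = 1, background = 0, sigma_add = 0, cv_bead = 0,
                    seed = 5)
  beads <- sample_beads(2, bins = c(1200, 2500), noise = nm)
  mc <- synth_model_config(t_end = 7200)
  ds <- render_traces(beads, mc, noise = nm)
  expect_equal(ds$traces, ds$ground_truth)
  nm2 <- noise_model(gain = 2, background = 10, sigma_add = 0, cv_bead = 0,
                     seed = 5)
  ds2 <- render_traces(beads, mc, noise = nm2)
  expect_equal(ds2$traces - 10, 2 * ds$traces)
})

test_that("bin-averaged traces meet the experimental precision", {
  ds <- render_traces(sample_beads(n_per_bin = 15))
  expect_lt(sem_percent(bin_and_average(ds)), 15)
})

test_that("the gain is recoverable from noiseless plateaus", {
  nm <- noise_model(sigma_add = 0, cv_bead = 0, seed = 2)
  ds <- render_traces(sample_beads(3, noise = nm), noise = nm)
  n_t <- ncol(ds$traces)
  obs <- ds$traces[, n_t] - nm$background
  truth <- ds$ground_truth[, n_t]
  slope <- stats::coef(stats::lm(obs ~ 0 + truth))[[1]]
  expect_equal(slope, nm$gain, tolerance = 0.05)
})

test_that("the log dialect round-trips and has the documented layout", {
  nm <- noise_model(seed = 9)
  ds <- render_traces(sample_beads(2, bins = c(600, 2500), noise = nm),
                      synth_model_config(t_end = 1800), noise = nm)
  f <- withr::local_tempfile()
  emit_log_format(ds, f)
  lines <- readLines(f)
  # per bead: 1 header + n_timepoints + 1 stop marker
  n_t <- ncol(ds$traces)
  expect_length(lines, nrow(ds$traces) * (n_t + 2))
  expect_equal(sum(lines == "!"), nrow(ds$traces))
  expect_true(all(endsWith(lines[lines != "!"], ",")))

  back <- parse_bead_log(f)
  expect_equal(back$traces, ds$traces, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$beads$area_px, ds$beads$area_px, tolerance = 1e-9)
  expect_equal(back$beads$perimeter_px, ds$beads$perimeter_px,
               tolerance = 1e-9)
})

test_that("rendered image stacks have a static GTPase channel and faithful disks", {
  nm <- noise_model(sigma_add = 0, cv_bead = 0, seed = 3)
  beads <- sample_beads(2, bins = c(1200, 2500), noise = nm)
  ds <- render_traces(beads, synth_model_config(t_end = 1800), noise = nm)
  img <- render_image_series(ds, frame_px = 256)
  expect_equal(dim(img$effector), c(256, 256, ncol(ds$traces)))
  # effector-channel mean inside a disk equals the trace value (quantized)
  i <- 1
  mask <- (row(img$gtpase) - img$centers$cx[i])^2 +
    (col(img$gtpase) - img$centers$cy[i])^2 <=
    (img$centers$radius_px[i] - 1)^2
  expect_equal(mean(img$effector[, , 2][mask]), ds$traces[i, 2],
               tolerance = 1 / ds$traces[i, 2])
  # detection on the noise-free GTPase frame recovers every placed bead
  det <- detect_beads(img$gtpase)
  expect_equal(nrow(det), nrow(beads))
  for (i in seq_len(nrow(beads))) {
    d2 <- (det$cx - img$centers$cx[i])^2 + (det$cy - img$centers$cy[i])^2
    expect_lt(min(d2), 2)
  }
  # overcrowded frames fail with a clear error
  nm4 <- noise_model(seed = 4)
  crowded <- render_traces(sample_beads(3, bins = 2500, noise = nm4,
                                        r_range = c(30, 32)),
                           synth_model_config(t_end = 900), noise = nm4)
  expect_error(render_image_series(crowded, frame_px = 110,
                                   max_attempts = 50), "without overlap")
})

test_that("image series export to multi-page 16-bit TIFF and read back", {
  nm <- noise_model(sigma_add = 0, cv_bead = 0, seed = 3)
  ds <- render_traces(sample_beads(1, bins = 2500, noise = nm),
                      synth_model_config(t_end = 1800), noise = nm)
  img <- render_image_series(ds, frame_px = 128)
  fg <- withr::local_tempfile(fileext = ".tif")
  fe <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(img, fg, fe)
  back <- tiff::readTIFF(fe, all = TRUE)
  expect_length(back, dim(img$effector)[3])
  expect_equal(round(back[[2]] * 65535), img$effector[, , 2],
               ignore_attr = TRUE)
})
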
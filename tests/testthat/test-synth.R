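test_that("simulated proteins are reproducible and frequency-driven", {
  p1 <- simulate_protein(100, seed = 1)
  p2 <- simulate_protein(100, seed = 1)
  p3 <- simulate_protein(100, seed = 2)
  expect_equal(nchar(p1$sequence), 100L)
  expect_identical(p1$sequence, p2$sequence)
  expect_false(identical(p1$sequence, p3$sequence))
})

test_that("reference maps are byte-identical under a fixed seed", {
  spec <- simulation_spec(n_peptides = 5, rt_range = c(100, 200), seed = 6)
  a <- simulate_reference_map(spec)
  b <- simulate_reference_map(spec)
  expect_identical(a$truth$sequence, b$truth$sequence)
  expect_identical(as.data.frame(a$map), as.data.frame(b$map))
})

test_that("ground truth is retained alongside the simulated map", {
  spec <- simulation_spec(n_peptides = 5, rt_range = c(100, 200), seed = 6)
  sim <- simulate_reference_map(spec)
  expect_true(all(c("sequence", "start", "end", "charge", "mono_mass",
                    "n_exchangeable", "rt_apex", "abundance",
                    "obs_mono_mass") %in% names(sim$truth)))
  expect_equal(nrow(sim$truth), 5L)
  expect_equal(sim$truth$mono_mass,
               vapply(sim$truth$sequence, peptide_mono_mass, 0,
                      USE.NAMES = FALSE), tolerance = 1e-9)
})

test_that("a calibration error shifts observed masses by the stated ppm", {
  spec0 <- simulation_spec(n_peptides = 20, rt_range = c(100, 300),
                           calibration_error_ppm = 0, mz_jitter_ppm = 0,
                           seed = 7)
  spec16 <- simulation_spec(n_peptides = 20, rt_range = c(100, 300),
                            calibration_error_ppm = 16, mz_jitter_ppm = 0,
                            seed = 7)
  s0 <- simulate_reference_map(spec0)
  s16 <- simulate_reference_map(spec16)
  ppm <- (s16$truth$obs_mono_mass - s0$truth$obs_mono_mass) /
    s0$truth$obs_mono_mass * 1e6
  # the 16 ppm error acts on m/z; on the neutral mass it carries an extra
  # factor (1 + z * m_proton / mass)
  expected <- 16 * (1 + s0$truth$charge * 1.007276466 / s0$truth$mono_mass)
  expect_equal(ppm, expected, tolerance = 1e-4)
})

test_that("rt distortion follows the ascending multiplier contract", {
  spec <- simulation_spec(n_peptides = 3, rt_range = c(200, 1400), seed = 8)
  sim <- simulate_reference_map(spec)
  ident <- apply_rt_distortion(sim$map, 1, 1)
  expect_equal(map_scans(ident)$rt, map_scans(sim$map)$rt)

  dist <- apply_rt_distortion(sim$map, 0.8, 1.2)
  rts <- map_scans(dist)$rt
  orig <- map_scans(sim$map)$rt
  expect_true(all(diff(rts) > 0))
  expect_equal(rts[1], orig[1] * 0.8)
  expect_equal(rts[length(rts)], orig[length(orig)] * 1.2)
  # shifts span a multi-hundred-second range, negative early and positive late
  expect_lt(min(rts - orig), -30)
  expect_gt(max(rts - orig), 250)
  # peaks untouched
  expect_equal(dist$mz, sim$map$mz)
})

test_that("deuterated maps place envelopes per the forward model", {
  spec <- simulation_spec(n_peptides = 4, rt_range = c(100, 220),
                          snr = 50, seed = 14)
  ref <- simulate_reference_map(spec)
  n <- nrow(ref$truth)
  # delta at 0: map statistically equals the reference
  d0 <- simulate_deuterated_map(ref, replicate(n, c(1), simplify = FALSE),
                                noise_seed = 55)
  expect_equal(nrow(map_scans(d0$map)), nrow(map_scans(ref$map)))
  # same mono positions present
  frow <- ref$truth[1, ]
  env_ref <- extract_envelope(ref$map, frow, NULL, 0)
  env_d0 <- extract_envelope(d0$map, frow, NULL, 0)
  expect_s3_class(env_d0, "observed_envelope")
  expect_equal(which.max(env_d0$intensities), which.max(env_ref$intensities))

  # bimodal truth yields a bimodal envelope
  dists <- replicate(n, c(1), simplify = FALSE)
  N1 <- ref$truth$n_exchangeable[1]
  bim <- numeric(N1 + 1); bim[1] <- 0.5; bim[min(10, N1 + 1)] <- 0.5
  dists[[1]] <- bim
  db <- simulate_deuterated_map(ref, dists, noise_seed = 56)
  envb <- extract_envelope(db$map, frow, NULL, N1)
  expect_s3_class(envb, "observed_envelope")
  prof <- envb$intensities / max(envb$intensities)
  peaks_at <- which(prof > 0.3)
  expect_gt(diff(range(peaks_at)), 6)  # two separated regions of intensity
})

test_that("simulated experiments carry exact ground truth for every module", {
  spec <- simulation_spec(n_peptides = 3, rt_range = c(100, 180), seed = 15)
  ex <- simulate_hdx_experiment(spec, times = c(15, 60), n_replicates = 2L)
  expect_equal(nrow(ex$deuterated), 4L)
  expect_equal(nrow(ex$truth_centroids), 6L)
  expect_true(all(lengths(ex$deuterated$dists[[1]]) ==
                    ex$reference$truth$n_exchangeable + 1L))
  # centroids consistent with the stored distributions
  d <- ex$deuterated$dists[[1]][[1]]
  cen <- ex$truth_centroids$centroid[ex$truth_centroids$feature == 1 &
                                       ex$truth_centroids$time == 15]
  expect_equal(sum((seq_along(d) - 1) * d), cen)
})
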
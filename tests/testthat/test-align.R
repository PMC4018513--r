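small_ref <- function(seed = 5, n = 30, rt = c(100, 500)) {
  spec <- simulation_spec(n_peptides = n, rt_range = rt, snr = 20, seed = seed)
  simulate_reference_map(spec)
}

test_that("an exact copy yields diagonal candidates for every feature", {
  sim <- small_ref()
  cand <- find_alignment_candidates(sim$truth, sim$map)
  expect_gt(nrow(cand), 0)
  diag_hit <- vapply(seq_len(nrow(sim$truth)), function(i) {
    ci <- cand[cand$feature == sim$truth$feature[i], ]
    any(abs(ci$rt_target - sim$truth$rt_apex[i]) <= 2 * 6)
  }, logical(1))
  expect_gte(mean(diag_hit), 0.95)
  expect_true(all(cand$n_isotopes_matched >= 3))
})

test_that("an empty target map yields no candidates", {
  sim <- small_ref()
  em <- lcms_map(data.frame(),
                 scans = tibble::tibble(scan = integer(), rt = double()))
  expect_equal(nrow(find_alignment_candidates(sim$truth, em)), 0L)
})

test_that("coarse fit recovers lines and rejects scattered outliers", {
  set.seed(2)
  x <- runif(200, 100, 1000)
  clean <- tibble::tibble(feature = 1:200, rt_ref = x, rt_target = x,
                          n_isotopes_matched = 3L)
  fit <- coarse_linear_fit(clean)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(nrow(fit$inliers), 200L)

  noisy <- clean
  out_idx <- 1:40
  noisy$rt_target[out_idx] <- runif(40, 100, 1000)
  noisy$rt_target[-out_idx] <- noisy$rt_ref[-out_idx] + rnorm(160, 0, 2)
  fit2 <- coarse_linear_fit(noisy)
  expect_lt(abs(fit2$slope - 1), 0.02)
  expect_lt(mean(out_idx %in% which(abs(noisy$rt_target - noisy$rt_ref) < 6 )), 0.5)

  stretched <- clean
  stretched$rt_target <- 1.2 * stretched$rt_ref
  fit3 <- coarse_linear_fit(stretched)
  expect_equal(fit3$slope, 1.2, tolerance = 0.01)

  expect_error(coarse_linear_fit(clean[1:5, ]), "insufficient")
})

test_that("piecewise fit reproduces linear truth and falls back sensibly", {
  set.seed(4)
  x <- sort(runif(300, 0, 1500))
  lin <- tibble::tibble(rt_ref = x, rt_target = 0.9 * x + 30)
  for (nseg in c(1L, 4L, 8L)) {
    mp <- piecewise_fit(lin, align_params(n_segments = nseg))
    expect_lt(max(abs(predict(mp, x) - lin$rt_target)), 1e-6)
  }
})

test_that("piecewise fit tracks a nonlinear stretch within 5 s", {
  set.seed(6)
  x <- sort(runif(1500, 0, 1500))
  truthfun <- function(t) t * (0.8 + 0.4 * t / 1500)
  pts <- tibble::tibble(rt_ref = x, rt_target = truthfun(x) + rnorm(1500, 0, 2))
  mp <- piecewise_fit(pts, align_params(n_segments = 8L))
  grid <- seq(50, 1450, by = 10)
  expect_lt(max(abs(predict(mp, grid) - truthfun(grid))), 5)
  # monotone nondecreasing over the fitted range
  expect_true(all(diff(predict(mp, grid)) >= 0))
})

test_that("tolerance windows floor at the configured minimum and widen locally", {
  x <- sort(runif(200, 0, 1000))
  exact <- tibble::tibble(rt_ref = x, rt_target = x)
  mp <- piecewise_fit(exact, align_params())
  mp <- tolerance_window(mp, ref_peak_width = 5, align_params())
  expect_true(all(mp$local_tolerance == 10))
  expect_equal(mp$peak_width_extension, 5)

  # noise in one region only
  y <- x + ifelse(x > 700, rnorm(length(x), 0, 25), 0)
  mp2 <- piecewise_fit(tibble::tibble(rt_ref = x, rt_target = y),
                       align_params())
  mp2 <- tolerance_window(mp2, 5, align_params())
  td <- tidy(mp2)
  expect_gt(max(td$tolerance[td$rt_ref > 700]), max(td$tolerance[td$rt_ref < 500]))
})

test_that("self-alignment is the identity within one scan interval", {
  sim <- small_ref(seed = 8, n = 40)
  mp <- align_map(sim$truth, sim$map, ref_peak_width = 12)
  sc <- map_scans(sim$map)
  expect_lt(max(abs(predict(mp, sc$rt) - sc$rt)), 2)
})

test_that("alignment recovers an ascending 0.8-1.2 scan-time distortion", {
  spec <- simulation_spec(n_peptides = 60, rt_range = c(150, 900),
                          snr = 20, seed = 9)
  sim <- simulate_reference_map(spec)
  target <- apply_rt_distortion(sim$map, 0.8, 1.2)
  mp <- align_map(sim$truth, target, ref_peak_width = 12)
  truth_rt <- distorted_rt_truth(sim$truth$rt_apex, sim$map, 0.8, 1.2)
  err <- predict(mp, sim$truth$rt_apex) - truth_rt
  expect_lt(mean(abs(err)), 3.3)
  expect_lt(sd(err), 8.5)
  expect_lte(mean(local_tolerance(mp, map_scans(sim$map)$rt)), 30)
})

test_that("candidate bands are denser on the true alignment than off it", {
  spec <- simulation_spec(n_peptides = 50, rt_range = c(150, 700),
                          snr = 20, seed = 10)
  sim <- simulate_reference_map(spec)
  target <- apply_rt_distortion(sim$map, 0.9, 1.1)
  cand <- find_alignment_candidates(sim$truth, target)
  truth_rt <- distorted_rt_truth(cand$rt_ref, sim$map, 0.9, 1.1)
  near <- abs(cand$rt_target - truth_rt) <= 25
  # density within the band vs. uniformly scattered background
  span <- diff(range(map_scans(target)$rt))
  band_rate <- sum(near) / 50
  bg_rate <- (sum(!near) / 50) * (50 / (span - 50))
  expect_gt(band_rate, 5 * bg_rate)
})
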
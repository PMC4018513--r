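tv_dist <- function(a, b) {
  n <- max(length(a), length(b))
  0.5 * sum(abs(c(a, numeric(n - length(a))) - c(b, numeric(n - length(b)))))
}

test_that("Gold deconvolution inverts the forward model on noise-free input", {
  nat <- averagine_pattern(1200, 1)
  for (k in c(0, 3, 9)) {
    d <- numeric(11); d[k + 1] <- 1
    obs <- deuterated_pattern(nat, d)
    rec <- gold_deconvolve(obs$intensities, nat, 10)
    expect_lt(tv_dist(rec$weights, d), 1e-3)
    expect_lt(abs(rec$centroid - k), 0.05)
  }
})

test_that("centroid is conserved through deconvolution", {
  nat <- averagine_pattern(2200, 2)
  set.seed(1)
  d <- runif(13); d <- d / sum(d)
  obs <- deuterated_pattern(nat, d)
  rec <- gold_deconvolve(obs$intensities, nat, 12)
  cen_y <- sum((seq_along(obs$intensities) - 1) * obs$intensities) /
    sum(obs$intensities)
  cen_nat <- sum((seq_along(nat$intensities) - 1) * nat$intensities) /
    sum(nat$intensities)
  expect_lt(abs(rec$centroid - (cen_y - cen_nat)), 0.05)
})

test_that("a planted bimodal distribution survives 2% noise with modes intact", {
  nat <- averagine_pattern(1200, 1)
  d <- numeric(11); d[1] <- 0.5; d[10] <- 0.5
  obs <- deuterated_pattern(nat, d)
  set.seed(7)
  y <- pmax(obs$intensities +
              rnorm(length(obs$intensities), 0, 0.02 * max(obs$intensities)), 0)
  rec <- gold_deconvolve(y, nat, 10)
  # modes at 0 and 9, each carrying substantial weight
  expect_gt(rec$weights[1], 0.3)
  expect_gt(rec$weights[10], 0.3)
  expect_lt(abs(rec$centroid - 4.5), 0.5)
  # never the single-state collapse failure mode
  expect_lt(max(rec$weights), 0.95)
})

test_that("smooth uptake distributions are recovered with spread intact", {
  nat <- averagine_pattern(1500, 1)
  d <- binomial_deuteration(12, 60, 0.01)
  obs <- deuterated_pattern(nat, d)
  rec <- gold_deconvolve(obs$intensities, nat, 12)
  expect_lt(tv_dist(rec$weights, d), 0.05)
  expect_gte(sum(rec$weights >= 0.05), 3)  # spread, not a single spike
})

test_that("every returned distribution is normalized and non-negative", {
  nat <- averagine_pattern(900, 1)
  set.seed(2)
  for (tr in 1:5) {
    d <- runif(8); d <- d / sum(d)
    y <- pmax(deuterated_pattern(nat, d)$intensities + rnorm(12, 0, 0.01), 0)
    rec <- gold_deconvolve(y, nat, 7)
    expect_true(all(rec$weights >= 0))
    expect_equal(sum(rec$weights), 1, tolerance = 1e-9)
    expect_equal(length(rec$weights), 8L)
  }
  expect_error(gold_deconvolve(numeric(5), nat, 4), "all-zero")
})

test_that("centroids follow the weighted-mean definition", {
  expect_equal(unname(deuteration_centroid(c(1, 0, 0))["deuterons"]), 0)
  expect_equal(unname(deuteration_centroid(rep(1, 11))["deuterons"]), 5)
  expect_equal(unname(deuteration_centroid(
    c(0.5, rep(0, 8), 0.5))["deuterons"]), 4.5)
  expect_equal(unname(deuteration_centroid(c(0.5, 0.5))["da"]),
               0.5 * 1.006277)
})

test_that("back-exchange correction is the Zhang-Smith ratio", {
  full <- 10 * 1.006277 * 0.7  # 70% recovery control
  expect_equal(back_exchange_correct(full, full, 10)$deuterons, 10)
  expect_equal(back_exchange_correct(0, full, 10)$deuterons, 0)
  expect_equal(back_exchange_correct(full / 2, full, 6)$deuterons, 3)
  un <- back_exchange_correct(3 * 1.006277, NA, 6)
  expect_false(un$corrected)
  expect_equal(un$deuterons, 0.5)
  expect_warning(over <- back_exchange_correct(full * 1.1, full, 10),
                 "exceeds")
  expect_true(over$flagged)
})

test_that("envelope extraction matches the planted deuterated signal", {
  spec <- simulation_spec(n_peptides = 6, rt_range = c(100, 300),
                          snr = 30, seed = 12)
  ref <- simulate_reference_map(spec)
  dists <- lapply(seq_len(nrow(ref$truth)), function(i)
    binomial_deuteration(ref$truth$n_exchangeable[i], 60, 0.01))
  dm <- simulate_deuterated_map(ref, dists, noise_seed = 77)
  for (i in 1:3) {
    frow <- ref$truth[i, ]
    env <- extract_envelope(dm$map, frow, NULL, frow$n_exchangeable)
    expect_s3_class(env, "observed_envelope")
    nat <- isotope_pattern(peptide_composition(frow$sequence), frow$charge,
                           mono_mz = mass_to_mz(frow$mono_mass, frow$charge))
    truthd <- deuterated_pattern(nat, dists[[i]])$intensities
    got <- env$intensities / max(env$intensities)
    n <- min(length(got), length(truthd))
    strong <- truthd[1:n] > 0.2
    expect_lt(max(abs(got[1:n][strong] - truthd[1:n][strong])), 0.2)
  }
})

test_that("absent features and out-of-range windows are rejected with reasons", {
  spec <- simulation_spec(n_peptides = 3, rt_range = c(100, 200),
                          snr = 20, seed = 13)
  ref <- simulate_reference_map(spec)
  ghost <- tibble::tibble(mono_mass = 1234.567, charge = 2L,
                          rt_start = 120, rt_end = 150)
  r1 <- extract_envelope(ref$map, ghost, NULL, 10)
  expect_s3_class(r1, "envelope_rejection")

  outside <- tibble::tibble(mono_mass = ref$truth$mono_mass[1],
                            charge = ref$truth$charge[1],
                            rt_start = 500, rt_end = 600)
  r2 <- extract_envelope(ref$map, outside, NULL, 10)
  expect_s3_class(r2, "envelope_rejection")
  expect_match(r2$reason, "outside")
})
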
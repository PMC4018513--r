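#' Specification of a synthetic HDX LC-MS experiment
#'
#' Collects the study conditions of the synthetic-data generator. Defaults
#' emulate a 20-min acetonitrile gradient sampled at 0.5 Hz on a
#' high-resolution TOF instrument: scans every 2 s over 200-1400 s, Gaussian
#' elution profiles, exact-formula isotope envelopes, ~4/3 ppm m/z jitter
#' (instrument precision 4 ppm), and sparse exponential-intensity background
#' peaks.
#'
#' @param protein Protein sequence string, or NULL to simulate one.
#' @param protein_length Length of the simulated protein when `protein` is
#'   NULL.
#' @param n_peptides Number of peptide features to plant.
#' @param rt_range Retention-time range (s).
#' @param scan_interval Scan spacing (s).
#' @param elution_sd Gaussian elution profile SD (s).
#' @param snr Signal-to-noise: intensity noise SD = abundance / snr.
#' @param calibration_error_ppm Global multiplicative m/z error.
#' @param mz_jitter_ppm Per-peak Gaussian m/z jitter SD (ppm).
#' @param charge_range Charge states sampled for planted peptides.
#' @param mz_range Observable m/z range (Th).
#' @param background_peaks Background peaks per scan.
#' @param bg_mean_intensity Mean background intensity above the threshold
#'   (exponential).
#' @param intensity_threshold Acquisition intensity cutoff (counts): peaks
#'   below it are discarded, as instrument software does upstream.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters.
#' @param min_len,max_len Digest length bounds.
#' @param min_protease_score Features are drawn from digest peptides with at
#'   least this cleavage score (pepsin-plausible peptides; both termini cut
#'   at favored residues or protein ends). Relaxed automatically when the
#'   pool is too small.
#' @param seed Integer seed; every map is reproducible from (spec, seed).
#' @return Named list of class `simulation_spec`.
#' @export
simulation_spec <- function(protein = NULL, protein_length = 450L,
                            n_peptides = 100L, rt_range = c(200, 1400),
                            scan_interval = 2, elution_sd = 6, snr = 20,
                            calibration_error_ppm = 0, mz_jitter_ppm = 4 / 3,
                            charge_range = 1:3, mz_range = c(300, 1500),
                            background_peaks = 50L, bg_mean_intensity = 50,
                            intensity_threshold = 100,
                            abundance_meanlog = log(2000),
                            abundance_sdlog = 0.5,
                            min_len = 4L, max_len = 40L,
                            min_protease_score = 4, seed = 1L) {
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate a protein sequence
#'
#' Residues are drawn independently from vertebrate background amino-acid
#' frequencies; deterministic per seed.
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return Single-row protein tibble compatible with [read_fasta()] output.
#' @export
simulate_protein <- function(length, seed = 1L) {
  withr_seed(seed)
  sequence <- paste(sample(names(AA_FREQUENCY), length, replace = TRUE,
                           prob = AA_FREQUENCY), collapse = "")
  tibble(id = sprintf("synthetic_protein_%d", seed), sequence = sequence,
         modifications = list(tibble(position = integer(), delta = double())))
}

# local seed without clobbering the caller's RNG state
withr_seed <- function(seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  set.seed(seed)
}

# choose the planted peptide pool: cleavage-favored digest peptides that are
# observable at some charge in the configured m/z range
planted_pool <- function(digest, spec) {
  feasible <- purrr::map(digest$mono_mass, function(m) {
    z <- spec$charge_range
    z[mass_to_mz(m, z) >= spec$mz_range[1] & mass_to_mz(m, z) <= spec$mz_range[2]]
  })
  ok_mz <- lengths(feasible) > 0
  thr <- spec$min_protease_score
  repeat {
    pool <- which(ok_mz & digest$protease_score >= thr)
    if (length(pool) >= spec$n_peptides || thr <= min(digest$protease_score)) break
    thr <- thr - 2
  }
  list(pool = pool, feasible = feasible)
}

#' Simulate an undeuterated reference LC-MS map
#'
#' Plants `n_peptides` cleavage-favored digest peptides at random retention
#' times with Gaussian elution profiles and exact-formula isotope envelopes,
#' applies the global calibration error and per-peak m/z jitter, adds
#' Gaussian intensity noise (SD = abundance/snr) and uniform background
#' peaks, and returns the map together with the ground truth.
#'
#' @param spec A [simulation_spec()].
#' @return List: `map` (`lcms_map`), `truth` (tibble: feature, sequence,
#'   start, end, charge, mono_mass, n_exchangeable, protease_score, rt_apex,
#'   rt_start, rt_end, abundance, obs_mono_mass), `protein`, `spec`.
#' @export
simulate_reference_map <- function(spec = simulation_spec()) {
  withr_seed(spec$seed)
  protein <- if (is.null(spec$protein)) {
    simulate_protein(spec$protein_length, spec$seed)
  } else {
    tibble(id = "user_protein", sequence = toupper(spec$protein),
           modifications = list(tibble(position = integer(), delta = double())))
  }
  withr_seed(spec$seed + 1L)
  digest <- digest_unspecific(protein, spec$min_len, spec$max_len)
  pp <- planted_pool(digest, spec)
  n <- min(spec$n_peptides, length(pp$pool))
  picked <- if (length(pp$pool) == 1) pp$pool else sample(pp$pool, n)
  truth <- digest[picked, ]
  truth$charge <- vapply(pp$feasible[picked],
                         function(z) if (length(z) == 1) z else sample(z, 1), 0L)
  inset <- 3 * spec$elution_sd
  truth$rt_apex <- runif(n, spec$rt_range[1] + inset, spec$rt_range[2] - inset)
  truth$abundance <- exp(rnorm(n, spec$abundance_meanlog, spec$abundance_sdlog))
  truth$rt_start <- truth$rt_apex - 2 * spec$elution_sd
  truth$rt_end <- truth$rt_apex + 2 * spec$elution_sd
  patterns <- purrr::map(seq_len(n), function(i) {
    isotope_pattern(peptide_composition(truth$sequence[i]), truth$charge[i],
                    min_rel_intensity = 1e-3,
                    mono_mz = mass_to_mz(truth$mono_mass[i], truth$charge[i]))
  })
  built <- build_map(truth, patterns, spec)
  truth$feature <- seq_len(n)
  truth$obs_mono_mass <- built$obs_mono_mass
  list(map = built$map, truth = truth, protein = protein, spec = spec)
}

# shared peak synthesis for reference and deuterated maps
build_map <- function(truth, patterns, spec, noise_seed = spec$seed + 2L,
                      label = "") {
  withr_seed(noise_seed)
  rts <- seq(spec$rt_range[1], spec$rt_range[2], by = spec$scan_interval)
  scans <- tibble(scan = seq_along(rts), rt = rts)
  calib <- 1 + spec$calibration_error_ppm * 1e-6
  n <- nrow(truth)
  obs_mono_mass <- rep(NA_real_, n)
  pk <- vector("list", n + 1L)
  for (i in seq_len(n)) {
    p <- patterns[[i]]
    scan_idx <- which(abs(rts - truth$rt_apex[i]) <= 3.5 * spec$elution_sd)
    if (length(scan_idx) == 0) next
    height <- truth$abundance[i] *
      exp(-(rts[scan_idx] - truth$rt_apex[i])^2 / (2 * spec$elution_sd^2))
    theo_mz <- p$mono_mz + (seq_along(p$intensities) - 1L) * p$spacing
    grid <- tidyr::expand_grid(s = seq_along(scan_idx), j = seq_along(theo_mz))
    expected <- height[grid$s] * p$intensities[grid$j]
    # Poisson-like noise: variance proportional to expected intensity, scaled
    # so the apex peak has SD = abundance / snr
    int <- expected +
      rnorm(nrow(grid), 0, sqrt(expected * truth$abundance[i]) / spec$snr)
    mz <- theo_mz[grid$j] * calib *
      (1 + rnorm(nrow(grid), 0, spec$mz_jitter_ppm) * 1e-6)
    keep <- int >= spec$intensity_threshold
    pk[[i]] <- tibble(scan = scan_idx[grid$s][keep], mz = mz[keep],
                      intensity = int[keep])
    # observed mono m/z at the apex scan, for calibration ground truth
    apex_s <- which.min(abs(rts[scan_idx] - truth$rt_apex[i]))
    sel <- which(grid$s == apex_s & grid$j == 1L)
    obs_mz <- if (keep[sel]) mz[sel] else theo_mz[1] * calib
    obs_mono_mass[i] <- mz_to_mass(obs_mz, truth$charge[i])
  }
  nbg <- spec$background_peaks * length(rts)
  pk[[n + 1L]] <- tibble(
    scan = rep(seq_along(rts), each = spec$background_peaks),
    mz = runif(nbg, spec$mz_range[1], spec$mz_range[2]),
    intensity = spec$intensity_threshold + rexp(nbg, 1 / spec$bg_mean_intensity)
  )
  list(map = lcms_map(bind_rows(pk), scans = scans, label = label),
       obs_mono_mass = obs_mono_mass)
}

#' Apply a nonlinear retention-time distortion
#'
#' Scan i of n gets `rt * (lo + (hi - lo) * (i - 1)/(n - 1))`; peaks are
#' unchanged. `lo = hi = 1` is the identity.
#'
#' @param map An `lcms_map`.
#' @param lo,hi Multiplier range applied across the scans, ascending.
#' @return Distorted `lcms_map`.
#' @export
apply_rt_distortion <- function(map, lo, hi) {
  sc <- map_scans(map)
  nsc <- nrow(sc)
  mult <- if (nsc == 1) lo else lo + (hi - lo) * (seq_len(nsc) - 1) / (nsc - 1)
  sc$rt <- sc$rt * mult
  tb <- as_tibble(map)
  tb$rt <- NULL
  lcms_map(tb, scans = sc, label = paste0(map_label(map), " distorted"))
}

#' Distortion multiplier applied to a reference retention time
#'
#' Ground-truth mapping of [apply_rt_distortion()]: reference rt to distorted
#' rt, for computing alignment errors.
#'
#' @param rt Reference retention times (s).
#' @param map The (undistorted) reference `lcms_map`.
#' @param lo,hi Multiplier range given to [apply_rt_distortion()].
#' @return Distorted retention times.
#' @export
distorted_rt_truth <- function(rt, map, lo, hi) {
  sc <- map_scans(map)
  nsc <- nrow(sc)
  mult <- if (nsc == 1) rep(lo, 1) else lo + (hi - lo) * (seq_len(nsc) - 1) / (nsc - 1)
  approx(sc$rt, sc$rt * mult, xout = rt, rule = 2)$y
}

#' Simulate a deuterated LC-MS map
#'
#' Replaces each planted peptide's envelope by the forward model
#' [deuterated_pattern()] under the given per-peptide deuteration-state
#' distributions, re-using the reference's elution positions, charges and
#' abundances and the same noise machinery (fresh noise seed).
#'
#' @param reference Output of [simulate_reference_map()].
#' @param dists List of numeric weight vectors, one per truth row (index 1 =
#'   0 deuterons).
#' @param noise_seed Seed for this map's noise (default derived from the
#'   spec seed).
#' @param label Map label.
#' @return List: `map` (`lcms_map`), `dists` (the ground truth, normalized).
#' @export
simulate_deuterated_map <- function(reference, dists,
                                    noise_seed = reference$spec$seed + 101L,
                                    label = "deuterated") {
  truth <- reference$truth
  spec <- reference$spec
  stopifnot(length(dists) == nrow(truth))
  dists <- purrr::map(dists, ~ .x / sum(.x))
  patterns <- purrr::map(seq_len(nrow(truth)), function(i) {
    nat <- isotope_pattern(peptide_composition(truth$sequence[i]),
                           truth$charge[i], min_rel_intensity = 1e-3,
                           mono_mz = mass_to_mz(truth$mono_mass[i],
                                                truth$charge[i]))
    deuterated_pattern(nat, dists[[i]])
  })
  built <- build_map(truth, patterns, spec, noise_seed = noise_seed,
                     label = label)
  list(map = built$map, dists = dists)
}

#' Binomial deuteration ground truth
#'
#' Convenience generator of realistic uptake distributions: each of the N
#' exchangeable amides exchanges independently with probability
#' `1 - exp(-rate * time)`.
#'
#' @param n_exchangeable N.
#' @param time Incubation time (s).
#' @param rate Exchange rate constant (1/s).
#' @return Numeric weight vector of length N + 1.
#' @export
binomial_deuteration <- function(n_exchangeable, time, rate) {
  p <- 1 - exp(-rate * time)
  stats::dbinom(0:n_exchangeable, n_exchangeable, p)
}

#' Simulate a complete HDX experiment
#'
#' One undeuterated reference map plus deuterated maps for each incubation
#' time and replicate (binomial uptake truth with per-peptide log-normal
#' rates), and optionally a fully deuterated control.
#'
#' @param spec A [simulation_spec()].
#' @param times Incubation times (s).
#' @param n_replicates Replicates per time point.
#' @param rate_meanlog,rate_sdlog Log-normal per-peptide exchange-rate
#'   parameters (1/s).
#' @param full_control Simulate a fully deuterated control map (95%
#'   exchange)?
#' @return List: `reference` (map + truth), `deuterated` (tibble with time,
#'   replicate, map, dists), `control` (map or NULL), `rates`,
#'   `truth_centroids` (tibble feature x time with true centroids).
#' @export
simulate_hdx_experiment <- function(spec = simulation_spec(),
                                    times = c(15, 60, 300, 1200),
                                    n_replicates = 3L,
                                    rate_meanlog = log(0.01), rate_sdlog = 1,
                                    full_control = FALSE) {
  ref <- simulate_reference_map(spec)
  withr_seed(spec$seed + 7L)
  n <- nrow(ref$truth)
  rates <- exp(rnorm(n, rate_meanlog, rate_sdlog))
  deut <- tidyr::expand_grid(time = times, replicate = seq_len(n_replicates))
  maps <- vector("list", nrow(deut))
  dists_by_time <- purrr::map(times, function(tt) {
    purrr::map(seq_len(n), function(i)
      binomial_deuteration(ref$truth$n_exchangeable[i], tt, rates[i]))
  })
  names(dists_by_time) <- as.character(times)
  for (r in seq_len(nrow(deut))) {
    sim <- simulate_deuterated_map(
      ref, dists_by_time[[as.character(deut$time[r])]],
      noise_seed = spec$seed + 101L + 13L * r,
      label = sprintf("t%gs_rep%d", deut$time[r], deut$replicate[r]))
    maps[[r]] <- sim$map
  }
  deut$map <- maps
  deut$dists <- purrr::map(as.character(deut$time), ~ dists_by_time[[.x]])
  control <- NULL
  if (full_control) {
    ctrl_dists <- purrr::map(seq_len(n), function(i)
      stats::dbinom(0:ref$truth$n_exchangeable[i],
                    ref$truth$n_exchangeable[i], 0.95))
    control <- simulate_deuterated_map(ref, ctrl_dists,
                                       noise_seed = spec$seed + 997L,
                                       label = "full_control")
  }
  truth_centroids <- tidyr::expand_grid(feature = ref$truth$feature,
                                        time = times)
  truth_centroids$centroid <- purrr::map2_dbl(
    truth_centroids$feature, as.character(truth_centroids$time),
    function(f, tt) deuteration_centroid(dists_by_time[[tt]][[f]])[["deuterons"]])
  list(reference = ref, deuterated = deut, control = control, rates = rates,
       truth_centroids = truth_centroids)
}
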
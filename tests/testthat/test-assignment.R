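test_that("unspecific digestion enumerates every substring in range", {
  prot <- tibble::tibble(id = "p", sequence = "ACDEFGHIKL",
                         modifications = list(tibble::tibble(
                           position = integer(), delta = double())))
  dig <- digest_unspecific(prot, 5L, 20L)
  expect_equal(nrow(dig), 21L)  # 6+5+4+3+2+1
  L <- 10
  lens <- 5:10
  expect_equal(nrow(dig), sum(L - lens + 1))
  expect_equal(dig$mono_mass[dig$sequence == "ACDEF"],
               peptide_mono_mass("ACDEF"))
  expect_true(all(dig$end - dig$start + 1L == dig$length))
})

test_that("modifications shift only covering peptides", {
  prot <- tibble::tibble(id = "p", sequence = "ACDEFGHIKL",
                         modifications = list(tibble::tibble(
                           position = 3L, delta = 15.995)))
  dig <- digest_unspecific(prot, 4L, 6L)
  plain <- digest_unspecific("ACDEFGHIKL", 4L, 6L)
  covers <- dig$start <= 3 & dig$end >= 3
  expect_equal(dig$mono_mass[covers], plain$mono_mass[covers] + 15.995)
  expect_equal(dig$mono_mass[!covers], plain$mono_mass[!covers])
})

test_that("mass matching respects the ppm tolerance", {
  pep <- digest_unspecific("ACDEFGHIKLMNPQRSTVWY", 4L, 10L)
  target <- pep[10, ]
  feats <- tibble::tibble(feature = 1:2,
                          mono_mass = c(target$mono_mass,
                                        target$mono_mass * (1 + 8e-6)),
                          charge = 1L)
  asg <- match_sequences(feats, pep, ppm_tol = 4)
  hit1 <- asg[asg$feature == 1 & asg$sequence == target$sequence, ]
  expect_equal(nrow(hit1), 1L)
  expect_equal(hit1$ppm_error, 0, tolerance = 1e-9)
  expect_false(any(asg$feature == 2 & asg$sequence == target$sequence))
})

test_that("calibration offset is found by the densest-window mode", {
  set.seed(3)
  errs <- c(rnorm(60, 10, 0.5), runif(40, -30, 30))
  asg <- tibble::tibble(ppm_error = errs)
  cal <- fit_calibration(asg, precision_ppm = 4)
  expect_lt(abs(cal$ppm_offset - 10), 1)
  oracle <- densest_window_mode(errs, 8)
  expect_lt(abs(cal$ppm_offset - oracle), 1e-9)

  clean <- fit_calibration(tibble::tibble(ppm_error = rnorm(200, 0, 1)))
  expect_lt(abs(clean$ppm_offset), 0.5)

  sixteen <- fit_calibration(tibble::tibble(ppm_error = rnorm(100, 16, 1)))
  expect_lt(abs(sixteen$ppm_offset - 16), 0.5)

  expect_warning(few <- fit_calibration(tibble::tibble(ppm_error = 1:3)),
                 "skipping")
  expect_equal(few$ppm_offset, 0)
})

test_that("protease scoring favors pepsin cut sites and protein termini", {
  prot <- "AFGPLKWYAL"
  tab <- pepsin_score_table()
  best_cut <- max(tab$p1_score) + max(tab$p1prime_score)
  # peptide 3..8: N-cut after F (position 2), C-cut after W? position 8 is Y
  sc <- protease_score(3, 8, prot)
  expect_equal(sc, 2 + 2)  # F at P1 N-terminal, W at P1 C-terminal
  # whole protein: both termini maximally favorable
  expect_equal(protease_score(1, 10, prot), 2 * best_cut)
  # monotonicity: disfavored P1 never scores above favored P1
  sc_fav <- protease_score(3, 6, "AFGPLKAAAA")   # C-cut P1 = K (forbidden)
  expect_lte(sc_fav, protease_score(3, 6, "AFGPLLAAAA"))
})

test_that("scoring is invariant to residues away from the cut sites", {
  # cut-relevant positions for peptide 3..6 are 2, 3, 6 and 7; vary 4-5 and
  # the residues outside the flanks
  a <- protease_score(3, 6, "AFGGGGWYAL")
  b <- protease_score(3, 6, "AFGMMGWYAW")
  expect_equal(a, b)
})

test_that("target-decoy FDR is the decoy/target ratio clipped to [0,1]", {
  t10 <- tibble::tibble(feature = 1:100)
  expect_equal(estimate_fdr(t10, t10[0, ]), 0)
  expect_equal(estimate_fdr(t10, t10[1:10, ]), 0.10)
  expect_equal(estimate_fdr(t10, rbind(t10, t10)), 1)
  expect_true(is.na(estimate_fdr(t10[0, ], t10)))
})

test_that("random-mass features match a shuffled decoy about as often as the target", {
  set.seed(11)
  prot <- simulate_protein(200, 8)
  dig <- digest_unspecific(prot, 4L, 30L)
  decoy_dig <- digest_unspecific(decoy_protein(prot), 4L, 30L)
  feats <- tibble::tibble(feature = 1:5000,
                          mono_mass = runif(5000, 500, 2500), charge = 1L)
  tgt <- match_sequences(feats, dig, 4)
  dcy <- match_sequences(feats, decoy_dig, 4)
  fdr <- estimate_fdr(tgt, dcy)
  expect_gt(fdr, 0.5)  # random masses: decoy matches as often as target
})

test_that("injected calibration errors are recovered within 2 ppm", {
  for (cerr in c(4, 16, 24)) {
    spec <- simulation_spec(protein_length = 300L, n_peptides = 150L,
                            calibration_error_ppm = cerr, seed = 40 + cerr)
    sim <- simulate_reference_map(spec)
    feats <- sim$truth
    feats$mono_mass <- feats$obs_mono_mass
    digest <- digest_unspecific(sim$protein, 4L, 40L)
    asg <- assign_sequences(feats, digest, precision_ppm = 4)
    expect_lt(abs(asg$calibration$ppm_offset - cerr), 2)
  }
})
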
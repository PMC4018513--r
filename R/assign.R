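#' Default pepsin cleavage score table
#'
#' Editable qualitative pepsin specificity ranking: strongly favored P1
#' residues (F, L, W, Y, M) score +2, forbidden P1 residues (H, K, R, P)
#' score -4, proline is penalized in P1' (-4), everything else is neutral
#' (0). A user table read with [read_score_table()] overrides these values.
#'
#' @return Tibble with columns residue, p1_score, p1prime_score.
#' @export
pepsin_score_table <- function() {
  tb <- tibble(residue = AMINO_ACIDS, p1_score = 0, p1prime_score = 0)
  tb$p1_score[tb$residue %in% c("F", "L", "W", "Y", "M")] <- 2
  tb$p1_score[tb$residue %in% c("H", "K", "R", "P")] <- -4
  tb$p1prime_score[tb$residue == "P"] <- -4
  tb
}

#' Unspecific in-silico digestion
#'
#' Enumerates every substring of the protein with length between `min_len`
#' and `max_len`, with 1-based inclusive positions, monoisotopic mass,
#' exchangeable-amide count and protease cleavage score. Modifications
#' declared on the protein shift the mass of every peptide covering their
#' position.
#'
#' @param protein One row of a [read_fasta()] tibble (or a list with
#'   `sequence` and optional `modifications`).
#' @param min_len,max_len Peptide length bounds (defaults 4 and 40).
#' @param score_table Protease score table (default [pepsin_score_table()]).
#' @return Tibble: sequence, start, end, length, mono_mass, n_exchangeable,
#'   protease_score.
#' @export
digest_unspecific <- function(protein, min_len = 4L, max_len = 40L,
                              score_table = pepsin_score_table()) {
  if (max_len < min_len || min_len < 1) abort("need max_len >= min_len >= 1")
  seqchr <- if (is.character(protein)) protein else protein$sequence
  if (is_tibble(protein) && nrow(protein) != 1) abort("pass exactly one protein")
  seqchr <- toupper(seqchr[[1]])
  res <- strsplit(seqchr, "")[[1]]
  L <- length(res)
  mods <- NULL
  if (!is.character(protein) && !is.null(protein$modifications)) {
    mods <- protein$modifications
    if (is.list(mods) && !is.data.frame(mods)) mods <- mods[[1]]
  }
  mod_at <- numeric(L)
  if (!is.null(mods) && nrow(mods) > 0) mod_at[mods$position] <- mods$delta
  cum_mass <- c(0, cumsum(RESIDUE_MASS[res] + mod_at))
  is_pro <- as.integer(res == "P")
  cum_pro <- c(0, cumsum(is_pro))

  lens <- min_len:min(max_len, L)
  if (length(lens) == 0 || min_len > L) {
    return(tibble(sequence = character(), start = integer(), end = integer(),
                  length = integer(), mono_mass = double(),
                  n_exchangeable = integer(), protease_score = double()))
  }
  starts <- unlist(lapply(lens, function(l) seq_len(L - l + 1L)))
  lengths <- rep(lens, times = L - lens + 1L)
  ends <- starts + lengths - 1L
  mono <- unname(cum_mass[ends + 1L] - cum_mass[starts]) + WATER_MASS
  # prolines at positions 2..length of the peptide = prolines in [start+1, end]
  n_pro_internal <- cum_pro[ends + 1L] - cum_pro[starts + 1L]
  n_exch <- lengths - 1L - n_pro_internal

  sc <- protease_score_positions(starts, ends, res, score_table)
  seqs <- vapply(seq_along(starts),
                 function(i) substr(seqchr, starts[i], ends[i]), "")
  tibble(sequence = seqs, start = starts, end = ends, length = lengths,
         mono_mass = mono, n_exchangeable = as.integer(n_exch),
         protease_score = sc)
}

# Vectorized cleavage scoring over start/end positions. Protein termini count
# as maximally favorable cuts (the table's best attainable cut score).
protease_score_positions <- function(starts, ends, res, score_table) {
  L <- length(res)
  p1 <- setNames(score_table$p1_score, score_table$residue)
  p1p <- setNames(score_table$p1prime_score, score_table$residue)
  lookup <- function(tab, r) {
    v <- unname(tab[r])
    miss <- is.na(v)
    if (any(miss)) {
      warn(paste0("residue(s) absent from score table: ",
                  paste(unique(r[miss]), collapse = ", "), "; scored 0"))
      v[miss] <- 0
    }
    v
  }
  best_cut <- max(p1) + max(p1p)
  n_cut <- ifelse(starts == 1L, best_cut,
                  lookup(p1, res[pmax(starts - 1L, 1L)]) + lookup(p1p, res[starts]))
  c_cut <- ifelse(ends == L, best_cut,
                  lookup(p1, res[ends]) + lookup(p1p, res[pmin(ends + 1L, L)]))
  unname(n_cut + c_cut)
}

#' Protease cleavage score of one peptide
#'
#' Sum of the N-terminal cut score (P1 = residue before the peptide, P1' =
#' first peptide residue) and the C-terminal cut score (P1 = last peptide
#' residue, P1' = residue after it). Protein termini count as maximally
#' favorable cuts.
#'
#' @param start,end 1-based inclusive positions of the peptide.
#' @param protein Protein row or sequence string.
#' @param score_table Score table (default pepsin).
#' @return Numeric score.
#' @export
protease_score <- function(start, end, protein, score_table = pepsin_score_table()) {
  seqchr <- if (is.character(protein)) protein[[1]] else protein$sequence[[1]]
  res <- strsplit(toupper(seqchr), "")[[1]]
  protease_score_positions(start, end, res, score_table)
}

#' Match features to candidate peptides by mass
#'
#' Every (feature, peptide) pair whose relative mass difference is within
#' `ppm_tol` is reported; features may receive multiple assignments.
#' MS/MS-confirmed peptides are flagged; unconfirmed matches are kept.
#'
#' @param features Feature tibble (needs feature, mono_mass columns; charge
#'   and rt_apex carried through if present).
#' @param peptides Digest tibble from [digest_unspecific()].
#' @param ppm_tol Match tolerance in ppm.
#' @param confirmed Optional tibble from [read_peptide_list()]; peptides with
#'   matching sequence (and start, when given) are flagged `confirmed`.
#' @return Assignment tibble: feature columns plus sequence, start, end,
#'   n_exchangeable, protease_score, peptide_mass, ppm_error, confirmed.
#' @export
match_sequences <- function(features, peptides, ppm_tol = 4,
                            confirmed = NULL) {
  pep <- arrange(peptides, .data$mono_mass)
  fm <- features$mono_mass
  lo <- findInterval(fm * (1 - ppm_tol * 1e-6), pep$mono_mass)
  hi <- findInterval(fm * (1 + ppm_tol * 1e-6), pep$mono_mass)
  rows <- purrr::map_dfr(seq_along(fm), function(i) {
    if (hi[i] <= lo[i]) return(NULL)
    idx <- (lo[i] + 1L):hi[i]
    out <- pep[idx, ]
    out$feature_row <- i
    out
  })
  if (nrow(rows) == 0) {
    out <- features[0, ]
    out$sequence <- character()
    return(out)
  }
  fcols <- features[rows$feature_row,
                    intersect(c("feature", "mono_mass", "charge", "rt_apex",
                                "rt_start", "rt_end", "abundance"),
                              names(features))]
  names(fcols)[names(fcols) == "mono_mass"] <- "feature_mass"
  out <- dplyr::bind_cols(fcols, rename(rows, peptide_mass = "mono_mass"))
  out$feature_row <- NULL
  out$ppm_error <- (out$feature_mass - out$peptide_mass) / out$peptide_mass * 1e6
  out$confirmed <- FALSE
  if (!is.null(confirmed) && nrow(confirmed) > 0) {
    out$confirmed <- out$sequence %in% confirmed$sequence[is.na(confirmed$start)] |
      paste(out$sequence, out$start) %in%
        paste(confirmed$sequence, confirmed$start)[!is.na(confirmed$start)]
  }
  out
}

#' Internal m/z recalibration from assignment mass errors
#'
#' Estimates a single global ppm offset as the dominant mass error: the
#' center of the densest fixed-width window (width = 2 x instrument
#' precision) over all candidate ppm errors, refined as the median error
#' inside that window. True assignments pile up at the calibration offset
#' while false ones scatter uniformly, so a mode estimator is robust where a
#' mean is not.
#'
#' @param assignments Assignment tibble with a `ppm_error` column (wide-pass
#'   matches).
#' @param precision_ppm Instrument precision (window half-width), default 4.
#' @param min_n Minimum number of matches required (default 30); below it an
#'   identity calibration is returned with a warning.
#' @return List of class `calibration_model`: `ppm_offset`, `n_support`.
#' @export
fit_calibration <- function(assignments, precision_ppm = 4, min_n = 30) {
  err <- sort(assignments$ppm_error)
  if (length(err) < min_n) {
    warn(sprintf("only %d assignments; skipping recalibration", length(err)))
    return(structure(list(ppm_offset = 0, n_support = length(err)),
                     class = "calibration_model"))
  }
  width <- 2 * precision_ppm
  # densest window: for each error as left edge, count errors within width
  hi <- findInterval(err + width, err)
  counts <- hi - seq_along(err) + 1L
  best <- which.max(counts)
  inside <- err[err >= err[best] & err <= err[best] + width]
  offset <- median(inside)
  if (abs(offset) >= 100) {
    warn("estimated calibration offset exceeds 100 ppm; ignoring it")
    return(structure(list(ppm_offset = 0, n_support = length(err)),
                     class = "calibration_model"))
  }
  structure(list(ppm_offset = offset, n_support = length(inside)),
            class = "calibration_model")
}

#' Apply a calibration model to feature masses
#'
#' @param features Feature tibble with `mono_mass`.
#' @param calibration A `calibration_model`.
#' @return Features with corrected `mono_mass` (original kept as
#'   `mono_mass_raw`).
#' @export
apply_calibration <- function(features, calibration) {
  out <- features
  out$mono_mass_raw <- out$mono_mass
  out$mono_mass <- out$mono_mass / (1 + calibration$ppm_offset * 1e-6)
  out
}

#' Two-pass sequence assignment with internal recalibration
#'
#' A wide first pass (default 30 ppm) collects candidate matches from which
#' the global calibration offset is estimated ([fit_calibration()]); features
#' are recalibrated and re-matched at the strict instrument precision.
#' Assignments per feature are ranked by MS/MS confirmation, protease score,
#' then |ppm error|.
#'
#' @param features Feature tibble.
#' @param peptides Digest tibble.
#' @param precision_ppm Strict (instrument) tolerance, default 4 ppm.
#' @param wide_ppm Wide bootstrap tolerance for calibration, default 30 ppm.
#' @param recalibrate Estimate and apply the internal calibration?
#' @param confirmed Optional MS/MS peptide list tibble.
#' @return List: `assignments` (ranked tibble), `calibration`
#'   (`calibration_model`), `features` (recalibrated).
#' @export
assign_sequences <- function(features, peptides, precision_ppm = 4,
                             wide_ppm = 30, recalibrate = TRUE,
                             confirmed = NULL) {
  cal <- structure(list(ppm_offset = 0, n_support = 0L),
                   class = "calibration_model")
  feats <- features
  if (recalibrate) {
    wide <- match_sequences(features, peptides, wide_ppm, confirmed)
    cal <- fit_calibration(wide, precision_ppm)
    feats <- apply_calibration(features, cal)
  }
  asg <- match_sequences(feats, peptides, precision_ppm, confirmed)
  if (nrow(asg) > 0) {
    asg <- asg %>%
      group_by(.data$feature) %>%
      arrange(desc(.data$confirmed), desc(.data$protease_score),
              abs(.data$ppm_error), .by_group = TRUE) %>%
      mutate(rank = row_number()) %>%
      ungroup()
  }
  list(assignments = asg, calibration = cal, features = feats)
}

#' Target-decoy false discovery rate
#'
#' Decoy assignments come from matching the same features against the digest
#' of the reversed protein sequence with identical parameters;
#' FDR = n_decoy / n_target, clipped to [0, 1].
#'
#' @param assignments_target,assignments_decoy Assignment tibbles.
#' @return FDR fraction, or `NA` when there are no target assignments.
#' @export
estimate_fdr <- function(assignments_target, assignments_decoy) {
  nt <- nrow(assignments_target)
  if (nt == 0) return(NA_real_)
  min(1, nrow(assignments_decoy) / nt)
}

#' Reverse a protein for decoy matching
#'
#' @param protein Protein row or sequence string.
#' @return Single-row protein tibble with the reversed sequence.
#' @export
reverse_protein <- function(protein) {
  seqchr <- if (is.character(protein)) protein[[1]] else protein$sequence[[1]]
  revseq <- paste(rev(strsplit(seqchr, "")[[1]]), collapse = "")
  tibble(id = "decoy", sequence = revseq,
         modifications = list(tibble(position = integer(), delta = double())))
}

#' Build a decoy protein for FDR estimation
#'
#' For mass-only matching a reversed decoy is degenerate: every substring of
#' the reversed protein is the reverse of a forward substring and has exactly
#' the same mass, so reversal preserves the target mass spectrum under
#' unspecific digestion. The default decoy therefore shuffles the residues
#' (deterministically, seeded from the sequence itself), which preserves
#' amino-acid composition but scrambles substring masses.
#'
#' @param protein Protein row or sequence string.
#' @param method `"shuffle"` (default) or `"reverse"`.
#' @return Single-row decoy protein tibble.
#' @export
decoy_protein <- function(protein, method = c("shuffle", "reverse")) {
  method <- match.arg(method)
  if (method == "reverse") return(reverse_protein(protein))
  seqchr <- if (is.character(protein)) protein[[1]] else protein$sequence[[1]]
  res <- strsplit(seqchr, "")[[1]]
  seed <- sum(utf8ToInt(seqchr)) %% 100000L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  shuf <- sample(res)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  tibble(id = "decoy", sequence = paste(shuf, collapse = ""),
         modifications = list(tibble(position = integer(), delta = double())))
}
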
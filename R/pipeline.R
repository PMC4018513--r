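#' Build / validate a run configuration
#'
#' A run configuration names the input files (or in-memory objects) and
#' overrides module parameters. Accepts a YAML file path or a list with
#' fields:
#' \describe{
#'   \item{reference}{mzXML path or `lcms_map` (undeuterated reference).}
#'   \item{deuterated}{List of entries with `time` (s), `replicate`, and
#'     `path` or `map`.}
#'   \item{fasta}{FASTA path or protein tibble.}
#'   \item{msms_list}{Optional MS/MS peptide list path or tibble.}
#'   \item{control}{Optional fully deuterated control (path or map).}
#'   \item{output_dir}{Optional directory for results.csv and run.log.}
#'   \item{params}{Optional named lists `detect`, `align`, `deut`,
#'     `assign` overriding [detect_params()], [align_params()],
#'     [deut_params()] and assignment settings (`precision_ppm`, `wide_ppm`,
#'     `min_len`, `max_len`, `recalibrate`).}
#' }
#'
#' @param config Path to a YAML file or a list as above.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$reference)) abort("config: missing reference map")
  if (is.null(config$fasta)) abort("config: missing protein (fasta)")
  if (is.null(config$deuterated) || length(config$deuterated) == 0) {
    abort("config: no deuterated maps")
  }
  for (fld in c("reference", "fasta", "msms_list", "control")) {
    v <- config[[fld]]
    if (is.character(v) && !file.exists(v)) {
      abort(sprintf("config: %s path does not exist: %s", fld, v))
    }
  }
  times <- vapply(config$deuterated, function(d) as.numeric(d$time), 0)
  if (any(is.na(times)) || any(times <= 0)) {
    abort("config: incubation times must be strictly positive")
  }
  ord <- order(times, vapply(config$deuterated,
                             function(d) as.numeric(d$replicate %||% 1), 0))
  config$deuterated <- config$deuterated[ord]
  for (d in config$deuterated) {
    if (!is.null(d$path) && !file.exists(d$path)) {
      abort(paste0("config: deuterated map path does not exist: ", d$path))
    }
    if (is.null(d$path) && is.null(d$map)) {
      abort("config: each deuterated entry needs a path or a map")
    }
  }
  config$params <- config$params %||% list()
  structure(config, class = "run_config")
}

load_map <- function(x, label = "") {
  if (inherits(x, "lcms_map")) x else read_mzxml(x, label = label)
}

load_protein <- function(x) {
  if (is.character(x)) read_fasta(x)[1, ] else x[1, , drop = FALSE]
}

#' Run the complete HDX analysis workflow
#'
#' Stages, in order: de-novo feature detection in the reference map;
#' sequence assignment with internal recalibration and target-decoy FDR;
#' per deuterated map: retention-time alignment, envelope extraction, Gold
#' deconvolution and centroid computation (back-exchange corrected when a
#' control is configured); replicate merging (mean +/- SD per time point);
#' CSV export. Per-feature rejections are logged and never abort the run;
#' a stage failure aborts with the stage name.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return List of class `hdx_run`: `results` (per replicate rows), `merged`
#'   (per time point), `features`, `assignments`, `calibration`, `fdr`,
#'   `mappings`, `log` (character), `config`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  logline <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, msg)
    inform(msg)
  }
  p_detect <- do.call(detect_params, config$params$detect %||% list())
  p_align <- do.call(align_params, config$params$align %||% list())
  p_deut <- do.call(deut_params, config$params$deut %||% list())
  p_assign <- utils::modifyList(
    list(precision_ppm = 4, wide_ppm = 30, min_len = 4L, max_len = 40L,
         recalibrate = TRUE),
    config$params$assign %||% list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ref_map <- stage("load", load_map(config$reference, "reference"))
  protein <- stage("load", load_protein(config$fasta))
  confirmed <- if (!is.null(config$msms_list)) {
    if (is.character(config$msms_list)) read_peptide_list(config$msms_list)
    else config$msms_list
  } else NULL

  features <- stage("detect", detect_features(ref_map, p_detect))
  say("detect: %d features in reference map", nrow(features))

  digest <- stage("assign", digest_unspecific(protein, p_assign$min_len,
                                              p_assign$max_len))
  asg <- stage("assign", assign_sequences(features, digest,
                                          precision_ppm = p_assign$precision_ppm,
                                          wide_ppm = p_assign$wide_ppm,
                                          recalibrate = p_assign$recalibrate,
                                          confirmed = confirmed))
  decoy_digest <- digest_unspecific(decoy_protein(protein),
                                    p_assign$min_len, p_assign$max_len)
  decoy <- match_sequences(asg$features, decoy_digest, p_assign$precision_ppm)
  fdr <- estimate_fdr(asg$assignments, decoy)
  say("assign: %d assignments for %d features, offset %.2f ppm, FDR %.3f",
      nrow(asg$assignments), length(unique(asg$assignments$feature)),
      asg$calibration$ppm_offset, fdr)

  features <- asg$features
  best <- asg$assignments %>% filter(.data$rank == 1)
  # upper exchangeable bound per feature for alignment probing
  nex <- asg$assignments %>% group_by(.data$feature) %>%
    summarise(n_exchangeable = max(.data$n_exchangeable), .groups = "drop")
  features <- left_join(features, nex, by = "feature")
  features$n_exchangeable[is.na(features$n_exchangeable)] <-
    ceiling(features$mono_mass[is.na(features$n_exchangeable)] / AVERAGINE_UNIT_MASS)
  ref_peak_width <- median(features$rt_end - features$rt_start) / 2

  natural <- purrr::map(seq_len(nrow(best)), function(i) {
    isotope_pattern(peptide_composition(best$sequence[i]), best$charge[i],
                    min_rel_intensity = 1e-3,
                    mono_mz = mass_to_mz(best$peptide_mass[i], best$charge[i]))
  })

  process_map <- function(dmap, dlabel) {
    mapping <- align_map(features, dmap, ref_peak_width, p_align)
    rows <- purrr::map_dfr(seq_len(nrow(best)), function(i) {
      frow <- features[features$feature == best$feature[i], ]
      frow$mono_mass <- best$peptide_mass[i]  # assigned (exact) mass
      env <- extract_envelope(dmap, frow, mapping, best$n_exchangeable[i],
                              p_deut)
      if (inherits(env, "envelope_rejection")) {
        return(tibble(feature = best$feature[i], rejected = env$reason,
                      centroid = NA_real_, centroid_da = NA_real_,
                      distribution = list(NULL)))
      }
      dd <- gold_deconvolve(env, natural[[i]], best$n_exchangeable[i], p_deut)
      tibble(feature = best$feature[i], rejected = NA_character_,
             centroid = dd$centroid, centroid_da = dd$centroid_da,
             distribution = list(dd$weights))
    })
    nrej <- sum(!is.na(rows$rejected))
    if (nrej > 0) {
      say("%s: %d/%d envelopes rejected (%s)", dlabel, nrej, nrow(rows),
          paste(unique(stats::na.omit(rows$rejected)), collapse = "; "))
    }
    list(mapping = mapping, rows = rows)
  }

  # optional fully deuterated control
  control_centroid <- NULL
  if (!is.null(config$control)) {
    cmap <- stage("control", load_map(config$control, "control"))
    ctl <- stage("control", process_map(cmap, "control"))
    control_centroid <- ctl$rows %>%
      select(feature = "feature", centroid_da_full = "centroid_da")
  }

  mappings <- list()
  res <- list()
  for (d in config$deuterated) {
    dlabel <- sprintf("t%gs_rep%s", as.numeric(d$time), d$replicate %||% 1)
    dmap <- stage(dlabel, load_map(d$path %||% d$map, dlabel))
    pm <- stage(dlabel, process_map(dmap, dlabel))
    mappings[[dlabel]] <- pm$mapping
    rows <- pm$rows
    rows$time <- as.numeric(d$time)
    rows$replicate <- as.numeric(d$replicate %||% 1)
    res[[dlabel]] <- rows
  }
  res <- bind_rows(res)

  meta <- best %>%
    select("feature", "sequence", "start", "end", "charge",
           mono_mass = "peptide_mass", "n_exchangeable", "protease_score",
           "ppm_error", rt_ref = "rt_apex")
  results <- inner_join(meta, res, by = "feature")
  results$relative_deuteration <- results$centroid / results$n_exchangeable
  if (!is.null(control_centroid)) {
    results <- left_join(results, control_centroid, by = "feature")
    results$corrected_deuteration <- purrr::pmap_dbl(
      list(results$centroid_da, results$centroid_da_full,
           results$n_exchangeable),
      function(cd, cf, nn) {
        if (is.na(cd) || is.na(cf)) NA_real_
        else back_exchange_correct(cd, cf, nn)$deuterons
      })
  } else {
    results$corrected_deuteration <- NA_real_
  }

  merged <- results %>%
    filter(is.na(.data$rejected)) %>%
    group_by(.data$sequence, .data$start, .data$end, .data$charge, .data$time) %>%
    summarise(mean_centroid = mean(.data$centroid),
              sd_centroid = sd(.data$centroid),
              n = dplyr::n(), .groups = "drop")
  say("results: %d rows, %d peptide/charge/time groups merged",
      nrow(results), nrow(merged))

  out <- structure(list(results = results, merged = merged,
                        features = features, assignments = asg$assignments,
                        calibration = asg$calibration, fdr = fdr,
                        mappings = mappings, log = logline, config = config),
                   class = "hdx_run")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_csv(results, file.path(config$output_dir, "results.csv"))
    writeLines(logline, file.path(config$output_dir, "run.log"))
  }
  out
}

#' Filter pipeline results by quality rules
#'
#' Rules are applied conjunctively; removed rows are recorded in the
#' `filter_log` attribute with the first rule that removed them.
#'
#' @param results Results tibble (e.g. `run$results`).
#' @param min_protease_score Minimum cleavage score.
#' @param max_abs_ppm Maximum |assignment ppm error|.
#' @param max_replicate_sd Maximum per-(peptide, charge, time) centroid SD.
#' @param require_full_series Keep only peptides observed at every incubation
#'   time present in `results`.
#' @return Filtered tibble with attribute `filter_log`.
#' @export
filter_results <- function(results, min_protease_score = -Inf,
                           max_abs_ppm = Inf, max_replicate_sd = Inf,
                           require_full_series = FALSE) {
  out <- as_tibble(results)
  log <- character(0)
  drop_rows <- function(df, bad, why) {
    if (any(bad)) {
      log <<- c(log, sprintf("%d rows removed: %s", sum(bad), why))
    }
    df[!bad, ]
  }
  if ("rejected" %in% names(out)) {
    out <- drop_rows(out, !is.na(out$rejected), "envelope rejected")
  }
  out <- drop_rows(out, out$protease_score < min_protease_score,
                   "protease score below minimum")
  out <- drop_rows(out, abs(out$ppm_error) > max_abs_ppm,
                   "ppm error above maximum")
  if (is.finite(max_replicate_sd) && nrow(out) > 0) {
    sds <- out %>%
      group_by(.data$sequence, .data$start, .data$charge, .data$time) %>%
      mutate(.repsd = sd(.data$centroid)) %>% ungroup()
    out <- drop_rows(out, !is.na(sds$.repsd) & sds$.repsd > max_replicate_sd,
                     "replicate SD above maximum")
  }
  if (require_full_series && nrow(out) > 0) {
    all_times <- unique(results$time)
    full <- out %>% group_by(.data$sequence, .data$start, .data$charge) %>%
      mutate(.full = length(unique(.data$time)) == length(all_times)) %>%
      ungroup()
    out <- drop_rows(out, !full$.full, "incomplete time series")
  }
  attr(out, "filter_log") <- log
  out
}

#' @export
print.hdx_run <- function(x, ...) {
  cat(sprintf("<hdx_run> %d features, %d assignments, %d result rows, FDR %.3f\n",
              nrow(x$features), nrow(x$assignments), nrow(x$results), x$fdr))
  invisible(x)
}
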
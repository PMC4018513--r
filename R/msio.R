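#' Read a centroided mzXML file
#'
#' Reads MS1 line spectra from an mzXML file into an [lcms_map()]. MS2 and
#' higher-level scans are skipped. Retention times are normalized to seconds.
#' A profile-mode flag in the file triggers a warning; the data are accepted
#' as-is.
#'
#' @param path Path to an mzXML file.
#' @param label Optional map label; defaults to the file name.
#' @return An `lcms_map`.
#' @export
read_mzxml <- function(path, label = basename(path)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  # cheap profile-mode sniff: mzXML has no per-scan centroid flag, but some
  # converters record it as an attribute
  head_txt <- suppressWarnings(readLines(path, n = 50))
  if (any(grepl("centroided=\"0\"|profileType=\"profile\"", head_txt))) {
    warn("file appears to contain profile-mode spectra; treating peaks as centroids")
  }
  fh <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) abort(paste0("mzXML parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  keep <- which(hd$msLevel == 1)
  scans <- tibble(scan = seq_along(keep), rt = hd$retentionTime[keep])
  pk <- purrr::map_dfr(seq_along(keep), function(i) {
    m <- mzR::peaks(fh, keep[i])
    if (is.null(dim(m)) || nrow(m) == 0) {
      return(tibble(scan = integer(), mz = double(), intensity = double()))
    }
    tibble(scan = i, mz = unname(m[, 1]), intensity = unname(m[, 2]))
  })
  lcms_map(pk, scans = scans, label = label)
}

#' Write an LC-MS map as mzXML
#'
#' Writes a minimal valid mzXML 3.2 document with one `<scan>` per scan
#' (msLevel 1, base64 big-endian 64-bit m/z-intensity pairs). The output
#' round-trips through [read_mzxml()].
#'
#' @param map An `lcms_map`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mzxml <- function(map, path) {
  sc <- map_scans(map)
  con <- tryCatch(file(path, "w"), error = function(e)
    abort(paste0("cannot write ", path, ": ", conditionMessage(e))))
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf('<msRun scanCount="%d">', nrow(sc))
  ), con)
  if (nrow(sc) > 0) {
    pk_by_scan <- split(as_tibble(map)[, c("mz", "intensity")], factor(map$scan, levels = sc$scan))
    for (i in seq_len(nrow(sc))) {
      p <- pk_by_scan[[i]]
      b64 <- if (nrow(p) > 0) {
        v <- as.vector(rbind(p$mz, p$intensity))
        # base64_enc wraps lines; the peaks element must be a single token
        gsub("\n", "", jsonlite::base64_enc(writeBin(v, raw(), size = 8,
                                                     endian = "big")))
      } else ""
      writeLines(sprintf(
        paste0('<scan num="%d" msLevel="1" peaksCount="%d" retentionTime="PT%.6fS">\n',
               '<peaks precision="64" byteOrder="network" contentType="m/z-int" ',
               'compressionType="none" compressedLen="0">%s</peaks>\n</scan>'),
        i, nrow(p), sc$rt[i], b64), con)
    }
  }
  writeLines(c('</msRun>', '</mzXML>'), con)
  invisible(path)
}

#' Parse an ISO-8601 duration to seconds
#'
#' Handles the `PT<m>M<s>S` forms that appear in mzXML retentionTime
#' attributes.
#'
#' @param x Character vector of durations, e.g. `"PT629.5S"`, `"PT10M29.5S"`.
#' @return Numeric seconds.
#' @export
parse_iso8601_duration <- function(x) {
  vapply(x, function(d) {
    d <- sub("^PT", "", d)
    mins <- if (grepl("M", d)) as.numeric(sub("M.*$", "", d)) else 0
    d <- sub("^.*M", "", d)
    secs <- if (grepl("S", d)) as.numeric(sub("S$", "", d)) else 0
    60 * mins + secs
  }, 0, USE.NAMES = FALSE)
}

#' Read protein sequences from FASTA
#'
#' Record ids are taken from the header up to the first whitespace; sequences
#' are uppercased and validated against the 20 canonical residues.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `sequence`, and a `modifications`
#'   list-column (empty tibbles; fill in to declare fixed modifications as
#'   (position, mass delta) pairs).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) abort(paste0("FASTA parse error: ",
                                                   conditionMessage(e))))
  if (length(aas) == 0) abort("empty FASTA file")
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1)
  seqs <- toupper(as.character(aas))
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[i], "")[[1]]
    bad <- which(!res %in% AMINO_ACIDS)
    if (length(bad) > 0) {
      abort(sprintf("illegal residue '%s' at position %d of record '%s'",
                    res[bad[1]], bad[1], ids[i]))
    }
  }
  tibble(id = ids, sequence = unname(seqs),
         modifications = purrr::map(seq_along(ids), ~ tibble(position = integer(),
                                                             delta = double())))
}

#' Read an MS/MS-confirmed peptide list
#'
#' Plain text, one peptide per line: `SEQUENCE` or `SEQUENCE,START` with a
#' 1-based inclusive start position in the protein. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to the list.
#' @return Tibble with columns `sequence`, `start` (NA when absent).
#' @export
read_peptide_list <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ",")
  tibble(
    sequence = toupper(vapply(parts, `[`, "", 1)),
    start = vapply(parts, function(p) if (length(p) > 1) as.integer(p[2]) else NA_integer_,
                   integer(1))
  )
}

#' Read a protease cleavage score table
#'
#' CSV with columns `residue`, `p1_score` (score of the residue N-terminal to
#' a cut), `p1prime_score` (C-terminal to a cut).
#'
#' @param path CSV path.
#' @return Tibble with those three columns.
#' @export
read_score_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("residue", "p1_score", "p1prime_score") %in% names(tb)))
  tb
}

#' Write pipeline results as CSV
#'
#' One row per (peptide, charge, incubation time, replicate). The deuteration
#' distribution is serialized as semicolon-joined weights. Comma separator,
#' `.` decimal, UTF-8, header row.
#'
#' @param results Results tibble as produced by [run_pipeline()], with a
#'   `distribution` list-column of numeric weight vectors.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(results, path) {
  cols <- c("sequence", "start", "end", "charge", "mono_mass", "rt_ref",
            "time", "replicate", "centroid_da", "relative_deuteration",
            "corrected_deuteration", "distribution", "protease_score",
            "ppm_error")
  out <- as_tibble(results)
  for (cc in setdiff(cols, names(out))) out[[cc]] <- rep(NA, nrow(out))
  if (is.list(out$distribution)) {
    out$distribution <- vapply(out$distribution, function(w) {
      if (is.null(w) || all(is.na(w))) "" else paste(format(w, trim = TRUE, digits = 6),
                                                     collapse = ";")
    }, "")
  }
  readr::write_csv(out[, cols], path, na = "")
  invisible(path)
}
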
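#' Build a centroided LC-MS map
#'
#' An LC-MS map is stored as a long tibble of peaks with one row per
#' (scan, m/z, intensity) triple, carrying a scan table (scan index and
#' retention time in seconds, including peak-less scans) as an attribute.
#' Scans are strictly increasing in retention time; peaks are sorted by m/z
#' within each scan.
#'
#' @param peaks Tibble/data frame with columns `scan` (integer), `mz` (Th),
#'   `intensity` (counts). May have zero rows.
#' @param scans Tibble with columns `scan` and `rt` (seconds) covering every
#'   scan index referenced by `peaks`. If `NULL`, built from distinct
#'   `scan`/`rt` columns of `peaks` (which must then contain `rt`).
#' @param label Free-text label (e.g. incubation time, replicate).
#' @return A tibble of class `lcms_map` with columns scan, rt, mz, intensity.
#' @export
lcms_map <- function(peaks, scans = NULL, label = "") {
  peaks <- as_tibble(peaks)
  if (is.null(scans)) {
    if (!"rt" %in% names(peaks)) abort("`scans` missing and `peaks` has no rt column")
    scans <- distinct(peaks[, c("scan", "rt")])
  }
  scans <- arrange(as_tibble(scans[, c("scan", "rt")]), .data$scan)
  if (any(scans$rt < 0)) abort("retention times must be non-negative")
  if (nrow(scans) > 1 && any(diff(scans$rt) <= 0)) {
    abort("scan retention times must be strictly increasing")
  }
  if (nrow(peaks) > 0) {
    if (!all(peaks$scan %in% scans$scan)) abort("peaks reference unknown scans")
    if (any(peaks$mz <= 0)) abort("m/z values must be positive")
    if (any(peaks$intensity < 0)) abort("intensities must be non-negative")
  } else {
    peaks <- tibble(scan = integer(), mz = double(), intensity = double())
  }
  peaks$rt <- NULL
  peaks <- left_join(peaks, scans, by = "scan")
  peaks <- arrange(peaks, .data$scan, .data$mz)
  out <- peaks[, c("scan", "rt", "mz", "intensity")]
  attr(out, "scans") <- scans
  attr(out, "label") <- label
  class(out) <- c("lcms_map", class(out))
  out
}

#' Scan table of an LC-MS map
#'
#' @param map An `lcms_map`.
#' @return Tibble with columns scan, rt (one row per scan, peak-less scans
#'   included).
#' @export
map_scans <- function(map) {
  sc <- attr(map, "scans")
  if (is.null(sc)) sc <- distinct(as_tibble(map)[, c("scan", "rt")])
  sc
}

#' Label of an LC-MS map
#' @param map An `lcms_map`.
#' @return Character label.
#' @export
map_label <- function(map) attr(map, "label") %||% ""

#' Peaks of one scan
#' @param map An `lcms_map`.
#' @param scan_idx Scan index.
#' @return Tibble of peaks sorted by m/z.
#' @export
scan_peaks <- function(map, scan_idx) {
  as_tibble(map)[map$scan == scan_idx, , drop = FALSE]
}

#' @export
print.lcms_map <- function(x, ...) {
  sc <- map_scans(x)
  cat(sprintf("<lcms_map> %d scans, %d peaks, rt %.1f-%.1f s%s\n",
              nrow(sc), nrow(x),
              if (nrow(sc)) min(sc$rt) else NA, if (nrow(sc)) max(sc$rt) else NA,
              if (nzchar(map_label(x))) paste0(", label: ", map_label(x)) else ""))
  NextMethod()
}
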
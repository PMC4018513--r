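test_that("mzXML round trip preserves scans, retention times and peaks", {
  spec <- simulation_spec(n_peptides = 4, rt_range = c(100, 160),
                          background_peaks = 10L, seed = 2)
  sim <- simulate_reference_map(spec)
  f <- withr::local_tempfile(fileext = ".mzXML")
  write_mzxml(sim$map, f)
  m2 <- read_mzxml(f)
  expect_equal(nrow(map_scans(m2)), nrow(map_scans(sim$map)))
  expect_equal(map_scans(m2)$rt, map_scans(sim$map)$rt, tolerance = 1e-6)
  expect_equal(nrow(m2), nrow(sim$map))
  expect_equal(m2$mz, sim$map$mz, tolerance = 1e-9)
  expect_equal(m2$intensity, sim$map$intensity, tolerance = 1e-9)
})

test_that("an empty map writes valid mzXML with scanCount 0", {
  em <- lcms_map(data.frame(),
                 scans = tibble::tibble(scan = integer(), rt = double()))
  f <- withr::local_tempfile(fileext = ".mzXML")
  write_mzxml(em, f)
  expect_true(any(grepl('scanCount="0"', readLines(f))))
  back <- read_mzxml(f)
  expect_equal(nrow(map_scans(back)), 0L)
  expect_equal(nrow(back), 0L)
})

test_that("MS2 scans are skipped and ISO-8601 durations parse", {
  f <- withr::local_tempfile(fileext = ".mzXML")
  enc <- function(mz, int) {
    v <- as.vector(rbind(mz, int))
    gsub("\n", "", jsonlite::base64_enc(writeBin(v, raw(), size = 8,
                                                 endian = "big")))
  }
  scan <- function(num, lvl, rt, mz, int) sprintf(
    paste0('<scan num="%d" msLevel="%d" peaksCount="%d" retentionTime="%s">',
           '<peaks precision="64" byteOrder="network" contentType="m/z-int" ',
           'compressionType="none" compressedLen="0">%s</peaks></scan>'),
    num, lvl, length(mz), rt, enc(mz, int))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    '<msRun scanCount="3">',
    scan(1, 1, "PT10S", c(400.1, 401.1), c(10, 5)),
    scan(2, 2, "PT15S", 200.5, 99),
    scan(3, 1, "PT30S", 500.2, 7),
    '</msRun>', '</mzXML>'), f)
  m <- read_mzxml(f)
  expect_equal(nrow(map_scans(m)), 2L)
  expect_equal(map_scans(m)$rt, c(10, 30))
  expect_equal(m$mz[m$scan == 1], c(400.1, 401.1))
  expect_equal(parse_iso8601_duration(c("PT10.5S", "PT2M5S", "PT1M")),
               c(10.5, 125, 60))
})

test_that("FASTA reading validates and normalizes records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "PEPTIDE", ">p2", "acd", "efg"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$sequence, c("PEPTIDE", "ACDEFG"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "PEPTIDEX123"), bad)
  expect_error(suppressWarnings(read_fasta(bad)), "illegal residue|parse error")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty|parse")
})

test_that("peptide lists parse sequences with optional start positions", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "PEPTIDE", "acdef,12", ""), f)
  pl <- read_peptide_list(f)
  expect_equal(pl$sequence, c("PEPTIDE", "ACDEF"))
  expect_equal(pl$start, c(NA_integer_, 12L))
})

test_that("results CSV has the documented shape and distribution format", {
  f <- withr::local_tempfile(fileext = ".csv")
  empty <- tibble::tibble(sequence = character(), distribution = list())
  write_results_csv(empty, f)
  expect_equal(length(readLines(f)), 1L)  # header only

  res <- tibble::tibble(
    sequence = "PEPTIDE", start = 1L, end = 7L, charge = 1L,
    mono_mass = 799.36, rt_ref = 300, time = c(15, 60, 300, 1200),
    replicate = 1, centroid_da = 1:4 * 0.5, relative_deuteration = 0.1,
    corrected_deuteration = NA_real_,
    distribution = list(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)),
    protease_score = 4, ppm_error = 0.2)
  write_results_csv(res, f)
  tab <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$distribution[1], "0.5;0.5")
  expect_true(all(c("sequence", "start", "end", "charge", "centroid_da",
                    "protease_score", "ppm_error") %in% names(tab)))
})
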
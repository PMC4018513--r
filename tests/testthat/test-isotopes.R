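test_that("Averagine composition scales linearly from the unit", {
  unit <- averagine_composition(111.1254, round_composition = FALSE)
  expect_equal(unname(unit),
               c(4.9384, 7.7583, 1.3577, 1.4773, 0.0417), tolerance = 1e-12)
  ten <- averagine_composition(1111.254, round_composition = FALSE)
  expect_equal(unname(ten), 10 * unname(unit), tolerance = 1e-9)
  expect_error(averagine_composition(-5), "positive")
})

test_that("rounded Averagine composition reproduces the target mass", {
  for (m in c(600, 1500, 3200)) {
    comp <- averagine_composition(m)
    expect_true(all(comp == round(comp)))
    got <- sum(hdxflow:::ELEMENT_MASS[names(comp)] * comp)
    expect_lt(abs(got - m), 1.1)  # within one hydrogen of the target
  }
})

test_that("isotope pattern of pure carbon matches the closed-form binomial", {
  pat <- isotope_pattern(c(C = 100, H = 0, N = 0, O = 0, S = 0),
                         charge = 1, min_rel_intensity = 1e-6)
  ref <- dbinom(0:(length(pat$intensities) - 1), 100, 0.0107)
  expect_equal(pat$intensities, ref / max(ref), tolerance = 1e-9)
})

test_that("a single hydrogen shows the natural deuterium abundance", {
  pat <- isotope_pattern(c(C = 0, H = 1, N = 0, O = 0, S = 0),
                         charge = 1, min_rel_intensity = 1e-6)
  expect_equal(pat$intensities[1], 1)
  expect_equal(pat$intensities[2], 0.000115 / 0.999885, tolerance = 1e-6)
})

test_that("patterns for exact peptide formulas match the enumeration oracle", {
  for (seqc in c("METMTNL", "LRVLID", "AMERDYETQREMETRYRVVL")) {
    comp <- peptide_composition(seqc)
    pat <- isotope_pattern(comp, charge = 1, min_rel_intensity = 1e-4)
    oracle <- enumerate_isotope_dist(as.list(comp))
    n <- min(length(pat$intensities), length(oracle))
    expect_equal(pat$intensities[1:n], oracle[1:n], tolerance = 0.01)
  }
})

test_that("pattern intensities are non-negative with finite sum", {
  pat <- averagine_pattern(2500, 2)
  expect_true(all(pat$intensities >= 0))
  expect_true(is.finite(sum(pat$intensities)))
  expect_equal(max(pat$intensities), 1)
})

test_that("exchangeable amide counting follows the backbone convention", {
  expect_equal(count_exchangeable_amides("METMTNL"), 6L)
  expect_equal(count_exchangeable_amides("LRVLID"), 5L)
  expect_equal(count_exchangeable_amides("APPA"), 1L)
  expect_equal(count_exchangeable_amides("A"), 0L)
})

test_that("deuterated pattern is the convolution forward model", {
  nat <- averagine_pattern(1000, 1)
  d0 <- deuterated_pattern(nat, c(1))
  expect_equal(d0$intensities, nat$intensities)

  dk <- deuterated_pattern(nat, c(0, 0, 0, 1))
  expect_equal(dk$intensities[4:(3 + length(nat$intensities))],
               nat$intensities)
  expect_true(all(dk$intensities[1:3] == 0))

  toy <- structure(list(mono_mz = 500, charge = 1L, intensities = c(1, 0.4),
                        spacing = 1.00335), class = "isotope_pattern")
  mixed <- deuterated_pattern(toy, c(0.5, 0.5))
  expect_equal(mixed$intensities * 0.7, c(0.5, 0.7, 0.2), tolerance = 1e-12)
})

test_that("predicted deuterated m/z grid covers deuteron/isotope combinations", {
  g0 <- predicted_deuterated_mz(500, 1, 0, max_isotopes = 2)
  expect_equal(nrow(g0), 3L)
  g1 <- predicted_deuterated_mz(500, 1, 5, max_isotopes = 2)
  g2 <- predicted_deuterated_mz(500, 2, 5, max_isotopes = 2)
  expect_equal(max(g2$mz) - 500, (max(g1$mz) - 500) / 2, tolerance = 1e-9)
  expect_true(all(diff(g1$mz) > 0))
  expect_true(all(g1$index == floor(g1$index) & g1$index >= 0))
})
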
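test_that("correction matrix reduces to identity without heavy isotopes", {
  opts <- correction_options(tracer_purity = 1,
                             natural_abundances = list(C = 1, H = 1, O = 1))
  M <- build_correction_matrix(ion_formula(), opts)
  expect_equal(unname(M), diag(3), tolerance = 1e-12)
})

test_that("matrix columns match brute-force isotope enumeration", {
  ab <- natural_abundances()
  counts <- c(C = 6, H = 11, O = 6)
  M <- build_correction_matrix(ion_formula(counts),
                               correction_options(tracer_purity = 1))
  expect_lt(max(abs(M[, 1] - oracle_isotopologue_dist(counts, ab, 2))), 1e-10)
  # fully labelled species at purity 1: natural envelope of C6H9O6 shifted +2
  nat9 <- oracle_isotopologue_dist(c(C = 6, H = 9, O = 6), ab, 2)
  expect_lt(max(abs(M[, 3] - c(0, 0, nat9[1]))), 1e-10)

  # purity 0.99: impurity feeds the M+1 column of the labelled species
  M99 <- build_correction_matrix(ion_formula(counts),
                                 correction_options(tracer_purity = 0.99))
  expect_lt(max(abs(M99[, 3] - oracle_labeled_dist(counts, ab, 2, 0.99, 2))),
            1e-10)
  expect_lt(max(abs(M99[, 2] - oracle_labeled_dist(counts, ab, 1, 0.99, 2))),
            1e-10)
})

test_that("correction matrix is well-formed for realistic abundances", {
  M <- build_correction_matrix()
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(colSums(M) <= 1 + 1e-12))
  # each species' largest mass fraction sits at its own shift
  expect_true(all(apply(M, 2, which.max) == seq_len(ncol(M))))
})

test_that("spectrum length shorter than the tracer shift is rejected", {
  expect_error(build_correction_matrix(ion_formula(),
                                       correction_options(max_shift = 1)),
               "tracer shift exceeds spectrum length")
  expect_error(build_correction_matrix(ion_formula(c(C = 6, H = 1, O = 6))),
               "fewer")
})

test_that("noiseless spectra round-trip through the correction", {
  M <- build_correction_matrix()
  expect_equal(correct_spectrum(as.numeric(M %*% c(0.7, 0, 0.3)), M)$fractions,
               c(0.7, 0, 0.3), tolerance = 1e-8)
  set.seed(42)
  for (i in 1:50) {
    f <- stats::runif(3)
    f <- f / sum(f)
    got <- correct_spectrum(as.numeric(M %*% f), M)
    expect_lt(max(abs(got$fractions - f)), 1e-8)
    expect_lt(got$residual_norm, 0.2)  # truncation loss only
  }
})

test_that("correction handles normalisation, noise and degenerate input", {
  expect_equal(correct_spectrum(c(2, 0, 6), diag(3))$fractions, c(0.25, 0, 0.75))
  expect_error(correct_spectrum(c(0, 0, 0), diag(3)), "empty spectrum")
  expect_error(correct_spectrum(c(1, 0), diag(3)), "does not match")
  M <- build_correction_matrix()
  set.seed(7)
  f <- c(0.85, 0, 0.15)
  for (i in 1:20) {
    y <- as.numeric(M %*% f) * exp(stats::rnorm(3, 0, 0.03))
    got <- correct_spectrum(y, M)$fractions
    expect_true(all(got >= 0))
    expect_lt(max(abs(got - f)), 0.05)
  }
})

test_that("enrichment is the clipped M+2 fraction", {
  expect_equal(enrichment_from_fractions(c(1, 0, 0))$enrichment, 0)
  expect_equal(enrichment_from_fractions(c(0, 0, 1))$enrichment, 1)
  expect_equal(enrichment_from_fractions(c(0.6, 0.05, 0.35))$enrichment, 0.35)
  e <- enrichment_from_fractions(c(1.001, 0, -0.001))
  expect_equal(e$enrichment, 0)
  expect_equal(e$enrichment_raw, -0.001)
  expect_error(enrichment_from_fractions(c(0.5, 0.1, 0.1)), "sum to 1")
})

test_that("pre-injection samples show near-zero enrichment after correction", {
  co <- make_cohort(c(LFD = 6, HFD = 6), seed = 11)
  enr <- correct_table(co$ms_areas)
  base <- enr[enr$time_min == 0, ]
  expect_true(all(base$enrichment <= 0.01))
  # without correction the natural M+2 background remains visible
  raw <- correct_table(co$ms_areas, correction = FALSE)
  rawbase <- raw[raw$time_min == 0, ]
  expect_gt(mean(rawbase$enrichment), mean(base$enrichment))
})

test_that("correct_table validates its input schema", {
  expect_error(correct_table(data.frame(animal_id = "a", time_min = 0)),
               "missing column")
  bad <- data.frame(animal_id = "a", time_min = 0,
                    area_m0 = -1, area_m1 = 0, area_m2 = 0)
  expect_error(correct_table(bad), "non-negative")
})
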
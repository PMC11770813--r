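test_that("fasting is an exact steady state of the model", {
  p <- noiseless("LFD", glucose_dose_g_per_kg = 0, insulin_dose_U_per_kg = 0)
  s <- simulate_test(p, "ITT")
  expect_equal(s$true_unlabeled, rep(p$Gb, 6), tolerance = 1e-6)
  expect_equal(s$true_labeled, rep(0, 6))
  expect_equal(s$meas_glucose, rep(p$Gb, 6), tolerance = 1e-6)
})

test_that("true enrichment is a molar fraction and exogenous starts at zero", {
  co <- make_cohort(c(LFD = 4, HFD = 4), seed = 61)
  expect_true(all(co$truth$true_enrichment >= 0 & co$truth$true_enrichment <= 1))
  expect_true(all(co$truth$true_enrichment[co$truth$time_min == 0] == 0))
  expect_true(all(co$ms_areas[, c("area_m0", "area_m1", "area_m2")] >= 0))
})

test_that("labelled kinetics are blind to EGP parameters (no recirculation)", {
  base <- noiseless("LFD")
  alt <- noiseless("LFD", sI = 0.5, sG = 0.02, EGP0 = 9)
  for (mode in c("GTT", "ITT")) {
    a <- simulate_test(base, mode)
    b <- simulate_test(alt, mode)
    expect_equal(a$true_labeled, b$true_labeled, tolerance = 1e-6)
    expect_false(isTRUE(all.equal(a$true_unlabeled, b$true_unlabeled)))
  }
})

test_that("GTT insulin stays basal; ITT insulin rises and decays", {
  g <- simulate_test(noiseless("LFD"), "GTT")
  expect_equal(g$true_insulin_excess, rep(0, 6))
  i <- simulate_test(noiseless("LFD"), "ITT")
  expect_true(all(i$true_insulin_excess[-1] > 0))
  expect_true(is.na(i$meas_insulin_ugl[1]))   # ELISA panel is GTT-only
  expect_equal(g$meas_insulin_ugl, rep(g$params$ins_basal_ugl, 6))
})

test_that("stronger insulin-stimulated uptake shrinks exogenous exposure", {
  aocs <- vapply(c(0, 0.05, 0.15, 0.3, 0.6), function(ki) {
    s <- simulate_test(noiseless("LFD", kI = ki), "ITT")
    oracle_trapz(s$times, s$true_labeled)
  }, numeric(1))
  expect_true(all(diff(aocs) < 0))
})

test_that("stronger EGP suppression deepens the endogenous dip", {
  aocs <- vapply(c(0, 1, 3, 6, 12), function(si) {
    s <- simulate_test(noiseless("LFD", sI = si), "ITT")
    oracle_trapz(s$times, s$true_unlabeled - s$true_unlabeled[1])
  }, numeric(1))
  expect_true(all(diff(aocs) < 0))
})

test_that("cohort generation is deterministic and reproduces study sizes", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_cohort(c(LFD = 14, HFD = 15), seed = 62, dir = d1)
  make_cohort(c(LFD = 14, HFD = 15), seed = 62, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  man <- utils::read.csv(file.path(d1, "manifest.csv"))
  expect_equal(as.vector(table(man$group)[c("LFD", "HFD")]), c(14, 15))
  diff_seed <- make_cohort(c(LFD = 2, HFD = 2), seed = 63)
  same_seed <- make_cohort(c(LFD = 2, HFD = 2), seed = 63)
  expect_identical(diff_seed$glucometer, same_seed$glucometer)
})

test_that("HFD-like animals are hyperglycemic relative to LFD-like", {
  set.seed(64)
  for (r in 1:20) {
    co <- make_cohort(c(LFD = 6, HFD = 6), seed = sample.int(1e6, 1),
                      modes = "GTT")
    g0 <- co$glucometer[co$glucometer$time_min == 0, ]
    m <- tapply(g0$glucose_mgdl,
                co$manifest$group[match(g0$animal_id, co$manifest$animal_id)],
                mean)
    expect_gt(m[["HFD"]], m[["LFD"]])
  }
})

test_that("parameter and size validation", {
  expect_error(make_cohort(c(LFD = 0, HFD = 3)), ">= 1")
  expect_error(make_cohort(c(3, 3)), "named")
  expect_error(sim_params(Gb = -1), "Gb")
  expect_error(sim_params(k0 = -0.1), "non-negative")
  expect_error(sim_params(schedule = c(5, 10)), "start at 0")
  expect_error(sim_preset("chow"), "unknown preset")
})
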
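test_that("compact letters agree with the pairwise tests that made them", {
  set.seed(8)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    pm <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      pm[i, j] <- pm[j, i] <- stats::runif(1)
    alpha <- 0.05
    lt <- dgtt:::cld_letters(pm, alpha)
    share <- function(a, b)
      length(intersect(strsplit(lt[a], "")[[1]], strsplit(lt[b], "")[[1]])) > 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (pm[i, j] < alpha) expect_false(share(i, j))
      else expect_true(share(i, j))
    }
  }
})

test_that("factorial analysis validates its design", {
  co <- make_cohort(c(LFD = 4, HFD = 4), seed = 51)
  res <- analyze_cohort(co)
  # single group
  expect_error(factorial_aoc(res$aoc, transform(co$manifest, group = "LFD")),
               "at least 2 diet groups")
  # underfilled cell
  small <- res$aoc[res$aoc$animal_id != "LFD_01" |
                     res$aoc$test_mode != "ITT", ]
  expect_error(factorial_aoc(small, co$manifest), "once per test mode")
  m3 <- co$manifest[co$manifest$animal_id != "LFD_01", ]
  expect_error(factorial_aoc(res$aoc, m3), "absent from manifest")
  expect_error(factorial_aoc(res$aoc, co$manifest, alpha = 1.2), "alpha")
})

test_that("factorial output is complete and well-formed", {
  co <- make_cohort(c(LFD = 5, HFD = 5), seed = 52)
  res <- analyze_cohort(co)
  f <- factorial_aoc(res$aoc, co$manifest)
  s <- summary(f)
  expect_setequal(unique(s$outcome),
                  c("aoc_total", "aoc_exogenous", "aoc_endogenous"))
  expect_true(all(s$p >= 0 & s$p <= 1))
  cells <- f$outcomes$aoc_total$cells
  expect_equal(sum(cells$n), 20)
  expect_true(all(nchar(cells$letters) >= 1))
  expect_equal(nrow(f$outcomes$aoc_total$pairwise), 6)
  expect_output(print(f), "ME diet")
  # with a real insulin effect, the insulin main effect must be detected
  expect_lt(f$outcomes$aoc_total$p_values[["insulin"]], 0.01)
})

test_that("timepoint comparison rejects degenerate groups", {
  co <- make_cohort(c(LFD = 2, HFD = 1), seed = 53)
  res <- analyze_cohort(co)
  expect_error(timepoint_compare(res$partitioned, co$manifest, mode = "ITT"),
               "fewer than 2 animals")
  expect_error(timepoint_compare(res$partitioned, co$manifest, mode = "OGTT"),
               "no data")
  expect_error(timepoint_compare(res$partitioned, co$manifest, value = "nope"),
               "no such curve")
})

test_that("an early-only EGP suppression difference flags 10/15 min", {
  # groups identical except the speed of insulin action: fast vs slow
  # absorption concentrates the group difference at the early timepoints
  fast <- sim_preset("LFD", ka_ins = 0.50)
  slow <- sim_preset("LFD", ka_ins = 0.06)
  set.seed(54)
  flags <- matrix(0, 0, 5)
  for (r in 1:25) {
    co <- make_cohort(c(FAST = 8, SLOW = 8),
                      presets = list(FAST = fast, SLOW = slow),
                      seed = sample.int(1e6, 1), modes = "ITT")
    res <- analyze_cohort(co)
    tp <- timepoint_compare(res$partitioned, co$manifest, mode = "ITT")
    flags <- rbind(flags, tp$flag)
  }
  early <- mean(flags[, 1:2])   # 10, 15 min
  late <- mean(flags[, 4:5])    # 40, 50 min
  expect_gt(early, 0.5)
  expect_gt(early, late + 0.25)
})

test_that("the diet effect on GTT endogenous AOC is detectable at study size", {
  set.seed(55)
  hits <- logical(200)
  for (r in seq_along(hits)) {
    co <- make_cohort(c(LFD = 14, HFD = 15), seed = sample.int(1e6, 1),
                      modes = "GTT")
    res <- analyze_cohort(co)
    a <- merge(res$aoc, co$manifest[, c("animal_id", "group")], by = "animal_id")
    hits[r] <- stats::t.test(aoc_endogenous ~ group, data = a)$p.value < 0.05
  }
  expect_gt(mean(hits), 0.5)
})
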
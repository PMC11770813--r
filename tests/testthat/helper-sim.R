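# run the in-memory analysis chain on a simulated cohort
analyze_cohort <- function(cohort, correction = TRUE) {
  enr <- correct_table(cohort$ms_areas, correction = correction)
  part <- partition_table(cohort$glucometer, enr)
  list(enrichment = enr, partitioned = part, aoc = summarize_cohort(part))
}

# noiseless preset: all measurement noise and between-animal variability off
noiseless <- function(name = "LFD", ...) {
  sim_preset(name, cv_glucometer = 0, cv_ms = 0, cv_insulin = 0, bio_cv = 0,
             mass_sd_g = 0, ...)
}

# AOC summaries computed straight from simulator truth tables
truth_aoc <- function(cohort) {
  blocks <- split(cohort$truth,
                  list(cohort$truth$animal_id, cohort$truth$test_mode), drop = TRUE)
  out <- do.call(rbind, lapply(blocks, function(b) {
    b <- b[order(b$time_min), ]
    tot <- b$true_labeled + b$true_unlabeled
    data.frame(animal_id = b$animal_id[1], test_mode = b$test_mode[1],
               aoc_total = oracle_trapz(b$time_min, tot - tot[1]),
               aoc_exogenous = oracle_trapz(b$time_min, b$true_labeled),
               aoc_endogenous = oracle_trapz(b$time_min,
                                             b$true_unlabeled - b$true_unlabeled[1]),
               stringsAsFactors = FALSE)
  }))
  out[order(out$animal_id, out$test_mode), ]
}
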
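#' Kinetic and noise parameters for the cohort simulator
#'
#' One-compartment, two-species (labelled/unlabelled) glucose kinetics with
#' insulin action, plus the full measurement model (glucometer noise, MS
#' areas convolved with natural isotope abundance, ELISA noise). Defaults
#' describe a chow-fed ("LFD-like") mouse; see [sim_preset()] for the
#' high-fat preset. Insulin is tracked as excess over basal in units of
#' U/kg lean mass, so a full ITT bolus contributes a depot of
#' `insulin_dose_U_per_kg`; `insulin_ugl_per_unit` is the conversion hook to
#' the ELISA scale (ug/L) for the measured insulin column.
#'
#' @param ka_depot IP depot absorption rate (/min).
#' @param Vd Glucose distribution volume (dL per kg lean mass).
#' @param k0 Basal (insulin-independent) fractional glucose uptake (/min).
#' @param kI Insulin-stimulated uptake (/min per insulin unit above basal).
#' @param EGP0 Basal endogenous glucose production (mg/dL/min); default
#'   `k0 * Gb`, which makes the fasting state an exact steady state.
#' @param sI Insulin sensitivity of EGP suppression (per insulin unit).
#' @param sG Glucose self-suppression of EGP (per mg/dL above `Gb`).
#' @param Gb Fasting blood glucose (mg/dL).
#' @param ka_ins,ke_ins Insulin absorption and clearance rates (/min).
#' @param ins_basal_ugl Basal plasma insulin on the ELISA scale (ug/L).
#' @param insulin_ugl_per_unit ELISA ug/L per internal insulin unit.
#' @param glucose_dose_g_per_kg,insulin_dose_U_per_kg Doses per kg lean mass.
#' @param cv_glucometer,cv_ms,cv_insulin Measurement coefficients of
#'   variation (glucometer additive-proportional Normal; MS areas and ELISA
#'   multiplicative log-normal, which keeps them positive).
#' @param bio_cv Between-animal log-normal coefficient of variation applied
#'   to the kinetic rates (and, halved, to `Gb`) when building cohorts.
#' @param body_mass_g,lean_mass_g,mass_sd_g Cohort body-composition means and
#'   between-animal SD (g).
#' @param ms_scale Arbitrary MS intensity scale (area units per molar unit).
#' @param schedule Sampling times in minutes; first must be 0.
#' @return Object of class `dgtt_sim_params`.
#' @export
sim_params <- function(ka_depot = 0.07, Vd = 2.0, k0 = 0.02, kI = 0.15,
                       EGP0 = NULL, sI = 6.0, sG = 0.0045, Gb = 150,
                       ka_ins = 0.20, ke_ins = 0.04, ins_basal_ugl = 0.6,
                       insulin_ugl_per_unit = 2.0,
                       glucose_dose_g_per_kg = 0.5, insulin_dose_U_per_kg = 0.75,
                       cv_glucometer = 0.05, cv_ms = 0.05, cv_insulin = 0.10,
                       bio_cv = 0.12,
                       body_mass_g = 28, lean_mass_g = 22, mass_sd_g = 1.5,
                       ms_scale = 1e6,
                       schedule = c(0, 10, 15, 30, 40, 50)) {
  if (is.null(EGP0)) EGP0 <- k0 * Gb
  p <- list(ka_depot = ka_depot, Vd = Vd, k0 = k0, kI = kI, EGP0 = EGP0,
            sI = sI, sG = sG, Gb = Gb, ka_ins = ka_ins, ke_ins = ke_ins,
            ins_basal_ugl = ins_basal_ugl,
            insulin_ugl_per_unit = insulin_ugl_per_unit,
            glucose_dose_g_per_kg = glucose_dose_g_per_kg,
            insulin_dose_U_per_kg = insulin_dose_U_per_kg,
            cv_glucometer = cv_glucometer, cv_ms = cv_ms,
            cv_insulin = cv_insulin, bio_cv = bio_cv,
            body_mass_g = body_mass_g, lean_mass_g = lean_mass_g,
            mass_sd_g = mass_sd_g, ms_scale = ms_scale, schedule = schedule)
  if (is.na(Gb) || Gb <= 0) stop("fasting glucose Gb must be positive")
  rates <- c("ka_depot", "Vd", "k0", "kI", "EGP0", "sI", "sG", "ka_ins",
             "ke_ins", "cv_glucometer", "cv_ms", "cv_insulin", "bio_cv")
  for (r in rates) if (is.na(p[[r]]) || p[[r]] < 0)
    stop("parameter ", r, " must be non-negative")
  if (Vd <= 0) stop("distribution volume Vd must be positive")
  if (schedule[1] != 0 || any(diff(schedule) <= 0))
    stop("schedule must start at 0 and be strictly increasing")
  structure(p, class = "dgtt_sim_params")
}

#' Cohort presets for the simulator
#'
#' `"LFD-like"`: insulin-sensitive chow-fed phenotype (the [sim_params()]
#' defaults). `"HFD-like"`: five-weeks-of-high-fat phenotype — higher
#' fasting glucose (hence higher basal EGP), blunted insulin-stimulated
#' uptake and blunted EGP suppression by both insulin and glucose, heavier
#' body at similar lean mass. Presets encode qualitative phenotype
#' orderings, not any measured values.
#'
#' @param name Preset name (case-insensitive; `"LFD"`/`"HFD"` accepted).
#' @param ... Overrides passed to [sim_params()].
#' @return A `dgtt_sim_params` object.
#' @export
sim_preset <- function(name = c("LFD-like", "HFD-like"), ...) {
  key <- toupper(substr(name[1], 1, 3))
  base <- if (key == "LFD") list()
  else if (key == "HFD")
    list(Gb = 180, kI = 0.08, sI = 3.5, sG = 0.0015,
         body_mass_g = 38, lean_mass_g = 23)
  else stop("unknown preset: ", name[1])
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_params, base)
}

# default-ion correction matrix, computed once per session
.dgtt_cache <- new.env(parent = emptyenv())
default_correction_matrix <- function() {
  if (is.null(.dgtt_cache$M))
    .dgtt_cache$M <- build_correction_matrix(ion_formula(), correction_options())
  .dgtt_cache$M
}

sim_ode <- function(t, y, p) {
  A <- y[["Ins"]]                     # insulin excess over basal, U/kg lean
  upt <- p$k0 + p$kI * A
  egp <- p$EGP0 * exp(-p$sI * A - p$sG * (y[["Gl"]] + y[["Gu"]] - p$Gb))
  list(c(Dep = -p$ka_depot * y[["Dep"]],
         Gl = p$ka_depot * y[["Dep"]] / p$VdL - upt * y[["Gl"]],
         Gu = egp - upt * y[["Gu"]],
         Sdep = -p$ka_ins * y[["Sdep"]],
         Ins = p$ka_ins * y[["Sdep"]] - p$ke_ins * y[["Ins"]]))
}

#' Simulate one animal's tracer GTT or ITT
#'
#' Integrates the two-species glucose model and applies the measurement
#' model. Assumptions: tracer glucose, once taken up, never recirculates
#' (EGP produces only unlabelled glucose, and there is no labelled inflow
#' other than the IP depot); the IP glucose bolus does not trigger insulin
#' secretion, so in GTT mode insulin stays at basal; in ITT mode insulin and
#' tracer are co-injected at t = 0 and insulin follows first-order
#' absorption and clearance.
#'
#' @param params A [sim_params()] object.
#' @param mode `"GTT"` or `"ITT"`.
#' @param lean_mass_g Lean mass of the animal (defaults to the preset mean).
#' @param seed Optional seed for the measurement noise.
#' @return List of class `dgtt_sim` holding the truth (labelled/unlabelled
#'   concentrations, molar enrichment) and the measurements (glucometer
#'   totals, MS areas for M+0..M+2, ELISA insulin in GTT mode).
#' @export
simulate_test <- function(params, mode = c("GTT", "ITT"),
                          lean_mass_g = params$lean_mass_g, seed = NULL) {
  stopifnot(inherits(params, "dgtt_sim_params"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  p <- unclass(params)
  lean_kg <- lean_mass_g / 1000
  p$VdL <- p$Vd * lean_kg
  dose_mg <- p$glucose_dose_g_per_kg * lean_kg * 1000
  sdep0 <- if (mode == "ITT") p$insulin_dose_U_per_kg else 0
  y0 <- c(Dep = dose_mg, Gl = 0, Gu = p$Gb, Sdep = sdep0, Ins = 0)
  sol <- try(deSolve::lsoda(y0, p$schedule, sim_ode, p,
                            rtol = 1e-8, atol = 1e-8), silent = TRUE)
  if (inherits(sol, "try-error") || any(is.na(sol)))
    stop("ODE integration failed; parameters: ",
         paste(names(p), vapply(p, function(z) paste(signif(unlist(z), 4), collapse = ","),
                                ""), sep = "=", collapse = " "))
  Gl <- sol[, "Gl"]; Gu <- sol[, "Gu"]; A <- sol[, "Ins"]
  total <- Gl + Gu
  enr <- Gl / total
  nt <- length(p$schedule)

  meas_glucose <- total * (1 + stats::rnorm(nt, 0, p$cv_glucometer))
  M <- default_correction_matrix()
  areas <- t(vapply(seq_len(nt), function(i) {
    f <- c(1 - enr[i], 0, enr[i])
    as.numeric(p$ms_scale * (M %*% f)) * exp(stats::rnorm(3, 0, p$cv_ms))
  }, numeric(3)))
  colnames(areas) <- c("area_m0", "area_m1", "area_m2")
  ins_true_ugl <- p$ins_basal_ugl + p$insulin_ugl_per_unit * A
  meas_insulin <- if (mode == "GTT")
    ins_true_ugl * exp(stats::rnorm(nt, 0, p$cv_insulin)) else rep(NA_real_, nt)

  structure(list(mode = mode, times = p$schedule, lean_mass_g = lean_mass_g,
                 true_labeled = as.numeric(Gl), true_unlabeled = as.numeric(Gu),
                 true_enrichment = as.numeric(enr),
                 true_insulin_excess = as.numeric(A),
                 meas_glucose = as.numeric(meas_glucose), meas_areas = areas,
                 meas_insulin_ugl = as.numeric(meas_insulin), params = params),
            class = "dgtt_sim")
}

#' @export
print.dgtt_sim <- function(x, ...) {
  cat("<simulated ", x$mode, "> lean mass ", round(x$lean_mass_g, 1), " g\n", sep = "")
  print(data.frame(time_min = x$times,
                   labeled = round(x$true_labeled, 1),
                   unlabeled = round(x$true_unlabeled, 1),
                   enrichment = round(x$true_enrichment, 3),
                   glucometer = round(x$meas_glucose, 1)))
  invisible(x)
}

draw_animal_params <- function(preset) {
  # between-animal biological variability; EGP0 re-derived per animal so each
  # animal's fasting state is its own steady state
  cv <- preset$bio_cv
  tweak <- function(v, s = cv) v * exp(stats::rnorm(1, 0, s))
  p <- unclass(preset)
  for (nm in c("ka_depot", "k0", "kI", "sI", "sG")) p[[nm]] <- tweak(p[[nm]])
  p$Gb <- tweak(p$Gb, cv / 2)
  p$EGP0 <- p$k0 * p$Gb
  lean <- max(stats::rnorm(1, p$lean_mass_g, p$mass_sd_g), 5)
  body <- max(stats::rnorm(1, p$body_mass_g, p$mass_sd_g), lean)
  p$lean_mass_g <- lean
  p$body_mass_g <- body
  class(p) <- "dgtt_sim_params"
  p
}

#' Generate a synthetic tracer-GTT/ITT cohort
#'
#' Draws animals per group (body composition and kinetic parameters vary
#' between animals; each animal keeps its parameters across both tests, as
#' in the paired one-week-apart protocol), simulates every animal in every
#' test mode, and returns — or writes as CSV — exactly the tables the
#' analysis pipeline ingests, alongside ground-truth tables for recovery
#' tests. Fully deterministic given `seed`.
#'
#' @param n_per_group Named integer vector of animals per group, e.g.
#'   `c(LFD = 14, HFD = 15)`.
#' @param presets Named list of [sim_params()] objects, one per group;
#'   defaults to the LFD-like/HFD-like presets for groups named LFD/HFD.
#' @param seed Integer seed controlling everything.
#' @param dir Optional output directory; when given, writes `manifest.csv`,
#'   `glucometer.csv`, `ms_areas.csv`, `truth_curves.csv`,
#'   `truth_params.csv`.
#' @param modes Test modes to simulate.
#' @return Object of class `dgtt_cohort`: list of data frames `manifest`,
#'   `glucometer`, `ms_areas`, `truth`, `truth_params`.
#' @export
make_cohort <- function(n_per_group = c(LFD = 14, HFD = 15),
                        presets = NULL, seed = 1, dir = NULL,
                        modes = c("GTT", "ITT")) {
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1 for every group")
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups)))
    stop("n_per_group must be a named vector of group sizes")
  if (is.null(presets))
    presets <- lapply(groups, function(g) {
      key <- toupper(substr(g, 1, 3))
      if (key %in% c("LFD", "HFD")) sim_preset(key) else
        stop("no default preset for group ", g, "; supply `presets`")
    })
  else presets <- presets[groups]
  names(presets) <- groups
  set.seed(seed)

  manifest <- glucometer <- ms <- truth <- tpar <- list()
  for (g in groups) {
    for (i in seq_len(n_per_group[[g]])) {
      aid <- sprintf("%s_%02d", g, i)
      ap <- draw_animal_params(presets[[g]])
      manifest[[aid]] <- data.frame(
        animal_id = aid, group = g,
        body_mass_g = round(ap$body_mass_g, 2),
        lean_mass_g = round(ap$lean_mass_g, 2), stringsAsFactors = FALSE)
      tpar[[aid]] <- data.frame(
        animal_id = aid, group = g, ka_depot = ap$ka_depot, k0 = ap$k0,
        kI = ap$kI, sI = ap$sI, sG = ap$sG, Gb = ap$Gb, EGP0 = ap$EGP0,
        stringsAsFactors = FALSE)
      for (mode in modes) {
        s <- simulate_test(ap, mode, lean_mass_g = ap$lean_mass_g)
        key <- paste(aid, mode)
        glucometer[[key]] <- data.frame(
          animal_id = aid, test_mode = mode, time_min = s$times,
          glucose_mgdl = s$meas_glucose, insulin_ugl = s$meas_insulin_ugl,
          stringsAsFactors = FALSE)
        ms[[key]] <- data.frame(
          animal_id = aid, test_mode = mode, time_min = s$times,
          s$meas_areas, stringsAsFactors = FALSE)
        truth[[key]] <- data.frame(
          animal_id = aid, test_mode = mode, time_min = s$times,
          true_labeled = s$true_labeled, true_unlabeled = s$true_unlabeled,
          true_enrichment = s$true_enrichment, stringsAsFactors = FALSE)
      }
    }
  }
  flat <- function(x) { y <- do.call(rbind, x); rownames(y) <- NULL; y }
  out <- structure(list(manifest = flat(manifest), glucometer = flat(glucometer),
                        ms_areas = flat(ms), truth = flat(truth),
                        truth_params = flat(tpar), seed = seed, modes = modes),
                   class = "dgtt_cohort")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(out$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(out$glucometer, file.path(dir, "glucometer.csv"), row.names = FALSE)
    utils::write.csv(out$ms_areas, file.path(dir, "ms_areas.csv"), row.names = FALSE)
    utils::write.csv(out$truth, file.path(dir, "truth_curves.csv"), row.names = FALSE)
    utils::write.csv(out$truth_params, file.path(dir, "truth_params.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.dgtt_cohort <- function(x, ...) {
  cat("<synthetic cohort> seed ", x$seed, "\n", sep = "")
  print(table(x$manifest$group))
  cat("modes: ", paste(x$modes, collapse = "/"), "; ",
      nrow(x$glucometer), " glucometer rows, ", nrow(x$ms_areas),
      " MS spectra\n", sep = "")
  invisible(x)
}
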
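#' Deconvolve one isotopologue spectrum
#'
#' Solves `observed = matrix %*% true` for the molar fractions of species
#' carrying 0..K tracer labels, by non-negative least squares
#' ([pracma::lsqnonneg()]). Non-negativity matters: with measurement noise a
#' plain inverse routinely produces negative fractions. The observed areas
#' are normalised to sum 1 before solving so the residual norm is comparable
#' across samples of different absolute intensity.
#'
#' @param areas Numeric vector of non-negative peak areas for M+0 .. M+K
#'   (length at least 3 so the M+2 tracer shift is present).
#' @param matrix Correction matrix from [build_correction_matrix()].
#' @param residual_threshold Relative residual above which the sample is
#'   flagged (not rejected) for quality control.
#' @return List with `fractions` (length K+1, non-negative, sums to 1),
#'   `residual_norm` (||M f - y|| / ||y||) and logical `qc_flag`.
#' @examples
#' M <- build_correction_matrix()
#' correct_spectrum(as.vector(M %*% c(0.7, 0, 0.3)), M)$fractions
#' @export
correct_spectrum <- function(areas, matrix, residual_threshold = 0.05) {
  areas <- as.numeric(areas)
  if (any(is.na(areas)) || any(areas < 0))
    stop("peak areas must be non-negative and non-missing")
  if (all(areas == 0)) stop("empty spectrum")
  if (length(areas) != nrow(matrix))
    stop("spectrum length (", length(areas), ") does not match correction matrix (",
         nrow(matrix), ")")
  y <- areas / sum(areas)
  fit <- pracma::lsqnonneg(matrix, y)
  x <- fit$x
  if (sum(x) <= 0) stop("non-negative least squares returned an all-zero solution")
  res <- sqrt(sum((matrix %*% x - y)^2)) / sqrt(sum(y^2))
  list(fractions = as.numeric(x / sum(x)),
       residual_norm = res,
       qc_flag = res > residual_threshold)
}

#' Tracer enrichment from corrected fractions
#'
#' Enrichment is the molar fraction of circulating glucose that is
#' tracer-derived: the corrected fraction at the tracer's mass shift (M+2 for
#' \[6,6-2H2\]glucose). The value is clipped to \[0, 1\] so downstream
#' partitioning stays physical; the raw value is kept for quality control.
#'
#' @param fractions Corrected molar fractions summing to 1.
#' @param tracer_shift Mass shift of the fully labelled tracer (default 2).
#' @return List with `enrichment` (clipped) and `enrichment_raw`.
#' @examples
#' enrichment_from_fractions(c(0.6, 0.05, 0.35))$enrichment
#' @export
enrichment_from_fractions <- function(fractions, tracer_shift = 2L) {
  fractions <- as.numeric(fractions)
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1")
  if (tracer_shift + 1L > length(fractions))
    stop("tracer shift exceeds spectrum length")
  raw <- fractions[tracer_shift + 1L]
  list(enrichment = min(max(raw, 0), 1), enrichment_raw = raw)
}

#' Compute per-sample tracer enrichment for a cohort
#'
#' Table-level front end of the correction stage: takes the tidy LC-MS/MS
#' area table and returns one enrichment per blood sample. With
#' `correction = TRUE` each spectrum is deconvolved against the
#' natural-abundance matrix; with `correction = FALSE` the uncorrected
#' fraction M+2 / sum(areas) is used (exposed for comparison with
#' ratio-based workflows that skip abundance correction).
#'
#' @param ms Data frame with columns `animal_id`, `time_min` and
#'   `area_m0`, `area_m1`, `area_m2` (further `area_mK` columns allowed);
#'   an optional `test_mode` column is carried through.
#' @param formula,opts Ion formula and correction options.
#' @param correction Apply natural-abundance/purity correction?
#' @param residual_threshold Passed to [correct_spectrum()].
#' @return Data frame with `animal_id`, (`test_mode`,) `time_min`,
#'   `enrichment`, `enrichment_raw`, `residual_norm`, `qc_flag`, ordered by
#'   animal and time.
#' @export
correct_table <- function(ms, formula = ion_formula(), opts = correction_options(),
                          correction = TRUE, residual_threshold = 0.05) {
  need <- c("animal_id", "time_min", "area_m0", "area_m1", "area_m2")
  miss <- setdiff(need, names(ms))
  if (length(miss))
    stop("MS area table is missing column(s): ", paste(miss, collapse = ", "))
  acol <- grep("^area_m[0-9]+$", names(ms), value = TRUE)
  acol <- acol[order(as.integer(sub("^area_m", "", acol)))]
  A <- as.matrix(ms[, acol, drop = FALSE])
  if (any(is.na(A)) || any(A < 0))
    stop("peak areas must be non-negative and non-missing")
  K <- length(acol) - 1L
  if (correction) {
    opts$max_shift <- K
    M <- build_correction_matrix(formula, opts)
  }
  n <- nrow(ms)
  enr <- raw <- resn <- numeric(n)
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (correction) {
      cs <- correct_spectrum(A[i, ], M, residual_threshold)
      fr <- cs$fractions
      resn[i] <- cs$residual_norm
      flag[i] <- cs$qc_flag
    } else {
      if (all(A[i, ] == 0)) stop("empty spectrum")
      fr <- A[i, ] / sum(A[i, ])
    }
    e <- enrichment_from_fractions(fr, tracer_shift = opts$n_label_positions)
    enr[i] <- e$enrichment
    raw[i] <- e$enrichment_raw
  }
  out <- data.frame(animal_id = ms$animal_id, time_min = ms$time_min,
                    enrichment = enr, enrichment_raw = raw,
                    residual_norm = resn, qc_flag = flag,
                    stringsAsFactors = FALSE)
  if ("test_mode" %in% names(ms)) {
    out$test_mode <- ms$test_mode
    out <- out[, c("animal_id", "test_mode", "time_min", "enrichment",
                   "enrichment_raw", "residual_norm", "qc_flag")]
    out <- out[order(out$animal_id, out$test_mode, out$time_min), ]
  } else {
    out <- out[order(out$animal_id, out$time_min), ]
  }
  rownames(out) <- NULL
  out
}
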
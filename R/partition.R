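#' Subtract the fasting baseline from a concentration curve
#'
#' @param values Concentrations over the sampling schedule.
#' @param baseline Baseline value; defaults to the first (t = 0) sample.
#' @return `values - baseline`; zero at t = 0 by construction when the
#'   default baseline is used.
#' @examples
#' baseline_subtract(c(150, 180, 200))
#' @export
baseline_subtract <- function(values, baseline = values[1]) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty curve")
  values - baseline
}

#' Partition total blood glucose into exogenous and endogenous components
#'
#' For each animal and test, the glucometer total at each timepoint is split
#' by the molar tracer enrichment: `exogenous = total * enrichment`,
#' `endogenous = total * (1 - enrichment)`. The glucometer is assumed to
#' respond equally to labelled and unlabelled glucose (2H2 substitution does
#' not measurably affect glucose-oxidase chemistry), so the split is exact by
#' construction: exogenous + endogenous reproduces the total.
#'
#' Glucometer and MS samples come from the same tail bleed, so the two time
#' grids must agree: a timepoint present in only one source is flagged,
#' warned about, and excluded pairwise; no interpolation is ever performed
#' (a grid mismatch indicates a data error, not a resampling problem).
#'
#' @param glucose Data frame with `animal_id`, `test_mode`, `time_min`,
#'   `glucose_mgdl` (> 0) and optionally `insulin_ugl`.
#' @param enrichment Data frame from [correct_table()] (needs `animal_id`,
#'   `time_min`, `enrichment`, and `test_mode` if `glucose` has one).
#' @return Data frame of class `dgtt_partition`: `animal_id`, `test_mode`,
#'   `time_min`, `total`, `exogenous`, `endogenous`, `d_total`,
#'   `d_exogenous`, `d_endogenous` (baseline-subtracted), plus carried-over
#'   `insulin_ugl` if present.
#' @export
partition_table <- function(glucose, enrichment) {
  need <- c("animal_id", "test_mode", "time_min", "glucose_mgdl")
  miss <- setdiff(need, names(glucose))
  if (length(miss))
    stop("glucometer table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("animal_id", "time_min", "enrichment") %in% names(enrichment)))
    stop("enrichment table must have animal_id, time_min and enrichment columns")
  if (any(is.na(glucose$glucose_mgdl)) || any(glucose$glucose_mgdl <= 0))
    stop("total glucose must be positive at every timepoint")
  if (any(enrichment$enrichment < 0 | enrichment$enrichment > 1))
    stop("enrichment must lie in [0, 1]")

  by_mode <- "test_mode" %in% names(enrichment)
  keys <- c("animal_id", if (by_mode) "test_mode")
  gkey <- do.call(paste, c(glucose[keys], sep = "\r"))
  ekey <- do.call(paste, c(enrichment[keys], sep = "\r"))
  out <- NULL
  dropped <- character(0)
  for (au in unique(paste(glucose$animal_id, glucose$test_mode, sep = "\r"))) {
    parts <- strsplit(au, "\r", fixed = TRUE)[[1]]
    aid <- parts[1]; mode <- parts[2]
    g <- glucose[glucose$animal_id == aid & glucose$test_mode == mode, ]
    e <- if (by_mode)
      enrichment[enrichment$animal_id == aid & enrichment$test_mode == mode, ]
    else enrichment[enrichment$animal_id == aid, ]
    if (nrow(e) == 0L)
      stop("no enrichment data for animal ", aid, " (", mode, ")")
    if (anyDuplicated(g$time_min) || anyDuplicated(e$time_min))
      stop("duplicated timepoints for animal ", aid, " (", mode, ")")
    common <- intersect(g$time_min, e$time_min)
    lost <- union(setdiff(g$time_min, common), setdiff(e$time_min, common))
    if (length(lost))
      dropped <- c(dropped, paste0(aid, "/", mode, " t=", lost))
    if (length(common) < 2L)
      stop("fewer than 2 shared timepoints for animal ", aid, " (", mode,
           "): glucometer and MS grids do not match")
    if (!0 %in% common)
      stop("baseline (t = 0) sample missing for animal ", aid, " (", mode, ")")
    common <- sort(common)
    g <- g[match(common, g$time_min), ]
    e <- e[match(common, e$time_min), ]
    total <- g$glucose_mgdl
    exo <- total * e$enrichment
    endo <- total * (1 - e$enrichment)
    block <- data.frame(animal_id = aid, test_mode = mode, time_min = common,
                        total = total, exogenous = exo, endogenous = endo,
                        d_total = baseline_subtract(total),
                        d_exogenous = baseline_subtract(exo, 0),
                        d_endogenous = baseline_subtract(endo),
                        stringsAsFactors = FALSE)
    if ("insulin_ugl" %in% names(g)) block$insulin_ugl <- g$insulin_ugl
    out <- rbind(out, block)
  }
  if (length(dropped))
    warning("timepoints present in only one of glucometer/MS data were excluded: ",
            paste(dropped, collapse = "; "))
  rownames(out) <- NULL
  class(out) <- c("dgtt_partition", "data.frame")
  out
}

#' @export
print.dgtt_partition <- function(x, ...) {
  cat("<partitioned glucose curves> ",
      length(unique(x$animal_id)), " animals, modes: ",
      paste(sort(unique(x$test_mode)), collapse = "/"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 12), ...)
  if (nrow(x) > 12) cat("... (", nrow(x), " rows)\n", sep = "")
  invisible(x)
}
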
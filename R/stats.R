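# Compact letter display by insert-and-absorb over a pairwise p-value matrix:
# cells not sharing a letter differ at alpha; non-different cells always share
# at least one letter.
cld_letters <- function(pmat, alpha = 0.05) {
  n <- nrow(pmat)
  groups <- list(seq_len(n))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    newg <- list()
    for (g in groups) {
      if (i %in% g && j %in% g)
        newg <- c(newg, list(setdiff(g, i)), list(setdiff(g, j)))
      else newg <- c(newg, list(g))
    }
    # absorb letters that are subsets of another
    keep <- rep(TRUE, length(newg))
    for (a in seq_along(newg)) for (b in seq_along(newg)) {
      if (a != b && keep[a] && keep[b] && all(newg[[a]] %in% newg[[b]]) &&
          !(all(newg[[b]] %in% newg[[a]]) && a < b))
        keep[a] <- FALSE
    }
    groups <- unique(newg[keep])
  }
  out <- character(n)
  for (k in seq_along(groups))
    out[groups[[k]]] <- paste0(out[groups[[k]]], letters[k])
  out
}

# degenerate (zero-variance) cells yield NA rather than aborting the report
safe_t <- function(...) {
  tryCatch(stats::t.test(...)$p.value, error = function(e) NA_real_)
}

merge_manifest <- function(x, manifest) {
  need <- c("animal_id", "group")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(x$animal_id), manifest$animal_id)
  if (length(unknown))
    stop("animal(s) absent from manifest: ", paste(unknown, collapse = ", "))
  x$group <- manifest$group[match(x$animal_id, manifest$animal_id)]
  x
}

#' Diet-by-insulin factorial analysis of AOC summaries
#'
#' Reproduces the factorial readout of a paired GTT/ITT design: a
#' mixed-design two-way ANOVA per AOC outcome, with diet group as the
#' between-animal factor and test mode (insulin absent/present) as the
#' within-animal factor, since each animal undergoes both tests. Reported
#' per outcome: main-effect p-values for diet and insulin, the interaction
#' p-value, cell means with standard errors, and Holm-adjusted pairwise
#' comparisons rendered as a compact letter display (cells not sharing a
#' letter differ at `alpha`). Within-group mode comparisons use paired
#' t-tests; all other cell pairs use Welch t-tests.
#'
#' @param aocs A [summarize_cohort()] table (or data frame with
#'   `animal_id`, `test_mode` and the outcome columns).
#' @param manifest Animal manifest with `animal_id` and `group`.
#' @param outcomes Outcome columns to analyse.
#' @param alpha Significance level for the letter display.
#' @return Object of class `dgtt_factorial`.
#' @export
factorial_aoc <- function(aocs, manifest,
                          outcomes = c("aoc_total", "aoc_exogenous", "aoc_endogenous"),
                          alpha = 0.05) {
  if (!all(c("animal_id", "test_mode") %in% names(aocs)))
    stop("AOC table must have animal_id and test_mode columns")
  miss <- setdiff(outcomes, names(aocs))
  if (length(miss)) stop("missing outcome column(s): ", paste(miss, collapse = ", "))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  d <- merge_manifest(as.data.frame(aocs), manifest)
  d$group <- factor(d$group)
  d$test_mode <- factor(d$test_mode)
  d$animal_id <- factor(d$animal_id)
  if (nlevels(d$group) < 2L || nlevels(d$test_mode) < 2L)
    stop("factorial design needs at least 2 diet groups and 2 test modes")
  tab <- table(d$group, d$test_mode)
  if (any(tab < 2L)) {
    bad <- which(tab < 2L, arr.ind = TRUE)[1, ]
    stop("empty or underfilled cell: group ", rownames(tab)[bad[1]],
         " x mode ", colnames(tab)[bad[2]], " (need >= 2 animals)")
  }
  paired_ok <- all(table(d$animal_id) == nlevels(d$test_mode))
  if (!paired_ok)
    stop("each animal must appear once per test mode (paired design)")

  cells <- expand.grid(group = levels(d$group), test_mode = levels(d$test_mode),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- list()
  for (oc in outcomes) {
    d$.y <- d[[oc]]
    a <- stats::aov(.y ~ group * test_mode + Error(animal_id), data = d)
    s <- summary(a)
    getp <- function(stratum, term) {
      tt <- s[[stratum]][[1]]
      row <- which(trimws(rownames(tt)) == term)
      unname(tt[row, "Pr(>F)"])
    }
    pv <- c(diet = getp("Error: animal_id", "group"),
            insulin = getp("Error: Within", "test_mode"),
            interaction = getp("Error: Within", "group:test_mode"))

    cell_stats <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      y <- d$.y[d$group == cells$group[i] & d$test_mode == cells$test_mode[i]]
      data.frame(group = cells$group[i], test_mode = cells$test_mode[i],
                 n = length(y), mean = mean(y), se = stats::sd(y) / sqrt(length(y)),
                 stringsAsFactors = FALSE)
    }))

    nc <- nrow(cells)
    pm <- matrix(NA_real_, nc, nc)
    pairs <- NULL
    for (i in seq_len(nc - 1)) for (j in seq(i + 1, nc)) {
      gi <- cells$group[i]; gj <- cells$group[j]
      mi <- cells$test_mode[i]; mj <- cells$test_mode[j]
      if (gi == gj) {
        di <- d[d$group == gi & d$test_mode == mi, ]
        dj <- d[d$group == gj & d$test_mode == mj, ]
        yi <- di$.y[order(di$animal_id)]
        yj <- dj$.y[order(dj$animal_id)]
        p <- safe_t(yi, yj, paired = TRUE)
      } else {
        yi <- d$.y[d$group == gi & d$test_mode == mi]
        yj <- d$.y[d$group == gj & d$test_mode == mj]
        p <- safe_t(yi, yj)
      }
      pairs <- rbind(pairs, data.frame(
        cell_a = paste(gi, mi, sep = ":"), cell_b = paste(gj, mj, sep = ":"),
        p = p, stringsAsFactors = FALSE))
    }
    pairs$p_adj <- stats::p.adjust(pairs$p, method = "holm")
    k <- 0
    for (i in seq_len(nc - 1)) for (j in seq(i + 1, nc)) {
      k <- k + 1
      pm[i, j] <- pm[j, i] <- pairs$p_adj[k]
    }
    cell_stats$letters <- cld_letters(pm, alpha)
    res[[oc]] <- list(p_values = pv, cells = cell_stats, pairwise = pairs)
  }
  structure(list(outcomes = res, alpha = alpha,
                 n_animals = nlevels(d$animal_id)),
            class = "dgtt_factorial")
}

#' @export
print.dgtt_factorial <- function(x, ...) {
  cat("Diet x insulin factorial analysis of AOC summaries (",
      x$n_animals, " animals, alpha = ", x$alpha, ")\n", sep = "")
  for (oc in names(x$outcomes)) {
    r <- x$outcomes[[oc]]
    cat("\n== ", oc, " ==\n", sep = "")
    cat(sprintf("  ME diet: P = %.4g | ME insulin: P = %.4g | interaction: P = %.4g\n",
                r$p_values["diet"], r$p_values["insulin"], r$p_values["interaction"]))
    cs <- r$cells
    for (i in seq_len(nrow(cs)))
      cat(sprintf("  %-18s mean %10.1f  SE %8.1f  n %2d  %s\n",
                  paste(cs$group[i], cs$test_mode[i], sep = ":"),
                  cs$mean[i], cs$se[i], cs$n[i], cs$letters[i]))
  }
  cat("\nCells not sharing a letter differ (Holm-adjusted P < ", x$alpha, ").\n",
      sep = "")
  invisible(x)
}

#' Tidy table of factorial p-values
#'
#' @param object A `dgtt_factorial` object.
#' @param ... Unused.
#' @return Data frame with one row per outcome x effect.
#' @export
summary.dgtt_factorial <- function(object, ...) {
  do.call(rbind, lapply(names(object$outcomes), function(oc) {
    pv <- object$outcomes[[oc]]$p_values
    data.frame(outcome = oc, effect = names(pv), p = unname(pv),
               stringsAsFactors = FALSE)
  }))
}

#' Per-timepoint two-group comparisons
#'
#' Tests, at each post-baseline timepoint, whether the two diet groups
#' differ on a chosen curve (default the baseline-subtracted endogenous
#' glucose, the readout for speed of EGP suppression). Welch t-tests with
#' Holm adjustment across the post-baseline timepoints; a timepoint is
#' flagged when its adjusted p-value falls below `alpha`.
#'
#' @param partitioned A [partition_table()] result.
#' @param manifest Animal manifest with `animal_id` and `group` (exactly two
#'   groups, each with at least 2 animals).
#' @param mode Test mode to analyse.
#' @param value Curve column to compare.
#' @param alpha Significance level for flagging.
#' @return Data frame: `time_min`, per-group means, `p`, `p_adj`, `flag`.
#' @export
timepoint_compare <- function(partitioned, manifest, mode = "ITT",
                              value = "d_endogenous", alpha = 0.05) {
  d <- merge_manifest(as.data.frame(partitioned), manifest)
  d <- d[d$test_mode == mode, ]
  if (nrow(d) == 0L) stop("no data for test mode ", mode)
  if (!value %in% names(d)) stop("no such curve column: ", value)
  gl <- sort(unique(d$group))
  if (length(gl) != 2L) stop("timepoint comparison requires exactly 2 groups")
  tps <- sort(unique(d$time_min))
  tps <- tps[tps > 0]
  rows <- lapply(tps, function(tp) {
    y1 <- d[[value]][d$group == gl[1] & d$time_min == tp]
    y2 <- d[[value]][d$group == gl[2] & d$time_min == tp]
    if (length(y1) < 2L || length(y2) < 2L)
      stop("fewer than 2 animals per group at t = ", tp)
    data.frame(time_min = tp, mean_1 = mean(y1), mean_2 = mean(y2),
               p = safe_t(y1, y2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", gl)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out$flag <- !is.na(out$p_adj) & out$p_adj < alpha
  attr(out, "groups") <- gl
  attr(out, "value") <- value
  out
}
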
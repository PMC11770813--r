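#' Pinned natural isotope abundances
#'
#' Representative terrestrial isotopic compositions (IUPAC 2013) for the
#' elements of common small-molecule ions, expressed as mass-shift
#' distributions: element `E` maps to a vector `p` where `p[k+1]` is the
#' abundance of the isotope `k` mass units above the lightest. These pinned
#' constants make natural-abundance correction reproducible; override any
#' element via the `natural_abundances` argument of [correction_options()].
#'
#' @return Named list of numeric abundance vectors, each summing to 1.
#' @examples
#' natural_abundances()$C   # 12C, 13C
#' @export
natural_abundances <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    P = 1,
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Elemental composition of the measured ion
#'
#' Describes the ion whose isotopologue envelope is integrated by the mass
#' spectrometer. The default is deprotonated glucose, `[C6H11O6]-`, the usual
#' species for LC-MS/MS glucose quantitation in negative mode; any formula
#' can be supplied for other ions or derivatives.
#'
#' @param element_counts Named integer vector of atom counts, e.g.
#'   `c(C = 6, H = 11, O = 6)`.
#' @param charge Integer charge of the ion (sign included).
#' @return An object of class `dgtt_formula`.
#' @examples
#' ion_formula()                      # deprotonated glucose
#' ion_formula(c(C = 6, H = 12, O = 6), charge = 0)
#' @seealso [parse_formula()] for building one from a string.
#' @export
ion_formula <- function(element_counts = c(C = 6, H = 11, O = 6), charge = -1L) {
  counts <- as.integer(round(element_counts))
  names(counts) <- names(element_counts)
  if (length(counts) == 0L || is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("element_counts must be a named vector with at least one element")
  if (any(is.na(counts)) || any(counts < 0L))
    stop("element counts must be non-negative integers")
  if (all(counts == 0L))
    stop("at least one element must be present")
  structure(list(element_counts = counts, charge = as.integer(charge)),
            class = "dgtt_formula")
}

#' Parse a molecular formula string
#'
#' @param x Formula string such as `"C6H11O6"`.
#' @param charge Integer charge.
#' @return A `dgtt_formula` object.
#' @examples
#' parse_formula("C6H11O6")
#' @export
parse_formula <- function(x, charge = -1L) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula string: ", x)
  counts <- integer(0)
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  ion_formula(counts, charge = charge)
}

#' @export
print.dgtt_formula <- function(x, ...) {
  f <- paste0(names(x$element_counts), ifelse(x$element_counts == 1, "", x$element_counts),
              collapse = "")
  ch <- if (x$charge == 0) "" else sprintf(" (charge %+d)", x$charge)
  cat("<ion formula> ", f, ch, "\n", sep = "")
  invisible(x)
}

#' Options for isotopologue natural-abundance correction
#'
#' @param tracer_purity Isotopic enrichment of the tracer at each labelled
#'   position, in (0, 1]. Commercial \[6,6-2H2\]glucose is typically specified
#'   at 99 atom % D, hence the 0.99 default.
#' @param natural_abundances Named list of per-element isotope mass-shift
#'   distributions; each must sum to 1 (see [natural_abundances()]).
#' @param max_shift Largest mass shift K retained in spectra and in the
#'   (K+1) x (K+1) correction matrix; must be at least `n_label_positions`.
#' @param n_label_positions Number of tracer-labelled atoms (2 for
#'   \[6,6-2H2\]glucose).
#' @param label_element Element symbol carrying the label (`"H"` for a
#'   deuterium tracer).
#' @return An object of class `dgtt_correction_options`.
#' @export
correction_options <- function(tracer_purity = 0.99,
                               natural_abundances = dgtt::natural_abundances(),
                               max_shift = 2L,
                               n_label_positions = 2L,
                               label_element = "H") {
  if (!is.numeric(tracer_purity) || length(tracer_purity) != 1L ||
      tracer_purity <= 0 || tracer_purity > 1)
    stop("tracer_purity must be in (0, 1]")
  for (el in names(natural_abundances)) {
    p <- natural_abundances[[el]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("isotope fractions for element ", el, " must be non-negative and sum to 1")
  }
  max_shift <- as.integer(max_shift)
  n_label_positions <- as.integer(n_label_positions)
  if (max_shift < 1L) stop("max_shift must be >= 1")
  if (n_label_positions < 1L) stop("n_label_positions must be >= 1")
  structure(list(tracer_purity = tracer_purity,
                 natural_abundances = natural_abundances,
                 max_shift = max_shift,
                 n_label_positions = n_label_positions,
                 label_element = label_element),
            class = "dgtt_correction_options")
}

# polynomial (open) convolution of two mass-shift distributions
conv_shift <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# natural-abundance mass-shift distribution of a whole formula
# (product of per-atom distributions; exact, untruncated)
formula_shift_dist <- function(counts, abundances) {
  dist <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0L) next
    p <- abundances[[el]]
    if (is.null(p)) stop("no natural abundance data for element ", el)
    for (i in seq_len(n)) dist <- conv_shift(dist, p)
  }
  dist
}

#' Build the isotopologue correction matrix
#'
#' Column `j+1` (j = 0..K) holds the expected mass-shift distribution, at
#' natural isotope abundance, of the ion species carrying `j` tracer labels.
#' The `j` labelled atoms are excluded from the natural-abundance convolution;
#' each contributes its +1 shift with probability `tracer_purity` (an impure
#' position contributes to shift j-1, and so on, binomially). Columns are
#' truncated at `max_shift` and deliberately NOT renormalised: mass lost past
#' K shows up in the non-negative least-squares residual, which is the
#' quality-control signal (renormalising would bias the recovered fractions).
#'
#' @param formula A [ion_formula()] object.
#' @param opts A [correction_options()] object.
#' @return A (K+1) x (K+1) numeric matrix, entries in \[0, 1\], column sums
#'   <= 1, with `dimnames` `M+0 ... M+K`.
#' @examples
#' M <- build_correction_matrix(ion_formula(), correction_options())
#' colSums(M)  # < 1: truncation loses high-shift mass
#' @export
build_correction_matrix <- function(formula = ion_formula(),
                                    opts = correction_options()) {
  stopifnot(inherits(formula, "dgtt_formula"),
            inherits(opts, "dgtt_correction_options"))
  K <- opts$max_shift
  nlab <- opts$n_label_positions
  el <- opts$label_element
  navail <- if (el %in% names(formula$element_counts)) formula$element_counts[[el]] else 0L
  if (navail < nlab)
    stop("formula has fewer ", el, " atoms than tracer-labelled positions")
  if (K < nlab)
    stop("tracer shift exceeds spectrum length")
  M <- matrix(0, K + 1L, K + 1L,
              dimnames = list(paste0("M+", 0:K), paste0("labels", 0:K)))
  for (j in 0:K) {
    counts <- formula$element_counts
    counts[[el]] <- counts[[el]] - j
    if (counts[[el]] < 0L)
      stop("formula has fewer ", el, " atoms than ", j, " labels")
    nat <- formula_shift_dist(counts, opts$natural_abundances)
    lab <- stats::dbinom(0:j, j, opts$tracer_purity)  # shift from retained labels
    full <- c(conv_shift(nat, lab), numeric(K + 1L))  # pad short envelopes
    M[, j + 1L] <- full[seq_len(K + 1L)]
  }
  M
}
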
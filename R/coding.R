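#' Binary genotype coding under a dominant or recessive model
#'
#' Codes minor-allele dosages into binary indicators with respect to the minor
#' allele B. Under dominant coding the genotypes (AA, AB, BB) map to
#' (0, 1, 1): the indicator is 1 when at least one copy of B is present. Under
#' recessive coding they map to (0, 0, 1): the indicator is 1 only for the BB
#' homozygote. Missing dosages (`NA`) stay missing. Additive dosage is the sum
#' of the two binary codings ((0,1,1) + (0,0,1) = (0,1,2)) and is therefore not
#' a separate scheme.
#'
#' @param dosage integer vector (or matrix) of minor-allele dosages in
#'   \{0, 1, 2\}, with `NA` for missing genotypes.
#' @param scheme `"dominant"` or `"recessive"`.
#' @return An object shaped like `dosage` with values in \{0, 1, `NA`\}.
#' @examples
#' code_marker(c(0, 1, 2, NA), "dominant")   # 0 1 1 NA
#' code_marker(c(0, 1, 2, NA), "recessive")  # 0 0 1 NA
#' @export
code_marker <- function(dosage, scheme = c("dominant", "recessive")) {
  scheme <- match.arg(scheme)
  bad <- !is.na(dosage) & !(dosage %in% c(0L, 1L, 2L))
  if (any(bad)) {
    stop("invalid dosage value(s): ", paste(unique(dosage[bad]), collapse = ", "),
         " (must be 0, 1, 2 or NA)")
  }
  threshold <- if (scheme == "dominant") 1L else 2L
  out <- ifelse(dosage >= threshold, 1L, 0L)
  # ifelse() drops dim for matrices; restore
  if (!is.null(dim(dosage))) dim(out) <- dim(dosage)
  out
}

#' Three-valued union indicator over a set of coded markers
#'
#' Combines per-marker binary codes into the union indicator x_ij for one
#' individual and one union using Kleene three-valued OR: the union is 1 if any
#' member is 1, 0 if every member is 0 with none missing, and missing (`NA`)
#' when no member is 1 but at least one is missing. A known 1 therefore
#' dominates missingness (the union is certainly realized), while a missing
#' member leaves an otherwise-zero union undetermined. For a single marker the
#' union indicator equals the marker's code, so a size-1 union reproduces
#' single-marker analysis.
#'
#' @param coded integer vector of per-marker codes in \{0, 1, `NA`\} for one
#'   individual.
#' @return A single value in \{0, 1, `NA`\}.
#' @examples
#' union_indicator(c(1, NA))  # 1: the union is realized regardless of the gap
#' union_indicator(c(0, NA))  # NA: undetermined
#' union_indicator(c(0, 0))   # 0
#' @seealso [union_indicator_matrix()] for the vectorized form used by scans.
#' @export
union_indicator <- function(coded) {
  if (length(coded) == 0L) stop("union must contain at least one marker")
  bad <- !is.na(coded) & !(coded %in% c(0L, 1L))
  if (any(bad)) stop("coded values must be 0, 1 or NA")
  if (any(coded == 1L, na.rm = TRUE)) return(1L)
  if (anyNA(coded)) return(NA_integer_)
  0L
}

#' Union indicators for all individuals at once
#'
#' Row-wise Kleene OR over a matrix of coded genotypes (individuals in rows,
#' the union's markers in columns). Equivalent to applying [union_indicator()]
#' to each row.
#'
#' @param coded integer matrix with entries in \{0, 1, `NA`\}.
#' @return Integer vector of length `nrow(coded)` with values in \{0, 1, `NA`\}.
#' @export
union_indicator_matrix <- function(coded) {
  if (!is.matrix(coded)) coded <- as.matrix(coded)
  if (ncol(coded) == 0L) stop("union must contain at least one marker")
  any1 <- rowSums(coded == 1L, na.rm = TRUE) > 0L
  anymiss <- rowSums(is.na(coded)) > 0L
  out <- integer(nrow(coded))
  out[any1] <- 1L
  out[!any1 & anymiss] <- NA_integer_
  out
}

#' Probability of the union of two correlated binary events
#'
#' Closed form for P(X or Y) given the marginals and the Pearson correlation r
#' of the two indicators:
#' \deqn{P(X \cup Y) = P(X) + P(Y) - P(X)P(Y) - r\sqrt{P(X)(1-P(X))P(Y)(1-P(Y))}.}
#' The implied intersection probability
#' \eqn{P(X \cap Y) = P(X)P(Y) + r\sqrt{\cdot}} must lie within the Frechet
#' bounds \eqn{[\max(0, P(X)+P(Y)-1), \min(P(X), P(Y))]}; an infeasible
#' combination raises an error naming the violated bound. With r = 1 and equal
#' marginals this reduces to P(X or X) = P(X).
#'
#' @param p_x,p_y marginal probabilities in \[0, 1\].
#' @param r Pearson correlation of the two indicators in \[-1, 1\].
#' @return The union probability, a number in \[0, 1\].
#' @examples
#' union_probability(0.2, 0.3, 0)    # independence: 0.44
#' union_probability(0.4, 0.4, 1)    # perfect coupling: 0.4
#' @export
union_probability <- function(p_x, p_y, r = 0) {
  p_int <- intersection_probability(p_x, p_y, r)
  p_x + p_y - p_int
}

#' Implied intersection probability for a correlated Bernoulli pair
#'
#' @inheritParams union_probability
#' @param tol numerical slack on the Frechet bound check.
#' @return P(X and Y) implied by the marginals and r.
#' @keywords internal
intersection_probability <- function(p_x, p_y, r, tol = 1e-12) {
  stopifnot(length(p_x) == 1L, length(p_y) == 1L, length(r) == 1L)
  if (p_x < 0 || p_x > 1 || p_y < 0 || p_y > 1) {
    stop("marginal probabilities must lie in [0, 1]")
  }
  if (r < -1 || r > 1) stop("correlation must lie in [-1, 1]")
  p_int <- p_x * p_y + r * sqrt(p_x * (1 - p_x) * p_y * (1 - p_y))
  lower <- max(0, p_x + p_y - 1)
  upper <- min(p_x, p_y)
  if (p_int < lower - tol) {
    stop(sprintf(
      "infeasible correlation: implied P(X&Y) = %.6g below Frechet lower bound %.6g",
      p_int, lower))
  }
  if (p_int > upper + tol) {
    stop(sprintf(
      "infeasible correlation: implied P(X&Y) = %.6g above Frechet upper bound %.6g",
      p_int, upper))
  }
  min(max(p_int, lower), upper)
}

#' Correlation coefficient from a squared correlation
#'
#' Linkage-disequilibrium strength is often quoted as r-squared, which leaves
#' the phase (sign) of the correlation unstated. This helper makes the sign
#' convention explicit: positive sign corresponds to coupling phase.
#'
#' @param r2 squared correlation in \[0, 1\].
#' @param sign `+1` (coupling, default) or `-1` (repulsion).
#' @return Signed correlation coefficient.
#' @export
r_from_r2 <- function(r2, sign = 1) {
  stopifnot(all(r2 >= 0), all(r2 <= 1), all(sign %in% c(-1, 1)))
  sign * sqrt(r2)
}
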
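#' Partition markers into consecutive, non-overlapping union windows
#'
#' Markers are taken in map order and partitioned, within each chromosome, into
#' consecutive windows of `k` markers. The last window on a chromosome may be
#' smaller than `k`; windows never span a chromosome boundary, since the unions
#' are motivated by linkage disequilibrium among neighbouring markers.
#'
#' @param markers data.frame of markers in map order with at least a
#'   `chrom` column (as produced by [read_ped_map()]).
#' @param k union size, an integer >= 1. `k = 1` yields singleton windows,
#'   i.e. single-marker analysis.
#' @param scheme coding scheme attached to each window spec.
#' @return A list of union specs; each is a list with `union_id`, `scheme`,
#'   `marker_indices` (strictly increasing, consecutive) and `chrom`.
#' @export
build_windows <- function(markers, k, scheme = c("dominant", "recessive")) {
  scheme <- match.arg(scheme)
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be a single integer >= 1")
  k <- as.integer(k)
  chrom <- as.character(markers$chrom)
  idx_by_chrom <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
  specs <- list()
  j <- 0L
  for (idx in idx_by_chrom) {
    starts <- seq.int(1L, length(idx), by = k)
    for (s in starts) {
      j <- j + 1L
      members <- idx[s:min(s + k - 1L, length(idx))]
      specs[[j]] <- list(union_id = j, scheme = scheme,
                         marker_indices = members,
                         chrom = chrom[members[1L]])
    }
  }
  specs
}

#' Testing burden of a union scan
#'
#' The number of unions of size k over M markers is ceiling(M / k); a scan over
#' several union sizes and coding schemes tests
#' `n_schemes * sum(ceiling(M / k))` hypotheses. With M = 319,813 autosomal
#' SNPs, sizes 1 through 5 and both codings this gives 1,460,484 tests and a
#' Bonferroni threshold of 0.05 / 1,460,484 = 3.42e-8.
#'
#' @param n_markers total marker count M (>= 1).
#' @param k_sizes integer vector of union sizes, all >= 1.
#' @param n_schemes number of coding schemes scanned (1 or 2).
#' @return The total number of tests as a double (counts can exceed
#'   `.Machine$integer.max` territory for large scans crossed with many sizes).
#' @examples
#' count_tests(319813, 1:5, 2)  # 1460484
#' @export
count_tests <- function(n_markers, k_sizes, n_schemes = 1) {
  if (length(k_sizes) == 0L) stop("k_sizes must be non-empty")
  if (any(k_sizes < 1)) stop("all union sizes must be >= 1")
  if (n_markers < 1) stop("n_markers must be >= 1")
  n_schemes * sum(ceiling(n_markers / k_sizes))
}

#' Tabulate a union indicator against case-control status
#'
#' Codes the union's markers under the spec's scheme, forms the per-individual
#' union indicator, and counts individuals with indicator 1 or 0 among cases
#' and controls. Individuals whose indicator is missing are excluded from the
#' union's table and counted in `n_excluded`.
#'
#' @param gt a `genotype_table`.
#' @param spec a union spec from [build_windows()] (or any list with
#'   `marker_indices` and `scheme`).
#' @return A list with counts `cases_1`, `cases_0`, `controls_1`, `controls_0`
#'   and `n_excluded`; the five always sum to the number of individuals.
#' @export
tabulate_union <- function(gt, spec) {
  idx <- spec$marker_indices
  if (any(idx < 1L) || any(idx > ncol(gt$dosage))) {
    stop("union spec indexes markers outside the genotype table")
  }
  coded <- code_marker(gt$dosage[, idx, drop = FALSE], spec$scheme)
  ind <- union_indicator_matrix(coded)
  is_case <- gt$phenotype == "case"
  miss <- is.na(ind)
  list(
    cases_1    = sum(!miss & is_case & ind == 1L),
    cases_0    = sum(!miss & is_case & ind == 0L),
    controls_1 = sum(!miss & !is_case & ind == 1L),
    controls_0 = sum(!miss & !is_case & ind == 0L),
    n_excluded = sum(miss)
  )
}

# Two-sided Fisher exact p-values for 2x2 tables, vectorized over tables.
# a = cases with indicator 1, b = cases with 0, c = controls with 1,
# d = controls with 0. The p-value conditions on both margins and sums the
# hypergeometric probabilities of every table at those margins whose point
# probability does not exceed that of the observed table (with a small
# relative tolerance so exact ties are kept despite floating point).
fisher_p_2x2 <- function(a, b, c, d, rel_tol = 1e-7) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]           # cases
    m2 <- c[i] + d[i]           # controls
    kk <- a[i] + c[i]           # indicator-1 column margin
    if (kk == 0L || b[i] + d[i] == 0L) { p[i] <- 1; next }  # constant indicator
    support <- max(0L, kk - m2):min(kk, m1)
    probs <- stats::dhyper(support, m1, m2, kk)
    p_obs <- probs[match(a[i], support)]
    p[i] <- min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
  }
  p
}

#' Fisher's exact test with odds ratio for a 2x2 union table
#'
#' Tests association between the union indicator and case-control status. The
#' two-sided p-value conditions on both margins of the 2x2 table and sums the
#' probabilities of all tables whose hypergeometric point probability is no
#' larger than the observed table's (the standard two-sided convention, as in
#' `stats::fisher.test`). The test has one degree of freedom regardless of the
#' number of markers in the union.
#'
#' The odds ratio is the sample cross-product ratio
#' (cases_1 * controls_0) / (cases_0 * controls_1); when any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells before the ratio and
#' interval are computed. The 95% confidence interval is the Woolf log-odds
#' normal approximation exp(log OR +/- z * sqrt(sum of reciprocal cells)). If
#' the indicator is constant over all individuals (a zero column margin) the
#' table is uninformative: p = 1 and the odds ratio is `NA`.
#'
#' @param table a list or named vector with `cases_1`, `cases_0`, `controls_1`,
#'   `controls_0` (as from [tabulate_union()]).
#' @param conf_level confidence level for the odds-ratio interval.
#' @return A list with `p_value`, `odds_ratio`, `ci_low`, `ci_high` and
#'   `degrees_of_freedom` (always 1).
#' @examples
#' fisher_exact_2x2(list(cases_1 = 5, cases_0 = 5, controls_1 = 5, controls_0 = 5))
#' @export
fisher_exact_2x2 <- function(table, conf_level = 0.95) {
  a <- table[["cases_1"]]; b <- table[["cases_0"]]
  c <- table[["controls_1"]]; d <- table[["controls_0"]]
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) stop("cell counts must be non-negative")
  if (a + b == 0L || c + d == 0L) {
    stop("untestable union: need at least one case and one control after exclusions")
  }
  if (a + c == 0L || b + d == 0L) {
    # indicator constant across all individuals: no information about association
    return(list(p_value = 1, odds_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, degrees_of_freedom = 1L))
  }
  p <- fisher_p_2x2(a, b, c, d)
  adj <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / adj))
  list(p_value = p,
       odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       degrees_of_freedom = 1L)
}

#' Genome-wide union scan
#'
#' Runs the union test over every combination of union size and coding scheme:
#' markers are partitioned into consecutive non-overlapping windows per
#' chromosome ([build_windows()]), each window's union indicator is tabulated
#' against case-control status ([tabulate_union()]) and tested with Fisher's
#' exact test ([fisher_exact_2x2()]). The per-test significance threshold is
#' `alpha / count_tests(M, k_sizes, length(schemes))`, recomputed from the
#' scanned marker count. Unions whose table has an empty case or control row
#' after missing-data exclusions are recorded as untestable (`NA` p-value) but
#' still count toward the Bonferroni denominator, which depends only on the
#' marker count.
#'
#' @param gt a `genotype_table` from [read_ped_map()] or [genotype_table()].
#' @param k_sizes integer vector of union sizes (default 1:5).
#' @param schemes coding schemes to scan (default both).
#' @param alpha family-wise significance level (default 0.05).
#' @return An object of class `union_scan`: a list with `results` (one row per
#'   union, sorted by p-value), `alpha`, `threshold`, `n_tests`, `k_sizes`,
#'   `schemes` and `n_markers`.
#' @export
run_scan <- function(gt, k_sizes = 1:5,
                     schemes = c("dominant", "recessive"), alpha = 0.05) {
  stopifnot(inherits(gt, "genotype_table"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (length(k_sizes) == 0L || any(k_sizes < 1)) stop("k_sizes must all be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- ncol(gt$dosage)
  if (m == 0L) stop("no markers to scan")
  n_tests <- count_tests(m, k_sizes, length(schemes))
  threshold <- alpha / n_tests

  rows <- list()
  for (scheme in schemes) {
    for (k in sort(unique(as.integer(k_sizes)))) {
      for (spec in build_windows(gt$markers, k, scheme)) {
        tab <- tabulate_union(gt, spec)
        res <- if (tab$cases_1 + tab$cases_0 == 0L ||
                   tab$controls_1 + tab$controls_0 == 0L) {
          list(p_value = NA_real_, odds_ratio = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_)
        } else {
          fisher_exact_2x2(tab)
        }
        idx <- spec$marker_indices
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme, k = k, union_id = spec$union_id,
          chrom = spec$chrom,
          rsids = paste(gt$markers$rsid[idx], collapse = ","),
          start = min(gt$markers$pos[idx]), end = max(gt$markers$pos[idx]),
          cases_1 = tab$cases_1, cases_0 = tab$cases_0,
          controls_1 = tab$controls_1, controls_0 = tab$controls_0,
          n_excluded = tab$n_excluded,
          p_value = res$p_value, odds_ratio = res$odds_ratio,
          ci_low = res$ci_low, ci_high = res$ci_high,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stop("no testable unions")
  results <- do.call(rbind, rows)
  results$significant <- !is.na(results$p_value) & results$p_value <= threshold
  results <- results[order(results$p_value), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, alpha = alpha, threshold = threshold,
                 n_tests = n_tests, k_sizes = sort(unique(as.integer(k_sizes))),
                 schemes = schemes, n_markers = m),
            class = "union_scan")
}

#' @export
print.union_scan <- function(x, ...) {
  cat("Union scan:", x$n_markers, "markers;",
      "union sizes", paste(x$k_sizes, collapse = ","), ";",
      "schemes", paste(x$schemes, collapse = ","), "\n")
  cat(sprintf("Testing burden: %d tests; Bonferroni threshold %.3g (alpha = %g)\n",
              as.integer(x$n_tests), x$threshold, x$alpha))
  cat(sum(x$results$significant), "union(s) significant at the threshold\n")
  cat("Top results:\n")
  print(utils::head(x$results[, c("scheme", "k", "chrom", "rsids",
                                  "p_value", "odds_ratio")], 5))
  invisible(x)
}
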
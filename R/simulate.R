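#' Specify one case-control simulation experiment
#'
#' Describes a simulated case-control experiment over binary coded genotypes:
#' per-marker coded-genotype frequencies, a logistic disease model with
#' per-marker odds ratios and optional epistatic (product) terms, optional
#' pairwise correlation between markers, optional differential correlation
#' (different r in cases vs controls, with equal marginal frequencies), group
#' sizes and replicate count. Defaults mirror a GWAS-scale design of 938 cases
#' and 863 controls with 1,000 replicates.
#'
#' Correlations are given as signed Pearson coefficients r of the coded
#' indicators (use [r_from_r2()] to convert a quoted r-squared; positive sign
#' is coupling phase). Every pair is checked for feasibility against the
#' Frechet bounds on the implied joint probability before any sampling.
#'
#' @param freqs numeric vector of coded-genotype frequencies in (0, 1), one
#'   per marker.
#' @param odds_ratios per-marker odds ratios (> 0); recycled to the number of
#'   markers. 1 = no effect.
#' @param n_cases,n_controls group sizes.
#' @param epistasis optional data.frame with columns `i`, `j`, `or`: each row
#'   adds log(or) * x_i * x_j to the logit.
#' @param corr_pairs optional data.frame with columns `i`, `j`, `r`: marker j
#'   is drawn jointly with marker i at correlation r (same in both groups).
#' @param diff_corr optional data.frame with columns `i`, `j`, `r_case`,
#'   `r_control`: group-specific correlation with equal marginals.
#' @param replicates number of independent replicates.
#' @param alpha per-comparison significance level.
#' @param seed optional integer seed; when set, estimation functions are
#'   deterministic.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(freqs, odds_ratios = 1,
                            n_cases = 938, n_controls = 863,
                            epistasis = NULL, corr_pairs = NULL,
                            diff_corr = NULL,
                            replicates = 1000, alpha = 0.05, seed = NULL) {
  m <- length(freqs)
  if (m == 0L) stop("at least one marker frequency is required")
  if (any(freqs <= 0) || any(freqs >= 1)) stop("frequencies must lie in (0, 1)")
  odds_ratios <- rep_len(odds_ratios, m)
  if (any(odds_ratios <= 0)) stop("odds ratios must be positive")
  if (n_cases < 1 || n_controls < 1) stop("both groups must be non-empty")
  if (replicates < 1) stop("replicates must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")

  check_pairs <- function(pairs, rcols) {
    if (is.null(pairs)) return(NULL)
    pairs <- as.data.frame(pairs)
    stopifnot(all(c("i", "j", rcols) %in% names(pairs)))
    if (any(pairs$i < 1 | pairs$i > m | pairs$j < 1 | pairs$j > m)) {
      stop("correlation pair indexes a marker outside 1..", m)
    }
    if (any(pairs$i == pairs$j)) stop("correlation pairs must link distinct markers")
    for (rc in rcols) {
      for (q in seq_len(nrow(pairs))) {
        # raises an infeasibility error naming the violated Frechet bound
        intersection_probability(freqs[pairs$i[q]], freqs[pairs$j[q]], pairs[[rc]][q])
      }
    }
    pairs
  }
  corr_pairs <- check_pairs(corr_pairs, "r")
  diff_corr <- check_pairs(diff_corr, c("r_case", "r_control"))
  if (!is.null(epistasis)) {
    epistasis <- as.data.frame(epistasis)
    stopifnot(all(c("i", "j", "or") %in% names(epistasis)))
    if (any(epistasis$or <= 0)) stop("epistatic odds ratios must be positive")
  }
  structure(list(freqs = freqs, odds_ratios = odds_ratios,
                 n_cases = n_cases, n_controls = n_controls,
                 epistasis = epistasis, corr_pairs = corr_pairs,
                 diff_corr = diff_corr, replicates = replicates,
                 alpha = alpha, seed = seed),
            class = "simulation_spec")
}

#' Sample binary coded genotypes, optionally with correlated pairs
#'
#' Each marker is drawn Bernoulli(f_j). For each correlated pair (i, j, r) the
#' j-th column is redrawn conditionally on the i-th so that the joint
#' distribution has P(X_i = X_j = 1) = f_i f_j + r sqrt(f_i(1-f_i) f_j(1-f_j))
#' with the marginals preserved. Pairs are applied in order, so structures
#' spanning more than two markers are composed as a chain of pairwise
#' conditionals (an approximation for higher-order dependence).
#'
#' @param n number of individuals to draw.
#' @param freqs per-marker coded-genotype frequencies.
#' @param corr_pairs optional data.frame with columns `i`, `j`, `r`.
#' @return An n x length(freqs) integer matrix of 0/1 values.
#' @export
sample_coded_genotypes <- function(n, freqs, corr_pairs = NULL) {
  m <- length(freqs)
  x <- matrix(stats::rbinom(n * m, 1L, rep(freqs, each = n)), nrow = n, ncol = m)
  if (!is.null(corr_pairs) && nrow(corr_pairs) > 0L) {
    for (q in seq_len(nrow(corr_pairs))) {
      i <- corr_pairs$i[q]; j <- corr_pairs$j[q]; r <- corr_pairs$r[q]
      p11 <- intersection_probability(freqs[i], freqs[j], r)
      p_cond <- ifelse(x[, i] == 1L, p11 / freqs[i],
                       (freqs[j] - p11) / (1 - freqs[i]))
      x[, j] <- stats::rbinom(n, 1L, pmin(pmax(p_cond, 0), 1))
    }
  }
  x
}

# Linear predictor of the logistic disease model (intercept 0).
disease_logit <- function(x, spec) {
  eta <- as.vector(x %*% log(spec$odds_ratios))
  ep <- spec$epistasis
  if (!is.null(ep) && nrow(ep) > 0L) {
    for (q in seq_len(nrow(ep))) {
      eta <- eta + log(ep$or[q]) * x[, ep$i[q]] * x[, ep$j[q]]
    }
  }
  eta
}

#' Generate one replicate with exact case and control quotas
#'
#' Draws individuals in batches until the case and control quotas are both
#' filled, discarding overflow. Without differential correlation, coded
#' genotypes come from the common population distribution (including any
#' shared correlated pairs) and disease status is Bernoulli with probability
#' plogis(sum of log-OR terms) — the logistic model with intercept 0. With
#' differential correlation, cases and controls are drawn directly from their
#' group-specific joint genotype distributions (equal marginals, different r);
#' any non-unit odds ratios are then honoured by retention sampling within
#' each stream (a draw is kept as a case with probability plogis(eta), as a
#' control with probability 1 - plogis(eta)).
#'
#' @param spec a [simulation_spec()].
#' @return A list with `x` (genotype matrix, cases first) and `status`
#'   (integer, 1 = case, 0 = control).
#' @export
simulate_replicate <- function(spec) {
  n_cases <- spec$n_cases; n_controls <- spec$n_controls
  batch <- max(2048L, as.integer(1.2 * (n_cases + n_controls)))
  max_draws <- 2000L * (n_cases + n_controls)
  case_rows <- list(); control_rows <- list()
  got_cases <- 0L; got_controls <- 0L; drawn <- 0L

  has_effects <- any(spec$odds_ratios != 1) ||
    (!is.null(spec$epistasis) && nrow(spec$epistasis) > 0L)

  if (is.null(spec$diff_corr)) {
    while (got_cases < n_cases || got_controls < n_controls) {
      if (drawn >= max_draws) {
        stop(sprintf(
          "quota not reached after %d draws (cases %d/%d, controls %d/%d)",
          drawn, got_cases, n_cases, got_controls, n_controls))
      }
      x <- sample_coded_genotypes(batch, spec$freqs, spec$corr_pairs)
      p <- stats::plogis(disease_logit(x, spec))
      status <- stats::rbinom(batch, 1L, p)
      drawn <- drawn + batch
      if (got_cases < n_cases) {
        take <- which(status == 1L)
        take <- take[seq_len(min(length(take), n_cases - got_cases))]
        if (length(take)) {
          case_rows[[length(case_rows) + 1L]] <- x[take, , drop = FALSE]
          got_cases <- got_cases + length(take)
        }
      }
      if (got_controls < n_controls) {
        take <- which(status == 0L)
        take <- take[seq_len(min(length(take), n_controls - got_controls))]
        if (length(take)) {
          control_rows[[length(control_rows) + 1L]] <- x[take, , drop = FALSE]
          got_controls <- got_controls + length(take)
        }
      }
    }
  } else {
    # group-specific joint distributions with equal marginals
    pairs_for <- function(group) {
      dc <- spec$diff_corr
      extra <- data.frame(i = dc$i, j = dc$j,
                          r = if (group == "case") dc$r_case else dc$r_control)
      rbind(spec$corr_pairs, extra)
    }
    fill_stream <- function(group, quota) {
      rows <- list(); got <- 0L
      pairs <- pairs_for(group)
      while (got < quota) {
        if (drawn >= max_draws) {
          stop(sprintf("quota not reached after %d draws (%s %d/%d)",
                       drawn, group, got, quota))
        }
        x <- sample_coded_genotypes(batch, spec$freqs, pairs)
        drawn <<- drawn + batch
        if (has_effects) {
          p <- stats::plogis(disease_logit(x, spec))
          keep_p <- if (group == "case") p else 1 - p
          keep <- stats::runif(batch) < keep_p
          x <- x[keep, , drop = FALSE]
        }
        take <- seq_len(min(nrow(x), quota - got))
        if (length(take)) {
          rows[[length(rows) + 1L]] <- x[take, , drop = FALSE]
          got <- got + length(take)
        }
      }
      rows
    }
    case_rows <- fill_stream("case", n_cases)
    control_rows <- fill_stream("control", n_controls)
  }
  x <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
  list(x = x, status = c(rep(1L, n_cases), rep(0L, n_controls)))
}

#' Monte-Carlo rejection rate of the union test under a simulation spec
#'
#' For each replicate, generates one case-control dataset from the spec, forms
#' the union indicator over the first `union_size` markers (coded genotypes
#' are already binary, so the indicator is 1 when any member is 1), tests the
#' 2x2 indicator-by-status table with Fisher's exact test, and records
#' rejection at the spec's alpha. Under a null spec this estimates the
#' per-comparison type-I error rate; under an alternative it estimates power.
#'
#' @param spec a [simulation_spec()]; if `spec$seed` is set, the estimate is
#'   reproducible.
#' @param union_size number of markers in the tested union (<= number of
#'   markers in the spec).
#' @return A list with `rejection_rate`, `mc_stderr` (binomial standard error
#'   sqrt(p(1-p)/R)) and `replicates_used`.
#' @export
estimate_rejection_rate <- function(spec, union_size = length(spec$freqs)) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (union_size < 1L || union_size > length(spec$freqs)) {
    stop("union_size must lie in 1..", length(spec$freqs))
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  R <- spec$replicates
  rej <- logical(R)
  idx <- seq_len(union_size)
  for (b in seq_len(R)) {
    d <- simulate_replicate(spec)
    ind <- as.integer(rowSums(d$x[, idx, drop = FALSE]) > 0L)
    a <- sum(ind == 1L & d$status == 1L)
    bb <- spec$n_cases - a
    cc <- sum(ind == 1L & d$status == 0L)
    dd <- spec$n_controls - cc
    rej[b] <- fisher_p_2x2(a, bb, cc, dd) <= spec$alpha
  }
  rate <- mean(rej)
  list(rejection_rate = rate,
       mc_stderr = sqrt(rate * (1 - rate) / R),
       replicates_used = R)
}

#' Validity and power suite over a frequency grid
#'
#' Runs a panel of simulation experiments patterned on a standard
#' validity/power study of union testing (938 cases, 863 controls, logistic
#' disease model, binomially sampled coded genotypes):
#' \describe{
#'   \item{A}{per-comparison error rate: all odds ratios 1, union sizes 1-5.}
#'   \item{B}{power, odds ratio 1.5 per marker, union sizes 1-5.}
#'   \item{C}{power, odds ratio 2 per marker, union sizes 1-5.}
#'   \item{D}{2-marker unions with opposing effects: odds-ratio pairs (2, 0.5),
#'     (1.5, 0.67), (1, 1).}
#'   \item{E}{signal dilution: one predictor with odds ratio 2, 1.5 or 1 plus
#'     four null predictors (union size 5).}
#'   \item{F}{2-marker unions, both markers at odds ratio 2, 1.5 or 1,
#'     independent vs correlated at r-squared 0.8.}
#'   \item{G}{epistasis: marginal odds ratios 1, epistatic odds ratio 1, 2 or
#'     0.5 on the product term.}
#'   \item{H}{differential correlation: case/control r-squared (0.8, 0) or
#'     (0, 0.8), both markers at odds ratio 2 or 1.}
#' }
#'
#' @param panel one of `"A"`..`"H"`.
#' @param grid coded-genotype frequency grid.
#' @param replicates replicates per configuration.
#' @param seed integer seed; per-configuration seeds are derived from it.
#' @param n_cases,n_controls group sizes.
#' @param alpha per-comparison significance level.
#' @return A data.frame with one row per (configuration, frequency):
#'   `panel`, `config`, `f`, `k`, `rejection_rate`, `mc_stderr`, `replicates`.
#' @export
run_figure1_suite <- function(panel, grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                              replicates = 1000, seed = 1,
                              n_cases = 938, n_controls = 863, alpha = 0.05) {
  panel <- match.arg(panel, LETTERS[1:8])
  configs <- switch(panel,
    A = lapply(1:5, function(k) list(config = sprintf("k=%d", k), k = k, or = 1)),
    B = lapply(1:5, function(k) list(config = sprintf("k=%d", k), k = k, or = 1.5)),
    C = lapply(1:5, function(k) list(config = sprintf("k=%d", k), k = k, or = 2)),
    D = lapply(list(c(2, 0.5), c(1.5, 0.67), c(1, 1)), function(ors)
      list(config = sprintf("OR=(%g,%g)", ors[1], ors[2]), k = 2, or = ors)),
    E = lapply(c(2, 1.5, 1), function(or1)
      list(config = sprintf("OR1=%g+4null", or1), k = 5, or = c(or1, 1, 1, 1, 1))),
    F = {
      out <- list()
      for (or in c(2, 1.5, 1)) for (r2 in c(0, 0.8)) {
        out[[length(out) + 1L]] <- list(
          config = sprintf("OR=%g,r2=%g", or, r2), k = 2, or = or, r2 = r2)
      }
      out
    },
    G = lapply(c(1, 2, 0.5), function(or_epi)
      list(config = sprintf("ORepi=%g", or_epi), k = 2, or = 1, or_epi = or_epi)),
    H = {
      out <- list()
      for (or in c(2, 1)) for (cc in list(c(0.8, 0), c(0, 0.8))) {
        out[[length(out) + 1L]] <- list(
          config = sprintf("OR=%g,r2case=%g,r2ctrl=%g", or, cc[1], cc[2]),
          k = 2, or = or, r2_case = cc[1], r2_control = cc[2])
      }
      out
    })

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(configs) * length(grid))
  rows <- list(); s <- 0L
  for (cfg in configs) {
    for (f in grid) {
      s <- s + 1L
      spec <- simulation_spec(
        freqs = rep(f, cfg$k),
        odds_ratios = cfg$or,
        n_cases = n_cases, n_controls = n_controls,
        epistasis = if (!is.null(cfg$or_epi))
          data.frame(i = 1, j = 2, or = cfg$or_epi),
        corr_pairs = if (!is.null(cfg$r2) && cfg$r2 > 0)
          data.frame(i = 1, j = 2, r = r_from_r2(cfg$r2)),
        diff_corr = if (!is.null(cfg$r2_case))
          data.frame(i = 1, j = 2, r_case = r_from_r2(cfg$r2_case),
                     r_control = r_from_r2(cfg$r2_control)),
        replicates = replicates, alpha = alpha, seed = sub_seeds[s])
      est <- estimate_rejection_rate(spec, union_size = cfg$k)
      rows[[s]] <- data.frame(panel = panel, config = cfg$config, f = f,
                              k = cfg$k, rejection_rate = est$rejection_rate,
                              mc_stderr = est$mc_stderr,
                              replicates = est$replicates_used,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a simulation spec from a YAML file
#'
#' Expected keys mirror the arguments of [simulation_spec()]: `freqs`
#' (required), `odds_ratios`, `n_cases`, `n_controls`, `replicates`, `alpha`,
#' `seed`, and optional lists `epistasis` (`i`, `j`, `or`), `corr_pairs`
#' (`i`, `j` and `r` or `r2`), `diff_corr` (`i`, `j` and `r_case`/`r_control`
#' or `r2_case`/`r2_control`).
#'
#' @param path YAML file path.
#' @return A [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$freqs)) stop("spec file must provide 'freqs'")
  to_df <- function(entries, convert = identity) {
    if (is.null(entries)) return(NULL)
    do.call(rbind, lapply(entries, function(e) as.data.frame(convert(e))))
  }
  corr <- to_df(y$corr_pairs, function(e) {
    if (!is.null(e$r2)) e$r <- r_from_r2(e$r2)
    e[c("i", "j", "r")]
  })
  dc <- to_df(y$diff_corr, function(e) {
    if (!is.null(e$r2_case)) e$r_case <- r_from_r2(e$r2_case)
    if (!is.null(e$r2_control)) e$r_control <- r_from_r2(e$r2_control)
    e[c("i", "j", "r_case", "r_control")]
  })
  ep <- to_df(y$epistasis, function(e) e[c("i", "j", "or")])
  simulation_spec(
    freqs = as.numeric(y$freqs),
    odds_ratios = if (is.null(y$odds_ratios)) 1 else as.numeric(y$odds_ratios),
    n_cases = if (is.null(y$n_cases)) 938 else y$n_cases,
    n_controls = if (is.null(y$n_controls)) 863 else y$n_controls,
    epistasis = ep, corr_pairs = corr, diff_corr = dc,
    replicates = if (is.null(y$replicates)) 1000 else y$replicates,
    alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
    seed = y$seed)
}

#' Export one simulated replicate as PED/MAP
#'
#' Coded 0/1 genotypes are written as dosage 0/2 homozygotes (alleles `A`
#' major, `B` minor), so re-reading the files and applying either coding
#' scheme recovers the simulated indicators.
#'
#' @param rep a replicate from [simulate_replicate()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the `genotype_table` that was written.
#' @export
export_replicate_ped <- function(rep, ped_path, map_path) {
  m <- ncol(rep$x)
  markers <- data.frame(chrom = "1", rsid = sprintf("sim%d", seq_len(m)),
                        cm = "0", pos = seq_len(m) * 1000L,
                        allele_minor = "B", allele_major = "A",
                        monomorphic = FALSE, stringsAsFactors = FALSE)
  gt <- genotype_table(rep$x * 2L, markers,
                       ifelse(rep$status == 1L, "case", "control"))
  write_ped_map(gt, ped_path, map_path)
  invisible(gt)
}
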
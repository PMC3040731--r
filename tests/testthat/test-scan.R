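test_that("windows partition markers within chromosomes, last window may be short", {
  mk1 <- data.frame(chrom = rep("1", 10), rsid = sprintf("rs%d", 1:10))
  w <- build_windows(mk1, k = 3)
  expect_length(w, 4)  # ceiling(10/3)
  expect_equal(lapply(w, `[[`, "marker_indices"),
               list(1:3, 4:6, 7:9, 10L))
  # k = 1: singleton windows, i.e. single-marker analysis
  expect_length(build_windows(mk1[1:5, , drop = FALSE], k = 1), 5)
  # chromosome boundary is never spanned
  mk2 <- data.frame(chrom = c(rep("1", 4), rep("2", 3)),
                    rsid = sprintf("rs%d", 1:7))
  w2 <- build_windows(mk2, k = 2)
  expect_equal(lapply(w2, `[[`, "marker_indices"),
               list(1:2, 3:4, 5:6, 7L))
  expect_equal(vapply(w2, `[[`, "", "chrom"), c("1", "1", "2", "2"))
  expect_error(build_windows(mk1, k = 0), "k must be")
})

test_that("testing burden is schemes times the sum of ceiling(M/k)", {
  expect_equal(count_tests(319813, 1:5, 2), 1460484)
  expect_equal(count_tests(10, 3, 1), 4)
  expect_equal(count_tests(7, c(2, 3), 2), 14)
  expect_error(count_tests(10, integer(0)), "non-empty")
})

test_that("union tables count indicators by group and exclude missing individuals", {
  dosage <- rbind(c(1L, 0L),   # case: dominant union 1
                  c(0L, 2L),   # case: 1
                  c(0L, 0L),   # control: 0
                  c(0L, NA),   # control: missing -> excluded
                  c(NA, 1L))   # control: 1 (known 1 beats missing)
  markers <- data.frame(chrom = "1", rsid = c("a", "b"), cm = "0",
                        pos = c(1L, 2L), allele_minor = "B",
                        allele_major = "A", monomorphic = FALSE)
  gt <- genotype_table(dosage, markers,
                       c("case", "case", "control", "control", "control"))
  tab <- tabulate_union(gt, list(marker_indices = 1:2, scheme = "dominant"))
  expect_equal(tab, list(cases_1 = 2L, cases_0 = 0L, controls_1 = 1L,
                         controls_0 = 1L, n_excluded = 1L))
  # conservation: cells + exclusions = individuals, under both schemes
  rec <- tabulate_union(gt, list(marker_indices = 1:2, scheme = "recessive"))
  for (t in list(tab, rec)) {
    expect_equal(t$cases_1 + t$cases_0 + t$controls_1 + t$controls_0 +
                   t$n_excluded, 5L)
  }
  # recessive: only dosage-2 genotypes fire; row 1 (1,0) codes (0,0) -> 0
  expect_equal(rec$cases_1, 1L)
  expect_equal(rec$n_excluded, 2L)  # rows (0,NA) and (NA,1): no BB seen
})

test_that("fisher_exact_2x2 matches stats::fisher.test and handles edge tables", {
  sym <- fisher_exact_2x2(list(cases_1 = 5, cases_0 = 5, controls_1 = 5, controls_0 = 5))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$degrees_of_freedom, 1L)

  set.seed(31)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(10:80, 1), prob = runif(4, 0.05, 1)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    mine <- fisher_exact_2x2(list(cases_1 = cells[1], cases_0 = cells[2],
                                  controls_1 = cells[3], controls_0 = cells[4]))
    ref <- fisher.test(matrix(cells, 2, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }

  # zero cell: Haldane-Anscombe correction on all four cells
  z <- fisher_exact_2x2(list(cases_1 = 0, cases_0 = 10, controls_1 = 5, controls_0 = 5))
  expect_equal(z$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  expect_true(z$ci_low < z$odds_ratio && z$odds_ratio < z$ci_high)

  # constant indicator: uninformative table
  const <- fisher_exact_2x2(list(cases_1 = 0, cases_0 = 10, controls_1 = 0, controls_0 = 8))
  expect_equal(const$p_value, 1)
  expect_true(is.na(const$odds_ratio))

  expect_error(fisher_exact_2x2(list(cases_1 = 0, cases_0 = 0,
                                     controls_1 = 3, controls_0 = 4)),
               "untestable")
})

test_that("odds ratio lies inside its Woolf confidence interval", {
  set.seed(32)
  for (i in 1:30) {
    cells <- as.integer(rmultinom(1, 60, prob = runif(4, 0.05, 1)))
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    r <- fisher_exact_2x2(list(cases_1 = cells[1], cases_0 = cells[2],
                               controls_1 = cells[3], controls_0 = cells[4]))
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  }
})

test_that("run_scan sets the Bonferroni threshold from the scanned marker count", {
  set.seed(33)
  gt <- random_genotype_table(n = 50, m = 10, n_chrom = 1)
  scan <- run_scan(gt, k_sizes = 2, schemes = "dominant", alpha = 0.05)
  expect_equal(nrow(scan$results), 5)
  expect_equal(scan$n_tests, 5)
  expect_equal(scan$threshold, 0.01)
  both <- run_scan(gt, k_sizes = 1:2, schemes = c("dominant", "recessive"))
  expect_equal(both$n_tests, 2 * (10 + 5))
  expect_equal(both$threshold, 0.05 / 30)
})

test_that("k = 1 scan reproduces per-marker Fisher tests exactly", {
  set.seed(34)
  gt <- random_genotype_table(n = 80, m = 6, miss_rate = 0.05, n_chrom = 1)
  for (scheme in c("dominant", "recessive")) {
    scan <- run_scan(gt, k_sizes = 1, schemes = scheme)
    res <- scan$results[order(scan$results$union_id), ]
    for (j in 1:6) {
      coded <- code_marker(gt$dosage[, j], scheme)
      keep <- !is.na(coded)
      tab <- table(factor(coded[keep], levels = c(1, 0)),
                   factor(gt$phenotype[keep], levels = c("case", "control")))
      ref <- if (sum(tab[, "case"]) == 0 || sum(tab[, "control"]) == 0) {
        NA_real_
      } else if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) {
        1
      } else {
        fisher.test(tab)$p.value
      }
      expect_equal(res$p_value[j], ref, tolerance = 1e-12,
                   label = sprintf("%s marker %d", scheme, j))
    }
  }
})

test_that("permuting phenotype labels permutes tables without hidden state", {
  set.seed(35)
  gt <- random_genotype_table(n = 40, m = 8, miss_rate = 0.1)
  perm <- sample(length(gt$phenotype))
  gt_perm <- genotype_table(gt$dosage[perm, , drop = FALSE], gt$markers,
                            gt$phenotype[perm])
  s1 <- run_scan(gt, k_sizes = 2, schemes = "dominant")
  s2 <- run_scan(gt_perm, k_sizes = 2, schemes = "dominant")
  o1 <- s1$results[order(s1$results$union_id), ]
  o2 <- s2$results[order(s2$results$union_id), ]
  expect_equal(o1$cases_1, o2$cases_1)
  expect_equal(o1$controls_0, o2$controls_0)
  expect_equal(o1$p_value, o2$p_value)
})

test_that("dominant unions over rare complete data equal the collapsing indicator", {
  set.seed(36)
  for (rep in 1:20) {
    n <- 30; m <- 4
    dosage <- matrix(rbinom(n * m, 2L, 0.04), n, m)  # rare: MAF <= 0.05
    coded <- code_marker(dosage, "dominant")
    union <- union_indicator_matrix(coded)
    collapsing <- as.integer(rowSums(dosage > 0) > 0)  # rare allele at any site
    expect_identical(union, collapsing)
  }
})
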
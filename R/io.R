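#' Construct a case-control genotype table
#'
#' The in-memory container consumed by the scan functions: a matrix of
#' minor-allele dosages (individuals x markers, entries 0/1/2 with `NA` for
#' missing), a marker map, and a binary phenotype.
#'
#' @param dosage integer matrix, individuals in rows, markers in columns;
#'   entries in \{0, 1, 2, `NA`\} counting copies of the minor allele.
#' @param markers data.frame with one row per dosage column: `chrom`, `rsid`,
#'   `cm` (genetic distance), `pos`, `allele_minor`, `allele_major`,
#'   `monomorphic` (logical).
#' @param phenotype factor or character with values `"case"`/`"control"`, one
#'   per dosage row.
#' @param samples optional data.frame of sample identifiers (`fid`, `iid`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(dosage, markers, phenotype, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(markers) != ncol(dosage)) {
    stop("marker map has ", nrow(markers), " rows but dosage has ",
         ncol(dosage), " columns")
  }
  if (length(phenotype) != nrow(dosage)) {
    stop("phenotype length does not match the number of individuals")
  }
  phenotype <- factor(as.character(phenotype), levels = c("control", "case"))
  if (anyNA(phenotype)) stop("phenotype must be 'case' or 'control'")
  bad <- !is.na(dosage) & !(dosage %in% c(0L, 1L, 2L))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  if (is.null(samples)) {
    samples <- data.frame(fid = paste0("F", seq_len(nrow(dosage))),
                          iid = paste0("I", seq_len(nrow(dosage))),
                          stringsAsFactors = FALSE)
  }
  structure(list(dosage = dosage, markers = markers,
                 phenotype = phenotype, samples = samples),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers;",
      sum(x$phenotype == "case"), "cases /",
      sum(x$phenotype == "control"), "controls\n")
  invisible(x)
}

#' Designate the minor allele from pooled allele tallies
#'
#' The minor allele B is the allele with the strictly lower frequency in the
#' pooled sample (cases and controls together, missing alleles excluded). An
#' exact tie is broken deterministically in favour of the lexicographically
#' smaller allele character. A monomorphic tally (one observed allele) is
#' flagged: the observed allele is major and no minor allele is assigned, so
#' the marker's dosage is all zero.
#'
#' @param tally named integer vector of allele counts, e.g. `c(A = 120, G = 80)`.
#' @return A list with `minor`, `major` (single characters, `minor` is `NA`
#'   for a monomorphic marker) and `monomorphic` (logical).
#' @examples
#' orient_minor_allele(c(A = 120, G = 80))  # minor G
#' orient_minor_allele(c(C = 50, T = 50))   # tie -> minor C
#' @export
orient_minor_allele <- function(tally) {
  tally <- tally[tally > 0]
  alleles <- names(tally)
  if (length(tally) == 0L) {
    return(list(minor = NA_character_, major = NA_character_, monomorphic = TRUE))
  }
  if (length(tally) == 1L) {
    return(list(minor = NA_character_, major = alleles[1L], monomorphic = TRUE))
  }
  if (length(tally) > 2L) {
    stop("more than two alleles observed: ", paste(alleles, collapse = ", "))
  }
  ord <- order(tally, alleles)  # lower count first; ties by allele character
  list(minor = alleles[ord[1L]], major = alleles[ord[2L]], monomorphic = FALSE)
}

#' Read case-control genotypes from PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PLINK text format: the MAP file gives
#' chromosome, rsid, genetic distance and base-pair position per marker; each
#' PED row gives family id, individual id, father, mother, sex and phenotype,
#' followed by two allele columns per marker. Allele `"0"` denotes missing; a
#' half-missing genotype (one allele `"0"`) is treated as fully missing.
#' Phenotype codes follow the PLINK case-control dialect: 1 = control,
#' 2 = case; individuals with any other code are dropped (a message reports
#' how many). Alleles are oriented to minor-allele dosage by pooled frequency
#' ([orient_minor_allele()]); monomorphic markers get an all-zero dosage
#' column.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [genotype_table()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character",
                           col.names = c("chrom", "rsid", "cm", "pos"))
  map$pos <- as.integer(map$pos)
  m <- nrow(map)

  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  expected_cols <- 6L + 2L * m
  if (ncol(ped) != expected_cols) {
    stop(sprintf(
      "PED/MAP mismatch: MAP lists %d markers so PED needs %d columns, found %d",
      m, expected_cols, ncol(ped)))
  }
  pheno_code <- ped[[6L]]
  keep <- pheno_code %in% c("1", "2")
  if (any(!keep)) {
    message(sum(!keep), " individual(s) excluded: phenotype code not 1/2")
    ped <- ped[keep, , drop = FALSE]
  }
  if (nrow(ped) == 0L) stop("no individuals with phenotype code 1 or 2")
  phenotype <- ifelse(ped[[6L]] == "2", "case", "control")
  n <- nrow(ped)

  dosage <- matrix(NA_integer_, n, m)
  markers <- map
  markers$allele_minor <- NA_character_
  markers$allele_major <- NA_character_
  markers$monomorphic <- FALSE
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    tally <- table(obs)
    if (length(tally) > 2L) {
      stop("marker ", map$rsid[j], " is not biallelic: alleles ",
           paste(names(tally), collapse = ", "))
    }
    ori <- orient_minor_allele(stats::setNames(as.integer(tally), names(tally)))
    markers$allele_minor[j] <- ori$minor
    markers$allele_major[j] <- ori$major
    markers$monomorphic[j] <- ori$monomorphic
    if (ori$monomorphic) {
      dos <- rep(0L, n)
    } else {
      dos <- (a1 == ori$minor) + (a2 == ori$minor)
    }
    dos[miss] <- NA_integer_
    dosage[, j] <- dos
  }
  genotype_table(dosage, markers, phenotype,
                 samples = data.frame(fid = ped[[1L]], iid = ped[[2L]],
                                      stringsAsFactors = FALSE))
}

#' Write a genotype table to PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: dosages are expanded back to two-allele
#' genotypes using the stored minor/major alleles (missing dosage becomes
#' `"0 0"`). For markers whose allele labels are unknown (e.g. simulated coded
#' data) placeholder alleles `A`/`B` are used, with `B` minor.
#'
#' @param gt a `genotype_table`.
#' @param ped_path,map_path output paths.
#' @return Invisibly, `gt`.
#' @export
write_ped_map <- function(gt, ped_path, map_path) {
  stopifnot(inherits(gt, "genotype_table"))
  mk <- gt$markers
  utils::write.table(data.frame(mk$chrom, mk$rsid, mk$cm, mk$pos),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  minor <- ifelse(is.na(mk$allele_minor), "B", mk$allele_minor)
  major <- ifelse(is.na(mk$allele_major), "A", mk$allele_major)
  n <- nrow(gt$dosage); m <- ncol(gt$dosage)
  geno <- matrix("", n, 2L * m)
  for (j in seq_len(m)) {
    d <- gt$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, minor[j], major[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, minor[j], major[j]))
    geno[, 2L * j - 1L] <- a1
    geno[, 2L * j] <- a2
  }
  lead <- data.frame(gt$samples$fid, gt$samples$iid, 0L, 0L, 0L,
                     ifelse(gt$phenotype == "case", 2L, 1L))
  utils::write.table(cbind(lead, geno), ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(gt)
}

#' Write union scan results as a tab-separated table
#'
#' One row per union, sorted by p-value: coding scheme, union size, member
#' rsids, chromosome, start/end positions, the four contingency counts, the
#' number of individuals excluded for missing indicators, p-value, odds ratio
#' with 95% interval, and a significance flag at the scan's Bonferroni
#' threshold.
#'
#' @param scan a `union_scan` from [run_scan()].
#' @param out_path output file path.
#' @return Invisibly, the written data.frame.
#' @export
write_scan_results <- function(scan, out_path) {
  stopifnot(inherits(scan, "union_scan"))
  if (nrow(scan$results) == 0L) stop("empty scan result")
  df <- scan$results[, c("scheme", "k", "rsids", "chrom", "start", "end",
                         "cases_1", "cases_0", "controls_1", "controls_0",
                         "n_excluded", "p_value", "odds_ratio",
                         "ci_low", "ci_high", "significant")]
  utils::write.table(df, out_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}
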
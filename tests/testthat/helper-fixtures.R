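# Fixture builders shared across test files. Everything is generated in code;
# PED/MAP files are written to tempdir() on demand.

# Four individuals, one marker: cases "T C","T T"; controls "C C","C C".
# Pooled counts T=3, C=5 so T is minor; case dosages (1,2), controls (0,0).
write_tiny_ped_map <- function(dir = tempfile("fix")) {
  dir.create(dir)
  ped <- c("F1 I1 0 0 1 2 T C",
           "F2 I2 0 0 2 2 T T",
           "F3 I3 0 0 1 1 C C",
           "F4 I4 0 0 2 1 C C")
  map <- "4\trs100\t0\t859000"
  writeLines(ped, file.path(dir, "tiny.ped"))
  writeLines(map, file.path(dir, "tiny.map"))
  list(ped = file.path(dir, "tiny.ped"), map = file.path(dir, "tiny.map"))
}

# Random genotype_table with optional missingness, for property tests.
random_genotype_table <- function(n = 40, m = 12, miss_rate = 0,
                                  n_chrom = 2, maf_range = c(0.1, 0.5)) {
  maf <- runif(m, maf_range[1], maf_range[2])
  dosage <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  if (miss_rate > 0) {
    dosage[runif(n * m) < miss_rate] <- NA_integer_
  }
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), m))
  markers <- data.frame(
    chrom = chrom, rsid = sprintf("rs%d", seq_len(m)), cm = "0",
    pos = unlist(lapply(split(seq_len(m), chrom), seq_along)) * 1000L,
    allele_minor = "B", allele_major = "A", monomorphic = FALSE,
    stringsAsFactors = FALSE)
  markers <- markers[order(markers$chrom, markers$pos), ]
  rownames(markers) <- NULL
  phenotype <- rep(c("case", "control"), length.out = n)
  genotype_table(dosage, markers, phenotype)
}

# Independent hypergeometric enumeration oracle for the two-sided Fisher
# p-value, built from binomial coefficients via lchoose (not dhyper).
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  m1 <- a + b; m2 <- c + d; K <- a + c
  if (K == 0 || b + d == 0) return(1)
  support <- max(0, K - m2):min(K, m1)
  logp <- lchoose(m1, support) + lchoose(m2, K - support) - lchoose(m1 + m2, K)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}
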
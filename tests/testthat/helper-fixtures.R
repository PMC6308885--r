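# Shared fixture builders for the test suite. Everything is constructed
# in code; no binary fixtures.

# A small genotype matrix with explicit dosages (rows = individuals).
toy_gm <- function(dosage, pops, depth = NULL, ...) {
  genotype_matrix(dosage, population = pops, depth = depth, ...)
}

# Hand-written VCF text (independent of write_vcf) so read_vcf is tested
# against a fixture the package did not itself produce.
write_test_vcf <- function(path, gt, dp = NULL, samples = colnames(gt),
                           alt = rep("T", nrow(gt))) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (!is.null(dp))
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  rows <- vapply(seq_len(nrow(gt)), function(i) {
    cell <- gt[i, ]
    if (!is.null(dp)) cell <- paste(cell, dp[i, ], sep = ":")
    paste(c("tag1", i, paste0("snp", i), "A", alt[i], ".", "PASS", ".",
            fmt, cell), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# Exact null distribution of the HWE chi-square statistic under random
# pairing of the observed allele copies (Levene's conditional
# distribution) -- the independent oracle for the permutation test.
levene_exact_p <- function(counts) {
  n <- sum(counts)
  nA <- 2 * counts[3] + counts[2]
  na <- 2 * n - nA
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  chs <- function(cc) {
    p <- (2 * cc[3] + cc[2]) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    ok <- e > 0
    sum((cc[ok] - e[ok])^2 / e[ok])
  }
  pr <- vapply(hs, function(h) {
    c11 <- (nA - h) / 2
    c00 <- n - h - c11
    exp(lfactorial(n) - lfactorial(c00) - lfactorial(h) -
          lfactorial(c11) + h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  st <- vapply(hs, function(h) {
    c11 <- (nA - h) / 2
    chs(c(n - h - c11, h, c11))
  }, numeric(1))
  sum(pr[st >= chs(counts) - 1e-9])
}

# Two-deme genotype matrix: background loci differ weakly between demes
# (bg_deme), a chosen set strongly (p_deme).
two_deme_gm <- function(n_per_deme = 50, n_loci = 500, diff_loci = 1,
                        bg_deme = c(0.5, 0.5), p_deme = c(0.9, 0.1),
                        seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_deme
  p <- matrix(rep(rep(bg_deme, each = n_per_deme), n_loci), n, n_loci)
  if (diff_loci > 0) {
    p[seq_len(n_per_deme), seq_len(diff_loci)] <- p_deme[1]
    p[-seq_len(n_per_deme), seq_len(diff_loci)] <- p_deme[2]
  }
  d <- matrix(rbinom(n * n_loci, 2, p), n, n_loci,
              dimnames = list(paste0(rep(c("A", "B"), each = n_per_deme),
                                     "_i", seq_len(n)),
                              sprintf("L%03d", seq_len(n_loci))))
  genotype_matrix(d, population = rep(c("A", "B"), each = n_per_deme))
}
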
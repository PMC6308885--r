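test_that("the cascade drops exactly the loci each rule targets", {
  # 6 loci x 10 individuals: A half missing, B monomorphic (MAF 0),
  # C fully heterozygous (Ho = 1), D-F clean
  set.seed(1)
  clean <- function() sample(c(0L, 1L, 2L), 10, replace = TRUE,
                             prob = c(0.5, 0.35, 0.15))
  d <- cbind(A = c(rep(NA_integer_, 5), clean()[1:5]),
             B = rep(0L, 10),
             C = rep(1L, 10),
             D = clean(), E = clean(), F = clean())
  gm <- toy_gm(d, rep(c("P1", "P2"), each = 5))
  res <- apply_qc(gm, qc_config(min_genotype_depth = 0))
  expect_identical(colnames(res$genotypes$dosage), c("D", "E", "F"))
  expect_equal(res$report$locus_reason[["A"]], "missingness")
  expect_equal(res$report$locus_reason[["B"]], "maf")
  expect_equal(res$report$locus_reason[["C"]], "observed_het")
  # survivor counts are non-increasing along the cascade
  expect_true(all(diff(res$report$steps$n_loci) <= 0))
  expect_true(all(diff(res$report$steps$n_individuals) <= 0))
})

test_that("a clean matrix passes unchanged and the cascade is idempotent", {
  set.seed(2)
  d <- matrix(rbinom(200, 2, 0.4), 20, 10)
  dep <- matrix(30L, 20, 10)
  gm <- toy_gm(d, rep(c("P1", "P2"), each = 10), depth = dep)
  res <- apply_qc(gm)
  expect_identical(res$genotypes$dosage, gm$dosage)
  expect_length(res$report$locus_reason, 0)
  res2 <- apply_qc(res$genotypes)
  expect_identical(res2$genotypes$dosage, res$genotypes$dosage)
  expect_length(res2$report$locus_reason, 0)
})

test_that("depth rules convert low-coverage genotypes and drop high-depth loci", {
  d <- matrix(1L, 8, 3)
  dep <- matrix(30L, 8, 3)
  dep[1, 1] <- 9L          # one genotype under 10 reads
  dep[, 3] <- 80L          # locus with mean depth > 50
  gm <- toy_gm(d, rep("P1", 8), depth = dep)
  res <- apply_qc(gm, qc_config(max_obs_het = 1, min_maf = 0))
  expect_true(is.na(res$genotypes$dosage[1, 1]))
  expect_false("locus3" %in% colnames(res$genotypes$dosage))
  expect_equal(res$report$locus_reason[["locus3"]], "mean_depth")
})

test_that("low call-rate individuals and undersized populations are removed", {
  set.seed(3)
  d <- matrix(rbinom(120, 2, 0.5), 12, 10)
  d[1, ] <- NA_integer_                      # call rate 0
  d[1, 1:3] <- 0L                            # 30% < 40%
  gm <- toy_gm(d, rep(c("P1", "P2", "P3"), each = 4))
  res <- apply_qc(gm, qc_config(min_genotype_depth = 0, min_maf = 0,
                                max_obs_het = 1))
  expect_false(rownames(gm$dosage)[1] %in% rownames(res$genotypes$dosage))
  # P1 falls to 3 genotyped individuals, under the minimum of 4
  expect_false("P1" %in% res$genotypes$population)
  expect_setequal(unique(res$genotypes$population), c("P2", "P3"))
})

test_that("HWE permutation p-values match the exact pairing distribution", {
  # Levene's conditional distribution is the exact null of the allele
  # re-pairing scheme; the permutation estimate must agree within
  # Monte-Carlo error
  for (counts in list(c(4, 2, 4), c(6, 0, 4), c(0, 10, 0))) {
    g <- rep(c(0L, 1L, 2L), counts)
    exact <- levene_exact_p(counts)
    set.seed(99)
    perm <- hwe_test(g, n_perm = 3000)$p_value
    se <- sqrt(exact * (1 - exact) / 3000)
    expect_lt(abs(perm - exact), 4 * se + 2 / 3001)
  }
})

test_that("HWE test handles equilibrium, fixed-heterozygote and monomorphic cases", {
  at_hw <- rep(c(0L, 1L, 2L), c(25, 50, 25))
  set.seed(4)
  expect_gt(hwe_test(at_hw, n_perm = 500)$p_value, 0.5)
  all_het <- rep(1L, 100)
  set.seed(4)
  expect_equal(hwe_test(all_het, n_perm = 1000)$p_value, 1 / 1001)
  expect_equal(hwe_test(rep(0L, 30))$p_value, 1)
  expect_equal(hwe_test(rep(2L, 30))$p_value, 1)
  expect_error(hwe_test(c(1L, NA)), "at least 2")
})

test_that("HWE p-values are valid and non-degenerate under equilibrium", {
  # permutation p-values at finite sample size are discrete and
  # conservative (stochastically at least uniform), so the correct
  # distributional property is validity: P(p <= t) <= t, up to
  # Monte-Carlo error, at every level, without collapsing to 1
  set.seed(5)
  pvals <- replicate(300, {
    p <- runif(1, 0.2, 0.8)
    g <- rbinom(60, 2, p)
    if (length(unique(g)) == 1) 1 else hwe_test(g, n_perm = 400)$p_value
  })
  for (t in c(0.01, 0.05, 0.10, 0.25, 0.5)) {
    mc <- 3 * sqrt(t * (1 - t) / 300)
    expect_lte(mean(pvals <= t), t + mc)
  }
  expect_gte(mean(pvals <= 0.5), 0.25)
  expect_gte(mean(pvals <= 0.10), 0.02)
})

test_that("clone detection groups identical multilocus genotypes only", {
  set.seed(6)
  d <- matrix(rbinom(500, 2, 0.5), 5, 100)
  d <- rbind(d, d[3, , drop = FALSE])  # duplicate individual 3
  rownames(d) <- paste0("i", 1:6)
  gm <- toy_gm(d, rep("P1", 6))
  grp <- detect_clones(gm, min_shared_loci = 50)
  expect_length(grp, 1)
  expect_setequal(grp[[1]], c("i3", "i6"))

  gm2 <- toy_gm(d[1:5, ], rep("P1", 5))
  expect_length(detect_clones(gm2, min_shared_loci = 50), 0)

  # equal at 100 shared loci but discordant at one more -> not clones
  d3 <- rbind(a = c(rep(0L, 100), 0L), b = c(rep(0L, 100), 1L),
              c = c(rep(1L, 50), rep(0L, 51)))
  gm3 <- toy_gm(d3, rep("P1", 3))
  expect_length(detect_clones(gm3, min_shared_loci = 50), 0)
})

test_that("hwe_report summarizes departures per population without filtering", {
  set.seed(7)
  d <- matrix(rbinom(300, 2, 0.5), 15, 20)
  gm <- toy_gm(d, rep(c("P1", "P2", "P3"), each = 5))
  rep_ <- hwe_report(gm, n_perm = 100)
  expect_equal(rep_$population, c("P1", "P2", "P3"))
  expect_true(all(rep_$fraction >= 0 & rep_$fraction <= 1))
})
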
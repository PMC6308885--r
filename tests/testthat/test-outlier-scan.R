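test_that("scree elbow recovers the single structured dimension of a two-deme system", {
  gm <- two_deme_gm(n_per_deme = 40, n_loci = 400, diff_loci = 80,
                    bg_deme = c(0.45, 0.55), p_deme = c(0.85, 0.15),
                    seed = 21)
  ck <- choose_k(gm, k_max = 10)
  expect_equal(ck$k, 1L)
  expect_length(ck$scree, 10)
  expect_true(all(diff(ck$scree) <= 1e-12))
  expect_error(choose_k(gm, k_max = 100), "smaller than")
})

test_that("a strongly differentiated locus tops the Mahalanobis ranking and is flagged", {
  # weak background differentiation (0.45 vs 0.55) aligns the first
  # component with the deme split; the 0.9-vs-0.1 locus then carries an
  # extreme z-score on it
  gm <- two_deme_gm(n_per_deme = 50, n_loci = 500, diff_loci = 1,
                    bg_deme = c(0.45, 0.55), p_deme = c(0.9, 0.1),
                    seed = 22)
  scan <- pca_scan(gm, k = 1, fdr_level = 0.10)
  expect_equal(names(which.max(scan$d2)), "L001")
  expect_true("L001" %in% scan$outliers)
  expect_true(all(scan$d2 >= 0))
  expect_true(all(scan$p_values > 0 & scan$p_values <= 1))
})

test_that("a panmictic population yields no inflation and almost no flags", {
  set.seed(23)
  n <- 100; L <- 500
  p <- runif(L, 0.1, 0.9)
  d <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  gm <- toy_gm(d, rep("P1", n))
  scan <- pca_scan(gm, k = 2)
  expect_lt(abs(scan$lambda - 1), 0.35)
  expect_lt(length(scan$outliers) / L, 0.02)
})

test_that("the PCA scan is deterministic for identical inputs", {
  gm <- two_deme_gm(n_per_deme = 30, n_loci = 200, diff_loci = 5, seed = 24)
  s1 <- pca_scan(gm, k = 2, seed = 9)
  s2 <- pca_scan(gm, k = 2, seed = 9)
  expect_identical(s1$outliers, s2$outliers)
  expect_identical(s1$d2, s2$d2)
})

test_that("collinearity prescreen removes the minimal offending set", {
  set.seed(25)
  z <- rnorm(30)
  env <- data.frame(a = z, b = z, c = rnorm(30))  # exact duplicate pair
  red <- prescreen_environment(env, r_threshold = 0.7)
  expect_length(attr(red, "removed"), 1)
  expect_true(attr(red, "removed") %in% c("a", "b"))

  env2 <- data.frame(a = rnorm(30), b = rnorm(30))
  red2 <- prescreen_environment(env2, r_threshold = 0.7)
  expect_length(attr(red2, "removed"), 0)
  expect_equal(ncol(red2), 2)

  # three mutually correlated variables: two must go
  base <- rnorm(40)
  env3 <- data.frame(a = base + rnorm(40, sd = 0.2),
                     b = base + rnorm(40, sd = 0.2),
                     c = base + rnorm(40, sd = 0.2),
                     d = rnorm(40))
  stopifnot(all(abs(cor(env3[, 1:3])[upper.tri(diag(3))]) > 0.7))
  red3 <- prescreen_environment(env3, r_threshold = 0.7)
  expect_length(attr(red3, "removed"), 2)
  expect_true("d" %in% colnames(red3))
})

test_that("variance inflation factors match their closed forms", {
  # orthonormal mean-centred predictors -> VIF exactly 1
  set.seed(29)
  Q <- qr.Q(qr(scale(matrix(rnorm(60), 20, 3), scale = FALSE)))
  env <- as.data.frame(Q)
  expect_equal(unname(vif_check(env)), rep(1, 3), tolerance = 1e-10)

  # two predictors with sample r = 0.6 exactly -> VIF = 1/(1-0.36)
  v1 <- Q[, 1]; v2 <- 0.6 * Q[, 1] + 0.8 * Q[, 2]
  env2 <- data.frame(v1 = v1, v2 = v2, v3 = Q[, 3])
  vif <- vif_check(env2)
  expect_equal(unname(vif[c("v1", "v2")]), rep(1.5625, 2), tolerance = 1e-8)

  env3 <- data.frame(a = v1, b = v1)
  w <- capture_warnings(out <- vif_check(env3))
  expect_true(any(grepl("VIF above", w)))
  expect_true(all(is.infinite(out)))
})

test_that("an environment-linear locus is the top RDA outlier", {
  set.seed(26)
  n_sites <- 12; per <- 5
  E <- seq(-1.5, 1.5, length.out = n_sites)
  pops <- rep(sprintf("S%02d", 1:n_sites), each = per)
  L <- 80
  d <- matrix(rbinom(n_sites * per * L, 2, 0.5), n_sites * per, L)
  # dosage of locus 1 tracks E with small noise
  lin <- rep(E, each = per) + rnorm(n_sites * per, sd = 0.2)
  d[, 1] <- pmin(pmax(round((lin + 1.8) / 3.6 * 2), 0), 2)
  colnames(d) <- sprintf("L%03d", 1:L)
  gm <- toy_gm(d, pops)
  env <- data.frame(E = E, row.names = sprintf("S%02d", 1:n_sites))
  scan <- rda_scan(gm, env, n_perm = 199, axes = 1, seed = 5)
  expect_equal(names(which.max(abs(scan$zloadings[, 1]))), "L001")
  expect_true("L001" %in% scan$outliers)
  expect_equal(unname(scan$axis_env[1]), "E")
  expect_true(scan$var_explained > 0 && scan$var_explained < 1)
  expect_true(all(scan$eig_share >= 0) && sum(scan$eig_share) <= 1 + 1e-9)
})

test_that("RDA axis retention under a pure-noise null is rare", {
  set.seed(27)
  retained <- vapply(1:60, function(b) {
    n_sites <- 9; per <- 3; L <- 40
    pops <- rep(sprintf("S%d", 1:n_sites), each = per)
    d <- matrix(rbinom(n_sites * per * L, 2, 0.5), n_sites * per, L,
                dimnames = list(NULL, sprintf("L%02d", 1:L)))
    env <- data.frame(E = rnorm(n_sites), V = rnorm(n_sites),
                      row.names = sprintf("S%d", 1:n_sites))
    scan <- suppressWarnings(
      rda_scan(toy_gm(d, pops), env, n_perm = 99, seed = b))
    length(scan$retained_axes)
  }, numeric(1))
  expect_lte(mean(retained > 0), 0.15)
})

test_that("partition arithmetic holds exactly, including the study-scale case", {
  loci <- sprintf("L%04d", 1:1709)
  pca <- loci[1:173]
  rda <- loci[135:229]           # overlap of 39 with the PCA set
  part <- build_partition(loci, pca, rda)
  expect_equal(unname(partition_sizes(part)),
               c(1709L, 1480L, 1670L, 229L, 39L))

  # disjoint flags: DS5 empty, DS3 = DS1
  p2 <- build_partition(loci, loci[1:10], loci[11:20])
  expect_equal(sum(p2$DS5), 0L)
  expect_identical(partition_loci(p2, "DS3"), loci)
  # identical flags: DS4 = DS5, DS2 = DS3
  p3 <- build_partition(loci, loci[1:50], loci[1:50])
  expect_identical(p3$DS4, p3$DS5)
  expect_identical(p3$DS2, p3$DS3)

  expect_error(build_partition(loci[1:10], "LX", character(0)),
               "unknown locus")
})

test_that("partition identities hold for arbitrary random flag sets", {
  set.seed(28)
  for (i in 1:25) {
    loci <- sprintf("L%03d", seq_len(sample(20:200, 1)))
    pca <- sample(loci, sample(0:length(loci), 1))
    rda <- sample(loci, sample(0:length(loci), 1))
    part <- build_partition(loci, pca, rda)
    s <- partition_sizes(part)
    expect_equal(s[["DS2"]], s[["DS1"]] - s[["DS4"]])
    expect_equal(s[["DS3"]], s[["DS1"]] - s[["DS5"]])
    expect_true(all(part$loci[part$DS5] %in% part$loci[part$DS4]))
    expect_setequal(partition_loci(part, "DS4"), union(pca, rda))
    expect_setequal(partition_loci(part, "DS5"), intersect(pca, rda))
  }
})
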
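test_that("identical seeds give identical scenarios; truth labels partition loci", {
  cfg <- scenario_config(n_sites = 8, individuals_per_site = 5,
                         n_neutral_loci = 60, n_adaptive_loci = 20)
  a <- simulate_sgdc_scenario(cfg, seed = 3)
  b <- simulate_sgdc_scenario(cfg, seed = 3)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$community, b$community)
  expect_identical(a$environment, b$environment)
  d <- simulate_sgdc_scenario(cfg, seed = 4)
  expect_false(identical(a$genotypes$dosage, d$genotypes$dosage))

  expect_equal(sort(unique(a$truth$class)), c("adaptive", "neutral"))
  expect_equal(table(a$truth$class)[["neutral"]], 60L)
  expect_equal(table(a$truth$class)[["adaptive"]], 20L)
  expect_identical(a$truth$locus_id, colnames(a$genotypes$dosage))
})

test_that("connectivity drives true-frequency heterozygosity monotonically", {
  # high-connectivity sites drift less, so their mean He (computed on the
  # simulated frequencies, before genotype sampling) ranks with c_i
  cfg <- scenario_config(n_sites = 20, individuals_per_site = 10,
                         n_neutral_loci = 900, n_adaptive_loci = 100,
                         cline_slope = 3, theta_range = c(10, 200))
  g <- simulate_genotypes(cfg, seed = 5)
  neutral <- g$truth$class == "neutral"
  he_true <- rowMeans(2 * g$freq[, neutral] * (1 - g$freq[, neutral]))
  expect_gt(cor(he_true, g$sites$connectivity, method = "spearman"), 0)
})

test_that("with no cline, adaptive loci look neutral to the outlier scan", {
  # b = 0 and uniform drift: adaptive loci vary between sites only through
  # site noise of the same order as drift, so the structure scan should
  # flag them at no more than the background false-positive rate
  cfg <- scenario_config(n_sites = 15, individuals_per_site = 6,
                         n_neutral_loci = 300, n_adaptive_loci = 300,
                         cline_slope = 0, theta_range = c(50, 50),
                         missingness = 0)
  g <- simulate_genotypes(cfg, seed = 11)
  v <- apply(g$freq, 2, var)
  cls <- g$truth$class
  # between-site frequency variances of the two classes on the same scale
  expect_lt(abs(log(mean(v[cls == "adaptive"]) / mean(v[cls == "neutral"]))),
            log(3))
  scan <- pca_scan(g$genotypes, k = 2)
  adaptive <- g$truth$locus_id[cls == "adaptive"]
  expect_lte(mean(adaptive %in% scan$outliers), 0.10)
})

test_that("a strong cline under weak drift inflates adaptive between-site variance", {
  cfg <- scenario_config(n_sites = 15, individuals_per_site = 6,
                         n_neutral_loci = 300, n_adaptive_loci = 300,
                         cline_slope = 3, theta_range = c(150, 200))
  g <- simulate_genotypes(cfg, seed = 12)
  v <- apply(g$freq, 2, var)
  cls <- g$truth$class
  expect_gt(mean(v[cls == "adaptive"]), 2 * mean(v[cls == "neutral"]))
})

test_that("community richness follows the connectivity model", {
  cfg0 <- scenario_config(n_sites = 10, richness_slope = 0,
                          richness_noise_sd = 0)
  com <- simulate_community(cfg0, seed = 2)
  S <- species_alpha(com$community)$richness
  expect_true(all(S == S[1]))

  cfg1 <- scenario_config(n_sites = 10, richness_slope = 12,
                          richness_noise_sd = 0)
  com <- simulate_community(cfg1, seed = 2)
  S <- species_alpha(com$community)$richness
  # monotone in connectivity (ties possible through rounding)
  expect_true(all(diff(S[order(com$sites$connectivity)]) >= 0))
  expect_gt(cor(S, com$sites$connectivity, method = "spearman"), 0.9)
  expect_true(all(S >= 2 & S <= cfg1$species_pool_size))
})

test_that("richness and neutral He covary positively across seed replicates", {
  cfg <- scenario_config(n_sites = 17, individuals_per_site = 5,
                         n_neutral_loci = 150, n_adaptive_loci = 0)
  hits <- vapply(1:100, function(s) {
    g <- simulate_genotypes(cfg, seed = 1000 + s)
    com <- simulate_community(cfg, seed = 1000 + s)
    he <- rowMeans(2 * g$freq * (1 - g$freq))
    S <- species_alpha(com$community)$richness
    cor(he, S) > 0
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("simulated environment exercises the collinearity prescreen", {
  cfg <- scenario_config(n_sites = 20,
                         nuisance_correlations = c(0.9, 0.3, 0.1))
  env <- simulate_environment(cfg, seed = 6)$environment
  red <- prescreen_environment(env, r_threshold = 0.7)
  expect_equal(length(attr(red, "removed")), 1L)  # one of the 0.9 pair
  expect_true(attr(red, "removed") %in% c("E", "V1"))

  cfg0 <- scenario_config(n_sites = 20,
                          nuisance_correlations = c(0.3, 0.2, 0.1))
  env0 <- simulate_environment(cfg0, seed = 6)$environment
  red0 <- prescreen_environment(env0, r_threshold = 0.7)
  expect_equal(length(attr(red0, "removed")), 0L)

  # two-level categorical encodes to a single indicator column
  X <- sgdcpart:::encode_environment(env0)
  expect_equal(sum(startsWith(colnames(X), "aspect_")), 1L)
  expect_true(all(X[, startsWith(colnames(X), "aspect_")] %in% 0:1))
})

test_that("degenerate scenario configs are rejected", {
  expect_error(scenario_config(n_sites = 1), "at least 2 sites")
  expect_error(scenario_config(n_neutral_loci = 0, n_adaptive_loci = 0),
               "at least one locus")
  expect_error(scenario_config(theta_range = c(5, 1)), "theta_range")
  expect_error(scenario_config(missingness = 1.2), "missingness")
})
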
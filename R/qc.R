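#' Quality-control thresholds for GBS SNP data
#'
#' Defaults follow the filtering cascade typical of genotyping-by-
#' sequencing population datasets: genotypes under 10 reads treated as
#' missing, loci with mean depth above 50 dropped (paralog-prone), loci
#' with 40\% or more missing data dropped, minor allele frequency at least
#' 0.04, biallelic loci only, observed heterozygosity at most 0.5 (paralog
#' screen), individuals with call rate under 40\% removed, and populations
#' left with fewer than 4 genotyped individuals dropped. A stricter
#' 30\%-missing sensitivity variant is available as a preset.
#'
#' @param min_genotype_depth genotypes with fewer reads become missing.
#' @param max_mean_locus_depth drop loci whose mean depth over non-missing
#'   genotypes exceeds this ("site depth" in VCF parlance).
#' @param max_locus_missing drop loci with missing fraction at or above
#'   this (strict-less retention).
#' @param min_maf minimum minor allele frequency over all remaining
#'   individuals.
#' @param max_obs_het drop loci with observed heterozygosity above this.
#' @param min_call_rate drop individuals genotyped at fewer than this
#'   fraction of loci.
#' @param min_per_population drop populations left with fewer individuals.
#' @param hwe_permutations permutations for [hwe_report()].
#' @param preset `"default"` or `"strict_missing"` (30\% missing filter).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_genotype_depth = 10, max_mean_locus_depth = 50,
                      max_locus_missing = 0.40, min_maf = 0.04,
                      max_obs_het = 0.5, min_call_rate = 0.40,
                      min_per_population = 4, hwe_permutations = 1000,
                      preset = c("default", "strict_missing")) {
  preset <- match.arg(preset)
  if (preset == "strict_missing") max_locus_missing <- 0.30
  cfg <- list(min_genotype_depth = min_genotype_depth,
              max_mean_locus_depth = max_mean_locus_depth,
              max_locus_missing = max_locus_missing, min_maf = min_maf,
              max_obs_het = max_obs_het, min_call_rate = min_call_rate,
              min_per_population = min_per_population,
              hwe_permutations = hwe_permutations)
  fr <- c("max_locus_missing", "min_maf", "max_obs_het", "min_call_rate")
  if (any(unlist(cfg[fr]) < 0 | unlist(cfg[fr]) > 1))
    stop("fractional thresholds must lie in [0, 1]")
  if (min_genotype_depth < 0 || min_per_population < 1)
    stop("count thresholds must be positive")
  structure(cfg, class = "qc_config")
}

#' Apply the SNP filtering cascade
#'
#' Runs the eight-step quality-control cascade in fixed order: (1) low-
#' depth genotypes to missing; (2) high mean-depth loci out; (3) high-
#' missingness loci out; (4) low-MAF loci out; (5) multiallelic-flagged
#' loci out; (6) high observed-heterozygosity loci out; (7) low call-rate
#' individuals out; (8) populations with too few individuals out. The
#' order matters (steps 3 and 4 do not commute); the cascade always uses
#' this order and records the surviving counts after each step. The
#' cascade is idempotent: a second pass with the same thresholds excludes
#' nothing further.
#'
#' @param x a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (a `qc_report`: per-step counts plus per-locus exclusion reasons).
#' @export
apply_qc <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(cfg, "qc_config"))
  steps <- data.frame(step = character(), n_loci = integer(),
                      n_individuals = integer(), stringsAsFactors = FALSE)
  note <- function(lab) {
    steps[nrow(steps) + 1L, ] <<- list(lab, ncol(x$dosage), nrow(x$dosage))
  }
  reasons <- stats::setNames(rep(NA_character_, ncol(x$dosage)),
                             colnames(x$dosage))
  drop_loci <- function(bad, why) {
    if (any(bad)) {
      reasons[colnames(x$dosage)[bad]] <<- why
      x <<- subset_gm(x, loci = !bad)
    }
  }
  note("input")

  if (!is.null(x$depth)) {
    x$dosage[x$depth < cfg$min_genotype_depth] <- NA_integer_
  } else if (cfg$min_genotype_depth > 0) {
    warning("no depth stored; depth-based steps skipped")
  }
  note("genotype_depth")

  if (!is.null(x$depth)) {
    md <- colSums(x$depth * !is.na(x$dosage)) /
      pmax(colSums(!is.na(x$dosage)), 1)
    drop_loci(md > cfg$max_mean_locus_depth, "mean_depth")
  }
  note("mean_locus_depth")

  miss <- colMeans(is.na(x$dosage))
  drop_loci(miss >= cfg$max_locus_missing, "missingness")
  note("locus_missingness")

  n_ok <- colSums(!is.na(x$dosage))
  p <- colSums(x$dosage, na.rm = TRUE) / (2 * pmax(n_ok, 1))
  maf <- pmin(p, 1 - p)
  drop_loci(maf < cfg$min_maf | n_ok == 0, "maf")
  note("maf")

  drop_loci(!x$biallelic, "multiallelic")
  note("biallelic")

  ho <- colMeans(x$dosage == 1L, na.rm = TRUE)
  drop_loci(!is.na(ho) & ho > cfg$max_obs_het, "observed_het")
  note("observed_het")

  cr <- rowMeans(!is.na(x$dosage))
  if (any(cr < cfg$min_call_rate))
    x <- subset_gm(x, individuals = cr >= cfg$min_call_rate)
  note("individual_call_rate")

  tab <- table(x$population)
  keep_pop <- names(tab)[tab >= cfg$min_per_population]
  if (length(keep_pop) < length(tab))
    x <- subset_gm(x, individuals = x$population %in% keep_pop)
  note("population_size")

  if (ncol(x$dosage) == 0 || nrow(x$dosage) == 0)
    warning("no loci or individuals survive quality control")
  report <- structure(list(steps = steps,
                           locus_reason = reasons[!is.na(reasons)],
                           config = cfg),
                      class = "qc_report")
  list(genotypes = x, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality-control cascade:\n")
  print(x$steps, row.names = FALSE)
  if (length(x$locus_reason)) {
    cat("loci excluded by reason:\n")
    print(table(x$locus_reason))
  }
  invisible(x)
}

# chi-square statistic of observed genotype counts vs Hardy-Weinberg
# expectation; counts = c(n00, n01, n11) of the counted allele.
hw_chisq <- function(counts) {
  n <- sum(counts)
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  ok <- e > 0
  sum((counts[ok] - e[ok])^2 / e[ok])
}

#' Permutation test for Hardy-Weinberg equilibrium at one locus
#'
#' The observed statistic is the chi-square discrepancy between genotype
#' counts and their Hardy-Weinberg expectation at the sample allele
#' frequency. The null distribution is generated by shuffling the 2n
#' allele copies and re-pairing them into n genotypes `n_perm` times;
#' the p-value uses the add-one rule (count >= observed + 1)/(n_perm + 1).
#' Monomorphic loci return p = 1 by convention. Departures are reported,
#' not used to drop loci.
#'
#' @param x a `genotype_matrix`, or a bare dosage vector (0/1/2, NA).
#' @param population site ID (ignored for a bare vector).
#' @param locus locus ID (ignored for a bare vector).
#' @param n_perm number of permutations (default 1000).
#' @return list with `statistic`, `p_value`, `n`.
#' @export
hwe_test <- function(x, population = NULL, locus = NULL, n_perm = 1000) {
  g <- if (inherits(x, "genotype_matrix")) {
    if (is.null(population) || is.null(locus))
      stop("give 'population' and 'locus' for a genotype_matrix")
    x$dosage[x$population == population, locus]
  } else as.integer(x)
  g <- g[!is.na(g)]
  n <- length(g)
  if (n < 2) stop("need at least 2 non-missing genotypes")
  counts <- tabulate(g + 1L, nbins = 3L)
  if (counts[1] == n || counts[3] == n)  # monomorphic
    return(list(statistic = 0, p_value = 1, n = n))
  obs <- hw_chisq(counts)
  alleles <- rep(c(0L, 1L), c(2 * counts[1] + counts[2],
                              counts[2] + 2 * counts[3]))
  perm <- vapply(seq_len(n_perm), function(b) {
    a <- sample(alleles)
    gs <- a[seq(1, 2 * n, 2)] + a[seq(2, 2 * n, 2)]
    hw_chisq(tabulate(gs + 1L, nbins = 3L))
  }, numeric(1))
  list(statistic = obs,
       p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
       n = n)
}

#' Per-population summary of Hardy-Weinberg departures
#'
#' Runs [hwe_test()] for every polymorphic locus within every population
#' and reports the fraction of loci departing at the given level. Reported
#' for inspection only; no loci are removed on this basis.
#'
#' @param x a `genotype_matrix`.
#' @param n_perm permutations per test.
#' @param alpha significance level for the departure count.
#' @param min_genotyped skip locus/population pairs with fewer non-missing
#'   genotypes.
#' @return data frame: population, n_tested, n_departing, fraction.
#' @export
hwe_report <- function(x, n_perm = 1000, alpha = 0.05, min_genotyped = 4) {
  pops <- unique(x$population)
  out <- lapply(pops, function(s) {
    gs <- x$dosage[x$population == s, , drop = FALSE]
    ok <- colSums(!is.na(gs)) >= min_genotyped
    pv <- vapply(which(ok), function(j) {
      g <- gs[, j]
      g <- g[!is.na(g)]
      if (all(g == g[1])) 1 else hwe_test(g, n_perm = n_perm)$p_value
    }, numeric(1))
    data.frame(population = s, n_tested = length(pv),
               n_departing = sum(pv <= alpha),
               fraction = if (length(pv)) mean(pv <= alpha) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect clonal individuals (identical multilocus genotypes)
#'
#' Two individuals are called clonal when their genotypes agree at every
#' locus non-missing in both, provided they share at least
#' `min_shared_loci` such loci. Clonal pairs are chained into groups.
#'
#' @param x a `genotype_matrix`.
#' @param min_shared_loci minimum jointly genotyped loci for a comparison
#'   to count (default 50).
#' @return list of character vectors of individual IDs (groups of size
#'   at least 2); empty list when no clones are found.
#' @export
detect_clones <- function(x, min_shared_loci = 50) {
  g <- x$dosage
  n <- nrow(g)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (sum(shared) >= min_shared_loci &&
          all(g[i, shared] == g[j, shared]))
        parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- split(rownames(g), root)
  unname(grp[lengths(grp) >= 2])
}
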
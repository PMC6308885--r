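#' Site-level (alpha) species-genetic diversity correlation
#'
#' Pearson correlation between per-site genetic diversity (He) and a
#' community alpha-diversity facet (richness or evenness), tested with
#' the exact t transform t = r sqrt(n-2)/sqrt(1-r^2) on n-2 degrees of
#' freedom. The default tail is one-sided positive — the direction both
#' neutral theory and island biogeography predict for connectivity-driven
#' systems.
#'
#' @param he numeric vector of per-site He (no missing values).
#' @param facet_values matching numeric vector of the species-diversity
#'   facet.
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @param dataset,facet optional labels carried into the result.
#' @return object of class `sgdc_result`: `r`, `n`, `statistic`,
#'   `p_value`, `test`, `tail`, `dataset`, `facet`.
#' @export
alpha_sgdc <- function(he, facet_values, tail = c("greater", "two.sided",
                                                  "less"),
                       dataset = NA_character_, facet = NA_character_) {
  tail <- match.arg(tail)
  if (length(he) != length(facet_values))
    stop("'he' and 'facet_values' must have equal length")
  ok <- stats::complete.cases(he, facet_values)
  if (any(!ok)) stop("missing values in the paired vectors")
  n <- length(he)
  if (n < 4) stop("need at least 4 paired sites")
  if (stats::sd(he) == 0 || stats::sd(facet_values) == 0)
    stop("zero variance in one of the vectors")
  r <- stats::cor(he, facet_values)
  t <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- switch(tail,
              greater = stats::pt(t, n - 2, lower.tail = FALSE),
              less = stats::pt(t, n - 2),
              two.sided = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
  structure(list(r = r, n = n, statistic = t, p_value = min(p, 1),
                 test = "pearson_t", tail = tail, dataset = dataset,
                 facet = facet),
            class = "sgdc_result")
}

#' @export
print.sgdc_result <- function(x, ...) {
  cat(sprintf("SGDC [%s%s]: r = %.3f (n = %d, %s, tail = %s), p = %.4g\n",
              ifelse(is.na(x$dataset), "", paste0(x$dataset, ", ")),
              ifelse(is.na(x$facet), "?", x$facet),
              x$r, x$n, x$test, x$tail, x$p_value))
  invisible(x)
}

# Pearson correlation over the lower-triangle entries of two symmetric
# matrices — the Mantel statistic.
mantel_r <- function(A, B) {
  lt <- lower.tri(A)
  stats::cor(A[lt], B[lt])
}

#' Mantel test between two site distance matrices
#'
#' Mantel statistic r = Pearson correlation over the n(n-1)/2 site
#' pairs; the null distribution is built by jointly permuting rows and
#' columns of the second matrix `n_perm` times, and the p-value uses the
#' add-one rule. The statistic is invariant to positive affine
#' transforms of either matrix and to any common reordering of the two
#' matrices.
#'
#' @param d_genetic,d_species symmetric matrices with zero diagonal over
#'   the same sites (row/column order must match).
#' @param n_perm permutations (default 9999).
#' @param tail `"greater"` (default: upper tail, the positive-association
#'   alternative), `"less"` or `"two.sided"`.
#' @param seed optional permutation seed.
#' @param dataset,facet optional labels.
#' @return an `sgdc_result` with the permutation null in `$null_r`.
#' @export
mantel_test <- function(d_genetic, d_species, n_perm = 9999,
                        tail = c("greater", "less", "two.sided"),
                        seed = NULL, dataset = NA_character_,
                        facet = "beta") {
  tail <- match.arg(tail)
  A <- as.matrix(d_genetic); B <- as.matrix(d_species)
  if (!identical(dim(A), dim(B)))
    stop("distance matrices must have the same sites")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("site order differs between the matrices")
  if (max(abs(A - t(A))) > 1e-8 || max(abs(B - t(B))) > 1e-8)
    stop("matrices must be symmetric")
  if (stats::sd(A[lower.tri(A)]) == 0 || stats::sd(B[lower.tri(B)]) == 0)
    stop("constant distance matrix")
  obs <- mantel_r(A, B)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample(n)
    mantel_r(A, B[idx, idx])
  }, numeric(1))
  p <- switch(tail,
              greater = (sum(perm >= obs) + 1) / (n_perm + 1),
              less = (sum(perm <= obs) + 1) / (n_perm + 1),
              two.sided = (sum(abs(perm) >= abs(obs)) + 1) / (n_perm + 1))
  structure(list(r = obs, n = n * (n - 1) / 2, statistic = obs,
                 p_value = p, test = "mantel", tail = tail,
                 dataset = dataset, facet = facet, null_r = perm),
            class = "sgdc_result")
}

#' Equal-size locus-subset randomization of an SGDC
#'
#' Tests whether the SGDC observed for an outlier locus set could arise
#' by chance from a (putatively neutral) reference set: draws
#' `n_subsets` random subsets of the reference loci of the same size as
#' the outlier set (without replacement within a draw), recomputes the
#' SGDC for each, and locates the outlier set's SGDC in that null. The
#' conventional tails are lower for alpha-SGDCs (are the outlier
#' correlations unusually low?) and upper for beta-SGDCs (unusually
#' high?). For `type = "beta"` the full chord-distance matrix is
#' recomputed for every subset and correlated (Mantel r) with
#' `d_species`.
#'
#' @param x a `genotype_matrix`.
#' @param reference_loci locus IDs of the reference dataset.
#' @param outlier_loci locus IDs of the outlier dataset; sets the subset
#'   size and the observed SGDC.
#' @param facet_values per-site species-diversity values
#'   (`type = "alpha"`).
#' @param d_species site dissimilarity matrix (`type = "beta"`); row
#'   order must match the sites of `x` as returned by
#'   [site_allele_freqs()].
#' @param type `"alpha"` or `"beta"`.
#' @param n_subsets number of random subsets (default 999).
#' @param tail `"less"`, `"greater"` or `"two.sided"`; default depends on
#'   `type` as described above.
#' @param min_genotyped per-site minimum for He / frequency estimates.
#' @param average chord-distance normalization (`type = "beta"`).
#' @param seed randomization seed.
#' @return object of class `randomization_result`: `observed_r`,
#'   `subset_size`, `n_subsets`, `null_r`, `p_value`, `tail`.
#' @export
subset_randomization <- function(x, reference_loci, outlier_loci,
                                 facet_values = NULL, d_species = NULL,
                                 type = c("alpha", "beta"),
                                 n_subsets = 999, tail = NULL,
                                 min_genotyped = 4, average = "inside",
                                 seed = 1) {
  type <- match.arg(type)
  if (is.null(tail)) tail <- if (type == "alpha") "less" else "greater"
  m <- length(outlier_loci)
  if (m == 0) stop("empty outlier locus set")
  if (m > length(reference_loci))
    stop("subset size exceeds the reference dataset")
  set.seed(seed)
  if (type == "alpha") {
    if (is.null(facet_values)) stop("facet_values required for type 'alpha'")
    H <- he_contributions(x, loci = union(reference_loci, outlier_loci),
                          min_genotyped = min_genotyped)
    sgdc_of <- function(loci) {
      he <- rowMeans(H[, loci, drop = FALSE], na.rm = TRUE)
      stats::cor(he, facet_values)
    }
  } else {
    if (is.null(d_species)) stop("d_species required for type 'beta'")
    af <- site_allele_freqs(x, loci = union(reference_loci, outlier_loci),
                            min_genotyped = min_genotyped)
    P <- af$freq
    S <- nrow(P)
    if (!identical(dim(as.matrix(d_species)), c(S, S)))
      stop("d_species does not match the site set")
    pairs <- which(lower.tri(matrix(0, S, S)), arr.ind = TRUE)
    # precompute per-pair, per-locus allele-sharing terms once
    SH <- matrix(NA_real_, nrow(pairs), ncol(P),
                 dimnames = list(NULL, colnames(P)))
    for (k in seq_len(nrow(pairs))) {
      xi <- P[pairs[k, 1], ]; yj <- P[pairs[k, 2], ]
      SH[k, ] <- pmin(sqrt(xi * yj) + sqrt((1 - xi) * (1 - yj)), 1)
    }
    dsp <- as.matrix(d_species)[lower.tri(as.matrix(d_species))]
    sgdc_of <- function(loci) {
      s <- rowMeans(SH[, loci, drop = FALSE], na.rm = TRUE)
      d <- if (average == "inside") (2 / pi) * sqrt(2 * (1 - s))
           else rowMeans((2 / pi) * sqrt(2 * (1 - SH[, loci, drop = FALSE])),
                         na.rm = TRUE)
      stats::cor(d, dsp)
    }
  }
  observed <- sgdc_of(outlier_loci)
  null_r <- vapply(seq_len(n_subsets), function(b)
    sgdc_of(sample(reference_loci, m)), numeric(1))
  p <- switch(tail,
              less = (sum(null_r <= observed) + 1) / (n_subsets + 1),
              greater = (sum(null_r >= observed) + 1) / (n_subsets + 1),
              two.sided = (sum(abs(null_r - stats::median(null_r)) >=
                                 abs(observed - stats::median(null_r))) + 1) /
                (n_subsets + 1))
  structure(list(observed_r = observed, subset_size = m,
                 n_subsets = n_subsets, null_r = null_r, p_value = p,
                 tail = tail, type = type),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "subset randomization (%s, %d loci, %d subsets): observed r = %.3f, p (%s) = %.4g\n",
    x$type, x$subset_size, x$n_subsets, x$observed_r, x$tail, x$p_value))
  invisible(x)
}

#' Concordance of two marker panels with influence diagnostics
#'
#' Pearson correlation between two per-site genetic diversity vectors
#' (e.g. SNP He vs an AFLP reference panel), with a greedy leave-one-out
#' search for discordant sites: sites whose sequential removal increases
#' the correlation by more than `threshold` are flagged, up to
#' `max_remove` sites.
#'
#' @param he_snp,he_reference paired per-site He vectors (named by site
#'   where available).
#' @param threshold minimum gain in r for a removal to be flagged
#'   (default 0.05).
#' @param max_remove maximum number of sites flagged (default 3).
#' @return list: `r_all`, `n`, `influential` (site names or indices in
#'   removal order), `r_excluding` (after removing the flagged sites),
#'   `trace` (data frame of the greedy steps).
#' @export
compare_marker_panels <- function(he_snp, he_reference, threshold = 0.05,
                                  max_remove = 3) {
  if (length(he_snp) != length(he_reference))
    stop("paired vectors must have equal length")
  if (length(he_snp) < 4) stop("need at least 4 paired sites")
  nm <- names(he_snp) %||% as.character(seq_along(he_snp))
  keep <- rep(TRUE, length(he_snp))
  r_all <- stats::cor(he_snp, he_reference)
  r_cur <- r_all
  flagged <- character()
  trace <- data.frame(removed = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  while (length(flagged) < max_remove && sum(keep) > 4) {
    idx <- which(keep)
    gains <- vapply(idx, function(i) {
      k2 <- keep; k2[i] <- FALSE
      stats::cor(he_snp[k2], he_reference[k2]) - r_cur
    }, numeric(1))
    if (max(gains) <= threshold) break
    best <- idx[which.max(gains)]
    keep[best] <- FALSE
    r_cur <- r_cur + max(gains)
    flagged <- c(flagged, nm[best])
    trace[nrow(trace) + 1L, ] <- list(nm[best], r_cur)
  }
  list(r_all = r_all, n = length(he_snp), influential = flagged,
       r_excluding = r_cur, trace = trace)
}
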
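# Standardize a dosage matrix for PCA: per locus, center at 2*p_hat and
# scale by sqrt(2*p_hat*(1-p_hat)); missing entries become 0 after
# centering (mean imputation on the standardized scale).
standardize_dosage <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  Z <- sweep(dosage[, keep, drop = FALSE], 2, 2 * p[keep])
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  Z[is.na(Z)] <- 0
  list(Z = Z, kept = keep)
}

# Elbow of a decreasing scree by maximum perpendicular distance to the
# chord joining the first and last points. The chord rule locates the
# corner where the plateau begins; the number of structured components is
# the point before it, so a one-dominant-then-flat spectrum gives k = 1.
elbow_point <- function(values) {
  m <- length(values)
  if (m < 3) stop("need at least 3 candidate components")
  x <- seq_len(m)
  dx <- m - 1; dy <- values[m] - values[1]
  d <- abs(dy * (x - 1) - dx * (values - values[1])) / sqrt(dx^2 + dy^2)
  if (max(d) < sqrt(.Machine$double.eps)) {
    warning("flat scree; defaulting to k = 1")
    return(1L)
  }
  max(which.max(d) - 1L, 1L)
}

#' Choose the number of principal components from the scree
#'
#' Computes the proportion-of-variance scree of the standardized dosage
#' matrix and returns its elbow via the maximum-distance-to-chord rule.
#' The scree values are returned so the choice can be overridden by eye —
#' scree reading is ultimately a judgement call.
#'
#' @param x a `genotype_matrix`.
#' @param k_max number of leading components to consider (must be below
#'   the number of individuals).
#' @return list with `k` (the elbow) and `scree` (proportions of
#'   variance).
#' @export
choose_k <- function(x, k_max = 20) {
  n <- nrow(x$dosage)
  if (k_max >= n) stop("k_max must be smaller than the number of individuals")
  Z <- standardize_dosage(x$dosage)$Z
  d2 <- svd(Z, nu = 0, nv = 0)$d^2
  scree <- (d2 / sum(d2))[seq_len(min(k_max, length(d2)))]
  list(k = elbow_point(scree), scree = scree)
}

#' PCA/Mahalanobis outlier scan for loci driving population structure
#'
#' A population-structure genome scan in the pcadapt mould. Dosages are
#' standardized per locus (centered at twice the allele frequency, scaled
#' by the binomial standard deviation, missing values mean-imputed), the
#' leading `k` principal components are extracted by singular value
#' decomposition, and each locus is scored by the z-statistics of its
#' multiple regression on the k component scores. The squared Mahalanobis
#' distance of each locus's z-vector — computed with a robust
#' minimum-covariance-determinant estimate (classical moments when
#' k = 1) — is rescaled by the genomic inflation factor
#' lambda = median(D2) / median(chi-square_k) and referred to a
#' chi-square(k) upper tail. Benjamini-Hochberg q-values at `fdr_level`
#' give the outlier flags. Monomorphic loci are excluded with a warning.
#'
#' @param x a `genotype_matrix`.
#' @param k number of retained components (see [choose_k()]).
#' @param fdr_level false discovery rate for the outlier flags
#'   (default 0.10).
#' @param seed seed for the robust covariance subsampling; fixed so
#'   identical inputs give identical flags.
#' @return object of class `pca_scan`: `k`, `zscores` (loci x k), `d2`,
#'   `lambda`, `p_values`, `q_values`, `outliers` (locus IDs),
#'   `tested` (locus IDs scanned).
#' @export
pca_scan <- function(x, k, fdr_level = 0.10, seed = 1) {
  n <- nrow(x$dosage)
  if (k >= n - 1) stop("k must be at most the number of individuals - 2")
  std <- standardize_dosage(x$dosage)
  if (any(!std$kept))
    warning(sum(!std$kept), " monomorphic locus/loci excluded from the scan")
  Z <- std$Z
  sv <- svd(Z, nu = k, nv = 0)
  U <- sv$u                      # n x k, orthonormal
  B <- crossprod(U, Z)           # k x L regression coefficients
  rss <- colSums(Z^2) - colSums(B^2)
  sigma2 <- pmax(rss, 0) / (n - k)
  zs <- t(B) / sqrt(pmax(sigma2, .Machine$double.eps))  # L x k
  colnames(zs) <- paste0("PC", seq_len(k))
  rownames(zs) <- colnames(Z)
  set.seed(seed)
  d2 <- tryCatch({
    rob <- MASS::cov.rob(zs, method = "mcd")
    stats::mahalanobis(zs, rob$center, rob$cov)
  }, error = function(e) {
    warning("robust covariance failed (", conditionMessage(e),
            "); falling back to classical moments")
    stats::mahalanobis(zs, colMeans(zs), stats::cov(zs))
  })
  lambda <- stats::median(d2) / stats::qchisq(0.5, df = k)
  p <- stats::pchisq(d2 / lambda, df = k, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  structure(list(k = k, zscores = zs, d2 = d2, lambda = lambda,
                 p_values = p, q_values = q, fdr_level = fdr_level,
                 outliers = names(q)[q <= fdr_level],
                 tested = colnames(Z)),
            class = "pca_scan")
}

#' @export
print.pca_scan <- function(x, ...) {
  cat(sprintf(
    "PCA outlier scan: k = %d, lambda = %.3f, %d/%d loci flagged at FDR %.0f%%\n",
    x$k, x$lambda, length(x$outliers), length(x$tested),
    100 * x$fdr_level))
  invisible(x)
}
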
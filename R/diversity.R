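# Per-site, per-locus expected-heterozygosity contributions:
# He_l = 1 - sum_a p_a^2 = 2p(1-p) for a biallelic locus, NA where the
# site has fewer than min_genotyped non-missing individuals. The optional
# small-sample correction multiplies by 2n/(2n-1).
he_contributions <- function(x, loci = NULL, min_genotyped = 4,
                             correction = FALSE) {
  af <- site_allele_freqs(x, loci = loci, min_genotyped = min_genotyped)
  h <- 2 * af$freq * (1 - af$freq)
  if (correction) h <- h * (2 * af$n) / (2 * af$n - 1)
  h
}

#' Within-site expected heterozygosity
#'
#' Per-site He averaged over loci: at each site, every locus with at
#' least `min_genotyped` non-missing individuals contributes
#' 1 - sum(p_a^2) (the plug-in estimator, matching the gstudio
#' convention; the n/(n-1)-corrected variant is available via
#' `correction = TRUE`), and unqualified loci are skipped for that site
#' only. A site with no qualifying locus gets `NA`, never 0.
#'
#' @param x a `genotype_matrix`.
#' @param loci optional locus IDs restricting the average (e.g. one
#'   dataset of a [build_partition()]).
#' @param min_genotyped minimum non-missing individuals per site per locus
#'   (default 4).
#' @param correction apply the small-sample 2n/(2n-1) factor.
#' @return data frame: `site`, `he`, `n_loci` (loci used at that site).
#' @export
expected_heterozygosity <- function(x, loci = NULL, min_genotyped = 4,
                                    correction = FALSE) {
  if (!is.null(loci) && length(loci) == 0) stop("empty locus set")
  h <- he_contributions(x, loci, min_genotyped, correction)
  data.frame(site = rownames(h),
             he = rowMeans(h, na.rm = TRUE),
             n_loci = rowSums(!is.na(h)),
             row.names = rownames(h), stringsAsFactors = FALSE)
}

#' Cavalli-Sforza chord distance between two frequency profiles
#'
#' For two populations typed at the same L biallelic loci with
#' counted-allele frequencies `x` and `y`, the per-locus allele-sharing
#' term is s_l = sqrt(x_l y_l) + sqrt((1-x_l)(1-y_l)). The default
#' normalization averages inside the radical,
#' D = (2/pi) sqrt(2 (1 - mean(s_l))), which is 0 for identical profiles
#' and attains its maximum (2/pi) sqrt(2) when every locus is fixed for
#' opposite alleles. `average = "outside"` instead averages the per-locus
#' chord segments (2/pi) sqrt(2 (1 - s_l)). Loci with an undefined
#' frequency in either population are dropped pairwise.
#'
#' @param x,y numeric vectors of counted-allele frequencies in [0, 1]
#'   (NA allowed, dropped pairwise).
#' @param average `"inside"` (default) or `"outside"`.
#' @return the chord distance (scalar).
#' @export
cavalli_sforza <- function(x, y, average = c("inside", "outside")) {
  average <- match.arg(average)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no loci with defined frequencies in both populations")
  x <- x[ok]; y <- y[ok]
  s <- sqrt(x * y) + sqrt((1 - x) * (1 - y))
  s <- pmin(s, 1)  # guard rounding
  if (average == "inside") (2 / pi) * sqrt(2 * (1 - mean(s)))
  else mean((2 / pi) * sqrt(2 * (1 - s)))
}

#' Pairwise Cavalli-Sforza distance matrix between sites
#'
#' Applies [cavalli_sforza()] to every site pair using within-site
#' counted-allele frequencies (loci qualifying with at least
#' `min_genotyped` individuals in both sites of a pair).
#'
#' @inheritParams expected_heterozygosity
#' @param average normalization, see [cavalli_sforza()].
#' @return symmetric site x site matrix with zero diagonal; attribute
#'   `metric` = `"cavalli_sforza"`, attribute `n_loci` = locus count per
#'   pair (matrix).
#' @export
genetic_distance_matrix <- function(x, loci = NULL, min_genotyped = 4,
                                    average = "inside") {
  af <- site_allele_freqs(x, loci = loci, min_genotyped = min_genotyped)
  P <- af$freq
  S <- nrow(P)
  D <- nl <- matrix(0, S, S, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) {
    D[i, j] <- D[j, i] <- cavalli_sforza(P[i, ], P[j, ], average = average)
    nl[i, j] <- nl[j, i] <- sum(!is.na(P[i, ]) & !is.na(P[j, ]))
  }
  attr(D, "metric") <- "cavalli_sforza"
  attr(D, "n_loci") <- nl
  D
}

#' Community alpha-diversity: richness, Shannon diversity, evenness
#'
#' Per site: richness S = number of species with positive biomass;
#' Shannon H' = -sum(q ln q) over biomass shares q (natural log); Pielou
#' evenness J = H'/ln S, reported `NA` when S = 1 (Hmax = 0). Biomass is
#' taken as pooled (accumulated) over quadrats.
#'
#' @param community a `community_table` (sites x species biomass) or a
#'   single site's biomass vector.
#' @return data frame: `site`, `richness`, `shannon`, `evenness`.
#' @export
species_alpha <- function(community) {
  m <- if (is.data.frame(community)) as.matrix(community)
       else matrix(community, 1, dimnames = list("site1", NULL))
  if (any(m < 0)) stop("negative biomass")
  if (any(rowSums(m) <= 0)) stop("site with no positive biomass")
  out <- t(apply(m, 1, function(b) {
    b <- b[b > 0]
    S <- length(b)
    q <- b / sum(b)
    H <- -sum(q * log(q))
    c(richness = S, shannon = H,
      evenness = if (S >= 2) H / log(S) else NA_real_)
  }))
  data.frame(site = rownames(m), out, row.names = rownames(m),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between site communities
#'
#' Computes BC_ij = 1 - 2 C_ij / (S_i + S_j) on transformed abundances,
#' where C_ij sums the lesser transformed abundance of species shared by
#' the pair and S_i, S_j are each site's total transformed abundance (the
#' standard quantitative Bray-Curtis, as in [vegan::vegdist()], which
#' performs the computation here). The default transform is
#' log10(x + 1), the usual compression for biomass data.
#'
#' @param community a `community_table`.
#' @param transform `"log10p1"` (default) or `"none"`.
#' @return symmetric site x site matrix in [0, 1] with zero diagonal;
#'   attribute `metric` = `"bray_curtis"`.
#' @export
bray_curtis <- function(community, transform = c("log10p1", "none")) {
  transform <- match.arg(transform)
  m <- as.matrix(community)
  if (transform == "log10p1") m <- log10(m + 1)
  if (any(rowSums(m) <= 0))
    stop("site with all-zero transformed abundance")
  D <- as.matrix(vegan::vegdist(m, method = "bray"))
  attr(D, "metric") <- "bray_curtis"
  D
}
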
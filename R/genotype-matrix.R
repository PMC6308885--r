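#' Genotype matrix for population-level SNP data
#'
#' The central container of the package: biallelic SNP genotypes coded as
#' allele dosages (0, 1, 2 copies of the counted allele, `NA` for missing)
#' for individuals sampled from discrete sites (populations), with optional
#' per-genotype read depth from genotyping-by-sequencing.
#'
#' @param dosage integer matrix, individuals x loci, values in
#'   \{0, 1, 2, NA\}. Row names are individual IDs, column names locus IDs;
#'   both must be unique.
#' @param population character vector mapping each individual (row) to its
#'   site ID; recycled names are not allowed — length must equal
#'   `nrow(dosage)`.
#' @param depth optional non-negative integer matrix of per-genotype read
#'   depths, same shape and dimnames as `dosage`.
#' @param biallelic logical vector per locus; loci from multiallelic
#'   variant records are loaded but flagged `FALSE` so quality control can
#'   exclude them. Defaults to all `TRUE`.
#' @param ref,alt optional character vectors of reference and counted
#'   (alternate) allele per locus, used for VCF round-trips and for the
#'   deterministic minor-allele orientation.
#'
#' @return an object of class `genotype_matrix`.
#' @seealso [read_vcf()], [apply_qc()], [recode_minor()]
#' @export
genotype_matrix <- function(dosage, population, depth = NULL,
                            biallelic = NULL, ref = NULL, alt = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("locus", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage)))
    stop("individual IDs are not unique")
  if (anyDuplicated(colnames(dosage)))
    stop("locus IDs are not unique")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage values must be in {0, 1, 2, NA}")
  population <- trimws(as.character(population))
  if (length(population) != nrow(dosage))
    stop("'population' must give one site ID per individual")
  names(population) <- rownames(dosage)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(dosage)))
      stop("'depth' must have the same shape as 'dosage'")
    if (any(depth < 0, na.rm = TRUE)) stop("negative read depth")
    dimnames(depth) <- dimnames(dosage)
  }
  L <- ncol(dosage)
  if (is.null(biallelic)) biallelic <- rep(TRUE, L)
  if (length(biallelic) != L) stop("'biallelic' must have one flag per locus")
  names(biallelic) <- colnames(dosage)
  for (v in c("ref", "alt")) {
    a <- get(v)
    if (!is.null(a) && length(a) != L)
      stop(sprintf("'%s' must have one allele per locus", v))
  }
  structure(list(dosage = dosage, population = population, depth = depth,
                 biallelic = biallelic, ref = ref, alt = alt),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d sites\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$population))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.1f%%; depth %s; %d multiallelic-flagged loci\n",
              100 * miss, if (is.null(x$depth)) "absent" else "present",
              sum(!x$biallelic)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param individuals,loci character IDs or logical/integer indices; `NULL`
#'   keeps everything on that axis.
#' @return a `genotype_matrix`.
#' @export
subset_gm <- function(x, individuals = NULL, loci = NULL) {
  i <- if (is.null(individuals)) seq_len(nrow(x$dosage)) else individuals
  j <- if (is.null(loci)) seq_len(ncol(x$dosage)) else loci
  if (is.character(j) && !all(j %in% colnames(x$dosage)))
    stop("unknown locus ID(s): ",
         paste(setdiff(j, colnames(x$dosage)), collapse = ", "))
  jj <- seq_len(ncol(x$dosage))
  names(jj) <- colnames(x$dosage)
  j <- if (is.character(j)) jj[j] else jj[j]
  ii <- seq_len(nrow(x$dosage))
  names(ii) <- rownames(x$dosage)
  i <- if (is.character(i)) ii[i] else ii[i]
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  population = x$population[i],
                  depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
                  biallelic = x$biallelic[j],
                  ref = x$ref[j], alt = x$alt[j])
}

#' Orient dosages to count the minor allele
#'
#' Recodes each locus so the dosage counts the minor allele computed over
#' all individuals (non-missing genotypes only): loci where the counted
#' allele has frequency above 0.5 are flipped `g -> 2 - g` and their
#' ref/alt labels swapped. Ties at frequency exactly 0.5 are broken so the
#' counted allele is the lexicographically smaller of the two, which makes
#' the orientation deterministic. Expected heterozygosity, chord distances
#' and all SGDCs are invariant under this recoding.
#'
#' @param x a `genotype_matrix`.
#' @return a `genotype_matrix` with minor-allele dosages.
#' @export
recode_minor <- function(x) {
  p <- colMeans(x$dosage, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  if (!is.null(x$ref) && !is.null(x$alt)) {
    tie <- !is.na(p) & p == 0.5 & x$alt > x$ref
    flip <- flip | tie
  }
  if (any(flip)) {
    x$dosage[, flip] <- 2L - x$dosage[, flip, drop = FALSE]
    if (!is.null(x$ref)) {
      tmp <- x$ref[flip]
      x$ref[flip] <- x$alt[flip]
      x$alt[flip] <- tmp
    }
  }
  x
}

#' Per-site counted-allele frequencies
#'
#' Frequency of the counted allele at each locus within each site, computed
#' from non-missing genotypes only. Loci genotyped in fewer than
#' `min_genotyped` individuals at a site get `NA` there, mirroring the
#' minimum-of-four rule used for within-population diversity estimates.
#'
#' @param x a `genotype_matrix`.
#' @param loci optional locus IDs (or indices) to restrict to.
#' @param min_genotyped minimum non-missing individuals per site per locus.
#' @return list with `freq` (sites x loci matrix of frequencies, `NA` where
#'   unqualified) and `n` (matching matrix of non-missing genotype counts).
#' @export
site_allele_freqs <- function(x, loci = NULL, min_genotyped = 4) {
  g <- if (is.null(loci)) x$dosage else {
    if (is.character(loci) && !all(loci %in% colnames(x$dosage)))
      stop("unknown locus ID(s) in 'loci'")
    x$dosage[, loci, drop = FALSE]
  }
  sites <- unique(x$population)
  freq <- n <- matrix(NA_real_, length(sites), ncol(g),
                      dimnames = list(sites, colnames(g)))
  for (s in sites) {
    gs <- g[x$population == s, , drop = FALSE]
    ns <- colSums(!is.na(gs))
    p <- colSums(gs, na.rm = TRUE) / (2 * ns)
    p[ns < min_genotyped] <- NA_real_
    freq[s, ] <- p
    n[s, ] <- ns
  }
  list(freq = freq, n = n)
}
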
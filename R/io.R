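#' Read a VCF file into a genotype matrix
#'
#' Parses GT (and, when present, DP) fields of a VCF 4.x file via
#' \pkg{vcfR} and returns allele dosages counting the ALT allele.
#' Genotypes with read depth below `min_genotype_depth` are set to missing,
#' the first step of the GBS filtering cascade. Multiallelic records are
#' loaded with their `biallelic` flag set to `FALSE` (genotypes carrying an
#' allele index above 1 become missing); quality control drops such loci
#' later. Contig names are taken as-is, so coordinate-free tag-pair loci
#' with placeholder contigs are accepted.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param min_genotype_depth depth below which a genotype is treated as
#'   missing (default 10). Ignored when the VCF has no DP field.
#' @param population site ID per sample, either a named character vector
#'   (names = sample IDs) or `NULL` to derive the site as the sample-ID
#'   prefix before the first underscore.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, min_genotype_depth = 10, population = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF contains no samples")
  samples <- colnames(v@gt)[-1]
  if (anyDuplicated(samples)) stop("sample IDs are not unique")
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  if (any(is.na(ids)) || anyDuplicated(ids))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt)
  # dosage = number of '1' alleles; any allele index > 1 -> missing
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  core <- gsub("\\|", "/", gt)
  dose[core %in% c("0/0", "0")] <- 0L
  dose[core %in% c("0/1", "1/0")] <- 1L
  dose[core %in% c("1/1", "1")] <- 2L
  dimnames(dose) <- dimnames(gt)
  depth <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    depth <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    low <- !is.na(depth) & depth < min_genotype_depth
    dose[low] <- NA_integer_
    depth[is.na(depth)] <- 0
  }
  if (is.null(population)) {
    population <- sub("_.*$", "", samples)
  } else {
    population <- population[samples]
    if (any(is.na(population)))
      stop("no population assignment for sample(s): ",
           paste(samples[is.na(population)], collapse = ", "))
  }
  genotype_matrix(t(dose), population = population,
                  depth = if (!is.null(depth)) t(depth),
                  biallelic = stats::setNames(biallelic, rownames(dose)),
                  ref = stats::setNames(fix[, "REF"], rownames(dose))[rownames(dose)],
                  alt = stats::setNames(alt, rownames(dose))[rownames(dose)])
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 file with GT (and DP when depth is stored)
#' fields that [read_vcf()] reproduces exactly: dosage 0/1/2 become
#' `0/0`, `0/1`, `1/1` and missing genotypes `./.`. Loci without stored
#' alleles are written with placeholder `A`/`T` alleles on a placeholder
#' contig, matching the coordinate-free records that reduced-representation
#' pipelines produce.
#'
#' @param x a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  L <- ncol(x$dosage)
  ref <- if (is.null(x$ref)) rep("A", L) else x$ref
  alt <- if (is.null(x$alt)) rep("T", L) else x$alt
  has_dp <- !is.null(x$depth)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sgdcpart",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (has_dp)
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(x$dosage)), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(L), function(j) {
    g <- x$dosage[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    if (has_dp) gt <- paste(gt, x$depth[, j], sep = ":")
    paste(c("un", j, colnames(x$dosage)[j], ref[j], alt[j], ".", "PASS",
            ".", if (has_dp) "GT:DP" else "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a community, environment or Table-1-style fixture table
#'
#' All three are delimited text files (comma or tab, autodetected) with a
#' header row and one row per site; the first column holds the site ID.
#'
#' * `kind = "community"`: remaining columns are species dry biomass
#'   (g/m2); negatives and all-zero site rows are rejected.
#' * `kind = "environment"`: remaining columns are environmental
#'   predictors; non-numeric columns are kept as categorical factors and
#'   indicator-encoded downstream.
#' * `kind = "fixture"`: a per-site reference-diversity table with columns
#'   `n`, `richness`, `he_ds1` ... `he_ds5`, `he_aflp` and a logical
#'   `outlier_site` column marking sites whose SNP diversity is
#'   conspicuously discordant with the reference marker panel.
#'
#' @param path delimited text file.
#' @param kind one of `"community"`, `"environment"`, `"fixture"`.
#' @return a data frame with site IDs as row names, classed
#'   `community_table`, `environment_table` or `fixture_table`.
#' @export
read_table <- function(path, kind = c("community", "environment", "fixture")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read table: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- trimws(as.character(df[[1]]))
  if (anyDuplicated(ids))
    stop("duplicate site ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  switch(kind,
    community = {
      m <- as.matrix(df)
      if (!is.numeric(m)) stop("non-numeric biomass value in community table")
      if (any(m < 0)) stop("negative biomass in community table")
      if (any(rowSums(m) <= 0))
        stop("site(s) with no positive biomass: ",
             paste(ids[rowSums(m) <= 0], collapse = ", "))
      structure(as.data.frame(m), class = c("community_table", "data.frame"))
    },
    environment = {
      structure(df, class = c("environment_table", "data.frame"))
    },
    fixture = {
      need <- c("n", "richness", paste0("he_ds", 1:5), "he_aflp")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop("fixture table lacks column(s): ", paste(miss, collapse = ", "))
      he <- as.matrix(df[, grep("^he_", names(df))])
      if (any(he < 0 | he > 1)) stop("He values must lie in [0, 1]")
      if (any(df$n < 4)) stop("fixture rows need n >= 4")
      if (is.null(df$outlier_site)) df$outlier_site <- FALSE
      structure(df, class = c("fixture_table", "data.frame"))
    })
}

#' The packaged 17-site reference diversity table
#'
#' Per-site sample size, plant species richness, expected heterozygosity of
#' the five SNP locus datasets (DS1 full, DS2/DS3 non-outlier, DS4/DS5
#' outlier) and of an independent AFLP marker panel for the 17 high-Andean
#' wetland sites of the Carex gayana study system, transcribed from the
#' published per-site table. Sites S6 and S21, whose SNP diversity is
#' conspicuously low relative to their AFLP diversity, carry
#' `outlier_site = TRUE`.
#'
#' @return a `fixture_table` data frame with 17 rows.
#' @export
table1_fixture <- function() {
  read_table(system.file("extdata", "table1_sgdc.csv", package = "sgdcpart",
                         mustWork = TRUE),
             kind = "fixture")
}
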
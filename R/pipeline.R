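#' Run the full SGDC partitioning pipeline
#'
#' End-to-end driver covering every stage: obtain genotype, community and
#' environment tables (simulated from a scenario or read from files),
#' apply the quality-control cascade, run both outlier scans, build the
#' five locus datasets, compute alpha/beta genetic and species diversity,
#' and estimate every SGDC with its test, including the equal-size
#' subset randomizations contrasting the outlier datasets with the
#' putatively neutral ones. All randomness derives from `config$seed`,
#' so an identical config gives identical outputs.
#'
#' The configuration is a nested list (or a path to a YAML file with the
#' same structure):
#' \describe{
#'   \item{seed}{master seed (default 1).}
#'   \item{simulate}{list of [scenario_config()] arguments (or `TRUE`
#'     for the defaults) to generate synthetic inputs.}
#'   \item{inputs}{alternatively, file paths: `vcf`, `community`,
#'     `environment`, and/or `fixture`. A config with only `fixture`
#'     runs the fixture-only analysis: alpha-SGDCs and marker-panel
#'     concordance straight from the per-site reference table, without
#'     the genotype-level stages.}
#'   \item{qc}{[qc_config()] arguments; `hwe_permutations = 0` skips the
#'     Hardy-Weinberg report.}
#'   \item{scan}{`k` (`NULL` = scree elbow), `fdr_level`, `n_perm`,
#'     `alpha`, `axes`, `loading_rule`, `r_threshold`.}
#'   \item{sgdc}{`n_subsets`, `mantel_perm`, `tail` (alpha-SGDC tail),
#'     `min_genotyped`.}
#' }
#'
#' @param config nested list or YAML file path.
#' @param out_dir optional directory; when given, writes the partition,
#'   diversity table, distance matrices, SGDC table, randomization
#'   summaries and a run log (all tab-separated text).
#' @return list of class `sgdc_run` with elements `genotypes`, `qc`,
#'   `scans`, `partition`, `diversity`, `distances`, `sgdc` (data
#'   frame), `randomizations`, `fixture_results`, `config`.
#' @export
run_sgdc_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  qc_cfg <- do.call(qc_config, config$qc %||% list())
  scan <- utils::modifyList(
    list(k = NULL, fdr_level = 0.10, n_perm = 999, alpha = 0.05,
         axes = NULL, loading_rule = list(multiplier = 2,
                                          anchor = "quartile"),
         r_threshold = 0.7),
    config$scan %||% list())
  sg <- utils::modifyList(
    list(n_subsets = 999, mantel_perm = 9999, tail = "greater",
         min_genotyped = 4),
    config$sgdc %||% list())

  fixture <- NULL
  if (!is.null(config$inputs$fixture))
    fixture <- read_table(config$inputs$fixture, kind = "fixture")
  fixture_results <- if (!is.null(fixture)) fixture_analysis(fixture, sg$tail)

  genotype_source <- !is.null(config$simulate) || !is.null(config$inputs$vcf)
  if (!genotype_source) {
    if (is.null(fixture))
      stop("config needs either 'simulate', an input VCF, or a fixture table")
    res <- structure(list(fixture_results = fixture_results,
                          config = config),
                     class = "sgdc_run")
    if (!is.null(out_dir)) write_outputs(res, out_dir)
    return(res)
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- if (isTRUE(config$simulate)) list() else config$simulate
    scen <- simulate_sgdc_scenario(do.call(scenario_config, sim_args), seed)
    gm <- scen$genotypes; community <- scen$community
    environment <- scen$environment; truth <- scen$truth
  } else {
    gm <- read_vcf(config$inputs$vcf,
                   min_genotype_depth = qc_cfg$min_genotype_depth)
    community <- read_table(config$inputs$community, kind = "community")
    environment <- read_table(config$inputs$environment, kind = "environment")
  }
  miss <- setdiff(unique(gm$population), rownames(community))
  if (length(miss))
    stop("community table missing genotyped site(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(unique(gm$population), rownames(environment))
  if (length(miss))
    stop("environment table missing genotyped site(s): ",
         paste(miss, collapse = ", "))

  qc <- apply_qc(recode_minor(gm), qc_cfg)
  gm <- qc$genotypes
  hwe <- if ((qc_cfg$hwe_permutations %||% 0) > 0) {
    set.seed(seed + 10)
    hwe_report(gm, n_perm = qc_cfg$hwe_permutations)
  }

  env <- prescreen_environment(environment, r_threshold = scan$r_threshold)
  vif <- vif_check(env)
  k <- scan$k %||% choose_k(gm, k_max = min(20, nrow(gm$dosage) - 2))$k
  pca <- pca_scan(gm, k = k, fdr_level = scan$fdr_level, seed = seed + 20)
  rda <- rda_scan(gm, env, n_perm = scan$n_perm,
                  loading_rule = scan$loading_rule, alpha = scan$alpha,
                  axes = scan$axes, seed = seed + 30)
  part <- build_partition(colnames(gm$dosage), pca, rda)

  ds <- paste0("DS", 1:5)
  he_tabs <- lapply(ds, function(d) {
    loci <- partition_loci(part, d)
    if (!length(loci)) return(NULL)
    expected_heterozygosity(gm, loci, min_genotyped = sg$min_genotyped)
  })
  names(he_tabs) <- ds
  sp <- species_alpha(community[rownames(he_tabs$DS1), , drop = FALSE])
  diversity <- data.frame(site = he_tabs$DS1$site,
                          n = as.vector(table(gm$population)[he_tabs$DS1$site]),
                          richness = sp$richness, shannon = sp$shannon,
                          evenness = sp$evenness,
                          row.names = he_tabs$DS1$site)
  for (d in ds)
    diversity[[paste0("he_", tolower(d))]] <-
      if (!is.null(he_tabs[[d]])) he_tabs[[d]]$he else NA_real_

  dmat <- lapply(ds, function(d) {
    loci <- partition_loci(part, d)
    if (length(loci) < 2) return(NULL)
    genetic_distance_matrix(gm, loci, min_genotyped = sg$min_genotyped)
  })
  names(dmat) <- ds
  bc <- bray_curtis(community[rownames(diversity), , drop = FALSE])

  sgdc_rows <- list()
  for (d in ds) {
    if (is.null(he_tabs[[d]]) || any(!is.finite(he_tabs[[d]]$he))) next
    for (facet in c("richness", "evenness")) {
      v <- diversity[[facet]]
      if (any(is.na(v))) next
      a <- alpha_sgdc(he_tabs[[d]]$he, v, tail = sg$tail,
                      dataset = d, facet = facet)
      sgdc_rows[[length(sgdc_rows) + 1L]] <- a
    }
    if (!is.null(dmat[[d]])) {
      m <- mantel_test(dmat[[d]], bc, n_perm = sg$mantel_perm,
                       seed = seed + 40 + match(d, ds), dataset = d)
      sgdc_rows[[length(sgdc_rows) + 1L]] <- m
    }
  }
  sgdc_tab <- do.call(rbind, lapply(sgdc_rows, function(x)
    data.frame(dataset = x$dataset, facet = x$facet, test = x$test,
               r = x$r, n = x$n, tail = x$tail, p_value = x$p_value,
               stringsAsFactors = FALSE)))

  rand <- list()
  for (out_ds in c("DS4", "DS5")) {
    out_loci <- partition_loci(part, out_ds)
    if (!length(out_loci)) next
    for (ref_ds in c("DS1", "DS2", "DS3")) {
      ref_loci <- partition_loci(part, ref_ds)
      if (length(out_loci) > length(ref_loci)) next
      key <- paste0(out_ds, "_vs_", ref_ds)
      rand[[paste0(key, "_richness")]] <- subset_randomization(
        gm, ref_loci, out_loci, facet_values = diversity$richness,
        type = "alpha", n_subsets = sg$n_subsets,
        min_genotyped = sg$min_genotyped, seed = seed + 50)
      rand[[paste0(key, "_beta")]] <- subset_randomization(
        gm, ref_loci, out_loci, d_species = bc, type = "beta",
        n_subsets = sg$n_subsets, min_genotyped = sg$min_genotyped,
        seed = seed + 60)
    }
  }

  res <- structure(list(genotypes = gm, qc = qc$report, hwe = hwe,
                        truth = truth, environment = env, vif = vif,
                        scans = list(pca = pca, rda = rda),
                        partition = part, diversity = diversity,
                        distances = c(dmat, list(bray_curtis = bc)),
                        sgdc = sgdc_tab, randomizations = rand,
                        fixture_results = fixture_results,
                        config = config),
                   class = "sgdc_run")
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}

# Fixture-only analysis: alpha-SGDCs of each He column against richness
# (all sites and excluding the flagged discordant sites) plus
# SNP-vs-reference marker concordance.
fixture_analysis <- function(fixture, tail = "greater") {
  ds <- paste0("he_ds", 1:5)
  keep <- !fixture$outlier_site
  rows <- lapply(ds, function(col) {
    all_r <- alpha_sgdc(fixture[[col]], fixture$richness, tail = tail,
                        dataset = toupper(sub("he_", "", col)),
                        facet = "richness")
    sub_r <- alpha_sgdc(fixture[[col]][keep], fixture$richness[keep],
                        tail = tail)
    data.frame(dataset = all_r$dataset, r = all_r$r, p_value = all_r$p_value,
               n = all_r$n, r_excl = sub_r$r, p_excl = sub_r$p_value,
               n_excl = sub_r$n, stringsAsFactors = FALSE)
  })
  panels <- compare_marker_panels(
    stats::setNames(fixture$he_ds1, rownames(fixture)), fixture$he_aflp)
  list(alpha_sgdc = do.call(rbind, rows), marker_concordance = panels,
       summary = data.frame(
         mean_richness = mean(fixture$richness),
         sd_richness = stats::sd(fixture$richness),
         mean_he_ds1 = mean(fixture$he_ds1),
         mean_he_ds4 = mean(fixture$he_ds4),
         mean_he_ds5 = mean(fixture$he_ds5),
         mean_he_aflp = mean(fixture$he_aflp),
         n_individuals = sum(fixture$n)))
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$partition)) {
    prov <- res$partition$provenance
    for (d in paste0("DS", 1:5)) prov[[d]] <- res$partition[[d]]
    w(prov, "partition.tsv")
  }
  if (!is.null(res$diversity)) w(res$diversity, "diversity.tsv")
  for (nm in names(res$distances)) {
    D <- res$distances[[nm]]
    if (is.null(D)) next
    utils::write.table(cbind(site = rownames(D), as.data.frame(D)),
                       file.path(out_dir, paste0("dist_", tolower(nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$sgdc)) w(res$sgdc, "sgdc.tsv")
  if (length(res$randomizations)) {
    rt <- do.call(rbind, lapply(names(res$randomizations), function(k) {
      x <- res$randomizations[[k]]
      data.frame(comparison = k, type = x$type, observed_r = x$observed_r,
                 subset_size = x$subset_size, n_subsets = x$n_subsets,
                 tail = x$tail, p_value = x$p_value,
                 stringsAsFactors = FALSE)
    }))
    w(rt, "randomizations.tsv")
  }
  if (!is.null(res$fixture_results)) {
    w(res$fixture_results$alpha_sgdc, "fixture_alpha_sgdc.tsv")
    w(res$fixture_results$summary, "fixture_summary.tsv")
  }
  writeLines(yaml::as.yaml(res$config), file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

#' @export
print.sgdc_run <- function(x, ...) {
  cat("sgdcpart pipeline run\n")
  if (!is.null(x$partition)) print(x$partition)
  if (!is.null(x$sgdc)) { cat("SGDC estimates:\n"); print(x$sgdc) }
  if (!is.null(x$fixture_results)) {
    cat("fixture alpha-SGDCs:\n")
    print(x$fixture_results$alpha_sgdc)
  }
  invisible(x)
}
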
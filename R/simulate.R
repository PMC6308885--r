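#' Scenario configuration for the synthetic study system
#'
#' Parameters of the generative model used to exercise the pipeline: a
#' metapopulation of discrete, isolated wetland-like sites along a
#' connectivity gradient. Neutral loci drift around an ancestral frequency
#' with site-specific intensity (well-connected sites drift less and keep
#' more heterozygosity); adaptive loci additionally follow a logit-linear
#' cline in an environmental gradient. Community richness increases with
#' connectivity, so a positive richness SGDC arises through the shared
#' neutral driver, as island-biogeography and drift theory jointly predict.
#'
#' Defaults mirror the scale of the motivating study system: 17 sites,
#' 9 individuals per site, 1,480 neutral + 229 adaptive loci, read depth
#' around 30x.
#'
#' @param n_sites number of sites.
#' @param individuals_per_site individuals sampled per site.
#' @param n_neutral_loci,n_adaptive_loci locus counts by truth class.
#' @param theta_range drift concentration (theta_min, theta_max): site i
#'   uses theta_i = theta_min + c_i * (theta_max - theta_min), so high
#'   connectivity c_i means high concentration, i.e. weak drift.
#' @param connectivity optional vector of site connectivities in [0, 1];
#'   drawn uniformly when `NULL`.
#' @param env_gradient optional vector of site values of the true selective
#'   gradient E; standard normal when `NULL`.
#' @param cline_slope slope b of the adaptive logit cline
#'   logit(p_il) = logit(pbar_l) + b * (E_i - mean(E)) + noise.
#' @param site_noise_sd sd of the per-site logit noise on adaptive loci.
#' @param species_pool_size size of the regional species pool.
#' @param richness_intercept,richness_slope,richness_noise_sd site richness
#'   model S_i = round(intercept + slope * c_i + N(0, sd)), clipped to
#'   [2, species_pool_size].
#' @param evenness_sdlog log-normal sd of species biomass; larger values
#'   give less even communities (lower Pielou J).
#' @param niche_width sd of the Gaussian species weighting along the
#'   connectivity gradient; smaller values make nearby-in-gradient sites
#'   share more species (stronger Bray-Curtis structure).
#' @param depth_mean,depth_dispersion negative-binomial read depth model
#'   (mean 30 matches a typical GBS run; dispersion is the NB size).
#' @param missingness fraction of genotypes masked missing at random.
#' @param nuisance_correlations target correlations of the simulated
#'   nuisance environmental variables with E; values above the 0.7
#'   prescreen threshold exercise collinearity removal.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 17, individuals_per_site = 9,
                            n_neutral_loci = 1480, n_adaptive_loci = 229,
                            theta_range = c(10, 200),
                            connectivity = NULL, env_gradient = NULL,
                            cline_slope = 3, site_noise_sd = 0.3,
                            species_pool_size = 40,
                            richness_intercept = 10, richness_slope = 10,
                            richness_noise_sd = 1.5,
                            evenness_sdlog = 1, niche_width = 0.35,
                            depth_mean = 30, depth_dispersion = 5,
                            missingness = 0.05,
                            nuisance_correlations = c(0.9, 0.5, 0.3, 0)) {
  cfg <- as.list(environment())
  if (cfg$n_sites < 2 || cfg$individuals_per_site < 1)
    stop("need at least 2 sites and 1 individual per site")
  if (cfg$n_neutral_loci + cfg$n_adaptive_loci < 1)
    stop("need at least one locus")
  if (cfg$theta_range[1] > cfg$theta_range[2] || any(cfg$theta_range <= 0))
    stop("theta_range must be positive with theta_min <= theta_max")
  if (cfg$missingness < 0 || cfg$missingness > 1)
    stop("missingness must be in [0, 1]")
  if (!is.null(cfg$connectivity) &&
      (length(cfg$connectivity) != cfg$n_sites ||
       any(cfg$connectivity < 0 | cfg$connectivity > 1)))
    stop("connectivity must give one value in [0, 1] per site")
  if (cfg$richness_intercept + cfg$richness_slope * 0 < 2 &&
      cfg$richness_noise_sd == 0)
    stop("richness model implies fewer than 2 species at low connectivity")
  class(cfg) <- "scenario_config"
  cfg
}

site_ids <- function(n) sprintf("S%02d", seq_len(n))

# Draw the site-level drivers (connectivity, gradient) for a scenario.
# Sub-stage seeds are derived from the master seed so each simulate_*
# function is reproducible on its own and within the full scenario.
draw_sites <- function(cfg, seed) {
  set.seed(seed %% .Machine$integer.max)
  c_i <- if (is.null(cfg$connectivity)) stats::runif(cfg$n_sites)
         else cfg$connectivity
  E_i <- if (is.null(cfg$env_gradient)) stats::rnorm(cfg$n_sites)
         else cfg$env_gradient
  data.frame(site = site_ids(cfg$n_sites), connectivity = c_i, E = E_i,
             stringsAsFactors = FALSE)
}

#' Simulate SNP genotypes under drift plus an environmental cline
#'
#' Neutral locus l at site i draws its frequency from a Beta distribution
#' with mean pbar_l (ancestral frequency uniform on [0.05, 0.95]) and
#' concentration theta_i = theta_min + c_i (theta_max - theta_min), so
#' poorly connected sites drift further from the ancestral frequency.
#' Adaptive loci instead follow logit(p_il) = logit(pbar_l) +
#' b (E_i - mean E) + site noise. All site frequencies are clipped to
#' [0.01, 0.99] to keep the realized MAF spectrum compatible with the
#' MAF >= 0.04 quality filter. Genotypes are Binomial(2, p_il) per
#' individual, depths negative-binomial, and genotypes are masked missing
#' at the configured rate.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed (master seed of the scenario).
#' @param sites optional site driver table from an enclosing scenario;
#'   regenerated from `seed` when `NULL`.
#' @return list with `genotypes` (a [genotype_matrix()]), `truth`
#'   (data frame locus_id, class in \{neutral, adaptive\}), `freq` (the
#'   true sites x loci frequencies before genotype sampling) and `sites`.
#' @export
simulate_genotypes <- function(cfg, seed = 1, sites = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(sites)) sites <- draw_sites(cfg, seed)
  set.seed((seed + 1) %% .Machine$integer.max)
  nl <- cfg$n_neutral_loci; na <- cfg$n_adaptive_loci
  L <- nl + na
  loci <- sprintf("L%04d", seq_len(L))
  cls <- rep(c("neutral", "adaptive"), c(nl, na))
  pbar <- stats::runif(L, 0.05, 0.95)
  theta <- cfg$theta_range[1] +
    sites$connectivity * diff(cfg$theta_range)
  S <- nrow(sites)
  freq <- matrix(NA_real_, S, L, dimnames = list(sites$site, loci))
  for (i in seq_len(S)) {
    p <- numeric(L)
    if (nl > 0)
      p[seq_len(nl)] <- stats::rbeta(nl, pbar[seq_len(nl)] * theta[i],
                                     (1 - pbar[seq_len(nl)]) * theta[i])
    if (na > 0) {
      j <- nl + seq_len(na)
      lin <- stats::qlogis(pbar[j]) +
        cfg$cline_slope * (sites$E[i] - mean(sites$E)) +
        stats::rnorm(na, sd = cfg$site_noise_sd)
      p[j] <- stats::plogis(lin)
    }
    freq[i, ] <- pmin(pmax(p, 0.01), 0.99)
  }
  n_ind <- S * cfg$individuals_per_site
  pop <- rep(sites$site, each = cfg$individuals_per_site)
  ind <- paste0(pop, "_i", sprintf("%02d", sequence(rep(cfg$individuals_per_site, S))))
  dose <- matrix(stats::rbinom(n_ind * L, 2, freq[pop, ]), n_ind, L,
                 dimnames = list(ind, loci))
  depth <- matrix(stats::rnbinom(n_ind * L, mu = cfg$depth_mean,
                                 size = cfg$depth_dispersion),
                  n_ind, L, dimnames = list(ind, loci))
  if (cfg$missingness > 0)
    dose[stats::runif(n_ind * L) < cfg$missingness] <- NA_integer_
  gm <- genotype_matrix(dose, population = pop, depth = depth,
                        ref = rep("A", L), alt = rep("T", L))
  list(genotypes = gm,
       truth = data.frame(locus_id = loci, class = cls,
                          stringsAsFactors = FALSE),
       freq = freq, sites = sites)
}

#' Simulate a site x species community table
#'
#' Site richness follows a linear model in connectivity (rounded, clipped
#' to [2, pool size]); the species present at a site are drawn without
#' replacement with Gaussian weights centred on each species' optimum along
#' the connectivity gradient, so nearby-in-gradient sites share species and
#' the Bray-Curtis structure is non-trivial. Biomass is log-normal with the
#' configured evenness shape.
#'
#' @inheritParams simulate_genotypes
#' @return list with `community` (a `community_table`) and `sites`.
#' @export
simulate_community <- function(cfg, seed = 1, sites = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(sites)) sites <- draw_sites(cfg, seed)
  set.seed((seed + 2) %% .Machine$integer.max)
  pool <- cfg$species_pool_size
  sp <- sprintf("sp%02d", seq_len(pool))
  optimum <- stats::runif(pool)
  S_i <- round(cfg$richness_intercept +
                 cfg$richness_slope * sites$connectivity +
                 stats::rnorm(nrow(sites), sd = cfg$richness_noise_sd))
  S_i <- pmin(pmax(S_i, 2), pool)
  biom <- matrix(0, nrow(sites), pool, dimnames = list(sites$site, sp))
  for (i in seq_len(nrow(sites))) {
    w <- exp(-(sites$connectivity[i] - optimum)^2 / (2 * cfg$niche_width^2))
    present <- sample(pool, S_i[i], prob = w)
    biom[i, present] <- stats::rlnorm(S_i[i], meanlog = log(10),
                                      sdlog = cfg$evenness_sdlog)
  }
  list(community = structure(as.data.frame(biom),
                             class = c("community_table", "data.frame")),
       sites = sites)
}

#' Simulate a site x environment predictor table
#'
#' Emits the true selective gradient `E`, nuisance continuous variables
#' with configured correlations to `E` (some above, some below the 0.7
#' collinearity prescreen threshold), and one two-level categorical
#' variable (`aspect`), matching the predictor structure the
#' genotype-environment scan expects.
#'
#' @inheritParams simulate_genotypes
#' @return list with `environment` (an `environment_table`) and `sites`.
#' @export
simulate_environment <- function(cfg, seed = 1, sites = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(sites)) sites <- draw_sites(cfg, seed)
  set.seed((seed + 3) %% .Machine$integer.max)
  n <- nrow(sites)
  Ez <- as.numeric(scale(sites$E))
  env <- data.frame(E = sites$E, row.names = sites$site)
  for (k in seq_along(cfg$nuisance_correlations)) {
    r <- cfg$nuisance_correlations[k]
    noise <- as.numeric(scale(stats::rnorm(n)))
    # residualize the noise on Ez so the sample correlation hits the target
    noise <- as.numeric(scale(stats::resid(stats::lm(noise ~ Ez))))
    env[[paste0("V", k)]] <- r * Ez + sqrt(max(0, 1 - r^2)) * noise
  }
  env$aspect <- sample(c("S_SE", "N_W_SW"), n, replace = TRUE)
  list(environment = structure(env,
                               class = c("environment_table", "data.frame")),
       sites = sites)
}

#' Simulate a complete scenario (genotypes + community + environment)
#'
#' The three tables share one draw of the site-level drivers, so the
#' genotype, community and environment structure are mutually consistent:
#' connectivity drives both neutral heterozygosity and species richness
#' (producing a positive neutral SGDC), while the environmental gradient
#' drives only the adaptive loci.
#'
#' @inheritParams simulate_genotypes
#' @return list with `genotypes`, `truth`, `freq`, `community`,
#'   `environment`, `sites`.
#' @export
simulate_sgdc_scenario <- function(cfg = scenario_config(), seed = 1) {
  sites <- draw_sites(cfg, seed)
  g <- simulate_genotypes(cfg, seed, sites)
  com <- simulate_community(cfg, seed, sites)
  env <- simulate_environment(cfg, seed, sites)
  list(genotypes = g$genotypes, truth = g$truth, freq = g$freq,
       community = com$community, environment = env$environment,
       sites = sites)
}
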
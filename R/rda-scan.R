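# Indicator-encode an environment table: numeric columns pass through,
# categorical columns become 0/1 dummies (c-level factor -> c-1 columns;
# the common two-level case gives a single indicator).
encode_environment <- function(env) {
  stopifnot(is.data.frame(env))
  cols <- lapply(names(env), function(v) {
    x <- env[[v]]
    if (is.numeric(x)) {
      out <- data.frame(x)
      names(out) <- v
      out
    } else {
      f <- factor(x)
      if (nlevels(f) < 2) stop("categorical variable '", v,
                               "' has a single level")
      mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, "_", levels(f)[-1])
      as.data.frame(mm)
    }
  })
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(env)
  if (any(is.na(out))) stop("environment table contains missing values")
  out
}

#' Collinearity prescreen of environmental predictors
#'
#' Iteratively removes the variable with the greatest number of pairwise
#' Pearson correlations exceeding `r_threshold` in absolute value (ties
#' broken by larger mean absolute correlation with its offending partners,
#' then by name order) until no pair exceeds the threshold. Categorical
#' variables enter through their indicator encoding.
#'
#' @param env an `environment_table` (or plain data frame, sites as rows).
#' @param r_threshold absolute-correlation threshold (default 0.7).
#' @return the reduced table, same class as the input, with an attribute
#'   `removed` listing the discarded variables in removal order.
#' @export
prescreen_environment <- function(env, r_threshold = 0.7) {
  X <- encode_environment(as.data.frame(env))
  if (ncol(X) < 2) stop("need at least 2 variables")
  removed <- character()
  repeat {
    R <- abs(stats::cor(X))
    diag(R) <- 0
    if (all(R <= r_threshold, na.rm = TRUE)) break
    offending <- R > r_threshold
    cnt <- colSums(offending, na.rm = TRUE)
    worst <- which(cnt == max(cnt))
    if (length(worst) > 1) {
      meanr <- vapply(worst, function(j)
        mean(R[offending[, j], j]), numeric(1))
      worst <- worst[meanr == max(meanr)]
      worst <- worst[order(names(worst))]
    }
    drop <- names(worst)[1]
    removed <- c(removed, drop)
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  # map indicator names back to original columns where possible
  keep <- names(env)[vapply(names(env), function(v)
    v %in% colnames(X) || any(startsWith(colnames(X), paste0(v, "_"))),
    logical(1))]
  out <- env[, keep, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Variance inflation factors of the predictor set
#'
#' VIF_j = 1 / (1 - R2_j), with R2_j from regressing predictor j on all
#' others (after indicator encoding). A perfectly collinear set yields an
#' infinite VIF, reported as `Inf`. Values above 5 trigger a warning, the
#' conventional multicollinearity alarm for constrained ordination.
#'
#' @param env an `environment_table` or data frame, sites as rows.
#' @param warn_above warning threshold (default 5).
#' @return named numeric vector of VIFs.
#' @export
vif_check <- function(env, warn_above = 5) {
  X <- encode_environment(as.data.frame(env))
  if (ncol(X) < 2) stop("need at least 2 variables")
  if (nrow(X) <= ncol(X))
    stop("need more sites than predictors for VIF estimation")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  if (any(vif > warn_above))
    warning("VIF above ", warn_above, " for: ",
            paste(names(vif)[vif > warn_above], collapse = ", "))
  vif
}

#' RDA genotype-environment outlier scan
#'
#' Constrained-ordination genome scan: individual dosages (missing values
#' imputed to the locus's most common genotype) are regressed on the
#' site-level environmental predictors replicated per individual, and a
#' PCA of the fitted values yields the constrained (RDA) axes, via
#' [vegan::rda()]. Each axis is tested with an ANOVA-like permutation
#' test (rows of the predictor table permuted across individuals, forward
#' conditioning on earlier axes, [vegan::anova.cca()] with
#' `by = "axis"`). Retained axes are those significant at `alpha` up to
#' the eigenvalue scree elbow, unless `axes` fixes the count explicitly.
#' Per-locus loadings on the retained axes are standardized to z-scores,
#' and a locus is flagged as an outlier when its z-score falls outside
#' the interval anchor +/- `multiplier` * IQR on any retained axis (the
#' default anchors at the quartiles, a Tukey-fence reading of the
#' "z-scores exceeding twice the interquartile range" convention; set
#' `loading_rule$anchor = "median"` for the median-anchored variant).
#'
#' @param x a `genotype_matrix`.
#' @param env prescreened `environment_table`, sites as rows (row names
#'   must cover every population in `x`).
#' @param n_perm permutations for the per-axis tests (default 9999).
#' @param loading_rule list with `multiplier` (default 2) and `anchor`
#'   (`"quartile"` or `"median"`).
#' @param alpha per-axis significance level (default 0.05).
#' @param axes `NULL` for the automatic scree-and-significance choice, or
#'   an integer fixing the number of retained axes.
#' @param seed permutation seed.
#' @return object of class `rda_scan`: `n_axes`, `eig_share` (per-axis
#'   share of constrained variance), `axis_p` (permutation p-values),
#'   `retained_axes`, `zloadings` (loci x retained axes), `outliers`,
#'   `axis_env` (strongest-correlated predictor per retained axis),
#'   `var_explained` (proportion of genetic variance explained by the
#'   model), and the fitted vegan `model`.
#' @export
rda_scan <- function(x, env, n_perm = 9999,
                     loading_rule = list(multiplier = 2, anchor = "quartile"),
                     alpha = 0.05, axes = NULL, seed = 1) {
  env <- as.data.frame(env)
  miss <- setdiff(unique(x$population), rownames(env))
  if (length(miss))
    stop("environment table lacks site(s): ", paste(miss, collapse = ", "))
  X <- encode_environment(env)[x$population, , drop = FALSE]
  if (ncol(X) >= length(unique(x$population)))
    stop("more predictors than sites")
  Y <- x$dosage
  # modal-genotype imputation per locus
  for (j in which(colSums(is.na(Y)) > 0)) {
    tab <- tabulate(Y[, j] + 1L, nbins = 3L)
    Y[is.na(Y[, j]), j] <- which.max(tab) - 1L
  }
  const <- apply(Y, 2, function(g) all(g == g[1]))
  if (all(const)) stop("all loci constant after imputation")
  if (any(const)) {
    warning(sum(const), " locus/loci constant after imputation excluded")
    Y <- Y[, !const, drop = FALSE]
  }
  dat <- as.data.frame(X)
  mod <- vegan::rda(Y ~ ., data = dat)
  eig <- mod$CCA$eig
  share <- eig / sum(eig)
  set.seed(seed)
  an <- vegan::anova.cca(mod, by = "axis", permutations = n_perm)
  axis_p <- an[["Pr(>F)"]][seq_along(eig)]
  names(axis_p) <- names(eig)
  if (is.null(axes)) {
    el <- if (length(eig) >= 3) elbow_point(as.numeric(share))
          else length(eig)
    retained <- which(seq_along(eig) <= el & axis_p <= alpha)
  } else {
    retained <- seq_len(min(axes, length(eig)))
  }
  loadings <- mod$CCA$v[, retained, drop = FALSE]
  zl <- scale(loadings)
  mult <- loading_rule$multiplier %||% 2
  anchor <- loading_rule$anchor %||% "quartile"
  flagged <- rep(FALSE, nrow(zl))
  for (a in seq_len(ncol(zl))) {
    z <- zl[, a]
    qs <- stats::quantile(z, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    lim <- if (anchor == "median") qs[2] + c(-1, 1) * mult * iqr
           else c(qs[1] - mult * iqr, qs[3] + mult * iqr)
    flagged <- flagged | z < lim[1] | z > lim[2]
  }
  site_sc <- vegan::scores(mod, display = "lc",
                           choices = retained)
  axis_env <- vapply(seq_along(retained), function(a) {
    r <- abs(stats::cor(site_sc[, a], X))
    colnames(X)[which.max(r)]
  }, character(1))
  names(axis_env) <- names(eig)[retained]
  structure(list(n_axes = length(eig), eig_share = share, axis_p = axis_p,
                 retained_axes = retained, zloadings = zl,
                 outliers = rownames(zl)[flagged], axis_env = axis_env,
                 var_explained = sum(eig) / mod$tot.chi,
                 tested = colnames(Y), model = mod),
            class = "rda_scan")
}

#' @export
print.rda_scan <- function(x, ...) {
  cat(sprintf(
    "RDA outlier scan: %d constrained axes (%d retained), %.1f%% variance explained\n",
    x$n_axes, length(x$retained_axes), 100 * x$var_explained))
  cat(sprintf("  %d/%d loci flagged; axis drivers: %s\n",
              length(x$outliers), length(x$tested),
              paste(sprintf("%s~%s", names(x$axis_env), x$axis_env),
                    collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
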
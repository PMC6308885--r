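#' Partition loci into the five derived datasets
#'
#' From the full post-QC locus set and the two outlier-flag sets, builds
#' the five standard datasets used to contrast neutral and putatively
#' selected diversity:
#' \describe{
#'   \item{DS1}{all post-QC loci;}
#'   \item{DS2}{DS1 minus every flagged locus (union of the two scans);}
#'   \item{DS3}{DS1 minus the loci flagged by both scans (intersection);}
#'   \item{DS4}{the union of the two scans' outliers;}
#'   \item{DS5}{their intersection.}
#' }
#' By construction |DS2| = |DS1| - |DS4|, |DS3| = |DS1| - |DS5| and
#' DS5 is a subset of DS4.
#'
#' @param all_loci character vector of post-QC locus IDs.
#' @param pca_flags,rda_flags locus IDs flagged by the population-
#'   structure and genotype-environment scans; each may also be a
#'   `pca_scan` / `rda_scan` object, whose `outliers` element is used.
#' @return object of class `locus_partition`: named list of five logical
#'   masks over `all_loci` plus a `provenance` flag table.
#' @export
build_partition <- function(all_loci, pca_flags, rda_flags) {
  if (inherits(pca_flags, "pca_scan")) pca_flags <- pca_flags$outliers
  if (inherits(rda_flags, "rda_scan")) rda_flags <- rda_flags$outliers
  unknown <- setdiff(c(pca_flags, rda_flags), all_loci)
  if (length(unknown))
    stop("flag(s) reference unknown locus ID(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  pca <- all_loci %in% pca_flags
  rda <- all_loci %in% rda_flags
  masks <- list(DS1 = rep(TRUE, length(all_loci)),
                DS2 = !(pca | rda),
                DS3 = !(pca & rda),
                DS4 = pca | rda,
                DS5 = pca & rda)
  masks <- lapply(masks, stats::setNames, all_loci)
  structure(c(masks,
              list(loci = all_loci,
                   provenance = data.frame(locus_id = all_loci,
                                           pca = pca, rda = rda,
                                           stringsAsFactors = FALSE))),
            class = "locus_partition")
}

#' Sizes of the five locus datasets
#' @param x a `locus_partition`.
#' @return named integer vector DS1..DS5.
#' @export
partition_sizes <- function(x) {
  stopifnot(inherits(x, "locus_partition"))
  vapply(paste0("DS", 1:5), function(d) sum(x[[d]]), integer(1))
}

#' Locus IDs belonging to one dataset
#' @param x a `locus_partition`.
#' @param dataset one of `"DS1"` ... `"DS5"`.
#' @return character vector of locus IDs.
#' @export
partition_loci <- function(x, dataset = c("DS1", "DS2", "DS3", "DS4", "DS5")) {
  dataset <- match.arg(dataset)
  x$loci[x[[dataset]]]
}

#' @export
print.locus_partition <- function(x, ...) {
  s <- partition_sizes(x)
  cat("locus partition:",
      paste(sprintf("%s=%d", names(s), s), collapse = ", "), "\n")
  invisible(x)
}
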
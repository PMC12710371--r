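#' Rarefy a feature table to an even depth
#'
#' Random subsampling without replacement (hypergeometric draws via
#' `vegan::rrarefy`) of each library to a common depth; libraries below
#' the depth are dropped (logged via message and recorded in the
#' `dropped_samples` attribute). The study depths used for the field
#' data were 13,407 (16S) and 17,182 (ITS2) reads.
#'
#' @param x a [feature_table()] of integer counts.
#' @param depth target sequencing depth (positive integer).
#' @param seed optional integer seed for reproducible subsampling.
#' @return A rarefied [feature_table()]; every retained sample sums to
#'   exactly `depth`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 || depth != round(depth))
    stop2("depth must be a positive integer")
  cs <- colSums(x$counts)
  keep <- cs >= depth
  if (!any(keep))
    stop2("all ", length(cs), " samples are below the rarefaction depth ", depth)
  dropped <- colnames(x$counts)[!keep]
  if (length(dropped) > 0)
    message("rarefy: dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  sub <- withCallingHandlers(
    t(vegan::rrarefy(t(x$counts[, keep, drop = FALSE]), depth)),
    warning = function(w) {
      # rrarefy's "observed counts" heuristic misfires on tables
      # without singletons; the inputs are validated integer counts
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- feature_table(sub, marker = x$marker, assay = x$assay)
  attr(out, "dropped_samples") <- dropped
  attr(out, "rarefaction_depth") <- depth
  out
}

#' Per-sample relative abundance
#'
#' @param x feature table or non-negative matrix (taxa x samples).
#' @return Matrix of proportions; each column sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- as_count_matrix(x)
  if (any(m < 0)) stop2("negative abundances")
  cs <- colSums(m)
  if (any(cs == 0))
    stop2("all-zero sample(s): ",
          paste(colnames(m)[cs == 0], collapse = ", "))
  sweep(m, 2, cs, "/")
}

#' Square-root transformation followed by Wisconsin double standardization
#'
#' The community-matrix transformation applied before Bray-Curtis in the
#' study's analysis chain: element-wise square root, then each taxon row
#' divided by its row maximum, then each sample column divided by its
#' column total (exactly this order, the canonical Wisconsin definition).
#' All-zero taxon rows are dropped with a warning; an all-zero sample is
#' an error.
#'
#' @param x feature table or non-negative matrix (taxa x samples).
#' @return Standardized matrix; every column sums to 1.
#' @export
sqrt_wisconsin <- function(x) {
  m <- as_count_matrix(x)
  if (any(m < 0)) stop2("negative abundances")
  cs0 <- colSums(m)
  if (any(cs0 == 0))
    stop2("all-zero sample(s): ", paste(colnames(m)[cs0 == 0], collapse = ", "))
  zero_rows <- rowSums(m) == 0
  if (any(zero_rows)) {
    warning("sqrt_wisconsin: dropping ", sum(zero_rows),
            " all-zero taxon row(s)", call. = FALSE)
    m <- m[!zero_rows, , drop = FALSE]
  }
  m <- sqrt(m)
  m <- m / apply(m, 1, max)
  sweep(m, 2, colSums(m), "/")
}

#' Centered log-ratio (CLR) transform
#'
#' Per sample, `log(x + pseudocount)` centered by the sample mean log;
#' every column of the result sums to zero. Used as the compositional
#' scale for the differential-abundance screen. Default pseudocount is
#' the standard half-count correction.
#'
#' @param x feature table or count matrix (taxa x samples).
#' @param pseudocount positive offset added before the log.
#' @return Real matrix with zero column means.
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  m <- as_count_matrix(x)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop2("pseudocount must be > 0")
  lg <- log(m + pseudocount)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Sums counts within each group at `rank`; groups whose mean relative
#' abundance falls below `min_mean_abundance` are pooled into `"other"`,
#' and taxa absent from the taxonomy map into `"unassigned"` (the
#' "dominant lineages above 0.1% relative abundance" style of summary).
#'
#' @param x a [feature_table()].
#' @param taxonomy data frame from [read_taxonomy()].
#' @param rank name of the rank column to aggregate at.
#' @param min_mean_abundance pooling threshold on mean relative
#'   abundance (proportion; 0 disables pooling).
#' @return A [feature_table()] with one row per retained group; total
#'   counts are conserved.
#' @export
aggregate_taxonomy <- function(x, taxonomy, rank, min_mean_abundance = 0) {
  stopifnot(inherits(x, "feature_table"))
  if (!is.data.frame(taxonomy) || nrow(taxonomy) == 0)
    stop2("empty taxonomy map")
  if (!rank %in% names(taxonomy))
    stop2("rank '", rank, "' not present in taxonomy map")
  assert_scalar_prob(min_mean_abundance, "min_mean_abundance")
  grp <- as.character(taxonomy[[rank]][match(rownames(x$counts),
                                             taxonomy$taxon_id)])
  grp[is.na(grp) | grp == ""] <- "unassigned"
  agg <- rowsum(x$counts, grp)
  if (min_mean_abundance > 0) {
    mean_ab <- rowMeans(relative_abundance(agg))
    pool <- mean_ab < min_mean_abundance & rownames(agg) != "unassigned"
    if (any(pool)) {
      other <- colSums(agg[pool, , drop = FALSE])
      agg <- rbind(agg[!pool, , drop = FALSE], other = other)
    }
  }
  feature_table(agg, marker = x$marker, assay = x$assay)
}
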
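#' Per-sample dormancy fraction
#'
#' For each RNA/DNA pair, the dormant fraction is one minus the number
#' of active taxa (detected in the RNA library) divided by the total
#' number of taxa detected in either library of that physical sample.
#' A pair with an empty union is flagged undefined (`NA`, neither 0 nor
#' 1) rather than imputed.
#'
#' @param pc a [align_pairs()] result.
#' @param presence_threshold minimum count for a taxon to count as
#'   detected (default 1).
#' @return data frame with one row per pair: `pair_id`,
#'   `active_richness`, `union_richness`, `dormant_fraction`,
#'   `undefined`.
#' @export
dormancy_profile <- function(pc, presence_threshold = 1) {
  stopifnot(inherits(pc, "paired_community"))
  if (presence_threshold < 1) stop2("presence_threshold must be >= 1")
  A <- pc$active$counts >= presence_threshold
  D <- pc$total$counts >= presence_threshold
  union_rich <- colSums(A | D)
  active_rich <- colSums(A)
  undefined <- union_rich == 0
  data.frame(pair_id = pc$pair_ids,
             active_richness = as.integer(active_rich),
             union_richness = as.integer(union_rich),
             dormant_fraction = ifelse(undefined, NA_real_,
                                       1 - active_rich / union_rich),
             undefined = undefined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shared fraction of the total community detected as active
#'
#' Per pair, the fraction of taxa detected in the DNA (total) library
#' that are also detected in the matched RNA (active) library — the
#' statistic behind "x% of total-community taxa were detected in the
#' corresponding active community sample". Pairs with an empty DNA
#' detection set are undefined and excluded from the summary with a
#' warning.
#'
#' @inheritParams dormancy_profile
#' @return list with `per_pair` (data frame: `pair_id`,
#'   `shared_fraction`), `mean`, `sd` (over defined pairs).
#' @export
shared_fraction <- function(pc, presence_threshold = 1) {
  stopifnot(inherits(pc, "paired_community"))
  A <- pc$active$counts >= presence_threshold
  D <- pc$total$counts >= presence_threshold
  denom <- colSums(D)
  frac <- ifelse(denom == 0, NA_real_, colSums(A & D) / denom)
  if (anyNA(frac))
    warning("shared_fraction: ", sum(is.na(frac)),
            " pair(s) with empty DNA detection set excluded from summary",
            call. = FALSE)
  list(per_pair = data.frame(pair_id = pc$pair_ids, shared_fraction = frac,
                             row.names = NULL, stringsAsFactors = FALSE),
       mean = mean(frac, na.rm = TRUE),
       sd = sd(frac, na.rm = TRUE))
}

#' Per-taxon occupancy
#'
#' The proportion of samples in which a taxon is detected.
#'
#' @param x feature table or count matrix (taxa x samples).
#' @param presence_threshold minimum count for detection.
#' @return Named numeric vector of proportions in `[0, 1]`.
#' @export
occupancy <- function(x, presence_threshold = 1) {
  m <- as_count_matrix(x)
  if (ncol(m) == 0) stop2("occupancy needs at least one sample")
  rowMeans(m >= presence_threshold)
}

#' Total and active core microbiomes with per-taxon activity frequency
#'
#' Flags a taxon as a member of the *total core microbiome* when its
#' occupancy in the DNA assay is at least `occupancy_threshold`, and of
#' the *active core microbiome* when its RNA-assay occupancy meets the
#' same threshold (default 0.95, applied as `>=`, pooled over all site
#' types and seasons). `activity_frequency` is the fraction of pairs in
#' which a DNA-detected taxon was also RNA-detected; total-core taxa
#' with activity frequency below `inactive_cutoff` are reported as
#' "frequently inactive" (the dormant-core pattern), and active-core
#' taxa absent from the total core are listed separately.
#'
#' @inheritParams dormancy_profile
#' @param occupancy_threshold core occupancy threshold tau in (0, 1].
#' @param inactive_cutoff activity-frequency cutoff below which a
#'   total-core taxon is flagged frequently inactive.
#' @return data frame of class `core_report` with per-taxon columns
#'   `taxon_id`, `occupancy_total`, `occupancy_active`, `is_core_total`,
#'   `is_core_active`, `n_occurrences_total`, `activity_frequency`,
#'   `frequently_inactive_core`; attributes `core_total`, `core_active`,
#'   `frequently_inactive_core`, `active_core_not_total_core`, and the
#'   configuration used.
#' @export
core_report <- function(pc, occupancy_threshold = 0.95,
                        presence_threshold = 1, inactive_cutoff = 0.5) {
  stopifnot(inherits(pc, "paired_community"))
  if (!is.numeric(occupancy_threshold) || length(occupancy_threshold) != 1L ||
      occupancy_threshold <= 0 || occupancy_threshold > 1)
    stop2("occupancy_threshold must be in (0, 1]")
  occ_tot <- occupancy(pc$total, presence_threshold)
  occ_act <- occupancy(pc$active, presence_threshold)
  A <- pc$active$counts >= presence_threshold
  D <- pc$total$counts >= presence_threshold
  n_occ <- rowSums(D)
  act_freq <- ifelse(n_occ == 0, NA_real_, rowSums(A & D) / n_occ)
  out <- data.frame(
    taxon_id = pc$taxon_universe,
    occupancy_total = unname(occ_tot),
    occupancy_active = unname(occ_act),
    is_core_total = unname(occ_tot >= occupancy_threshold),
    is_core_active = unname(occ_act >= occupancy_threshold),
    n_occurrences_total = as.integer(n_occ),
    activity_frequency = unname(act_freq),
    row.names = NULL, stringsAsFactors = FALSE)
  out$frequently_inactive_core <- out$is_core_total &
    !is.na(out$activity_frequency) & out$activity_frequency < inactive_cutoff
  attr(out, "core_total") <- out$taxon_id[out$is_core_total]
  attr(out, "core_active") <- out$taxon_id[out$is_core_active]
  attr(out, "frequently_inactive_core") <-
    out$taxon_id[out$frequently_inactive_core]
  attr(out, "active_core_not_total_core") <-
    out$taxon_id[out$is_core_active & !out$is_core_total]
  attr(out, "config") <- list(occupancy_threshold = occupancy_threshold,
                              presence_threshold = presence_threshold,
                              inactive_cutoff = inactive_cutoff,
                              denominator = "retained_samples",
                              n_pairs = length(pc$pair_ids))
  class(out) <- c("core_report", "data.frame")
  out
}

#' @export
print.core_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(paste0("<core_report> tau = %.2f over %d pairs: %d total-core, ",
                     "%d active-core taxa (%d total-core frequently inactive)\n"),
              cfg$occupancy_threshold, cfg$n_pairs,
              sum(x$is_core_total), sum(x$is_core_active),
              sum(x$frequently_inactive_core)))
  invisible(as.data.frame(x))
}
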
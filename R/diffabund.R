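#' Differential-abundance screen configuration
#'
#' @param min_prevalence minimum detection prevalence (proportion of
#'   tested samples) for a taxon to enter testing; default 0.10.
#' @param min_fold_change fold-change rule for calling enrichment in the
#'   active/total contrast (default 2, i.e. |log2FC| >= 1).
#' @param alpha BH-adjusted significance level.
#' @param n_perm permutations for the per-taxon F reference; the floor
#'   of attainable BH-adjusted p-values is `m / (k (n_perm + 1))` for
#'   `k` discoveries among `m` tested taxa, so screens over hundreds of
#'   taxa need the default 999 or more.
#' @param seed optional integer seed for the permutations.
#' @param pseudocount CLR pseudocount (half-count correction).
#' @return list of class `diffabund_config`.
#' @export
diffabund_config <- function(min_prevalence = 0.10, min_fold_change = 2,
                             alpha = 0.05, n_perm = 999, seed = NULL,
                             pseudocount = 0.5) {
  assert_scalar_prob(min_prevalence, "min_prevalence")
  if (!is.numeric(min_fold_change) || min_fold_change < 1)
    stop2("min_fold_change must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop2("alpha must be in (0, 1)")
  if (!is.numeric(n_perm) || n_perm < 1) stop2("n_perm must be >= 1")
  structure(list(min_prevalence = min_prevalence,
                 min_fold_change = min_fold_change, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = seed,
                 pseudocount = pseudocount),
            class = "diffabund_config")
}

# residuals of the rows of Y after projection on the column space of X
proj_resid <- function(Y, X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  list(res = Y - (Y %*% Q) %*% t(Q), rank = q$rank)
}

#' Per-taxon differential abundance on the CLR scale
#'
#' A linear model is fitted per taxon to CLR-transformed counts with the
#' blocking factor as a fixed additive effect; the design term is
#' assessed by its F statistic against a permutation reference built by
#' permuting the term labels within blocks, and BH adjustment is applied
#' across the tested taxa. A compositional bias correction (the median
#' of the per-taxon group effects, the common CLR shift induced by any
#' genuinely enriched taxa) is removed inside the test statistic and
#' recomputed for every permutation, keeping the reference exact. This
#' is a documented native screen in the spirit of compositional
#' mixed-model testers (LinDA-style) but with a fixed block effect and
#' a permutation reference instead of asymptotic mixed-model inference.
#'
#' @param table a [feature_table()].
#' @param meta data frame with a `sample_id` column (or rownames)
#'   matching the table's samples, containing `term` (and `block`).
#' @param term name of the factor to test (e.g. `site_type`, `season`,
#'   `assay`).
#' @param block optional name of a blocking factor (e.g. `site` or the
#'   pair id); permutations are restricted within blocks.
#' @param config a [diffabund_config()].
#' @return data frame of class `da_result`, one row per taxon:
#'   `taxon_id`, `tested`, `log2FC` (difference of CLR group means
#'   rescaled to log2; max minus min group for terms with more than two
#'   levels), `statistic` (F), `p`, `p_adj`, `max_group`.
#' @export
da_test <- function(table, meta, term, block = NULL,
                    config = diffabund_config()) {
  counts <- as_count_matrix(table)
  if (!is.null(meta$sample_id)) rownames(meta) <- meta$sample_id
  if (!all(colnames(counts) %in% rownames(meta)))
    stop2("metadata does not cover all samples of the table")
  meta <- meta[colnames(counts), , drop = FALSE]
  if (!term %in% names(meta)) stop2("term '", term, "' not in metadata")
  f <- factor(meta[[term]])
  if (nlevels(droplevels(f)) < 2) stop2("term '", term, "' has fewer than 2 levels")
  f <- droplevels(f)
  n <- ncol(counts)

  if (!is.null(block)) {
    if (!block %in% names(meta)) stop2("block '", block, "' not in metadata")
    b <- droplevels(factor(meta[[block]]))
    if (all(tapply(as.character(f), b, function(z) length(unique(z)) == 1)))
      stop2("term '", term, "' is confounded with block '", block,
            "': constant within every block")
    X0 <- model.matrix(~b)
  } else {
    b <- NULL
    X0 <- matrix(1, n, 1)
  }

  prevalence <- rowMeans(counts >= 1)
  tested <- prevalence >= config$min_prevalence
  if (!any(tested)) stop2("no taxon passes the prevalence filter")

  Y <- clr_transform(counts, config$pseudocount)
  Yt <- Y[tested, , drop = FALSE]

  # compositional bias correction: a handful of truly enriched taxa
  # shifts the CLR reference of every sample in one group, handing all
  # null taxa a spurious common effect. As in bias-corrected
  # compositional testers, the median of the per-taxon group effects
  # estimates that common shift and is removed. The correction is part
  # of the test statistic, recomputed for every permuted labelling, so
  # the permutation reference stays exact.
  debias <- function(fac) {
    gm <- vapply(levels(fac), function(lv)
      rowMeans(Yt[, fac == lv, drop = FALSE]), numeric(nrow(Yt)))
    if (nrow(Yt) == 1) gm <- matrix(gm, nrow = 1)
    out <- Yt
    for (l in seq_along(levels(fac))[-1]) {
      bias <- median(gm[, l] - gm[, 1])
      out[, fac == levels(fac)[l]] <- out[, fac == levels(fac)[l]] - bias
    }
    out
  }
  q0 <- qr(X0)
  rank0 <- q0$rank
  Q0 <- qr.Q(q0)[, seq_len(rank0), drop = FALSE]
  term_cols <- function(fac) model.matrix(~fac)[, -1, drop = FALSE]
  f_stat <- function(fac) {
    Ya <- debias(fac)
    res0 <- Ya - (Ya %*% Q0) %*% t(Q0)
    rss0 <- rowSums(res0^2)
    fit1 <- proj_resid(Ya, cbind(X0, term_cols(fac)))
    df1 <- fit1$rank - rank0
    df2 <- n - fit1$rank
    if (df1 < 1 || df2 < 1) stop2("design leaves no degrees of freedom")
    rss1 <- rowSums(fit1$res^2)
    ((rss0 - rss1) / df1) / pmax(rss1, .Machine$double.eps) * df2
  }
  F_obs <- f_stat(f)

  if (!is.null(config$seed)) set.seed(config$seed)
  perm_within <- function() {
    if (is.null(b)) return(sample(n))
    idx <- seq_len(n)
    for (lv in levels(b)) {
      w <- which(b == lv)
      if (length(w) > 1) idx[w] <- w[sample(length(w))]
    }
    idx
  }
  exceed <- rep(0L, sum(tested))
  for (i in seq_len(config$n_perm)) {
    Fp <- f_stat(f[perm_within()])
    exceed <- exceed + (Fp >= F_obs - 1e-12)
  }
  p <- (exceed + 1) / (config$n_perm + 1)
  p_adj <- p.adjust(p, method = "BH")

  Yadj <- debias(f)
  gm <- vapply(levels(f), function(lv)
    rowMeans(Yadj[, f == lv, drop = FALSE]), numeric(sum(tested)))
  if (sum(tested) == 1) gm <- matrix(gm, nrow = 1,
                                     dimnames = list(NULL, levels(f)))
  if (nlevels(f) == 2) {
    l2fc <- (gm[, 2] - gm[, 1]) / log(2)
  } else {
    l2fc <- (apply(gm, 1, max) - apply(gm, 1, min)) / log(2)
  }
  max_group <- levels(f)[apply(gm, 1, which.max)]

  out <- data.frame(taxon_id = rownames(counts), tested = tested,
                    log2FC = NA_real_, statistic = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    max_group = NA_character_,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$log2FC[tested] <- l2fc
  out$statistic[tested] <- F_obs
  out$p[tested] <- p
  out$p_adj[tested] <- p_adj
  out$max_group[tested] <- max_group
  attr(out, "term") <- term
  attr(out, "levels") <- levels(f)
  attr(out, "block") <- block
  attr(out, "config") <- config
  class(out) <- c("da_result", "data.frame")
  out
}

#' Active vs total enrichment screen
#'
#' Runs [da_test()] with the assay (RNA vs DNA) as the term and the
#' pair id as the block, then applies the joint rule for calling a
#' taxon enriched: BH-adjusted p below `alpha` *and* fold change of at
#' least `min_fold_change` between the active and total communities.
#' `log2FC > 0` means more abundant in the active (RNA) community.
#'
#' @param pc a [align_pairs()] result.
#' @param config a [diffabund_config()].
#' @return A `da_result` data frame with additional columns `enriched`
#'   and `direction` (`"active-enriched"` / `"total-enriched"`).
#' @export
active_vs_total_enrichment <- function(pc, config = diffabund_config()) {
  stopifnot(inherits(pc, "paired_community"))
  counts <- cbind(pc$total$counts, pc$active$counts)
  ids <- c(paste0(pc$pair_ids, "_DNA"), paste0(pc$pair_ids, "_RNA"))
  colnames(counts) <- ids
  combined <- feature_table(counts, marker = pc$total$marker, assay = "DNA")
  meta <- data.frame(sample_id = ids,
                     assay = factor(rep(c("DNA", "RNA"),
                                        each = length(pc$pair_ids)),
                                    levels = c("DNA", "RNA")),
                     pair = rep(pc$pair_ids, 2),
                     stringsAsFactors = FALSE)
  res <- da_test(combined, meta, term = "assay", block = "pair",
                 config = config)
  res$enriched <- res$tested & !is.na(res$p_adj) &
    res$p_adj < config$alpha &
    abs(res$log2FC) >= log2(config$min_fold_change)
  res$direction <- ifelse(!res$tested, NA_character_,
                          ifelse(res$log2FC > 0, "active-enriched",
                                 "total-enriched"))
  attr(res, "n_enriched") <- sum(res$enriched)
  res
}

#' Overlap of two differential-abundance screens
#'
#' Cross-tabulates which taxa are significant by one term only, the
#' other only, both, or neither (the Venn-diagram counts of a site-type
#' screen against a season screen within one community).
#'
#' @param result_a,result_b two [da_test()] results over the same taxon
#'   universe.
#' @param alpha significance level applied to `p_adj`.
#' @return list with `counts` (named: `both`, `only_a`, `only_b`,
#'   `neither`), the significant id sets, and a per-taxon table.
#' @export
overlap_summary <- function(result_a, result_b, alpha = 0.05) {
  if (!identical(result_a$taxon_id, result_b$taxon_id))
    stop2("results are not over the same taxon universe")
  sig <- function(r) !is.na(r$p_adj) & r$p_adj < alpha
  a <- sig(result_a)
  b <- sig(result_b)
  tab <- data.frame(taxon_id = result_a$taxon_id,
                    significant_a = a, significant_b = b,
                    stringsAsFactors = FALSE)
  list(counts = c(both = sum(a & b), only_a = sum(a & !b),
                  only_b = sum(!a & b), neither = sum(!a & !b)),
       significant_a = result_a$taxon_id[a],
       significant_b = result_b$taxon_id[b],
       table = tab)
}

#' Seasonal abundance-delta contrast between site partitions
#'
#' For a taxon group (e.g. one fungal class), computes the per-plot
#' change in relative abundance from one season to another, summarizes
#' the mean change (+/- SE) per site, and compares the two site
#' partitions (e.g. warm vs cool sites split at a soil-temperature
#' threshold) with a Welch t-test on the site means — the "decline from
#' June to August only at the warmest sites" style of analysis.
#'
#' @param table a [feature_table()] covering both seasons.
#' @param meta sample metadata for the table's samples.
#' @param taxa character vector of taxon ids forming the group.
#' @param from_season,to_season season levels to contrast.
#' @param site_partition named character vector mapping each site to one
#'   of two partition labels (e.g. `"warm"`/`"cool"`), or a named
#'   numeric vector of site temperatures plus `threshold`.
#' @param threshold when `site_partition` is numeric: sites at or above
#'   it are labelled `"warm"`, the rest `"cool"`.
#' @return list: `per_site` (site, partition, mean delta, se, n plots),
#'   `estimate` (difference of partition means), `p` (Welch), plus the
#'   per-plot deltas.
#' @export
seasonal_delta_contrast <- function(table, meta, taxa,
                                    from_season = "June",
                                    to_season = "August",
                                    site_partition, threshold = NULL) {
  stopifnot(inherits(table, "feature_table"))
  meta <- as_sample_metadata(meta)
  sm <- meta[sample_ids(table), ]
  if (is.numeric(site_partition)) {
    if (is.null(threshold)) stop2("threshold required for numeric site_partition")
    site_partition <- setNames(ifelse(site_partition >= threshold,
                                      "warm", "cool"),
                               names(site_partition))
  }
  missing_taxa <- setdiff(taxa, taxon_ids(table))
  if (length(missing_taxa) > 0)
    stop2("taxa not in table: ", paste(missing_taxa, collapse = ", "))
  rel <- relative_abundance(table)
  grp_ab <- colSums(rel[taxa, , drop = FALSE])

  sm$key <- paste(sm$site, sm$plot, sep = "/")
  ab_of <- function(season) {
    sel <- sm$season == season
    setNames(grp_ab[sel], sm$key[sel])
  }
  a_from <- ab_of(from_season)
  a_to <- ab_of(to_season)
  keys <- intersect(names(a_from), names(a_to))
  delta <- a_to[keys] - a_from[keys]
  site_of <- sub("/.*$", "", keys)

  all_sites <- unique(as.character(sm$site))
  incomplete <- setdiff(all_sites, unique(site_of))
  if (length(incomplete) > 0)
    warning("seasonal_delta_contrast: site(s) missing a season excluded: ",
            paste(incomplete, collapse = ", "), call. = FALSE)

  per_site <- do.call(rbind, lapply(unique(site_of), function(s) {
    d <- delta[site_of == s]
    data.frame(site = s,
               partition = unname(site_partition[s]),
               mean_delta = mean(d),
               se = sd(d) / sqrt(length(d)),
               n_plots = length(d), stringsAsFactors = FALSE)
  }))
  if (anyNA(per_site$partition))
    stop2("site_partition does not cover site(s): ",
          paste(per_site$site[is.na(per_site$partition)], collapse = ", "))
  parts <- split(per_site$mean_delta, per_site$partition)
  if (length(parts) != 2 || any(lengths(parts) < 2))
    stop2("each partition needs at least 2 sites for a variance estimate")
  if (all(vapply(parts, var, numeric(1)) == 0)) {
    # degenerate: no within-partition variance (e.g. identical abundances)
    p <- if (isTRUE(all.equal(mean(parts[[1]]), mean(parts[[2]])))) 1 else 0
    est <- mean(parts[[2]]) - mean(parts[[1]])
  } else {
    tt <- t.test(parts[[2]], parts[[1]])
    p <- tt$p.value
    est <- mean(parts[[2]]) - mean(parts[[1]])
  }
  list(per_site = per_site, estimate = est, p = p,
       per_plot = data.frame(plot = keys, site = site_of,
                             delta = unname(delta),
                             stringsAsFactors = FALSE))
}
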
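#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x - y| / sum (x + y)` over taxa, computed on a
#' (typically [sqrt_wisconsin()]-standardized) abundance matrix with
#' samples in columns. Implemented through a Manhattan distance kernel
#' so large sample sets stay fast; tests cross-check a naive double
#' loop and `vegan::vegdist`.
#'
#' @param x non-negative abundance matrix (taxa x samples) or feature
#'   table.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- as_count_matrix(x)
  if (any(m < 0)) stop2("negative abundances")
  cs <- colSums(m)
  tot <- outer(cs, cs, "+")
  if (any(tot[upper.tri(tot)] == 0))
    stop2("Bray-Curtis undefined: a pair of all-zero samples")
  man <- as.matrix(dist(t(m), method = "manhattan"))
  d <- man / tot
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  validate_distance_matrix(d)
}

#' Shannon diversity (nats)
#'
#' `H = -sum p log p` over taxa with nonzero abundance, per sample.
#'
#' @param x abundance vector (one sample) or matrix (taxa x samples) or
#'   feature table.
#' @return Numeric value (vector input) or named vector per sample.
#' @export
shannon_diversity <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (any(x < 0)) stop2("negative abundances")
    if (sum(x) == 0) stop2("all-zero sample")
    return(unname(vegan::diversity(x, index = "shannon")))
  }
  m <- as_count_matrix(x)
  if (any(m < 0)) stop2("negative abundances")
  cs <- colSums(m)
  if (any(cs == 0))
    stop2("all-zero sample(s): ", paste(colnames(m)[cs == 0], collapse = ", "))
  vegan::diversity(t(m), index = "shannon")
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Eigen-decomposition of the double-centered squared-distance matrix.
#' Axes with negative eigenvalues (non-Euclidean distances such as
#' Bray-Curtis) are reported as a diagnostic and dropped from the
#' returned coordinates. Used as the deterministic ordination whose
#' axes feed the environment-linkage screen.
#'
#' @param d distance matrix (square symmetric with ids).
#' @return list of class `pcoa_result`: `coordinates`
#'   (samples x retained axes), `eigenvalues` (all), dropped
#'   `negative_eigenvalues`, `proportion_explained` (per retained axis,
#'   relative to the positive-eigenvalue total).
#' @export
pcoa <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) stop2("PCoA needs at least 3 samples")
  fit <- suppressWarnings(cmdscale(as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- sqrt(.Machine$double.eps) * max(abs(eig))
  pos <- which(eig > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 negative_eigenvalues = eig[eig < -tol],
                 proportion_explained = eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type-I) partition of a distance matrix by the design
#' terms in the order given, with pseudo-F and permutation p-values,
#' computed by `vegan::adonis2`. Permutations are free by default and
#' can be restricted within `strata` (e.g. site as stratum when testing
#' season in a plots-within-sites design, which otherwise inflates
#' significance).
#'
#' @param d distance matrix.
#' @param data data frame of design variables, rows matching the ids of
#'   `d` (reordered by id when a `sample_id` column or rownames are
#'   present).
#' @param terms character vector of term names, tested sequentially in
#'   this order.
#' @param n_perm number of permutations (p reported as (b+1)/(m+1)).
#' @param seed optional integer seed.
#' @param strata optional name of a grouping column; permutations are
#'   then restricted within its levels.
#' @param permutations optional explicit permutation matrix
#'   (rows = permutations), overriding `n_perm`/`strata`; used for
#'   exhaustive enumeration on tiny designs.
#' @return data frame of class `permanova_result`: one row per term
#'   plus `Residual` and `Total`, columns `term`, `df`,
#'   `sum_of_squares`, `r2`, `pseudo_f`, `p`; attributes
#'   `n_permutations` and `seed`.
#' @export
permanova <- function(d, data, terms, n_perm = 999, seed = NULL,
                      strata = NULL, permutations = NULL) {
  d <- validate_distance_matrix(d)
  if (!is.null(data$sample_id)) rownames(data) <- data$sample_id
  if (!is.null(rownames(data)) && all(rownames(d) %in% rownames(data)))
    data <- data[rownames(d), , drop = FALSE]
  if (nrow(data) != nrow(d)) stop2("design rows do not match distance ids")
  missing <- setdiff(terms, names(data))
  if (length(missing) > 0)
    stop2("term(s) not in design data: ", paste(missing, collapse = ", "))
  for (tm in terms) {
    v <- data[[tm]]
    if (!is.numeric(v) && length(unique(v)) < 2)
      stop2("term '", tm, "' has a single level")
  }
  if (is.null(permutations)) {
    if (!is.numeric(n_perm) || n_perm < 1) stop2("n_perm must be >= 1")
    perm <- if (is.null(strata)) n_perm else
      permute::how(nperm = n_perm, blocks = data[[strata]])
  } else {
    perm <- permutations
    n_perm <- nrow(permutations)
  }
  dd <- as.dist(d)
  fml <- as.formula(paste("dd ~", paste(terms, collapse = " + ")))
  environment(fml) <- environment()
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::adonis2(fml, data = data, permutations = perm, by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df,
                    sum_of_squares = fit$SumOfSqs, r2 = fit$R2,
                    pseudo_f = fit$F, p = fit$`Pr(>F)`,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Beta dispersion (multivariate homogeneity of group spreads)
#'
#' Distance of each sample to its group centroid in principal-coordinate
#' space (with the standard imaginary-part correction for negative
#' eigenvalues), followed by a permutation F-test of equal mean
#' dispersion, via `vegan::betadisper` + `vegan::permutest`. Singleton
#' groups are excluded with a warning.
#'
#' @param d distance matrix.
#' @param groups factor of group memberships, aligned to the ids of `d`.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list of class `beta_dispersion_result`: per-sample
#'   `distances`, `group_means`, `f`, `p`, `n_perm`, `excluded` groups.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- validate_distance_matrix(d)
  groups <- factor(groups)
  if (length(groups) != nrow(d)) stop2("groups length must match distance ids")
  tab <- table(groups)
  singletons <- names(tab)[tab < 2]
  if (length(singletons) > 0) {
    warning("beta_dispersion: excluding singleton group(s): ",
            paste(singletons, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% singletons)
    d <- d[keep, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop2("need at least 2 groups with >= 2 members")
  mod <- withCallingHandlers(
    vegan::betadisper(as.dist(d), groups, type = "centroid"),
    warning = function(w) {
      # the standard imaginary-part correction for non-Euclidean
      # (e.g. Bray-Curtis) distances; expected, not actionable
      if (grepl("squared distances are negative", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::permutest(mod, permutations = n_perm)
  structure(list(distances = setNames(as.numeric(mod$distances), rownames(d)),
                 group_means = tapply(mod$distances, groups, mean),
                 f = pt$tab$F[1], p = pt$tab$`Pr(>F)`[1],
                 n_perm = n_perm, excluded = singletons),
            class = "beta_dispersion_result")
}

#' Mantel test between two distance matrices
#'
#' Correlation of the unfolded upper triangles (Pearson or Spearman with
#' average ranks for ties), with significance by permuting the ids of
#' one matrix (`vegan::mantel`).
#'
#' @param d1,d2 distance matrices over the same ids in the same order.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list: `r`, `p`, `method`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  d1 <- validate_distance_matrix(d1)
  d2 <- validate_distance_matrix(d2)
  if (!identical(rownames(d1), rownames(d2)))
    stop2("distance matrices must share ids in the same order")
  for (v in list(upper_tri_vec(d1), upper_tri_vec(d2)))
    if (diff(range(v)) <= 1e-10 * max(abs(v), 1))
      stop2("constant distance triangle: correlation undefined")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(as.dist(d1), as.dist(d2), method = method,
                       permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif, method = method,
       n_perm = n_perm)
}

#' Partial Mantel test
#'
#' Partial correlation of `d_comm` and `d_geo` given `d_env` on the
#' unfolded upper triangles, permutation p via `vegan::mantel.partial` —
#' the "distance decay after accounting for soil chemistry" check.
#'
#' @param d_comm,d_geo,d_env three aligned distance matrices.
#' @inheritParams mantel_test
#' @return list: `r`, `p`, `method`, `n_perm`.
#' @export
partial_mantel <- function(d_comm, d_geo, d_env,
                           method = c("pearson", "spearman"),
                           n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  d_comm <- validate_distance_matrix(d_comm)
  d_geo <- validate_distance_matrix(d_geo)
  d_env <- validate_distance_matrix(d_env)
  if (!identical(rownames(d_comm), rownames(d_geo)) ||
      !identical(rownames(d_comm), rownames(d_env)))
    stop2("distance matrices must share ids in the same order")
  for (m in list(d_comm, d_geo, d_env)) {
    v <- upper_tri_vec(m)
    if (diff(range(v)) <= 1e-10 * max(abs(v), 1))
      stop2("constant distance triangle: correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel.partial(as.dist(d_comm), as.dist(d_geo),
                               as.dist(d_env), method = method,
                               permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif, method = method,
       n_perm = n_perm)
}

#' Distance decay of community composition
#'
#' Tests whether community dissimilarity increases with (log10)
#' geographic distance between plots, per season and overall, with an
#' optional partial version controlling a soil-chemistry distance
#' matrix. Community dissimilarity is Bray-Curtis on the
#' [sqrt_wisconsin()]-standardized table; the overall test uses the
#' season-averaged community distances between plots.
#'
#' @param x feature table (one assay; all seasons).
#' @param meta sample metadata covering the samples of `x`.
#' @param coordinates data frame with columns `site`, `plot`, `x`, `y`
#'   (planar coordinates, metres), one row per plot.
#' @param env optional plot-level environmental data frame (`site`,
#'   `plot`, numeric covariates); when given, partial Mantel results
#'   controlling the Euclidean distance of the scaled covariates are
#'   added.
#' @param method,n_perm,seed passed to [mantel_test()].
#' @return list of class `distance_decay_result`: `stats` (one row per
#'   season plus `overall`: `r`, `p`, and `r_partial`, `p_partial` when
#'   `env` is given) and `pairs` (long table of plot-pair geographic
#'   distance and dissimilarity per season).
#' @export
distance_decay <- function(x, meta, coordinates, env = NULL,
                           method = "pearson", n_perm = 999, seed = NULL) {
  stopifnot(inherits(x, "feature_table"))
  meta <- as_sample_metadata(meta)
  need <- c("site", "plot", "x", "y")
  if (!all(need %in% names(coordinates)))
    stop2("coordinates must have columns: ", paste(need, collapse = ", "))
  sm <- meta[sample_ids(x), ]
  plot_key <- function(site, plot) paste(site, plot, sep = "/")
  coordinates$key <- plot_key(coordinates$site, coordinates$plot)
  sm$key <- plot_key(sm$site, sm$plot)
  missing <- setdiff(unique(sm$key), coordinates$key)
  if (length(missing) > 0)
    stop2("missing coordinates for plot(s): ", paste(missing, collapse = ", "))

  env_d <- NULL
  if (!is.null(env)) {
    env$key <- plot_key(env$site, env$plot)
    num <- vapply(env, is.numeric, logical(1)) &
      !names(env) %in% c("site", "plot")
    ek <- as.matrix(scale(env[, num, drop = FALSE]))
    rownames(ek) <- env$key
    env_d <- as.matrix(dist(ek))
  }

  seasons <- levels(droplevels(sm$season))
  per_season <- list()
  comm_mats <- list()
  for (s in seasons) {
    sel <- sample_ids(x)[sm$season == s]
    keys <- sm[sel, "key"]
    if (anyDuplicated(keys))
      stop2("more than one sample per plot in season ", s)
    cm <- x$counts[, sel, drop = FALSE]
    colnames(cm) <- keys
    dcomm <- bray_curtis(suppressWarnings(sqrt_wisconsin(cm)))
    comm_mats[[s]] <- dcomm
    per_season[[s]] <- dcomm
  }
  common <- Reduce(intersect, lapply(comm_mats, rownames))
  geo <- coordinates[match(common, coordinates$key), ]
  gxy <- as.matrix(geo[, c("x", "y")])
  rownames(gxy) <- common
  gd <- as.matrix(dist(gxy))
  if (any(upper_tri_vec(gd) <= 0))
    stop2("coincident plot coordinates: log distance undefined")
  lgd <- log10(gd)
  diag(lgd) <- 0

  run_one <- function(dcomm) {
    dcomm <- dcomm[common, common]
    mt <- mantel_test(dcomm, lgd, method = method, n_perm = n_perm,
                      seed = seed)
    row <- data.frame(r = mt$r, p = mt$p, r_partial = NA_real_,
                      p_partial = NA_real_)
    if (!is.null(env_d)) {
      ed <- env_d[common, common]
      pm <- partial_mantel(dcomm, lgd, ed, method = method,
                           n_perm = n_perm, seed = seed)
      row$r_partial <- pm$r
      row$p_partial <- pm$p
    }
    row
  }
  stats <- do.call(rbind, lapply(per_season, run_one))
  stats$season <- seasons
  avg <- Reduce(`+`, lapply(comm_mats, function(m) m[common, common])) /
    length(comm_mats)
  overall <- run_one(avg)
  overall$season <- "overall"
  stats <- rbind(stats, overall)
  stats <- stats[, c("season", "r", "p", "r_partial", "p_partial")]
  rownames(stats) <- NULL

  pairs <- do.call(rbind, lapply(seasons, function(s) {
    m <- per_season[[s]][common, common]
    ut <- upper.tri(m)
    data.frame(season = s,
               plot_a = rownames(m)[row(m)[ut]],
               plot_b = colnames(m)[col(m)[ut]],
               geo_distance = gd[common, common][ut],
               dissimilarity = m[ut], stringsAsFactors = FALSE)
  }))
  structure(list(stats = stats, pairs = pairs),
            class = "distance_decay_result")
}
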
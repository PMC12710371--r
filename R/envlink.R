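#' Collapse correlated covariates into PCA index variables
#'
#' Replaces each named group of correlated covariates by the scores of
#' its first principal component (standardized members), e.g. cation
#' exchange capacity + soil calcium + total organic carbon collapsing
#' into a single soil-organic-matter index. Scores are rescaled to zero
#' mean and unit variance, and loadings are sign-fixed so the index
#' correlates positively with the first-named member.
#'
#' @param env data frame of plot- or site-level covariates.
#' @param groups named list of character vectors; each element names the
#'   covariates to collapse and supplies the index name.
#' @return `env` with each group's members replaced by the index column;
#'   attribute `index_variables` holds per-index details (`members`,
#'   `loadings`, `scores`, `variance_explained`).
#' @export
collapse_covariates <- function(env, groups) {
  stopifnot(is.data.frame(env), is.list(groups), !is.null(names(groups)))
  info <- list()
  for (nm in names(groups)) {
    members <- groups[[nm]]
    if (length(members) < 2) stop2("group '", nm, "' needs >= 2 covariates")
    missing <- setdiff(members, names(env))
    if (length(missing) > 0)
      stop2("group '", nm, "' references unknown covariate(s): ",
            paste(missing, collapse = ", "))
    X <- as.matrix(env[, members, drop = FALSE])
    if (any(apply(X, 2, sd) == 0))
      stop2("group '", nm, "' contains a constant covariate")
    pc <- prcomp(X, center = TRUE, scale. = TRUE)
    s <- pc$x[, 1]
    loadings <- pc$rotation[, 1]
    if (cor(s, X[, 1]) < 0) {
      s <- -s
      loadings <- -loadings
    }
    s <- as.numeric(scale(s))
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
    env <- env[, setdiff(names(env), members), drop = FALSE]
    env[[nm]] <- s
    info[[nm]] <- list(name = nm, members = members, loadings = loadings,
                       scores = s, variance_explained = ve)
  }
  attr(env, "index_variables") <- info
  env
}

#' Random-forest regressor (default pluggable regressor)
#'
#' The importance screen takes any regressor exposing `fit(X, y)` and
#' `predict(model, X)`; this is the default tree-ensemble backend
#' (`randomForest`). `regularizing = TRUE` marks that it tolerates more
#' covariates than samples.
#'
#' @param ntree number of trees.
#' @param ... passed to `randomForest::randomForest`.
#' @return list with `fit`, `predict`, `regularizing`.
#' @export
rf_regressor <- function(ntree = 500, ...) {
  list(fit = function(X, y)
         randomForest::randomForest(x = as.data.frame(X), y = y,
                                    ntree = ntree, ...),
       predict = function(model, X) predict(model, as.data.frame(X)),
       regularizing = TRUE)
}

#' Deterministic linear regressor (testing stub)
#'
#' Ordinary least squares behind the same fit/predict contract; used in
#' tests where a deterministic regressor is needed.
#' @return list with `fit`, `predict`, `regularizing = FALSE`.
#' @export
lm_regressor <- function() {
  list(fit = function(X, y) {
         df <- data.frame(y = y, X, check.names = TRUE)
         lm(y ~ ., data = df)
       },
       predict = function(model, X)
         unname(predict(model, data.frame(X, check.names = TRUE))),
       regularizing = FALSE)
}

#' Permutation importance and partial-dependence screening
#'
#' Ranks covariates by held-out permutation importance: K-fold
#' cross-validation, each fold scoring the increase in squared
#' prediction error when one covariate is permuted among the held-out
#' rows. Partial-dependence curves are computed for every covariate on
#' an evenly spaced grid between its 2.5th and 97.5th percentiles
#' (avoiding edge extrapolation) from a model fitted on all rows.
#'
#' @param response numeric response, one value per row of `env`.
#' @param env data frame of numeric covariates.
#' @param n_repeats permutation repeats per fold.
#' @param seed optional integer seed.
#' @param regressor regressor contract (see [rf_regressor()]).
#' @param n_folds cross-validation folds.
#' @param grid_size partial-dependence grid points.
#' @return list of class `importance_screen`: `importance` (data frame
#'   ranked by mean importance) and `partial_dependence` (named list of
#'   data frames `grid`, `value`).
#' @export
screen_importance <- function(response, env, n_repeats = 5, seed = NULL,
                              regressor = rf_regressor(), n_folds = 5,
                              grid_size = 50) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  env <- env[, num, drop = FALSE]
  n <- length(response)
  if (nrow(env) != n) stop2("response and covariates have different lengths")
  if (n <= ncol(env) + 1 && !isTRUE(regressor$regularizing))
    stop2("fewer samples than covariates and no regularizing regressor")
  if (!is.null(seed)) set.seed(seed)
  n_folds <- min(n_folds, n)
  fold <- sample(rep_len(seq_len(n_folds), n))
  imp <- matrix(0, ncol(env), n_folds,
                dimnames = list(names(env), NULL))
  for (k in seq_len(n_folds)) {
    test <- fold == k
    model <- regressor$fit(env[!test, , drop = FALSE], response[!test])
    base_mse <- mean((response[test] -
                        regressor$predict(model, env[test, , drop = FALSE]))^2)
    for (j in seq_along(env)) {
      incs <- vapply(seq_len(n_repeats), function(r) {
        Xp <- env[test, , drop = FALSE]
        Xp[[j]] <- Xp[[j]][sample(nrow(Xp))]
        mean((response[test] - regressor$predict(model, Xp))^2) - base_mse
      }, numeric(1))
      imp[j, k] <- mean(incs)
    }
  }
  importance <- data.frame(covariate = rownames(imp),
                           importance = rowMeans(imp),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), ]
  rownames(importance) <- NULL

  full <- regressor$fit(env, response)
  pd <- lapply(names(env), function(v) {
    q <- quantile(env[[v]], c(0.025, 0.975))
    grid <- seq(q[1], q[2], length.out = grid_size)
    value <- vapply(grid, function(g) {
      Xg <- env
      Xg[[v]] <- g
      mean(regressor$predict(full, Xg))
    }, numeric(1))
    data.frame(grid = grid, value = value)
  })
  names(pd) <- names(env)
  structure(list(importance = importance, partial_dependence = pd),
            class = "importance_screen")
}

#' Localize a threshold in a partial-dependence curve
#'
#' Returns the grid interval containing the maximum absolute first
#' difference of the curve when that jump exceeds `min_jump` times the
#' interquartile range of the curve values — the "community composition
#' changed rapidly within a narrow temperature window" pattern. Returns
#' `NULL` for effectively flat curves.
#'
#' @param grid ordered numeric grid (>= 3 points).
#' @param values curve values on the grid.
#' @param min_jump jump threshold as a fraction of `IQR(values)`.
#' @return `NULL`, or a list with `interval` (the two grid points
#'   bracketing the jump), `index`, and `jump`.
#' @export
locate_threshold <- function(grid, values, min_jump = 0.5) {
  if (length(grid) < 3) stop2("need at least 3 grid points")
  if (length(values) != length(grid)) stop2("grid and values differ in length")
  if (is.unsorted(grid, strictly = TRUE)) stop2("grid must be strictly increasing")
  jumps <- abs(diff(values))
  i <- which.max(jumps)
  scale <- IQR(values)
  if (scale == 0 || jumps[i] <= min_jump * scale) return(NULL)
  list(interval = c(grid[i], grid[i + 1]), index = i, jump = jumps[i])
}

#' Scale dependence of an environment-response association
#'
#' Compares a common-slope model (site intercepts + one slope) against a
#' per-site-slope model (site intercepts + site-specific slopes), both
#' fitted by least squares with a Gaussian likelihood. The likelihood
#' ratio `2(lB - lA) = n log(RSS_A / RSS_B)` has `df = n_sites - 1`; the
#' primary p-value uses the exact finite-sample F distribution of the
#' equivalent F statistic (the LRT is monotone in it), with the
#' asymptotic chi-square p also reported (`p_chisq`). A significant
#' result indicates that within-site slopes differ from the among-site
#' slope — scale dependence of the association.
#'
#' @param response,covariate numeric vectors, one value per plot.
#' @param site factor of site memberships (>= 3 sites, >= 3 plots each).
#' @param alpha significance level for the `scale_dependent` flag.
#' @return list of class `scale_dependence_result`: `pooled_slope`,
#'   `per_site_slopes`, `lrt_statistic`, `df`, `p`, `p_chisq`,
#'   `scale_dependent`.
#' @export
scale_dependence_test <- function(response, covariate, site, alpha = 0.05) {
  site <- droplevels(factor(site))
  n <- length(response)
  if (length(covariate) != n || length(site) != n)
    stop2("response, covariate and site must have equal length")
  if (nlevels(site) < 3) stop2("need at least 3 sites")
  if (any(table(site) < 3)) stop2("every site needs at least 3 plots")
  const <- tapply(covariate, site, function(z) sd(z) == 0)
  if (any(const))
    stop2("covariate constant within site(s) ",
          paste(names(const)[const], collapse = ", "),
          ": site slope inestimable")
  fitA <- lm(response ~ site + covariate)
  fitB <- lm(response ~ site + site:covariate)
  rssA <- sum(fitA$residuals^2)
  rssB <- sum(fitB$residuals^2)
  q <- nlevels(site) - 1L
  pB <- n - fitB$df.residual
  lrt <- n * log(rssA / rssB)
  f <- ((rssA - rssB) / q) / (rssB / (n - pB))
  p <- pf(f, q, n - pB, lower.tail = FALSE)
  slopes <- coef(fitB)[grep(":covariate$", names(coef(fitB)))]
  names(slopes) <- levels(site)
  structure(list(pooled_slope = unname(coef(fitA)["covariate"]),
                 per_site_slopes = slopes,
                 lrt_statistic = lrt, df = q,
                 p = p, p_chisq = pchisq(lrt, q, lower.tail = FALSE),
                 f_statistic = f,
                 scale_dependent = p < alpha),
            class = "scale_dependence_result")
}

#' Logistic presence model
#'
#' Probability of detecting a taxon group (e.g. in the active
#' community) as a function of a covariate, fitted by IRLS
#' (`stats::glm`, binomial/logit), with Wald CI and p. Complete
#' separation is detected and flagged rather than reported with a
#' meaningless Wald test.
#'
#' @param presence binary (0/1 or logical) outcome per sample.
#' @param covariate numeric predictor.
#' @param block optional factor added as a fixed effect (e.g. site).
#' @return list of class `presence_glm_result`: `intercept`, `slope`,
#'   `ci` (Wald 95% for the slope), `p`, `separation`, `curve`
#'   (fitted probability over the covariate range), `model`.
#' @export
presence_glm <- function(presence, covariate, block = NULL) {
  y <- as.integer(as.logical(presence))
  if (length(unique(y)) < 2)
    stop2("presence has a single outcome class; model inestimable")
  if (sd(covariate) == 0) stop2("constant covariate; slope inestimable")
  df <- data.frame(y = y, x = covariate)
  fml <- y ~ x
  if (!is.null(block)) {
    df$block <- factor(block)
    fml <- y ~ x + block
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (max(abs(fit$linear.predictors)) > 15) sep <- TRUE
  cf <- summary(fit)$coefficients
  grid <- seq(min(covariate), max(covariate), length.out = 100)
  nd <- data.frame(x = grid)
  if (!is.null(block)) nd$block <- factor(levels(factor(block))[1],
                                          levels = levels(factor(block)))
  curve <- data.frame(covariate = grid,
                      probability = predict(fit, nd, type = "response"))
  if (sep) {
    res <- list(intercept = unname(coef(fit)[1]),
                slope = unname(coef(fit)["x"]),
                ci = c(NA_real_, NA_real_), p = NA_real_,
                separation = TRUE, curve = curve, model = fit)
  } else {
    est <- cf["x", "Estimate"]
    se <- cf["x", "Std. Error"]
    res <- list(intercept = unname(coef(fit)[1]), slope = est,
                ci = est + c(-1, 1) * 1.96 * se,
                p = cf["x", "Pr(>|z|)"],
                separation = FALSE, curve = curve, model = fit)
  }
  structure(res, class = "presence_glm_result")
}

#' Link the dormancy profile to environmental covariates
#'
#' Aggregates per-pair dormant fractions to the plot level (mean over
#' seasons), screens covariate importance with [screen_importance()],
#' and reports per-covariate slope, sign and p from a site-blocked
#' linear model, plus a [scale_dependence_test()] for each covariate —
#' the machinery behind "dormancy was positively associated with soil
#' organic matter".
#'
#' @param profile a [dormancy_profile()] result.
#' @param env plot-level covariate data frame with `site` and `plot`
#'   columns.
#' @param meta sample metadata (maps pair ids to sites/plots); the
#'   paired community's `pair_meta` also works.
#' @param regressor,seed passed to [screen_importance()].
#' @return list of class `dormancy_env_link`: `associations` (covariate,
#'   slope, p, scale-dependence p) and the `importance_screen` result.
#' @export
dormancy_env_link <- function(profile, env, meta, regressor = rf_regressor(),
                              seed = NULL) {
  ok <- !is.na(profile$dormant_fraction)
  if (!any(ok)) stop2("all dormant fractions are undefined")
  if (!is.null(meta$pair_id)) {
    rows <- meta[match(profile$pair_id, meta$pair_id), ]
  } else {
    rows <- meta[profile$pair_id, ]
  }
  key <- paste(rows$site, rows$plot, sep = "/")
  resp <- tapply(profile$dormant_fraction[ok], key[ok], mean)
  env$key <- paste(env$site, env$plot, sep = "/")
  env_m <- env[match(names(resp), env$key), , drop = FALSE]
  if (anyNA(env_m$key))
    stop2("environmental covariates missing for some plots")
  covs <- env_m[, vapply(env_m, is.numeric, logical(1)), drop = FALSE]
  covs <- covs[, setdiff(names(covs), c("plot")), drop = FALSE]
  site <- factor(env_m$site)
  scr <- screen_importance(as.numeric(resp), covs, seed = seed,
                           regressor = regressor)
  assoc <- do.call(rbind, lapply(names(covs), function(v) {
    x <- covs[[v]]
    site_level <- all(tapply(x, site, function(z) sd(z) == 0))
    if (site_level) {
      # sensor-style covariate measured per site: aggregate the
      # response to site means and regress at that level
      ys <- tapply(as.numeric(resp), site, mean)
      xs <- tapply(x, site, mean)
      fit <- lm(ys ~ xs)
      cf <- summary(fit)$coefficients
      est <- unname(cf["xs", "Estimate"])
      pv <- unname(cf["xs", "Pr(>|t|)"])
      sdp <- NA_real_
    } else {
      # pooled plot-level association; the within- vs among-site
      # decomposition is the scale-dependence test's job
      fit <- lm(as.numeric(resp) ~ x)
      cf <- summary(fit)$coefficients
      est <- unname(cf["x", "Estimate"])
      pv <- unname(cf["x", "Pr(>|t|)"])
      sdp <- tryCatch(scale_dependence_test(as.numeric(resp), x, site)$p,
                      error = function(e) NA_real_)
    }
    data.frame(covariate = v, level = if (site_level) "site" else "plot",
               slope = est, p = pv, sign = sign(est),
               p_scale_dependence = sdp, stringsAsFactors = FALSE)
  }))
  structure(list(associations = assoc, importance = scr,
                 response = resp),
            class = "dormancy_env_link")
}
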
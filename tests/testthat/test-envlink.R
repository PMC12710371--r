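test_that("collapse_covariates builds standardized, sign-fixed PCA indices", {
  set.seed(41)
  base <- rnorm(40)
  env <- data.frame(toc = base, cec = base, calcium = base + rnorm(40, 0, 0.1),
                    ph = rnorm(40))
  # perfectly correlated pair: PC1 explains everything
  out <- collapse_covariates(env[, c("toc", "cec")],
                             list(om = c("toc", "cec")))
  iv <- attr(out, "index_variables")$om
  expect_equal(iv$variance_explained, 1, tolerance = 1e-12)

  out2 <- collapse_covariates(env, list(om = c("toc", "cec", "calcium")))
  iv2 <- attr(out2, "index_variables")$om
  expect_gt(iv2$variance_explained, 0.9)  # duplicate + small noise
  expect_equal(mean(iv2$scores), 0, tolerance = 1e-10)
  expect_equal(var(iv2$scores), 1, tolerance = 1e-10)
  expect_gt(cor(out2$om, env$toc), 0)  # sign fixed to first member
  expect_false(any(c("toc", "cec", "calcium") %in% names(out2)))
  expect_true("ph" %in% names(out2))

  env$flat <- 1
  expect_error(collapse_covariates(env, list(bad = c("toc", "flat"))),
               "constant covariate")
  expect_error(collapse_covariates(env, list(bad = "toc")), ">= 2")
})

test_that("screen_importance ranks the driving covariate first", {
  set.seed(42)
  n <- 80
  env <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * env$x1 + rnorm(n, 0, 0.3)
  scr <- screen_importance(y, env, seed = 1, regressor = lm_regressor())
  expect_equal(scr$importance$covariate[1], "x1")
  expect_gt(scr$importance$importance[1],
            10 * max(abs(scr$importance$importance[-1])))

  # null response: importances hover near zero
  y0 <- rnorm(n)
  scr0 <- screen_importance(y0, env, seed = 2, regressor = lm_regressor())
  expect_lt(max(abs(scr0$importance$importance)), 0.5 * var(y0))

  # partial dependence of a linear effect is monotone over the grid
  pd <- scr$partial_dependence$x1
  expect_true(all(diff(pd$value) > 0))
  expect_error(screen_importance(y[1:3], env[1:3, ],
                                 regressor = lm_regressor()),
               "regularizing")
})

test_that("screen_importance recovers the driver with the tree-ensemble default", {
  set.seed(43)
  n <- 60
  env <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- sin(2 * env$x1) + rnorm(n, 0, 0.2)
  scr <- screen_importance(y, env, seed = 3,
                           regressor = rf_regressor(ntree = 300))
  expect_equal(scr$importance$covariate[1], "x1")
})

test_that("locate_threshold finds steps, rejects flat curves, is grid-equivariant", {
  grid <- seq(0, 1, length.out = 20)
  step <- ifelse(grid <= grid[5], 0, 1)
  hit <- locate_threshold(grid, step)
  expect_equal(hit$interval, c(grid[5], grid[6]))

  expect_null(locate_threshold(grid, rep(0.3, 20)))
  expect_null(locate_threshold(grid, grid))  # linear ramp: no dominant jump

  # monotone relabeling of the grid moves the interval, not the index
  grid2 <- exp(grid)
  hit2 <- locate_threshold(grid2, step)
  expect_equal(hit2$index, hit$index)
  expect_equal(hit2$interval, exp(hit$interval))
  expect_error(locate_threshold(grid[1:2], step[1:2]), "3 grid points")
})

test_that("scale_dependence_test separates common from site-specific slopes", {
  set.seed(44)
  site <- factor(rep(1:6, each = 8))
  x <- rnorm(48)
  # identical slopes: not scale dependent (single realization sanity check)
  y_common <- 1.5 * x + rnorm(48, 0, 0.5) + as.numeric(site)
  res_c <- scale_dependence_test(y_common, x, site)
  expect_equal(res_c$df, 5)
  expect_gt(res_c$p, 0.01)
  expect_equal(res_c$pooled_slope, 1.5, tolerance = 0.2)

  # alternating strong slopes: detected
  b <- rep(c(2, -2), 3)[as.integer(site)]
  y_alt <- b * x + rnorm(48, 0, 0.3) + as.numeric(site)
  res_a <- scale_dependence_test(y_alt, x, site)
  expect_true(res_a$scale_dependent)
  expect_equal(unname(sign(res_a$per_site_slopes)),
               rep(c(1, -1), 3))

  # LRT invariant to affine rescaling of the covariate
  res_scaled <- scale_dependence_test(y_alt, 100 * x - 7, site)
  expect_equal(res_scaled$lrt_statistic, res_a$lrt_statistic,
               tolerance = 1e-10)

  expect_error(scale_dependence_test(y_alt[1:8], x[1:8], site[1:8]),
               "at least 3 sites")
  x_const <- x; x_const[site == 2] <- 1
  expect_error(scale_dependence_test(y_alt, x_const, site), "site.*2")
})

test_that("presence_glm estimates the logistic slope and flags separation", {
  set.seed(45)
  covered <- vapply(1:100, function(i) {
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(-2 * x))
    fit <- presence_glm(y, x)
    fit$ci[1] <= -2 && -2 <= fit$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.88)  # nominal 95% Wald coverage

  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  sep <- presence_glm(y, x)
  expect_true(sep$separation)
  expect_true(is.na(sep$p))

  expect_error(presence_glm(rep(1, 10), rnorm(10)), "single outcome class")
  expect_error(presence_glm(rep(c(0, 1), 5), rep(2, 10)), "constant covariate")
})

test_that("dormancy_env_link recovers a planted dormancy-organic-matter association", {
  sp <- synth_params(n_taxa = 150, depth = 5000, core_taxa = NULL,
                     enriched_taxa = NULL, dormancy_covariate_slope = 1.5)
  sim <- synth_community(sp, seed = 46)
  prof <- dormancy_profile(sim$paired)
  link <- dormancy_env_link(prof, sim$env, sim$paired$pair_meta, seed = 1,
                            regressor = lm_regressor())
  om_rows <- link$associations[link$associations$covariate %in%
                                 c("toc", "cec", "calcium"), ]
  # organic-matter proxies associate positively with dormancy
  expect_true(all(om_rows$sign == 1))
  expect_true(any(om_rows$p < 0.05))

  # collapsed organic-matter index feeds through unchanged
  env_idx <- collapse_covariates(sim$env,
                                 list(organic_matter = c("toc", "cec",
                                                         "calcium")))
  link2 <- dormancy_env_link(prof, env_idx, sim$paired$pair_meta, seed = 1,
                             regressor = lm_regressor())
  om2 <- link2$associations[link2$associations$covariate == "organic_matter", ]
  expect_equal(om2$sign, 1)
  expect_lt(om2$p, 0.05)

  prof_na <- prof
  prof_na$dormant_fraction <- NA_real_
  expect_error(dormancy_env_link(prof_na, sim$env, sim$paired$pair_meta),
               "undefined")
})
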
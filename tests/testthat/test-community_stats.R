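test_that("Bray-Curtis matches its definition and vegan", {
  x <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
              dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(bray_curtis(x)["s1", "s2"], 0)
  y <- matrix(c(1, 0, 0, 2), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis(y)["s1", "s2"], 1)  # disjoint supports
  # continuation of the Wisconsin worked example
  w <- matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2, 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  expect_equal(bray_curtis(w)["s1", "s2"], 1 / 3, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:5) {
    m <- rand_counts(7, 5)
    d <- bray_curtis(m)
    expect_equal(d, oracle_bray(m), tolerance = 1e-12)
    expect_equal(unname(d),
                 unname(as.matrix(vegan::vegdist(t(m), "bray"))),
                 tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("Shannon diversity matches analytic values", {
  expect_equal(shannon_diversity(c(5, 0, 0)), 0)
  expect_equal(shannon_diversity(rep(10, 4)), log(4))
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  m <- matrix(c(1, 1, 2, 0), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(shannon_diversity(m)), c(log(2), 0))
  expect_error(shannon_diversity(c(0, 0)), "all-zero")
})

test_that("PCoA reproduces Euclidean geometry", {
  set.seed(22)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  d <- as.matrix(dist(pts))
  fit <- pcoa(d)
  expect_equal(as.matrix(dist(fit$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))  # sorted
  expect_lte(sum(fit$proportion_explained), 1 + 1e-12)

  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  f3 <- pcoa(d3)
  pos <- f3$eigenvalues[f3$eigenvalues > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  # duplicated sample lands on coincident coordinates
  d4 <- as.matrix(dist(rbind(pts, s11 = pts["s1", ])))
  f4 <- pcoa(d4)
  expect_equal(f4$coordinates["s11", ], f4$coordinates["s1", ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcoa(d3[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA on a perfectly separated toy matches exhaustive enumeration", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(1, 4, 4, dimnames = list(ids, ids))
  d["a1", "a2"] <- d["a2", "a1"] <- 0
  d["b1", "b2"] <- d["b2", "b1"] <- 0
  diag(d) <- 0
  design <- data.frame(group = c("A", "A", "B", "B"), row.names = ids)
  perms <- permute::allPerms(4)  # all 23 non-identity permutations
  res <- permanova(d, design, "group", permutations = perms)
  expect_equal(res$r2[res$term == "group"], 1)
  # 8 of the 24 labelings (incl. identity) reproduce the partition
  expect_equal(res$p[res$term == "group"], 1 / 3)
})

test_that("PERMANOVA R2 partitions to one and p respects the permutation floor", {
  set.seed(23)
  m <- rand_counts(15, 12)
  d <- bray_curtis(sqrt_wisconsin(m))
  design <- data.frame(g = rep(c("x", "y", "z"), 4),
                       h = rep(c("u", "v"), 6),
                       row.names = colnames(m))
  res <- permanova(d, design, c("g", "h"), n_perm = 99, seed = 1)
  expect_equal(sum(res$r2[res$term != "Total"]), 1, tolerance = 1e-10)
  expect_true(all(res$p >= 1 / 100, na.rm = TRUE))
  expect_error(permanova(d, design, "missing_term"), "not in design")
  design$one <- "same"
  expect_error(permanova(d, design, "one"), "single level")
})

test_that("beta dispersion: hand-computed centroid distances and degenerate groups", {
  pts <- rbind(a1 = c(0, 0), a2 = c(2, 0), a3 = c(1, 2),
               b1 = c(10, 0), b2 = c(12, 0), b3 = c(11, 2))
  d <- as.matrix(dist(pts))
  g <- factor(rep(c("A", "B"), each = 3))
  bd <- beta_dispersion(d, g, n_perm = 99, seed = 1)
  # distances to centroid (1, 2/3): sqrt(13)/3 twice, 4/3 once, per group
  expect_equal(sort(unname(bd$distances[1:3])),
               sort(c(sqrt(13) / 3, sqrt(13) / 3, 4 / 3)), tolerance = 1e-8)
  expect_equal(unname(bd$group_means["A"]), unname(bd$group_means["B"]),
               tolerance = 1e-8)

  # identical samples: zero dispersion
  same <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  pts2 <- rbind(c1 = c(5, 5), c2 = c(6, 5), c3 = c(5, 6), c4 = c(9, 9))
  d2 <- as.matrix(dist(rbind(pts2[1:3, ], d1 = c(0, 0), d2 = c(0, 0))))
  bd2 <- beta_dispersion(d2, factor(c("C", "C", "C", "D", "D")),
                         n_perm = 49, seed = 2)
  expect_equal(unname(bd2$group_means["D"]), 0, tolerance = 1e-10)
  pts3 <- rbind(pts2[1:3, ], d1 = c(0, 0), d2 = c(1, 0), e1 = c(20, 20))
  d3 <- as.matrix(dist(pts3))
  expect_warning(
    beta_dispersion(d3, factor(c("C", "C", "C", "D", "D", "E")), n_perm = 9),
    "singleton")
})

test_that("Mantel equals direct triangle correlation", {
  set.seed(24)
  p1 <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  d1 <- as.matrix(dist(p1))
  m <- mantel_test(d1, 2 * d1, n_perm = 9)
  expect_equal(m$r, 1, tolerance = 1e-12)

  p2 <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  d2 <- as.matrix(dist(p2))
  mt <- mantel_test(d1, d2, n_perm = 9)
  expect_equal(mt$r, cor(d1[upper.tri(d1)], d2[upper.tri(d2)]),
               tolerance = 1e-10)
  ms <- mantel_test(d1, d2, method = "spearman", n_perm = 9)
  expect_equal(ms$r, cor(d1[upper.tri(d1)], d2[upper.tri(d2)],
                         method = "spearman"), tolerance = 1e-10)
  const <- d1 * 0
  expect_error(mantel_test(d1, const, n_perm = 9), "constant")
})

test_that("partial Mantel matches the closed-form partial correlation", {
  set.seed(25)
  mk <- function() {
    p <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
    as.matrix(dist(p))
  }
  da <- mk(); db <- mk(); dc <- mk()
  r12 <- cor(da[upper.tri(da)], db[upper.tri(db)])
  r13 <- cor(da[upper.tri(da)], dc[upper.tri(dc)])
  r23 <- cor(db[upper.tri(db)], dc[upper.tri(dc)])
  expected <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  pm <- partial_mantel(da, db, dc, n_perm = 9)
  expect_equal(pm$r, expected, tolerance = 1e-10)

  # geography confounded with environment: conditioning on the
  # environment collapses the apparent distance effect
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("q", 1:12), NULL))
  d_geo <- as.matrix(dist(pts))
  noise <- function(sd) {
    e <- matrix(rnorm(144, 0, sd), 12, 12)
    e <- (e + t(e)) / 2; diag(e) <- 0
    e
  }
  d_env <- pmax(d_geo + noise(0.02), 0); dimnames(d_env) <- dimnames(d_geo)
  d_comm <- pmax(d_geo + noise(0.3), 0); dimnames(d_comm) <- dimnames(d_geo)
  simple <- mantel_test(d_comm, d_geo, n_perm = 9)
  pm2 <- partial_mantel(d_comm, d_geo, d_env, n_perm = 9)
  expect_gt(simple$r, 0.6)
  expect_lt(abs(pm2$r), 0.3)
})

test_that("distance decay is detected under spatial structure, absent without", {
  sp <- synth_params(n_taxa = 120, depth = 4000, core_taxa = NULL,
                     enriched_taxa = NULL)
  sim <- synth_community(sp, seed = 31)
  dd <- distance_decay(sim$total, sim$metadata, sim$coordinates,
                       env = sim$env, n_perm = 99, seed = 1)
  ov <- dd$stats[dd$stats$season == "overall", ]
  expect_gt(ov$r, 0.2)
  expect_lte(ov$p, 0.05)
  expect_false(anyNA(dd$stats$r_partial))

  # no site/plot hierarchy -> no spatial signal
  sp0 <- synth_params(n_taxa = 120, depth = 4000, core_taxa = NULL,
                      enriched_taxa = NULL, site_type_effect = 0,
                      site_effect = 0, plot_effect = 0)
  sim0 <- synth_community(sp0, seed = 32)
  dd0 <- distance_decay(sim0$total, sim0$metadata, sim0$coordinates,
                        n_perm = 99, seed = 1)
  expect_lt(abs(dd0$stats$r[dd0$stats$season == "overall"]), 0.3)

  # equidistant plots: constant geographic triangle is an error
  coords3 <- data.frame(site = factor(1), plot = factor(1:3),
                        x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2))
  sub <- sim$metadata$site == "1" & sim$metadata$plot %in% c("1", "2", "3")
  meta3 <- sim$metadata[sub, ]
  keep <- intersect(sample_ids(sim$total), meta3$sample_id)
  ft3 <- feature_table(sim$total$counts[, keep], assay = "DNA")
  expect_error(distance_decay(ft3, meta3, coords3, n_perm = 9), "constant")
})
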
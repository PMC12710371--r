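#' Parameters for the paired-community generator
#'
#' Defaults emulate the field design the package targets: 3 site types
#' (riparian, mid-elevation, high-elevation) x 3 sites x 5 plots x 3
#' seasons, each physical sample sequenced in both assays (135 pairs,
#' 270 libraries). Composition is hierarchical on the log scale with
#' plot > site > site type effect sizes (mirroring the observed
#' ordering of spatial R-squared values), the season acts more strongly
#' on activity than on population abundance (the headline active/total
#' contrast), and planted core and enriched taxa provide ground truth
#' for occupancy and enrichment recovery.
#'
#' @param n_site_types,n_sites_per_type,n_plots_per_site design sizes.
#' @param seasons season labels (ordered).
#' @param n_taxa number of taxa (planted taxa are a subset of these).
#' @param depth sequencing depth per library (multinomial total).
#' @param base_abundance_sd log-scale SD of baseline taxon abundances.
#' @param site_type_effect,site_effect,plot_effect log-scale SDs of the
#'   hierarchical composition offsets.
#' @param season_population_amplitude log-scale SD of per-taxon seasonal
#'   effects on true abundance.
#' @param season_activity_amplitude logit-scale SD of per-taxon seasonal
#'   effects on activity probability.
#' @param activity_prob baseline per-taxon probability of being
#'   metabolically active in a sample (scalar or length `n_taxa`).
#' @param activity_intensity_sd log-scale SD of the continuous activity
#'   intensity multiplier applied to RNA abundances of active taxa.
#' @param core_taxa data frame with columns `occupancy` (target
#'   occupancy) and `activity_prob` (per-taxon activity probability,
#'   allowing "core but frequently inactive" members); `NULL` for none.
#' @param enriched_taxa data frame with column `ratio` (planted RNA:DNA
#'   abundance ratio); `NULL` for none.
#' @param core_log_abundance log abundance assigned to planted core
#'   taxa (high enough that detection at `depth` is near-certain).
#' @param core_effect_damping multiplier (< 1) on the hierarchical and
#'   seasonal abundance effects of planted core taxa — they are habitat
#'   generalists, which is what makes high occupancy attainable.
#' @param dormancy_covariate_slope logit-scale effect of the site
#'   organic-matter index on dormancy probability (positive values
#'   increase dormancy with organic matter).
#' @param marker marker label for the generated tables.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_site_types = 3, n_sites_per_type = 3,
                         n_plots_per_site = 5,
                         seasons = c("June", "August", "October"),
                         n_taxa = 500, depth = 20000,
                         base_abundance_sd = 1.5,
                         site_type_effect = 0.6, site_effect = 0.9,
                         plot_effect = 1.2,
                         season_population_amplitude = 0.25,
                         season_activity_amplitude = 0.9,
                         activity_prob = 0.6,
                         activity_intensity_sd = 0.5,
                         core_taxa = default_core_taxa(),
                         enriched_taxa = default_enriched_taxa(),
                         core_log_abundance = 3,
                         core_effect_damping = 0.15,
                         dormancy_covariate_slope = 0,
                         marker = "ITS2") {
  stopifnot(n_site_types >= 1, n_sites_per_type >= 1, n_plots_per_site >= 1,
            length(seasons) >= 1, n_taxa >= 1, depth >= 1)
  for (v in c(site_type_effect, site_effect, plot_effect,
              season_population_amplitude, season_activity_amplitude,
              activity_intensity_sd))
    if (!is.numeric(v) || v < 0) stop2("effect amplitudes must be >= 0")
  if (any(activity_prob < 0 | activity_prob > 1))
    stop2("activity_prob must be in [0, 1]")
  if (!length(activity_prob) %in% c(1L, n_taxa))
    stop2("activity_prob must be a scalar or length n_taxa")
  n_core <- if (is.null(core_taxa)) 0L else nrow(core_taxa)
  n_enr <- if (is.null(enriched_taxa)) 0L else nrow(enriched_taxa)
  if (n_core > 0) {
    if (!all(c("occupancy", "activity_prob") %in% names(core_taxa)))
      stop2("core_taxa needs columns 'occupancy' and 'activity_prob'")
    if (any(core_taxa$occupancy < 0 | core_taxa$occupancy > 1) ||
        any(core_taxa$activity_prob < 0 | core_taxa$activity_prob > 1))
      stop2("core_taxa probabilities must be in [0, 1]")
  }
  if (n_enr > 0) {
    if (!"ratio" %in% names(enriched_taxa))
      stop2("enriched_taxa needs a 'ratio' column")
    if (any(enriched_taxa$ratio <= 0)) stop2("enrichment ratios must be > 0")
  }
  if (n_core + n_enr > n_taxa)
    stop2("planted taxa exceed n_taxa")
  structure(list(n_site_types = n_site_types,
                 n_sites_per_type = n_sites_per_type,
                 n_plots_per_site = n_plots_per_site,
                 seasons = seasons, n_taxa = n_taxa, depth = depth,
                 base_abundance_sd = base_abundance_sd,
                 site_type_effect = site_type_effect,
                 site_effect = site_effect, plot_effect = plot_effect,
                 season_population_amplitude = season_population_amplitude,
                 season_activity_amplitude = season_activity_amplitude,
                 activity_prob = activity_prob,
                 activity_intensity_sd = activity_intensity_sd,
                 core_taxa = core_taxa, enriched_taxa = enriched_taxa,
                 core_log_abundance = core_log_abundance,
                 core_effect_damping = core_effect_damping,
                 dormancy_covariate_slope = dormancy_covariate_slope,
                 marker = marker),
            class = "synth_params")
}

#' @rdname synth_params
#' @export
default_core_taxa <- function() {
  # 8 planted core taxa: mostly consistently active, plus frequently
  # inactive members and one never-active member (the dormant-core
  # pattern observable in DNA-only surveys)
  data.frame(occupancy = rep(1, 8),
             activity_prob = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.3, 0.2, 0))
}

#' @rdname synth_params
#' @export
default_enriched_taxa <- function() {
  # 5 active-enriched and 5 total-enriched taxa at 4x
  data.frame(ratio = c(rep(4, 5), rep(0.25, 5)))
}

# per-taxon structural vectors shared by the generator and its oracle
synth_taxon_structure <- function(p) {
  m <- p$n_taxa
  n_core <- if (is.null(p$core_taxa)) 0L else nrow(p$core_taxa)
  n_enr <- if (is.null(p$enriched_taxa)) 0L else nrow(p$enriched_taxa)
  core_idx <- seq_len(n_core)
  enr_idx <- if (n_enr > 0) n_core + seq_len(n_enr) else integer(0)
  mult <- rep(1, m)
  mult[core_idx] <- p$core_effect_damping
  delta <- rep_len(p$activity_prob, m)
  if (n_core > 0) delta[core_idx] <- p$core_taxa$activity_prob
  ratio <- rep(1, m)
  if (n_enr > 0) ratio[enr_idx] <- p$enriched_taxa$ratio
  if (n_enr > 0) delta[enr_idx] <- 1  # planted ratio is the clean fold change
  occ <- rep(1, m)
  if (n_core > 0) occ[core_idx] <- p$core_taxa$occupancy
  list(m = m, core_idx = core_idx, enr_idx = enr_idx, mult = mult,
       delta = delta, ratio = ratio, occ = occ)
}

# seasonal activity probability on the logit scale; exact 0/1 preserved
activity_prob_at <- function(delta, a_act, z, env_shift) {
  p <- plogis(qlogis(pmin(pmax(delta, 1e-12), 1 - 1e-12)) +
                a_act * z - env_shift)
  p[delta == 0] <- 0
  p[delta == 1] <- 1
  p
}

#' Generate a synthetic paired active/total community
#'
#' Draws true abundances from a hierarchical log-normal model (site
#' type, site and plot offsets plus a per-taxon seasonal population
#' term), per-sample Bernoulli activity states (with a logit-scale
#' seasonal activity term and an optional organic-matter dormancy
#' slope), and fixed-depth multinomial sequencing for both assays: DNA
#' counts from the true abundances, RNA counts from the abundances of
#' active taxa scaled by a continuous activity intensity and any
#' planted enrichment ratio. The same seed reproduces the output
#' bit-identically.
#'
#' @param params a [synth_params()].
#' @param seed integer seed.
#' @return list of class `synth_community`: `paired`
#'   ([align_pairs()] output), `active`/`total` feature tables,
#'   `metadata`, `env` (plot-level covariates), `coordinates` (plot
#'   positions, metres), and `truth` (every planted effect: activity
#'   probabilities, core and enriched taxon ids, per-sample activity
#'   states, site covariate fields).
#' @export
synth_community <- function(params, seed = 1) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(seed)
  st <- synth_taxon_structure(p)
  m <- st$m

  type_names <- if (p$n_site_types == 3)
    c("riparian", "mid_elevation", "high_elevation") else
    paste0("type", seq_len(p$n_site_types))
  n_sites <- p$n_site_types * p$n_sites_per_type
  site_type_of <- rep(seq_len(p$n_site_types), each = p$n_sites_per_type)
  n_plots <- n_sites * p$n_plots_per_site
  plot_site <- rep(seq_len(n_sites), each = p$n_plots_per_site)
  n_seasons <- length(p$seasons)
  z <- if (n_seasons == 1) 0 else seq(-1, 1, length.out = n_seasons)

  taxa <- sprintf("taxon_%03d", seq_len(m))
  if (length(st$core_idx) > 0)
    taxa[st$core_idx] <- sprintf("core_%02d", seq_along(st$core_idx))
  if (length(st$enr_idx) > 0)
    taxa[st$enr_idx] <- sprintf("enriched_%02d", seq_along(st$enr_idx))

  base <- rnorm(m, 0, p$base_abundance_sd)
  base[st$core_idx] <- p$core_log_abundance
  u_type <- matrix(rnorm(m * p$n_site_types), m) * p$site_type_effect * st$mult
  u_site <- matrix(rnorm(m * n_sites), m) * p$site_effect * st$mult
  u_plot <- matrix(rnorm(m * n_plots), m) * p$plot_effect * st$mult
  b_pop <- rnorm(m, 0, p$season_population_amplitude) * st$mult
  a_act <- rnorm(m, 0, p$season_activity_amplitude)
  a_act[st$enr_idx] <- 0

  # site-level environment: riparian warmest/iron-rich, high elevation
  # coldest and most organic-matter rich (typical montane gradients)
  mean_of <- function(values) {
    v <- rep_len(values, p$n_site_types)
    v[site_type_of]
  }
  temp_site <- mean_of(c(14.4, 12.8, 11.2)) + rnorm(n_sites, 0, 0.4)
  om_site <- mean_of(c(-0.6, 0, 0.8)) + rnorm(n_sites, 0, 0.4)
  acid_site <- mean_of(c(0, 0.3, -0.3)) + rnorm(n_sites, 0, 0.3)
  iron_site <- mean_of(c(1, 0, 0)) + rnorm(n_sites, 0, 0.3)
  grass_site <- pmin(pmax(mean_of(c(0.7, 0.3, 0.2)) +
                            rnorm(n_sites, 0, 0.1), 0), 1)
  moist_site <- rnorm(n_sites, 0.25, 0.07)
  om_z <- as.numeric(scale(om_site))
  env_shift_site <- p$dormancy_covariate_slope * om_z

  env <- data.frame(
    site = factor(plot_site, levels = seq_len(n_sites)),
    plot = factor(rep(seq_len(p$n_plots_per_site), n_sites)),
    soil_temp = temp_site[plot_site],
    moisture = pmax(moist_site[plot_site] + rnorm(n_plots, 0, 0.03), 0.01),
    toc = om_site[plot_site] + rnorm(n_plots, 0, 0.3),
    cec = om_site[plot_site] + rnorm(n_plots, 0, 0.3),
    calcium = om_site[plot_site] + rnorm(n_plots, 0, 0.3),
    ph = 6 + acid_site[plot_site] + rnorm(n_plots, 0, 0.15),
    base_saturation = 50 + 10 * acid_site[plot_site] + rnorm(n_plots, 0, 3),
    iron = iron_site[plot_site] + rnorm(n_plots, 0, 0.2),
    nitrate_flux = rnorm(n_plots, 1, 0.5),
    grass_cover = pmin(pmax(grass_site[plot_site] +
                              rnorm(n_plots, 0, 0.05), 0), 1))

  # plot coordinates: sites spread over ~8 km, plots 20 m apart along a
  # transect (the spatial scales of the field design)
  site_x <- runif(n_sites, 0, 8000)
  site_y <- runif(n_sites, 0, 2000)
  coordinates <- data.frame(
    site = env$site, plot = env$plot,
    x = site_x[plot_site] + (rep(seq_len(p$n_plots_per_site), n_sites) - 1) * 20,
    y = site_y[plot_site] + rnorm(n_plots, 0, 2))

  n_pairs <- n_plots * n_seasons
  dna <- matrix(0, m, n_pairs)
  rna <- matrix(0, m, n_pairs)
  activity_state <- matrix(0L, m, n_pairs)
  pair_ids <- character(n_pairs)
  meta_rows <- vector("list", n_pairs)
  col <- 0L
  for (pl in seq_len(n_plots)) {
    s <- plot_site[pl]
    tt <- site_type_of[s]
    plot_within <- (pl - 1L) %% p$n_plots_per_site + 1L
    for (t in seq_len(n_seasons)) {
      col <- col + 1L
      pid <- sprintf("S%02dP%d_%s", s, plot_within, p$seasons[t])
      pair_ids[col] <- pid
      incl <- rep(1, m)
      if (any(st$occ < 1)) {
        sub <- st$occ < 1
        incl[sub] <- rbinom(sum(sub), 1, st$occ[sub])
      }
      lam <- exp(base + u_type[, tt] + u_site[, s] + u_plot[, pl] +
                   b_pop * z[t]) * incl
      dna[, col] <- rmultinom(1, p$depth, lam)
      pact <- activity_prob_at(st$delta, a_act, z[t], env_shift_site[s])
      A <- rbinom(m, 1, pact)
      activity_state[, col] <- A
      lam_rna <- lam * A * exp(rnorm(m, 0, p$activity_intensity_sd)) * st$ratio
      if (sum(lam_rna) > 0) rna[, col] <- rmultinom(1, p$depth, lam_rna)
      meta_rows[[col]] <- data.frame(
        site_type = type_names[tt], site = s, plot = plot_within,
        season = p$seasons[t], pair_id = pid, stringsAsFactors = FALSE)
    }
  }
  dimnames(dna) <- list(taxa, paste0(pair_ids, "_DNA"))
  dimnames(rna) <- list(taxa, paste0(pair_ids, "_RNA"))
  dimnames(activity_state) <- list(taxa, pair_ids)

  base_meta <- do.call(rbind, meta_rows)
  metadata <- rbind(
    data.frame(sample_id = colnames(dna), base_meta, assay = "DNA",
               stringsAsFactors = FALSE),
    data.frame(sample_id = colnames(rna), base_meta, assay = "RNA",
               stringsAsFactors = FALSE))
  metadata <- as_sample_metadata(
    metadata, site_types = type_names,
    seasons = p$seasons)

  marker <- if (p$marker %in% c("ITS2", "16S")) p$marker else "ITS2"
  total <- feature_table(dna, marker = marker, assay = "DNA")
  active <- feature_table(rna, marker = marker, assay = "RNA")
  paired <- align_pairs(active, total, metadata)

  truth <- list(taxa = taxa,
                core_ids = taxa[st$core_idx],
                core = p$core_taxa,
                enriched_ids = taxa[st$enr_idx],
                enriched = p$enriched_taxa,
                activity_prob = setNames(st$delta, taxa),
                seasonal_activity_loading = setNames(a_act, taxa),
                seasonal_population_loading = setNames(b_pop, taxa),
                activity_state = activity_state,
                site_type_of_site = setNames(type_names[site_type_of],
                                             seq_len(n_sites)),
                soil_temp_site = temp_site, organic_matter_site = om_site,
                organic_matter_z = om_z,
                dormancy_covariate_slope = p$dormancy_covariate_slope,
                seed = seed)
  structure(list(paired = paired, active = active, total = total,
                 metadata = metadata, env = env,
                 coordinates = coordinates, truth = truth,
                 params = p),
            class = "synth_community")
}

#' Monte-Carlo oracle for the expected dormant fraction
#'
#' Estimates `E[1 - active richness / union richness]` under the
#' generator's distributional assumptions by simulating independent
#' pairs directly (a code path separate from the generator's
#' bookkeeping), for parameter-recovery tests.
#'
#' @param params a [synth_params()].
#' @param depth sequencing depth (defaults to the params' depth).
#' @param n_pairs Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list: `estimate`, `se`, `n_pairs`.
#' @export
expected_dormant_fraction <- function(params, depth = params$depth,
                                      n_pairs = 200, seed = 1) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(seed)
  st <- synth_taxon_structure(p)
  m <- st$m
  n_seasons <- length(p$seasons)
  zs <- if (n_seasons == 1) 0 else seq(-1, 1, length.out = n_seasons)
  sd_hier <- sqrt(p$site_type_effect^2 + p$site_effect^2 + p$plot_effect^2)
  fr <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    z <- zs[sample.int(n_seasons, 1)]
    base <- rnorm(m, 0, p$base_abundance_sd)
    base[st$core_idx] <- p$core_log_abundance
    loglam <- base + rnorm(m, 0, sd_hier) * st$mult +
      rnorm(m, 0, p$season_population_amplitude) * st$mult * z
    incl <- rep(1, m)
    sub <- st$occ < 1
    if (any(sub)) incl[sub] <- rbinom(sum(sub), 1, st$occ[sub])
    lam <- exp(loglam) * incl
    dna <- rmultinom(1, depth, lam)[, 1]
    a_act <- rnorm(m, 0, p$season_activity_amplitude)
    a_act[st$enr_idx] <- 0
    env_shift <- if (p$dormancy_covariate_slope == 0) 0 else
      p$dormancy_covariate_slope * rnorm(1)
    pact <- activity_prob_at(st$delta, a_act, z, env_shift)
    A <- rbinom(m, 1, pact)
    lam_rna <- lam * A * exp(rnorm(m, 0, p$activity_intensity_sd)) * st$ratio
    rna <- if (sum(lam_rna) > 0) rmultinom(1, depth, lam_rna)[, 1] else
      rep(0, m)
    act <- sum(rna > 0)
    uni <- sum(rna > 0 | dna > 0)
    fr[k] <- if (uni == 0) NA_real_ else 1 - act / uni
  }
  fr <- fr[!is.na(fr)]
  list(estimate = mean(fr), se = sd(fr) / sqrt(length(fr)),
       n_pairs = length(fr))
}
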
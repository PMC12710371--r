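#' Run the full paired-community analysis pipeline
#'
#' Orchestrates the analysis plan end-to-end: read (or simulate) the
#' paired tables, rarefy, align pairs, compute dormancy and shared
#' fractions, total/active core microbiomes, the transformation chain
#' and PERMANOVA / beta dispersion per assay, the active/total
#' enrichment screen, and (when coordinates / environment are
#' available) distance decay and the dormancy-environment link. Every
#' report is stamped with the configuration hash and seed; rerunning
#' with the same configuration is bit-identical.
#'
#' @param config a list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{out_dir}{output directory (created).}
#'     \item{seed}{global seed; per-stage seeds are derived from it.}
#'     \item{synthetic}{optional list passed to [synth_params()]; when
#'       present the input tables are generated.}
#'     \item{inputs}{otherwise, list with `active`, `total`, `metadata`
#'       (+ optional `format`, `marker`) file paths.}
#'     \item{rarefaction_depth}{depth for [rarefy()]; `NULL` skips
#'       rarefaction (e.g. simulated equal-depth libraries).}
#'     \item{core}{list of [core_report()] arguments.}
#'     \item{diffabund}{list of [diffabund_config()] arguments.}
#'     \item{permanova_terms}{character vector of design terms
#'       (default `c("site_type", "season")`).}
#'     \item{n_perm}{permutations for all permutation tests.}
#'   }
#' @return (invisibly) a list with every stage's in-memory result and
#'   `out_dir`; files are written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop2("config$out_dir is required")
  if (is.null(config$seed)) config$seed <- 1L
  use_synth <- !is.null(config$synthetic)
  if (!use_synth) {
    ins <- config$inputs
    for (f in c("active", "total", "metadata"))
      if (is.null(ins[[f]])) stop2("config$inputs$", f, " is required")
    for (f in c("active", "total", "metadata"))
      if (!file.exists(ins[[f]])) stop2("input file not found: ", ins[[f]])
  }
  # hash of the analysis-relevant configuration (output location excluded)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_perm <- config$n_perm %||% 999
  log_stage <- function(...) message("[paircomm] ", sprintf(...))

  if (use_synth) {
    sp <- do.call(synth_params, config$synthetic)
    gen_seed <- derive_seed(config$seed, "synthetic")
    sim <- synth_community(sp, seed = gen_seed)
    active <- sim$active
    total <- sim$total
    meta <- sim$metadata
    env <- sim$env
    coords <- sim$coordinates
    log_stage("simulate: %d taxa, %d pairs (seed %d)",
              sp$n_taxa, length(sim$paired$pair_ids), gen_seed)
  } else {
    fmt <- config$inputs$format %||% "tsv"
    marker <- config$inputs$marker %||% "ITS2"
    active <- read_feature_table(config$inputs$active, fmt, marker, "RNA")
    total <- read_feature_table(config$inputs$total, fmt, marker, "DNA")
    meta <- read_metadata(config$inputs$metadata)
    env <- if (!is.null(config$inputs$env))
      read_tsv_schema(config$inputs$env) else NULL
    coords <- if (!is.null(config$inputs$coordinates))
      read_tsv_schema(config$inputs$coordinates) else NULL
    sim <- NULL
  }

  depth <- config$rarefaction_depth
  if (!is.null(depth)) {
    active <- rarefy(active, depth, seed = derive_seed(config$seed, "rarefy_rna"))
    total <- rarefy(total, depth, seed = derive_seed(config$seed, "rarefy_dna"))
    log_stage("rarefy: depth %d; dropped %d RNA, %d DNA libraries", depth,
              length(attr(active, "dropped_samples")),
              length(attr(total, "dropped_samples")))
  }

  pc <- align_pairs(active, total, meta)
  log_stage("align: %d complete pairs over %d taxa",
            length(pc$pair_ids), length(pc$taxon_universe))

  dorm <- dormancy_profile(pc)
  shared <- shared_fraction(pc)
  core_args <- config$core %||% list()
  core <- do.call(core_report, c(list(pc = pc), core_args))
  log_stage("activity: mean dormant fraction %.3f; %d total-core, %d active-core",
            mean(dorm$dormant_fraction, na.rm = TRUE),
            sum(core$is_core_total), sum(core$is_core_active))

  community <- list()
  for (assay in c("total", "active")) {
    ft <- pc[[assay]]
    dmat <- bray_curtis(suppressWarnings(sqrt_wisconsin(ft)))
    terms <- config$permanova_terms %||% c("site_type", "season")
    design <- pc$pair_meta
    design$sample_id <- rownames(design)
    pm <- permanova(dmat, design, terms, n_perm = n_perm,
                    seed = derive_seed(config$seed, paste0("permanova_", assay)))
    bd <- beta_dispersion(dmat, design$site_type, n_perm = n_perm,
                          seed = derive_seed(config$seed, paste0("disp_", assay)))
    community[[assay]] <- list(distance = dmat, permanova = pm,
                               dispersion = bd)
    log_stage("community (%s): PERMANOVA %s", assay,
              paste(sprintf("%s R2=%.3f p=%.3g", pm$term[seq_along(terms)],
                            pm$r2[seq_along(terms)],
                            pm$p[seq_along(terms)]), collapse = "; "))
  }

  da_args <- config$diffabund %||% list()
  da_args$n_perm <- da_args$n_perm %||% n_perm
  da_args$seed <- da_args$seed %||% derive_seed(config$seed, "diffabund")
  enr <- active_vs_total_enrichment(pc, do.call(diffabund_config, da_args))
  log_stage("diffabund: %d taxa enriched at |FC| >= %g", sum(enr$enriched),
            attr(enr, "config")$min_fold_change)

  decay <- NULL
  if (!is.null(coords)) {
    decay <- tryCatch(
      distance_decay(total, meta, coords, env = env, n_perm = n_perm,
                     seed = derive_seed(config$seed, "decay")),
      error = function(e) {
        log_stage("distance decay skipped: %s", conditionMessage(e))
        NULL
      })
  }
  envlink <- NULL
  if (!is.null(env)) {
    envlink <- tryCatch(
      dormancy_env_link(dorm, env, pc$pair_meta,
                        seed = derive_seed(config$seed, "envlink")),
      error = function(e) {
        log_stage("dormancy-environment link skipped: %s", conditionMessage(e))
        NULL
      })
  }

  stamp <- list(config_hash = hash, seed = config$seed, n_perm = n_perm)
  write_table(dorm, file.path(out_dir, "dormancy.tsv"))
  write_table(shared$per_pair, file.path(out_dir, "shared_fraction.tsv"))
  write_report(c(stamp, list(
    core_total = attr(core, "core_total"),
    core_active = attr(core, "core_active"),
    frequently_inactive_core = attr(core, "frequently_inactive_core"),
    active_core_not_total_core = attr(core, "active_core_not_total_core"))),
    file.path(out_dir, "core_report.json"), schema = "core-report")
  write_table(as.data.frame(core), file.path(out_dir, "core_report.tsv"))
  for (assay in names(community)) {
    write_distance_matrix(community[[assay]]$distance,
                          file.path(out_dir, paste0("bray_curtis_", assay, ".tsv")))
    write_table(as.data.frame(community[[assay]]$permanova),
                file.path(out_dir, paste0("permanova_", assay, ".tsv")))
  }
  write_table(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
  if (!is.null(decay))
    write_table(decay$stats, file.path(out_dir, "distance_decay.tsv"))
  if (!is.null(envlink))
    write_table(envlink$associations, file.path(out_dir, "dormancy_env.tsv"))
  summary <- c(stamp, list(
    n_pairs = length(pc$pair_ids),
    n_taxa = length(pc$taxon_universe),
    mean_dormant_fraction = mean(dorm$dormant_fraction, na.rm = TRUE),
    mean_shared_fraction = shared$mean,
    n_core_total = sum(core$is_core_total),
    n_core_active = sum(core$is_core_active),
    n_enriched = sum(enr$enriched)))
  write_report(summary, file.path(out_dir, "summary.json"), schema = "summary")

  invisible(list(paired = pc, dormancy = dorm, shared = shared,
                 core = core, community = community, enrichment = enr,
                 distance_decay = decay, dormancy_env = envlink,
                 synthetic = sim, summary = summary, out_dir = out_dir))
}
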
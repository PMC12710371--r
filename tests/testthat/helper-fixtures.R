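# fixtures and independent oracles used across the suite

# random count matrix with no all-zero row or column
rand_counts <- function(n_taxa, n_samples, lambda = 3) {
  repeat {
    m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                sprintf("s%02d", seq_len(n_samples))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

rand_ft <- function(n_taxa, n_samples, assay = "DNA", lambda = 3) {
  feature_table(rand_counts(n_taxa, n_samples, lambda), assay = assay)
}

# minimal valid metadata for a set of sample ids
stub_meta <- function(sample_id, assay, pair_id,
                      site_type = "riparian", site = 1, plot = 1,
                      season = "June") {
  data.frame(sample_id = sample_id, site_type = site_type, site = site,
             plot = plot, season = season, assay = assay,
             pair_id = pair_id, stringsAsFactors = FALSE)
}

# paired community from two matrices whose columns are pair ids
make_pc <- function(dna, rna, marker = "ITS2") {
  pids <- colnames(dna)
  stopifnot(identical(pids, colnames(rna)))
  d <- dna; colnames(d) <- paste0(pids, "_D")
  r <- rna; colnames(r) <- paste0(pids, "_R")
  meta <- rbind(stub_meta(colnames(d), "DNA", pids),
                stub_meta(colnames(r), "RNA", pids))
  align_pairs(feature_table(r, marker = marker, assay = "RNA"),
              feature_table(d, marker = marker, assay = "DNA"), meta)
}

# paired community from presence sets (lists of taxon-id vectors per pair)
pc_from_sets <- function(dna_sets, rna_sets) {
  taxa <- sort(unique(unlist(c(dna_sets, rna_sets))))
  pids <- sprintf("p%02d", seq_along(dna_sets))
  to_mat <- function(sets) {
    m <- matrix(0, length(taxa), length(sets),
                dimnames = list(taxa, pids))
    for (j in seq_along(sets)) m[match(sets[[j]], taxa), j] <- 1
    m
  }
  make_pc(to_mat(dna_sets), to_mat(rna_sets))
}

rand_sets <- function(taxa, n_pairs, p = 0.5) {
  lapply(seq_len(n_pairs), function(i) taxa[runif(length(taxa)) < p])
}

## --- independent brute-force oracles -------------------------------

oracle_wisconsin <- function(m) {
  m <- m[rowSums(m) > 0, , drop = FALSE]
  s <- sqrt(m)
  for (i in seq_len(nrow(s))) s[i, ] <- s[i, ] / max(s[i, ])
  for (j in seq_len(ncol(s))) s[, j] <- s[, j] / sum(s[, j])
  s
}

oracle_bray <- function(x) {
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(x[, i] - x[, j])) / sum(x[, i] + x[, j])
  d
}

# literal BH step-up rule
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    prev <- min(prev, n * p[o[k]] / k)
    adj[o[k]] <- prev
  }
  pmin(adj, 1)
}

# set-operation oracles for one pair of presence sets
oracle_dormant <- function(dna, rna) {
  u <- union(dna, rna)
  if (length(u) == 0) return(NA_real_)
  1 - length(rna) / length(u)
}
oracle_shared <- function(dna, rna) {
  if (length(dna) == 0) return(NA_real_)
  length(intersect(dna, rna)) / length(dna)
}
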
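#' Align an active (RNA) and a total (DNA) feature table into pairs
#'
#' Matches the two assays of each physical sample through the metadata
#' `pair_id` column (pairing is never inferred from sample names). Only
#' pair ids with both assays present are kept; both tables are
#' zero-filled on the union of their taxa and column-ordered identically
#' by pair id, so all downstream active/total contrasts line up.
#'
#' @param active RNA [feature_table()].
#' @param total DNA [feature_table()] of the same marker.
#' @param meta sample metadata (see [as_sample_metadata()]) covering all
#'   samples of both tables.
#' @return An object of class `paired_community`: list with `active` and
#'   `total` feature tables (columns named by pair id), `pair_ids`,
#'   `taxon_universe`, and `pair_meta` (one metadata row per pair, taken
#'   from the DNA library's row minus the assay-specific fields).
#' @export
align_pairs <- function(active, total, meta) {
  stopifnot(inherits(active, "feature_table"), inherits(total, "feature_table"))
  if (active$assay != "RNA") stop2("'active' table must have assay RNA")
  if (total$assay != "DNA") stop2("'total' table must have assay DNA")
  if (active$marker != total$marker)
    stop2("active and total tables are from different markers (",
          active$marker, " vs ", total$marker, ")")
  meta <- as_sample_metadata(meta)
  need <- c(sample_ids(active), sample_ids(total))
  missing <- setdiff(need, meta$sample_id)
  if (length(missing) > 0)
    stop2("sample(s) missing from metadata: ", paste(missing, collapse = ", "))

  pair_of <- function(ft, assay) {
    rows <- meta[sample_ids(ft), ]
    if (any(rows$assay != assay))
      stop2("metadata assay disagrees with table assay for sample(s): ",
            paste(rows$sample_id[rows$assay != assay], collapse = ", "))
    setNames(rows$pair_id, rows$sample_id)
  }
  pr <- pair_of(active, "RNA")
  pd <- pair_of(total, "DNA")
  pair_ids <- intersect(pd[sample_ids(total)], pr[sample_ids(active)])
  if (length(pair_ids) == 0)
    stop2("no pair_id has both an RNA and a DNA library; nothing to align")

  universe <- union(taxon_ids(total), taxon_ids(active))
  fill <- function(ft, pair_map, pair_ids, universe) {
    m <- matrix(0, length(universe), length(pair_ids),
                dimnames = list(universe, pair_ids))
    keep <- names(pair_map)[pair_map %in% pair_ids]
    m[taxon_ids(ft), pair_map[keep]] <- ft$counts[, keep, drop = FALSE]
    feature_table(m, marker = ft$marker, assay = ft$assay)
  }
  act <- fill(active, pr, pair_ids, universe)
  tot <- fill(total, pd, pair_ids, universe)

  dna_rows <- meta[meta$assay == "DNA" & meta$pair_id %in% pair_ids, ]
  pair_meta <- dna_rows[match(pair_ids, dna_rows$pair_id),
                        setdiff(names(dna_rows), c("sample_id", "assay"))]
  rownames(pair_meta) <- pair_ids

  structure(list(active = act, total = tot, pair_ids = pair_ids,
                 taxon_universe = universe, pair_meta = pair_meta),
            class = "paired_community")
}

#' @export
print.paired_community <- function(x, ...) {
  cat(sprintf("<paired_community> %s: %d taxa x %d RNA/DNA pairs\n",
              x$active$marker, length(x$taxon_universe), length(x$pair_ids)))
  invisible(x)
}
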
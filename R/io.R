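#' Read a feature table from TSV or BIOM 1.0 JSON
#'
#' The TSV dialect is taxa as rows with the taxon id in the first column
#' and sample ids in the header (QIIME classic export). BIOM support
#' covers the JSON 1.0 format, dense and sparse, via the `biomformat`
#' package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom_json"`.
#' @inheritParams feature_table
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom_json"),
                               marker = c("ITS2", "16S"),
                               assay = c("DNA", "RNA")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "tsv") {
    df <- read_tsv_schema(path)
    if (ncol(df) < 2) stop2("feature-table TSV needs a taxon id column and at least one sample")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
  }
  feature_table(m, marker = marker, assay = assay)
}

#' Write a feature table as TSV
#'
#' Writes the taxa x samples count matrix with a `taxon_id` first column
#' and a leading schema comment; [read_feature_table()] round-trips it.
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write_tsv_schema(df, path, "feature-table")
}

REQUIRED_META_COLS <- c("site_type", "site", "plot", "season", "assay", "pair_id")
SITE_TYPES <- c("riparian", "mid_elevation", "high_elevation")
SEASONS <- c("June", "August", "October")
ASSAYS <- c("DNA", "RNA")

#' Validate a sample metadata data frame
#'
#' Required columns: `sample_id`, `site_type`, `site`, `plot`, `season`,
#' `assay`, `pair_id`. Site types follow the three habitat classes of
#' the sampling design (riparian, mid-elevation, high-elevation aspen
#' stands); `season` is the ordered June < August < October factor;
#' `pair_id` links the RNA and DNA libraries of one physical sample.
#' Unknown extra columns are preserved as opaque covariates.
#'
#' @param df a data frame with one row per sequencing library.
#' @param site_types,seasons allowed factor levels; defaults are the
#'   field design's levels.
#' @return The validated data frame (season as ordered factor).
#' @export
as_sample_metadata <- function(df, site_types = SITE_TYPES, seasons = SEASONS) {
  names(df)[1] <- sub("^#SampleID$", "sample_id", names(df)[1])
  if (!"sample_id" %in% names(df))
    stop2("metadata must have a 'sample_id' (or '#SampleID') column")
  missing <- setdiff(REQUIRED_META_COLS, names(df))
  if (length(missing) > 0)
    stop2("metadata is missing required column(s): ",
          paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop2("duplicate sample id(s): ",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad) > 0)
      stop2("invalid ", what, " value(s) ", paste(bad, collapse = ", "),
            "; allowed levels: ", paste(levels, collapse = ", "))
  }
  check_levels(df$site_type, site_types, "site_type")
  check_levels(df$season, seasons, "season")
  check_levels(df$assay, ASSAYS, "assay")
  df$site_type <- factor(df$site_type, levels = site_types)
  df$season <- factor(df$season, levels = seasons, ordered = TRUE)
  df$assay <- factor(df$assay, levels = ASSAYS)
  df$site <- factor(df$site)
  df$plot <- factor(df$plot)
  df$pair_id <- as.character(df$pair_id)
  dup <- table(df$pair_id, df$assay)
  if (any(dup > 1)) {
    bad <- rownames(dup)[apply(dup > 1, 1, any)][1]
    stop2("pair_id '", bad, "' maps to more than one library of the same assay")
  }
  rownames(df) <- df$sample_id
  df
}

#' Read sample metadata from TSV
#'
#' First column is the sample id; the QIIME-style `#SampleID` header is
#' accepted. See [as_sample_metadata()] for the required columns.
#'
#' @inheritParams read_feature_table
#' @inheritParams as_sample_metadata
#' @export
read_metadata <- function(path, site_types = SITE_TYPES, seasons = SEASONS) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- read_tsv_schema(path)
  as_sample_metadata(df, site_types = site_types, seasons = seasons)
}

#' Read a taxonomy map from TSV
#'
#' First column `taxon_id`, remaining columns ranked lineage fields
#' (e.g. kingdom .. species); missing ranks may be empty or NA.
#'
#' @inheritParams read_feature_table
#' @return data frame keyed by unique `taxon_id`.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_schema(path)
  names(df)[1] <- "taxon_id"
  df$taxon_id <- as.character(df$taxon_id)
  if (anyDuplicated(df$taxon_id)) stop2("duplicate taxon id in taxonomy map")
  df
}

#' Write / read a square distance matrix as TSV
#'
#' Square layout with sample ids in both the header row and the first
#' column; round-trips through [read_distance_matrix()].
#'
#' @param d symmetric distance matrix with zero diagonal and dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  d <- validate_distance_matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write_tsv_schema(df, path, "distance-matrix")
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read_tsv_schema(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance_matrix(m)
}

#' Validate a distance matrix
#'
#' Checks squareness, matching ids, symmetry (to 1e-12 relative),
#' non-negativity and a zero diagonal; symmetrizes exactly.
#'
#' @param d matrix to validate.
#' @export
validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop2("distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop2("distance matrix must carry sample ids as dimnames")
  if (!identical(rownames(d), colnames(d)))
    stop2("distance matrix row and column ids differ")
  if (any(d < -1e-12)) stop2("negative dissimilarities")
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(abs(d))))
    stop2("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop2("distance matrix diagonal is not zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Write an analysis report as JSON
#'
#' Serializes lists / data frames with a `schema_version` field so
#' reports are self-describing; deterministic (no timestamps).
#'
#' @param x report object (list or data frame).
#' @param path output path.
#' @param schema short schema name recorded in the file.
#' @export
write_report <- function(x, path, schema = "report") {
  payload <- list(schema_version = paste0("paircomm-", schema, "/1"),
                  content = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a data frame as TSV with a schema comment
#' @param x data frame.
#' @param path output path.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  write_tsv_schema(x, path, "table")
}
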
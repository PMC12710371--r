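#' Construct a feature table
#'
#' A feature table holds non-negative integer amplicon counts for one
#' marker (ITS2 for fungi, 16S for bacteria/archaea) and one assay
#' (DNA for the total community, RNA/cDNA for the active community),
#' oriented taxa x samples (observation-major, the BIOM convention).
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; must
#'   have unique row and column names and non-negative integral entries.
#' @param marker marker gene, `"ITS2"` or `"16S"`.
#' @param assay `"DNA"` (total community) or `"RNA"` (active community).
#' @return An object of class `feature_table`: a list with elements
#'   `counts`, `marker`, `assay`.
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2,
#'             dimnames = list(c("taxA", "taxB"), c("s1", "s2")))
#' ft <- feature_table(m, marker = "ITS2", assay = "DNA")
#' @export
feature_table <- function(counts, marker = c("ITS2", "16S"),
                          assay = c("DNA", "RNA")) {
  marker <- match.arg(marker)
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicate taxon ids: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate sample ids: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop2("counts must be numeric with no missing values")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop2("negative or non-integral count at taxon '",
          rownames(counts)[bad[1, 1]], "', sample '",
          colnames(counts)[bad[1, 2]], "' (value ",
          counts[bad[1, 1], bad[1, 2]], ")")
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  structure(list(counts = counts, marker = marker, assay = assay),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s/%s: %d taxa x %d samples, total %.0f reads\n",
              x$marker, x$assay, nrow(x$counts), ncol(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x$counts)

as_count_matrix <- function(x) {
  if (inherits(x, "feature_table")) x$counts
  else if (is.matrix(x)) x
  else stop2("expected a feature_table or a matrix")
}
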
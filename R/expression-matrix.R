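#' Construct a spatiotemporal expression matrix
#'
#' Container for a genes-by-samples expression matrix with per-sample
#' spatiotemporal annotation. Values are either raw RPKM (reads per kilobase
#' per million mapped reads) or the log2(RPKM + 1) working scale used by the
#' downstream feature table; the `scale` tag guards against accidental double
#' transformation.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param sample_meta data frame with columns `sample_id`, `region`, `stage`,
#'   `donor` and logical `prenatal`; one row per column of `values`.
#' @param scale `"rpkm"` or `"log2"`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, sample_meta, scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(sprintf("Duplicate gene identifiers: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    abort(sprintf("Duplicate sample identifiers: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite expression value at gene '%s', sample '%s'.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (scale == "rpkm" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative RPKM at gene '%s', sample '%s'.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  sample_meta <- as_tibble(sample_meta)
  required <- c("sample_id", "region", "stage", "donor")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols)) {
    abort(sprintf("`sample_meta` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  absent <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(absent)) {
    abort(sprintf("Sample(s) missing from metadata: %s",
                  paste(head(absent, 5), collapse = ", ")))
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  structure(
    list(values = values, sample_meta = sample_meta, scale = scale),
    class = "expr_matrix"
  )
}

#' @export
#' @method print expr_matrix
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples [%s scale]; %d regions, %d stages\n",
    nrow(x$values), ncol(x$values), x$scale,
    length(unique(x$sample_meta$region)), length(unique(x$sample_meta$stage))
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Log-transform an RPKM expression matrix
#'
#' Applies the log2(RPKM + 1) working transform. Refuses already-log-scale
#' input so the transform can never be applied twice.
#'
#' @param expr an [expr_matrix()] on the RPKM scale.
#' @return An `expr_matrix` on the log2 scale, same shape and metadata.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "rpkm") {
    abort("`expr` is already log2-scale; refusing to double-transform.")
  }
  expr$values <- log2(expr$values + 1)
  expr$scale <- "log2"
  expr
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The expression file has a header row of sample ids and gene ids in the
#' first column; the companion metadata file has columns `sample_id`,
#' `region`, `stage`, `donor` (and optionally logical `prenatal`).
#'
#' @param path TSV file of expression values.
#' @param meta_path TSV file of sample metadata.
#' @param scale scale tag of the stored values, `"rpkm"` (default) or `"log2"`.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, meta_path, scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort(sprintf("'%s': expected gene column plus samples.", path))
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[, -1], is.numeric, TRUE))[1]
    abort(sprintf("'%s': non-numeric expression values in column '%s'.",
                  path, names(tab)[-1][bad]))
  }
  rownames(mat) <- genes
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  if (!"prenatal" %in% names(meta)) meta$prenatal <- NA
  expr_matrix(mat, meta, scale = scale)
}

#' Write an expression matrix and its sample metadata to TSV
#'
#' @param expr an [expr_matrix()].
#' @param path,meta_path output TSV paths for values and sample metadata.
#' @return Invisibly, `c(path, meta_path)`.
#' @export
write_expression <- function(expr, path, meta_path) {
  stopifnot(inherits(expr, "expr_matrix"))
  out <- tibble(gene = rownames(expr$values)) |>
    dplyr::bind_cols(as_tibble(expr$values))
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_tsv(expr$sample_meta, meta_path, progress = FALSE)
  invisible(c(path, meta_path))
}
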
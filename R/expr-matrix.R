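#' Expression matrix with sample annotations
#'
#' Lightweight container for a gene-by-sample matrix of log2 expression
#' values together with the per-sample group label
#' (`"normal"`, `"responder"` or `"nonresponder"`) and a dataset/platform
#' label. All downstream relative-expression-ordering (REO) operations work
#' on within-sample orderings only, so values from different platforms never
#' need to be normalised against each other.
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). No missing values.
#' @param group character vector, one of `"normal"`, `"responder"`,
#'   `"nonresponder"` per sample; recycled if length 1.
#' @param dataset single dataset/platform label.
#' @return An object of class `expr_matrix`: the matrix with `group` and
#'   `dataset` attributes.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- expr_matrix(m, group = "normal", dataset = "platformA")
#' sample_groups(em)
#' @export
expr_matrix <- function(values, group = "normal", dataset = "dataset1") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("`values` must have unique rownames (gene ids)", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique colnames (sample ids)", call. = FALSE)
  }
  if (anyNA(values)) stop("missing expression values are not allowed", call. = FALSE)
  group <- rep_len(as.character(group), ncol(values))
  bad <- setdiff(unique(group), c("normal", "responder", "nonresponder"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(values,
            group = stats::setNames(group, colnames(values)),
            dataset = as.character(dataset)[1L],
            class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
sample_groups <- function(x) attr(x, "group")

#' @rdname expr_matrix
#' @export
dataset_label <- function(x) attr(x, "dataset")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (dataset '%s')\n",
              nrow(x), ncol(x), dataset_label(x)))
  print(table(sample_groups(x)))
  invisible(x)
}

# Coerce a plain matrix (or expr_matrix) to the bare numeric matrix used by
# the numeric internals.
.as_values <- function(x) {
  if (inherits(x, "expr_matrix")) x <- unclass(x)
  attr(x, "group") <- NULL
  attr(x, "dataset") <- NULL
  x
}

#' Read and write expression matrices and sample metadata as TSV
#'
#' The on-disk convention is the one the synthetic-cohort generator writes:
#' an expression TSV with a `gene_id` first column and one column per sample,
#' and a metadata TSV with columns `sample_id`, `group`, `dataset`.
#'
#' @param path file path.
#' @param metadata optional data.frame with columns `sample_id`, `group`,
#'   `dataset` (as written by [write_sample_metadata()]); when supplied the
#'   result is an [expr_matrix()] with those annotations.
#' @return `read_expr_tsv`: a numeric matrix or `expr_matrix`.
#' @export
read_expr_tsv <- function(path, metadata = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (is.null(metadata)) return(m)
  idx <- match(colnames(m), metadata$sample_id)
  if (anyNA(idx)) stop("metadata is missing some samples", call. = FALSE)
  expr_matrix(m, group = metadata$group[idx],
              dataset = metadata$dataset[idx][1L])
}

#' @rdname read_expr_tsv
#' @param x matrix or `expr_matrix` to write.
#' @export
write_expr_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), .as_values(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expr_tsv
#' @export
read_sample_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_expr_tsv
#' @param matrices list of `expr_matrix` objects whose annotations to collect.
#' @export
write_sample_metadata <- function(matrices, path) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  md <- do.call(rbind, lapply(matrices, function(m) {
    data.frame(sample_id = colnames(m), group = unname(sample_groups(m)),
               dataset = dataset_label(m), stringsAsFactors = FALSE)
  }))
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
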
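#' Build a gene-by-set design matrix
#'
#' Constructs the binary n-genes x m-sets membership matrix X of the gene-set
#' regression: `X[i, j] = 1` iff gene i belongs to set j. Sets with no member
#' inside the gene universe would produce an all-zero column and are rejected
#' (or dropped with a warning when `drop_empty = TRUE`, as the pipeline does
#' for real annotation collections). Genes belonging to no set keep an
#' all-zero row, which is valid.
#'
#' @param collection A [gene_set_collection].
#' @param gene_ids Character vector: the gene universe, in response order.
#' @param drop_empty Drop sets with no gene in the universe instead of
#'   erroring.
#' @return Object of class `gene_set_design` with fields `gene_ids`,
#'   `set_ids`, `X`.
#' @export
gene_set_design <- function(collection, gene_ids, drop_empty = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop_gsblr("duplicated gene ids in universe", class = "gsblr_validation_error")
  n <- length(gene_ids)
  m <- length(collection$set_id)
  X <- matrix(0, nrow = n, ncol = m,
              dimnames = list(gene_ids, collection$set_id))
  for (j in seq_len(m)) {
    idx <- match(collection$genes[[j]], gene_ids)
    idx <- idx[!is.na(idx)]
    X[idx, j] <- 1
  }
  empty <- colSums(X) == 0
  if (any(empty)) {
    if (drop_empty) {
      warning(sum(empty), " set(s) with no gene in the universe dropped: ",
              paste(utils::head(collection$set_id[empty], 3), collapse = ", "))
      X <- X[, !empty, drop = FALSE]
    } else {
      stop_gsblr("set(s) with no gene in the universe (all-zero column): ",
                 paste(utils::head(collection$set_id[empty], 3), collapse = ", "),
                 class = "gsblr_validation_error")
    }
  }
  if (ncol(X) == 0L)
    stop_gsblr("design has zero sets", class = "gsblr_argument_error")
  structure(list(gene_ids = gene_ids, set_ids = colnames(X), X = X),
            class = "gene_set_design")
}

#' @export
print.gene_set_design <- function(x, ...) {
  cat("gene_set_design:", length(x$gene_ids), "genes x",
      length(x$set_ids), "sets\n")
  invisible(x)
}

#' @export
dim.gene_set_design <- function(x) dim(x$X)
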
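#' Read GWAS summary statistics
#'
#' Reads a TSV/CSV of per-variant association results into a validated
#' data frame of variant statistics. Either a z-score column or a pair of
#' effect/standard-error columns must be present; in the latter case
#' `z = beta / se` is computed at read time. Rows with a non-finite z are
#' dropped (with a logged count). Allele columns are carried through but never
#' used for harmonization.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named list mapping the roles `id`, `chr`, `pos`, `a1`,
#'   `a2`, `z`, `beta`, `se`, `n` to column names in the file. Roles omitted
#'   from the map use the role name itself as the column name. `a1`, `a2` and
#'   `n` are optional.
#' @return A `data.frame` with columns `variant_id`, `chrom`, `pos`, `a1`,
#'   `a2`, `z`, `n` (class `variant_stats`).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("variant_id\tchr\tpos\ta1\ta2\tz",
#'              "rs1\t1\t100\tA\tG\t2.0"), f)
#' read_gwas(f, column_map = list(chr = "chr"))
#' @export
read_gwas <- function(path, column_map = list()) {
  stopifnot(is.character(path), length(path) == 1L)
  defaults <- list(id = "variant_id", chr = "chrom", pos = "pos",
                   a1 = "a1", a2 = "a2", z = "z", beta = "beta", se = "se",
                   n = "n")
  cm <- utils::modifyList(defaults, as.list(column_map))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  need <- c("id", "chr", "pos")
  for (role in need) {
    if (!cm[[role]] %in% names(dt))
      stop_gsblr("GWAS file is missing mandatory column '", cm[[role]],
                 "' (role: ", role, ")", class = "gsblr_format_error")
  }
  has_z <- cm$z %in% names(dt)
  has_bse <- all(c(cm$beta, cm$se) %in% names(dt))
  if (!has_z && !has_bse)
    stop_gsblr("GWAS file must contain a '", cm$z, "' column or both '",
               cm$beta, "' and '", cm$se, "' columns",
               class = "gsblr_format_error")
  z <- if (has_z) as.numeric(dt[[cm$z]]) else
    as.numeric(dt[[cm$beta]]) / as.numeric(dt[[cm$se]])
  out <- data.frame(
    variant_id = as.character(dt[[cm$id]]),
    chrom = as.character(dt[[cm$chr]]),
    pos = as.integer(dt[[cm$pos]]),
    a1 = if (cm$a1 %in% names(dt)) as.character(dt[[cm$a1]]) else NA_character_,
    a2 = if (cm$a2 %in% names(dt)) as.character(dt[[cm$a2]]) else NA_character_,
    z = z,
    n = if (cm$n %in% names(dt)) as.integer(dt[[cm$n]]) else NA_integer_,
    stringsAsFactors = FALSE)
  bad <- !is.finite(out$z)
  if (any(bad)) {
    gsblr_log("read_gwas: dropped ", sum(bad), " row(s) with non-finite z")
    out <- out[!bad, , drop = FALSE]
  }
  validate_variant_stats(out)
}

validate_variant_stats <- function(x) {
  if (anyDuplicated(x$variant_id))
    stop_gsblr("duplicated variant_id: ",
               paste(unique(x$variant_id[duplicated(x$variant_id)])[1:3],
                     collapse = ", "),
               class = "gsblr_validation_error")
  if (any(x$pos < 1L, na.rm = TRUE))
    stop_gsblr("variant positions must be >= 1 (1-based coordinates)",
               class = "gsblr_validation_error")
  if (any(!is.finite(x$z)))
    stop_gsblr("non-finite z-scores present", class = "gsblr_validation_error")
  rownames(x) <- NULL
  class(x) <- c("variant_stats", "data.frame")
  x
}

#' Construct a gene-set collection
#'
#' @param set_ids Character vector of unique set identifiers.
#' @param descriptions Character vector of descriptions (recycled if length 1).
#' @param genes List of character vectors of gene ids, one per set.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(set_ids, descriptions, genes) {
  set_ids <- as.character(set_ids)
  if (length(descriptions) == 1L) descriptions <- rep(descriptions, length(set_ids))
  stopifnot(length(set_ids) == length(genes),
            length(descriptions) == length(set_ids))
  if (anyDuplicated(set_ids))
    stop_gsblr("duplicated set_id: ",
               set_ids[duplicated(set_ids)][1L], class = "gsblr_validation_error")
  for (i in seq_along(genes)) {
    g <- as.character(genes[[i]])
    if (length(g) == 0L)
      stop_gsblr("gene set '", set_ids[i], "' is empty",
                 class = "gsblr_validation_error")
    if (anyDuplicated(g))
      stop_gsblr("gene set '", set_ids[i], "' contains duplicated gene ids",
                 class = "gsblr_validation_error")
    genes[[i]] <- g
  }
  structure(list(set_id = set_ids, description = as.character(descriptions),
                 genes = genes),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$genes)
  cat("gene_set_collection:", length(x$set_id), "sets;",
      "sizes", min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$set_id)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-delimited as
#' `set_id TAB description TAB gene1 TAB gene2 ...`. Trailing empty fields are
#' ignored; a line with fewer than three non-empty fields is a format error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_gsblr("empty GMT file: ", path, class = "gsblr_format_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- character(length(parts)); desc <- character(length(parts))
  genes <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    g <- p[-(1:2)]
    g <- g[nzchar(g)]
    if (length(p) < 3L || length(g) == 0L)
      stop_gsblr("GMT line ", i, " has fewer than 3 fields (no genes)",
                 class = "gsblr_format_error")
    ids[i] <- p[1L]; desc[i] <- p[2L]; genes[[i]] <- g
  }
  gene_set_collection(ids, desc, genes)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$set_id), function(i) {
    paste(c(collection$set_id[i], collection$description[i],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene records from a GTF file
#'
#' Extracts `gene` feature lines from a GTF annotation (1-based inclusive
#' coordinates, as printed). Strand `.`/`*` is mapped to `"unknown"`. If the
#' file contains no `gene` features an empty set of records is returned with a
#' warning.
#'
#' @param path Path to a GTF file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (values `+`, `-`, `unknown`).
#' @export
read_gtf_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop_gsblr("failed to parse GTF '", path, "': ",
                              conditionMessage(e), class = "gsblr_format_error"))
  feat <- as.character(gr$type)
  gr <- gr[feat == "gene"]
  if (length(gr) == 0L) {
    warning("no 'gene' features found in ", path,
            "; returning zero gene records")
    return(empty_gene_records())
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "unknown"
  out <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  validate_gene_records(out)
}

empty_gene_records <- function() {
  data.frame(gene_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

validate_gene_records <- function(x) {
  if (anyDuplicated(x$gene_id))
    stop_gsblr("duplicated gene_id: ", x$gene_id[duplicated(x$gene_id)][1L],
               class = "gsblr_validation_error")
  if (any(x$start > x$end))
    stop_gsblr("gene records with start > end", class = "gsblr_validation_error")
  rownames(x) <- NULL
  x
}

#' Construct an LD matrix object
#'
#' A per-gene LD matrix holds pairwise correlations between the variants of a
#' gene. The matrix is symmetrized as `(K + t(K)) / 2` and validated: entries
#' in `[-1, 1]`, unit diagonal (within 1e-6).
#'
#' @param K Square numeric matrix of correlations.
#' @param variant_ids Character vector naming the rows/columns, in order.
#' @return An object of class `ld_matrix` with fields `variant_ids` and `K`.
#' @export
ld_matrix <- function(K, variant_ids) {
  K <- as.matrix(K)
  variant_ids <- as.character(variant_ids)
  if (nrow(K) != ncol(K))
    stop_gsblr("LD matrix is not square (", nrow(K), "x", ncol(K), ")",
               class = "gsblr_format_error")
  if (nrow(K) != length(variant_ids))
    stop_gsblr("LD matrix dimension (", nrow(K), ") does not match the ",
               length(variant_ids), " variant ids",
               class = "gsblr_format_error")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-4)
    stop_gsblr("matrix is far from symmetric (max asymmetry ",
               format(asym), "); not a correlation matrix",
               class = "gsblr_validation_error")
  K <- (K + t(K)) / 2
  if (any(abs(K) > 1 + 1e-6))
    stop_gsblr("LD matrix entries outside [-1, 1]",
               class = "gsblr_validation_error")
  if (any(abs(diag(K) - 1) > 1e-6))
    stop_gsblr("LD matrix diagonal differs from 1 beyond tolerance",
               class = "gsblr_validation_error")
  K[K > 1] <- 1; K[K < -1] <- -1
  dimnames(K) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, K = K), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix:", length(x$variant_ids), "variants\n")
  invisible(x)
}

#' Read a plain-text LD matrix
#'
#' Reads a whitespace-delimited square numeric matrix whose rows/columns
#' correspond, in order, to `variant_ids`.
#'
#' @param path Path to the matrix file.
#' @param variant_ids Character vector of variant ids (row order).
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path, variant_ids) {
  K <- tryCatch(as.matrix(utils::read.table(path, header = FALSE)),
                error = function(e)
                  stop_gsblr("failed to read LD matrix '", path, "': ",
                             conditionMessage(e), class = "gsblr_format_error"))
  storage.mode(K) <- "double"
  ld_matrix(K, variant_ids)
}

#' Write an LD matrix as plain text
#'
#' Full double precision is retained so a write/read round trip reproduces the
#' matrix to numerical identity.
#'
#' @param ld An [ld_matrix] (or plain square matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  K <- if (inherits(ld, "ld_matrix")) ld$K else as.matrix(ld)
  txt <- apply(K, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(txt, path)
  invisible(path)
}
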
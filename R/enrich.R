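#' Hypergeometric enrichment of a gene set in a disease gene list
#'
#' Exact upper-tail hypergeometric test of the overlap between a gene set and
#' an external disease-gene list over a stated gene universe: with `N` genes
#' in the universe, `M` disease genes, `K` set genes and `k` overlapping
#' genes, the p-value is `P(X >= k)` for `X ~ Hypergeom(N, M, K)`. The
#' survival sum is accumulated in log space for numerical stability in the
#' far tail.
#'
#' @param set_genes Character vector of gene ids (must lie in the universe).
#' @param disease_genes Character vector; intersected with the universe first.
#' @param universe_genes Character vector: the gene universe (by default the
#'   pipeline uses all genes present in the gene-statistics table).
#' @param set_id Optional label carried into the result.
#' @return A one-row `data.frame` with `set_id`, `universe_size`, `set_size`,
#'   `list_size`, `overlap`, `p_value`.
#' @examples
#' hypergeom_enrichment(paste0("g", 1:5), paste0("g", 1:5), paste0("g", 1:10))
#' # p = 1 / choose(10, 5) = 1/252
#' @export
hypergeom_enrichment <- function(set_genes, disease_genes, universe_genes,
                                 set_id = "") {
  universe <- unique(as.character(universe_genes))
  set_genes <- unique(as.character(set_genes))
  if (length(universe) == 0L)
    stop_gsblr("empty gene universe", class = "gsblr_argument_error")
  if (length(set_genes) == 0L)
    stop_gsblr("empty gene set", class = "gsblr_argument_error")
  if (!all(set_genes %in% universe))
    stop_gsblr("gene set contains genes outside the universe",
               class = "gsblr_argument_error")
  disease <- intersect(unique(as.character(disease_genes)), universe)
  N <- length(universe); K <- length(set_genes); M <- length(disease)
  k <- length(intersect(set_genes, disease))
  p <- hypergeom_sf(k, N, M, K)
  data.frame(set_id = set_id, universe_size = N, set_size = K,
             list_size = M, overlap = k, p_value = p,
             stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, M, K)` (universe N, M "successes", K
#' draws), computed by log-space summation of the point masses.
#'
#' @param k Observed overlap.
#' @param N Universe size.
#' @param M Number of success states (disease genes in the universe).
#' @param K Number of draws (set size).
#' @return Probability in `(0, 1]`.
#' @export
hypergeom_sf <- function(k, N, M, K) {
  stopifnot(N >= 1, M >= 0, M <= N, K >= 1, K <= N, k >= 0)
  if (k <= max(0L, K + M - N)) return(1)
  hi <- min(K, M)
  if (k > hi) return(0)  # unreachable overlap; caller guarantees k <= min(K,M)
  terms <- stats::dhyper(k:hi, m = M, n = N - M, k = K, log = TRUE)
  min(1, exp(logsumexp(terms)))
}

#' Read a two-column disease gene list
#'
#' Generic ingestion for disease-gene association files (e.g. the channel
#' files of gene-disease databases): a TSV with a gene-id column and an
#' optional score column; genes at or above `score_cutoff` are kept.
#'
#' @param path Path to a TSV (header optional; first column gene id, second,
#'   if present, a numeric score).
#' @param score_cutoff Optional minimum score.
#' @return Character vector of gene ids.
#' @export
read_disease_list <- function(path, score_cutoff = NULL) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE,
                          showProgress = FALSE)
  genes <- as.character(dt[[1L]])
  if (!is.null(score_cutoff)) {
    if (ncol(dt) < 2L)
      stop_gsblr("score_cutoff given but the file has no score column",
                 class = "gsblr_format_error")
    genes <- genes[as.numeric(dt[[2L]]) >= score_cutoff]
  }
  unique(genes)
}

#' Enrichment of every set in a collection
#'
#' @param collection A [gene_set_collection]; sets are intersected with the
#'   universe (sets with no gene in the universe are skipped with a warning).
#' @param disease_genes Character vector of disease genes.
#' @param universe_genes Character vector, e.g. `gene_stats$gene_id`.
#' @return A `data.frame`, one row per tested set, ordered by p-value.
#' @export
enrich_collection <- function(collection, disease_genes, universe_genes) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- lapply(seq_along(collection$set_id), function(i) {
    g <- intersect(collection$genes[[i]], universe_genes)
    if (length(g) == 0L) {
      warning("set '", collection$set_id[i],
              "' has no gene in the universe; skipped")
      return(NULL)
    }
    hypergeom_enrichment(g, disease_genes, universe_genes,
                         set_id = collection$set_id[i])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[order(out$p_value), , drop = FALSE]
}
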
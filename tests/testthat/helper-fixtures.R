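# Shared fixture builders and independent oracles. Oracles here are written
# against the model definitions directly and never call the sampler code they
# check.

# disjoint toy design: k sets of `size` genes over a universe of n genes
toy_design <- function(k = 3L, size = 20L, n = k * size,
                       prefix = "S") {
  stopifnot(n >= k * size)
  members <- lapply(seq_len(k), function(j)
    paste0("g", ((j - 1L) * size + 1L):(j * size)))
  gene_set_collection(paste0(prefix, seq_len(k)), "toy", members) |>
    gene_set_design(paste0("g", seq_len(n)))
}

# random overlapping design
random_design <- function(m, n, size, seed = 1L) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n))
  members <- lapply(seq_len(m), function(j) sample(genes, size))
  gene_set_design(gene_set_collection(paste0("S", seq_len(m)), "rnd", members),
                  genes)
}

# Exact spike-and-slab posterior inclusion by enumeration over all 2^m
# submodels with conjugate Gaussian marginal likelihoods (fixed variances,
# fixed pi). Independent of the Gibbs sampler.
enum_pip <- function(y, X, pi0, sb2, se2) {
  yc <- y - mean(y)
  n <- length(yc)
  m <- ncol(X)
  logw <- numeric(2^m)
  inc <- matrix(0, 2^m, m)
  for (c in 0:(2^m - 1)) {
    sel <- which(bitwAnd(c, 2^(0:(m - 1))) > 0)
    S <- diag(se2, n)
    if (length(sel))
      S <- S + sb2 * X[, sel, drop = FALSE] %*% t(X[, sel, drop = FALSE])
    ch <- chol(S)
    logml <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                       sum(backsolve(ch, yc, transpose = TRUE)^2))
    logw[c + 1] <- logml + length(sel) * log(pi0) +
      (m - length(sel)) * log(1 - pi0)
    inc[c + 1, sel] <- 1
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  as.numeric(t(inc) %*% w)
}

# brute-force upper-tail hypergeometric by enumerating all C(N, K) draws
hyper_sf_brute <- function(k, N, M, K) {
  draws <- utils::combn(N, K)
  succ <- colSums(draws <= M)   # treat items 1..M as the "disease" genes
  mean(succ >= k)
}

# a tiny GTF fixture written on the fly
write_toy_gtf <- function(path) {
  lines <- c(
    paste("1", "ens", "gene", "1000", "2000", ".", "+", ".",
          'gene_id "GENE1"; gene_name "A";', sep = "\t"),
    paste("1", "ens", "transcript", "1000", "2000", ".", "+", ".",
          'gene_id "GENE1"; transcript_id "T1";', sep = "\t"),
    paste("2", "ens", "gene", "5000", "9000", ".", "-", ".",
          'gene_id "GENE2";', sep = "\t"),
    paste("2", "ens", "gene", "20000", "21000", ".", ".", ".",
          'gene_id "GENE3";', sep = "\t"))
  writeLines(lines, path)
  path
}

# minimal GWAS TSV fixture
write_toy_gwas <- function(path, df) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
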
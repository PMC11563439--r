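# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
gsblr_log <- function(..., verbose = getOption("gsblr.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[gsblr] ", ...)
  invisible(NULL)
}

stop_gsblr <- function(..., class = "gsblr_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `code` under a given seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Effective sample size via Geyer's initial positive sequence on the
# autocorrelation function of one chain.
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2L, 500L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  # pair consecutive lags; stop at first non-positive pair sum
  npair <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g <= 0) break
    s <- s + g
  }
  max(1, n / (1 + 2 * s))
}

# Split-chain potential scale reduction. `x` is a matrix with one column per
# chain; each column is split in half so a single chain still yields a value.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  chains <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(chains); nn <- nrow(chains)
  mu <- colMeans(chains)
  B <- nn * stats::var(mu)
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Write a data.frame as TSV preceded by "#"-prefixed metadata lines.
write_tsv_with_meta <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("gsblr ", as.character(utils::packageVersion("gsblr")))),
            meta)
  lines <- vapply(names(meta), function(k) paste0("# ", k, ": ", meta[[k]]),
                  character(1))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_meta <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = "#", data.table = FALSE,
                                  showProgress = FALSE))
}

# MD5 of an in-memory object via its JSON serialization (config hashing).
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
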
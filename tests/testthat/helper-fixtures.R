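# Shared fixture builders. Everything is generated in code; nothing binary.

# A hit table with the 15 FoldSeek columns, all values already quantized to
# the precision the TSV writer uses, so write/read round-trips are exact.
make_hits <- function(n, seed = 1, query = NULL) {
  withr::with_seed(seed, {
    q <- if (is.null(query)) sprintf("Q%02d", sample.int(5L, n, replace = TRUE)) else rep(query, n)
    qstart <- sample.int(50L, n, replace = TRUE)
    qend <- qstart + sample.int(40L, n, replace = TRUE)
    data.frame(
      query = q,
      target = sprintf("T%04d", seq_len(n)),
      fident = as.numeric(sprintf("%.4f", runif(n))),
      alnlen = qend - qstart + 5L,
      mismatch = sample(0:20, n, replace = TRUE),
      gapopen = sample(0:4, n, replace = TRUE),
      qstart = qstart, qend = qend,
      tstart = qstart, tend = qend,
      evalue = as.numeric(sprintf("%.3e", 10^runif(n, -15, 0))),
      bits = as.numeric(sprintf("%.1f", runif(n, 30, 500))),
      prob = as.numeric(sprintf("%.3f", runif(n))),
      lddt = as.numeric(sprintf("%.3f", runif(n))),
      lddtfull = replicate(n, paste(sprintf("%.3f", runif(3)), collapse = ",")),
      stringsAsFactors = FALSE)
  })
}

# Sorted single-query hit table with prescribed header tiers, plus the
# header database mapping each target to a label of that tier.
make_tiered_hits <- function(labels, db = "AFDB", bits_start = 300) {
  n <- length(labels)
  hits <- data.frame(
    query = rep("Q01", n), target = sprintf("T%03d", seq_len(n)),
    fident = rep(0.5, n), alnlen = rep(50L, n), mismatch = rep(5L, n),
    gapopen = rep(1L, n), qstart = rep(1L, n), qend = rep(50L, n),
    tstart = rep(1L, n), tend = rep(50L, n),
    evalue = rep(1e-10, n), bits = bits_start - 10 * seq_len(n),
    prob = rep(0.9, n), lddt = rep(0.8, n),
    lddtfull = rep("0.8,0.8", n), stringsAsFactors = FALSE)
  header_db <- list(db = db, labels = stats::setNames(labels, hits$target))
  list(hits = hits, header_db = header_db)
}

make_records <- function(lengths, ids = NULL, description = "hypothetical protein") {
  n <- length(lengths)
  ids <- ids %||% sprintf("P%03d", seq_len(n))
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "D", "E", "F", "G"), L, replace = TRUE), collapse = "")
  }, character(1L))
  data.frame(protein_id = ids, description = description, sequence = seqs,
             length = lengths, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact one-sided Mann-Whitney p by exhaustive enumeration over all
# assignments of the pooled observations to the two groups (tie-free case).
# Independent of the package's wilcox.test-backed implementation.
mw_exact_enum <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  picks <- utils::combn(length(pooled), n)
  u_all <- apply(picks, 2L, function(ix) u_of(pooled[ix], pooled[-ix]))
  if (alternative == "less") mean(u_all <= u_obs) else mean(u_all >= u_obs)
}
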
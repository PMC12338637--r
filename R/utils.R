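# Internal helpers shared across modules.

# Quantize a numeric vector through a fixed-precision text representation so
# the in-memory value is bit-identical to what a reader recovers from file.
quantize <- function(x, digits = 2L) {
  as.numeric(sprintf(paste0("%.", digits, "f"), x))
}

quantize_sci <- function(x, digits = 3L) {
  as.numeric(sprintf(paste0("%.", digits, "e"), x))
}

# Locale-independent ordering (C collation), so reports are reproducible
# regardless of LC_COLLATE.
radix_order <- function(...) order(..., method = "radix")

radix_sort <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.frame construction without the deparse/row-name overhead of
# data.frame(); used on hot per-cluster paths.
fast_df <- function(...) {
  cols <- list(...)
  n <- length(cols[[1L]])
  structure(cols, class = "data.frame",
            row.names = if (n == 0L) integer() else c(NA_integer_, -n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Tier machinery: total order NONE < LOW < HIGH used by every preference rule.
TIER_LEVELS <- c("NONE", "LOW", "HIGH")

tier_rank <- function(tier) {
  r <- match(tier, TIER_LEVELS)
  if (anyNA(r)) stopf("unknown annotation tier: %s",
                      paste(unique(tier[is.na(r)]), collapse = ", "))
  r
}

DB_TAGS <- c("PDB", "AFDB", "PHOLD")

# Run an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
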
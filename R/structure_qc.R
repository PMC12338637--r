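#' Mean per-protein pLDDT
#'
#' @param profile Numeric per-residue pLDDT vector (0-100 scale).
#' @return Arithmetic mean over residues.
#' @export
mean_plddt <- function(profile) {
  if (length(profile) == 0L) stopf("empty pLDDT profile")
  mean(profile)
}

#' Per-position MSA depth of an A3M alignment
#'
#' Depth at query position i is the number of sequences (query included)
#' with a non-gap residue aligned at i. `mode = "sequences"` instead reports
#' the raw sequence count of the alignment as the maximum (the two coincide
#' whenever at least one column is fully occupied).
#'
#' @param msa Alignment from [read_a3m()] (sequences in query coordinates).
#' @param mode `"coverage"` (per-position non-gap count, default) or
#'   `"sequences"`.
#' @return list with `depths` (integer per query position) and `max_depth`.
#' @export
msa_depth_profile <- function(msa, mode = c("coverage", "sequences")) {
  mode <- match.arg(mode)
  seqs <- msa$seqs
  if (length(seqs) == 0L) stopf("empty alignment")
  qlen <- nchar(seqs[1L])
  raw <- charToRaw(paste(seqs, collapse = ""))
  m <- matrix(raw, nrow = qlen)
  gap <- charToRaw("-")
  depths <- as.integer(rowSums(matrix(m != gap, nrow = qlen)))
  max_depth <- if (mode == "coverage") max(depths) else length(seqs)
  list(depths = depths, max_depth = max_depth)
}

#' Assemble the per-protein structure-quality table
#'
#' @param profiles Named list `protein_id -> pLDDT profile`.
#' @param msas Named list `protein_id -> A3M alignment` ([read_a3m()]);
#'   identifiers must match `profiles`.
#' @param depth_mode Passed to [msa_depth_profile()].
#' @return data.frame (`protein_id`, `length`, `mean_plddt`,
#'   `max_msa_depth`), ordered by protein id (C collation).
#' @export
structure_qc_table <- function(profiles, msas, depth_mode = "coverage") {
  ids <- radix_sort(names(profiles))
  missing <- setdiff(ids, names(msas))
  if (length(missing) > 0L) {
    stopf("no MSA for protein(s): %s", paste(utils::head(missing, 3L), collapse = ", "))
  }
  data.frame(
    protein_id = ids,
    length = vapply(profiles[ids], length, integer(1L)),
    mean_plddt = vapply(profiles[ids], mean_plddt, numeric(1L)),
    max_msa_depth = vapply(msas[ids], function(m) msa_depth_profile(m, depth_mode)$max_depth,
                           integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Contrast prediction quality across an MSA-depth threshold
#'
#' Splits proteins at `max_msa_depth >= threshold` and compares mean pLDDT
#' between the deep and shallow groups with a one-sided Mann-Whitney U test
#' (alternative: the deep group is stochastically larger).
#'
#' @param qc QC table from [structure_qc_table()].
#' @param threshold Depth tipping point (default 10 sequences).
#' @return A [mann_whitney_one_sided()] group comparison, deep group first.
#' @export
depth_contrast <- function(qc, threshold = 10L) {
  deep <- qc$mean_plddt[qc$max_msa_depth >= threshold]
  shallow <- qc$mean_plddt[qc$max_msa_depth < threshold]
  if (length(deep) < 2L) stopf("fewer than 2 proteins with MSA depth >= %d", threshold)
  if (length(shallow) < 2L) stopf("fewer than 2 proteins with MSA depth < %d", threshold)
  mann_whitney_one_sided(deep, shallow, alternative = "greater",
                         group_labels = c(sprintf("depth>=%d", threshold),
                                          sprintf("depth<%d", threshold)))
}

#' Length-pLDDT correlation with binning and resampling
#'
#' Bins protein lengths into half-open windows `[origin + k*w, origin +
#' (k+1)*w)` and measures the squared Pearson correlation between length and
#' mean pLDDT either pooled (`raw`), within each bin (`per_bin`), or pooled
#' after balancing bin occupancy by undersampling (without replacement, to
#' the smallest bin) or oversampling (with replacement, to the largest bin).
#'
#' @param qc QC table from [structure_qc_table()].
#' @param bin_width Bin width in residues (default 50).
#' @param mode `"raw"`, `"per_bin"`, `"undersample"` or `"oversample"`.
#' @param seed Integer seed, required for the resampling modes; the
#'   caller's RNG state is left untouched.
#' @param origin Left edge of the first bin (default 100, the size-filter
#'   minimum).
#' @param min_bin_n Bins with fewer records are excluded from per-bin and
#'   resampled statistics (default 3).
#' @return list of class `binned_correlation` with `mode`, `pooled_r2`
#'   (raw/resampled modes), `bins` (per-bin data.frame), `max_r2` and
#'   `mean_r2` (per-bin mode).
#' @export
binned_length_correlation <- function(qc, bin_width = 50L,
                                      mode = c("raw", "per_bin", "undersample", "oversample"),
                                      seed = NULL, origin = 100L, min_bin_n = 3L) {
  mode <- match.arg(mode)
  x <- qc$length
  y <- qc$mean_plddt
  if (length(x) < 3L) stopf("need at least 3 records for a correlation")
  bin <- floor((x - origin) / bin_width)
  bins_present <- radix_sort(unique(bin))
  out <- list(mode = mode, bin_width = bin_width, origin = origin,
              pooled_r2 = NA_real_, bins = NULL,
              max_r2 = NA_real_, mean_r2 = NA_real_)
  if (mode == "raw") {
    out$pooled_r2 <- correlation_r2(x, y, "pearson")
  } else if (mode == "per_bin") {
    if (length(bins_present) < 2L) {
      stopf("all records fall in a single length bin; per-bin correlation is degenerate")
    }
    r2 <- vapply(bins_present, function(b) {
      xi <- x[bin == b]; yi <- y[bin == b]
      if (length(xi) < min_bin_n || stats::sd(xi) == 0 || stats::sd(yi) == 0) return(NA_real_)
      correlation_r2(xi, yi, "pearson")
    }, numeric(1L))
    out$bins <- data.frame(bin_start = origin + bins_present * bin_width,
                           n = vapply(bins_present, function(b) sum(bin == b), integer(1L)),
                           r2 = r2, stringsAsFactors = FALSE)
    ok <- !is.na(r2)
    if (!any(ok)) stopf("no length bin has enough non-degenerate records for a correlation")
    out$max_r2 <- max(r2[ok])
    out$mean_r2 <- mean(r2[ok])
  } else {
    if (is.null(seed)) stopf("resampling mode '%s' requires a seed", mode)
    keep <- bin %in% bins_present[vapply(bins_present, function(b) sum(bin == b), integer(1L)) >= min_bin_n]
    xb <- x[keep]; yb <- y[keep]; bb <- bin[keep]
    counts <- table(bb)
    target <- if (mode == "undersample") min(counts) else max(counts)
    idx <- with_seed(seed, {
      unlist(lapply(radix_sort(unique(bb)), function(b) {
        ib <- which(bb == b)
        if (mode == "undersample") sample(ib, target, replace = FALSE)
        else sample(ib, target, replace = TRUE)
      }))
    })
    out$pooled_r2 <- correlation_r2(xb[idx], yb[idx], "pearson")
  }
  structure(out, class = "binned_correlation")
}

#' @export
print.binned_correlation <- function(x, ...) {
  cat(sprintf("Length-pLDDT correlation (%s mode, bin width %d aa)\n", x$mode, x$bin_width))
  if (!is.na(x$pooled_r2)) cat(sprintf("  pooled Pearson R^2 = %.4f\n", x$pooled_r2))
  if (!is.null(x$bins)) {
    cat(sprintf("  %d bins; max R^2 = %.4f, mean R^2 = %.4f\n",
                nrow(x$bins), x$max_r2, x$mean_r2))
  }
  invisible(x)
}

#' Write the QC table as TSV
#' @param qc QC table from [structure_qc_table()].
#' @param path Output path.
#' @export
write_qc_tsv <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
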
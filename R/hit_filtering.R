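#' Hit filter thresholds
#'
#' The two-stage FoldSeek hit filter: significance retains hits with
#' E-value strictly below `evalue_max`; the quality stage retains hits with
#' alignment lDDT strictly above `min_aln_lddt`, mean query pLDDT over the
#' aligned fraction strictly above `min_aligned_query_plddt` and
#' same-SCOP-class probability strictly above `min_same_scop_prob`.
#' Boundary values are removed on every axis.
#'
#' @param evalue_max Retain `evalue < evalue_max` (default 0.001).
#' @param min_aln_lddt Retain `lddt > min_aln_lddt` (default 0.5).
#' @param min_aligned_query_plddt Retain aligned-fraction mean pLDDT
#'   strictly above this (default 70, on the 0-100 scale).
#' @param min_same_scop_prob Retain `prob > min_same_scop_prob` (default 0.5).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(evalue_max = 0.001, min_aln_lddt = 0.5,
                              min_aligned_query_plddt = 70,
                              min_same_scop_prob = 0.5) {
  stopifnot(is.finite(evalue_max), is.finite(min_aln_lddt),
            is.finite(min_aligned_query_plddt), is.finite(min_same_scop_prob),
            min_aln_lddt >= 0, min_aln_lddt <= 1,
            min_same_scop_prob >= 0, min_same_scop_prob <= 1)
  structure(list(evalue_max = evalue_max, min_aln_lddt = min_aln_lddt,
                 min_aligned_query_plddt = min_aligned_query_plddt,
                 min_same_scop_prob = min_same_scop_prob),
            class = "filter_thresholds")
}

#' Significance filter on FoldSeek hits
#'
#' @param hits Hit table ([read_foldseek_tsv()]).
#' @param thresholds [filter_thresholds()].
#' @return Hits with `evalue` strictly below the cutoff; row order preserved.
#' @export
significance_filter <- function(hits, thresholds = filter_thresholds()) {
  hits[hits$evalue < thresholds$evalue_max, , drop = FALSE]
}

#' Mean query pLDDT over the aligned fraction of a hit
#'
#' Arithmetic mean of the query's per-residue pLDDT over the 1-based
#' inclusive range `qstart..qend` of the hit.
#'
#' @param qstart,qend 1-based inclusive query coordinates.
#' @param profile Per-residue pLDDT profile of the query.
#' @param hit_id Identifier used in error messages.
#' @return Mean pLDDT of the aligned query residues.
#' @export
aligned_query_mean_plddt <- function(qstart, qend, profile, hit_id = "<hit>") {
  if (qend > length(profile)) {
    stopf("hit %s: qend %d exceeds query profile length %d", hit_id, qend, length(profile))
  }
  if (qstart < 1L) stopf("hit %s: qstart %d < 1", hit_id, qstart)
  mean(profile[qstart:qend])
}

#' Quality filter on FoldSeek hits
#'
#' Removes poor alignments (alignment lDDT at or below the cutoff, aligned
#' query mean pLDDT at or below the cutoff) and hits unlikely to share the
#' query's function (same-SCOP-class probability at or below the cutoff).
#' By default the aligned-fraction pLDDT comes from the query structure's
#' own profile; `plddt_source = "lddtfull"` instead averages the hit's
#' per-position alignment lDDT values (rescaled to 0-100).
#'
#' @param hits Hit table.
#' @param profiles Named list `query id -> per-residue pLDDT profile`.
#'   Every query in `hits` must have a profile (missing profiles are an
#'   error, never a silent pass-through).
#' @param thresholds [filter_thresholds()].
#' @param plddt_source `"structure"` (default) or `"lddtfull"`.
#' @return Filtered hits; row order preserved.
#' @export
quality_filter <- function(hits, profiles, thresholds = filter_thresholds(),
                           plddt_source = c("structure", "lddtfull")) {
  plddt_source <- match.arg(plddt_source)
  if (nrow(hits) == 0L) return(hits)
  if (plddt_source == "structure") {
    missing <- setdiff(unique(hits$query), names(profiles))
    if (length(missing) > 0L) {
      stopf("no pLDDT profile for query(ies): %s",
            paste(utils::head(missing, 3L), collapse = ", "))
    }
    aln_mean <- vapply(seq_len(nrow(hits)), function(i) {
      aligned_query_mean_plddt(hits$qstart[i], hits$qend[i],
                               profiles[[hits$query[i]]],
                               hit_id = paste(hits$query[i], hits$target[i], sep = "->"))
    }, numeric(1L))
  } else {
    aln_mean <- vapply(parse_lddtfull(hits$lddtfull), function(v) {
      if (length(v) == 0L) return(NA_real_)
      mean(v) * 100
    }, numeric(1L))
    aln_mean[is.na(aln_mean)] <- -Inf
  }
  keep <- hits$lddt > thresholds$min_aln_lddt &
    aln_mean > thresholds$min_aligned_query_plddt &
    hits$prob > thresholds$min_same_scop_prob
  hits[keep, , drop = FALSE]
}

#' Canonical hit ordering
#'
#' Sorts hits by descending bitscore; ties are broken by ascending E-value,
#' then ascending target identifier (C collation), making the order
#' deterministic across runs and platforms.
#'
#' @param hits Hit table.
#' @return The same rows in canonical order.
#' @export
sort_hits <- function(hits) {
  hits[radix_order(-hits$bits, hits$evalue, hits$target), , drop = FALSE]
}

#' Per-cluster hit presence across databases
#'
#' For each cluster (represented by its query protein) and each database,
#' records whether at least one significance-filtered hit survives, and
#' tallies all 2^k membership patterns (the UpSet-plot counts).
#'
#' @param hits_by_db Named list of significance-filtered hit tables, names
#'   are database tags (e.g. `PDB`, `AFDB`, `PHOLD`).
#' @param clusters Character vector of cluster representative ids. Hits
#'   whose query is not among them are an error.
#' @return list with `membership` (data.frame `cluster_id` + one logical
#'   column per database, ordered by cluster id) and `pattern_counts`
#'   (named integer vector over all patterns, names like `"PDB+AFDB"`,
#'   `"none"`; sums to `length(clusters)`).
#' @export
per_cluster_hit_presence <- function(hits_by_db, clusters) {
  dbs <- names(hits_by_db)
  if (is.null(dbs) || any(!nzchar(dbs))) stopf("hits_by_db must be a named list")
  ids <- radix_sort(clusters)
  membership <- data.frame(cluster_id = ids, stringsAsFactors = FALSE)
  for (db in dbs) {
    q <- unique(hits_by_db[[db]]$query)
    unknown <- setdiff(q, clusters)
    if (length(unknown) > 0L) {
      stopf("%s hits reference unknown cluster representative(s): %s", db,
            paste(utils::head(unknown, 3L), collapse = ", "))
    }
    membership[[db]] <- ids %in% q
  }
  pat <- apply(as.matrix(membership[, dbs, drop = FALSE]), 1L, function(row) {
    if (!any(row)) "none" else paste(dbs[row], collapse = "+")
  })
  all_patterns <- c("none", unlist(lapply(seq_along(dbs), function(k) {
    apply(utils::combn(dbs, k), 2L, paste, collapse = "+")
  })))
  counts <- vapply(all_patterns, function(p) sum(pat == p), integer(1L))
  list(membership = membership, pattern_counts = counts)
}
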
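# End-to-end pipeline over a bundle directory, and the closed-form report
# computed from a truth manifest. The two must agree exactly on synthetic
# bundles; that equivalence is the package's central validation property.

pattern_names <- function(dbs) {
  c("none", unlist(lapply(seq_along(dbs), function(k) {
    apply(utils::combn(dbs, k), 2L, paste, collapse = "+")
  })))
}

# Group comparison that records degeneracy (a side with < 2 observations)
# instead of failing, so whole-report generation always completes.
safe_contrast <- function(x, y, alternative, group_labels) {
  if (length(x) < 2L || length(y) < 2L) {
    return(structure(list(groups = group_labels, n = c(length(x), length(y)),
                          degenerate = TRUE), class = "group_comparison"))
  }
  mann_whitney_one_sided(x, y, alternative = alternative, group_labels = group_labels)
}

sort_calls <- function(calls) {
  calls <- calls[radix_order(calls$method, calls$db, calls$cluster_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

# Report pieces computed identically by both routes once the per-cluster
# facts are known: `facts` has one row per cluster with cluster_id, size,
# seq_annotated, length, max_msa_depth, mean_plddt and presence_<db> flags,
# ordered by cluster id.
assemble_report <- function(facts, filter_counts, calls, bin_width = 50L,
                            depth_threshold = 10L, top_k = 10L) {
  tu <- !facts$seq_annotated
  partition <- data.frame(protein_id = facts$cluster_id,
                          status = ifelse(facts$seq_annotated, "annotated", "truly_unannotated"),
                          stringsAsFactors = FALSE)
  dataset <- list(
    n_clusters = nrow(facts),
    n_proteins = sum(facts$size),
    n_truly_unannotated = sum(tu),
    n_seq_annotated = sum(!tu),
    n_proteins_truly_unannotated = sum(facts$size[tu]),
    n_proteins_seq_annotated = sum(facts$size[!tu]))

  pres <- as.matrix(facts[tu, paste0("presence_", DB_TAGS), drop = FALSE])
  colnames(pres) <- DB_TAGS
  pat <- apply(pres, 1L, function(row) if (!any(row)) "none" else paste(DB_TAGS[row], collapse = "+"))
  pattern_counts <- vapply(pattern_names(DB_TAGS), function(p) sum(pat == p), integer(1L))
  any_hit <- rowSums(pres) > 0
  membership <- list(
    pattern_counts = pattern_counts,
    per_db_rate = stats::setNames(colMeans(pres), DB_TAGS),
    any_rate = mean(any_hit),
    any_rate_proteins = sum(facts$size[tu][any_hit]) / sum(facts$size[tu]))

  calls <- sort_calls(calls)
  annotation <- annotation_report(calls, partition, top_k = top_k)

  qc_df <- data.frame(length = facts$length, mean_plddt = facts$mean_plddt,
                      max_msa_depth = facts$max_msa_depth)
  deep <- qc_df$mean_plddt[qc_df$max_msa_depth >= depth_threshold]
  shal <- qc_df$mean_plddt[qc_df$max_msa_depth < depth_threshold]
  qc <- list(
    mean_plddt_mean = mean(facts$mean_plddt),
    mean_plddt_sd = stats::sd(facts$mean_plddt),
    median_max_depth = stats::median(facts$max_msa_depth),
    depth_contrast = safe_contrast(deep, shal, "greater",
                                   c(sprintf("depth>=%d", depth_threshold),
                                     sprintf("depth<%d", depth_threshold))),
    length_corr_raw_r2 = correlation_r2(facts$length, facts$mean_plddt, "pearson"),
    length_corr_binned = local({
      b <- binned_length_correlation(qc_df, bin_width = bin_width, mode = "per_bin")
      list(max_r2 = b$max_r2, mean_r2 = b$mean_r2)
    }))

  ## structure-annotated = joint UniProt-supplemented best-annotated-hit call
  ju <- calls[calls$method == "BAH_UP" & calls$db == "JOINT", , drop = FALSE]
  struct_ann <- facts$cluster_id %in% ju$cluster_id[ju$tier != "NONE"]
  contrasts <- list(
    length_by_seq_annotation = safe_contrast(
      facts$length[!tu], facts$length[tu], "greater", c("seq-annotated", "truly unannotated")),
    size_by_seq_annotation = safe_contrast(
      facts$size[!tu], facts$size[tu], "greater", c("seq-annotated", "truly unannotated")),
    plddt_by_hit = safe_contrast(
      facts$mean_plddt[tu][any_hit], facts$mean_plddt[tu][!any_hit], "greater",
      c("with hits", "without hits")),
    depth_by_hit = safe_contrast(
      facts$max_msa_depth[tu][any_hit], facts$max_msa_depth[tu][!any_hit], "greater",
      c("with hits", "without hits")),
    size_by_hit = safe_contrast(
      facts$size[tu][any_hit], facts$size[tu][!any_hit], "greater",
      c("with hits", "without hits")),
    length_by_struct_annotation = safe_contrast(
      facts$length[tu & struct_ann], facts$length[tu & !struct_ann], "greater",
      c("structure-annotated", "unannotated")),
    plddt_by_struct_annotation = safe_contrast(
      facts$mean_plddt[tu & struct_ann], facts$mean_plddt[tu & !struct_ann], "greater",
      c("structure-annotated", "unannotated")),
    depth_by_struct_annotation = safe_contrast(
      facts$max_msa_depth[tu & struct_ann], facts$max_msa_depth[tu & !struct_ann], "greater",
      c("structure-annotated", "unannotated")))

  structure(list(dataset = dataset, filtering = filter_counts,
                 membership = membership, annotation = annotation,
                 qc = qc, contrasts = contrasts, calls = calls),
            class = "annotation_pipeline_report")
}

#' Run the full structure-informed annotation pipeline on a bundle directory
#'
#' Reads every input from `dir` (the layout written by [simulate_bundle()]:
#' `proteins.fasta`, `clusters.tsv`, `annotations_seq.tsv`,
#' `structures/<rep>.pdb`, `msas/<rep>.a3m`, `foldseek_<db>.tsv`,
#' `headers_<db>.tsv`, `idmap.tsv`), applies the truly-unannotated split,
#' structure QC, two-stage hit filtering, canonical sorting, all four
#' single-hit annotation strategies per database plus the joint
#' combination, and assembles the report.
#'
#' @param dir Bundle directory.
#' @param thresholds [filter_thresholds()].
#' @param ruleset [annotation_ruleset()].
#' @param params [curation_params()] (patterns used by the
#'   truly-unannotated split).
#' @param dialect Annotation-table dialect for `annotations_seq.tsv`.
#' @param depth_mode Passed to [msa_depth_profile()].
#' @param bin_width,depth_threshold,top_k Report parameters.
#' @return list of class `annotation_pipeline_report` with elements
#'   `dataset`, `filtering`, `membership`, `annotation`, `qc`, `contrasts`
#'   and the full `calls` table.
#' @export
run_pipeline <- function(dir, thresholds = filter_thresholds(),
                         ruleset = annotation_ruleset(),
                         params = curation_params(), dialect = "generic",
                         depth_mode = "coverage", bin_width = 50L,
                         depth_threshold = 10L, top_k = 10L) {
  clusters <- read_cluster_tsv(file.path(dir, "clusters.tsv"))
  records <- read_fasta(file.path(dir, "proteins.fasta"))
  seq_annot <- read_annotation_table(file.path(dir, "annotations_seq.tsv"), dialect)
  split <- split_truly_unannotated(clusters, seq_annot, params)
  ids <- radix_sort(names(clusters))

  profiles <- lapply(ids, function(id) {
    read_plddt(file.path(dir, "structures", paste0(id, ".pdb")))$plddt
  })
  names(profiles) <- ids
  msas <- lapply(ids, function(id) read_a3m(file.path(dir, "msas", paste0(id, ".a3m"))))
  names(msas) <- ids
  qc <- structure_qc_table(profiles, msas, depth_mode = depth_mode)

  headers <- lapply(stats::setNames(DB_TAGS, DB_TAGS), function(db) {
    read_header_table(file.path(dir, sprintf("headers_%s.tsv", tolower(db))), db)
  })
  idmap <- read_idmap(file.path(dir, "idmap.tsv"))

  sig_by_db <- list()
  sorted_by_query <- list()
  filter_counts <- data.frame(db = DB_TAGS, n_raw = 0L, n_significant = 0L,
                              n_quality = 0L, stringsAsFactors = FALSE)
  for (db in DB_TAGS) {
    raw <- read_foldseek_tsv(file.path(dir, sprintf("foldseek_%s.tsv", tolower(db))))
    sig <- significance_filter(raw, thresholds)
    qual <- quality_filter(sig, profiles, thresholds)
    srt <- sort_hits(qual)
    filter_counts[filter_counts$db == db, c("n_raw", "n_significant", "n_quality")] <-
      c(nrow(raw), nrow(sig), nrow(qual))
    sig_by_db[[db]] <- sig
    sorted_by_query[[db]] <- split(srt, factor(srt$query, levels = ids))
  }

  ## membership over truly unannotated clusters
  tu_ids <- split$truly_unannotated
  sig_tu <- lapply(sig_by_db, function(h) h[h$query %in% tu_ids, , drop = FALSE])
  presence <- per_cluster_hit_presence(sig_tu, tu_ids)

  ## annotation calls: four strategies per database, then joint per method
  empty_sorted <- empty_foldseek_hits()
  acc <- vector("list", length(ids) * length(DB_TAGS))
  k <- 0L
  for (db in DB_TAGS) {
    hdb <- headers[[db]]
    per_q <- sorted_by_query[[db]]
    for (id in ids) {
      h <- per_q[[id]]
      if (is.null(h)) h <- empty_sorted
      k <- k + 1L
      acc[[k]] <- strategy_calls(h, hdb, ruleset, id, idmap = idmap)
    }
  }
  cols <- lapply(stats::setNames(nm = names(acc[[1L]])), function(nm) {
    unlist(lapply(acc, `[[`, nm), use.names = FALSE)
  })
  calls <- do.call(calls_to_df_cols, cols)
  calls <- rbind(calls, joint_calls(calls))
  rownames(calls) <- NULL

  ## per-cluster facts for the report
  sizes <- cluster_sizes(clusters)[ids]
  facts <- data.frame(cluster_id = ids, size = as.integer(unname(sizes)),
                      seq_annotated = ids %in% split$annotated,
                      length = qc$length[match(ids, qc$protein_id)],
                      max_msa_depth = qc$max_msa_depth[match(ids, qc$protein_id)],
                      mean_plddt = qc$mean_plddt[match(ids, qc$protein_id)],
                      stringsAsFactors = FALSE)
  for (db in DB_TAGS) {
    facts[[paste0("presence_", db)]] <-
      ids %in% unique(sig_by_db[[db]]$query)
  }
  report <- assemble_report(facts, filter_counts, calls, bin_width = bin_width,
                            depth_threshold = depth_threshold, top_k = top_k)
  # sanity: UpSet counts from the shared facts must equal the dedicated
  # presence accounting on significance-filtered hits
  stopifnot(identical(report$membership$pattern_counts,
                      {
                        m <- presence$membership
                        pm <- as.matrix(m[, DB_TAGS, drop = FALSE])
                        pat <- apply(pm, 1L, function(row) if (!any(row)) "none" else paste(DB_TAGS[row], collapse = "+"))
                        vapply(pattern_names(DB_TAGS), function(p) sum(pat == p), integer(1L))
                      }))
  report
}

#' Closed-form expected report from a truth manifest
#'
#' Computes, from the planted truth alone (no file parsing, no filtering,
#' no hit selection), the exact report [run_pipeline()] must produce on the
#' bundle the manifest describes.
#'
#' @param manifest Manifest from [simulate_bundle()].
#' @param bin_width,depth_threshold,top_k Must match the pipeline call.
#' @return list of class `annotation_pipeline_report`.
#' @export
expected_report <- function(manifest, bin_width = 50L, depth_threshold = 10L,
                            top_k = 10L) {
  cl <- manifest$clusters
  cl <- cl[radix_order(cl$cluster_id), , drop = FALSE]
  facts <- data.frame(cluster_id = cl$cluster_id, size = as.integer(cl$size),
                      seq_annotated = cl$seq_annotated,
                      length = as.integer(cl$length),
                      max_msa_depth = as.integer(cl$max_msa_depth),
                      mean_plddt = cl$mean_plddt,
                      stringsAsFactors = FALSE)
  for (db in DB_TAGS) facts[[paste0("presence_", db)]] <- cl[[paste0("presence_", db)]]
  assemble_report(facts, manifest$filter_counts, manifest$calls,
                  bin_width = bin_width, depth_threshold = depth_threshold,
                  top_k = top_k)
}

#' @export
print.annotation_pipeline_report <- function(x, ...) {
  d <- x$dataset
  cat(sprintf("Structure-informed annotation report\n"))
  cat(sprintf("  %d clusters (%d proteins); %d truly unannotated, %d sequence-annotated\n",
              d$n_clusters, d$n_proteins, d$n_truly_unannotated, d$n_seq_annotated))
  cat(sprintf("  mean per-protein pLDDT %.2f +/- %.2f; median MSA depth %d\n",
              x$qc$mean_plddt_mean, x$qc$mean_plddt_sd, x$qc$median_max_depth))
  cat(sprintf("  hit presence (truly unannotated): %s; any database %.1f%% of clusters (%.1f%% of proteins)\n",
              paste(sprintf("%s %.1f%%", names(x$membership$per_db_rate),
                            100 * x$membership$per_db_rate), collapse = ", "),
              100 * x$membership$any_rate, 100 * x$membership$any_rate_proteins))
  r <- x$annotation$rates
  tu <- r[r$denominator == "truly_unannotated", ]
  for (m in unique(tu$method)) {
    rm_ <- tu[tu$method == m, ]
    cat(sprintf("  %-7s %s\n", m,
                paste(sprintf("%s %.1f%%", rm_$db, 100 * rm_$rate), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a pipeline report as a directory of TSV files plus a summary
#'
#' @param report Report from [run_pipeline()] or [expected_report()].
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$filtering, file.path(dir, "filter_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$annotation$rates, file.path(dir, "annotation_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$annotation$top_labels, file.path(dir, "top_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_calls_tsv(report$calls, file.path(dir, "annotation_calls.tsv"))
  mem <- report$membership
  utils::write.table(
    data.frame(pattern = names(mem$pattern_counts), count = unname(mem$pattern_counts)),
    file.path(dir, "upset_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  keyvals <- c(
    n_clusters = report$dataset$n_clusters,
    n_proteins = report$dataset$n_proteins,
    n_truly_unannotated = report$dataset$n_truly_unannotated,
    mean_plddt_mean = report$qc$mean_plddt_mean,
    mean_plddt_sd = report$qc$mean_plddt_sd,
    median_max_depth = report$qc$median_max_depth,
    any_hit_rate = mem$any_rate,
    any_hit_rate_proteins = mem$any_rate_proteins)
  writeLines(paste(names(keyvals), unname(keyvals), sep = "\t"),
             file.path(dir, "summary.tsv"))
  invisible(dir)
}
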
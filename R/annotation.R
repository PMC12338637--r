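#' Annotation informativeness ruleset
#'
#' Ordered, case-insensitive regular-expression sets that classify a
#' free-text annotation label into one of three tiers: `NONE`
#' (non-informative, e.g. "hypothetical protein"), `LOW` (named but
#' functionally uninformative, e.g. DUF domains) and `HIGH` (a proper
#' functional annotation). Non-informative patterns take precedence over
#' low-information patterns; anything matching neither set is `HIGH`. The
#' `unknown function` pattern carries a lookbehind so that
#' "domain of unknown function (DUF...)" labels stay in the LOW tier.
#'
#' @param noninformative_patterns Perl-compatible regexes whose match means
#'   tier `NONE`.
#' @param lowinfo_patterns Regexes whose match (absent any non-informative
#'   match) means tier `LOW`.
#' @return list of class `annotation_ruleset`.
#' @seealso [read_ruleset()] for loading a ruleset from a plain-text file.
#' @export
annotation_ruleset <- function(
    noninformative_patterns = c(
      "hypothetical protein",
      "uncharacteri[sz]ed protein",
      "(?<!domain of )unknown function",
      "unannotated",
      "phage protein"),
    lowinfo_patterns = c(
      "DUF[0-9]+",
      "domain of unknown function",
      "^putative protein$",
      "^\\S+ domain-containing protein$")) {
  if (length(noninformative_patterns) == 0L) stopf("non-informative pattern list must be non-empty")
  structure(list(noninformative_patterns = noninformative_patterns,
                 lowinfo_patterns = lowinfo_patterns),
            class = "annotation_ruleset")
}

#' Read an annotation ruleset from a plain-text pattern file
#'
#' One pattern per line, `TIER<TAB>regex`, where TIER is `NONE` or `LOW`.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Pattern file path.
#' @return [annotation_ruleset()].
#' @export
read_ruleset <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stopf("ruleset %s: line %d is not 'TIER<TAB>pattern'", path, which(lengths(parts) != 2L)[1L])
  }
  tier <- toupper(vapply(parts, `[[`, character(1L), 1L))
  pat <- vapply(parts, `[[`, character(1L), 2L)
  if (any(!tier %in% c("NONE", "LOW"))) {
    stopf("ruleset %s: unknown tier '%s' (expected NONE or LOW)", path, tier[!tier %in% c("NONE", "LOW")][1L])
  }
  annotation_ruleset(noninformative_patterns = pat[tier == "NONE"],
                     lowinfo_patterns = pat[tier == "LOW"])
}

#' Write an annotation ruleset to a plain-text pattern file
#' @param ruleset [annotation_ruleset()].
#' @param path Output path.
#' @export
write_ruleset <- function(ruleset, path) {
  writeLines(c(paste("NONE", ruleset$noninformative_patterns, sep = "\t"),
               paste("LOW", ruleset$lowinfo_patterns, sep = "\t")), path)
  invisible(path)
}

match_any <- function(label, patterns) {
  hit <- rep(FALSE, length(label))
  for (p in patterns) {
    hit <- hit | grepl(p, label, ignore.case = TRUE, perl = TRUE)
  }
  hit
}

#' Classify an annotation label into an informativeness tier
#'
#' @param label Character vector of free-text labels (NA or empty labels are
#'   `NONE`).
#' @param ruleset [annotation_ruleset()].
#' @return Character vector over `"NONE"`, `"LOW"`, `"HIGH"`.
#' @export
classify_label <- function(label, ruleset = annotation_ruleset()) {
  label <- ifelse(is.na(label), "", label)
  tier <- rep("HIGH", length(label))
  tier[match_any(label, ruleset$lowinfo_patterns)] <- "LOW"
  tier[!nzchar(label) | match_any(label, ruleset$noninformative_patterns)] <- "NONE"
  tier
}

CALL_METHODS <- c("BH", "BAH", "BAH_3T", "BAH_UP")

# Vectorized selection core: all four single-hit strategies on one query's
# sorted, filtered hits. Returns a list of 8 parallel length-4 vectors
# (cluster_id, db, method, label, tier, target, bits, caution), one entry
# per method in CALL_METHODS order.
strategy_calls <- function(sorted_hits, header_db, ruleset, cluster_id,
                           idmap = NULL) {
  h <- sorted_hits
  n <- nrow(h)
  if (n > 0L) {
    lab <- header_labels(header_db, h$target)
    tier <- classify_label(lab, ruleset)
  } else {
    lab <- character()
    tier <- character()
  }
  up_lab <- lab
  up_caut <- rep(FALSE, n)
  if (n > 0L && !is.null(idmap) && nrow(idmap) > 0L) {
    mi <- match(h$target, idmap$target_id)
    repl <- !is.na(mi) & idmap$status[mi] != "unmapped"
    up_lab[repl] <- idmap$protein_name[mi[repl]]
    up_caut[repl] <- idmap$status[mi[repl]] == "removed_uniparc"
  }
  up_tier <- if (n > 0L) classify_label(up_lab, ruleset) else character()

  idx_3t <- which(tier == "HIGH")[1L]
  if (is.na(idx_3t)) idx_3t <- which(tier == "LOW")[1L]
  idx <- c(if (n > 0L) 1L else NA_integer_,   # BH: the top hit, whatever its tier
           which(tier != "NONE")[1L],          # BAH: first informatively labelled
           idx_3t,                             # BAH_3T: first HIGH, else first LOW
           which(up_tier != "NONE")[1L])       # BAH_UP: first informative after supplement
  keep_none_label <- c(TRUE, FALSE, FALSE, FALSE)
  use_up <- c(FALSE, FALSE, FALSE, TRUE)
  label <- target <- rep(NA_character_, 4L)
  tiers <- rep("NONE", 4L)
  bits <- rep(NA_real_, 4L)
  caution <- rep(FALSE, 4L)
  for (j in 1:4) {
    i <- idx[j]
    if (is.na(i)) next
    tj <- if (use_up[j]) up_tier[i] else tier[i]
    if (tj == "NONE" && !keep_none_label[j]) next
    label[j] <- if (use_up[j]) up_lab[i] else lab[i]
    tiers[j] <- tj
    target[j] <- h$target[i]
    bits[j] <- h$bits[i]
    caution[j] <- if (use_up[j]) up_caut[i] else FALSE
  }
  list(cluster_id = rep(cluster_id, 4L), db = rep(header_db$db, 4L),
       method = CALL_METHODS, label = label, tier = tiers, target = target,
       bits = bits, caution = caution)
}

calls_to_df_cols <- function(cluster_id, db, method, label, tier, target,
                             bits, caution) {
  fast_df(cluster_id = cluster_id, db = db, method = method, label = label,
          tier = tier, target = target, bits = bits, caution = caution)
}

calls_to_df <- function(x) do.call(calls_to_df_cols, x)

one_call <- function(sorted_hits, header_db, ruleset, cluster_id, method,
                     idmap = NULL) {
  cluster_id <- cluster_id %||%
    (if (nrow(sorted_hits) > 0L) sorted_hits$query[1L] else NA_character_)
  tab <- calls_to_df(strategy_calls(sorted_hits, header_db, ruleset, cluster_id, idmap))
  out <- tab[tab$method == method, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 'Best hit' annotation transfer
#'
#' Transfers the header annotation of the top-scoring hit, whatever its
#' informativeness; if the top hit's label is non-informative the cluster
#' counts as unannotated (tier `NONE`, label still recorded).
#'
#' @param sorted_hits Hits for one query, in [sort_hits()] order.
#' @param header_db Header annotation database ([read_header_table()]).
#' @param ruleset [annotation_ruleset()].
#' @param cluster_id Cluster identifier for the call (defaults to the query).
#' @return One-row annotation-call data.frame (`cluster_id`, `db`, `method`,
#'   `label`, `tier`, `target`, `bits`, `caution`).
#' @export
best_hit <- function(sorted_hits, header_db, ruleset = annotation_ruleset(),
                     cluster_id = NULL) {
  one_call(sorted_hits, header_db, ruleset, cluster_id, "BH")
}

#' 'Best annotated hit' annotation transfer
#'
#' Transfers the header annotation of the top-scoring hit whose label is
#' informative (tier not `NONE`), skipping non-annotated hits.
#'
#' @inheritParams best_hit
#' @return One-row annotation-call data.frame.
#' @export
best_annotated_hit <- function(sorted_hits, header_db, ruleset = annotation_ruleset(),
                               cluster_id = NULL) {
  one_call(sorted_hits, header_db, ruleset, cluster_id, "BAH")
}

#' Tier-preferring 'best annotated hit' annotation transfer
#'
#' Prefers the top-scoring `HIGH`-tier hit; only if no hit carries a proper
#' annotation does the top `LOW`-tier hit get transferred; otherwise the
#' cluster stays unannotated.
#'
#' @inheritParams best_hit
#' @return One-row annotation-call data.frame.
#' @export
best_annotated_hit_tiered <- function(sorted_hits, header_db,
                                      ruleset = annotation_ruleset(),
                                      cluster_id = NULL) {
  one_call(sorted_hits, header_db, ruleset, cluster_id, "BAH_3T")
}

#' Supplement a hit's label with a UniProt-mapped protein name
#'
#' An `active` mapping replaces the header label with the mapped protein
#' name; a `removed_uniparc` mapping does the same but raises a caution
#' flag (the name was recovered through UniParc after removal of the
#' UniProt entry); an unmapped or absent target keeps the header label.
#'
#' @param target Target identifier of the hit.
#' @param header_label The header annotation of the hit.
#' @param idmap Identifier-mapping table ([read_idmap()]).
#' @return list with `label` and `caution`.
#' @export
supplement_with_idmap <- function(target, header_label, idmap) {
  i <- match(target, idmap$target_id)
  if (is.na(i) || idmap$status[i] == "unmapped") {
    return(list(label = header_label, caution = FALSE))
  }
  list(label = idmap$protein_name[i], caution = idmap$status[i] == "removed_uniparc")
}

#' 'Best annotated hit' with UniProt-supplemented labels
#'
#' Every hit's header label is first supplemented through the identifier
#' map ([supplement_with_idmap()]); the best-annotated-hit selection then
#' runs on the supplemented labels, so hits whose header is uninformative
#' but whose UniProt (or UniParc-recovered) protein name is informative
#' become eligible. UniParc-derived calls carry a caution flag.
#'
#' @inheritParams best_hit
#' @param idmap Identifier-mapping table ([read_idmap()]).
#' @return One-row annotation-call data.frame (method `BAH_UP`).
#' @export
best_annotated_hit_uniprot <- function(sorted_hits, header_db, idmap,
                                       ruleset = annotation_ruleset(),
                                       cluster_id = NULL) {
  one_call(sorted_hits, header_db, ruleset, cluster_id, "BAH_UP", idmap = idmap)
}

DB_PRECEDENCE <- c(PDB = 1L, PHOLD = 2L, AFDB = 3L)

#' Combine per-database annotation calls into a joint call
#'
#' The joint tier is the maximum tier across databases; the representative
#' label is taken from the call with the highest tier, ties broken by
#' database precedence (PDB over Phold over AlphaFold database — the PDB
#' carries experimental evidence), then by descending bitscore.
#'
#' @param calls data.frame of annotation calls for one cluster, at most one
#'   row per database.
#' @return One-row annotation-call data.frame with db `JOINT`.
#' @export
combine_databases <- function(calls) {
  if (nrow(calls) == 0L) stopf("no per-database calls to combine")
  if (length(unique(calls$cluster_id)) != 1L) stopf("calls span multiple clusters")
  if (anyDuplicated(calls$db)) {
    stopf("cluster %s: two calls share database tag %s", calls$cluster_id[1L],
          calls$db[duplicated(calls$db)][1L])
  }
  method <- unique(calls$method)
  if (length(method) != 1L) stopf("calls mix methods: %s", paste(method, collapse = ", "))
  prec <- DB_PRECEDENCE[calls$db]
  if (anyNA(prec)) stopf("unknown database tag: %s", calls$db[is.na(prec)][1L])
  ord <- order(-tier_rank(calls$tier), prec, -ifelse(is.na(calls$bits), -Inf, calls$bits))
  top <- calls[ord[1L], , drop = FALSE]
  none <- top$tier == "NONE"
  fast_df(cluster_id = top$cluster_id, db = "JOINT", method = method,
          label = if (none) NA_character_ else top$label,
          tier = top$tier,
          target = if (none) NA_character_ else top$target,
          bits = if (none) NA_real_ else top$bits,
          caution = if (none) FALSE else top$caution)
}

# Vectorized joint combination over a whole calls table (one row per
# cluster x db x method): per cluster and method, maximum tier wins, label
# ties broken by database precedence then bitscore. combine_databases() is
# the per-cluster unit with identical semantics.
joint_calls <- function(calls) {
  out <- list()
  for (method in unique(calls$method)) {
    mc <- calls[calls$method == method, , drop = FALSE]
    prec <- DB_PRECEDENCE[mc$db]
    if (anyNA(prec)) stopf("unknown database tag: %s", mc$db[is.na(prec)][1L])
    bitsf <- ifelse(is.na(mc$bits), -Inf, mc$bits)
    ord <- radix_order(mc$cluster_id, -tier_rank(mc$tier), prec, -bitsf)
    sel <- ord[!duplicated(mc$cluster_id[ord])]
    none <- mc$tier[sel] == "NONE"
    out[[method]] <- fast_df(
      cluster_id = mc$cluster_id[sel],
      db = rep("JOINT", length(sel)),
      method = rep(method, length(sel)),
      label = ifelse(none, NA_character_, mc$label[sel]),
      tier = mc$tier[sel],
      target = ifelse(none, NA_character_, mc$target[sel]),
      bits = ifelse(none, NA_real_, mc$bits[sel]),
      caution = ifelse(none, FALSE, mc$caution[sel]))
  }
  do.call(rbind, out)
}

#' Annotation rate, tier-composition and top-label report
#'
#' @param calls data.frame of annotation calls (any mix of methods and
#'   databases; one row per cluster x db x method).
#' @param partition Partition from [split_truly_unannotated()].
#' @param top_k How many most-common labels to report per method x db.
#' @return list with `rates` (per method x db x denominator: cluster
#'   counts, annotated counts, rate, HIGH/LOW composition, caution count),
#'   and `top_labels` (per method x db over truly unannotated clusters;
#'   ties broken by label, C collation).
#' @export
annotation_report <- function(calls, partition, top_k = 10L) {
  unknown <- setdiff(calls$cluster_id, partition$protein_id)
  if (length(unknown) > 0L) {
    stopf("annotation call(s) reference unknown cluster(s): %s",
          paste(utils::head(unknown, 3L), collapse = ", "))
  }
  status <- partition$status[match(calls$cluster_id, partition$protein_id)]
  denominators <- list(
    truly_unannotated = partition$protein_id[partition$status == "truly_unannotated"],
    seq_annotated = partition$protein_id[partition$status == "annotated"])
  combos <- unique(calls[, c("method", "db")])
  combos <- combos[radix_order(combos$method, combos$db), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- calls$method == combos$method[i] & calls$db == combos$db[i]
    for (den in names(denominators)) {
      ids <- denominators[[den]]
      n_den <- length(ids)
      cc <- calls[sel & calls$cluster_id %in% ids, , drop = FALSE]
      ann <- cc$tier != "NONE"
      rate <- if (n_den == 0L) NA_real_ else sum(ann) / n_den
      rows[[length(rows) + 1L]] <- data.frame(
        method = combos$method[i], db = combos$db[i], denominator = den,
        n_clusters = n_den, n_annotated = sum(ann), rate = rate,
        n_high = sum(cc$tier == "HIGH"), n_low = sum(cc$tier == "LOW"),
        n_caution = sum(cc$caution & ann), stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rows)
  tu <- denominators$truly_unannotated
  top_rows <- list()
  for (i in seq_len(nrow(combos))) {
    cc <- calls[calls$method == combos$method[i] & calls$db == combos$db[i] &
                  calls$cluster_id %in% tu & calls$tier != "NONE", , drop = FALSE]
    if (nrow(cc) == 0L) next
    counts <- table(cc$label)
    lab <- names(counts)
    ord <- radix_order(-as.integer(counts), lab)
    k <- min(top_k, length(lab))
    top_rows[[length(top_rows) + 1L]] <- data.frame(
      method = combos$method[i], db = combos$db[i],
      label = lab[ord][seq_len(k)], count = as.integer(counts)[ord][seq_len(k)],
      stringsAsFactors = FALSE)
  }
  top_labels <- if (length(top_rows) > 0L) do.call(rbind, top_rows) else
    data.frame(method = character(), db = character(), label = character(),
               count = integer(), stringsAsFactors = FALSE)
  rownames(rates) <- NULL
  rownames(top_labels) <- NULL
  list(rates = rates, top_labels = top_labels)
}

#' Write annotation calls as TSV
#' @param calls Annotation-call data.frame.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
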
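#' Curation parameters
#'
#' Dataset-construction settings: the residue size window (100-850,
#' inclusive on both ends) and the ordered, case-insensitive pattern list
#' that defines an "unannotated" NCBI protein name (`hypothetical protein`,
#' `phage protein`).
#'
#' @param min_length,max_length Inclusive residue-count bounds.
#' @param unannotated_patterns Character vector of case-insensitive
#'   substring patterns.
#' @return list of class `curation_params`.
#' @export
curation_params <- function(min_length = 100L, max_length = 850L,
                            unannotated_patterns = c("hypothetical protein",
                                                     "phage protein")) {
  if (min_length > max_length) stopf("min_length (%d) > max_length (%d)", min_length, max_length)
  if (length(unannotated_patterns) == 0L) stopf("unannotated pattern list must be non-empty")
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 unannotated_patterns = unannotated_patterns),
            class = "curation_params")
}

#' Is a protein description an "unannotated" label?
#'
#' Case-insensitive substring match of the description against the
#' unannotated-name patterns (`hypothetical protein`, `phage protein` by
#' default).
#'
#' @param description Character vector of free-text protein names.
#' @param params [curation_params()].
#' @return Logical vector.
#' @export
is_unannotated_label <- function(description, params = curation_params()) {
  description <- tolower(description)
  hit <- rep(FALSE, length(description))
  for (p in params$unannotated_patterns) {
    hit <- hit | grepl(tolower(p), description, fixed = TRUE)
  }
  hit
}

#' Retain proteins within the size window
#'
#' @param records Protein record table ([read_fasta()]).
#' @param params [curation_params()]; bounds are inclusive.
#' @return Filtered record table (row order preserved).
#' @export
size_filter <- function(records, params = curation_params()) {
  records[records$length >= params$min_length & records$length <= params$max_length, ,
          drop = FALSE]
}

#' Deduplicate proteins on exact sequence identity
#'
#' Keeps the first-seen record per distinct amino-acid sequence and reports
#' which records each kept one absorbed.
#'
#' @param records Protein record table.
#' @return list with `records` (deduplicated table) and `dedup_map`, a named
#'   list `kept_id -> character vector of duplicate ids` (only sequences
#'   that actually had duplicates appear).
#' @export
deduplicate <- function(records) {
  first <- !duplicated(records$sequence)
  kept <- records[first, , drop = FALSE]
  dedup_map <- list()
  if (any(!first)) {
    kept_of <- kept$protein_id[match(records$sequence[!first], kept$sequence)]
    dedup_map <- split(records$protein_id[!first], factor(kept_of, levels = unique(kept_of)))
    dedup_map <- as.list(dedup_map)
  }
  list(records = kept, dedup_map = dedup_map)
}

#' Split cluster representatives into sequence-annotated and truly unannotated
#'
#' A representative counts as annotated by the sequence-based search iff it
#' is present in the annotation table, its PHROG category is not
#' `"unknown function"`, and its label is not itself an unannotated-name
#' match. Every representative falls in exactly one side.
#'
#' @param cluster_table `cluster_table` from [read_cluster_tsv()].
#' @param seq_annotation Annotation table from [read_annotation_table()].
#' @param params [curation_params()] supplying the unannotated-name patterns.
#' @return list with character vectors `annotated` and `truly_unannotated`
#'   (in cluster-table order) and a `partition` data.frame
#'   (`protein_id`, `status`).
#' @export
split_truly_unannotated <- function(cluster_table, seq_annotation,
                                    params = curation_params()) {
  reps <- names(cluster_table)
  orphans <- setdiff(seq_annotation$protein_id, reps)
  if (length(orphans) > 0L) {
    stopf("annotation table contains %d protein(s) that are not cluster representatives: %s",
          length(orphans), paste(utils::head(orphans, 3L), collapse = ", "))
  }
  i <- match(reps, seq_annotation$protein_id)
  found <- !is.na(i)
  label <- ifelse(found, seq_annotation$label[i], NA_character_)
  category <- ifelse(found, seq_annotation$category[i], NA_character_)
  annotated <- found & !is.na(category) & tolower(category) != "unknown function" &
    !is_unannotated_label(ifelse(is.na(label), "", label), params)
  list(annotated = reps[annotated],
       truly_unannotated = reps[!annotated],
       partition = data.frame(protein_id = reps,
                              status = ifelse(annotated, "annotated", "truly_unannotated"),
                              stringsAsFactors = FALSE))
}
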
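#' Read a protein FASTA file
#'
#' Parses a FASTA file into a protein record table. The identifier is the
#' first whitespace-delimited token of the header; everything after it is
#' kept verbatim as the description (the NCBI-style free-text protein name
#' used by the curation filters).
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `protein_id`, `description`, `sequence`
#'   and `length` (residue count), one row per record.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_protein_records())
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stopf("FASTA parse error at line 1: expected '>' header, got '%s'", lines[1L])
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  # records with no sequence lines are absent from `seqs`
  all_ids <- as.character(seq_along(headers))
  missing <- setdiff(all_ids, names(seqs))
  if (length(missing) > 0L) {
    line_no <- which(hdr)[as.integer(missing[1L])]
    stopf("FASTA parse error at line %d: record '%s' has an empty sequence",
          line_no, headers[as.integer(missing[1L])])
  }
  seqs <- unname(seqs[all_ids])
  ids <- sub("[ \t].*$", "", headers)
  desc <- ifelse(grepl("[ \t]", headers),
                 sub("^[^ \t]+[ \t]+", "", headers), "")
  if (anyDuplicated(ids)) {
    stopf("duplicated protein identifiers in FASTA: %s",
          paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))], collapse = ", "))
  }
  data.frame(protein_id = ids, description = desc, sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

empty_protein_records <- function() {
  data.frame(protein_id = character(), description = character(),
             sequence = character(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Write a protein record table to FASTA
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(nzchar(records$description),
                paste0(">", records$protein_id, " ", records$description),
                paste0(">", records$protein_id))
  writeLines(as.vector(rbind(hdr, records$sequence)), path)
  invisible(path)
}

FOLDSEEK_COLUMNS <- c("query", "target", "fident", "alnlen", "mismatch",
                      "gapopen", "qstart", "qend", "tstart", "tend",
                      "evalue", "bits", "prob", "lddt", "lddtfull")
.FS_NUMERIC <- c("fident", "evalue", "bits", "prob", "lddt")
.FS_INTEGER <- c("alnlen", "mismatch", "gapopen", "qstart", "qend", "tstart", "tend")

#' Read a FoldSeek 15-column hit table
#'
#' Reads tabular FoldSeek output produced with
#' `--format-output "query,target,fident,alnlen,mismatch,gapopen,qstart,qend,
#' tstart,tend,evalue,bits,prob,lddt,lddtfull"`. FoldSeek writes no header
#' row by default; deposited tables that do carry one can be read with
#' `header = TRUE`. A first row whose E-value field is non-numeric is
#' rejected with an error rather than silently skipped.
#'
#' @param path Path to a tab-separated hit table.
#' @param header Logical; skip a single leading header row.
#' @return data.frame with the 15 FoldSeek columns in search-output order
#'   (`lddtfull` kept as its comma-separated string; see
#'   [parse_lddtfull()]). Row order and count are preserved exactly.
#' @export
read_foldseek_tsv <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_foldseek_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 15L)) {
    bad <- which(nf != 15L)[1L]
    stopf("FoldSeek table %s: row %d has %d fields, expected 15",
          path, bad + as.integer(header), nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 15L, byrow = TRUE)
  colnames(m) <- FOLDSEEK_COLUMNS
  hits <- data.frame(m, stringsAsFactors = FALSE)
  for (col in .FS_NUMERIC) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stopf("FoldSeek table %s: row %d has non-numeric '%s' field: '%s'",
            path, bad + as.integer(header), col, hits[[col]][bad])
    }
    hits[[col]] <- v
  }
  for (col in .FS_INTEGER) {
    v <- suppressWarnings(as.integer(hits[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stopf("FoldSeek table %s: row %d has non-integer '%s' field: '%s'",
            path, bad + as.integer(header), col, hits[[col]][bad])
    }
    hits[[col]] <- v
  }
  validate_foldseek_hits(hits, path)
  hits
}

empty_foldseek_hits <- function() {
  hits <- data.frame(query = character(), target = character(),
                     fident = numeric(), alnlen = integer(),
                     mismatch = integer(), gapopen = integer(),
                     qstart = integer(), qend = integer(),
                     tstart = integer(), tend = integer(),
                     evalue = numeric(), bits = numeric(),
                     prob = numeric(), lddt = numeric(),
                     lddtfull = character(), stringsAsFactors = FALSE)
  hits
}

validate_foldseek_hits <- function(hits, path = "<hits>") {
  chk <- function(ok, what) {
    if (!all(ok)) stopf("FoldSeek table %s: row %d violates %s",
                        path, which(!ok)[1L], what)
  }
  chk(hits$qstart <= hits$qend, "qstart <= qend")
  chk(hits$tstart <= hits$tend, "tstart <= tend")
  chk(hits$fident >= 0 & hits$fident <= 1, "0 <= fident <= 1")
  chk(hits$prob >= 0 & hits$prob <= 1, "0 <= prob <= 1")
  chk(hits$lddt >= 0 & hits$lddt <= 1, "0 <= lddt <= 1")
  chk(hits$evalue >= 0, "evalue >= 0")
  nlddt <- lengths(strsplit(hits$lddtfull, ",", fixed = TRUE))
  nlddt[!nzchar(hits$lddtfull)] <- 0L
  # shorter than alnlen is tolerated (gapped positions omitted), longer is not
  chk(nlddt <= hits$alnlen, "length(lddtfull) <= alnlen")
  invisible(hits)
}

#' Split the per-position alignment lDDT string of a hit into numbers
#'
#' @param lddtfull Character vector of comma-separated lDDT values.
#' @return list of numeric vectors, one per hit.
#' @export
parse_lddtfull <- function(lddtfull) {
  lapply(strsplit(lddtfull, ",", fixed = TRUE), function(x) {
    x <- x[nzchar(x)]
    as.numeric(x)
  })
}

#' Write hits in the FoldSeek 15-column format
#'
#' Numeric fields are written in the fixed precision used throughout the
#' package (E-values in scientific notation), so that write/read round-trips
#' are exact.
#'
#' @param hits Hit table as returned by [read_foldseek_tsv()].
#' @param path Output path.
#' @export
write_foldseek_tsv <- function(hits, path) {
  fmt <- cbind(hits$query, hits$target,
               sprintf("%.4f", hits$fident),
               as.character(hits$alnlen), as.character(hits$mismatch),
               as.character(hits$gapopen), as.character(hits$qstart),
               as.character(hits$qend), as.character(hits$tstart),
               as.character(hits$tend),
               sprintf("%.3e", hits$evalue),
               sprintf("%.1f", hits$bits),
               sprintf("%.3f", hits$prob),
               sprintf("%.3f", hits$lddt),
               hits$lddtfull)
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Extract a per-residue pLDDT profile from a predicted structure
#'
#' AlphaFold-family predictors store the per-residue pLDDT confidence
#' (0-100) in the B-factor field of every atom of that residue. The profile
#' is taken from the CA atom of each residue in file order by default;
#' `source = "mean"` averages over all atoms of the residue instead (the two
#' agree on AlphaFold output, which writes uniform per-residue values).
#'
#' @param path Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param source `"ca"` (default) or `"mean"`.
#' @param protein_id Identifier to attach; defaults to the file base name.
#' @return list with `protein_id` and `plddt`, a numeric vector with one
#'   value in \[0, 100\] per residue.
#' @export
read_plddt <- function(path, source = c("ca", "mean"), protein_id = NULL) {
  source <- match.arg(source)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("cif", "mmcif")) read_atoms_mmcif(path) else read_atoms_pdb(path)
  if (nrow(tab) == 0L) stopf("no ATOM records found in %s", path)
  res_key <- paste(tab$chain, tab$resseq, tab$icode, sep = "|")
  res_f <- factor(res_key, levels = unique(res_key))
  plddt <- if (source == "ca") {
    is_ca <- tab$atom == "CA"
    has_ca <- tapply(is_ca, res_f, any)
    if (!all(has_ca)) {
      bad <- levels(res_f)[which(!has_ca)[1L]]
      stopf("residue %s in %s has no CA atom", bad, path)
    }
    # first CA per residue (altloc duplicates resolved to the first seen)
    unname(tab$b[is_ca][!duplicated(res_f[is_ca])])
  } else {
    unname(as.numeric(tapply(tab$b, res_f, mean)))
  }
  if (any(plddt < 0 | plddt > 100)) {
    stopf("pLDDT values outside [0,100] in %s (residue %d)",
          path, which(plddt < 0 | plddt > 100)[1L])
  }
  list(protein_id = protein_id %||% tools::file_path_sans_ext(basename(path)),
       plddt = plddt)
}

read_atoms_pdb <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  lines <- lines[startsWith(lines, "ATOM  ")]
  data.frame(
    atom = trimws(substr(lines, 13L, 16L)),
    chain = substr(lines, 22L, 22L),
    resseq = trimws(substr(lines, 23L, 26L)),
    icode = substr(lines, 27L, 27L),
    b = as.numeric(substr(lines, 61L, 66L)),
    stringsAsFactors = FALSE
  )
}

read_atoms_mmcif <- function(path) {
  lines <- readLines(path)
  in_loop <- FALSE
  tags <- character()
  rows <- character()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "loop_") {
      j <- i + 1L
      t <- character()
      while (j <= length(lines) && startsWith(trimws(lines[j]), "_")) {
        t <- c(t, trimws(lines[j])); j <- j + 1L
      }
      if (length(t) > 0L && all(startsWith(t, "_atom_site."))) {
        tags <- sub("^_atom_site\\.", "", t)
        k <- j
        while (k <= length(lines)) {
          lk <- trimws(lines[k])
          if (lk == "" || startsWith(lk, "_") || startsWith(lk, "loop_") ||
              startsWith(lk, "#") || startsWith(lk, "data_")) break
          rows <- c(rows, lk); k <- k + 1L
        }
        in_loop <- TRUE
        i <- k
        next
      }
      i <- j
      next
    }
    i <- i + 1L
  }
  if (!in_loop || length(rows) == 0L) {
    return(data.frame(atom = character(), chain = character(),
                      resseq = character(), icode = character(),
                      b = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(rows, "[ \t]+")
  m <- matrix(unlist(parts), ncol = length(tags), byrow = TRUE)
  colnames(m) <- tags
  grp <- if ("group_PDB" %in% tags) m[, "group_PDB"] else "ATOM"
  keep <- grp == "ATOM"
  icode <- if ("pdbx_PDB_ins_code" %in% tags) m[keep, "pdbx_PDB_ins_code"] else ""
  icode[icode %in% c("?", ".")] <- ""
  data.frame(
    atom = m[keep, "label_atom_id"],
    chain = if ("auth_asym_id" %in% tags) m[keep, "auth_asym_id"] else m[keep, "label_asym_id"],
    resseq = if ("auth_seq_id" %in% tags) m[keep, "auth_seq_id"] else m[keep, "label_seq_id"],
    icode = icode,
    b = as.numeric(m[keep, "B_iso_or_equiv"]),
    stringsAsFactors = FALSE
  )
}

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", X = "UNK")

#' Write a CA-only PDB model carrying a pLDDT profile in the B-factor field
#'
#' @param sequence Amino-acid string (one CA atom is written per residue).
#' @param plddt Numeric vector of per-residue pLDDT values, same length as
#'   the sequence.
#' @param path Output path.
#' @export
write_plddt_pdb <- function(sequence, plddt, path) {
  n <- nchar(sequence)
  if (length(plddt) != n) stopf("pLDDT length %d != sequence length %d", length(plddt), n)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  res3 <- unname(AA3[aa])
  res3[is.na(res3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), res3, seq_len(n),
    seq_len(n) * 3.8, 0, 0, 1, plddt)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read an A3M multiple sequence alignment
#'
#' In the A3M dialect the first sequence is the ungapped query master and
#' lowercase letters in member sequences are insertions relative to the
#' query; insertion columns are removed so every returned sequence lives in
#' query coordinates.
#'
#' @param path Path to an A3M file.
#' @return list with `ids` (headers' first tokens), `seqs` (uppercase/gap
#'   sequences, all of query length), `query_id` and `depth` (number of
#'   sequences).
#' @export
read_a3m <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stopf("empty A3M file: %s", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stopf("A3M parse error in %s: first line is not a header", path)
  rec <- cumsum(hdr)
  ids <- sub("[ \t].*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], factor(rec[!hdr], levels = seq_along(ids))),
                 function(x) paste(x, collapse = ""), character(1L))
  if (anyNA(seqs) || any(!nzchar(seqs))) stopf("A3M parse error in %s: record with empty sequence", path)
  seqs <- unname(seqs)
  if (grepl("[a-z]", seqs[1L])) {
    stopf("A3M parse error in %s: query (first sequence) contains lowercase insertion states", path)
  }
  qlen <- nchar(seqs[1L])
  aligned <- gsub("[a-z]", "", seqs)
  bad <- which(nchar(aligned) != qlen)
  if (length(bad) > 0L) {
    stopf("A3M parse error in %s: sequence '%s' has %d match columns, query has %d",
          path, ids[bad[1L]], nchar(aligned[bad[1L]]), qlen)
  }
  list(ids = ids, seqs = aligned, query_id = ids[1L], depth = length(aligned))
}

#' Write an A3M alignment
#'
#' @param ids Sequence identifiers (first is the query).
#' @param seqs Sequences; lowercase insertions allowed in non-query rows.
#' @param path Output path.
#' @export
write_a3m <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}

#' Read an MMseqs2 two-column cluster assignment table
#'
#' @param path TSV with rows `representative_id TAB member_id` (MMseqs2
#'   `createtsv` convention; the representative lists itself as a member).
#' @return A named list mapping representative id to the character vector of
#'   member ids, with class `cluster_table`.
#' @export
read_cluster_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), class = "cluster_table"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stopf("cluster table %s: row %d does not have 2 fields",
          path, which(lengths(parts) != 2L)[1L])
  }
  rep_id <- vapply(parts, `[[`, character(1L), 1L)
  member <- vapply(parts, `[[`, character(1L), 2L)
  as_cluster_table(rep_id, member, path)
}

as_cluster_table <- function(rep_id, member, src = "<cluster table>") {
  if (anyDuplicated(member)) {
    dup <- member[duplicated(member)][1L]
    if (length(unique(rep_id[member == dup])) > 1L || sum(member == dup) > 1L) {
      stopf("cluster table %s: member '%s' appears in more than one cluster row", src, dup)
    }
  }
  tab <- split(member, factor(rep_id, levels = unique(rep_id)))
  self_ok <- mapply(function(r, m) r %in% m, names(tab), tab)
  if (!all(self_ok)) {
    stopf("cluster table %s: representative '%s' is not listed among its members",
          src, names(tab)[which(!self_ok)[1L]])
  }
  structure(as.list(tab), class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  sz <- lengths(x)
  cat(sprintf("Cluster table: %d clusters, %d proteins (%d singletons)\n",
              length(x), sum(sz), sum(sz == 1L)))
  invisible(x)
}

#' Write a cluster table in the MMseqs2 two-column format
#'
#' @param clusters `cluster_table` object.
#' @param path Output path.
#' @export
write_cluster_tsv <- function(clusters, path) {
  rep_id <- rep(names(clusters), lengths(clusters))
  writeLines(paste(rep_id, unlist(clusters, use.names = FALSE), sep = "\t"), path)
  invisible(path)
}

#' Sizes of clusters in a cluster table
#' @param clusters `cluster_table` object.
#' @return Named integer vector of member counts.
#' @export
cluster_sizes <- function(clusters) lengths(clusters)

.ANNOT_DIALECTS <- list(
  generic = c(id = "protein_id", label = "label", category = "category"),
  pharokka = c(id = "ID", label = "annot", category = "category"),
  phold = c(id = "cds_id", label = "function_label", category = "category")
)

#' Read a sequence-based annotation table (Pharokka/Phold style)
#'
#' @param path TSV file with a header row.
#' @param dialect One of `"generic"`, `"pharokka"`, `"phold"`; selects the
#'   column names carrying the protein id, the free-text functional label
#'   and the PHROG category.
#' @return data.frame with columns `protein_id`, `label`, `category`.
#'   Proteins absent from the table are simply absent; use
#'   [lookup_annotation()] for absence-aware lookup.
#' @export
read_annotation_table <- function(path, dialect = c("generic", "pharokka", "phold")) {
  dialect <- match.arg(dialect)
  cols <- .ANNOT_DIALECTS[[dialect]]
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(cols), colnames(tab))
  if (length(missing) > 0L) {
    stopf("annotation table %s (dialect %s): missing required column(s): %s",
          path, dialect, paste(missing, collapse = ", "))
  }
  out <- data.frame(protein_id = as.character(tab[[cols[["id"]]]]),
                    label = as.character(tab[[cols[["label"]]]]),
                    category = as.character(tab[[cols[["category"]]]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$protein_id)) {
    stopf("annotation table %s: duplicated protein id '%s'",
          path, out$protein_id[duplicated(out$protein_id)][1L])
  }
  out
}

#' Look up a protein's sequence-based annotation
#'
#' @param annotation data.frame from [read_annotation_table()].
#' @param protein_id Single protein identifier.
#' @return list with `found` (logical), `label`, `category` (NA when absent).
#' @export
lookup_annotation <- function(annotation, protein_id) {
  i <- match(protein_id, annotation$protein_id)
  if (is.na(i)) list(found = FALSE, label = NA_character_, category = NA_character_)
  else list(found = TRUE, label = annotation$label[i], category = annotation$category[i])
}

#' Write a generic-dialect annotation table
#' @param annotation data.frame with `protein_id`, `label`, `category`.
#' @param path Output path.
#' @export
write_annotation_table <- function(annotation, path) {
  utils::write.table(annotation[, c("protein_id", "label", "category")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a database header annotation table
#'
#' Maps FoldSeek target identifiers to the free-text annotation stored in
#' the structure database's header file. Lookup of a missing target is a
#' detectable error, never an empty string (see [header_labels()]).
#'
#' @param path Two-column TSV `target_id TAB label` with a header row.
#' @param db Database tag, one of `"PDB"`, `"AFDB"`, `"PHOLD"`.
#' @return list with `db` and `labels` (named character vector).
#' @export
read_header_table <- function(path, db = c("PDB", "AFDB", "PHOLD")) {
  db <- match.arg(db)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("target_id", "label") %in% colnames(tab))) {
    stopf("header table %s: expected columns target_id, label", path)
  }
  labels <- as.character(tab$label)
  names(labels) <- as.character(tab$target_id)
  if (anyDuplicated(names(labels))) {
    stopf("header table %s: duplicated target id '%s'",
          path, names(labels)[duplicated(names(labels))][1L])
  }
  list(db = db, labels = labels)
}

#' Write a header annotation table
#' @param header_db list as returned by [read_header_table()].
#' @param path Output path.
#' @export
write_header_table <- function(header_db, path) {
  utils::write.table(
    data.frame(target_id = names(header_db$labels), label = unname(header_db$labels),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fetch header annotations for a set of targets
#'
#' @param header_db list from [read_header_table()].
#' @param targets Character vector of target identifiers.
#' @return Character vector of labels.
#' @export
header_labels <- function(header_db, targets) {
  i <- match(targets, names(header_db$labels))
  if (anyNA(i)) {
    stopf("target(s) missing from %s header annotations: %s", header_db$db,
          paste(utils::head(targets[is.na(i)], 3L), collapse = ", "))
  }
  unname(header_db$labels[i])
}

IDMAP_STATUSES <- c("active", "removed_uniparc", "unmapped")

#' Read a UniProt identifier-mapping table
#'
#' @param path Three-column TSV `target_id TAB protein_name TAB status` with
#'   a header row; status is one of `active`, `removed_uniparc`, `unmapped`.
#'   Unmapped rows must carry an empty name.
#' @return data.frame with columns `target_id`, `protein_name` (NA when
#'   unmapped) and `status`.
#' @export
read_idmap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = character())
  need <- c("target_id", "protein_name", "status")
  if (!all(need %in% colnames(tab))) {
    stopf("idmap table %s: expected columns %s", path, paste(need, collapse = ", "))
  }
  bad <- !tab$status %in% IDMAP_STATUSES
  if (any(bad)) stopf("idmap table %s: unknown status '%s'", path, tab$status[bad][1L])
  name <- as.character(tab$protein_name)
  unmapped <- tab$status == "unmapped"
  if (any(unmapped & nzchar(name))) {
    stopf("idmap table %s: unmapped target '%s' carries a protein name",
          path, tab$target_id[unmapped & nzchar(name)][1L])
  }
  name[unmapped] <- NA_character_
  if (anyDuplicated(tab$target_id)) {
    stopf("idmap table %s: duplicated target id '%s'",
          path, tab$target_id[duplicated(tab$target_id)][1L])
  }
  data.frame(target_id = as.character(tab$target_id), protein_name = name,
             status = as.character(tab$status), stringsAsFactors = FALSE)
}

#' Write a UniProt identifier-mapping table
#' @param idmap data.frame from [read_idmap()].
#' @param path Output path.
#' @export
write_idmap <- function(idmap, path) {
  out <- idmap
  out$protein_name[is.na(out$protein_name)] <- ""
  utils::write.table(out[, c("target_id", "protein_name", "status")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
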
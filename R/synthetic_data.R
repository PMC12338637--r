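# Synthetic input bundles with exact ground truth.
#
# The generator emulates every upstream artifact the pipeline consumes
# (FASTA, cluster table, per-protein CA-only structures carrying pLDDT,
# A3M alignments, per-database FoldSeek hit tables, header annotation
# tables, a UniProt identifier map and a sequence-based annotation table)
# and returns a truth manifest from which every report number is computable
# without re-running the pipeline.

LABEL_POOLS <- list(
  HIGH = c("terminase large subunit", "major capsid protein", "portal protein",
           "tail fiber protein", "baseplate wedge protein",
           "single-stranded DNA-binding protein", "DNA polymerase",
           "holin", "endolysin", "tail spike depolymerase", "RNA ligase",
           "anti-CRISPR protein", "thymidylate synthase",
           "head-tail connector protein", "peptidoglycan hydrolase",
           "putative tail fiber protein", "HNH homing endonuclease"),
  LOW = c("DUF2786 domain-containing protein",
          "domain of unknown function (DUF4183)",
          "DUF551 domain-containing protein", "putative protein",
          "YopX domain-containing protein",
          "domain of unknown function (DUF1342)"),
  NONE = c("hypothetical protein", "uncharacterized protein",
           "protein of unknown function", "unannotated protein",
           "phage protein")
)

PHROG_CATEGORIES <- c("head and packaging", "DNA, RNA and nucleotide metabolism",
                      "transcription regulation", "lysis", "tail", "connector",
                      "integration and excision",
                      "moron, auxiliary metabolic gene and host takeover", "other")

#' Simulation configuration
#'
#' Defaults emulate the curated *Pseudomonas*-phage protein dataset: a
#' singleton-heavy cluster-size law with mean size 4, log-normal length laws
#' moment-matched per group (159 +/- 166 aa for truly unannotated, 343 +/-
#' 288 aa for sequence-annotated representatives, truncated to the 100-850
#' size window), a 27% sequence-annotated fraction, per-database
#' significant-hit probabilities of 0.09 (PDB) / 0.47 (AFDB) / 0.66 (Phold)
#' for truly unannotated clusters, pLDDT regimes of 82 +/- 12 above vs 55
#' +/- 16 below an MSA depth of 10 sequences, and a 21% low-outranks-high
#' label fraction of which 13/21 also carry a lower-scoring proper
#' annotation. Group-level fractions are planted as exact counts; a shared
#' latent annotatability score couples hit presence, MSA depth, cluster
#' size and length across databases.
#'
#' @param n_clusters Number of protein clusters.
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   config and seed.
#' @param singleton_fraction Fraction of clusters of size 1.
#' @param mean_cluster_size Target mean cluster size, singletons included.
#' @param max_cluster_size Upper truncation of the power-law size tail.
#' @param seq_annotated_fraction Fraction of clusters whose representative
#'   the sequence-based search annotates.
#' @param length_mean,length_sd Per-group length moments (aa) for groups
#'   `truly_unannotated` and `seq_annotated`.
#' @param length_range Inclusive truncation window for lengths.
#' @param shallow_depth_fraction Fraction of clusters with MSA depth below
#'   `depth_threshold`.
#' @param depth_meanlog,depth_sdlog,depth_max Log-normal law (truncated to
#'   `[depth_threshold, depth_max]`) for deep-MSA cluster depths.
#' @param depth_threshold The depth tipping point (sequences).
#' @param plddt_regimes Mean/sd of the per-protein mean pLDDT above
#'   (`deep`) and below (`shallow`) the tipping point.
#' @param plddt_residue_sd Per-residue spread around the protein mean.
#' @param presence_prob Per-group named vectors (PDB/AFDB/PHOLD) of
#'   significant-hit probabilities.
#' @param p_annotated_given_hit Per-group probability that a cluster with
#'   hits has at least one informatively-labelled hit.
#' @param p_top_annotated Probability that the top surviving hit is itself
#'   annotated, given any annotated hit exists (drives best-hit rates).
#' @param low_outranks_high Fraction of annotated calls whose best
#'   annotated hit is low-information.
#' @param high_below_low_fraction Fraction of those that also have a
#'   lower-scoring proper annotation (tier-preferring scheme rescues them).
#' @param up_rescue_prob Probability that a cluster with hits but no
#'   informative header label carries a hit whose UniProt-mapped name is
#'   informative (per database; Phold labels are PHROG-curated and get no
#'   identifier mapping).
#' @param idmap_status_mix Mixture over idmap statuses for mapped targets
#'   of annotated hits.
#' @param extra_hits_lambda,sigfail_lambda,qualfail_lambda Poisson means
#'   for additional surviving hits, significance-failing decoys and
#'   quality-failing decoys per cluster and database.
#' @param coupling Latent-score coupling strength in \[0, 1) shared by hit
#'   presence, depth, size and length.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_clusters = 500L,
    seed = 1L,
    singleton_fraction = 6978 / 10498,
    mean_cluster_size = 4,
    max_cluster_size = 200L,
    seq_annotated_fraction = 0.27,
    length_mean = c(truly_unannotated = 159, seq_annotated = 343),
    length_sd = c(truly_unannotated = 166, seq_annotated = 288),
    length_range = c(100L, 850L),
    shallow_depth_fraction = 0.18,
    depth_meanlog = log(131),
    depth_sdlog = 1.0,
    depth_max = 250L,
    depth_threshold = 10L,
    plddt_regimes = list(deep = c(mean = 82, sd = 12), shallow = c(mean = 55, sd = 16)),
    plddt_residue_sd = 6,
    presence_prob = list(
      truly_unannotated = c(PDB = 0.09, AFDB = 0.47, PHOLD = 0.66),
      seq_annotated = c(PDB = 0.30, AFDB = 0.70, PHOLD = 0.99)),
    p_annotated_given_hit = list(
      truly_unannotated = c(PDB = 0.78, AFDB = 0.43, PHOLD = 0.35),
      seq_annotated = c(PDB = 0.95, AFDB = 0.75, PHOLD = 0.99)),
    p_top_annotated = c(PDB = 1.0, AFDB = 0.30, PHOLD = 0.50),
    low_outranks_high = c(PDB = 0.04, AFDB = 0.21, PHOLD = 0.10),
    high_below_low_fraction = 13 / 21,
    up_rescue_prob = c(PDB = 0.30, AFDB = 0.35, PHOLD = 0),
    idmap_status_mix = c(active = 0.7, removed_uniparc = 0.2, unmapped = 0.1),
    extra_hits_lambda = 2,
    sigfail_lambda = 0.4,
    qualfail_lambda = 0.8,
    coupling = 0.5) {
  cfg <- list(n_clusters = as.integer(n_clusters), seed = as.integer(seed),
              singleton_fraction = singleton_fraction,
              mean_cluster_size = mean_cluster_size,
              max_cluster_size = as.integer(max_cluster_size),
              seq_annotated_fraction = seq_annotated_fraction,
              length_mean = length_mean, length_sd = length_sd,
              length_range = as.integer(length_range),
              shallow_depth_fraction = shallow_depth_fraction,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              depth_max = as.integer(depth_max),
              depth_threshold = as.integer(depth_threshold),
              plddt_regimes = plddt_regimes,
              plddt_residue_sd = plddt_residue_sd,
              presence_prob = presence_prob,
              p_annotated_given_hit = p_annotated_given_hit,
              p_top_annotated = p_top_annotated,
              low_outranks_high = low_outranks_high,
              high_below_low_fraction = high_below_low_fraction,
              up_rescue_prob = up_rescue_prob,
              idmap_status_mix = idmap_status_mix,
              extra_hits_lambda = extra_hits_lambda,
              sigfail_lambda = sigfail_lambda,
              qualfail_lambda = qualfail_lambda,
              coupling = coupling)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  frac_fields <- c("singleton_fraction", "seq_annotated_fraction",
                   "shallow_depth_fraction", "high_below_low_fraction")
  for (f in frac_fields) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("config: %s must be in [0,1]", f)
  }
  for (g in c("truly_unannotated", "seq_annotated")) {
    pp <- cfg$presence_prob[[g]]
    if (is.null(pp) || !all(DB_TAGS %in% names(pp))) {
      stopf("config: presence_prob$%s must name %s", g, paste(DB_TAGS, collapse = ", "))
    }
    if (any(pp < 0 | pp > 1)) stopf("config: presence_prob$%s outside [0,1]", g)
    pa <- cfg$p_annotated_given_hit[[g]]
    if (any(pa < 0 | pa > 1)) stopf("config: p_annotated_given_hit$%s outside [0,1]", g)
  }
  if (any(cfg$low_outranks_high < 0 | cfg$low_outranks_high > 1) ||
      any(cfg$p_top_annotated < 0 | cfg$p_top_annotated > 1) ||
      any(cfg$up_rescue_prob < 0 | cfg$up_rescue_prob > 1)) {
    stopf("config: per-database probabilities must lie in [0,1]")
  }
  if (cfg$coupling < 0 || cfg$coupling >= 1) stopf("config: coupling must be in [0,1)")
  if (cfg$length_range[1L] < 1L || cfg$length_range[2L] > 5000L ||
      cfg$length_range[1L] > cfg$length_range[2L]) {
    stopf("config: length_range must be an increasing window within [1,5000]")
  }
  # cluster-size law feasibility: the non-singleton mean implied by the
  # singleton fraction and overall mean must be attainable on [2, max]
  if (cfg$singleton_fraction < 1) {
    m2 <- (cfg$mean_cluster_size - cfg$singleton_fraction) / (1 - cfg$singleton_fraction)
    if (m2 < 2) {
      stopf("config: singleton_fraction %.3f with mean cluster size %.2f implies a non-singleton mean of %.2f (< 2); infeasible",
            cfg$singleton_fraction, cfg$mean_cluster_size, m2)
    }
    if (m2 > (2 + cfg$max_cluster_size) / 2) {
      stopf("config: non-singleton mean %.2f exceeds what a power law on [2,%d] can reach", m2, cfg$max_cluster_size)
    }
  } else if (cfg$mean_cluster_size != 1) {
    stopf("config: singleton_fraction = 1 forces mean cluster size 1, not %.2f", cfg$mean_cluster_size)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d clusters, seed %d\n", x$n_clusters, x$seed))
  cat(sprintf("  seq-annotated fraction %.2f; singleton fraction %.3f; mean size %.1f\n",
              x$seq_annotated_fraction, x$singleton_fraction, x$mean_cluster_size))
  cat(sprintf("  presence (truly unannotated): PDB %.2f, AFDB %.2f, PHOLD %.2f\n",
              x$presence_prob$truly_unannotated[["PDB"]],
              x$presence_prob$truly_unannotated[["AFDB"]],
              x$presence_prob$truly_unannotated[["PHOLD"]]))
  invisible(x)
}

# power-law (zipf-like) size sampler on [2, kmax] matched to a target mean
zipf_sizes <- function(n, target_mean, kmax) {
  k <- 2:kmax
  mean_for <- function(a) {
    w <- k^(-a)
    sum(k * w) / sum(w)
  }
  a <- stats::uniroot(function(a) mean_for(a) - target_mean,
                      lower = 1e-6, upper = 25, tol = 1e-9)$root
  w <- k^(-a)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

# exact-count subset of ids, highest latent scores first
top_by_score <- function(ids, scores, k) {
  if (k <= 0L) return(character())
  ids[radix_order(-scores, ids)][seq_len(min(k, length(ids)))]
}

sample_exact <- function(ids, k) {
  k <- min(k, length(ids))
  if (k <= 0L) return(character())
  if (length(ids) == 1L) return(ids[seq_len(k)])
  sample(ids, k)
}

rand_sequence <- function(len) {
  paste(sample(names(AA3)[1:20], len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, n_sub = 3L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), min(n_sub, length(chars)))
  chars[pos] <- sample(names(AA3)[1:20], length(pos), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a complete synthetic input bundle
#'
#' Writes all pipeline inputs to `dir` (FASTA, MMseqs2-style cluster table,
#' CA-only PDB structures with pLDDT B-factors, A3M alignments, three
#' FoldSeek hit tables, three header annotation tables, an identifier map
#' and a sequence-based annotation table) and returns the truth manifest.
#' Identical config and seed give a byte-identical bundle.
#'
#' @param config [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisible list of class `truth_manifest` with elements
#'   `clusters` (per-cluster planted truth), `calls` (the annotation calls
#'   every strategy must produce), `filter_counts` (per-database raw /
#'   significant / quality-surviving hit counts), `config` and `dir`.
#' @export
simulate_bundle <- function(config = simulation_config(), dir) {
  validate_simulation_config(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sub in c("structures", "msas")) {
    d <- file.path(dir, sub)
    if (!dir.exists(d)) dir.create(d)
  }
  with_seed(config$seed, simulate_bundle_impl(config, dir))
}

simulate_bundle_impl <- function(cfg, dir) {
  n <- cfg$n_clusters
  ids <- sprintf("REP%05d", seq_len(n))
  z <- stats::rnorm(n)
  mix <- function(rho) rho * z + sqrt(1 - rho^2) * stats::rnorm(n)

  ## group assignment (exact count, coupled to latent score)
  n_seq <- round(cfg$seq_annotated_fraction * n)
  seq_annotated <- ids %in% top_by_score(ids, mix(0.4), n_seq)
  group <- ifelse(seq_annotated, "seq_annotated", "truly_unannotated")

  ## cluster sizes
  n_single <- round(cfg$singleton_fraction * n)
  size <- rep(1L, n)
  if (n_single < n) {
    m2 <- (cfg$mean_cluster_size - cfg$singleton_fraction) / (1 - cfg$singleton_fraction)
    big <- !(ids %in% top_by_score(ids, -mix(0.4), n_single))
    sz <- radix_sort(zipf_sizes(sum(big), m2, cfg$max_cluster_size))
    ord <- radix_order(mix(0.2)[big])
    size[which(big)[ord]] <- sz
  }

  ## lengths: per-group truncated log-normal via a Gaussian copula
  len <- integer(n)
  for (g in c("truly_unannotated", "seq_annotated")) {
    sel <- group == g
    if (!any(sel)) next
    mu_x <- cfg$length_mean[[g]]
    sd_x <- cfg$length_sd[[g]]
    s2 <- log(1 + (sd_x / mu_x)^2)
    mu <- log(mu_x) - s2 / 2
    lo <- stats::plnorm(cfg$length_range[1L], mu, sqrt(s2))
    hi <- stats::plnorm(cfg$length_range[2L], mu, sqrt(s2))
    w <- 0.3 * z[sel] + sqrt(1 - 0.09) * stats::rnorm(sum(sel))
    u <- lo + stats::pnorm(w) * (hi - lo)
    len[sel] <- as.integer(pmin(cfg$length_range[2L],
                                pmax(cfg$length_range[1L], round(stats::qlnorm(u, mu, sqrt(s2))))))
  }

  ## MSA depth (exact shallow count, coupled) and pLDDT regime
  n_shallow <- round(cfg$shallow_depth_fraction * n)
  shallow <- ids %in% top_by_score(ids, -mix(cfg$coupling), n_shallow)
  depth <- integer(n)
  if (any(shallow)) depth[shallow] <- sample(seq_len(cfg$depth_threshold - 1L), sum(shallow), replace = TRUE)
  if (any(!shallow)) {
    lo <- stats::plnorm(cfg$depth_threshold, cfg$depth_meanlog, cfg$depth_sdlog)
    hi <- stats::plnorm(cfg$depth_max, cfg$depth_meanlog, cfg$depth_sdlog)
    u <- lo + stats::runif(sum(!shallow)) * (hi - lo)
    depth[!shallow] <- as.integer(pmin(cfg$depth_max,
                                       pmax(cfg$depth_threshold,
                                            round(stats::qlnorm(u, cfg$depth_meanlog, cfg$depth_sdlog)))))
  }
  regime <- ifelse(shallow, "shallow", "deep")
  m_target <- vapply(regime, function(r) {
    stats::rnorm(1L, cfg$plddt_regimes[[r]][["mean"]], cfg$plddt_regimes[[r]][["sd"]])
  }, numeric(1L))
  m_target <- pmin(99, pmax(5, m_target))

  ## sequences, profiles, structures, MSAs
  sequences <- character(n)
  mean_plddt_realized <- numeric(n)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    sequences[i] <- rand_sequence(len[i])
    prof <- quantize(pmin(100, pmax(0, m_target[i] + stats::rnorm(len[i], 0, cfg$plddt_residue_sd))))
    profiles[[i]] <- prof
    mean_plddt_realized[i] <- mean(prof)
    write_plddt_pdb(sequences[i], prof, file.path(dir, "structures", paste0(ids[i], ".pdb")))
    write_bundle_a3m(ids[i], sequences[i], depth[i], file.path(dir, "msas", paste0(ids[i], ".a3m")))
  }
  capable <- mean_plddt_realized > 70

  ## FASTA + cluster table (members are mutated copies of the representative)
  member_ids <- vector("list", n)
  member_seqs <- vector("list", n)
  for (i in seq_len(n)) {
    k <- size[i]
    mids <- ids[i]
    mseqs <- sequences[i]
    if (k > 1L) {
      extra <- sprintf("%s_m%03d", ids[i], seq_len(k - 1L))
      mids <- c(mids, extra)
      mseqs <- c(mseqs, vapply(seq_len(k - 1L), function(j) mutate_sequence(sequences[i]), character(1L)))
    }
    member_ids[[i]] <- mids
    member_seqs[[i]] <- mseqs
  }
  records <- data.frame(protein_id = unlist(member_ids),
                        description = "hypothetical protein",
                        sequence = unlist(member_seqs), stringsAsFactors = FALSE)
  records$length <- nchar(records$sequence)
  write_fasta(records, file.path(dir, "proteins.fasta"))
  writeLines(paste(rep(ids, size), unlist(member_ids), sep = "\t"),
             file.path(dir, "clusters.tsv"))

  ## sequence-based annotation table: annotated representatives get an
  ## informative label and a real PHROG category; a share of the truly
  ## unannotated ones appear with labels/categories the split must reject
  u <- stats::runif(n)
  in_tab <- seq_annotated | u < 0.45
  lab <- character(n)
  cat_ <- character(n)
  lab[seq_annotated] <- sample(LABEL_POOLS$HIGH, sum(seq_annotated), replace = TRUE)
  cat_[seq_annotated] <- sample(PHROG_CATEGORIES, sum(seq_annotated), replace = TRUE)
  hypo <- !seq_annotated & u < 0.3
  weak <- !seq_annotated & u >= 0.3 & u < 0.45
  lab[hypo] <- "hypothetical protein"
  cat_[hypo] <- "unknown function"
  lab[weak] <- sample(LABEL_POOLS$HIGH, sum(weak), replace = TRUE)
  cat_[weak] <- "unknown function"
  write_annotation_table(
    fast_df(protein_id = ids[in_tab], label = lab[in_tab], category = cat_[in_tab]),
    file.path(dir, "annotations_seq.tsv"))

  ## per-database planting
  state <- new.env(parent = emptyenv())
  state$target_counter <- stats::setNames(rep(0L, length(DB_TAGS)), DB_TAGS)
  state$idmap_target <- character()
  state$idmap_name <- character()
  state$idmap_status <- character()
  presence <- matrix(FALSE, n, length(DB_TAGS), dimnames = list(ids, DB_TAGS))
  filter_counts <- data.frame(db = DB_TAGS, n_raw = 0L, n_significant = 0L,
                              n_quality = 0L, stringsAsFactors = FALSE)
  call_acc <- list()

  for (db in DB_TAGS) {
    plan <- list()
    for (g in c("truly_unannotated", "seq_annotated")) {
      gids <- ids[group == g]
      if (length(gids) == 0L) next
      gscore <- mix(cfg$coupling)[group == g]
      pres <- top_by_score(gids, gscore, round(cfg$presence_prob[[g]][[db]] * length(gids)))
      ann <- sample_exact(pres, round(cfg$p_annotated_given_hit[[g]][[db]] * length(pres)))
      top_ann <- sample_exact(ann, round(cfg$p_top_annotated[[db]] * length(ann)))
      low <- sample_exact(ann, round(cfg$low_outranks_high[[db]] * length(ann)))
      rescue <- sample_exact(low, round(cfg$high_below_low_fraction * length(low)))
      no_ann <- setdiff(pres, ann)
      up_rescue <- sample_exact(no_ann, round(cfg$up_rescue_prob[[db]] * length(no_ann)))
      plan[[g]] <- list(pres = pres, ann = ann, top_ann = top_ann, low = low,
                        rescue = rescue, up_rescue = up_rescue)
    }
    pres_all <- unlist(lapply(plan, `[[`, "pres"), use.names = FALSE)
    presence[, db] <- ids %in% pres_all
    flag <- function(field) ids %in% unlist(lapply(plan, `[[`, field), use.names = FALSE)
    in_ann <- flag("ann"); in_top <- flag("top_ann"); in_low <- flag("low")
    in_rescue <- flag("rescue"); in_up <- flag("up_rescue")

    hit_acc <- list()
    hdr_target <- list()
    hdr_label <- list()
    n_raw <- n_sig <- n_qual <- 0L
    for (i in seq_len(n)) {
      slots <- NULL
      if (presence[i, db]) {
        slots <- build_slots(cfg, db, state,
                             ann_avail = in_ann[i], top_annotated = in_top[i],
                             bah_low = in_low[i], rescue = in_rescue[i],
                             up_rescue = in_up[i])
      }
      rows <- build_hit_rows(cfg, db, state, ids[i], len[i], slots)
      if (!is.null(rows$hits)) {
        hit_acc[[length(hit_acc) + 1L]] <- rows$hits
        hdr_target[[length(hdr_target) + 1L]] <- rows$hits$target
        hdr_label[[length(hdr_label) + 1L]] <- rows$header_label
      }
      n_raw <- n_raw + rows$n_raw
      n_sig <- n_sig + rows$n_sig
      if (capable[i]) n_qual <- n_qual + rows$n_surv
      call_acc[[length(call_acc) + 1L]] <-
        truth_calls(ids[i], db, rows$slots, capable = capable[i])
    }
    filter_counts[filter_counts$db == db, c("n_raw", "n_significant", "n_quality")] <-
      c(n_raw, n_sig, n_qual)

    hits <- if (length(hit_acc) > 0L) {
      cols <- lapply(stats::setNames(nm = FOLDSEEK_COLUMNS), function(nm) {
        unlist(lapply(hit_acc, `[[`, nm), use.names = FALSE)
      })
      do.call(fast_df, cols)
    } else empty_foldseek_hits()
    write_foldseek_tsv(hits, file.path(dir, sprintf("foldseek_%s.tsv", tolower(db))))
    labels <- stats::setNames(unlist(hdr_label, use.names = FALSE),
                              unlist(hdr_target, use.names = FALSE))
    if (is.null(labels)) labels <- character()
    write_header_table(list(db = db, labels = labels),
                       file.path(dir, sprintf("headers_%s.tsv", tolower(db))))
  }
  write_idmap(fast_df(target_id = state$idmap_target,
                      protein_name = as.character(ifelse(state$idmap_status == "unmapped",
                                                         NA_character_, state$idmap_name)),
                      status = state$idmap_status),
              file.path(dir, "idmap.tsv"))

  ## assemble truth
  call_cols <- lapply(stats::setNames(nm = names(call_acc[[1L]])), function(nm) {
    unlist(lapply(call_acc, `[[`, nm), use.names = FALSE)
  })
  calls <- do.call(calls_to_df_cols, call_cols)
  joint <- joint_truth_calls(calls)
  clusters_truth <- data.frame(
    cluster_id = ids, size = size, seq_annotated = seq_annotated,
    length = len, max_msa_depth = depth, shallow = shallow,
    mean_plddt = mean_plddt_realized, capable = capable,
    stringsAsFactors = FALSE)
  for (db in DB_TAGS) clusters_truth[[paste0("presence_", db)]] <- presence[, db]
  manifest <- list(clusters = clusters_truth,
                   calls = rbind(calls, joint),
                   filter_counts = filter_counts,
                   config = cfg, dir = dir)
  class(manifest) <- "truth_manifest"
  invisible(manifest)
}

# A3M with exactly `depth` sequences; the first ten query positions are kept
# ungapped in every member so the maximum per-position coverage equals the
# sequence count. A few members carry gaps and lowercase insertions to
# exercise the reader.
write_bundle_a3m <- function(id, sequence, depth, path) {
  qlen <- nchar(sequence)
  seqs <- c(sequence, rep(sequence, max(0L, depth - 1L)))
  n_mod <- min(depth - 1L, 4L)
  if (n_mod > 0L) {
    for (j in seq_len(n_mod)) {
      chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
      gap_pos <- sample((11L):qlen, min(5L, qlen - 10L))
      chars[gap_pos] <- "-"
      s <- paste(chars, collapse = "")
      if (j == 1L) s <- paste0(substr(s, 1L, 10L), "gga", substr(s, 11L, qlen))
      seqs[1L + j] <- s
    }
  }
  hdrs <- c(id, sprintf("%s_h%04d", id, seq_len(max(0L, depth - 1L))))
  write_a3m(hdrs, seqs, path)
}

new_targets <- function(state, db, k) {
  if (k == 0L) return(character())
  idx <- state$target_counter[[db]] + seq_len(k)
  state$target_counter[[db]] <- state$target_counter[[db]] + k
  sprintf("%s_T%06d", db, idx)
}

draw_labels <- function(tiers) {
  out <- character(length(tiers))
  for (t in unique(tiers)) {
    sel <- tiers == t
    out[sel] <- sample(LABEL_POOLS[[t]], sum(sel), replace = TRUE)
  }
  out
}

add_idmap <- function(state, target, name, status) {
  state$idmap_target <- c(state$idmap_target, target)
  state$idmap_name <- c(state$idmap_name, name)
  state$idmap_status <- c(state$idmap_status, status)
}

# Attach an idmap entry for a target. kind: "informative" (active/uniparc
# name of the given tier), "same_tier" (annotated hit mapped to a same-tier
# name with the configured status mixture) or "noise" (unmapped row or no
# row at all). Phold targets are PHROG-curated and never mapped.
assign_idmap <- function(state, cfg, db, target, kind, tier = "HIGH") {
  if (db == "PHOLD") return(list(label = NULL, caution = FALSE))
  if (kind == "informative") {
    p_act <- cfg$idmap_status_mix[["active"]]
    p_up <- cfg$idmap_status_mix[["removed_uniparc"]]
    status <- if (stats::runif(1L) < p_act / (p_act + p_up)) "active" else "removed_uniparc"
    nm <- draw_labels(tier)
    add_idmap(state, target, nm, status)
    return(list(label = nm, caution = status == "removed_uniparc"))
  }
  if (kind == "same_tier") {
    r <- stats::runif(1L)
    mix <- cfg$idmap_status_mix
    if (r < mix[["active"]] + mix[["removed_uniparc"]]) {
      status <- if (r < mix[["active"]]) "active" else "removed_uniparc"
      nm <- draw_labels(tier)
      add_idmap(state, target, nm, status)
      return(list(label = nm, caution = status == "removed_uniparc"))
    }
    if (stats::runif(1L) < 0.5) add_idmap(state, target, "", "unmapped")
    return(list(label = NULL, caution = FALSE))
  }
  if (stats::runif(1L) < 0.3) add_idmap(state, target, "", "unmapped")
  list(label = NULL, caution = FALSE)
}

# Ordered surviving-slot plan for one cluster x database: header tier per
# slot plus the label the UniProt supplement step would see.
build_slots <- function(cfg, db, state, ann_avail, top_annotated, bah_low,
                        rescue, up_rescue) {
  if (!ann_avail) {
    k <- 1L + stats::rpois(1L, cfg$extra_hits_lambda)
    tiers <- rep("NONE", k)
    up_slot <- if (up_rescue) sample.int(k, 1L) else 0L
  } else {
    bah_tier <- if (bah_low) "LOW" else "HIGH"
    prefix <- if (top_annotated) 0L else sample(1:2, 1L)
    tiers <- c(rep("NONE", prefix), bah_tier)
    if (bah_low && rescue) tiers <- c(tiers, "HIGH")
    n_extra <- stats::rpois(1L, cfg$extra_hits_lambda)
    if (n_extra > 0L) {
      pool <- if (bah_low && !rescue) c("NONE", "LOW") else c("NONE", "LOW", "HIGH")
      tiers <- c(tiers, sample(pool, n_extra, replace = TRUE))
    }
    up_slot <- 0L
  }
  k <- length(tiers)
  slots <- fast_df(tier = tiers, label = draw_labels(tiers),
                   target = new_targets(state, db, k))
  slots$up_label <- slots$label
  slots$up_tier <- slots$tier
  slots$up_caution <- rep(FALSE, k)
  for (j in seq_len(k)) {
    kind <- if (slots$tier[j] == "NONE") {
      if (j == up_slot) "informative" else "noise"
    } else "same_tier"
    res <- assign_idmap(state, cfg, db, slots$target[j], kind,
                        tier = if (kind == "informative") {
                          if (stats::runif(1L) < 0.8) "HIGH" else "LOW"
                        } else slots$tier[j])
    if (!is.null(res$label)) {
      slots$up_label[j] <- res$label
      slots$up_tier[j] <- classify_label(res$label)
      slots$up_caution[j] <- res$caution
    }
  }
  slots
}

# Materialize FoldSeek rows for one cluster x database from the slot plan,
# interleaving quality-failing and significance-failing decoys, with
# strictly decreasing bitscores along the intended sorted order.
build_hit_rows <- function(cfg, db, state, query, qlen, slots) {
  n_surv <- if (is.null(slots)) 0L else nrow(slots)
  n_qf <- stats::rpois(1L, cfg$qualfail_lambda)
  n_sf <- stats::rpois(1L, cfg$sigfail_lambda)
  if (n_surv == 0L) {
    n_qf <- 0L
    # clusters without significant hits occasionally carry sub-threshold rows
    n_sf <- if (stats::runif(1L) < 0.3) 1L + stats::rpois(1L, 0.5) else 0L
  }
  total <- n_surv + n_qf + n_sf
  if (total == 0L) {
    return(list(hits = NULL, header_label = NULL, slots = NULL,
                n_raw = 0L, n_sig = 0L, n_surv = 0L))
  }
  kind <- c(rep("surv", n_surv), rep("qf", n_qf), rep("sf", n_sf))
  # decoys interleave among the surviving slots in sorted order
  ord_rank <- numeric(total)
  ord_rank[kind == "surv"] <- seq_len(n_surv)
  ord_rank[kind != "surv"] <- stats::runif(n_qf + n_sf, 0, n_surv + 1)
  rank <- rank(ord_rank, ties.method = "first")
  bits <- quantize(500 - 5 * rank + stats::runif(total, 0, 4), 1L)

  n_decoy <- n_qf + n_sf
  target <- character(total)
  label <- character(total)
  if (n_surv > 0L) {
    target[kind == "surv"] <- slots$target
    label[kind == "surv"] <- slots$label
  }
  if (n_decoy > 0L) {
    target[kind != "surv"] <- new_targets(state, db, n_decoy)
    label[kind != "surv"] <- draw_labels(sample(TIER_LEVELS, n_decoy, replace = TRUE))
  }

  evalue <- quantize_sci(10^stats::runif(total, -30, -3.2), 3L)
  if (n_sf > 0L) evalue[kind == "sf"] <- quantize_sci(10^stats::runif(n_sf, -2, 0.5), 3L)
  lddt <- quantize(stats::runif(total, 0.55, 0.98), 3L)
  prob <- quantize(stats::runif(total, 0.55, 0.99), 3L)
  if (n_qf > 0L) {
    # each quality decoy fails exactly one quality axis
    axis <- sample(c("lddt", "prob"), n_qf, replace = TRUE)
    qf_idx <- which(kind == "qf")
    lddt[qf_idx[axis == "lddt"]] <- quantize(stats::runif(sum(axis == "lddt"), 0.05, 0.45), 3L)
    prob[qf_idx[axis == "prob"]] <- quantize(stats::runif(sum(axis == "prob"), 0.05, 0.45), 3L)
  }
  alnlen <- rep(qlen, total)
  hits <- fast_df(
    query = rep(query, total), target = target,
    fident = quantize(stats::runif(total, 0.05, 0.6), 4L),
    alnlen = alnlen,
    mismatch = as.integer(pmax(0, round(alnlen * stats::runif(total, 0.3, 0.8)))),
    gapopen = sample(0:3, total, replace = TRUE),
    qstart = rep(1L, total), qend = rep(qlen, total),
    tstart = rep(1L, total), tend = rep(qlen, total),
    evalue = evalue, bits = bits, prob = prob, lddt = lddt,
    lddtfull = vapply(seq_len(total), function(j) {
      paste(sprintf("%.3f", stats::runif(5L, 0.3, 1)), collapse = ",")
    }, character(1L)))
  # file rows appear in randomized order; the pipeline re-sorts canonically
  perm <- sample.int(total)
  hits <- hits[perm, , drop = FALSE]
  rownames(hits) <- NULL
  if (n_surv > 0L) slots$bits <- bits[kind == "surv"]
  list(hits = hits, header_label = label[perm], slots = slots,
       n_raw = total, n_sig = n_surv + n_qf, n_surv = n_surv)
}

# The annotation calls each strategy must make, derived by walking the slot
# plan (independent bookkeeping, not the pipeline's selection functions).
# Returns parallel length-4 vectors in BH / BAH / BAH_3T / BAH_UP order.
truth_calls <- function(cluster_id, db, slots, capable) {
  k <- if (!capable || is.null(slots)) 0L else nrow(slots)
  label <- target <- rep(NA_character_, 4L)
  tier <- rep("NONE", 4L)
  bits <- rep(NA_real_, 4L)
  caution <- rep(FALSE, 4L)
  if (k > 0L) {
    # BH: the top surviving slot, label recorded even when non-informative
    label[1L] <- slots$label[1L]; tier[1L] <- slots$tier[1L]
    target[1L] <- slots$target[1L]; bits[1L] <- slots$bits[1L]
    i2 <- which(slots$tier != "NONE")[1L]
    if (!is.na(i2)) {
      label[2L] <- slots$label[i2]; tier[2L] <- slots$tier[i2]
      target[2L] <- slots$target[i2]; bits[2L] <- slots$bits[i2]
    }
    i3 <- which(slots$tier == "HIGH")[1L]
    if (is.na(i3)) i3 <- which(slots$tier == "LOW")[1L]
    if (!is.na(i3)) {
      label[3L] <- slots$label[i3]; tier[3L] <- slots$tier[i3]
      target[3L] <- slots$target[i3]; bits[3L] <- slots$bits[i3]
    }
    i4 <- which(slots$up_tier != "NONE")[1L]
    if (!is.na(i4)) {
      label[4L] <- slots$up_label[i4]; tier[4L] <- slots$up_tier[i4]
      target[4L] <- slots$target[i4]; bits[4L] <- slots$bits[i4]
      caution[4L] <- slots$up_caution[i4]
    }
  }
  list(cluster_id = rep(cluster_id, 4L), db = rep(db, 4L),
       method = c("BH", "BAH", "BAH_3T", "BAH_UP"),
       label = label, tier = tier, target = target, bits = bits,
       caution = caution)
}

# Joint (multi-database) truth calls per method: max tier wins; the label
# follows PDB > PHOLD > AFDB precedence, then bitscore.
joint_truth_calls <- function(calls) {
  out <- list()
  for (method in unique(calls$method)) {
    mc <- calls[calls$method == method, , drop = FALSE]
    key_tier <- match(mc$tier, c("HIGH", "LOW", "NONE"))
    key_db <- match(mc$db, c("PDB", "PHOLD", "AFDB"))
    o <- radix_order(mc$cluster_id, key_tier, key_db,
                     -ifelse(is.na(mc$bits), -Inf, mc$bits))
    keep <- o[!duplicated(mc$cluster_id[o])]
    none <- mc$tier[keep] == "NONE"
    out[[method]] <- fast_df(
      cluster_id = mc$cluster_id[keep],
      db = rep("JOINT", length(keep)),
      method = rep(method, length(keep)),
      label = ifelse(none, NA_character_, mc$label[keep]),
      tier = mc$tier[keep],
      target = ifelse(none, NA_character_, mc$target[keep]),
      bits = ifelse(none, NA_real_, mc$bits[keep]),
      caution = ifelse(none, FALSE, mc$caution[keep]))
  }
  do.call(rbind, out)
}

#' Synthetic hit table for stress-testing the two-stage filter
#'
#' Generates hits whose E-values, alignment lDDT, same-SCOP-class
#' probabilities and aligned-window pLDDT straddle the filter thresholds,
#' including rows planted exactly on each boundary (which the strict
#' filters must remove). One dedicated query carries a constant-70 pLDDT
#' profile so its aligned-fraction mean sits exactly on the pLDDT cutoff.
#'
#' @param n Number of hits.
#' @param seed Integer seed.
#' @param n_queries Number of distinct query proteins.
#' @param thresholds [filter_thresholds()] the boundaries are planted on.
#' @return list with `hits` (FoldSeek-format data.frame, exactly `n` rows),
#'   `profiles` (named list of per-residue pLDDT profiles) and
#'   `boundary_targets` (target ids of the planted boundary rows).
#' @export
simulate_filter_fixture <- function(n = 10000L, seed = 1L, n_queries = 40L,
                                    thresholds = filter_thresholds()) {
  with_seed(seed, {
    qlen <- 120L
    qids <- sprintf("Q%03d", seq_len(n_queries))
    profiles <- lapply(seq_len(n_queries), function(i) {
      quantize(pmin(100, pmax(0, stats::rnorm(qlen, stats::runif(1L, 55, 90), 12))))
    })
    names(profiles) <- qids
    # boundary query: constant profile exactly at the pLDDT cutoff
    profiles$QBND <- rep(thresholds$min_aligned_query_plddt, qlen)
    query <- sample(qids, n, replace = TRUE)
    qstart <- sample.int(qlen %/% 2L, n, replace = TRUE)
    qend <- qstart + sample.int(qlen %/% 2L - 1L, n, replace = TRUE)
    hits <- data.frame(
      query = query,
      target = sprintf("T%06d", seq_len(n)),
      fident = quantize(stats::runif(n, 0, 1), 4L),
      alnlen = qend - qstart + 1L,
      mismatch = sample(0:50, n, replace = TRUE),
      gapopen = sample(0:5, n, replace = TRUE),
      qstart = qstart, qend = qend, tstart = qstart, tend = qend,
      evalue = quantize_sci(10^stats::runif(n, -20, 1), 3L),
      bits = quantize(stats::runif(n, 30, 600), 1L),
      prob = quantize(stats::runif(n, 0, 1), 2L),
      lddt = quantize(stats::runif(n, 0, 1), 2L),
      lddtfull = sprintf("%.3f,%.3f,%.3f", stats::runif(n), stats::runif(n), stats::runif(n)),
      stringsAsFactors = FALSE)
    # plant one row exactly on each threshold, the other axes passing wide
    b <- sample.int(n, 4L)
    hits$evalue[b] <- 1e-10
    hits$lddt[b] <- 0.9
    hits$prob[b] <- 0.9
    hits$query[b] <- qids[1L]
    hits$qstart[b] <- 1L; hits$qend[b] <- 10L
    hits$alnlen[b] <- 10L
    hits$evalue[b[1L]] <- thresholds$evalue_max
    hits$lddt[b[2L]] <- thresholds$min_aln_lddt
    hits$prob[b[3L]] <- thresholds$min_same_scop_prob
    hits$query[b[4L]] <- "QBND"
    list(hits = hits, profiles = profiles, boundary_targets = hits$target[b])
  })
}

#' @export
print.truth_manifest <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf("Truth manifest: %d clusters (%d truly unannotated), %d proteins\n",
              nrow(cl), sum(!cl$seq_annotated), sum(cl$size)))
  cat(sprintf("  hit presence (truly unannotated): PDB %.2f, AFDB %.2f, PHOLD %.2f\n",
              mean(cl$presence_PDB[!cl$seq_annotated]),
              mean(cl$presence_AFDB[!cl$seq_annotated]),
              mean(cl$presence_PHOLD[!cl$seq_annotated])))
  invisible(x)
}

#' Serialize a truth manifest as TSV files
#'
#' @param manifest Manifest from [simulate_bundle()].
#' @param dir Output directory.
#' @export
write_manifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(manifest$clusters, file.path(dir, "manifest_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest$calls, file.path(dir, "manifest_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(manifest$filter_counts, file.path(dir, "manifest_filter_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
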
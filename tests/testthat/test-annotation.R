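test_that("label classification follows the three-tier ruleset", {
  rs <- annotation_ruleset()
  expect_identical(classify_label("hypothetical protein", rs), "NONE")
  expect_identical(classify_label("Domain of unknown function (DUF2786)", rs), "LOW")
  expect_identical(classify_label("major capsid protein", rs), "HIGH")
  expect_identical(classify_label("", rs), "NONE")
  expect_identical(classify_label(NA_character_, rs), "NONE")
  expect_identical(classify_label("Uncharacterised protein", rs), "NONE")
  expect_identical(classify_label("DUF551 domain-containing protein", rs), "LOW")
  expect_identical(classify_label("putative protein", rs), "LOW")
  expect_identical(classify_label("putative tail fiber protein", rs), "HIGH")
  expect_identical(classify_label("protein of unknown function", rs), "NONE")
})

test_that("the default ruleset round-trips through its plain-text file format", {
  f <- withr::local_tempfile(fileext = ".txt")
  rs <- annotation_ruleset()
  write_ruleset(rs, f)
  expect_identical(read_ruleset(f), rs)
})

test_that("the generator's label pools classify as planted under the default ruleset", {
  pools <- foldannot:::LABEL_POOLS
  rs <- annotation_ruleset()
  for (tier in names(pools)) {
    expect_identical(classify_label(pools[[tier]], rs), rep(tier, length(pools[[tier]])),
                     label = paste("pool", tier))
  }
})

test_that("best hit transfers the top label, informative or not", {
  fx <- make_tiered_hits(c("hypothetical protein", "terminase large subunit"))
  call <- best_hit(fx$hits, fx$header_db)
  expect_identical(call$tier, "NONE")
  expect_identical(call$label, "hypothetical protein")  # recorded, counted unannotated

  fx2 <- make_tiered_hits("terminase large subunit")
  call2 <- best_hit(fx2$hits, fx2$header_db)
  expect_identical(call2$tier, "HIGH")
  expect_identical(call2$label, "terminase large subunit")

  empty <- fx$hits[0, ]
  call3 <- best_hit(empty, fx$header_db, cluster_id = "c1")
  expect_identical(call3$tier, "NONE")
  expect_identical(call3$target, NA_character_)
})

test_that("best annotated hit skips non-informative labels", {
  fx <- make_tiered_hits(c("hypothetical protein", "uncharacterized protein",
                           "tail fiber protein"))
  call <- best_annotated_hit(fx$hits, fx$header_db)
  expect_identical(call$label, "tail fiber protein")
  expect_identical(call$target, "T003")

  fx2 <- make_tiered_hits(rep("hypothetical protein", 3))
  expect_identical(best_annotated_hit(fx2$hits, fx2$header_db)$tier, "NONE")
})

test_that("tier-preferring selection rescues lower-scoring proper annotations", {
  fx <- make_tiered_hits(c("DUF2786 domain-containing protein", "portal protein"))
  expect_identical(best_annotated_hit(fx$hits, fx$header_db)$label,
                   "DUF2786 domain-containing protein")
  t3 <- best_annotated_hit_tiered(fx$hits, fx$header_db)
  expect_identical(t3$label, "portal protein")
  expect_identical(t3$tier, "HIGH")

  fx_low <- make_tiered_hits(c("hypothetical protein", "putative protein",
                               "DUF551 domain-containing protein"))
  t_low <- best_annotated_hit_tiered(fx_low$hits, fx_low$header_db)
  expect_identical(t_low$label, "putative protein")  # best LOW when no HIGH exists
  expect_identical(t_low$tier, "LOW")
})

test_that("every strategy equals a brute-force scan over the unsorted hits", {
  rs <- annotation_ruleset()
  withr::with_seed(41, {
    pools <- foldannot:::LABEL_POOLS
    for (trial in 1:25) {
      n <- sample(1:100, 1)
      labels <- unlist(pools)[sample(length(unlist(pools)), n, replace = TRUE)]
      fx <- make_tiered_hits(labels)
      shuffled <- fx$hits[sample.int(n), ]
      srt <- sort_hits(shuffled)
      tiers <- classify_label(header_labels(fx$header_db, srt$target), rs)
      # brute-force oracle: explicit predicate scans in bitscore order
      brute_first <- function(keep) {
        i <- which(keep)[1]
        if (is.na(i)) NA_character_ else srt$target[i]
      }
      expect_identical(best_hit(srt, fx$header_db, rs)$target, srt$target[1])
      expect_identical(best_annotated_hit(srt, fx$header_db, rs)$target %||% NA_character_,
                       brute_first(tiers != "NONE"))
      exp_3t <- if (any(tiers == "HIGH")) brute_first(tiers == "HIGH") else brute_first(tiers == "LOW")
      expect_identical(best_annotated_hit_tiered(srt, fx$header_db, rs)$target %||% NA_character_,
                       exp_3t)
    }
  })
})

test_that("UniProt supplementation replaces labels and flags UniParc recoveries", {
  idmap <- data.frame(
    target_id = c("T001", "T002", "T003"),
    protein_name = c("Baseplate wedge protein", "Tail fiber protein", NA),
    status = c("active", "removed_uniparc", "unmapped"),
    stringsAsFactors = FALSE)
  s1 <- supplement_with_idmap("T001", "hypothetical protein", idmap)
  expect_identical(s1, list(label = "Baseplate wedge protein", caution = FALSE))
  s2 <- supplement_with_idmap("T002", "hypothetical protein", idmap)
  expect_true(s2$caution)
  s3 <- supplement_with_idmap("T003", "hypothetical protein", idmap)
  expect_identical(s3$label, "hypothetical protein")
  expect_identical(supplement_with_idmap("T999", "x", idmap)$label, "x")

  # the UP strategy picks a hit only informative after supplementation
  fx <- make_tiered_hits(c("hypothetical protein", "hypothetical protein"))
  up <- best_annotated_hit_uniprot(fx$hits, fx$header_db, idmap)
  expect_identical(up$label, "Baseplate wedge protein")
  expect_identical(up$tier, "HIGH")
  expect_false(up$caution)
  expect_identical(best_annotated_hit(fx$hits, fx$header_db)$tier, "NONE")

  # UniParc-derived calls carry the caution flag
  idmap2 <- idmap[2, , drop = FALSE]
  fx2 <- make_tiered_hits("hypothetical protein")
  fx2$hits$target <- "T002"
  names(fx2$header_db$labels) <- "T002"
  up2 <- best_annotated_hit_uniprot(fx2$hits, fx2$header_db, idmap2)
  expect_true(up2$caution)
  expect_identical(up2$tier, "HIGH")
})

test_that("database combination takes the maximum tier with PDB precedence", {
  mk <- function(db, tier, label, bits = 100) {
    data.frame(cluster_id = "c1", db = db, method = "BAH",
               label = if (tier == "NONE") NA_character_ else label,
               tier = tier,
               target = if (tier == "NONE") NA_character_ else "t",
               bits = if (tier == "NONE") NA_real_ else bits,
               caution = FALSE, stringsAsFactors = FALSE)
  }
  j1 <- combine_databases(rbind(mk("PDB", "NONE", NA), mk("AFDB", "HIGH", "portal protein")))
  expect_identical(j1$tier, "HIGH")
  expect_identical(j1$label, "portal protein")

  j2 <- combine_databases(rbind(mk("PDB", "HIGH", "terminase"), mk("AFDB", "HIGH", "portal protein", 500)))
  expect_identical(j2$label, "terminase")  # PDB precedence beats a higher AFDB bitscore

  j3 <- combine_databases(rbind(mk("PHOLD", "LOW", "putative protein"), mk("AFDB", "HIGH", "holin")))
  expect_identical(j3$tier, "HIGH")

  expect_error(combine_databases(rbind(mk("PDB", "HIGH", "a"), mk("PDB", "HIGH", "b"))),
               "share database tag")
})

test_that("vectorized joint combination equals the per-cluster unit", {
  withr::with_seed(43, {
    rows <- list()
    for (cid in sprintf("c%02d", 1:30)) {
      for (db in c("PDB", "AFDB", "PHOLD")) {
        tier <- sample(c("NONE", "LOW", "HIGH"), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = cid, db = db, method = "BAH",
          label = if (tier == "NONE") NA_character_ else "some protein",
          tier = tier,
          target = if (tier == "NONE") NA_character_ else paste0(db, "_t"),
          bits = if (tier == "NONE") NA_real_ else round(runif(1, 50, 500), 1),
          caution = FALSE, stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, rows)
    fast <- foldannot:::joint_calls(calls)
    for (cid in unique(calls$cluster_id)) {
      unit <- combine_databases(calls[calls$cluster_id == cid, ])
      vec <- fast[fast$cluster_id == cid, ]
      rownames(vec) <- NULL
      expect_identical(vec, unit)
    }
  })
})

test_that("annotation report computes rates, compositions and top labels", {
  partition <- data.frame(protein_id = sprintf("c%02d", 1:10),
                          status = rep(c("truly_unannotated", "annotated"), c(8, 2)),
                          stringsAsFactors = FALSE)
  calls <- data.frame(
    cluster_id = sprintf("c%02d", 1:10), db = "AFDB", method = "BAH",
    label = c(rep("portal protein", 3), "putative protein", rep(NA, 6)),
    tier = c(rep("HIGH", 3), "LOW", rep("NONE", 6)),
    target = c(sprintf("t%d", 1:4), rep(NA, 6)),
    bits = c(100, 90, 80, 70, rep(NA, 6)),
    caution = FALSE, stringsAsFactors = FALSE)
  rep <- annotation_report(calls, partition)
  tu <- rep$rates[rep$rates$denominator == "truly_unannotated", ]
  expect_identical(tu$n_annotated, 4L)
  expect_identical(tu$rate, 0.5)
  expect_identical(tu$n_high, 3L)
  expect_identical(tu$n_low, 1L)
  expect_identical(rep$top_labels$label[1], "portal protein")
  expect_identical(rep$top_labels$count[1], 3L)

  empty_part <- data.frame(protein_id = sprintf("c%02d", 1:10),
                           status = "truly_unannotated", stringsAsFactors = FALSE)
  r2 <- annotation_report(calls, empty_part)
  expect_true(is.na(r2$rates$rate[r2$rates$denominator == "seq_annotated"]))

  bad <- calls; bad$cluster_id[1] <- "zz"
  expect_error(annotation_report(bad, partition), "unknown cluster")
})

test_that("tier monotonicity holds for every cluster on synthetic bundles", {
  dir <- withr::local_tempdir()
  man <- simulate_bundle(simulation_config(n_clusters = 150, seed = 53), dir)
  rep <- run_pipeline(dir)
  calls <- rep$calls
  rank_of <- function(m, db) {
    cc <- calls[calls$method == m & calls$db == db, ]
    stats::setNames(match(cc$tier, c("NONE", "LOW", "HIGH")), cc$cluster_id)
  }
  for (db in c("PDB", "AFDB", "PHOLD")) {
    bh <- rank_of("BH", db); bah <- rank_of("BAH", db); b3 <- rank_of("BAH_3T", db)
    ids <- names(bh)
    expect_true(all((bah[ids] > 1) >= (bh[ids] > 1)))   # annotated-or-not: BH <= BAH
    expect_true(all(b3[ids] >= bah[ids]))               # tier: BAH_3T >= BAH
  }
})
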
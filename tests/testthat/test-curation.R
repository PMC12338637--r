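test_that("unannotated-label detection is case-insensitive substring matching", {
  p <- curation_params()
  expect_true(is_unannotated_label("hypothetical protein PA123_gp42", p))
  expect_true(is_unannotated_label("Phage Protein", p))
  expect_false(is_unannotated_label("putative tail fiber protein", p))
  expect_false(is_unannotated_label("", p))
  expect_true(is_unannotated_label("conserved phage protein gp7", p))
})

test_that("size filter keeps the inclusive 100-850 window", {
  recs <- make_records(c(99L, 100L, 850L, 851L))
  kept <- size_filter(recs)
  expect_identical(kept$length, c(100L, 850L))
  expect_identical(nrow(size_filter(recs[0, ])), 0L)

  # 1,000 random records equal a brute-force scan, and the filter is idempotent
  withr::with_seed(5, {
    recs <- make_records(sample(50:1000, 1000, replace = TRUE))
    kept <- size_filter(recs)
    brute <- recs[vapply(recs$length, function(L) L >= 100 && L <= 850, logical(1)), ]
    expect_identical(kept, brute)
    expect_identical(size_filter(kept), kept)
  })
})

test_that("deduplication keeps first-seen records and accounts for every input", {
  recs <- make_records(c(120L, 130L, 140L))
  recs$sequence[2] <- recs$sequence[1]
  dd <- deduplicate(recs)
  expect_identical(dd$records$protein_id, c("P001", "P003"))
  expect_identical(dd$dedup_map, list(P001 = "P002"))

  all_distinct <- make_records(c(101L, 102L, 103L))
  dd2 <- deduplicate(all_distinct)
  expect_identical(dd2$records, all_distinct)
  expect_identical(length(dd2$dedup_map), 0L)
})

test_that("a planted 20% duplicate fraction is recovered exactly", {
  withr::with_seed(9, {
    base <- make_records(sample(100:400, 400, replace = TRUE))
    dup_idx <- sample(400, 100)
    dups <- base[dup_idx, ]
    dups$protein_id <- sprintf("DUP%03d", seq_len(100))
    recs <- rbind(base, dups)
    dd <- deduplicate(recs)
    expect_identical(nrow(dd$records), 400L)
    expect_identical(sum(lengths(dd$dedup_map)), 100L)
    expect_identical(nrow(dd$records) + sum(lengths(dd$dedup_map)), nrow(recs))
    expect_false(anyDuplicated(dd$records$sequence) > 0)
  })
})

test_that("the truly-unannotated split partitions representatives exactly", {
  clusters <- structure(list(r1 = "r1", r2 = c("r2", "x1"), r3 = "r3", r4 = "r4"),
                        class = "cluster_table")
  ann <- data.frame(
    protein_id = c("r1", "r2", "r3"),
    label = c("major capsid protein", "hypothetical protein", "portal protein"),
    category = c("head and packaging", "unknown function", "unknown function"),
    stringsAsFactors = FALSE)
  sp <- split_truly_unannotated(clusters, ann)
  expect_identical(sp$annotated, "r1")                 # informative label + real category
  expect_identical(sp$truly_unannotated, c("r2", "r3", "r4"))
  expect_identical(sort(c(sp$annotated, sp$truly_unannotated)),
                   sort(names(clusters)))

  ann_bad <- rbind(ann, data.frame(protein_id = "zz", label = "x", category = "tail"))
  expect_error(split_truly_unannotated(clusters, ann_bad), "not cluster representatives")
})

test_that("a planted 27% sequence-annotated fraction splits 135/365 at 500 clusters", {
  dir <- withr::local_tempdir()
  man <- simulate_bundle(simulation_config(n_clusters = 500, seed = 21), dir)
  clusters <- read_cluster_tsv(file.path(dir, "clusters.tsv"))
  ann <- read_annotation_table(file.path(dir, "annotations_seq.tsv"), "generic")
  sp <- split_truly_unannotated(clusters, ann)
  expect_identical(length(sp$annotated), 135L)
  expect_identical(length(sp$truly_unannotated), 365L)
  expect_identical(sort(sp$annotated),
                   sort(man$clusters$cluster_id[man$clusters$seq_annotated]))
})
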
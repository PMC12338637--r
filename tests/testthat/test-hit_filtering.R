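test_that("significance filter retains strictly sub-threshold E-values", {
  hits <- make_hits(3)
  hits$evalue <- c(0.01, 0.001, 0.0009)
  kept <- significance_filter(hits)
  expect_identical(kept$evalue, 0.0009)

  withr::with_seed(13, {
    hits <- make_hits(1000)
    kept <- significance_filter(hits)
    expect_identical(kept, hits[hits$evalue < 0.001, ])
    expect_identical(significance_filter(kept), kept)
  })
})

test_that("aligned-fraction mean pLDDT slices the query profile inclusively", {
  prof <- c(80, 80, 60, 60, 100)
  expect_identical(aligned_query_mean_plddt(1L, 4L, prof), 70)
  expect_identical(aligned_query_mean_plddt(5L, 5L, prof), 100)
  expect_error(aligned_query_mean_plddt(2L, 6L, prof, hit_id = "q->t"), "q->t")

  withr::with_seed(17, {
    prof <- runif(300, 0, 100)
    for (k in 1:20) {
      a <- sample(300, 1); b <- min(300, a + sample(0:50, 1))
      expect_identical(aligned_query_mean_plddt(a, b, prof), mean(prof[a:b]))
    }
  })
})

test_that("quality filter applies the strict three-way conjunction", {
  fx <- make_tiered_hits(rep("portal protein", 3))
  hits <- fx$hits
  profiles <- list(Q01 = rep(90, 50))
  hits$lddt <- c(0.4, 0.8, 0.8)
  hits$prob <- c(0.9, 0.6, 0.9)
  kept <- quality_filter(hits, profiles)
  expect_identical(kept$target, c("T002", "T003"))

  expect_error(quality_filter(hits, list()), "Q01")

  # lddtfull-based variant gates on the alignment lDDT values instead
  hits$lddtfull <- c("0.9,0.9", "0.5,0.5", "0.9,0.9")
  kept2 <- quality_filter(hits, profiles, plddt_source = "lddtfull")
  expect_identical(kept2$target, "T003")
})

test_that("filters are idempotent, order-independent and nested", {
  withr::with_seed(23, {
    hits <- make_hits(500)
    profiles <- lapply(stats::setNames(nm = sprintf("Q%02d", 1:5)),
                       function(q) runif(120, 20, 100))
    th <- filter_thresholds()
    s <- significance_filter(hits, th)
    q <- quality_filter(hits, profiles, th)
    sq <- quality_filter(s, profiles, th)
    qs <- significance_filter(q, th)
    expect_identical(sq, qs)
    expect_identical(quality_filter(sq, profiles, th), sq)
    expect_true(nrow(sq) <= nrow(s), nrow(s) <= nrow(hits))
  })
})

test_that("canonical sorting is by bitscore with deterministic tie-breaks", {
  hits <- make_hits(3)
  hits$bits <- c(50, 100, 75)
  expect_identical(sort_hits(hits)$bits, c(100, 75, 50))

  hits2 <- make_hits(2)
  hits2$bits <- c(80, 80)
  hits2$evalue <- c(1e-5, 1e-5)
  hits2$target <- c("B", "A")
  expect_identical(sort_hits(hits2)$target, c("A", "B"))

  withr::with_seed(29, {
    hits <- make_hits(500)
    hits$bits <- sample(hits$bits)  # engineered ties via quantization
    srt <- sort_hits(hits)
    ord <- order(-hits$bits, hits$evalue, hits$target, method = "radix")
    expect_identical(srt, hits[ord, ])
    expect_identical(sort(srt$target), sort(hits$target))  # permutation
  })
})

test_that("per-cluster presence tallies all membership patterns", {
  clusters <- c("c1", "c2", "c3")
  hits_by_db <- list(
    PDB = make_hits(1, query = "c1"),
    AFDB = make_hits(2, query = "c1"),
    PHOLD = make_hits(1, query = "c2"))
  pres <- per_cluster_hit_presence(hits_by_db, clusters)
  expect_identical(pres$membership$PDB, c(TRUE, FALSE, FALSE))
  expect_identical(sum(pres$pattern_counts), 3L)
  expect_identical(unname(pres$pattern_counts[["PDB+AFDB"]]), 1L)
  expect_identical(unname(pres$pattern_counts[["PHOLD"]]), 1L)
  expect_identical(unname(pres$pattern_counts[["none"]]), 1L)

  bad <- list(PDB = make_hits(1, query = "zz"))
  expect_error(per_cluster_hit_presence(bad, clusters), "zz")
})

test_that("planted per-database presence rates are recovered from the bundle", {
  dir <- withr::local_tempdir()
  man <- simulate_bundle(simulation_config(n_clusters = 300, seed = 77), dir)
  rep <- run_pipeline(dir)
  tu <- !man$clusters$seq_annotated
  for (db in c("PDB", "AFDB", "PHOLD")) {
    expect_identical(unname(rep$membership$per_db_rate[db]),
                     mean(man$clusters[[paste0("presence_", db)]][tu]))
  }
  expect_identical(sum(rep$membership$pattern_counts), sum(tu))
})
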
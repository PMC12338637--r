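test_that("identical config and seed give byte-identical bundles", {
  cfg <- simulation_config(n_clusters = 60, seed = 101)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- simulate_bundle(cfg, d1)
  m2 <- simulate_bundle(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  m1$dir <- m2$dir <- NULL
  expect_identical(m1, m2)
})

test_that("infeasible configurations fail before any file is written", {
  expect_error(simulation_config(singleton_fraction = 1, mean_cluster_size = 4),
               "singleton_fraction = 1")
  expect_error(simulation_config(singleton_fraction = 0.5, mean_cluster_size = 1.2),
               "infeasible")
  expect_error(simulation_config(seq_annotated_fraction = 1.2), "\\[0,1\\]")
  expect_error(simulation_config(coupling = 1), "coupling")
  cfg <- simulation_config()
  cfg$presence_prob$truly_unannotated[["AFDB"]] <- 2
  dir <- withr::local_tempdir()
  expect_error(simulate_bundle(cfg, file.path(dir, "x")), "outside")
  expect_false(dir.exists(file.path(dir, "x", "structures")) &&
                 length(list.files(file.path(dir, "x"))) > 0)
})

test_that("zero hit probabilities give an all-empty membership and no calls", {
  cfg <- simulation_config(n_clusters = 40, seed = 103)
  for (g in c("truly_unannotated", "seq_annotated")) {
    cfg$presence_prob[[g]][] <- 0
  }
  dir <- withr::local_tempdir()
  man <- simulate_bundle(cfg, dir)
  rep <- run_pipeline(dir)
  expect_identical(unname(rep$membership$pattern_counts[["none"]]),
                   rep$dataset$n_truly_unannotated)
  expect_true(all(rep$annotation$rates$n_annotated == 0L))
  expect_identical(rep, expected_report(man))
})

test_that("every written file is re-read losslessly by the format readers", {
  dir <- withr::local_tempdir()
  man <- simulate_bundle(simulation_config(n_clusters = 50, seed = 107), dir)
  # FoldSeek tables: read -> write -> read is the identity
  for (db in c("pdb", "afdb", "phold")) {
    p <- file.path(dir, sprintf("foldseek_%s.tsv", db))
    hits <- read_foldseek_tsv(p)
    p2 <- withr::local_tempfile(fileext = ".tsv")
    write_foldseek_tsv(hits, p2)
    expect_identical(read_foldseek_tsv(p2), hits)
  }
  recs <- read_fasta(file.path(dir, "proteins.fasta"))
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, p2)
  expect_identical(read_fasta(p2), recs)
  clusters <- read_cluster_tsv(file.path(dir, "clusters.tsv"))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_tsv(clusters, p3)
  expect_identical(read_cluster_tsv(p3), clusters)
  idmap <- read_idmap(file.path(dir, "idmap.tsv"))
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write_idmap(idmap, p4)
  expect_identical(read_idmap(p4), idmap)
  # structures and alignments agree with the manifest's planted values
  cl <- man$clusters
  for (i in sample(nrow(cl), 10)) {
    prof <- read_plddt(file.path(dir, "structures", paste0(cl$cluster_id[i], ".pdb")))
    expect_identical(mean(prof$plddt), cl$mean_plddt[i])
    expect_identical(length(prof$plddt), cl$length[i])
    msa <- read_a3m(file.path(dir, "msas", paste0(cl$cluster_id[i], ".a3m")))
    expect_identical(msa_depth_profile(msa)$max_depth, cl$max_msa_depth[i])
  }
})

test_that("generated samples match their laws at scale", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_clusters = 5000, seed = 109)
  man <- simulate_bundle(cfg, dir)
  cl <- man$clusters
  expect_identical(nrow(cl), 5000L)

  # singleton fraction and mean cluster size
  expect_equal(mean(cl$size == 1), cfg$singleton_fraction, tolerance = 0.05)
  expect_equal(mean(cl$size), cfg$mean_cluster_size, tolerance = 0.05 * cfg$mean_cluster_size)

  # group length means against the truncated log-normal expectation
  trunc_mean <- function(mu_x, sd_x, lo, hi) {
    s2 <- log(1 + (sd_x / mu_x)^2); mu <- log(mu_x) - s2 / 2
    f <- function(t) t * stats::dlnorm(t, mu, sqrt(s2))
    stats::integrate(f, lo, hi)$value /
      (stats::plnorm(hi, mu, sqrt(s2)) - stats::plnorm(lo, mu, sqrt(s2)))
  }
  m_tu <- trunc_mean(cfg$length_mean[["truly_unannotated"]],
                     cfg$length_sd[["truly_unannotated"]], 100, 850)
  m_sa <- trunc_mean(cfg$length_mean[["seq_annotated"]],
                     cfg$length_sd[["seq_annotated"]], 100, 850)
  expect_equal(mean(cl$length[!cl$seq_annotated]), m_tu, tolerance = 0.05 * m_tu)
  expect_equal(mean(cl$length[cl$seq_annotated]), m_sa, tolerance = 0.05 * m_sa)
  expect_true(mean(cl$length[cl$seq_annotated]) > mean(cl$length[!cl$seq_annotated]))

  # pLDDT regimes around the depth tipping point
  expect_equal(mean(cl$mean_plddt[!cl$shallow]), 82, tolerance = 0.05 * 82)
  expect_equal(mean(cl$mean_plddt[cl$shallow]), 55, tolerance = 0.05 * 55)
  expect_true(all(cl$max_msa_depth[cl$shallow] < 10))
  expect_true(all(cl$max_msa_depth[!cl$shallow] >= 10))

  unlink(dir, recursive = TRUE)
})

test_that("the filter fixture plants exact boundary rows", {
  fx <- simulate_filter_fixture(n = 500, seed = 113)
  th <- filter_thresholds()
  b <- match(fx$boundary_targets, fx$hits$target)
  expect_identical(fx$hits$evalue[b[1]], th$evalue_max)
  expect_identical(fx$hits$lddt[b[2]], th$min_aln_lddt)
  expect_identical(fx$hits$prob[b[3]], th$min_same_scop_prob)
  prof <- fx$profiles[[fx$hits$query[b[4]]]]
  expect_identical(aligned_query_mean_plddt(fx$hits$qstart[b[4]], fx$hits$qend[b[4]], prof),
                   th$min_aligned_query_plddt)
})
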
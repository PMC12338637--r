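test_that("mean pLDDT is the arithmetic residue mean, bounded by the profile", {
  expect_identical(mean_plddt(c(70, 70, 70)), 70)
  expect_identical(mean_plddt(c(80, 80, 60, 60)), 70)
  expect_error(mean_plddt(numeric()), "empty")
  withr::with_seed(2, {
    prof <- runif(200, 0, 100)
    expect_identical(mean_plddt(prof), sum(prof) / length(prof))
    expect_true(mean_plddt(prof) >= min(prof) && mean_plddt(prof) <= max(prof))
  })
})

test_that("MSA depth counts per-position non-gap coverage", {
  msa1 <- list(ids = "q", seqs = "ACDEF", query_id = "q", depth = 1L)
  d <- msa_depth_profile(msa1)
  expect_identical(d$depths, rep(1L, 5))
  expect_identical(d$max_depth, 1L)

  msa3 <- list(ids = c("q", "a", "b"), seqs = c("ACDEF", "ACDEF", "ACDEF"))
  expect_identical(msa_depth_profile(msa3)$max_depth, 3L)

  # staggered gaps against a hand count
  msa <- list(ids = c("q", "a", "b"), seqs = c("ACDEF", "A--EF", "-CD-F"))
  expect_identical(msa_depth_profile(msa)$depths, c(2L, 2L, 2L, 2L, 3L))
  expect_identical(msa_depth_profile(msa)$max_depth, 3L)
  # sequence-count mode reports the alignment size instead
  expect_identical(msa_depth_profile(msa, mode = "sequences")$max_depth, 3L)
  expect_error(msa_depth_profile(list(ids = character(), seqs = character())), "empty")
})

make_qc <- function(n, depth, plddt, length = NULL) {
  data.frame(protein_id = sprintf("P%04d", seq_len(n)),
             length = length %||% rep(200L, n),
             mean_plddt = plddt, max_msa_depth = depth,
             stringsAsFactors = FALSE)
}

test_that("depth contrast recovers the planted tipping-point regimes", {
  # identical groups: no effect, p >= 0.5
  qc <- make_qc(40, depth = rep(c(5L, 50L), each = 20), plddt = rep(60, 40))
  expect_true(depth_contrast(qc)$p >= 0.5)

  withr::with_seed(31, {
    qc <- make_qc(400, depth = rep(c(50L, 3L), each = 200),
                  plddt = c(rnorm(200, 82, 12), rnorm(200, 55, 16)))
    ct <- depth_contrast(qc)
    expect_true(ct$mean[1] > ct$mean[2])
    expect_lt(ct$p, 0.01)
    expect_identical(ct$n, c(200L, 200L))
  })

  qc_all_shallow <- make_qc(10, depth = rep(2L, 10), plddt = runif(10, 40, 90))
  expect_error(depth_contrast(qc_all_shallow), "depth >= 10")
})

test_that("length correlations behave under binning and resampling", {
  withr::with_seed(7, {
    len <- sample(100:600, 300, replace = TRUE)
    qc_lin <- make_qc(300, depth = rep(20L, 300),
                      plddt = 10 + 0.1 * len, length = len)
    expect_equal(binned_length_correlation(qc_lin, mode = "raw")$pooled_r2, 1.0)

    # pLDDT independent of length: raw r^2 stays near zero
    qc_null <- make_qc(2000, depth = rep(20L, 2000),
                       plddt = runif(2000, 40, 95),
                       length = sample(100:850, 2000, replace = TRUE))
    expect_lt(binned_length_correlation(qc_null, mode = "raw")$pooled_r2, 0.05)

    pb <- binned_length_correlation(qc_null, mode = "per_bin")
    expect_true(all(pb$bins$r2[!is.na(pb$bins$r2)] <= pb$max_r2))
    expect_lt(pb$mean_r2, 0.05)

    u1 <- binned_length_correlation(qc_null, mode = "undersample", seed = 99)
    u2 <- binned_length_correlation(qc_null, mode = "undersample", seed = 99)
    expect_identical(u1, u2)
    o1 <- binned_length_correlation(qc_null, mode = "oversample", seed = 99)
    expect_false(identical(u1$pooled_r2, o1$pooled_r2))
    expect_error(binned_length_correlation(qc_null, mode = "oversample"), "seed")

    one_bin <- make_qc(10, depth = rep(20L, 10), plddt = runif(10, 50, 90),
                       length = rep(120L, 10) + sample(0:30, 10, TRUE))
    expect_error(binned_length_correlation(one_bin, mode = "per_bin"), "single length bin")
  })
})

test_that("the QC table assembles per-protein statistics from profiles and MSAs", {
  profiles <- list(P1 = c(80, 90), P2 = c(50, 60, 70))
  msas <- list(P1 = list(ids = c("q", "a"), seqs = c("MK", "MK")),
               P2 = list(ids = "q", seqs = "MKV"))
  qc <- structure_qc_table(profiles, msas)
  expect_identical(qc$protein_id, c("P1", "P2"))
  expect_identical(qc$mean_plddt, c(85, 60))
  expect_identical(qc$max_msa_depth, c(2L, 1L))
  expect_identical(qc$length, c(2L, 3L))
  expect_error(structure_qc_table(profiles, msas["P1"]), "no MSA")
})
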
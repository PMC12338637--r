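# Random but feasible simulation configs for the end-to-end equivalence
# checks: every rate the generator plants is drawn from a range that keeps
# all report statistics well-defined at n_clusters >= 250.
random_config <- function(seed, n_clusters = 500L) {
  withr::with_seed(seed, {
    simulation_config(
      n_clusters = n_clusters,
      seed = seed + 1000L,
      seq_annotated_fraction = runif(1, 0.15, 0.35),
      singleton_fraction = runif(1, 0.5, 0.75),
      mean_cluster_size = runif(1, 3, 5),
      shallow_depth_fraction = runif(1, 0.12, 0.25),
      presence_prob = list(
        truly_unannotated = c(PDB = runif(1, 0.05, 0.20),
                              AFDB = runif(1, 0.30, 0.60),
                              PHOLD = runif(1, 0.50, 0.80)),
        seq_annotated = c(PDB = runif(1, 0.20, 0.40),
                          AFDB = runif(1, 0.50, 0.80),
                          PHOLD = runif(1, 0.80, 1.00))),
      p_annotated_given_hit = list(
        truly_unannotated = c(PDB = runif(1, 0.50, 0.90),
                              AFDB = runif(1, 0.30, 0.60),
                              PHOLD = runif(1, 0.20, 0.50)),
        seq_annotated = c(PDB = 0.95, AFDB = 0.75, PHOLD = 0.99)),
      p_top_annotated = c(PDB = runif(1, 0.7, 1), AFDB = runif(1, 0.2, 0.5),
                          PHOLD = runif(1, 0.3, 0.7)),
      low_outranks_high = c(PDB = runif(1, 0, 0.10), AFDB = runif(1, 0.10, 0.30),
                            PHOLD = runif(1, 0, 0.20)),
      up_rescue_prob = c(PDB = runif(1, 0.1, 0.4), AFDB = runif(1, 0.2, 0.5),
                         PHOLD = 0),
      extra_hits_lambda = runif(1, 1, 3),
      coupling = runif(1, 0.3, 0.7))
  })
}
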
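# Shared fixtures built in code.

# Small deterministic feature cohort with a given transmission strength.
make_cohort <- function(n_dyads = 6, n_features = 20, alpha = 0.5, seed = 42,
                        modality = "FC") {
  simulate_dyad_features(n_dyads, n_features, alpha = alpha, seed = seed,
                         modality = modality)
}

# Perfect-transmission cohort: child vectors identical to parent vectors.
make_copy_cohort <- function(n_dyads = 6, n_features = 12, seed = 7) {
  set.seed(seed)
  p <- matrix(rnorm(n_dyads * n_features), n_dyads, n_features,
              dimnames = list(sprintf("p%02d", 1:n_dyads),
                              sprintf("f%03d", 1:n_features)))
  c_ <- p
  rownames(c_) <- sprintf("c%02d", 1:n_dyads)
  dyad_cohort(feature_matrix(c_, "FC"), feature_matrix(p, "FC"))
}

# The worked 3-dyad similarity matrix used throughout the spec-level checks.
hand_sim <- function() {
  matrix(c(0.9, 0.1, 0.4,
           0.2, 0.8, 0.3,
           0.5, 0.9, 0.6), nrow = 3)
}

# Small synthetic atlas wrapper.
make_atlas <- function(n_nodes = 30, n_networks = 10) {
  dyadprint:::synthetic_atlas(n_nodes, n_networks)
}

extdata <- function(name) {
  system.file("extdata", name, package = "dyadprint", mustWork = TRUE)
}
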
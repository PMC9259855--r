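# Small shared fixtures built in code.

band_alpha <- function() band_definition("alpha", 8, 12)
band_beta <- function() band_definition("beta", 13, 30)
band_gamma <- function() band_definition("gamma", 31, 80)

# a small graph-level cohort configuration (no signals)
small_cohort_config <- function(n_subjects = 20, n_nodes = 24, seed = 1,
                                ...) {
  cohort_config(n_subjects = n_subjects, n_nodes = n_nodes,
                bands = list(beta = band_beta(), gamma = band_gamma()),
                fs = 600, seed = seed, ...)
}

# analytic series from independent band-limited noise
noise_analytic <- function(n_nodes, duration, fs, band = band_alpha(),
                           seed = 1) {
  X <- generate_coupled_band_series(n_nodes, band, duration, fs,
                                    envelope_coupling = 0, seed = seed)
  analytic_signal(X, fs, band = band)
}

star_graph <- function(n_leaves = 4) {
  A <- matrix(0, n_leaves + 1, n_leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  A
}

path_graph <- function(n = 3) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

complete_graph <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}
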
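# shared fixtures, all built in code

flat_eem <- function(value = 2, sample_id = "flat") {
  eem(sample_id, std_ex_grid(), std_em_grid(),
      matrix(value, 45, 301), units = "QSU")
}

random_eem <- function(seed = 1, sample_id = "rnd") {
  set.seed(seed)
  eem(sample_id, std_ex_grid(), std_em_grid(),
      matrix(runif(45 * 301, 0.1, 5), 45, 301), units = "QSU")
}

# small three-fluorophore truth with well-separated components
truth3 <- function(seed = 5, noise_frac = 0, K = 10) {
  comps <- default_component_library()[c("C1", "C3", "C5")]
  set.seed(seed)
  C <- matrix(runif(K * 3, 1, 10), K, 3,
              dimnames = list(paste0("S", seq_len(K)), names(comps)))
  prof <- component_profiles(comps)
  mx <- max(vapply(seq_len(K), function(k)
    max(prof$S_ex %*% diag(C[k, ], 3) %*% prof$S_em), numeric(1)))
  synthetic_truth(comps, C, noise_sigma = noise_frac * mx, seed = seed)
}

# six-fluorophore truth at the full default library positions
truth6 <- function(seed = 11, noise_frac = 0.01, K = 10) {
  comps <- default_component_library()
  set.seed(seed)
  C <- matrix(runif(K * 6, 1, 10), K, 6,
              dimnames = list(paste0("S", seq_len(K)), names(comps)))
  prof <- component_profiles(comps)
  mx <- max(vapply(seq_len(K), function(k)
    max(prof$S_ex %*% diag(C[k, ], 6) %*% prof$S_em), numeric(1)))
  synthetic_truth(comps, C, noise_sigma = noise_frac * mx, seed = seed)
}
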
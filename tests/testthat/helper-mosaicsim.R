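# Small fixtures, built in code.

tiny_founder_cfg <- function(S = 3, n_h = 20, tau = 0.3, L = 2e6,
                             theta = 1e-4, rho = 1e-4) {
  founder_config(S = S, n_h_per_source = n_h, tau = tau, theta = theta,
                 rho = rho, map_length_bp = L)
}

tiny_panel <- function(seed = 1, ...) {
  simulate_founders(tiny_founder_cfg(...), seed = seed)
}

# Per-site source codes of one chromosome, straight from its tracts.
expand_tract_sources <- function(tr, positions) {
  tr$src[findInterval(positions, tr$ends) + 1L]
}

# Hand-built sample_set for toy examples (no tracts).
make_sample_set <- function(alleles, anc1, anc2, positions = NULL,
                            pops = NULL, admixed = NULL, S = NULL,
                            L = 4e7) {
  alleles <- as.matrix(alleles)
  M <- nrow(alleles)
  o <- ncol(alleles) / 2L
  anc1 <- matrix(as.raw(as.matrix(anc1)), M, o)
  anc2 <- matrix(as.raw(as.matrix(anc2)), M, o)
  if (is.null(S)) S <- max(as.integer(c(anc1, anc2)))
  if (is.null(positions)) positions <- (seq_len(M) - 0.5) / M
  if (is.null(pops)) pops <- rep(1L, o)
  if (is.null(admixed)) admixed <- rep(TRUE, o)
  structure(list(
    alleles = matrix(as.raw(alleles), M, 2L * o),
    anc1 = anc1, anc2 = anc2,
    tracts = NULL,
    positions = positions,
    bp_positions = as.integer(1 + floor(positions * L)),
    pop_of_individual = as.integer(pops),
    is_admixed = as.logical(admixed),
    S = as.integer(S),
    map_length_bp = L,
    generation = 0L,
    kept_index = seq_len(M)), class = "sample_set")
}

# A small end-to-end dataset used by several files.
small_dataset <- function(seed = 99, G = 8L, n_h = 20, L = 4e5,
                          o_src = 5L, o_admx = 8L) {
  set.seed(seed)
  panel <- simulate_founders(tiny_founder_cfg(n_h = n_h, L = L, tau = 0.3))
  contrib <- rbind(diag(3), rep(1 / 3, 3))
  pops <- found_populations(panel, contrib, sizes = rep(15L, 4))
  pops <- run_forward(pops, reproduction_schedule(4, G), mu_site = 0)
  smp <- sample_individuals(pops, c(rep(o_src, 3), o_admx),
                            is_admixed = c(FALSE, FALSE, FALSE, TRUE))
  filter_monomorphic(smp)
}

# Mean pairwise off-diagonal value of a symmetric matrix.
mean_offdiag <- function(m) mean(m[lower.tri(m)])

# Naive double-loop accuracy oracle over dense arrays.
alpha_naive <- function(Z, X, mask = NULL, admixed = NULL) {
  o <- dim(Z)[1]; M <- dim(Z)[2]
  if (is.null(mask)) mask <- matrix(TRUE, o, M)
  if (is.null(admixed)) admixed <- rep(TRUE, o)
  tot <- 0; n <- 0
  for (i in seq_len(o)) {
    for (m in seq_len(M)) {
      if (admixed[i] && mask[i, m]) {
        tot <- tot + 1 - sum(abs(Z[i, m, ] - X[i, m, ])) / 2
        n <- n + 1
      }
    }
  }
  tot / n
}
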
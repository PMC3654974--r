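# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; the oracles deliberately re-derive quantities with
# different (slower, simpler) code than the package implementation.

# A small but structurally consistent parameter set: 3 chromosomes, toy
# breeding counts (20 potential-dam + 8 drone-producing queens per
# generation, 4 dams, 2 dummy sires of 4 sisters).
toy_params <- function(...) {
  bee_params(
    "reduced",
    chrom_table = data.frame(chrom = 1:3,
                             length_bp = c(2e6, 1.5e6, 1e6),
                             n_loci = c(250L, 200L, 150L)),
    n_hist_generations = 30L, n_sire_queens = 16L, n_dam_queens = 4L,
    n_keep = 200L, n_qtl = 55L,
    qtl_class_sizes = c(direct = 20L, pleiotropic = 15L, maternal = 20L),
    n_potential = 20L, n_dpq = 8L, n_dams = 4L, n_dummy = 2L,
    group_size = 4L, n_dpq_dams = 2L,
    ...
  )
}

# Memoised toy simulation shared across test files.
.fixture_env <- new.env(parent = emptyenv())
get_toy_sim <- function(seed = 4242) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    p <- toy_params()
    set.seed(seed)
    map <- build_genome_map(p$chrom_table, p$recomb_rate_cM_per_Mb)
    base <- run_historical(map, p$n_hist_generations, p$n_sire_queens,
                           p$n_dam_queens, p$mutation_rate)
    panel <- select_panel(base, p$n_keep, p$maf_cutoff, p$n_qtl,
                          p$qtl_class_sizes)
    sim <- run_breeding(base, panel, p)
    .fixture_env[[key]] <- list(params = p, map = map, base = base,
                                panel = panel, sim = sim)
  }
  .fixture_env[[key]]
}

# Independent classical tabular-method oracle (Wright/Henderson numerator
# relationship matrix, sire path 0.5), plain R.
classical_A_oracle <- function(dam, sire) {
  n <- length(dam)
  A <- diag(n)
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    for (j in seq_len(i - 1)) {
      v <- 0
      if (!is.na(d)) v <- v + 0.5 * A[j, d]
      if (!is.na(s)) v <- v + 0.5 * A[j, s]
      A[i, j] <- A[j, i] <- v
    }
    if (!is.na(d) && !is.na(s)) A[i, i] <- 1 + 0.5 * A[d, s]
  }
  A
}

# Random pedigree sorted parents-before-offspring; founders have no parents.
random_pedigree <- function(n, n_founders = 8) {
  dam <- rep(NA_integer_, n)
  sire <- rep(NA_integer_, n)
  for (i in (n_founders + 1):n) {
    dam[i] <- sample.int(i - 1L, 1)
    sire[i] <- sample.int(i - 1L, 1)
  }
  data.frame(id = seq_len(n), dam_id = dam, sire_id = sire)
}

# Generalized-least-squares / BLUP oracle by direct inversion of the full
# record covariance matrix, with the random effects stacked as
# u = (u1', u2')' and Var(u) = G0 (x) K (Kronecker).
gls_oracle <- function(y, worker_pos, queen_pos, G0, sigma2e, K) {
  n <- nrow(K)
  nr <- length(y)
  Z <- matrix(0, nr, 2 * n)
  for (r in seq_len(nr)) {
    Z[r, worker_pos[r]] <- 1
    Z[r, n + queen_pos[r]] <- 1
  }
  Sigma_u <- kronecker(G0, K)
  V <- Z %*% Sigma_u %*% t(Z) + diag(nr) * sigma2e
  Vi <- solve(V)
  X <- matrix(1, nr, 1)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- Sigma_u %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b),
       ebv_direct = as.numeric(u[seq_len(n)]),
       ebv_maternal = as.numeric(u[n + seq_len(n)]))
}

# Small hand-built evaluation problem on a toy pedigree: founders f1 f2 and
# dummy sire ds, two offspring (o1, o2 = queen-like, their "workers" w1, w2),
# records on (w1, o1) and (w2, o2).
toy_eval_problem <- function(seed = 99, Pp = 0.367) {
  set.seed(seed)
  ped <- data.frame(
    id = 1:7,
    dam_id = c(NA, NA, NA, 1, 1, 4, 5),
    sire_id = c(NA, NA, NA, 3, 3, 3, 3))
  K <- build_A(ped, Pp = Pp)
  y <- c(2.1, -0.7)
  list(ped = ped, K = K, y = y,
       worker_pos = c(6L, 7L), queen_pos = c(4L, 5L),
       G0 = matrix(c(1.3, -0.4, -0.4, 2.0), 2), sigma2e = 2.5)
}
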
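test_that("QTL effects respect class structure and sign rules", {
  fx <- get_toy_sim()
  panel <- fx$panel
  set.seed(21)
  for (mode in c("none", "negative")) {
    eff <- assign_qtl_effects(panel, mode)
    cls <- panel$qtl_class
    expect_true(all(eff$a_direct[cls == "maternal"] == 0))
    expect_true(all(eff$a_maternal[cls == "direct"] == 0))
    expect_true(all(eff$a_maternal[cls != "direct"] != 0))
    expect_true(all(eff$a_direct[cls != "maternal"] != 0))
    # pleiotropic magnitudes shared
    expect_equal(abs(eff$a_maternal[cls == "pleiotropic"]),
                 abs(eff$a_direct[cls == "pleiotropic"]))
    if (mode == "negative")
      expect_true(all(sign(eff$a_maternal[cls == "pleiotropic"]) ==
                      -sign(eff$a_direct[cls == "pleiotropic"])))
  }
})

test_that("negative-mode TBV correlation concentrates at the analytic ratio", {
  # idealized unlinked population in Hardy-Weinberg at p = 0.5: the expected
  # maternal-direct correlation with 86/78/86 classes and shared pleiotropic
  # magnitudes is -78/164 ~ -0.476
  set.seed(31)
  panel <- structure(list(
    qtl_idx = 1:250,
    qtl_class = factor(rep(c("direct", "pleiotropic", "maternal"),
                           c(86, 78, 86)),
                       levels = c("direct", "pleiotropic", "maternal")),
    base_freq = rep(0.5, 250)), class = "marker_panel")
  n_queens <- 1500
  r <- replicate(25, {
    eff <- assign_qtl_effects(panel, "negative")
    dos <- matrix(rbinom(n_queens * 250, 2, 0.5), n_queens, 250)
    tbv <- beeblup:::compute_tbv_matrix(dos, eff)
    cor(tbv$tbv_maternal, tbv$tbv_direct)
  })
  expect_equal(mean(r), -78 / 164, tolerance = 0.03)
  # no-correlation mode averages to zero
  r0 <- replicate(25, {
    eff <- assign_qtl_effects(panel, "none")
    dos <- matrix(rbinom(n_queens * 250, 2, 0.5), n_queens, 250)
    tbv <- beeblup:::compute_tbv_matrix(dos, eff)
    cor(tbv$tbv_maternal, tbv$tbv_direct)
  })
  expect_lt(abs(mean(r0)), 3 * sd(r0) / sqrt(25))
})

test_that("TBVs equal the locus-by-locus substitution-effect sum", {
  fx <- get_toy_sim()
  panel <- fx$panel
  nq <- length(panel$qtl_idx)
  set.seed(41)
  eff <- assign_qtl_effects(panel, "none")
  L <- fx$map$n_loci_total
  genome <- list(hap1 = sample(1:2, L, TRUE), hap2 = sample(1:2, L, TRUE))
  got <- compute_tbv(genome, panel, eff)
  # brute-force oracle: explicit loop over QTL
  tm <- 0; td <- 0
  for (j in seq_len(nq)) {
    l <- panel$qtl_idx[j]
    a1 <- genome$hap1[l]; a2 <- genome$hap2[l]
    q <- if (a1 == 2 && a2 == 2) 1 else if (a1 == 1 && a2 == 1) -1 else 0
    tm <- tm + q * eff$a_maternal[j]
    td <- td + q * eff$a_direct[j]
  }
  expect_equal(got$tbv_maternal, tm)
  expect_equal(got$tbv_direct, td)
  expect_equal(got$tbv_overall, tm + td)
  # all-heterozygous genome scores zero everywhere
  het <- list(hap1 = rep(1L, L), hap2 = rep(2L, L))
  expect_equal(compute_tbv(het, panel, eff)$tbv_overall, 0)
  # single homozygous maternal QTL contributes its effect exactly
  m1 <- which(panel$qtl_class == "maternal")[1]
  g1 <- list(hap1 = rep(1L, L), hap2 = rep(2L, L))
  g1$hap1[panel$qtl_idx[m1]] <- 2L
  expect_equal(compute_tbv(g1, panel, eff)$tbv_maternal, eff$a_maternal[m1])
})

test_that("variance components follow the heritability identities", {
  tbv <- data.frame(tbv_maternal = c(1, 3, 5, 7), tbv_direct = c(2, 2, 4, 4))
  tbv$tbv_overall <- tbv$tbv_maternal + tbv$tbv_direct
  vc <- derive_variances(tbv, 0.25)
  expect_equal(vc$sigma2_p, var(tbv$tbv_maternal) / 0.25)
  expect_equal(vc$sigma2_g,
               vc$sigma2_q + vc$sigma2_w + 2 * vc$sigma_qw)
  expect_equal(vc$sigma2_e, vc$sigma2_p - vc$sigma2_g)
  expect_equal(vc$h2_d, vc$sigma2_w / vc$sigma2_p)
  expect_equal(vc$r_qw, cor(tbv$tbv_maternal, tbv$tbv_direct))
  # location invariance
  shifted <- tbv
  shifted$tbv_maternal <- shifted$tbv_maternal + 100
  shifted$tbv_direct <- shifted$tbv_direct - 42
  vc2 <- derive_variances(shifted, 0.25)
  expect_equal(vc2$sigma2_e, vc$sigma2_e)
  # infeasible heritability errors with diagnostics
  hot <- data.frame(tbv_maternal = rnorm(50), tbv_direct = rnorm(50) * 10)
  expect_error(derive_variances(hot, 0.9), "infeasible heritability")
  expect_error(derive_variances(tbv, 1.5), "invalid configuration")
})

test_that("colony phenotypes add a residual to the overall TBV", {
  tbv <- data.frame(tbv_maternal = rnorm(10), tbv_direct = rnorm(10))
  tbv$tbv_overall <- tbv$tbv_maternal + tbv$tbv_direct
  # zero residual variance: phenotype equals the overall TBV
  rec <- simulate_phenotypes(1:10, 101:110, tbv, 0)
  expect_equal(rec$y, tbv$tbv_overall)
  expect_equal(rec$queen_id, 1:10)
  expect_equal(rec$worker_id, 101:110)
  # queen and worker share one record per colony
  expect_equal(nrow(rec), 10)
  # phenotypic variance matches sigma2_p at scale
  set.seed(51)
  n <- 10000
  t2 <- data.frame(tbv_maternal = rnorm(n), tbv_direct = rnorm(n))
  t2$tbv_overall <- t2$tbv_maternal + t2$tbv_direct
  s2e <- 6
  rec2 <- simulate_phenotypes(seq_len(n), seq_len(n) + n, t2, s2e)
  s2p <- var(t2$tbv_overall) + s2e
  se_var <- s2p * sqrt(2 / (n - 1))
  expect_lt(abs(var(rec2$y) - s2p), 3 * se_var)
  expect_error(simulate_phenotypes(1:2, 3:4, t2[1:2, ], -1), "negative")
})
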
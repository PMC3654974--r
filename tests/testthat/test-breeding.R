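test_that("drones are haploid meiotic gametes of their mother", {
  fx <- get_toy_sim()
  map <- fx$map
  L <- map$n_loci_total
  set.seed(61)
  # homozygous queen: all drones identical
  hom <- list(hap1 = rep(1L, L), hap2 = rep(1L, L))
  d <- produce_drones(hom, 6, map)
  expect_equal(ncol(d), 6)
  expect_true(all(d == 1L))
  # heterozygous queen: drones carry only her alleles
  q <- list(hap1 = sample(1:2, L, TRUE), hap2 = sample(1:2, L, TRUE))
  d2 <- produce_drones(q, 8, map)
  for (k in 1:8)
    expect_true(all(d2[, k] == q$hap1 | d2[, k] == q$hap2))
  expect_error(produce_drones(q, 0, map), "invalid configuration")
})

test_that("breeding scheme restores per-generation counts and roles", {
  fx <- get_toy_sim()
  p <- fx$params
  ped <- build_pedigree(fx$sim)
  for (g in 1:p$n_generations) {
    expect_equal(sum(ped$role == "queen" & ped$generation == g &
                     ped$subrole %in% c("potential_dam", "dam")),
                 p$n_potential)
    expect_equal(sum(ped$subrole == "drone_producing" & ped$generation == g),
                 p$n_dpq)
    expect_equal(sum(ped$role == "dummy_sire" & ped$generation == g),
                 p$n_dummy)
  }
  # dams: n_dams per generation 0..(n_generations-1)
  for (g in 1:(p$n_generations - 1))
    expect_equal(sum(ped$subrole == "dam" & ped$generation == g), p$n_dams)
  expect_equal(sum(ped$subrole == "base_dam"), p$n_dam_queens)
  # genotyped queens and their workers
  n_genotyped <- p$n_dam_queens + p$n_generations * p$n_potential
  expect_equal(sum(ped$genotyped), n_genotyped)
  expect_equal(sum(ped$role == "worker"), n_genotyped)
  # juveniles: last-generation potential-dams, genotyped but unphenotyped
  juv <- ped$generation == p$n_generations & ped$subrole == "potential_dam"
  expect_equal(sum(juv), p$n_potential)
  expect_true(all(ped$genotyped[juv]))
  expect_false(any(ped$phenotyped[juv]))
})

test_that("pedigree links realize polyandry and overlapping generations", {
  fx <- get_toy_sim()
  p <- fx$params
  ped <- build_pedigree(fx$sim)
  qs <- ped[ped$role == "queen" & ped$generation >= 1, ]
  # every non-base queen's sire is a dummy sire whose member queens come from
  # two generations before her (one generation before her dam)
  sires <- ped[match(qs$sire_id, ped$id), ]
  dams <- ped[match(qs$dam_id, ped$id), ]
  expect_true(all(sires$role == "dummy_sire"))
  expect_true(all(dams$generation == qs$generation - 1))
  later <- qs$generation >= 3
  expect_true(all(sires$generation[later] == qs$generation[later] - 2))
  # worker entries: dam is the queen, sire is the queen's mate
  w <- ped[ped$role == "worker", ]
  wq <- ped[match(w$dam_id, ped$id), ]
  expect_true(all(wq$genotyped))
  expect_equal(w$sire_id, wq$mate_id)
  # each mated dam shares her dummy sire with exactly dams_per_sire dams
  dams_per_sire <- p$n_dams / p$n_dummy
  for (g in 0:(p$n_generations - 1)) {
    sel <- ped$subrole %in% c("dam", "base_dam") & ped$generation == g
    expect_true(all(table(ped$mate_id[sel]) == dams_per_sire))
  }
  # dummy-sire member sisters: group_size drone-producing queens share the
  # dummy sire's dam and sire
  ds <- ped[ped$role == "dummy_sire" & ped$generation >= 1, ]
  dpq <- ped[ped$subrole == "drone_producing", ]
  for (i in seq_len(nrow(ds))) {
    members <- dpq$dam_id == ds$dam_id[i] & dpq$generation == ds$generation[i]
    expect_equal(sum(members), p$group_size)
    expect_true(all(dpq$sire_id[members] == ds$sire_id[i]))
  }
})

test_that("colony mates fall into super-sib / full-sib / half-sib classes", {
  fx <- get_toy_sim()
  p <- fx$params
  sim <- fx$sim
  q <- sim$queens[sim$queens$generation >= 1, ]
  ped <- sim$ped
  q$dam <- ped$dam_id[match(q$id, ped$id)]
  drones_per_sire <- p$group_size * p$drones_per_member
  within_sire <- (q$drone - 1L) %% drones_per_sire + 1L
  member <- (within_sire - 1L) %/% p$drones_per_member + 1L
  found <- c(super = FALSE, full = FALSE, half = FALSE)
  for (d in unique(q$dam)) {
    sibs <- which(q$dam == d)
    if (length(sibs) < 2) next
    for (a in sibs) for (b in sibs) {
      if (a >= b) next
      if (q$drone[a] == q$drone[b]) found["super"] <- TRUE
      else if (member[a] == member[b]) found["full"] <- TRUE
      else found["half"] <- TRUE
    }
  }
  expect_true(all(found))
  # super-sibs receive the identical paternal gamete: with 0/1/2 dosages and
  # a shared maternal meiosis distribution this shows as identical paternal
  # contribution at every panel locus for drones drawn twice
  ss <- NULL
  for (d in unique(q$dam)) {
    sibs <- which(q$dam == d)
    dr <- q$drone[sibs]
    dup <- sibs[dr %in% dr[duplicated(dr)]]
    if (length(dup) >= 2) { ss <- dup[1:2]; break }
  }
  expect_false(is.null(ss))
})

test_that("pedigree integrity violations are caught", {
  fx <- get_toy_sim()
  sim <- fx$sim
  broken <- sim
  broken$ped$dam_id[broken$ped$role == "worker"][1] <- 999999L
  expect_error(build_pedigree(broken), "dangling dam")
  swapped <- sim
  i <- which(swapped$ped$generation == 2 & swapped$ped$role == "queen")[1]
  swapped$ped$dam_id[i] <- swapped$ped$id[nrow(swapped$ped)]
  expect_error(build_pedigree(swapped), "precede")
})

test_that("the same seed reproduces the simulation bit-for-bit", {
  p <- toy_params()
  run <- function() {
    set.seed(777)
    map <- build_genome_map(p$chrom_table, p$recomb_rate_cM_per_Mb)
    base <- run_historical(map, 10, p$n_sire_queens, p$n_dam_queens,
                           p$mutation_rate)
    panel <- select_panel(base, p$n_keep, p$maf_cutoff, p$n_qtl,
                          p$qtl_class_sizes)
    run_breeding(base, panel, p)
  }
  s1 <- run()
  s2 <- run()
  expect_identical(s1$ped, s2$ped)
  expect_identical(s1$dosage_snp, s2$dosage_snp)
  expect_identical(s1$dosage_qtl, s2$dosage_qtl)
})

test_that("simulation exports are plain-text round-trippable", {
  fx <- get_toy_sim()
  dir <- tempfile()
  eff <- local({set.seed(9); assign_qtl_effects(fx$panel, "negative")})
  tbv <- beeblup:::compute_tbv_matrix(fx$sim$dosage_qtl, eff)
  write_simulation(fx$sim, tbvs = tbv, dir = dir)
  ped <- read.csv(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(ped), nrow(fx$sim$ped))
  geno <- read.delim(file.path(dir, "genotypes.tsv"))
  expect_equal(dim(geno), c(nrow(fx$sim$queens),
                            length(fx$panel$snp_idx) + 1L))
  expect_true(all(as.matrix(geno[, -1]) %in% 0:2))
  unlink(dir, recursive = TRUE)
})
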
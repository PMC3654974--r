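#' Produce drones from a queen
#'
#' Drones are haploid: each drone is a single meiotic gamete of its mother
#' queen and contributes his entire haploid genome as the paternal gamete of
#' any offspring he sires (so two offspring sired by the same drone are
#' "super-sibs" with identical paternal gametes). No mutation is applied
#' during the breeding phase.
#'
#' @param queen list with allele vectors/matrices \code{hap1}, \code{hap2}.
#' @param n number of drones.
#' @param map a \code{\link{genome_map}}.
#' @return Integer matrix of \code{n} haploid drone genomes (loci in rows).
#' @export
produce_drones <- function(queen, n, map) {
  if (n < 1) stop("invalid configuration: need at least one drone")
  meiosis(queen, map, n = n)
}

# Internal constructor of pedigree record batches.
new_ped_batch <- function(id, role, subrole, dam_id, sire_id, generation,
                          genotyped, phenotyped, mate_id, in_A) {
  data.frame(id = id, role = role, subrole = subrole,
             dam_id = dam_id, sire_id = sire_id, generation = generation,
             genotyped = genotyped, phenotyped = phenotyped,
             mate_id = mate_id, in_A = in_A)
}

#' Run the five-generation breeding phase
#'
#' Simulates the breeding population on top of a historical base population:
#' the base provides 50 dam queens and 500 sire queens; the sire queens form
#' two founder cohorts of 25 dummy sires (10 members each) that mate the
#' generation-0 (base) and generation-1 dams. Every later dummy-sire cohort
#' consists of 25 groups of 10 sister drone-producing queens, so the queens
#' constituting a dummy sire are always one generation older than the dam
#' queens they mate (overlapping generations). Each generation, 10% of the
#' 500 potential-dam queens are randomly selected as dams, each dam mates
#' exactly one dummy sire (two dams per sire), produces 10 potential-dam
#' queens, and 25 of the 50 dams additionally produce 10 drone-producing
#' queens each, restoring the 500/250 per-generation counts. Polyandry is
#' modelled by each dummy sire offering 20 drones (2 per member queen); every
#' offspring queen's paternal gamete is one of the mate's drones drawn
#' uniformly with replacement.
#'
#' @param base a \code{\link{run_historical}} result (its dam-queen count must
#'   equal \code{params$n_dams} and its sire-queen count
#'   \code{2 * params$n_dpq}).
#' @param panel a \code{\link{select_panel}} result (defines the loci at which
#'   genotyped queens are scored).
#' @param params a \code{\link{bee_params}} object.
#' @return An object of class \code{bee_sim}: the full pedigree, the genotype
#'   dosage matrices (queens x SNP and queens x QTL, 0/1/2 copies of allele
#'   2) for the genotyped queens, and index bookkeeping for evaluation.
#' @export
run_breeding <- function(base, panel, params) {
  map <- base$map
  np <- params$n_potential; nd <- params$n_dams; ndpq <- params$n_dpq
  nsire <- params$n_dummy; gs <- params$group_size
  dpm <- params$drones_per_member; ndd <- params$n_dpq_dams
  ngen <- params$n_generations
  off_per_dam <- np %/% nd
  dpq_per_dam <- ndpq %/% ndd
  drones_per_sire <- gs * dpm
  if (length(base$dam_cols) != nd)
    stop("configuration error: base dam-queen count must equal n_dams")
  if (length(base$sire_cols) != 2L * ndpq)
    stop("configuration error: base sire-queen count must equal 2 * n_dpq")

  next_id <- 0L
  take_ids <- function(n) {
    ids <- next_id + seq_len(n)
    next_id <<- next_id + n
    ids
  }
  ped <- list()
  panel_loci <- c(panel$snp_idx, panel$qtl_idx)
  n_snp <- length(panel$snp_idx)
  n_genotyped <- nd + ngen * np
  dosage <- matrix(0L, n_genotyped, length(panel_loci))
  geno_row <- 0L
  queens <- list()

  score_queens <- function(hap1, hap2, ids, generation, drone = NA_integer_) {
    n <- length(ids)
    rows <- geno_row + seq_len(n)
    dosage[rows, ] <<- t((hap1[panel_loci, , drop = FALSE] == 2L) +
                         (hap2[panel_loci, , drop = FALSE] == 2L))
    geno_row <<- geno_row + n
    queens[[length(queens) + 1L]] <<-
      data.frame(id = ids, generation = generation, row = rows,
                 drone = drone)
  }

  # --- base generation (generation 0) ---
  base_dam_ids <- take_ids(nd)
  ped[["base_dams"]] <- new_ped_batch(
    base_dam_ids, "queen", "base_dam", NA_integer_, NA_integer_, 0L,
    TRUE, TRUE, NA_integer_, TRUE)
  score_queens(base$hap1[, base$dam_cols, drop = FALSE],
               base$hap2[, base$dam_cols, drop = FALSE], base_dam_ids, 0L)

  # two founder dummy-sire cohorts from the 500 base sire queens
  sire_perm <- sample(base$sire_cols)
  cohortA_members <- matrix(sire_perm[seq_len(ndpq)], gs, nsire)
  cohortB_members <- matrix(sire_perm[ndpq + seq_len(ndpq)], gs, nsire)
  cohortA_ids <- take_ids(nsire)
  cohortB_ids <- take_ids(nsire)
  ped[["cohortA"]] <- new_ped_batch(
    cohortA_ids, "dummy_sire", "none", NA_integer_, NA_integer_, 0L,
    FALSE, FALSE, NA_integer_, TRUE)
  ped[["cohortB"]] <- new_ped_batch(
    cohortB_ids, "dummy_sire", "none", NA_integer_, NA_integer_, 0L,
    FALSE, FALSE, NA_integer_, TRUE)

  # drones of a cohort: drones_per_sire gametes per dummy sire, sire-major
  cohort_drones <- function(hap1, hap2, member_cols) {
    idx <- rep(as.vector(member_cols), each = dpm)
    meiosis_batch(hap1, hap2, idx, map)
  }

  # mate assignment for one generation of queens: dams get exactly
  # dams_per_sire = nd / nsire each; the remaining queens draw uniformly
  assign_mates <- function(queen_ids, dam_ids, sire_ids) {
    mate <- setNames(rep(NA_integer_, length(queen_ids)),
                     as.character(queen_ids))
    mate[as.character(dam_ids)] <- sample(rep(sire_ids, nd %/% nsire))
    rest <- setdiff(queen_ids, dam_ids)
    if (length(rest))
      mate[as.character(rest)] <- sample(sire_ids, length(rest),
                                         replace = TRUE)
    mate
  }

  # state of the current dam generation
  cur <- list(ids = base_dam_ids, hap1 = base$hap1[, base$dam_cols, drop = FALSE],
              hap2 = base$hap2[, base$dam_cols, drop = FALSE],
              dam_ids = base_dam_ids)  # all base dams are dams
  mate_of <- assign_mates(cur$ids, cur$dam_ids, cohortA_ids)
  # queue of dummy-sire cohorts: the cohort mating generation-g dams is
  # element g+1 (base dams use cohort A, generation-1 dams cohort B, and
  # generation-g dams for g >= 2 the cohort built from generation-(g-1)
  # drone-producing queens)
  sire_queue <- list(
    list(ids = cohortA_ids, hap1 = base$hap1, hap2 = base$hap2,
         members = cohortA_members),
    list(ids = cohortB_ids, hap1 = base$hap1, hap2 = base$hap2,
         members = cohortB_members))
  all_mates <- mate_of

  for (g in seq_len(ngen)) {
    cohort <- sire_queue[[g]]
    drones <- cohort_drones(cohort$hap1, cohort$hap2, cohort$members)
    sire_of_dam <- mate_of[as.character(cur$dam_ids)]
    sire_pos <- match(sire_of_dam, cohort$ids)

    # offspring potential-dam queens
    pd_ids <- take_ids(np)
    dam_rep <- rep(seq_len(nd), each = off_per_dam)
    m_gam <- meiosis_batch(cur$hap1, cur$hap2,
                           match(cur$dam_ids, cur$ids)[dam_rep], map)
    drone_pick <- (sire_pos[dam_rep] - 1L) * drones_per_sire +
      sample.int(drones_per_sire, np, replace = TRUE)
    p_gam <- drones[, drone_pick, drop = FALSE]
    ped[[paste0("pd_gen", g)]] <- new_ped_batch(
      pd_ids, "queen", "potential_dam", cur$dam_ids[dam_rep],
      sire_of_dam[dam_rep], g, TRUE, g < ngen, NA_integer_, TRUE)
    score_queens(m_gam, p_gam, pd_ids, g, drone = drone_pick)

    # offspring drone-producing queens from a random subset of the dams
    dpq_dam_sel <- sort(sample(seq_len(nd), ndd))
    dpq_ids <- take_ids(ndpq)
    dpq_dam_rep <- rep(dpq_dam_sel, each = dpq_per_dam)
    dpq_m <- meiosis_batch(cur$hap1, cur$hap2,
                           match(cur$dam_ids, cur$ids)[dpq_dam_rep], map)
    dpq_pick <- (sire_pos[dpq_dam_rep] - 1L) * drones_per_sire +
      sample.int(drones_per_sire, ndpq, replace = TRUE)
    dpq_p <- drones[, dpq_pick, drop = FALSE]
    ped[[paste0("dpq_gen", g)]] <- new_ped_batch(
      dpq_ids, "queen", "drone_producing", cur$dam_ids[dpq_dam_rep],
      sire_of_dam[dpq_dam_rep], g, FALSE, FALSE, NA_integer_, FALSE)

    # the 10 sisters of one drone-producing dam form one new dummy sire
    new_cohort_ids <- take_ids(nsire)
    ped[[paste0("cohort_gen", g)]] <- new_ped_batch(
      new_cohort_ids, "dummy_sire", "none", cur$dam_ids[dpq_dam_sel],
      sire_of_dam[dpq_dam_sel], g, FALSE, FALSE, NA_integer_, TRUE)
    sire_queue[[length(sire_queue) + 1L]] <-
      list(ids = new_cohort_ids, hap1 = dpq_m, hap2 = dpq_p,
           members = matrix(seq_len(ndpq), gs, nsire))

    # select next dams among the new potential-dam queens; assign mates for
    # every new queen's own colony (worker paternity), from the next cohort
    dam_sel <- if (g < ngen) sort(sample(seq_len(np), nd)) else integer(0)
    dam_ids_new <- pd_ids[dam_sel]
    mate_of <- assign_mates(pd_ids, dam_ids_new, sire_queue[[g + 1L]]$ids)
    all_mates <- c(all_mates, mate_of)
    cur <- list(ids = pd_ids, hap1 = m_gam, hap2 = p_gam,
                dam_ids = dam_ids_new)
  }

  ped <- do.call(rbind, ped)
  rownames(ped) <- NULL
  # mark selected dams
  dam_ids_all <- unique(stats::na.omit(ped$dam_id))
  ped$subrole[ped$id %in% dam_ids_all & ped$subrole == "potential_dam"] <- "dam"
  ped$mate_id <- all_mates[as.character(ped$id)]

  # one average worker per genotyped (base-dam or potential-dam) queen; the
  # worker is the queen x her-mate cross and shares the colony record
  qmask <- ped$genotyped
  worker_ids <- next_id + seq_len(sum(qmask))
  workers <- new_ped_batch(
    worker_ids, "worker", "none", ped$id[qmask], ped$mate_id[qmask],
    ped$generation[qmask], FALSE, ped$phenotyped[qmask], NA_integer_, TRUE)
  next_id <- next_id + sum(qmask)
  worker_of <- setNames(worker_ids, as.character(ped$id[qmask]))
  ped <- rbind(ped, workers)

  queens <- do.call(rbind, queens)
  queens$worker_id <- worker_of[as.character(queens$id)]
  queens$juvenile <- queens$generation == ngen
  queens$phenotyped <- ped$phenotyped[match(queens$id, ped$id)]

  structure(list(
    ped = ped,
    queens = queens,
    dosage_snp = dosage[, seq_len(n_snp), drop = FALSE],
    dosage_qtl = dosage[, n_snp + seq_along(panel$qtl_idx), drop = FALSE],
    panel = panel,
    params = params
  ), class = "bee_sim")
}

#' @export
print.bee_sim <- function(x, ...) {
  cat("bee_sim: ", nrow(x$ped), " pedigree entries (",
      sum(x$ped$role == "queen"), " queens, ",
      sum(x$ped$role == "worker"), " workers, ",
      sum(x$ped$role == "dummy_sire"), " dummy sires); ",
      nrow(x$queens), " genotyped queens, ",
      sum(x$queens$juvenile), " juvenile\n", sep = "")
  invisible(x)
}

#' Extract and validate the full pedigree
#'
#' Returns the pedigree table of a breeding simulation after checking
#' referential integrity (every recorded dam/sire id exists and precedes its
#' offspring; dummy-sire member cohorts are generation-consistent).
#'
#' @param sim a \code{\link{run_breeding}} result.
#' @return data.frame with one row per pedigree entry: \code{id},
#'   \code{role} (queen / worker / dummy_sire), \code{subrole}, \code{dam_id},
#'   \code{sire_id}, \code{generation}, \code{genotyped}, \code{phenotyped},
#'   \code{mate_id}, and \code{in_A} (whether the entry receives a row in the
#'   relationship matrices; drone-producing queens are recorded but evaluated
#'   only through their dummy-sire groups).
#' @export
build_pedigree <- function(sim) {
  ped <- sim$ped
  pos <- match(ped$dam_id, ped$id)
  if (any(!is.na(ped$dam_id) & is.na(pos)))
    stop("pedigree integrity error: dangling dam reference")
  if (any(pos >= seq_len(nrow(ped)), na.rm = TRUE))
    stop("pedigree integrity error: dam does not precede offspring")
  pos <- match(ped$sire_id, ped$id)
  if (any(!is.na(ped$sire_id) & is.na(pos)))
    stop("pedigree integrity error: dangling sire reference")
  if (any(pos >= seq_len(nrow(ped)), na.rm = TRUE))
    stop("pedigree integrity error: sire does not precede offspring")
  if (any(ped$role[pos[!is.na(pos)]] != "dummy_sire"))
    stop("pedigree integrity error: sire is not a dummy sire")
  ped
}

#' Write pedigree, phenotype and genotype files
#'
#' Plain-text exports of a simulated dataset: pedigree CSV (empty string for
#' missing parents), colony phenotype CSV, TBV CSV, and the SNP genotype
#' matrix of the genotyped queens as a headered TSV of 0/1/2 allele-2 counts.
#'
#' @param sim a \code{\link{run_breeding}} result.
#' @param records colony records from \code{\link{simulate_phenotypes}}.
#' @param tbvs TBV table aligned with \code{sim$queens}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, records = NULL, tbvs = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- sim$ped[, c("id", "role", "subrole", "dam_id", "sire_id",
                     "generation", "genotyped", "phenotyped")]
  write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE, na = "")
  if (!is.null(records))
    write.csv(records, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  if (!is.null(tbvs)) {
    out <- cbind(queen_id = sim$queens$id, tbvs)
    write.csv(out, file.path(dir, "tbv.csv"), row.names = FALSE)
  }
  geno <- as.data.frame(sim$dosage_snp)
  names(geno) <- paste0("snp", seq_along(sim$panel$snp_idx))
  geno <- cbind(queen_id = sim$queens$id, geno)
  utils::write.table(geno, file.path(dir, "genotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
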
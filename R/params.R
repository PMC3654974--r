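#' Honey bee chromosome table
#'
#' Physical lengths (bp) of the 16 honey bee linkage groups and the number of
#' simulated loci per chromosome at the full simulation scale (100,000 loci in
#' total over 219,629,612 bp). Locus counts per chromosome follow the relative
#' SNP density of the honey bee genome assembly.
#'
#' @return A data.frame with columns \code{chrom}, \code{length_bp},
#'   \code{n_loci}.
#' @export
honeybee_chrom_table <- function() {
  data.frame(
    chrom = 1:16,
    length_bp = c(29893408L, 15549267L, 13234341L, 12718334L, 14363272L,
                  18472937L, 13219345L, 13546544L, 11120453L, 12965953L,
                  14726556L, 11902654L, 10288499L, 10253655L, 10167229L,
                  7207165L),
    n_loci = c(14137L, 6335L, 7119L, 5589L, 6330L, 7877L, 5973L, 6235L,
               5578L, 5068L, 6957L, 5812L, 5082L, 4874L, 3879L, 3155L)
  )
}

# Rescale per-chromosome locus counts to a new total, preserving proportions
# (largest-remainder rounding so the counts sum exactly to `total`).
rescale_loci <- function(tab, total) {
  raw <- tab$n_loci * total / sum(tab$n_loci)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  tab$n_loci <- as.integer(base)
  tab
}

#' Simulation parameters for the honey bee breeding study
#'
#' Bundles every tunable of the simulation: genome map, historical base
#' population, marker/QTL panel, breeding scheme structure, and evaluation
#' constants. Two presets are provided. \code{"full"} is the study scale
#' (1000 historical generations, 100,000 loci, 44,000 panel loci).
#' \code{"reduced"} keeps every structural count of the breeding scheme
#' (500 potential-dam queens and 250 drone-producing queens per generation, 50
#' dams, 25 dummy sires of 10 sisters, 2550 genotyped queens, ...) but scales
#' the genome down to 10,000 loci, the panel to 4,000 loci and the historical
#' phase to 200 generations, which preserves the mutation-drift-recombination
#' equilibrium character of the base population at desk-scale runtimes.
#'
#' @param scale \code{"reduced"} (default) or \code{"full"}.
#' @param ... named overrides for any parameter (e.g. \code{n_hist_generations},
#'   \code{n_potential}, \code{n_qtl}). Structural overrides must keep the
#'   scheme consistent (see Details).
#'
#' @details Structural consistency requirements, checked at construction:
#'   \itemize{
#'     \item \code{n_dpq} = \code{n_dummy * group_size} (each dummy sire is a
#'       group of \code{group_size} sister drone-producing queens);
#'     \item \code{n_dams} divides \code{n_potential}, \code{n_dummy} divides
#'       \code{n_dams} (every dummy sire serves \code{n_dams / n_dummy} dams);
#'     \item \code{n_dpq_dams <= n_dams} and \code{n_dpq_dams * dpq_per_dam =
#'       n_dpq};
#'     \item \code{n_sire_queens = 2 * n_dpq}: the base sire queens provide the
#'       two founder cohorts of dummy sires that mate the generation-1 and
#'       generation-2 dams (overlapping generations: dummy sires are built from
#'       queens one generation older than the dams they mate).
#'   }
#'   QTL class sizes are (direct, pleiotropic, maternal) = (86, 78, 86) at any
#'   scale unless overridden.
#'
#' @return An object of class \code{bee_params} (a named list).
#' @export
bee_params <- function(scale = c("reduced", "full"), ...) {
  scale <- match.arg(scale)
  p <- list(
    scale = scale,
    # genome
    chrom_table = honeybee_chrom_table(),
    recomb_rate_cM_per_Mb = 19,
    locus_placement = "uniform",
    mutation_rate = 0.0025,
    # historical base population
    n_hist_generations = 1000L,
    n_sire_queens = 500L,
    n_dam_queens = 50L,
    # marker/QTL panel
    n_keep = 44000L,
    maf_cutoff = 0.05,
    n_qtl = 250L,
    qtl_class_sizes = c(direct = 86L, pleiotropic = 78L, maternal = 86L),
    # breeding scheme (five overlapping generations)
    n_generations = 5L,
    n_potential = 500L,
    n_dpq = 250L,
    n_dams = 50L,
    n_dummy = 25L,
    group_size = 10L,
    n_dpq_dams = 25L,
    drones_per_member = 2L,
    # evaluation constants
    paternal_path = 0.367,
    blend_w = 0.99
  )
  if (scale == "reduced") {
    p$n_hist_generations <- 200L
    p$chrom_table <- rescale_loci(p$chrom_table, 10000L)
    p$n_keep <- 4000L
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_bee_params(structure(p, class = "bee_params"))
}

validate_bee_params <- function(p) {
  stopifnot(
    all(p$chrom_table$length_bp > 0), all(p$chrom_table$n_loci > 0),
    p$recomb_rate_cM_per_Mb > 0,
    p$mutation_rate >= 0, p$mutation_rate <= 1,
    p$n_hist_generations >= 0,
    p$n_sire_queens >= 1, p$n_dam_queens >= 1,
    p$n_keep >= p$n_qtl
  )
  if (p$n_qtl != sum(p$qtl_class_sizes))
    stop("invalid configuration: n_qtl must equal the sum of qtl_class_sizes")
  if (p$n_dpq != p$n_dummy * p$group_size)
    stop("invalid configuration: n_dpq must equal n_dummy * group_size")
  if (p$n_potential %% p$n_dams != 0)
    stop("invalid configuration: n_dams must divide n_potential")
  if (p$n_dams %% p$n_dummy != 0)
    stop("invalid configuration: n_dummy must divide n_dams")
  if (p$n_dpq %% p$n_dpq_dams != 0)
    stop("invalid configuration: n_dpq_dams must divide n_dpq")
  if (p$n_dpq_dams > p$n_dams)
    stop("invalid configuration: n_dpq_dams cannot exceed n_dams")
  if (p$n_sire_queens != 2L * p$n_dpq)
    stop("invalid configuration: n_sire_queens must equal 2 * n_dpq ",
         "(two founder dummy-sire cohorts)")
  p
}

#' @export
print.bee_params <- function(x, ...) {
  cat("bee_params (scale: ", x$scale, ")\n", sep = "")
  cat("  genome: ", nrow(x$chrom_table), " chromosomes, ",
      sum(x$chrom_table$n_loci), " loci, ",
      x$recomb_rate_cM_per_Mb, " cM/Mb\n", sep = "")
  cat("  history: ", x$n_hist_generations, " generations, ",
      x$n_sire_queens, " sire + ", x$n_dam_queens, " dam queens\n", sep = "")
  cat("  panel: keep ", x$n_keep, " (MAF > ", x$maf_cutoff, "), ",
      x$n_qtl, " QTL (", paste(x$qtl_class_sizes, collapse = "/"), ")\n",
      sep = "")
  cat("  breeding: ", x$n_generations, " generations x (",
      x$n_potential, " potential-dam + ", x$n_dpq, " drone-producing queens), ",
      x$n_dams, " dams, ", x$n_dummy, " dummy sires\n", sep = "")
  cat("  evaluation: Pp = ", x$paternal_path, ", w = ", x$blend_w, "\n",
      sep = "")
  invisible(x)
}
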
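#' Simulate the historical random-mating base population
#'
#' Runs a discrete-generation random-mating population of constant size
#' (\code{n_sire} sire queens + \code{n_dam} dam queens) forward for
#' \code{n_generations} with meiosis, Haldane recombination and symmetric
#' bidirectional mutation, producing a base population in mutation-drift
#' equilibrium with linkage disequilibrium. Every offspring receives a
#' mutated gamete from a uniformly drawn dam and a mutated gamete from a
#' uniformly drawn sire; all historical individuals are kept diploid. Founders
#' at the start of the historical phase carry alleles drawn Bernoulli(0.5).
#'
#' @param map a \code{\link{genome_map}}.
#' @param n_generations number of historical generations (0 returns the
#'   founders unchanged).
#' @param n_sire,n_dam numbers of sire queens and dam queens kept constant
#'   every generation.
#' @param mutation_rate per-locus, per-gamete, per-generation mutation
#'   probability (0.0025 at the study scale).
#' @return An object of class \code{base_population}: haplotype matrices
#'   \code{hap1}/\code{hap2} (loci x individuals; dam queens in columns
#'   \code{dam_cols}, sire queens in \code{sire_cols}), the per-locus
#'   frequency \code{base_freq} of allele 2 in the final generation, and the
#'   map.
#' @export
run_historical <- function(map, n_generations, n_sire, n_dam, mutation_rate) {
  if (n_sire < 1 || n_dam < 1)
    stop("invalid configuration: zero population size")
  if (n_generations < 0)
    stop("invalid configuration: negative generation count")
  n <- n_sire + n_dam
  L <- map$n_loci_total
  hap1 <- matrix(as.integer(runif(L * n) < 0.5) + 1L, L, n)
  hap2 <- matrix(as.integer(runif(L * n) < 0.5) + 1L, L, n)
  dam_cols <- seq_len(n_dam)
  sire_cols <- n_dam + seq_len(n_sire)
  if (n_generations > 0) {
    for (g in seq_len(n_generations)) {
      dams <- sample(dam_cols, n, replace = TRUE)
      sires <- sample(sire_cols, n, replace = TRUE)
      new1 <- cpp_mutate_batch(meiosis_batch(hap1, hap2, dams, map),
                               mutation_rate)
      new2 <- cpp_mutate_batch(meiosis_batch(hap1, hap2, sires, map),
                               mutation_rate)
      hap1 <- new1
      hap2 <- new2
    }
  }
  structure(list(
    hap1 = hap1, hap2 = hap2,
    dam_cols = dam_cols, sire_cols = sire_cols,
    base_freq = (rowSums(hap1 == 2L) + rowSums(hap2 == 2L)) / (2 * n),
    map = map
  ), class = "base_population")
}

#' @export
print.base_population <- function(x, ...) {
  cat("base_population: ", length(x$dam_cols), " dam queens + ",
      length(x$sire_cols), " sire queens, ",
      nrow(x$hap1), " loci (mean allele-2 frequency ",
      round(mean(x$base_freq), 3), ")\n", sep = "")
  invisible(x)
}

#' Select the marker and QTL panel from the base population
#'
#' Keeps the \code{n_keep} loci with the highest minor allele frequency in
#' the base population (all strictly above \code{maf_cutoff}); of these, the
#' \code{n_qtl} loci with the highest MAF become QTL and the remainder become
#' the SNP marker panel. QTL are randomly partitioned into direct-only,
#' pleiotropic and maternal-only classes of the given sizes. Ties in the MAF
#' ranking are broken by ascending locus index (stable, reproducible panels).
#'
#' @param base a \code{\link{run_historical}} result.
#' @param n_keep total panel size (SNP + QTL); 44,000 at the study scale.
#' @param maf_cutoff minimum minor allele frequency (exclusive).
#' @param n_qtl number of QTL.
#' @param class_sizes named integer vector \code{c(direct, pleiotropic,
#'   maternal)}; (86, 78, 86) at the study scale.
#' @return An object of class \code{marker_panel}: sorted locus indices
#'   \code{snp_idx} and \code{qtl_idx}, \code{qtl_class} (factor aligned with
#'   \code{qtl_idx}), per-locus \code{maf} and base allele-2 frequencies.
#' @export
select_panel <- function(base, n_keep = 44000L, maf_cutoff = 0.05,
                         n_qtl = 250L,
                         class_sizes = c(direct = 86L, pleiotropic = 78L,
                                         maternal = 86L)) {
  if (n_qtl != sum(class_sizes))
    stop("invalid configuration: class sizes must sum to n_qtl")
  p <- base$base_freq
  maf <- pmin(p, 1 - p)
  eligible <- sum(maf > maf_cutoff)
  if (eligible < n_keep)
    stop(sprintf(
      "panel selection error: only %d loci exceed MAF cutoff %.3g (need %d, shortfall %d)",
      eligible, maf_cutoff, n_keep, n_keep - eligible))
  ord <- order(maf, -seq_along(maf), decreasing = TRUE)
  kept <- ord[seq_len(n_keep)]
  qtl <- sort(kept[seq_len(n_qtl)])
  snp <- sort(kept[-seq_len(n_qtl)])
  cls <- factor(sample(rep.int(names(class_sizes), class_sizes)),
                levels = c("direct", "pleiotropic", "maternal"))
  structure(list(
    snp_idx = snp, qtl_idx = qtl, qtl_class = cls,
    maf = maf, base_freq = p,
    n_keep = n_keep, maf_cutoff = maf_cutoff
  ), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel: ", length(x$snp_idx), " SNPs + ", length(x$qtl_idx),
      " QTL (", paste(table(x$qtl_class), collapse = "/"),
      "), MAF cutoff > ", x$maf_cutoff, "\n", sep = "")
  invisible(x)
}

# Mean r^2 linkage disequilibrium between locus pairs, given haplotype
# matrices and a two-column matrix of locus index pairs.
ld_r2_pairs <- function(hap1, hap2, pairs) {
  H <- cbind(hap1, hap2) == 2L
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- H[pairs[k, 1], ]
    b <- H[pairs[k, 2], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)^2
  }, 0)
  mean(r2, na.rm = TRUE)
}
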
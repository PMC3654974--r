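#' Haldane mapping function
#'
#' Converts a map distance in Morgans into a recombination fraction,
#' \eqn{R = 0.5 (1 - e^{-2d})}, assuming crossovers occur without
#' interference.
#'
#' @param d map distance in Morgans (non-negative).
#' @return Recombination fraction in \code{[0, 0.5)}.
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("invalid configuration: negative map distance")
  0.5 * (1 - exp(-2 * d))
}

#' Build a genetic map for the simulated genome
#'
#' Lays loci out along each chromosome and converts adjacent-locus physical
#' distances into recombination fractions with the Haldane mapping function,
#' using a uniform genome-wide recombination rate (19 cM/Mb for the honey
#' bee).
#'
#' @param chrom_table data.frame with columns \code{length_bp} and
#'   \code{n_loci} (one row per chromosome), e.g.
#'   \code{\link{honeybee_chrom_table}()}.
#' @param recomb_rate_cM_per_Mb recombination rate in cM per Mb.
#' @param locus_placement \code{"uniform"}: loci evenly spaced along the
#'   chromosome; \code{"random"}: positions drawn uniformly without
#'   replacement (uses the current RNG stream).
#' @return An object of class \code{genome_map}: per-locus positions (1-based
#'   bp), chromosome assignment, per-interval recombination fractions and the
#'   per-locus source-switch probabilities used by \code{\link{meiosis}}
#'   (0.5 at every chromosome start for the fair-coin choice of the starting
#'   haplotype).
#' @export
build_genome_map <- function(chrom_table,
                             recomb_rate_cM_per_Mb = 19,
                             locus_placement = c("uniform", "random")) {
  locus_placement <- match.arg(locus_placement)
  if (!all(c("length_bp", "n_loci") %in% names(chrom_table)))
    stop("invalid configuration: chrom_table needs length_bp and n_loci")
  if (any(chrom_table$length_bp <= 0) || any(chrom_table$n_loci <= 0))
    stop("invalid configuration: non-positive chromosome length or locus count")
  if (recomb_rate_cM_per_Mb <= 0)
    stop("invalid configuration: non-positive recombination rate")
  n_chrom <- nrow(chrom_table)
  positions <- vector("list", n_chrom)
  r_adjacent <- vector("list", n_chrom)
  for (c in seq_len(n_chrom)) {
    L <- chrom_table$length_bp[c]
    k <- chrom_table$n_loci[c]
    pos <- if (locus_placement == "uniform") {
      if (k == 1L) as.integer(round((L + 1) / 2))
      else as.integer(round(seq(1, L, length.out = k)))
    } else {
      sort(sample.int(L, k))
    }
    if (any(diff(pos) <= 0))
      stop("invalid configuration: locus positions not strictly increasing")
    # bp -> cM -> Morgans, then Haldane
    d <- diff(pos) * recomb_rate_cM_per_Mb / 1e6 / 100
    positions[[c]] <- pos
    r_adjacent[[c]] <- haldane_r(d)
  }
  n_loci <- chrom_table$n_loci
  chrom_of <- rep.int(seq_len(n_chrom), n_loci)
  chrom_start <- cumsum(c(1L, n_loci[-n_chrom]))
  switch_prob <- unlist(lapply(seq_len(n_chrom), function(c)
    c(0.5, r_adjacent[[c]])), use.names = FALSE)
  structure(list(
    chrom_table = chrom_table,
    n_loci_total = sum(n_loci),
    positions = unlist(positions, use.names = FALSE),
    chrom = chrom_of,
    chrom_start = chrom_start,
    r_adjacent = r_adjacent,
    r_max = vapply(r_adjacent, function(r) if (length(r)) max(r) else 0, 0),
    switch_prob = switch_prob,
    morgans = vapply(seq_len(n_chrom), function(c)
      sum(diff(positions[[c]])) * recomb_rate_cM_per_Mb / 1e6 / 100, 0),
    recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
    locus_placement = locus_placement
  ), class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map: ", nrow(x$chrom_table), " chromosomes, ",
      x$n_loci_total, " loci, ", format(sum(x$chrom_table$length_bp),
      big.mark = ","), " bp, ", round(sum(x$morgans), 2), " Morgans (",
      x$recomb_rate_cM_per_Mb, " cM/Mb, ", x$locus_placement,
      " placement)\n", sep = "")
  invisible(x)
}

#' Simulate meiosis
#'
#' Produces crossover-mosaic gametes: each chromosome starts from a
#' fair-coin-chosen parental haplotype and switches source haplotype between
#' adjacent loci with the map's Haldane recombination fraction (per-interval
#' Bernoulli switches, i.e. a no-interference crossover process).
#'
#' @param parent a diploid genome: list with integer allele vectors (or
#'   loci-by-n matrices) \code{hap1} and \code{hap2} over \{1, 2\}.
#' @param map a \code{\link{genome_map}}.
#' @param n number of gametes to draw.
#' @return An integer matrix of \code{n} gamete haplotypes (loci in rows).
#' @export
meiosis <- function(parent, map, n = 1L) {
  h1 <- as.matrix(parent$hap1)
  h2 <- as.matrix(parent$hap2)
  if (nrow(h1) != map$n_loci_total || nrow(h2) != map$n_loci_total)
    stop("dimension error: parent genome does not conform to map")
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"
  cpp_meiosis_batch(h1, h2, rep.int(1L, n), map$switch_prob,
                    map$chrom_start - 1L, map_r_max(map))
}

# Upper bound of the per-interval switch probabilities per chromosome; maps
# with hand-edited switch probabilities (tests, sensitivity checks) are
# honoured by taking the elementwise maximum with the stored Haldane bound.
map_r_max <- function(map) {
  n_chrom <- length(map$chrom_start)
  vapply(seq_len(n_chrom), function(c) {
    idx <- which(map$chrom == c)[-1]
    if (!length(idx)) return(0)
    max(map$switch_prob[idx])
  }, 0)
}

# Batch meiosis over a population: one gamete per entry of `parent_idx`
# (columns of hap1/hap2).
meiosis_batch <- function(hap1, hap2, parent_idx, map) {
  if (nrow(hap1) != map$n_loci_total)
    stop("dimension error: haplotypes do not conform to map")
  cpp_meiosis_batch(hap1, hap2, as.integer(parent_idx), map$switch_prob,
                    map$chrom_start - 1L, map_r_max(map))
}

#' Apply bidirectional mutation to gametes
#'
#' Each locus flips allele (1 to 2 or 2 to 1) independently with the given
#' per-locus probability. In the simulation pipeline mutation acts only
#' during the historical phase, up to the base generation.
#'
#' @param gametes integer vector or matrix of alleles over \{1, 2\}.
#' @param rate per-locus mutation probability in \code{[0, 1]}.
#' @return Object of the same shape with mutated alleles.
#' @export
mutate_gametes <- function(gametes, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("invalid configuration: mutation rate outside [0, 1]")
  g <- as.matrix(gametes)
  storage.mode(g) <- "integer"
  out <- cpp_mutate_batch(g, rate)
  if (is.null(dim(gametes))) dim(out) <- NULL
  out
}

#' Write a genome map as a tab-separated table
#'
#' One row per locus: chromosome, 0-based locus index within the chromosome,
#' 1-based physical position, and the recombination fraction to the next
#' locus (empty for the last locus of a chromosome).
#'
#' @param map a \code{\link{genome_map}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_genome_map <- function(map, path) {
  r_next <- unlist(lapply(map$r_adjacent, function(r) c(r, NA_real_)),
                   use.names = FALSE)
  idx <- unlist(lapply(map$chrom_table$n_loci, function(k) seq_len(k) - 1L),
                use.names = FALSE)
  df <- data.frame(chrom = map$chrom, locus_index = idx,
                   position_bp = map$positions,
                   recomb_fraction_to_next = r_next)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
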
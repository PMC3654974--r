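#' Numerator relationship matrix with uncertain paternity
#'
#' Builds the honey-bee numerator relationship matrix by a tabular recursion
#' in which the usual 0.5 sire path is replaced by a paternal path
#' coefficient \code{Pp} (0.367 in the German honey-bee genetic evaluation)
#' to account for polyandrous mating with a dummy-sire drone group: for entry
#' x with dam d and (dummy-)sire s,
#' \deqn{a(x, y) = 0.5 a(d, y) + P_p a(s, y), \quad
#'       a(x, x) = 1 + 2 \cdot 0.5 \cdot P_p \cdot a(d, s),}
#' with missing-parent terms dropped and founders set to identity. With
#' \code{Pp = 0.5} the recursion reduces to the classical Wright/Henderson
#' numerator relationship matrix.
#'
#' @param pedigree data.frame with columns \code{id}, \code{dam_id},
#'   \code{sire_id} (NA for unknown), sorted parents-before-offspring.
#' @param Pp paternal path coefficient.
#' @return Symmetric relationship matrix with ids as dimnames.
#' @export
build_A <- function(pedigree, Pp = 0.367) {
  id <- pedigree$id
  dam <- match(pedigree$dam_id, id)
  sire <- match(pedigree$sire_id, id)
  if (any(!is.na(pedigree$dam_id) & is.na(dam)) ||
      any(!is.na(pedigree$sire_id) & is.na(sire)))
    stop("ordering error: parent id missing from pedigree")
  n <- length(id)
  rows <- seq_len(n)
  if (any(dam >= rows, na.rm = TRUE) || any(sire >= rows, na.rm = TRUE))
    stop("ordering error: pedigree not sorted parents-before-offspring")
  dam[is.na(dam)] <- 0L
  sire[is.na(sire)] <- 0L
  A <- cpp_tabular_A(as.integer(dam), as.integer(sire), Pp)
  dimnames(A) <- list(id, id)
  A
}

#' Invert a relationship matrix by the genotyped/non-genotyped partition
#'
#' Computes \eqn{A^{-1}} through the block formula with the Schur complement
#' of the genotyped block,
#' \eqn{(A_{22} - A_{21} A_{11}^{-1} A_{12})^{-1}}, with blocks ordered
#' genotyped-first. With no genotyped individuals this reduces to a plain
#' inversion.
#'
#' @param A symmetric relationship matrix.
#' @param genotyped_idx integer indices of the genotyped entries (may be
#'   empty).
#' @return \eqn{A^{-1}} in the original entry order.
#' @export
invert_A_partitioned <- function(A, genotyped_idx) {
  n <- nrow(A)
  if (length(genotyped_idx) == 0) return(sym_inverse(A, "A"))
  if (length(genotyped_idx) == n) return(sym_inverse(A, "A11"))
  g <- sort(genotyped_idx)
  u <- setdiff(seq_len(n), g)
  A11i <- sym_inverse(A[g, g, drop = FALSE], "A11")
  W <- A11i %*% A[g, u, drop = FALSE]              # A11^-1 A12
  S <- A[u, u, drop = FALSE] - A[u, g, drop = FALSE] %*% W
  Si <- sym_inverse(S, "Schur complement")
  out <- matrix(0, n, n, dimnames = dimnames(A))
  out[g, g] <- A11i + W %*% Si %*% t(W)
  out[g, u] <- -W %*% Si
  out[u, g] <- t(out[g, u])
  out[u, u] <- Si
  out
}

# Symmetric inverse via Cholesky with an informative error.
sym_inverse <- function(M, what) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    rc <- tryCatch(rcond(M), error = function(e) NA_real_)
    stop(sprintf(
      "numerical error: %s not positive definite (reciprocal condition ~ %.3g)",
      what, rc))
  }
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(M)
  (inv + t(inv)) / 2
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{G = ZZ' / (2 \sum_i p_i (1 - p_i))} where Z = M - P, M codes SNP
#' genotypes as -1/0/+1 (allele-2 count minus 1) and P broadcasts
#' \eqn{2(p_i - 0.5)} with \eqn{p_i} the allele-2 frequency at locus i in the
#' base population. QTL are excluded from the marker panel.
#'
#' @param genotypes matrix of 0/1/2 allele-2 counts, one row per genotyped
#'   queen, one column per SNP.
#' @param base_freqs base-population allele-2 frequency per SNP.
#' @return Genomic relationship matrix (queens x queens).
#' @export
build_G <- function(genotypes, base_freqs) {
  if (ncol(genotypes) != length(base_freqs))
    stop("dimension error: one base frequency per SNP column required")
  denom <- 2 * sum(base_freqs * (1 - base_freqs))
  if (denom <= 0)
    stop("monomorphic marker panel: VanRaden denominator is zero")
  Z <- sweep(genotypes - 1, 2, 2 * (base_freqs - 0.5), "-")
  tcrossprod(Z) / denom
}

#' Blend the genomic matrix with the pedigree block
#'
#' \eqn{G_w = w G + (1 - w) A_{11}}: a convex combination that keeps the
#' genomic matrix invertible; (1 - w) can be read as the relative weight on a
#' residual polygenic component.
#'
#' @param G genomic relationship matrix.
#' @param A11 pedigree relationship block of the genotyped entries.
#' @param w blending weight in [0, 1]; 0.99 by default.
#' @return The blended matrix.
#' @export
blend_Gw <- function(G, A11, w = 0.99) {
  if (!all(dim(G) == dim(A11))) stop("dimension error: G and A11 must conform")
  if (w < 0 || w > 1) stop("invalid configuration: w outside [0, 1]")
  w * G + (1 - w) * A11
}

#' Inverse of the unified single-step relationship matrix
#'
#' \eqn{H^{-1} = A^{-1} + \begin{pmatrix} G_w^{-1} - A_{11}^{-1} & 0 \\
#' 0 & 0\end{pmatrix}}: the pedigree inverse plus a genomic correction
#' confined to the genotyped block.
#'
#' @param Ainv inverse pedigree relationship matrix (full order).
#' @param Gw blended genomic matrix over the genotyped entries.
#' @param A11 pedigree block of the genotyped entries.
#' @param genotyped_idx indices of the genotyped entries within \code{Ainv}.
#' @return \eqn{H^{-1}} (full order).
#' @export
build_H_inverse <- function(Ainv, Gw, A11, genotyped_idx) {
  Gwi <- tryCatch(sym_inverse(Gw, "Gw"), error = function(e)
    stop("singular Gw: consider a smaller blending weight w", call. = FALSE))
  A11i <- sym_inverse(A11, "A11")
  H <- Ainv
  H[genotyped_idx, genotyped_idx] <-
    H[genotyped_idx, genotyped_idx, drop = FALSE] + Gwi - A11i
  H
}

#' Unified relationship matrix in covariance form
#'
#' Direct construction of H (the matrix whose inverse
#' \code{\link{build_H_inverse}} assembles): conditioning the non-genotyped
#' entries on the genotyped ones gives
#' \deqn{H = \begin{pmatrix} G_w & G_w A_{11}^{-1} A_{12} \\
#'   A_{21} A_{11}^{-1} G_w &
#'   A_{22} + A_{21} A_{11}^{-1} (G_w - A_{11}) A_{11}^{-1} A_{12}
#'   \end{pmatrix}}
#' with blocks ordered genotyped-first. Used by the covariance-form BLUP
#' solver, where it avoids any full-order inversion.
#'
#' @param A pedigree relationship matrix ordered genotyped-first.
#' @param Gw blended genomic matrix over the genotyped block.
#' @param n_genotyped number of genotyped entries (leading block size).
#' @return H, same order as \code{A}.
#' @export
build_H <- function(A, Gw, n_genotyped) {
  n <- nrow(A)
  g <- seq_len(n_genotyped)
  if (n_genotyped == n) return(Gw)
  u <- (n_genotyped + 1L):n
  A11 <- A[g, g, drop = FALSE]
  A12 <- A[g, u, drop = FALSE]
  ch <- chol(A11)
  W <- backsolve(ch, backsolve(ch, A12, transpose = TRUE))  # A11^-1 A12
  H12 <- Gw %*% W
  H <- A
  H[g, g] <- Gw
  H[g, u] <- H12
  H[u, g] <- t(H12)
  H[u, u] <- A[u, u, drop = FALSE] + crossprod(W, H12 - A12)
  (H + t(H)) / 2
}
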
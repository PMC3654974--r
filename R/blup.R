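#' Assemble the maternal-effects mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side of Henderson's mixed
#' model equations for the maternal-effects animal model
#' \deqn{y = Xb + Z_1 u_1 + Z_2 u_2 + e,}
#' where \eqn{u_1} are direct (worker) effects, \eqn{u_2} maternal (queen)
#' effects, every relationship-matrix entry carries one level of each, X is a
#' column of ones (a single overall mean), and the random block is penalized
#' by \eqn{G_0^{-1} \otimes K^{-1} \sigma_e^2} with
#' \eqn{G_0 = \begin{pmatrix} \sigma_w^2 & \sigma_{qw} \\ \sigma_{qw} &
#' \sigma_q^2 \end{pmatrix}} and \eqn{K^{-1}} the pedigree \eqn{A^{-1}} or the
#' unified \eqn{H^{-1}}. Each colony record is linked to its average worker's
#' direct effect through \eqn{Z_1} and to its queen's maternal effect
#' through \eqn{Z_2}. Unknown ordering: mean, then \eqn{u_1} (all entries),
#' then \eqn{u_2}.
#'
#' @param y colony records.
#' @param worker_pos,queen_pos relationship-matrix row of the average worker
#'   resp. queen of each record.
#' @param G0 2x2 genetic covariance matrix (direct first).
#' @param sigma2_e residual variance (> 0).
#' @param Kinv inverse relationship kernel (n x n).
#' @return List with coefficient matrix \code{C}, right-hand side \code{rhs},
#'   and bookkeeping (\code{n_entries}, \code{n_fixed}).
#' @export
build_mme <- function(y, worker_pos, queen_pos, G0, sigma2_e, Kinv) {
  n <- nrow(Kinv)
  nr <- length(y)
  stopifnot(length(worker_pos) == nr, length(queen_pos) == nr, sigma2_e > 0)
  det_G0 <- G0[1, 1] * G0[2, 2] - G0[1, 2]^2
  if (det_G0 <= 0)
    stop("non-invertible G0: require sigma_qw^2 < sigma2_q * sigma2_w")
  G0i <- solve(G0)
  m <- 1L + 2L * n
  C <- matrix(0, m, m)
  i1 <- 1L + seq_len(n)        # u1 block
  i2 <- 1L + n + seq_len(n)    # u2 block
  # penalty G0^-1 (x) K^-1 * sigma_e^2
  C[i1, i1] <- G0i[1, 1] * Kinv * sigma2_e
  C[i1, i2] <- G0i[1, 2] * Kinv * sigma2_e
  C[i2, i1] <- G0i[2, 1] * Kinv * sigma2_e
  C[i2, i2] <- G0i[2, 2] * Kinv * sigma2_e
  # data part: X = 1, Z1/Z2 are 0/1 incidences
  C[1, 1] <- nr
  tw <- tabulate(worker_pos, nbins = n)
  tq <- tabulate(queen_pos, nbins = n)
  C[1, i1] <- C[1, i1] + tw
  C[i1, 1] <- C[i1, 1] + tw
  C[1, i2] <- C[1, i2] + tq
  C[i2, 1] <- C[i2, 1] + tq
  for (r in seq_len(nr)) {
    w <- 1L + worker_pos[r]
    q <- 1L + n + queen_pos[r]
    C[w, w] <- C[w, w] + 1
    C[q, q] <- C[q, q] + 1
    C[w, q] <- C[w, q] + 1
    C[q, w] <- C[q, w] + 1
  }
  rhs <- numeric(m)
  rhs[1] <- sum(y)
  zw <- numeric(n); zq <- numeric(n)
  for (r in seq_len(nr)) {
    zw[worker_pos[r]] <- zw[worker_pos[r]] + y[r]
    zq[queen_pos[r]] <- zq[queen_pos[r]] + y[r]
  }
  rhs[i1] <- zw
  rhs[i2] <- zq
  list(C = C, rhs = rhs, n_entries = n, n_fixed = 1L)
}

#' Solve assembled mixed-model equations
#'
#' Direct dense solve of the system from \code{\link{build_mme}}, with a
#' relative-residual check of 1e-8.
#'
#' @param system a \code{\link{build_mme}} result.
#' @return List with the estimated mean \code{b}, and per-entry
#'   \code{ebv_direct}, \code{ebv_maternal}, \code{ebv_overall}.
#' @export
solve_mme <- function(system) {
  sol <- tryCatch(solve(system$C, system$rhs), error = function(e) {
    stop(sprintf("singular mixed-model equations (rank < %d): %s",
                 nrow(system$C), conditionMessage(e)), call. = FALSE)
  })
  resid <- max(abs(system$C %*% sol - system$rhs))
  scale <- max(abs(system$rhs), 1)
  if (resid / scale > 1e-8)
    stop(sprintf("mixed-model solve did not meet tolerance (rel. residual %.2g)",
                 resid / scale))
  n <- system$n_entries
  u1 <- sol[1L + seq_len(n)]
  u2 <- sol[1L + n + seq_len(n)]
  list(b = sol[1], ebv_direct = u1, ebv_maternal = u2,
       ebv_overall = u1 + u2)
}

#' Covariance-form BLUP solver
#'
#' Solves the same maternal-effects animal model as
#' \code{\link{build_mme}}/\code{\link{solve_mme}} in covariance (kernel)
#' form, which only requires the relationship matrix K itself (A or H), never
#' its inverse: with \eqn{V = Z (G_0 \otimes K) Z' + I\sigma_e^2} over the
#' records,
#' \deqn{\hat b = (1'V^{-1}1)^{-1} 1'V^{-1}y, \qquad
#'       \hat u = \mathrm{Cov}(u, y) V^{-1} (y - 1\hat b).}
#' The solutions are algebraically identical to the mixed-model-equation
#' solutions and the implementation is exercised against them in the test
#' suite; at the study scale (5275 entries, 2050 records) this form is the
#' cheaper route because V has the order of the records.
#'
#' @param K relationship matrix over all entries.
#' @param worker_pos,queen_pos entry index of each record's average worker
#'   resp. queen.
#' @param y colony records.
#' @param G0 2x2 genetic covariance matrix (direct first).
#' @param sigma2_e residual variance.
#' @param ebv_pos entries for which EBVs are returned (default all).
#' @return List with \code{b}, \code{ebv_direct}, \code{ebv_maternal},
#'   \code{ebv_overall} for \code{ebv_pos}.
#' @export
solve_blup_kernel <- function(K, worker_pos, queen_pos, y, G0, sigma2_e,
                              ebv_pos = seq_len(nrow(K))) {
  Kww <- K[worker_pos, worker_pos, drop = FALSE]
  Kwq <- K[worker_pos, queen_pos, drop = FALSE]
  Kqq <- K[queen_pos, queen_pos, drop = FALSE]
  V <- G0[1, 1] * Kww + G0[1, 2] * (Kwq + t(Kwq)) + G0[2, 2] * Kqq
  diag(V) <- diag(V) + sigma2_e
  ch <- tryCatch(chol(V), error = function(e)
    stop("record covariance matrix V not positive definite", call. = FALSE))
  vs <- function(x) backsolve(ch, backsolve(ch, x, transpose = TRUE))
  ones <- rep(1, length(y))
  Vi1 <- vs(ones)
  b <- sum(Vi1 * y) / sum(Vi1)
  alpha <- vs(y - b)
  Cw <- K[ebv_pos, worker_pos, drop = FALSE]
  Cq <- K[ebv_pos, queen_pos, drop = FALSE]
  u1 <- as.numeric((G0[1, 1] * Cw + G0[1, 2] * Cq) %*% alpha)
  u2 <- as.numeric((G0[1, 2] * Cw + G0[2, 2] * Cq) %*% alpha)
  list(b = b, ebv_direct = u1, ebv_maternal = u2, ebv_overall = u1 + u2)
}

#' Accuracy of estimated breeding values
#'
#' Pearson correlation between estimated and true breeding values over a
#' queen subset.
#'
#' @param ebv estimated breeding values.
#' @param tbv matching true breeding values.
#' @return The correlation.
#' @export
accuracy <- function(ebv, tbv) {
  if (length(ebv) != length(tbv) || length(ebv) < 2)
    stop("undefined accuracy: need matching EBV/TBV vectors of length >= 2")
  if (sd(ebv) == 0 || sd(tbv) == 0)
    stop("undefined accuracy: zero-variance vector")
  cor(ebv, tbv)
}
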
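#' Assign allele-substitution effects to the QTL panel
#'
#' Draws one N(0, 1) effect magnitude per QTL. Direct-only QTL affect only
#' the direct (worker) component, maternal-only QTL only the maternal (queen)
#' component. Pleiotropic QTL share a single magnitude between the two
#' components; under \code{correlation_mode = "negative"} their maternal and
#' direct effects receive opposite signs (which induces a negative
#' maternal-direct genetic correlation with expectation -78/164 at the study
#' class sizes), while under \code{"none"} both signs are randomized
#' independently so the expected correlation is zero.
#'
#' @param panel a \code{\link{select_panel}} result.
#' @param correlation_mode \code{"none"} or \code{"negative"}.
#' @return An object of class \code{effect_set}: per-QTL vectors
#'   \code{a_maternal} and \code{a_direct} (zero outside the respective
#'   classes) aligned with \code{panel$qtl_idx}.
#' @export
assign_qtl_effects <- function(panel, correlation_mode = c("none", "negative")) {
  correlation_mode <- match.arg(correlation_mode)
  cls <- panel$qtl_class
  n <- length(cls)
  if (n == 0) stop("configuration error: empty QTL panel")
  magnitude <- rnorm(n)
  a_mat <- numeric(n)
  a_dir <- numeric(n)
  is_m <- cls == "maternal"
  is_d <- cls == "direct"
  is_p <- cls == "pleiotropic"
  a_mat[is_m] <- magnitude[is_m]
  a_dir[is_d] <- magnitude[is_d]
  if (correlation_mode == "negative") {
    a_mat[is_p] <- magnitude[is_p]
    a_dir[is_p] <- -magnitude[is_p]
  } else {
    s_m <- sample(c(-1, 1), sum(is_p), replace = TRUE)
    s_d <- sample(c(-1, 1), sum(is_p), replace = TRUE)
    a_mat[is_p] <- s_m * abs(magnitude[is_p])
    a_dir[is_p] <- s_d * abs(magnitude[is_p])
  }
  structure(list(a_maternal = a_mat, a_direct = a_dir,
                 correlation_mode = correlation_mode),
            class = "effect_set")
}

#' True breeding values for one diploid genome
#'
#' Genotypes at each QTL are scored +1 (homozygous allele 2), -1 (homozygous
#' allele 1) or 0 (heterozygous); the maternal and direct true breeding
#' values are the score-weighted sums of the corresponding allele-substitution
#' effects over the QTL, and the overall TBV is their sum.
#'
#' @param genome list with allele vectors \code{hap1}, \code{hap2}.
#' @param panel a \code{\link{select_panel}} result.
#' @param effects an \code{\link{assign_qtl_effects}} result.
#' @return List with \code{tbv_maternal}, \code{tbv_direct},
#'   \code{tbv_overall}.
#' @export
compute_tbv <- function(genome, panel, effects) {
  q <- (genome$hap1[panel$qtl_idx] == 2L) + (genome$hap2[panel$qtl_idx] == 2L) - 1L
  tm <- sum(q * effects$a_maternal)
  td <- sum(q * effects$a_direct)
  list(tbv_maternal = tm, tbv_direct = td, tbv_overall = tm + td)
}

# Vectorized TBVs from a QTL dosage matrix (queens x QTL, 0/1/2 copies of
# allele 2).
compute_tbv_matrix <- function(qtl_dosage, effects) {
  q <- qtl_dosage - 1
  data.frame(
    tbv_maternal = as.numeric(q %*% effects$a_maternal),
    tbv_direct = as.numeric(q %*% effects$a_direct)
  ) |> transform(tbv_overall = tbv_maternal + tbv_direct)
}

#' Derive variance components from realized true breeding values
#'
#' Maternal variance, direct variance and their covariance are the empirical
#' (co)variances of the simulated TBVs. The total genetic variance is
#' \eqn{\sigma_g^2 = \sigma_q^2 + \sigma_w^2 + 2\sigma_{qw}}; the phenotypic
#' variance follows from the fixed target maternal heritability,
#' \eqn{\sigma_p^2 = \sigma_q^2 / h_m^2}, and the residual variance is
#' \eqn{\sigma_e^2 = \sigma_p^2 - \sigma_g^2}. The achieved direct
#' heritability \eqn{h_d^2 = \sigma_w^2 / \sigma_p^2} and the realized
#' maternal-direct correlation are reported alongside.
#'
#' @param tbv_table data.frame with columns \code{tbv_maternal} and
#'   \code{tbv_direct} (one row per queen).
#' @param h2_m_target fixed maternal heritability in (0, 1).
#' @return An object of class \code{variance_components}.
#' @export
derive_variances <- function(tbv_table, h2_m_target) {
  if (nrow(tbv_table) < 2) stop("need at least two queens with TBVs")
  if (h2_m_target <= 0 || h2_m_target >= 1)
    stop("invalid configuration: h2_m_target must lie in (0, 1)")
  s2q <- var(tbv_table$tbv_maternal)
  s2w <- var(tbv_table$tbv_direct)
  sqw <- cov(tbv_table$tbv_maternal, tbv_table$tbv_direct)
  s2g <- s2q + s2w + 2 * sqw
  s2p <- s2q / h2_m_target
  s2e <- s2p - s2g
  if (s2e <= 0)
    stop(sprintf(
      "infeasible heritability: residual variance <= 0 (sigma2_p = %.4g, sigma2_g = %.4g)",
      s2p, s2g))
  structure(list(
    sigma2_q = s2q, sigma2_w = s2w, sigma_qw = sqw,
    sigma2_g = s2g, sigma2_p = s2p, sigma2_e = s2e,
    h2_m = h2_m_target, h2_d = s2w / s2p,
    r_qw = sqw / sqrt(s2q * s2w)
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: s2_q %.3f  s2_w %.3f  s_qw %.3f  s2_g %.3f  s2_p %.3f  s2_e %.3f\n",
    x$sigma2_q, x$sigma2_w, x$sigma_qw, x$sigma2_g, x$sigma2_p, x$sigma2_e))
  cat(sprintf("  h2_m %.3f (target)  h2_d %.3f (achieved)  r_qw %.3f\n",
              x$h2_m, x$h2_d, x$r_qw))
  invisible(x)
}

#' Simulate colony phenotypes
#'
#' A colony record is the queen's overall true breeding value plus a Gaussian
#' residual, \eqn{y = TBV_q + TBV_w + e} with \eqn{e \sim N(0, \sigma_e^2)}.
#' The phenotype is a whole-colony observation: the queen and the colony's
#' average worker share the same record.
#'
#' @param queen_ids ids of the phenotyped queens.
#' @param worker_ids ids of the corresponding average workers.
#' @param tbvs data.frame of TBVs aligned with \code{queen_ids}.
#' @param sigma2_e residual variance (>= 0).
#' @param residuals optional pre-drawn standard-normal residuals (scaled by
#'   \code{sqrt(sigma2_e)}); used by the replicate driver so that scenarios
#'   differing only in heritability share the same residual ranks.
#' @return data.frame with columns \code{colony_id}, \code{queen_id},
#'   \code{worker_id}, \code{y}.
#' @export
simulate_phenotypes <- function(queen_ids, worker_ids, tbvs, sigma2_e,
                                residuals = NULL) {
  if (sigma2_e < 0) stop("invalid configuration: negative residual variance")
  n <- length(queen_ids)
  if (is.null(residuals)) residuals <- rnorm(n)
  stopifnot(length(worker_ids) == n, nrow(tbvs) == n, length(residuals) == n)
  data.frame(
    colony_id = seq_len(n),
    queen_id = queen_ids,
    worker_id = worker_ids,
    y = tbvs$tbv_overall + sqrt(sigma2_e) * residuals
  )
}
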
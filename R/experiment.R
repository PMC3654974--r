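#' Run one simulation replicate across evaluation scenarios
#'
#' Executes the full pipeline once - genome map, historical base population,
#' marker/QTL panel, five breeding generations - and then evaluates every
#' requested scenario on that one population. Scenarios share the simulated
#' genomes and pedigree: the correlation mode changes only the QTL effect
#' signs (one effect draw per mode) and the maternal heritability changes
#' only the residual variance, so scenario contrasts are paired within a
#' replicate. One residual draw (standard normal) per correlation mode is
#' scaled by the scenario's residual standard deviation.
#'
#' @param params a \code{\link{bee_params}} object.
#' @param seed integer seed; the replicate is bit-reproducible given
#'   \code{params} and \code{seed}.
#' @param h2_m_levels maternal heritabilities to evaluate.
#' @param corr_modes correlation modes (\code{"none"}, \code{"negative"}).
#' @param methods evaluation methods: \code{"PED"} (pedigree numerator
#'   relationship matrix with paternal path coefficient) and/or \code{"UNI"}
#'   (unified single-step H).
#' @param full_eval if FALSE, stop after the trait model (no relationship
#'   matrices or BLUP; metrics restricted to heritability/correlation
#'   bookkeeping). Cheap replicates for TBV-level statistics.
#' @return List with \code{metrics} (one row per scenario x method x queen
#'   subset x EBV component: the accuracy), \code{scenario_stats} (realized
#'   variance components per scenario), and \code{seed}.
#' @export
run_replicate <- function(params, seed,
                          h2_m_levels = c(0.15, 0.25, 0.35),
                          corr_modes = c("none", "negative"),
                          methods = c("PED", "UNI"),
                          full_eval = TRUE) {
  set.seed(seed)
  map <- build_genome_map(params$chrom_table, params$recomb_rate_cM_per_Mb,
                          params$locus_placement)
  base <- run_historical(map, params$n_hist_generations,
                         params$n_sire_queens, params$n_dam_queens,
                         params$mutation_rate)
  panel <- select_panel(base, params$n_keep, params$maf_cutoff,
                        params$n_qtl, params$qtl_class_sizes)
  sim <- run_breeding(base, panel, params)
  rm(base)

  effects <- lapply(setNames(corr_modes, corr_modes), function(mode)
    assign_qtl_effects(panel, mode))
  tbv <- lapply(effects, function(e) compute_tbv_matrix(sim$dosage_qtl, e))
  ph <- sim$queens$phenotyped
  resid_std <- lapply(setNames(corr_modes, corr_modes),
                      function(mode) rnorm(sum(ph)))

  eval_ctx <- NULL
  if (full_eval) eval_ctx <- build_eval_context(sim, params)

  metrics <- list()
  stats <- list()
  for (mode in corr_modes) {
    for (h2m in h2_m_levels) {
      vc <- derive_variances(tbv[[mode]], h2m)
      stats[[paste(mode, h2m)]] <- data.frame(
        h2_m = h2m, corr_mode = mode,
        h2_d = vc$h2_d, r_qw = vc$r_qw,
        sigma2_q = vc$sigma2_q, sigma2_w = vc$sigma2_w,
        sigma_qw = vc$sigma_qw, sigma2_g = vc$sigma2_g,
        sigma2_p = vc$sigma2_p, sigma2_e = vc$sigma2_e)
      if (!full_eval) next
      records <- simulate_phenotypes(
        sim$queens$id[ph], sim$queens$worker_id[ph],
        tbv[[mode]][ph, , drop = FALSE], vc$sigma2_e,
        residuals = resid_std[[mode]])
      G0 <- matrix(c(vc$sigma2_w, vc$sigma_qw, vc$sigma_qw, vc$sigma2_q), 2)
      for (method in methods) {
        K <- if (method == "PED") eval_ctx$A else eval_ctx$H
        fit <- solve_blup_kernel(K, eval_ctx$worker_pos, eval_ctx$queen_pos,
                                 records$y, G0, vc$sigma2_e,
                                 ebv_pos = eval_ctx$queen_rows)
        metrics[[paste(mode, h2m, method)]] <-
          accuracy_rows(fit, tbv[[mode]], sim$queens$juvenile,
                        h2m, mode, method)
      }
    }
  }
  list(metrics = if (length(metrics)) do.call(rbind, c(metrics,
         list(make.row.names = FALSE))) else NULL,
       scenario_stats = do.call(rbind, c(stats, list(make.row.names = FALSE))),
       seed = seed)
}

# Relationship matrices and record/entry index bookkeeping for one simulated
# population: A and H in evaluation order (genotyped queens first, in
# sim$queens order).
build_eval_context <- function(sim, params) {
  pedA <- sim$ped[sim$ped$in_A, c("id", "dam_id", "sire_id")]
  A <- build_A(pedA, params$paternal_path)
  n <- nrow(A)
  g_rows <- match(sim$queens$id, pedA$id)
  perm <- c(g_rows, setdiff(seq_len(n), g_rows))
  A <- A[perm, perm]
  n1 <- length(g_rows)
  G <- build_G(sim$dosage_snp, sim$panel$base_freq[sim$panel$snp_idx])
  Gw <- blend_Gw(G, A[seq_len(n1), seq_len(n1)], params$blend_w)
  H <- build_H(A, Gw, n1)
  row_of <- setNames(seq_len(n), pedA$id[perm])
  ph <- sim$queens$phenotyped
  list(A = A, H = H, G = G, Gw = Gw, n_genotyped = n1,
       queen_rows = seq_len(n1),
       worker_pos = unname(row_of[as.character(sim$queens$worker_id[ph])]),
       queen_pos = which(ph),
       row_of = row_of)
}

# Accuracy rows for one fitted scenario/method: overall, maternal and direct
# EBV components for juvenile and all queens.
accuracy_rows <- function(fit, tbv, juvenile, h2m, mode, method) {
  comp <- list(overall = c("ebv_overall", "tbv_overall"),
               maternal = c("ebv_maternal", "tbv_maternal"),
               direct = c("ebv_direct", "tbv_direct"))
  subs <- list(juvenile_queens = juvenile,
               all_queens = rep(TRUE, length(juvenile)))
  out <- expand.grid(component = names(comp), subset = names(subs),
                     stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(cp, sb) {
    accuracy(fit[[comp[[cp]][1]]][subs[[sb]]], tbv[[comp[[cp]][2]]][subs[[sb]]])
  }, out$component, out$subset)
  cbind(data.frame(h2_m = h2m, corr_mode = mode, method = method), out)
}

#' Run a replicated simulation experiment
#'
#' Runs \code{n_replicates} full replicates (simulation + both evaluation
#' methods across the scenario grid) plus optionally \code{n_light}
#' additional simulation-only replicates that contribute TBV-level
#' statistics (realized direct heritability and maternal-direct correlation)
#' without the evaluation step. Per-replicate seeds are drawn from the
#' master seed.
#'
#' @param params a \code{\link{bee_params}} object.
#' @param seed master seed.
#' @param n_replicates full replicates (20 in the study design).
#' @param n_light additional simulation-only replicates.
#' @inheritParams run_replicate
#' @param verbose print per-replicate progress.
#' @return List with pooled \code{metrics} and \code{scenario_stats} (with a
#'   \code{replicate} column), the per-cell \code{summary} (see
#'   \code{\link{summarize_replicates}}), the significance annotation, seeds
#'   and params.
#' @export
run_experiment <- function(params, seed, n_replicates = 20L, n_light = 0L,
                           h2_m_levels = c(0.15, 0.25, 0.35),
                           corr_modes = c("none", "negative"),
                           methods = c("PED", "UNI"),
                           verbose = FALSE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates + n_light)
  metrics <- list()
  stats <- list()
  for (i in seq_len(n_replicates + n_light)) {
    full <- i <= n_replicates
    if (verbose)
      message(sprintf("replicate %d/%d (%s, seed %d)", i,
                      n_replicates + n_light,
                      if (full) "full" else "simulation-only", seeds[i]))
    rep_i <- run_replicate(params, seeds[i], h2_m_levels, corr_modes,
                           methods, full_eval = full)
    if (!is.null(rep_i$metrics)) {
      rep_i$metrics$replicate <- i
      metrics[[i]] <- rep_i$metrics
    }
    rep_i$scenario_stats$replicate <- i
    stats[[i]] <- rep_i$scenario_stats
  }
  metrics <- do.call(rbind, metrics)
  stats <- do.call(rbind, stats)
  out <- list(metrics = metrics, scenario_stats = stats,
              summary = summarize_replicates(metrics, stats),
              significance = if (n_replicates >= 2)
                significance_tests(metrics) else NULL,
              seeds = seeds, params = params)
  class(out) <- "bee_experiment"
  out
}

#' Summarize replicate metrics into study tables
#'
#' Means and standard errors (sample SD across replicates divided by the
#' square root of the replicate count) per scenario cell, the achieved direct
#' heritability and realized maternal-direct correlation per scenario, and
#' the percent increase of the unified over the pedigree evaluation.
#'
#' @param metrics pooled accuracy rows from \code{\link{run_experiment}}.
#' @param scenario_stats pooled variance-component rows.
#' @return List of data.frames \code{accuracy}, \code{heritability},
#'   \code{increase}.
#' @export
summarize_replicates <- function(metrics, scenario_stats = NULL) {
  acc <- NULL
  inc <- NULL
  if (!is.null(metrics)) {
    keys <- c("h2_m", "corr_mode", "method", "subset", "component")
    acc <- aggregate(metrics$accuracy, metrics[keys], function(v)
      c(mean = mean(v), se = sd(v) / sqrt(length(v)), n = length(v)))
    acc <- cbind(acc[keys], as.data.frame(acc$x))
    wide <- merge(
      acc[acc$method == "UNI", c("h2_m", "corr_mode", "subset", "component",
                                 "mean")],
      acc[acc$method == "PED", c("h2_m", "corr_mode", "subset", "component",
                                 "mean")],
      by = c("h2_m", "corr_mode", "subset", "component"),
      suffixes = c("_UNI", "_PED"))
    if (nrow(wide)) {
      wide$pct_increase <- 100 * (wide$mean_UNI - wide$mean_PED) / wide$mean_PED
      inc <- wide
    }
  }
  her <- NULL
  if (!is.null(scenario_stats)) {
    her <- aggregate(cbind(h2_d, r_qw) ~ h2_m + corr_mode, scenario_stats,
                     function(v) c(mean = mean(v),
                                   se = sd(v) / sqrt(length(v))))
    her <- do.call(data.frame, her)
    names(her) <- c("h2_m", "corr_mode", "h2_d_mean", "h2_d_se",
                    "r_qw_mean", "r_qw_se")
  }
  list(accuracy = acc, heritability = her, increase = inc)
}

#' Paired significance tests across replicates
#'
#' Two-sided paired t-tests on per-replicate accuracies: unified vs pedigree
#' evaluation within each scenario cell, negative vs no correlation within
#' each method, and all heritability pairs within each method and
#' correlation mode. Significance is flagged at P < 0.05 per contrast
#' (pairwise, no multiplicity correction).
#'
#' @param metrics pooled accuracy rows from \code{\link{run_experiment}}.
#' @return data.frame with one row per contrast and cell: means, mean
#'   difference, t statistic, p value, \code{significant}.
#' @export
significance_tests <- function(metrics) {
  res <- list()
  pair_test <- function(df, split_on, label) {
    stopifnot(length(unique(df[[split_on]])) == 2)
    lv <- sort(unique(df[[split_on]]))
    keys <- setdiff(c("h2_m", "corr_mode", "method", "subset", "component"),
                    split_on)
    for (cell in split(df, df[keys], drop = TRUE)) {
      a <- cell[cell[[split_on]] == lv[1], ]
      b <- cell[cell[[split_on]] == lv[2], ]
      shared <- intersect(a$replicate, b$replicate)
      if (length(shared) < 2) stop("cannot test: fewer than 2 paired replicates")
      x <- a$accuracy[match(shared, a$replicate)]
      y <- b$accuracy[match(shared, b$replicate)]
      d <- x - y
      # constant differences: a zero shift is never significant, an exactly
      # constant nonzero shift is the infinite-t limit
      tt <- if (sd(d) < 1e-9 * (abs(mean(d)) + 1))
        list(statistic = NA_real_,
             p.value = if (abs(mean(d)) < 1e-12) 1 else 0)
      else t.test(x, y, paired = TRUE)
      scen <- cell[1, c("h2_m", "corr_mode", "method", "subset", "component")]
      scen[[split_on]] <- NA
      res[[length(res) + 1L]] <<- data.frame(
        contrast = label,
        level_a = as.character(lv[1]), level_b = as.character(lv[2]),
        scen,
        mean_a = mean(x), mean_b = mean(y), mean_diff = mean(d),
        t = unname(tt$statistic), p = tt$p.value,
        significant = tt$p.value < 0.05, row.names = NULL)
    }
  }
  if (length(unique(metrics$method)) == 2)
    pair_test(metrics, "method", "UNI vs PED")
  if (length(unique(metrics$corr_mode)) == 2)
    pair_test(metrics, "corr_mode", "correlation mode")
  h2 <- sort(unique(metrics$h2_m))
  if (length(h2) >= 2) {
    for (i in seq_along(h2)) for (j in seq_along(h2)) {
      if (i >= j) next
      sub <- metrics[metrics$h2_m %in% h2[c(i, j)], ]
      pair_test(sub, "h2_m", "heritability")
    }
  }
  do.call(rbind, res)
}

#' Write the study summary tables as CSV files
#'
#' Emits \code{table2_heritability.csv} (achieved direct heritability per
#' scenario), \code{table3_overall_accuracy.csv} (overall-EBV accuracy per
#' scenario, method and queen subset) and
#' \code{table4_component_accuracy.csv} (direct and maternal EBV accuracy).
#'
#' @param experiment a \code{\link{run_experiment}} result.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_experiment_tables <- function(experiment, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- experiment$summary
  write.csv(s$heritability, file.path(dir, "table2_heritability.csv"),
            row.names = FALSE)
  acc <- s$accuracy
  write.csv(acc[acc$component == "overall", ],
            file.path(dir, "table3_overall_accuracy.csv"), row.names = FALSE)
  write.csv(acc[acc$component != "overall", ],
            file.path(dir, "table4_component_accuracy.csv"), row.names = FALSE)
  invisible(dir)
}
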
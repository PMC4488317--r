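#' Random estimation/test split of DH lines
#'
#' @param n_lines Total number of lines.
#' @param n_est Estimation-set size (`< n_lines`); the source experiment
#'   used 50 estimation and 1500 test lines.
#' @return List with disjoint, exhaustive index vectors `estimation` and
#'   `test`.
#' @export
split_estimation_test <- function(n_lines, n_est) {
  if (n_est >= n_lines) stop("`n_est` must be < `n_lines`", call. = FALSE)
  if (n_est < 1) stop("`n_est` must be >= 1", call. = FALSE)
  est <- sort(sample.int(n_lines, n_est))
  list(estimation = est, test = setdiff(seq_len(n_lines), est))
}

#' Prediction accuracy as the Pearson correlation with true performance
#'
#' True performance is the noiseless growth-model yield computed from the
#' true latent traits (never the noisy phenotype), so the accuracy is not
#' attenuated by heritability.
#'
#' @param predicted,true_perf Equal-length vectors (`>= 3`).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
prediction_accuracy <- function(predicted, true_perf) {
  if (length(predicted) != length(true_perf) || length(predicted) < 3)
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(true_perf) == 0)
    stop("zero variance: accuracy undefined", call. = FALSE)
  stats::cor(predicted, true_perf)
}

#' Configuration of a replicated prediction experiment
#'
#' Defaults are the desk-scale preset: a 225-line DH population genotyped
#' at 28 markers of which 8 are hidden QTL (2 per trait, leaving 20
#' observed markers), 25 estimation and 200 test lines, 5 replicates, and
#' the desk [abc_control()] (target acceptance 1e-3, 50 posterior
#' samples). The full-scale configuration of the source experiment is
#' `experiment_config(n_lines = 1550, n_markers = 140, n_qtl = 40,
#' per_trait = 10, n_est = 50, replicates = 50,
#' control = abc_control(target_acceptance = 1e-6, n_samples = 100))`.
#'
#' @param n_lines,n_markers,n_qtl,per_trait,h2 Synthetic-population design
#'   passed to [simulate_dataset()].
#' @param n_est Estimation-set size; the remaining lines are the test set.
#' @param replicates Number of independent datasets.
#' @param methods Which predictors to run.
#' @param control An [abc_control()].
#' @param params A [cgm_params()].
#' @param seed Master seed; each replicate derives its own.
#' @return Named list of class `experiment_config`.
#' @export
experiment_config <- function(n_lines = 225, n_markers = 28, n_qtl = 8,
                              per_trait = 2, h2 = 0.85, n_est = 25,
                              replicates = 5,
                              methods = c("CGM-WGP", "GBLUP"),
                              control = abc_control(),
                              params = cgm_params(), seed = 1L) {
  structure(list(n_lines = n_lines, n_markers = n_markers, n_qtl = n_qtl,
                 per_trait = per_trait, h2 = h2, n_est = n_est,
                 replicates = replicates, methods = methods,
                 control = control, params = params, seed = seed),
            class = "experiment_config")
}

#' Run the replicated estimation/prediction experiment
#'
#' For every replicate: generate an independent synthetic dataset (fresh
#' weather, population, architecture, noise), draw a random
#' estimation/test split, fit each method separately per estimation
#' environment, predict the test lines in every environment, and score
#' Pearson accuracy against true performance. Also records the Spearman
#' rank correlation of test-set true yields between the two environments
#' (a summary of crossover genotype-by-environment interaction).
#' Per-replicate failures are caught, recorded and skipped.
#'
#' @param config An [experiment_config()].
#' @param verbose Progress messages per replicate.
#' @return Object of class `experiment_result`: `results` (tidy data frame:
#'   replicate, estimation_env, prediction_env, method, accuracy),
#'   `summary` (mean accuracy per scenario and method, wide layout),
#'   `rank_correlation` (per replicate, plus its mean as an attribute),
#'   `failures`.
#' @export
run_replicated_experiment <- function(config = experiment_config(),
                                      verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rep_seeds <- derive_seeds(config$seed, config$replicates)
  rows <- list()
  rankcor <- rep(NA_real_, config$replicates)
  failures <- character(0)

  for (r in seq_len(config$replicates)) {
    res_r <- tryCatch(
      run_one_replicate(config, rep_seeds[r], r, verbose),
      error = function(e) e)
    if (inherits(res_r, "error")) {
      failures <- c(failures,
                    sprintf("replicate %d: %s", r, conditionMessage(res_r)))
      next
    }
    rows[[r]] <- res_r$rows
    rankcor[r] <- res_r$rank_correlation
    if (verbose) message(sprintf("replicate %d/%d done", r,
                                 config$replicates))
  }
  results <- do.call(rbind, rows)
  if (is.null(results))
    stop("all replicates failed:\n", paste(failures, collapse = "\n"),
         call. = FALSE)
  agg <- stats::aggregate(accuracy ~ estimation_env + prediction_env +
                            method, data = results, FUN = mean)
  wide <- stats::reshape(agg, direction = "wide",
                         idvar = c("estimation_env", "prediction_env"),
                         timevar = "method")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  wide <- wide[order(wide$estimation_env, wide$prediction_env), ]
  rownames(wide) <- NULL
  structure(list(results = results, summary = wide,
                 rank_correlation = rankcor,
                 mean_rank_correlation = mean(rankcor, na.rm = TRUE),
                 failures = failures, config = config),
            class = "experiment_result")
}

run_one_replicate <- function(config, seed, replicate_id, verbose = FALSE) {
  seeds <- derive_seeds(seed, 4)
  dataset <- simulate_dataset(
    n_lines = config$n_lines,
    map = marker_genome(1.5, config$n_markers),
    n_qtl = config$n_qtl, per_trait = config$per_trait, h2 = config$h2,
    params = config$params, seed = seeds[1])
  set.seed(seeds[2])
  split <- split_estimation_test(config$n_lines, config$n_est)
  Z_obs <- dataset$observed_genotypes
  envs <- dataset$envs
  trait_means <- colMeans(dataset$traits)
  trait_vars <- apply(dataset$traits, 2, stats::var)
  true_test <- dataset$true_yields[split$test, , drop = FALSE]

  rows <- list()
  fit_seeds <- derive_seeds(seeds[3], length(envs))
  for (ei in seq_along(envs)) {
    est_env <- envs[[ei]]
    y_est <- dataset$phenotypes[split$estimation, ei]

    if ("CGM-WGP" %in% config$methods) {
      fit <- fit_cgmwgp(y_est, Z_obs[split$estimation, , drop = FALSE],
                        est_env, trait_means, trait_vars,
                        v_e = dataset$v_e[ei], control = config$control,
                        params = config$params, seed = fit_seeds[ei],
                        verbose = verbose)
      for (pj in seq_along(envs)) {
        pred <- predict(fit, Z_obs[split$test, , drop = FALSE], envs[[pj]])
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = replicate_id, estimation_env = est_env$label,
          prediction_env = envs[[pj]]$label, method = "CGM-WGP",
          accuracy = prediction_accuracy(pred, true_test[, pj]))
      }
    }
    if ("GBLUP" %in% config$methods) {
      Zc <- code_markers(Z_obs)
      gfit <- fit_gblup(y_est, Zc[split$estimation, , drop = FALSE])
      gpred <- predict_gblup(gfit, Zc[split$test, , drop = FALSE])
      for (pj in seq_along(envs)) {
        # GBLUP ignores the target environment: one prediction vector
        # serves every prediction environment by construction
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = replicate_id, estimation_env = est_env$label,
          prediction_env = envs[[pj]]$label, method = "GBLUP",
          accuracy = prediction_accuracy(gpred, true_test[, pj]))
      }
    }
  }
  rc <- stats::cor(true_test[, 1], true_test[, 2], method = "spearman")
  list(rows = do.call(rbind, rows), rank_correlation = rc)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  cat(sprintf("  replicates: %d (failures: %d)\n",
              x$config$replicates, length(x$failures)))
  cat(sprintf("  mean rank correlation between environments: %.2f\n",
              x$mean_rank_correlation))
  cat("  mean accuracy by scenario:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write experiment results as tidy CSV plus summary
#'
#' @param result An [run_replicated_experiment()] result.
#' @param dir Output directory (created if needed). Writes
#'   `accuracies.csv` (tidy per-replicate records), `summary.csv` (mean
#'   accuracy per scenario and method) and `metadata.json`.
#' @export
write_experiment_results <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$results, file.path(dir, "accuracies.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  meta <- list(seed = result$config$seed,
               replicates = result$config$replicates,
               failures = result$failures,
               rank_correlation = result$rank_correlation,
               mean_rank_correlation = result$mean_rank_correlation,
               control = unclass(result$config$control))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
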
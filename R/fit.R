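#' Control settings for a CGM-WGP estimation run
#'
#' The full-scale configuration of the source experiment used a target
#' acceptance rate of about 1e-6 and 100 posterior samples (around 1e8
#' growth-model evaluations per fit). The defaults here are the desk-scale
#' preset: target acceptance 1e-3 and 50 posterior samples, which preserves
#' every qualitative property of the method at a computing budget suitable
#' for a single CPU.
#'
#' @param target_acceptance Desired ABC acceptance rate.
#' @param n_samples Number of posterior draws to accept.
#' @param n_pilot Pilot draws used to tune the tolerance.
#' @param perturbation Prior perturbation half-width (see
#'   [build_perturbed_prior()]).
#' @param batch_size Proposals per vectorised chunk.
#' @param max_attempts Proposal budget.
#' @param workers Parallel workers for the rejection sampler.
#' @return Named list of class `abc_control`.
#' @export
abc_control <- function(target_acceptance = 1e-3, n_samples = 50,
                        n_pilot = 2000, perturbation = 0.2,
                        batch_size = 1000, max_attempts = 1e9,
                        workers = 1L) {
  structure(list(target_acceptance = target_acceptance,
                 n_samples = n_samples, n_pilot = n_pilot,
                 perturbation = perturbation, batch_size = batch_size,
                 max_attempts = max_attempts, workers = workers),
            class = "abc_control")
}

#' Fit the CGM-WGP model to one estimation environment
#'
#' Runs the whole estimation pipeline: draw the perturbed prior once, tune
#' the tolerance on a pilot run, then run the ABC rejection sampler until
#' the requested number of acceptances. Trait means/variances supply the
#' prior location and shrinkage scale; in the synthetic pipeline they are
#' the generator's population values (the proof-of-concept setting), for
#' real data they come from extraneous knowledge.
#'
#' @param y Observed yields of the estimation lines (length `N`).
#' @param genotypes `N x M` observed marker matrix (0/1).
#' @param env Estimation [cgm_environment()].
#' @param trait_means,trait_vars Named (tln, am, sre, mtu) trait summaries.
#' @param v_e Residual variance of the phenotypes used for fitting.
#' @param control An [abc_control()] list.
#' @param params A [cgm_params()] object.
#' @param yield_fun Deterministic yield map (defaults to the growth model).
#' @param seed Integer seed; sub-seeds are derived for the prior draw, the
#'   pilot run and the sampler workers.
#' @param verbose Progress messages.
#' @return Object of class `cgmwgp_fit`: `posterior`, `prior`, `epsilon`,
#'   `control`, `params`, `estimation_env` label.
#' @export
fit_cgmwgp <- function(y, genotypes, env, trait_means, trait_vars, v_e,
                       control = abc_control(), params = cgm_params(),
                       yield_fun = cgm_yield, seed = 1L, verbose = FALSE) {
  Z <- as.matrix(genotypes)
  stopifnot(length(y) == nrow(Z))
  seeds <- derive_seeds(seed, 3)
  set.seed(seeds[1])
  prior <- build_perturbed_prior(trait_means, trait_vars, v_e, ncol(Z),
                                 perturbation = control$perturbation)
  set.seed(seeds[2])
  epsilon <- tune_tolerance(y, Z, env, prior,
                            target_acceptance = control$target_acceptance,
                            n_pilot = control$n_pilot, params = params,
                            yield_fun = yield_fun,
                            batch_size = control$batch_size)
  posterior <- abc_rejection(y, Z, env, prior, epsilon,
                             n_samples = control$n_samples, params = params,
                             yield_fun = yield_fun,
                             max_attempts = control$max_attempts,
                             batch_size = control$batch_size,
                             workers = control$workers, seed = seeds[3],
                             verbose = verbose)
  structure(list(posterior = posterior, prior = prior, epsilon = epsilon,
                 control = control, params = params,
                 estimation_env = env$label, seed = seed),
            class = "cgmwgp_fit")
}

#' @export
print.cgmwgp_fit <- function(x, ...) {
  cat(sprintf(paste0("<cgmwgp_fit> estimation env '%s': %d posterior draws,",
                     " epsilon %.3g, acceptance %.2g\n"),
              x$estimation_env, nrow(x$posterior$theta), x$epsilon,
              x$posterior$acceptance_rate))
  invisible(x)
}

#' Predict yields for new lines in a target environment
#'
#' @param object A [fit_cgmwgp()] result.
#' @param genotypes Marker matrix of lines to predict.
#' @param env Target [cgm_environment()] (may differ from the estimation
#'   environment; the growth model is re-evaluated with its weather and
#'   management).
#' @param ... Unused.
#' @return Predicted yield vector.
#' @export
predict.cgmwgp_fit <- function(object, genotypes, env, ...) {
  posterior_predict(object$posterior, genotypes, env,
                    params = object$params)
}

#' Save / load a fitted posterior
#'
#' The posterior is written as a tabular CSV (one row per accepted
#' parameter vector, named columns, plus its distance) and a JSON metadata
#' record (tolerance, attempts, acceptance rate, prior draws).
#'
#' @param fit A `cgmwgp_fit`.
#' @param path CSV path; metadata goes to the same path with `.json`.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "cgmwgp_fit"))
  df <- data.frame(fit$posterior$theta, distance = fit$posterior$distances,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(epsilon = fit$epsilon,
               attempts = fit$posterior$attempts,
               acceptance_rate = fit$posterior$acceptance_rate,
               estimation_env = fit$estimation_env, seed = fit$seed,
               prior = list(m = as.list(fit$prior$m),
                            s2_mu = as.list(fit$prior$s2_mu),
                            s2_u = as.list(fit$prior$s2_u),
                            s2_e = fit$prior$s2_e, M = fit$prior$M))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
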
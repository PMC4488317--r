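#' Build the (deliberately imperfect) prior for one estimation run
#'
#' Priors are independent Normals for all components of the joint parameter
#' vector. To emulate imperfect extraneous prior knowledge, the intercept
#' prior means, the shared per-trait marker-effect variances and the noise
#' variance are each drawn once per estimation run from a Uniform window
#' around the population value: `m_tau ~ U[(1-p)*mean_tau, (1+p)*mean_tau]`,
#' `s2_u_tau ~ U[(1-p)*var_tau/M, (1+p)*var_tau/M]` and
#' `s2_e ~ U[(1-p)*v_e, (1+p)*v_e]`. With the default `p = 0.2` the average
#' relative discrepancy between prior mean and population mean is 10%.
#' The intercept prior standard deviations are fixed at (2.25, 150, 0.3,
#' 225) for (TLN, AM, SRE, MTU). The marker-effect prior variance is shared
#' across markers (BayesC-style shrinkage) and is not estimated.
#'
#' @param trait_means,trait_vars Named (tln, am, sre, mtu) population means
#'   and variances of the physiological traits.
#' @param v_e Residual variance of the phenotypic yields used to fit the
#'   model (`> 0`).
#' @param M Number of observed markers.
#' @param perturbation Half-width `p` of the Uniform windows, in `[0, 1)`.
#' @param intercept_sd Fixed intercept prior standard deviations.
#' @return Object of class `prior_spec` with elements `m`, `s2_mu`, `s2_u`,
#'   `s2_e`, `M`, `perturbation`.
#' @export
build_perturbed_prior <- function(trait_means, trait_vars, v_e, M,
                                  perturbation = 0.2,
                                  intercept_sd = c(tln = 2.25, am = 150,
                                                   sre = 0.3, mtu = 225)) {
  traits <- c("tln", "am", "sre", "mtu")
  trait_means <- trait_means[traits]; trait_vars <- trait_vars[traits]
  check_finite(unlist(trait_means), "trait_means")
  check_finite(unlist(trait_vars), "trait_vars")
  if (any(trait_vars <= 0) || v_e <= 0)
    stop("`trait_vars` and `v_e` must be positive", call. = FALSE)
  if (perturbation < 0 || perturbation >= 1)
    stop("`perturbation` must be in [0, 1)", call. = FALSE)
  p <- perturbation
  m <- stats::runif(4, (1 - p) * trait_means, (1 + p) * trait_means)
  s2_u <- stats::runif(4, (1 - p) * trait_vars / M,
                       (1 + p) * trait_vars / M)
  s2_e <- stats::runif(1, (1 - p) * v_e, (1 + p) * v_e)
  structure(list(m = stats::setNames(m, traits),
                 s2_mu = stats::setNames(intercept_sd[traits]^2, traits),
                 s2_u = stats::setNames(s2_u, traits),
                 s2_e = s2_e, M = as.integer(M), perturbation = p),
            class = "prior_spec")
}

abc_traits <- c("tln", "am", "sre", "mtu")

# Draw a batch of B parameter vectors from the prior.
# Returns list(mu = 4 x B matrix, u = list of four M x B matrices).
sample_theta_batch <- function(prior, B) {
  mu <- matrix(stats::rnorm(4L * B, prior$m, sqrt(prior$s2_mu)), 4L, B,
               dimnames = list(abc_traits, NULL))
  u <- lapply(stats::setNames(abc_traits, abc_traits), function(tr)
    matrix(stats::rnorm(prior$M * B, 0, sqrt(prior$s2_u[tr])), prior$M, B))
  list(mu = mu, u = u, B = B)
}

#' Draw one parameter vector from the prior
#'
#' Intercepts are Normal around the perturbed prior means; every marker
#' effect is Normal with mean zero and its trait's shared shrinkage
#' variance. The joint vector has dimension `4 * (M + 1)` (404 under the
#' default 100-marker design).
#'
#' @param prior A [build_perturbed_prior()] object.
#' @return Named numeric vector: four intercepts followed by the four
#'   length-`M` marker-effect blocks.
#' @export
sample_theta <- function(prior) {
  theta_to_vector(sample_theta_batch(prior, 1L), 1L, prior$M)
}

theta_to_vector <- function(batch, j, M) {
  v <- c(batch$mu[, j], unlist(lapply(batch$u, function(U) U[, j]),
                               use.names = FALSE))
  names(v) <- theta_names(M)
  v
}

theta_names <- function(M) {
  c(paste0("mu_", abc_traits),
    unlist(lapply(abc_traits, function(tr)
      sprintf("u_%s_%03d", tr, seq_len(M)))))
}

vector_to_theta <- function(v, M) {
  stopifnot(length(v) == 4L * (M + 1L))
  mu <- v[1:4]
  rest <- matrix(v[-(1:4)], M, 4L)
  list(mu = matrix(mu, 4L, 1L, dimnames = list(abc_traits, NULL)),
       u = stats::setNames(lapply(1:4, function(k)
         rest[, k, drop = FALSE]), abc_traits),
       B = 1L)
}

# Latent traits for a theta batch: list of four N x B matrices.
latent_batch <- function(batch, Z) {
  lapply(stats::setNames(seq_along(abc_traits), abc_traits), function(k) {
    tr <- abc_traits[k]
    sweep(Z %*% batch$u[[tr]], 2L, batch$mu[tr, ], `+`)
  })
}

#' Latent physiological traits implied by a parameter vector
#'
#' Per line, each trait equals its intercept plus the inner product of the
#' line's observed marker genotypes with that trait's marker-effect vector.
#'
#' @param theta Parameter vector from [sample_theta()] (length
#'   `4 * (M + 1)`).
#' @param genotypes `N x M` marker matrix.
#' @return `N x 4` matrix with columns `tln`, `am`, `sre`, `mtu`.
#' @export
latent_traits <- function(theta, genotypes) {
  Z <- as.matrix(genotypes)
  if (length(theta) != 4L * (ncol(Z) + 1L))
    stop(sprintf("dimension mismatch: theta has length %d but %d markers %s",
                 length(theta), ncol(Z), "imply 4*(M+1)"), call. = FALSE)
  batch <- vector_to_theta(theta, ncol(Z))
  lt <- latent_batch(batch, Z)
  out <- do.call(cbind, lapply(lt, drop))
  colnames(out) <- abc_traits
  rownames(out) <- rownames(Z)
  out
}

#' Stochastic model operator behind the ABC sampler
#'
#' The growth model supplies the deterministic component; i.i.d. Gaussian
#' noise with variance `sigma2_e` is added per line so the model operator is
#' stochastic (a fully deterministic operator would collapse the sampled
#' distribution to a point mass as the tolerance goes to zero).
#'
#' @param theta Parameter vector.
#' @param genotypes `N x M` marker matrix.
#' @param env A [cgm_environment()].
#' @param sigma2_e Noise variance (`>= 0`).
#' @param params A [cgm_params()] object.
#' @param yield_fun Deterministic yield map `function(traits, env, params)`;
#'   defaults to [cgm_yield()]. Swappable so closed-form test oracles can
#'   replace the growth model.
#' @return Simulated phenotype vector of length `N`.
#' @export
model_operator <- function(theta, genotypes, env, sigma2_e,
                           params = cgm_params(), yield_fun = cgm_yield) {
  lt <- latent_traits(theta, genotypes)
  yield_fun(lt, env, params) +
    stats::rnorm(nrow(lt), 0, sqrt(sigma2_e))
}

#' Euclidean distance between observed and simulated yields
#'
#' @param y_obs,y_sim Equal-length numeric vectors.
#' @return `sqrt(sum((y_obs - y_sim)^2))`; zero iff identical.
#' @export
abc_distance <- function(y_obs, y_sim) {
  if (length(y_obs) != length(y_sim))
    stop("`y_obs` and `y_sim` must have equal length", call. = FALSE)
  sqrt(sum((y_obs - y_sim)^2))
}

# Distances for B prior draws simulated exactly as in the main run.
# Returns list(batch, distances).
simulate_distances <- function(prior, B, y_obs, Z, env, params, yield_fun) {
  batch <- sample_theta_batch(prior, B)
  lt <- latent_batch(batch, Z)            # four N x B matrices
  N <- nrow(Z)
  traits_flat <- cbind(tln = as.vector(lt$tln), am = as.vector(lt$am),
                       sre = as.vector(lt$sre), mtu = as.vector(lt$mtu))
  y_det <- matrix(yield_fun(traits_flat, env, params), N, B)
  y_sim <- y_det + matrix(stats::rnorm(N * B, 0, sqrt(prior$s2_e)), N, B)
  d <- sqrt(colSums((y_sim - y_obs)^2))
  list(batch = batch, distances = d)
}

#' Tune the ABC tolerance from a pilot run
#'
#' The tolerance is the empirical `target_acceptance` quantile (lower,
#' linearly interpolated) of `n_pilot` distances simulated exactly as in the
#' main run. If the expected number of pilot acceptances is below one, the
#' quantile extrapolates into the lower tail and a warning is issued.
#'
#' @param y_obs Observed estimation-set yields.
#' @param genotypes Estimation-set marker matrix.
#' @param env Estimation [cgm_environment()].
#' @param prior A [build_perturbed_prior()] object.
#' @param target_acceptance Desired acceptance rate (the full-scale setting
#'   in the source experiment is about 1e-6; the desk preset uses 1e-3).
#' @param n_pilot Number of pilot draws (`>= 100`).
#' @param params,yield_fun As in [model_operator()].
#' @param batch_size Internal vectorisation chunk.
#' @return Tolerance `epsilon`.
#' @export
tune_tolerance <- function(y_obs, genotypes, env, prior,
                           target_acceptance = 1e-3, n_pilot = 2000,
                           params = cgm_params(), yield_fun = cgm_yield,
                           batch_size = 1000) {
  if (n_pilot < 100) stop("`n_pilot` must be >= 100", call. = FALSE)
  if (n_pilot * target_acceptance < 1)
    warning("expected pilot acceptances < 1; tolerance extrapolated from ",
            "the lower tail", call. = FALSE)
  Z <- as.matrix(genotypes)
  d <- numeric(0)
  left <- n_pilot
  while (left > 0) {
    B <- min(batch_size, left)
    d <- c(d, simulate_distances(prior, B, y_obs, Z, env, params,
                                 yield_fun)$distances)
    left <- left - B
  }
  unname(stats::quantile(d, target_acceptance, type = 7))
}

#' ABC rejection sampler
#'
#' Repeatedly draws candidate parameter vectors from the prior, simulates
#' yields through the stochastic model operator, and accepts candidates
#' whose Euclidean distance to the observed yields is at most `epsilon`,
#' until `n_samples` acceptances. Proposals are partitioned across `workers`
#' independent RNG streams with fixed per-worker acceptance quotas, so the
#' result is identical for a given `(seed, workers)` regardless of
#' scheduling.
#'
#' @param y_obs Observed estimation-set yields (length `N`).
#' @param genotypes `N x M` estimation-set marker matrix.
#' @param env Estimation [cgm_environment()].
#' @param prior A [build_perturbed_prior()] object.
#' @param epsilon Tolerance (`> 0`), from [tune_tolerance()].
#' @param n_samples Posterior sample size (100 at full scale, 50 in the
#'   desk preset).
#' @param params,yield_fun As in [model_operator()].
#' @param max_attempts Proposal budget; exceeding it is an error reporting
#'   the realized acceptance rate.
#' @param batch_size Proposals simulated per vectorised chunk.
#' @param workers Number of parallel workers (forked via
#'   [parallel::mclapply()] when `> 1`).
#' @param seed Optional integer; per-worker sub-seeds derive from it.
#' @param verbose Print progress every `progress_every` proposals.
#' @param progress_every Proposal interval for progress messages.
#' @return Object of class `posterior_samples`: `theta` (`n_samples x
#'   4(M+1)` matrix), `distances`, `epsilon`, `attempts`,
#'   `acceptance_rate`, `M`.
#' @export
abc_rejection <- function(y_obs, genotypes, env, prior, epsilon, n_samples,
                          params = cgm_params(), yield_fun = cgm_yield,
                          max_attempts = 1e9, batch_size = 1000,
                          workers = 1L, seed = NULL, verbose = FALSE,
                          progress_every = 1e6) {
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  Z <- as.matrix(genotypes)
  quotas <- rep(n_samples %/% workers, workers) +
    (seq_len(workers) <= n_samples %% workers)
  wseeds <- if (is.null(seed)) rep(list(NULL), workers)
            else as.list(derive_seeds(seed, workers))

  run_worker <- function(w) {
    if (!is.null(wseeds[[w]])) set.seed(wseeds[[w]])
    quota <- quotas[w]
    acc_theta <- vector("list", quota)
    acc_dist <- numeric(0)
    got <- 0L
    attempts <- 0
    while (got < quota) {
      if (attempts >= max_attempts)
        stop(sprintf(paste0("ABC attempt budget (%g) exceeded; realized ",
                            "acceptance rate %.3g"),
                     max_attempts, got / max(attempts, 1)), call. = FALSE)
      sim <- simulate_distances(prior, batch_size, y_obs, Z, env, params,
                                yield_fun)
      attempts <- attempts + batch_size
      hit <- which(sim$distances <= epsilon)
      for (j in hit) {
        if (got >= quota) break
        got <- got + 1L
        acc_theta[[got]] <- theta_to_vector(sim$batch, j, prior$M)
        acc_dist[got] <- sim$distances[j]
      }
      if (verbose && attempts %% progress_every < batch_size)
        message(sprintf("worker %d: %g proposals, %d/%d accepted",
                        w, attempts, got, quota))
    }
    list(theta = do.call(rbind, acc_theta), distances = acc_dist,
         attempts = attempts)
  }

  res <- if (workers > 1L)
    parallel::mclapply(seq_len(workers), run_worker, mc.cores = workers)
  else lapply(seq_len(workers), run_worker)
  for (r in res) if (inherits(r, "try-error") || !is.list(r))
    stop("ABC worker failed: ", paste(as.character(r), collapse = " "),
         call. = FALSE)
  keep <- quotas > 0
  theta <- do.call(rbind, lapply(res[keep], `[[`, "theta"))
  structure(list(
    theta = theta,
    distances = unlist(lapply(res[keep], `[[`, "distances")),
    epsilon = epsilon,
    attempts = sum(vapply(res, `[[`, numeric(1), "attempts")),
    acceptance_rate = n_samples /
      sum(vapply(res, `[[`, numeric(1), "attempts")),
    M = prior$M, workers = workers
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(paste0("<posterior_samples> %d draws (dim %d), epsilon %.3g,",
                     " %g attempts (acceptance %.2g)\n"),
              nrow(x$theta), ncol(x$theta), x$epsilon, x$attempts,
              x$acceptance_rate))
  invisible(x)
}

#' Posterior-predictive mean yield per line
#'
#' Evaluates the deterministic growth model over every accepted parameter
#' vector using the target environment's weather and management, and
#' averages. No noise is added: the Gaussian noise component has mean zero,
#' so the posterior-predictive mean is the average of the deterministic
#' evaluations.
#'
#' @param posterior A [abc_rejection()] result (non-empty).
#' @param genotypes_new Marker matrix of the lines to predict.
#' @param env_target Target [cgm_environment()].
#' @param params,yield_fun As in [model_operator()].
#' @return Predicted yield vector (g m^-2), one entry per line.
#' @export
posterior_predict <- function(posterior, genotypes_new, env_target,
                              params = cgm_params(), yield_fun = cgm_yield) {
  stopifnot(inherits(posterior, "posterior_samples"))
  S <- nrow(posterior$theta)
  if (is.null(S) || S == 0) stop("empty posterior", call. = FALSE)
  Z <- as.matrix(genotypes_new)
  N <- nrow(Z)
  M <- posterior$M
  # one flattened growth-model pass over all (line, sample) pairs
  mu <- t(posterior$theta[, 1:4, drop = FALSE])            # 4 x S
  rownames(mu) <- abc_traits
  u <- lapply(stats::setNames(seq_len(4), abc_traits), function(k)
    t(posterior$theta[, 4L + (k - 1L) * M + seq_len(M), drop = FALSE]))
  lt <- latent_batch(list(mu = mu, u = u, B = S), Z)
  traits_flat <- cbind(tln = as.vector(lt$tln), am = as.vector(lt$am),
                       sre = as.vector(lt$sre), mtu = as.vector(lt$mtu))
  y <- matrix(yield_fun(traits_flat, env_target, params), N, S)
  stats::setNames(rowMeans(y), rownames(Z))
}
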
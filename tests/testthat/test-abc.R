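trait_means <- c(tln = 14.5, am = 750, sre = 1.6, mtu = 1150)
trait_vars <- c(tln = 9, am = 400, sre = 0.002, mtu = 1500)

test_that("perturbed prior draws match their specification", {
  set.seed(1)
  p0 <- build_perturbed_prior(trait_means, trait_vars, v_e = 900, M = 100,
                              perturbation = 0)
  expect_equal(p0$m, trait_means)
  expect_equal(unname(p0$s2_u), unname(trait_vars / 100))
  expect_equal(p0$s2_e, 900)
  # fixed intercept prior sds
  expect_equal(unname(sqrt(p0$s2_mu)), c(2.25, 150, 0.3, 225))

  # with 20% half-width the mean relative discrepancy of the prior mean is
  # 10% (mean of |U(-0.2, 0.2)| = 0.1)
  set.seed(2)
  dev <- replicate(1e5, {
    pr <- build_perturbed_prior(trait_means["tln"] * c(tln = 1,
                                                       am = 1, sre = 1,
                                                       mtu = 1),
                                trait_vars, 900, 100, 0.2)
    abs(pr$m[["tln"]] - trait_means[["tln"]]) / trait_means[["tln"]]
  })
  expect_equal(mean(dev), 0.10, tolerance = 0.002 / 0.10)

  expect_error(build_perturbed_prior(trait_means, trait_vars, -1, 100),
               "positive")
  expect_error(build_perturbed_prior(trait_means, trait_vars, 900, 100,
                                     perturbation = 1), "perturbation")
})

test_that("theta sampling has the right dimension and moments", {
  set.seed(3)
  prior <- build_perturbed_prior(trait_means, trait_vars, 900, M = 100)
  th <- sample_theta(prior)
  expect_length(th, 404)  # 4 * (M + 1)
  expect_named(th)

  batch <- cgmwgp:::sample_theta_batch(prior, 1e5)
  expect_equal(mean(batch$mu["tln", ]), prior$m[["tln"]],
               tolerance = 3 * 2.25 / sqrt(1e5) / prior$m[["tln"]])
  expect_equal(var(batch$u$mtu[1, ]), prior$s2_u[["mtu"]],
               tolerance = 0.05)

  # near-zero shrinkage variance collapses marker effects
  tiny <- prior
  tiny$s2_u[] <- 1e-20
  expect_lt(max(abs(cgmwgp:::sample_theta_batch(tiny, 100)$u$tln)), 1e-8)
})

test_that("latent traits are intercept plus genotype dot effects", {
  set.seed(4)
  M <- 10; N <- 5
  Z <- matrix(rbinom(N * M, 1, 0.5), N, M)
  prior <- build_perturbed_prior(trait_means, trait_vars, 900, M)
  th <- sample_theta(prior)
  lt <- latent_traits(th, Z)
  # brute-force loop oracle
  traits <- c("tln", "am", "sre", "mtu")
  for (i in seq_len(N)) for (k in seq_len(4)) {
    val <- th[k]
    for (j in seq_len(M))
      val <- val + Z[i, j] * th[4 + (k - 1) * M + j]
    expect_equal(unname(lt[i, traits[k]]), unname(val), tolerance = 1e-12)
  }
  # all effects zero -> intercepts
  th0 <- th; th0[-(1:4)] <- 0
  lt0 <- latent_traits(th0, Z)
  expect_true(all(abs(sweep(lt0, 2, th0[1:4])) < 1e-12))
  # single-marker contrast
  th1 <- c(rep(0, 4), 2, rep(0, 3 * 1))
  lt1 <- latent_traits(th1, matrix(c(0, 1), 2, 1))
  expect_equal(unname(diff(lt1[, "tln"])), 2)
  expect_error(latent_traits(th[-1], Z), "dimension mismatch")
})

test_that("the model operator adds calibrated Gaussian noise to the CGM", {
  env <- constant_env(days = 60)
  set.seed(5)
  M <- 4
  Z <- matrix(rbinom(3 * M, 1, 0.5), 3, M)
  th <- c(trait_means, rep(0, 4 * M))
  det <- cgm_yield(latent_traits(th, Z), env)
  y0 <- model_operator(th, Z, env, sigma2_e = 0)
  expect_equal(y0, det, tolerance = 1e-12)
  draws <- replicate(1e4, model_operator(th, Z, env, sigma2_e = 25)[1])
  expect_equal(var(draws), 25, tolerance = 3 * 25 * sqrt(2 / 1e4) / 25)
})

test_that("the distance is Euclidean", {
  expect_equal(abc_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(abc_distance(c(3, 4), c(0, 0)), 5)
  set.seed(6)
  a <- rnorm(50); b <- rnorm(50)
  brute <- 0
  for (i in 1:50) brute <- brute + (a[i] - b[i])^2
  expect_equal(abc_distance(a, b), sqrt(brute), tolerance = 1e-12)
  expect_error(abc_distance(1:3, 1:4), "equal length")
})

test_that("tolerance tuning returns the target acceptance quantile", {
  # with one observation, zero deterministic yield and unit noise, the
  # pilot distances are |N(0,1)|, whose a-quantile is qnorm(0.5 + a/2)
  prior <- build_perturbed_prior(trait_means, trait_vars, v_e = 1, M = 1,
                                 perturbation = 0)
  prior$s2_e <- 1
  Z1 <- matrix(0, 1, 1)
  set.seed(7)
  eps <- tune_tolerance(0, Z1, constant_env(days = 5), prior,
                        target_acceptance = 0.1, n_pilot = 1e5,
                        yield_fun = function(tr, env, par) rep(0, nrow(tr)))
  expect_equal(eps, qnorm(0.55), tolerance = 0.01 / qnorm(0.55))
  # everything accepted at target 1
  set.seed(8)
  eps1 <- tune_tolerance(0, Z1, constant_env(days = 5), prior,
                         target_acceptance = 1, n_pilot = 200,
                         yield_fun = function(tr, env, par) rep(0, nrow(tr)))
  expect_gt(eps1, 2)  # the pilot maximum of 200 half-normal draws
  expect_error(tune_tolerance(0, Z1, constant_env(days = 5), prior,
                              n_pilot = 50), "n_pilot")
  expect_warning(tune_tolerance(0, Z1, constant_env(days = 5), prior,
                                target_acceptance = 1e-6, n_pilot = 200,
                                yield_fun = function(tr, env, par)
                                  rep(0, nrow(tr))),
                 "extrapolated")
})

test_that("with an infinite tolerance the sampler reproduces the prior", {
  set.seed(9)
  prior <- build_perturbed_prior(trait_means, trait_vars, v_e = 1, M = 2)
  Z <- matrix(rbinom(8, 1, 0.5), 4, 2)
  post <- abc_rejection(rep(14, 4), Z, constant_env(days = 5), prior,
                        epsilon = 1e9, n_samples = 1e4,
                        yield_fun = identity_yield, seed = 10)
  expect_equal(mean(post$theta[, "mu_tln"]), prior$m[["tln"]],
               tolerance = 3 * 2.25 / sqrt(1e4) / prior$m[["tln"]])
  expect_equal(sd(post$theta[, "mu_am"]), 150, tolerance = 0.05)
  expect_equal(var(post$theta[, "u_sre_001"]), prior$s2_u[["sre"]],
               tolerance = 0.1)
  expect_true(all(post$distances <= 1e9))
  expect_equal(nrow(post$theta), 1e4)
})

test_that("ABC matches the conjugate Normal-Normal posterior on a toy", {
  # y_i ~ N(mu, 1), prior mu ~ N(m, 2.25^2); markers all zero so only the
  # TLN intercept matters and the identity operator exposes it directly
  set.seed(11)
  n <- 5
  mu_true <- 16
  y <- rnorm(n, mu_true, 1)
  prior <- build_perturbed_prior(trait_means, trait_vars, v_e = 1, M = 1,
                                 perturbation = 0)
  prior$s2_e <- 1
  Z <- matrix(0, n, 1)
  m0 <- prior$m[["tln"]]; s0sq <- prior$s2_mu[["tln"]]
  post_var <- 1 / (1 / s0sq + n / 1)
  post_mean <- post_var * (m0 / s0sq + sum(y) / 1)

  env <- constant_env(days = 5)
  eps <- tune_tolerance(y, Z, env, prior, target_acceptance = 5e-4,
                        n_pilot = 2e4, yield_fun = identity_yield)
  post <- abc_rejection(y, Z, env, prior, eps, n_samples = 200,
                        yield_fun = identity_yield, seed = 12,
                        batch_size = 5000)
  mu_draws <- post$theta[, "mu_tln"]
  mcse <- sd(mu_draws) / sqrt(length(mu_draws))
  expect_lt(abs(mean(mu_draws) - post_mean), 3 * mcse + 0.02)
  # the ABC posterior variance approaches the analytic one from above
  expect_equal(var(mu_draws), post_var, tolerance = 0.6)
  expect_gt(var(mu_draws), post_var * 0.5)
})

test_that("the sampler is deterministic given seed and worker count", {
  prior <- build_perturbed_prior(trait_means, trait_vars, v_e = 1, M = 2)
  Z <- matrix(rbinom(8, 1, 0.5), 4, 2)
  env <- constant_env(days = 5)
  run <- function(workers) abc_rejection(
    rep(14, 4), Z, env, prior, epsilon = 6, n_samples = 20,
    yield_fun = identity_yield, seed = 13, workers = workers,
    batch_size = 500)
  expect_identical(run(1)$theta, run(1)$theta)
  expect_identical(run(2)$theta, run(2)$theta)

  # tightening the tolerance cannot raise the acceptance rate
  loose <- run(1)
  tight <- abc_rejection(rep(14, 4), Z, env, prior, epsilon = 3,
                         n_samples = 20, yield_fun = identity_yield,
                         seed = 13, batch_size = 500)
  expect_lte(tight$acceptance_rate, loose$acceptance_rate + 1e-12)

  expect_error(abc_rejection(rep(14, 4), Z, env, prior, epsilon = 0.001,
                             n_samples = 5, yield_fun = identity_yield,
                             seed = 14, max_attempts = 2000,
                             batch_size = 1000),
               "acceptance rate")
})

test_that("posterior prediction averages the CGM over accepted draws", {
  env <- constant_env(days = 60)
  set.seed(15)
  M <- 6
  Z <- matrix(rbinom(3 * M, 1, 0.5), 3, M)
  prior <- build_perturbed_prior(trait_means, trait_vars, v_e = 900, M)
  batch <- cgmwgp:::sample_theta_batch(prior, 5)
  theta_mat <- t(sapply(1:5, function(j)
    cgmwgp:::theta_to_vector(batch, j, M)))
  post <- structure(list(theta = theta_mat, distances = rep(1, 5),
                         epsilon = 2, attempts = 10, acceptance_rate = 0.5,
                         M = M), class = "posterior_samples")
  pred <- posterior_predict(post, Z, env)
  # explicit loop-and-average oracle
  oracle <- rowMeans(sapply(1:5, function(j)
    cgm_yield(latent_traits(theta_mat[j, ], Z), env)))
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-10)

  one <- post; one$theta <- theta_mat[1, , drop = FALSE]
  one$distances <- 1
  expect_equal(unname(posterior_predict(one, Z, env)),
               unname(cgm_yield(latent_traits(theta_mat[1, ], Z), env)),
               tolerance = 1e-10)
  empty <- post; empty$theta <- theta_mat[0, , drop = FALSE]
  expect_error(posterior_predict(empty, Z, env), "empty")
})

test_that("posterior-mean latent TLN tracks true TLN on synthetic data", {
  ds <- small_dataset(n_lines = 120, seed = 55)
  set.seed(56)
  sp <- split_estimation_test(120, 40)
  tm <- colMeans(ds$traits)
  tv <- apply(ds$traits, 2, var)
  fit <- fit_cgmwgp(ds$phenotypes[sp$estimation, 1],
                    ds$observed_genotypes[sp$estimation, ], ds$envs[[1]],
                    tm, tv, ds$v_e[1],
                    control = abc_control(target_acceptance = 5e-3,
                                          n_samples = 30, n_pilot = 1000),
                    seed = 57)
  # average the implied latent TLN over the posterior draws
  lt <- sapply(seq_len(nrow(fit$posterior$theta)), function(j)
    latent_traits(fit$posterior$theta[j, ],
                  ds$observed_genotypes[sp$estimation, ])[, "tln"])
  r <- cor(rowMeans(lt), ds$traits[sp$estimation, "tln"])
  expect_gt(r, 0.3)
})
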
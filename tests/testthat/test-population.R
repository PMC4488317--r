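test_that("meiosis reproduces the Haldane mapping function", {
  map <- marker_genome(1.5, 2)
  map$positions <- c(0.5, 1.0)   # 0.5 Morgan apart
  set.seed(101)
  n <- 1e5
  g <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) g[i, ] <- simulate_gamete(map)
  rec <- mean(g[, 1] != g[, 2])
  # closed form r = (1 - exp(-2d)) / 2 = 0.3161 at d = 0.5
  expect_equal(rec, (1 - exp(-1)) / 2, tolerance = 0.005 / 0.3161)
  # symmetry: allele frequency 0.5 at each locus
  expect_equal(unname(colMeans(g)), c(0.5, 0.5), tolerance = 0.02)

  # zero distance -> always co-inherited
  map$positions <- c(0.7, 0.7)
  set.seed(102)
  co <- replicate(2000, { h <- simulate_gamete(map); h[1] == h[2] })
  expect_true(all(co))
})

test_that("DH population is homozygous-coded and reproducible", {
  map <- marker_genome()
  set.seed(7)
  pop <- build_dh_population(map, 40)
  expect_equal(dim(pop$genotypes), c(40, 140))
  expect_true(all(pop$genotypes %in% c(0L, 1L)))
  set.seed(7)
  pop2 <- build_dh_population(map, 40)
  expect_identical(pop$genotypes, pop2$genotypes)
  expect_error(build_dh_population(map, 0), "n_lines")
  one <- build_dh_population(map, 1)
  expect_equal(nrow(one$genotypes), 1)
})

test_that("QTL architecture hides 40 markers, 10 per trait, disjoint", {
  map <- marker_genome()
  set.seed(11)
  arch <- assign_architecture(map)
  expect_length(arch$observed, 100)
  expect_equal(lengths(arch$qtl_indices), c(tln = 10, am = 10, sre = 10,
                                            mtu = 10))
  all_qtl <- unlist(arch$qtl_indices)
  expect_length(unique(all_qtl), 40)
  expect_length(intersect(all_qtl, arch$observed), 0)
  expect_error(assign_architecture(marker_genome(1.5, 30), 40, 10),
               "exceeds")
  empty <- assign_architecture(map, 0, 0)
  expect_length(empty$observed, 140)
})

test_that("trait rescaling hits the intervals, preserves ranks", {
  map <- marker_genome()
  set.seed(21)
  pop <- build_dh_population(map, 300)
  arch <- assign_architecture(map)
  tv <- genetic_trait_values(pop, arch)
  iv <- trait_intervals()
  for (tr in colnames(tv)) {
    expect_gte(min(tv[, tr]), iv[[tr]][1])
    expect_lte(max(tv[, tr]), iv[[tr]][2])
    # realized extremes map exactly onto the interval endpoints
    expect_equal(range(tv[, tr]), iv[[tr]], tolerance = 1e-12)
  }
  # affine rescale is rank-preserving
  raw <- drop(pop$genotypes[, arch$qtl_indices$tln] %*%
                arch$qtl_effects$tln)
  expect_equal(cor(raw, tv[, "tln"], method = "spearman"), 1)

  # degenerate population: all lines identical at a trait's QTL
  pop$genotypes[, arch$qtl_indices$sre] <- 1L
  expect_error(genetic_trait_values(pop, arch), "sre")

  # empty architecture pins every line at the midpoint
  tv0 <- genetic_trait_values(build_dh_population(map, 10),
                              assign_architecture(map, 0, 0))
  expect_true(all(tv0[, "am"] == 750))
})

test_that("phenotype noise is calibrated to the target heritability", {
  set.seed(31)
  true <- cbind(a = rnorm(1550, 1000, 80), b = rnorm(1550, 900, 60))
  ph <- make_phenotypes(true, h2 = 0.85)
  expect_equal(unname(ph$v_e),
               unname(apply(true, 2, var)) * 0.15 / 0.85, tolerance = 1e-12)
  # realized noise variance matches the calibrated v_e (chi-square bound)
  noise_var <- apply(ph$phenotypes - true, 2, var)
  expect_equal(unname(noise_var), unname(ph$v_e),
               tolerance = 3 * sqrt(2 / 1549))
  realized <- apply(true, 2, var) / apply(ph$phenotypes, 2, var)
  expect_equal(unname(realized), c(0.85, 0.85), tolerance = 0.06)

  exact <- make_phenotypes(true, h2 = 1)
  expect_equal(exact$phenotypes, true)
  expect_equal(unname(exact$v_e), c(0, 0))
  const <- make_phenotypes(cbind(rep(5, 10)), h2 = 0.85)
  expect_true(all(const$phenotypes == 5))
  expect_error(make_phenotypes(true, h2 = 0), "h2")
  expect_error(make_phenotypes(true, h2 = 1.2), "h2")
})

test_that("population structure matches the biparental DH design", {
  ds <- small_dataset(n_lines = 400, seed = 77)
  af <- colMeans(ds$pop$genotypes)
  expect_true(all(af > 0.4 & af < 0.6))  # binomial bound at n = 400

  # LD decays with map distance: mean squared genotype correlation in the
  # nearest-distance tercile exceeds that in the farthest tercile
  G <- ds$pop$genotypes
  pos <- ds$pop$map$positions
  cc <- cor(G)^2
  dd <- as.matrix(dist(pos))
  up <- upper.tri(dd)
  near <- dd[up] < quantile(dd[up], 1 / 3)
  far <- dd[up] > quantile(dd[up], 2 / 3)
  expect_gt(mean(cc[up][near]), mean(cc[up][far]))

  # distinct seeds give distinct populations; equal seeds identical ones
  a <- simulate_dataset(n_lines = 30, map = marker_genome(1.5, 20),
                        n_qtl = 4, per_trait = 1, seed = 1)
  b <- simulate_dataset(n_lines = 30, map = marker_genome(1.5, 20),
                        n_qtl = 4, per_trait = 1, seed = 2)
  a2 <- simulate_dataset(n_lines = 30, map = marker_genome(1.5, 20),
                         n_qtl = 4, per_trait = 1, seed = 1)
  expect_false(identical(a$pop$genotypes, b$pop$genotypes))
  expect_identical(a$phenotypes, a2$phenotypes)
})

test_that("datasets round-trip through CSV plus JSON sidecar", {
  ds <- small_dataset(n_lines = 25, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(unname(back$genotypes),
               unname(ds$observed_genotypes))
  expect_equal(back$traits, ds$traits, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(back$phenotypes), unname(ds$phenotypes),
               tolerance = 1e-12)
  expect_equal(back$meta$h2, 0.85)
  expect_length(back$meta$observed, 20)
})
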
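#' Genetic map of a single chromosome
#'
#' @param chrom_length Genetic length in Morgan (default 1.5).
#' @param n_markers Number of equidistant marker positions (default 140).
#' @return Object of class `marker_genome` with strictly increasing
#'   `positions` in `[0, chrom_length]`.
#' @export
marker_genome <- function(chrom_length = 1.5, n_markers = 140) {
  stopifnot(chrom_length > 0, n_markers >= 2)
  structure(list(chrom_length = chrom_length,
                 positions = seq(0, chrom_length, length.out = n_markers),
                 n_markers = as.integer(n_markers)),
            class = "marker_genome")
}

#' Simulate one gamete from the biparental cross
#'
#' Meiosis follows the Haldane model: the crossover count on the chromosome
#' is Poisson with mean equal to its length in Morgan, breakpoints are
#' uniform and there is no interference. Parent A carries allele 0 at every
#' locus, parent B allele 1 (fully informative markers); the parental origin
#' at the start of the chromosome is a fair coin and alternates at each
#' breakpoint.
#'
#' @param map A [marker_genome()].
#' @return Integer vector of 0/1 parental-origin alleles, one per marker.
#' @export
simulate_gamete <- function(map) {
  stopifnot(inherits(map, "marker_genome"))
  n_xo <- stats::rpois(1L, map$chrom_length)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (n_xo == 0L) return(rep.int(start, map$n_markers))
  bp <- sort(stats::runif(n_xo, 0, map$chrom_length))
  crossings <- findInterval(map$positions, bp)
  (start + crossings) %% 2L
}

#' Build a doubled-haploid population
#'
#' Each DH line is one independent gamete doubled, so every line is fully
#' homozygous and the genotype matrix stores a single 0/1 allele per locus.
#'
#' @param map A [marker_genome()].
#' @param n_lines Number of DH lines (default 1550).
#' @return Object of class `dh_population`: `genotypes` (`n_lines x
#'   n_markers` 0/1 matrix with line ids as rownames) and `map`.
#' @export
build_dh_population <- function(map, n_lines = 1550) {
  stopifnot(inherits(map, "marker_genome"))
  if (n_lines < 1) stop("`n_lines` must be >= 1", call. = FALSE)
  G <- t(vapply(seq_len(n_lines), function(i) simulate_gamete(map),
                integer(map$n_markers)))
  rownames(G) <- sprintf("DH%04d", seq_len(n_lines))
  colnames(G) <- sprintf("M%03d", seq_len(map$n_markers))
  structure(list(genotypes = G, map = map, n_lines = as.integer(n_lines)),
            class = "dh_population")
}

#' Assign the hidden QTL architecture
#'
#' A random subset of markers becomes QTL; each physiological trait is
#' controlled by an equal share of them, with additive substitution effects
#' drawn from a Standard Normal distribution. QTL are removed from the set
#' of observed markers available for analysis, so the four per-trait QTL
#' index sets are pairwise disjoint and the observed panel is their
#' complement.
#'
#' @param map A [marker_genome()].
#' @param n_qtl Total number of QTL (default 40).
#' @param per_trait QTL per trait (default 10); `4 * per_trait` must equal
#'   `n_qtl`.
#' @return Object of class `trait_architecture`: `qtl_indices` (named list
#'   of four index vectors), `qtl_effects` (named list of effect vectors),
#'   `observed` (observed-marker indices), `target_intervals`.
#' @export
assign_architecture <- function(map, n_qtl = 40, per_trait = 10) {
  stopifnot(inherits(map, "marker_genome"))
  if (n_qtl > map$n_markers)
    stop("`n_qtl` exceeds the number of markers", call. = FALSE)
  if (4L * per_trait != n_qtl)
    stop("`n_qtl` must equal 4 * `per_trait`", call. = FALSE)
  traits <- c("tln", "am", "sre", "mtu")
  if (per_trait == 0) {
    qtl <- stats::setNames(rep(list(integer(0)), 4), traits)
    eff <- stats::setNames(rep(list(numeric(0)), 4), traits)
    observed <- seq_len(map$n_markers)
  } else {
    all_qtl <- sample.int(map$n_markers, n_qtl)
    qtl <- split(all_qtl, rep(traits, each = per_trait))[traits]
    eff <- lapply(qtl, function(ix) stats::rnorm(length(ix)))
    observed <- setdiff(seq_len(map$n_markers), all_qtl)
  }
  structure(list(qtl_indices = qtl, qtl_effects = eff, observed = observed,
                 target_intervals = trait_intervals()),
            class = "trait_architecture")
}

#' The simulated physiological trait intervals
#'
#' Literature-typical maize ranges used to rescale raw QTL scores: TLN
#' `[6, 23]` leaves, AM `[700, 800]` cm^2, SRE `[1.5, 1.7]` g MJ^-1, MTU
#' `[1050, 1250]` degC day.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
trait_intervals <- function() {
  list(tln = c(6, 23), am = c(700, 800), sre = c(1.5, 1.7),
       mtu = c(1050, 1250))
}

#' Latent physiological trait values of every line
#'
#' Raw genetic scores per trait are sums of that trait's QTL effects over
#' each line's QTL genotypes; scores are then rescaled by the affine map
#' sending the realized population minimum and maximum onto the target
#' interval endpoints. With symmetric Standard-Normal effects the resulting
#' population mean lands near the interval midpoint; the realized means are
#' recorded in the `"rescale"` attribute. The map is affine, hence
#' rank-preserving.
#'
#' @param pop A [build_dh_population()] object.
#' @param arch A [assign_architecture()] object. With an empty architecture
#'   every line sits at the interval midpoint.
#' @return `n_lines x 4` matrix (columns `tln`, `am`, `sre`, `mtu`) with a
#'   `"rescale"` attribute holding slope/intercept/realized mean per trait.
#' @export
genetic_trait_values <- function(pop, arch) {
  stopifnot(inherits(pop, "dh_population"),
            inherits(arch, "trait_architecture"))
  traits <- names(arch$qtl_indices)
  out <- matrix(NA_real_, pop$n_lines, 4,
                dimnames = list(rownames(pop$genotypes), traits))
  rescale <- list()
  for (tr in traits) {
    ix <- arch$qtl_indices[[tr]]
    iv <- arch$target_intervals[[tr]]
    if (length(ix) == 0L) {
      out[, tr] <- mean(iv)
      rescale[[tr]] <- list(slope = 0, intercept = mean(iv),
                            realized_mean = mean(iv))
      next
    }
    if (max(ix) > ncol(pop$genotypes))
      stop("architecture indices exceed marker count", call. = FALSE)
    raw <- drop(pop$genotypes[, ix, drop = FALSE] %*% arch$qtl_effects[[tr]])
    rng <- range(raw)
    if (diff(rng) == 0)
      stop(sprintf(
        "degenerate raw-score variance for trait '%s': population is %s",
        tr, "genotypically identical at its QTL"), call. = FALSE)
    slope <- diff(iv) / diff(rng)
    intercept <- iv[1] - slope * rng[1]
    out[, tr] <- intercept + slope * raw
    rescale[[tr]] <- list(slope = slope, intercept = intercept,
                          realized_mean = mean(out[, tr]))
  }
  attr(out, "rescale") <- rescale
  out
}

#' Add heritability-calibrated noise to true yields
#'
#' Per environment, the residual variance is set from that environment's
#' true-yield variance so the within-environment heritability equals `h2`:
#' `v_e = var(true) * (1 - h2) / h2`. Phenotypes are the true (noiseless)
#' growth-model yields plus i.i.d. Gaussian noise.
#'
#' @param true_yields `n_lines x n_env` matrix of noiseless yields.
#' @param h2 Within-environment heritability, in `(0, 1]` (default 0.85).
#' @return List with `phenotypes` (same shape as `true_yields`) and `v_e`
#'   (named per-environment noise variances).
#' @export
make_phenotypes <- function(true_yields, h2 = 0.85) {
  true_yields <- as.matrix(true_yields)
  if (h2 <= 0 || h2 > 1) stop("`h2` must be in (0, 1]", call. = FALSE)
  v_e <- apply(true_yields, 2, stats::var) * (1 - h2) / h2
  noise <- sapply(seq_len(ncol(true_yields)), function(j)
    stats::rnorm(nrow(true_yields), 0, sqrt(v_e[j])))
  ph <- true_yields + matrix(noise, nrow(true_yields))
  list(phenotypes = ph, v_e = v_e)
}

#' Generate one complete synthetic dataset
#'
#' Runs the whole in-silico pipeline: build the genetic map, simulate the
#' biparental DH population by Haldane meiosis, draw the hidden QTL
#' architecture, rescale raw QTL scores into the physiological trait
#' intervals, compute true (noiseless) growth-model yields in every
#' environment, and add heritability-calibrated Gaussian noise. One master
#' seed drives deterministic sub-streams for weather, meiosis, architecture
#' and noise, so replicate datasets from distinct seeds are independent.
#'
#' @param n_lines Number of DH lines (default 1550).
#' @param map A [marker_genome()] (default 140 markers on 1.5 Morgan).
#' @param n_qtl,per_trait QTL architecture sizes (defaults 40 and 10).
#' @param h2 Within-environment heritability of the phenotypes (0.85).
#' @param envs List of [cgm_environment()]s; defaults to
#'   [default_environments()] driven by a weather sub-seed.
#' @param params A [cgm_params()] object.
#' @param seed Master seed for the replicate.
#' @return Object of class `synthetic_dataset`: `pop`, `arch`, `traits`
#'   (latent trait matrix), `observed_genotypes` (QTL columns removed),
#'   `true_yields`, `phenotypes`, `v_e`, `envs`, `h2`, `seed`.
#' @export
simulate_dataset <- function(n_lines = 1550, map = marker_genome(),
                             n_qtl = 40, per_trait = 10, h2 = 0.85,
                             envs = NULL, params = cgm_params(),
                             seed = 1L) {
  seeds <- derive_seeds(seed, 4)
  if (is.null(envs)) envs <- default_environments(seeds[1])
  set.seed(seeds[2])
  pop <- build_dh_population(map, n_lines)
  set.seed(seeds[3])
  arch <- assign_architecture(map, n_qtl, per_trait)
  traits <- genetic_trait_values(pop, arch)
  true_yields <- sapply(envs, function(e) cgm_yield(traits, e, params))
  rownames(true_yields) <- rownames(pop$genotypes)
  set.seed(seeds[4])
  ph <- make_phenotypes(true_yields, h2)
  structure(list(
    pop = pop, arch = arch, traits = traits,
    observed_genotypes = pop$genotypes[, arch$observed, drop = FALSE],
    true_yields = true_yields, phenotypes = ph$phenotypes, v_e = ph$v_e,
    envs = envs, h2 = h2, seed = seed, params = params
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_dataset> %d DH lines, %d observed markers (%d QTL hidden),",
    " %d environments, h2 = %.2f, seed = %s\n"),
    x$pop$n_lines, ncol(x$observed_genotypes),
    x$pop$map$n_markers - ncol(x$observed_genotypes),
    length(x$envs), x$h2, format(x$seed)))
  invisible(x)
}

#' Write / read a synthetic dataset as CSV plus JSON sidecar
#'
#' The CSV has one row per DH line: id, observed marker genotypes, the four
#' latent trait values, and per-environment phenotypes. The JSON sidecar
#' (same path with extension `.json`) records the seed, per-environment
#' noise variances, heritability and the QTL architecture (indices, effects,
#' rescale maps), which is enough to audit the generation but not to
#' regenerate weather; the reader restores the tabular content exactly.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path CSV path.
#' @return `read_dataset()` returns a list with `table` (the data frame),
#'   `genotypes`, `traits`, `phenotypes` matrices and `meta` (sidecar).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  G <- dataset$observed_genotypes
  ph <- dataset$phenotypes
  colnames(ph) <- paste0("yield_", names(dataset$envs))
  df <- data.frame(id = rownames(G), G,
                   dataset$traits, ph, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = dataset$seed, h2 = dataset$h2,
               v_e = as.list(dataset$v_e),
               qtl_indices = dataset$arch$qtl_indices,
               qtl_effects = dataset$arch$qtl_effects,
               rescale = attr(dataset$traits, "rescale"),
               observed = dataset$arch$observed,
               environments = lapply(dataset$envs, function(e)
                 list(label = e$label, sowing_date = format(e$sowing_date),
                      season_length = e$season_length, ppop = e$ppop)))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else NULL
  gcols <- grep("^M[0-9]+$", names(df))
  tcols <- match(c("tln", "am", "sre", "mtu"), names(df))
  ycols <- grep("^yield_", names(df))
  list(table = df,
       genotypes = as.matrix(df[, gcols, drop = FALSE]),
       traits = as.matrix(df[, tcols, drop = FALSE]),
       phenotypes = as.matrix(df[, ycols, drop = FALSE]),
       meta = meta)
}
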
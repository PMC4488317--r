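#' Physiological trait quadruple
#'
#' The four genotype-dependent inputs of the growth model: total leaf number
#' (TLN, count, possibly non-integer), area of the largest leaf (AM, cm^2 per
#' plant), solar radiation use efficiency (SRE, g per MJ) and thermal units
#' from sowing to physiological maturity (MTU, degC day).
#'
#' Values proposed by the ABC sampler may fall outside the physiological
#' simulation intervals; the engine evaluates them totally (see
#' [simulate_genotype()]).
#'
#' @param tln,am,sre,mtu Finite numeric scalars.
#' @return An object of class `physio_traits`.
#' @export
physio_traits <- function(tln, am, sre, mtu) {
  for (v in c("tln", "am", "sre", "mtu")) check_finite(get(v), v)
  structure(list(tln = tln, am = am, sre = sre, mtu = mtu),
            class = "physio_traits")
}

#' Cumulative thermal units
#'
#' Daily thermal-unit increment is `max(0, tavg - t_base)`; the series is the
#' running sum from the first day.
#'
#' @param tavg Daily mean air temperature series (degC).
#' @param t_base Base temperature (degC), default 8.
#' @return Non-decreasing cumulative thermal-unit series (degC day).
#' @export
thermal_units <- function(tavg, t_base = 8) {
  if (length(tavg) == 0L) stop("`tavg` must be non-empty", call. = FALSE)
  check_finite(tavg, "tavg")
  check_finite(t_base, "t_base")
  cumsum(pmax(0, tavg - t_base))
}

#' Daily dry-matter increment from intercepted radiation
#'
#' Dry-matter growth is intercepted solar radiation converted with
#' efficiency SRE; interception follows Beer's law through a canopy of
#' leaf area per plant LAPP at plant population PPOP:
#' `DM_g = SR * SRE * (1 - exp(-k * LAPP * PPOP))`.
#'
#' @param sr Incident solar radiation (MJ m^-2 day^-1), `>= 0`.
#' @param sre Radiation use efficiency (g MJ^-1), `>= 0`.
#' @param lapp Green leaf area per plant (m^2 plant^-1), `>= 0`.
#' @param ppop Plant population (plants m^-2), `> 0`.
#' @param k Light extinction coefficient, `> 0`.
#' @return Dry-matter increment (g m^-2 day^-1), bounded above by `sr * sre`.
#' @export
daily_biomass_increment <- function(sr, sre, lapp, ppop, k = 0.4) {
  for (v in c("sr", "sre", "lapp", "ppop", "k")) check_finite(get(v), v)
  if (any(sr < 0) || any(sre < 0) || any(lapp < 0))
    stop("`sr`, `sre` and `lapp` must be non-negative", call. = FALSE)
  if (any(ppop <= 0) || any(k <= 0))
    stop("`ppop` and `k` must be positive", call. = FALSE)
  sr * sre * (1 - exp(-k * lapp * ppop))
}

# Per-leaf area profile: area of leaf i (continuous leaf index) is
# AM * exp(a*(i - i0)^2 + b*(i - i0)^3), i0 the largest-leaf position.
# Returns an L x ncap matrix of full-leaf areas (cm^2) for vectors of
# tln/am (already clamped), zeroed beyond each line's leaf count.
leaf_area_matrix <- function(tln, am, params) {
  ncap <- max(1L, min(params$max_leaves, ceiling(max(tln))))
  i <- seq_len(ncap)
  x0 <- params$largest_leaf_frac * tln
  dev <- outer(-x0, i, `+`)                       # i - x0
  A <- am * exp(params$leaf_a * dev^2 + params$leaf_b * dev^3)
  A[dev + x0 > tln + 1] <- 0                      # leaves beyond ceiling(tln)
  A
}

# Expanded leaf area (cm^2 per plant) at fractional expanded-leaf count n,
# by linear interpolation within the currently expanding leaf.
expanded_area <- function(n, A, Cpad) {
  L <- nrow(A)
  fl <- floor(n)
  idx_full <- cbind(seq_len(L), fl + 1L)
  idx_part <- cbind(seq_len(L), pmin(fl + 1L, ncol(A)))
  Cpad[idx_full] + (n - fl) * A[idx_part]
}

# Vectorised engine core shared by simulate_genotype() and cgm_yield().
# tln/am/sre/mtu are equal-length vectors (one entry per genotype).
cgm_core <- function(tln, am, sre, mtu, env, params, trajectory = FALSE) {
  stopifnot(inherits(env, "cgm_environment"))
  L <- length(tln)
  D <- env$season_length
  tavg <- env$tavg
  sr <- env$sr
  if (length(tavg) < D || length(sr) < D)
    stop("environment weather series shorter than season_length",
         call. = FALSE)

  # ABC totality: clamp non-physiological proposals instead of failing
  tln_c <- pmin(pmax(tln, 0), params$max_leaves)
  am_c <- pmax(am, 0)
  sre_c <- pmax(sre, 0)

  biomass <- numeric(L)
  fill_days <- numeric(L)
  stop_day <- integer(L)
  if (D == 0L) {
    return(list(final_yield = numeric(L), biomass = biomass,
                stop_day = stop_day, maturity_reached = mtu <= 0,
                trajectory = NULL))
  }

  tu <- thermal_units(tavg[seq_len(D)], params$t_base)
  tu_prev <- c(0, tu[-D])
  A <- leaf_area_matrix(tln_c, am_c, params)
  # row-wise cumulative sums via triangular multiply (fast for big batches)
  ut <- upper.tri(diag(ncol(A)), diag = TRUE) + 0
  Cpad <- cbind(0, A %*% ut)
  tu_silk <- params$tu_emerge + params$phyllochron * tln_c + params$silk_lag
  tu_fill <- tu_silk + params$fill_lag

  traj <- NULL
  if (trajectory)
    traj <- list(biomass = matrix(0, L, D), lapp = matrix(0, L, D),
                 senescent = matrix(0, L, D), grain = matrix(0, L, D))

  for (t in seq_len(D)) {
    active <- tu_prev[t] < mtu
    n_t <- pmin(pmax((tu[t] - params$tu_emerge) / params$phyllochron, 0),
                tln_c)
    e_cm2 <- expanded_area(n_t, A, Cpad)
    sen_frac <- pmin(pmax((tu[t] - tu_silk) / params$sen_dur, 0), 1)^2
    sen_cm2 <- sen_frac * e_cm2
    green_m2 <- (e_cm2 - sen_cm2) * 1e-4
    dm <- sr[t] * sre_c * (1 - exp(-params$k * green_m2 * env$ppop)) * active
    biomass <- biomass + dm
    fill_days <- fill_days + (tu[t] >= tu_fill & active)
    stop_day <- stop_day + active
    if (trajectory) {
      traj$biomass[, t] <- biomass
      traj$lapp[, t] <- green_m2 * active
      traj$senescent[, t] <- sen_cm2 * 1e-4 * active
      traj$grain[, t] <- pmin(params$hi_rate * fill_days, params$hi_max) *
        biomass
    }
  }
  hi <- pmin(params$hi_rate * fill_days, params$hi_max)
  list(final_yield = hi * biomass, biomass = biomass, stop_day = stop_day,
       maturity_reached = tu[D] >= mtu, trajectory = traj)
}

#' Green and senescent leaf-area development for one genotype
#'
#' Expanded leaf area follows the running sum of the bell-shaped individual
#' leaf-area profile as leaves appear (one leaf per phyllochron of thermal
#' units after emergence); senescence removes an increasing fraction of the
#' expanded area between silking and physiological maturity. A non-positive
#' total leaf number gives an all-zero canopy rather than an error, so the
#' engine stays total under arbitrary ABC proposals.
#'
#' @param traits A [physio_traits()] object.
#' @param thermal_units Cumulative thermal-unit series from [thermal_units()].
#' @param params A [cgm_params()] object.
#' @return A list of per-day series (m^2 plant^-1): `expanded`, `senescent`
#'   and green `lapp` (= expanded - senescent).
#' @export
leaf_area_profile <- function(traits, thermal_units, params = cgm_params()) {
  stopifnot(inherits(traits, "physio_traits"))
  check_finite(thermal_units, "thermal_units")
  D <- length(thermal_units)
  tln_c <- min(max(traits$tln, 0), params$max_leaves)
  am_c <- max(traits$am, 0)
  if (tln_c == 0 || am_c == 0) {
    z <- numeric(D)
    return(list(expanded = z, senescent = z, lapp = z))
  }
  A <- leaf_area_matrix(tln_c, am_c, params)
  Cpad <- matrix(c(0, cumsum(A[1L, ])), nrow = 1L)
  tu_silk <- params$tu_emerge + params$phyllochron * tln_c + params$silk_lag
  n_t <- pmin(pmax((thermal_units - params$tu_emerge) / params$phyllochron,
                   0), tln_c)
  e <- vapply(n_t, function(n) expanded_area(n, A, Cpad), numeric(1))
  sen_frac <- pmin(pmax((thermal_units - tu_silk) / params$sen_dur, 0), 1)^2
  sen <- sen_frac * e
  list(expanded = e * 1e-4, senescent = sen * 1e-4, lapp = (e - sen) * 1e-4)
}

#' Simulate one genotype's growth and yield in one environment
#'
#' Deterministic daily-timestep simulation from sowing to the earlier of
#' physiological maturity (cumulative thermal units reaching MTU) and the end
#' of the growing season. Grain yield accrues as a linearly increasing
#' harvest index applied to cumulative biomass, starting a fixed thermal lag
#' after silking; if the season ends first, the trajectory is truncated there
#' regardless of maturity.
#'
#' @param traits A [physio_traits()] object. Non-physiological values are
#'   handled totally: negative SRE/AM are clamped to zero, `tln <= 0` gives
#'   no canopy, `mtu <= 0` means immediate maturity (zero yield).
#' @param env A [cgm_environment()] object.
#' @param params A [cgm_params()] object.
#' @return An object of class `growth_trajectory`: per-day series `biomass`
#'   (g m^-2, cumulative), `lapp` (green leaf area, m^2 plant^-1),
#'   `senescent` (m^2 plant^-1), `grain` (g m^-2), plus `final_yield`
#'   (g m^-2), `days_simulated` and `maturity_reached`.
#' @export
simulate_genotype <- function(traits, env, params = cgm_params()) {
  stopifnot(inherits(traits, "physio_traits"))
  res <- cgm_core(traits$tln, traits$am, traits$sre, traits$mtu, env, params,
                  trajectory = TRUE)
  e <- res$stop_day
  take <- seq_len(e)
  out <- list(
    biomass = if (e) res$trajectory$biomass[1L, take] else numeric(0),
    lapp = if (e) res$trajectory$lapp[1L, take] else numeric(0),
    senescent = if (e) res$trajectory$senescent[1L, take] else numeric(0),
    grain = if (e) res$trajectory$grain[1L, take] else numeric(0),
    final_yield = res$final_yield,
    days_simulated = e,
    maturity_reached = res$maturity_reached
  )
  structure(out, class = "growth_trajectory")
}

#' Final grain yield for many genotypes at once
#'
#' Vectorised wrapper around the engine core used by the ABC sampler and the
#' experiment driver; one call evaluates the growth model for every row of a
#' trait table in a single pass over the season.
#'
#' @param traits Matrix or data frame with columns `tln`, `am`, `sre`, `mtu`
#'   (one row per genotype).
#' @param env A [cgm_environment()] object.
#' @param params A [cgm_params()] object.
#' @return Numeric vector of final grain yields (g m^-2), one per row.
#' @export
cgm_yield <- function(traits, env, params = cgm_params()) {
  traits <- as.matrix(traits[, c("tln", "am", "sre", "mtu"), drop = FALSE])
  cgm_core(traits[, "tln"], traits[, "am"], traits[, "sre"],
           traits[, "mtu"], env, params)$final_yield
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf(
    "<growth_trajectory> %d days, final yield %.1f g m^-2, maturity %s\n",
    x$days_simulated, x$final_yield,
    if (x$maturity_reached) "reached" else "not reached"))
  invisible(x)
}
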
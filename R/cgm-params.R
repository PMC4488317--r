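#' Coefficients of the maize growth model
#'
#' A single frozen default coefficient set for the daily-timestep maize
#' simulator. The model follows the classical radiation-capture structure of
#' temperate maize simulators: phenology driven by thermal units above a base
#' temperature, a bell-shaped individual leaf-area profile centred on the
#' largest leaf, Beer's-law light interception with extinction coefficient
#' `k`, dry-matter growth proportional to intercepted radiation, and grain
#' fill as a linearly increasing harvest index after silking.
#'
#' Defaults (units in brackets):
#' \describe{
#'   \item{t_base}{Base temperature for thermal units (8 degC). Daily
#'     increment is `max(0, tavg - t_base)`.}
#'   \item{k}{Canopy light extinction coefficient (0.4, dimensionless).}
#'   \item{tu_emerge}{Thermal units from sowing to emergence (87 degC day).}
#'   \item{phyllochron}{Thermal units per fully expanded leaf (21 degC day
#'     per leaf); full expansion of `tln` leaves therefore takes
#'     `tln * phyllochron` after emergence.}
#'   \item{silk_lag}{Thermal units from completed leaf expansion to silking
#'     (50 degC day).}
#'   \item{sen_dur}{Thermal-time span of leaf senescence: the senesced
#'     fraction of expanded area rises quadratically from silking to
#'     complete senescence `sen_dur` (800 degC day) later. The schedule is
#'     deliberately independent of MTU, so raising MTU beyond what the
#'     season can supply has exactly no effect on the trajectory.}
#'   \item{fill_lag}{Thermal units from silking to the start of effective
#'     grain fill (100 degC day).}
#'   \item{hi_rate}{Daily increase in harvest index during grain fill
#'     (0.015 per day).}
#'   \item{hi_max}{Harvest index cap (0.5, dimensionless).}
#'   \item{leaf_a, leaf_b}{Quadratic/cubic coefficients of the log
#'     individual-leaf-area profile around the largest leaf
#'     (-0.0344, 0.000731), standard maize values.}
#'   \item{largest_leaf_frac}{Position of the largest leaf as a fraction of
#'     total leaf number (0.67).}
#'   \item{max_leaves}{Numerical cap on the leaf count used when evaluating
#'     the area profile (50); protects against absurd ABC proposals.}
#' }
#'
#' The defaults are internally consistent with thermal-unit-to-maturity
#' values in `[1050, 1250]`: even at `tln = 23` the start of grain fill
#' (`87 + 23*21 + 50 + 100 = 720` degC day) precedes the lowest maturity
#' target, so every genotype in the simulated trait ranges has a positive
#' potential grain-fill window.
#'
#' @param ... Named overrides for any coefficient.
#' @return An object of class `cgm_params` (named list).
#' @seealso [simulate_genotype()], [write_cgm_params()]
#' @export
cgm_params <- function(...) {
  p <- list(
    t_base            = 8,
    k                 = 0.4,
    tu_emerge         = 87,
    phyllochron       = 21,
    silk_lag          = 50,
    sen_dur           = 800,
    fill_lag          = 100,
    hi_rate           = 0.015,
    hi_max            = 0.5,
    leaf_a            = -0.0344,
    leaf_b            = 0.000731,
    largest_leaf_frac = 0.67,
    max_leaves        = 50
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown CGM coefficient(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  for (nm in names(p)) check_finite(p[[nm]], nm)
  if (p$k <= 0) stop("`k` must be > 0", call. = FALSE)
  structure(p, class = "cgm_params")
}

#' Write / read CGM coefficients as a flat YAML file
#'
#' @param params A [cgm_params()] object.
#' @param path File path.
#' @return `read_cgm_params()` returns a `cgm_params` object.
#' @export
write_cgm_params <- function(params, path) {
  stopifnot(inherits(params, "cgm_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_cgm_params
#' @export
read_cgm_params <- function(path) {
  do.call(cgm_params, yaml::read_yaml(path))
}
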
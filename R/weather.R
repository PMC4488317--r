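#' Seasonal weather profile for the synthetic generator
#'
#' Smooth annual cycles for daily mean temperature and solar radiation are
#' modelled as sinusoids peaking in mid-summer, with independent Gaussian
#' day-to-day noise around them. The shipped presets emulate a continental
#' US Corn Belt location; the two years share the climate curve and differ
#' in their noise realisation (and slightly in radiation, the first season
#' being the sunnier one).
#'
#' @param year One of `"2012"`, `"2013"` for the shipped presets.
#' @param ... Overrides for any profile parameter: `tavg_mean`, `tavg_amp`,
#'   `tavg_peak_doy`, `tavg_sd` (degC), `sr_mean`, `sr_amp`, `sr_peak_doy`,
#'   `sr_sd` (MJ m^-2 day^-1), `start_date`.
#' @return A named list of class `weather_profile`.
#' @export
weather_profile <- function(year = "2012", ...) {
  year <- match.arg(year, c("2012", "2013"))
  p <- list(
    tavg_mean = 8, tavg_amp = 12.5, tavg_peak_doy = 200, tavg_sd = 3,
    sr_mean = 13, sr_amp = 9, sr_peak_doy = 195, sr_sd = 3.5,
    start_date = as.Date(paste0(year, "-01-01"))
  )
  if (year == "2012") p$sr_mean <- 14  # drier, sunnier season
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown profile parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p[names(dots)] <- dots
  structure(p, class = "weather_profile")
}

#' Generate a synthetic daily weather series
#'
#' @param profile A [weather_profile()].
#' @param n_days Number of consecutive days to generate (default a full
#'   year).
#' @param seed Optional integer seed; the series is deterministic given it.
#' @return A `data.frame` of class `weather_series` with columns `date`,
#'   `tavg_c` and `sr_mj_m2` (radiation clamped at zero).
#' @export
synthesize_weather <- function(profile = weather_profile(), n_days = 365,
                               seed = NULL) {
  stopifnot(inherits(profile, "weather_profile"))
  if (n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dates <- profile$start_date + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  tavg <- profile$tavg_mean +
    profile$tavg_amp * cos(2 * pi * (doy - profile$tavg_peak_doy) / 365) +
    stats::rnorm(n_days, 0, profile$tavg_sd)
  sr <- pmax(0, profile$sr_mean +
               profile$sr_amp * cos(2 * pi * (doy - profile$sr_peak_doy) / 365) +
               stats::rnorm(n_days, 0, profile$sr_sd))
  structure(data.frame(date = dates, tavg_c = tavg, sr_mj_m2 = sr),
            class = c("weather_series", "data.frame"))
}

#' Read / write a daily weather CSV
#'
#' The file must have a header with columns `date` (ISO-8601), `tavg_c` and
#' `sr_mj_m2`. Records must be contiguous daily values with no duplicates,
#' and radiation must be non-negative.
#'
#' @param path CSV file path.
#' @return A `weather_series` data frame.
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tavg_c", "sr_mj_m2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weather file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop("unparseable date(s) in weather file", call. = FALSE)
  if (anyDuplicated(dates))
    stop("duplicate date(s) in weather file: ",
         paste(unique(dates[duplicated(dates)]), collapse = ", "),
         call. = FALSE)
  full <- seq(min(dates), max(dates), by = "day")
  gap <- setdiff(as.character(full), as.character(dates))
  if (length(gap))
    stop("weather file has gaps; missing dates: ",
         paste(utils::head(gap, 10), collapse = ", "), call. = FALSE)
  check_finite(df$tavg_c, "tavg_c")
  check_finite(df$sr_mj_m2, "sr_mj_m2")
  if (any(df$sr_mj_m2 < 0))
    stop("negative solar radiation in weather file", call. = FALSE)
  df <- df[order(dates), ]
  df$date <- sort(dates)
  structure(df, class = c("weather_series", "data.frame"))
}

#' @rdname read_weather
#' @param weather A `weather_series` data frame.
#' @export
write_weather <- function(weather, path) {
  stopifnot(inherits(weather, "weather_series"))
  out <- data.frame(date = format(weather$date, "%Y-%m-%d"),
                    tavg_c = weather$tavg_c, sr_mj_m2 = weather$sr_mj_m2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Growing environment: weather plus management
#'
#' Bundles the daily weather from sowing onwards with the management
#' variables the growth model needs: season length (after which simulation
#' is terminated regardless of maturity) and plant population.
#'
#' @param label Environment identifier (e.g. `"2012"`).
#' @param weather A `weather_series` covering at least `season_length` days
#'   from `sowing_date`.
#' @param sowing_date Sowing date (`Date` or ISO string); day 1 of the
#'   simulation.
#' @param season_length Maximum growing-season length in days (`> 0`).
#' @param ppop Plant population (plants m^-2, `> 0`).
#' @return An object of class `cgm_environment` with from-sowing series
#'   `tavg` and `sr`.
#' @export
cgm_environment <- function(label, weather, sowing_date, season_length,
                            ppop) {
  stopifnot(inherits(weather, "weather_series"))
  sowing_date <- as.Date(sowing_date)
  if (is.na(sowing_date)) stop("unparseable `sowing_date`", call. = FALSE)
  if (season_length < 0) stop("`season_length` must be >= 0", call. = FALSE)
  if (ppop <= 0) stop("`ppop` must be > 0", call. = FALSE)
  idx <- match(sowing_date, weather$date)
  if (is.na(idx)) stop("sowing date not covered by weather series",
                       call. = FALSE)
  if (nrow(weather) - idx + 1L < season_length)
    stop("weather series covers fewer than `season_length` days from sowing",
         call. = FALSE)
  take <- seq.int(idx, length.out = max(season_length, 1L))
  if (season_length == 0) take <- integer(0)
  structure(list(label = label,
                 tavg = weather$tavg_c[take],
                 sr = weather$sr_mj_m2[take],
                 sowing_date = sowing_date,
                 sowing_index = idx,
                 season_length = as.integer(season_length),
                 ppop = ppop),
            class = "cgm_environment")
}

#' The two default growing environments
#'
#' A short and a long season in the style of the proof-of-concept setup:
#' sowing April 15 with a 120-day season at 8 plants m^-2, and sowing
#' May 15 with a 130-day season at 10 plants m^-2, each driven by its own
#' synthetic weather year. The shipped climate profile is calibrated so the
#' short season accumulates only about 1000-1100 thermal units -- below the
#' whole simulated maturity interval, so every genotype is truncated by
#' season end there, while the long season supplies about 1300-1400 and
#' lets almost all genotypes mature. This asymmetry (maturity genetics
#' inert in one environment, active in the other, and late leaf canopies
#' unrewarded in the short season) is what generates crossover
#' genotype-by-environment interaction between the two seasons.
#'
#' @param seed Integer seed for the two weather realisations.
#' @return Named list of two [cgm_environment()] objects (`"2012"`,
#'   `"2013"`).
#' @export
default_environments <- function(seed = 1L) {
  seeds <- derive_seeds(seed, 2)
  w12 <- synthesize_weather(weather_profile("2012"), 365, seeds[1])
  w13 <- synthesize_weather(weather_profile("2013"), 365, seeds[2])
  list(
    "2012" = cgm_environment("2012", w12, "2012-04-15", 120, 8),
    "2013" = cgm_environment("2013", w13, "2013-05-15", 130, 10)
  )
}
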
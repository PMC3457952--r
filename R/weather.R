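# Daily weather series: synthetic generator and CSV I/O.

#' Synthetic daily weather series
#'
#' Sinusoidal annual temperature with seeded daily noise, plus gamma
#' precipitation.  Two climate profiles are provided: a Finland-like
#' profile (colder, later spring) and a Denmark-like profile (milder
#' maritime climate whose spring crossing of the grass-growth
#' temperature occurs earlier).  A \code{constant} profile holds
#' temperature fixed (useful for controlled experiments).  Years are 365
#' days; the series is deterministic given (profile, years, seed).
#'
#' @param profile \code{"finland_like"}, \code{"denmark_like"} or
#'   \code{"constant"}.
#' @param years number of 365-day years.
#' @param seed integer seed.
#' @param constant_temp temperature used by the constant profile (deg C).
#' @return data.frame: day (1..365*years), year, doy, temp_c, precip_mm.
#' @export
syntheticWeather <- function(profile = c("finland_like", "denmark_like",
                                         "constant"),
                             years = 1, seed = 1, constant_temp = 10) {
  profile <- match.arg(profile)
  n <- years * 365
  doy <- rep(1:365, years)
  temp <- switch(profile,
    constant = rep(constant_temp, n),
    finland_like = 4.5 + 12.5 * sin(2 * pi * (doy - 110) / 365),
    denmark_like = 8.0 + 8.5 * sin(2 * pi * (doy - 105) / 365))
  if (profile != "constant") {
    temp <- .with_seed(seed, temp + rnorm(n, 0, 1.5))
  }
  precip <- .with_seed(seed + 1, rgamma(n, shape = 0.6, scale = 3))
  data.frame(day = seq_len(n), year = rep(seq_len(years), each = 365),
             doy = doy, temp_c = temp, precip_mm = precip)
}

#' Read and write daily weather CSV
#'
#' Format: header \code{date,temp_c,precip_mm} with ISO dates.  Dates
#' must be contiguous (no gaps); leap days are accepted on input and
#' dropped from the internal day-of-year representation, which uses
#' 365-day years throughout the simulation.
#'
#' @param path file path.
#' @return \code{readWeatherCsv}: data.frame day, year, doy, temp_c,
#'   precip_mm.
#' @export
readWeatherCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "temp_c", "precip_mm")
  if (!identical(names(df)[1:3], need))
    stop("weather CSV must have header: ", paste(need, collapse = ","))
  dates <- as.Date(df$date)
  if (any(is.na(dates))) stop("unparseable date(s) at row(s): ",
                              paste(which(is.na(dates)), collapse = ", "))
  gaps <- which(diff(dates) != 1)
  if (length(gaps))
    stop("missing day(s) after: ", paste(dates[gaps], collapse = ", "))
  doy <- as.integer(strftime(dates, "%j"))
  leap <- strftime(dates, "%m-%d") == "02-29"
  df <- df[!leap, ]; dates <- dates[!leap]; doy <- doy[!leap]
  # renumber after dropping Feb 29 in leap years
  doy[strftime(dates, "%m") >= "03" &
        as.integer(strftime(dates, "%Y")) %% 4 == 0 &
        doy > 59] <- doy[strftime(dates, "%m") >= "03" &
                           as.integer(strftime(dates, "%Y")) %% 4 == 0 &
                           doy > 59] - 1L
  data.frame(day = seq_len(nrow(df)),
             year = cumsum(doy == 1L) + as.integer(doy[1] != 1L),
             doy = doy, temp_c = df$temp_c, precip_mm = df$precip_mm)
}

#' @rdname readWeatherCsv
#' @param weather data.frame with doy, temp_c, precip_mm columns.
#' @param start_date calendar date of the first row.
#' @export
writeWeatherCsv <- function(weather, path, start_date = "2001-01-01") {
  dates <- seq(as.Date(start_date), by = 1, length.out = nrow(weather) +
                 100)
  dates <- dates[strftime(dates, "%m-%d") != "02-29"][seq_len(nrow(weather))]
  out <- data.frame(date = format(dates, "%Y-%m-%d"),
                    temp_c = weather$temp_c, precip_mm = weather$precip_mm)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
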
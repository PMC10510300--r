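#' Dew point from dry-bulb temperature and relative humidity
#'
#' Magnus-Tetens approximation with constants a = 17.62 and b = 243.12 degC:
#' \deqn{DP = b \alpha / (a - \alpha), \quad
#'       \alpha = \ln(RH/100) + a\,DBT / (b + DBT).}
#' At saturation (\code{rh = 100}) the dew point equals the dry-bulb
#' temperature exactly.
#'
#' @param dbt dry-bulb temperature in degC; must lie in the approximation's
#'   validity window \code{[-45, 60]}.
#' @param rh relative humidity in percent, in (0, 100]. Values above 100
#'   (sensor artifact) are clamped to 100; values <= 0 are an error.
#' @return dew point in degC, same length as the inputs.
#' @examples
#' dew_point(25, 100)  # 25
#' dew_point(30, 50)   # about 18.4
#' @export
dew_point <- function(dbt, rh) {
  stopifnot(is.numeric(dbt), is.numeric(rh))
  if (any(!is.finite(dbt)) || any(!is.finite(rh)))
    stop("dew_point: non-finite inputs")
  if (any(dbt < -45 | dbt > 60))
    stop("dew_point: dry-bulb temperature outside the validity window [-45, 60] degC")
  if (any(rh <= 0))
    stop("dew_point: relative humidity must be > 0")
  rh <- pmin(rh, 100)
  a <- 17.62
  b <- 243.12
  alpha <- log(rh / 100) + a * dbt / (b + dbt)
  if (any(alpha >= a))
    stop("dew_point: alpha >= a, outside the approximation's domain")
  b * alpha / (a - alpha)
}

#' Add dew point to a climate series
#'
#' @param climate data frame with columns \code{dbt_c} and \code{rh_pct}
#'   (the layout written by [simulate_climate()]).
#' @return the same data frame with a derived \code{dp_c} column.
#' @export
add_dew_point <- function(climate) {
  stopifnot(all(c("dbt_c", "rh_pct") %in% names(climate)))
  climate$dp_c <- dew_point(climate$dbt_c, climate$rh_pct)
  climate
}

#' Hourly climate aggregates per room
#'
#' Averages all 5-min records of all functioning loggers of a room within each
#' clock hour. A record at time t belongs to the half-open hour
#' [H:00, H+1:00). Hours without any record are absent from the output.
#' When individual loggers stop reporting mid-hour, the mean is simply taken
#' over the surviving records.
#'
#' @param climate data frame with columns \code{room}, \code{timestamp}
#'   (POSIXct), \code{dbt_c}, \code{rh_pct} and optionally \code{dp_c}
#'   (computed with [add_dew_point()] when absent).
#' @param room optional room identifier to restrict to a single room.
#' @return data frame with one row per room-hour: \code{room}, \code{date},
#'   \code{hour}, \code{avgtemp_c}, \code{avg_rh_pct}, \code{avg_dp_c} and the
#'   number of contributing records \code{n_records}.
#' @export
hourly_average <- function(climate, room = NULL) {
  stopifnot(all(c("room", "timestamp", "dbt_c", "rh_pct") %in% names(climate)))
  if (!is.null(room)) climate <- climate[climate$room %in% room, , drop = FALSE]
  if (nrow(climate) == 0) {
    return(data.frame(room = character(), date = as.Date(character()),
                      hour = integer(), avgtemp_c = numeric(),
                      avg_rh_pct = numeric(), avg_dp_c = numeric(),
                      n_records = integer(), stringsAsFactors = FALSE))
  }
  if (!("dp_c" %in% names(climate))) climate <- add_dew_point(climate)
  lt <- as.POSIXlt(climate$timestamp, tz = attr(climate$timestamp, "tzone") %||% "UTC")
  key <- data.frame(room = as.character(climate$room),
                    date = as.Date(format(climate$timestamp, "%Y-%m-%d",
                                          tz = attr(climate$timestamp, "tzone") %||% "UTC")),
                    hour = lt$hour, stringsAsFactors = FALSE)
  agg <- aggregate(cbind(avgtemp_c = climate$dbt_c,
                         avg_rh_pct = climate$rh_pct,
                         avg_dp_c = climate$dp_c),
                   by = key, FUN = mean)
  cnt <- aggregate(list(n_records = climate$dbt_c), by = key, FUN = length)
  out <- merge(agg, cnt, by = c("room", "date", "hour"))
  out <- out[order(out$room, out$date, out$hour), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach the hourly climate covariate to phenotype records
#'
#' Each phenotype record measured at hour H in location (room) L receives the
#' hourly aggregate of the hour containing the measurement time.
#'
#' @param pheno phenotype table with columns \code{location}, \code{date}
#'   (Date) and \code{time} (integer clock hour).
#' @param hourly output of [hourly_average()].
#' @param which one of \code{"avgtemp_c"}, \code{"avg_rh_pct"},
#'   \code{"avg_dp_c"}.
#' @return \code{pheno} with an added \code{climate} column (NA where no
#'   aggregate exists for the record's room-hour).
#' @export
attach_climate <- function(pheno, hourly, which = "avgtemp_c") {
  which <- match.arg(which, c("avgtemp_c", "avg_rh_pct", "avg_dp_c"))
  stopifnot(all(c("location", "date", "time") %in% names(pheno)))
  k1 <- paste(pheno$location, pheno$date, floor(pheno$time))
  k2 <- paste(hourly$room, hourly$date, hourly$hour)
  pheno$climate <- hourly[[which]][match(k1, k2)]
  pheno
}
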
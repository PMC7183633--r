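# Engine time model: timezone-naive local datetimes, represented internally
# as POSIXct pinned to UTC so arithmetic is pure calendar arithmetic with no
# DST transitions. Formatted ISO-8601 (no zone designator) on output.

#' Parse an ISO-8601 local datetime
#'
#' Accepts \code{"YYYY-MM-DD"}, \code{"YYYY-MM-DDTHH:MM"} or
#' \code{"YYYY-MM-DDTHH:MM:SS"} (a space is accepted in place of \code{T}).
#' Times are local to the participant; no timezone field exists in the
#' engine.
#'
#' @param x character vector.
#' @return POSIXct vector.
#' @export
parse_dt <- function(x) {
  x <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out)) stop("unparsable datetime: ", x[which(is.na(out))[1]])
  out
}

#' Format a datetime as ISO-8601 (naive local, seconds precision)
#' @param x POSIXct vector.
#' @return character vector; NA elements stay NA.
#' @export
fmt_iso <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

# midnight of the calendar day of `x`, offset by `days`
local_day <- function(x, days = 0) {
  as.POSIXct(as.Date(x, tz = "UTC") + days, tz = "UTC")
}

# combine a calendar day (midnight POSIXct) with an "HH:MM" clock time
at_clock_time <- function(day, hhmm) {
  parts <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  day + parts[1] * 3600 + parts[2] * 60
}

minutes <- function(m) m * 60

# elapsed whole minutes between two instants (floor)
elapsed_minutes <- function(from, to) {
  floor(as.numeric(difftime(to, from, units = "mins")))
}
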
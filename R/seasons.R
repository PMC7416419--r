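#' Map sampling dates to polar seasons
#'
#' The sampling design covers seven months of the year: December, January and
#' February are summer; July and August are winter; October and November are
#' spring. The remaining months were never sampled and are rejected rather
#' than silently binned.
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @return Character vector with values `"summer"`, `"winter"`, `"spring"`.
#' @export
#' @examples
#' lake_season(as.Date(c("2014-12-15", "2014-07-20", "2014-10-01")))
lake_season <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  out <- rep(NA_character_, length(m))
  out[m %in% c(12L, 1L, 2L)] <- "summer"
  out[m %in% c(7L, 8L)] <- "winter"
  out[m %in% c(10L, 11L)] <- "spring"
  if (anyNA(out)) {
    bad <- unique(format(date[is.na(out)], "%B"))
    abort(sprintf("no season defined for month(s): %s (only Dec-Feb, Jul-Aug, Oct-Nov are sampled)",
                  paste(bad, collapse = ", ")))
  }
  out
}

#' Time-period label for a sampling date
#'
#' Viral cluster abundances are aggregated per calendar month of sampling,
#' labelled like `"Dec. 2006"`.
#'
#' @param date A `Date` vector.
#' @return Character vector of period labels.
#' @export
period_label <- function(date) {
  date <- as.Date(date)
  mon <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
           "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  paste0(mon[as.integer(format(date, "%m"))], ". ", format(date, "%Y"))
}

#' Depth codes of the sampling design
#'
#' Upper oxic zone (U1--U3), the oxic/anoxic interface (I), and the lower
#' anoxic zone (L1--L3).
#'
#' @return Character vector of the seven depth codes in order.
#' @export
depth_codes <- function() c("U1", "U2", "U3", "I", "L1", "L2", "L3")

#' Filter fractions of the sampling design (micrometres)
#' @return Numeric vector `c(3.0, 0.8, 0.1)`.
#' @export
filter_fractions <- function() c(3.0, 0.8, 0.1)
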
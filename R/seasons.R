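#' Season labels in their fixed ordering
#'
#' Season-crossed design columns are always expanded in this order, so that
#' coefficient indexing is reproducible across runs and platforms.
#'
#' @return Character vector `c("Spring", "Summer", "Autumn", "Winter")`.
#' @export
season_levels <- function() c("Spring", "Summer", "Autumn", "Winter")

#' Construct a month-to-season mapping
#'
#' A season map assigns each calendar month (1--12) to exactly one of the four
#' seasons. The map is total: every date resolves to a season.
#'
#' @param months Character vector of length 12; element `m` is the season of
#'   month `m` and must be one of [season_levels()].
#' @return A `season_map` object (named character vector of length 12).
#' @seealso [default_season_map()], [assign_season()]
#' @export
season_map <- function(months) {
  months <- as.character(months)
  if (length(months) != 12L) {
    config_error("season map must assign all 12 months")
  }
  bad <- setdiff(unique(months), season_levels())
  if (length(bad)) {
    config_error(paste0("unknown season label(s): ", paste(bad, collapse = ", ")))
  }
  names(months) <- month.abb
  structure(months, class = "season_map")
}

#' Default meteorological season map
#'
#' Mar--May Spring, Jun--Aug Summer, Sep--Nov Autumn, Dec--Feb Winter: the
#' standard meteorological convention for subtropical Taiwan. Override with
#' [season_map()] where a different convention is required.
#'
#' @return A `season_map` object.
#' @export
default_season_map <- function() {
  season_map(c("Winter", "Winter", "Spring", "Spring", "Spring",
               "Summer", "Summer", "Summer",
               "Autumn", "Autumn", "Autumn", "Winter"))
}

#' Assign a season to a date
#'
#' @param date A `Date` vector.
#' @param map A [season_map()]; defaults to [default_season_map()].
#' @return Character vector of season labels, one per date.
#' @examples
#' assign_season(as.Date("2010-04-15"))  # "Spring"
#' @export
assign_season <- function(date, map = default_season_map()) {
  if (!inherits(map, "season_map")) map <- season_map(map)
  date <- as.Date(date)
  unname(unclass(map)[as.POSIXlt(date)$mon + 1L])
}
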
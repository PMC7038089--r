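#' Daily multi-site pollutant concentration panel
#'
#' Observed daily concentrations (ug/m3) on a consecutive-day grid with
#' missing cells coded `NA`. Observed values must be strictly positive
#' because the latent model works on the log scale.
#'
#' @param dates `Date` vector of strictly consecutive days (length T).
#' @param site_ids site labels (length S).
#' @param values T x S numeric matrix of concentrations, `NA` = missing.
#' @return object of class `pollution_panel`.
#' @export
pollution_panel <- function(dates, site_ids, values) {
  dates <- as.Date(dates)
  values <- as.matrix(values)
  if (nrow(values) != length(dates) || ncol(values) != length(site_ids))
    stop("values must be length(dates) x length(site_ids)")
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("dates must be strictly consecutive days")
  if (!any(is.finite(values))) stop("panel contains no observations")
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-positive concentration at date %s, site %s",
                 dates[bad[1L, 1L]], site_ids[bad[1L, 2L]]))
  dimnames(values) <- NULL
  p <- list(dates = dates, site_ids = as.character(site_ids), values = values)
  class(p) <- "pollution_panel"
  p
}

#' @export
print.pollution_panel <- function(x, ...) {
  cat("pollution_panel:", length(x$dates), "days x", length(x$site_ids),
      "sites,", round(100 * mean(is.na(x$values)), 1), "% missing\n")
  invisible(x)
}

#' Log-transform a pollution panel
#'
#' Concentrations are modelled on the natural-log scale (they are positive
#' and right-skewed). Missing cells stay missing; a zero or negative
#' observed value is an error naming the offending date and site rather
#' than being silently offset.
#'
#' @param panel a [pollution_panel].
#' @return object of class `log_panel` with fields `dates`, `site_ids`, `Y`
#'   (T x S log concentrations, `NA` = missing).
#' @export
log_transform <- function(panel) {
  stopifnot(inherits(panel, "pollution_panel"))
  bad <- which(!is.na(panel$values) & panel$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("cannot log-transform non-positive value at date %s, site %s",
                 panel$dates[bad[1L, 1L]], panel$site_ids[bad[1L, 2L]]))
  lp <- list(dates = panel$dates, site_ids = panel$site_ids,
             Y = log(panel$values))
  class(lp) <- "log_panel"
  lp
}

#' Read a long-format pollutant panel CSV
#'
#' Columns `date, site_id, value` with ISO dates; an empty value field (or
#' absent date/site combination) is treated as missing. The returned panel
#' spans every day from the earliest to the latest date.
#'
#' @param path CSV file path.
#' @param site_ids optional site ordering; defaults to sorted unique sites.
#' @return a [pollution_panel].
#' @export
read_pollution_csv <- function(path, site_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(NA, "character", NA))
  need <- c("date", "site_id", "value")
  if (!all(need %in% names(df)))
    stop("pollution CSV must have columns date, site_id, value")
  d <- as.Date(df$date)
  if (anyNA(d)) stop("unparseable date at line ", which(is.na(d))[1L] + 1L)
  if (is.null(site_ids)) site_ids <- sort(unique(df$site_id))
  dates <- seq(min(d), max(d), by = "day")
  vals <- matrix(NA_real_, length(dates), length(site_ids))
  ri <- match(d, dates)
  ci <- match(df$site_id, site_ids)
  if (anyNA(ci)) stop("unknown site_id at line ", which(is.na(ci))[1L] + 1L)
  v <- suppressWarnings(as.numeric(df$value))
  keep <- !is.na(v)
  vals[cbind(ri[keep], ci[keep])] <- v[keep]
  pollution_panel(dates, site_ids, vals)
}

#' Write a pollution panel as long-format CSV
#'
#' @param panel a [pollution_panel].
#' @param path output path. Missing cells are written with an empty value.
#' @export
write_pollution_csv <- function(panel, path) {
  long <- data.frame(
    date = rep(as.character(panel$dates), times = length(panel$site_ids)),
    site_id = rep(panel$site_ids, each = length(panel$dates)),
    value = as.vector(panel$values))
  long$value <- ifelse(is.na(long$value), "", format(long$value, digits = 10,
                                                     trim = TRUE))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
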
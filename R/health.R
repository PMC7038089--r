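#' Daily admission-count series
#'
#' @param dates consecutive `Date`s.
#' @param counts nonnegative integer daily admissions.
#' @param stratum one of `"total"`, `"male"`, `"female"`, `"age65plus"`,
#'   `"age65minus"`.
#' @return object of class `admission_series`.
#' @export
admission_series <- function(dates, counts, stratum = "total") {
  dates <- as.Date(dates)
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("dates must be consecutive days")
  if (length(counts) != length(dates)) stop("counts/dates length mismatch")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  stratum <- match.arg(stratum, c("total", "male", "female",
                                  "age65plus", "age65minus"))
  a <- list(dates = dates, counts = as.integer(round(counts)),
            stratum = stratum)
  class(a) <- "admission_series"
  a
}

#' Daily meteorology series
#'
#' @param dates consecutive `Date`s.
#' @param temperature daily mean temperature, deg C.
#' @param rh daily mean relative humidity, percent.
#' @param wind daily mean wind speed, m/s.
#' @param pressure daily mean pressure, hPa.
#' @return object of class `meteorology_series` (a data.frame).
#' @export
meteorology_series <- function(dates, temperature, rh, wind, pressure) {
  dates <- as.Date(dates)
  df <- data.frame(date = dates, temperature = temperature, rh = rh,
                   wind = wind, pressure = pressure)
  if (any(!is.finite(as.matrix(df[, -1L]))))
    stop("meteorology values must be finite")
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("dates must be consecutive days")
  class(df) <- c("meteorology_series", "data.frame")
  df
}

#' Stage-2 health model specification
#'
#' Degrees of freedom of the natural-spline confounder adjustments default
#' to the analysis protocol: calendar time 7 df per year, temperature 4,
#' relative humidity 4, wind speed 3, pressure 5, plus day-of-week dummy
#' variables (Monday reference).
#'
#' @param lag exposure lag in days, 0-6.
#' @param df_time_per_year calendar-time spline df per year of data.
#' @param df_temp,df_rh,df_wind,df_pressure meteorology spline df.
#' @param dow include day-of-week dummies.
#' @return object of class `health_model_spec`.
#' @export
health_model_spec <- function(lag = 0L, df_time_per_year = 7,
                              df_temp = 4L, df_rh = 4L, df_wind = 3L,
                              df_pressure = 5L, dow = TRUE) {
  if (lag < 0L || lag > 6L) stop("lag must be in 0..6")
  if (any(c(df_time_per_year, df_temp, df_rh, df_wind, df_pressure) <= 0))
    stop("spline df must be positive")
  sp <- list(lag = as.integer(lag), df_time_per_year = df_time_per_year,
             df_temp = as.integer(df_temp), df_rh = as.integer(df_rh),
             df_wind = as.integer(df_wind),
             df_pressure = as.integer(df_pressure), dow = isTRUE(dow))
  class(sp) <- "health_model_spec"
  sp
}

#' Lag an exposure series
#'
#' The value used on analysis day t is the exposure on day t - lag; the
#' first `lag` days carry `NA` and are dropped from the analysis window
#' (all model series are trimmed consistently by the fitters).
#'
#' @param x exposure values, one per day.
#' @param lag integer lag in days (0-6).
#' @return vector of the same length with the first `lag` entries `NA`.
#' @export
build_lagged <- function(x, lag) {
  if (lag < 0L || lag > 6L) stop("lag must be in 0..6")
  n <- length(x)
  if (lag >= n) stop("lag must be smaller than the series length")
  if (lag == 0L) return(x)
  c(rep(NA_real_, lag), x[seq_len(n - lag)])
}

#' Assemble the confounder design matrix
#'
#' Intercept + natural splines of the day index (round(7 x years) df by
#' default), temperature, relative humidity, wind speed and pressure, plus
#' six day-of-week dummies (Monday reference). Returns the matrix together
#' with a named map of column indices per block.
#'
#' @param dates analysis dates (consecutive days).
#' @param met a [meteorology_series] aligned to `dates`.
#' @param spec a [health_model_spec].
#' @return list with `X` (design matrix) and `blocks` (named index list).
#' @export
assemble_design <- function(dates, met, spec = health_model_spec()) {
  dates <- as.Date(dates)
  i <- match(dates, met$date)
  if (anyNA(i)) stop("meteorology does not cover all analysis dates")
  met <- met[i, , drop = FALSE]
  T_ <- length(dates)
  years <- T_ / 365.25
  df_time <- max(1L, as.integer(round(spec$df_time_per_year * years)))
  blocks <- list()
  X <- matrix(1, T_, 1L)
  colnames(X) <- "intercept"
  blocks$intercept <- 1L
  add_block <- function(X, B, name, prefix) {
    colnames(B) <- paste0(prefix, seq_len(ncol(B)))
    idx <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
    attr(X, "newidx") <- idx
    X
  }
  for (blk in list(
    list(name = "time", x = seq_len(T_), df = df_time, prefix = "time_ns"),
    list(name = "temperature", x = met$temperature, df = spec$df_temp,
         prefix = "temp_ns"),
    list(name = "rh", x = met$rh, df = spec$df_rh, prefix = "rh_ns"),
    list(name = "wind", x = met$wind, df = spec$df_wind, prefix = "wind_ns"),
    list(name = "pressure", x = met$pressure, df = spec$df_pressure,
         prefix = "pres_ns"))) {
    B <- tryCatch(ns_basis(blk$x, blk$df), error = function(e)
      stop("cannot build spline block `", blk$name, "`: ",
           conditionMessage(e)))
    X <- add_block(X, B, blk$name, blk$prefix)
    blocks[[blk$name]] <- attr(X, "newidx")
    attr(X, "newidx") <- NULL
  }
  if (spec$dow) {
    dow <- factor(format(dates, "%u"), levels = as.character(1:7))
    Bd <- stats::model.matrix(~dow)[, -1L, drop = FALSE]
    colnames(Bd) <- paste0("dow", 2:7)
    idx <- ncol(X) + seq_len(ncol(Bd))
    X <- cbind(X, Bd)
    blocks$dow <- idx
  }
  if (qr(X)$rank < ncol(X)) {
    for (nm in names(blocks)) {
      sub <- X[, unlist(blocks[names(blocks) != nm]), drop = FALSE]
      if (qr(cbind(sub, X[, blocks[[nm]], drop = FALSE]))$rank <
          ncol(sub) + length(blocks[[nm]]))
        stop("design rank deficiency involving block `", nm, "`")
    }
    stop("design matrix rank deficient")
  }
  list(X = X, blocks = blocks)
}

# normalise the various exposure inputs to a numeric vector on `dates`
exposure_on_dates <- function(exposure, dates) {
  if (inherits(exposure, "exposure_series") || is.data.frame(exposure)) {
    i <- match(as.Date(dates), as.Date(exposure$date))
    if (anyNA(i)) stop("exposure series does not cover all analysis dates")
    exposure$estimate[i]
  } else {
    if (length(exposure) != length(dates))
      stop("exposure vector length must match dates")
    as.numeric(exposure)
  }
}

health_result_row <- function(pollutant, lag, stratum, adjustment, pc, p,
                              dispersion) {
  data.frame(pollutant = pollutant, lag = lag, stratum = stratum,
             adjustment = adjustment, pct = pc[["pct"]], lo = pc[["lo"]],
             hi = pc[["hi"]], p = p, dispersion = dispersion,
             stringsAsFactors = FALSE)
}

fit_health_core <- function(adm, exposures, met, lag, spec, adjustment) {
  stopifnot(inherits(adm, "admission_series"))
  spec$lag <- as.integer(lag)
  ex <- lapply(exposures, exposure_on_dates, dates = adm$dates)
  if (length(ex) > 1L) {
    C <- stats::cor(do.call(cbind, ex))
    bad <- which(abs(C) > 0.999 & upper.tri(C), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("collinear exposures: ", names(ex)[bad[1L, 1L]], " and ",
           names(ex)[bad[1L, 2L]], " (|r| > 0.999)")
  }
  lagged <- lapply(ex, build_lagged, lag = spec$lag)
  keep <- if (spec$lag > 0L) -(seq_len(spec$lag)) else seq_along(adm$dates)
  dates <- adm$dates[keep]
  y <- adm$counts[keep]
  des <- assemble_design(dates, met, spec)
  E <- do.call(cbind, lapply(lagged, function(v) v[keep]))
  colnames(E) <- names(exposures)
  X <- cbind(des$X, E)
  fit <- fit_quasipoisson(y, X)
  rows <- do.call(rbind, lapply(names(exposures), function(nm) {
    j <- match(nm, colnames(X))
    beta <- fit$coefficients[[j]]
    se <- sqrt(fit$cov[j, j])
    pc <- percent_change(beta, se, delta = 10)
    p <- 2 * stats::pnorm(-abs(beta / se))
    health_result_row(nm, spec$lag, adm$stratum, adjustment[[nm]], pc, p,
                      fit$dispersion)
  }))
  attr(rows, "fit") <- fit
  rows
}

#' Single-pollutant health-effect fit
#'
#' Quasi-Poisson regression of daily admissions on the lagged exposure plus
#' the confounder design; reports the percent change in relative risk (with
#' 95% CI and two-sided Wald p-value) per 10 ug/m3 exposure increase.
#'
#' @param adm an [admission_series].
#' @param exposure an `exposure_series` (e.g. from [summarize_exposure]),
#'   a data.frame with `date`/`estimate`, or a numeric vector aligned to
#'   `adm$dates`, in ug/m3.
#' @param met a [meteorology_series] covering the analysis dates.
#' @param lag exposure lag, 0-6 days.
#' @param spec a [health_model_spec] (its `lag` field is overridden).
#' @param pollutant label used in the output.
#' @return one-row data.frame of class `health_effect_result` columns:
#'   `pollutant, lag, stratum, adjustment, pct, lo, hi, p, dispersion`.
#' @export
fit_single_pollutant <- function(adm, exposure, met, lag = 0L,
                                 spec = health_model_spec(),
                                 pollutant = "pollutant") {
  ex <- stats::setNames(list(exposure), pollutant)
  out <- fit_health_core(adm, ex, met, lag, spec,
                         stats::setNames("single", pollutant))
  class(out) <- c("health_effect_result", "data.frame")
  out
}

#' Multipollutant health-effect fit
#'
#' One quasi-Poisson fit with 2-4 exposure columns entered jointly at the
#' same lag; returns one result row per pollutant with the adjustment set
#' recorded (`"+X"` for a pairwise model, `"+All"` when all other
#' pollutants are included).
#'
#' @param adm an [admission_series].
#' @param exposures named list of 2-4 exposure inputs (see
#'   [fit_single_pollutant]).
#' @inheritParams fit_single_pollutant
#' @return data.frame of class `health_effect_result`, one row per
#'   pollutant.
#' @export
fit_multipollutant <- function(adm, exposures, met, lag = 0L,
                               spec = health_model_spec()) {
  if (length(exposures) < 2L || length(exposures) > 4L)
    stop("need 2-4 exposures")
  if (is.null(names(exposures)) || anyDuplicated(names(exposures)))
    stop("exposures must be uniquely named")
  adj <- vapply(names(exposures), function(nm) {
    others <- setdiff(names(exposures), nm)
    if (length(others) >= 3L) "+All" else
      paste0("+", paste(others, collapse = "+"))
  }, character(1L))
  out <- fit_health_core(adm, exposures, met, lag, spec, as.list(adj))
  class(out) <- c("health_effect_result", "data.frame")
  out
}

#' Fit a single-pollutant model at every lag 0-6
#'
#' Independent fits per lag, each on its own trimmed analysis window; no lag
#' selection is performed, but the minimum-p lag is flagged in the
#' `min_p_lag` attribute for convenience.
#'
#' @inheritParams fit_single_pollutant
#' @return `health_effect_result` data.frame with 7 rows ordered by lag.
#' @export
lag_scan <- function(adm, exposure, met, spec = health_model_spec(),
                     pollutant = "pollutant") {
  out <- do.call(rbind, lapply(0:6, function(l)
    fit_single_pollutant(adm, exposure, met, lag = l, spec = spec,
                         pollutant = pollutant)))
  attr(out, "min_p_lag") <- out$lag[which.min(out$p)]
  class(out) <- c("health_effect_result", "data.frame")
  out
}

#' Stratified health-effect fits
#'
#' Independent single-pollutant fits per stratum series. When both sex
#' strata (or both age strata) and the total are supplied, their counts are
#' validated against the total (warning on mismatch).
#'
#' @param adm_by_stratum named list of [admission_series], names among
#'   `total, male, female, age65plus, age65minus`.
#' @inheritParams fit_single_pollutant
#' @return `health_effect_result` data.frame, one row per stratum.
#' @export
subgroup_analysis <- function(adm_by_stratum, exposure, met, lag = 0L,
                              spec = health_model_spec(),
                              pollutant = "pollutant") {
  if (any(vapply(adm_by_stratum, function(a) sum(a$counts), 0) == 0))
    stop("empty stratum series")
  chk <- function(parts) {
    if (all(c(parts, "total") %in% names(adm_by_stratum))) {
      s <- Reduce(`+`, lapply(adm_by_stratum[parts], `[[`, "counts"))
      if (!all(s == adm_by_stratum$total$counts))
        warning("strata ", paste(parts, collapse = "+"),
                " do not sum to total counts")
    }
  }
  chk(c("male", "female"))
  chk(c("age65plus", "age65minus"))
  out <- do.call(rbind, lapply(names(adm_by_stratum), function(nm)
    fit_single_pollutant(adm_by_stratum[[nm]], exposure, met, lag = lag,
                         spec = spec, pollutant = pollutant)))
  class(out) <- c("health_effect_result", "data.frame")
  out
}

#' QAIC scan over spline degrees of freedom
#'
#' Quasi-likelihood AIC, `QAIC = deviance / dispersion_hat + 2p`, with the
#' dispersion estimated once from the largest (most parameters) candidate
#' model; the table is sorted ascending by QAIC.
#'
#' @param adm an [admission_series].
#' @param exposure exposure input (see [fit_single_pollutant]).
#' @param met a [meteorology_series].
#' @param df_grid data.frame of candidate df configurations; recognised
#'   columns: `df_time_per_year, df_temp, df_rh, df_wind, df_pressure`
#'   (missing columns take the defaults).
#' @param lag exposure lag.
#' @return data.frame with the candidate configurations, `p` (parameter
#'   count), `deviance` and `qaic`, sorted ascending.
#' @export
qaic_scan <- function(adm, exposure, met, df_grid, lag = 0L) {
  df_grid <- as.data.frame(df_grid)
  fits <- lapply(seq_len(nrow(df_grid)), function(i) {
    args <- as.list(df_grid[i, , drop = FALSE])
    spec <- do.call(health_model_spec, c(args, list(lag = lag)))
    r <- fit_single_pollutant(adm, exposure, met, lag = lag, spec = spec)
    attr(r, "fit")
  })
  p <- vapply(fits, function(f) f$rank, 0)
  dev <- vapply(fits, function(f) f$deviance, 0)
  disp <- fits[[which.max(p)]]$dispersion
  out <- cbind(df_grid, p = p, deviance = dev, qaic = dev / disp + 2 * p)
  out[order(out$qaic), , drop = FALSE]
}

#' Read/write the health-analysis CSV interfaces
#'
#' Admissions CSV has columns `date,count[,stratum]` (one series per
#' stratum); meteorology CSV has `date,temperature,rh,wind,pressure`;
#' results CSV mirrors the reporting-table columns.
#'
#' @param path file path.
#' @return `read_admissions_csv`: named list of [admission_series] (one per
#'   stratum present); `read_meteorology_csv`: a [meteorology_series].
#' @export
read_admissions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "count") %in% names(df)))
    stop("admissions CSV must have columns date, count")
  if (!"stratum" %in% names(df)) df$stratum <- "total"
  out <- lapply(split(df, df$stratum), function(d) {
    d <- d[order(as.Date(d$date)), ]
    admission_series(d$date, d$count, d$stratum[1L])
  })
  out[order(match(names(out), c("total", "male", "female", "age65plus",
                                "age65minus")))]
}

#' @rdname read_admissions_csv
#' @export
read_meteorology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "temperature", "rh", "wind", "pressure")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("meteorology CSV missing column(s): ", paste(miss, collapse = ", "))
  meteorology_series(df$date, df$temperature, df$rh, df$wind, df$pressure)
}

#' @rdname read_admissions_csv
#' @param results a `health_effect_result` data.frame.
#' @param city_label label written into the `city_label` column.
#' @export
write_results_csv <- function(results, path, city_label = "synthetic") {
  df <- cbind(city_label = city_label, as.data.frame(results))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
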
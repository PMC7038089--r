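# Independent oracles used across tests.

# great-circle distance in km (haversine), independent of the projection
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# dense Gaussian conditional: x ~ N(prior_mean, prior_cov), observed
# y = H x + noise, noise cov R  ->  posterior mean/cov of x
gauss_posterior <- function(prior_mean, prior_cov, H, y, R) {
  P0 <- solve(prior_cov)
  Pn <- P0 + t(H) %*% solve(R) %*% H
  Vn <- solve(Pn)
  mn <- Vn %*% (P0 %*% prior_mean + t(H) %*% solve(R) %*% y)
  list(mean = as.vector(mn), cov = Vn)
}

# stationary AR(1) covariance matrix of length n
ar1_cov <- function(n, mu_var, rho) {
  mu_var * rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

# build a log_panel directly (bypassing the positive-value check of the
# concentration-scale constructor) for conditional-level tests
fake_log_panel <- function(Y, dates = NULL, site_ids = NULL) {
  if (is.null(dates)) dates <- as.Date("2015-01-01") + seq_len(nrow(Y)) - 1L
  if (is.null(site_ids)) site_ids <- paste0("s", seq_len(ncol(Y)))
  structure(list(dates = dates, site_ids = site_ids, Y = Y),
            class = "log_panel")
}

# fake posterior holding given latent-path draws, for summary-math tests
fake_posterior <- function(Zdraws, dates = NULL) {
  if (is.null(dates))
    dates <- as.Date("2015-01-01") + seq_len(ncol(Zdraws)) - 1L
  structure(list(dates = dates, site_ids = "s1", Z = Zdraws,
                 draws = matrix(0, nrow(Zdraws), 6)),
            class = "exposure_posterior")
}

# inverse-gamma moments (shape a, rate b)
ig_mean <- function(a, b) b / (a - 1)
ig_var <- function(a, b) b^2 / ((a - 1)^2 * (a - 2))
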
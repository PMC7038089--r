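#' Project geographic coordinates to planar kilometres
#'
#' Azimuthal-equidistant projection about the coordinate centroid. The
#' spatial correlation kernel is defined on Euclidean distance, so monitor
#' coordinates given in WGS84 degrees are first mapped to a local planar
#' system. At study extents below ~200 km the planar distances agree with
#' great-circle distances to well within 0.5% at any latitude.
#'
#' @param lonlat two-column matrix or data.frame of longitude and latitude
#'   in decimal degrees (WGS84).
#' @return a two-column matrix of planar coordinates in km, centred on the
#'   coordinate centroid, with columns `x_km`, `y_km`.
#' @export
project_coordinates <- function(lonlat) {
  lonlat <- as.matrix(lonlat)
  if (nrow(lonlat) == 0L) stop("no coordinates supplied")
  if (ncol(lonlat) != 2L) stop("`lonlat` must have two columns (lon, lat)")
  lon <- lonlat[, 1L]
  lat <- lonlat[, 2L]
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(lat <= -90 | lat >= 90)) stop("latitude out of range (-90, 90)")
  if (any(lon <= -180 | lon >= 180)) stop("longitude out of range (-180, 180)")
  r_earth <- 6371.0088  # mean Earth radius, km
  to_rad <- pi / 180
  lam <- lon * to_rad
  phi <- lat * to_rad
  lam0 <- mean(lam)
  phi0 <- mean(phi)
  dlam <- lam - lam0
  # central angle from the centroid (haversine form, numerically stable)
  a <- sin((phi - phi0) / 2)^2 + cos(phi0) * cos(phi) * sin(dlam / 2)^2
  c_ang <- 2 * asin(pmin(1, sqrt(a)))
  # bearing from the centroid
  theta <- atan2(sin(dlam) * cos(phi),
                 cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  x <- r_earth * c_ang * sin(theta)
  y <- r_earth * c_ang * cos(theta)
  ext <- max(c(diff(range(x)), diff(range(y))))
  if (ext > 250)
    warning("spatial extent ", round(ext), " km exceeds the ~200 km range ",
            "where the planar approximation is accurate")
  cbind(x_km = x, y_km = y)
}

#' Pairwise Euclidean distances between monitor sites
#'
#' @param coords two-column matrix of planar coordinates (km).
#' @return symmetric zero-diagonal distance matrix (km).
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 sites")
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- NULL
  if (any(D[upper.tri(D)] == 0))
    warning("duplicate coordinates: zero off-diagonal distance")
  D
}

#' Monitor network
#'
#' Bundles site labels, planar coordinates and the pairwise distance matrix
#' that parameterises the exponential spatial kernel.
#'
#' @param site_ids character or integer vector of site labels.
#' @param coords matrix of planar coordinates in km (one row per site), or
#'   lon/lat degrees with `lonlat = TRUE`.
#' @param lonlat if `TRUE`, `coords` are degrees and are projected first.
#' @return an object of class `monitor_network` with fields `site_ids`,
#'   `coords` and `D`.
#' @export
monitor_network <- function(site_ids, coords, lonlat = FALSE) {
  coords <- as.matrix(coords)
  if (lonlat) coords <- project_coordinates(coords)
  if (length(site_ids) != nrow(coords))
    stop("site_ids length must equal number of coordinate rows")
  if (nrow(coords) < 2L) stop("need at least 2 sites")
  if (anyDuplicated(site_ids)) stop("duplicate site_ids")
  net <- list(site_ids = as.character(site_ids), coords = coords,
              D = pairwise_distances(coords))
  class(net) <- "monitor_network"
  net
}

#' @export
print.monitor_network <- function(x, ...) {
  cat("monitor_network:", length(x$site_ids), "sites, max distance",
      round(max(x$D), 2), "km\n")
  invisible(x)
}

#' Exponential spatial correlation matrix
#'
#' `Sigma[i, j] = exp(-D[i, j] / phi)` — the Matern family with smoothness
#' fixed at 0.5, i.e. the exponential kernel with range parameter `phi` km.
#'
#' @param D distance matrix (km).
#' @param phi range parameter, km; must be positive.
#' @return correlation matrix with unit diagonal.
#' @export
exp_correlation <- function(D, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("phi must be a positive scalar")
  S <- exp(-D / phi)
  diag(S) <- 1
  S
}

#' Cholesky factorisation with escalating diagonal jitter
#'
#' Upper-triangular Cholesky factor of a nominally positive-definite matrix;
#' if factorisation fails, jitter starting at 1e-10 is added to the diagonal
#' and escalated tenfold up to 1e-6 before giving up.
#'
#' @param M symmetric matrix.
#' @return upper triangular matrix `R` with `t(R) %*% R = M` (+ jitter).
#' @export
chol_spd <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  jitter <- 1e-10
  while (is.null(R) && jitter <= 1e-6) {
    R <- tryCatch(chol(M + diag(jitter, nrow(M))), error = function(e) NULL)
    jitter <- jitter * 10
  }
  if (is.null(R)) stop("matrix not positive definite even after 1e-6 jitter")
  R
}

#' Discrete grid of candidate spatial range values
#'
#' Support of the discrete-uniform prior on the spatial range: `n_grid`
#' equally spaced values spanning the minimum positive to the maximum
#' pairwise monitor distance, both inclusive.
#'
#' @param D distance matrix (km).
#' @param n_grid number of grid values (>= 2); default 50.
#' @return object of class `phi_grid`: list with `values`, `a_phi`, `b_phi`.
#' @export
make_phi_grid <- function(D, n_grid = 50L) {
  if (n_grid < 2L) stop("n_grid must be >= 2")
  off <- D[upper.tri(D)]
  off <- off[off > 0]
  if (length(off) == 0L) stop("all pairwise distances are zero")
  a_phi <- min(off)
  b_phi <- max(off)
  g <- list(values = seq(a_phi, b_phi, length.out = n_grid),
            a_phi = a_phi, b_phi = b_phi)
  class(g) <- "phi_grid"
  g
}

#' Read a monitor coordinates CSV
#'
#' Accepts either `site_id, lon, lat` (WGS84 degrees, projected to planar
#' km) or `site_id, x_km, y_km`. A header row is required.
#'
#' @param path CSV file path.
#' @return a [monitor_network].
#' @export
read_monitors_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(df))
    stop("monitors CSV must have a `site_id` column")
  if (all(c("lon", "lat") %in% names(df))) {
    monitor_network(df$site_id, cbind(df$lon, df$lat), lonlat = TRUE)
  } else if (all(c("x_km", "y_km") %in% names(df))) {
    monitor_network(df$site_id, cbind(df$x_km, df$y_km))
  } else {
    stop("monitors CSV needs columns lon,lat or x_km,y_km")
  }
}

#' Write a monitor coordinates CSV
#'
#' @param network a [monitor_network].
#' @param path output path.
#' @export
write_monitors_csv <- function(network, path) {
  utils::write.csv(
    data.frame(site_id = network$site_ids,
               x_km = network$coords[, 1L], y_km = network$coords[, 2L]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
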
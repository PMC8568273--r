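# Spectral and phase-space estimators: spectral entropy, phase entropy
# (second-order difference plane) and gridded distribution entropy
# (Poincare census).

#' Spectral entropy (SpecEn)
#'
#' Shannon entropy of the normalised one-sided power spectrum, divided by
#' the log of the number of frequency bins so the value lies in \[0, 1\]:
#' near 0 for a pure tone, near 1 for white noise. When `band` is given,
#' the band-spectral entropy (the same statistic restricted to the stated
#' normalised-frequency interval before renormalising) is returned as a
#' secondary output.
#'
#' @inheritParams apen
#' @param band optional numeric length-2 normalised frequency interval
#'   within \[0, 0.5\].
#' @return [entropy_result]; secondary `band_specen` when `band` is given.
#' @examples
#' specen(sin(2 * pi * 5 * (0:255) / 256))
#' @export
specen <- function(x, band = NULL, log_base = exp(1)) {
  x <- validate_series(x, min_length = 8L)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  half <- pw[seq_len(floor(n / 2) + 1L)]
  p <- half / sum(half)
  H <- shannon_entropy(p, log_base) /
    (log(length(p)) / log(log_base))
  secondary <- list(power = p)
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] < 0 || band[2] > 0.5 ||
        band[2] <= band[1])
      stop("`band` must be an increasing interval within [0, 0.5]",
           call. = FALSE)
    freqs <- (seq_along(half) - 1L) / n
    sel <- freqs >= band[1] & freqs <= band[2]
    if (!any(sel)) stop("`band` contains no frequency bins", call. = FALSE)
    pb <- half[sel] / sum(half[sel])
    hb <- shannon_entropy(pb, log_base)
    secondary$band_specen <- if (sum(sel) > 1L)
      hb / (log(sum(sel)) / log(log_base)) else 0
  }
  entropy_result("SpecEn", H, secondary,
                 list(band = band, log_base = log_base))
}

#' Phase entropy (PhasEn)
#'
#' Rohila-Sharma phase entropy from the second-order difference plot: the
#' scatter of `y = x(t + 2 tau) - x(t + tau)` against
#' `u = x(t + tau) - x(t)`. The plane is divided into `K` equal angular
#' sectors about the origin, each sector weighted by the sum of point
#' radii, and the Shannon entropy of the sector masses is returned,
#' normalised by `log(K)` by default.
#'
#' @inheritParams apen
#' @param K number of angular sectors (default 4; the display convention
#'   in the field often uses 9).
#' @param normalise divide by `log(K)` (default `TRUE`).
#' @return [entropy_result]; secondary `sector_mass` and the plot
#'   coordinates `u`, `y`.
#' @export
phasen <- function(x, K = 4L, tau = 1L, normalise = TRUE,
                   log_base = exp(1)) {
  x <- validate_series(x)
  K <- check_positive_int(K, "K", min = 2L)
  tau <- check_positive_int(tau, "tau")
  n <- length(x)
  if (n <= 2L * tau)
    stop("series too short: need n > 2*tau", call. = FALSE)
  u <- x[(1L + tau):(n - tau)] - x[seq_len(n - 2L * tau)]
  y <- x[(1L + 2L * tau):n] - x[(1L + tau):(n - tau)]
  rad <- sqrt(u^2 + y^2)
  keep <- rad > 0
  if (!any(keep)) {
    warning("degenerate second-order difference plot (all points at origin)",
            call. = FALSE)
    return(entropy_result("PhasEn", 0, list(sector_mass = rep(0, K)),
                          list(K = K, tau = tau, normalise = normalise,
                               log_base = log_base)))
  }
  ang <- atan2(y[keep], u[keep]) %% (2 * pi)
  sector <- pmin(K, floor(ang / (2 * pi / K)) + 1L)
  mass <- vapply(seq_len(K), function(s) sum(rad[keep][sector == s]),
                 numeric(1))
  H <- shannon_entropy(mass / sum(mass), log_base)
  if (normalise) H <- H / (log(K) / log(log_base))
  entropy_result("PhasEn", H,
                 list(sector_mass = mass, u = u, y = y),
                 list(K = K, tau = tau, normalise = normalise,
                      log_base = log_base))
}

#' Gridded distribution entropy (GridEn)
#'
#' Entropy of the Poincare plot `(x_t, x_{t + tau})`: both axes are
#' rescaled to \[0, 1\], the unit square is partitioned into an `m x m`
#' grid, and the Shannon entropy of the cell occupancy is returned,
#' together with the gridded distribution rate (fraction of occupied
#' cells). The cell census (bivariate histogram) is kept as a secondary
#' output for plotting.
#'
#' @inheritParams apen
#' @param m grid partitions per axis (default 3).
#' @return [entropy_result]; secondary `gdr` (occupied-cell fraction) and
#'   `census` (m x m count matrix), plus the plot coordinates.
#' @export
griden <- function(x, m = 3L, tau = 1L, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  n <- length(x)
  a <- x[seq_len(n - tau)]
  b <- x[(1L + tau):n]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    cells <- matrix(0L, m, m)
    cells[ceiling(m / 2), ceiling(m / 2)] <- length(a)
  } else {
    ia <- pmin(m, floor((a - rng[1]) / ((rng[2] - rng[1]) / m)) + 1L)
    ib <- pmin(m, floor((b - rng[1]) / ((rng[2] - rng[1]) / m)) + 1L)
    cells <- matrix(0L, m, m)
    for (k in seq_along(ia)) cells[ia[k], ib[k]] <- cells[ia[k], ib[k]] + 1L
  }
  H <- census_entropy(cells[cells > 0], log_base)
  gdr <- sum(cells > 0) / m^2
  entropy_result("GridEn", H,
                 list(gdr = gdr, census = cells, a = a, b = b),
                 list(m = m, tau = tau, log_base = log_base))
}
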
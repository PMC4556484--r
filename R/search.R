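#' Unconstrained search for the best single dispersal origin
#'
#' Treats every candidate gridpoint as a putative single origin: fast
#' marching from the point, quantile envelope fit of age on cost distance,
#' AICc with `K = 3` (the candidate's coordinates are not counted as
#' parameters). A gridpoint from which no site is reachable gets an `Inf`
#' sentinel.
#'
#' @param domain A [build_domain()] result.
#' @param sites Analysis-set site table.
#' @param gridpoints Candidate origins from [origin_gridpoints()] (computed
#'   at `spacing_km` when omitted).
#' @param spacing_km Lattice spacing used when `gridpoints` is `NULL`.
#' @param q_exceed Envelope fraction.
#' @param progress Print progress every so many gridpoints (0 = quiet).
#' @return An `origin_search`: per-gridpoint tibble (`row`, `col`, `lon`,
#'   `lat`, `aicc`, `n_unreachable`), `best` row, and the domain spec.
#' @export
search_origins <- function(domain, sites, gridpoints = NULL,
                           spacing_km = 100, q_exceed = 0.10, progress = 0) {
  if (is.null(gridpoints)) gridpoints <- origin_gridpoints(domain, spacing_km)
  if (nrow(gridpoints) < 2) abort("need at least two candidate gridpoints")
  if (nrow(sites) == 0) abort("empty analysis set")
  aicc_vals <- numeric(nrow(gridpoints))
  unreach <- integer(nrow(gridpoints))
  for (i in seq_len(nrow(gridpoints))) {
    fld <- fast_march(domain,
                      source_spec(gridpoints$row[i], gridpoints$col[i]))
    d <- distances_at_sites(fld, sites)
    ok <- !d$unreachable
    unreach[i] <- sum(!ok)
    aicc_vals[i] <- if (sum(ok) >= 10) {
      fit_quantile_loglog(d$median_age[ok], d$distance_km[ok], q_exceed)$aicc
    } else Inf
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  gridpoint %d / %d", i, nrow(gridpoints)))
  }
  res <- gridpoints
  res$aicc <- aicc_vals
  res$n_unreachable <- unreach
  best <- res[which.min(res$aicc), ]
  structure(list(gridpoints = res, best = best, spec = domain$spec,
                 q_exceed = q_exceed),
            class = "origin_search")
}

#' @export
print.origin_search <- function(x, ...) {
  cat(sprintf("<origin_search> %d gridpoints; best AICc %.4f at (%.4g, %.4g)\n",
              nrow(x$gridpoints), x$best$aicc, x$best$lon, x$best$lat))
  invisible(x)
}

# ---- ordinary kriging with exponential covariance, ML parameters ----------

# profile Gaussian log-likelihood for range phi (constant mean, sigma2
# profiled out); returns the fitted pieces
.krige_ml_profile <- function(coords, z, phi, nugget_frac) {
  n <- length(z)
  D <- as.matrix(stats::dist(coords))
  R <- exp(-D / phi)
  if (nugget_frac > 0) R <- (1 - nugget_frac) * R + nugget_frac * diag(n)
  diag(R) <- diag(R) + 1e-10
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  one <- rep(1, n)
  Ri_z <- backsolve(ch, forwardsolve(t(ch), z))
  Ri_1 <- backsolve(ch, forwardsolve(t(ch), one))
  beta <- sum(Ri_z) / sum(Ri_1)
  r <- z - beta
  Ri_r <- backsolve(ch, forwardsolve(t(ch), r))
  sigma2 <- sum(r * Ri_r) / n
  if (sigma2 <= 0) return(list(loglik = -Inf))
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(ch))) + n)
  list(loglik = loglik, beta = beta, sigma2 = sigma2, chol = ch, D = D)
}

#' Kriged delta-AICc support surface
#'
#' Interpolates the gridpoint AICc values onto the full domain raster by
#' ordinary kriging with an exponential covariance whose range and sill are
#' fitted by maximum likelihood (constant unknown mean). The interpolated
#' AICc surface is then rescaled to `delta = AICc - min(AICc)` relative to
#' the best gridpoint, matching the convention of interpolating first and
#' subtracting afterwards. With no nugget the surface honours the observed
#' values exactly at the gridpoints. Non-finite gridpoints are excluded with
#' a message.
#'
#' @param search An [search_origins()] result.
#' @param domain The matching `domain_grid`.
#' @param nugget_frac Nugget as a fraction of the total sill (default 0).
#' @return A `delta_surface`: `delta` matrix (`NA` off-domain), covariance
#'   `params`, the observation tibble, and the spec.
#' @export
krige_delta <- function(search, domain, nugget_frac = 0) {
  obs <- dplyr::filter(search$gridpoints, is.finite(.data$aicc))
  n_dropped <- nrow(search$gridpoints) - nrow(obs)
  if (n_dropped > 0)
    message(sprintf("excluding %d non-finite gridpoint(s) from kriging",
                    n_dropped))
  if (nrow(obs) < 10) abort("need at least 10 finite gridpoint values to krige")
  coords <- cbind(obs$x, obs$y)
  z <- obs$aicc

  if (sd(z) < 1e-12) {
    # constant field: kriging surface is that constant
    pred_fun <- function(px, py) rep(z[1], length(px))
    params <- list(model = "exponential", range = NA_real_, sill = 0,
                   nugget = 0, mean = z[1])
  } else {
    dists <- stats::dist(coords)
    lo <- log(max(min(dists), 1e-3))
    hi <- log(max(dists) * 4)
    opt <- optimize(function(lphi)
      .krige_ml_profile(coords, z, exp(lphi), nugget_frac)$loglik,
      interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    phi <- exp(opt$maximum)
    ml <- .krige_ml_profile(coords, z, phi, nugget_frac)
    if (!is.finite(ml$loglik) || !is.finite(opt$objective)) {
      warn("kriging ML did not converge; using moment-based range estimate")
      phi <- stats::median(dists) / 3
      ml <- .krige_ml_profile(coords, z, phi, nugget_frac)
    }
    ch <- ml$chol
    r <- z - ml$beta
    Ri_r <- backsolve(ch, forwardsolve(t(ch), r))
    pred_fun <- function(px, py) {
      # ordinary kriging = simple kriging about the GLS-estimated mean:
      # beta_gls + c' R^{-1} (z - beta_gls)
      dx <- outer(px, coords[, 1], "-")
      dy <- outer(py, coords[, 2], "-")
      C <- exp(-sqrt(dx^2 + dy^2) / phi) * (1 - nugget_frac)
      as.numeric(ml$beta + C %*% Ri_r)
    }
    params <- list(model = "exponential", range = phi,
                   sill = ml$sigma2 * (1 - nugget_frac),
                   nugget = ml$sigma2 * nugget_frac, mean = ml$beta)
  }

  spec <- domain$spec
  cells <- which(domain$traversable, arr.ind = TRUE)
  xy <- cell_to_xy(cells[, 1], cells[, 2], spec)
  pred <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  # predict in chunks to bound memory on large domains
  idx <- split(seq_len(nrow(cells)), ceiling(seq_len(nrow(cells)) / 20000))
  for (ii in idx)
    pred[cells[ii, , drop = FALSE]] <- pred_fun(xy$x[ii], xy$y[ii])
  delta <- pred - min(z)
  structure(list(delta = delta, params = params, observations = obs,
                 spec = spec, min_aicc = min(z)),
            class = "delta_surface")
}

#' @export
print.delta_surface <- function(x, ...) {
  cat(sprintf(
    "<delta_surface> exponential covariance (range %.4g km, sill %.4g, nugget %.4g)\n",
    x$params$range, x$params$sill, x$params$nugget))
  invisible(x)
}

#' Support region below a delta-AICc cutoff
#'
#' The region of the domain with `delta <= cutoff`. The default cutoff of 4
#' is the AIC analogue of a log-likelihood support interval of 2 units:
#' models (here, origin locations) more than 4 AIC units above the best have
#' very little empirical support. Area is exact cell counting on the
#' equal-area grid.
#'
#' @param surface A [krige_delta()] result.
#' @param cutoff Delta cutoff (default 4).
#' @return A `support_region`: logical `mask`, `area_km2`, contour tibble
#'   (`level`, `piece`, `x`, `y`, `lon`, `lat`), and the cutoff.
#' @export
support_region <- function(surface, cutoff = 4) {
  delta <- surface$delta
  fin <- is.finite(delta)
  if (!any(fin)) abort("empty delta surface")
  min_delta <- min(delta[fin])
  if (cutoff < min_delta)
    abort(sprintf("empty support region: cutoff %.4g below min delta %.4g",
                  cutoff, min_delta))
  mask <- !is.na(delta) & delta <= cutoff
  spec <- surface$spec
  area <- sum(mask) * spec$cell_size^2

  zc <- delta
  zc[is.na(zc)] <- max(delta[fin]) + 2 * abs(cutoff) + 1
  xs <- spec$origin_x + (seq_len(spec$n_cols) - 1) * spec$cell_size
  ys <- spec$origin_y - (seq_len(spec$n_rows) - 1) * spec$cell_size
  # contourLines wants increasing coordinates: flip rows (y)
  cl <- grDevices::contourLines(x = xs, y = rev(ys),
                                z = t(zc[spec$n_rows:1, , drop = FALSE]),
                                levels = cutoff)
  contour <- purrr::map_dfr(seq_along(cl), function(i) {
    ll <- laea_inverse(cl[[i]]$x, cl[[i]]$y, spec)
    tibble(level = cl[[i]]$level, piece = i, x = cl[[i]]$x, y = cl[[i]]$y,
           lon = ll$lon, lat = ll$lat)
  })
  structure(list(mask = mask, area_km2 = area, contour = contour,
                 cutoff = cutoff, spec = spec),
            class = "support_region")
}

#' @export
print.support_region <- function(x, ...) {
  cat(sprintf("<support_region> delta <= %.4g: %d cells, %.4g km^2\n",
              x$cutoff, sum(x$mask), x$area_km2))
  invisible(x)
}

#' @export
autoplot.delta_surface <- function(object, cutoff = 4, ...) {
  df <- tidyr::expand_grid(row = seq_len(object$spec$n_rows),
                           col = seq_len(object$spec$n_cols))
  df$delta <- object$delta[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$delta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(Delta * "AICc")) +
    ggplot2::theme_minimal()
}
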
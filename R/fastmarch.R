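#' One-cell eikonal update
#'
#' The first-order upwind update used by the fast marching solver: given the
#' best accepted horizontal and vertical neighbour arrival times, the new
#' arrival at a cell of size `h` for a front of the given speed is the root of
#' the discretised eikonal equation. When the two directions disagree by more
#' than one cell crossing time, the update degenerates to the one-sided form
#' `min(t) + h/speed`.
#'
#' @param t_horizontal,t_vertical Accepted neighbour arrival values (use `Inf`
#'   for "no accepted neighbour").
#' @param h Cell size (km).
#' @param speed Front speed (dimensionless ratio to the base process).
#' @return Updated arrival value; errors if both neighbours are infinite.
#' @export
eikonal_update <- function(t_horizontal, t_vertical, h, speed = 1) {
  stopifnot(h > 0, speed > 0)
  if (!is.finite(t_horizontal) && !is.finite(t_vertical))
    abort("no update: both neighbour values are infinite")
  hs <- h / speed
  a <- min(t_horizontal, t_vertical)
  b <- max(t_horizontal, t_vertical)
  if (!is.finite(b) || (b - a) >= hs) return(a + hs)
  (a + b) / 2 + sqrt(2 * hs^2 - (b - a)^2) / 2
}

#' Specify dispersal sources
#'
#' @param row,col Source cell indices.
#' @param speed_ratio Front speed relative to the first process (the first
#'   source's ratio is conventionally 1).
#' @param start_offset Start time offset, in the first process's distance
#'   units (default 0: all fronts start simultaneously).
#' @return Tibble of source specifications.
#' @export
source_spec <- function(row, col, speed_ratio = 1, start_offset = 0) {
  stopifnot(all(speed_ratio > 0), all(start_offset >= 0))
  tibble(row = as.integer(row), col = as.integer(col),
         speed_ratio = as.numeric(speed_ratio),
         start_offset = as.numeric(start_offset))
}

#' Fast marching arrival field with competing sources
#'
#' Computes, for every traversable cell, the effective cost distance from the
#' nearest dispersal source, negotiating masked regions. Each source expands
#' as a unit-speed front in its own time scale; with homogeneous friction the
#' combined field is exactly the pointwise minimum over sources of
#' `start_offset + distance / speed_ratio`, expressed in the first process's
#' distance units. The `label` raster records which source claims each cell
#' (ties broken towards the lowest source index).
#'
#' @param domain A [build_domain()] result.
#' @param sources A [source_spec()] tibble (at least one source, all on
#'   traversable cells).
#' @return An `arrival_field`: `arrival` matrix (km, `Inf` = unreachable or
#'   masked), `label` matrix (`NA` where arrival infinite), `sources`, `spec`.
#' @export
fast_march <- function(domain, sources) {
  stopifnot(inherits(domain, "domain_grid"), nrow(sources) >= 1)
  on_grid <- sources$row >= 1 & sources$row <= domain$spec$n_rows &
    sources$col >= 1 & sources$col <= domain$spec$n_cols
  if (!all(on_grid)) abort("source cell outside the grid")
  if (!all(domain$traversable[cbind(sources$row, sources$col)]))
    abort("source placed on a masked cell")

  arr <- NULL
  lab <- NULL
  for (k in seq_len(nrow(sources))) {
    res <- .fmm_solve(domain$traversable,
                      sources$row[k] - 1L, sources$col[k] - 1L,
                      domain$spec$cell_size)
    eff <- sources$start_offset[k] + res$arrival / sources$speed_ratio[k]
    if (is.null(arr)) {
      arr <- eff
      lab <- matrix(ifelse(is.finite(eff), 1L, NA_integer_),
                    nrow(eff), ncol(eff))
    } else {
      better <- eff < arr           # strict: ties keep the lower index
      arr[better] <- eff[better]
      lab[better] <- k
    }
  }
  structure(list(arrival = arr, label = lab, sources = sources,
                 spec = domain$spec),
            class = "arrival_field")
}

#' @export
print.arrival_field <- function(x, ...) {
  fin <- is.finite(x$arrival)
  cat(sprintf("<arrival_field> %d source(s); %d reachable cells; max %.4g km\n",
              nrow(x$sources), sum(fin),
              if (any(fin)) max(x$arrival[fin]) else NA_real_))
  invisible(x)
}

#' Effective distances from an arrival field at site locations
#'
#' Sites are snapped to their grid cell; a site on a masked cell falls back to
#' the nearest traversable cell within one cell (8-neighbourhood), otherwise
#' it is flagged unreachable. Distances smaller than one cell size are clamped
#' to the cell size so that downstream log transforms are defined.
#'
#' @param field An [fast_march()] result.
#' @param sites A site table (or any data frame with `lon`, `lat`).
#' @return The input tibble plus `distance_km`, `source_label`, `unreachable`.
#' @export
distances_at_sites <- function(field, sites) {
  spec <- field$spec
  cells <- lonlat_to_cell(sites$lon, sites$lat, spec, strict = FALSE)
  n <- nrow(sites)
  dist <- rep(NA_real_, n)
  label <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- cells$row[i]; c <- cells$col[i]
    if (is.na(r)) next
    if (!is.finite(field$arrival[r, c])) {
      # nearest traversable cell within one cell
      nb <- expand.grid(dr = -1:1, dc = -1:1)
      rr <- r + nb$dr; cc <- c + nb$dc
      ok <- rr >= 1 & rr <= spec$n_rows & cc >= 1 & cc <= spec$n_cols
      rr <- rr[ok]; cc <- cc[ok]
      vals <- field$arrival[cbind(rr, cc)]
      if (any(is.finite(vals))) {
        j <- which.min(vals)
        r <- rr[j]; c <- cc[j]
      }
    }
    if (is.finite(field$arrival[r, c])) {
      dist[i] <- max(field$arrival[r, c], spec$cell_size)
      label[i] <- field$label[r, c]
    }
  }
  out <- as_tibble(sites)
  out$distance_km <- dist
  out$source_label <- label
  out$unreachable <- !is.finite(dist) | is.na(dist)
  out
}

#' @export
autoplot.arrival_field <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(object$spec$n_rows),
                           col = seq_len(object$spec$n_cols))
  df$arrival <- object$arrival[cbind(df$row, df$col)]
  df$arrival[!is.finite(df$arrival)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$arrival)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "cost distance (km)") +
    ggplot2::theme_minimal()
}
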
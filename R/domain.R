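#' Domain construction configuration
#'
#' Thresholds for building the traversable modelling domain. Defaults follow
#' the rice-dispersal setting: land is excluded where the annual growing
#' degree-day total falls below 2,500 (rice cannot grow) or where desert is
#' mapped; sea is traversable only within a 40 km coastal buffer, which
#' bridges islands up to 80 km offshore; candidate origins are laid out
#' every 100 km.
#'
#' @param dd_threshold Degree-days below which land is masked out.
#' @param dd_base_temp Base temperature (deg C) for degree-day accumulation.
#' @param buffer_km Coastal buffer width in km.
#' @param origin_spacing_km Candidate-origin lattice spacing in km.
#' @return A `domain_config` list.
#' @export
domain_config <- function(dd_threshold = 2500, dd_base_temp = 0,
                          buffer_km = 40, origin_spacing_km = 100) {
  stopifnot(dd_threshold > 0, buffer_km > 0, origin_spacing_km > 0)
  structure(list(dd_threshold = dd_threshold, dd_base_temp = dd_base_temp,
                 buffer_km = buffer_km, origin_spacing_km = origin_spacing_km),
            class = "domain_config")
}

.days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Annual growing degree-days from monthly mean temperatures
#'
#' Accumulates `max(0, T_m - base_temp) * days_in_month` over the twelve
#' months of a 365-day calendar. The result is monotone non-increasing in
#' `base_temp`.
#'
#' @param monthly_temps List of 12 co-registered matrices of monthly mean
#'   temperature (deg C), January first.
#' @param base_temp Base temperature in deg C.
#' @return Matrix of degree-days per year.
#' @export
compute_degree_days <- function(monthly_temps, base_temp = 0) {
  if (length(monthly_temps) != 12)
    abort(sprintf("need 12 monthly rasters, got %d", length(monthly_temps)))
  dims <- unique(lapply(monthly_temps, dim))
  if (length(dims) != 1)
    abort("monthly rasters are not co-registered (differing dimensions)")
  dd <- matrix(0, dims[[1]][1], dims[[1]][2])
  for (m in 1:12)
    dd <- dd + pmax(0, monthly_temps[[m]] - base_temp) * .days_in_month[m]
  dd
}

# tag codes for domain cells
.tag_levels <- c(land = 1L, coastal_buffer = 2L, masked_cold = 3L,
                 masked_desert = 4L, masked_sea = 5L)

#' Build the traversable modelling domain
#'
#' Combines the ecological masks on the equal-area grid: a land cell is
#' excluded when its degree-day total is below the threshold (`masked_cold`)
#' or when it is desert (`masked_desert`); a sea cell is traversable
#' (`coastal_buffer`) when its centre lies within `buffer_km` of the nearest
#' land-cell centre, and `masked_sea` otherwise. Traversable = `land` or
#' `coastal_buffer`. Two 40 km buffers meeting give a maximum 80 km offshore
#' bridge between landmasses; islands further out stay disconnected.
#'
#' @param degree_days Degree-day matrix from [compute_degree_days()].
#' @param desert Logical matrix, `TRUE` = desert.
#' @param land Logical matrix, `TRUE` = land.
#' @param spec The [grid_spec()] shared by all layers.
#' @param config A [domain_config()].
#' @return A `domain_grid` object: `spec`, integer `tags` matrix, logical
#'   `traversable` matrix.
#' @export
build_domain <- function(degree_days, desert, land, spec,
                         config = domain_config()) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!all(dim(degree_days) == c(spec$n_rows, spec$n_cols)) ||
      !all(dim(desert) == dim(degree_days)) ||
      !all(dim(land) == dim(degree_days)))
    abort("layers are not co-registered with the grid spec")
  if (!any(land)) abort("degenerate domain: no land cells")

  tags <- matrix(.tag_levels[["masked_sea"]], spec$n_rows, spec$n_cols)
  tags[land] <- .tag_levels[["land"]]
  tags[land & degree_days < config$dd_threshold] <- .tag_levels[["masked_cold"]]
  tags[land & desert] <- .tag_levels[["masked_desert"]]
  sea <- !land
  dist_to_land <- .edt_km(land, spec$cell_size)
  tags[sea & dist_to_land <= config$buffer_km] <- .tag_levels[["coastal_buffer"]]

  structure(list(spec = spec, tags = tags,
                 traversable = tags <= .tag_levels[["coastal_buffer"]]),
            class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  n <- table(factor(x$tags, levels = .tag_levels, labels = names(.tag_levels)))
  cat(sprintf("<domain_grid> %d x %d cells (%.6g km), %d traversable\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size,
              sum(x$traversable)))
  print(n)
  invisible(x)
}

#' Candidate-origin lattice on the traversable domain
#'
#' Lays a regular lattice at `spacing_km` over the projected extent (both
#' edges included), snaps nodes to the nearest cell, and keeps those on
#' traversable cells, in row-major order.
#'
#' @param domain A [build_domain()] result.
#' @param spacing_km Lattice spacing in km.
#' @return Tibble of candidate origins: `row`, `col`, `x`, `y`, `lon`, `lat`.
#' @export
origin_gridpoints <- function(domain, spacing_km = 100) {
  spec <- domain$spec
  if (spacing_km < spec$cell_size)
    abort("origin spacing finer than the grid resolution")
  xs <- seq(spec$origin_x, spec$origin_x + (spec$n_cols - 1) * spec$cell_size,
            by = spacing_km)
  ys <- seq(spec$origin_y, spec$origin_y - (spec$n_rows - 1) * spec$cell_size,
            by = -spacing_km)
  lattice <- tidyr::expand_grid(y = ys, x = xs)  # row-major: north to south
  col <- as.integer(round((lattice$x - spec$origin_x) / spec$cell_size)) + 1L
  row <- as.integer(round((spec$origin_y - lattice$y) / spec$cell_size)) + 1L
  keep <- domain$traversable[cbind(row, col)]
  if (!any(keep)) {
    warn("no candidate origins: lattice misses the traversable domain")
    return(tibble(row = integer(), col = integer(), x = numeric(),
                  y = numeric(), lon = numeric(), lat = numeric()))
  }
  row <- row[keep]; col <- col[keep]
  xy <- cell_to_xy(row, col, spec)
  ll <- cell_to_lonlat(row, col, spec)
  dplyr::distinct(tibble(row = row, col = col, x = xy$x, y = xy$y,
                         lon = ll$lon, lat = ll$lat))
}

#' Write the domain tags to an ASCII grid
#'
#' @param domain A `domain_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain <- function(domain, path) {
  write_ascii_grid(domain$tags, path, domain$spec)
}

#' @export
autoplot.domain_grid <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(object$spec$n_rows),
                           col = seq_len(object$spec$n_cols))
  df$tag <- factor(object$tags[cbind(df$row, df$col)],
                   levels = .tag_levels, labels = names(.tag_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$tag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      land = "grey70", coastal_buffer = "palegreen3", masked_cold = "steelblue",
      masked_desert = "indianred", masked_sea = "grey95"), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "cell class") +
    ggplot2::theme_minimal()
}
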
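#' Specify a dispersal hypothesis
#'
#' A named, ordered set of dispersal origins. The first origin's speed ratio
#' is fixed at 1 (it defines the distance units); further origins may have
#' fixed ratios or free ratios (`NA`) to be estimated within `ratio_bounds`.
#' The parameter count of a fitted hypothesis is `K = 3 + number of free
#' ratios` (two regression coefficients, one scale, one ratio per extra
#' process); searched origin coordinates are not counted.
#'
#' @param name Model label.
#' @param origins Data frame with `lon`, `lat` and optionally `speed_ratio`
#'   (`NA` = estimate) and `start_offset` (default 0).
#' @param ratio_bounds Lower and upper bounds for estimated speed ratios.
#' @return A `dispersal_hypothesis`.
#' @export
dispersal_hypothesis <- function(name, origins, ratio_bounds = c(0.01, 20)) {
  origins <- as_tibble(origins)
  stopifnot(nrow(origins) >= 1, all(c("lon", "lat") %in% names(origins)))
  if (!"speed_ratio" %in% names(origins))
    origins$speed_ratio <- c(1, rep(NA_real_, nrow(origins) - 1))
  if (!"start_offset" %in% names(origins)) origins$start_offset <- 0
  origins$speed_ratio[1] <- 1
  structure(list(name = name, origins = origins,
                 ratio_bounds = ratio_bounds),
            class = "dispersal_hypothesis")
}

#' @export
print.dispersal_hypothesis <- function(x, ...) {
  cat(sprintf("<dispersal_hypothesis> %s: %d origin(s), ratios {%s}\n",
              x$name, nrow(x$origins),
              paste(ifelse(is.na(x$origins$speed_ratio), "free",
                           format(x$origins$speed_ratio)), collapse = ", ")))
  invisible(x)
}

# per-origin unit-speed cost distances at the analysis sites
.site_distance_matrix <- function(hyp, domain, sites) {
  vapply(seq_len(nrow(hyp$origins)), function(j) {
    cell <- lonlat_to_cell(hyp$origins$lon[j], hyp$origins$lat[j], domain$spec)
    if (!domain$traversable[cell$row, cell$col])
      abort(sprintf("origin %d of '%s' is on a masked cell", j, hyp$name))
    fld <- fast_march(domain, source_spec(cell$row, cell$col))
    distances_at_sites(fld, sites)$distance_km
  }, numeric(nrow(sites)))
}

# effective distance in process-1 units for given ratios/offsets; a site
# unreachable from one source (NA) can still be claimed by another
.effective_distance <- function(dmat, ratios, offsets, cell_size) {
  eff <- sweep(sweep(dmat, 2, ratios, "/"), 2, offsets, "+")
  eff[!is.finite(eff)] <- Inf
  pmax(apply(eff, 1, min), cell_size)
}

#' Fit a dispersal hypothesis to the analysis set
#'
#' Computes per-origin cost-distance fields by fast marching, combines them
#' into effective distances (minimum over competing fronts, in the first
#' process's units), and fits the power-law quantile envelope. Free speed
#' ratios are estimated by maximising the asymmetric-Laplace log-likelihood
#' over the bounded ratio box: a coarse log-spaced multi-start grid followed
#' by bounded local refinement (deterministic). Ratios that end on a bound
#' are flagged as boundary estimates.
#'
#' @param hyp A [dispersal_hypothesis()].
#' @param domain A [build_domain()] result.
#' @param sites Analysis-set site table (see [select_analysis_set()]).
#' @param q_exceed Envelope fraction (default 0.10).
#' @param n_starts Multi-start grid points per free ratio.
#' @return A `hypothesis_fit`: the `quantile_fit`, fitted `ratios`,
#'   `boundary` flags, unreachable-site count, per-site distances.
#' @export
fit_hypothesis <- function(hyp, domain, sites, q_exceed = 0.10, n_starts = 9) {
  stopifnot(inherits(hyp, "dispersal_hypothesis"))
  dmat <- .site_distance_matrix(hyp, domain, sites)
  reachable <- apply(is.finite(dmat), 1, any)
  n_unreachable <- sum(!reachable)
  dmat <- dmat[reachable, , drop = FALSE]
  ages <- sites$median_age[reachable]
  offsets <- hyp$origins$start_offset
  free <- which(is.na(hyp$origins$speed_ratio))
  lb <- hyp$ratio_bounds[1]
  ub <- hyp$ratio_bounds[2]
  cell <- domain$spec$cell_size

  loglik_for <- function(free_ratios) {
    ratios <- hyp$origins$speed_ratio
    ratios[free] <- free_ratios
    eff <- .effective_distance(dmat, ratios, offsets, cell)
    fit_quantile_loglog(ages, eff, q_exceed, K = 3 + length(free))$loglik
  }

  if (length(free) == 0) {
    ratios <- hyp$origins$speed_ratio
  } else {
    grid1 <- exp(seq(log(lb), log(ub), length.out = n_starts))
    cand <- as.matrix(do.call(tidyr::expand_grid,
                              setNames(rep(list(grid1), length(free)),
                                       paste0("r", seq_along(free)))))
    vals <- apply(cand, 1, loglik_for)
    best <- cand[which.max(vals), ]
    if (length(free) == 1) {
      # bracket around the best start, then golden-section on log ratio
      opt <- optimize(function(lr) loglik_for(exp(lr)),
                      interval = log(pmin(pmax(best * c(1 / 4, 4), lb), ub)),
                      maximum = TRUE, tol = 1e-8)
      est <- exp(opt$maximum)
      if (loglik_for(est) < max(vals)) est <- best    # keep grid winner
    } else {
      to_box <- function(z) lb + (ub - lb) / (1 + exp(-z))
      from_box <- function(r) -log((ub - lb) / (r - lb) - 1)
      opt <- optim(from_box(pmin(pmax(best, lb * 1.001), ub * 0.999)),
                   function(z) -loglik_for(to_box(z)),
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 500))
      est <- to_box(opt$par)
      if (loglik_for(est) < max(vals)) est <- best
    }
    # a front that vanishes (or dominates) leaves the likelihood flat up to
    # the bound: snap to the bound when it fits no worse
    ll_est <- loglik_for(est)
    for (j in seq_along(est)) {
      for (bnd in c(lb, ub)) {
        trial <- est
        trial[j] <- bnd
        if (loglik_for(trial) >= ll_est - 1e-9) {
          est <- trial
          ll_est <- loglik_for(est)
          break
        }
      }
    }
    ratios <- hyp$origins$speed_ratio
    ratios[free] <- est
  }

  eff <- .effective_distance(dmat, ratios, offsets, cell)
  fit <- fit_quantile_loglog(ages, eff, q_exceed, K = 3 + length(free))
  boundary <- rep(FALSE, nrow(hyp$origins))
  boundary[free] <- ratios[free] <= lb * 1.01 | ratios[free] >= ub * 0.99
  if (any(boundary))
    warn(sprintf("'%s': speed ratio estimate on a bound (%s)", hyp$name,
                 paste(signif(ratios[free][boundary[free]], 3), collapse = ", ")))
  distances <- as_tibble(sites[reachable, ])
  distances$distance_km <- eff
  structure(list(name = hyp$name, fit = fit, ratios = ratios,
                 boundary = boundary, n_unreachable = n_unreachable,
                 distances = distances, q_exceed = q_exceed),
            class = "hypothesis_fit")
}

#' @export
print.hypothesis_fit <- function(x, ...) {
  cat(sprintf("<hypothesis_fit> %s: ratios {%s}%s\n", x$name,
              paste(signif(x$ratios, 4), collapse = ", "),
              if (any(x$boundary)) " [boundary]" else ""))
  print(x$fit)
  invisible(x)
}

#' @export
glance.hypothesis_fit <- function(x, ...) {
  dplyr::mutate(glance(x$fit), model = x$name,
                ratios = paste(signif(x$ratios, 4), collapse = ", "),
                .before = 1)
}

#' Compare fitted dispersal models by AICc
#'
#' Builds the model-comparison table: AICc differences from the best model
#' (`delta`), relative likelihoods `exp(-delta / 2)`, and Akaike weights
#' (relative likelihoods normalised to sum to one). All fits must use the
#' same site set (equal `n`).
#'
#' @param fits List of `hypothesis_fit` and/or `quantile_fit` objects.
#' @param names Optional model labels (defaults to hypothesis names).
#' @return Tibble sorted by ascending AICc: `model`, `params`, `n`, `K`,
#'   `loglik`, `aicc`, `delta`, `rel_likelihood`, `akaike_weight`.
#' @export
compare_models <- function(fits, names = NULL) {
  stopifnot(length(fits) >= 2)
  rows <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "hypothesis_fit")) {
      tibble(model = f$name,
             params = paste(signif(f$ratios, 4), collapse = ", "),
             n = f$fit$n, K = f$fit$K, loglik = f$fit$loglik,
             aicc = f$fit$aicc)
    } else if (inherits(f, "quantile_fit")) {
      tibble(model = if (is.null(names)) sprintf("model%d", i) else names[i],
             params = "", n = f$n, K = f$K, loglik = f$loglik, aicc = f$aicc)
    } else abort("compare_models expects hypothesis_fit or quantile_fit objects")
  })
  if (!is.null(names)) rows$model <- names
  if (length(unique(rows$n)) != 1)
    abort("models are not comparable: fitted on different site sets (unequal n)")
  rows <- dplyr::arrange(rows, .data$aicc)
  rows$delta <- rows$aicc - rows$aicc[1]
  rows$rel_likelihood <- exp(-rows$delta / 2)
  rows$akaike_weight <- rows$rel_likelihood / sum(rows$rel_likelihood)
  rows
}
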
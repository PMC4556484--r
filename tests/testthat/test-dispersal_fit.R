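test_that("check loss and AL log-likelihood match direct arithmetic", {
  set.seed(4)
  r <- rnorm(50)
  tau <- 0.9
  expect_equal(check_loss(r, tau), r * (tau - (r < 0)))
  # closed form: n * (log(tau(1-tau)) - 1 - log(mean check loss))
  expect_equal(al_loglik(r, tau),
               50 * (log(0.9 * 0.1) - 1 - log(mean(r * (0.9 - (r < 0))))),
               tolerance = 1e-12)
  # n = 1 with check loss tau(1-tau)/e gives exactly zero
  r1 <- 0.9 * 0.1 / exp(1) / 0.9
  expect_equal(al_loglik(r1, 0.9), 0, tolerance = 1e-12)
  # tau <-> 1-tau symmetry under mirrored residuals
  expect_equal(al_loglik(r, 0.9), al_loglik(-r, 0.1))
  expect_equal(al_loglik(rep(0, 5), 0.5), Inf)
})

test_that("AICc reproduces its definition and limits", {
  expect_equal(aicc(0, 10, 1), 2.5)
  expect_error(aicc(0, 5, 4), "too small")
  # correction vanishes for large n
  expect_lt(abs(aicc(-100, 1e5, 4) - (200 + 8)), 1e-3)
  # ranking by AICc equals ranking by loglik at fixed n and K
  lls <- c(-120, -100, -150, -90)
  expect_equal(order(vapply(lls, aicc, 0, n = 330, K = 3)),
               order(-lls))
})

test_that("quantile line fit agrees with the point-pair enumeration oracle", {
  # median variant of a 3-point configuration
  f <- fit_quantile_line(c(0, 1, 2), c(0, 1, 1), tau = 0.5)
  oracle <- enum_quantile_line(c(0, 1, 2), c(0, 1, 1), 0.5)
  expect_equal(f$slope, oracle$slope)
  expect_equal(f$intercept, oracle$intercept)
  expect_equal(sum(check_loss(f$residuals, 0.5)), oracle$loss)
  expect_equal(oracle$loss, 0.25)        # total |residual| 0.5 at tau = 0.5
  expect_equal(oracle$slope, 0.5)
  expect_equal(oracle$intercept, 0)

  set.seed(8)
  for (tau in c(0.1, 0.5, 0.9)) {
    x <- rnorm(25); y <- 1 - 2 * x + rexp(25)
    f <- fit_quantile_line(x, y, tau)
    oracle <- enum_quantile_line(x, y, tau)
    expect_equal(sum(check_loss(f$residuals, tau)), oracle$loss,
                 tolerance = 1e-9)
  }
})

test_that("power-law envelope fit recovers exact data and reports K, AICc", {
  d <- seq(10, 2000, length.out = 40)
  ages <- 100 * d^-0.5
  f <- fit_quantile_loglog(ages, d)
  expect_true(f$perfect_fit)
  expect_equal(f$power_A, 100, tolerance = 1e-8)
  expect_equal(f$power_b, -0.5, tolerance = 1e-10)
  expect_equal(f$loglik, Inf)
  expect_equal(f$K, 3)
  expect_error(fit_quantile_loglog(ages[1:5], d[1:5]), "too few")
  expect_error(fit_quantile_loglog(-ages, d), "positive")
})

test_that("envelope coverage approaches the q_exceed fraction", {
  set.seed(10)
  n <- 5000
  d <- runif(n, 20, 4000)
  true_age <- 20000 * d^-0.2
  obs <- true_age * pmax(1 - rrayleigh(n, 0.15), 0.05)
  f <- fit_quantile_loglog(obs, d, q_exceed = 0.10)
  above <- mean(log(obs) - (f$intercept_log + f$slope * log(d)) > 0)
  expect_lt(abs(above - 0.10), 0.02)
  expect_lt(f$power_b, 0)
})

test_that("model comparison table reproduces the AICc arithmetic identities", {
  mk <- function(name, ll, K) {
    structure(list(name = name, ratios = 1, boundary = FALSE,
                   fit = structure(list(n = 330, K = K, loglik = ll,
                                        aicc = aicc(ll, 330, K)),
                                   class = "quantile_fit")),
              class = "hypothesis_fit")
  }
  fits <- list(mk("best", -111.5, 4), mk("mid", -142.7, 3),
               mk("worst", -228.5, 5))
  tab <- compare_models(fits)
  expect_equal(tab$delta[1], 0)
  expect_equal(tab$rel_likelihood[1], 1)
  expect_equal(tab$rel_likelihood, exp(-tab$delta / 2))
  expect_equal(sum(tab$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(tab$model, c("best", "mid", "worst"))
  # delta of 4 halves twice: exp(-2)
  expect_equal(exp(-4 / 2), 0.1353, tolerance = 5e-4)
  bad <- list(mk("a", -100, 3),
              mk("b", -100, 3))
  bad[[2]]$fit$n <- 300
  expect_error(compare_models(bad), "unequal n")
})

test_that("power-law prediction and outlier flagging use strict exceedance", {
  curve <- power_law_curve(20346.7404, -0.210026)
  expect_equal(predict_age(curve, 1), 20346.7404)
  expect_equal(predict_age(power_law_curve(100, 0), c(1, 50, 2000)),
               rep(100, 3))
  expect_error(predict_age(curve, -5), "positive")
  # direct evaluation as the outlier threshold
  thr <- 20346.7404 * 1000^-0.210026
  sites <- tibble::tibble(site_id = c("on", "older", "younger"),
                          median_age = c(thr, thr + 3000, thr - 500))
  out <- find_outliers(sites, rep(1000, 3), curve)
  expect_equal(out$outlier, c(FALSE, TRUE, FALSE))
  expect_equal(out$age_excess[2], 3000)
})

test_that("seeded early sites are exactly the flagged outliers", {
  set.seed(11)
  n <- 60
  d <- runif(n, 100, 3000)
  curve <- power_law_curve(15000, -0.25)
  ages <- predict_age(curve, d) * runif(n, 0.6, 0.98)
  early <- sample(n, 5)
  ages[early] <- predict_age(curve, d[early]) * runif(5, 1.1, 1.5)
  sites <- tibble::tibble(site_id = sprintf("s%02d", 1:n), median_age = ages)
  out <- find_outliers(sites, d, curve)
  expect_setequal(which(out$outlier), early)
})

test_that("predicted arrival rasters decrease away from the origin", {
  dom <- helper_domain(matrix(TRUE, 15, 15), cell_size = 40)
  fld <- fast_march(dom, source_spec(8, 8))
  curve <- power_law_curve(20000, -0.2)
  ras <- predict_arrival_raster(curve, fld)
  expect_equal(ras[8, 8], predict_age(curve, 40))   # clamped at one cell
  expect_equal(max(ras, na.rm = TRUE), ras[8, 8])
  # contours follow arrival-field level sets: equal distances, equal ages
  expect_equal(ras[8, 12], ras[8, 4])
  expect_equal(ras[1, 8], predict_age(curve, fld$arrival[1, 8]))
  # monotone along a shortest path out of the origin (row 8 eastwards)
  expect_true(all(diff(ras[8, 8:15]) <= 1e-9))
})

test_that("hypothesis fitting recovers generating speed ratios", {
  cfg <- helper_toy_config(seed = 3, noise_sigma = 0.1)
  sim <- simulate_site_table(cfg)
  org <- sim$world$origins
  hyp <- dispersal_hypothesis("dual", tibble::tibble(
    lon = org$lon, lat = org$lat, speed_ratio = c(1, NA)))
  hf <- fit_hypothesis(hyp, sim$world$domain, sim$sites)
  expect_equal(hf$fit$K, 4)
  expect_lt(abs(hf$ratios[2] - 0.78), 0.15)
  expect_false(any(hf$boundary))

  # single-origin hypothesis: no free ratios, K = 3
  h1 <- dispersal_hypothesis("single", tibble::tibble(
    lon = org$lon[1], lat = org$lat[1], speed_ratio = 1))
  hf1 <- fit_hypothesis(h1, sim$world$domain, sim$sites)
  expect_equal(hf1$fit$K, 3)
  expect_gt(hf1$fit$aicc, hf$fit$aicc)   # truth beats the misspecified model
})

test_that("a spurious second front is pushed to a bound and flagged", {
  cfg <- helper_toy_config(seed = 5, noise_sigma = 0.08,
                           origins = NULL)
  # single-origin truth
  world <- make_toy_domain(cfg)
  world$origins <- world$origins[1, ]
  world$origins$speed_ratio <- 1
  sim <- simulate_site_table(cfg, world)
  far <- cell_to_lonlat(world$origins$row[1] - 8, world$origins$col[1] + 20,
                        world$domain$spec)
  hyp <- dispersal_hypothesis("dual-on-single", tibble::tibble(
    lon = c(world$origins$lon[1], far$lon),
    lat = c(world$origins$lat[1], far$lat),
    speed_ratio = c(1, NA)))
  expect_warning(hf <- fit_hypothesis(hyp, world$domain, sim$sites),
                 "bound")
  expect_true(any(hf$boundary))
})
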
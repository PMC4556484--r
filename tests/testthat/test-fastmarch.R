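test_that("eikonal update reproduces the closed-form solutions", {
  expect_equal(eikonal_update(0, Inf, 1, 1), 1)
  expect_equal(eikonal_update(1, 1, 1, 1), 1 + sqrt(2) / 2)
  expect_equal(eikonal_update(0, 0, 2, 2), sqrt(2) / 2)
  # one-sided regime when neighbours disagree by a full cell crossing
  expect_equal(eikonal_update(0, 5, 1, 1), 1)
  expect_error(eikonal_update(Inf, Inf, 1, 1), "no update")
})

test_that("axis-aligned propagation is exact and masked cells stay infinite", {
  mask <- matrix(TRUE, 1, 11)
  dom <- helper_domain(mask, cell_size = 20)
  fld <- fast_march(dom, source_spec(1, 1))
  expect_equal(fld$arrival[1, ], 20 * (0:10))
  mask2 <- matrix(TRUE, 5, 5); mask2[3, ] <- FALSE; mask2[3, 3] <- TRUE
  dom2 <- helper_domain(mask2)
  fld2 <- fast_march(dom2, source_spec(1, 1))
  expect_true(all(is.infinite(fld2$arrival[3, c(1, 2, 4, 5)])))
  expect_error(fast_march(dom2, source_spec(3, 1)), "masked")
})

test_that("single-source arrivals stay within the stencil error of Euclidean", {
  # provable bracket: Euclidean <= FMM <= 4-connected path length <= sqrt(2) d
  ratio_stats <- function(n) {
    dom <- helper_domain(matrix(TRUE, n, n))
    s <- n %/% 2
    fld <- fast_march(dom, source_spec(s, s))
    d_euc <- sqrt(outer((1:n - s)^2, (1:n - s)^2, "+"))
    far <- d_euc >= n / 10
    rel <- fld$arrival[far] / d_euc[far]
    c(min = min(rel), max = max(rel))
  }
  r30 <- ratio_stats(30)
  r60 <- ratio_stats(60)
  expect_true(r30[["min"]] >= 1 - 1e-9)
  expect_true(r30[["max"]] <= sqrt(2) + 1e-9)
  # the relative overshoot shrinks as the grid refines relative to distance
  expect_lt(r60[["max"]], r30[["max"]] + 1e-9)
  expect_lt(r60[["max"]], 1.18)
})

test_that("arrivals are bracketed by 8- and 4-connected Dijkstra oracles", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(15:40, 1)
    mask <- matrix(runif(n * n) > 0.25, n, n)
    src <- which(mask, arr.ind = TRUE)[1, ]
    mask_dom <- helper_domain(mask)
    fld <- fast_march(mask_dom, source_spec(src[1], src[2]))
    d4 <- dijkstra_grid(mask, src[1], src[2], neighbours = 4)
    d8 <- dijkstra_grid(mask, src[1], src[2], neighbours = 8)
    fin <- is.finite(d4)
    expect_equal(is.finite(fld$arrival), fin)   # same reachable set
    expect_true(all(fld$arrival[fin] <= d4[fin] + 1e-9))
    expect_true(all(fld$arrival[fin] >= d8[fin] / sqrt(2) - 1e-9))
  }
})

test_that("heap pops occur in non-decreasing arrival order", {
  set.seed(5)
  mask <- matrix(runif(900) > 0.3, 30, 30)
  src <- which(mask, arr.ind = TRUE)[1, ]
  res <- ricewave:::.fmm_solve(mask, src[1] - 1L, src[2] - 1L, 1,
                               record_order = TRUE)
  expect_true(all(diff(res$pop_order) >= -1e-12))
})

test_that("competing fronts take the pointwise minimum over sources", {
  # 1D corridor: A (ratio 1) at cell 1, B (ratio 2) at cell 11
  dom <- helper_domain(matrix(TRUE, 1, 11))
  fld <- fast_march(dom, source_spec(c(1, 1), c(1, 11),
                                     speed_ratio = c(1, 2)))
  k <- 0:10
  expect_equal(fld$arrival[1, ], pmin(k, (10 - k) / 2))
  # fronts meet at k = 10/3: k <= 3 claimed by A, k > 10/3 by B
  expect_equal(fld$label[1, ], c(rep(1L, 4), rep(2L, 7)))
  expect_equal(fld$arrival[1, 7], (10 - 6) / 2)   # cell k = 6

  # independent runs + min equals the multi-source field on random grids
  set.seed(12)
  for (rep in 1:3) {
    mask <- matrix(runif(625) > 0.2, 25, 25)
    cells <- which(mask, arr.ind = TRUE)
    pick <- cells[sample(nrow(cells), 2), ]
    ratios <- c(1, runif(1, 0.3, 3))
    multi <- fast_march(helper_domain(mask),
                        source_spec(pick[, 1], pick[, 2], ratios))
    singles <- lapply(1:2, function(i)
      fast_march(helper_domain(mask),
                 source_spec(pick[i, 1], pick[i, 2]))$arrival / ratios[i])
    expect_equal(multi$arrival, pmin(singles[[1]], singles[[2]]))
  }
})

test_that("adding a source never increases any arrival", {
  set.seed(21)
  mask <- matrix(runif(400) > 0.2, 20, 20)
  cells <- which(mask, arr.ind = TRUE)
  pick <- cells[sample(nrow(cells), 3), ]
  dom <- helper_domain(mask)
  one <- fast_march(dom, source_spec(pick[1, 1], pick[1, 2]))
  three <- fast_march(dom, source_spec(pick[, 1], pick[, 2]))
  expect_true(all(three$arrival <= one$arrival + 1e-12 |
                    (is.infinite(three$arrival) & is.infinite(one$arrival))))
})

test_that("site distances snap, clamp and flag unreachable records", {
  mask <- matrix(TRUE, 5, 11)
  mask[, 6] <- FALSE                      # full wall
  dom <- helper_domain(mask, cell_size = 20)
  fld <- fast_march(dom, source_spec(3, 1))
  ll <- cell_to_lonlat(c(3, 3, 3), c(1, 5, 9), dom$spec)
  sites <- tibble::tibble(site_id = c("at-source", "corridor", "behind-wall"),
                          lon = ll$lon, lat = ll$lat)
  d <- distances_at_sites(fld, sites)
  expect_equal(d$distance_km[1], 20)      # clamped to one cell
  expect_equal(d$distance_km[2], 80)      # 4 cells along the axis
  expect_true(d$unreachable[3])

  # a site on a masked cell falls back to a traversable neighbour
  llm <- cell_to_lonlat(1, 6, dom$spec)
  dm <- distances_at_sites(fld, tibble::tibble(lon = llm$lon, lat = llm$lat))
  expect_false(dm$unreachable[1])
  nbhd <- fld$arrival[1:2, 5:7]
  expect_equal(dm$distance_km[1], min(nbhd[is.finite(nbhd)]))
})
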
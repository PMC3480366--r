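# Occurrence gridding, alpha/beta/gamma diversity, regridding, effective
# species numbers, calibration, and cross-correlation.

occ <- function(species, x, y) {
  data.frame(species = species, x = x, y = y,
             date = rep("2001-01-15", length(species)),
             stringsAsFactors = FALSE)
}

test_that("records land in the nearest pixel with deterministic tie-breaks", {
  g <- grid_occurrences(occ("A", 45, 15), resolution = 30, origin = c(0, 0),
                        dim = c(4, 4))
  expect_equal(names(g$cells), "0,1")
  expect_equal(g$cells[["0,1"]], "A")
  # duplicate (species, pixel) pairs collapse: alpha counts unique species
  g2 <- grid_occurrences(occ(c("A", "A", "B"), c(45, 50, 40), c(15, 20, 10)),
                         30, c(0, 0), c(4, 4))
  expect_equal(sort(g2$cells[["0,1"]]), c("A", "B"))
  expect_equal(alpha_diversity(g2)$per_cell[["0,1"]], 2L)
  # a record equidistant between two pixel centers goes to the smaller index
  gt <- grid_occurrences(occ("A", 30, 15), 30, c(0, 0), c(4, 4))
  expect_equal(names(gt$cells), "0,0")
})

test_that("out-of-domain records are excluded with a warning", {
  expect_warning(
    g <- grid_occurrences(occ(c("A", "B"), c(15, 500), c(15, 15)),
                          30, c(0, 0), c(4, 4)),
    "outside the domain")
  expect_equal(g$n_dropped, 1L)
  expect_equal(gamma_diversity(g), 1L)
})

test_that("alpha and gamma summarize cells and their union", {
  g <- grid_occurrences(occ(c("A", "B", "A"), c(15, 20, 75), c(15, 15, 15)),
                        30, c(0, 0), c(4, 4))
  a <- alpha_diversity(g)
  expect_equal(unname(sort(a$per_cell, decreasing = TRUE)), c(2L, 1L))
  expect_equal(a$mean, 1.5)
  expect_equal(gamma_diversity(g), 2L)
  expect_gte(gamma_diversity(g), max(a$per_cell))
  expect_gte(gamma_diversity(g), a$mean)
  # empty grid
  e <- grid_occurrences(occ(character(0), numeric(0), numeric(0)),
                        30, c(0, 0), c(4, 4))
  expect_equal(as.numeric(alpha_diversity(e)$mean), 0)
  expect_true(isTRUE(attr(alpha_diversity(e)$mean, "zero_cells")))
  expect_equal(gamma_diversity(e), 0L)
})

test_that("turnover is the complement of the temporal Jaccard index", {
  mk <- function(sp) grid_occurrences(occ(sp, rep(15, length(sp)), rep(15, length(sp))),
                                      30, c(0, 0), c(2, 2), period = "p")
  g1 <- mk(c("A", "B", "C")); g2 <- mk(c("B", "C", "D"))
  bt <- beta_turnover(g1, g2)
  expect_equal(unname(bt$per_cell), 0.5)   # |common| = 2, |union| = 4
  expect_equal(beta_turnover(g1, g1)$mean, 0)
  g3 <- mk(c("X", "Y"))
  expect_equal(beta_turnover(g1, g3)$mean, 1)
  # symmetry and range
  expect_equal(beta_turnover(g1, g2)$mean, beta_turnover(g2, g1)$mean)
  expect_true(all(bt$per_cell >= 0 & bt$per_cell <= 1))
  # incompatible grids are refused
  g4 <- grid_occurrences(occ("A", 15, 15), 60, c(0, 0), c(2, 2))
  expect_error(beta_turnover(g1, g4), class = "texdiv_incompatible_error")
})

test_that("regridding unions on coarsening, replicates on refining, keeps gamma", {
  recs <- occ(c("A", "B", "A"), c(15, 45, 15), c(15, 15, 45))
  g <- grid_occurrences(recs, 30, c(0, 0), dim = c(2, 2))
  expect_equal(length(g$cells), 3L)
  same <- regrid(g, 30)
  expect_equal(same$cells[order(names(same$cells))], g$cells[order(names(g$cells))])
  coarse <- regrid(g, 60)
  expect_equal(length(coarse$cells), 1L)
  expect_equal(sort(coarse$cells[[1]]), c("A", "B"))
  expect_equal(gamma_diversity(coarse), gamma_diversity(g))
  fine <- regrid(g, 15)
  expect_equal(gamma_diversity(fine), gamma_diversity(g))
  # each parent cell's set replicated into its 2x2 children
  expect_equal(length(fine$cells), 12L)
})

test_that("gamma is invariant under random regrids", {
  set.seed(33)
  recs <- occ(sprintf("sp%02d", sample(1:40, 200, TRUE)),
              runif(200, 0, 600), runif(200, 0, 600))
  g <- grid_occurrences(recs, 30, c(0, 0), c(20, 20))
  for (res in c(10, 30, 45, 90, 300)) {
    expect_equal(gamma_diversity(regrid(g, res)), gamma_diversity(g))
  }
})

test_that("effective species numbers invert community entropy", {
  expect_equal(diversity_number(0), 1)
  expect_equal(diversity_number(3, 2), 8)
  for (S in 2:20) {
    H <- -sum(rep(1 / S, S) * log2(1 / S))
    expect_equal(diversity_number(H, 2), S, tolerance = 1e-9)
  }
  expect_error(diversity_number(-1), class = "texdiv_domain_error")
})

test_that("calibration reproduces exact lines and degenerate cases", {
  x <- seq(1, 10, length.out = 20)
  f <- calibrate_linear(x, 2 * x + 1, n_boot = 100, seed = 1)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  fc <- calibrate_linear(x, rep(5, 20), n_boot = 100, seed = 1)
  expect_equal(fc$slope, 0, tolerance = 1e-10)
  expect_equal(fc$r_squared, 0)
  expect_error(calibrate_linear(rep(1, 10), rnorm(10)), class = "texdiv_domain_error")
  # R^2 is the squared Pearson correlation
  set.seed(2)
  y <- 3 * x + rnorm(20)
  expect_equal(calibrate_linear(x, y, n_boot = 50, seed = 1)$r_squared, cor(x, y)^2)
  # jackknife interval brackets the point estimate
  fj <- calibrate_linear(x, y, method = "jackknife")
  expect_lte(fj$ci_low, fj$slope); expect_gte(fj$ci_high, fj$slope)
})

test_that("cross-correlation peaks at the constructed shift", {
  set.seed(9)
  a <- as.numeric(arima.sim(list(ar = 0.6), 120))
  cc0 <- cross_correlation(a, a, max_lag = 5)
  expect_equal(cc0$correlation[cc0$lag == 0], 1)
  k <- 3
  b <- c(rep(0, k), a)[seq_along(a)]   # b lags a by k steps
  cc <- cross_correlation(a, b, max_lag = 6)
  expect_equal(cc$lag[which.max(cc$correlation)], k)
  # independent noise stays weakly correlated at lag 0
  set.seed(10)
  r0 <- replicate(20, {
    u <- rnorm(200); v <- rnorm(200)
    cross_correlation(u, v, 0)$correlation
  })
  expect_lt(mean(abs(r0)), 0.2)
  expect_error(cross_correlation(rep(1, 50), rnorm(50), 3),
               class = "texdiv_domain_error")
})
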
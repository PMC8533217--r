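fes_from_counts <- function(counts, x_origin = 2.0, y_origin = 2.2,
                            width = 0.1, empty = 10) {
  h <- structure(list(counts = counts, bin_width = width,
                      x_origin = x_origin, y_origin = y_origin,
                      x_label = "x", y_label = "y", total = sum(counts)),
                 class = "hist2d")
  free_energy(h, empty)
}

test_that("2D binning uses half-open tenth-of-angstrom bins and conserves
           counts", {
  h <- bin2d(2.05, 2.25)
  expect_equal(sum(h$counts), 1L)
  expect_equal(h$x_origin, 2.0)
  expect_equal(h$y_origin, 2.2)

  h2 <- bin2d(rep(3.14, 1000), rep(2.71, 1000))
  expect_equal(max(h2$counts), 1000L)
  expect_equal(h2$total, 1000L)

  # boundary value falls in the bin it starts
  hb <- bin2d(c(2.05, 2.10), c(2.25, 2.25))
  expect_equal(dim(hb$counts)[1], 2L)
  expect_equal(hb$counts[2, 1], 1L)

  expect_error(bin2d(1:3, 1:2), "frame-aligned")
})

test_that("Boltzmann inversion matches its closed form, bin by bin", {
  fes <- fes_from_counts(matrix(100))
  expect_identical(fes$dG[1, 1], 0)

  counts <- rbind(c(100L, 50L), c(0L, 25L))
  fes <- fes_from_counts(counts)
  expect_equal(fes$dG, rbind(c(0, log(2)), c(10, log(4))), tolerance = 1e-12)
  expect_equal(fes$rho, counts / 175)
  # monotonicity: more counts, lower dG
  ord <- order(as.vector(counts), decreasing = TRUE)
  expect_true(all(diff(as.vector(fes$dG)[ord]) >= -1e-12))
  expect_error(fes_from_counts(matrix(0L)), "no observations")
})

test_that("kT-level populations count observations and sum to 100", {
  fes <- fes_from_counts(matrix(100))
  lev <- level_populations(fes)
  expect_equal(lev$percent[1], 100)

  fes <- fes_from_counts(rbind(c(100L, 50L), c(0L, 25L)))
  lev <- level_populations(fes)
  expect_equal(lev$percent[1], 100 * 150 / 175, tolerance = 1e-9)
  expect_equal(lev$percent[2], 100 * 25 / 175, tolerance = 1e-9)
  expect_equal(sum(lev$percent), 100, tolerance = 1e-6)

  # the minimum bin's population is a lower bound on level 1
  set.seed(21)
  x <- rnorm(5000, 2, 0.4); y <- rnorm(5000, 3, 0.4)
  fes <- free_energy(bin2d(x, y))
  expect_gte(level_populations(fes)$percent[1], fes_minimum(fes)$percent)
  expect_equal(sum(level_populations(fes)$percent), 100, tolerance = 1e-6)
})

test_that("the landscape minimum reports bin centers and population share", {
  fes <- fes_from_counts(rbind(c(100L, 50L), c(0L, 25L)))
  m <- fes_minimum(fes)
  expect_equal(m$x, 2.05)
  expect_equal(m$y, 2.25)
  expect_equal(m$x_start, 2.0)
  expect_equal(m$percent, 100 * 100 / 175, tolerance = 1e-9)
  expect_warning(fes_minimum(fes_from_counts(matrix(5L, 2, 2))), "tie")
})

test_that("binning, inversion and level tables match brute-force
           enumeration on small inputs", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    x <- round(runif(n, 1.9, 2.4), 3)
    y <- round(runif(n, 2.1, 2.8), 3)
    oracle <- brute_force_landscape(x, y, 0.1)
    h <- bin2d(x, y, 0.1)
    fes <- free_energy(h)
    expect_equal(h$x_origin, oracle$x_origin)
    expect_equal(unname(h$counts), unname(oracle$counts))
    expect_equal(fes$dG, oracle$dG, tolerance = 1e-12)
    lev <- level_populations(fes)
    np <- length(oracle$level_percent)
    expect_equal(lev$percent[seq_len(np)], oracle$level_percent,
                 tolerance = 1e-9)
    expect_true(all(lev$percent[-seq_len(np)] == 0))
  }
})

test_that("pooling adds counts over absolute bin edges", {
  set.seed(41)
  xs <- lapply(1:5, function(i) rnorm(100, 2 + 0.2 * i, 0.3))
  ys <- lapply(1:5, function(i) rnorm(100, 3, 0.3))
  hs <- Map(function(x, y) bin2d(x, y), xs, ys)
  pooled <- pool_histograms(hs)
  expect_equal(pooled$total, 500L)
  expect_equal(sum(pooled$counts), 500L)
  # pooling a histogram with itself doubles every count
  dbl <- pool_histograms(list(hs[[1]], hs[[1]]))
  expect_equal(dbl$counts, hs[[1]]$counts * 2L)
  # direct binning of concatenated data equals pooled histogram
  all_h <- bin2d(unlist(xs), unlist(ys))
  expect_equal(sum(abs(pooled$counts - all_h$counts)), 0L)
  expect_error(pool_histograms(list(hs[[1]], bin2d(1, 1, 0.2))),
               "bin widths")
})

test_that("1D histogram mode recovery on constant, unimodal and bimodal
           series", {
  expect_equal(as.numeric(modal_bin(hist1d(rep(7.6, 10), 0.3))),
               c(7.5, 7.8))

  set.seed(51)
  v <- rnorm(10000, 7.65, 0.5)
  v <- v[v >= 6.5 & v <= 10.5]
  mb <- modal_bin(hist1d(v, 0.3))
  expect_equal(as.numeric(mb), c(7.5, 7.8))
  expect_gte(attr(mb, "min"), 6.5)
  expect_lte(attr(mb, "max"), 10.5)

  w <- c(rnorm(3000, 6.9, 0.15), rnorm(7000, 8.4, 0.15))
  mb2 <- modal_bin(hist1d(w, 0.3))
  expect_true(mb2[1] <= 8.4 && 8.4 <= mb2[2])
})

test_that("landscape tables expose starts, centers and sentinel bins", {
  fes <- fes_from_counts(rbind(c(100L, 50L), c(0L, 25L)))
  tab <- fes_table(fes)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$x_center - tab$x_bin_start, rep(0.05, 4))
  expect_equal(tab$dG_kT[tab$count == 0], 10)
  expect_equal(nrow(fes_table(fes, drop_empty = TRUE)), 3)
})
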
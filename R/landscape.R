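# Population-based free-energy landscapes: distances are binned on a grid
# whose edges sit at exact multiples of the bin width (anchored at 0 A), so
# histograms from different replicates align by absolute edge and can be
# pooled by addition. Bins are half-open [edge, edge + width).

bin_index <- function(v, origin, width) {
  as.integer(floor((v - origin) / width + 1e-9)) + 1L
}

#' Bin two aligned observable series on a 2D grid
#'
#' @param x,y Numeric vectors of equal length (paired per-frame values, in
#'   angstrom), e.g. the two tunnel hydrogen-bond distances.
#' @param bin_width Bin width in angstrom (default 0.1, i.e. tenths of
#'   angstrom).
#' @param x_label,y_label Axis labels carried through to outputs.
#' @return An object of class `"hist2d"`: integer count matrix (`x` rows),
#'   origins, bin width and total count.
#' @export
bin2d <- function(x, y, bin_width = 0.1,
                  x_label = "x", y_label = "y") {
  if (length(x) != length(y))
    stop(sprintf("x and y are not frame-aligned (%d vs %d values)",
                 length(x), length(y)), call. = FALSE)
  if (!length(x)) stop("no observations to bin", call. = FALSE)
  stopifnot(all(is.finite(x)), all(is.finite(y)), bin_width > 0)
  x_origin <- floor(min(x) / bin_width + 1e-9) * bin_width
  y_origin <- floor(min(y) / bin_width + 1e-9) * bin_width
  ix <- bin_index(x, x_origin, bin_width)
  iy <- bin_index(y, y_origin, bin_width)
  nx <- max(ix); ny <- max(iy)
  counts <- matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny), nx, ny)
  structure(list(counts = counts, bin_width = bin_width,
                 x_origin = x_origin, y_origin = y_origin,
                 x_label = x_label, y_label = y_label,
                 total = length(x)),
            class = "hist2d")
}

#' @export
print.hist2d <- function(x, ...) {
  cat(sprintf("<hist2d> %s vs %s: %d x %d bins of %.3g A, %d observations\n",
              x$x_label, x$y_label, nrow(x$counts), ncol(x$counts),
              x$bin_width, x$total))
  invisible(x)
}

hist2d_bin_starts <- function(h) {
  list(x = h$x_origin + (seq_len(nrow(h$counts)) - 1L) * h$bin_width,
       y = h$y_origin + (seq_len(ncol(h$counts)) - 1L) * h$bin_width)
}

#' Pool per-replicate 2D histograms by absolute bin edges
#'
#' Counts add; grids are aligned on absolute edges (all inputs share the
#' anchored-at-zero edge convention), so replicates with different observed
#' ranges pool correctly.
#'
#' @param hists List of [bin2d()] histograms with matching labels and bin
#'   width.
#' @return A pooled `"hist2d"`.
#' @export
pool_histograms <- function(hists) {
  stopifnot(length(hists) >= 1, all(vapply(hists, inherits, TRUE, "hist2d")))
  h1 <- hists[[1]]
  for (h in hists[-1]) {
    if (h$x_label != h1$x_label || h$y_label != h1$y_label)
      stop("cannot pool histograms with different axis labels", call. = FALSE)
    if (abs(h$bin_width - h1$bin_width) > 1e-12)
      stop("cannot pool histograms with different bin widths", call. = FALSE)
  }
  w <- h1$bin_width
  xo <- min(vapply(hists, `[[`, 0, "x_origin"))
  yo <- min(vapply(hists, `[[`, 0, "y_origin"))
  nx <- max(vapply(hists, function(h)
    round((h$x_origin - xo) / w) + nrow(h$counts), 0))
  ny <- max(vapply(hists, function(h)
    round((h$y_origin - yo) / w) + ncol(h$counts), 0))
  counts <- matrix(0L, nx, ny)
  for (h in hists) {
    ox <- round((h$x_origin - xo) / w)
    oy <- round((h$y_origin - yo) / w)
    sel_x <- ox + seq_len(nrow(h$counts))
    sel_y <- oy + seq_len(ncol(h$counts))
    counts[sel_x, sel_y] <- counts[sel_x, sel_y] + h$counts
  }
  structure(list(counts = counts, bin_width = w, x_origin = xo, y_origin = yo,
                 x_label = h1$x_label, y_label = h1$y_label,
                 total = sum(vapply(hists, `[[`, 0L, "total"))),
            class = "hist2d")
}

#' Boltzmann inversion of a binned population landscape
#'
#' Converts bin populations to free energies in kT units:
#' dG_i = -ln(rho_i / rho_max), where rho_i is the fraction of observations
#' in bin i and rho_max that of the most populated bin. The most populated
#' bin therefore sits at exactly 0 kT. Bins without observations carry an
#' arbitrary sentinel value (default 10 kT) that marks them as unsampled;
#' the sentinel is excluded from any averaging and is only a plot ceiling.
#'
#' @param hist A [bin2d()] histogram with at least one observation.
#' @param empty_bin_value Sentinel dG for unsampled bins, in kT.
#' @return An object of class `"fes"` with fields `histogram`, `rho`,
#'   `rho_max`, `dG` (kT) and `empty_bin_value`.
#' @export
free_energy <- function(hist, empty_bin_value = 10) {
  stopifnot(inherits(hist, "hist2d"))
  if (hist$total <= 0 || all(hist$counts == 0))
    stop("histogram has no observations", call. = FALSE)
  rho <- hist$counts / hist$total
  rho_max <- max(rho)
  dG <- matrix(empty_bin_value, nrow(rho), ncol(rho))
  pop <- hist$counts > 0
  dG[pop] <- -log(rho[pop] / rho_max)
  structure(list(histogram = hist, rho = rho, rho_max = rho_max, dG = dG,
                 empty_bin_value = empty_bin_value),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  m <- fes_minimum(x)
  cat(sprintf(
    "<fes> %s vs %s: minimum at (%.2f, %.2f) A holding %.2f%% of %d observations\n",
    x$histogram$x_label, x$histogram$y_label, m$x, m$y, m$percent,
    x$histogram$total))
  invisible(x)
}

#' Locate the free-energy minimum bin
#'
#' Returns the most populated (dG = 0) bin. Ties are broken towards the
#' smallest x then y bin center, with a warning.
#'
#' @param fes A [free_energy()] surface.
#' @return List with `x`, `y` (bin centers, angstrom), `x_start`, `y_start`
#'   (bin lower edges) and `percent` (percent of all observations in that
#'   bin).
#' @export
fes_minimum <- function(fes) {
  h <- fes$histogram
  mx <- max(h$counts)
  hits <- which(h$counts == mx, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    warning(sprintf("dG-minimum tie across %d bins; reporting smallest center",
                    nrow(hits)), call. = FALSE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  }
  i <- unname(hits[1, 1]); j <- unname(hits[1, 2])
  list(x = h$x_origin + (i - 0.5) * h$bin_width,
       y = h$y_origin + (j - 0.5) * h$bin_width,
       x_start = h$x_origin + (i - 1) * h$bin_width,
       y_start = h$y_origin + (j - 1) * h$bin_width,
       percent = 100 * mx / h$total)
}

#' Locate the lowest secondary basin of a surface
#'
#' Among populated bins farther than `min_separation` (Euclidean, angstrom)
#' from the global minimum, returns the one with the lowest dG (highest
#' count), i.e. the secondary energetically favourable conformation of a
#' two-basin landscape.
#'
#' @param fes A [free_energy()] surface.
#' @param min_separation Minimum center-to-center distance from the global
#'   minimum, in angstrom.
#' @return As [fes_minimum()], plus `dG` of the secondary bin; `NULL` if no
#'   populated bin lies beyond the separation.
#' @export
secondary_minimum <- function(fes, min_separation = 0.5) {
  h <- fes$histogram
  g <- fes_minimum(fes)
  starts <- hist2d_bin_starts(h)
  cx <- starts$x + h$bin_width / 2
  cy <- starts$y + h$bin_width / 2
  d2 <- outer(cx - g$x, cy - g$y, function(a, b) a^2 + b^2)
  eligible <- h$counts > 0 & d2 > min_separation^2
  if (!any(eligible)) return(NULL)
  mx <- max(h$counts[eligible])
  hits <- which(h$counts == mx & eligible, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- unname(hits[1, 1]); j <- unname(hits[1, 2])
  list(x = cx[i], y = cy[j],
       x_start = starts$x[i], y_start = starts$y[j],
       percent = 100 * h$counts[i, j] / h$total,
       dG = fes$dG[i, j])
}

#' Percentage of observations per integer-kT free-energy level
#'
#' Level n collects the observations in bins whose dG lies in (n-1, n] kT,
#' with level 1 also including the dG = 0 minimum bin. Percentages are over
#' observations (frame counts), not over bins, so they sum to 100: unsampled
#' bins hold zero observations. Levels beyond `max_level` are appended when
#' a populated bin exceeds it.
#'
#' @param fes A [free_energy()] surface.
#' @param max_level Minimum number of levels to tabulate (default 10).
#' @return Data frame with columns `level_kT` and `percent`.
#' @export
level_populations <- function(fes, max_level = 10) {
  h <- fes$histogram
  pop <- h$counts > 0
  lev <- ceiling(fes$dG[pop] - 1e-12)
  lev[lev < 1L] <- 1L
  nlev <- max(max_level, lev)
  pct <- vapply(seq_len(nlev), function(n)
    100 * sum(h$counts[pop][lev == n]) / h$total, 0)
  data.frame(level_kT = seq_len(nlev), percent = pct)
}

# -- 1D histogram utilities --------------------------------------------------

#' Bin one observable series on a 1D grid
#'
#' @param v Non-empty numeric vector (angstrom).
#' @param bin_width Bin width in angstrom.
#' @return An object of class `"hist1d"`: counts, origin, bin width, and
#'   the observed `min`/`max` of the series.
#' @export
hist1d <- function(v, bin_width = 0.1) {
  if (!length(v)) stop("empty series", call. = FALSE)
  stopifnot(all(is.finite(v)), bin_width > 0)
  origin <- floor(min(v) / bin_width + 1e-9) * bin_width
  i <- bin_index(v, origin, bin_width)
  structure(list(counts = tabulate(i, nbins = max(i)), origin = origin,
                 bin_width = bin_width, total = length(v),
                 min = min(v), max = max(v)),
            class = "hist1d")
}

#' Bounds of the most populated 1D bin
#'
#' @param h A [hist1d()] histogram.
#' @return Numeric `c(start, end)` of the modal bin in angstrom, with the
#'   observed series range as attributes `min`/`max`. The first bin wins a
#'   tie.
#' @export
modal_bin <- function(h) {
  stopifnot(inherits(h, "hist1d"))
  i <- which.max(h$counts)
  structure(c(h$origin + (i - 1) * h$bin_width, h$origin + i * h$bin_width),
            min = h$min, max = h$max)
}

# -- export / plotting -------------------------------------------------------

#' Flatten a free-energy surface to a long-format table
#'
#' @param fes A [free_energy()] surface.
#' @param drop_empty Drop unsampled bins (default `FALSE`; they carry the
#'   sentinel dG).
#' @return Data frame with columns `x_bin_start`, `y_bin_start`, `x_center`,
#'   `y_center`, `count`, `rho`, `dG_kT`.
#' @export
fes_table <- function(fes, drop_empty = FALSE) {
  h <- fes$histogram
  starts <- hist2d_bin_starts(h)
  out <- data.frame(
    x_bin_start = rep(starts$x, times = ncol(h$counts)),
    y_bin_start = rep(starts$y, each = nrow(h$counts)),
    count = as.vector(h$counts),
    rho = as.vector(fes$rho),
    dG_kT = as.vector(fes$dG))
  out$x_center <- out$x_bin_start + h$bin_width / 2
  out$y_center <- out$y_bin_start + h$bin_width / 2
  if (drop_empty) out <- out[out$count > 0, , drop = FALSE]
  out[, c("x_bin_start", "y_bin_start", "x_center", "y_center",
          "count", "rho", "dG_kT")]
}

#' Filled-contour rendering of a free-energy surface
#'
#' Integer-kT contour levels; the empty-bin sentinel is the colour ceiling.
#'
#' @param x A [free_energy()] surface.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.fes <- function(x, ...) {
  h <- x$histogram
  starts <- hist2d_bin_starts(h)
  cx <- starts$x + h$bin_width / 2
  cy <- starts$y + h$bin_width / 2
  z <- pmin(x$dG, x$empty_bin_value)
  graphics::image(cx, cy, z, xlab = h$x_label, ylab = h$y_label,
                  col = grDevices::hcl.colors(x$empty_bin_value * 2,
                                              "viridis"),
                  ...)
  graphics::contour(cx, cy, z, levels = seq_len(x$empty_bin_value),
                    add = TRUE, col = "grey20")
  invisible(x)
}
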
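# Independent brute-force oracles and small shared fixtures. These
# deliberately re-derive results observation by observation, without using
# the package's binned/vectorized code paths.

# Per-observation enumeration of a 2D landscape: assign each (x, y) pair to
# its half-open bin by direct comparison against explicit edge lists, then
# apply the Boltzmann inversion definition literally.
brute_force_landscape <- function(x, y, width, empty_bin_value = 10) {
  xe <- seq(floor(min(x) / width) * width,
            floor(max(x) / width) * width + width, by = width)
  ye <- seq(floor(min(y) / width) * width,
            floor(max(y) / width) * width + width, by = width)
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  counts <- matrix(0L, nx, ny)
  for (t in seq_along(x)) {
    i <- j <- NA
    for (a in seq_len(nx))
      if (x[t] >= xe[a] - 1e-12 && x[t] < xe[a + 1] - 1e-12) { i <- a; break }
    for (b in seq_len(ny))
      if (y[t] >= ye[b] - 1e-12 && y[t] < ye[b + 1] - 1e-12) { j <- b; break }
    counts[i, j] <- counts[i, j] + 1L
  }
  rho <- counts / length(x)
  dG <- matrix(empty_bin_value, nx, ny)
  for (a in seq_len(nx)) for (b in seq_len(ny))
    if (counts[a, b] > 0) dG[a, b] <- -log(rho[a, b] / max(rho))
  # observations per integer-kT level, enumerated bin by bin
  lev_of <- function(g) max(1L, as.integer(ceiling(g - 1e-12)))
  levels <- numeric(0)
  for (a in seq_len(nx)) for (b in seq_len(ny)) if (counts[a, b] > 0) {
    n <- lev_of(dG[a, b])
    if (n > length(levels)) levels <- c(levels, rep(0, n - length(levels)))
    levels[n] <- levels[n] + counts[a, b]
  }
  list(counts = counts, dG = dG,
       level_percent = 100 * levels / length(x),
       x_origin = xe[1], y_origin = ye[1])
}

# deterministic rigid transform generator
random_rigid_transform <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, tr) xyz %*% t(tr$R) +
  matrix(tr$t, nrow(xyz), 3, byrow = TRUE)

# minimal in-memory topology for I/O tests
tiny_topology <- function(n = 2) {
  data.frame(serial = seq_len(n),
             atom_name = paste0("C", seq_len(n)),
             residue_name = "LIG",
             residue_number = 1L,
             chain_id = "A",
             element = "C",
             b_factor = 0,
             stringsAsFactors = FALSE)
}

# standard-condition replicate set used by recovery tests
simulate_replicates <- function(preset, n_reps = 5, n_frames = 10000,
                                seed_base = 100) {
  model <- preset_model(preset)
  lapply(seq_len(n_reps), function(r)
    simulate_trajectory(model, n_frames, seed_base + r,
                        replicate_id = sprintf("%s_rep%d", preset, r)))
}

observable_series <- function(lt) {
  ser <- extract_series(lt$trajectory, tunnel_specs())
  list(d1 = series_values(ser, "Gln147-Trp153"),
       d2 = series_values(ser, "Gln147-Thr261"),
       chi = series_values(ser, "C8-C9-C10-C11"))
}
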
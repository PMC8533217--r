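test_that("dihedral distribution is normalized, periodic and
           permutation-invariant", {
  d <- dihedral_distribution(rep(-60, 100), 5)
  expect_equal(sum(d$rho), 1, tolerance = 1e-12)
  expect_equal(sum(d$rho > 0), 1L)
  expect_equal(d$bin_start[which(d$rho > 0)], -65) # -60 in (-65, -60]

  set.seed(61)
  chi <- wrap_angle(runif(72000, -180, 180))
  du <- dihedral_distribution(chi, 5)
  expect_equal(length(du$rho), 72L)
  expect_lt(max(abs(du$rho - 1 / 72)), 5 / sqrt(1000) / 72 * 5)

  perm <- sample(length(chi))
  expect_equal(dihedral_distribution(chi[perm], 5)$rho, du$rho)

  # +180 and just-above -180 share the periodic boundary bin
  db <- dihedral_distribution(c(180, -179.99), 5)
  expect_equal(sum(db$counts[c(1, 72)]), 2L)
  expect_error(dihedral_distribution(c(0, 200)), "wrap")
})

test_that("trans-dominant circular data puts the modal bin at the
           periodic boundary", {
  set.seed(62)
  chi <- rvonmises(10000, 180, 20)
  d <- dihedral_distribution(chi, 5)
  i <- which.max(d$rho)
  expect_true(i %in% c(1L, 72L)) # bins adjacent to +/-180
})

test_that("PMF follows phi = -0.6 ln rho and round-trips the
           distribution", {
  d1 <- dihedral_distribution(rep(-60, 10), 5)
  p1 <- dihedral_pmf(d1)
  expect_equal(p1$phi[d1$rho > 0], 0)
  expect_true(all(is.na(p1$phi[d1$rho == 0])))

  d2 <- dihedral_distribution(c(rep(-60, 5), rep(180, 5)), 5)
  p2 <- dihedral_pmf(d2)
  expect_equal(unique(round(p2$phi[d2$rho > 0], 12)),
               round(0.6 * log(2), 12))

  set.seed(63)
  chi <- rvonmises(5000, -60, 2)
  pmf <- dihedral_pmf(dihedral_distribution(chi, 5))
  pop <- pmf$distribution$rho > 0
  expect_equal(exp(-pmf$phi[pop] / 0.6), pmf$distribution$rho[pop],
               tolerance = 1e-12)
  # halving a bin's population raises phi by 0.6 ln 2
  da <- dihedral_distribution(c(rep(-62, 4), rep(100, 4)), 5)
  db <- dihedral_distribution(c(rep(-62, 2), rep(100, 6)), 5)
  ia <- which(da$bin_start == -65)
  expect_equal(dihedral_pmf(db)$phi[ia] - dihedral_pmf(da)$phi[ia],
               0.6 * log(2), tolerance = 1e-12)
})

test_that("conformer classes partition the circle with the documented
           boundaries", {
  cl <- classify_conformer(c(-60, -111.1, 180, 60, -30, -90, 150, -150,
                             149.9999, 0))
  expect_equal(as.character(cl$class),
               c("gauche_minus", "other", "trans", "gauche_plus",
                 "gauche_minus", "gauche_minus", "trans", "trans",
                 "other", "other"))
  expect_equal(cl$actionable,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE))
  # every angle gets exactly one class
  grid <- wrap_angle(seq(-179.5, 180, by = 0.5))
  expect_false(any(is.na(classify_conformer(grid)$class)))
  # actionable window widens with the tolerance
  expect_true(classify_conformer(-69, actionable_tol = 10)$actionable)
  expect_false(classify_conformer(-69, actionable_tol = 5)$actionable)
})

test_that("hydrogen-bond state requires both pairs within the inclusive
           cutoff", {
  crit <- hbond_criterion(2.5)
  expect_true(hbond_state(2.0, 2.2, crit))
  expect_false(hbond_state(4.1, 5.6, crit))
  expect_true(hbond_state(2.5, 2.5, crit))
  expect_false(hbond_state(2.5000001, 2.0, crit))
  expect_equal(hbond_state(c(1, 3), c(1, 1), crit), c(TRUE, FALSE))
})

test_that("conditional actionable fractions match hand enumeration and
           the law of total probability", {
  # 12 hand-written frames: 7 bonded (frames 1-7), 5 not (8-12);
  # actionable (within 5 deg of -60): frames 1,2,3 bonded; frame 8 not.
  chi <- c(-60, -57, -64.9, -70, 100, 180, -40,
           -61, -120, 175, 55, -66)
  d1 <- c(2.0, 2.1, 1.9, 2.5, 2.2, 2.0, 2.3,
          3.0, 4.1, 2.0, 5.0, 2.6)
  d2 <- c(2.2, 2.0, 2.4, 2.5, 2.1, 2.3, 2.2,
          2.0, 5.6, 3.1, 4.0, 2.2)
  ca <- conditional_actionable(chi, d1, d2)
  expect_equal(ca$n_bonded, 7L)
  expect_equal(ca$n_unbonded, 5L)
  expect_equal(ca$fraction_bonded, 3 / 7)
  expect_equal(ca$fraction_unbonded, 1 / 5)
  # law of total probability, exact on counts
  total_act <- ca$fraction_bonded * ca$n_bonded +
    ca$fraction_unbonded * ca$n_unbonded
  expect_equal(total_act, sum(abs(chi + 60) <= 5))

  all_bonded <- conditional_actionable(rep(-60, 4), rep(2, 4), rep(2, 4))
  expect_equal(all_bonded$fraction_bonded, 1)
  expect_true(is.na(all_bonded$fraction_unbonded))
})

test_that("conditional fractions recover the generative contrast on
           synthetic data", {
  model <- preset_model("substrate")
  lt <- simulate_trajectory(model, 50000, seed = 71)
  obs <- observable_series(lt)
  ca <- conditional_actionable(obs$chi, obs$d1, obs$d2)
  truth <- model_conditional_actionable(model)
  se_b <- sqrt(truth$p_actionable_bonded *
                 (1 - truth$p_actionable_bonded) / ca$n_bonded)
  se_u <- sqrt(truth$p_actionable_unbonded *
                 (1 - truth$p_actionable_unbonded) / ca$n_unbonded)
  expect_lt(abs(ca$fraction_bonded - truth$p_actionable_bonded), 3 * se_b)
  expect_lt(abs(ca$fraction_unbonded - truth$p_actionable_unbonded),
            3 * se_u)
  # the kinked-state actionable mass is the designed 18% vs 3.5% contrast
  expect_equal(truth$p_actionable_state[["kinked"]], 0.18, tolerance = 1e-6)
  expect_equal(truth$p_actionable_state[["open"]], 0.035, tolerance = 1e-6)
})
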
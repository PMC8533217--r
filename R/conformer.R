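# Substrate torsion statistics: the C8-C9-C10-C11 dihedral distribution,
# its free-energy profile, gauche/trans classification, and the actionable
# (-60 degree, negative gauche) fraction conditioned on whether the tunnel
# triad Gln147/Trp153/Thr261 satisfies a distance hydrogen-bond criterion.

check_chi_range <- function(chi) {
  if (any(!is.finite(chi)))
    stop("non-finite dihedral values", call. = FALSE)
  if (any(chi <= -180 | chi > 180))
    stop("dihedral values outside (-180, 180]; wrap first with wrap_angle()",
         call. = FALSE)
  invisible(TRUE)
}

#' Wrap angles into (-180, 180]
#' @param x Angles in degrees.
#' @return Angles wrapped into (-180, 180].
#' @export
wrap_angle <- function(x) {
  out <- x - 360 * floor((x + 180) / 360)
  out[out <= -180] <- out[out <= -180] + 360
  out
}

#' Normalized dihedral-angle distribution
#'
#' Bins tile (-180, 180] with right-closed bins anchored at -180, so the
#' periodic boundary (+180 == -180) falls inside the last bin. rho sums to
#' one.
#'
#' @param chi Dihedral series in degrees, values in (-180, 180].
#' @param bin_width Bin width in degrees; must divide 360 (default 5).
#' @return Object of class `"dihedral_distribution"`: `rho`, `counts`,
#'   `bin_start` (lower edges), `bin_width`, `n`.
#' @export
dihedral_distribution <- function(chi, bin_width = 5) {
  if (!length(chi)) stop("empty dihedral series", call. = FALSE)
  check_chi_range(chi)
  nb <- round(360 / bin_width)
  if (abs(nb * bin_width - 360) > 1e-9)
    stop("bin_width must divide 360 degrees", call. = FALSE)
  i <- as.integer(ceiling((chi + 180) / bin_width - 1e-9))
  i[i < 1L] <- 1L
  counts <- tabulate(i, nbins = nb)
  structure(list(rho = counts / length(chi), counts = counts,
                 bin_start = -180 + (seq_len(nb) - 1L) * bin_width,
                 bin_width = bin_width, n = length(chi)),
            class = "dihedral_distribution")
}

#' Dihedral free-energy profile
#'
#' phi = -prefactor * ln(rho) per populated bin, in kcal/mol, with the
#' default prefactor 0.6 kcal/mol (~RT near 300 K). phi is reported
#' unshifted (no minimum subtraction). Unsampled bins carry `NA`, never 0.
#'
#' @param dist A [dihedral_distribution()].
#' @param prefactor Energy prefactor in kcal/mol.
#' @return Object of class `"dihedral_pmf"` with fields `distribution`,
#'   `phi` (kcal/mol, `NA` where unsampled) and `prefactor`.
#' @export
dihedral_pmf <- function(dist, prefactor = 0.6) {
  stopifnot(inherits(dist, "dihedral_distribution"), prefactor > 0)
  phi <- rep(NA_real_, length(dist$rho))
  pop <- dist$rho > 0
  phi[pop] <- -prefactor * log(dist$rho[pop])
  structure(list(distribution = dist, phi = phi, prefactor = prefactor),
            class = "dihedral_pmf")
}

#' Tabulate a dihedral PMF
#' @param pmf A [dihedral_pmf()].
#' @return Data frame `(chi_bin_start_deg, rho, phi_kcal_mol)`.
#' @export
pmf_table <- function(pmf) {
  d <- pmf$distribution
  data.frame(chi_bin_start_deg = d$bin_start, rho = d$rho,
             phi_kcal_mol = pmf$phi)
}

#' Classify dihedrals into gauche/trans conformer classes
#'
#' Negative gauche is centered at -60 degrees, positive gauche at +60
#' (30-degree half-width each), trans at |chi| >= 150; anything else
#' (including the crystal's -111.1 degree torsion) is `other`. The
#' `actionable` flag marks torsions within `actionable_tol` of -60 degrees,
#' the conformation required for desaturation at the C9-C10 bond.
#'
#' @param chi Dihedral(s) in degrees, in (-180, 180].
#' @param actionable_tol Half-width of the actionable window in degrees
#'   (5 for the "within five degrees" statistic, 10 for the broader
#'   description).
#' @return Data frame with columns `chi`, `class` (factor: `gauche_minus`,
#'   `gauche_plus`, `trans`, `other`) and `actionable` (logical).
#' @export
#' @examples
#' classify_conformer(c(-60, -111.1, 180))
classify_conformer <- function(chi, actionable_tol = 10) {
  check_chi_range(chi)
  cls <- rep("other", length(chi))
  cls[abs(chi + 60) <= 30] <- "gauche_minus"
  cls[abs(chi - 60) <= 30] <- "gauche_plus"
  cls[abs(chi) >= 150] <- "trans"
  data.frame(chi = chi,
             class = factor(cls, levels = c("gauche_minus", "gauche_plus",
                                            "trans", "other")),
             actionable = abs(chi + 60) <= actionable_tol)
}

#' Geometric hydrogen-bond criterion for the tunnel triad
#'
#' The triad counts as hydrogen-bonded when both pair distances
#' (Gln147-Trp153 and Gln147-Thr261) simultaneously fall at or below
#' `max_distance`. 2.5 A on the hydrogen-acceptor distances is the standard
#' geometric criterion and brackets the landscape minima near 2.0-2.3 A;
#' it is configurable because the source description of the cutoff is
#' ambiguous.
#'
#' @param max_distance Inclusive distance cutoff in angstrom.
#' @return Object of class `"hbond_criterion"`.
#' @export
hbond_criterion <- function(max_distance = 2.5) {
  stopifnot(max_distance > 0)
  structure(list(max_distance = max_distance), class = "hbond_criterion")
}

#' Evaluate the hydrogen-bond state per frame
#'
#' @param d1,d2 Distance series in angstrom (frame-aligned).
#' @param criterion An [hbond_criterion()].
#' @return Logical vector: `TRUE` where both distances are within the
#'   cutoff (boundary inclusive).
#' @export
hbond_state <- function(d1, d2, criterion = hbond_criterion()) {
  stopifnot(inherits(criterion, "hbond_criterion"),
            length(d1) == length(d2))
  if (any(d1 < 0 | d2 < 0)) stop("negative distances", call. = FALSE)
  d1 <= criterion$max_distance & d2 <= criterion$max_distance
}

#' Actionable-conformer fraction conditioned on the hydrogen-bond state
#'
#' Fraction of frames whose torsion lies within `tolerance` of -60 degrees,
#' separately among hydrogen-bonded and non-bonded frames. An empty
#' conditioning class yields `NA` (undefined), never 0. By the law of total
#' probability the two conditional fractions, weighted by class occupancy,
#' reproduce the unconditional actionable fraction exactly on counts.
#'
#' @param chi Dihedral series in degrees, in (-180, 180].
#' @param d1,d2 Frame-aligned distance series in angstrom.
#' @param criterion An [hbond_criterion()].
#' @param tolerance Actionable half-width in degrees (default 5).
#' @return List: `fraction_bonded`, `fraction_unbonded`, and the counts
#'   `n_bonded`, `n_unbonded`, `n_actionable_bonded`,
#'   `n_actionable_unbonded`.
#' @export
conditional_actionable <- function(chi, d1, d2,
                                   criterion = hbond_criterion(),
                                   tolerance = 5) {
  if (length(chi) != length(d1) || length(chi) != length(d2))
    stop("chi, d1 and d2 must be frame-aligned", call. = FALSE)
  check_chi_range(chi)
  bonded <- hbond_state(d1, d2, criterion)
  act <- abs(chi + 60) <= tolerance
  nb <- sum(bonded); nu <- sum(!bonded)
  ab <- sum(act & bonded); au <- sum(act & !bonded)
  list(fraction_bonded = if (nb > 0) ab / nb else NA_real_,
       fraction_unbonded = if (nu > 0) au / nu else NA_real_,
       n_bonded = nb, n_unbonded = nu,
       n_actionable_bonded = ab, n_actionable_unbonded = au)
}

#' Tabulate a conditional-actionable report
#' @param ca Result of [conditional_actionable()].
#' @return Data frame `(class, n_frames, n_actionable, fraction)`.
#' @export
conditional_table <- function(ca) {
  data.frame(class = c("hbonded", "not_hbonded"),
             n_frames = c(ca$n_bonded, ca$n_unbonded),
             n_actionable = c(ca$n_actionable_bonded,
                              ca$n_actionable_unbonded),
             fraction = c(ca$fraction_bonded, ca$fraction_unbonded))
}
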
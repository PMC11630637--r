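## Trajectory-derived metrics: equipartition (fluctuation) stiffness with
## block averaging, force-extension departure energy, geometric H-bond
## detection, radius of gyration, inertia-axis angles, pairwise-Coulomb
## punctual stress, and the nonparametric condition comparison.

#' Extensional stiffness from length fluctuations (equipartition)
#'
#' For a reaction-coordinate length `L(t)` fluctuating in a harmonic well at
#' temperature `T`, equipartition gives `k = kB*T / var(L)` (population
#' variance). With `L` in nm the result is in pN/nm; kB*T at 310 K is
#' 4.28 pN nm.
#'
#' @param series `time_series` of the length channel (nm), or a numeric
#'   vector of lengths.
#' @param T_K temperature in kelvin (default 310).
#' @return stiffness (pN/nm).
#' @export
extensional_stiffness <- function(series, T_K = 310) {
  y <- if (inherits(series, "time_series")) series$y else as.numeric(series)
  if (length(y) < 2) stop("need at least 2 samples")
  v <- mean((y - mean(y))^2)
  if (v == 0) stop("zero variance: rigid-body series has no fluctuation signal")
  kBT(T_K) / v
}

#' Block-averaged extensional stiffness
#'
#' Applies the equipartition estimator to contiguous blocks and reports the
#' per-block values with their mean and standard deviation, the standard way
#' to attach sampling error to a fluctuation estimate. Defaults mirror the
#' usual setup of five 10 ns blocks of 1000 samples.
#'
#' @param series `time_series` of the length channel (nm).
#' @param n_blocks number of contiguous blocks (>= 1).
#' @param block_len optional block duration in the series' time unit;
#'   when supplied, the sample count per block is derived from the median
#'   sampling interval and the series must cover `n_blocks * block_len`.
#' @param T_K temperature (K).
#' @return object of class `stiffness_estimate` with fields `k_blocks`,
#'   `mean`, `sd`, `T_K`.
#' @export
block_stiffness <- function(series, n_blocks = 5, block_len = NULL,
                            T_K = 310) {
  series <- as_time_series(series, unit = "nm", name = "length")
  n <- length(series$t)
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (!is.null(block_len)) {
    dt <- stats::median(diff(series$t))
    per <- floor(block_len / dt)
  } else {
    per <- floor(n / n_blocks)
  }
  if (per < 2 || n_blocks * per > n)
    stop("insufficient samples: need n_blocks * block_len worth of data")
  ks <- vapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1) * per + 1):(b * per)
    extensional_stiffness(series$y[idx], T_K)
  }, numeric(1))
  structure(list(k_blocks = ks, mean = mean(ks),
                 sd = if (n_blocks > 1) sd(ks) else NA_real_, T_K = T_K),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("Extensional stiffness: %.4g +/- %.3g pN/nm (%d blocks, T = %g K)\n",
              x$mean, x$sd, length(x$k_blocks), x$T_K))
  invisible(x)
}

#' Locate the first major force peak
#'
#' First local maximum (or a terminal running maximum) whose topographic
#' prominence -- height above the higher of the two bracketing minima, each
#' taken between the peak and the nearest higher sample (or the series
#' edge) -- exceeds `prominence_frac` of the global maximum. Prominence,
#' unlike raw height, ignores noise bumps riding on a rising ramp, so this
#' finds the point just before the rapid increase in extension rate on a
#' pulling curve.
#'
#' @param y force values.
#' @param prominence_frac prominence threshold as a fraction of the global
#'   maximum (default 0.1).
#' @return index of the peak sample.
#' @export
find_force_peak <- function(y, prominence_frac = 0.1) {
  n <- length(y)
  if (n < 3) stop("series too short for peak detection")
  thr <- prominence_frac * max(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  if (y[n] >= max(y[1:(n - 1)])) is_peak[n] <- TRUE  # terminal running max
  for (i in which(is_peak)) {
    higher_l <- which(y[seq_len(i - 1)] > y[i])
    lmin <- min(y[(if (length(higher_l)) max(higher_l) else 1):i])
    higher_r <- which(y[i:n] > y[i])
    rmin <- min(y[i:(if (length(higher_r)) i - 1 + min(higher_r) else n)])
    base <- if (i == n) lmin else max(lmin, rmin)  # terminal peak: left base
    if (y[i] - base >= thr) return(i)
  }
  stop("no force peak found above the prominence threshold; ",
       "set peak_index manually")
}

#' Continuous piecewise-linear least-squares fit
#'
#' Fits a continuous piecewise-linear function on fixed knots (tent basis)
#' by least squares, with a tiny ridge to handle knots not covered by data.
#'
#' @param x,y data; @param knots increasing knot positions spanning the
#'   integration range.
#' @return numeric vector of fitted values at the knots.
#' @export
fit_piecewise_linear <- function(x, y, knots) {
  K <- length(knots)
  B <- vapply(seq_len(K), function(j) {
    ## tent at knot j: rising ramp from j-1, falling ramp to j+1; the first
    ## and last knots keep only their single ramp
    up <- if (j > 1)
      pmax(0, pmin(1, (x - knots[j - 1]) / (knots[j] - knots[j - 1])))
    else rep(1, length(x))
    dn <- if (j < K)
      pmax(0, pmin(1, (knots[j + 1] - x) / (knots[j + 1] - knots[j])))
    else rep(1, length(x))
    pmin(up, dn)
  }, numeric(length(x)))
  A <- crossprod(B) + 1e-9 * diag(K)
  as.numeric(solve(A, crossprod(B, y)))
}

#' Departure energy from a force-extension curve
#'
#' Area under the force-extension curve up to the first major force peak,
#' used as a proxy for the unbinding barrier: (1) locate the peak on the
#' force channel, (2) fit a continuous piecewise-linear function (default
#' 20 knots, uniform in extension) to the nonmonotonic data up to the peak,
#' (3) integrate the fit with the trapezoid rule from extension 0 to the
#' peak extension.
#'
#' @param force `time_series` of force (pN).
#' @param extension `time_series` of extension (nm), same time base.
#' @param n_knots number of fit knots (default 20).
#' @param prominence_frac peak threshold, fraction of global max.
#' @param peak_index optional manual override of the peak sample.
#' @return energy in pN nm, with attributes `peak_index`, `peak_force`,
#'   `peak_extension`, `knots`, `fit`.
#' @export
departure_energy <- function(force, extension, n_knots = 20,
                             prominence_frac = 0.1, peak_index = NULL) {
  force <- as_time_series(force, unit = "pN", name = "force")
  extension <- as_time_series(extension, unit = "nm", name = "extension")
  if (length(force$t) != length(extension$t) ||
      any(abs(force$t - extension$t) > 1e-9 * max(abs(force$t), 1)))
    stop("force and extension must share a common time base")
  ip <- if (is.null(peak_index)) find_force_peak(force$y, prominence_frac)
        else as.integer(peak_index)
  x <- extension$y[1:ip]; f <- force$y[1:ip]
  xp <- x[ip]
  if (xp <= 0) stop("peak extension must be positive")
  knots <- seq(0, xp, length.out = n_knots)
  fit <- fit_piecewise_linear(x, f, knots)
  energy <- pracma::trapz(knots, fit)
  structure(energy, peak_index = ip, peak_force = force$y[ip],
            peak_extension = xp, knots = knots, fit = fit)
}

#' Geometric hydrogen-bond detection
#'
#' A donor-hydrogen-acceptor triplet is a hydrogen bond iff the
#' donor-acceptor distance is at most `dist_cutoff` (0.35 nm) and the
#' deviation of the D-H-A angle from linearity is at most `angle_cutoff`
#' (30 degrees) -- the standard VMD-style geometric criterion.
#'
#' @param struct `toy_structure` with roles and donor-hydrogen pairs.
#' @param dist_cutoff donor-acceptor distance cutoff (nm).
#' @param angle_cutoff deviation-from-linearity cutoff (degrees).
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance_nm`, `deviation_deg` (zero rows when nothing is found).
#' @export
detect_hbonds <- function(struct, dist_cutoff = 0.35, angle_cutoff = 30) {
  stopifnot(inherits(struct, "toy_structure"))
  hyd <- which(struct$role == "hydrogen")
  if (length(hyd) && nrow(struct$dh_pairs) == 0)
    stop("structure has hydrogens but no donor assignments")
  acc <- which(struct$role == "acceptor")
  out <- list()
  for (r in seq_len(nrow(struct$dh_pairs))) {
    h <- struct$dh_pairs[r, "hydrogen"]; d <- struct$dh_pairs[r, "donor"]
    if (struct$role[h] != "hydrogen" || struct$role[d] != "donor")
      stop("donor-hydrogen pair ", r, " does not match the role labels")
    for (a in acc) {
      if (a == d || a == h) next
      da <- struct$coords[a, ] - struct$coords[d, ]
      dist <- sqrt(sum(da^2))
      if (dist > dist_cutoff) next
      u <- struct$coords[d, ] - struct$coords[h, ]
      v <- struct$coords[a, ] - struct$coords[h, ]
      cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi  # D-H-A angle
      dev <- 180 - ang
      if (dev <= angle_cutoff)
        out[[length(out) + 1]] <- data.frame(donor = d, hydrogen = h,
                                             acceptor = a, distance_nm = dist,
                                             deviation_deg = dev)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance_nm = numeric(0),
                      deviation_deg = numeric(0)))
  do.call(rbind, out)
}

#' Mass-weighted radius of gyration
#'
#' RMS distance of atoms from their centre of mass, mass-weighted (the
#' `gmx gyrate` convention).
#'
#' @param coords N x 3 coordinates (nm); @param masses per-atom masses.
#' @return radius of gyration (nm).
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (any(masses <= 0)) stop("masses must be positive")
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Principal inertia axis of a rigid body
#'
#' Eigenvector of the inertia tensor with the smallest moment (the long
#' axis). Errors on (near-)degenerate bodies where the axis is undefined.
#'
#' @param coords N x 3 (nm); @param masses per-atom masses.
#' @return unit 3-vector.
#' @export
principal_axis <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  I3 <- diag(3) * sum(masses * rowSums(r^2)) -
    t(r) %*% (r * masses)
  eg <- eigen(I3, symmetric = TRUE)
  vals <- rev(eg$values)            # increasing
  vecs <- eg$vectors[, 3:1, drop = FALSE]
  ## a clear spectral gap between the two smallest moments is required for
  ## the long axis to be well defined (near-spherical bodies are rejected)
  if ((vals[2] - vals[1]) <= 0.1 * max(vals[3], .Machine$double.eps))
    stop("degenerate inertia axes: principal axis is not defined")
  vecs[, 1]
}

#' Angle between the principal inertia axes of two bodies
#'
#' By default the undirected (folded) convention
#' `acos(|u_A . u_B|)` in `[0, 90]` degrees; when reference orientations are
#' supplied, each eigenvector's sign is fixed against its reference and the
#' unfolded angle `acos(u_A . u_B)` in `[0, 180]` is reported (eigenvectors
#' have no intrinsic sign, so frame-to-frame work needs a reference, e.g.
#' the first frame's axis).
#'
#' @param coords_a,masses_a first body.
#' @param coords_b,masses_b second body.
#' @param ref_a,ref_b optional reference orientation vectors.
#' @return angle in degrees.
#' @export
inertia_axis_angle <- function(coords_a, masses_a = NULL,
                               coords_b, masses_b = NULL,
                               ref_a = NULL, ref_b = NULL) {
  ua <- principal_axis(coords_a, masses_a)
  ub <- principal_axis(coords_b, masses_b)
  if (!is.null(ref_a)) { if (sum(ua * ref_a) < 0) ua <- -ua }
  if (!is.null(ref_b)) { if (sum(ub * ref_b) < 0) ub <- -ub }
  d <- sum(ua * ub)
  if (is.null(ref_a) && is.null(ref_b)) d <- abs(d)
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Per-residue punctual stress from pairwise Coulomb forces
#'
#' For each residue, the sum of absolute pairwise Coulomb force magnitudes
#' `ke * |q_i q_j| / r^2` over atom pairs with one atom in the residue and
#' the partner in a different residue within the cutoff. Reported in the
#' force-like MD unit kJ mol^-1 nm^-1 (1 kJ/mol/nm = 1.6605 pN); a
#' Coulomb-only simplification of force-distribution analysis
#' (Lennard-Jones terms are not included).
#'
#' @param struct `toy_structure` with charges.
#' @param cutoff pair distance cutoff (nm), default 1.2.
#' @return named numeric vector of per-residue punctual stress
#'   (kJ mol^-1 nm^-1), names = residue ids.
#' @export
punctual_stress <- function(struct, cutoff = 1.2) {
  stopifnot(inherits(struct, "toy_structure"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  ke <- adhesim_constants$ke_kJ_mol_nm_e2
  res_ids <- sort(unique(struct$residue_id))
  out <- setNames(numeric(length(res_ids)), res_ids)
  n <- nrow(struct$coords)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (struct$residue_id[i] == struct$residue_id[j]) next
      d2 <- sum((struct$coords[i, ] - struct$coords[j, ])^2)
      if (d2 == 0)
        stop("overlapping atoms ", i, " and ", j, " (r = 0)")
      if (d2 > cutoff^2) next
      q <- struct$charges[i] * struct$charges[j]
      if (q == 0) next
      fmag <- ke * abs(q) / d2
      out[as.character(struct$residue_id[i])] <-
        out[as.character(struct$residue_id[i])] + fmag
      out[as.character(struct$residue_id[j])] <-
        out[as.character(struct$residue_id[j])] + fmag
    }
  }
  out
}

#' Nonparametric paired comparison of two conditions
#'
#' Kolmogorov-Smirnov normality check per sample (against a normal with the
#' sample's moments) followed by the Wilcoxon signed rank test on the paired
#' differences, with a decision at `alpha`.
#'
#' @param a,b equal-length paired samples (n >= 5).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return list with `ks_p_a`, `ks_p_b`, `wilcoxon_p`, `different`
#'   (logical), `alpha`.
#' @export
compare_conditions <- function(a, b, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (length(a) != length(b))
    stop("paired comparison needs equal-length samples")
  if (length(a) < 5) stop("n < 5: paired signed-rank test undefined")
  ksp <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  d <- a - b
  wp <- if (all(d == 0)) 1
        else suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                          exact = FALSE)$p.value)
  list(ks_p_a = ksp(a), ks_p_b = ksp(b), wilcoxon_p = wp,
       different = is.finite(wp) && wp < alpha, alpha = alpha)
}
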
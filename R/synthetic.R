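## Seeded synthetic generators. Every generator emits ground truth alongside
## its data (as attributes or list fields) and is bit-reproducible under a
## fixed seed, so each analysis stage can be tested without MD runs.

#' Harmonic length-fluctuation series
#'
#' Emulates the fluctuating reaction-coordinate length of a molecule held in
#' a harmonic well of stiffness `k0` at temperature `T`: Gaussian samples
#' with variance `kB*T/k0` around `L0`. `ar1` switches on an AR(1)
#' autocorrelation (same marginal variance) to mimic correlated MD samples
#' for block-averaging studies; the default is i.i.d.
#'
#' @param k0 planted stiffness (pN/nm).
#' @param T_K temperature (K).
#' @param n number of samples (>= 2).
#' @param dt sampling interval (ns).
#' @param seed RNG seed.
#' @param L0 mean length (nm).
#' @param ar1 lag-1 autocorrelation in `[0, 1)`.
#' @return `time_series` (nm) with attribute `k0`.
#' @export
gen_harmonic_series <- function(k0, T_K = 310, n = 5000, dt = 0.01, seed = 1,
                                L0 = 5, ar1 = 0) {
  stopifnot(k0 > 0, n >= 2, ar1 >= 0, ar1 < 1)
  set.seed(seed)
  sdv <- sqrt(kBT(T_K) / k0)
  if (ar1 == 0) {
    x <- rnorm(n, 0, sdv)
  } else {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sdv)
    eps <- rnorm(n - 1, 0, sdv * sqrt(1 - ar1^2))
    for (i in 2:n) x[i] <- ar1 * x[i - 1] + eps[i - 1]
  }
  ts <- time_series((0:(n - 1)) * dt, L0 + x, unit = "nm",
                    name = "reaction_coordinate", t_unit = "ns")
  attr(ts, "k0") <- k0
  ts
}

#' Piecewise-linear force-extension curve with known area
#'
#' Ground truth is the polygon through `segments` (vertices `(x, F)` with
#' strictly increasing extension); Gaussian noise of sd `noise_sd` is added
#' to the force channel. The analytic trapezoid area up to each vertex is
#' attached as ground truth.
#'
#' @param segments matrix/data.frame of vertices, columns extension (nm) and
#'   force (pN), x strictly increasing.
#' @param noise_sd force noise standard deviation (pN).
#' @param seed RNG seed.
#' @param n number of samples along the curve.
#' @return list with `force`, `extension` (`time_series` on a common time
#'   base) and `area_to_vertex` (cumulative analytic areas, pN nm).
#' @export
gen_force_extension <- function(segments, noise_sd = 0, seed = 1, n = 1000) {
  segments <- as.matrix(segments)
  stopifnot(ncol(segments) == 2, nrow(segments) >= 2)
  xv <- segments[, 1]; fv <- segments[, 2]
  if (any(diff(xv) <= 0)) stop("vertex extensions must be strictly increasing")
  set.seed(seed)
  x <- seq(xv[1], xv[length(xv)], length.out = n)
  f <- approx(xv, fv, xout = x)$y + rnorm(n, 0, noise_sd)
  t <- seq(0, 1, length.out = n)
  area <- c(0, cumsum(diff(xv) * (head(fv, -1) + tail(fv, -1)) / 2))
  list(force = time_series(t, f, unit = "pN", name = "force", t_unit = "ns"),
       extension = time_series(t, x, unit = "nm", name = "extension",
                               t_unit = "ns"),
       area_to_vertex = area)
}

#' Two rod-like domains with a planted inter-axis angle
#'
#' Two elongated point clouds whose principal inertia axes are separated by
#' the requested angle (in the plane, measured with the directed/unfolded
#' convention). The planted axis directions are attached for use as
#' reference orientations.
#'
#' @param angle_deg planted angle in `[0, 180]`.
#' @param n_atoms total atom count (split between the domains).
#' @param seed RNG seed.
#' @param length_nm rod length.
#' @param jitter transverse Gaussian jitter sd (nm).
#' @return `toy_structure` (residues 1 and 2) with attributes `axis_a`,
#'   `axis_b`, `angle_deg`.
#' @export
gen_two_domain <- function(angle_deg, n_atoms = 400, seed = 1,
                           length_nm = 10, jitter = 0.02) {
  stopifnot(angle_deg >= 0, angle_deg <= 180, n_atoms >= 8)
  set.seed(seed)
  na <- n_atoms %/% 2; nb <- n_atoms - na
  th <- angle_deg * pi / 180
  dir_a <- c(1, 0, 0)
  dir_b <- c(cos(th), sin(th), 0)
  rod <- function(nk, dir, centre) {
    s <- seq(-length_nm / 2, length_nm / 2, length.out = nk)
    pts <- outer(s, dir) + matrix(rnorm(3 * nk, 0, jitter), nk, 3)
    sweep(pts, 2, centre, `+`)
  }
  pa <- rod(na, dir_a, c(0, 0, 0))
  pb <- rod(nb, dir_b, c(3 * length_nm, 0, 0))
  st <- toy_structure(rbind(pa, pb),
                      residue_id = rep(c(1L, 2L), c(na, nb)))
  attr(st, "axis_a") <- dir_a
  attr(st, "axis_b") <- dir_b
  attr(st, "angle_deg") <- angle_deg
  st
}

#' Planted hydrogen-bond set with single-criterion decoys
#'
#' Each triplet (donor, hydrogen, acceptor) sits in its own residue on a
#' widely spaced grid (3 nm spacing, so no cross-triplet contacts) and is
#' randomly rotated. Planted true bonds satisfy both the 0.35 nm
#' donor-acceptor cutoff and the 30 degree linearity cutoff with margin
#' (0.299 nm, 10 deg); distance decoys fail only the distance criterion
#' (0.450 nm, 5 deg); angle decoys fail only the angle criterion
#' (0.300 nm, 45 deg). Violating exactly one criterion localises detector
#' failures.
#'
#' @param n_true,n_decoy_dist,n_decoy_angle triplet counts (>= 0).
#' @param seed RNG seed.
#' @return `toy_structure` with attribute `truth`: data.frame of atom
#'   indices (`donor`, `hydrogen`, `acceptor`) and `type` in
#'   `{"true", "decoy_dist", "decoy_angle"}`.
#' @export
gen_hbond_set <- function(n_true, n_decoy_dist, n_decoy_angle, seed = 1) {
  stopifnot(n_true >= 0, n_decoy_dist >= 0, n_decoy_angle >= 0)
  set.seed(seed)
  types <- rep(c("true", "decoy_dist", "decoy_angle"),
               c(n_true, n_decoy_dist, n_decoy_angle))
  ntr <- length(types)
  coords <- matrix(0, 0, 3); roles <- character(0); res <- integer(0)
  dh <- NULL
  truth <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), type = character(0))
  ## geometry per type: H-A distance r and deviation-from-linearity delta
  geom <- list(true = c(r = 0.20, delta = 10),
               decoy_dist = c(r = 0.35, delta = 5),
               decoy_angle = c(r = 0.2209, delta = 45))
  grid_n <- max(1, ceiling(ntr^(1 / 3)))
  for (i in seq_len(ntr)) {
    g <- geom[[types[i]]]
    delta <- g["delta"] * pi / 180
    d_local <- c(0, 0, 0)
    h_local <- c(0.1, 0, 0)
    a_local <- h_local + g["r"] * c(cos(delta), sin(delta), 0)
    ## random proper rotation (QR of a Gaussian matrix)
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    cell <- 3 * c(i %% grid_n, (i %/% grid_n) %% grid_n,
                  i %/% (grid_n^2))
    pts <- t(Q %*% rbind(d_local, h_local, a_local)) +
      matrix(cell, 3, 3, byrow = TRUE)
    base <- nrow(coords)
    coords <- rbind(coords, pts)
    roles <- c(roles, c("donor", "hydrogen", "acceptor"))
    res <- c(res, rep(i, 3))
    dh <- rbind(dh, c(hydrogen = base + 2L, donor = base + 1L))
    truth <- rbind(truth, data.frame(donor = base + 1L, hydrogen = base + 2L,
                                     acceptor = base + 3L, type = types[i]))
  }
  if (ntr == 0) {
    st <- toy_structure(matrix(numeric(0), 0, 3))
  } else {
    st <- toy_structure(coords,
                        masses = rep(c(14, 1, 16), ntr),
                        residue_id = res, role = roles, dh_pairs = dh)
  }
  attr(st, "truth") <- truth
  st
}
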
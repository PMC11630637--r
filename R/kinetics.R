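## Catch-slip bond kinetics: force-dependent dissociation, bond spring
## mechanics, and the mean-field (explicit Euler) concentration update that
## couples the bond field to the cell model.

#' Catch-slip bond kinetic parameter set
#'
#' Bundles the two-pathway dissociation parameters with the bond spring
#' constant and the maximum areal bond density. The dissociation rate is
#' `Koff(f) = Ka*exp(f/Fa) + Kb*exp(-f/Fb)`: the first (slip) term grows with
#' force, the second (catch) term decays, so when `Kb*Fa > Ka*Fb` the bond
#' lifetime `1/Koff` has an interior maximum.
#'
#' @param Kon association rate (1/s).
#' @param Ka slip-pathway prefactor (1/s).
#' @param Fa slip force scale (pN).
#' @param Kb catch-pathway prefactor (1/s).
#' @param Fb catch force scale (pN).
#' @param kint bond spring constant (pN/nm); 0.5 pN/nm for
#'   alpha5beta1-fibronectin.
#' @param rho_max maximum areal bond density (bonds/um^2); default 100.
#' @return object of class `catch_bond_params`.
#' @export
catch_bond_params <- function(Kon, Ka, Fa, Kb, Fb, kint = 0.5, rho_max = 100) {
  p <- list(Kon = Kon, Ka = Ka, Fa = Fa, Kb = Kb, Fb = Fb,
            kint = kint, rho_max = rho_max)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
    stop("all kinetic parameters must be finite numeric scalars")
  ## Ka or Kb may be zero (pure-catch / pure-slip limits), but not both:
  ## Koff must stay positive so the lifetime 1/Koff is finite at any force.
  if (Ka < 0 || Kb < 0 || Ka + Kb <= 0)
    stop("Ka and Kb must be >= 0 with Ka + Kb > 0")
  if (any(c(Kon, Fa, Fb, kint, rho_max) <= 0))
    stop("Kon, Fa, Fb, kint and rho_max must be > 0")
  structure(p, class = "catch_bond_params")
}

#' @export
print.catch_bond_params <- function(x, ...) {
  cat("Catch-slip bond parameters\n")
  cat(sprintf("  Kon = %g 1/s;  Koff(f) = %g*exp(f/%g) + %g*exp(-f/%g) 1/s\n",
              x$Kon, x$Ka, x$Fa, x$Kb, x$Fb))
  cat(sprintf("  kint = %g pN/nm;  rho_max = %g /um^2\n", x$kint, x$rho_max))
  if (x$Kb * x$Fa > x$Ka * x$Fb)
    cat(sprintf("  catch regime: lifetime maximum at f* = %.3g pN\n",
                lifetime_peak_force(x)))
  invisible(x)
}

#' Load a named kinetic preset
#'
#' Presets are stored in a YAML config shipped with the package
#' (`inst/extdata/bond_presets.yaml`); `"wildtype"` is a unimodal catch bond,
#' `"mutant_R1374_9A"` the synergy-site mutant with 11-fold lower zero-force
#' equilibrium bond concentration. A custom file with the same layout can be
#' supplied.
#'
#' @param name preset name.
#' @param file optional YAML file with presets; defaults to the shipped one.
#' @return `catch_bond_params`.
#' @export
catch_bond_preset <- function(name = c("wildtype", "mutant_R1374_9A"),
                              file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "bond_presets.yaml", package = "adhesim")
  presets <- yaml::read_yaml(file)
  name <- if (length(name) > 1) match.arg(name) else name
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  do.call(catch_bond_params, presets[[name]])
}

#' Force-dependent dissociation rate
#'
#' Two-pathway catch-slip model `Koff(f) = Ka*exp(f/Fa) + Kb*exp(-f/Fb)`.
#'
#' @param f bond force magnitude(s), pN; must be >= 0.
#' @param p `catch_bond_params`.
#' @return dissociation rate(s), 1/s; strictly positive.
#' @export
koff <- function(f, p) {
  stopifnot(inherits(p, "catch_bond_params"))
  if (length(f) == 0 || !is.numeric(f) || any(!is.finite(f)))
    stop("f must be finite numeric")
  if (any(f < 0))
    stop("force per bond is a magnitude; f must be >= 0")
  p$Ka * exp(f / p$Fa) + p$Kb * exp(-f / p$Fb)
}

#' Closed-form location of the lifetime maximum
#'
#' For catch parameters (`Kb*Fa > Ka*Fb`) the lifetime `1/Koff` peaks at
#' `f* = (Fa*Fb/(Fa+Fb)) * log(Kb*Fa/(Ka*Fb))`.
#'
#' @param p `catch_bond_params`.
#' @return f* in pN, or `NA` for slip-like parameters (no interior maximum).
#' @export
lifetime_peak_force <- function(p) {
  stopifnot(inherits(p, "catch_bond_params"))
  if (p$Kb * p$Fa <= p$Ka * p$Fb) return(NA_real_)
  (p$Fa * p$Fb / (p$Fa + p$Fb)) * log(p$Kb * p$Fa / (p$Ka * p$Fb))
}

#' Bond lifetime versus applied force
#'
#' @param f_grid nonnegative, strictly increasing force grid (pN).
#' @param p `catch_bond_params`.
#' @return data.frame with columns `force_pN`, `lifetime_s` (= 1/Koff).
#' @export
lifetime_curve <- function(f_grid, p) {
  if (length(f_grid) == 0) stop("empty force grid")
  if (any(diff(f_grid) <= 0)) stop("force grid must be strictly increasing")
  if (any(f_grid < 0)) stop("force grid must be nonnegative")
  data.frame(force_pN = f_grid, lifetime_s = 1 / koff(f_grid, p))
}

#' Bond spring force
#'
#' Linear spring `f = kint * u_int` acting along the extension vector.
#'
#' @param u_int spring extension vector (nm), any length.
#' @param p `catch_bond_params`.
#' @return force vector (pN) of the same length.
#' @export
bond_force <- function(u_int, p) {
  stopifnot(inherits(p, "catch_bond_params"))
  if (!is.numeric(u_int) || any(!is.finite(u_int)))
    stop("u_int must be finite numeric")
  p$kint * u_int
}

#' Nodal adhesion force from the mean-field bond field
#'
#' `f_node = C * rho_max * A * f_int`: the per-bond spring force scaled by
#' the expected number of bonds (`C*rho_max*A`) attached under the node.
#'
#' @param C dimensionless bond concentration in `[0, 1]`.
#' @param A local adhesion area (um^2), > 0.
#' @param f_int per-bond force vector (pN).
#' @param p `catch_bond_params`.
#' @return nodal force vector (pN).
#' @export
nodal_adhesion_force <- function(C, A, f_int, p) {
  stopifnot(inherits(p, "catch_bond_params"))
  if (!is.numeric(C) || C < 0 || C > 1) stop("C must lie in [0, 1]")
  if (!is.numeric(A) || A <= 0) stop("adhesion area A must be > 0")
  C * p$rho_max * A * f_int
}

#' Explicit-Euler update of the mean-field bond concentration
#'
#' `C' = C*(1 - Koff*dt) + Kon*dt*(1 - C)`, clamped to `[0, 1]`. The fixed
#' point at constant force is `Kon/(Kon + Koff)`. A warning is raised when
#' `Koff*dt > 1` (the explicit scheme is outside its stability region; the
#' clamp keeps the state admissible).
#'
#' @param C current concentration in `[0, 1]` (vectorised).
#' @param koff_val dissociation rate(s), 1/s.
#' @param Kon association rate, 1/s.
#' @param dt time step, s (> 0).
#' @return updated concentration(s), clamped to `[0, 1]`.
#' @export
update_concentration <- function(C, koff_val, Kon, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (any(C < 0 | C > 1)) stop("C must lie in [0, 1]")
  if (any(koff_val * dt > 1))
    warning("Koff*dt > 1: explicit Euler update outside stability region; ",
            "result clamped")
  pmin(1, pmax(0, C * (1 - koff_val * dt) + Kon * dt * (1 - C)))
}

#' Equilibrium bond concentration at constant force
#'
#' @param f force per bond (pN), vectorised.
#' @param p `catch_bond_params`.
#' @return `Kon / (Kon + Koff(f))`.
#' @export
equilibrium_concentration <- function(f, p) {
  p$Kon / (p$Kon + koff(f, p))
}
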
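## Whole-cell 2D finite-element model: neo-Hookean plane-stress disk under a
## ramped isotropic active contraction, coupled at every node to mean-field
## catch-slip adhesion. The R functions here are the reference
## implementations of each force term (used directly in tests); the time
## loop itself runs in compiled code (src/fe_core.cpp) which mirrors them
## and is cross-checked against them in the test suite.

#' Cell material and regularization parameters
#'
#' Shear modulus and density follow the standard whole-cell values
#' (mu_c = 1 kPa, rho_c = 1000 kg/m^3). The boundary/body regularization
#' coefficients (viscous drag, curvature smoothing, actin protrusion noise,
#' global area penalty) have no published values; the defaults are chosen to
#' be small relative to the contractile load (see the methods vignette) and
#' are freely configurable. `density_scale` is the selective mass-scaling
#' factor that makes the quasi-static explicit integration stable at the
#' 50 us time step (see vignette, Numerical choices).
#'
#' @param mu_c shear modulus (Pa).
#' @param rho_c density (kg/m^3).
#' @param drag_coeff per-node viscous coefficient (pN s/um).
#' @param kappa_coeff curvature regularization coefficient (pN um).
#' @param area_coeff global area penalty coefficient (pN/um^2 per node share).
#' @param actin_amp amplitude of the outward actin protrusion noise (pN).
#' @param density_scale mass scaling factor for quasi-static explicit
#'   dynamics (dimensionless).
#' @return object of class `cell_material`.
#' @export
cell_material <- function(mu_c = 1000, rho_c = 1000, drag_coeff = 10,
                          kappa_coeff = 10, area_coeff = 0, actin_amp = 0.5,
                          density_scale = 1e4) {
  stopifnot(mu_c > 0, rho_c > 0, drag_coeff >= 0, kappa_coeff >= 0,
            area_coeff >= 0, actin_amp >= 0, density_scale > 0)
  structure(list(mu_c = mu_c, rho_c = rho_c, drag_coeff = drag_coeff,
                 kappa_coeff = kappa_coeff, area_coeff = area_coeff,
                 actin_amp = actin_amp, density_scale = density_scale),
            class = "cell_material")
}

#' Passive neo-Hookean plane-stress Cauchy stress
#'
#' Incompressible neo-Hookean material under plane stress:
#' `sigma = mu_c * b2D - p_c * I` with `b2D = F %*% t(F)` and the pressure
#' `p_c = mu_c / det(F)^2` fixed by the condition `sigma_33 = 0` (the
#' out-of-plane stretch is `1/det(F)` by incompressibility).
#'
#' @param F2D in-plane deformation gradient (2 x 2), `det(F2D) > 0`.
#' @param mu_c shear modulus (Pa).
#' @return 2 x 2 Cauchy stress (Pa).
#' @export
passive_stress <- function(F2D, mu_c) {
  F2D <- as.matrix(F2D)
  stopifnot(all(dim(F2D) == c(2, 2)), is.finite(mu_c), mu_c > 0)
  J <- F2D[1, 1] * F2D[2, 2] - F2D[1, 2] * F2D[2, 1]
  if (J <= 0) stop("element inversion: det(F2D) <= 0")
  b <- F2D %*% t(F2D)
  mu_c * b - (mu_c / J^2) * diag(2)
}

#' Ramped isotropic active contraction
#'
#' Actomyosin traction `t_myo(t)`: linear ramp 100 Pa/s for 0 < t < 2 s,
#' then held at 200 Pa (the hold is extended past 30 s for longer runs).
#'
#' @param t simulation time (s), >= 0; vectorised.
#' @return active traction (Pa).
#' @export
active_traction <- function(t) {
  if (any(t < 0)) stop("t must be >= 0")
  pmin(100 * t, 200)
}

#' Boundary regularization forces
#'
#' Per-boundary-node forces on the cell contour:
#' * curvature smoothing `f_kappa = -kappa_coeff * kappa_i * n_i`, with the
#'   discrete curvature `kappa_i` from the turning angle divided by the mean
#'   adjacent segment length, and `n_i` the outward unit normal;
#' * area penalty `f_A = area_coeff * (A0 - A) * w_i * n_i`, the global area
#'   deficit distributed over the loop by node length share
#'   `w_i = l_i / sum(l)`;
#' * actin protrusion noise `f_ac = actin_amp * xi_i * n_i` with
#'   `xi_i ~ U(0, 1)` drawn per node per step (pass `xi` for determinism).
#'
#' @param positions N x 2 current node coordinates (um).
#' @param boundary ordered CCW boundary node loop (indices).
#' @param material `cell_material`.
#' @param A0 reference (target) enclosed area (um^2).
#' @param xi per-boundary-node uniform draws in `[0,1]`; drawn internally
#'   when `NULL`.
#' @return list with `f_kappa`, `f_ac`, `f_A` (each B x 2, pN), plus the
#'   outward normals `normal` and discrete curvatures `kappa`.
#' @export
boundary_forces <- function(positions, boundary, material, A0, xi = NULL) {
  b <- as.integer(boundary)
  nb <- length(b)
  if (nb < 3) stop("boundary loop must be closed with at least 3 nodes")
  p <- positions[b, , drop = FALSE]
  if (is.null(xi)) xi <- runif(nb)
  prev <- p[c(nb, 1:(nb - 1)), , drop = FALSE]
  nxt <- p[c(2:nb, 1), , drop = FALSE]
  e1 <- p - prev
  e2 <- nxt - p
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  if (any(l1 == 0 | l2 == 0)) stop("degenerate boundary segment")
  ## signed turning angle from e1 to e2 (positive = left/convex for CCW loop)
  cross <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  dot <- rowSums(e1 * e2)
  theta <- atan2(cross, dot)
  lbar <- (l1 + l2) / 2
  kappa <- theta / lbar
  ## outward normal: rotate the mean tangent direction by -90 deg (CCW loop)
  tanv <- e1 / l1 + e2 / l2
  n_out <- cbind(tanv[, 2], -tanv[, 1])
  n_out <- n_out / pmax(sqrt(rowSums(n_out^2)), 1e-300)
  A <- polygon_area(p)
  w <- lbar / sum(lbar)
  list(f_kappa = -material$kappa_coeff * kappa * n_out,
       f_ac = material$actin_amp * xi * n_out,
       f_A = material$area_coeff * (A0 - A) * w * n_out,
       normal = n_out, kappa = kappa, area = A)
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

#' Body forces: adhesion springs and viscous drag
#'
#' The adhesion force points from each node toward its substrate anchor and
#' scales with the expected number of attached bonds:
#' `f_adh = -C * rho_max * A * kint * u_int` (u_int in nm, anchored at the
#' node's initial position). Drag is linear: `f_drag = -drag_coeff * v`.
#'
#' @param positions,velocities N x 2 (um, um/s).
#' @param anchors N x 2 substrate attachment points (um).
#' @param C per-node bond concentration in `[0,1]`.
#' @param A_trib per-node adhesion (tributary) area (um^2).
#' @param kin `catch_bond_params`.
#' @param material `cell_material`.
#' @return list with `f_adh`, `f_drag` (N x 2, pN) and per-bond force
#'   magnitudes `f_int` (pN).
#' @export
body_forces <- function(positions, velocities, anchors, C, A_trib, kin,
                        material) {
  if (any(C < 0 | C > 1)) stop("C must lie in [0,1]")
  u_nm <- um_to_nm(positions - anchors)
  f_int_vec <- kin$kint * u_nm                    # pN, per bond
  f_int <- sqrt(rowSums(f_int_vec^2))
  f_adh <- -C * kin$rho_max * A_trib * f_int_vec  # toward anchor
  f_drag <- -material$drag_coeff * velocities
  list(f_adh = f_adh, f_drag = f_drag, f_int = f_int)
}

#' Internal force residual of the deformed cell
#'
#' Single-point quadrature on linear triangles of the total Cauchy stress
#' (passive neo-Hookean plus the isotropic active traction `tmyo * I`):
#' node `a` of each element receives
#' `R_a = thickness * A_cur * sigma %*% grad N_a`, so the equation of motion
#' is `m a = -R + f_circ + f_body`. The residual sums to zero over the mesh
#' (partition of unity), so momentum is conserved in the absence of external
#' forces.
#'
#' @param positions N x 2 current coordinates (um).
#' @param mesh reference `cell_mesh`.
#' @param mu_c shear modulus (Pa).
#' @param tmyo active traction (Pa).
#' @return N x 2 residual (pN).
#' @export
assemble_internal_forces <- function(positions, mesh, mu_c, tmyo = 0) {
  el <- mesh$elements
  X <- mesh$nodes
  R <- matrix(0, nrow(positions), 2)
  for (e in seq_len(nrow(el))) {
    i <- el[e, ]
    Dm <- cbind(X[i[2], ] - X[i[1], ], X[i[3], ] - X[i[1], ])
    Ds <- cbind(positions[i[2], ] - positions[i[1], ],
                positions[i[3], ] - positions[i[1], ])
    detDs <- Ds[1, 1] * Ds[2, 2] - Ds[1, 2] * Ds[2, 1]
    if (detDs <= 0) stop("element inversion in element ", e)
    Fg <- Ds %*% solve(Dm)
    sig <- passive_stress(Fg, mu_c) + tmyo * diag(2)
    Dsinv <- solve(Ds)
    grads <- rbind(-Dsinv[1, ] - Dsinv[2, ], Dsinv[1, ], Dsinv[2, ])  # dN/dx
    A_cur <- detDs / 2
    R[i, ] <- R[i, ] + mesh$thickness * A_cur * grads %*% sig
  }
  R
}

#' Analytic free-contraction stretch
#'
#' Uniform equilibrium stretch of a traction-free incompressible
#' plane-stress neo-Hookean sheet under an isotropic active traction:
#' the root of `mu_c*(lambda^2 - lambda^-4) + tmyo = 0` in (0, 1].
#'
#' @param mu_c shear modulus (Pa); @param tmyo active traction (Pa).
#' @return equilibrium stretch lambda.
#' @export
plane_stress_contraction_stretch <- function(mu_c, tmyo) {
  stopifnot(mu_c > 0, tmyo >= 0)
  if (tmyo == 0) return(1)
  uniroot(function(l) mu_c * (l^2 - l^-4) + tmyo,
          interval = c(1e-3, 1), tol = 1e-12)$root
}

#' Bundle mesh, material, kinetics and switches into a simulation system
#'
#' @param mesh `cell_mesh`.
#' @param material `cell_material`.
#' @param kinetics `catch_bond_params`.
#' @param use_adhesion couple the catch-bond field (default TRUE).
#' @param use_active apply the contraction ramp (default TRUE).
#' @param ramp_rate,plateau active traction ramp (Pa/s) and plateau (Pa).
#' @return object of class `cell_system`.
#' @export
cell_system <- function(mesh, material = cell_material(),
                        kinetics = catch_bond_preset("wildtype"),
                        use_adhesion = TRUE, use_active = TRUE,
                        ramp_rate = 100, plateau = 200) {
  stopifnot(inherits(mesh, "cell_mesh"), inherits(material, "cell_material"),
            inherits(kinetics, "catch_bond_params"))
  structure(list(mesh = mesh, material = material, kinetics = kinetics,
                 use_adhesion = use_adhesion, use_active = use_active,
                 ramp_rate = ramp_rate, plateau = plateau,
                 trib_area = tributary_areas(mesh),
                 A0 = sum(element_areas(mesh$nodes, mesh$elements))),
            class = "cell_system")
}

#' Initial cell state
#'
#' Nodes at the reference mesh, zero velocity, bond anchors at the initial
#' node positions, and the bond field at its zero-force equilibrium
#' `Kon/(Kon + Koff(0))`.
#'
#' @param system `cell_system`.
#' @param C0 optional initial concentration (scalar or per node).
#' @return object of class `cell_state`.
#' @export
cell_state_init <- function(system, C0 = NULL) {
  n <- nrow(system$mesh$nodes)
  if (is.null(C0)) C0 <- equilibrium_concentration(0, system$kinetics)
  C <- rep_len(C0, n)
  if (any(C < 0 | C > 1)) stop("C0 must lie in [0,1]")
  structure(list(positions = system$mesh$nodes,
                 velocities = matrix(0, n, 2),
                 C = C, anchors = system$mesh$nodes, time = 0),
            class = "cell_state")
}

#' Advance the cell state with the explicit midpoint rule
#'
#' Runs the compiled time loop: half-step velocity/position update, force
#' re-evaluation at the midpoint, full update; lumped (mass-scaled) nodal
#' masses from tributary areas; viscous drag folded in semi-implicitly
#' (unconditionally stable); bond concentrations advanced per node by the
#' explicit Euler kinetics using the per-bond force magnitude at the
#' current extension.
#'
#' @param system `cell_system`; @param state `cell_state`.
#' @param dt time step (s), default 50 us.
#' @param n_steps number of steps to take.
#' @param save_every record summary channels every this many steps.
#' @param record_fields also record per-node C and per-bond force fields at
#'   each save point.
#' @return list with the updated `state` and a `trace` data.frame
#'   (time, mean_C, mean_f, mean_f_bond, boundary_radius), plus field
#'   matrices when requested.
#' @export
step_cell <- function(system, state, dt = 50e-6, n_steps = 1,
                      save_every = n_steps, record_fields = FALSE) {
  stopifnot(inherits(system, "cell_system"), inherits(state, "cell_state"),
            dt > 0, n_steps >= 1)
  m <- system$material; k <- system$kinetics
  res <- fe_core_run(
    system$mesh$nodes, system$mesh$elements, system$mesh$boundary,
    system$trib_area,
    state$positions, state$velocities, state$C, state$anchors, state$time,
    list(mu_c = m$mu_c, rho_c = m$rho_c, thickness = system$mesh$thickness,
         drag_coeff = m$drag_coeff, kappa_coeff = m$kappa_coeff,
         area_coeff = m$area_coeff, actin_amp = m$actin_amp,
         density_scale = m$density_scale, A0 = system$A0),
    list(Kon = k$Kon, Ka = k$Ka, Fa = k$Fa, Kb = k$Kb, Fb = k$Fb,
         kint = k$kint, rho_max = k$rho_max),
    list(dt = dt, n_steps = as.integer(n_steps),
         save_every = as.integer(save_every),
         record_fields = isTRUE(record_fields),
         use_adhesion = isTRUE(system$use_adhesion),
         use_active = isTRUE(system$use_active),
         ramp_rate = system$ramp_rate, plateau = system$plateau))
  state$positions <- res$positions
  state$velocities <- res$velocities
  state$C <- as.numeric(res$C)
  state$time <- res$time
  trace <- data.frame(time = res$times, mean_C = res$mean_C,
                      mean_f = res$mean_f, mean_f_bond = res$mean_f_bond,
                      boundary_radius = res$boundary_radius)
  out <- list(state = state, trace = trace)
  if (isTRUE(record_fields)) {
    out$C_fields <- res$C_fields
    out$f_fields <- res$f_fields
  }
  out
}

#' Run replicate whole-cell contraction simulations
#'
#' Full protocol: contraction ramp to the plateau over `t_sim` seconds of
#' simulated time, one run per seed, then the arithmetic replicate average
#' of the summary channels (mean bond concentration over nodes, node-mean
#' and bond-averaged per-bond force, boundary radius).
#'
#' @param config nested list (or YAML/JSON file path) with optional sections
#'   `mesh` (radius, target_elements), `material` (see [cell_material()]),
#'   `kinetics` (preset name or explicit parameters), and `run`
#'   (dt, t_sim, save_stride, seeds, use_adhesion, use_active).
#' @return object of class `cell_sim`: replicate traces, their average, the
#'   final states, and per-node fields of the last save point per replicate.
#' @export
run_simulation <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  mesh_cfg <- modifyList(list(radius = 10, target_elements = 400),
                         config$mesh %||% list())
  run_cfg <- modifyList(list(dt = 50e-6, t_sim = 30, save_stride = 0.01,
                             seeds = c(1, 2, 3), use_adhesion = TRUE,
                             use_active = TRUE, record_fields = TRUE),
                        config$run %||% list())
  if (anyDuplicated(run_cfg$seeds)) stop("seeds must be unique")
  material <- do.call(cell_material, config$material %||% list())
  kin_cfg <- config$kinetics %||% "wildtype"
  kinetics <- if (is.character(kin_cfg)) catch_bond_preset(kin_cfg)
              else do.call(catch_bond_params, kin_cfg)
  mesh <- gen_disk_mesh(mesh_cfg$radius, mesh_cfg$target_elements)
  system <- cell_system(mesh, material, kinetics,
                        use_adhesion = run_cfg$use_adhesion,
                        use_active = run_cfg$use_active)
  n_steps <- ceiling(run_cfg$t_sim / run_cfg$dt)
  save_every <- max(1L, round(run_cfg$save_stride / run_cfg$dt))
  reps <- lapply(run_cfg$seeds, function(s) {
    set.seed(s)
    st <- cell_state_init(system)
    step_cell(system, st, dt = run_cfg$dt, n_steps = n_steps,
              save_every = save_every,
              record_fields = isTRUE(run_cfg$record_fields))
  })
  traces <- lapply(reps, `[[`, "trace")
  avg <- traces[[1]]
  if (length(traces) > 1) {
    for (ch in c("mean_C", "mean_f", "mean_f_bond", "boundary_radius")) {
      avg[[ch]] <- Reduce(`+`, lapply(traces, `[[`, ch)) / length(traces)
    }
  }
  structure(list(system = system, traces = traces, average = avg,
                 states = lapply(reps, `[[`, "state"),
                 C_fields = lapply(reps, `[[`, "C_fields"),
                 f_fields = lapply(reps, `[[`, "f_fields"),
                 seeds = run_cfg$seeds, config = config),
            class = "cell_sim")
}

#' @export
print.cell_sim <- function(x, ...) {
  a <- x$average
  cat(sprintf("Whole-cell adhesion simulation: %d replicates, t = %.3g s\n",
              length(x$traces), max(a$time)))
  cat(sprintf("  final mean bond concentration: %.4g\n", tail(a$mean_C, 1)))
  cat(sprintf("  final bond-averaged force:     %.4g pN (peak %.4g pN)\n",
              tail(a$mean_f_bond, 1), max(a$mean_f_bond)))
  invisible(x)
}

#' Free-contraction benchmark
#'
#' Runs the disk with adhesion, drag-free boundary regularization and noise
#' disabled, ramping to the traction plateau, and compares the realised
#' boundary radius ratio with the analytic uniform stretch
#' [plane_stress_contraction_stretch()].
#'
#' @param radius disk radius (um); @param target_elements mesh size.
#' @param t_sim simulated duration (s); the ramp ends at 2 s.
#' @param dt time step (s).
#' @return list with `lambda_fe`, `lambda_exact`, `rel_error`, `trace`.
#' @export
free_contraction_benchmark <- function(radius = 10, target_elements = 400,
                                       t_sim = 4, dt = 50e-6) {
  mesh <- gen_disk_mesh(radius, target_elements)
  material <- cell_material(kappa_coeff = 0, area_coeff = 0, actin_amp = 0)
  system <- cell_system(mesh, material, use_adhesion = FALSE)
  st <- cell_state_init(system)
  n_steps <- ceiling(t_sim / dt)
  res <- step_cell(system, st, dt = dt, n_steps = n_steps,
                   save_every = max(1L, round(0.01 / dt)))
  lam_fe <- tail(res$trace$boundary_radius, 1) / radius
  lam_ex <- plane_stress_contraction_stretch(material$mu_c,
                                             active_traction(t_sim))
  list(lambda_fe = lam_fe, lambda_exact = lam_ex,
       rel_error = abs(lam_fe - lam_ex) / lam_ex, trace = res$trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
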
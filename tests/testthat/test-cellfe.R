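test_that("passive plane-stress neo-Hookean stress matches closed forms", {
  mu <- 1000
  expect_equal(passive_stress(diag(2), mu), matrix(0, 2, 2))
  ## equibiaxial stretch
  for (lam in c(0.9, 0.97, 1.05)) {
    s <- passive_stress(diag(c(lam, lam)), mu)
    expect_equal(s[1, 1], mu * (lam^2 - lam^-4), tolerance = 1e-12)
    expect_equal(s[2, 2], s[1, 1])
    expect_equal(s[1, 2], 0)
  }
  ## uniaxial in-plane stretch, checked against the independent 3D
  ## incompressible formula sigma = mu*B - p*I with lambda3 = 1/det(F2D)
  ## and p fixed by sigma33 = 0
  lam <- 1.13
  s <- passive_stress(diag(c(lam, 1)), mu)
  lam3 <- 1 / lam
  p3 <- mu * lam3^2
  expect_equal(s[1, 1], mu * lam^2 - p3, tolerance = 1e-12)
  expect_equal(s[2, 2], mu * 1 - p3, tolerance = 1e-12)
  expect_equal(s[1, 2], 0)
  expect_error(passive_stress(diag(c(-1, 1)), mu), "inversion")
})

test_that("active traction ramps at 100 Pa/s and holds at 200 Pa", {
  expect_equal(active_traction(0), 0)
  expect_equal(active_traction(1), 100)
  expect_equal(active_traction(2), 200)
  expect_equal(active_traction(30), 200)
  expect_equal(active_traction(45), 200)  # documented hold past 30 s
  expect_error(active_traction(-0.1), ">= 0")
})

test_that("discrete curvature vanishes on straight segments and recovers 1/R on a circle", {
  mat <- cell_material(kappa_coeff = 2, area_coeff = 0, actin_amp = 0)
  ## convex pentagon with one collinear midpoint on the bottom edge
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 2), c(0, 2))
  bf <- boundary_forces(pos, 1:5, mat, A0 = 4, xi = rep(0, 5))
  expect_equal(bf$kappa[2], 0)
  expect_equal(bf$f_kappa[2, ], c(0, 0))

  ## regular 256-gon approximating a circle of radius R
  R <- 7; N <- 256
  th <- 2 * pi * (0:(N - 1)) / N
  circ <- R * cbind(cos(th), sin(th))
  bf <- boundary_forces(circ, 1:N, mat, A0 = pi * R^2, xi = rep(0, N))
  expect_equal(bf$kappa, rep(1 / R, N), tolerance = 0.005)
  ## outward normals are radial
  expect_true(all(rowSums(bf$normal * circ / R) > 0.999))
  ## area penalty vanishes at the target area
  mat2 <- cell_material(kappa_coeff = 0, area_coeff = 5, actin_amp = 0)
  bf2 <- boundary_forces(circ, 1:N, mat2, A0 = polygon_area_ref(circ),
                         xi = rep(0, N))
  expect_equal(max(abs(bf2$f_A)), 0)
})

test_that("body forces reproduce the adhesion force chain and linear drag", {
  kin <- catch_bond_preset("wildtype")
  mat <- cell_material()
  pos <- rbind(c(0, 0), c(1, 0.01))  # node 2 displaced 10 nm in x
  anchors <- rbind(c(0, 0), c(1, 0))
  vel <- rbind(c(0, 0), c(0, -2))
  bo <- body_forces(pos, vel, anchors, C = c(1, 1), A_trib = c(1, 1),
                    kin = kin, material = mat)
  expect_equal(bo$f_adh[1, ], c(0, 0))
  expect_equal(bo$f_drag[1, ], c(0, 0))
  ## 10 nm extension, C=1, A=1 um^2: |f_adh| = C*rho_max*A*kint*10 = 500 pN
  expect_equal(sqrt(sum(bo$f_adh[2, ]^2)), 1 * 100 * 1 * 0.5 * 10)
  expect_equal(bo$f_int[2], 0.5 * 10)
  ## drag antiparallel to velocity and linear in |v|
  expect_equal(bo$f_drag[2, ], -mat$drag_coeff * vel[2, ])
})

test_that("internal forces vanish on the undeformed mesh and sum to zero", {
  mesh <- gen_disk_mesh(5, 96)
  R0 <- assemble_internal_forces(mesh$nodes, mesh, mu_c = 1000, tmyo = 0)
  expect_lt(max(abs(R0)), 1e-9)
  cfg <- deformed_mesh_config()
  R <- assemble_internal_forces(cfg$pos, cfg$mesh, mu_c = 1000, tmyo = 150)
  expect_lt(max(abs(colSums(R))), 1e-9)  # partition of unity
})

test_that("one-element patch assembly matches hand-computed edge integrals", {
  ## unit right triangle, uniform deformation F = diag(1.08, 0.94)
  X <- rbind(c(0, 0), c(1, 0), c(0, 1))
  mesh <- cell_mesh(X, rbind(c(1, 2, 3)), boundary = 1:3)
  Fg <- diag(c(1.08, 0.94))
  pos <- X %*% t(Fg)
  tm <- 50
  R <- assemble_internal_forces(pos, mesh, mu_c = 1000, tmyo = tm)
  sig <- passive_stress(Fg, 1000) + tm * diag(2)
  ## for constant stress, the consistent nodal force on node a is
  ## -sum over the two adjacent edges of sigma * n_edge * L_edge / 2
  edge_int <- function(a, b) {  # outward normal integral of edge a->b
    e <- pos[b, ] - pos[a, ]
    n <- c(e[2], -e[1])  # outward for CCW loop
    n
  }
  hand <- matrix(0, 3, 2)
  loops <- rbind(c(1, 2), c(2, 3), c(3, 1))
  for (k in 1:3) {
    a <- loops[k, 1]; b <- loops[k, 2]
    contrib <- as.numeric(sig %*% edge_int(a, b)) / 2
    hand[a, ] <- hand[a, ] + contrib
    hand[b, ] <- hand[b, ] + contrib
  }
  ## R_a = -(external boundary traction equivalent) on a self-stressed patch
  expect_equal(R, hand, tolerance = 1e-9)
})

test_that("compiled force evaluation matches the R reference assembly", {
  cfg <- deformed_mesh_config()
  mesh <- cfg$mesh; pos <- cfg$pos; n <- cfg$n
  set.seed(5)
  C <- runif(n); xi <- runif(length(mesh$boundary))
  kin <- catch_bond_preset("wildtype")
  mat <- cell_material(actin_amp = 0.8, area_coeff = 2, kappa_coeff = 5)
  sys <- cell_system(mesh, mat, kin)
  tA <- tributary_areas(mesh)
  fcpp <- fe_core_forces(mesh$nodes, mesh$elements, mesh$boundary, tA,
                         pos, C, mesh$nodes, 1.3, xi,
                         c(unclass(mat), list(thickness = 1, A0 = sys$A0)),
                         unclass(kin),
                         list(use_adhesion = TRUE, use_active = TRUE,
                              ramp_rate = 100, plateau = 200))
  fr <- -assemble_internal_forces(pos, mesh, mat$mu_c, active_traction(1.3))
  bf <- boundary_forces(pos, mesh$boundary, mat, sys$A0, xi = xi)
  fr[mesh$boundary, ] <- fr[mesh$boundary, ] + bf$f_kappa + bf$f_ac + bf$f_A
  bo <- body_forces(pos, matrix(0, n, 2), mesh$nodes, C, tA, kin, mat)
  fr <- fr + bo$f_adh
  expect_equal(fcpp, fr, tolerance = 1e-10)
})

test_that("a quiescent state at equilibrium is a fixed point of the stepper", {
  mesh <- gen_disk_mesh(4, 96)
  sys <- cell_system(mesh, cell_material(actin_amp = 0, kappa_coeff = 0),
                     use_active = FALSE)
  st <- cell_state_init(sys)
  out <- step_cell(sys, st, dt = 50e-6, n_steps = 50)
  expect_equal(out$state$positions, st$positions)
  expect_equal(out$state$C, st$C)
  expect_equal(max(abs(out$state$velocities)), 0)
})

test_that("the midpoint integrator tracks a harmonic oscillator for 10 periods", {
  ## rigid translation of a one-element patch on frozen adhesion springs:
  ## no elastic restoring force, every node oscillates about its anchor
  X <- rbind(c(0, 0), c(1, 0), c(0, 1))
  mesh <- cell_mesh(X, rbind(c(1, 2, 3)), boundary = 1:3)
  kin <- frozen_bond_params()
  mat <- cell_material(drag_coeff = 0, kappa_coeff = 0, area_coeff = 0,
                       actin_amp = 0, density_scale = 1e6)
  sys <- cell_system(mesh, mat, kin, use_active = FALSE)
  st <- cell_state_init(sys, C0 = 1)
  d0 <- 0.05
  st$positions <- st$positions + cbind(rep(d0, 3), 0)
  omega <- sqrt(kin$rho_max * kin$kint * 1e3 /
                  (mat$rho_c * 1 * 1e-12 * mat$density_scale))
  period <- 2 * pi / omega
  dt <- period / 200
  xs <- numeric(2000)
  for (i in 1:2000) {
    out <- step_cell(sys, st, dt = dt, n_steps = 1)
    st <- out$state
    xs[i] <- st$positions[1, 1]
  }
  analytic <- d0 * cos(omega * (1:2000) * dt)
  rms_rel <- sqrt(mean((xs - analytic)^2)) / (d0 / sqrt(2))
  expect_lt(rms_rel, 0.01)
})

test_that("free contraction reaches the analytic plane-stress stretch", {
  fc <- free_contraction_benchmark(radius = 5, target_elements = 216,
                                   t_sim = 3.5)
  expect_lt(fc$rel_error, 0.01)
  expect_lt(fc$lambda_exact, 1)
})

test_that("momentum is conserved without body or boundary forces", {
  cfg <- deformed_mesh_config()
  mesh <- cfg$mesh
  ## undamped run: raise the mass scaling so the undamped midpoint rule
  ## stays in its stability region for the whole window
  mat <- cell_material(drag_coeff = 0, kappa_coeff = 0, area_coeff = 0,
                       actin_amp = 0, density_scale = 1e6)
  sys <- cell_system(mesh, mat, use_adhesion = FALSE)
  tA <- tributary_areas(mesh)
  f <- fe_core_forces(mesh$nodes, mesh$elements, mesh$boundary, tA,
                      cfg$pos, rep(0.5, cfg$n), mesh$nodes, 1.0,
                      numeric(length(mesh$boundary)),
                      c(unclass(mat), list(thickness = 1, A0 = sys$A0)),
                      unclass(catch_bond_preset("wildtype")),
                      list(use_adhesion = FALSE, use_active = TRUE,
                           ramp_rate = 100, plateau = 200))
  expect_lt(max(abs(colSums(f))), 1e-8)
  ## and the centre of mass stays put over many steps
  st <- cell_state_init(sys)
  out <- step_cell(sys, st, dt = 50e-6, n_steps = 4000)
  com0 <- node_com(mesh, st$positions)
  com1 <- node_com(mesh, out$state$positions)
  expect_equal(com1, com0, tolerance = 1e-10)
})

test_that("without contraction the bond field relaxes to a uniform kinetic fixed point", {
  mesh <- gen_disk_mesh(4, 96)
  kin <- catch_bond_preset("wildtype")
  sys <- cell_system(mesh, cell_material(actin_amp = 0, kappa_coeff = 0),
                     kin, use_active = FALSE)
  st <- cell_state_init(sys, C0 = 0.9)
  out <- step_cell(sys, st, dt = 50e-6, n_steps = 80000)
  Cstar <- equilibrium_concentration(0, kin)
  expect_equal(out$state$C, rep(Cstar, nrow(mesh$nodes)), tolerance = 2e-4)
  expect_lt(diff(range(out$state$C)), 1e-12)  # uniform field
})

test_that("bond concentrations stay within [0,1] at every node and save point", {
  mesh <- gen_disk_mesh(6, 150)
  sys <- cell_system(mesh, cell_material(), catch_bond_preset("mutant_R1374_9A"))
  set.seed(1)
  st <- cell_state_init(sys)
  out <- step_cell(sys, st, dt = 50e-6, n_steps = 60000, save_every = 2000,
                   record_fields = TRUE)
  expect_true(all(out$C_fields >= 0 & out$C_fields <= 1))
})

test_that("contraction localizes concentration and force at the cell periphery", {
  mesh <- gen_disk_mesh(10, 216)
  sys <- cell_system(mesh, cell_material(), catch_bond_preset("wildtype"))
  set.seed(2)
  st <- cell_state_init(sys)
  out <- step_cell(sys, st, dt = 50e-6, n_steps = 120000, save_every = 120000,
                   record_fields = TRUE)
  b <- mesh$boundary
  interior <- setdiff(seq_len(nrow(mesh$nodes)), b)
  lastC <- out$C_fields[nrow(out$C_fields), ]
  lastf <- out$f_fields[nrow(out$f_fields), ]
  expect_gte(max(lastC[b]), max(lastC[interior]))
  expect_gte(max(lastf[b]), max(lastf[interior]))
})

test_that("halving the time step leaves the concentration trace unchanged to <0.5%", {
  run_at <- function(dt) {
    mesh <- gen_disk_mesh(6, 216)
    sys <- cell_system(mesh, cell_material(actin_amp = 0),
                       catch_bond_preset("wildtype"))
    st <- cell_state_init(sys)
    step_cell(sys, st, dt = dt, n_steps = round(3 / dt),
              save_every = round(0.1 / dt))$trace
  }
  a <- run_at(50e-6)
  b <- run_at(25e-6)
  expect_equal(a$time, b$time, tolerance = 1e-9)
  expect_lt(max(abs(a$mean_C - b$mean_C) / a$mean_C), 0.005)
})

test_that("unstable configurations abort with a diagnostic instead of returning garbage", {
  mesh <- gen_disk_mesh(4, 96)
  sys <- cell_system(mesh, cell_material(actin_amp = 0))
  st <- cell_state_init(sys, C0 = 1)
  expect_error(step_cell(sys, st, dt = 0.05, n_steps = 5000),
               "reduce dt|inversion|blow-up")
  ## inverted element is reported with its id
  cfg <- deformed_mesh_config()
  bad <- cfg$pos
  bad[cfg$mesh$elements[1, 1], ] <- colMeans(bad[cfg$mesh$elements[1, 2:3], ]) +
    c(10, 10)
  expect_error(assemble_internal_forces(bad, cfg$mesh, 1000), "element")
})

test_that("replicate simulations average the summary channels and emit a manifest-ready config", {
  cfgl <- list(mesh = list(radius = 5, target_elements = 96),
               kinetics = "wildtype",
               run = list(t_sim = 0.5, seeds = c(1, 2), record_fields = FALSE))
  sim <- run_simulation(cfgl)
  expect_s3_class(sim, "cell_sim")
  expect_length(sim$traces, 2)
  expect_equal(sim$average$mean_C,
               (sim$traces[[1]]$mean_C + sim$traces[[2]]$mean_C) / 2)
  expect_error(run_simulation(list(run = list(seeds = c(1, 1)))), "unique")
})
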
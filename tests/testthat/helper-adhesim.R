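## shared fixtures built in code

## random catch-regime parameter draws (Kb*Fa > Ka*Fb guaranteed)
random_catch_params <- function() {
  Fa <- runif(1, 5, 30)
  Fb <- runif(1, 2, 15)
  Ka <- runif(1, 0.005, 0.1)
  ## force the catch condition with a margin so f* is interior
  Kb <- runif(1, 2, 50) * Ka * Fb / Fa
  catch_bond_params(Kon = runif(1, 0.1, 5), Ka = Ka, Fa = Fa,
                    Kb = Kb, Fb = Fb)
}

## a small deformed configuration for force-assembly tests
deformed_mesh_config <- function(radius = 5, elements = 96, seed = 7,
                                 squeeze = 0.97, wobble = 0.01) {
  set.seed(seed)
  mesh <- gen_disk_mesh(radius, elements)
  n <- nrow(mesh$nodes)
  pos <- mesh$nodes * squeeze + matrix(rnorm(2 * n, 0, wobble), n, 2)
  list(mesh = mesh, pos = pos, n = n)
}

## direct access to the compiled single force evaluation (internal)
fe_core_forces <- function(...) adhesim:::fe_core_forces(...)

## shoelace area of a closed polygon given as ordered vertices
polygon_area_ref <- function(p) {
  n <- nrow(p); j <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

## tributary-area-weighted centre of mass of the mesh nodes
node_com <- function(mesh, pos) {
  w <- tributary_areas(mesh)
  colSums(pos * w) / sum(w)
}

## kinetics that freeze the bond field at C = 1 (negligible on/off rates)
frozen_bond_params <- function(kint = 0.5, rho_max = 100) {
  catch_bond_params(Kon = 1, Ka = 1e-12, Fa = 10, Kb = 1e-12, Fb = 5,
                    kint = kint, rho_max = rho_max)
}
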
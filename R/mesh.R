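## Fixed-topology triangulated disk meshes for the whole-cell model.
## Polar layout: ring k (k = 1..nr) carries 6k nodes at radius R*k/nr, which
## keeps radial and tangential spacing within ~5% of each other everywhere,
## so all triangles are near-equilateral without any mesh optimisation.

#' Construct and validate a cell mesh
#'
#' @param nodes N x 2 matrix of node coordinates (um).
#' @param elements M x 3 integer matrix of triangle connectivity (1-based,
#'   positively oriented).
#' @param boundary ordered, closed counterclockwise loop of boundary node
#'   indices (first index not repeated at the end).
#' @param thickness out-of-plane depth (um), default 1.
#' @return object of class `cell_mesh`.
#' @export
cell_mesh <- function(nodes, elements, boundary, thickness = 1) {
  nodes <- as.matrix(nodes)
  elements <- matrix(as.integer(as.matrix(elements)), ncol = 3)
  boundary <- as.integer(boundary)
  stopifnot(ncol(nodes) == 2, all(is.finite(nodes)), thickness > 0)
  if (any(elements < 1L) || any(elements > nrow(nodes)))
    stop("element connectivity out of range")
  ar <- element_areas(nodes, elements)
  if (any(ar <= 0))
    stop("elements must be positively oriented and non-degenerate; bad: ",
         paste(which(ar <= 0), collapse = ", "))
  if (length(boundary) < 3) stop("boundary loop needs at least 3 nodes")
  if (anyDuplicated(boundary)) stop("boundary loop must not repeat nodes")
  structure(list(nodes = nodes, elements = elements, boundary = boundary,
                 thickness = thickness),
            class = "cell_mesh")
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("Cell mesh: %d nodes, %d triangles, %d boundary nodes, area %.4g um^2\n",
              nrow(x$nodes), nrow(x$elements), length(x$boundary),
              sum(element_areas(x$nodes, x$elements))))
  invisible(x)
}

#' Signed triangle areas
#'
#' @param nodes N x 2 coordinates; @param elements M x 3 connectivity.
#' @return vector of signed areas (positive for counterclockwise triangles).
#' @export
element_areas <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE]
  c <- nodes[elements[, 3], , drop = FALSE]
  0.5 * ((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
}

#' Nodal tributary areas (one third of each adjacent triangle)
#'
#' Used both for lumped masses and as the local adhesion area per node.
#'
#' @param mesh `cell_mesh`.
#' @return numeric vector of length `nrow(mesh$nodes)` (um^2).
#' @export
tributary_areas <- function(mesh) {
  ar <- element_areas(mesh$nodes, mesh$elements)
  out <- numeric(nrow(mesh$nodes))
  for (j in 1:3) {
    idx <- mesh$elements[, j]
    contrib <- ar / 3
    out <- out + as.vector(tapply(contrib, factor(idx, levels = seq_along(out)),
                                  sum, default = 0))
  }
  out[is.na(out)] <- 0
  out
}

#' Triangle quality (inradius / circumradius ratio)
#'
#' 0.5 for an equilateral triangle, -> 0 for slivers.
#'
#' @param mesh `cell_mesh`.
#' @return quality per element in (0, 0.5].
#' @export
mesh_quality <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elements
  la <- sqrt(rowSums((n[e[, 2], ] - n[e[, 3], ])^2))
  lb <- sqrt(rowSums((n[e[, 3], ] - n[e[, 1], ])^2))
  lc <- sqrt(rowSums((n[e[, 1], ] - n[e[, 2], ])^2))
  ar <- abs(element_areas(n, e))
  s <- (la + lb + lc) / 2
  r_in <- ar / s
  r_circ <- la * lb * lc / (4 * ar)
  r_in / r_circ
}

#' Generate a triangulated disk mesh
#'
#' Concentric-ring triangulation of a disk centred at the origin: ring `k`
#' holds `6k` nodes, giving `6*nr^2` near-equilateral triangles for `nr`
#' rings. The outer ring is returned as the (counterclockwise) boundary loop.
#'
#' @param radius disk radius (um), > 0.
#' @param target_elements requested element count (>= 16); the realised count
#'   is the nearest `6*nr^2`.
#' @return `cell_mesh`.
#' @export
gen_disk_mesh <- function(radius = 10, target_elements = 400) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(target_elements) || target_elements < 16)
    stop("target_elements must be >= 16")
  nr <- max(2L, as.integer(round(sqrt(target_elements / 6))))

  ring_idx <- vector("list", nr + 1)
  nodes <- matrix(0, nrow = 1, ncol = 2)  # centre node
  ring_idx[[1]] <- 1L
  for (k in 1:nr) {
    nk <- 6L * k
    th <- 2 * pi * (seq_len(nk) - 1L) / nk
    ring_idx[[k + 1]] <- nrow(nodes) + seq_len(nk)
    nodes <- rbind(nodes, radius * k / nr * cbind(cos(th), sin(th)))
  }

  tris <- vector("list", nr)
  ## central fan
  out1 <- ring_idx[[2]]
  tris[[1]] <- cbind(1L, out1, c(out1[-1], out1[1]))
  ## annuli: merge inner (n1 nodes) and outer (n2 nodes) rings by angle sweep
  for (k in 2:nr) {
    inner <- ring_idx[[k]]; outer <- ring_idx[[k + 1]]
    n1 <- length(inner); n2 <- length(outer)
    tri <- matrix(0L, nrow = n1 + n2, ncol = 3)
    ci <- 0L; cj <- 0L; m <- 0L
    while (ci < n1 || cj < n2) {
      adv_outer <- cj < n2 && (ci == n1 || (cj + 1) / n2 <= (ci + 1) / n1)
      m <- m + 1L
      if (adv_outer) {
        tri[m, ] <- c(inner[ci %% n1 + 1L], outer[cj %% n2 + 1L],
                      outer[(cj + 1L) %% n2 + 1L])
        cj <- cj + 1L
      } else {
        tri[m, ] <- c(inner[ci %% n1 + 1L], outer[cj %% n2 + 1L],
                      inner[(ci + 1L) %% n1 + 1L])
        ci <- ci + 1L
      }
    }
    tris[[k]] <- tri
  }
  elements <- do.call(rbind, tris)
  ## enforce positive orientation (construction should already give it)
  ar <- element_areas(nodes, elements)
  flip <- ar < 0
  if (any(flip)) elements[flip, c(2, 3)] <- elements[flip, c(3, 2)]
  cell_mesh(nodes, elements, boundary = ring_idx[[nr + 1]])
}
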
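#' Toy molecular structure
#'
#' Minimal structure container for the trajectory metrics: 3D coordinates in
#' nm, per-atom masses (amu), partial charges (e), residue ids, hydrogen-bond
#' role labels and explicit donor-hydrogen bonding.
#'
#' @param coords N x 3 coordinates (nm).
#' @param masses per-atom masses (amu), positive.
#' @param charges per-atom partial charges (e).
#' @param residue_id integer residue id per atom.
#' @param role per-atom role: one of `"none"`, `"donor"`, `"hydrogen"`,
#'   `"acceptor"`.
#' @param dh_pairs matrix with columns `hydrogen`, `donor` (atom indices);
#'   every hydrogen must appear exactly once.
#' @return object of class `toy_structure`.
#' @export
toy_structure <- function(coords, masses = NULL, charges = NULL,
                          residue_id = NULL, role = NULL, dh_pairs = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (is.null(masses)) masses <- rep(12, n)
  if (is.null(charges)) charges <- rep(0, n)
  if (is.null(residue_id)) residue_id <- rep(1L, n)
  if (is.null(role)) role <- rep("none", n)
  if (length(masses) != n || length(charges) != n ||
      length(residue_id) != n || length(role) != n)
    stop("per-atom fields must match the number of atoms")
  if (any(masses <= 0)) stop("masses must be positive")
  if (!all(role %in% valid_roles))
    stop("unknown role string(s): ",
         paste(unique(setdiff(role, valid_roles)), collapse = ", "))
  if (is.null(dh_pairs))
    dh_pairs <- matrix(integer(0), ncol = 2,
                       dimnames = list(NULL, c("hydrogen", "donor")))
  dh_pairs <- as.matrix(dh_pairs)
  colnames(dh_pairs) <- c("hydrogen", "donor")
  hyd <- which(role == "hydrogen")
  cnt <- table(factor(dh_pairs[, "hydrogen"], levels = hyd))
  if (length(hyd) && any(cnt != 1))
    stop("every hydrogen must have exactly one donor; offending atom(s): ",
         paste(hyd[cnt != 1], collapse = ", "))
  structure(list(coords = coords, masses = as.numeric(masses),
                 charges = as.numeric(charges),
                 residue_id = as.integer(residue_id),
                 role = role, dh_pairs = dh_pairs),
            class = "toy_structure")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat(sprintf("Toy structure: %d atoms, %d residues, %d donor-H pairs, %d acceptors\n",
              nrow(x$coords), length(unique(x$residue_id)),
              nrow(x$dh_pairs), sum(x$role == "acceptor")))
  invisible(x)
}
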
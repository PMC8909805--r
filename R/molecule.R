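#' Construct a posed 3D molecule
#'
#' A light container for one posed conformer: atoms (element symbol, formal
#' charge, aromatic flag), bonds (atom indices and order; order 4 denotes an
#' aromatic bond, SDF convention) and Cartesian coordinates in Angstrom.
#' Conformers of the same library molecule share a `mol_id` and are told
#' apart by `conf_id`.
#'
#' @param mol_id Molecule identifier (string).
#' @param conf_id Conformer index, integer >= 0.
#' @param atoms data.frame with columns `element` (symbol), and optionally
#'   `charge` (formal charge, default 0) and `aromatic` (logical; if absent,
#'   derived from membership in an order-4 bond).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3 or 4 = aromatic). May have zero rows.
#' @param coords Numeric matrix, one row per atom, columns x/y/z (A).
#' @return An object of class `molecule3d`.
#' @export
molecule3d <- function(mol_id, conf_id = 0L, atoms, bonds, coords) {
  if (!is.data.frame(atoms) || nrow(atoms) < 1L) {
    stop("molecule needs at least one atom", call. = FALSE)
  }
  n <- nrow(atoms)
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || nrow(coords) != n || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix matching the atom count",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("molecule has missing or non-finite coordinates", call. = FALSE)
  }
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.integer(bonds$order))
  if (nrow(bonds)) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("bond indices out of range", call. = FALSE)
    }
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed",
                                      call. = FALSE)
  }
  a <- data.frame(
    element = as.character(atoms$element),
    charge = if ("charge" %in% names(atoms)) as.integer(atoms$charge)
             else 0L,
    stringsAsFactors = FALSE
  )
  if ("aromatic" %in% names(atoms)) {
    a$aromatic <- as.logical(atoms$aromatic)
  } else {
    arom <- rep(FALSE, n)
    if (nrow(bonds)) {
      ab <- bonds[bonds$order == 4L, , drop = FALSE]
      arom[unique(c(ab$i, ab$j))] <- TRUE
    }
    a$aromatic <- arom
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(mol_id = as.character(mol_id)[1], conf_id = as.integer(conf_id),
         atoms = a, bonds = bonds, coords = coords),
    class = "molecule3d"
  )
}

#' @export
print.molecule3d <- function(x, ...) {
  cat("molecule3d", x$mol_id, "conf", x$conf_id, "--",
      nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule3d`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# adjacency list over heavy bonds (all bonds; hydrogens included)
mol_neighbors <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$i[k]]] <- c(nb[[b$i[k]]], b$j[k])
    nb[[b$j[k]]] <- c(nb[[b$j[k]]], b$i[k])
  }
  nb
}

# implicit hydrogen count from default valences (N:3, O:2, adjusted by
# formal charge); aromatic bonds count 1.5 with the total rounded up.
implicit_h <- function(mol) {
  n <- n_atoms(mol)
  used <- numeric(n)
  b <- mol$bonds
  if (nrow(b)) {
    ord <- ifelse(b$order == 4L, 1.5, b$order)
    for (k in seq_len(nrow(b))) {
      used[b$i[k]] <- used[b$i[k]] + ord[k]
      used[b$j[k]] <- used[b$j[k]] + ord[k]
    }
  }
  el <- mol$atoms$element
  defval <- ifelse(el == "N", 3L, ifelse(el == "O", 2L, NA_integer_)) +
    mol$atoms$charge
  h <- defval - ceiling(used)
  h[is.na(h)] <- 0L
  pmax(0L, h)
}

#' Apply a rigid transform to a molecule's coordinates
#'
#' @param mol A `molecule3d`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 numeric vector (A).
#' @return A `molecule3d` with transformed coordinates.
#' @export
transform_molecule <- function(mol, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  stopifnot(inherits(mol, "molecule3d"))
  mol$coords <- sweep(mol$coords %*% t(rotation), 2, -translation)
  mol
}
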
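#' Perceive pharmacophore features on a posed molecule
#'
#' Detects candidate interaction points of the four kinds used by the
#' matcher, with purely rule-based typing:
#'
#' * **aromatic** -- every smallest ring (5 or 6 atoms) whose atoms are all
#'   aromatic-flagged; the feature point is the unweighted ring centroid.
#' * **donor** -- every N or O bearing at least one hydrogen (an explicit H
#'   neighbour, or implicit hydrogens inferred from default valence); the
#'   point sits on the heavy atom.
#' * **acceptor** -- every O without positive formal charge, and every N
#'   without positive charge that carries no hydrogen and is not an amide
#'   nitrogen (i.e. not bonded to a carbonyl carbon); point on the heavy
#'   atom. Pyridine-type ring nitrogens qualify.
#' * **hydrophobic** -- every connected component of three or more
#'   non-aromatic carbons none of which touches a heteroatom (centroid of
#'   the component), plus each methyl carbon hanging off an aromatic ring
#'   as a one-atom point.
#'
#' No directional information (ring normals, lone-pair projections) is
#' attached: the matcher uses spherical distance tolerances only. An atom
#' may contribute to features of different kinds (a hydroxyl oxygen is both
#' donor and acceptor), but aromatic ring carbons never also count as
#' hydrophobic. Perception is deterministic and equivariant: rigidly
#' transforming the coordinates rigidly transforms every centroid.
#'
#' @param mol A [molecule3d()].
#' @return A data.frame of class `detected_features` with columns `kind`,
#'   `x`, `y`, `z` (centroid, A) and `atoms` (list column of contributing
#'   1-based atom indices), ordered by kind then by smallest atom index.
#' @seealso [feature_census()], [match_pose()]
#' @export
perceive_features <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  nb <- mol_neighbors(mol)
  el <- mol$atoms$element
  arom <- mol$atoms$aromatic
  chg <- mol$atoms$charge
  xyz <- mol$coords
  ih <- implicit_h(mol)
  has_explicit_h <- vapply(nb, function(v) any(el[v] == "H"), logical(1))

  feats <- list()
  add <- function(kind, idx) {
    ctr <- colMeans(xyz[idx, , drop = FALSE])
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, x = ctr[1], y = ctr[2], z = ctr[3],
      atoms = I(list(sort(as.integer(idx)))), stringsAsFactors = FALSE)
  }

  # aromatic rings (smallest rings, 5- or 6-membered, all atoms flagged)
  for (ring in aromatic_rings(mol)) add("aromatic", ring)

  # donors: N/O with explicit or implicit H
  don <- which(el %in% c("N", "O") & (has_explicit_h | ih > 0L))
  for (i in don) add("donor", i)

  # acceptors: O (charge <= 0); N (charge <= 0, no H, not amide)
  carbonyl_c <- carbonyl_carbons(mol)
  acc <- vapply(seq_along(el), function(i) {
    if (chg[i] > 0L) return(FALSE)
    if (el[i] == "O") return(TRUE)
    if (el[i] != "N") return(FALSE)
    if (has_explicit_h[i] || ih[i] > 0L) return(FALSE)
    !any(nb[[i]] %in% carbonyl_c)
  }, logical(1))
  for (i in which(acc)) add("acceptor", i)

  # hydrophobic: components of >=3 clean aliphatic carbons
  hetero <- !(el %in% c("C", "H"))
  clean_c <- el == "C" & !arom &
    !vapply(nb, function(v) any(hetero[v]), logical(1))
  for (comp in carbon_components(mol, clean_c)) {
    if (length(comp) >= 3L) add("hydrophobic", comp)
  }
  # methyl substituents on aromatic rings: one-atom points
  for (i in which(clean_c)) {
    heavy_nb <- nb[[i]][el[nb[[i]]] != "H"]
    if (length(heavy_nb) == 1L && arom[heavy_nb]) add("hydrophobic", i)
  }

  out <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(), x = numeric(), y = numeric(),
               z = numeric(), atoms = I(list()))
  first_atom <- vapply(out$atoms, function(a) a[1], numeric(1))
  out <- out[order(match(out$kind, feature_kinds()), first_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detected_features", "data.frame")
  out
}

#' Count perceived features per kind
#'
#' @param mol A [molecule3d()].
#' @return Named integer vector over all four kinds (zeros included); its
#'   sum equals the total feature count.
#' @export
feature_census <- function(mol) {
  f <- perceive_features(mol)
  tab <- table(factor(f$kind, levels = feature_kinds()))
  stats::setNames(as.integer(tab), feature_kinds())
}

# Smallest aromatic rings: for each bond between two aromatic-flagged atoms
# find the shortest cycle through it (BFS in the aromatic subgraph minus
# that bond); keep rings of 5 or 6 atoms, deduplicated by atom set.
aromatic_rings <- function(mol) {
  arom <- mol$atoms$aromatic
  b <- mol$bonds
  ab <- b[arom[b$i] & arom[b$j], , drop = FALSE]
  if (!nrow(ab)) return(list())
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(ab))) {
    adj[[ab$i[k]]] <- c(adj[[ab$i[k]]], ab$j[k])
    adj[[ab$j[k]]] <- c(adj[[ab$j[k]]], ab$i[k])
  }
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(ab))) {
    s <- ab$i[k]; t <- ab$j[k]
    # BFS from s to t avoiding the direct edge
    prev <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
    dist[s] <- 0L; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == t) break
      for (w in adj[[v]]) {
        if (v == s && w == t) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; prev[w] <- v; queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[t])) next
    path <- t
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    if (length(path) %in% c(5L, 6L)) {
      key <- paste(sort(path), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- sort(path)
      }
    }
  }
  rings
}

# carbons double-bonded to an oxygen (for the amide-nitrogen exclusion)
carbonyl_carbons <- function(mol) {
  b <- mol$bonds
  el <- mol$atoms$element
  dbl <- b[b$order == 2L, , drop = FALSE]
  cc <- integer()
  for (k in seq_len(nrow(dbl))) {
    if (el[dbl$i[k]] == "C" && el[dbl$j[k]] == "O") cc <- c(cc, dbl$i[k])
    if (el[dbl$j[k]] == "C" && el[dbl$i[k]] == "O") cc <- c(cc, dbl$j[k])
  }
  unique(cc)
}

# connected components (via bonds) restricted to atoms flagged in `keep`
carbon_components <- function(mol, keep) {
  idx <- which(keep)
  if (!length(idx)) return(list())
  comp <- stats::setNames(seq_along(idx), idx)  # union-find by relabel
  b <- mol$bonds
  bb <- b[keep[b$i] & keep[b$j], , drop = FALSE]
  lab <- comp
  for (k in seq_len(nrow(bb))) {
    li <- lab[as.character(bb$i[k])]; lj <- lab[as.character(bb$j[k])]
    if (li != lj) lab[lab == lj] <- li
  }
  unname(lapply(split(idx, lab), sort))
}

#' Write a feature table to TSV
#'
#' One row per detected feature: `mol_id`, `conf_id`, `kind`, `x`, `y`,
#' `z`, `atom_indices` (comma-separated, 1-based).
#'
#' @param mols A list of [molecule3d()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(mols, path) {
  rows <- lapply(mols, function(m) {
    f <- perceive_features(m)
    if (!nrow(f)) return(NULL)
    data.frame(mol_id = m$mol_id, conf_id = m$conf_id, kind = f$kind,
               x = f$x, y = f$y, z = f$z,
               atom_indices = vapply(f$atoms, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
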
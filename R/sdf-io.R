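#' @importClassesFrom ChemmineR SDF SDFset
NULL

# SDF (V2000) reading/writing, delegated to ChemmineR. Conformers of one
# library molecule are repeated SDF records sharing a MOL_ID property field
# (grouping is by property, never by record adjacency); CONF_ID carries the
# conformer index. Old-style atom-block charge codes are honoured.

charge_from_code <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
           `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

charge_to_code <- function(charge) {
  map <- c(`0` = 0L, `3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L,
           `-3` = 7L)
  out <- map[as.character(charge)]
  if (any(is.na(out))) stop("formal charge outside [-3, 3] not representable",
                            call. = FALSE)
  unname(out)
}

#' Read a multi-conformer library from an SDF file
#'
#' Reads a V2000 SDF and returns one [molecule3d()] per record. Molecule and
#' conformer identity come from the `MOL_ID` and `CONF_ID` property fields
#' when present; records lacking them fall back to the record title and a
#' within-file counter. Atom aromaticity is derived from order-4 (aromatic)
#' bonds.
#'
#' @param path Path to an SDF file.
#' @return A list of `molecule3d` objects, in file order.
#' @seealso [write_sdf_library()], [screen_library()]
#' @export
read_sdf_library <- function(path) {
  if (!file.exists(path)) stop("SDF file not found: ", path, call. = FALSE)
  sset <- ChemmineR::read.SDFset(path)
  if (length(sset) == 0L) stop("no molecules in SDF: ", path, call. = FALSE)
  out <- vector("list", length(sset))
  for (k in seq_along(sset)) {
    sdf <- sset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_[0-9]+$", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    chg <- if ("C6" %in% colnames(ab)) charge_from_code(ab[, "C6"])
           else rep(0L, nrow(ab))
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) NULL else
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    db <- ChemmineR::datablock(sdf)
    mol_id <- if ("MOL_ID" %in% names(db)) unname(db[["MOL_ID"]])
              else ChemmineR::header(sdf)[["Molecule_Name"]]
    conf_id <- if ("CONF_ID" %in% names(db))
                 as.integer(db[["CONF_ID"]]) else k - 1L
    out[[k]] <- molecule3d(
      mol_id = mol_id, conf_id = conf_id,
      atoms = data.frame(element = el, charge = chg,
                         stringsAsFactors = FALSE),
      bonds = bonds, coords = coords)
  }
  out
}

#' Write a conformer library to an SDF file
#'
#' One V2000 record per conformer, with `MOL_ID` and `CONF_ID` property
#' fields. Coordinates are written to 4 decimal places (0.1 mA), the
#' resolution of the fixed-width SDF atom block.
#'
#' @param mols A list of [molecule3d()] objects.
#' @param path Output SDF path.
#' @return `path`, invisibly.
#' @export
write_sdf_library <- function(mols, path) {
  stopifnot(length(mols) >= 1L)
  sdfs <- lapply(mols, function(m) {
    n <- n_atoms(m)
    nb <- nrow(m$bonds)
    ab <- matrix(0, nrow = n, ncol = 15)
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    rownames(ab) <- paste(m$atoms$element, seq_len(n), sep = "_")
    ab[, 1:3] <- round(m$coords, 4)
    ab[, "C6"] <- charge_to_code(m$atoms$charge)
    bb <- matrix(0L, nrow = nb, ncol = 7)
    colnames(bb) <- paste0("C", 1:7)
    if (nb) {
      rownames(bb) <- seq_len(nb)
      bb[, 1] <- m$bonds$i; bb[, 2] <- m$bonds$j; bb[, 3] <- m$bonds$order
    }
    hdr <- c(Molecule_Name = m$mol_id, Source = "  pharmscreen",
             Comment = "",
             Counts_Line = sprintf(
               "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    methods::new("SDF", header = hdr, atomblock = ab, bondblock = bb,
                 datablock = c(MOL_ID = m$mol_id,
                               CONF_ID = as.character(m$conf_id)))
  })
  ids <- vapply(mols, function(m) paste0(m$mol_id, "_c", m$conf_id), "")
  sset <- methods::new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(sset, path)
  invisible(path)
}
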
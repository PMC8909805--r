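#' Pharmacophore feature kinds
#'
#' The four feature kinds used throughout the package. Aromatic and
#' hydrophobic queries are mutually compatible during matching (an aromatic
#' ring may occupy a hydrophobic query and vice versa); donor and acceptor
#' queries are each satisfied only by features of their own kind.
#'
#' @return Character vector of the four kind names.
#' @export
feature_kinds <- function() {
  c("aromatic", "hydrophobic", "donor", "acceptor")
}

#' Default distance tolerance for a feature kind
#'
#' Polar queries (donor, acceptor) default to a 2.0 A tolerance sphere;
#' hydrophobic and aromatic queries default to 2.5 A.
#'
#' @param kind Character vector of feature kinds.
#' @return Numeric vector of tolerances in Angstrom.
#' @export
default_tolerance <- function(kind) {
  stopifnot(all(kind %in% feature_kinds()))
  ifelse(kind %in% c("donor", "acceptor"), 2.0, 2.5)
}

#' Are two feature kinds compatible for matching?
#'
#' @param a,b Character vectors of feature kinds (recycled).
#' @return Logical vector.
#' @export
kinds_compatible <- function(a, b) {
  stopifnot(all(a %in% feature_kinds()), all(b %in% feature_kinds()))
  greasy <- c("aromatic", "hydrophobic")
  a == b | (a %in% greasy & b %in% greasy)
}

#' Construct a pharmacophore model
#'
#' A pharmacophore model is an ordered set of typed point queries, each with
#' a position (A), a spherical distance tolerance (A) and a required flag,
#' plus a minimum-match count: a pose is accepted only if at least
#' `min_match` queries are matched and every required ("must-have") query is
#' among them.
#'
#' @param name Model name.
#' @param queries A data.frame with columns `id` (unique short strings),
#'   `kind` (one of [feature_kinds()]), `x`, `y`, `z` (A), and optionally
#'   `tolerance` (A; `NA` entries take the kind default) and `required`
#'   (logical; default `FALSE`).
#' @param min_match Minimum number of matched queries for acceptance
#'   (default 5).
#' @return An object of class `pharmacophore_model`.
#' @seealso [default_dvl1_model()], [read_pharmacophore()]
#' @export
pharmacophore_model <- function(name, queries, min_match = 5L) {
  if (!is.data.frame(queries)) {
    stop("`queries` must be a data.frame", call. = FALSE)
  }
  need <- c("id", "kind", "x", "y", "z")
  miss <- setdiff(need, names(queries))
  if (length(miss)) {
    stop("query table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(queries) == 0L) {
    stop("model has zero queries; an empty model cannot screen",
         call. = FALSE)
  }
  q <- data.frame(
    id = as.character(queries$id),
    kind = as.character(queries$kind),
    x = as.numeric(queries$x),
    y = as.numeric(queries$y),
    z = as.numeric(queries$z),
    tolerance = if ("tolerance" %in% names(queries))
      as.numeric(queries$tolerance) else NA_real_,
    required = if ("required" %in% names(queries))
      as.logical(queries$required) else FALSE,
    stringsAsFactors = FALSE
  )
  q$required[is.na(q$required)] <- FALSE
  bad_kind <- setdiff(unique(q$kind), feature_kinds())
  if (length(bad_kind)) {
    stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  q$tolerance[is.na(q$tolerance)] <- default_tolerance(q$kind[is.na(q$tolerance)])
  m <- structure(
    list(name = as.character(name)[1], queries = q,
         min_match = as.integer(min_match)),
    class = "pharmacophore_model"
  )
  validate_pharmacophore_model(m)
}

#' Validate a pharmacophore model
#'
#' Checks every structural invariant of the model: at least one query,
#' unique ids, known kinds, finite coordinates, positive tolerances and
#' `1 <= min_match <= n_queries`. Invalid models never escape construction
#' or loading.
#'
#' @param m A `pharmacophore_model`.
#' @return `m`, invisibly unchanged, or an error.
#' @export
validate_pharmacophore_model <- function(m) {
  if (!inherits(m, "pharmacophore_model")) {
    stop("not a pharmacophore_model", call. = FALSE)
  }
  q <- m$queries
  if (nrow(q) == 0L) {
    stop("model has zero queries; an empty model cannot screen", call. = FALSE)
  }
  if (anyDuplicated(q$id)) {
    stop("duplicate query id(s): ",
         paste(unique(q$id[duplicated(q$id)]), collapse = ", "), call. = FALSE)
  }
  if (!all(q$kind %in% feature_kinds())) {
    stop("unknown feature kind(s): ",
         paste(setdiff(q$kind, feature_kinds()), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(as.matrix(q[, c("x", "y", "z")])))) {
    stop("query positions must be finite", call. = FALSE)
  }
  if (!all(is.finite(q$tolerance)) || any(q$tolerance <= 0)) {
    stop("query tolerances must be positive and finite", call. = FALSE)
  }
  if (is.na(m$min_match) || m$min_match < 1L || m$min_match > nrow(q)) {
    stop("min_match must lie in [1, number of queries] (got ", m$min_match,
         " for ", nrow(q), " queries)", call. = FALSE)
  }
  invisible(m)
}

#' Query positions as a matrix
#' @param m A `pharmacophore_model`.
#' @return Numeric matrix, one row per query, columns x/y/z (A).
#' @export
query_positions <- function(m) {
  validate_pharmacophore_model(m)
  p <- as.matrix(m$queries[, c("x", "y", "z")])
  rownames(p) <- m$queries$id
  p
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("Pharmacophore model:", x$name, "\n")
  cat(" ", nrow(x$queries), "queries; min_match =", x$min_match, "\n")
  tab <- table(factor(x$queries$kind, levels = feature_kinds()))
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  req <- x$queries$id[x$queries$required]
  cat("  required:", if (length(req)) paste(req, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Read a pharmacophore model from JSON
#'
#' The file format is a JSON object
#' `{"name": str, "min_match": int, "queries": [...]}` where each query is
#' `{"id": str, "kind": "aromatic|hydrophobic|donor|acceptor",
#' "xyz": [x, y, z], "tolerance": num?, "required": bool?}`. Omitted
#' tolerances take the kind defaults (2.0 A polar, 2.5 A
#' hydrophobic/aromatic); omitted `min_match` defaults to 5; omitted
#' `required` defaults to false. The returned model has passed full
#' validation.
#'
#' @param path Path to a model JSON file.
#' @return A `pharmacophore_model`.
#' @seealso [write_pharmacophore()]
#' @export
read_pharmacophore <- function(path) {
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) {
                  stop("malformed model JSON in ", path, ": ",
                       conditionMessage(e), call. = FALSE)
                })
  if (!is.list(j) || is.null(j$queries)) {
    stop("model JSON must be an object with a 'queries' array", call. = FALSE)
  }
  if (length(j$queries) == 0L) {
    stop("model has zero queries; an empty model cannot screen", call. = FALSE)
  }
  rows <- lapply(j$queries, function(qq) {
    if (is.null(qq$id) || is.null(qq$kind) || is.null(qq$xyz) ||
        length(qq$xyz) != 3L) {
      stop("each query needs 'id', 'kind' and a 3-element 'xyz'",
           call. = FALSE)
    }
    data.frame(
      id = as.character(qq$id), kind = as.character(qq$kind),
      x = as.numeric(qq$xyz[[1]]), y = as.numeric(qq$xyz[[2]]),
      z = as.numeric(qq$xyz[[3]]),
      tolerance = if (is.null(qq$tolerance)) NA_real_
                  else as.numeric(qq$tolerance),
      required = isTRUE(qq$required),
      stringsAsFactors = FALSE
    )
  })
  pharmacophore_model(
    name = if (is.null(j$name)) tools::file_path_sans_ext(basename(path))
           else as.character(j$name),
    queries = do.call(rbind, rows),
    min_match = if (is.null(j$min_match)) 5L else as.integer(j$min_match)
  )
}

#' Write a pharmacophore model to JSON
#'
#' Inverse of [read_pharmacophore()]: `read_pharmacophore(write_pharmacophore(m, f))`
#' reproduces `m` (ids, kinds, flags exactly; positions and tolerances to
#' better than 1e-6 A).
#'
#' @param m A `pharmacophore_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(m, path) {
  validate_pharmacophore_model(m)
  q <- m$queries
  queries <- lapply(seq_len(nrow(q)), function(i) {
    list(id = q$id[i], kind = q$kind[i],
         xyz = c(q$x[i], q$y[i], q$z[i]),
         tolerance = q$tolerance[i], required = q$required[i])
  })
  jsonlite::write_json(
    list(name = m$name, min_match = m$min_match, queries = queries),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' The default DVL1 PDZ selectivity pharmacophore model
#'
#' The seven-query model used to screen for selective inhibitors of the
#' Dishevelled-1 (DVL1) PDZ domain: 3 aromatic queries (the peptide-groove
#' aromatic stack, including the arginine pi-cation contact region),
#' 2 hydrophobic queries, 1 hydrogen-bond donor (the indole-NH point) and
#' 1 hydrogen-bond acceptor (the carbonyl-oxygen point). Exactly one
#' hydrophobic query -- the sub-pocket lined by Leu12, Val75 and Ile81 that
#' distinguishes DVL1 from the NHERF1 PDZ -- is flagged `required`
#' ("must-have"): poses that fail to occupy it are rejected regardless of
#' how many other queries they match. Acceptance additionally demands at
#' least `min_match = 5` matched queries.
#'
#' Query coordinates are an idealized geometry in an arbitrary right-handed
#' Cartesian frame: no experimental structure of the model frame is
#' distributed, so anchor points are placed at chemically plausible mutual
#' separations (all pairwise distances at least 5.7 A, aromatic centroids
#' 6-7 A apart). The matcher's behaviour depends only on relative geometry,
#' never on the absolute frame.
#'
#' @return A `pharmacophore_model` with 7 queries and `min_match = 5`.
#' @export
default_dvl1_model <- function() {
  pharmacophore_model(
    name = "DVL1-PDZ-selectivity",
    queries = data.frame(
      id = c("A1", "A2", "A3", "H1", "H2", "D1", "X1"),
      kind = c("aromatic", "aromatic", "aromatic",
               "hydrophobic", "hydrophobic", "donor", "acceptor"),
      x = c(0.0, 6.5, 3.2,  3.2, 9.5, -3.0, 2.0),
      y = c(0.0, 0.0, 5.6,  1.9, 5.0,  4.2, -5.5),
      z = c(0.0, 0.0, 0.0,  4.8, 2.0,  2.5, 2.0),
      required = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    ),
    min_match = 5L
  )
}
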
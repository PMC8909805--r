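#' Screening configuration
#'
#' @param n_conformers_expected Conformers expected per molecule (default
#'   10, the docking protocol's conformer count). Molecules with fewer are
#'   screened anyway, with a warning.
#' @param top_n Shortlist size (default 500, the visual-inspection pool
#'   size of the original screen).
#' @param mode Matching mode, `"prealigned"` (default; poses are docked in
#'   the model frame) or `"align"`.
#' @param seed Integer seed for any stochastic sub-steps.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_conformers_expected = 10L, top_n = 500L,
                          mode = c("prealigned", "align"), seed = 1L) {
  mode <- match.arg(mode)
  n_conformers_expected <- as.integer(n_conformers_expected)
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  if (is.na(n_conformers_expected) || n_conformers_expected < 1L) {
    stop("n_conformers_expected must be >= 1", call. = FALSE)
  }
  structure(list(n_conformers_expected = n_conformers_expected,
                 top_n = top_n, mode = mode, seed = as.integer(seed)),
            class = "screen_config")
}

#' Screen a conformer library against a pharmacophore model
#'
#' The library screen: every conformer of every molecule is feature-
#' perceived and matched against the model; each molecule is represented by
#' its best-scoring conformer (ties broken by lower conformer id); a
#' molecule is accepted iff its best conformer is accepted (matches at
#' least `min_match` queries including every required one). Records are
#' sorted by fitness, descending, ties by `mol_id`; the `top_n`
#' best-fitting *accepted* molecules carry ranks 1..K without gaps,
#' everything else is unranked.
#'
#' @param sdf_path Path to a multi-conformer SDF (conformers grouped by the
#'   `MOL_ID` property field), or a list of [molecule3d()] objects.
#' @param model A [pharmacophore_model()].
#' @param config A [screen_config()].
#' @return A data.frame of class `screen_records` with columns `mol_id`,
#'   `best_conf_id`, `fitness`, `n_matched`, `accepted`, `rank` (`NA` when
#'   unranked), sorted by fitness. A `summary` attribute records totals
#'   (molecules, conformers, accepted, shortlisted).
#' @seealso [shortlist()], [generate_library()]
#' @export
screen_library <- function(sdf_path, model, config = screen_config()) {
  validate_pharmacophore_model(model)
  stopifnot(inherits(config, "screen_config"))
  mols <- if (is.character(sdf_path)) read_sdf_library(sdf_path) else sdf_path
  if (!length(mols)) stop("no conformers to screen", call. = FALSE)
  ids <- vapply(mols, function(m) m$mol_id, "")
  groups <- split(seq_along(mols), ids)

  short <- vapply(groups, length, 0L) < config$n_conformers_expected
  if (any(short)) {
    warning(sum(short), " molecule(s) have fewer than ",
            config$n_conformers_expected, " conformers; screened anyway",
            call. = FALSE)
  }

  rows <- lapply(names(groups), function(mid) {
    best <- NULL
    for (k in groups[[mid]]) {
      m <- mols[[k]]
      res <- match_pose(perceive_features(m), model, mode = config$mode,
                        mol_id = m$mol_id, conf_id = m$conf_id)
      if (is.null(best) || res$fitness > best$fitness ||
          (res$fitness == best$fitness && res$conf_id < best$conf_id)) {
        best <- res
      }
    }
    data.frame(mol_id = mid, best_conf_id = best$conf_id,
               fitness = best$fitness, n_matched = best$n_matched,
               accepted = best$accepted, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec <- rec[order(-rec$fitness, rec$mol_id), , drop = FALSE]
  rec$rank <- NA_integer_
  acc <- which(rec$accepted)
  ranked <- acc[seq_len(min(length(acc), config$top_n))]
  rec$rank[ranked] <- seq_along(ranked)
  rownames(rec) <- NULL
  attr(rec, "summary") <- list(
    n_molecules = length(groups), n_conformers = length(mols),
    n_accepted = length(acc), n_shortlisted = length(ranked))
  class(rec) <- c("screen_records", "data.frame")
  rec
}

#' Extract the ranked shortlist from screening records
#'
#' The first `min(top_n, number accepted)` records: the best-fitting
#' accepted molecules, fitness non-increasing.
#'
#' @param records A `screen_records` table from [screen_library()].
#' @param top_n Maximum shortlist size (default 500).
#' @return The shortlisted subset of `records`.
#' @export
shortlist <- function(records, top_n = 500L) {
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  acc <- records[records$accepted, , drop = FALSE]
  out <- acc[seq_len(min(nrow(acc), top_n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write screening records to TSV
#'
#' @param records A `screen_records` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
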
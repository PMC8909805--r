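#' Specification for a planted-truth screening library
#'
#' Describes a synthetic conformer library with known ground truth:
#' `frac_active` of the molecules are actives constructed to satisfy the
#' acceptance rule of a given pharmacophore model, the rest are decoys each
#' violating it in one specific, recorded way. The default scale (200
#' molecules x 10 conformers) emulates the structure of a ~7000 x 10
#' docking screen at desk size.
#'
#' @param n_molecules Number of molecules (default 200).
#' @param n_conformers Conformers per molecule (default 10).
#' @param frac_active Fraction of actives in `[0, 1]` (default 0.25).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param jitter_sd Positional noise (A) applied to planted feature points,
#'   as an isotropic Gaussian truncated at 2 standard deviations so the
#'   planting margin `tolerance - 2 * jitter_sd` is a hard guarantee
#'   (default 0.15 A). Must be below half the smallest model tolerance.
#' @param decoy_modes Which failure modes to cycle through for decoys, a
#'   subset of `missing_required`, `too_few_features`,
#'   `displaced_beyond_tolerance`, `kind_mismatch` (default all four).
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_molecules = 200L, n_conformers = 10L,
                         frac_active = 0.25, seed = 1L, jitter_sd = 0.15,
                         decoy_modes = c("missing_required",
                                         "too_few_features",
                                         "displaced_beyond_tolerance",
                                         "kind_mismatch")) {
  all_modes <- c("missing_required", "too_few_features",
                 "displaced_beyond_tolerance", "kind_mismatch")
  decoy_modes <- match.arg(decoy_modes, all_modes, several.ok = TRUE)
  if (frac_active < 0 || frac_active > 1) {
    stop("frac_active must lie in [0, 1]", call. = FALSE)
  }
  if (jitter_sd < 0) stop("jitter_sd must be non-negative", call. = FALSE)
  if (n_conformers < 1L) stop("n_conformers must be >= 1", call. = FALSE)
  if (n_molecules < 1L) stop("n_molecules must be >= 1", call. = FALSE)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_conformers = as.integer(n_conformers),
                 frac_active = frac_active, seed = as.integer(seed),
                 jitter_sd = jitter_sd, decoy_modes = decoy_modes),
            class = "library_spec")
}

# --- fragment builders ---------------------------------------------------
# Minimal scaffolds chosen to trigger exactly one perception rule each:
# benzene ring (aromatic), propane patch (hydrophobic), amine N-H (donor),
# carbonyl C=O with the point on O (acceptor). Atom tables use the
# molecule3d layout; `at` is where the feature point must land.

frag_aromatic <- function(at, rot) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0) %*% t(rot)
  xyz <- sweep(xyz, 2, -at)
  list(atoms = data.frame(element = rep("C", 6), charge = 0L,
                          stringsAsFactors = FALSE),
       bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
       coords = xyz)
}

frag_hydrophobic <- function(at, rot) {
  base <- rbind(c(-1.27, -0.26, 0), c(0, 0.52, 0), c(1.27, -0.26, 0))
  xyz <- sweep(base %*% t(rot), 2, -at)
  list(atoms = data.frame(element = rep("C", 3), charge = 0L,
                          stringsAsFactors = FALSE),
       bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1L),
       coords = xyz)
}

frag_donor <- function(at, rot) {
  base <- rbind(c(0, 0, 0), c(1.01, 0, 0))  # N, H
  xyz <- sweep(base %*% t(rot), 2, -at)
  list(atoms = data.frame(element = c("N", "H"), charge = 0L,
                          stringsAsFactors = FALSE),
       bonds = data.frame(i = 1L, j = 2L, order = 1L),
       coords = xyz)
}

frag_acceptor <- function(at, rot) {
  base <- rbind(c(0, 0, 0), c(1.22, 0, 0))  # O, C (point on O)
  xyz <- sweep(base %*% t(rot), 2, -at)
  list(atoms = data.frame(element = c("O", "C"), charge = 0L,
                          stringsAsFactors = FALSE),
       bonds = data.frame(i = 1L, j = 2L, order = 2L),
       coords = xyz)
}

fragment_for <- function(kind, at, rot) {
  switch(kind,
         aromatic = frag_aromatic(at, rot),
         hydrophobic = frag_hydrophobic(at, rot),
         donor = frag_donor(at, rot),
         acceptor = frag_acceptor(at, rot))
}

# fragment of a kind deliberately incompatible with `kind`
mismatched_fragment_for <- function(kind, at, rot) {
  wrong <- switch(kind, aromatic = "acceptor", hydrophobic = "acceptor",
                  donor = "acceptor", acceptor = "donor")
  fragment_for(wrong, at, rot)
}

random_rotation <- function() {
  # QR-based uniform random rotation, made proper
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Gaussian jitter truncated at 2 sd (resampled), so planted points move at
# most 2 * jitter_sd from their target
truncated_jitter <- function(sd) {
  if (sd == 0) return(c(0, 0, 0))
  repeat {
    v <- stats::rnorm(3, 0, sd)
    if (sqrt(sum(v^2)) <= 2 * sd) return(v)
  }
}

assemble_molecule <- function(mol_id, conf_id, frags) {
  atoms <- do.call(rbind, lapply(frags, `[[`, "atoms"))
  offs <- cumsum(c(0L, vapply(frags, function(f) nrow(f$atoms),
                              0L)))[seq_along(frags)]
  bonds <- do.call(rbind, Map(function(f, o) {
    data.frame(i = f$bonds$i + o, j = f$bonds$j + o, order = f$bonds$order)
  }, frags, offs))
  coords <- do.call(rbind, lapply(frags, `[[`, "coords"))
  molecule3d(mol_id, conf_id, atoms, bonds, coords)
}

#' Generate a planted-truth screening library
#'
#' Builds a synthetic conformer library with known ground truth against a
#' pharmacophore model and writes it as a multi-conformer SDF. Molecules
#' are multi-fragment pseudo-molecules whose fragments (benzene rings,
#' propane patches, amine N-H, carbonyl C=O) each trigger exactly one
#' feature-perception rule, so planted geometry translates directly into
#' detected features.
#'
#' **Actives** carry, on one randomly chosen conformer, fragments realizing
#' at least `min_match` kind-compatible features including every required
#' query; each feature point sits within `tolerance - 2 * jitter_sd` of its
#' query before jitter, and jitter is truncated at `2 * jitter_sd`, so
#' planted actives satisfy the acceptance rule with certainty. The other
#' conformers are rigidly displaced copies (20 A away), guaranteed worse.
#' **Decoys** violate the rule in the recorded way: `missing_required`
#' realizes many queries but never the required one; `too_few_features`
#' realizes only `min_match - 1` (including the required);
#' `displaced_beyond_tolerance` places every fragment 0.2-0.5 A outside
#' its query's tolerance sphere; `kind_mismatch` puts kind-incompatible
#' fragments at the query positions. Because every pairwise query
#' separation in the default model exceeds 5.7 A, a fragment placed for
#' one query can never stray inside another query's tolerance sphere, and
#' the truth labels are guaranteed, not merely probable, under prealigned
#' screening.
#'
#' @param spec A [library_spec()].
#' @param model A [pharmacophore_model()].
#' @param sdf_path Output SDF path.
#' @param truth_path Optional output TSV path for the truth table.
#' @return Invisibly, a list with `sdf_path` and `truth` (data.frame
#'   `mol_id`, `is_active`, `decoy_mode`, `planted_conf_id`).
#' @export
generate_library <- function(spec, model, sdf_path, truth_path = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  validate_pharmacophore_model(model)
  qs <- model$queries
  min_tol <- min(qs$tolerance)
  if (spec$jitter_sd >= min_tol / 2) {
    stop("jitter_sd = ", spec$jitter_sd, " A is too large to guarantee ",
         "active construction (must be < ", min_tol / 2,
         ", half the smallest tolerance)", call. = FALSE)
  }
  set.seed(spec$seed)
  n_act <- round(spec$n_molecules * spec$frac_active)
  qpos <- as.matrix(qs[, c("x", "y", "z")])
  req_idx <- which(qs$required)
  nq <- nrow(qs)

  place_planted <- function(qi, displaced = FALSE, mismatch = FALSE) {
    tol <- qs$tolerance[qi]
    if (displaced) {
      off <- random_unit() * stats::runif(1, tol + 0.2, tol + 0.5)
      at <- qpos[qi, ] + off
    } else {
      margin <- max(0, tol - 2 * spec$jitter_sd)
      at <- qpos[qi, ] + random_unit() * stats::runif(1, 0, margin) +
        truncated_jitter(spec$jitter_sd)
    }
    if (mismatch) mismatched_fragment_for(qs$kind[qi], at, random_rotation())
    else fragment_for(qs$kind[qi], at, random_rotation())
  }

  mols <- list()
  truth <- vector("list", spec$n_molecules)
  width <- max(4L, nchar(spec$n_molecules))
  for (m in seq_len(spec$n_molecules)) {
    mid <- sprintf(paste0("mol%0", width, "d"), m)
    active <- m <= n_act
    if (active) {
      sizes <- model$min_match:nq
      n_plant <- sizes[sample.int(length(sizes), 1)]
      pool <- setdiff(sample(nq), req_idx)
      planted_q <- sort(c(req_idx, pool[seq_len(n_plant - length(req_idx))]))
      frags <- lapply(planted_q, place_planted)
      mode <- NA_character_
    } else {
      mode <- spec$decoy_modes[((m - n_act - 1L) %% length(spec$decoy_modes)) + 1L]
      if (mode == "missing_required") {
        planted_q <- setdiff(seq_len(nq), req_idx)
        frags <- lapply(planted_q, place_planted)
      } else if (mode == "too_few_features") {
        pool <- setdiff(sample(nq), req_idx)
        planted_q <- sort(c(req_idx,
                            pool[seq_len(model$min_match - 1L - length(req_idx))]))
        frags <- lapply(planted_q, place_planted)
      } else if (mode == "displaced_beyond_tolerance") {
        planted_q <- seq_len(nq)
        frags <- lapply(planted_q, place_planted, displaced = TRUE)
      } else {  # kind_mismatch
        planted_q <- seq_len(nq)
        frags <- lapply(planted_q, place_planted, mismatch = TRUE)
      }
    }
    best_conf <- if (active) sample.int(spec$n_conformers, 1) - 1L
                 else NA_integer_
    in_frame <- if (active) best_conf else 0L  # decoy geometry stays posed
    base <- assemble_molecule(mid, 0L, frags)
    for (k in seq_len(spec$n_conformers) - 1L) {
      conf <- base
      conf$conf_id <- k
      if (!identical(k, in_frame)) {
        # displaced copy, far outside every tolerance sphere
        conf$coords <- sweep(conf$coords, 2, -(20 + stats::runif(1, 0, 5)) *
                               random_unit())
      }
      mols[[length(mols) + 1L]] <- conf
    }
    truth[[m]] <- data.frame(mol_id = mid, is_active = active,
                             decoy_mode = mode,
                             planted_conf_id = best_conf,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  write_sdf_library(mols, sdf_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(sdf_path = sdf_path, truth = truth))
}

#' Simulate a FRET saturation binding curve
#'
#' Evaluates the competitive-binding hyperbola
#' `F(c) = F0 + Fmax * c / (Kd_app + c)` over a titration design, with
#' `Kd_app = apparent_kd(Kd, Ki, inhibitor_conc)` when a competitor is
#' present (Ki given) and `Kd_app = Kd` otherwise, then applies
#' multiplicative Gaussian noise `signal * (1 + N(0, noise_sd_frac))` --
#' fluorescence error scales with intensity. Deterministic per seed.
#'
#' @param Kd True dissociation constant, uM, > 0.
#' @param Ki Inhibition constant of the competitor, uM, or `NULL` for no
#'   competitor.
#' @param inhibitor_conc Competitor concentration, uM (default 0).
#' @param concentrations Titration design, uM (default 10 points, 2-38 uM,
#'   the FRET titration range).
#' @param noise_sd_frac Fractional noise standard deviation (default 0).
#' @param seed Optional integer seed.
#' @param F0,Fmax Baseline and amplitude of the normalized signal
#'   (defaults 0 and 1).
#' @return A [binding_curve()].
#' @export
generate_binding_curve <- function(Kd, Ki = NULL, inhibitor_conc = 0,
                                   concentrations = seq(2, 38,
                                                        length.out = 10),
                                   noise_sd_frac = 0, seed = NULL,
                                   F0 = 0, Fmax = 1) {
  if (Kd <= 0) stop("Kd must be positive", call. = FALSE)
  if (noise_sd_frac < 0) stop("noise_sd_frac must be non-negative",
                              call. = FALSE)
  kd_app <- if (is.null(Ki)) Kd else apparent_kd(Kd, Ki, inhibitor_conc)
  y <- F0 + Fmax * concentrations / (kd_app + concentrations)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd_frac > 0) {
    y <- y * (1 + stats::rnorm(length(y), 0, noise_sd_frac))
  }
  binding_curve(concentrations, y, inhibitor_conc)
}

#' Simulate a dose-response series
#'
#' Evaluates the four-parameter logistic
#' `bottom + (top - bottom) / (1 + (d / EC50)^hill)` over a dose design and
#' applies multiplicative Gaussian noise. Deterministic per seed. The
#' default design spans 0.01x to 100x the generating EC50 with 8
#' log-spaced points.
#'
#' @param EC50 Generating EC50, uM, > 0.
#' @param hill Hill slope (default 1).
#' @param top,bottom Plateaus (defaults 100 and 0, percent scale).
#' @param doses Dose design, uM; default 8 log-spaced points over
#'   `0.01 * EC50` to `100 * EC50`.
#' @param noise_sd_frac Fractional noise standard deviation (default 0).
#' @param seed Optional integer seed.
#' @return A [dose_response()].
#' @export
generate_dose_response <- function(EC50, hill = 1, top = 100, bottom = 0,
                                   doses = NULL, noise_sd_frac = 0,
                                   seed = NULL) {
  if (EC50 <= 0) stop("EC50 must be positive", call. = FALSE)
  if (noise_sd_frac < 0) stop("noise_sd_frac must be non-negative",
                              call. = FALSE)
  if (is.null(doses)) {
    doses <- exp(seq(log(0.01 * EC50), log(100 * EC50), length.out = 8))
  }
  y <- bottom + (top - bottom) / (1 + (doses / EC50)^hill)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd_frac > 0) {
    y <- y * (1 + stats::rnorm(length(y), 0, noise_sd_frac))
  }
  dose_response(doses, y)
}
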
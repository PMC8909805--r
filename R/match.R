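#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of point set `P` onto point set `Q`: returns
#' the proper rotation `R` (determinant +1) and translation `t` minimizing
#' the RMSD of `P %*% t(R) + t` against `Q`, via singular value
#' decomposition of the cross-covariance of the centred sets.
#'
#' @param P,Q Numeric matrices of equal dimension (n x 3, n >= 1), rows are
#'   corresponding points.
#' @return A list with `rotation` (3x3), `translation` (length 3) and
#'   `rmsd` (A).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (length(P) && is.null(dim(P))) P <- matrix(P, ncol = 3)
  if (length(Q) && is.null(dim(Q))) Q <- matrix(Q, ncol = 3)
  if (nrow(P) == 0L || nrow(Q) == 0L) {
    stop("point sets must be non-empty", call. = FALSE)
  }
  if (!all(dim(P) == dim(Q))) {
    stop("point sets must have equal size", call. = FALSE)
  }
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- qc - as.vector(R %*% pc)
  resid <- sweep(P %*% t(R), 2, -tvec) - Q
  list(rotation = R, translation = as.vector(tvec),
       rmsd = sqrt(mean(rowSums(resid^2))))
}

#' Match a conformer's features against a pharmacophore model
#'
#' Finds the injective assignment of detected features to model queries
#' that maximizes the number of matched queries, subject to kind
#' compatibility (aromatic and hydrophobic are interchangeable; donor and
#' acceptor match only themselves) and to each query's spherical distance
#' tolerance. Ties on the match count are broken by lower RMSD over the
#' matched pairs, then by query-id order, so results are deterministic.
#'
#' In `"prealigned"` mode feature coordinates are taken to be in the model
#' frame already (the screening default: poses come from docking into that
#' frame). In `"align"` mode a rigid transform of the pose is searched
#' jointly with the assignment: seed correspondences of three
#' kind-compatible pairs whose internal distance geometry agrees within the
#' summed tolerances are Kabsch-aligned, greedily extended with the nearest
#' compatible pairs inside tolerance and re-aligned; when the number of
#' injective kind-compatible assignments is below `exact_cap` an exhaustive
#' enumeration (align on each assignment, keep the best) is used instead,
#' so small instances are solved exactly.
#'
#' A pose is **accepted** iff it matches at least `model$min_match` queries
#' *and* every `required` ("must-have") query is matched.
#'
#' @param features A `detected_features` table from [perceive_features()],
#'   or any data.frame with columns `kind`, `x`, `y`, `z`.
#' @param model A [pharmacophore_model()].
#' @param mode `"prealigned"` or `"align"`.
#' @param mol_id,conf_id Identifiers copied into the result (defaults taken
#'   from attributes when absent).
#' @param exact_cap Assignment-count cap below which align mode enumerates
#'   exhaustively (default 1e5).
#' @return An object of class `match_result`: list with `mol_id`,
#'   `conf_id`, `assignment` (data.frame `query_id`, `feature_idx`,
#'   `dist`), `n_matched`, `rmsd_matched`, `fitness`, `accepted`, `mode`.
#' @export
match_pose <- function(features, model, mode = c("prealigned", "align"),
                       mol_id = NA_character_, conf_id = NA_integer_,
                       exact_cap = 1e5) {
  mode <- match.arg(mode)
  validate_pharmacophore_model(model)
  f <- as.data.frame(features)
  nf <- nrow(f)
  qs <- model$queries
  nq <- nrow(qs)
  fxyz <- if (nf) as.matrix(f[, c("x", "y", "z")]) else
    matrix(numeric(), ncol = 3)
  qxyz <- as.matrix(qs[, c("x", "y", "z")])

  if (mode == "prealigned") {
    sol <- best_assignment(qs, qxyz, f$kind, fxyz)
  } else {
    sol <- align_and_match(qs, qxyz, f$kind, fxyz, exact_cap)
  }
  finalize_match(sol, model, mode, mol_id, conf_id)
}

# --- internal: exact assignment search in a fixed frame ------------------

# Depth-first search over queries (in table order), maximizing match count,
# then minimizing the sum of squared pair distances. Exact: explores
# matching and skipping each query, pruned by the optimistic bound
# count + remaining >= best count.
best_assignment <- function(qs, qxyz, fkind, fxyz) {
  nq <- nrow(qs); nf <- length(fkind)
  cand <- vector("list", nq)
  for (qi in seq_len(nq)) {
    if (nf) {
      ok <- which(kinds_compatible(qs$kind[qi], fkind))
      if (length(ok)) {
        d2 <- rowSums(sweep(fxyz[ok, , drop = FALSE], 2, qxyz[qi, ])^2)
        keep <- d2 <= qs$tolerance[qi]^2 + 1e-12
        cand[[qi]] <- list(idx = ok[keep], d2 = d2[keep])
      } else cand[[qi]] <- list(idx = integer(), d2 = numeric())
    } else cand[[qi]] <- list(idx = integer(), d2 = numeric())
  }
  best <- list(count = -1L, ssd = Inf, assign = integer(nq))
  used <- rep(FALSE, nf)
  assign <- rep(NA_integer_, nq)
  rec <- function(qi, count, ssd) {
    if (count + (nq - qi + 1L) < best$count) return()
    if (qi > nq) {
      if (count > best$count ||
          (count == best$count && ssd < best$ssd - 1e-12)) {
        best <<- list(count = count, ssd = ssd, assign = assign)
      }
      return()
    }
    cc <- cand[[qi]]
    ord <- order(cc$d2)
    for (k in ord) {
      fi <- cc$idx[k]
      if (used[fi]) next
      used[fi] <<- TRUE; assign[qi] <<- fi
      rec(qi + 1L, count + 1L, ssd + cc$d2[k])
      used[fi] <<- FALSE; assign[qi] <<- NA_integer_
    }
    rec(qi + 1L, count, ssd)
  }
  rec(1L, 0L, 0)
  list(assign = best$assign,
       d2 = vapply(seq_len(nq), function(qi) {
         fi <- best$assign[qi]
         if (is.na(fi)) NA_real_ else sum((fxyz[fi, ] - qxyz[qi, ])^2)
       }, numeric(1)))
}

# count injective kind-compatible assignments (capped)
count_assignments <- function(compat, cap) {
  nq <- nrow(compat); nf <- ncol(compat)
  total <- 0
  used <- rep(FALSE, nf)
  rec <- function(qi) {
    if (total > cap) return()
    if (qi > nq) { total <<- total + 1; return() }
    rec(qi + 1L)  # skip
    for (fi in which(compat[qi, ] & !used)) {
      used[fi] <<- TRUE
      rec(qi + 1L)
      used[fi] <<- FALSE
    }
  }
  if (nq && nf) rec(1L) else total <- 1
  total
}

# --- internal: align mode ------------------------------------------------

align_and_match <- function(qs, qxyz, fkind, fxyz, exact_cap) {
  nq <- nrow(qs); nf <- length(fkind)
  empty <- list(assign = rep(NA_integer_, nq), d2 = rep(NA_real_, nq))
  if (!nf) return(empty)
  compat <- outer(seq_len(nq), seq_len(nf),
                  function(a, b) kinds_compatible(qs$kind[a], fkind[b]))
  pairs <- which(compat, arr.ind = TRUE)
  if (!nrow(pairs)) return(empty)

  score_of <- function(sol) {
    cnt <- sum(!is.na(sol$assign))
    c(cnt, -sum(sol$d2, na.rm = TRUE))
  }
  better <- function(a, b) {
    sa <- score_of(a); sb <- score_of(b)
    sa[1] > sb[1] || (sa[1] == sb[1] && sa[2] > sb[2] + 1e-12)
  }

  # evaluate one candidate correspondence: align on it, re-assign in the
  # aligned frame, iterate alignment on the matched set until stable
  evaluate <- function(qi_set, fi_set) {
    sol <- NULL
    for (iter in 1:5) {
      fit <- kabsch_superpose(fxyz[fi_set, , drop = FALSE],
                              qxyz[qi_set, , drop = FALSE])
      moved <- sweep(fxyz %*% t(fit$rotation), 2, -fit$translation)
      new_sol <- best_assignment(qs, qxyz, fkind, moved)
      m <- which(!is.na(new_sol$assign))
      if (length(m) < 1L) return(new_sol)
      nqi <- m; nfi <- new_sol$assign[m]
      if (length(nqi) == length(qi_set) && all(nqi == qi_set) &&
          all(nfi == fi_set)) return(new_sol)
      sol <- new_sol; qi_set <- nqi; fi_set <- nfi
    }
    sol
  }

  best <- empty
  n_assign <- count_assignments(compat, exact_cap)
  if (n_assign <= exact_cap) {
    # exhaustive: Kabsch-align on every injective compatible assignment;
    # an assignment is feasible when, at its own least-squares alignment,
    # every pair sits inside its query's tolerance (supersets and subsets
    # are enumerated separately, so the maximum feasible size is found)
    used <- rep(FALSE, nf)
    sel_q <- integer(); sel_f <- integer()
    check_sel <- function() {
      fit <- kabsch_superpose(fxyz[sel_f, , drop = FALSE],
                              qxyz[sel_q, , drop = FALSE])
      moved <- sweep(fxyz[sel_f, , drop = FALSE] %*% t(fit$rotation), 2,
                     -fit$translation)
      d2 <- rowSums((moved - qxyz[sel_q, , drop = FALSE])^2)
      if (all(d2 <= qs$tolerance[sel_q]^2 + 1e-12)) {
        sol <- list(assign = rep(NA_integer_, nq), d2 = rep(NA_real_, nq))
        sol$assign[sel_q] <- sel_f
        sol$d2[sel_q] <- d2
        if (better(sol, best)) best <<- sol
      }
    }
    rec <- function(qi) {
      if (length(sel_q) >= 1L) check_sel()
      if (qi > nq) return()
      for (nxt in qi:nq) {
        for (fi in which(compat[nxt, ] & !used)) {
          used[fi] <<- TRUE
          sel_q <<- c(sel_q, nxt); sel_f <<- c(sel_f, fi)
          rec(nxt + 1L)
          sel_q <<- sel_q[-length(sel_q)]; sel_f <<- sel_f[-length(sel_f)]
          used[fi] <<- FALSE
        }
      }
    }
    rec(1L)
  } else {
    # seed triples with consistent internal distance geometry
    dq <- as.matrix(stats::dist(qxyz))
    df <- as.matrix(stats::dist(fxyz))
    np <- nrow(pairs)
    if (np >= 3L) for (a in seq_len(np - 2)) for (b in (a + 1):(np - 1)) {
      qa <- pairs[a, 1]; fa <- pairs[a, 2]
      qb <- pairs[b, 1]; fb <- pairs[b, 2]
      if (qa == qb || fa == fb) next
      if (abs(dq[qa, qb] - df[fa, fb]) >
          qs$tolerance[qa] + qs$tolerance[qb]) next
      for (cc in (b + 1):np) {
        qc <- pairs[cc, 1]; fc <- pairs[cc, 2]
        if (qc %in% c(qa, qb) || fc %in% c(fa, fb)) next
        if (abs(dq[qa, qc] - df[fa, fc]) >
            qs$tolerance[qa] + qs$tolerance[qc]) next
        if (abs(dq[qb, qc] - df[fb, fc]) >
            qs$tolerance[qb] + qs$tolerance[qc]) next
        sol <- evaluate(c(qa, qb, qc), c(fa, fb, fc))
        if (better(sol, best)) best <- sol
      }
    }
    if (sum(!is.na(best$assign)) == 0L) {
      # fewer than 3 consistent pairs: try single-pair seeds (translation)
      for (a in seq_len(np)) {
        sol <- evaluate(pairs[a, 1], pairs[a, 2])
        if (better(sol, best)) best <- sol
      }
    }
  }
  best
}

finalize_match <- function(sol, model, mode, mol_id, conf_id) {
  qs <- model$queries
  m <- which(!is.na(sol$assign))
  dists <- sqrt(sol$d2[m])
  assignment <- data.frame(query_id = qs$id[m],
                           feature_idx = sol$assign[m],
                           dist = dists, stringsAsFactors = FALSE)
  n_matched <- length(m)
  rmsd <- if (n_matched) sqrt(mean(dists^2)) else NA_real_
  req <- which(qs$required)
  accepted <- n_matched >= model$min_match && all(req %in% m)
  res <- structure(
    list(mol_id = mol_id, conf_id = conf_id, assignment = assignment,
         n_matched = n_matched, rmsd_matched = rmsd, fitness = NA_real_,
         accepted = accepted, mode = mode),
    class = "match_result")
  res$fitness <- fitness_score(res, model)
  res
}

#' Fitness score of a match
#'
#' `fitness = n_matched - mean(dist_i / tolerance_i)` over the matched
#' pairs. The residual term lies in `[0, 1)`, so the score is bounded in
#' `(n_matched - 1, n_matched]`: any match with more features strictly
#' outscores any match with fewer, and among equal counts a geometrically
#' tighter fit scores higher. A perfect match of k queries scores exactly
#' k. Unmatched (0-feature) results score 0. Rejected poses still receive
#' a score; acceptance is carried separately by the `accepted` flag.
#'
#' @param result A `match_result` from [match_pose()].
#' @param model The [pharmacophore_model()] the result was matched against.
#' @return A single numeric score.
#' @export
fitness_score <- function(result, model) {
  a <- result$assignment
  if (is.null(a) || nrow(a) == 0L) return(0)
  tol <- model$queries$tolerance[match(a$query_id, model$queries$id)]
  nrow(a) - mean(a$dist / tol)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result %s/%s: n_matched=%d rmsd=%.3f fitness=%.3f %s (%s)\n",
              x$mol_id, x$conf_id, x$n_matched,
              ifelse(is.na(x$rmsd_matched), NaN, x$rmsd_matched),
              x$fitness, if (x$accepted) "ACCEPTED" else "rejected", x$mode))
  invisible(x)
}
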
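# Independent brute-force oracle for the assignment problem: enumerate
# every injective kind-compatible within-tolerance assignment of features
# to queries and return the maximum match count. Plain enumeration, no
# pruning, no shared code with the package matcher.

oracle_max_matched <- function(features, model) {
  q <- model$queries
  fxyz <- as.matrix(features[, c("x", "y", "z")])
  qxyz <- as.matrix(q[, c("x", "y", "z")])
  nq <- nrow(q); nf <- nrow(features)
  ok <- matrix(FALSE, nq, nf)
  for (qi in seq_len(nq)) for (fi in seq_len(nf)) {
    if (kinds_compatible(q$kind[qi], features$kind[fi]) &&
        sqrt(sum((fxyz[fi, ] - qxyz[qi, ])^2)) <= q$tolerance[qi] + 1e-12) {
      ok[qi, fi] <- TRUE
    }
  }
  best <- 0L
  recurse <- function(qi, used, count) {
    if (qi > nq) {
      best <<- max(best, count)
      return()
    }
    recurse(qi + 1L, used, count)
    for (fi in which(ok[qi, ])) {
      if (!used[fi]) recurse(qi + 1L, `[<-`(used, fi, TRUE), count + 1L)
    }
  }
  recurse(1L, rep(FALSE, nf), 0L)
  best
}

# random small matching instance: a model with nq queries and a feature
# cloud of nf typed points in a shared box
random_instance <- function(nq, nf) {
  kinds <- feature_kinds()
  model <- pharmacophore_model(
    "rand",
    data.frame(id = sprintf("q%02d", seq_len(nq)),
               kind = sample(kinds, nq, replace = TRUE),
               x = runif(nq, 0, 8), y = runif(nq, 0, 8),
               z = runif(nq, 0, 8),
               required = FALSE),
    min_match = sample.int(nq, 1))
  features <- data.frame(kind = sample(kinds, nf, replace = TRUE),
                         x = runif(nf, 0, 8), y = runif(nf, 0, 8),
                         z = runif(nf, 0, 8), stringsAsFactors = FALSE)
  list(model = model, features = features)
}
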
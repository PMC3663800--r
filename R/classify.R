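#' Absolute fold change
#'
#' `afc(a, b) = max(a, b) / min(a, b)` for two positive expression values on
#' the exponentiated scale. Symmetric, always `>= 1`, equal to 1 iff `a == b`,
#' and invariant under multiplying both operands by a positive constant.
#'
#' @param a,b positive numbers (vectorized).
#' @return numeric vector of fold changes, each `>= 1`.
#' @export
absolute_fold_change <- function(a, b) {
  if (any(a <= 0) || any(b <= 0))
    stop("absolute fold change is defined for positive values only")
  pmax(a, b) / pmin(a, b)
}

#' Exponentiate log-scale expression values
#'
#' Mapping log-normalized values through `exp()` makes every value strictly
#' positive so fold changes are well defined; order is preserved.
#'
#' @param values finite numeric vector on the log scale.
#' @return positive numeric vector.
#' @export
exponentiate <- function(values) {
  if (any(!is.finite(values))) stop("expression values must be finite")
  exp(values)
}

#' Neighborhood of a candidate representative
#'
#' The neighborhood of `a` within the value multiset `V` is the collection of
#' values deemed similarly expressed to `a`: those whose absolute fold change
#' to `a` is at most the neighborhood threshold `n`. It always contains `a`
#' itself, and is invariant under rescaling all of `V` by a positive constant.
#'
#' @param a a member of `V` (exponentiated scale).
#' @param V positive numeric vector of a probe's exponentiated values.
#' @param n neighborhood threshold, `>= 1`.
#' @return the elements of `V` in the neighborhood of `a`.
#' @export
neighborhood <- function(a, V, n) {
  stopifnot(n >= 1, all(V > 0))
  if (!any(V == a)) stop("'a' must be an element of 'V'")
  V[pmax(a / V, V / a) <= n]
}

#' Score a candidate pair of representatives
#'
#' The score of representatives `a < b` with neighborhoods `A`, `B` rewards
#' (i) joint data coverage, quadratically — the product of two coverage terms
#' `|A U B|`, counted over the samples of `V`; (ii) balanced neighborhood
#' sizes, via `min(|A|,|B|) / max(|A|,|B|)`; and (iii) representatives central
#' to their neighborhoods — each coverage term is divided by the penalty
#' `afc(rep, mean(neighborhood))`, the penalties entering only one of the two
#' coverage factors. The final score applies the separation constraint: it is
#' zero unless `afc(a, b)` exceeds the fold threshold `f`, so probes without
#' two genuinely separated expression levels score 0.
#'
#' @param a,b the two representatives (exponentiated scale).
#' @param A,B their neighborhoods, as value multisets drawn from `V`.
#' @param V the probe's full multiset of exponentiated values.
#' @param pair numeric `(f, n)` threshold pair.
#' @return the final score, `>= 0`.
#' @export
score_pair <- function(a, b, A, B, V, pair) {
  if (length(A) == 0L || length(B) == 0L)
    stop("neighborhoods must be nonempty")
  f <- pair[[1L]]
  if (pmax(a, b) / pmin(a, b) <= f) return(0)
  cov <- sum(V %in% A | V %in% B)
  pa <- {ma <- sum(A) / length(A); pmax(a / ma, ma / a)}
  pb <- {mb <- sum(B) / length(B); pmax(b / mb, mb / b)}
  bal <- min(length(A), length(B)) / max(length(A), length(B))
  cov * (cov / (pa * pb)) * bal
}

#' State boundaries from two neighborhoods
#'
#' The lower boundary is the upper limit of the lower representative's
#' neighborhood and the upper boundary is the lower limit of the upper one's;
#' if the neighborhoods overlap so that the boundaries cross, they are
#' switched.
#'
#' @param A neighborhood of the lower representative (values).
#' @param B neighborhood of the higher representative (values).
#' @return numeric `c(b1, b2)` with `b1 <= b2`.
#' @export
compute_boundaries <- function(A, B) {
  stopifnot(length(A) > 0L, length(B) > 0L)
  b1 <- max(A)
  b2 <- min(B)
  if (b1 > b2) c(b2, b1) else c(b1, b2)
}

## Assign L/M/H states from exponentiated values and boundaries.
## v <= b1 -> L, v >= b2 -> H, else M; at b1 == b2, L takes precedence.
assign_states <- function(w, b1, b2) {
  ifelse(w <= b1, "L", ifelse(w >= b2, "H", "M"))
}

#' Classify one probe's expression values into low/medium/high states
#'
#' Exponentiates the log-scale values, then searches every ordered pair of
#' distinct observed values `(a < b)` as candidate representatives, for every
#' `(f, n)` threshold pair in the configuration, and keeps the global
#' maximizer of the final score (see [score_pair()]). Ties are resolved
#' deterministically: larger joint coverage first, then the earlier threshold
#' pair, then the lexicographically smallest `(a, b)`. Boundaries follow
#' [compute_boundaries()]; each sample below the lower boundary is `L`, above
#' the upper boundary `H`, in between `M`.
#'
#' When no candidate pair satisfies the separation constraint (e.g. a constant
#' probe), the best score is 0, no pair is chosen, and all samples are
#' assigned `M`; such probes are removed downstream by
#' [filter_probes_by_score()].
#'
#' @param values numeric vector of one probe's log-normalized values
#'   (`>= 2` samples).
#' @param config a [cape_config()].
#' @return a list of class `probe_classification` with elements `states`
#'   (character vector over `L`/`M`/`H`), `best_score`, `chosen_pair`,
#'   `rep_low`, `rep_high`, `boundary_low`, `boundary_high`,
#'   `neighborhood_low`, `neighborhood_high` (sample indices).
#' @export
classify_probe <- function(values, config = cape_config()) {
  m <- length(values)
  if (m < 2L) stop("classification needs at least 2 samples")
  if (any(!is.finite(values))) stop("expression values must be finite")
  w <- exp(values)
  u <- sort(unique(w))
  r <- length(u)
  tp <- config$threshold_pairs

  best <- list(score = 0, cov = -Inf, i = NA_integer_, j = NA_integer_,
               pair_idx = NA_integer_, members = NULL)
  if (r >= 2L) {
    wrep <- matrix(w, nrow = r, ncol = m, byrow = TRUE)
    urep <- matrix(u, nrow = r, ncol = m)
    afc_uv <- pmax(urep / wrep, wrep / urep)  # r x m: afc(u_i, w_j)
    sep <- outer(u, u, function(a, b) b / a)  # upper triangle: afc(u_i, u_j)
    lower <- row(sep) >= col(sep)
    for (k in seq_len(nrow(tp))) {
      f <- tp[k, 1L]; n <- tp[k, 2L]
      M <- afc_uv <= n                       # neighborhood membership
      sz <- rowSums(M)
      mu <- rowSums(M * wrep) / sz           # neighborhood means
      pen <- pmax(u / mu, mu / u)
      inter <- tcrossprod(M * 1)
      uni <- outer(sz, sz, "+") - inter      # |A U B| (sample counts)
      bal <- outer(sz, sz, pmin) / outer(sz, sz, pmax)
      score <- uni * (uni / outer(pen, pen)) * bal
      score[sep <= f | lower] <- 0
      smax <- max(score)
      if (smax <= 0) next
      cand <- which(score == smax, arr.ind = TRUE)
      cov <- uni[cand]
      cand <- cand[cov == max(cov), , drop = FALSE]
      ord <- order(cand[, 1L], cand[, 2L])[1L]
      ci <- cand[ord, 1L]; cj <- cand[ord, 2L]
      if (smax > best$score ||
          (smax == best$score && uni[ci, cj] > best$cov)) {
        best <- list(score = smax, cov = uni[ci, cj], i = ci, j = cj,
                     pair_idx = k, members = list(A = M[ci, ], B = M[cj, ]))
      }
    }
  }

  if (best$score <= 0) {
    res <- list(states = rep("M", m), best_score = 0,
                chosen_pair = c(f = NA_real_, n = NA_real_),
                rep_low = NA_real_, rep_high = NA_real_,
                boundary_low = NA_real_, boundary_high = NA_real_,
                neighborhood_low = integer(0), neighborhood_high = integer(0))
  } else {
    A <- w[best$members$A]
    B <- w[best$members$B]
    bnd <- compute_boundaries(A, B)
    res <- list(states = assign_states(w, bnd[1L], bnd[2L]),
                best_score = best$score,
                chosen_pair = c(f = unname(tp[best$pair_idx, 1L]),
                                n = unname(tp[best$pair_idx, 2L])),
                rep_low = u[best$i], rep_high = u[best$j],
                boundary_low = bnd[1L], boundary_high = bnd[2L],
                neighborhood_low = which(best$members$A),
                neighborhood_high = which(best$members$B))
  }
  names(res$states) <- names(values)
  class(res) <- "probe_classification"
  res
}

#' Classify every probe of an expression matrix
#'
#' @param mat numeric matrix of log-normalized expression (probes x samples).
#' @param config a [cape_config()].
#' @return a list of class `probe_states`: `states` (character matrix
#'   probes x samples over `L`/`M`/`H`) and `stats` (data.frame of per-probe
#'   `probe_id`, `best_score`, `fold_threshold`, `neighborhood_threshold`,
#'   `rep_low`, `rep_high`, `boundary_low`, `boundary_high`).
#' @export
classify_matrix <- function(mat, config = cape_config()) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  cls <- lapply(seq_len(nrow(mat)), function(i) classify_probe(mat[i, ], config))
  states <- do.call(rbind, lapply(cls, `[[`, "states"))
  dimnames(states) <- dimnames(mat)
  stats <- data.frame(
    probe_id = rownames(mat),
    best_score = vapply(cls, `[[`, numeric(1), "best_score"),
    fold_threshold = vapply(cls, function(x) x$chosen_pair[["f"]], numeric(1)),
    neighborhood_threshold = vapply(cls, function(x) x$chosen_pair[["n"]], numeric(1)),
    rep_low = vapply(cls, `[[`, numeric(1), "rep_low"),
    rep_high = vapply(cls, `[[`, numeric(1), "rep_high"),
    boundary_low = vapply(cls, `[[`, numeric(1), "boundary_low"),
    boundary_high = vapply(cls, `[[`, numeric(1), "boundary_high"),
    stringsAsFactors = FALSE)
  structure(list(states = states, stats = stats), class = "probe_states")
}

#' @export
print.probe_states <- function(x, ...) {
  cat(sprintf("probe state classification: %d probes x %d samples\n",
              nrow(x$states), ncol(x$states)))
  cat(sprintf("  surviving a score filter at t = 0.5: %d\n",
              sum(x$stats$best_score > 0.5 * ncol(x$states))))
  invisible(x)
}

#' Filter probe classifications by score
#'
#' Keeps exactly the probes whose best classification score strictly exceeds
#' `t * n_samples`; row order is preserved.
#'
#' @param classified a `probe_states` object from [classify_matrix()].
#' @param t probe score factor (any real; negative keeps everything).
#' @param n_samples number of samples; defaults to the matrix width.
#' @return the filtered `probe_states` object.
#' @export
filter_probes_by_score <- function(classified, t,
                                   n_samples = ncol(classified$states)) {
  stopifnot(inherits(classified, "probe_states"))
  keep <- classified$stats$best_score > t * n_samples
  structure(list(states = classified$states[keep, , drop = FALSE],
                 stats = classified$stats[keep, , drop = FALSE]),
            class = "probe_states")
}
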
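# Independent oracles: plain-loop exhaustive implementations used to verify
# the package's vectorized/closed-form routines.

# Exhaustive search over every ordered pair of distinct observed values and
# every threshold pair; same score definition and tie order as the package
# (score desc, coverage desc, threshold-pair order, smallest (a, b)), written
# as straight loops.
oracle_classify <- function(values, config) {
  w <- exp(values)
  m <- length(w)
  u <- sort(unique(w))
  tp <- config$threshold_pairs
  best <- list(score = 0, cov = -Inf, a = NA_real_, b = NA_real_,
               A = NULL, B = NULL, pair = c(NA_real_, NA_real_))
  if (length(u) >= 2L) {
    for (k in seq_len(nrow(tp))) {
      f <- tp[k, 1L]; n <- tp[k, 2L]
      for (i in seq_len(length(u) - 1L)) {
        for (j in (i + 1L):length(u)) {
          a <- u[i]; b <- u[j]
          if (b / a <= f) next
          inA <- pmax(a / w, w / a) <= n
          inB <- pmax(b / w, w / b) <= n
          cov <- sum(inA | inB)
          ma <- sum(w[inA]) / sum(inA)
          mb <- sum(w[inB]) / sum(inB)
          pa <- max(a / ma, ma / a)
          pb <- max(b / mb, mb / b)
          bal <- min(sum(inA), sum(inB)) / max(sum(inA), sum(inB))
          sc <- cov * (cov / (pa * pb)) * bal
          if (sc > best$score || (sc == best$score && cov > best$cov)) {
            best <- list(score = sc, cov = cov, a = a, b = b,
                         A = w[inA], B = w[inB],
                         pair = unname(c(tp[k, 1L], tp[k, 2L])))
          }
        }
      }
    }
  }
  if (best$score <= 0)
    return(list(states = rep("M", m), best_score = 0,
                chosen_pair = c(NA_real_, NA_real_)))
  b1 <- max(best$A); b2 <- min(best$B)
  if (b1 > b2) { tmp <- b1; b1 <- b2; b2 <- tmp }
  list(states = ifelse(w <= b1, "L", ifelse(w >= b2, "H", "M")),
       best_score = best$score, chosen_pair = best$pair,
       rep_low = best$a, rep_high = best$b,
       boundary_low = b1, boundary_high = b2)
}

# Pair-counting Jaccard by explicit enumeration of all unordered sample pairs.
oracle_jaccard <- function(p, q) {
  n <- length(p)
  n11 <- n10 <- n01 <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cp <- p[i] == p[j]
      cq <- q[i] == q[j]
      if (cp && cq) n11 <- n11 + 1L
      else if (cp) n10 <- n10 + 1L
      else if (cq) n01 <- n01 + 1L
    }
  }
  if (n11 + n10 + n01 == 0L) return(0)
  n11 / (n11 + n10 + n01)
}

random_partition <- function(n, max_blocks = 4L) {
  sample.int(sample.int(max_blocks, 1L), n, replace = TRUE)
}

# a vector of random log-expression values exercising varied shapes:
# two-level, diffuse, duplicated values, near-constant
random_probe <- function(m) {
  shape <- sample(4L, 1L)
  v <- switch(shape,
              rnorm(m, 0, 1.2),
              rep(c(0, 2.5), length.out = m) + rnorm(m, 0, 0.3),
              round(rnorm(m, 1, 1), 1),          # duplicated values likely
              rnorm(m, 0, 0.05))                 # nearly constant
  v
}
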
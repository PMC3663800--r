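#' Numeric substitution of interaction states
#'
#' Maps each interaction state to a real value encoding the direction and
#' strength of the implied regulation: `LH -> -1`, `MH`/`LM -> -0.5`,
#' `LL`/`MM`/`HH -> 0`, `HM`/`ML -> 0.5`, `HL -> 1`. The mapping is
#' antisymmetric (`value(XY) = -value(YX)` for `X != Y`) and sums to zero over
#' the alphabet.
#'
#' @return named numeric vector over the nine states.
#' @export
state_substitution <- function() {
  c(LH = -1, MH = -0.5, LM = -0.5, LL = 0, MM = 0, HH = 0,
    HM = 0.5, ML = 0.5, HL = 1)
}

#' Substitute interaction states into a numeric matrix
#'
#' @param table an `interaction_states` object.
#' @return numeric matrix (interactions x samples) under [state_substitution()].
#' @export
substitute_states <- function(table) {
  stopifnot(inherits(table, "interaction_states"))
  sub <- state_substitution()
  bad <- setdiff(unique(as.vector(table$states)), names(sub))
  if (length(bad)) stop("unknown interaction state(s): ",
                        paste(bad, collapse = ", "))
  matrix(sub[table$states], nrow = nrow(table$states),
         dimnames = dimnames(table$states))
}

#' City-block distance matrix between samples
#'
#' @param numeric_matrix matrix from [substitute_states()] (interactions x
#'   samples); distances are computed between sample columns.
#' @return symmetric matrix of Manhattan distances with zero diagonal.
#' @export
sample_distance_matrix <- function(numeric_matrix) {
  stopifnot(ncol(numeric_matrix) >= 2L)
  as.matrix(stats::dist(t(numeric_matrix), method = "manhattan"))
}

#' Ward hierarchical clustering of a sample distance matrix
#'
#' Agglomerative clustering with Ward's minimum-variance update
#' (`stats::hclust(method = "ward.D2")`) applied to the city-block
#' dissimilarities. Ward's criterion classically assumes squared Euclidean
#' input; applying it to city-block distances follows the method being
#' reproduced, with the caveat documented in the methods vignette.
#'
#' @param dist_matrix symmetric distance matrix (e.g. from
#'   [sample_distance_matrix()]).
#' @return an `hclust` tree with `n - 1` merges.
#' @export
ward_clustering <- function(dist_matrix) {
  stats::hclust(stats::as.dist(dist_matrix), method = "ward.D2")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' PCA of the sample distance matrix
#'
#' The `N x N` distance matrix is treated as `N` observations in `N`
#' dimensions: columns are centered (not scaled) and decomposed by singular
#' values. Component signs are fixed so the largest-magnitude loading of each
#' component is positive, making coordinates reproducible.
#'
#' @param dist_matrix symmetric distance matrix.
#' @return list of class `distance_pca`: `coordinates` (samples x components),
#'   `explained` (variance fractions summing to 1), `sdev`.
#' @export
pca_of_distance_matrix <- function(dist_matrix) {
  stopifnot(nrow(dist_matrix) >= 2L)
  pc <- stats::prcomp(dist_matrix, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    top <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[top, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  vars <- pc$sdev^2
  structure(list(coordinates = pc$x,
                 explained = vars / sum(vars),
                 sdev = pc$sdev),
            class = "distance_pca")
}

#' @export
print.distance_pca <- function(x, ...) {
  cat("PCA of the sample distance matrix\n")
  k <- min(3L, length(x$explained))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
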
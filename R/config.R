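#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. Each `threshold_pairs` row
#' is a (fold threshold `f`, neighborhood threshold `n`) pair on the
#' absolute-fold-change scale; the discretizer picks, per probe, the pair that
#' maximizes the classification score. `f > n >= 1` is required for every
#' pair: two values closer than `n` are "similarly expressed", two values
#' further apart than `f` are "differentially expressed", and the band in
#' between is ambiguous.
#'
#' @param threshold_pairs numeric matrix with columns `f` and `n`, one row per
#'   candidate pair. The default `rbind(c(2, 1.5), c(1.5, 1.25))` is a
#'   documented stand-in: override it when reproducing a specific study.
#' @param probe_score_factor scalar `t`; probes survive the score filter iff
#'   their best classification score exceeds `t * n_samples`.
#' @param medium_ratio_max fraction `r_M` in \[0,1\]; rows whose fraction of
#'   `M` states exceeds this are dropped before interactions are built.
#' @param undefined_freq_max fraction `u` in \[0,1\]; interactions whose
#'   fraction of undefined states (HH/LL/MM) exceeds this are dropped.
#' @param correlation_cutoff Spearman cutoff; interactions are kept when
#'   `rho <= cutoff` in at least one experimental group.
#' @param present_call_min_fraction minimum fraction of samples with a present
#'   call for a probe to be analyzed.
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return an object of class `cape_config` (a validated list).
#' @export
cape_config <- function(threshold_pairs = rbind(c(2, 1.5), c(1.5, 1.25)),
                        probe_score_factor = 0.5,
                        medium_ratio_max = 0.5,
                        undefined_freq_max = 0.5,
                        correlation_cutoff = -0.4,
                        present_call_min_fraction = 0.2,
                        rng_seed = 1L) {
  threshold_pairs <- as.matrix(threshold_pairs)
  if (ncol(threshold_pairs) != 2L || nrow(threshold_pairs) < 1L)
    stop("'threshold_pairs' must be a matrix with columns (f, n) and >= 1 row")
  storage.mode(threshold_pairs) <- "double"
  colnames(threshold_pairs) <- c("f", "n")
  if (any(!is.finite(threshold_pairs)))
    stop("'threshold_pairs' must be finite")
  bad <- threshold_pairs[, "f"] <= threshold_pairs[, "n"] |
    threshold_pairs[, "n"] < 1
  if (any(bad))
    stop("every threshold pair must satisfy f > n >= 1; offending row(s): ",
         paste(which(bad), collapse = ", "))
  for (frac in c(medium_ratio_max, undefined_freq_max,
                 present_call_min_fraction)) {
    if (!is.numeric(frac) || length(frac) != 1L || is.na(frac) ||
        frac < 0 || frac > 1)
      stop("fraction parameters must be single values in [0, 1]")
  }
  stopifnot(is.numeric(probe_score_factor), length(probe_score_factor) == 1L,
            is.finite(probe_score_factor),
            is.numeric(correlation_cutoff), length(correlation_cutoff) == 1L)
  structure(
    list(threshold_pairs = threshold_pairs,
         probe_score_factor = probe_score_factor,
         medium_ratio_max = medium_ratio_max,
         undefined_freq_max = undefined_freq_max,
         correlation_cutoff = correlation_cutoff,
         present_call_min_fraction = present_call_min_fraction,
         rng_seed = as.integer(rng_seed)),
    class = "cape_config")
}

#' @export
print.cape_config <- function(x, ...) {
  cat("capeRNA analysis configuration\n")
  cat("  threshold pairs (f, n):",
      paste(sprintf("(%g, %g)", x$threshold_pairs[, 1], x$threshold_pairs[, 2]),
            collapse = " "), "\n")
  cat(sprintf("  probe score factor t: %g\n", x$probe_score_factor))
  cat(sprintf("  medium ratio max r_M: %g\n", x$medium_ratio_max))
  cat(sprintf("  undefined freq max u: %g\n", x$undefined_freq_max))
  cat(sprintf("  correlation cutoff:   %g\n", x$correlation_cutoff))
  cat(sprintf("  present-call min:     %g\n", x$present_call_min_fraction))
  cat(sprintf("  rng seed:             %d\n", x$rng_seed))
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' The mandatory keys are `threshold_pairs` (list of two-element `[f, n]`
#' lists), `probe_score_factor`, `medium_ratio_max` and `undefined_freq_max`;
#' a missing mandatory key is a hard error naming the key. Remaining keys fall
#' back to the [cape_config()] defaults.
#'
#' @param path file path.
#' @return [read_config()] returns a `cape_config`; [write_config()] returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mandatory <- c("threshold_pairs", "probe_score_factor",
                 "medium_ratio_max", "undefined_freq_max")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("config file ", path, " is missing mandatory key(s): ",
         paste(missing, collapse = ", "))
  tp <- do.call(rbind, lapply(raw$threshold_pairs, function(p) {
    if (length(p) != 2L) stop("each threshold pair must have two entries")
    as.numeric(p)
  }))
  args <- list(threshold_pairs = tp,
               probe_score_factor = raw$probe_score_factor,
               medium_ratio_max = raw$medium_ratio_max,
               undefined_freq_max = raw$undefined_freq_max)
  for (key in c("correlation_cutoff", "present_call_min_fraction", "rng_seed"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  do.call(cape_config, args)
}

#' @rdname read_config
#' @param config a `cape_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cape_config"))
  out <- list(
    threshold_pairs = lapply(seq_len(nrow(config$threshold_pairs)),
                             function(i) as.numeric(config$threshold_pairs[i, ])),
    probe_score_factor = config$probe_score_factor,
    medium_ratio_max = config$medium_ratio_max,
    undefined_freq_max = config$undefined_freq_max,
    correlation_cutoff = config$correlation_cutoff,
    present_call_min_fraction = config$present_call_min_fraction,
    rng_seed = config$rng_seed)
  yaml::write_yaml(out, path)
  invisible(path)
}
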
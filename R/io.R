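#' Read an expression matrix from TSV
#'
#' Expression tables are tab-separated with a header row of sample identifiers
#' and a first column (header literal `id`) of probe identifiers. Values are
#' log-normalized intensities. The reader validates rather than coerces:
#' duplicate probe ids, non-numeric cells and non-finite values are hard
#' errors naming the offender.
#'
#' @param path TSV file path.
#' @param entity `"miRNA"` or `"mRNA"`, recorded as an attribute.
#' @return numeric matrix (probes x samples) with `entity` attribute.
#' @export
read_expression <- function(path, entity = c("miRNA", "mRNA")) {
  entity <- match.arg(entity)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("expression table ", path, " needs >= 2 sample columns")
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate probe id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  samp <- colnames(tab)[-1L]
  if (anyDuplicated(samp))
    stop("duplicate sample id(s) in ", path)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric or non-finite value in ", path, " at probe '",
         ids[bad[1L, 1L]], "', sample '", samp[bad[1L, 2L]], "'")
  dimnames(num) <- list(ids, samp)
  attr(num, "entity") <- entity
  num
}

#' @rdname read_expression
#' @param mat numeric matrix with probe rownames and sample colnames.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping (two columns: probe_id, gene_id)
#'
#' Every probe must map to exactly one gene; genes may have many probes.
#' @param path TSV file path.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_gene_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("probe-gene map needs two columns")
  map <- data.frame(probe_id = tab[[1L]], gene_id = tab[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$probe_id))
    stop("probe(s) mapped to more than one gene: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", "))
  if (any(!nzchar(map$probe_id)) || any(!nzchar(map$gene_id)))
    stop("empty identifier in probe-gene map")
  map
}

#' Read a putative interaction catalog (two columns: mirna_id, gene_id)
#'
#' @param path TSV file path.
#' @return data.frame with columns `mirna_id`, `gene_id`; pairs unique.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("interaction catalog needs two columns")
  cat_ <- data.frame(mirna_id = tab[[1L]], gene_id = tab[[2L]],
                     stringsAsFactors = FALSE)
  if (any(!nzchar(cat_$mirna_id)) || any(!nzchar(cat_$gene_id)))
    stop("empty identifier in interaction catalog")
  if (anyDuplicated(cat_))
    stop("duplicate interaction pair(s) in catalog")
  cat_
}

#' Read sample group labels (two columns: sample_id, group)
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group table needs two columns")
  g <- data.frame(sample_id = tab[[1L]], group = tab[[2L]],
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$sample_id)) stop("duplicate sample id in group table")
  if (any(!nzchar(g$group))) stop("unlabeled sample in group table")
  g
}

#' Read a present-call indicator matrix (cells 0/1)
#'
#' @param path TSV file path, same layout as expression tables.
#' @return logical matrix (probes x samples).
#' @export
read_present_calls <- function(path) {
  m <- read_expression(path, entity = "mRNA")
  attr(m, "entity") <- NULL
  if (!all(m %in% c(0, 1)))
    stop("present-call matrix must contain only 0/1")
  mode(m) <- "logical"
  m
}

#' Filter probes by present-call fraction
#'
#' Keeps exactly the probes flagged present in at least `min_fraction` of the
#' samples (inclusive bound). Surviving rows keep their input order. When
#' `calls` is `NULL` the filter is skipped with a warning, since present calls
#' are an optional artifact of the normalization software.
#'
#' @param mat expression matrix (probes x samples).
#' @param calls logical/0-1 matrix aligned with `mat`, or `NULL`.
#' @param min_fraction minimum present fraction, default 0.2.
#' @return the filtered expression matrix.
#' @export
apply_present_call_filter <- function(mat, calls, min_fraction = 0.2) {
  if (is.null(calls)) {
    warning("no present calls supplied; present-call filter skipped")
    return(mat)
  }
  if (!all(dim(calls) == dim(mat)) ||
      !identical(rownames(calls), rownames(mat)) ||
      !identical(colnames(calls), colnames(mat)))
    stop("present-call matrix does not align with the expression matrix")
  keep <- rowMeans(calls == TRUE | calls == 1) >= min_fraction
  mat[keep, , drop = FALSE]
}

#' Write a generic result table as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
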
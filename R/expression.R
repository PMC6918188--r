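#' Load an expression meta-matrix from TSV
#'
#' Reads a gene-by-array matrix of M-values (log2 expression ratios). The
#' file must have a header row of array identifiers and a first column of
#' gene identifiers. Empty cells, `NA` and `nan` are treated as missing.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene ids as rownames and array ids as
#'   colnames; missing cells are `NA`.
#' @export
load_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression matrix must have at least 1 gene and 1 array", call. = FALSE)
  }
  gene_ids <- raw[[1]]
  array_ids <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(gene_ids, array_ids))
  na_tokens <- c("", "NA", "nan", "NaN")
  for (j in seq_len(ncol(vals))) {
    cell <- trimws(vals[, j])
    miss <- cell %in% na_tokens | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & (is.na(num) | !is.finite(num)))
    if (length(bad)) {
      stop(sprintf("malformed numeric cell at row '%s', column '%s': '%s'",
                   gene_ids[bad[1]], array_ids[j], cell[bad[1]]), call. = FALSE)
    }
    num[miss] <- NA_real_
    m[, j] <- num
  }
  validate_expression_matrix(m)
}

#' Validate a gene-by-array M-value matrix
#'
#' @param m numeric matrix, genes in rows (rownames), arrays in columns
#'   (colnames); values finite or `NA`.
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("expression matrix must have at least 1 gene and 1 array", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and array colnames", call. = FALSE)
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) {
    stop("duplicate array ids: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(is.infinite(m))) {
    stop("expression matrix contains non-finite (infinite) values", call. = FALSE)
  }
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [load_expression_matrix()]; values round-trip exactly
#' (written with full precision), missing cells as `NA`.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(m))
  df[-1][is.na(m)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call two-fold regulation states per array
#'
#' Divides genes, per array, into induced / suppressed / neutral by an
#' M-value threshold: induced when `M >= log2(cutoff)`, suppressed when
#' `M <= -log2(cutoff)` (boundary inclusive), neutral otherwise. The default
#' cutoff is 2 (two-fold); individual arrays (e.g. those with compressed
#' M-value ranges) can be given a lower cutoff such as 1.5 via
#' `per_array_cutoffs`.
#'
#' @param m expression matrix (see [validate_expression_matrix()]).
#' @param default_cutoff fold-change cutoff, must be > 1. Default 2.
#' @param per_array_cutoffs optional named numeric vector of per-array fold
#'   cutoffs overriding the default.
#' @return an object of class `regulation_calls`: list with `calls` (a
#'   character matrix over `"I"`, `"S"`, `"N"`, `NA`) and `fold_cutoff`
#'   (named numeric per array).
#' @examples
#' m <- matrix(c(1, 0, -0.6), 3, 1, dimnames = list(c("g1","g2","g3"), "a1"))
#' call_regulation(m, default_cutoff = 1.5)$calls
#' @export
call_regulation <- function(m, default_cutoff = 2, per_array_cutoffs = NULL) {
  m <- validate_expression_matrix(m)
  cutoffs <- stats::setNames(rep(default_cutoff, ncol(m)), colnames(m))
  if (!is.null(per_array_cutoffs)) {
    unknown <- setdiff(names(per_array_cutoffs), colnames(m))
    if (length(unknown)) {
      stop("per-array cutoff for unknown array: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cutoffs[names(per_array_cutoffs)] <- per_array_cutoffs
  }
  if (any(cutoffs <= 1)) {
    stop("fold cutoffs must be > 1", call. = FALSE)
  }
  thr <- log2(cutoffs)
  calls <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    cj <- ifelse(is.na(x), NA_character_,
                 ifelse(x >= thr[j], "I", ifelse(x <= -thr[j], "S", "N")))
    calls[, j] <- cj
  }
  structure(list(calls = calls, fold_cutoff = cutoffs),
            class = "regulation_calls")
}

#' @export
print.regulation_calls <- function(x, ...) {
  cat(sprintf("Regulation calls: %d genes x %d arrays\n",
              nrow(x$calls), ncol(x$calls)))
  tab <- table(factor(x$calls, levels = c("I", "S", "N")), useNA = "always")
  cat(sprintf("  induced %d, suppressed %d, neutral %d, missing %d\n",
              tab[["I"]], tab[["S"]], tab[["N"]], tab[[length(tab)]]))
  invisible(x)
}

#' Write regulation calls to TSV (values I/S/N/NA)
#' @param calls a `regulation_calls` object.
#' @param path output file.
#' @export
write_regulation_calls <- function(calls, path) {
  stopifnot(inherits(calls, "regulation_calls"))
  df <- data.frame(gene_id = rownames(calls$calls), calls$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Genome-wide background regulation rates for one array
#'
#' Proportions of induced / suppressed / neutral genes among the genes with
#' a non-missing call on the array; these are the expected rates against
#' which a CRE gene set is tested.
#'
#' @param calls a `regulation_calls` object.
#' @param array_id array identifier.
#' @return list with `array_id`, `n_called`, `p_induced`, `p_suppressed`,
#'   `p_neutral`.
#' @export
array_background <- function(calls, array_id) {
  stopifnot(inherits(calls, "regulation_calls"))
  if (!array_id %in% colnames(calls$calls)) {
    stop("unknown array: ", array_id, call. = FALSE)
  }
  v <- calls$calls[, array_id]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("degenerate array (zero non-missing calls): ", array_id, call. = FALSE)
  }
  n <- length(v)
  list(array_id = array_id, n_called = n,
       p_induced = sum(v == "I") / n,
       p_suppressed = sum(v == "S") / n,
       p_neutral = sum(v == "N") / n)
}

#' K-means co-expression clustering of M-value profiles
#'
#' Partitions genes into k clusters of similar expression profiles, used to
#' seed forward motif searches. Genes with more than 50% missing values are
#' dropped; remaining missing cells are imputed with per-array means for the
#' distance computation only. Clustering is Lloyd k-means with k distinct
#' seeded rows as initial centers, so the partition is deterministic given
#' the seed.
#'
#' @param m expression matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer RNG seed.
#' @param max_missing maximum tolerated fraction of missing cells per gene.
#' @return list of character vectors of gene ids (one per cluster), ordered
#'   by decreasing cluster size.
#' @export
cluster_coexpressed <- function(m, k, seed = 1L, max_missing = 0.5) {
  m <- validate_expression_matrix(m)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  keep <- rowMeans(is.na(m)) <= max_missing
  x <- m[keep, , drop = FALSE]
  if (k > nrow(x)) {
    stop(sprintf("k (%d) exceeds retained gene count (%d)", k, nrow(x)),
         call. = FALSE)
  }
  col_means <- colMeans(x, na.rm = TRUE)
  col_means[is.nan(col_means)] <- 0
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- col_means[j]
  }
  fit <- with_seed(seed, {
    centers <- x[seed_distinct_rows(x, k), , drop = FALSE]
    suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
    )
  })
  groups <- split(rownames(x), fit$cluster)
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  names(groups) <- NULL
  groups
}

# sample k row indices whose rows are pairwise distinct (as vectors)
seed_distinct_rows <- function(x, k) {
  key <- apply(x, 1, paste, collapse = "\r")
  uniq <- which(!duplicated(key))
  if (length(uniq) < k) {
    stop(sprintf("fewer than k = %d distinct expression profiles", k),
         call. = FALSE)
  }
  sample(uniq, k)
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
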
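#' Per-array z-score profile of a gene set
#'
#' For each array, Z = (X - mu) * sqrt(n) / delta, where X is the mean
#' M-value of the set's genes with non-missing values on that array, mu and
#' delta are the mean and (by default population) standard deviation of all
#' genes' M-values on the array, and n is the set's effective size there.
#' The Z profile across arrays summarises the average regulation of the
#' gene set and is the quantity correlated with TF expression. Z is missing
#' on arrays with no callable set gene or zero genome-wide variance.
#'
#' @param gene_set character vector of gene ids (subset of matrix genes).
#' @param m expression matrix.
#' @param sd_type `"population"` (default) or `"sample"` denominator for
#'   delta.
#' @param name profile name for reporting.
#' @return object of class `z_profile`: list with `name`, `z` (named
#'   numeric per array, NA when undefined), `n` (effective set size per
#'   array) and `flags`.
#' @examples
#' m <- matrix(rnorm(300), 100, 3,
#'             dimnames = list(sprintf("g%03d", 1:100), c("a1","a2","a3")))
#' zscore_profile(rownames(m)[1:10], m)$z
#' @export
zscore_profile <- function(gene_set, m, sd_type = c("population", "sample"),
                           name = "gene_set") {
  sd_type <- match.arg(sd_type)
  m <- validate_expression_matrix(m)
  unknown <- setdiff(gene_set, rownames(m))
  if (length(unknown)) {
    stop("gene set contains genes absent from the matrix: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  sub <- m[gene_set, , drop = FALSE]
  z <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  nn <- stats::setNames(integer(ncol(m)), colnames(m))
  flags <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[!is.na(col)]
    x <- sub[, j]
    x <- x[!is.na(x)]
    nn[j] <- length(x)
    if (length(x) == 0L) { flags <- c(flags, paste0("empty:", colnames(m)[j])); next }
    mu <- mean(col)
    delta <- if (sd_type == "population") {
      sqrt(mean((col - mu)^2))
    } else {
      stats::sd(col)
    }
    if (!is.finite(delta) || delta == 0) {
      flags <- c(flags, paste0("zero_variance:", colnames(m)[j]))
      next
    }
    z[j] <- (mean(x) - mu) * sqrt(length(x)) / delta
  }
  structure(list(name = name, z = z, n = nn, flags = flags),
            class = "z_profile")
}

#' @export
print.z_profile <- function(x, ...) {
  ok <- !is.na(x$z)
  cat(sprintf("Z profile '%s': %d arrays (%d defined), range [%.2f, %.2f]\n",
              x$name, length(x$z), sum(ok),
              if (any(ok)) min(x$z[ok]) else NA, if (any(ok)) max(x$z[ok]) else NA))
  invisible(x)
}

#' Correlate a CRE z-score profile with one TF's expression
#'
#' Pearson correlation r over pairwise-complete arrays between the gene
#' set's Z profile and the TF's M-values, with the t statistic
#' T = r * sqrt((n - 2) / (1 - r^2)) and a two-sided p-value from the t
#' distribution with n - 2 degrees of freedom. Associations with fewer
#' complete pairs than `n_min` (default: 80% of the arrays, rounded up)
#' are flagged `below_coverage` and excluded from ranking.
#'
#' @param zprofile a `z_profile`.
#' @param tf_gene_id TF gene id (must be a matrix row).
#' @param m expression matrix.
#' @param n_min minimum complete pairs; default `ceiling(0.8 * ncol(m))`.
#' @param tf_family optional family label.
#' @return one-row data.frame with `cre`, `tf`, `tf_family`, `r`,
#'   `n_pairs`, `T`, `p`, `strength`, `below_coverage`.
#' @export
correlate_tf <- function(zprofile, tf_gene_id, m, n_min = NULL,
                         tf_family = NA_character_) {
  stopifnot(inherits(zprofile, "z_profile"))
  m <- validate_expression_matrix(m)
  if (!tf_gene_id %in% rownames(m)) {
    stop("TF not present in matrix: ", tf_gene_id, call. = FALSE)
  }
  if (is.null(n_min)) n_min <- ceiling(0.8 * ncol(m))
  z <- zprofile$z[colnames(m)]
  tf <- m[tf_gene_id, ]
  ok <- !is.na(z) & !is.na(tf)
  n_pairs <- sum(ok)
  if (n_pairs < 3L) {
    return(data.frame(cre = zprofile$name, tf = tf_gene_id,
                      tf_family = tf_family, r = NA_real_, n_pairs = n_pairs,
                      T = NA_real_, p = NA_real_, strength = NA_character_,
                      below_coverage = TRUE, stringsAsFactors = FALSE))
  }
  r <- stats::cor(z[ok], tf[ok])
  if (is.na(r)) {
    tval <- NA_real_; p <- NA_real_
  } else if (abs(r) >= 1 - 1e-15) {
    tval <- sign(r) * Inf
    p <- .Machine$double.xmin
  } else {
    tval <- r * sqrt((n_pairs - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n_pairs - 2)
    if (p == 0) p <- .Machine$double.xmin
  }
  data.frame(cre = zprofile$name, tf = tf_gene_id, tf_family = tf_family,
             r = r, n_pairs = n_pairs, T = tval, p = p,
             strength = if (is.na(r)) NA_character_ else classify_strength(r),
             below_coverage = n_pairs < n_min, stringsAsFactors = FALSE)
}

#' Classify correlation strength
#'
#' Strong when |r| >= 0.5 (signed `strong+` / `strong-`), moderate when
#' 0.3 < |r| < 0.5, weak otherwise (|r| <= 0.3).
#'
#' @param r numeric vector of Pearson correlations in \[-1, 1\].
#' @return character vector of labels.
#' @examples
#' classify_strength(c(0.63, 0.45, -0.2))
#' @export
classify_strength <- function(r) {
  stopifnot(all(is.na(r) | (r >= -1 & r <= 1)))
  ifelse(is.na(r), NA_character_,
    ifelse(r >= 0.5, "strong+",
      ifelse(r <= -0.5, "strong-",
        ifelse(r > 0.3, "moderate+",
          ifelse(r < -0.3, "moderate-", "weak")))))
}

#' Build the full CRE-TF association table
#'
#' Runs [correlate_tf()] for every TF, attaches autoregulation flags when a
#' 1-kb-upstream hit table is supplied, and ranks by |r| (below-coverage
#' TFs sink to the bottom, unranked).
#'
#' @param zprofile a `z_profile` for the CRE gene set.
#' @param tf_table data.frame with columns `tf_gene_id` and optionally
#'   `family` (see [read_tf_list()]), or a character vector of TF ids.
#' @param m expression matrix.
#' @param hits_up1k optional `motif_hits` on up1k regions, for the
#'   autoregulation flag.
#' @param n_min minimum complete pairs (default 80% of arrays).
#' @return object of class `tf_association`: data.frame of associations
#'   sorted by decreasing |r| with an `autoregulated` column.
#' @export
tf_association_table <- function(zprofile, tf_table, m, hits_up1k = NULL,
                                 n_min = NULL) {
  if (is.character(tf_table)) {
    tf_table <- data.frame(tf_gene_id = tf_table, family = NA_character_,
                           stringsAsFactors = FALSE)
  }
  if (!"family" %in% colnames(tf_table)) tf_table$family <- NA_character_
  present <- tf_table$tf_gene_id %in% rownames(m)
  if (any(!present)) {
    warning(sum(!present), " TF(s) absent from the matrix were skipped",
            call. = FALSE)
  }
  tf_table <- tf_table[present, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tf_table)), function(i) {
    correlate_tf(zprofile, tf_table$tf_gene_id[i], m, n_min = n_min,
                 tf_family = tf_table$family[i])
  })
  out <- do.call(rbind, rows)
  if (!is.null(hits_up1k)) {
    flags <- autoregulation_flags(tf_table$tf_gene_id, hits_up1k)
    out$autoregulated <- flags[out$tf]
  } else {
    out$autoregulated <- NA
  }
  out <- out[order(out$below_coverage, -abs(out$r), out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tf_association", "data.frame"))
}

#' @export
print.tf_association <- function(x, ...) {
  cat(sprintf("TF associations for %s: %d TFs (%d strong, %d below coverage)\n",
              x$cre[1], nrow(x),
              sum(grepl("strong", x$strength), na.rm = TRUE),
              sum(x$below_coverage)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Autoregulation flags
#'
#' A TF is flagged autoregulated for a CRE when the TF's own gene carries
#' at least one occurrence of the CRE in its 1-kb upstream region.
#'
#' @param tf_ids character vector of TF gene ids.
#' @param hits a `motif_hits` object computed on up1k regions.
#' @return named logical vector; NA (with a warning) for TFs absent from
#'   the scanned annotation.
#' @export
autoregulation_flags <- function(tf_ids, hits) {
  stopifnot(inherits(hits, "motif_hits"))
  if (!identical(attr(hits, "region_kind"), "up1k")) {
    stop("autoregulation flags require hits on up1k regions", call. = FALSE)
  }
  universe <- attr(hits, "genes_scanned")
  carriers <- carrier_genes(hits)
  out <- stats::setNames(tf_ids %in% carriers, tf_ids)
  absent <- !tf_ids %in% universe
  if (any(absent)) {
    warning(sum(absent), " TF(s) absent from the annotation; flag set to NA",
            call. = FALSE)
    out[absent] <- NA
  }
  out
}

#' Read a TF list TSV (`tf_gene_id<TAB>family`)
#' @param path input file.
#' @return data.frame with `tf_gene_id` and `family`.
#' @export
read_tf_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!"tf_gene_id" %in% colnames(df)) {
    stop("TF list needs a 'tf_gene_id' column", call. = FALSE)
  }
  if (!"family" %in% colnames(df)) df$family <- NA_character_
  df
}

#' Export a CRE-TF network edge list
#'
#' Writes a TSV edge list (`cre`, `tf`, `r`, `T`, `p`, `sign`,
#' `autoregulated`, `tf_family`) of associations with |r| at or above the
#' threshold (inclusive), sorted by decreasing |r| then increasing p;
#' below-coverage associations are never exported. The file is loadable by
#' standard network tools.
#'
#' @param associations a `tf_association` table (or a list of them).
#' @param path output file.
#' @param r_threshold inclusive |r| cutoff (default 0.45).
#' @return the exported data.frame, invisibly.
#' @export
export_network <- function(associations, path, r_threshold = 0.45) {
  if (inherits(associations, "tf_association")) {
    associations <- list(associations)
  }
  all <- do.call(rbind, lapply(associations, as.data.frame))
  keep <- !all$below_coverage & !is.na(all$r) & abs(all$r) >= r_threshold
  edges <- all[keep, , drop = FALSE]
  edges <- edges[order(-abs(edges$r), edges$p), , drop = FALSE]
  out <- data.frame(cre = edges$cre, tf = edges$tf,
                    r = sprintf("%.6f", edges$r),
                    T = sprintf("%.6f", edges$T),
                    p = sprintf("%.6e", edges$p),
                    sign = ifelse(edges$r >= 0, "positive", "negative"),
                    autoregulated = edges$autoregulated,
                    tf_family = edges$tf_family, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}
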
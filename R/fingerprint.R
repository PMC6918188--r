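#' Chi-squared enrichment of regulation states in a gene set
#'
#' Tests, for one array, whether genes in the set are more often induced
#' (or suppressed, or differentially expressed) than expected from the
#' genome-wide background of that array. The test is a 1-df goodness-of-fit
#' chi-squared of the binary split (target state vs rest) against the
#' proportions from [array_background()] over all called genes; no
#' continuity correction is applied. `mode = "combined"` pools induced and
#' suppressed against neutral (the default binary form) or, with
#' `combined_classes = "three"`, performs the 2-df three-category test.
#' Genes with a missing call on the array are excluded from the set.
#'
#' @param gene_set character vector of gene ids (must be a subset of the
#'   matrix genes).
#' @param calls a `regulation_calls` object.
#' @param array_id array identifier.
#' @param mode `"induced"`, `"suppressed"` or `"combined"`.
#' @param combined_classes for `mode = "combined"`: `"binary"` (default,
#'   induced+suppressed vs neutral, 1 df) or `"three"` (2 df over all three
#'   categories).
#' @return list with `array_id`, `n`, `observed`, `expected` (both named
#'   over induced/suppressed/neutral), `chi2`, `p`, `df`, `direction`
#'   (`"enriched"`/`"depleted"`/`"none"`), and `flags` (character vector;
#'   `"low_expected"` when any expected cell < 5, `"zero_background"` when
#'   the background rate of the target state is zero but it was observed).
#' @examples
#' m <- matrix(rnorm(200), 100, 2,
#'             dimnames = list(sprintf("g%03d", 1:100), c("a1", "a2")))
#' calls <- call_regulation(m)
#' enrichment_test(rownames(m)[1:20], calls, "a1", mode = "induced")
#' @export
enrichment_test <- function(gene_set, calls, array_id,
                            mode = c("induced", "suppressed", "combined"),
                            combined_classes = c("binary", "three")) {
  mode <- match.arg(mode)
  combined_classes <- match.arg(combined_classes)
  stopifnot(inherits(calls, "regulation_calls"))
  unknown <- setdiff(gene_set, rownames(calls$calls))
  if (length(unknown)) {
    stop("gene set contains genes absent from the matrix: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  bg <- array_background(calls, array_id)
  v <- calls$calls[gene_set, array_id]
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) {
    stop("degenerate gene set: no non-missing calls on array ", array_id,
         call. = FALSE)
  }
  obs <- c(induced = sum(v == "I"), suppressed = sum(v == "S"),
           neutral = sum(v == "N"))
  exp_counts <- n * c(induced = bg$p_induced, suppressed = bg$p_suppressed,
                      neutral = bg$p_neutral)
  flags <- character(0)

  if (mode == "combined" && combined_classes == "three") {
    df <- 2L
    cells_o <- obs
    cells_e <- exp_counts
    o_t <- obs[["induced"]] + obs[["suppressed"]]
    e_t <- exp_counts[["induced"]] + exp_counts[["suppressed"]]
  } else {
    df <- 1L
    o_t <- switch(mode,
                  induced = obs[["induced"]],
                  suppressed = obs[["suppressed"]],
                  combined = obs[["induced"]] + obs[["suppressed"]])
    e_t <- switch(mode,
                  induced = exp_counts[["induced"]],
                  suppressed = exp_counts[["suppressed"]],
                  combined = exp_counts[["induced"]] + exp_counts[["suppressed"]])
    cells_o <- c(target = o_t, rest = n - o_t)
    cells_e <- c(target = e_t, rest = n - e_t)
  }

  if (any(cells_e < 5)) flags <- c(flags, "low_expected")
  zero <- cells_e == 0
  if (any(zero & cells_o > 0)) {
    flags <- c(flags, "zero_background")
    chi2 <- Inf
    p <- .Machine$double.xmin
  } else {
    chi2 <- sum((cells_o[!zero] - cells_e[!zero])^2 / cells_e[!zero])
    p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
    if (p == 0) p <- .Machine$double.xmin
  }
  direction <- if (o_t > e_t) "enriched" else if (o_t < e_t) "depleted" else "none"
  list(array_id = array_id, n = n, observed = obs, expected = exp_counts,
       chi2 = unname(chi2), p = unname(p), df = df, direction = direction,
       flags = flags)
}

#' Assemble the regulatory fingerprint of a CRE
#'
#' Scans a region set for the pattern (or takes precomputed hits), takes
#' the genes with at least one occurrence as the CRE gene set, and runs
#' [enrichment_test()] in all three modes (induced-only, suppressed-only,
#' combined) on every array of the expression matrix. The resulting vector
#' of per-array enrichment significance is the CRE's regulatory
#' fingerprint. Arrays where the test is degenerate (no callable genes)
#' are reported as flagged rows, not failures.
#'
#' @param pattern a `motif_pattern` or IUPAC string.
#' @param regions a `region_set`, or a precomputed `motif_hits` object for
#'   the same pattern.
#' @param calls a `regulation_calls` object.
#' @param name CRE name for reporting (defaults to the pattern name).
#' @param alpha significance level for the per-array calls (default 0.05).
#' @param combined_classes passed to [enrichment_test()].
#' @param correction `"none"` (default; raw p-values, the published
#'   convention) or `"bh"` for Benjamini-Hochberg adjustment of each mode's
#'   p-values across arrays.
#' @return object of class `cre_fingerprint`: list with `cre`, `pattern`,
#'   `region_kind`, `n_genes` (carriers), `alpha` and `results`, a
#'   data.frame with one row per array (columns `array_id`, `n`, observed
#'   and expected counts, `chi2_*`, `p_*` for the three modes, `direction`,
#'   `significant`, `flags`).
#' @export
regulatory_fingerprint <- function(pattern, regions, calls, name = NULL,
                                   alpha = 0.05,
                                   combined_classes = c("binary", "three"),
                                   correction = c("none", "bh")) {
  combined_classes <- match.arg(combined_classes)
  correction <- match.arg(correction)
  if (inherits(regions, "motif_hits")) {
    hits <- regions
    pattern <- attr(hits, "pattern")
  } else {
    if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
    hits <- scan_region_set(regions, pattern)
  }
  genes <- intersect(carrier_genes(hits), rownames(calls$calls))
  if (length(genes) == 0L) {
    stop("pattern ", pattern$iupac, " occurs in no gene of the matrix",
         call. = FALSE)
  }
  if (is.null(name)) name <- pattern$name
  res <- fingerprint_rows(genes, calls, alpha, combined_classes)
  if (correction == "bh") {
    for (col in c("p_induced", "p_suppressed", "p_combined")) {
      res[[col]] <- stats::p.adjust(res[[col]], method = "BH")
    }
    res$significant <- !is.na(res$p_induced) &
      (pmin(res$p_induced, res$p_suppressed, res$p_combined) < alpha)
  }
  structure(list(cre = name, pattern = pattern$iupac,
                 region_kind = attr(hits, "region_kind"),
                 n_genes = length(genes), alpha = alpha, results = res),
            class = "cre_fingerprint")
}

# one row of enrichment results per array for a fixed gene set
fingerprint_rows <- function(genes, calls, alpha, combined_classes = "binary") {
  arrays <- colnames(calls$calls)
  rows <- lapply(arrays, function(a) {
    out <- tryCatch({
      ti <- enrichment_test(genes, calls, a, "induced")
      ts <- enrichment_test(genes, calls, a, "suppressed")
      tc <- enrichment_test(genes, calls, a, "combined",
                            combined_classes = combined_classes)
      data.frame(
        array_id = a, n = ti$n,
        obs_induced = ti$observed[["induced"]],
        obs_suppressed = ti$observed[["suppressed"]],
        obs_neutral = ti$observed[["neutral"]],
        exp_induced = ti$expected[["induced"]],
        exp_suppressed = ti$expected[["suppressed"]],
        exp_neutral = ti$expected[["neutral"]],
        chi2_induced = ti$chi2, p_induced = ti$p,
        chi2_suppressed = ts$chi2, p_suppressed = ts$p,
        chi2_combined = tc$chi2, p_combined = tc$p,
        dir_induced = ti$direction, dir_suppressed = ts$direction,
        flags = paste(unique(c(ti$flags, ts$flags, tc$flags)), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(array_id = a, n = 0L, obs_induced = NA_integer_,
                 obs_suppressed = NA_integer_, obs_neutral = NA_integer_,
                 exp_induced = NA_real_, exp_suppressed = NA_real_,
                 exp_neutral = NA_real_, chi2_induced = NA_real_,
                 p_induced = NA_real_, chi2_suppressed = NA_real_,
                 p_suppressed = NA_real_, chi2_combined = NA_real_,
                 p_combined = NA_real_, dir_induced = NA_character_,
                 dir_suppressed = NA_character_, flags = "degenerate",
                 stringsAsFactors = FALSE)
    })
    out
  })
  res <- do.call(rbind, rows)
  res$significant <- !is.na(res$p_induced) &
    (pmin(res$p_induced, res$p_suppressed, res$p_combined) < alpha)
  res
}

#' @export
print.cre_fingerprint <- function(x, ...) {
  cat(sprintf("Regulatory fingerprint of %s (%s, %s): %d carrier genes\n",
              x$cre, x$pattern, x$region_kind, x$n_genes))
  sig <- x$results[x$results$significant & !is.na(x$results$p_induced), ]
  cat(sprintf("  significant (alpha = %g) in %d / %d arrays\n", x$alpha,
              nrow(sig), nrow(x$results)))
  if (nrow(sig)) {
    for (i in seq_len(min(nrow(sig), 10L))) {
      r <- sig[i, ]
      cat(sprintf("  %s: p_ind = %.3g (%s), p_sup = %.3g (%s)\n", r$array_id,
                  r$p_induced, r$dir_induced, r$p_suppressed, r$dir_suppressed))
    }
    if (nrow(sig) > 10L) cat(sprintf("  ... and %d more\n", nrow(sig) - 10L))
  }
  invisible(x)
}

#' Stratified regulatory fingerprints
#'
#' Splits the carrier genes by position, orientation or copy number
#' ([stratify_hits()]) and tests each stratum's gene set independently
#' against the same genome background. Strata smaller than `min_stratum_n`
#' are flagged `underpowered` but still reported.
#'
#' @param hits a `motif_hits` object.
#' @param calls a `regulation_calls` object.
#' @param mode `"position"`, `"orientation"` or `"copy_number"`.
#' @param arrays optional subset of array ids to test (default: all).
#' @param min_stratum_n minimum stratum size before the underpowered flag
#'   (default 20).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (stratum, array): enrichment
#'   columns as in [regulatory_fingerprint()] plus `stratum`,
#'   `stratum_n` and `underpowered`.
#' @export
stratified_fingerprint <- function(hits, calls,
                                   mode = c("position", "orientation", "copy_number"),
                                   arrays = NULL, min_stratum_n = 20,
                                   alpha = 0.05) {
  mode <- match.arg(mode)
  strata <- stratify_hits(hits, mode)
  strata <- lapply(strata, intersect, y = rownames(calls$calls))
  if (all(vapply(strata, length, integer(1)) == 0L)) {
    stop("all strata are empty", call. = FALSE)
  }
  if (!is.null(arrays)) {
    calls$calls <- calls$calls[, arrays, drop = FALSE]
  }
  out <- lapply(names(strata), function(s) {
    genes <- strata[[s]]
    if (length(genes) == 0L) return(NULL)
    res <- fingerprint_rows(genes, calls, alpha)
    cbind(data.frame(stratum = s, stratum_n = length(genes),
                     underpowered = length(genes) < min_stratum_n,
                     stringsAsFactors = FALSE), res)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Tabular fingerprint report
#'
#' One row per (CRE, array) with the three p-values split by direction;
#' the significance matrix encodes each (CRE, array) cell as `N` when no
#' test reaches `alpha`, otherwise as `p_ind:<p>` / `p_sup:<p>` entries
#' (induced-only / suppressed-only significance), mirroring the usual
#' published layout. Output is deterministic: numbers are fixed-format.
#'
#' @param fingerprints list of `cre_fingerprint` objects.
#' @param path optional output prefix; writes `<path>_report.tsv` and
#'   `<path>_matrix.tsv`.
#' @param alpha significance level used for the `N` coding (default: each
#'   fingerprint's own alpha).
#' @return list with `table` (long data.frame) and `matrix` (CRE x array
#'   character matrix), invisibly when `path` is given.
#' @export
fingerprint_report <- function(fingerprints, path = NULL, alpha = NULL) {
  if (inherits(fingerprints, "cre_fingerprint")) {
    fingerprints <- list(fingerprints)
  }
  long <- do.call(rbind, lapply(fingerprints, function(fp) {
    r <- fp$results
    data.frame(cre = fp$cre, pattern = fp$pattern, array = r$array_id,
               n = r$n, p_induced = r$p_induced,
               p_suppressed = r$p_suppressed, p_combined = r$p_combined,
               direction = ifelse(is.na(r$dir_induced), "NA",
                                  paste0("ind:", r$dir_induced, ";sup:",
                                         r$dir_suppressed)),
               flags = r$flags, stringsAsFactors = FALSE)
  }))
  arrays <- unique(long$array)
  cres <- vapply(fingerprints, `[[`, character(1), "cre")
  mat <- matrix("N", length(cres), length(arrays),
                dimnames = list(cres, arrays))
  for (fp in fingerprints) {
    a <- if (is.null(alpha)) fp$alpha else alpha
    r <- fp$results
    for (i in seq_len(nrow(r))) {
      if (is.na(r$p_induced[i])) { mat[fp$cre, r$array_id[i]] <- "NA"; next }
      parts <- character(0)
      if (r$p_induced[i] < a) {
        parts <- c(parts, sprintf("p_ind:%.3e", r$p_induced[i]))
      }
      if (r$p_suppressed[i] < a) {
        parts <- c(parts, sprintf("p_sup:%.3e", r$p_suppressed[i]))
      }
      if (length(parts)) mat[fp$cre, r$array_id[i]] <- paste(parts, collapse = ";")
    }
  }
  out <- list(table = long, matrix = mat)
  if (!is.null(path)) {
    tab <- long
    for (col in c("p_induced", "p_suppressed", "p_combined")) {
      tab[[col]] <- sprintf("%.6e", tab[[col]])
    }
    utils::write.table(tab, paste0(path, "_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mdf <- data.frame(cre = rownames(mat), mat, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(mdf, paste0(path, "_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Compose a CRE name in the OS_<REGION>_<NNN> convention
#'
#' Novel motifs are named by the region they were discovered in (1K, 3K,
#' 5U, UT for introns, 1D) and their discovery order, zero-padded to three
#' digits, e.g. `OS_1K_001` for the first motif from 1-kb upstream regions.
#'
#' @param region_kind one of the five region kinds.
#' @param index discovery order (1-based).
#' @return character name.
#' @export
cre_name <- function(region_kind, index) {
  region_kind <- match.arg(region_kind, REGION_KINDS)
  sprintf("OS_%s_%03d", REGION_CODES[[region_kind]], as.integer(index))
}
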
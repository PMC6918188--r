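#' Construct a degenerate motif pattern
#'
#' @param iupac pattern string over the 15-letter IUPAC alphabet, length
#'   4 to 25.
#' @param name optional pattern name (defaults to the IUPAC string).
#' @return object of class `motif_pattern` with fields `name`, `iupac`,
#'   `width` and `is_palindromic` (whether the pattern equals its own
#'   reverse complement as a degenerate set; computed, never user-set).
#' @examples
#' motif_pattern("CACGTG", "G-box")$is_palindromic  # TRUE
#' @export
motif_pattern <- function(iupac, name = iupac) {
  iupac <- toupper(iupac)
  check_iupac(iupac)
  w <- nchar(iupac)
  if (w < 4L || w > 25L) {
    stop("pattern length must be between 4 and 25 nt: ", iupac, call. = FALSE)
  }
  structure(list(name = name, iupac = iupac, width = w,
                 is_palindromic = identical(reverse_complement(iupac), iupac)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("Motif pattern %s: %s (%d nt%s)\n", x$name, x$iupac, x$width,
              if (x$is_palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Compile an IUPAC pattern into a matcher
#'
#' The matcher recognises exactly the set product of each position's base
#' set, with PATMATCH semantics: all (possibly overlapping) occurrences are
#' reported, and an `N` in the subject sequence never matches any pattern
#' position. Implemented as a perl regex with a capturing lookahead (so
#' overlapping matches are found); subject `N` is a literal absent from
#' every character class, which realises the N rule.
#'
#' @param iupac pattern string (or `motif_pattern`).
#' @return function `(sequence) -> integer vector` of 1-based match start
#'   offsets.
#' @examples
#' m <- compile_pattern("RCCGAC")
#' m("GCCGAC"); m("CCCGAC")
#' @export
compile_pattern <- function(iupac) {
  if (inherits(iupac, "motif_pattern")) iupac <- iupac$iupac
  iupac <- toupper(iupac)
  check_iupac(iupac)
  classes <- vapply(strsplit(iupac, "", fixed = TRUE)[[1]], function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  rx <- paste0("(?=", paste(classes, collapse = ""), ")")
  force(rx)
  function(sequence) {
    hits <- gregexpr(rx, toupper(sequence), perl = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
}

#' Scan a region set for a degenerate pattern
#'
#' Reports every occurrence of the pattern in every gene's region sequence,
#' on the forward strand and (unless `strands = "forward_only"`) the
#' reverse strand. For palindromic patterns only the forward scan is
#' performed, so occurrences are never double-counted. For upstream regions
#' (`up1k`/`up3k`) positions are reported as upstream distance: the 1-based
#' distance from the TSS to the occurrence base nearest the TSS (for both
#' orientations); for other kinds the 1-based in-region offset is reported.
#'
#' @param regions a `region_set`.
#' @param pattern a `motif_pattern` (or IUPAC string).
#' @param strands `"both"` (default) or `"forward_only"`.
#' @return object of class `motif_hits`: data.frame with columns `gene_id`,
#'   `region`, `pattern`, `distance`, `orientation` (one row per
#'   occurrence), with attributes `pattern` (the `motif_pattern`) and
#'   `genes_scanned` (all gene ids in the region set, the scan universe).
#' @export
scan_region_set <- function(regions, pattern, strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  stopifnot(inherits(regions, "region_set"))
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  if (length(regions$sequences) == 0L) {
    stop("region set is empty", call. = FALSE)
  }
  w <- pattern$width
  upstream <- regions$kind %in% c("up1k", "up3k")
  if (all(nchar(regions$sequences) < w)) {
    warning("pattern longer than every sequence; empty hit table",
            call. = FALSE)
  }
  fwd <- compile_pattern(pattern$iupac)
  rev_scan <- strands == "both" && !pattern$is_palindromic
  if (rev_scan) rev_matcher <- compile_pattern(reverse_complement(pattern$iupac))

  rows <- vector("list", length(regions$sequences))
  for (i in seq_along(regions$sequences)) {
    s <- regions$sequences[[i]]
    gid <- names(regions$sequences)[i]
    L <- nchar(s)
    if (L < w) next
    starts <- fwd(s)
    ori <- rep("forward", length(starts))
    if (rev_scan) {
      # occurrences of the reverse-complement pattern on the forward string
      # are reverse-orientation occurrences of the pattern itself
      rstarts <- rev_matcher(s)
      starts <- c(starts, rstarts)
      ori <- c(ori, rep("reverse", length(rstarts)))
    }
    if (!length(starts)) next
    dist <- if (upstream) L - (starts + w - 1L) + 1L else starts
    rows[[i]] <- data.frame(gene_id = gid, region = regions$kind,
                            pattern = pattern$name, distance = dist,
                            orientation = ori, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), region = character(0),
                      pattern = character(0), distance = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(match(out$gene_id, names(regions$sequences)), out$distance), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, pattern = pattern, region_kind = regions$kind,
            genes_scanned = names(regions$sequences),
            class = c("motif_hits", "data.frame"))
}

#' Gene-level copy numbers from a hit table
#' @param hits a `motif_hits` object.
#' @return named integer vector: occurrences per gene (genes with >= 1 hit).
#' @export
copy_number <- function(hits) {
  stopifnot(inherits(hits, "motif_hits"))
  tab <- table(hits$gene_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Genes carrying at least one occurrence
#' @param hits a `motif_hits` object.
#' @return character vector of gene ids.
#' @export
carrier_genes <- function(hits) {
  stopifnot(inherits(hits, "motif_hits"))
  unique(hits$gene_id)
}

#' Stratify motif hits by position, orientation or copy number
#'
#' Position strata are 200-bp upstream bins (1-200, 201-400, ...); a gene
#' appears in every bin where it has an occurrence. Orientation strata are
#' genes with >= 1 forward hit vs genes with >= 1 reverse hit (a gene may
#' appear in both); for palindromic patterns all genes fall in the forward
#' stratum. Copy-number strata are exact per-gene occurrence counts 1, 2, 3
#' and ">=4".
#'
#' @param hits a `motif_hits` object.
#' @param mode `"position"`, `"orientation"` or `"copy_number"`. Position
#'   mode is only valid for upstream regions.
#' @return named list of character vectors of gene ids, one per stratum.
#' @export
stratify_hits <- function(hits, mode = c("position", "orientation", "copy_number")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hits, "motif_hits"))
  kind <- attr(hits, "region_kind")
  if (mode == "position") {
    if (!kind %in% c("up1k", "up3k")) {
      stop("position stratification applies only to upstream regions",
           call. = FALSE)
    }
    region_len <- if (kind == "up3k") 3000L else 1000L
    n_bins <- region_len %/% 200L
    bin <- pmin(((hits$distance - 1L) %/% 200L) + 1L, n_bins)
    labels <- sprintf("%d-%d", (seq_len(n_bins) - 1L) * 200L + 1L,
                      seq_len(n_bins) * 200L)
    out <- lapply(seq_len(n_bins), function(b) unique(hits$gene_id[bin == b]))
    names(out) <- labels
  } else if (mode == "orientation") {
    out <- list(
      forward = unique(hits$gene_id[hits$orientation == "forward"]),
      reverse = unique(hits$gene_id[hits$orientation == "reverse"])
    )
  } else {
    cn <- copy_number(hits)
    out <- list(
      `1` = names(cn)[cn == 1L],
      `2` = names(cn)[cn == 2L],
      `3` = names(cn)[cn == 3L],
      `>=4` = names(cn)[cn >= 4L]
    )
  }
  out
}

#' Read a pattern catalog TSV (`name<TAB>iupac<TAB>source`)
#' @param path catalog file.
#' @return data.frame with columns `name`, `iupac`, `source`.
#' @export
read_pattern_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("name", "iupac") %in% colnames(df))) {
    stop("pattern catalog needs 'name' and 'iupac' columns", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("pattern catalog is empty", call. = FALSE)
  check_iupac(df$iupac)
  df
}

#' Write a hit table to TSV
#' @param hits a `motif_hits` object.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
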
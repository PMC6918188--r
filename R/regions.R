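REGION_KINDS <- c("up1k", "up3k", "utr5", "intron", "down1k")

# region -> code used in CRE names (OS_<code>_<NNN>)
REGION_CODES <- c(up1k = "1K", up3k = "3K", utr5 = "5U", intron = "UT",
                  down1k = "1D")

# separator between concatenated introns: one run of 30 N's, longer than the
# maximum pattern width (25), so no pattern can bridge two introns
INTRON_SEPARATOR <- strrep("N", 30)

#' Parse gene models from a GFF3 annotation
#'
#' Builds one gene model per gene from `gene`/`mRNA`/`exon` (and optionally
#' `five_prime_UTR`, `CDS`) features. When a gene has several mRNAs, the one
#' with the longest genomic span is used. The transcription start site (TSS)
#' is the mRNA 5' end; the translational stop (TSC) is the CDS 3' end in
#' transcription direction (falling back to the mRNA 3' end when no CDS is
#' annotated). Genes without exons are skipped with a warning.
#'
#' @param gff3 path to a GFF3 file (1-based inclusive coordinates).
#' @param contig_lengths optional named integer vector of contig lengths;
#'   when given, coordinates outside a contig raise an error.
#' @return an object of class `gene_models`: a named list of gene models,
#'   each a list with `gene_id`, `chrom`, `strand`, `tss`, `tsc`,
#'   `mrna_start`, `mrna_end`, and two-column matrices `exons`, `utr5`,
#'   `introns` (start, end; genomic, ascending).
#' @export
parse_annotation <- function(gff3, contig_lengths = NULL) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  # plain vectors up front: S4 subsetting inside the per-gene loop is slow
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  parent <- gr$Parent  # CharacterList
  plen <- S4Vectors::elementNROWS(parent)
  parent1 <- rep(NA_character_, length(gr))
  parent1[plen > 0L] <- unlist(parent)[cumsum(plen)[plen > 0L]]

  by_parent <- split(seq_along(gr), parent1)
  children <- function(id, kinds) {
    idx <- by_parent[[id]]
    idx[type[idx] %in% kinds]
  }

  genes <- which(type == "gene")
  models <- vector("list", length(genes))
  names(models) <- ids[genes]
  for (g in seq_along(genes)) {
    gi <- genes[g]
    gid <- ids[gi]
    mrnas <- children(gid, c("mRNA", "transcript"))
    if (length(mrnas) == 0L) {
      warning("gene without mRNA skipped: ", gid, call. = FALSE)
      next
    }
    mi <- mrnas[which.max(ends[mrnas] - starts[mrnas])]
    mid <- ids[mi]
    exons <- children(mid, "exon")
    if (length(exons) == 0L) {
      warning("gene without exons skipped: ", gid, call. = FALSE)
      next
    }
    chrom <- chroms[mi]
    strand <- strands[mi]
    if (!strand %in% c("+", "-")) {
      warning("gene with unstranded mRNA skipped: ", gid, call. = FALSE)
      next
    }
    ms <- starts[mi]; me <- ends[mi]
    if (!is.null(contig_lengths)) {
      if (!chrom %in% names(contig_lengths)) {
        stop("unknown contig in annotation: ", chrom, call. = FALSE)
      }
      if (ms < 1L || me > contig_lengths[[chrom]]) {
        stop(sprintf("coordinates of %s outside contig %s", gid, chrom),
             call. = FALSE)
      }
    }
    ex <- sort_intervals(starts[exons], ends[exons])
    utr_idx <- children(mid, "five_prime_UTR")
    utr5 <- if (length(utr_idx)) {
      sort_intervals(starts[utr_idx], ends[utr_idx])
    } else {
      matrix(integer(0), 0, 2)
    }
    cds_idx <- children(mid, "CDS")
    tss <- if (strand == "+") ms else me
    tsc <- if (length(cds_idx)) {
      if (strand == "+") max(ends[cds_idx]) else min(starts[cds_idx])
    } else {
      if (strand == "+") me else ms
    }
    models[[gid]] <- list(
      gene_id = gid, chrom = chrom, strand = strand,
      tss = tss, tsc = tsc, mrna_start = ms, mrna_end = me,
      exons = ex, utr5 = utr5, introns = interval_gaps(ex)
    )
  }
  models <- models[!vapply(models, is.null, logical(1))]
  if (length(models) == 0L) stop("no usable gene models found", call. = FALSE)
  structure(models, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  strands <- vapply(x, `[[`, character(1), "strand")
  cat(sprintf("%d gene models (%d on +, %d on -)\n",
              length(x), sum(strands == "+"), sum(strands == "-")))
  invisible(x)
}

sort_intervals <- function(s, e) {
  o <- order(s)
  m <- cbind(start = s[o], end = e[o])
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2])) {
    stop("overlapping exons in gene model", call. = FALSE)
  }
  m
}

# gaps between sorted non-overlapping intervals (the introns)
interval_gaps <- function(m) {
  if (nrow(m) < 2) return(matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("start", "end"))))
  cbind(start = m[-nrow(m), 2] + 1L, end = m[-1, 1] - 1L)
}

#' Extract one analysis region for one gene
#'
#' Returns the region sequence written 5' to 3' in the gene's reading
#' orientation. For upstream/downstream kinds the region is measured from
#' the TSS / the base after the translational stop codon and truncated at
#' contig boundaries (a zero-length result at a contig edge is returned
#' with a warning, the gene is retained). Introns are concatenated with a
#' 30-N separator so no motif can bridge two introns.
#'
#' @param genome a `Biostrings::DNAStringSet` (or named character vector).
#' @param model one element of a [parse_annotation()] result.
#' @param kind one of `"up1k"`, `"up3k"`, `"utr5"`, `"intron"`, `"down1k"`.
#' @param length region length in bp for up/down kinds (defaults: 1000 for
#'   up1k/down1k, 3000 for up3k).
#' @return list with `sequence` (character) and `interval` (data.frame of
#'   genomic start/end used, ascending coordinates).
#' @export
extract_region <- function(genome, model, kind, length = NULL) {
  kind <- match.arg(kind, REGION_KINDS)
  genome <- as_dnastringset(genome)
  if (!model$chrom %in% names(genome)) {
    stop("unknown chrom: ", model$chrom, call. = FALSE)
  }
  contig <- genome[[model$chrom]]
  L <- Biostrings::nchar(contig)
  minus <- model$strand == "-"
  if (is.null(length)) {
    length <- switch(kind, up3k = 3000L, 1000L)
  }

  fetch <- function(s, e, rc) {
    s <- max(1L, s); e <- min(L, e)
    if (s > e) return("")
    x <- Biostrings::subseq(contig, s, e)
    if (rc) x <- Biostrings::reverseComplement(x)
    as.character(x)
  }

  if (kind %in% c("up1k", "up3k")) {
    if (minus) { s <- model$tss + 1L; e <- model$tss + length }
    else       { s <- model$tss - length; e <- model$tss - 1L }
    seq <- fetch(s, e, minus)
    iv <- data.frame(start = max(1L, s), end = min(L, e))
  } else if (kind == "down1k") {
    if (minus) { s <- model$tsc - length; e <- model$tsc - 1L }
    else       { s <- model$tsc + 1L; e <- model$tsc + length }
    seq <- fetch(s, e, minus)
    iv <- data.frame(start = max(1L, s), end = min(L, e))
  } else if (kind == "utr5") {
    m <- model$utr5
    if (nrow(m) == 0L) {
      seq <- ""; iv <- data.frame(start = integer(0), end = integer(0))
    } else {
      ord <- if (minus) rev(seq_len(nrow(m))) else seq_len(nrow(m))
      seq <- paste(vapply(ord, function(i) fetch(m[i, 1], m[i, 2], minus),
                          character(1)), collapse = "")
      iv <- data.frame(start = m[, 1], end = m[, 2])
    }
  } else { # intron
    m <- model$introns
    if (nrow(m) == 0L) {
      seq <- ""; iv <- data.frame(start = integer(0), end = integer(0))
    } else {
      ord <- if (minus) rev(seq_len(nrow(m))) else seq_len(nrow(m))
      seq <- paste(vapply(ord, function(i) fetch(m[i, 1], m[i, 2], minus),
                          character(1)), collapse = INTRON_SEPARATOR)
      iv <- data.frame(start = m[, 1], end = m[, 2])
    }
  }
  if (nchar(seq) == 0L) {
    warning(sprintf("zero-length %s region for gene %s", kind, model$gene_id),
            call. = FALSE)
  }
  list(sequence = seq, interval = iv)
}

#' Extract a region set (one region kind, all genes)
#'
#' @param genome `DNAStringSet` or named character vector of contigs.
#' @param models a `gene_models` object.
#' @inheritParams extract_region
#' @return an object of class `region_set`: list with `kind`, `sequences`
#'   (named character, 5'->3' in gene orientation) and `intervals`.
#' @export
extract_regions <- function(genome, models, kind, length = NULL) {
  genome <- as_dnastringset(genome)
  entries <- lapply(models, extract_region, genome = genome, kind = kind,
                    length = length)
  structure(list(
    kind = kind,
    sequences = vapply(entries, `[[`, character(1), "sequence"),
    intervals = lapply(entries, `[[`, "interval")
  ), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  n <- length(x$sequences)
  cat(sprintf("Region set '%s': %d genes, median length %d bp\n", x$kind, n,
              as.integer(stats::median(nchar(x$sequences)))))
  invisible(x)
}

#' Write a region set as FASTA
#'
#' Headers follow `>gene_id|kind|chrom:start-end(strand)`.
#'
#' @param regions a `region_set`.
#' @param models the `gene_models` the regions came from.
#' @param path output FASTA file.
#' @export
write_regions_fasta <- function(regions, models, path) {
  keep <- nchar(regions$sequences) > 0L
  ids <- names(regions$sequences)[keep]
  headers <- vapply(ids, function(g) {
    mo <- models[[g]]
    iv <- regions$intervals[[g]]
    sprintf("%s|%s|%s:%d-%d(%s)", g, regions$kind, mo$chrom,
            min(iv$start), max(iv$end), mo$strand)
  }, character(1))
  dss <- Biostrings::DNAStringSet(regions$sequences[keep])
  names(dss) <- headers
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

as_dnastringset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) return(Biostrings::DNAStringSet(genome))
  stop("genome must be a DNAStringSet or named character vector", call. = FALSE)
}
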
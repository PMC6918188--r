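#' Specification of a motif planting
#'
#' @param pattern IUPAC pattern (string or `motif_pattern`).
#' @param fraction fraction of genes to carry the motif, in (0, 1].
#' @param copies named numeric distribution over copy numbers `"1"`..`"4"`
#'   (must sum to 1). Default: single copy.
#' @param positions optional named numeric distribution over 200-bp
#'   upstream bins (`"1-200"`, ...; must sum to 1). Default: uniform over
#'   the region.
#' @param orientation `"forward"`, `"reverse"` or `"both"` (both = each
#'   copy random).
#' @param region_kind region to plant into (default `"up1k"`).
#' @return object of class `planting_spec`.
#' @export
planting_spec <- function(pattern, fraction, copies = c(`1` = 1),
                          positions = NULL,
                          orientation = c("forward", "reverse", "both"),
                          region_kind = "up1k") {
  orientation <- match.arg(orientation)
  region_kind <- match.arg(region_kind, REGION_KINDS)
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  if (abs(sum(copies) - 1) > 1e-9) stop("copies distribution must sum to 1", call. = FALSE)
  if (!all(names(copies) %in% c("1", "2", "3", "4"))) {
    stop("copies distribution is over copy numbers 1..4", call. = FALSE)
  }
  if (!is.null(positions) && abs(sum(positions) - 1) > 1e-9) {
    stop("positions distribution must sum to 1", call. = FALSE)
  }
  structure(list(pattern = pattern, fraction = fraction, copies = copies,
                 positions = positions, orientation = orientation,
                 region_kind = region_kind),
            class = "planting_spec")
}

#' Specification of an expression effect tied to motif carriers
#'
#' @param responsive_arrays array ids (or indices) where the effect acts.
#' @param direction `"induce"` (M shifted by +delta) or `"suppress"`
#'   (-delta).
#' @param delta M-value shift for responders (default 1.5).
#' @param responder_fraction fraction of carrier genes that respond
#'   (default 0.5).
#' @param noise_sd standard deviation of responder M-values around the
#'   shift (default 0.5).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(responsive_arrays, direction = c("induce", "suppress"),
                        delta = 1.5, responder_fraction = 0.5,
                        noise_sd = 0.5) {
  direction <- match.arg(direction)
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("responder_fraction must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(responsive_arrays = responsive_arrays, direction = direction,
                 delta = delta, responder_fraction = responder_fraction,
                 noise_sd = noise_sd),
            class = "effect_spec")
}

# fixed gene geometry (bp, transcription direction):
# exon1 = 5'UTR (120) + CDS (180), intron 150, exon2 = CDS (150) + 3'UTR (100)
GENE_GEOMETRY <- list(utr5 = 120L, cds1 = 180L, intron = 150L, cds2 = 150L,
                      utr3 = 100L)

gene_span <- function() {
  g <- GENE_GEOMETRY
  g$utr5 + g$cds1 + g$intron + g$cds2 + g$utr3
}

#' Generate a synthetic genome with annotated gene models
#'
#' Emits contigs of order-1 Markov background sequence (configurable GC,
#' default 0.43, rice-like) carrying `n_genes` gene models on alternating
#' strands, each with a 5'-UTR, two exons, one intron and a 3'-UTR, spaced
#' so that every gene has a full upstream region of `promoter_len` bp and
#' a full 1-kb downstream region. Deterministic given `seed`.
#'
#' @param n_genes number of genes.
#' @param promoter_len upstream flank length per gene (>= 1000; use 3000
#'   when 3-kb upstream analyses are wanted).
#' @param contig_len optional contig length; an error is raised when the
#'   genes do not fit (overcrowded layout).
#' @param n_contigs number of contigs to spread genes over.
#' @param order Markov order of the background (0 or 1).
#' @param gc GC content of the background composition.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_genome`: list with `fasta` (named
#'   character contigs), `models` (a `gene_models` object), `genes`
#'   (summary data.frame), `truth` (placement data.frame, initially
#'   empty), `promoter_len` and `params`.
#' @export
make_genome <- function(n_genes = 100L, promoter_len = 1000L,
                        contig_len = NULL, n_contigs = 2L, order = 1L,
                        gc = 0.43, seed = 1L) {
  if (promoter_len < 1000L) stop("promoter_len must be >= 1000", call. = FALSE)
  margin <- max(promoter_len, 1000L) + 50L
  slot <- 2L * margin + gene_span()
  per_contig <- ceiling(n_genes / n_contigs)
  need <- per_contig * slot + 100L
  if (is.null(contig_len)) contig_len <- need
  if (contig_len < need) {
    stop(sprintf("overcrowded layout: contig_len %d < required %d",
                 contig_len, need), call. = FALSE)
  }
  comp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  # order-1 transitions with mild autocorrelation; stationary law = comp
  e <- if (order >= 1L) 0.1 else 0
  trans <- (1 - e) * matrix(comp, 4, 4, byrow = TRUE) + e * diag(4)

  g <- GENE_GEOMETRY
  fasta <- character(n_contigs)
  models <- list()
  rows <- list()
  with_seed(seed, {
    gi <- 0L
    for (ci in seq_len(n_contigs)) {
      chrom <- sprintf("contig_%02d", ci)
      fasta[ci] <- int_to_dna(markov_sim_cpp(contig_len, comp, trans))
      n_here <- min(per_contig, n_genes - gi)
      for (s in seq_len(n_here)) {
        gi <- gi + 1L
        gid <- sprintf("gene_%05d", gi)
        strand <- if (gi %% 2L == 1L) "+" else "-"
        s0 <- (s - 1L) * slot + 1L
        span <- gene_span()
        if (strand == "+") {
          start <- s0 + margin
          end <- start + span - 1L
          tss <- start
          exon1 <- c(tss, tss + g$utr5 + g$cds1 - 1L)
          intron <- c(exon1[2] + 1L, exon1[2] + g$intron)
          exon2 <- c(intron[2] + 1L, end)
          utr5 <- c(tss, tss + g$utr5 - 1L)
          tsc <- intron[2] + g$cds2  # last base of CDS
        } else {
          end <- s0 + margin + span - 1L
          start <- s0 + margin
          tss <- end
          exon1 <- c(tss - g$utr5 - g$cds1 + 1L, tss)
          intron <- c(exon1[1] - g$intron, exon1[1] - 1L)
          exon2 <- c(start, intron[1] - 1L)
          utr5 <- c(tss - g$utr5 + 1L, tss)
          tsc <- intron[1] - g$cds2  # last base of CDS (transcription dir)
        }
        exons <- rbind(sort(c(exon1[1], exon1[2])), sort(c(exon2[1], exon2[2])))
        exons <- exons[order(exons[, 1]), , drop = FALSE]
        colnames(exons) <- c("start", "end")
        models[[gid]] <- list(
          gene_id = gid, chrom = chrom, strand = strand, tss = tss,
          tsc = tsc, mrna_start = start, mrna_end = end,
          exons = exons,
          utr5 = matrix(sort(utr5), 1, 2, dimnames = list(NULL, c("start", "end"))),
          introns = matrix(sort(intron), 1, 2,
                           dimnames = list(NULL, c("start", "end")))
        )
        rows[[gi]] <- data.frame(gene_id = gid, chrom = chrom,
                                 strand = strand, start = start, end = end,
                                 tss = tss, tsc = tsc,
                                 stringsAsFactors = FALSE)
      }
    }
  })
  names(fasta) <- sprintf("contig_%02d", seq_len(n_contigs))
  structure(list(
    fasta = fasta,
    models = structure(models, class = "gene_models"),
    genes = do.call(rbind, rows),
    truth = empty_truth(),
    promoter_len = promoter_len,
    params = list(n_genes = n_genes, order = order, gc = gc, seed = seed,
                  contig_len = contig_len, margin = margin)
  ), class = "synthetic_genome")
}

empty_truth <- function() {
  data.frame(gene_id = character(0), pattern = character(0),
             region = character(0), distance = integer(0),
             orientation = character(0), word = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d genes on %d contig(s) (%d bp each), %d planted site(s)\n",
              nrow(x$genes), length(x$fasta), nchar(x$fasta[[1]]),
              nrow(x$truth)))
  invisible(x)
}

# genomic placement of a region-local position for one gene
# For upstream kinds `pos` is the upstream distance of the base nearest the
# TSS; elsewhere it is the 1-based offset into the region sequence.
region_window_coords <- function(model, kind, pos, w, promoter_len) {
  minus <- model$strand == "-"
  if (kind %in% c("up1k", "up3k")) {
    d <- pos
    if (minus) c(model$tss + d, model$tss + d + w - 1L)
    else c(model$tss - (d + w - 1L), model$tss - d)
  } else if (kind == "down1k") {
    if (minus) c(model$tsc - pos - w + 1L, model$tsc - pos)
    else c(model$tsc + pos, model$tsc + pos + w - 1L)
  } else {
    iv <- if (kind == "utr5") model$utr5[1, ] else model$introns[1, ]
    if (minus) c(iv[2] - (pos + w - 1L) + 1L, iv[2] - pos + 1L)
    else c(iv[1] + pos - 1L, iv[1] + pos + w - 2L)
  }
}

region_length_for <- function(kind, promoter_len) {
  switch(kind,
         up1k = 1000L, up3k = min(3000L, promoter_len), down1k = 1000L,
         utr5 = GENE_GEOMETRY$utr5, intron = GENE_GEOMETRY$intron)
}

#' Plant motif occurrences into a synthetic genome
#'
#' Samples carrier genes (exactly `round(fraction * n_genes)` of them),
#' copy numbers, positions and orientations from the planting spec,
#' instantiates one concrete word per site uniformly from the pattern's
#' degenerate expansion, and writes the words into the genomic sequence
#' strand-aware. Planted sites never overlap each other. By default any
#' chance occurrence of the pattern already present in the target region
#' of any gene is first scrubbed (resampled away), so that the carrier set
#' exactly equals the truth table.
#'
#' @param genome a `synthetic_genome`.
#' @param spec a `planting_spec`.
#' @param seed integer RNG seed.
#' @param scrub_background remove chance occurrences of the pattern from
#'   the target region of all genes before planting (default TRUE).
#' @return the updated `synthetic_genome`; `$truth` gains one row per
#'   planted site (`gene_id`, `pattern`, `region`, `distance`,
#'   `orientation`, `word`).
#' @export
plant_motifs <- function(genome, spec, seed = 1L, scrub_background = TRUE) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(spec, "planting_spec"))
  pat <- spec$pattern
  w <- pat$width
  kind <- spec$region_kind
  Lr <- region_length_for(kind, genome$promoter_len)
  if (Lr < w) stop("region too short for the pattern", call. = FALSE)
  contigs <- genome$fasta

  fwd <- compile_pattern(pat$iupac)
  rev_m <- if (pat$is_palindromic) NULL else
    compile_pattern(reverse_complement(pat$iupac))
  # work on per-gene region substrings; write each contig back once at the
  # end (in-place edits on Mb-scale strings copy the whole contig)
  gene_ids <- genome$genes$gene_id
  spans <- t(vapply(gene_ids, function(gid) {
    model <- genome$models[[gid]]
    region_genomic_span(model, kind, Lr, w, genome$promoter_len,
                        nchar(contigs[[model$chrom]]))
  }, integer(2)))
  regs <- stats::setNames(vapply(seq_along(gene_ids), function(i) {
    substr(contigs[[genome$models[[gene_ids[i]]]$chrom]],
           spans[i, 1], spans[i, 2])
  }, character(1)), gene_ids)

  with_seed(seed, {
    if (scrub_background) {
      for (i in seq_along(regs)) {
        regs[i] <- scrub_string(regs[[i]], fwd, rev_m, w)
      }
    }
    n <- length(gene_ids)
    n_carriers <- round(spec$fraction * n)
    carriers <- sample(gene_ids, n_carriers)
    rows <- list()
    for (gid in carriers) {
      model <- genome$models[[gid]]
      lo <- spans[match(gid, gene_ids), 1]
      reg <- regs[[gid]]
      k <- as.integer(sample(names(spec$copies), 1L, prob = spec$copies))
      placed <- matrix(integer(0), 0, 2)
      for (cc in seq_len(k)) {
        ok <- FALSE
        for (try in 1:100) {
          pos <- sample_region_pos(spec, Lr, w)
          gw <- region_window_coords(model, kind, pos, w, genome$promoter_len)
          if (nrow(placed) == 0L ||
              all(gw[2] < placed[, 1] | gw[1] > placed[, 2])) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("cannot place motif copies without overlap", call. = FALSE)
        placed <- rbind(placed, gw)
        ori <- switch(spec$orientation,
                      forward = "forward", reverse = "reverse",
                      both = if (stats::runif(1) < 0.5) "forward" else "reverse")
        word <- instantiate_pattern(pat$iupac)
        # word as it appears on the genomic forward strand
        fwd_word <- word
        if (ori == "reverse") fwd_word <- reverse_complement(fwd_word)
        if (model$strand == "-") fwd_word <- reverse_complement(fwd_word)
        substr(reg, gw[1] - lo + 1L, gw[2] - lo + 1L) <- fwd_word
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, pattern = pat$name, region = kind,
          distance = pos, orientation = ori, word = word,
          stringsAsFactors = FALSE)
      }
      if (scrub_background && nrow(placed)) {
        # planting can create chance occurrences spanning a planted word
        # and its flanking context; resample the flanking bases away
        reg <- fix_junction_hits(reg, placed - lo + 1L, fwd, rev_m, w)
      }
      regs[gid] <- reg
    }
  })
  # reassemble contigs from untouched stretches and edited regions
  for (ch in names(contigs)) {
    on_ch <- which(vapply(gene_ids, function(g) {
      genome$models[[g]]$chrom == ch
    }, logical(1)))
    if (!length(on_ch)) next
    on_ch <- on_ch[order(spans[on_ch, 1])]
    s <- contigs[[ch]]
    pieces <- character(0)
    cursor <- 1L
    for (i in on_ch) {
      pieces <- c(pieces, substr(s, cursor, spans[i, 1] - 1L),
                  regs[[gene_ids[i]]])
      cursor <- spans[i, 2] + 1L
    }
    pieces <- c(pieces, substr(s, cursor, nchar(s)))
    contigs[[ch]] <- paste(pieces, collapse = "")
  }
  genome$fasta <- contigs
  genome$truth <- rbind(genome$truth, do.call(rbind, rows))
  genome
}

sample_region_pos <- function(spec, Lr, w) {
  max_pos <- Lr - w + 1L
  if (!is.null(spec$positions) && spec$region_kind %in% c("up1k", "up3k")) {
    lab <- sample(names(spec$positions), 1L, prob = spec$positions)
    bounds <- as.integer(strsplit(lab, "-", fixed = TRUE)[[1]])
    lo <- bounds[1]; hi <- min(bounds[2], max_pos)
    if (lo > hi) stop("position bin outside the region", call. = FALSE)
    sample(lo:hi, 1L)
  } else {
    sample.int(max_pos, 1L)
  }
}

# one concrete word, each degenerate position drawn uniformly from its set
instantiate_pattern <- function(iupac) {
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

# genomic span [lo, hi] of the whole region of one gene, clipped to contig
region_genomic_span <- function(model, kind, Lr, w, promoter_len, contig_len) {
  gw <- range(region_window_coords(model, kind, 1L, 1L, promoter_len),
              region_window_coords(model, kind, Lr - w + 1L, w, promoter_len))
  c(max(1L, min(gw)), min(contig_len, max(gw)))
}

# resample unintended occurrences inside one region string, touching only
# bases outside the planted windows (`placed`, region-local coordinates)
fix_junction_hits <- function(reg, placed, fwd, rev_m, w) {
  for (pass in 1:50) {
    starts <- unique(c(fwd(reg), if (!is.null(rev_m)) rev_m(reg)))
    extras <- setdiff(starts, placed[, 1])
    if (!length(extras)) break
    changed <- FALSE
    for (st in extras) {
      span <- st:(st + w - 1L)
      inside <- vapply(span, function(p) {
        any(p >= placed[, 1] & p <= placed[, 2])
      }, logical(1))
      free <- span[!inside]
      if (!length(free)) next
      for (p in free) {
        substr(reg, p, p) <- sample(DNA_BASES, 1L)
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  reg
}

# resample away chance occurrences (both strands) in one region string
scrub_string <- function(reg, fwd, rev_m, w) {
  for (pass in 1:50) {
    starts <- c(fwd(reg), if (!is.null(rev_m)) rev_m(reg))
    if (!length(starts)) break
    for (st in starts) {
      repl <- paste(sample(DNA_BASES, w, replace = TRUE,
                           prob = c(0.285, 0.215, 0.215, 0.285)),
                    collapse = "")
      substr(reg, st, st + w - 1L) <- repl
    }
  }
  reg
}

#' Simulate an expression meta-matrix with planted regulation effects
#'
#' Every cell starts as baseline noise, M ~ Normal(0, `baseline_sd`). For
#' each effect, a `responder_fraction` subset of the carrier genes is
#' drawn once; in the effect's responsive arrays those responders get
#' M ~ Normal(+/- delta, `noise_sd`). Missing values are injected
#' completely at random at `missing_rate`.
#'
#' @param gene_ids character vector of gene ids (matrix rows).
#' @param n_arrays number of arrays.
#' @param effects list of effects; each a list with `carriers` (gene ids)
#'   and `spec` (an `effect_spec`).
#' @param seed integer RNG seed.
#' @param baseline_sd baseline M-value standard deviation (default 0.5).
#' @param missing_rate fraction of cells set missing (default 0).
#' @param array_ids optional array names (default `array_01`...).
#' @return list with `m` (expression matrix) and `responders` (list of
#'   gene-id vectors, one per effect).
#' @export
simulate_expression <- function(gene_ids, n_arrays, effects = list(),
                                seed = 1L, baseline_sd = 0.5,
                                missing_rate = 0, array_ids = NULL) {
  if (is.null(array_ids)) array_ids <- sprintf("array_%02d", seq_len(n_arrays))
  with_seed(seed, {
    m <- matrix(stats::rnorm(length(gene_ids) * n_arrays, 0, baseline_sd),
                length(gene_ids), n_arrays,
                dimnames = list(gene_ids, array_ids))
    responders <- vector("list", length(effects))
    for (i in seq_along(effects)) {
      ef <- effects[[i]]
      spec <- ef$spec
      stopifnot(inherits(spec, "effect_spec"))
      carriers <- intersect(ef$carriers, gene_ids)
      resp <- sample(carriers, round(spec$responder_fraction * length(carriers)))
      shift <- if (spec$direction == "induce") spec$delta else -spec$delta
      arr <- spec$responsive_arrays
      if (is.numeric(arr)) arr <- array_ids[arr]
      stopifnot(all(arr %in% array_ids))
      for (a in arr) {
        m[resp, a] <- stats::rnorm(length(resp), shift, spec$noise_sd)
      }
      responders[[i]] <- resp
    }
    if (missing_rate > 0) {
      drop <- stats::runif(length(m)) < missing_rate
      m[drop] <- NA_real_
    }
    list(m = m, responders = responders)
  })
}

#' Simulate TF expression rows correlated with a Z profile
#'
#' Each TF row is `c * z + e` with the scale and noise chosen so the
#' population Pearson correlation with the given profile equals
#' `target_r` exactly: `c = r / (sd(z) * sqrt(1 - r^2))`, `e ~ N(0, 1)`.
#'
#' @param z numeric Z-score profile over arrays (must have nonzero
#'   variance).
#' @param target_r vector of population correlations in (-1, 1), one per
#'   TF row.
#' @param seed integer RNG seed.
#' @param tf_ids optional TF row names (default `TF_0001`...).
#' @return matrix of TF rows (length(target_r) x length(z)) with the
#'   target correlations as a `target_r` attribute.
#' @export
simulate_tf_profiles <- function(z, target_r, seed = 1L, tf_ids = NULL) {
  if (any(abs(target_r) >= 1)) stop("target_r must be in (-1, 1)", call. = FALSE)
  sdz <- sqrt(mean((z - mean(z))^2))
  if (!is.finite(sdz) || sdz == 0) {
    stop("degenerate Z profile (zero variance)", call. = FALSE)
  }
  if (is.null(tf_ids)) tf_ids <- sprintf("TF_%04d", seq_along(target_r))
  with_seed(seed, {
    rows <- t(vapply(target_r, function(r) {
      cc <- if (r == 0) 0 else r / (sdz * sqrt(1 - r^2))
      cc * z + stats::rnorm(length(z))
    }, numeric(length(z))))
  })
  dimnames(rows) <- list(tf_ids, names(z))
  attr(rows, "target_r") <- stats::setNames(target_r, tf_ids)
  rows
}

#' Write a synthetic genome to FASTA
#' @param genome a `synthetic_genome`.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome$fasta)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write a synthetic genome annotation to GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `five_prime_UTR` and `CDS` features with
#' 1-based inclusive coordinates and ID/Parent attributes.
#'
#' @param genome a `synthetic_genome`.
#' @param path output GFF3 path.
#' @export
write_genome_gff <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(genome$fasta)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       nchar(genome$fasta[[ch]])), con)
  }
  g <- GENE_GEOMETRY
  for (model in genome$models) {
    gid <- model$gene_id
    mid <- paste0(gid, ".1")
    line <- function(type, s, e, attrs) {
      sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
              model$chrom, type, s, e, model$strand, attrs)
    }
    out <- c(
      line("gene", model$mrna_start, model$mrna_end, paste0("ID=", gid)),
      line("mRNA", model$mrna_start, model$mrna_end,
           paste0("ID=", mid, ";Parent=", gid))
    )
    for (i in seq_len(nrow(model$exons))) {
      out <- c(out, line("exon", model$exons[i, 1], model$exons[i, 2],
                         paste0("ID=", mid, ".exon", i, ";Parent=", mid)))
    }
    out <- c(out, line("five_prime_UTR", model$utr5[1, 1], model$utr5[1, 2],
                       paste0("ID=", mid, ".utr5;Parent=", mid)))
    # CDS: exon1 minus 5'UTR, exon2 minus 3'UTR
    if (model$strand == "+") {
      cds1 <- c(model$utr5[1, 2] + 1L, model$exons[1, 2])
      cds2 <- c(model$exons[2, 1], model$exons[2, 1] + g$cds2 - 1L)
    } else {
      cds1 <- c(model$exons[2, 1], model$utr5[1, 1] - 1L)
      cds2 <- c(model$exons[1, 2] - g$cds2 + 1L, model$exons[1, 2])
    }
    out <- c(out,
             line("CDS", cds1[1], cds1[2], paste0("ID=", mid, ".cds1;Parent=", mid)),
             line("CDS", cds2[1], cds2[2], paste0("ID=", mid, ".cds2;Parent=", mid)))
    writeLines(out, con)
  }
  invisible(path)
}
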
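# A tiny hand-built genome: one 5-kb contig, two genes (one per strand).
tiny_genome <- function() {
  set.seed(400)
  contig <- random_dna(5000)
  list(fasta = c(chr1 = contig), contig = contig)
}

write_tiny_gff <- function(path, lines) {
  writeLines(c("##gff-version 3", "##sequence-region chr1 1 5000", lines),
             path)
}

gff_gene <- function(id, start, end, strand, exons, utr5 = NULL, cds = NULL) {
  mid <- paste0(id, ".1")
  out <- c(
    sprintf("chr1\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s", start, end, strand, id),
    sprintf("chr1\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            start, end, strand, mid, id)
  )
  for (i in seq_along(exons)) {
    out <- c(out, sprintf("chr1\t.\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                          exons[[i]][1], exons[[i]][2], strand, mid, i, mid))
  }
  for (i in seq_along(utr5)) {
    out <- c(out, sprintf("chr1\t.\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tID=%s.u%d;Parent=%s",
                          utr5[[i]][1], utr5[[i]][2], strand, mid, i, mid))
  }
  for (i in seq_along(cds)) {
    out <- c(out, sprintf("chr1\t.\tCDS\t%d\t%d\t.\t%s\t.\tID=%s.c%d;Parent=%s",
                          cds[[i]][1], cds[[i]][2], strand, mid, i, mid))
  }
  out
}

test_that("introns are the complement of exons and strand sets the TSS", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_tiny_gff(path, c(
    gff_gene("gplus", 101, 400, "+", list(c(101, 200), c(301, 400))),
    gff_gene("gminus", 2001, 2400, "-", list(c(2001, 2100), c(2301, 2400)))
  ))
  models <- parse_annotation(path)
  expect_named(models, c("gplus", "gminus"))
  expect_equal(unname(models$gplus$introns), cbind(201, 300),
               ignore_attr = TRUE)
  expect_equal(models$gplus$tss, 101)
  # minus strand: TSS is the maximum mRNA coordinate
  expect_equal(models$gminus$tss, 2400)
  expect_equal(unname(models$gminus$introns), cbind(2101, 2300),
               ignore_attr = TRUE)
})

test_that("longest-span mRNA is chosen and exonless genes are skipped", {
  path <- withr::local_tempfile(fileext = ".gff3")
  long <- c(
    "chr1\t.\tgene\t101\t900\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t101\t500\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\t.\texon\t101\t500\t.\t+\t.\tID=g1.1.e1;Parent=g1.1",
    "chr1\t.\tmRNA\t101\t900\t.\t+\t.\tID=g1.2;Parent=g1",
    "chr1\t.\texon\t101\t900\t.\t+\t.\tID=g1.2.e1;Parent=g1.2",
    "chr1\t.\tgene\t1001\t1200\t.\t+\t.\tID=g2",
    "chr1\t.\tmRNA\t1001\t1200\t.\t+\t.\tID=g2.1;Parent=g2"
  )
  write_tiny_gff(path, long)
  expect_warning(models <- parse_annotation(path), "without exons")
  expect_named(models, "g1")
  expect_equal(models$g1$mrna_end, 900)
})

test_that("upstream extraction follows the worked coordinate examples", {
  g <- tiny_genome()
  model_plus <- list(gene_id = "gp", chrom = "chr1", strand = "+",
                     tss = 2001, tsc = 2500, mrna_start = 2001,
                     mrna_end = 2700,
                     exons = cbind(start = 2001, end = 2700),
                     utr5 = matrix(integer(0), 0, 2),
                     introns = matrix(integer(0), 0, 2))
  r <- extract_region(g$fasta, model_plus, "up1k")
  expect_identical(r$sequence, substr(g$contig, 1001, 2000))
  expect_equal(c(r$interval$start, r$interval$end), c(1001, 2000))

  model_minus <- model_plus
  model_minus$strand <- "-"; model_minus$tss <- 3000
  r2 <- extract_region(g$fasta, model_minus, "up1k")
  expect_identical(
    r2$sequence,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(g$contig, 3001, 4000)))))
})

test_that("downstream region starts after the stop codon, truncates at edges", {
  g <- tiny_genome()
  model <- list(gene_id = "gp", chrom = "chr1", strand = "+", tss = 1000,
                tsc = 4500, mrna_start = 1000, mrna_end = 4600,
                exons = cbind(start = 1000, end = 4600),
                utr5 = matrix(integer(0), 0, 2),
                introns = matrix(integer(0), 0, 2))
  r <- extract_region(g$fasta, model, "down1k")
  expect_identical(r$sequence, substr(g$contig, 4501, 5000))  # truncated
  expect_equal(nchar(r$sequence), 500)
  # zero-length at the very edge: warning, gene retained
  model$tsc <- 5000
  expect_warning(r0 <- extract_region(g$fasta, model, "down1k"),
                 "zero-length")
  expect_identical(r0$sequence, "")
  expect_error(extract_region(g$fasta,
                              modifyList(model, list(chrom = "chrX")),
                              "up1k"),
               "unknown chrom")
})

test_that("intron regions concatenate with an unmatchable N separator", {
  g <- tiny_genome()
  model <- list(gene_id = "gp", chrom = "chr1", strand = "+", tss = 101,
                tsc = 880, mrna_start = 101, mrna_end = 900,
                exons = rbind(c(101, 200), c(301, 400), c(501, 900)),
                utr5 = matrix(integer(0), 0, 2),
                introns = rbind(c(201, 300), c(401, 500)))
  r <- extract_region(g$fasta, model, "intron")
  expect_identical(
    r$sequence,
    paste0(substr(g$contig, 201, 300), strrep("N", 30),
           substr(g$contig, 401, 500)))
  # no pattern (max width 25) can bridge the separator
  expect_equal(nchar(strsplit(r$sequence, "N+")[[1]][1]), 100)
})

test_that("synthetic GFF round-trips to the generator's own models", {
  genome <- make_genome(n_genes = 30, seed = 77)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "g.gff3")
  write_genome_fasta(genome, fa)
  write_genome_gff(genome, gff)
  models <- parse_annotation(gff)
  expect_length(models, 30)
  for (gid in c("gene_00001", "gene_00002", "gene_00015", "gene_00030")) {
    a <- genome$models[[gid]]; b <- models[[gid]]
    expect_equal(a[c("chrom", "strand", "tss", "tsc")],
                 b[c("chrom", "strand", "tss", "tsc")])
    expect_equal(unname(a$exons), unname(b$exons))
    expect_equal(unname(a$introns), unname(b$introns))
    expect_equal(unname(a$utr5), unname(b$utr5))
  }
  # regions from files equal regions from the in-memory bundle
  g2 <- Biostrings::readDNAStringSet(fa)
  names(g2) <- sub("\\s.*$", "", names(g2))
  for (kind in c("up1k", "utr5", "intron", "down1k")) {
    expect_identical(extract_regions(g2, models, kind)$sequences,
                     extract_regions(genome$fasta, genome$models,
                                     kind)$sequences)
  }
})

test_that("extraction is strand-symmetric under genome reverse complement", {
  genome <- make_genome(n_genes = 10, n_contigs = 1, seed = 88)
  contig <- genome$fasta[[1]]
  L <- nchar(contig)
  flipped <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  flip_model <- function(m) {
    flip <- function(iv) {
      if (nrow(iv) == 0) return(iv)
      out <- cbind(L - iv[, 2] + 1L, L - iv[, 1] + 1L)
      out[order(out[, 1]), , drop = FALSE]
    }
    list(gene_id = m$gene_id, chrom = m$chrom,
         strand = if (m$strand == "+") "-" else "+",
         tss = L - m$tss + 1L, tsc = L - m$tsc + 1L,
         mrna_start = L - m$mrna_end + 1L, mrna_end = L - m$mrna_start + 1L,
         exons = flip(m$exons), utr5 = flip(m$utr5),
         introns = flip(m$introns))
  }
  flipped_models <- structure(lapply(genome$models, flip_model),
                              class = "gene_models")
  for (kind in c("up1k", "utr5", "intron", "down1k")) {
    orig <- extract_regions(genome$fasta, genome$models, kind)
    flip <- extract_regions(c(contig_01 = flipped), flipped_models, kind)
    expect_identical(flip$sequences, orig$sequences)
  }
})

test_that("every gene far from contig edges has a full-length up1k region", {
  genome <- make_genome(n_genes = 40, seed = 91)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  expect_true(all(nchar(regions$sequences) == 1000L))
  # purity: re-extraction is byte-identical
  regions2 <- extract_regions(genome$fasta, genome$models, "up1k")
  expect_identical(regions$sequences, regions2$sequences)
})
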
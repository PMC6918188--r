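test_that("background models normalise, smooth and recover known transitions", {
  # order 0 on a homopolymer: p(A) near 1, limited by the pseudocount
  bg0 <- train_background(strrep("A", 1000), order = 0)
  expect_gt(bg0$prob[1, "A"], 0.99)
  expect_equal(unname(rowSums(bg0$prob)), rep(1, nrow(bg0$prob)),
               tolerance = 1e-12)

  # order 1 trained on a chain from a known transition matrix
  comp <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  trans <- 0.8 * matrix(comp, 4, 4, byrow = TRUE) + 0.2 * diag(4)
  seq <- withr::with_seed(701, {
    code <- creFingerprint:::markov_sim_cpp(100000L, comp, trans)
    creFingerprint:::int_to_dna(code)
  })
  bg1 <- train_background(seq, order = 1)
  expect_equal(unname(bg1$prob), unname(trans), tolerance = 0.02)
  expect_equal(unname(rowSums(bg1$prob)), rep(1, 4), tolerance = 1e-12)

  expect_error(train_background("ACGTACGT", order = 2), "lower order")
})

test_that("consensus extraction covers bases above the frequency threshold", {
  pfm <- rbind(c(1, 0, 0, 0),
               c(0.5, 0.5, 0, 0),
               c(0.3, 0.3, 0.3, 0.1),
               c(0.25, 0.25, 0.25, 0.25))
  colnames(pfm) <- c("A", "C", "G", "T")
  expect_identical(pwm_consensus(pfm), "AMVN")
})

test_that("the sampler's site-set score equals a direct independent computation", {
  genome <- make_genome(n_genes = 40, seed = 702)
  genome <- plant_motifs(genome, planting_spec("CACGTGTC", fraction = 0.8),
                         seed = 703)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  bg <- train_background(regions, order = 1)
  res <- gibbs_motif_search(regions$sequences, bg, width = 8,
                            iterations = 60, restarts = 3, seed = 704)
  expect_gte(length(res), 1)
  motif <- res[[1]]
  # direct re-derivation: PFM from the words, then sum of log ratios
  sites <- motif$sites
  words <- t(vapply(seq_len(nrow(sites)), function(r) {
    s <- regions$sequences[[sites$seq_id[r]]]
    word <- substr(s, sites$offset[r], sites$offset[r] + 7L)
    if (sites$strand[r] == "-") word <- oracle_rc(word)
    strsplit(word, "")[[1]]
  }, character(8)))
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(words == b), numeric(8))
  pfm <- (counts + matrix(bg$marginal, 8, 4, byrow = TRUE)) /
    (nrow(words) + 1)
  direct <- 0
  for (r in seq_len(nrow(sites))) {
    word <- words[r, ]
    idx <- match(word, c("A", "C", "G", "T"))
    lp_motif <- sum(log(pfm[cbind(1:8, idx)]))
    # background log prob of the window on its own strand
    s <- regions$sequences[[sites$seq_id[r]]]
    if (sites$strand[r] == "-") {
      s <- oracle_rc(s)
      off <- nchar(s) - (sites$offset[r] + 7L) + 1L
    } else {
      off <- sites$offset[r]
    }
    code <- creFingerprint:::dna_to_int(s)
    lp_bg <- creFingerprint:::window_logprob(code, bg, 8L)[off]
    direct <- direct + lp_motif - lp_bg
  }
  expect_equal(motif$score, direct, tolerance = 1e-9)
  # the exported helper agrees too
  expect_equal(site_set_score(regions$sequences, bg, sites, 8L), direct,
               tolerance = 1e-9)
})

test_that("discovery is deterministic given the seed", {
  genome <- make_genome(n_genes = 30, seed = 712)
  genome <- plant_motifs(genome, planting_spec("TTGACC", fraction = 0.8),
                         seed = 713)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  bg <- train_background(regions, order = 1)
  r1 <- gibbs_motif_search(regions$sequences, bg, width = 6,
                           iterations = 40, restarts = 2, seed = 99)
  r2 <- gibbs_motif_search(regions$sequences, bg, width = 6,
                           iterations = 40, restarts = 2, seed = 99)
  expect_identical(r1[[1]]$sites, r2[[1]]$sites)
  expect_identical(r1[[1]]$pfm, r2[[1]]$pfm)
})

test_that("null sequences score below planted sequences", {
  genome0 <- make_genome(n_genes = 50, seed = 721)
  regions0 <- extract_regions(genome0$fasta, genome0$models, "up1k")
  bg <- train_background(regions0, order = 1)
  null_res <- gibbs_motif_search(regions0$sequences, bg, width = 8,
                                 iterations = 80, restarts = 3, seed = 722)
  genome1 <- plant_motifs(genome0, planting_spec("CACGTGTC", fraction = 0.6),
                          seed = 723)
  regions1 <- extract_regions(genome1$fasta, genome1$models, "up1k")
  planted_res <- gibbs_motif_search(regions1$sequences, bg, width = 8,
                                    iterations = 80, restarts = 3, seed = 722)
  null_score <- if (length(null_res)) null_res[[1]]$score else 0
  expect_gt(planted_res[[1]]$score, null_score)
  # and the planted motif is the one found
  expect_gte(consensus_match_positions(planted_res[[1]]$consensus,
                                       "CACGTGTC"), 7)
})

test_that("successive motifs never share sites (masking idempotence)", {
  genome <- make_genome(n_genes = 60, seed = 731)
  genome <- plant_motifs(genome, planting_spec("CACGTGTC", fraction = 0.7),
                         seed = 732)
  genome <- plant_motifs(genome, planting_spec("GGGCCCAA", fraction = 0.7),
                         seed = 733)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  bg <- train_background(regions, order = 1)
  res <- gibbs_motif_search(regions$sequences, bg, width = 8, n_motifs = 2,
                            iterations = 80, restarts = 4, seed = 734)
  expect_gte(length(res), 2)
  span <- function(sites) {
    unlist(lapply(seq_len(nrow(sites)), function(r) {
      paste0(sites$seq_id[r], ":", sites$offset[r]:(sites$offset[r] + 7L))
    }))
  }
  overlap <- intersect(span(res[[1]]$sites), span(res[[2]]$sites))
  expect_length(overlap, 0)
})

test_that("co-existing motifs are found with the anchor masked", {
  genome <- make_genome(n_genes = 120, seed = 741)
  genome <- plant_motifs(genome, planting_spec("CACGTGTC", fraction = 0.9),
                         seed = 742)
  # co-plant a second motif in (most of) the anchor carriers
  genome <- plant_motifs(genome, planting_spec("GATCGATC", fraction = 0.7),
                         seed = 743)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  bg <- train_background(regions, order = 1)
  res <- find_coexisting_motifs(regions, "CACGTGTC", bg, width = 8,
                                iterations = 100, restarts = 5, seed = 744)
  expect_gte(length(res), 1)
  top <- res[[1]]
  # the co-planted motif is recovered, the anchor is not re-reported
  expect_gte(consensus_match_positions(top$consensus, "GATCGATC"), 7)
  expect_lt(consensus_match_positions(top$consensus, "CACGTGTC"), 7)
  # masking: no site overlaps an anchor occurrence
  anchor_hits <- scan_region_set(regions, motif_pattern("CACGTGTC"))
  anchor_span <- unlist(lapply(seq_len(nrow(anchor_hits)), function(r) {
    g <- anchor_hits$gene_id[r]
    L <- nchar(regions$sequences[[g]])
    start <- L - anchor_hits$distance[r] - 8L + 2L
    paste0(g, ":", start:(start + 7L))
  }))
  site_span <- unlist(lapply(seq_len(nrow(top$sites)), function(r) {
    paste0(top$sites$seq_id[r], ":",
           top$sites$offset[r]:(top$sites$offset[r] + 7L))
  }))
  expect_length(intersect(anchor_span, site_span), 0)
})

test_that("recovery rate is monotone in the planted fraction", {
  rates <- vapply(c(0.2, 0.5, 0.8), function(f) {
    hits <- 0L
    for (s in 1:3) {
      genome <- make_genome(n_genes = 60, seed = 750 + s)
      genome <- plant_motifs(genome, planting_spec("CACGTGTC", fraction = f),
                             seed = 760 + s)
      regions <- extract_regions(genome$fasta, genome$models, "up1k")
      bg <- train_background(regions, order = 1)
      res <- gibbs_motif_search(regions$sequences, bg, width = 8,
                                iterations = 80, restarts = 4,
                                seed = 770 + s)
      if (length(res) &&
          consensus_match_positions(res[[1]]$consensus, "CACGTGTC") >= 7) {
        hits <- hits + 1L
      }
    }
    hits
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[[3]], 3)
})
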
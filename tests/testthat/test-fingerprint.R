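test_that("the worked enrichment cell gives chi2 = 21.05", {
  # genome: 1000 genes, 5% induced; gene set: 100 genes, 15 induced
  m <- matrix_with_calls(50, 0, 950)
  calls <- call_regulation(m)
  gene_set <- c(rownames(m)[1:15], rownames(m)[51:135])
  res <- enrichment_test(gene_set, calls, "a1", "induced")
  expect_equal(res$n, 100L)
  expect_equal(unname(res$expected["induced"]), 5)
  # hand computation: (15-5)^2/5 + (85-95)^2/95
  expect_equal(res$chi2, (15 - 5)^2 / 5 + (85 - 95)^2 / 95, tolerance = 1e-12)
  expect_equal(res$chi2, 21.05, tolerance = 1e-3)
  # independent oracle
  want <- stats::chisq.test(c(15, 85), p = c(0.05, 0.95), correct = FALSE)
  expect_equal(res$chi2, unname(want$statistic), tolerance = 1e-12)
  expect_equal(res$p, want$p.value, tolerance = 1e-12)
  expect_equal(res$direction, "enriched")
})

test_that("observed equal to expected gives chi2 = 0, p = 1", {
  m <- matrix_with_calls(10, 10, 180)
  calls <- call_regulation(m)
  # a 20-gene set with exactly the genome proportions: 1 I, 1 S, 18 N
  gene_set <- c(rownames(m)[1], rownames(m)[11], rownames(m)[21:38])
  res <- enrichment_test(gene_set, calls, "a1", "induced")
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$direction, "none")
  # the full gene set is always exactly at expectation
  all_res <- enrichment_test(rownames(m), calls, "a1", "combined")
  expect_equal(all_res$chi2, 0)
  expect_equal(all_res$p, 1)
})

test_that("enrichment agrees with the textbook chi-squared on random configurations", {
  set.seed(601)
  for (rep in 1:500) {
    n_bg <- sample(200:2000, 1)
    k_i <- rbinom(1, n_bg, 0.08) + 1L
    k_s <- rbinom(1, n_bg, 0.08) + 1L
    k_n <- n_bg - k_i - k_s
    m <- matrix_with_calls(k_i, k_s, k_n)
    calls <- call_regulation(m)
    n_set <- sample(20:150, 1)
    gene_set <- sample(rownames(m), n_set)
    mode <- sample(c("induced", "suppressed", "combined"), 1)
    res <- enrichment_test(gene_set, calls, "a1", mode)
    o_t <- switch(mode,
                  induced = res$observed[["induced"]],
                  suppressed = res$observed[["suppressed"]],
                  combined = res$observed[["induced"]] + res$observed[["suppressed"]])
    p_t <- switch(mode,
                  induced = k_i / n_bg, suppressed = k_s / n_bg,
                  combined = (k_i + k_s) / n_bg)
    want <- suppressWarnings(
      stats::chisq.test(c(o_t, n_set - o_t), p = c(p_t, 1 - p_t),
                        correct = FALSE))
    expect_equal(res$chi2, unname(want$statistic), tolerance = 1e-9)
    expect_equal(res$p, want$p.value, tolerance = 1e-9)
  }
})

test_that("three-category combined mode matches a 2-df goodness-of-fit oracle", {
  m <- matrix_with_calls(60, 40, 900)
  calls <- call_regulation(m)
  set.seed(602)
  gene_set <- sample(rownames(m), 80)
  res <- enrichment_test(gene_set, calls, "a1", "combined",
                         combined_classes = "three")
  v <- calls$calls[gene_set, "a1"]
  obs <- c(sum(v == "I"), sum(v == "S"), sum(v == "N"))
  want <- suppressWarnings(
    stats::chisq.test(obs, p = c(0.06, 0.04, 0.90), correct = FALSE))
  expect_equal(res$chi2, unname(want$statistic), tolerance = 1e-9)
  expect_equal(res$p, want$p.value, tolerance = 1e-9)
  expect_equal(res$df, 2L)
})

test_that("degenerate sets, missing calls and flags behave as specified", {
  m <- matrix_with_calls(5, 5, 90)
  m <- cbind(m, a2 = NA_real_)
  m["g00001", "a2"] <- 0
  calls <- call_regulation(m)
  # genes missing on a2 are excluded from n
  res <- enrichment_test(rownames(m)[1:10], calls, "a2", "induced")
  expect_equal(res$n, 1L)
  expect_true("low_expected" %in% res$flags)
  # empty effective set
  expect_error(enrichment_test(rownames(m)[2:10], calls, "a2", "induced"),
               "degenerate")
  expect_error(enrichment_test("nope", calls, "a1", "induced"), "absent")
  # zero-background state observed
  m0 <- matrix_with_calls(0, 3, 97)
  calls0 <- call_regulation(m0)
  r0 <- enrichment_test(rownames(m0)[1:10], calls0, "a1", "induced")
  expect_equal(r0$p, 1)  # nothing induced anywhere: observed 0 = expected 0
})

test_that("adding an induced gene never decreases chi2 when enriched", {
  m <- matrix_with_calls(50, 30, 920)
  calls <- call_regulation(m)
  base_set <- c(rownames(m)[1:10], rownames(m)[81:130])  # 10 I of 60
  res <- enrichment_test(base_set, calls, "a1", "induced")
  expect_equal(res$direction, "enriched")
  chis <- res$chi2
  for (extra in rownames(m)[11:20]) {
    base_set <- c(base_set, extra)
    r <- enrichment_test(base_set, calls, "a1", "induced")
    expect_gte(r$chi2, chis - 1e-12)
    chis <- r$chi2
  }
})

test_that("regulatory fingerprints flag planted arrays and only those", {
  genome <- make_genome(n_genes = 400, seed = 611)
  genome <- plant_motifs(genome, planting_spec("TTGACY", fraction = 0.25),
                         seed = 612)
  carriers <- unique(genome$truth$gene_id)
  sim <- simulate_expression(
    genome$genes$gene_id, 8,
    effects = list(list(carriers = carriers,
                        spec = effect_spec(1:2, "induce", delta = 1.5,
                                           responder_fraction = 0.6))),
    seed = 613)
  calls <- call_regulation(sim$m)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  fp <- regulatory_fingerprint(motif_pattern("TTGACY"), regions, calls)
  expect_s3_class(fp, "cre_fingerprint")
  expect_equal(fp$n_genes, length(carriers))
  expect_true(all(fp$results$p_induced[1:2] < 0.05))
  expect_true(all(fp$results$dir_induced[1:2] == "enriched"))
  expect_true(all(fp$results$p_induced[3:8] > 0.05))
  expect_error(
    regulatory_fingerprint(motif_pattern("ACGTACGTACGTACGTACGTA"),
                           regions, calls),
    "occurs in no gene")
})

test_that("stratified fingerprints are pure and flag underpowered strata", {
  genome <- make_genome(n_genes = 300, seed = 621)
  genome <- plant_motifs(genome, planting_spec("CACGTGTC", fraction = 0.3),
                         seed = 622)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  hits <- scan_region_set(regions, motif_pattern("CACGTGTC"))
  sim <- simulate_expression(genome$genes$gene_id, 4, effects = list(),
                             seed = 623)
  calls <- call_regulation(sim$m)
  st <- stratified_fingerprint(hits, calls, "copy_number")
  # strata with identical gene sets give identical rows: compare stratum 1
  # against a direct fingerprint of the same gene set
  ones <- stratify_hits(hits, "copy_number")[["1"]]
  direct <- enrichment_test(ones, calls, "array_01", "induced")
  row <- st[st$stratum == "1" & st$array_id == "array_01", ]
  expect_equal(row$chi2_induced, direct$chi2, tolerance = 1e-12)
  expect_equal(row$p_induced, direct$p, tolerance = 1e-12)
  expect_true(all(st$underpowered[st$stratum_n < 20]))
})

test_that("fingerprint reports are deterministic and use the N convention", {
  m <- matrix_with_calls(0, 0, 500)
  m <- cbind(m, a2 = m[, 1])
  colnames(m) <- c("a1", "a2")
  calls <- call_regulation(m)
  regions <- make_region_set(
    stats::setNames(rep("AATTGACCTT", 40), rownames(m)[41:80]), "up1k")
  fp <- regulatory_fingerprint(motif_pattern("TTGACC"), regions, calls)
  rep1 <- fingerprint_report(list(fp))
  expect_equal(dim(rep1$matrix), c(1L, 2L))
  # neutral-only carrier set: both cells "N"
  expect_true(all(rep1$matrix == "N"))
  dir <- withr::local_tempdir()
  fingerprint_report(list(fp), file.path(dir, "r1"))
  fingerprint_report(list(fp), file.path(dir, "r2"))
  expect_identical(readLines(file.path(dir, "r1_report.tsv")),
                   readLines(file.path(dir, "r2_report.tsv")))
  expect_identical(readLines(file.path(dir, "r1_matrix.tsv")),
                   readLines(file.path(dir, "r2_matrix.tsv")))
})

test_that("Benjamini-Hochberg correction across arrays is available as a flag", {
  genome <- make_genome(n_genes = 200, seed = 631)
  genome <- plant_motifs(genome, planting_spec("CACGTGTC", fraction = 0.3),
                         seed = 632)
  regions <- extract_regions(genome$fasta, genome$models, "up1k")
  sim <- simulate_expression(genome$genes$gene_id, 10, effects = list(),
                             seed = 633)
  calls <- call_regulation(sim$m)
  raw <- regulatory_fingerprint(motif_pattern("CACGTGTC"), regions, calls)
  adj <- regulatory_fingerprint(motif_pattern("CACGTGTC"), regions, calls,
                                correction = "bh")
  expect_equal(adj$results$p_induced,
               p.adjust(raw$results$p_induced, "BH"), tolerance = 1e-12)
  expect_true(all(adj$results$p_induced >= raw$results$p_induced - 1e-12))
})

test_that("CRE names follow the OS_<REGION>_<NNN> convention", {
  expect_identical(cre_name("up1k", 1), "OS_1K_001")
  expect_identical(cre_name("up3k", 12), "OS_3K_012")
  expect_identical(cre_name("utr5", 3), "OS_5U_003")
  expect_identical(cre_name("intron", 4), "OS_UT_004")
  expect_identical(cre_name("down1k", 123), "OS_1D_123")
})
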
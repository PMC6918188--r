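#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML file with keys: `paths` (fasta, gff,
#' matrix, tf_list, catalog), `region_kinds`, `default_cutoff`,
#' `per_array_cutoffs`, `alpha`, `discovery` (width, n_motifs, iterations,
#' restarts, order, k_clusters, max_sequences, min_cluster), `n_min_frac`,
#' `seed` and `out_dir`. Referenced paths must exist at validation time.
#'
#' @param path YAML config file.
#' @return validated config list (class `run_config`).
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    region_kinds = "up1k", default_cutoff = 2, alpha = 0.05,
    correction = "none", min_stratum_n = 20L,
    n_min_frac = 0.8, seed = 1L,
    discovery = list(width = 8L, n_motifs = 2L, iterations = 200L,
                     restarts = 10L, order = 1L, k_clusters = 4L,
                     max_sequences = 200L, min_cluster = 20L)
  )
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in names(defaults$discovery)) {
    if (is.null(cfg$discovery[[k]])) cfg$discovery[[k]] <- defaults$discovery[[k]]
  }
  if (is.null(cfg$paths)) stop("config needs a 'paths' block", call. = FALSE)
  for (k in setdiff(names(cfg$paths), "out_dir")) {
    if (!file.exists(cfg$paths[[k]])) {
      stop("config path does not exist: ", k, " = ", cfg$paths[[k]],
           call. = FALSE)
    }
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- "crefp_out"
  cfg$region_kinds <- match.arg(cfg$region_kinds, REGION_KINDS,
                                several.ok = TRUE)
  structure(cfg, class = "run_config")
}

load_run_inputs <- function(config) {
  genome <- Biostrings::readDNAStringSet(config$paths$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  models <- parse_annotation(config$paths$gff)
  m <- load_expression_matrix(config$paths$matrix)
  cutoffs <- NULL
  if (!is.null(config$paths$per_array_cutoffs)) {
    co <- utils::read.delim(config$paths$per_array_cutoffs, header = FALSE,
                            col.names = c("array_id", "fold"))
    cutoffs <- stats::setNames(co$fold, co$array_id)
  }
  calls <- call_regulation(m, default_cutoff = config$default_cutoff,
                           per_array_cutoffs = cutoffs)
  list(genome = genome, models = models, m = m, calls = calls)
}

write_manifest <- function(config, out_dir, files, extra = list()) {
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("creFingerprint")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    alpha = config$alpha,
    region_kinds = config$region_kinds,
    outputs = files
  ), extra)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

#' Reverse search: fingerprint every catalog pattern
#'
#' For every pattern in the catalog and every configured region kind:
#' scans the regions, assembles the regulatory fingerprint, and (for
#' upstream regions) the position / orientation / copy-number stratified
#' reports. Per-pattern failures are logged and the run continues; the
#' result lists the errors.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, list with `fingerprints`, `out_dir`, `errors`.
#' @export
run_reverse_search <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  inputs <- load_run_inputs(config)
  catalog <- read_pattern_catalog(config$paths$catalog)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  fps <- list()
  files <- character(0)
  for (kind in config$region_kinds) {
    regions <- suppressWarnings(
      extract_regions(inputs$genome, inputs$models, kind))
    for (i in seq_len(nrow(catalog))) {
      pname <- catalog$name[i]
      res <- tryCatch({
        pat <- motif_pattern(catalog$iupac[i], pname)
        hits <- scan_region_set(regions, pat)
        fp <- regulatory_fingerprint(pat, hits, inputs$calls,
                                     alpha = config$alpha,
                                     correction = config$correction)
        tag <- paste0(gsub("[^A-Za-z0-9_.-]", "_", pname), "_", kind)
        fingerprint_report(list(fp), file.path(out_dir, tag))
        files <- c(files, paste0(tag, c("_report.tsv", "_matrix.tsv")))
        if (kind %in% c("up1k", "up3k") && nrow(hits) > 0) {
          for (mode in c("position", "orientation", "copy_number")) {
            strat <- tryCatch(
              stratified_fingerprint(hits, inputs$calls, mode,
                                     min_stratum_n = config$min_stratum_n,
                                     alpha = config$alpha),
              error = function(e) NULL)
            if (!is.null(strat)) {
              f <- file.path(out_dir, paste0(tag, "_", mode, ".tsv"))
              num <- vapply(strat, is.numeric, logical(1))
              strat[num] <- lapply(strat[num], function(x) sprintf("%.6g", x))
              utils::write.table(strat, f, sep = "\t", quote = FALSE,
                                 row.names = FALSE)
              files <- c(files, basename(f))
            }
          }
        }
        fp
      }, error = function(e) {
        errors <<- c(errors, sprintf("%s/%s: %s", pname, kind,
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) fps[[paste(pname, kind, sep = "/")]] <- res
    }
  }
  if (length(fps) == 0L) stop("reverse search produced no fingerprints",
                              call. = FALSE)
  fingerprint_report(fps, file.path(out_dir, "all"))
  files <- c(files, "all_report.tsv", "all_matrix.tsv")
  write_manifest(config, out_dir, files,
                 list(mode = "reverse", n_patterns = nrow(catalog),
                      errors = as.list(errors)))
  invisible(list(fingerprints = fps, out_dir = out_dir, errors = errors))
}

#' Forward search: discover motifs in co-expressed clusters, then
#' fingerprint them
#'
#' Clusters genes by expression ([cluster_coexpressed()]); for each
#' sufficiently large cluster and each region kind, trains a background
#' model on all sequences of that kind, runs the Gibbs sampler on the
#' cluster's sequences (subsampled to `max_sequences`), names each
#' discovered consensus in discovery order (`OS_1K_001`, ...), and
#' immediately assembles its regulatory fingerprint over all genes.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, list with `motifs` (named by CRE), `fingerprints`,
#'   `out_dir`, `errors`.
#' @export
run_forward_search <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  inputs <- load_run_inputs(config)
  d <- config$discovery
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  clusters <- cluster_coexpressed(inputs$m, k = d$k_clusters,
                                  seed = config$seed)
  clusters <- clusters[vapply(clusters, length, integer(1)) >= d$min_cluster]
  if (length(clusters) == 0L) stop("no cluster large enough for discovery",
                                   call. = FALSE)
  motifs <- list()
  fps <- list()
  files <- character(0)
  for (kind in config$region_kinds) {
    regions <- suppressWarnings(
      extract_regions(inputs$genome, inputs$models, kind))
    bg <- train_background(regions, order = d$order)
    counter <- 0L
    for (ci in seq_along(clusters)) {
      res <- tryCatch({
        genes <- intersect(clusters[[ci]], names(regions$sequences))
        genes <- genes[nchar(regions$sequences[genes]) >= max(d$width)]
        if (length(genes) < 10L) stop("cluster too small after filtering")
        if (length(genes) > d$max_sequences) {
          genes <- with_seed(config$seed + ci,
                             sample(genes, d$max_sequences))
        }
        found <- gibbs_motif_search(regions$sequences[genes], bg,
                                    width = d$width, n_motifs = d$n_motifs,
                                    iterations = d$iterations,
                                    restarts = d$restarts,
                                    seed = config$seed + 1000L * ci)
        for (mm in found) {
          counter <- counter + 1L
          nm <- cre_name(kind, counter)
          motifs[[nm]] <- mm
          fp <- tryCatch(
            regulatory_fingerprint(motif_pattern(mm$consensus, nm), regions,
                                   inputs$calls, name = nm,
                                   alpha = config$alpha),
            error = function(e) NULL)
          if (!is.null(fp)) fps[[nm]] <- fp
        }
        TRUE
      }, error = function(e) {
        errors <<- c(errors, sprintf("cluster %d/%s: %s", ci, kind,
                                     conditionMessage(e)))
        FALSE
      })
    }
    if (length(motifs)) {
      f <- file.path(out_dir, paste0("discovered_", kind, ".txt"))
      sel <- vapply(names(motifs), function(nm) {
        startsWith(nm, paste0("OS_", REGION_CODES[[kind]]))
      }, logical(1))
      if (any(sel)) {
        write_motif_report(motifs[sel], f, names = names(motifs)[sel])
        files <- c(files, basename(f))
      }
    }
  }
  if (length(fps)) {
    fingerprint_report(fps, file.path(out_dir, "discovered"))
    files <- c(files, "discovered_report.tsv", "discovered_matrix.tsv")
  }
  write_manifest(config, out_dir, files,
                 list(mode = "forward", n_clusters = length(clusters),
                      errors = as.list(errors)))
  invisible(list(motifs = motifs, fingerprints = fps, out_dir = out_dir,
                 errors = errors))
}

#' CRE-to-TF association for a catalog pattern
#'
#' Convenience wrapper chaining scan -> z-score profile -> TF correlation
#' -> network export.
#'
#' @param pattern `motif_pattern` or IUPAC string.
#' @param regions a `region_set` (up1k for autoregulation flags).
#' @param m expression matrix (genes and TFs as rows).
#' @param tf_table TF list (see [tf_association_table()]).
#' @param n_min minimum complete pairs (default 80% of arrays).
#' @param path optional edge-list output path.
#' @param r_threshold network export threshold (default 0.45).
#' @return a `tf_association` table.
#' @export
run_tf_association <- function(pattern, regions, m, tf_table, n_min = NULL,
                               path = NULL, r_threshold = 0.45) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  hits <- scan_region_set(regions, pattern)
  genes <- intersect(carrier_genes(hits), rownames(m))
  if (length(genes) == 0L) stop("pattern occurs in no matrix gene",
                                call. = FALSE)
  zp <- zscore_profile(genes, m, name = pattern$name)
  hits_flag <- if (identical(regions$kind, "up1k")) hits else NULL
  assoc <- tf_association_table(zp, tf_table, m, hits_up1k = hits_flag,
                                n_min = n_min)
  if (!is.null(path)) export_network(assoc, path, r_threshold = r_threshold)
  assoc
}

#' Build the default synthetic demo scenario on disk
#'
#' Writes a complete input bundle to `dir`: a synthetic genome (FASTA +
#' GFF3) with two planted CREs in 1-kb upstream regions (the ABRE-core
#' 8-mer CACGTGTC, induced in arrays 1-3; the GCC-box-type 8-mer
#' CGCCGCCG, suppressed in arrays 4-6), an expression meta-matrix with the
#' planted effects plus constructed TF rows (strong positive and negative
#' TFs for each CRE plus null decoys), a TF list, a pattern catalog and a
#' run-config YAML. Returns the config path and all ground truth.
#'
#' @param dir output directory.
#' @param seed integer RNG seed.
#' @param n_genes number of genes (default 2000).
#' @param n_arrays number of arrays (default 24).
#' @param n_planted_tfs strong TFs per CRE (default 10).
#' @param n_decoy_tfs null TF rows (default 200).
#' @return list with `config` (path), `truth` (planting + responders +
#'   TF targets) and `paths`.
#' @export
demo_scenario <- function(dir, seed = 1L, n_genes = 2000L, n_arrays = 24L,
                          n_planted_tfs = 10L, n_decoy_tfs = 200L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(n_genes = n_genes, promoter_len = 1000L,
                        n_contigs = 4L, seed = seed)
  spec1 <- planting_spec("CACGTGTC", fraction = 0.10)
  spec2 <- planting_spec("CGCCGCCG", fraction = 0.10)
  genome <- plant_motifs(genome, spec1, seed = seed + 1L)
  genome <- plant_motifs(genome, spec2, seed = seed + 2L)
  carriers1 <- unique(genome$truth$gene_id[genome$truth$pattern == "CACGTGTC"])
  carriers2 <- unique(genome$truth$gene_id[genome$truth$pattern == "CGCCGCCG"])

  eff1 <- effect_spec(1:3, "induce", delta = 1.5, responder_fraction = 0.5,
                      noise_sd = 0.5)
  eff2 <- effect_spec(4:6, "suppress", delta = 1.5, responder_fraction = 0.5,
                      noise_sd = 0.5)
  sim <- simulate_expression(genome$genes$gene_id, n_arrays,
                             effects = list(list(carriers = carriers1, spec = eff1),
                                            list(carriers = carriers2, spec = eff2)),
                             seed = seed + 3L)
  m <- sim$m

  # TF rows: for each CRE, strong positive and negative TFs built from the
  # carrier set's Z profile, plus null decoys
  zp1 <- zscore_profile(carriers1, m, name = "CRE1")
  zp2 <- zscore_profile(carriers2, m, name = "CRE2")
  half <- ceiling(n_planted_tfs / 2)
  tr1 <- c(rep(0.6, half), rep(-0.6, n_planted_tfs - half))
  tr2 <- c(rep(0.6, half), rep(-0.6, n_planted_tfs - half))
  tf1 <- simulate_tf_profiles(zp1$z, tr1, seed = seed + 4L,
                              tf_ids = sprintf("TF_CRE1_%03d", seq_along(tr1)))
  tf2 <- simulate_tf_profiles(zp2$z, tr2, seed = seed + 5L,
                              tf_ids = sprintf("TF_CRE2_%03d", seq_along(tr2)))
  decoys <- simulate_tf_profiles(zp1$z, rep(0, n_decoy_tfs), seed = seed + 6L,
                                 tf_ids = sprintf("TF_NULL_%03d",
                                                  seq_len(n_decoy_tfs)))
  m_all <- rbind(m, tf1, tf2, decoys)
  tf_table <- data.frame(
    tf_gene_id = c(rownames(tf1), rownames(tf2), rownames(decoys)),
    family = c(rep("bZIP", nrow(tf1)), rep("ERF", nrow(tf2)),
               rep("decoy", nrow(decoys))),
    stringsAsFactors = FALSE)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    matrix = file.path(dir, "expression.tsv"),
    tf_list = file.path(dir, "tfs.tsv"),
    catalog = file.path(dir, "catalog.tsv")
  )
  write_genome_fasta(genome, paths$fasta)
  write_genome_gff(genome, paths$gff)
  write_expression_matrix(m_all, paths$matrix)
  utils::write.table(tf_table, paths$tf_list, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(name = c("ABRE_demo", "GCC_demo"),
               iupac = c("CACGTGTC", "CGCCGCCG"),
               source = c("planted", "planted")),
    paths$catalog, sep = "\t", quote = FALSE, row.names = FALSE)

  cfg <- list(paths = paths, region_kinds = "up1k", default_cutoff = 2,
              alpha = 0.05, seed = seed,
              out_dir = file.path(dir, "out"),
              discovery = list(width = 8L, n_motifs = 1L, iterations = 150L,
                               restarts = 5L, order = 1L, k_clusters = 4L,
                               max_sequences = 150L, min_cluster = 20L))
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config_path)
  list(config = config_path,
       truth = list(planting = genome$truth,
                    carriers = list(CACGTGTC = carriers1,
                                    CGCCGCCG = carriers2),
                    responders = sim$responders,
                    responsive_arrays = list(CACGTGTC = colnames(m)[1:3],
                                             CGCCGCCG = colnames(m)[4:6]),
                    tf_target_r = c(attr(tf1, "target_r"),
                                    attr(tf2, "target_r"),
                                    attr(decoys, "target_r"))),
       paths = c(paths, config = config_path))
}
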
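#' Gibbs-sampling motif discovery with a Markov background
#'
#' Seeded ZOOPS (zero-or-one occurrence per sequence) Gibbs sampler: each
#' sequence contributes at most one motif site; in every sweep each
#' sequence's site is resampled from the posterior over all window
#' positions on both strands (weighted by the PWM / background
#' log-likelihood ratio) plus the no-site option (prior `site_prior`).
#' The best of `restarts` independent chains (by total log-likelihood-ratio
#' score) is kept. When `n_motifs > 1`, each found motif's sites are masked
#' to N before searching the next, so successive motifs never share sites.
#' Results are deterministic given `seed`.
#'
#' @param sequences character vector of DNA sequences (>= 10), or a
#'   `region_set`.
#' @param background a `markov_background` (see [train_background()]).
#' @param width motif width (8-25; default 8). A vector gives a range and
#'   the best-scoring width wins.
#' @param n_motifs number of motifs to extract (default 1).
#' @param iterations Gibbs sweeps per restart (default 200).
#' @param restarts independent chains (default 10).
#' @param seed integer RNG seed.
#' @param site_prior prior probability that a sequence contains a site
#'   (default 0.5).
#' @param both_strands sample sites on both strands (default TRUE).
#' @return list of `motif_model` objects ranked by score (possibly empty,
#'   with a notice, when nothing beats the background). Each model has
#'   `width`, `pfm` (width x 4 position frequency matrix), `sites`
#'   (data.frame `seq_id`, `offset`, `strand`, `word`), `score` (total
#'   log-likelihood ratio vs background), `ic` (information content in
#'   bits) and `consensus` (IUPAC, via [pwm_consensus()]).
#' @export
gibbs_motif_search <- function(sequences, background, width = 8L,
                               n_motifs = 1L, iterations = 200L,
                               restarts = 10L, seed = 1L, site_prior = 0.5,
                               both_strands = TRUE) {
  if (inherits(sequences, "region_set")) sequences <- sequences$sequences
  sequences <- sequences[nchar(sequences) > 0L]
  if (length(sequences) < 10L) {
    stop("motif discovery needs at least 10 sequences", call. = FALSE)
  }
  width <- as.integer(width)
  if (any(width < 4L | width > 25L)) {
    stop("motif width must be within 4..25", call. = FALSE)
  }
  if (max(width) > min(nchar(sequences))) {
    stop("width exceeds the shortest sequence", call. = FALSE)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%04d", seq_along(sequences))
  }
  codes <- lapply(sequences, dna_to_int)
  found <- list()
  with_seed(seed, {
    for (mi in seq_len(n_motifs)) {
      best <- NULL
      for (w in width) {
        cand <- gibbs_one_motif(codes, background, w, iterations, restarts,
                                site_prior, both_strands)
        if (!is.null(cand) && (is.null(best) || cand$score > best$score)) {
          best <- cand
        }
      }
      if (is.null(best) || best$score <= 0 || nrow(best$sites) < 2L) {
        message("no motif exceeding the background score; stopping at ",
                length(found), " motif(s)")
        break
      }
      best$sites$seq_id <- names(codes)[best$sites$seq_index]
      best$sites$seq_index <- NULL
      best$consensus <- pwm_consensus(best)
      found[[length(found) + 1L]] <- best
      # mask discovered sites to N before the next search
      for (r in seq_len(nrow(best$sites))) {
        i <- match(best$sites$seq_id[r], names(codes))
        span <- best$sites$offset[r]:(best$sites$offset[r] + best$width - 1L)
        codes[[i]][span] <- 5L
      }
    }
  })
  found[order(-vapply(found, `[[`, numeric(1), "score"))]
}

# one motif, one width: restarts x iterations ZOOPS Gibbs; the sweep runs
# in compiled code (gibbs_chain_cpp), driven by R's RNG
gibbs_one_motif <- function(codes, background, w, iterations, restarts,
                            site_prior, both_strands) {
  n <- length(codes)
  pseudo <- background$marginal  # background-proportional pseudocounts
  # precompute per sequence: window embeddings and background log-probs,
  # forward and reverse strand (reverse in its own coordinates)
  pre <- lapply(codes, function(code) {
    L <- length(code)
    np <- L - w + 1L
    embF <- vapply(seq_len(w), function(j) code[j:(j + np - 1L)],
                   integer(np))
    if (np == 1L) embF <- matrix(embF, 1L, w)
    bgF <- window_logprob(code, background, w)
    # windows containing N (incl. masked sites) must be unsamplable: a +1e9
    # background sentinel drives their log-likelihood ratio to -Inf range
    # (the -1e9 PWM and background penalties would otherwise cancel)
    bgF[rowSums(embF > 4L) > 0L] <- 1e9
    if (both_strands) {
      rc <- revcomp_int(code)
      embR <- vapply(seq_len(w), function(j) rc[j:(j + np - 1L)],
                     integer(np))
      if (np == 1L) embR <- matrix(embR, 1L, w)
      bgR <- window_logprob(rc, background, w)
      bgR[rowSums(embR > 4L) > 0L] <- 1e9
    } else {
      embR <- matrix(integer(0), 0, w); bgR <- numeric(0)
    }
    list(L = L, np = np, embF = embF, bgF = bgF, embR = embR, bgR = bgR)
  })
  embF <- lapply(pre, `[[`, "embF")
  embR <- lapply(pre, `[[`, "embR")
  bgF <- lapply(pre, `[[`, "bgF")
  bgR <- lapply(pre, `[[`, "bgR")

  best <- NULL
  for (rs in seq_len(restarts)) {
    chain <- gibbs_chain_cpp(embF, embR, bgF, bgR, w, iterations, site_prior,
                             pseudo, both_strands)
    state <- lapply(seq_len(n), function(i) {
      if (chain$pos[i] == 0L) return(NULL)
      list(pos = chain$pos[i], strand = if (chain$strand[i] == 1L) "+" else "-")
    })
    counts <- matrix(0, w, 4)
    nsites <- 0L
    for (i in seq_len(n)) {
      st <- state[[i]]
      if (is.null(st)) next
      wc <- if (st$strand == "+") pre[[i]]$embF[st$pos, ] else
        pre[[i]]$embR[st$pos, ]
      counts <- counts + count_window(wc, w)
      nsites <- nsites + 1L
    }
    model <- finalize_motif(state, pre, counts, nsites, pseudo, w)
    if (!is.null(model) && (is.null(best) || model$score > best$score)) {
      best <- model
    }
  }
  best
}

pseudo_matrix <- function(pseudo, w) {
  matrix(pseudo, w, 4, byrow = TRUE)
}

count_window <- function(wc, w) {
  m <- matrix(0, w, 4)
  ok <- wc <= 4L
  m[cbind(which(ok), wc[ok])] <- 1
  m
}

# score and package the final site configuration
finalize_motif <- function(state, pre, counts, nsites, pseudo, w) {
  if (nsites < 2L) return(NULL)
  pfm <- (counts + pseudo_matrix(pseudo, w)) / (nsites + 1)
  lpw5 <- cbind(log(pfm), -1e9)
  score <- 0
  rows <- list()
  for (i in seq_along(state)) {
    st <- state[[i]]
    if (is.null(st)) next
    p <- pre[[i]]
    wc <- if (st$strand == "+") p$embF[st$pos, ] else p$embR[st$pos, ]
    bgw <- if (st$strand == "+") p$bgF[st$pos] else p$bgR[st$pos]
    score <- score + sum(lpw5[cbind(seq_len(w), wc)]) - bgw
    # report offsets in forward-strand coordinates
    offset <- if (st$strand == "+") st$pos else p$L - (st$pos + w - 1L) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      seq_index = i, offset = offset, strand = st$strand,
      word = int_to_dna(wc), stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  ic <- sum(pfm * log2(pmax(pfm, 1e-12) / 0.25))
  structure(list(width = w, pfm = pfm, sites = sites, score = score, ic = ic),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("Motif model (w = %d): consensus %s, %d sites, score %.2f, IC %.2f bits\n",
              x$width,
              if (is.null(x$consensus)) pwm_consensus(x) else x$consensus,
              nrow(x$sites), x$score, x$ic))
  invisible(x)
}

#' Total log-likelihood-ratio score of a fixed site set
#'
#' Builds the PWM from the given sites (with background-proportional
#' pseudocounts) and sums, over sites, the log ratio of the PWM likelihood
#' to the background likelihood of each site window. This is the quantity
#' the Gibbs sampler maximises.
#'
#' @param sequences named character vector of sequences.
#' @param background a `markov_background`.
#' @param sites data.frame with `seq_id`, `offset` (forward 1-based),
#'   `strand` (`"+"`/`"-"`).
#' @param width motif width.
#' @return numeric scalar.
#' @export
site_set_score <- function(sequences, background, sites, width) {
  codes <- lapply(sequences, dna_to_int)
  wins <- lapply(seq_len(nrow(sites)), function(r) {
    code <- codes[[sites$seq_id[r]]]
    span <- sites$offset[r]:(sites$offset[r] + width - 1L)
    wc <- code[span]
    if (sites$strand[r] == "-") wc <- revcomp_int(wc)
    wc
  })
  counts <- Reduce(`+`, lapply(wins, count_window, w = width))
  pfm <- (counts + pseudo_matrix(background$marginal, width)) /
    (length(wins) + 1)
  lpw <- log(pfm)
  total <- 0
  for (r in seq_len(nrow(sites))) {
    code <- codes[[sites$seq_id[r]]]
    span <- sites$offset[r]:(sites$offset[r] + width - 1L)
    wc <- code[span]
    if (sites$strand[r] == "-") {
      rc <- revcomp_int(code)
      L <- length(code)
      rpos <- L - (sites$offset[r] + width - 1L) + 1L
      bgw <- window_logprob(rc, background, width)[rpos]
      wc <- revcomp_int(wc)
    } else {
      bgw <- window_logprob(code, background, width)[sites$offset[r]]
    }
    total <- total + sum(lpw[cbind(seq_len(width), wc)]) - bgw
  }
  total
}

#' IUPAC consensus of a motif model
#'
#' Per column, the smallest degenerate code covering all bases whose
#' frequency is at least `min_freq`.
#'
#' @param motif a `motif_model` (or a width x 4 frequency matrix).
#' @param min_freq inclusion threshold (default 0.25).
#' @return IUPAC consensus string.
#' @export
pwm_consensus <- function(motif, min_freq = 0.25) {
  pfm <- if (inherits(motif, "motif_model")) motif$pfm else motif
  paste(apply(pfm, 1, function(col) {
    sel <- DNA_BASES[col >= min_freq]
    if (length(sel) == 0L) sel <- DNA_BASES[which.max(col)]
    IUPAC_FROM_SET[[paste(sort(sel), collapse = "")]]
  }), collapse = "")
}

#' Search for motifs co-existing with an anchor CRE
#'
#' Restricts the region set to genes carrying the anchor pattern, masks
#' every anchor occurrence to N (so the anchor is not re-discovered;
#' disable with `mask_anchor = FALSE`), and runs [gibbs_motif_search()]
#' against a background model that should be trained on ALL sequences of
#' the region kind, not just the anchor-bearing subset.
#'
#' @param regions a `region_set`.
#' @param anchor a `motif_pattern` (or IUPAC string).
#' @param background a `markov_background` trained on the full region set.
#' @param mask_anchor mask anchor occurrences before the search (default
#'   TRUE).
#' @param ... passed to [gibbs_motif_search()].
#' @return ranked list of `motif_model` objects (sites never overlap
#'   anchor occurrences when masking is on).
#' @export
find_coexisting_motifs <- function(regions, anchor, background,
                                   mask_anchor = TRUE, ...) {
  if (!inherits(anchor, "motif_pattern")) anchor <- motif_pattern(anchor)
  hits <- scan_region_set(regions, anchor)
  genes <- carrier_genes(hits)
  if (length(genes) == 0L) {
    stop("anchor pattern occurs in no sequence", call. = FALSE)
  }
  seqs <- regions$sequences[genes]
  if (mask_anchor) {
    fwd <- compile_pattern(anchor$iupac)
    rev_m <- if (anchor$is_palindromic) NULL else
      compile_pattern(reverse_complement(anchor$iupac))
    w <- anchor$width
    seqs <- vapply(seqs, function(s) {
      starts <- c(fwd(s), if (!is.null(rev_m)) rev_m(s))
      for (st in starts) substr(s, st, st + w - 1L) <- strrep("N", w)
      s
    }, character(1))
  }
  gibbs_motif_search(seqs, background, ...)
}

#' Write motif models as a plain-text report
#'
#' One block per motif: consensus, score, information content, the
#' position frequency matrix and the site list.
#'
#' @param motifs list of `motif_model` objects.
#' @param path output file.
#' @param names optional character vector of motif names.
#' @export
write_motif_report <- function(motifs, path, names = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    nm <- if (is.null(names)) sprintf("motif_%02d", i) else names[i]
    cons <- if (is.null(m$consensus)) pwm_consensus(m) else m$consensus
    writeLines(sprintf("MOTIF %s consensus=%s width=%d sites=%d score=%.4f ic=%.4f",
                       nm, cons, m$width, nrow(m$sites), m$score, m$ic), con)
    writeLines("# PFM rows: position; columns: A C G T", con)
    for (j in seq_len(m$width)) {
      writeLines(paste(sprintf("%.4f", m$pfm[j, ]), collapse = "\t"), con)
    }
    writeLines("# sites: seq_id offset strand word", con)
    for (r in seq_len(nrow(m$sites))) {
      writeLines(paste(m$sites$seq_id[r], m$sites$offset[r],
                       m$sites$strand[r], m$sites$word[r], sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
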
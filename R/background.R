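#' Train an order-k Markov background model
#'
#' Estimates conditional base probabilities for every k-mer context from a
#' set of sequences (maximum likelihood with a +1 pseudocount per cell).
#' Separate background models are intended per region kind (upstream,
#' 5'-UTR, intron, downstream), since their base compositions differ.
#'
#' @param sequences character vector of DNA sequences (or a `region_set`).
#' @param order Markov order k, 0 to 3. Training requires a total sequence
#'   length of at least `100 * 4^k`.
#' @param label optional label recording what the model was trained on.
#' @return object of class `markov_background`: list with `order`, `prob`
#'   (a `4^k x 4` matrix of conditional probabilities, contexts as
#'   rownames), `marginal` (base composition) and `label`.
#' @export
train_background <- function(sequences, order = 1L, label = NULL) {
  if (inherits(sequences, "region_set")) {
    if (is.null(label)) label <- sequences$kind
    sequences <- sequences$sequences
  }
  sequences <- sequences[nchar(sequences) > 0L]
  k <- as.integer(order)
  if (k < 0L || k > 3L) stop("order must be 0..3", call. = FALSE)
  total <- sum(nchar(sequences))
  if (total < 100 * 4^k) {
    stop(sprintf(paste0("insufficient sequence (%d bp) for order %d ",
                        "(need >= %d bp); use a lower order"),
                 total, k, 100L * 4L^k), call. = FALSE)
  }
  n_ctx <- 4L^k
  counts <- matrix(1, n_ctx, 4)  # +1 pseudocount per cell
  marg <- rep(0, 4)
  for (s in sequences) {
    code <- dna_to_int(s)
    ok <- code <= 4L
    marg <- marg + tabulate(code[ok], 4L)
    L <- length(code)
    if (L <= k) next
    pos <- (k + 1L):L
    valid <- ok[pos]
    ctx <- rep(0L, length(pos))
    if (k > 0L) {
      for (j in seq_len(k)) {
        prev <- code[pos - j]
        valid <- valid & prev <= 4L
        ctx <- ctx + (pmin(prev, 4L) - 1L) * 4L^(j - 1L)
      }
    }
    idx <- cbind(ctx[valid] + 1L, code[pos][valid])
    inc <- table(factor(idx[, 1], levels = seq_len(n_ctx)),
                 factor(idx[, 2], levels = 1:4))
    counts <- counts + as.matrix(inc)
  }
  prob <- counts / rowSums(counts)
  rownames(prob) <- context_labels(k)
  colnames(prob) <- DNA_BASES
  structure(list(order = k, prob = prob, marginal = marg / sum(marg),
                 label = label),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("Order-%d Markov background%s; composition A %.3f C %.3f G %.3f T %.3f\n",
              x$order,
              if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              x$marginal[1], x$marginal[2], x$marginal[3], x$marginal[4]))
  invisible(x)
}

context_labels <- function(k) {
  if (k == 0L) return("")
  grid <- do.call(expand.grid, rep(list(DNA_BASES), k))
  # context index encodes the immediately preceding base in the lowest digit
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

# per-position conditional log-probabilities of a coded sequence under the
# background; positions with N (or N in context) get a large negative
# sentinel. The first k positions use the marginal composition.
seq_position_logprob <- function(code, bg) {
  k <- bg$order
  L <- length(code)
  lp <- rep(-1e9, L)
  ok <- code <= 4L
  lmarg <- log(bg$marginal)
  head_n <- min(k, L)
  if (head_n > 0L) {
    idx <- seq_len(head_n)
    lp[idx][ok[idx]] <- lmarg[code[idx][ok[idx]]]
  }
  if (L > k) {
    pos <- (k + 1L):L
    valid <- ok[pos]
    ctx <- rep(0L, length(pos))
    if (k > 0L) {
      for (j in seq_len(k)) {
        prev <- code[pos - j]
        valid <- valid & prev <= 4L
        ctx <- ctx + (pmin(prev, 4L) - 1L) * 4L^(j - 1L)
      }
    }
    lprob <- log(bg$prob)
    sel <- which(valid)
    lp[pos[sel]] <- lprob[cbind(ctx[sel] + 1L, code[pos[sel]])]
    # valid base after an N (unknown context): fall back to the marginal
    fb <- which(ok[pos] & !valid)
    lp[pos[fb]] <- lmarg[code[pos[fb]]]
  }
  lp
}

# log background probability of every width-w window
window_logprob <- function(code, bg, w) {
  L <- length(code)
  if (L < w) return(numeric(0))
  lp <- seq_position_logprob(code, bg)
  cs <- cumsum(lp)
  if (L == w) cs[w] else c(cs[w], cs[(w + 1L):L] - cs[1L:(L - w)])
}
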
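#' Construct a local Markov-chain background model
#'
#' Backgrounds are order-`k` Markov chains over \{A,C,G,T\}: the
#' probability of each base is conditioned on the preceding `k` bases.
#' Lower-order chains (down to order 0) are carried alongside and used as
#' fallback for the first positions of a sequence, where fewer than `k`
#' preceding bases exist, and for contexts containing `N`.
#'
#' @param order Nonnegative integer Markov order.
#' @param tables List of `order + 1` conditional-probability matrices;
#'   element `o + 1` is the order-`o` table with `4^o` context rows
#'   (contexts in base-4 lexicographic order over A,C,G,T) and 4 columns
#'   (next base A,C,G,T), each row summing to 1.
#' @return An object of class `markov_background`.
#' @export
markov_background <- function(order, tables) {
  order <- as.integer(order)
  stopifnot(order >= 0L, length(tables) == order + 1L)
  for (o in 0:order) {
    tab <- tables[[o + 1L]]
    if (!is.matrix(tab) || nrow(tab) != 4^o || ncol(tab) != 4L)
      stop("order-", o, " table must be ", 4^o, " x 4")
    if (any(abs(rowSums(tab) - 1) > 1e-9))
      stop("order-", o, " table rows must sum to 1")
  }
  structure(list(order = order, tables = tables),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("Markov background, order", x$order, "\n")
  print(round(x$tables[[x$order + 1L]], 3))
  invisible(x)
}

#' Estimate background models from sequences
#'
#' Maximum-likelihood conditional k-mer frequencies with a pseudocount of 1
#' per context cell, for the inter-CRM background (order `k`) and the
#' intra-CRM background (order `k_prime`). Both are estimated from the full
#' input: true intra-CRM regions are unknown before training.
#'
#' @param seqs Named character vector of sequences over \{A,C,G,T,N\}.
#' @param k Order of the inter-CRM background chain; default 1.
#' @param k_prime Order of the intra-CRM background chain; default 2.
#' @param pseudocount Added to every (context, base) cell; default 1.
#' @return List with elements `theta0` and `theta1`
#'   ([markov_background] objects).
#' @export
estimate_backgrounds <- function(seqs, k = 1L, k_prime = 2L,
                                 pseudocount = 1) {
  if (length(seqs) == 0L) stop("no sequences given")
  list(theta0 = estimate_markov_background(seqs, k, pseudocount),
       theta1 = estimate_markov_background(seqs, k_prime, pseudocount))
}

#' Estimate a single Markov background of a given order
#'
#' @inheritParams estimate_backgrounds
#' @param order Markov order.
#' @return A [markov_background] object.
#' @export
estimate_markov_background <- function(seqs, order, pseudocount = 1) {
  enc <- lapply(seqs, encode_dna)
  tables <- vector("list", order + 1L)
  for (o in 0:order) {
    counts <- matrix(pseudocount, nrow = 4^o, ncol = 4L)
    for (s in enc) {
      n <- length(s)
      if (n <= o) next
      pos <- (o + 1L):n
      nxt <- s[pos]
      ctx_ok <- nxt != 5L
      ctx <- rep(1L, length(pos))  # 1-based context row index
      if (o > 0L) {
        for (j in seq_len(o)) {
          prev <- s[pos - j]
          ctx_ok <- ctx_ok & prev != 5L
          ctx <- ctx + (prev - 1L) * 4L^(o - j)
        }
      }
      use <- which(ctx_ok)
      if (length(use) > 0L) {
        tab <- table(factor(ctx[use], levels = seq_len(4^o)),
                     factor(nxt[use], levels = 1:4))
        counts <- counts + as.matrix(tab)
      }
    }
    tables[[o + 1L]] <- counts / rowSums(counts)
  }
  markov_background(order, tables)
}

#' Log-probability of a segment under a background model
#'
#' Sum of log conditional probabilities of each base given its preceding
#' context. The context may come from `context` (bases preceding the
#' segment in the sequence); when fewer than `order` context bases are
#' available (sequence start), the lower-order fallback chain is used for
#' the affected positions. `N` bases emit with probability 0.25 and force
#' order-0 treatment of positions whose context they enter.
#'
#' @param bg A [markov_background] object.
#' @param segment Character string over \{A,C,G,T,N\} (may be empty).
#' @param context Character string of bases immediately preceding the
#'   segment; default `""`.
#' @return Natural-log probability (0 for an empty segment).
#' @export
background_log_probability <- function(bg, segment, context = "") {
  if (nchar(segment) == 0L) return(0)
  seg <- encode_dna(segment)
  ctx <- if (nchar(context) > 0L) encode_dna(context) else integer(0)
  sum(background_position_logprobs(bg, c(ctx, seg))[
    length(ctx) + seq_along(seg)])
}

# Per-position log conditional probability of an integer-encoded sequence
# (1..4 bases, 5 = N).  Entry t is log P(x_t | x_{t-order..t-1}), with
# lower-order fallback near the sequence start and around N bases.
background_position_logprobs <- function(bg, seq_int) {
  n <- length(seq_int)
  out <- numeric(n)
  for (t in seq_len(n)) {
    if (seq_int[t] == 5L) { out[t] <- log(0.25); next }
    o <- min(bg$order, t - 1L)
    # shrink order past any N in the context window
    while (o > 0L && any(seq_int[(t - o):(t - 1L)] == 5L)) o <- o - 1L
    row <- 1L
    if (o > 0L) {
      prev <- seq_int[(t - o):(t - 1L)]
      row <- 1L + sum((prev - 1L) * 4L^((o - 1L):0L))
    }
    out[t] <- log(bg$tables[[o + 1L]][row, seq_int[t]])
  }
  out
}
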
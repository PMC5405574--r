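#' Most likely state path of a sequence (duration Viterbi)
#'
#' Decodes the argmax-probability segmentation of the sequence into
#' inter-CRM background, motif sites and spacers. Ties are broken
#' deterministically: background is preferred over ending a CRM, lower
#' motif state indices over higher, and shorter spacers over longer.
#'
#' @param model A [crm_model].
#' @param seq Character string over \{A,C,G,T,N\}.
#' @return A [state_path] with attribute `"score"` (the joint log
#'   probability of sequence and path).
#' @export
viterbi_decode <- function(model, seq) {
  em <- build_emissions(model, seq)
  if (em$L == 0L) stop("empty sequence")
  vt <- crm_viterbi_cpp(em$e0, em$e1, em$memit, as.integer(em$lens),
                        model$p_r, model$q0, model$q,
                        transition_matrix(model), model$p_h)
  n <- length(vt$state)
  state <- c("bg", "motif", "spacer")[vt$state + 1L]
  crm <- rep(NA_integer_, n)
  crm_counter <- 0L
  for (s in seq_len(n)) {
    if (state[s] == "motif" && vt$crm_start[s] == 1L)
      crm_counter <- crm_counter + 1L
    if (state[s] != "bg") crm[s] <- crm_counter
  }
  path <- state_path(state, vt$start, vt$end, motif = vt$motif, crm = crm)
  validate_state_path(path, model, em$L)
  attr(path, "score") <- vt$score
  path
}

#' Extract CRM predictions from a decoded state path
#'
#' One prediction per maximal run of motif/spacer segments; the CRM spans
#' from its first site's start to its last site's end (flanking background
#' is never included). Sites on the reverse-complement motif states
#' (index `> K'`) are reported on the `-` strand under the forward
#' motif's id. Each site carries a log-odds score: its PWM log
#' probability minus the intra-CRM background log probability of the same
#' span.
#'
#' @param path A [state_path] from [viterbi_decode].
#' @param model A [crm_model].
#' @param seq The decoded sequence.
#' @param seq_id Sequence identifier used in the output; default `"seq"`.
#' @return List of class `crm_predictions` with data.frames `crms`
#'   (`seq_id`, `crm_id`, `start`, `end`, `n_sites`, `motifs`, `llr`,
#'   `llr_log2`) and `sites` (`seq_id`, `crm_id`, `motif_id`, `strand`,
#'   `start`, `end`, `log_odds`). Coordinates 0-based half-open.
#' @export
extract_crms <- function(path, model, seq, seq_id = "seq") {
  seq_int <- encode_dna(seq)
  validate_state_path(path, model, length(seq_int))
  e1 <- background_position_logprobs(model$theta1, seq_int)
  crm_rows <- list(); site_rows <- list()
  for (cid in sort(unique(stats::na.omit(path$crm)))) {
    segs <- path[!is.na(path$crm) & path$crm == cid, , drop = FALSE]
    msegs <- segs[segs$state == "motif", , drop = FALSE]
    if (nrow(msegs) == 0L) next
    sites <- data.frame(
      seq_id = seq_id, crm_id = cid,
      motif_id = vapply(msegs$motif, function(i)
        model$motifs[[if (i <= model$K) i else i - model$K]]$id, ""),
      strand = ifelse(msegs$motif <= model$K, "+", "-"),
      start = msegs$start, end = msegs$end,
      log_odds = vapply(seq_len(nrow(msegs)), function(s) {
        i <- msegs$motif[s]; a <- msegs$start[s]; b <- msegs$end[s]
        site_probability(model$motifs[[i]],
                         substr(seq, a + 1L, b), log = TRUE) -
          sum(e1[(a + 1L):b])
      }, 0),
      stringsAsFactors = FALSE
    )
    llr <- llr_score_segments(segs, model, seq)
    crm_rows[[length(crm_rows) + 1L]] <- data.frame(
      seq_id = seq_id, crm_id = cid,
      start = min(msegs$start), end = max(msegs$end),
      n_sites = nrow(msegs),
      motifs = paste(unique(sites$motif_id), collapse = ","),
      llr = llr, llr_log2 = llr / log(2),
      stringsAsFactors = FALSE
    )
    site_rows[[length(site_rows) + 1L]] <- sites
  }
  empty_crms <- data.frame(
    seq_id = character(), crm_id = integer(), start = integer(),
    end = integer(), n_sites = integer(), motifs = character(),
    llr = numeric(), llr_log2 = numeric(), stringsAsFactors = FALSE)
  empty_sites <- data.frame(
    seq_id = character(), crm_id = integer(), motif_id = character(),
    strand = character(), start = integer(), end = integer(),
    log_odds = numeric(), stringsAsFactors = FALSE)
  structure(
    list(crms = if (length(crm_rows)) do.call(rbind, crm_rows)
         else empty_crms,
         sites = if (length(site_rows)) do.call(rbind, site_rows)
         else empty_sites),
    class = "crm_predictions"
  )
}

# Log-likelihood ratio of one CRM's segments (motif/spacer rows of a
# state path): CRM-internal generative probability of the spanned
# subsequence along the decoded segmentation versus the inter-CRM
# background probability of the same span.  The CRM initiation factor
# p_r is not part of the score; the transition structure (q_first,
# (1 - q0) q_{i,j}, final q0) is.
llr_score_segments <- function(segs, model, seq) {
  seq_int <- encode_dna(seq)
  e0 <- background_position_logprobs(model$theta0, seq_int)
  e1 <- background_position_logprobs(model$theta1, seq_int)
  lQ <- log(transition_matrix(model))
  msegs <- segs[segs$state == "motif", , drop = FALSE]
  num <- log(model$q[msegs$motif[1L]])
  prev <- NA_integer_
  for (s in seq_len(nrow(segs))) {
    a <- segs$start[s]; b <- segs$end[s]
    if (segs$state[s] == "motif") {
      i <- segs$motif[s]
      if (!is.na(prev))
        num <- num + log1p(-model$q0) + lQ[prev, i]
      num <- num + site_probability(model$motifs[[i]],
                                    substr(seq, a + 1L, b), log = TRUE)
      prev <- i
    } else if (segs$state[s] == "spacer") {
      num <- num + spacer_duration_probability(model, b - a, log = TRUE) +
        sum(e1[(a + 1L):b])
    }
  }
  num <- num + log(model$q0)
  span <- (min(msegs$start) + 1L):max(msegs$end)
  num - sum(e0[span])
}

#' Log-likelihood-ratio score of a predicted CRM
#'
#' @param crm One row of the `crms` data.frame of [extract_crms], or a
#'   list with `crm_id`.
#' @param path The decoded [state_path] the CRM came from.
#' @param model A [crm_model].
#' @param seq The decoded sequence.
#' @return Natural-log likelihood ratio of the CRM model over the
#'   inter-CRM background for the spanned subsequence.
#' @export
llr_score <- function(crm, path, model, seq) {
  segs <- path[!is.na(path$crm) & path$crm == crm$crm_id, , drop = FALSE]
  if (nrow(segs) == 0L) stop("CRM id not found in path")
  llr_score_segments(segs, model, seq)
}

#' Decode and score CRMs over a set of sequences
#'
#' Convenience wrapper: [viterbi_decode] + [extract_crms] per sequence,
#' results combined; CRM ids are made unique across sequences.
#'
#' @param model A [crm_model].
#' @param seqs Named character vector of sequences.
#' @return A `crm_predictions` object covering all sequences.
#' @export
predict_crms <- function(model, seqs) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  preds <- lapply(seq_along(seqs), function(k) {
    path <- viterbi_decode(model, seqs[[k]])
    extract_crms(path, model, seqs[[k]], seq_id = ids[k])
  })
  combine_predictions(preds)
}

combine_predictions <- function(preds) {
  out <- structure(list(crms = do.call(rbind, lapply(preds, `[[`, "crms")),
                        sites = do.call(rbind, lapply(preds, `[[`, "sites"))),
                   class = "crm_predictions")
  rownames(out$crms) <- NULL; rownames(out$sites) <- NULL
  # unique CRM keys across sequences
  if (nrow(out$crms) > 0L) {
    key <- paste(out$crms$seq_id, out$crms$crm_id, sep = ":")
    out$crms$crm_key <- key
    out$sites$crm_key <- paste(out$sites$seq_id, out$sites$crm_id, sep = ":")
  } else {
    out$crms$crm_key <- character(0)
    out$sites$crm_key <- character(0)
  }
  out
}

#' @export
print.crm_predictions <- function(x, ...) {
  cat("CRM predictions:", nrow(x$crms), "CRM(s),",
      nrow(x$sites), "site(s) across",
      length(unique(x$crms$seq_id)), "sequence(s)\n")
  if (nrow(x$crms) > 0L) print(utils::head(x$crms, 10L))
  invisible(x)
}
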
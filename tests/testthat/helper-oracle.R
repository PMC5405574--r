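# Independent brute-force oracle: enumerate every valid segmentation of a
# short sequence, score each with the generative-story path scorer, and
# reduce.  Kept deliberately naive (recursive enumeration, no dynamic
# programming) so it shares no machinery with the forward/Viterbi code
# it checks.

enumerate_state_paths <- function(model, L) {
  lens <- vapply(model$motifs, `[[`, 0L, "length")
  M <- length(lens)
  paths <- list()
  seg <- function(state, start, end, motif = NA_integer_,
                  crm = NA_integer_) {
    list(state = state, start = start, end = end, motif = motif, crm = crm)
  }
  emit <- function(segs) paths[[length(paths) + 1L]] <<- segs
  # at a decision point with t bases consumed
  decision <- function(t, segs, crm_id) {
    if (t == L) { emit(segs); return(invisible()) }
    decision(t + 1L, append_bg(segs, t), crm_id)           # one bg base
    for (i in seq_len(M))                                   # start a CRM
      if (t + lens[i] <= L)
        in_crm(t + lens[i],
               c(segs, list(seg("motif", t, t + lens[i], i, crm_id + 1L))),
               crm_id + 1L, i)
  }
  append_bg <- function(segs, t) {
    n <- length(segs)
    if (n > 0L && segs[[n]]$state == "bg") {
      segs[[n]]$end <- t + 1L
      segs
    } else c(segs, list(seg("bg", t, t + 1L)))
  }
  # inside a CRM, last site of motif i ended at t
  in_crm <- function(t, segs, crm_id, i) {
    decision(t, segs, crm_id)                               # CRM ends here
    for (j in seq_len(M))
      for (d in seq_len(max(L - t - lens[j], 0L)))
        in_crm(t + d + lens[j],
               c(segs, list(seg("spacer", t, t + d, crm = crm_id),
                            seg("motif", t + d, t + d + lens[j], j,
                                crm_id))),
               crm_id, j)
  }
  decision(0L, list(), 0L)
  lapply(paths, function(segs)
    crmscan::state_path(
      state = vapply(segs, `[[`, "", "state"),
      start = vapply(segs, `[[`, 0L, "start"),
      end = vapply(segs, `[[`, 0L, "end"),
      motif = vapply(segs, `[[`, NA_integer_, "motif"),
      crm = vapply(segs, `[[`, NA_integer_, "crm")))
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log-likelihood, best path and path scores by exhaustive enumeration
oracle_enumerate <- function(model, seq) {
  L <- nchar(seq)
  paths <- enumerate_state_paths(model, L)
  ll <- vapply(paths, function(p)
    crmscan::path_log_likelihood(model, seq, p), 0)
  list(paths = paths, loglik_per_path = ll,
       loglik = logsumexp(ll),
       best = max(ll), best_path = paths[[which.max(ll)]])
}

# number of adjacent (i, j) motif pairs (one spacer apart) in a path
oracle_pair_count <- function(path, i, j) {
  m <- path[path$state != "bg", , drop = FALSE]
  cnt <- 0L
  for (s in seq_len(nrow(m))) {
    if (s + 2L > nrow(m)) break
    if (m$state[s] == "motif" && m$state[s + 1L] == "spacer" &&
        m$state[s + 2L] == "motif" &&
        m$crm[s] == m$crm[s + 2L] &&
        m$motif[s] == i && m$motif[s + 2L] == j)
      cnt <- cnt + 1L
  }
  cnt
}

# posterior mean/variance of the (i, j) pair count, and posterior
# expected total pair matrix, from the enumeration
oracle_pair_moments <- function(enum, model, i, j) {
  w <- exp(enum$loglik_per_path - enum$loglik)
  cnt <- vapply(enum$paths, oracle_pair_count, 0L, i = i, j = j)
  list(mean = sum(w * cnt), second_moment = sum(w * cnt^2),
       variance = sum(w * cnt^2) - sum(w * cnt)^2)
}

oracle_T_matrix <- function(enum, model) {
  M <- model$M
  w <- exp(enum$loglik_per_path - enum$loglik)
  Tm <- matrix(0, M, M)
  for (i in seq_len(M))
    for (j in seq_len(M))
      Tm[i, j] <- sum(w * vapply(enum$paths, oracle_pair_count, 0L,
                                 i = i, j = j))
  Tm
}
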
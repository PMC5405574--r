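# Emission tables for one sequence: per-position background/spacer log
# probabilities and, per motif state, the log probability of a full site
# ending at each position.  These depend only on Theta (PWMs, theta0,
# theta1), which is held fixed during training, so they are computed once
# per sequence and reused across EM iterations.
build_emissions <- function(model, seq) {
  seq_int <- encode_dna(seq)
  L <- length(seq_int)
  memit <- matrix(-Inf, nrow = model$M, ncol = max(L, 1L))
  for (i in seq_len(model$M))
    if (L >= model$motifs[[i]]$length)
      memit[i, ] <- pwm_scan_log(model$motifs[[i]], seq_int)
  list(seq_int = seq_int, L = L,
       e0 = background_position_logprobs(model$theta0, seq_int),
       e1 = background_position_logprobs(model$theta1, seq_int),
       memit = memit,
       lens = vapply(model$motifs, `[[`, 0L, "length"))
}

#' Forward-backward pass over one sequence
#'
#' Runs the explicit-duration forward and backward recursions, returning
#' the exact sequence log-likelihood and segment-level posteriors: the
#' probability that each motif state's site ends at each position, the
#' per-position state occupancy (background / motif / spacer), expected
#' adjacent motif-pair transition counts, expected first-motif usage and
#' expected spacer base count.
#'
#' @param model A [crm_model].
#' @param seq Character string over \{A,C,G,T,N\}.
#' @param posteriors Compute posterior tables (default) or only the
#'   log-likelihood?
#' @return List with elements `loglik`, `loglik_backward`, and (when
#'   requested) `T` (`2K' x 2K'` expected pair counts), `first_motif`,
#'   `gamma_site` (`2K' x L`), `occupancy` (`3 x L`; rows background,
#'   motif, spacer) and `expected_spacer_bases`.
#' @export
forward_backward <- function(model, seq, posteriors = TRUE) {
  em <- build_emissions(model, seq)
  if (em$L == 0L) stop("empty sequence")
  if (em$L < min(em$lens))
    warning("sequence shorter than every motif; posteriors are ",
            "all-background")
  crm_forward_backward_cpp(em$e0, em$e1, em$memit, as.integer(em$lens),
                           model$p_r, model$q0, model$q,
                           transition_matrix(model), model$p_h,
                           posteriors = posteriors)
}

#' Exact posterior moments of one motif pair's adjacency count
#'
#' Propagates first and second moments of the number of
#' `m_i -> spacer -> m_j` adjacencies through the forward recursion,
#' giving the exact posterior mean and variance of the pair count for one
#' sequence (a diagnostic for the co-occurrence statistics).
#'
#' @param model A [crm_model].
#' @param seq Character string.
#' @param i,j Motif state indices (`1..2K'`).
#' @return List with `loglik`, `mean`, `second_moment`, `variance`.
#' @export
pair_count_moments <- function(model, seq, i, j) {
  stopifnot(i >= 1L, i <= model$M, j >= 1L, j <= model$M)
  em <- build_emissions(model, seq)
  crm_pair_moments_cpp(em$e0, em$e1, em$memit, as.integer(em$lens),
                       model$p_r, model$q0, model$q,
                       transition_matrix(model), model$p_h,
                       as.integer(i), as.integer(j))
}
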
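#' Co-occurrence statistics of motif pairs on a training set
#'
#' `T[i, j]` is the posterior expected number of times a site of motif
#' state `i` is followed, across one spacer within a CRM, by a site of
#' motif state `j`, summed over the training sequences (sequences are
#' independent, so per-sequence counts add). `E` and `sigma` are the mean
#' and standard deviation of `T[i, j]` under the no-correlation null in
#' which each of the `N = sum(T)` adjacency slots draws its (predecessor,
#' successor) pair independently from the observed marginals, so that
#' `T[i, j] ~ Binomial(N, a_i * b_j)` with `a`, `b` the row/column
#' marginal frequencies. `z` is the co-occurrence z-score
#' [cooccurrence_zscore]; entries whose null standard deviation is 0 have
#' `z = NA` and are never gated.
#'
#' @param model A [crm_model].
#' @param seqs Named character vector of training sequences.
#' @param fb_list Optional list of precomputed [forward_backward] results
#'   (one per sequence), to avoid recomputation inside EM.
#' @return List with matrices `T`, `E`, `sigma`, `z` (all `2K' x 2K'`) and
#'   `n_slots = sum(T)`.
#' @export
expected_cooccurrences <- function(model, seqs, fb_list = NULL) {
  M <- model$M
  if (is.null(fb_list))
    fb_list <- lapply(seqs, function(s) forward_backward(model, s))
  Tm <- matrix(0, M, M)
  for (fb in fb_list)
    if (isTRUE(fb$posteriors_available)) Tm <- Tm + fb$T
  N <- sum(Tm)
  if (N > 0) {
    a <- rowSums(Tm) / N
    b <- colSums(Tm) / N
    p <- outer(a, b)
    E <- N * p
    sigma <- sqrt(N * p * (1 - p))
  } else {
    E <- sigma <- matrix(0, M, M)
  }
  z <- matrix(NA_real_, M, M)
  ok <- sigma > 0
  z[ok] <- (Tm[ok] - E[ok]) / sigma[ok]
  list(T = Tm, E = E, sigma = sigma, z = z, n_slots = N)
}

#' Detect correlated motif pairs and update correlation parameters
#'
#' Pairs passing the detection gate (`z >= z_threshold` and
#' `E >= E_threshold`, see [is_correlated]) form the correlated partner
#' set `R_i` of each state; for `j` in `R_i` the correlation parameter is
#' set to the expected-count share `r_{i,j} = T[i, j] / sum_k T[i, k]`
#' (which reduces to normalization within `R_i` when every partner of `i`
#' is correlated). Rows with zero total count keep `R_i` empty.
#'
#' @param stats Result of [expected_cooccurrences].
#' @param model A [crm_model].
#' @param freeze_gate Optional logical matrix: when supplied, the partner
#'   sets are taken from it instead of the z-gate (used after the gate is
#'   frozen during training) and only the `r` values are re-estimated.
#' @return The model with updated `corr`.
#' @export
update_correlations <- function(stats, model, freeze_gate = NULL) {
  M <- model$M
  gate <- if (!is.null(freeze_gate)) freeze_gate else {
    g <- matrix(FALSE, M, M)
    for (i in seq_len(M))
      for (j in seq_len(M))
        g[i, j] <- is_correlated(stats$z[i, j], stats$E[i, j],
                                 model$z_threshold, model$E_threshold)
    g
  }
  corr <- rep(list(numeric(0)), M)
  for (i in seq_len(M)) {
    R_i <- which(gate[i, ])
    if (length(R_i) == 0L) next
    tot <- sum(stats$T[i, ])
    if (tot <= 0) next                  # no support: pair dropped
    r <- stats$T[i, R_i] / tot
    keep <- r > 0
    if (!any(keep)) next
    r <- pmin(r[keep], 1)
    names(r) <- R_i[keep]
    corr[[i]] <- r
  }
  model$corr <- corr
  model
}

#' Fit the CRM model by extended Baum-Welch EM
#'
#' Iterates the exact E-step ([forward_backward] on every sequence; the
#' sequences are independent, and accumulation follows the fixed input
#' order so results do not depend on scheduling) and an M-step that
#' re-estimates the motif frequencies `q` (from expected first-motif usage
#' plus transitions through the uncorrelated channel), the spacer
#' parameter `p_h` (from expected spacer lengths, unless pinned) and the
#' correlation parameters `r` of gated pairs. `p_r`, `q0`, the PWMs and
#' the background chains are held fixed: they are either supplied by
#' configuration or precomputed, since re-estimating them from small
#' training sets overfits. All motif pairs start uncorrelated; after
#' `burn_in` iterations the co-occurrence gate ([update_correlations])
#' runs once and the detected pair set is frozen, while its `r` values
#' keep being re-estimated each iteration. Convergence is never declared
#' before the gate has run, so the burn-in always completes.
#'
#' @param model0 Initial [crm_model].
#' @param seqs Named character vector of training sequences.
#' @param max_iter Maximum EM iterations; default 50. `max_iter = 0`
#'   evaluates the likelihood of `model0` and returns it unchanged.
#' @param tol Relative log-likelihood improvement below which EM stops;
#'   default 1e-4.
#' @param burn_in Iterations before correlation detection; default 5.
#' @param update_p_h Re-estimate `p_h`? Default `TRUE`.
#' @param update_q Re-estimate `q`? Default `TRUE`.
#' @param tie_orientations Share one frequency between the forward and
#'   reverse-complement states of each motif (strand-symmetric motif
#'   frequency)? Default `TRUE`.
#' @param detect_correlations Run the co-occurrence gate? Default `TRUE`.
#' @param verbose Print per-iteration log-likelihoods?
#' @return List of class `crm_training` with `model`, `loglik_trace`
#'   (one value per E-step, evaluated before that iteration's M-step),
#'   `iterations`, `converged`, and the final co-occurrence `stats`.
#' @export
em_fit <- function(model0, seqs, max_iter = 50L, tol = 1e-4,
                   burn_in = 5L, update_p_h = TRUE, update_q = TRUE,
                   tie_orientations = TRUE, detect_correlations = TRUE,
                   verbose = FALSE) {
  if (length(seqs) == 0L) stop("no training sequences")
  model <- model0
  emis <- lapply(seqs, function(s) build_emissions(model0, s))
  seq_ids <- names(seqs) %||% as.character(seq_along(seqs))

  e_step <- function(model) {
    Q <- transition_matrix(model)
    fb_list <- vector("list", length(emis))
    for (k in seq_along(emis)) {
      em <- emis[[k]]
      fb <- crm_forward_backward_cpp(em$e0, em$e1, em$memit,
                                     as.integer(em$lens), model$p_r,
                                     model$q0, model$q, Q, model$p_h)
      if (!is.finite(fb$loglik))
        stop("non-finite likelihood on sequence '", seq_ids[k], "'")
      fb_list[[k]] <- fb
    }
    fb_list
  }

  trace <- numeric(0)
  gate <- NULL
  gate_iter <- NA_integer_
  stats <- NULL
  iterations <- 0L
  converged <- FALSE

  for (it in seq_len(max_iter + 1L)) {
    fb_list <- e_step(model)
    ll <- sum(vapply(fb_list, `[[`, 0, "loglik"))
    trace <- c(trace, ll)
    if (verbose)
      message(sprintf("iter %3d  loglik %.6f", it - 1L, ll))
    if (it > max_iter) break
    # convergence is suspended while the correlation gate is pending and
    # for `burn_in` further iterations after it fires, so the posterior
    # re-equilibrates under the new correlation structure before stopping
    gate_pending <- detect_correlations &&
      (is.null(gate) || it <= gate_iter + burn_in)
    if (it > 1L && !gate_pending) {
      rel <- (ll - trace[it - 1L]) / abs(trace[it - 1L])
      if (is.finite(rel) && rel < tol) { converged <- TRUE; break }
    }
    # ---- M-step ----
    M <- model$M
    Tm <- matrix(0, M, M); C1 <- numeric(M); sp_bases <- 0
    for (fb in fb_list)
      if (isTRUE(fb$posteriors_available)) {
        Tm <- Tm + fb$T
        C1 <- C1 + fb$first_motif
        sp_bases <- sp_bases + fb$expected_spacer_bases
      }
    stats <- expected_cooccurrences(model, seqs, fb_list = fb_list)
    if (detect_correlations && is.null(gate) && it > burn_in) {
      model <- update_correlations(stats, model)
      gate_iter <- it
      gate <- matrix(FALSE, M, M)
      for (i in seq_len(M))
        gate[i, as.integer(names(model$corr[[i]]))] <- TRUE
    } else if (!is.null(gate)) {
      model <- update_correlations(stats, model, freeze_gate = gate)
    }
    # q is held at its initialization until the correlation gate has run:
    # frequencies and correlations are confounded, and re-estimating q
    # while pairs are still (wrongly) assumed uncorrelated folds the
    # correlation mass into q, from which EM does not recover
    if (update_q && !(detect_correlations && is.null(gate)))
      model$q <- maximize_q(model, C1, Tm, tie_orientations)
    if (update_p_h) {
      n_spacers <- sum(Tm)
      if (n_spacers > 0 && sp_bases >= n_spacers) {
        model$p_h <- n_spacers / sp_bases
        model$h <- 1 / model$p_h
      }
    }
    iterations <- it
  }

  structure(list(model = model, loglik_trace = trace,
                 iterations = iterations, converged = converged,
                 stats = stats),
            class = "crm_training")
}

# Exact M-step for the motif frequencies q.  The expected complete-data
# log-likelihood terms involving q are
#   sum_j W_j log q_j  -  sum_i U_i log S_i,   S_i = sum_{k notin R_i} q_k
# with W_j = (expected first-motif count of j) + (expected transitions
# into j through the uncorrelated channel) and U_i the expected
# uncorrelated transitions out of i (the -log S_i term is the
# renormalization of Eq-style transitions q_j (1 - rho_i) / S_i).  When no
# state has correlated partners all S_i = 1 and the maximizer is the
# usual normalized expected count.  Otherwise we iterate an MM scheme:
# linearizing -log S_i at the current q gives the surrogate maximizer
# q_j = W_j / (lambda + d_j), d_j = sum_{i: j notin R_i} U_i / S_i, with
# lambda chosen so q sums to 1 (monotone, solved by bisection).  Each MM
# step does not decrease the objective, preserving EM monotonicity.
#
# With tie_orientations, the forward and reverse-complement states of a
# motif share one frequency parameter (a binding site on the reverse
# strand is the same physical event, so motif frequency is
# strand-symmetric); counts pool across the orientation pair.
maximize_q <- function(model, C1, Tm, tie_orientations = FALSE) {
  M <- model$M
  uncorr <- lapply(seq_len(M), function(i)
    setdiff(seq_len(M), as.integer(names(model$corr[[i]]))))
  W <- C1
  for (i in seq_len(M)) W[uncorr[[i]]] <- W[uncorr[[i]]] + Tm[i, uncorr[[i]]]
  if (sum(W) <= 0) return(model$q)
  W <- pmax(W, 1e-8 * sum(W))
  U <- vapply(seq_len(M), function(i) sum(Tm[i, uncorr[[i]]]), 0)
  group <- if (tie_orientations) rep(seq_len(model$K), 2L) else seq_len(M)
  nG <- max(group)
  Wg <- as.vector(rowsum(W, group))
  q <- model$q
  for (mm in seq_len(100L)) {
    d <- numeric(M)
    for (i in seq_len(M)) {
      S_i <- sum(q[uncorr[[i]]])
      if (S_i > 0 && U[i] > 0)
        d[uncorr[[i]]] <- d[uncorr[[i]]] + U[i] / S_i
    }
    # per-group surrogate slope: members of a group share their mass
    # equally, so each contributes half (or all, untied) of its d
    share <- 1 / tabulate(group, nG)[group]
    dg <- as.vector(rowsum(d * share, group))
    # root of g(lambda) = sum_g Wg / (lambda + dg) - 1 (decreasing)
    lo <- -min(dg) + 1e-10
    hi <- sum(Wg) + max(dg)
    for (b in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (sum(Wg / (mid + dg)) > 1) lo <- mid else hi <- mid
    }
    v <- Wg / ((lo + hi) / 2 + dg)
    v <- v / sum(v)
    q_new <- (v * share[match(seq_len(nG), group)])[group]
    q_new <- q_new / sum(q_new)
    if (max(abs(q_new - q)) < 1e-12) { q <- q_new; break }
    q <- q_new
  }
  q
}

#' @export
print.crm_training <- function(x, ...) {
  cat("CRM model training:", x$iterations, "iteration(s),",
      if (x$converged) "converged" else "not converged", "\n")
  cat(sprintf("  log-likelihood %.4f -> %.4f\n",
              x$loglik_trace[1], x$loglik_trace[length(x$loglik_trace)]))
  np <- sum(lengths(x$model$corr))
  cat("  correlated pairs detected:", np, "\n")
  invisible(x)
}
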
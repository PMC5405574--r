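#' Construct a CRM duration-HMM
#'
#' The model generates a sequence as inter-CRM background (state `b_g`, an
#' order-`k` Markov chain whose run length is geometric with mean
#' `1 / p_r`) interleaved with CRMs. A CRM starts with probability `p_r`,
#' picks its first motif state with frequencies `q`, and after each motif
#' site either terminates (probability `q0`) or continues (`1 - q0`) to a
#' next motif chosen by the transition law of [transition_matrix], with a
#' spacer (state `b_c`, order-`k'` Markov chain, geometric length with mean
#' `h = 1 / p_h`) implanted between consecutive sites. Each of the `K'`
#' input motifs contributes two motif states: the forward matrix (state
#' `i`) and its reverse complement (state `K' + i`), so sites are found on
#' either strand.
#'
#' @param pwms List of `K'` forward-strand [pwm] objects (reverse
#'   complements are added internally).
#' @param theta0,theta1 Inter- and intra-CRM background models
#'   ([markov_background]); see [estimate_backgrounds].
#' @param p_r CRM initiation probability per background position; default
#'   0.001.
#' @param q0 CRM termination probability after a motif site; default 0.1.
#' @param h Mean spacer length between motif sites within a CRM (bp); the
#'   geometric spacer parameter is `p_h = 1 / h`. Default 50 (use ~20 for
#'   densely packed CRMs).
#' @param q Motif state frequencies over all `2 K'` states (first/next
#'   motif choice). Default uniform; forward and reverse-complement states
#'   of a motif start with equal mass.
#' @param corr Correlation parameters: a list of length `2 K'` (or `NULL`
#'   for none) whose element `i` is a numeric vector of `r_{i,j}` values
#'   named by partner state index `j`. `sum(corr[[i]]) <= 1` is required.
#' @param z_threshold,E_threshold Thresholds of the co-occurrence z-score
#'   and its expectation for declaring a motif pair correlated; both
#'   default 1.
#' @return An object of class `crm_model`. `model$motifs` holds all
#'   `2 K'` PWMs (reverse complements in positions `K'+1 .. 2K'`).
#' @export
crm_model <- function(pwms, theta0, theta1, p_r = 0.001, q0 = 0.1, h = 50,
                      q = NULL, corr = NULL, z_threshold = 1,
                      E_threshold = 1) {
  if (length(pwms) < 1L) stop("at least one PWM is required")
  lapply(pwms, validate_pwm)
  ids <- vapply(pwms, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("PWM ids must be unique")
  stopifnot(inherits(theta0, "markov_background"),
            inherits(theta1, "markov_background"))
  K <- length(pwms)
  M <- 2L * K
  motifs <- c(pwms, lapply(pwms, reverse_complement_pwm))
  if (is.null(q)) q <- rep(1 / M, M)
  if (length(q) != M || any(q <= 0) || abs(sum(q) - 1) > 1e-9)
    stop("q must be a length-", M, " positive vector summing to 1")
  if (!(p_r > 0 && p_r < 1)) stop("p_r must lie in (0, 1)")
  if (!(q0 > 0 && q0 < 1)) stop("q0 must lie in (0, 1)")
  if (!(h >= 1)) stop("h must be >= 1")
  if (is.null(corr)) corr <- rep(list(numeric(0)), M)
  if (length(corr) != M) stop("corr must have one element per motif state")
  for (i in seq_len(M)) {
    ri <- corr[[i]]
    if (length(ri) == 0L) next
    j <- as.integer(names(ri))
    if (anyNA(j) || any(j < 1L | j > M) || anyDuplicated(j))
      stop("corr[[", i, "]] must be named by distinct state indices 1..", M)
    if (any(ri <= 0 | ri > 1) || sum(ri) > 1 + 1e-9)
      stop("corr[[", i, "]]: each r must lie in (0,1] and sum to <= 1")
  }
  structure(
    list(motifs = motifs, K = K, M = M,
         p_r = p_r, q0 = q0, h = h, p_h = 1 / h, q = q, corr = corr,
         theta0 = theta0, theta1 = theta1,
         z_threshold = z_threshold, E_threshold = E_threshold),
    class = "crm_model"
  )
}

#' @export
print.crm_model <- function(x, ...) {
  cat("CRM duration-HMM:", x$K, "motif(s),", x$M, "motif states\n")
  cat(sprintf("  p_r = %g, q0 = %g, h = %g (p_h = %g)\n",
              x$p_r, x$q0, x$h, x$p_h))
  cat("  background orders:", x$theta0$order, "(inter-CRM),",
      x$theta1$order, "(intra-CRM)\n")
  np <- sum(lengths(x$corr))
  cat("  correlated pairs:", np, "\n")
  if (np > 0)
    for (i in seq_len(x$M))
      for (jn in names(x$corr[[i]]))
        cat(sprintf("    r[%d,%s] = %.4f\n", i, jn, x$corr[[i]][[jn]]))
  invisible(x)
}

motif_state_label <- function(model, i) {
  if (i <= model$K) model$motifs[[i]]$id
  else paste0(model$motifs[[i - model$K]]$id, "(-)")
}

#' Motif-to-motif transition probability
#'
#' For a correlated partner `j` of state `i` the transition probability is
#' the learned `r_{i,j}`; uncorrelated partners share the remaining mass in
#' proportion to their frequencies:
#' `q_j * (1 - sum_{k in R_i} r_{i,k}) / sum_{k notin R_i} q_k`.
#' Each row sums to 1.
#'
#' @param model A [crm_model].
#' @param i,j Motif state indices in `1..2K'`.
#' @return The transition probability `q_{i,j}`.
#' @seealso [transition_matrix] for the full matrix.
#' @export
transition_probability <- function(model, i, j) {
  transition_matrix(model)[i, j]
}

#' Full motif-state transition matrix
#'
#' @param model A [crm_model].
#' @return `2K' x 2K'` stochastic matrix of next-motif probabilities.
#' @export
transition_matrix <- function(model) {
  M <- model$M
  Q <- matrix(0, M, M)
  for (i in seq_len(M)) {
    ri <- model$corr[[i]]
    R_i <- as.integer(names(ri))
    mass <- sum(ri)
    if (mass > 1 + 1e-9)
      stop("invalid model: correlation mass of state ", i, " exceeds 1")
    notR <- setdiff(seq_len(M), R_i)
    if (length(ri) > 0L) Q[i, R_i] <- ri
    if (length(notR) > 0L)
      Q[i, notR] <- model$q[notR] * (1 - mass) / sum(model$q[notR])
  }
  Q
}

#' Co-occurrence z-score of a motif pair
#'
#' `z = (T - E) / sigma` where `T` is the observed (expected) number of
#' adjacent co-occurrences of the pair and `E`, `sigma` are its mean and
#' standard deviation under the no-correlation null.
#'
#' @param T_ij Co-occurrence count (may be a posterior expectation).
#' @param E_ij,sigma_ij Null mean and standard deviation; `sigma_ij` must
#'   be positive.
#' @return The z-score.
#' @seealso [is_correlated] for the detection gate.
#' @export
cooccurrence_zscore <- function(T_ij, E_ij, sigma_ij) {
  if (!is.finite(sigma_ij) || sigma_ij <= 0)
    stop("sigma_ij must be positive; z-score undefined")
  (T_ij - E_ij) / sigma_ij
}

#' Correlation detection gate
#'
#' A pair is declared correlated when its z-score reaches `z_threshold`
#' and its null expectation reaches `E_threshold` (both default 1); the
#' expectation gate suppresses significant-looking pairs that are too rare
#' to support a parameter.
#'
#' @param z Co-occurrence z-score.
#' @param E_ij Null expectation of the co-occurrence count.
#' @param z_threshold,E_threshold Detection thresholds; default 1.
#' @return Logical.
#' @export
is_correlated <- function(z, E_ij, z_threshold = 1, E_threshold = 1) {
  is.finite(z) && is.finite(E_ij) && z >= z_threshold && E_ij >= E_threshold
}

#' Spacer length distribution
#'
#' The intra-CRM background between consecutive motif sites has geometric
#' length: `P(d) = (1 - p_h)^(d-1) * p_h`, `d >= 1`, with mean
#' `h = 1 / p_h`.
#'
#' @param model A [crm_model].
#' @param d Integer spacer length(s), `d >= 1`.
#' @param log Return log probabilities?
#' @return Probability (or log probability) of each length in `d`.
#' @export
spacer_duration_probability <- function(model, d, log = FALSE) {
  if (any(d < 1 | d != floor(d))) stop("spacer length d must be >= 1")
  lp <- (d - 1) * log1p(-model$p_h) + log(model$p_h)
  if (log) lp else exp(lp)
}

#' Construct a state path
#'
#' A state path tiles a sequence with segments labelled inter-CRM
#' background (`"bg"`), motif site (`"motif"`, with a motif state index)
#' or spacer (`"spacer"`). Coordinates are 0-based half-open. Motif and
#' spacer segments carry a CRM id (`crm`) grouping them into CRMs;
#' consecutive CRMs may abut (the model may close one CRM and open
#' another with no background between).
#'
#' @param state Character vector: `"bg"`, `"motif"` or `"spacer"`.
#' @param start,end Integer vectors, 0-based half-open.
#' @param motif Integer motif state index (`1..2K'`) for motif segments,
#'   `NA` otherwise.
#' @param crm Integer CRM id for motif/spacer segments, `NA` for `"bg"`.
#' @return A `data.frame` of class `state_path`.
#' @export
state_path <- function(state, start, end, motif = NA_integer_,
                       crm = NA_integer_) {
  df <- data.frame(state = state, start = as.integer(start),
                   end = as.integer(end),
                   motif = as.integer(motif), crm = as.integer(crm),
                   stringsAsFactors = FALSE)
  class(df) <- c("state_path", "data.frame")
  df
}

#' Validate a state path against a model and sequence
#'
#' Checks the tiling (no gaps or overlaps, full coverage), motif segment
#' durations (exactly the motif length), and the rule that every spacer is
#' flanked by two motif segments of the same CRM.
#'
#' @param path A [state_path].
#' @param model A [crm_model].
#' @param seq_length Length of the tiled sequence.
#' @return `path`, invisibly; errors describe the first violation.
#' @export
validate_state_path <- function(path, model, seq_length) {
  if (nrow(path) == 0L) {
    if (seq_length != 0L) stop("empty path cannot tile a nonempty sequence")
    return(invisible(path))
  }
  if (path$start[1L] != 0L || path$end[nrow(path)] != seq_length ||
      (nrow(path) > 1L && any(path$start[-1L] != path$end[-nrow(path)])))
    stop("path segments must tile [0, ", seq_length, ") exactly")
  if (any(path$end <= path$start)) stop("segments must have positive length")
  for (s in which(path$state == "motif")) {
    i <- path$motif[s]
    if (is.na(i) || i < 1L || i > model$M)
      stop("motif segment with invalid state index")
    if (path$end[s] - path$start[s] != model$motifs[[i]]$length)
      stop("motif segment duration != motif length for state ", i)
    if (is.na(path$crm[s])) stop("motif segment lacks a CRM id")
  }
  for (s in which(path$state == "motif"))
    if (s > 1L && path$state[s - 1L] == "motif" &&
        path$crm[s - 1L] == path$crm[s])
      stop("motif sites within a CRM must be separated by a spacer")
  for (s in which(path$state == "spacer")) {
    if (s == 1L || s == nrow(path) ||
        path$state[s - 1L] != "motif" || path$state[s + 1L] != "motif" ||
        path$crm[s - 1L] != path$crm[s] || path$crm[s + 1L] != path$crm[s])
      stop("spacer segments must be flanked by motif segments of their CRM")
  }
  crm_ids <- path$crm[path$state != "bg"]
  if (length(crm_ids) > 0L) {
    runs <- rle(crm_ids)
    if (anyDuplicated(runs$values))
      stop("CRM ids must label contiguous runs")
  }
  invisible(path)
}

#' Joint log-likelihood of a sequence and a state path
#'
#' Scores `log P(x, path | model)` under the generative story: each
#' background base costs `log(1 - p_r)` plus its Markov-chain emission;
#' each CRM costs `log(p_r)`, `log(q_first)`, its site emissions, per
#' continuation `log(1 - q0) + log(q_{i,j})` plus the spacer duration and
#' emission, and a final `log(q0)` (also paid by a CRM cut short by the
#' sequence end). Trailing background pays no terminal factor.
#'
#' @param model A [crm_model].
#' @param seq Character string over \{A,C,G,T,N\}.
#' @param path A [state_path] tiling `seq`.
#' @return Natural-log joint probability.
#' @export
path_log_likelihood <- function(model, seq, path) {
  n <- nchar(seq)
  validate_state_path(path, model, n)
  seq_int <- encode_dna(seq)
  e0 <- background_position_logprobs(model$theta0, seq_int)
  e1 <- background_position_logprobs(model$theta1, seq_int)
  Q <- log(transition_matrix(model))
  ll <- 0
  prev_motif <- NA_integer_
  prev_crm <- NA_integer_
  for (s in seq_len(nrow(path))) {
    a <- path$start[s]; b <- path$end[s]
    st <- path$state[s]
    if (st == "bg") {
      if (!is.na(prev_crm)) { ll <- ll + log(model$q0); prev_crm <- NA }
      ll <- ll + (b - a) * log1p(-model$p_r) + sum(e0[(a + 1L):b])
      prev_motif <- NA
    } else if (st == "motif") {
      i <- path$motif[s]
      if (is.na(prev_crm)) {                       # CRM start
        ll <- ll + log(model$p_r) + log(model$q[i])
      } else if (path$crm[s] != prev_crm) {        # back-to-back CRMs
        ll <- ll + log(model$q0) + log(model$p_r) + log(model$q[i])
      } else {                                     # continuation
        ll <- ll + log1p(-model$q0) + Q[prev_motif, i]
      }
      site <- substr(seq, a + 1L, b)
      ll <- ll + site_probability(model$motifs[[i]], site, log = TRUE)
      prev_motif <- i
      prev_crm <- path$crm[s]
    } else {                                       # spacer
      d <- b - a
      ll <- ll + spacer_duration_probability(model, d, log = TRUE) +
        sum(e1[(a + 1L):b])
      # continuation factors are charged when the next motif is reached
    }
  }
  if (!is.na(prev_crm)) ll <- ll + log(model$q0)   # CRM open at sequence end
  ll
}
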
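#' @useDynLib crmscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM)
#'
#' A PWM describes a motif as one probability distribution over \{A,C,G,T\}
#' per position. Columns are positions; rows are bases in the fixed order
#' A, C, G, T.
#'
#' @param id Character identifier, unique within a motif set.
#' @param matrix Numeric 4 x L matrix of per-position base probabilities
#'   (each column sums to 1) or nonnegative counts (see `counts`).
#' @param tf_label Optional transcription-factor label.
#' @param counts Logical; if `TRUE`, `matrix` holds counts which are
#'   converted to probabilities column-wise after adding `pseudocount`.
#' @param pseudocount Additive smoothing per base applied to count matrices
#'   before normalization. Default 0.01.
#' @return An object of class `pwm` with elements `id`, `tf_label`,
#'   `matrix` (4 x L, rownames A,C,G,T) and `length`.
#' @examples
#' p <- pwm("m1", matrix(c(10, 0, 0, 0), nrow = 4), counts = TRUE)
#' p$matrix[, 1]  # ~ (0.997, 0.001, 0.001, 0.001)
#' @export
pwm <- function(id, matrix, tf_label = NULL, counts = FALSE,
                pseudocount = 0.01) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L)
    stop("PWM '", id, "': matrix must have 4 rows (A, C, G, T), got ",
         nrow(m))
  if (ncol(m) < 1L)
    stop("PWM '", id, "': matrix must have at least one position")
  if (any(!is.finite(m)) || any(m < 0))
    stop("PWM '", id, "': matrix entries must be finite and nonnegative")
  storage.mode(m) <- "double"
  if (counts) {
    m <- m + pseudocount
    m <- sweep(m, 2L, colSums(m), "/")
  } else {
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-6))
      stop("PWM '", id, "': probability columns must sum to 1 (max |dev| = ",
           format(max(abs(cs - 1))), "); use counts = TRUE for count matrices")
    m <- sweep(m, 2L, cs, "/")  # exact renormalization within tolerance
  }
  dimnames(m) <- list(DNA_BASES, NULL)
  structure(
    list(id = as.character(id), tf_label = tf_label, matrix = m,
         length = ncol(m)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id,
      if (!is.null(x$tf_label)) paste0("(", x$tf_label, ")"),
      "- length", x$length, "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

validate_pwm <- function(p) {
  stopifnot(inherits(p, "pwm"))
  if (p$length != ncol(p$matrix))
    stop("PWM '", p$id, "': length field disagrees with matrix")
  cs <- colSums(p$matrix)
  if (any(abs(cs - 1) > 1e-9))
    stop("PWM '", p$id, "': columns do not sum to 1")
  if (any(p$matrix < 0 | p$matrix > 1))
    stop("PWM '", p$id, "': probabilities outside [0,1]")
  invisible(p)
}

#' Reverse complement of a PWM
#'
#' Positions are reversed and, within each position, probabilities are
#' swapped A<->T and C<->G, so the returned PWM describes the same motif
#' read on the opposite strand. The id is suffixed with `"_rc"` (applying
#' the operation twice restores the original id).
#'
#' @param p A [pwm] object.
#' @return A [pwm] object.
#' @export
reverse_complement_pwm <- function(p) {
  validate_pwm(p)
  m <- p$matrix[c(4L, 3L, 2L, 1L), p$length:1L, drop = FALSE]
  dimnames(m) <- list(DNA_BASES, NULL)
  new_id <- if (endsWith(p$id, "_rc")) sub("_rc$", "", p$id)
            else paste0(p$id, "_rc")
  structure(
    list(id = new_id, tf_label = p$tf_label, matrix = m, length = p$length),
    class = "pwm"
  )
}

#' Probability of a motif site under a PWM
#'
#' The probability that the motif generates the given site is the product
#' over positions of the matched base probability. `N` bases contribute a
#' neutral 0.25 factor.
#'
#' @param p A [pwm] object.
#' @param site Character string over \{A,C,G,T,N\} with `nchar(site) ==
#'   p$length`.
#' @param log Return the natural-log probability? Default `FALSE`.
#' @return Probability (or log probability) of the site.
#' @examples
#' u <- pwm("u", matrix(0.25, 4, 3))
#' site_probability(u, "ACG")  # 0.25^3
#' @export
site_probability <- function(p, site, log = FALSE) {
  validate_pwm(p)
  site <- toupper(site)
  if (nchar(site) != p$length)
    stop("site length ", nchar(site), " != PWM length ", p$length)
  idx <- match(strsplit(site, "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
  if (anyNA(idx))
    stop("site contains characters outside {A,C,G,T,N}")
  pr <- numeric(length(idx))
  is_n <- idx == 5L
  pr[is_n] <- 0.25
  if (any(!is_n))
    pr[!is_n] <- p$matrix[cbind(idx[!is_n], which(!is_n))]
  lp <- sum(log(pr))
  if (log) lp else exp(lp)
}

#' Per-column information content of a PWM
#'
#' Information content of column j is `2 + sum_b p_bj * log2(p_bj)` bits
#' (0 for a uniform column, 2 for a deterministic one).
#'
#' @param p A [pwm] object.
#' @return Numeric vector of length `p$length`, in bits.
#' @export
pwm_information_content <- function(p) {
  validate_pwm(p)
  apply(p$matrix, 2L, function(col) {
    nz <- col[col > 0]
    2 + sum(nz * log2(nz))
  })
}

#' Consensus string of a PWM (per-position argmax base)
#' @param p A [pwm] object.
#' @return Character string of length `p$length`.
#' @export
pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(p$matrix, 2L, which.max)], collapse = "")
}

# Log-probability of every site of length p$length ending at each position
# of an integer-encoded sequence (1..4 = A,C,G,T; 5 = N).  Entry t is the
# log-probability of the site occupying [t - L + 1, t]; -Inf for t < L.
pwm_scan_log <- function(p, seq_int) {
  L <- p$length
  n <- length(seq_int)
  out <- rep(-Inf, n)
  if (n < L) return(out)
  logm <- log(p$matrix)
  acc <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    idx <- seq_int[(j):(n - L + j)]
    lp <- ifelse(idx == 5L, log(0.25), logm[cbind(idx, j)])
    acc <- acc + lp
  }
  out[L:n] <- acc
  out
}

encode_dna <- function(bases) {
  idx <- match(strsplit(toupper(bases), "", fixed = TRUE)[[1]],
               c(DNA_BASES, "N"))
  if (anyNA(idx))
    stop("sequence contains characters outside {A,C,G,T,N}")
  idx
}

decode_dna <- function(idx) {
  paste(c(DNA_BASES, "N")[idx], collapse = "")
}
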
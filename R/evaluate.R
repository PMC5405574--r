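#' Nucleotide-level confusion counts
#'
#' CRM prediction is treated as a per-base binary classification: bases
#' inside a predicted CRM are predicted positive, bases inside a true
#' CRM are actually positive. Counts are pooled over sequences by
#' summation.
#'
#' @param truth,pred Data frames with columns `seq_id`, `start`, `end`
#'   (0-based half-open intervals; intervals of one set may overlap, they
#'   are unioned per sequence).
#' @param seq_lengths Named integer vector of sequence lengths; every
#'   `seq_id` must appear, and all intervals must lie within bounds.
#' @return Named vector with `nTP`, `nFP`, `nTN`, `nFN` (and attributes
#'   none); `nTP + nFP + nTN + nFN == sum(seq_lengths)`.
#' @export
confusion <- function(truth, pred, seq_lengths) {
  if (is.null(names(seq_lengths)) || any(!nzchar(names(seq_lengths))))
    stop("seq_lengths must be named by sequence id")
  as_ranges <- function(df, id) {
    df <- df[df$seq_id == id, , drop = FALSE]
    if (nrow(df) == 0L) return(IRanges::IRanges())
    if (any(df$start < 0 | df$end > seq_lengths[[id]] | df$end <= df$start))
      stop("interval out of bounds on sequence '", id, "'")
    IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  }
  counts <- c(nTP = 0, nFP = 0, nTN = 0, nFN = 0)
  for (id in names(seq_lengths)) {
    tr <- as_ranges(truth, id)
    pr <- as_ranges(pred, id)
    L <- seq_lengths[[id]]
    tp <- sum(IRanges::width(IRanges::intersect(tr, pr)))
    counts["nTP"] <- counts["nTP"] + tp
    counts["nFP"] <- counts["nFP"] + sum(IRanges::width(pr)) - tp
    counts["nFN"] <- counts["nFN"] + sum(IRanges::width(tr)) - tp
    counts["nTN"] <- counts["nTN"] + L - sum(IRanges::width(
      IRanges::union(tr, pr)))
  }
  counts
}

#' Correlation coefficient of a base-level prediction
#'
#' The Matthews-style correlation coefficient
#' `CC = (nTP*nTN - nFN*nFP) / sqrt((nTP+nFN)(nTN+nFP)(nTP+nFP)(nTN+nFN))`,
#' the Pearson correlation of the predicted and actual per-base binary
#' labels. When any factor of the denominator is 0 the value is
#' undefined; 0 is returned with attribute `degenerate = TRUE`.
#'
#' @param counts Confusion counts from [confusion] (or any vector with
#'   named elements `nTP`, `nFP`, `nTN`, `nFN`).
#' @return CC in \[-1, 1\].
#' @export
correlation_coefficient <- function(counts) {
  tp <- counts[["nTP"]]; fp <- counts[["nFP"]]
  tn <- counts[["nTN"]]; fn <- counts[["nFN"]]
  f <- c(tp + fn, tn + fp, tp + fp, tn + fn)
  if (any(f == 0)) return(structure(0, degenerate = TRUE))
  # product of four counts can overflow doubles' comfort zone; use sqrt
  # factor-wise
  cc <- (tp * tn - fn * fp) / prod(sqrt(f))
  structure(unname(cc), degenerate = FALSE)
}

#' Full metric report from confusion counts
#'
#' Sensitivity `Sn = nTP / (nTP + nFN)`, precision `Pr = nTP / (nTP +
#' nFP)`, their harmonic mean `F1`, arithmetic mean `ASP`, and the
#' correlation coefficient `CC`. Undefined ratios (zero denominators)
#' are reported as `NA`.
#'
#' @param counts Confusion counts from [confusion].
#' @return Named numeric vector `sn`, `pr`, `f1`, `asp`, `cc`.
#' @export
metric_report <- function(counts) {
  tp <- counts[["nTP"]]; fp <- counts[["nFP"]]; fn <- counts[["nFN"]]
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sn) && !is.na(pr) && sn + pr > 0)
    2 * sn * pr / (sn + pr) else NA_real_
  asp <- if (!is.na(sn) && !is.na(pr)) (sn + pr) / 2 else NA_real_
  c(sn = sn, pr = pr, f1 = f1, asp = asp,
    cc = as.numeric(correlation_coefficient(counts)))
}

#' Fixed-length evaluation protocol: one window per sequence
#'
#' Benchmark protocol for length-controlled comparison: every method must
#' output, per sequence, exactly one predicted CRM of a given target
#' length (the average true CRM length of the subdataset), which forces
#' `nPP = nAP` and hence `Sn = Pr` when each sequence carries one true
#' CRM of that average length. The window is centered on the
#' highest-LLR candidate CRM of the sequence and clipped to the sequence
#' bounds; a candidate longer than the target is trimmed symmetrically,
#' a shorter one extended symmetrically. Sequences without a candidate
#' take the maximum-sum window of `scores` when per-position scores are
#' supplied, otherwise the centered window, and are flagged in the
#' `fallback` column.
#'
#' @param pred A `crm_predictions` object (or its `$crms` data.frame).
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param target_length Window length (bp).
#' @param scores Optional named list of per-position numeric scores (one
#'   vector per sequence) used for the no-candidate fallback.
#' @return Data frame with one row per sequence: `seq_id`, `start`,
#'   `end` (0-based half-open, width `target_length` unless the sequence
#'   is shorter — then the whole sequence, with a warning), `fallback`.
#' @export
fixed_length_protocol <- function(pred, seq_lengths, target_length,
                                  scores = NULL) {
  crms <- if (inherits(pred, "crm_predictions")) pred$crms else pred
  out <- lapply(names(seq_lengths), function(id) {
    L <- seq_lengths[[id]]
    if (target_length > L) {
      warning("target length ", target_length, " exceeds sequence '",
              id, "' (", L, " bp); using the whole sequence")
      return(data.frame(seq_id = id, start = 0L, end = L,
                        fallback = FALSE, stringsAsFactors = FALSE))
    }
    cand <- crms[crms$seq_id == id, , drop = FALSE]
    if (nrow(cand) > 0L) {
      best <- cand[order(-cand$llr, cand$start), , drop = FALSE][1L, ]
      center <- (best$start + best$end) / 2
      start <- as.integer(round(center - target_length / 2))
      fallback <- FALSE
    } else if (!is.null(scores) && !is.null(scores[[id]])) {
      sc <- scores[[id]]
      stopifnot(length(sc) == L)
      win <- stats::filter(sc, rep(1, target_length), sides = 1)
      start <- which.max(win[target_length:L]) - 1L
      fallback <- TRUE
    } else {
      start <- as.integer(round((L - target_length) / 2))
      fallback <- TRUE
    }
    start <- max(0L, min(start, L - as.integer(target_length)))
    data.frame(seq_id = id, start = start,
               end = start + as.integer(target_length),
               fallback = fallback, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Empirical p-value of an observed sensitivity
#'
#' The probability that a stochastic fixed-length prediction reaches the
#' observed sensitivity: each simulation places one uniformly random
#' window of `target_length` per sequence, pooled sensitivity against
#' `truth` is computed, and the p-value is
#' `(#\{Sn_sim >= observed\} + 1) / (n_sim + 1)` (the add-one estimator
#' avoids zero p-values; `>=` makes it conservative). Predictions with
#' `p <= 0.05` are conventionally called significant.
#'
#' @param observed_sn Observed pooled sensitivity.
#' @param truth Data frame of true CRMs (`seq_id`, `start`, `end`).
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param target_length Window length of the protocol.
#' @param n_sim Number of simulations; default 1000.
#' @param seed Integer seed; default 1.
#' @return The empirical p-value, with attribute `sn_sim` (the simulated
#'   sensitivities).
#' @export
empirical_pvalue <- function(observed_sn, truth, seq_lengths,
                             target_length, n_sim = 1000L, seed = 1L) {
  stopifnot(n_sim >= 1L)
  ids <- names(seq_lengths)
  truth_by_id <- lapply(ids, function(id) {
    df <- truth[truth$seq_id == id, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  })
  names(truth_by_id) <- ids
  nAP <- sum(vapply(truth_by_id, function(r)
    sum(IRanges::width(r)), 0))
  if (nAP == 0) stop("truth contains no CRM bases")
  sn_sim <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      tp <- 0
      for (id in ids) {
        L <- seq_lengths[[id]]
        w <- min(target_length, L)
        start0 <- sample.int(L - w + 1L, 1L) - 1L
        win <- IRanges::IRanges(start = start0 + 1L, end = start0 + w)
        tp <- tp + sum(IRanges::width(
          IRanges::intersect(truth_by_id[[id]], win)))
      }
      tp / nAP
    }, 0)
  })
  structure((sum(sn_sim >= observed_sn) + 1) / (n_sim + 1),
            sn_sim = sn_sim)
}

#' Maximum attainable pooled sensitivity under the fixed-length protocol
#'
#' With one prediction of exactly `target_length` per sequence, at most
#' `min(L_i, target_length)` of each true CRM's `L_i` bases can be
#' recovered, so the pooled sensitivity is bounded by
#' `sum_i min(L_i, target_length) / sum_i L_i`.
#'
#' @param truth_lengths True CRM lengths, one per sequence.
#' @param target_length Window length of the protocol.
#' @return Upper bound in \[0, 1\].
#' @export
max_sensitivity <- function(truth_lengths, target_length) {
  stopifnot(all(truth_lengths > 0), target_length > 0)
  sum(pmin(truth_lengths, target_length)) / sum(truth_lengths)
}

#' Bundled fixed-length evaluation summary on the REDfly benchmark
#'
#' Published per-subdataset results of an HMM-based CRM predictor under
#' the fixed-length protocol on the 33 REDfly Drosophila subdatasets:
#' sequence counts, total lengths, the per-subdataset maximum attainable
#' sensitivity, and the predictor's empirical p-value and sensitivity.
#' Ships with the package for the protocol-summary examples.
#'
#' @return Data frame with columns `subdataset`, `n_seq`,
#'   `total_length`, `max_sens`, `pvalue`, `sensitivity`.
#' @export
redfly_protocol_summary <- function() {
  path <- system.file("extdata", "redfly_protocol_summary.tsv",
                      package = "crmscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Summarize fixed-length protocol results over subdatasets
#'
#' @param df Data frame in the layout of [redfly_protocol_summary].
#' @param alpha Significance level on the empirical p-value; default
#'   0.05.
#' @return List: `n_subdatasets`, `n_significant`, `sn_range` (range of
#'   sensitivities among significant subdatasets), `sn_mean` (their
#'   mean), `max_sens_mean` (mean of the per-subdataset maximum
#'   sensitivities).
#' @export
summarize_protocol_results <- function(df, alpha = 0.05) {
  sig <- df$pvalue <= alpha
  list(n_subdatasets = nrow(df),
       n_significant = sum(sig),
       sn_range = if (any(sig)) range(df$sensitivity[sig])
                  else c(NA_real_, NA_real_),
       sn_mean = if (any(sig)) mean(df$sensitivity[sig]) else NA_real_,
       max_sens_mean = mean(df$max_sens))
}
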
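# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# near-uniform order-1 genomic background: slight AT richness and a mild
# same-base stacking preference
default_background_chain <- function() {
  pi0 <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  t1 <- matrix(rep(pi0, each = 4L), nrow = 4L) * 0.85 + diag(4L) * 0.15
  t1 <- t1 / rowSums(t1)
  markov_background(1L, list(matrix(pi0, nrow = 1L), t1))
}

sample_background <- function(bg, n, context = integer(0)) {
  out <- integer(n)
  hist <- context
  for (t in seq_len(n)) {
    o <- min(bg$order, length(hist))
    while (o > 0L && any(hist[(length(hist) - o + 1L):length(hist)] == 5L))
      o <- o - 1L
    row <- 1L
    if (o > 0L) {
      prev <- hist[(length(hist) - o + 1L):length(hist)]
      row <- 1L + sum((prev - 1L) * 4L^((o - 1L):0L))
    }
    out[t] <- sample.int(4L, 1L, prob = bg$tables[[o + 1L]][row, ])
    hist <- c(hist, out[t])
  }
  out
}

sample_site <- function(p) {
  vapply(seq_len(p$length), function(j)
    sample.int(4L, 1L, prob = p$matrix[, j]), 0L)
}

#' Random demonstration PWMs
#'
#' Generates informative synthetic PWMs: each column puts `dominant`
#' probability on a random base and splits the rest evenly. Useful for
#' examples and as true motifs of the synthetic benchmarks.
#'
#' @param k Number of PWMs.
#' @param length Motif length (recycled); default 8.
#' @param dominant Probability of each column's preferred base; default
#'   0.85.
#' @param seed Integer seed.
#' @return List of [pwm] objects with ids `synthetic_m1`, ...
#' @export
demo_pwms <- function(k, length = 8L, dominant = 0.85, seed = 1L) {
  length <- rep_len(length, k)
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      m <- matrix((1 - dominant) / 3, nrow = 4L, ncol = length[i])
      for (j in seq_len(length[i]))
        m[sample.int(4L, 1L), j] <- dominant
      pwm(paste0("synthetic_m", i), m)
    })
  })
}

#' Generate an implanted-CRM benchmark dataset
#'
#' Emulates the classic implanted-CRM benchmark construction: fixed-length
#' background sequences, most of which carry one implanted CRM built from
#' sites of the true motifs. Each CRM has `sites_min`–`sites_max` sites
#' (motif and strand drawn uniformly, bases drawn per-position from the
#' PWM) separated by gaps drawn from a Poisson distribution with mean
#' `spacing_mean` (resampled to be >= 1); a CRM whose span would exceed
#' `max_crm_len` is redrawn. The CRM is placed uniformly within its
#' sequence.
#'
#' @param motif_pwms List of true [pwm] objects.
#' @param n_seq Number of sequences; default 22.
#' @param n_with_crm Number of sequences carrying an implanted CRM;
#'   default 20.
#' @param seq_len Sequence length (bp); default 1000.
#' @param max_crm_len Maximum CRM span (bp); default 164.
#' @param spacing_mean Mean inter-site gap (bp); default 10.
#' @param sites_min,sites_max Range of sites per CRM; defaults 3 and 6.
#' @param background Background [markov_background]; default a
#'   near-uniform order-1 chain.
#' @param seed Integer seed; regenerating with the same seed and
#'   parameters is bit-identical.
#' @param max_retries Redraws allowed per CRM before erroring; default
#'   1000.
#' @return Object of class `synthetic_dataset`: `sequences` (named
#'   character), `truth_crms` and `truth_sites` (data.frames, 0-based
#'   half-open), `pwms`, `seed`, `params`.
#' @export
generate_xie_style <- function(motif_pwms, n_seq = 22L, n_with_crm = 20L,
                               seq_len = 1000L, max_crm_len = 164L,
                               spacing_mean = 10, sites_min = 3L,
                               sites_max = 6L, background = NULL,
                               seed = 1L, max_retries = 1000L) {
  stopifnot(length(motif_pwms) >= 1L, n_with_crm <= n_seq,
            seq_len >= max_crm_len)
  lapply(motif_pwms, validate_pwm)
  if (is.null(background)) background <- default_background_chain()
  max_site <- max(vapply(motif_pwms, `[[`, 0L, "length"))
  if (sites_min * max_site > max_crm_len)
    stop("sites cannot fit: ", sites_min, " sites of up to ", max_site,
         " bp exceed max_crm_len = ", max_crm_len)
  with_seed(seed, {
    seqs <- character(n_seq)
    names(seqs) <- sprintf("seq%02d", seq_len(n_seq))
    crm_rows <- list(); site_rows <- list()
    for (s in seq_len(n_seq)) {
      bases <- sample_background(background, seq_len)
      if (s <= n_with_crm) {
        for (try in seq_len(max_retries + 1L)) {
          if (try > max_retries)
            stop("could not fit a CRM within max_crm_len after ",
                 max_retries, " retries")
          n_sites <- sample(sites_min:sites_max, 1L)
          which_m <- sample.int(length(motif_pwms), n_sites, replace = TRUE)
          strands <- sample(c("+", "-"), n_sites, replace = TRUE)
          gaps <- vapply(seq_len(max(n_sites - 1L, 0L)), function(g) {
            d <- 0L
            while (d < 1L) d <- stats::rpois(1L, spacing_mean)
            d
          }, 0L)
          site_lens <- vapply(which_m, function(i)
            motif_pwms[[i]]$length, 0L)
          span <- sum(site_lens) + sum(gaps)
          if (span <= max_crm_len) break
        }
        crm_start <- sample.int(seq_len - span + 1L, 1L) - 1L
        pos <- crm_start
        for (k in seq_len(n_sites)) {
          p <- motif_pwms[[which_m[k]]]
          site <- sample_site(if (strands[k] == "+") p
                              else reverse_complement_pwm(p))
          bases[(pos + 1L):(pos + p$length)] <- site
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            seq_id = names(seqs)[s], motif_id = p$id,
            strand = strands[k], start = pos, end = pos + p$length,
            stringsAsFactors = FALSE)
          pos <- pos + p$length
          if (k < n_sites) pos <- pos + gaps[k]
        }
        crm_rows[[length(crm_rows) + 1L]] <- data.frame(
          seq_id = names(seqs)[s], start = crm_start,
          end = crm_start + span, stringsAsFactors = FALSE)
      }
      seqs[s] <- decode_dna(bases)
    }
    empty_crm <- data.frame(seq_id = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
    empty_site <- data.frame(seq_id = character(), motif_id = character(),
                             strand = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
    structure(
      list(sequences = seqs,
           truth_crms = if (length(crm_rows)) do.call(rbind, crm_rows)
                        else empty_crm,
           truth_sites = if (length(site_rows)) do.call(rbind, site_rows)
                         else empty_site,
           pwms = motif_pwms, seed = seed,
           params = list(mode = "xie", n_seq = n_seq,
                         n_with_crm = n_with_crm, seq_len = seq_len,
                         max_crm_len = max_crm_len,
                         spacing_mean = spacing_mean,
                         sites_min = sites_min, sites_max = sites_max)),
      class = "synthetic_dataset")
  })
}

#' Inter-site gaps of a synthetic dataset
#'
#' Gap lengths between consecutive true sites within each true CRM, for
#' calibration checks of the spacing model.
#'
#' @param ds A `synthetic_dataset`.
#' @return Integer vector of gap lengths (bp).
#' @export
truth_site_gaps <- function(ds) {
  unlist(lapply(split(ds$truth_sites, ds$truth_sites$seq_id), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) < 2L) return(integer(0))
    df$start[-1L] - df$end[-nrow(df)]
  }), use.names = FALSE)
}

#' Build decoy-augmented PWM collections
#'
#' For each noise ratio `d/t`, emits `n_collections` motif collections of
#' `t` PWMs: the `t - d` true PWMs plus `d` decoys sampled without
#' replacement from `decoy_pool`. The default pool consists of
#' column-shuffled variants of the true PWMs (column order permuted and
#' base identities permuted within each column), which preserves
#' per-column information content, so decoys look like real motifs while
#' matching none of the implanted sites.
#'
#' @param true_pwms List of true [pwm] objects.
#' @param ratios List of `c(d, t)` pairs (or strings `"d/t"`); default
#'   the benchmark ratios 7/10, 17/20, 27/30, 37/40.
#' @param n_collections Collections per ratio; default 10.
#' @param decoy_pool Optional list of decoy [pwm] objects.
#' @param seed Integer seed.
#' @return Named list (one element per ratio, `"d/t"`), each a list of
#'   `n_collections` PWM lists.
#' @export
make_decoy_sets <- function(true_pwms,
                            ratios = list(c(7L, 10L), c(17L, 20L),
                                          c(27L, 30L), c(37L, 40L)),
                            n_collections = 10L, decoy_pool = NULL,
                            seed = 1L) {
  ratios <- lapply(ratios, function(r) {
    if (is.character(r)) as.integer(strsplit(r, "/")[[1]]) else as.integer(r)
  })
  for (r in ratios) {
    if (length(r) != 2L || r[1] >= r[2])
      stop("each ratio must be c(d, t) with d < t")
    if (r[2] - r[1] != length(true_pwms))
      stop("ratio ", r[1], "/", r[2], " implies ", r[2] - r[1],
           " true PWMs, got ", length(true_pwms))
  }
  max_d <- max(vapply(ratios, `[`, 0L, 1L))
  with_seed(seed, {
    if (is.null(decoy_pool))
      decoy_pool <- shuffle_column_decoys(true_pwms, 2L * max_d)
    if (length(decoy_pool) < max_d)
      stop("decoy pool exhausted: need ", max_d, ", have ",
           length(decoy_pool))
    out <- lapply(ratios, function(r) {
      lapply(seq_len(n_collections), function(cl) {
        decoys <- decoy_pool[sample.int(length(decoy_pool), r[1])]
        c(true_pwms, decoys)
      })
    })
    names(out) <- vapply(ratios, function(r) paste(r, collapse = "/"), "")
    out
  })
}

# decoys by shuffling: permute column order, then permute the base
# identities within each column (draws from the current RNG stream)
shuffle_column_decoys <- function(true_pwms, n) {
  lapply(seq_len(n), function(i) {
    src <- true_pwms[[(i - 1L) %% length(true_pwms) + 1L]]
    m <- src$matrix[, sample.int(src$length), drop = FALSE]
    for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(4L), j]
    pwm(sprintf("synthetic_decoy%03d", i), m)
  })
}

#' Sample sequences from a CRM model (ancestral sampling)
#'
#' Draws sequences from the exact generative process of [crm_model]:
#' geometric background runs, CRM initiation with `p_r`, first motif from
#' `q`, continuation with `(1 - q0) q_{i,j}`, geometric spacers, motif
#' site bases from the PWMs and background bases from the Markov chains.
#' The true state path is recorded. An element that would cross the
#' sequence end closes its CRM after the last complete site and the
#' remainder is filled with background.
#'
#' @param model A [crm_model].
#' @param n_seq Number of sequences.
#' @param seq_len Sequence length (bp).
#' @param seed Integer seed.
#' @return A `synthetic_dataset`; `truth_paths` holds one [state_path]
#'   per sequence and `truth_sites$motif_state` the motif state index.
#' @export
generate_from_model <- function(model, n_seq, seq_len, seed = 1L) {
  Q <- transition_matrix(model)
  with_seed(seed, {
    seqs <- character(n_seq)
    names(seqs) <- sprintf("seq%02d", seq_len(n_seq))
    crm_rows <- list(); site_rows <- list(); paths <- list()
    for (s in seq_len(n_seq)) {
      bases <- integer(0)
      segs <- list()
      crm_id <- 0L
      add_seg <- function(state, len, motif = NA_integer_,
                          crm = NA_integer_) {
        segs[[length(segs) + 1L]] <<- list(
          state = state, start = length(bases) - len, end = length(bases),
          motif = motif, crm = crm)
      }
      while (length(bases) < seq_len) {
        if (stats::runif(1L) < model$p_r) {
          # try to start a CRM
          i <- sample.int(model$M, 1L, prob = model$q)
          li <- model$motifs[[i]]$length
          if (length(bases) + li > seq_len) break  # no room: background fill
          crm_id <- crm_id + 1L
          bases <- c(bases, sample_site(model$motifs[[i]]))
          add_seg("motif", li, motif = i, crm = crm_id)
          repeat {
            if (stats::runif(1L) < model$q0) break
            j <- sample.int(model$M, 1L, prob = Q[i, ])
            d <- stats::rgeom(1L, model$p_h) + 1L
            lj <- model$motifs[[j]]$length
            if (length(bases) + d + lj > seq_len) break
            bases <- c(bases,
                       sample_background(model$theta1, d, context = bases))
            add_seg("spacer", d, crm = crm_id)
            bases <- c(bases, sample_site(model$motifs[[j]]))
            add_seg("motif", lj, motif = j, crm = crm_id)
            i <- j
          }
        } else {
          bases <- c(bases, sample_background(model$theta0, 1L,
                                              context = bases))
          n <- length(segs)
          if (n > 0L && segs[[n]]$state == "bg") {
            segs[[n]]$end <- length(bases)
          } else add_seg("bg", 1L)
        }
      }
      if (length(bases) < seq_len) {
        fill <- seq_len - length(bases)
        bases <- c(bases, sample_background(model$theta0, fill,
                                            context = bases))
        n <- length(segs)
        if (n > 0L && segs[[n]]$state == "bg") {
          segs[[n]]$end <- length(bases)
        } else add_seg("bg", fill)
      }
      path <- state_path(
        state = vapply(segs, `[[`, "", "state"),
        start = vapply(segs, `[[`, 0L, "start"),
        end = vapply(segs, `[[`, 0L, "end"),
        motif = vapply(segs, `[[`, NA_integer_, "motif"),
        crm = vapply(segs, `[[`, NA_integer_, "crm"))
      validate_state_path(path, model, seq_len)
      paths[[s]] <- path
      seqs[s] <- decode_dna(bases)
      for (cid in unique(stats::na.omit(path$crm))) {
        m <- path[!is.na(path$crm) & path$crm == cid &
                    path$state == "motif", , drop = FALSE]
        crm_rows[[length(crm_rows) + 1L]] <- data.frame(
          seq_id = names(seqs)[s], start = min(m$start), end = max(m$end),
          stringsAsFactors = FALSE)
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          seq_id = names(seqs)[s],
          motif_id = vapply(m$motif, function(i)
            model$motifs[[if (i <= model$K) i else i - model$K]]$id, ""),
          strand = ifelse(m$motif <= model$K, "+", "-"),
          start = m$start, end = m$end, motif_state = m$motif,
          stringsAsFactors = FALSE)
      }
    }
    empty_crm <- data.frame(seq_id = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
    empty_site <- data.frame(seq_id = character(), motif_id = character(),
                             strand = character(), start = integer(),
                             end = integer(), motif_state = integer(),
                             stringsAsFactors = FALSE)
    structure(
      list(sequences = seqs,
           truth_crms = if (length(crm_rows)) do.call(rbind, crm_rows)
                        else empty_crm,
           truth_sites = if (length(site_rows)) do.call(rbind, site_rows)
                         else empty_site,
           truth_paths = paths,
           pwms = model$motifs[seq_len(model$K)], seed = seed,
           params = list(mode = "model", n_seq = n_seq,
                         seq_len = seq_len)),
      class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (", x$params$mode, " mode): ",
      length(x$sequences), " sequence(s), ",
      nrow(x$truth_crms), " true CRM(s), ",
      nrow(x$truth_sites), " true site(s); seed ", x$seed, "\n", sep = "")
  invisible(x)
}
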
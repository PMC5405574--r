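#' Filter CRM predictions by log-likelihood-ratio weight
#'
#' Marks each CRM with `passed_weight_filter = llr >= w_c`. Nothing is
#' dropped: downstream screening only considers passing CRMs, but all
#' predictions stay reported.
#'
#' @param pred A `crm_predictions` object ([predict_crms]).
#' @param w_c LLR threshold in natural-log units; default 0.
#' @return `pred` with a `passed_weight_filter` column on `$crms`.
#' @export
weight_filter <- function(pred, w_c = 0) {
  pred$crms$passed_weight_filter <-
    if (nrow(pred$crms)) pred$crms$llr >= w_c else logical(0)
  pred
}

# ordinal site identities of one CRM: (motif id, strand, occurrence rank
# of that motif within the CRM).  Site coordinates differ across
# sequences, so identity is positional-rank-based, making the site-level
# Jaccard meaningful between CRMs of different sequences.
crm_site_identities <- function(sites) {
  if (nrow(sites) == 0L) return(character(0))
  sites <- sites[order(sites$start), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(sites)), sites$motif_id,
                     FUN = seq_along)
  paste(sites$motif_id, sites$strand, rank, sep = "|")
}

#' Similarity between two CRMs
#'
#' Weighted sum of two Jaccard indices: over the distinct motif sets and
#' over the ordinal site identity sets (intra-CRM background is ignored):
#' `D = mu_m * |Ma ∩ Mb| / |Ma ∪ Mb| + (1 - mu_m) * |MSa ∩ MSb| / |MSa ∪ MSb|`.
#' Two CRMs with no sites at all score 0 by convention.
#'
#' @param sites_a,sites_b Site data.frames of the two CRMs (rows of the
#'   `$sites` table of a `crm_predictions` object, columns `motif_id`,
#'   `strand`, `start`).
#' @param mu_m Weight of the motif-set term, in \[0, 1\]; default 0.5.
#' @return Similarity in \[0, 1\].
#' @export
crm_similarity <- function(sites_a, sites_b, mu_m = 0.5) {
  stopifnot(mu_m >= 0, mu_m <= 1)
  if (nrow(sites_a) == 0L && nrow(sites_b) == 0L) return(0)
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0L) 0 else length(intersect(x, y)) / u
  }
  mu_m * jac(unique(sites_a$motif_id), unique(sites_b$motif_id)) +
    (1 - mu_m) * jac(crm_site_identities(sites_a),
                     crm_site_identities(sites_b))
}

#' Build the CRM similarity graph
#'
#' Nodes are weight-passing CRMs; edges join CRMs from *different*
#' sequences whose [crm_similarity] reaches `edge_threshold`.
#'
#' @param pred A `crm_predictions` object after [weight_filter].
#' @param edge_threshold Similarity cutoff; default 0.5.
#' @param mu_m Motif-set weight for [crm_similarity]; default 0.5.
#' @return An [igraph::graph] whose vertex names are CRM keys
#'   (`seq_id:crm_id`) and whose edges carry `weight` = similarity.
#' @export
build_crm_graph <- function(pred, edge_threshold = 0.5, mu_m = 0.5) {
  crms <- pred$crms
  if (is.null(crms$passed_weight_filter))
    crms$passed_weight_filter <- TRUE
  crms <- crms[crms$passed_weight_filter, , drop = FALSE]
  keys <- crms$crm_key
  g <- igraph::make_empty_graph(n = length(keys), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  g <- igraph::set_vertex_attr(g, "seq_id", value = crms$seq_id)
  if (length(keys) >= 2L) {
    site_sets <- lapply(keys, function(k)
      pred$sites[pred$sites$crm_key == k, , drop = FALSE])
    el <- utils::combn(length(keys), 2L)
    sims <- apply(el, 2L, function(e)
      if (crms$seq_id[e[1]] == crms$seq_id[e[2]]) -1
      else crm_similarity(site_sets[[e[1]]], site_sets[[e[2]]], mu_m))
    keep <- sims >= edge_threshold
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(el[, keep, drop = FALSE]))
      g <- igraph::set_edge_attr(g, "weight", value = sims[keep])
    }
  }
  g
}

#' Enumerate conserved CRM sets (maximal cliques)
#'
#' Each maximal clique with at least three nodes of the CRM similarity
#' graph is one putative CRM type conserved across sequences. Its
#' conservation score is the sum of pairwise similarities among clique
#' members divided by the total number of input sequences `N` (the
#' printed normalization; `normalize = "pairs"` divides by the number of
#' member pairs instead). Output is ordered lexicographically by smallest
#' member key.
#'
#' @param graph Graph from [build_crm_graph].
#' @param pred The `crm_predictions` object the graph was built from.
#' @param n_sequences Total number of input sequences `N`.
#' @param mu_m Motif-set weight used to recompute member similarities.
#' @param normalize `"total_sequences"` (default) or `"pairs"`.
#' @return List of conserved sets, each with `members` (CRM keys, sorted)
#'   and `conservation_score`.
#' @export
conserved_cliques <- function(graph, pred, n_sequences, mu_m = 0.5,
                              normalize = c("total_sequences", "pairs")) {
  normalize <- match.arg(normalize)
  cl <- igraph::max_cliques(graph, min = 3L)
  sets <- lapply(cl, function(v) {
    members <- sort(igraph::V(graph)$name[v])
    pairs <- utils::combn(members, 2L)
    d <- vapply(seq_len(ncol(pairs)), function(p) {
      crm_similarity(
        pred$sites[pred$sites$crm_key == pairs[1, p], , drop = FALSE],
        pred$sites[pred$sites$crm_key == pairs[2, p], , drop = FALSE],
        mu_m)
    }, 0)
    denom <- if (normalize == "total_sequences") n_sequences
             else ncol(pairs)
    list(members = members, conservation_score = sum(d) / denom)
  })
  sets[order(vapply(sets, function(s) s$members[1L], ""))]
}

#' Screen CRM predictions for cross-sequence conservation
#'
#' Applies the weight filter, builds the CRM similarity graph and keeps
#' CRMs that belong to a maximal clique of size >= 3 (a conserved CRM
#' type). Screening only runs when more than three sequences carry
#' predicted CRMs; otherwise all weight-passing candidates pass through
#' unscreened. Screened-out CRMs remain in the output, flagged
#' `conserved = FALSE`, so the gate never silently drops data.
#'
#' @param pred A `crm_predictions` object.
#' @param n_sequences Total number of input sequences.
#' @param w_c LLR weight threshold; default 0.
#' @param edge_threshold CRM similarity edge cutoff; default 0.5.
#' @param mu_m Motif-set weight; default 0.5.
#' @param normalize Conservation-score normalization, see
#'   [conserved_cliques].
#' @return `pred` with `$crms` columns `passed_weight_filter` and
#'   `conserved` (`NA` when screening did not run), plus elements
#'   `conserved_sets` (list) and `screened` (logical: did screening run).
#' @export
screen_crms <- function(pred, n_sequences, w_c = 0, edge_threshold = 0.5,
                        mu_m = 0.5,
                        normalize = c("total_sequences", "pairs")) {
  pred <- weight_filter(pred, w_c)
  n_seq_with_crms <- length(unique(
    pred$crms$seq_id[pred$crms$passed_weight_filter]))
  if (n_seq_with_crms <= 3L) {
    pred$crms$conserved <- NA
    pred$conserved_sets <- list()
    pred$screened <- FALSE
    return(pred)
  }
  g <- build_crm_graph(pred, edge_threshold, mu_m)
  sets <- conserved_cliques(g, pred, n_sequences, mu_m, normalize)
  conserved_keys <- unique(unlist(lapply(sets, `[[`, "members")))
  pred$crms$conserved <- pred$crms$passed_weight_filter &
    pred$crms$crm_key %in% conserved_keys
  pred$conserved_sets <- sets
  pred$screened <- TRUE
  pred
}
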
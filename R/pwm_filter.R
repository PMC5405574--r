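#' Similarity between two PWMs
#'
#' Information-content-weighted agreement over the best ungapped alignment
#' of the two matrices, maximized over all offsets and both relative
#' orientations. For an aligned column pair the agreement is
#' `1 - 0.5 * L1` distance between the two probability columns, weighted by
#' the mean of the two columns' information contents; the score is the
#' weighted mean over overlapping columns. Conserved (high-IC) positions
#' therefore dominate the score. Alignments with fewer than
#' `min(min_overlap, shorter length)` overlapping columns are not
#' considered. Two PWMs whose every overlapping column is uniform carry no
#' information and score 0 by convention.
#'
#' @param a,b [pwm] objects (lengths may differ).
#' @param min_overlap Minimum number of overlapping columns; default 4.
#' @return Similarity in \[0, 1\]; symmetric in its arguments and invariant
#'   under reverse-complementing both.
#' @export
pwm_similarity <- function(a, b, min_overlap = 4L) {
  validate_pwm(a); validate_pwm(b)
  need <- min(min_overlap, a$length, b$length)
  best <- 0
  for (bb in list(b, reverse_complement_pwm(b))) {
    for (off in seq(-(bb$length - need), a$length - need)) {
      ia <- max(1L, 1L + off):min(a$length, bb$length + off)
      if (length(ia) < need) next
      ib <- ia - off
      agree <- 1 - 0.5 * colSums(abs(a$matrix[, ia, drop = FALSE] -
                                     bb$matrix[, ib, drop = FALSE]))
      ic_a <- pwm_information_content(a)[ia]
      ic_b <- pwm_information_content(bb)[ib]
      w <- (ic_a + ic_b) / 2
      s <- if (sum(w) > 0) sum(w * agree) / sum(w) else 0
      if (s > best) best <- s
    }
  }
  # clamp tiny numerical excursions
  min(max(best, 0), 1)
}

#' Build a PWM similarity graph
#'
#' Nodes are PWM ids; edges join distinct PWMs whose [pwm_similarity] is at
#' least `edge_threshold`, weighted by that similarity.
#'
#' @param pwms List of [pwm] objects with unique ids.
#' @param edge_threshold Similarity cutoff for edges; default 0.8.
#' @param min_overlap Passed to [pwm_similarity].
#' @return An [igraph::graph] with vertex attribute `name` (PWM ids) and
#'   edge attribute `weight`.
#' @export
build_similarity_graph <- function(pwms, edge_threshold = 0.8,
                                   min_overlap = 4L) {
  ids <- vapply(pwms, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("PWM ids must be unique")
  n <- length(pwms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (n >= 2L) {
    el <- utils::combn(n, 2L)
    sims <- apply(el, 2L, function(e)
      pwm_similarity(pwms[[e[1]]], pwms[[e[2]]], min_overlap = min_overlap))
    keep <- sims >= edge_threshold
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(el[, keep, drop = FALSE]))
      g <- igraph::set_edge_attr(g, "weight", value = sims[keep])
    }
  }
  g
}

#' Partition a similarity graph into dense clusters
#'
#' Greedy maximal quasi-clique extraction: repeatedly grow a cluster from
#' the seed vertex of smallest id by adding, among vertices adjacent to the
#' current cluster, the one (smallest id on ties) that keeps the induced
#' edge density (edges present / edges possible; singletons have density 1)
#' at or above `density_threshold`, maximally; the cluster is removed and
#' the process repeats. Every vertex ends up in exactly one cluster;
#' vertices that cannot join any dense group become singletons. Output
#' order is lexicographic by smallest member id.
#'
#' @param g Similarity graph from [build_similarity_graph].
#' @param density_threshold Minimum induced edge density; default 0.7.
#' @return List of clusters, each a list with `members` (character vector,
#'   sorted) and `representative` (`NA`; fill with [choose_representative]).
#' @export
find_dense_clusters <- function(g, density_threshold = 0.7) {
  ids <- sort(igraph::V(g)$name)
  adj <- lapply(ids, function(v)
    sort(igraph::V(g)$name[igraph::neighbors(
      g, which(igraph::V(g)$name == v))]))
  names(adj) <- ids
  remaining <- ids
  clusters <- list()
  density <- function(members) {
    k <- length(members)
    if (k <= 1L) return(1)
    e <- sum(vapply(seq_along(members), function(i)
      sum(adj[[members[i]]] %in% members[-seq_len(i)]), 0L))
    e / (k * (k - 1L) / 2L)
  }
  while (length(remaining) > 0L) {
    cur <- remaining[1L]
    repeat {
      cand <- setdiff(
        sort(unique(unlist(adj[cur]))), c(cur, setdiff(ids, remaining)))
      if (length(cand) == 0L) break
      dens <- vapply(cand, function(v) density(c(cur, v)), 0)
      ok <- dens >= density_threshold
      if (!any(ok)) break
      pick <- cand[ok][which.max(dens[ok])]  # ties: first = smallest id
      cur <- sort(c(cur, pick))
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = cur, representative = NA_character_)
    remaining <- setdiff(remaining, cur)
  }
  clusters[order(vapply(clusters, function(cl) cl$members[1L], ""))]
}

#' Choose a cluster representative
#'
#' The representative is the member whose length is closest to the mean
#' length of the cluster's members; ties are broken by the lexicographically
#' smaller id.
#'
#' @param cluster A cluster as returned by [find_dense_clusters].
#' @param pwms List of [pwm] objects covering the cluster members.
#' @return The representative PWM id.
#' @export
choose_representative <- function(cluster, pwms) {
  ids <- vapply(pwms, `[[`, "", "id")
  members <- sort(cluster$members)
  if (length(members) == 0L) stop("cluster has no members")
  if (!all(members %in% ids))
    stop("cluster members missing from PWM list: ",
         paste(setdiff(members, ids), collapse = ", "))
  lens <- vapply(members, function(m) pwms[[match(m, ids)]]$length, 0L)
  dist <- abs(lens - mean(lens))
  members[which.min(dist)]  # which.min takes the first = smallest id on ties
}

#' Collapse redundant PWMs to cluster representatives
#'
#' Motif libraries often carry several PWMs for the same transcription
#' factor; redundant motif states enlarge the HMM for no benefit. This
#' optional preprocessing clusters similar PWMs and keeps one
#' representative per cluster.
#'
#' @param pwms List of [pwm] objects.
#' @param edge_threshold Similarity cutoff for graph edges; default 0.8.
#' @param density_threshold Minimum cluster edge density; default 0.7.
#' @param min_overlap Minimum alignment overlap for [pwm_similarity].
#' @return List with `pwms` (representatives, in cluster order), `clusters`
#'   (each with `members` and `representative`) and `report` (data.frame:
#'   cluster, representative, members).
#' @export
filter_pwms <- function(pwms, edge_threshold = 0.8, density_threshold = 0.7,
                        min_overlap = 4L) {
  g <- build_similarity_graph(pwms, edge_threshold, min_overlap)
  clusters <- find_dense_clusters(g, density_threshold)
  ids <- vapply(pwms, `[[`, "", "id")
  clusters <- lapply(clusters, function(cl) {
    cl$representative <- choose_representative(cl, pwms)
    cl
  })
  reps <- vapply(clusters, `[[`, "", "representative")
  list(
    pwms = pwms[match(reps, ids)],
    clusters = clusters,
    report = data.frame(
      cluster = seq_along(clusters),
      representative = reps,
      members = vapply(clusters, function(cl)
        paste(cl$members, collapse = ","), ""),
      stringsAsFactors = FALSE
    )
  )
}
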
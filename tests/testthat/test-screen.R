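# minimal crm_predictions fixture: CRMs with given sites per sequence
make_preds <- function(spec) {
  # spec: list of list(seq_id, crm_id, llr, sites = data.frame(motif_id,
  # strand)); site coordinates synthesized in order
  crms <- list(); sites <- list()
  for (s in spec) {
    n <- nrow(s$sites)
    pos <- cumsum(rep(10L, n)) - 10L
    sites[[length(sites) + 1L]] <- data.frame(
      seq_id = s$seq_id, crm_id = s$crm_id, motif_id = s$sites$motif_id,
      strand = s$sites$strand, start = pos, end = pos + 8L,
      log_odds = 1, crm_key = paste(s$seq_id, s$crm_id, sep = ":"),
      stringsAsFactors = FALSE)
    crms[[length(crms) + 1L]] <- data.frame(
      seq_id = s$seq_id, crm_id = s$crm_id, start = 0L,
      end = max(pos) + 8L, n_sites = n,
      motifs = paste(unique(s$sites$motif_id), collapse = ","),
      llr = s$llr, llr_log2 = s$llr / log(2),
      crm_key = paste(s$seq_id, s$crm_id, sep = ":"),
      stringsAsFactors = FALSE)
  }
  structure(list(crms = do.call(rbind, crms),
                 sites = do.call(rbind, sites)),
            class = "crm_predictions")
}

site_df <- function(...) {
  v <- c(...)
  data.frame(motif_id = v[seq(1, length(v), 2)],
             strand = v[seq(2, length(v), 2)], stringsAsFactors = FALSE)
}

test_that("weight filter flags CRMs below the LLR threshold", {
  pred <- make_preds(list(
    list(seq_id = "s1", crm_id = 1L, llr = 2, sites = site_df("a", "+")),
    list(seq_id = "s2", crm_id = 1L, llr = 5, sites = site_df("a", "+")),
    list(seq_id = "s3", crm_id = 1L, llr = 9, sites = site_df("a", "+"))))
  expect_true(all(weight_filter(pred, -Inf)$crms$passed_weight_filter))
  expect_false(any(weight_filter(pred, 10)$crms$passed_weight_filter))
  expect_equal(sum(weight_filter(pred, 4)$crms$passed_weight_filter), 2L)
})

test_that("CRM similarity: identity, disjointness, hand example", {
  a <- data.frame(motif_id = c("m1", "m2"), strand = "+",
                  start = c(0L, 20L), stringsAsFactors = FALSE)
  expect_equal(crm_similarity(a, a), 1)
  b <- data.frame(motif_id = c("m3", "m4"), strand = "+",
                  start = c(0L, 20L), stringsAsFactors = FALSE)
  expect_equal(crm_similarity(a, b), 0)
  expect_equal(crm_similarity(a[0, ], b[0, ]), 0)
  # motifs {m1,m2} vs {m2,m3}: motif Jaccard 1/3; site identities chosen
  # so the site Jaccard is 1/5
  a2 <- data.frame(motif_id = c("m1", "m2", "m2"), strand = "+",
                   start = c(0L, 20L, 40L), stringsAsFactors = FALSE)
  b2 <- data.frame(motif_id = c("m2", "m3", "m3"), strand = "+",
                   start = c(0L, 20L, 40L), stringsAsFactors = FALSE)
  # identities: a2 = {m1#1, m2#1, m2#2}, b2 = {m2#1, m3#1, m3#2};
  # intersection {m2#1}, union of 5
  expect_equal(crm_similarity(a2, b2, mu_m = 0.5),
               0.5 * (1 / 3) + 0.5 * (1 / 5), tolerance = 1e-12)
  expect_equal(crm_similarity(a2, b2), crm_similarity(b2, a2))
  # strand enters the site identity but not the motif set
  a3 <- a; a3$strand <- c("-", "+")
  expect_equal(crm_similarity(a, a3, mu_m = 0),
               1 / 3, tolerance = 1e-12)   # only m2#+#1 shared of 3
})

test_that("cross-sequence rule and conserved cliques with printed score", {
  trio <- site_df("m1", "+", "m2", "+")
  pred <- make_preds(list(
    list(seq_id = "s1", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s2", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s3", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s3", crm_id = 2L, llr = 5, sites = trio)))
  pred <- weight_filter(pred, 0)
  g <- build_crm_graph(pred, edge_threshold = 0.5)
  # no edge between the two s3 CRMs despite identity
  expect_false(igraph::are_adjacent(g, "s3:1", "s3:2"))
  sets <- conserved_cliques(g, pred, n_sequences = 10)
  # identical CRMs in 3 sequences: cliques of size 3, each pair D = 1,
  # CS = 3 pairs / N = 10
  expect_true(length(sets) >= 1L)
  expect_equal(sets[[1]]$conservation_score, 3 / 10, tolerance = 1e-12)
  alt <- conserved_cliques(g, pred, n_sequences = 10,
                           normalize = "pairs")
  expect_equal(alt[[1]]$conservation_score, 1, tolerance = 1e-12)
})

test_that("maximal clique enumeration matches brute force", {
  set.seed(77)
  for (k in 1:5) {
    n <- sample(5:9, 1)
    g <- igraph::sample_gnp(n, 0.5)
    g <- igraph::set_vertex_attr(g, "name",
                                 value = sprintf("s%02d:1", seq_len(n)))
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    is_clique <- function(v) all(adj[v, v][upper.tri(adj[v, v])] == 1)
    subsets <- unlist(lapply(3:n, function(sz)
      utils::combn(n, sz, simplify = FALSE)), recursive = FALSE)
    brute <- Filter(function(v) {
      is_clique(v) &&
        !any(vapply(setdiff(seq_len(n), v), function(w)
          is_clique(c(v, w)), TRUE))
    }, subsets)
    brute_sets <- sort(vapply(brute, function(v)
      paste(sort(igraph::V(g)$name[v]), collapse = ","), ""))
    got <- sort(vapply(igraph::max_cliques(g, min = 3L), function(v)
      paste(sort(igraph::V(g)$name[v]), collapse = ","), ""))
    expect_equal(got, brute_sets)
  }
})

test_that("screening gate passes candidates through on small inputs", {
  trio <- site_df("m1", "+")
  pred <- make_preds(list(
    list(seq_id = "s1", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s2", crm_id = 1L, llr = 5, sites = trio)))
  out <- screen_crms(pred, n_sequences = 5)
  expect_false(out$screened)
  expect_true(all(is.na(out$crms$conserved)))
  expect_true(all(out$crms$passed_weight_filter))
})

test_that("screening never invents CRMs and flags the non-conserved", {
  trio <- site_df("m1", "+", "m2", "+")
  lone <- site_df("m9", "-")
  pred <- make_preds(list(
    list(seq_id = "s1", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s2", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s3", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s4", crm_id = 1L, llr = 5, sites = trio),
    list(seq_id = "s5", crm_id = 1L, llr = 5, sites = lone),
    list(seq_id = "s6", crm_id = 1L, llr = -4, sites = trio)))
  out <- screen_crms(pred, n_sequences = 6, w_c = 0)
  expect_true(out$screened)
  expect_setequal(out$crms$crm_key[which(out$crms$conserved)],
                  c("s1:1", "s2:1", "s3:1", "s4:1"))
  # the weight-failing CRM is reported but neither passed nor conserved
  expect_false(out$crms$passed_weight_filter[out$crms$seq_id == "s6"])
  expect_false(out$crms$conserved[out$crms$seq_id == "s6"])
})
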
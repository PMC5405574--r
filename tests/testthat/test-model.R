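test_that("transition law: no correlation reduces to frequencies", {
  m <- tiny_model(list(uniform_pwm("a", 2L), uniform_pwm("b", 2L)))
  Q <- transition_matrix(m)
  expect_equal(Q, matrix(0.25, 4, 4))
  expect_equal(transition_probability(m, 2, 3), 0.25)
})

test_that("transition law redistributes mass around correlated partners", {
  m <- tiny_model(list(uniform_pwm("a", 2L), uniform_pwm("b", 2L)),
                  corr = list(c("2" = 0.5), numeric(0), numeric(0),
                              numeric(0)))
  Q <- transition_matrix(m)
  expect_equal(Q[1, 2], 0.5)
  expect_equal(Q[1, c(1, 3, 4)], rep(0.25 * 0.5 / 0.75, 3))
  expect_equal(rowSums(Q), rep(1, 4))
  # deterministic follow-up
  m2 <- tiny_model(list(uniform_pwm("a", 2L), uniform_pwm("b", 2L)),
                   corr = list(c("2" = 1), numeric(0), numeric(0),
                               numeric(0)))
  expect_equal(transition_matrix(m2)[1, ], c(0, 1, 0, 0))
})

test_that("transition rows sum to 1 for randomized correlation structures", {
  set.seed(23)
  for (k in 1:8) {
    K <- sample(1:3, 1)
    M <- 2 * K
    q <- rexp(M); q <- q / sum(q)
    corr <- lapply(seq_len(M), function(i) {
      if (runif(1) < 0.5) return(numeric(0))
      n_p <- sample.int(M - 1L, 1)
      part <- sample(M, n_p)
      r <- runif(n_p); r <- r / sum(r) * runif(1)
      names(r) <- part
      r
    })
    m <- tiny_model(lapply(seq_len(K), function(i)
      uniform_pwm(paste0("p", i), 2L)), q = q, corr = corr)
    expect_equal(rowSums(transition_matrix(m)), rep(1, M),
                 tolerance = 1e-12)
  }
})

test_that("co-occurrence z-score and detection gate", {
  expect_equal(cooccurrence_zscore(8, 8, 2), 0)
  expect_equal(cooccurrence_zscore(12, 8, 2), 2)
  expect_error(cooccurrence_zscore(1, 1, 0), "positive")
  expect_false(is_correlated(cooccurrence_zscore(8, 8, 2), 8))
  expect_true(is_correlated(2, 8))
  # expectation gate: significant-looking but too rare
  expect_false(is_correlated(1.5, 0.5))
})

test_that("spacer duration is geometric with mean h", {
  m <- tiny_model(h = 10)
  expect_equal(spacer_duration_probability(m, 1), 0.1)
  expect_equal(spacer_duration_probability(m, 3), 0.9^2 * 0.1)
  expect_error(spacer_duration_probability(m, 0), "d must be >= 1")
  expect_equal(sum(spacer_duration_probability(m, 1:1000)), 1,
               tolerance = 1e-9)
})

test_that("background log probability with context and fallback", {
  bg0 <- uniform_bg(0L)
  expect_equal(background_log_probability(bg0, "ACG"), 3 * log(0.25))
  expect_equal(background_log_probability(bg0, ""), 0)
  # order 1 with specified conditionals
  t1 <- matrix(c(0.3, 0.4, 0.2, 0.1,   # row context A
                 0.3, 0.2, 0.3, 0.2,   # row context C
                 0.25, 0.25, 0.25, 0.25,
                 0.25, 0.25, 0.25, 0.25), 4, 4, byrow = TRUE)
  bg1 <- markov_background(1L, list(matrix(0.25, 1, 4), t1))
  expect_equal(background_log_probability(bg1, "CG", context = "A"),
               log(0.4) + log(0.3))
  # no context: first position falls back to order 0
  expect_equal(background_log_probability(bg1, "CG"),
               log(0.25) + log(0.3))
})

test_that("background estimation recovers strong dependencies", {
  seqs <- c(s = strrep("A", 100))
  bg <- estimate_markov_background(seqs, 1L)
  expect_gt(bg$tables[[2]][1, 1], 0.95)      # P(A | A) ~ 1
  seqs2 <- c(s = strrep("AC", 50))
  bg2 <- estimate_markov_background(seqs2, 1L)
  expect_gt(bg2$tables[[2]][1, 2], 0.9)      # P(C | A)
  expect_gt(bg2$tables[[2]][2, 1], 0.9)      # P(A | C)
  # order 0 with equal base counts is uniform (pseudocount exact)
  bg3 <- estimate_markov_background(c(s = "ACGTACGT"), 0L)
  expect_equal(unname(bg3$tables[[1]][1, ]), rep(0.25, 4))
  bgs <- estimate_backgrounds(seqs2, k = 1L, k_prime = 2L)
  expect_equal(bgs$theta0$order, 1L)
  expect_equal(bgs$theta1$order, 2L)
})

test_that("path log-likelihood matches hand-computed structure costs", {
  p <- consensus_pwm("site", "ACGT", dominant = 0.9)
  m <- crm_model(list(p), theta0 = uniform_bg(0L), theta1 = uniform_bg(0L),
                 p_r = 0.001, q0 = 0.1, h = 5)
  seq <- paste0(strrep("G", 10), "ACGT", strrep("G", 16))
  path <- state_path(state = c("bg", "motif", "bg"),
                     start = c(0L, 10L, 14L), end = c(10L, 14L, 30L),
                     motif = c(NA, 1L, NA), crm = c(NA, 1L, NA))
  expected <- 26 * (log(1 - 0.001) + log(0.25)) +  # background bases
    log(0.001) + log(0.5) +                        # CRM start, first motif
    4 * log(0.9) +                                 # consensus site emission
    log(0.1)                                       # CRM termination
  expect_equal(path_log_likelihood(m, seq, path), expected,
               tolerance = 1e-12)
  # all-background path: duration plus emission terms only
  bg_path <- state_path("bg", 0L, 30L)
  expect_equal(path_log_likelihood(m, seq, bg_path),
               30 * (log(1 - 0.001) + log(0.25)), tolerance = 1e-12)
})

test_that("invalid paths are rejected", {
  m <- tiny_model()
  expect_error(validate_state_path(
    state_path("bg", 0L, 5L), m, 10L), "tile")
  expect_error(validate_state_path(
    state_path(c("bg", "spacer"), c(0L, 5L), c(5L, 10L),
               crm = c(NA, 1L)), m, 10L), "flanked")
  # motif segment with wrong duration
  expect_error(validate_state_path(
    state_path(c("motif", "bg"), c(0L, 3L), c(3L, 10L),
               motif = c(1L, NA), crm = c(1L, NA)), m, 10L), "duration")
})

test_that("uncorrelated motif labels are exchangeable", {
  set.seed(4)
  p1 <- random_pwm("p1", 3L); p2 <- random_pwm("p2", 2L)
  q <- c(0.1, 0.4, 0.2, 0.3)
  mA <- tiny_model(list(p1, p2), q = q)
  mB <- tiny_model(list(p2, p1), q = q[c(2, 1, 4, 3)])
  s <- random_dna(40L)
  expect_equal(forward_backward(mA, s)$loglik,
               forward_backward(mB, s)$loglik, tolerance = 1e-10)
})

test_that("model files round-trip through YAML", {
  set.seed(9)
  m <- tiny_model(list(random_pwm("p1", 3L), random_pwm("p2", 4L)),
                  p_r = 0.002, q0 = 0.15, h = 25,
                  q = c(0.3, 0.2, 0.25, 0.25),
                  corr = list(c("2" = 0.4), numeric(0), numeric(0),
                              numeric(0)), bg_order = 1L)
  f <- tempfile(fileext = ".yaml")
  write_crm_model(m, f)
  m2 <- read_crm_model(f)
  expect_equal(m2$p_r, m$p_r)
  expect_equal(m2$q, m$q, tolerance = 1e-9)
  expect_equal(m2$corr[[1]], m$corr[[1]], tolerance = 1e-9)
  expect_equal(m2$motifs[[1]]$matrix, m$motifs[[1]]$matrix,
               tolerance = 1e-9)
  s <- random_dna(50L)
  expect_equal(forward_backward(m2, s)$loglik,
               forward_backward(m, s)$loglik, tolerance = 1e-6)
})
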
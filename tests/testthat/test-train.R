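test_that("correlation update normalizes expected-count shares", {
  m <- tiny_model(list(uniform_pwm("a", 2L), uniform_pwm("b", 2L)))
  Tm <- matrix(0, 4, 4)
  Tm[1, 2] <- 6; Tm[1, 3] <- 2
  stats <- list(T = Tm, E = Tm, sigma = Tm, z = Tm)
  gate <- matrix(FALSE, 4, 4); gate[1, c(2, 3)] <- TRUE
  m2 <- update_correlations(stats, m, freeze_gate = gate)
  expect_equal(m2$corr[[1]], c("2" = 0.75, "3" = 0.25))
  expect_lte(sum(m2$corr[[1]]), 1)
  for (i in 2:4) expect_length(m2$corr[[i]], 0L)
})

test_that("no pair passing the gate leaves the model uncorrelated", {
  m <- tiny_model(list(uniform_pwm("a", 2L)))
  Tm <- matrix(1, 2, 2); E <- matrix(1, 2, 2)
  sigma <- matrix(1, 2, 2)
  z <- (Tm - E) / sigma                      # all zero: below threshold
  m2 <- update_correlations(list(T = Tm, E = E, sigma = sigma, z = z), m)
  expect_true(all(lengths(m2$corr) == 0L))
})

test_that("co-occurrence statistics are additive and null-calibrated", {
  set.seed(14)
  gen <- crm_model(list(consensus_pwm("m1", "ATGCAAGTCC", 0.95),
                        consensus_pwm("m2", "CTTGACGGAT", 0.95)),
                   theta0 = uniform_bg(1L), theta1 = uniform_bg(1L),
                   p_r = 0.004, q0 = 0.1, h = 20)
  ds <- generate_from_model(gen, 6L, 600L, seed = 14L)
  fb_list <- lapply(ds$sequences, function(s) forward_backward(gen, s))
  st <- expected_cooccurrences(gen, ds$sequences, fb_list = fb_list)
  expect_equal(st$T, Reduce(`+`, lapply(fb_list, `[[`, "T")),
               tolerance = 1e-12)
  expect_true(all(st$T >= 0))
  expect_true(all(st$E >= 0))
  expect_equal(sum(st$E), sum(st$T), tolerance = 1e-8)
})

test_that("EM with max_iter = 0 evaluates but does not move the model", {
  set.seed(6)
  m0 <- tiny_model(list(random_pwm("p", 3L)), p_r = 0.01)
  seqs <- c(a = random_dna(80L), b = random_dna(80L))
  fit <- em_fit(m0, seqs, max_iter = 0L)
  expect_equal(fit$model$q, m0$q)
  expect_length(fit$loglik_trace, 1L)
  expect_false(fit$converged)
  expect_equal(fit$iterations, 0L)
})

test_that("EM log-likelihood is non-decreasing on random instances", {
  set.seed(101)
  for (k in 1:4) {
    K <- sample(1:2, 1)
    pwms <- lapply(seq_len(K), function(i)
      consensus_pwm(paste0("p", i),
                    random_dna(sample(4:6, 1)), dominant = 0.8))
    gen <- crm_model(pwms, theta0 = uniform_bg(0L),
                     theta1 = uniform_bg(0L),
                     p_r = runif(1, 0.005, 0.02), q0 = runif(1, 0.1, 0.4),
                     h = sample(5:15, 1))
    ds <- generate_from_model(gen, 3L, 150L, seed = 100L + k)
    m0 <- crm_model(pwms, theta0 = uniform_bg(0L),
                    theta1 = uniform_bg(0L), p_r = 0.01, q0 = 0.2, h = 10)
    fit <- em_fit(m0, ds$sequences, max_iter = 6L, tol = 0,
                  burn_in = 2L)
    expect_gte(min(diff(fit$loglik_trace)), -1e-6)
  }
})

test_that("one EM step from the generating parameters drifts little", {
  pwms <- list(consensus_pwm("m1", "ATGCAAGTCC", 0.95),
               consensus_pwm("m2", "CTTGACGGAT", 0.95))
  gen <- crm_model(pwms, theta0 = uniform_bg(1L), theta1 = uniform_bg(1L),
                   p_r = 0.004, q0 = 0.1, h = 20)
  ds <- generate_from_model(gen, 10L, 800L, seed = 77L)
  fit <- em_fit(gen, ds$sequences, max_iter = 1L,
                detect_correlations = FALSE)
  expect_gte(diff(fit$loglik_trace)[1], -1e-6)
  expect_lt(max(abs(fit$model$q - gen$q)), 0.06)
  expect_lt(abs(fit$model$h - gen$h) / gen$h, 0.35)
})

test_that("training is invariant to sequence order", {
  set.seed(55)
  pwms <- list(consensus_pwm("m", "ACGTTGCA", 0.9))
  gen <- crm_model(pwms, theta0 = uniform_bg(0L), theta1 = uniform_bg(0L),
                   p_r = 0.01, q0 = 0.2, h = 10)
  ds <- generate_from_model(gen, 4L, 300L, seed = 56L)
  m0 <- crm_model(pwms, theta0 = uniform_bg(0L), theta1 = uniform_bg(0L))
  f1 <- em_fit(m0, ds$sequences, max_iter = 4L, burn_in = 1L)
  f2 <- em_fit(m0, rev(ds$sequences), max_iter = 4L, burn_in = 1L)
  expect_equal(f1$loglik_trace, f2$loglik_trace, tolerance = 1e-9)
  expect_equal(f1$model$q, f2$model$q, tolerance = 1e-9)
  expect_equal(f1$model$p_h, f2$model$p_h, tolerance = 1e-9)
})

test_that("exact q maximizer beats the naive share when correlations exist", {
  # fixed weights with one correlated partner; verify the KKT conditions
  m <- tiny_model(list(uniform_pwm("a", 2L), uniform_pwm("b", 2L)),
                  corr = list(c("2" = 0.5), numeric(0), numeric(0),
                              numeric(0)))
  C1 <- c(30, 35, 20, 15)
  Tm <- matrix(c(5, 40, 3, 2,
                 20, 25, 15, 10,
                 10, 12, 8, 6,
                 7, 9, 6, 5), 4, 4, byrow = TRUE)
  q <- crmscan:::maximize_q(m, C1, Tm, tie_orientations = FALSE)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  # objective value at the maximizer dominates nearby perturbations
  unc <- list(c(1, 3, 4), 1:4, 1:4, 1:4)
  W <- C1; U <- numeric(4)
  for (i in 1:4) { W[unc[[i]]] <- W[unc[[i]]] + Tm[i, unc[[i]]]
                   U[i] <- sum(Tm[i, unc[[i]]]) }
  F_obj <- function(qq) sum(W * log(qq)) -
    sum(U * vapply(1:4, function(i) log(sum(qq[unc[[i]]])), 0))
  set.seed(1)
  for (k in 1:20) {
    pert <- q + rnorm(4, sd = 0.01); pert <- pmax(pert, 1e-6)
    pert <- pert / sum(pert)
    expect_gte(F_obj(q), F_obj(pert) - 1e-9)
  }
  # tied orientations pool the orientation pair
  qt <- crmscan:::maximize_q(m, C1, Tm, tie_orientations = TRUE)
  expect_equal(qt[1:2], qt[3:4], tolerance = 1e-12)
})
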
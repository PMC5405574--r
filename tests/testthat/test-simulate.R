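test_that("implanted-CRM benchmark has the documented shape", {
  pwms <- demo_pwms(3L, length = 8L, seed = 2L)
  ds <- generate_xie_style(pwms, seed = 3L)
  expect_length(ds$sequences, 22L)
  expect_true(all(nchar(ds$sequences) == 1000L))
  expect_equal(nrow(ds$truth_crms), 20L)
  expect_true(all(ds$truth_crms$end - ds$truth_crms$start <= 164L))
  # sites lie inside their CRM, non-overlapping and ordered
  for (id in unique(ds$truth_sites$seq_id)) {
    s <- ds$truth_sites[ds$truth_sites$seq_id == id, , drop = FALSE]
    crm <- ds$truth_crms[ds$truth_crms$seq_id == id, ]
    expect_true(all(s$start >= crm$start & s$end <= crm$end))
    s <- s[order(s$start), ]
    if (nrow(s) > 1L) expect_true(all(s$start[-1L] >= s$end[-nrow(s)]))
  }
  expect_true(all(table(ds$truth_sites$seq_id) >= 3L &
                    table(ds$truth_sites$seq_id) <= 6L))
})

test_that("generation is bit-identical under a fixed seed", {
  pwms <- demo_pwms(2L, seed = 4L)
  a <- generate_xie_style(pwms, seed = 11L)
  b <- generate_xie_style(pwms, seed = 11L)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth_sites, b$truth_sites)
  c <- generate_xie_style(pwms, seed = 12L)
  expect_false(identical(a$sequences, c$sequences))
})

test_that("inter-site gaps follow the spacing model", {
  pwms <- demo_pwms(3L, seed = 2L)
  gaps <- unlist(lapply(1:4, function(k)
    truth_site_gaps(generate_xie_style(pwms, seed = 20L + k))))
  expect_gte(length(gaps), 200L)
  expect_true(all(gaps >= 1L))
  expect_lt(abs(mean(gaps) - 10), 4 * sqrt(10) / sqrt(length(gaps)))
})

test_that("decoy collections respect the noise ratios", {
  true_pwms <- demo_pwms(3L, seed = 6L)
  sets <- make_decoy_sets(true_pwms, ratios = list(c(7L, 10L), "17/20"),
                          n_collections = 4L, seed = 9L)
  expect_named(sets, c("7/10", "17/20"))
  for (ratio in names(sets)) {
    d_t <- as.integer(strsplit(ratio, "/")[[1]])
    expect_length(sets[[ratio]], 4L)
    for (coll in sets[[ratio]]) {
      expect_length(coll, d_t[2])
      ids <- vapply(coll, `[[`, "", "id")
      expect_true(all(vapply(true_pwms, `[[`, "", "id") %in% ids))
      expect_equal(sum(grepl("decoy", ids)), d_t[1])
      expect_false(anyDuplicated(ids) > 0)
    }
  }
  # decoys preserve per-column information content up to permutation
  decoy <- sets[["7/10"]][[1]][[4L]]
  src_ic <- sort(unlist(lapply(true_pwms, pwm_information_content)))
  expect_true(all(round(pwm_information_content(decoy), 6) %in%
                    round(src_ic, 6)))
  # zero-decoy ratio returns the true set
  none <- make_decoy_sets(true_pwms, ratios = list(c(0L, 3L)),
                          n_collections = 1L, seed = 1L)
  expect_equal(vapply(none[["0/3"]][[1]], `[[`, "", "id"),
               vapply(true_pwms, `[[`, "", "id"))
  expect_error(make_decoy_sets(true_pwms, ratios = list(c(5L, 10L))),
               "implies")
  # determinism
  s1 <- make_decoy_sets(true_pwms, ratios = list(c(7L, 10L)), seed = 3L)
  s2 <- make_decoy_sets(true_pwms, ratios = list(c(7L, 10L)), seed = 3L)
  expect_identical(vapply(s1[[1]][[1]], `[[`, "", "id"),
                   vapply(s2[[1]][[1]], `[[`, "", "id"))
})

test_that("model-mode sampling respects the generative process", {
  pwms <- list(consensus_pwm("m1", "ATGCAAGTCC", 0.95),
               consensus_pwm("m2", "CTTGACGGAT", 0.95))
  gen <- crm_model(pwms, theta0 = uniform_bg(1L), theta1 = uniform_bg(1L),
                   p_r = 0.002, q0 = 0.1, h = 10)
  ds <- generate_from_model(gen, 10L, 2000L, seed = 13L)
  # truth paths tile and validate
  for (k in seq_along(ds$truth_paths))
    expect_silent(validate_state_path(ds$truth_paths[[k]], gen, 2000L))
  # spacer lengths consistent with h
  sp <- unlist(lapply(ds$truth_paths, function(p)
    (p$end - p$start)[p$state == "spacer"]))
  expect_gte(length(sp), 100L)
  expect_lt(abs(mean(sp) - 10), 4 * sqrt((1 - 0.1) / 0.01) /
              sqrt(length(sp)))
  # vanishing initiation -> no CRMs
  gen0 <- crm_model(pwms, theta0 = uniform_bg(1L),
                    theta1 = uniform_bg(1L), p_r = 1e-12, q0 = 0.1, h = 10)
  ds0 <- generate_from_model(gen0, 5L, 500L, seed = 2L)
  expect_equal(nrow(ds0$truth_crms), 0L)
})

test_that("deterministic correlation forces the follow-up motif", {
  pwms <- list(consensus_pwm("m1", "ATGCAAGTCC", 0.95),
               consensus_pwm("m2", "CTTGACGGAT", 0.95))
  gen <- crm_model(pwms, theta0 = uniform_bg(0L), theta1 = uniform_bg(0L),
                   p_r = 0.01, q0 = 0.05, h = 5,
                   corr = list(c("2" = 1), numeric(0), numeric(0),
                               numeric(0)))
  ds <- generate_from_model(gen, 5L, 800L, seed = 21L)
  checked <- 0L
  for (p in ds$truth_paths) {
    m <- p[p$state == "motif", , drop = FALSE]
    for (s in seq_len(max(nrow(m) - 1L, 0L)))
      if (m$crm[s] == m$crm[s + 1L] && m$motif[s] == 1L) {
        expect_equal(m$motif[s + 1L], 2L)
        checked <- checked + 1L
      }
  }
  expect_gt(checked, 5L)
})
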
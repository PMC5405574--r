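iv <- function(seq_id, start, end)
  data.frame(seq_id = seq_id, start = start, end = end,
             stringsAsFactors = FALSE)

test_that("confusion counts follow interval arithmetic", {
  lens <- c(s = 1000L)
  truth <- iv("s", 0L, 100L)
  expect_equal(confusion(truth, truth, lens),
               c(nTP = 100, nFP = 0, nTN = 900, nFN = 0))
  got <- confusion(truth, iv("s", 50L, 150L), lens)
  expect_equal(got, c(nTP = 50, nFP = 50, nTN = 850, nFN = 50))
  expect_equal(sum(got), 1000)
  empty <- iv(character(0), integer(0), integer(0))
  expect_equal(confusion(truth, empty, lens),
               c(nTP = 0, nFP = 0, nTN = 900, nFN = 100))
  expect_error(confusion(iv("s", -5L, 10L), empty, lens), "bounds")
  # pooled across sequences by summation
  lens2 <- c(a = 100L, b = 200L)
  got2 <- confusion(iv(c("a", "b"), c(0L, 50L), c(10L, 100L)),
                    iv("a", 0L, 10L), lens2)
  expect_equal(got2, c(nTP = 10, nFP = 0, nTN = 240, nFN = 50))
})

test_that("correlation coefficient reproduces the closed form", {
  expect_equal(as.numeric(correlation_coefficient(
    c(nTP = 10, nFP = 0, nTN = 90, nFN = 0))), 1)
  expect_equal(as.numeric(correlation_coefficient(
    c(nTP = 50, nFP = 50, nTN = 850, nFN = 50))),
    (50 * 850 - 50 * 50) / sqrt(100 * 900 * 100 * 900))
  expect_equal(as.numeric(correlation_coefficient(
    c(nTP = 0, nFP = 30, nTN = 0, nFN = 70))), -1)
  deg <- correlation_coefficient(c(nTP = 0, nFP = 0, nTN = 100, nFN = 0))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("CC equals the Pearson correlation of the label vectors", {
  set.seed(90)
  for (k in 1:25) {
    L <- sample(50:200, 1)
    t0 <- sort(sample.int(L - 1L, 2L)); p0 <- sort(sample.int(L - 1L, 2L))
    lens <- c(s = L)
    truth <- iv("s", t0[1], t0[2]); pred <- iv("s", p0[1], p0[2])
    cts <- confusion(truth, pred, lens)
    lab_t <- rep(0, L); lab_t[(t0[1] + 1):t0[2]] <- 1
    lab_p <- rep(0, L); lab_p[(p0[1] + 1):p0[2]] <- 1
    pearson <- suppressWarnings(cor(lab_t, lab_p))
    cc <- correlation_coefficient(cts)
    if (is.na(pearson)) {
      expect_true(attr(cc, "degenerate"))
    } else {
      expect_equal(as.numeric(cc), pearson, tolerance = 1e-12)
    }
  }
})

test_that("metric report combines Sn, Pr, F1, ASP and CC", {
  rep <- metric_report(c(nTP = 50, nFP = 50, nTN = 850, nFN = 50))
  expect_equal(rep[["sn"]], 0.5)
  expect_equal(rep[["pr"]], 0.5)
  expect_equal(rep[["f1"]], 0.5)
  expect_equal(rep[["asp"]], 0.5)
  expect_equal(rep[["cc"]], 4 / 9, tolerance = 1e-12)
})

test_that("fixed-length protocol emits one window per sequence", {
  crms <- data.frame(seq_id = "s", crm_id = 1L, start = 100L, end = 200L,
                     llr = 5, stringsAsFactors = FALSE)
  # candidate exactly of target length -> itself
  out <- fixed_length_protocol(crms, c(s = 1000L), 100L)
  expect_equal(c(out$start, out$end), c(100L, 200L))
  expect_false(out$fallback)
  # shorter candidate: symmetric extension around its center
  crms2 <- data.frame(seq_id = "s", crm_id = 1L, start = 40L, end = 60L,
                      llr = 5, stringsAsFactors = FALSE)
  out2 <- fixed_length_protocol(crms2, c(s = 1000L), 40L)
  expect_equal(c(out2$start, out2$end), c(30L, 70L))
  # highest-LLR candidate anchors the window
  crms3 <- rbind(crms, data.frame(seq_id = "s", crm_id = 2L, start = 700L,
                                  end = 800L, llr = 9,
                                  stringsAsFactors = FALSE))
  out3 <- fixed_length_protocol(crms3, c(s = 1000L), 100L)
  expect_equal(out3$start, 700L)
  # no candidate: centered fallback, flagged
  out4 <- fixed_length_protocol(crms[0, ], c(s = 1000L), 100L)
  expect_true(out4$fallback)
  expect_equal(out4$end - out4$start, 100L)
  # per-position scores steer the fallback
  sc <- rep(0, 1000); sc[401:500] <- 1
  out5 <- fixed_length_protocol(crms[0, ], c(s = 1000L), 100L,
                                scores = list(s = sc))
  expect_equal(c(out5$start, out5$end), c(400L, 500L))
  # window exceeding the sequence clips to the whole sequence
  expect_warning(out6 <- fixed_length_protocol(crms, c(s = 80L), 100L),
                 "exceeds")
  expect_equal(c(out6$start, out6$end), c(0L, 80L))
})

test_that("protocol forces Sn = Pr when every truth CRM has target length", {
  set.seed(61)
  for (k in 1:10) {
    lens <- c(a = 500L, b = 400L)
    target <- 60L
    truth <- iv(c("a", "b"), c(100L, 200L), c(160L, 260L))
    crms <- data.frame(seq_id = c("a", "b"),
                       crm_id = 1L,
                       start = sample.int(300L, 2L),
                       llr = runif(2), stringsAsFactors = FALSE)
    crms$end <- crms$start + sample(10:80, 2L)
    pred <- fixed_length_protocol(crms, lens, target)
    cts <- confusion(truth, pred, lens)
    rep <- metric_report(cts)
    expect_equal(cts[["nTP"]] + cts[["nFP"]],
                 cts[["nTP"]] + cts[["nFN"]])  # nPP = nAP
    expect_equal(rep[["sn"]], rep[["pr"]])
  }
})

test_that("empirical p-value brackets and closed-form overlap oracle", {
  lens <- c(s = 1000L)
  truth <- iv("s", 0L, 100L)
  p_low <- empirical_pvalue(0, truth, lens, 100L, n_sim = 200L, seed = 1L)
  expect_equal(as.numeric(p_low), 1, tolerance = 0.01)
  p_high <- empirical_pvalue(1.0000001, truth, lens, 100L, n_sim = 200L,
                             seed = 1L)
  expect_equal(as.numeric(p_high), 1 / 201)
  # P(overlap >= 50) for a uniform window start in 0..900 is 51/901
  n_sim <- 4000L
  p <- empirical_pvalue(0.5, truth, lens, 100L, n_sim = n_sim, seed = 7L)
  p_true <- 51 / 901
  mc_sigma <- sqrt(p_true * (1 - p_true) / n_sim)
  expect_lt(abs(as.numeric(p) - p_true), 3 * mc_sigma + 1 / n_sim)
})

test_that("maximum sensitivity bound", {
  expect_equal(max_sensitivity(c(100, 100), 100), 1)
  expect_equal(max_sensitivity(200, 100), 0.5)
  expect_equal(max_sensitivity(c(50, 150), 100), 0.75)
})

test_that("bundled protocol summary loads with expected layout", {
  df <- redfly_protocol_summary()
  expect_equal(nrow(df), 33L)
  expect_true(all(c("subdataset", "n_seq", "total_length", "max_sens",
                    "pvalue", "sensitivity") %in% names(df)))
  expect_true(all(df$pvalue >= 0 & df$pvalue <= 1))
  expect_true(all(df$max_sens > 0 & df$max_sens <= 1))
})
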
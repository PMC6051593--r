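test_that("the min-overlap index reproduces its closed-form examples", {
  expect_equal(per_context_pi(rep(0.25, 4), c(0.72, 0.18, 0.05, 0.05)), 0.53)
  expect_equal(per_context_pi(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4)), 1)
  expect_equal(per_context_pi(c(0.5, 0.5, 0, 0), c(0.8, 0.2, 0, 0)), 0.7)
  expect_error(per_context_pi(c(0.5, 0.2, 0, 0), c(0.8, 0.2, 0, 0)), "sum")
})

test_that("min overlap equals one minus total-variation distance", {
  set.seed(51)
  for (i in 1:1000) {
    p <- random_prob4(sparse = i %% 3 == 0)
    q <- random_prob4(sparse = i %% 5 == 0)
    expect_equal(per_context_pi(p, q), 1 - 0.5 * sum(abs(p - q)),
                 tolerance = 1e-12)
  }
})

test_that("overall PI is the context-probability-weighted mean", {
  expect_equal(overall_pi(c(0.5, 1.0), c(0.6, 0.4)), 0.7)
  expect_equal(overall_pi(0.83, 1), 0.83)
  set.seed(52)
  w <- random_prob4()
  expect_equal(overall_pi(rep(0.61, 4), w), 0.61)
  expect_error(overall_pi(c(a = 0.5, b = 1), c(b = 0.6, a = 0.4)),
               "names")
  expect_error(overall_pi(c(0.5, 1), c(0.9, 0.4)), "sum")
})

test_that("analytic random-guess baselines match the closed form by level", {
  expect_equal(random_baseline_pi(build_model(0)), 0.53, tolerance = 1e-12)
  expect_equal(random_baseline_pi(build_model(1)), 0.45, tolerance = 1e-12)
  expect_equal(random_baseline_pi(build_model(2)), 0.45, tolerance = 1e-12)
  # a uniform model is indistinguishable from uniform guessing
  m_flat <- build_model(0, level0_probs = rep(0.25, 4))
  expect_equal(random_baseline_pi(m_flat), 1)
})

test_that("simulated baseline converges to the analytic value for long blocks", {
  m <- build_model(1)
  set.seed(53)
  sim <- random_baseline_pi(m, "simulated", n_blocks = 20,
                            block_trials = 1e4, pool_responses = FALSE)
  expect_lt(abs(sim - 0.45), 0.01)
})

test_that("session-scale stratified estimation explains the printed level-2 baseline", {
  # a uniform responder whose per-context response distribution is estimated
  # from ~280 trials (one session) has expected overlap ~0.44 at level-2,
  # 0.01 below the analytic 0.45
  m2 <- build_model(2)
  set.seed(54)
  sim <- random_baseline_pi(m2, "simulated", n_blocks = 400,
                            block_trials = 280, pool_responses = FALSE)
  expect_lt(abs(sim - 0.44), 0.01)
  expect_lt(sim, 0.45)
})

test_that("response tables recover the generating conditional distributions", {
  m <- build_model(1)
  set.seed(55)
  n <- 1e5
  ctx <- sample(m$contexts, n, replace = TRUE, prob = m$context_weights)
  resp <- vapply(match(ctx, m$contexts), function(ci)
    sample(colnames(m$table), 1, prob = m$table[ci, ]), character(1))
  rec <- make_records(ctx, resp)
  rt <- response_tables(rec, 1)
  expect_lt(max(abs(rt$p_resp[m$contexts, colnames(m$table)] - m$table)),
            0.01)
  expect_equal(sum(rt$weights), 1)
  expect_equal(rt$n_used + rt$n_null, n)
})

test_that("null responses are excluded from distributions but counted", {
  rec <- make_records(rep("A", 10), c(rep("B", 6), rep(NA, 2), "", "C"))
  rt <- response_tables(rec, 1)
  expect_equal(rt$n_null, 3L)
  expect_equal(rt$n_used, 7L)
  expect_equal(unname(rt$p_resp["A", ]), c(0, 6 / 7, 1 / 7, 0))
  expect_error(response_tables(make_records("A", NA_character_), 1), "null")
})

test_that("a distributional matcher scores PI = 1 in every block", {
  for (level in 1:2) {
    m <- build_model(level)
    rec <- rbind(matcher_records(m, block_id = 1),
                 matcher_records(m, block_id = 2))
    rep <- score_session(rec, m, presented = "model")
    expect_equal(rep$blocks$pi, c(1, 1))
    expect_equal(rep$blocks$pi_normalized, c(0.55, 0.55))
    expect_equal(rep$session$pi, 1)
  }
})

test_that("a uniform responder's session score approaches the analytic baseline", {
  m0 <- build_model(0)
  set.seed(56)
  n_blocks <- 30
  rec <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    make_records(rep("A", 56), sample(c("A", "B", "C", "D"), 56,
                                      replace = TRUE), level = 0,
                 block_id = b)))
  rep <- score_session(rec, m0, presented = "model")
  expect_equal(nrow(rep$blocks), n_blocks)
  expect_lt(abs(mean(rep$blocks$pi) - 0.53), 0.02)
})

test_that("scoring validates its inputs", {
  m <- build_model(1)
  expect_error(score_session(make_records(character(0), character(0)), m),
               "empty|no scoreable")
  bad <- make_records("AE", "B")
  expect_error(score_session(bad, m), "invalid presented")
})

test_that("normalized PI subtracts the baseline and tracks the criterion", {
  expect_equal(normalized_pi(0.53, 0.53), 0)
  expect_equal(normalized_pi(1.0, 0.45), 0.55)
  # training criterion: PI above 0.70 is at least 0.25 over chance
  expect_equal(normalized_pi(0.70, 0.45), 0.25)
  expect_true(reached_criterion(0.71))
  expect_false(reached_criterion(0.70))
  # monotone in pi for fixed baseline
  pis <- seq(0, 1, 0.1)
  expect_true(all(diff(normalized_pi(pis, 0.45)) > 0))
})
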
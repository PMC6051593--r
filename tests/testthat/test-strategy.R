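test_that("maximization baseline puts all mass on the modal targets", {
  bm0 <- baseline_models(build_model(0))
  expect_equal(unname(bm0$maximization[1, ]), c(0, 1, 0, 0))
  expect_equal(bm0$matching, build_model(0)$table)
  m1 <- build_model(1)
  bm1 <- baseline_models(m1)
  expect_true(all(rowSums(bm1$maximization == 1) == 1))
  expect_true(all(bm1$maximization[m1$table == 0.8] == 1))
  # an already-degenerate row is unchanged; exact ties split equally
  tied <- baseline_models(build_model(1, high_p = 0.5))
  expect_true(all(tied$maximization[tied$matching > 0] == 0.5))
})

test_that("baseline-to-response KL matches hand values and the loop oracle", {
  m0 <- build_model(0)
  bm <- baseline_models(m0)
  # KL(maximization || matching) at level 0 is a single term: ln(1/0.72)
  expect_equal(kl_model_to_response(bm$maximization, bm$matching,
                                    bm$context_weights),
               log(1 / 0.72), tolerance = 1e-4)
  expect_lt(kl_model_to_response(bm$matching, bm$matching,
                                 bm$context_weights), 1e-5)
  set.seed(61)
  for (level in 0:2) {
    m <- build_model(level)
    bml <- baseline_models(m)
    for (i in 1:5) {
      R <- random_response_table(m, sparse = i %% 2 == 0)
      for (M in list(bml$matching, bml$maximization)) {
        got <- kl_model_to_response(M, R, bml$context_weights)
        expect_gte(got, 0)
        expect_equal(got, oracle_kl(M, R, unname(bml$context_weights)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("delta-KL orients the matching-to-maximization continuum", {
  for (level in 0:2) {
    m <- build_model(level)
    bm <- baseline_models(m)
    d_match <- strategy_choice(bm$matching, m)
    d_max <- strategy_choice(bm$maximization, m)
    expect_lt(d_match, 0)
    expect_gt(d_max, 0)
    expect_lt(d_match, d_max)
    expect_equal(d_match, matcher_reference(m))
    # responses mid-way between the baselines fall strictly between the
    # extremes, monotonically in the blend
    alphas <- c(0, 0.25, 0.5, 0.75, 1)
    deltas <- vapply(alphas, function(a)
      strategy_choice((1 - a) * bm$matching + a * bm$maximization, m),
      numeric(1))
    expect_true(all(diff(deltas) > 0))
  }
  expect_equal(matcher_reference(build_model(0)), -log(1 / 0.72),
               tolerance = 1e-4)
})

test_that("delta-KL is stable under the smoothing constant for full-support tables", {
  m <- build_model(1)
  R <- matrix(c(0.7, 0.2, 0.06, 0.04), 4, 4, byrow = TRUE,
              dimnames = dimnames(m$table))
  vals <- vapply(c(1e-8, 1e-6, 1e-5), function(eps)
    strategy_choice(R, m, epsilon = eps), numeric(1))
  expect_lt(max(abs(vals - vals[1])) / abs(vals[1]), 0.01)
})

test_that("an exact matcher's curve is constant and its index exactly zero", {
  for (level in 0:2) {
    m <- build_model(level)
    tables <- rep(list(baseline_models(m)$matching), 6)
    curve <- strategy_curve_from_tables(tables, m)
    expect_true(all(curve$delta_kl == curve$reference))
    expect_identical(strategy_index(curve)$icd, 0)
  }
})

test_that("the index integrates the curve relative to the matching reference", {
  m <- build_model(1)
  curve <- strategy_curve_from_tables(
    rep(list(baseline_models(m)$matching), 5), m)
  # shifting the whole curve by c shifts the index by c (integral linearity)
  shifted <- curve
  shifted$delta_kl <- shifted$delta_kl + 0.3
  expect_equal(strategy_index(shifted)$icd, 0.3)
  # one window degenerates to a plain difference
  single <- curve[1, , drop = FALSE]
  single$delta_kl <- single$delta_kl + 0.12
  expect_equal(strategy_index(single)$icd, 0.12)
})

test_that("a pure maximizer's windows all exceed the matching reference", {
  m <- build_model(1)
  set.seed(62)
  ss <- select_sequences(m, n_generate = 50, length = 300, n_select = 20)
  trials <- do.call(rbind, lapply(1:10, function(b)
    make_training_block(ss, block_id = b)))
  cfg <- agent_config(lambda_max = 1, lapse = 0, null_rate = 0, seed = 63)
  rec <- simulate_agent(m, trials, cfg)
  curve <- strategy_curve(rec, m, window = 56)
  expect_equal(nrow(curve), 10L)
  expect_true(all(curve$delta_kl > curve$reference))
  expect_gt(strategy_index(curve)$icd, 0)
})

test_that("window count is the floor of trials over window size", {
  m <- build_model(1)
  rec <- matcher_records(m, per_context = 20)   # 80 trials
  expect_equal(nrow(strategy_curve(rec, m, window = 30)), 2L)
  expect_error(strategy_curve(rec[1:10, ], m, window = 56), "window")
})

test_that("pooling the conditional-level indices averages them", {
  idx <- function(v) structure(list(icd = v, level = 1, n_windows = 5),
                               class = "strategy_index")
  expect_equal(pooled_context_index(idx(0.2), idx(0.4))$icd, 0.3)
  expect_equal(pooled_context_index(idx(0.7), idx(0.7))$icd, 0.7)
  expect_equal(pooled_context_index(idx(0.2), idx(0.4))$icd,
               pooled_context_index(idx(0.4), idx(0.2))$icd)
  expect_equal(pooled_context_index(idx(0.2), idx(0.4))$level, "pooled")
})
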
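test_that("generated sequences contain only model-legal transitions", {
  for (level in 0:2) {
    m <- build_model(level)
    set.seed(10 + level)
    for (s in generate_sequences(m, 5, 60)) {
      items <- strsplit(s, "")[[1]]
      if (level == 0) next
      for (i in seq.int(level + 1, length(items))) {
        ctx <- paste(items[(i - level):(i - 1)], collapse = "")
        expect_gt(m$table[ctx, items[i]], 0)
      }
    }
  }
})

test_that("identical seeds reproduce identical sequences and trial material", {
  m <- build_model(1)
  set.seed(7); a <- generate_sequences(m, 20, 100)
  set.seed(7); b <- generate_sequences(m, 20, 100)
  expect_identical(a, b)
  set.seed(7); r1 <- make_random_sequence(50)
  set.seed(7); r2 <- make_random_sequence(50)
  expect_identical(r1, r2)
  set.seed(3); s1 <- select_sequences(m, n_generate = 50, length = 80,
                                      n_select = 5)
  set.seed(3); s2 <- select_sequences(m, n_generate = 50, length = 80,
                                      n_select = 5)
  expect_identical(s1$sequences, s2$sequences)
  set.seed(4); b1 <- make_training_block(s1)
  set.seed(4); b2 <- make_training_block(s1)
  expect_identical(b1, b2)
  set.seed(5); t1 <- make_test_run(m)
  set.seed(5); t2 <- make_test_run(m)
  expect_identical(t1, t2)
})

test_that("long-run conditional frequencies converge to the model rows", {
  m <- build_model(1)
  set.seed(11)
  emp <- empirical_distribution(generate_sequence(m, 1e5), 1)
  expect_lt(max(abs(emp[rownames(m$table), colnames(m$table)] - m$table)),
            0.01)
  m0 <- build_model(0)
  set.seed(12)
  expect_length(generate_sequence(m0, 1), 1L)
})

test_that("empirical_distribution counts conditional frequencies", {
  emp <- empirical_distribution("ABABABAB", 1)
  expect_equal(emp["A", "B"], 1)
  expect_equal(emp["B", "A"], 1)
  expect_equal(empirical_distribution("BBBB", 0)[1, "B"], 1)
  m <- build_model(2)
  set.seed(13)
  emp2 <- empirical_distribution(generate_sequence(m, 672), 2)
  expect_equal(unname(rowSums(emp2)), rep(1, nrow(emp2)))
  expect_error(empirical_distribution("AB", 2), "longer")
})

test_that("kl_to_ideal matches hand computation and the summation oracle", {
  # Q = (0.72, 0.18, 0.05, 0.05) against empirical (0.70, 0.20, 0.05, 0.05):
  # 0.72 ln(0.72/0.70) + 0.18 ln(0.18/0.20) ~ 0.00132 nats
  m <- build_model(0, level0_probs = c(0.72, 0.18, 0.05, 0.05))
  seqc <- paste(rep(c("A", "B", "C", "D"), c(70, 20, 5, 5)), collapse = "")
  expect_equal(kl_to_ideal(seqc, m), 0.00132, tolerance = 2e-2)
  expect_equal(kl_to_ideal(seqc, m),
               0.72 * log(0.72 / 0.70) + 0.18 * log(0.18 / 0.20),
               tolerance = 5e-3)

  # empirical equal to the model -> divergence at the smoothing floor
  exact <- paste(rep(c("A", "B", "C", "D"), c(72, 18, 5, 5)), collapse = "")
  expect_lt(kl_to_ideal(exact, m), 1e-5)

  # any generated sequence: non-negative and equal to the loop oracle
  for (level in 0:2) {
    ml <- build_model(level)
    set.seed(20 + level)
    for (s in generate_sequences(ml, 3, 150)) {
      got <- kl_to_ideal(s, ml)
      expect_gte(got, 0)
      expect_equal(got,
                   oracle_kl(ml$table, empirical_distribution(s, level),
                             unname(ml$context_weights)),
                   tolerance = 1e-12)
    }
  }
})

test_that("select_sequences equals the brute-force score-sort oracle", {
  m <- build_model(1)
  set.seed(31)
  pool <- generate_sequences(m, 40, 90)
  got <- select_sequences(m, pool = pool, n_select = 7)
  kl <- vapply(pool, kl_to_ideal, numeric(1), model = m, USE.NAMES = FALSE)
  keep <- order(kl)[1:7]
  expect_identical(got$sequences, pool[keep])
  expect_equal(got$kl, kl[keep])
  expect_false(is.unsorted(got$kl))
  # empty selection
  expect_length(select_sequences(m, pool = pool, n_select = 0)$sequences, 0L)
  expect_error(select_sequences(m, pool = pool, n_select = 41), "exceed")
})

test_that("selected sequences are stochastically closer to the ideal model", {
  m <- build_model(1)
  set.seed(32)
  ss <- select_sequences(m, n_generate = 500, length = 300, n_select = 50)
  expect_lte(max(ss$kl), min(ss$pool_kl[-order(ss$pool_kl)[1:50]]))
  set.seed(33)
  random_subset <- sample(ss$pool_kl, 50)
  expect_lt(wilcox.test(ss$kl, random_subset,
                        alternative = "less")$p.value, 0.01)
})

test_that("training blocks balance stream lengths and cut valid windows", {
  m <- build_model(1)
  set.seed(41)
  ss <- select_sequences(m, n_generate = 30, length = 120, n_select = 10)
  blk <- make_training_block(ss)
  expect_equal(nrow(blk), 56L)
  expect_equal(as.vector(table(nchar(blk$presented))), rep(8L, 7))
  # every trial's final context has positive model weight
  ctx <- substr(blk$presented, nchar(blk$presented), nchar(blk$presented))
  expect_true(all(m$context_weights[ctx] > 0))
  # windows are substrings of the selected sequences
  expect_true(all(vapply(blk$presented, function(p)
    any(grepl(p, ss$sequences, fixed = TRUE)), logical(1))))
  one_per <- make_training_block(ss, n_trials = 7)
  expect_equal(sort(nchar(one_per$presented)), 8:14)
  expect_error(make_training_block(ss, n_trials = 30), "divisible")
})

test_that("test runs hold 10 structured and 10 random trials of 10 items", {
  m <- build_model(2)
  set.seed(42)
  run <- make_test_run(m)
  expect_equal(nrow(run), 20L)
  expect_equal(sum(run$condition == "structured"), 10L)
  expect_equal(sum(run$condition == "random"), 10L)
  expect_true(all(nchar(run$presented) == 10L))
  expect_equal(length(unique(run$block_id)), 10L)
  # blocks are condition-pure with two trials each
  expect_true(all(tapply(run$condition, run$block_id,
                         function(x) length(x) == 2 && length(unique(x)) == 1)))
})

test_that("random sequences are uniform over the four items", {
  set.seed(43)
  freq <- table(make_random_sequence(4e5)) / 4e5
  expect_equal(unname(as.vector(freq)), rep(0.25, 4), tolerance = 0.02)
  expect_true(all(abs(freq - 0.25) < 0.005))
  expect_length(make_random_sequence(1), 1L)
})
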
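# Independent brute-force oracles and small fixture builders, kept free of
# the package's vectorized computation paths.

# Term-by-term conditional KL divergence with epsilon-smoothed denominator:
# plain double loop over (context, target) pairs.
oracle_kl <- function(M, R, weights, epsilon = 1e-6, base = exp(1)) {
  total <- 0
  for (ci in seq_len(nrow(M))) {
    rrow <- rep(0, ncol(M))
    ri <- match(rownames(M)[ci], rownames(R))
    if (!is.na(ri)) {
      rrow <- as.numeric(R[ri, match(colnames(M), colnames(R))])
    }
    rrow <- (rrow + epsilon) / (sum(rrow) + ncol(M) * epsilon)
    for (ti in seq_len(ncol(M))) {
      m <- M[ci, ti]
      if (m > 0) {
        total <- total + weights[ci] * m * log(m / rrow[ti], base = base)
      }
    }
  }
  total
}

# Stationary context distribution by brute-force power iteration of the
# context-transition operator assembled directly from the model table.
oracle_stationary <- function(model, iters = 10000) {
  contexts <- model$contexts
  n <- length(contexts)
  tm <- matrix(0, n, n)
  items <- colnames(model$table)
  for (ci in seq_len(n)) {
    for (ti in seq_along(items)) {
      p <- model$table[ci, ti]
      if (p <= 0) next
      nxt <- if (model$level == 0) "" else
        paste0(substr(contexts[ci], 2, model$level), items[ti])
      tm[ci, match(nxt, contexts)] <- tm[ci, match(nxt, contexts)] + p
    }
  }
  pi <- rep(1 / n, n)
  for (i in seq_len(iters)) pi <- as.vector(pi %*% tm)
  stats::setNames(pi / sum(pi), contexts)
}

# Random probability vector over 4 items (occasionally sparse).
random_prob4 <- function(sparse = FALSE) {
  x <- stats::rgamma(4, shape = 1)
  if (sparse) x[sample(4, sample(0:2, 1))] <- 0
  if (sum(x) == 0) x[1] <- 1
  x / sum(x)
}

# Random response table over the model's contexts.
random_response_table <- function(model, sparse = FALSE) {
  R <- t(vapply(seq_along(model$contexts), function(i) random_prob4(sparse),
                numeric(4)))
  dimnames(R) <- dimnames(model$table)
  R
}

# Minimal trial records: one row per element of `presented`.
make_records <- function(presented, response, level = 1,
                         block_id = 1, session_id = 1) {
  n <- length(presented)
  data.frame(session_id = rep_len(session_id, n),
             block_id = rep_len(block_id, n),
             trial_id = seq_len(n), condition = rep_len("structured", n),
             level = rep_len(level, n), presented = presented,
             response = response, stringsAsFactors = FALSE)
}

# Distributional (noise-free) matcher records for a conditional model:
# `per_context` trials per context, responses in exact model proportions.
# Requires per_context * p to be integral for every table entry.
matcher_records <- function(model, per_context = 10, block_id = 1) {
  stopifnot(model$level >= 1)
  presented <- character(0)
  response <- character(0)
  for (ctx in model$contexts) {
    counts <- round(model$table[ctx, ] * per_context)
    stopifnot(sum(counts) == per_context)
    presented <- c(presented, rep(ctx, per_context))
    response <- c(response, rep(colnames(model$table), counts))
  }
  make_records(presented, response, level = model$level,
               block_id = block_id)
}
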
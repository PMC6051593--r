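## Sequence generation, KL scoring against the ideal model, selection of
## presentation sets, and assembly of training blocks and test runs.

as_item_vector <- function(sequence) {
  if (is.character(sequence) && length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (!all(sequence %in% sl_items)) {
    stop("sequence contains items outside A-D", call. = FALSE)
  }
  sequence
}

## Sample index vectors in parallel: one draw per row of `prob` selected by
## `rows`, via inverse-CDF lookup.
sample_rows <- function(prob_cum, rows) {
  u <- stats::runif(length(rows))
  1L + rowSums(u > prob_cum[rows, , drop = FALSE])
}

#' Generate stochastic Markov sequences from a stimulus model
#'
#' `generate_sequence()` draws a single item sequence; `generate_sequences()`
#' draws a pool of independent sequences (used to build candidate pools for
#' [select_sequences()]). The initial k-item context is drawn from the
#' model's stationary context distribution, so empirical statistics of long
#' sequences are free of burn-in bias; every subsequent item is drawn from
#' the model's conditional row for the current context.
#'
#' Randomness comes from R's global RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param model A [build_model()] object.
#' @param length Items per sequence; must be at least `model$level + 1`.
#' @param n Number of sequences.
#' @return `generate_sequence()`: a character vector of items;
#'   `generate_sequences()`: a character vector of `n` collapsed item
#'   strings.
#' @examples
#' set.seed(1)
#' paste(generate_sequence(build_model(1), 12), collapse = "")
#' @export
generate_sequence <- function(model, length) {
  strsplit(generate_sequences(model, 1L, length), "")[[1]]
}

#' @rdname generate_sequence
#' @export
generate_sequences <- function(model, n, length) {
  stopifnot(inherits(model, "markov_model"))
  k <- model$level
  if (length < k + 1L) {
    stop(sprintf("`length` must be at least order + 1 = %d", k + 1L),
         call. = FALSE)
  }
  contexts <- model$contexts
  items <- colnames(model$table)
  prob_cum <- t(apply(model$table, 1L, cumsum))
  if (ncol(model$table) == 1L) prob_cum <- t(prob_cum)

  ## next-context index given current context and emitted target
  nci <- matrix(NA_integer_, length(contexts), 4L)
  for (ci in seq_along(contexts)) {
    for (ti in 1:4) {
      if (model$table[ci, ti] <= 0) next
      nxt <- if (k == 0L) "" else
        paste0(substr(contexts[ci], 2L, k), items[ti])
      nci[ci, ti] <- match(nxt, contexts)
    }
  }

  out <- matrix(NA_integer_, n, length)
  ctx <- sample.int(length(contexts), n, replace = TRUE,
                    prob = model$context_weights)
  if (k > 0L) {
    ctx_items <- do.call(rbind, strsplit(contexts, ""))
    for (j in seq_len(k)) {
      out[, j] <- match(ctx_items[ctx, j], items)
    }
  }
  for (pos in seq.int(k + 1L, length)) {
    tgt <- sample_rows(prob_cum, ctx)
    out[, pos] <- tgt
    ctx <- nci[cbind(ctx, tgt)]
  }
  apply(out, 1L, function(ix) paste(items[ix], collapse = ""))
}

#' Uniform random item sequence
#'
#' Items A--D drawn i.i.d. with probability 0.25 each, as in the random
#' condition of test runs and the familiarization phase.
#'
#' @param length Number of items (>= 1).
#' @return Character vector of items.
#' @export
make_random_sequence <- function(length) {
  stopifnot(length >= 1L)
  sample(sl_items, length, replace = TRUE)
}

#' Empirical (conditional) target distribution of a sequence
#'
#' Tabulates, for every k-item context occurring in the sequence, the
#' relative frequencies of the item that follows it. Contexts never observed
#' are absent from the result rather than zero-filled.
#'
#' @param sequence Character vector of items, or a single collapsed string.
#' @param order Context length k (0, 1 or 2).
#' @return Matrix with one row per observed context (row name `""` for
#'   k = 0) and one column per item; rows sum to 1.
#' @examples
#' empirical_distribution("ABABABAB", 1)
#' @export
empirical_distribution <- function(sequence, order) {
  sequence <- as_item_vector(sequence)
  n <- length(sequence)
  if (n <= order) {
    stop("sequence must be longer than the context order", call. = FALSE)
  }
  pos <- seq.int(order + 1L, n)
  ctx <- if (order == 0L) rep("", length(pos)) else
    vapply(pos, function(i)
      paste(sequence[(i - order):(i - 1L)], collapse = ""), character(1))
  tgt <- sequence[pos]
  counts <- table(factor(ctx, levels = sort(unique(ctx))),
                  factor(tgt, levels = sl_items))
  counts <- matrix(counts, nrow = nrow(counts),
                   dimnames = dimnames(counts))
  counts / rowSums(counts)
}

## Epsilon-smooth and renormalize the rows of a denominator distribution.
## All-zero rows (contexts absent from the data) become uniform.
smooth_rows <- function(tab, epsilon) {
  sw <- sweep(tab + epsilon, 1L, rowSums(tab) + ncol(tab) * epsilon, "/")
  sw
}

## Context-weighted conditional KL divergence sum_c w_c sum_t
## M(t|c) log(M(t|c) / R(t|c)), with the denominator table R aligned to M's
## contexts (missing rows -> zeros -> uniform after smoothing) and
## epsilon-smoothed. Terms with M(t|c) = 0 contribute 0. `weights` is
## aligned positionally with the rows of M (name lookup would break on the
## level-0 empty-string context).
kl_cond <- function(M, R, weights, epsilon = 1e-6, base = exp(1),
                    smooth = TRUE) {
  stopifnot(length(weights) == nrow(M))
  aligned <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  common <- intersect(rownames(M), rownames(R))
  aligned[match(common, rownames(M)), ] <-
    R[match(common, rownames(R)), match(colnames(M), colnames(R)),
      drop = FALSE]
  if (smooth) aligned <- smooth_rows(aligned, epsilon)
  terms <- ifelse(M > 0, M * (log(M) - log(aligned)), 0)
  sum(unname(weights) * rowSums(terms)) / log(base)
}

#' KL divergence of a sequence's empirical statistics from its ideal model
#'
#' Measures how representative a candidate sequence is of the generating
#' Markov model: `sum_c Q(c) sum_t Q(t|c) log(Q(t|c) / P(t|c))`, where Q is
#' the ideal model (context weights Q(c) from the stationary context
#' distribution) and P the sequence's epsilon-smoothed empirical conditional
#' distribution. For a level-0 model this reduces to the unconditional
#' divergence `sum_t Q(t) log(Q(t)/P(t))`.
#'
#' @param sequence Character item vector or collapsed string.
#' @param model A [build_model()] object.
#' @param epsilon Additive smoothing applied to the empirical (denominator)
#'   distribution before renormalization; contexts absent from the sequence
#'   enter as the smoothed uniform floor.
#' @param base Logarithm base; natural log (nats) by default.
#' @return Non-negative scalar divergence.
#' @examples
#' m <- build_model(1)
#' set.seed(1)
#' kl_to_ideal(generate_sequence(m, 672), m)
#' @export
kl_to_ideal <- function(sequence, model, epsilon = 1e-6, base = exp(1)) {
  stopifnot(inherits(model, "markov_model"))
  P <- empirical_distribution(sequence, model$level)
  kl_cond(model$table, P, model$context_weights, epsilon = epsilon,
          base = base)
}

#' Generate a candidate pool and select the most representative sequences
#'
#' Draws `n_generate` stochastic sequences from the model (or scores a
#' supplied `pool`), computes each sequence's [kl_to_ideal()] divergence,
#' and keeps the `n_select` sequences with the smallest divergence --- the
#' sequences whose empirical statistics match the ideal Markov model most
#' closely. Defaults are the presentation-set design used in training:
#' 10,000 candidates of 672 items each, of which the best 50 are kept.
#'
#' Ties in the divergence are broken by generation order (stable sort).
#'
#' @param model A [build_model()] object.
#' @param n_generate Candidate pool size.
#' @param length Items per candidate sequence.
#' @param n_select Number of sequences to keep (`<= n_generate`).
#' @param pool Optional pre-generated pool (character vector of collapsed
#'   item strings); overrides `n_generate`/`length`.
#' @param epsilon,base Passed to the KL computation.
#' @return An object of class `sequence_set`: list with `sequences`
#'   (character strings, ascending divergence), `kl` (their scores),
#'   `pool_kl` (scores of the full candidate pool, in generation order),
#'   `length`, and the generating `model`.
#' @export
select_sequences <- function(model, n_generate = 10000L, length = 672L,
                             n_select = 50L, pool = NULL,
                             epsilon = 1e-6, base = exp(1)) {
  stopifnot(inherits(model, "markov_model"))
  if (is.null(pool)) {
    pool <- generate_sequences(model, n_generate, length)
  } else {
    n_generate <- base::length(pool)
    length <- nchar(pool[1L])
  }
  if (n_select > n_generate) {
    stop("`n_select` cannot exceed the pool size", call. = FALSE)
  }
  kl <- kl_pool(pool, model, epsilon = epsilon, base = base)
  keep <- order(kl)[seq_len(n_select)]   # order() is stable: ties by index
  structure(
    list(sequences = pool[keep],
         kl = kl[keep],
         pool_kl = kl,
         length = as.integer(length),
         model = model),
    class = "sequence_set")
}

## Vectorized KL-to-ideal over a pool of equal-length sequences: one pass
## tabulating (sequence, context, target) transition counts, then the
## context-weighted divergence per sequence in matrix form.
kl_pool <- function(pool, model, epsilon = 1e-6, base = exp(1)) {
  k <- model$level
  items <- colnames(model$table)
  n <- length(pool)
  L <- nchar(pool[1L])
  if (any(nchar(pool) != L)) stop("pool sequences must have equal length")
  codes <- matrix(match(unlist(strsplit(pool, "")), items), nrow = n,
                  byrow = TRUE)
  ncx <- length(model$contexts)
  pos <- seq.int(k + 1L, L)
  tgt <- codes[, pos, drop = FALSE]
  ctx <- if (k == 0L) {
    matrix(1L, n, length(pos))
  } else if (k == 1L) {
    ctx1 <- codes[, pos - 1L, drop = FALSE]
    matrix(match(items[ctx1], model$contexts), n)
  } else {
    pair_lookup <- rep(NA_integer_, 16L)
    for (ci in seq_along(model$contexts)) {
      xy <- match(strsplit(model$contexts[ci], "")[[1]], items)
      pair_lookup[(xy[1L] - 1L) * 4L + xy[2L]] <- ci
    }
    matrix(pair_lookup[(codes[, pos - 2L, drop = FALSE] - 1L) * 4L +
                         codes[, pos - 1L, drop = FALSE]], n)
  }
  if (anyNA(ctx)) stop("pool contains transitions illegal under the model")

  idx <- (row(tgt) - 1L) * (ncx * 4L) + (ctx - 1L) * 4L + tgt
  counts <- array(tabulate(idx, n * ncx * 4L), dim = c(4L, ncx, n))

  Q <- model$table
  w <- model$context_weights
  kl <- numeric(n)
  for (ci in seq_len(ncx)) {
    cnt <- t(counts[, ci, ])                      # n x 4
    tot <- rowSums(cnt)
    p <- cnt / ifelse(tot > 0, tot, 1)            # zero rows stay zero
    P <- (p + epsilon) / (rowSums(p) + 4 * epsilon)
    qrow <- Q[ci, ]
    live <- qrow > 0
    term <- sweep(-log(P[, live, drop = FALSE]), 2L,
                  log(qrow[live]), "+")
    kl <- kl + w[ci] * as.vector(term %*% qrow[live])
  }
  kl / log(base)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("Sequence set: %d sequences of %d items (level-%d model)\n",
              length(x$sequences), x$length, x$model$level))
  cat(sprintf("KL to ideal: min %.4g, max %.4g (pool of %d: min %.4g, max %.4g)\n",
              min(x$kl), max(x$kl), length(x$pool_kl),
              min(x$pool_kl), max(x$pool_kl)))
  invisible(x)
}

#' Assemble a training block of prediction trials
#'
#' Cuts trial streams as contiguous windows from the selected presentation
#' sequences: a block of `n_trials` trials containing each stream length in
#' `lengths` equally often (the default 56 trials over lengths 8--14 gives 8
#' trials per length), in randomized order. Window offsets and source
#' sequences are drawn from R's global RNG.
#'
#' @param seqset A [select_sequences()] set.
#' @param n_trials Trials per block; must be divisible by `length(lengths)`.
#' @param lengths Distinct stream lengths to use.
#' @param block_id,session_id Identifiers stamped on the trials.
#' @return Data frame with columns `session_id`, `block_id`, `trial_id`,
#'   `condition` (`"structured"`), `level`, `presented` (collapsed item
#'   string).
#' @export
make_training_block <- function(seqset, n_trials = 56L, lengths = 8:14,
                                block_id = 1L, session_id = 1L) {
  stopifnot(inherits(seqset, "sequence_set"))
  n_len <- length(lengths)
  if (n_trials %% n_len != 0L) {
    stop("`n_trials` must be divisible by the number of distinct lengths",
         call. = FALSE)
  }
  per <- n_trials %/% n_len
  len <- sample(rep(lengths, per))           # shuffled trial lengths
  src <- sample.int(length(seqset$sequences), n_trials, replace = TRUE)
  offset <- vapply(len, function(l)
    sample.int(seqset$length - l + 1L, 1L), integer(1))
  presented <- substr(seqset$sequences[src], offset, offset + len - 1L)
  data.frame(session_id = session_id,
             block_id = block_id,
             trial_id = seq_len(n_trials),
             condition = "structured",
             level = seqset$model$level,
             presented = presented,
             stringsAsFactors = FALSE)
}

#' Assemble a test run of structured and random trials
#'
#' A run of 10 blocks of two trials each --- five structured blocks drawn
#' from the model and five random blocks of uniform i.i.d. items --- in
#' counterbalanced random order. Every trial stream has 10 items.
#'
#' @param model A [build_model()] object.
#' @param session_id Identifier stamped on the trials.
#' @return Data frame in the same layout as [make_training_block()], with
#'   `condition` either `"structured"` or `"random"`.
#' @export
make_test_run <- function(model, session_id = 1L) {
  stopifnot(inherits(model, "markov_model"))
  cond_block <- sample(rep(c("structured", "random"), each = 5L))
  trials <- lapply(seq_along(cond_block), function(b) {
    presented <- if (cond_block[b] == "structured") {
      generate_sequences(model, 2L, 10L)
    } else {
      replicate(2L, paste(make_random_sequence(10L), collapse = ""))
    }
    data.frame(session_id = session_id,
               block_id = b,
               trial_id = 1:2,
               condition = cond_block[b],
               level = model$level,
               presented = presented,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, trials)
}
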
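## Synthetic observers on the probability-matching <-> maximization
## continuum: decayed-count Dirichlet learners with lapses, cohort
## simulation, and the end-to-end parameter-recovery experiment.

#' Configuration of a synthetic observer
#'
#' A synthetic observer learns context-conditional target counts from every
#' within-stream transition of the presented sequences (decayed-count
#' Dirichlet updating) and predicts the next symbol with a policy blending
#' probability matching and probability maximization:
#' with probability `null_rate` no response is recorded (timeout); otherwise
#' with probability `lapse` the response is uniform at random; otherwise
#' with probability `lambda_max` the observer picks the arg-max target of
#' its posterior-mean conditional row (maximization) and with probability
#' `1 - lambda_max` it samples a target from that row (matching).
#' `lambda_max = 0` is an asymptotic probability matcher and
#' `lambda_max = 1` an asymptotic maximizer.
#'
#' @param lambda_max Blend toward maximization, in `[0, 1]`.
#' @param prior_count Dirichlet pseudo-count per (context, target) pair.
#' @param decay Per-trial multiplicative forgetting factor on accumulated
#'   counts, in `(0, 1]`; 1 = no forgetting.
#' @param lapse Probability of a uniform random response.
#' @param null_rate Probability of a null (timeout) response.
#' @param seed Mandatory integer seed; the simulation is deterministic
#'   given the seed and restores the caller's RNG state on exit.
#' @return List of class `agent_config`.
#' @export
agent_config <- function(lambda_max, prior_count = 1, decay = 1,
                         lapse = 0.02, null_rate = 0.01, seed) {
  stopifnot(length(lambda_max) == 1L, lambda_max >= 0, lambda_max <= 1,
            prior_count > 0, decay > 0, decay <= 1,
            lapse >= 0, lapse <= 1, null_rate >= 0, null_rate <= 1)
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory for a synthetic observer", call. = FALSE)
  }
  structure(list(lambda_max = lambda_max, prior_count = prior_count,
                 decay = decay, lapse = lapse, null_rate = null_rate,
                 seed = as.integer(seed)),
            class = "agent_config")
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a synthetic observer over a list of trials
#'
#' Runs the observer of [agent_config()] through the trials in order: for
#' each trial the per-context counts are decayed and updated with all
#' within-stream transitions of the presented stream, then a prediction is
#' emitted for the trial's final context under the blended
#' matching/maximization policy.
#'
#' @param model The generating [build_model()] object.
#' @param trials Trial data frame from [make_training_block()] /
#'   [make_test_run()] (or rows of a read trial log).
#' @param config An [agent_config()].
#' @return The trials with a `response` column appended (`NA` for null
#'   responses).
#' @export
simulate_agent <- function(model, trials, config) {
  stopifnot(inherits(model, "markov_model"),
            inherits(config, "agent_config"))
  k <- model$level
  items <- colnames(model$table)
  contexts <- model$contexts
  ncx <- length(contexts)
  ctx_index <- function(ctx_chr) match(ctx_chr, contexts)

  codes <- lapply(strsplit(trials$presented, ""),
                  function(s) match(s, items))
  ## precompute per-trial transition indices and final context
  pre <- lapply(codes, function(s) {
    n <- length(s)
    pos <- seq.int(k + 1L, n)
    ctx <- if (k == 0L) rep(1L, length(pos)) else if (k == 1L) {
      ctx_index(items[s[pos - 1L]])
    } else {
      ctx_index(paste0(items[s[pos - 2L]], items[s[pos - 1L]]))
    }
    final <- if (k == 0L) 1L else if (k == 1L) {
      ctx_index(items[s[n]])
    } else {
      ctx_index(paste0(items[s[n - 1L]], items[s[n]]))
    }
    if (anyNA(c(ctx, final))) {
      stop("presented stream contains contexts unknown to the model",
           call. = FALSE)
    }
    list(inc = tabulate((ctx - 1L) * 4L + s[pos], ncx * 4L), final = final)
  })

  with_preserved_rng(config$seed, {
    counts <- matrix(config$prior_count, ncx, 4L)
    response <- character(nrow(trials))
    for (i in seq_along(pre)) {
      counts <- config$decay * counts +
        matrix(pre[[i]]$inc, ncx, 4L, byrow = TRUE)
      row <- counts[pre[[i]]$final, ]
      row <- row / sum(row)
      u <- stats::runif(1L)
      response[i] <- if (u < config$null_rate) {
        NA_character_
      } else if (u < config$null_rate + config$lapse) {
        sample(items, 1L)
      } else if (stats::runif(1L) < config$lambda_max) {
        top <- which(abs(row - max(row)) < 1e-12)
        items[if (length(top) == 1L) top else sample(top, 1L)]
      } else {
        sample(items, 1L, prob = row)
      }
    }
    out <- trials
    out$response <- response
    out
  })
}

derive_seeds <- function(master_seed, n) {
  with_preserved_rng(master_seed,
                     sample.int(.Machine$integer.max - 2L, n))
}

#' Simulate a cohort of synthetic observers through the training protocol
#'
#' Generates one trial log per observer covering sequential training on the
#' supplied levels (each observer completes a per-level number of sessions
#' drawn from `sessions_range`, five 56-trial blocks per session, matching
#' the 840--1400 trials-per-level protocol), with per-observer blend
#' parameters `lambda` and reproducible per-(observer, level) seed
#' derivation from `master_seed`: base seeds are drawn from R's RNG seeded
#' with the master seed; each (observer, level) uses its base seed for
#' trial assembly and base seed + 1 for observer behavior.
#'
#' @param seqsets Named list of [select_sequences()] sets, one per trained
#'   level, in training order.
#' @param n_agents Number of observers.
#' @param lambda Vector of `lambda_max` values (recycled) or `NULL` to draw
#'   them uniformly on `[0, 1]`.
#' @param sessions_range Possible sessions per level (default 3:5).
#' @param blocks_per_session,trials_per_block,lengths Block structure.
#' @param master_seed Master seed for the cohort.
#' @param ... Further arguments passed to [agent_config()].
#' @return List with `logs` (one trial-log data frame per observer, levels
#'   concatenated) and `manifest` (data frame: `agent_id`, `lambda`,
#'   `level`, `seed`, `n_sessions`, `n_trials`).
#' @export
simulate_cohort <- function(seqsets, n_agents = 21L, lambda = NULL,
                            sessions_range = 3:5, blocks_per_session = 5L,
                            trials_per_block = 56L, lengths = 8:14,
                            master_seed, ...) {
  stopifnot(all(vapply(seqsets, inherits, logical(1), "sequence_set")))
  if (missing(master_seed)) stop("`master_seed` is mandatory", call. = FALSE)
  n_levels <- length(seqsets)
  base_seeds <- matrix(derive_seeds(master_seed, n_agents * n_levels),
                       n_agents, n_levels)
  draws <- with_preserved_rng(master_seed + 1L, list(
    lambda = if (is.null(lambda)) stats::runif(n_agents) else
      rep_len(lambda, n_agents),
    sessions = matrix(sample(sessions_range, n_agents * n_levels,
                             replace = TRUE), n_agents, n_levels)))

  manifest <- list()
  logs <- vector("list", n_agents)
  for (a in seq_len(n_agents)) {
    agent_log <- list()
    for (l in seq_len(n_levels)) {
      seqset <- seqsets[[l]]
      n_sess <- draws$sessions[a, l]
      base <- base_seeds[a, l]
      trials <- with_preserved_rng(base, {
        do.call(rbind, lapply(seq_len(n_sess), function(s)
          do.call(rbind, lapply(seq_len(blocks_per_session), function(b)
            make_training_block(seqset, trials_per_block, lengths,
                                block_id = b, session_id = s)))))
      })
      cfg <- agent_config(lambda_max = draws$lambda[a],
                          seed = base + 1L, ...)
      agent_log[[l]] <- simulate_agent(seqset$model, trials, cfg)
      manifest[[length(manifest) + 1L]] <- data.frame(
        agent_id = a, lambda = draws$lambda[a],
        level = seqset$model$level, seed = base,
        n_sessions = n_sess, n_trials = nrow(trials))
    }
    logs[[a]] <- do.call(rbind, agent_log)
  }
  list(logs = logs, manifest = do.call(rbind, manifest))
}

#' Parameter-recovery experiment for the strategy index
#'
#' Simulates observers at each blend value of `lambda_grid`, runs the full
#' strategy pipeline (training trials -> synthetic responses -> windowed
#' delta-KL curve -> ICD strategy index), and summarizes how well the index
#' recovers the generating blend: per-lambda mean and SD of the index and
#' the Spearman rank correlation between lambda and index.
#'
#' @param seqset A [select_sequences()] set for the level under study.
#' @param lambda_grid Blend values to simulate.
#' @param n_replicates Seeded replicates per blend value.
#' @param n_trials Training trials per replicate (default 1120, the
#'   mid-range of the 840--1400 protocol).
#' @param window Trials per strategy-curve window.
#' @param trials_per_block,lengths Block structure.
#' @param master_seed Master seed; per-replicate seeds are derived as in
#'   [simulate_cohort()].
#' @param epsilon KL smoothing constant.
#' @param ... Further arguments passed to [agent_config()].
#' @return Data frame of class `recovery_table` (`level`, `lambda`,
#'   `replicate`, `icd`) with a `summary` attribute: per-lambda mean/sd and
#'   `spearman`, the rank correlation between lambda and index.
#' @export
recovery_experiment <- function(seqset, lambda_grid = c(0, 0.25, 0.5, 0.75, 1),
                                n_replicates = 20L, n_trials = 1120L,
                                window = 56L, trials_per_block = 56L,
                                lengths = 8:14, master_seed,
                                epsilon = 1e-6, ...) {
  stopifnot(inherits(seqset, "sequence_set"), length(lambda_grid) >= 1L)
  if (missing(master_seed)) stop("`master_seed` is mandatory", call. = FALSE)
  model <- seqset$model
  n_blocks <- n_trials %/% trials_per_block
  stopifnot(n_blocks * trials_per_block == n_trials)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      lambda = lambda_grid)
  base_seeds <- derive_seeds(master_seed, nrow(grid))

  icd <- vapply(seq_len(nrow(grid)), function(g) {
    base <- base_seeds[g]
    trials <- with_preserved_rng(base, {
      do.call(rbind, lapply(seq_len(n_blocks), function(b)
        make_training_block(seqset, trials_per_block, lengths,
                            block_id = b,
                            session_id = ceiling(b / 5))))
    })
    cfg <- agent_config(lambda_max = grid$lambda[g], seed = base + 1L, ...)
    records <- simulate_agent(model, trials, cfg)
    strategy_index(strategy_curve(records, model, window = window,
                                  epsilon = epsilon))$icd
  }, numeric(1))

  out <- data.frame(level = model$level, lambda = grid$lambda,
                    replicate = grid$replicate, icd = icd)
  means <- tapply(out$icd, out$lambda, mean)
  sds <- tapply(out$icd, out$lambda, stats::sd)
  summary <- list(
    by_lambda = data.frame(lambda = as.numeric(names(means)),
                           mean_icd = as.numeric(means),
                           sd_icd = as.numeric(sds)),
    spearman = stats::cor(out$lambda, out$icd, method = "spearman"))
  structure(out, class = c("recovery_table", "data.frame"),
            summary = summary)
}

#' @export
print.recovery_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Strategy-index recovery, level-%d (%d runs)\n",
              x$level[1L], nrow(x)))
  print(s$by_lambda, row.names = FALSE)
  cat(sprintf("Spearman rho(lambda, index) = %.3f\n", s$spearman))
  invisible(x)
}
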
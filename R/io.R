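## Trial-log / sequence-set / score / strategy file formats, run
## configuration, and the end-to-end pipeline.
##
## CSV dialect: comma-separated, UTF-8, mandatory header row, no quoting
## (item strings are [A-D]+). Null responses are empty cells.

trial_log_columns <- c("session_id", "block_id", "trial_id", "condition",
                       "level", "presented", "response")

#' Read and write trial logs
#'
#' A trial log records one prediction trial per row: columns `session_id`,
#' `block_id`, `trial_id`, `condition` (`structured`/`random`), `level`,
#' `presented` (collapsed item string), `response` (single item; empty for
#' a null response) and optionally `rt_ms`. Reading validates the layout:
#' missing columns, item letters outside A--D, and duplicated trial ids
#' within a block are hard errors naming the offending row.
#'
#' @param path File path.
#' @param records Trial records as produced by [simulate_agent()].
#' @return `read_trial_log()`: data frame of records in file order with
#'   `response` equal to `NA` for null responses.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such trial log: ", path, call. = FALSE)
  log <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(trial_log_columns, names(log))
  if (length(missing)) {
    stop("trial log ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  log$response[log$response == ""] <- NA_character_
  log$level <- as.integer(log$level)
  for (col in c("session_id", "block_id", "trial_id")) {
    suppressWarnings(num <- as.integer(log[[col]]))
    if (!anyNA(num)) log[[col]] <- num
  }
  if ("rt_ms" %in% names(log)) {
    log$rt_ms <- suppressWarnings(as.numeric(log$rt_ms))
  }
  bad <- which(!grepl("^[A-D]+$", log$presented))
  if (length(bad)) {
    stop(sprintf("trial log %s: invalid item letters in `presented` at row %d",
                 path, bad[1L]), call. = FALSE)
  }
  bad <- which(!(is.na(log$response) | log$response %in% sl_items))
  if (length(bad)) {
    stop(sprintf("trial log %s: invalid `response` at row %d", path, bad[1L]),
         call. = FALSE)
  }
  key <- paste(log$level, log$session_id, log$block_id, log$trial_id)
  if (anyDuplicated(key)) {
    stop(sprintf("trial log %s: duplicate trial_id within block at row %d",
                 path, anyDuplicated(key)), call. = FALSE)
  }
  log
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(records, path) {
  validate_records(records)
  out <- records
  out$response[is.na(out$response)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write selected sequence sets
#'
#' The CSV variant has columns `sequence_id`, `kl_score`, `sequence`. The
#' plain-text variant has one sequence per line preceded by a `#` header
#' comment carrying the model level, the KL range and an optional seed tag.
#'
#' @param seqset A [select_sequences()] object.
#' @param path File path.
#' @param format `"csv"` or `"txt"`.
#' @param seed_tag Optional seed annotation written into the `txt` header.
#' @return `read_sequence_set()`: a data frame (`sequence_id`, `kl_score`,
#'   `sequence`).
#' @export
write_sequence_set <- function(seqset, path, format = c("csv", "txt"),
                               seed_tag = NA) {
  stopifnot(inherits(seqset, "sequence_set"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(sequence_id = seq_along(seqset$sequences),
                                kl_score = seqset$kl,
                                sequence = seqset$sequences),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    header <- sprintf("# level-%d model; %d sequences of %d items; kl %.6g..%.6g; seed=%s",
                      seqset$model$level, length(seqset$sequences),
                      seqset$length, min(seqset$kl), max(seqset$kl),
                      as.character(seed_tag))
    writeLines(c(header, seqset$sequences), path)
  }
  invisible(path)
}

#' @rdname write_sequence_set
#' @export
read_sequence_set <- function(path) {
  utils::read.csv(path, colClasses = c(sequence_id = "integer",
                                       kl_score = "numeric",
                                       sequence = "character"))
}

#' Default run configuration
#'
#' All defaults equal the training-protocol parameters: three levels with
#' occurrence probabilities 0.18/0.72/0.05/0.05 (level 0) and conditional
#' probabilities 0.8/0.2 (levels 1--2); candidate pools of 10,000 sequences
#' of 672 items from which the 50 lowest-KL are selected; 56-trial blocks
#' of stream lengths 8--14, five blocks per session, three to five sessions
#' per level; 21 observers; 56-trial strategy windows; smoothing
#' epsilon 1e-6; natural logarithms.
#'
#' @param seed Master seed for the run.
#' @return Nested list of class `run_config`; round-trips losslessly
#'   through [write_run_config()] / [read_run_config()].
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    levels = c(0L, 1L, 2L),
    level0_probs = c(0.18, 0.72, 0.05, 0.05),
    high_p = 0.8,
    sequences = list(n_generate = 10000L, length = 672L, n_select = 50L),
    blocks = list(trials_per_block = 56L, blocks_per_session = 5L,
                  lengths = 8:14, sessions_range = 3:5),
    cohort = list(n_agents = 21L, prior_count = 1, decay = 1,
                  lapse = 0.02, null_rate = 0.01),
    strategy = list(window = 56L, epsilon = 1e-6, log_base = "e"),
    recovery = list(enabled = TRUE, lambda_grid = c(0, 0.25, 0.5, 0.75, 1),
                    n_replicates = 20L, n_trials = 1120L)),
    class = "run_config")
}

#' @rdname default_run_config
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @rdname default_run_config
#' @export
validate_run_config <- function(config) {
  p <- config$level0_probs
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("config: `level0_probs` must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  if (config$high_p < 0 || config$high_p > 1) {
    stop("config: `high_p` must be a probability", call. = FALSE)
  }
  with(config$sequences, if (n_select > n_generate)
    stop("config: n_select exceeds n_generate", call. = FALSE))
  with(config$blocks, if (trials_per_block %% length(lengths) != 0L)
    stop("config: trials_per_block not divisible by number of lengths",
         call. = FALSE))
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full design -> simulate -> score -> strategy pipeline
#'
#' Executes every stage of the workflow under one configuration: builds the
#' per-level models, selects presentation sequence sets, simulates a cohort
#' of synthetic observers, scores performance per block, computes strategy
#' curves and indices (including the pooled context-based index), and
#' optionally runs the parameter-recovery experiment. All outputs are
#' written as CSV under `out_dir` together with a deterministic run log
#' carrying the resolved configuration, its MD5 hash and the master seed.
#' Reruns with the same configuration produce byte-identical outputs.
#'
#' @param config A [default_run_config()]-style list.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the written file paths and the in-memory
#'   result objects (`models`, `seqsets`, `cohort`, `scores`, `strategy`,
#'   `recovery`).
#' @export
run_full_pipeline <- function(config = default_run_config(), out_dir) {
  config <- stage("config", validate_run_config(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "logs"), showWarnings = FALSE)
  hash <- config_hash(config)

  models <- stage("models", {
    ms <- lapply(config$levels, function(l)
      build_model(l, level0_probs = config$level0_probs,
                  high_p = config$high_p))
    names(ms) <- paste0("level", config$levels)
    ms
  })

  seqsets <- stage("sequence sets", {
    ss <- lapply(seq_along(models), function(i) {
      with_preserved_rng(config$seed + i,
        select_sequences(models[[i]],
                         n_generate = config$sequences$n_generate,
                         length = config$sequences$length,
                         n_select = config$sequences$n_select,
                         epsilon = config$strategy$epsilon))
    })
    names(ss) <- names(models)
    for (i in seq_along(ss)) {
      write_sequence_set(ss[[i]],
                         file.path(out_dir, paste0("sequences_",
                                                   names(ss)[i], ".csv")))
    }
    ss
  })

  cohort <- stage("cohort", {
    co <- simulate_cohort(seqsets,
                          n_agents = config$cohort$n_agents,
                          sessions_range = config$blocks$sessions_range,
                          blocks_per_session = config$blocks$blocks_per_session,
                          trials_per_block = config$blocks$trials_per_block,
                          lengths = config$blocks$lengths,
                          master_seed = config$seed,
                          prior_count = config$cohort$prior_count,
                          decay = config$cohort$decay,
                          lapse = config$cohort$lapse,
                          null_rate = config$cohort$null_rate)
    for (a in seq_along(co$logs)) {
      write_trial_log(co$logs[[a]],
                      file.path(out_dir, "logs",
                                sprintf("agent_%02d.csv", a)))
    }
    utils::write.csv(co$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    co
  })

  scores <- stage("scoring", {
    rows <- list()
    for (a in seq_along(cohort$logs)) {
      log <- cohort$logs[[a]]
      for (lv in unique(log$level)) {
        rep <- score_session(log[log$level == lv, , drop = FALSE],
                             models[[paste0("level", lv)]])
        blk <- rep$blocks
        blk$agent_id <- a
        blk$level <- lv
        rows[[length(rows) + 1L]] <- blk
      }
    }
    sc <- do.call(rbind, rows)
    sc <- sc[, c("agent_id", "level", "session_id", "block_id", "n_used",
                 "n_null", "n_dropped", "pi", "pi_rand", "pi_normalized")]
    utils::write.csv(sc, file.path(out_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    sc
  })

  strategy <- stage("strategy", {
    win_rows <- list()
    idx_rows <- list()
    for (a in seq_along(cohort$logs)) {
      log <- cohort$logs[[a]]
      per_level <- list()
      for (lv in unique(log$level)) {
        curve <- strategy_curve(log[log$level == lv, , drop = FALSE],
                                models[[paste0("level", lv)]],
                                window = config$strategy$window,
                                epsilon = config$strategy$epsilon)
        idx <- strategy_index(curve)
        per_level[[as.character(lv)]] <- idx
        win_rows[[length(win_rows) + 1L]] <-
          data.frame(agent_id = a, level = lv,
                     window_id = curve$window_id,
                     delta_kl = curve$delta_kl,
                     reference = curve$reference)
        idx_rows[[length(idx_rows) + 1L]] <-
          data.frame(agent_id = a, level = as.character(lv), icd = idx$icd)
      }
      if (all(c("1", "2") %in% names(per_level))) {
        pooled <- pooled_context_index(per_level[["1"]], per_level[["2"]])
        idx_rows[[length(idx_rows) + 1L]] <-
          data.frame(agent_id = a, level = "pooled", icd = pooled$icd)
      }
    }
    windows <- do.call(rbind, win_rows)
    indices <- do.call(rbind, idx_rows)
    utils::write.csv(windows, file.path(out_dir, "strategy_windows.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(indices, file.path(out_dir, "strategy_index.csv"),
                     row.names = FALSE, quote = FALSE)
    list(windows = windows, indices = indices)
  })

  recovery <- NULL
  if (isTRUE(config$recovery$enabled)) {
    recovery <- stage("recovery", {
      lvl <- if ("level1" %in% names(seqsets)) "level1" else names(seqsets)[1L]
      rec <- recovery_experiment(seqsets[[lvl]],
                                 lambda_grid = config$recovery$lambda_grid,
                                 n_replicates = config$recovery$n_replicates,
                                 n_trials = config$recovery$n_trials,
                                 window = config$strategy$window,
                                 trials_per_block = config$blocks$trials_per_block,
                                 lengths = config$blocks$lengths,
                                 master_seed = config$seed + 1000L,
                                 epsilon = config$strategy$epsilon,
                                 prior_count = config$cohort$prior_count,
                                 decay = config$cohort$decay,
                                 lapse = config$cohort$lapse,
                                 null_rate = config$cohort$null_rate)
      utils::write.csv(as.data.frame(rec),
                       file.path(out_dir, "recovery.csv"),
                       row.names = FALSE, quote = FALSE)
      rec
    })
  }

  stage("run log", {
    cfg_lines <- utils::capture.output(utils::str(unclass(config)))
    writeLines(c(
      sprintf("seqstrat run"),
      sprintf("package version: %s",
              as.character(utils::packageVersion("seqstrat"))),
      sprintf("master seed: %d", config$seed),
      sprintf("config md5: %s", hash),
      "resolved configuration:", cfg_lines),
      file.path(out_dir, "run_log.txt"))
  })

  invisible(list(out_dir = out_dir, config_hash = hash, models = models,
                 seqsets = seqsets, cohort = cohort, scores = scores,
                 strategy = strategy, recovery = recovery))
}
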
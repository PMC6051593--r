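## Matching vs maximization baselines, the delta-KL strategy-choice
## statistic, windowed strategy curves, and the integral-curve-difference
## (ICD) strategy index.

#' Matching and maximization baseline models
#'
#' Two reference response profiles against which an observer's response
#' distribution is compared: *probability matching* reproduces the
#' generating model's conditional target distributions exactly, while
#' *probability maximization* puts all response mass on the most likely
#' target of each context (mass split equally among tied maxima, which
#' cannot occur under the 0.8/0.2 design but matters for custom models).
#'
#' @param model A [build_model()] object.
#' @return List of class `baseline_models` with matrices `matching` and
#'   `maximization` (contexts x items) and the model's `context_weights`.
#' @examples
#' baseline_models(build_model(0))$maximization  # all mass on item B
#' @export
baseline_models <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  maxi <- t(apply(model$table, 1L, function(row) {
    top <- abs(row - max(row)) < 1e-12
    ifelse(top, 1 / sum(top), 0)
  }))
  dimnames(maxi) <- dimnames(model$table)
  structure(list(matching = model$table,
                 maximization = maxi,
                 context_weights = model$context_weights),
            class = "baseline_models")
}

#' KL divergence from a baseline model to a response distribution
#'
#' `sum_c M(c) sum_t M(t|c) log(M(t|c) / R(t|c))` for conditional designs
#' (reducing to the unconditional sum for level 0), where M is a baseline
#' model (matching or maximization), R the observed response table, and
#' M(c) the model's stationary context weights. The response table is
#' epsilon-smoothed and renormalized before entering the denominator;
#' contexts absent from R contribute through the smoothed uniform floor.
#' The `direction` flag reverses numerator and denominator for sensitivity
#' analyses.
#'
#' @param M Baseline model table (contexts x items).
#' @param R Response table; rows need not cover all model contexts.
#' @param weights Context weights aligned with the rows of `M`.
#' @param epsilon Additive smoothing for the denominator distribution.
#' @param base Logarithm base (natural log by default).
#' @param direction `"model_to_response"` places M in the numerator
#'   (default); `"response_to_model"` reverses the divergence.
#' @return Non-negative scalar divergence.
#' @export
kl_model_to_response <- function(M, R, weights, epsilon = 1e-6,
                                 base = exp(1),
                                 direction = c("model_to_response",
                                               "response_to_model")) {
  direction <- match.arg(direction)
  if (direction == "model_to_response") {
    kl_cond(M, R, weights, epsilon = epsilon, base = base)
  } else {
    ## align R to M's contexts; contexts without responses carry no mass
    ## information and enter as uniform rows
    aligned <- matrix(1 / ncol(M), nrow(M), ncol(M), dimnames = dimnames(M))
    common <- intersect(rownames(M), rownames(R))
    aligned[match(common, rownames(M)), ] <-
      R[match(common, rownames(R)), match(colnames(M), colnames(R)),
        drop = FALSE]
    kl_cond(aligned, M, weights, epsilon = epsilon, base = base)
  }
}

#' Strategy choice: delta-KL between the two baseline comparisons
#'
#' `delta KL = KL(matching || R) - KL(maximization || R)`: the difference
#' between the divergence of the response distribution R from the
#' probability-matching baseline and from the probability-maximization
#' baseline. The orientation makes larger values indicate responding closer
#' to maximization; an exact matcher scores the (negative) constant
#' `-KL(maximization || matching)` returned by [matcher_reference()].
#'
#' @param R Response table (contexts x items).
#' @param model The generating [build_model()] object.
#' @inheritParams kl_model_to_response
#' @return Scalar delta-KL.
#' @export
strategy_choice <- function(R, model, epsilon = 1e-6, base = exp(1)) {
  stopifnot(inherits(model, "markov_model"))
  bm <- baseline_models(model)
  kl_model_to_response(bm$matching, R, bm$context_weights,
                       epsilon = epsilon, base = base) -
    kl_model_to_response(bm$maximization, R, bm$context_weights,
                         epsilon = epsilon, base = base)
}

#' Reference delta-KL of an exact probability matcher
#'
#' The constant value of [strategy_choice()] when the response distribution
#' equals the matching baseline itself; the strategy curve of an exact
#' matcher sits at this value in every window, and the strategy index
#' subtracts it out.
#'
#' @inheritParams strategy_choice
#' @return Scalar reference delta-KL.
#' @export
matcher_reference <- function(model, epsilon = 1e-6, base = exp(1)) {
  strategy_choice(baseline_models(model)$matching, model,
                  epsilon = epsilon, base = base)
}

new_strategy_curve <- function(window_id, delta_kl, reference, model,
                               window) {
  structure(data.frame(window_id = window_id, delta_kl = delta_kl,
                       reference = reference),
            class = c("strategy_curve", "data.frame"),
            level = model$level, window = window)
}

#' Windowed strategy curve of a trial log
#'
#' Splits the trials into consecutive non-overlapping windows (default 56
#' trials, one training block), estimates the per-context response
#' distribution within each window, and computes the [strategy_choice()]
#' delta-KL per window. `strategy_curve_from_tables()` accepts
#' precomputed window-level response tables instead (e.g. noise-free
#' distributional profiles).
#'
#' @param records Trial records in presentation order.
#' @param model The generating [build_model()] object.
#' @param window Trials per window.
#' @param tables List of response tables, one per window.
#' @inheritParams kl_model_to_response
#' @return A `strategy_curve` data frame with columns `window_id`,
#'   `delta_kl` and the constant matcher `reference`.
#' @export
strategy_curve <- function(records, model, window = 56L, epsilon = 1e-6,
                           base = exp(1)) {
  stopifnot(inherits(model, "markov_model"))
  validate_records(records)
  n_win <- nrow(records) %/% window
  if (n_win < 1L) {
    stop("fewer trials than one window", call. = FALSE)
  }
  deltas <- vapply(seq_len(n_win), function(w) {
    ix <- seq.int((w - 1L) * window + 1L, w * window)
    R <- response_tables(records[ix, , drop = FALSE], model$level)$p_resp
    strategy_choice(R, model, epsilon = epsilon, base = base)
  }, numeric(1))
  new_strategy_curve(seq_len(n_win), deltas,
                     matcher_reference(model, epsilon, base),
                     model, window)
}

#' @rdname strategy_curve
#' @export
strategy_curve_from_tables <- function(tables, model, epsilon = 1e-6,
                                       base = exp(1)) {
  stopifnot(inherits(model, "markov_model"), length(tables) >= 1L)
  deltas <- vapply(tables, strategy_choice, numeric(1), model = model,
                   epsilon = epsilon, base = base)
  new_strategy_curve(seq_along(deltas), deltas,
                     matcher_reference(model, epsilon, base),
                     model, NA_integer_)
}

#' Integral-curve-difference strategy index
#'
#' The strategy index is the integral of the observer's strategy curve
#' minus the integral of the exact-matching reference curve, both taken
#' over the window axis normalized to `[0, 1]` (trapezoidal rule; for a
#' single window the index degenerates to `delta_kl - reference`). By
#' construction the index is 0 for an exact matcher and grows positive as
#' responding shifts toward maximization.
#'
#' @param curve A [strategy_curve()] object.
#' @return Object of class `strategy_index`: list with `icd`, `level` and
#'   `n_windows`.
#' @export
strategy_index <- function(curve) {
  stopifnot(inherits(curve, "strategy_curve"), nrow(curve) >= 1L)
  n <- nrow(curve)
  icd <- if (n == 1L) {
    curve$delta_kl - curve$reference
  } else {
    x <- seq(0, 1, length.out = n)
    pracma::trapz(x, curve$delta_kl) - pracma::trapz(x, curve$reference)
  }
  structure(list(icd = icd, level = attr(curve, "level"), n_windows = n),
            class = "strategy_index")
}

#' Pool strategy indices across the conditional levels
#'
#' The indices of the two context-based designs (levels 1 and 2) are highly
#' correlated across observers and are combined into a single
#' context-based-statistics index by arithmetic mean.
#'
#' @param index_l1,index_l2 [strategy_index()] objects.
#' @return A `strategy_index` with `level = "pooled"`.
#' @export
pooled_context_index <- function(index_l1, index_l2) {
  stopifnot(inherits(index_l1, "strategy_index"),
            inherits(index_l2, "strategy_index"))
  structure(list(icd = mean(c(index_l1$icd, index_l2$icd)),
                 level = "pooled",
                 n_windows = NA_integer_),
            class = "strategy_index")
}

#' @export
print.strategy_index <- function(x, ...) {
  cat(sprintf("Strategy index (ICD): %.4f  [level %s, %s window%s]\n",
              x$icd, as.character(x$level),
              ifelse(is.na(x$n_windows), "-", x$n_windows),
              ifelse(identical(x$n_windows, 1L), "", "s")))
  invisible(x)
}
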
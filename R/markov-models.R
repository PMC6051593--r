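#' @keywords internal
"_PACKAGE"

## Canonical item labels. Concrete stimulus glyphs are assigned to items at
## the I/O boundary via the `permutation` argument of `build_model()`.
sl_items <- c("A", "B", "C", "D")

## Level-1 cyclic successor skeleton: each item allows exactly two
## successors, the next item (high probability) and the one after (low).
sl_succ_high <- c(A = "B", B = "C", C = "D", D = "A")
sl_succ_low  <- c(A = "C", B = "D", C = "A", D = "B")

#' Construct an order-k Markov stimulus model
#'
#' Builds the context-conditional target distributions used to generate
#' probabilistic symbol sequences over the four items A--D.
#'
#' * **Level 0** is a memoryless source: one row of unconditional occurrence
#'   probabilities (default `0.18, 0.72, 0.05, 0.05`), so that two items
#'   dominate and two are rare.
#' * **Level 1** conditions on the previous item. Each of the four contexts
#'   allows exactly two successor items, one with probability `high_p`
#'   (default 0.8) and one with `low_p`. The canonical topology is cyclic:
#'   A -> \{B: high, C: low\}, B -> \{C, D\}, C -> \{D, A\}, D -> \{A, B\}.
#' * **Level 2** conditions on the previous two items. Its contexts are the
#'   eight ordered pairs realisable under the level-1 skeleton, and each
#'   context again allows the two skeleton successors of its last item.
#'   The high/low assignment is flipped whenever the context's own last
#'   transition was the high-probability edge, so the target distribution
#'   genuinely depends on both items of the context and the induced context
#'   chain is ergodic. (A four-symbol order-2 design with support-2 rows
#'   necessarily has at least eight recurrent contexts; see the methods
#'   vignette.)
#'
#' By construction every conditional row has the same two-point shape across
#' levels 1 and 2, so memory-conditional uncertainty is equal across levels
#' and the levels differ only in context length.
#'
#' @param level Integer order k of the model: 0, 1 or 2.
#' @param level0_probs Numeric vector of 4 occurrence probabilities for the
#'   canonical items A--D (level 0 only). Must sum to 1.
#' @param high_p,low_p Conditional probabilities of the likely and unlikely
#'   successor (levels 1 and 2). Must sum to 1.
#' @param permutation Character permutation of `c("A","B","C","D")` mapping
#'   canonical items to presented item labels, used to counterbalance the
#'   item/symbol correspondence across observers. `permutation[i]` is the
#'   label presented for canonical item i.
#' @return An object of class `markov_model`: a list with elements `level`,
#'   `items`, `contexts` (character vector; `""` for level 0), `table`
#'   (matrix of contexts x 4 target probabilities) and `context_weights`
#'   (stationary distribution of the induced context chain).
#' @examples
#' m1 <- build_model(1)
#' m1$table["A", ]          # B follows A with probability 0.8, C with 0.2
#' build_model(0)$table     # occurrence probabilities 0.18/0.72/0.05/0.05
#' @seealso [stationary_context_distribution()], [generate_sequence()]
#' @export
build_model <- function(level,
                        level0_probs = c(0.18, 0.72, 0.05, 0.05),
                        high_p = 0.8,
                        low_p = 1 - high_p,
                        permutation = sl_items) {
  if (!is.numeric(level) || length(level) != 1L || !(level %in% 0:2)) {
    stop("`level` must be 0, 1 or 2", call. = FALSE)
  }
  level <- as.integer(level)
  if (length(permutation) != 4L || !setequal(permutation, sl_items)) {
    stop("`permutation` must be a permutation of A, B, C, D", call. = FALSE)
  }

  if (level == 0L) {
    if (length(level0_probs) != 4L || any(level0_probs < 0) ||
        abs(sum(level0_probs) - 1) > 1e-9) {
      stop("`level0_probs` must be 4 non-negative values summing to 1",
           call. = FALSE)
    }
    table <- matrix(level0_probs, nrow = 1,
                    dimnames = list("", sl_items))
  } else {
    if (any(c(high_p, low_p) < 0) || abs(high_p + low_p - 1) > 1e-9) {
      stop("`high_p` and `low_p` must be non-negative and sum to 1",
           call. = FALSE)
    }
    if (level == 1L) {
      contexts <- sl_items
      table <- matrix(0, 4, 4, dimnames = list(contexts, sl_items))
      for (x in contexts) {
        table[x, sl_succ_high[[x]]] <- high_p
        table[x, sl_succ_low[[x]]] <- low_p
      }
    } else {
      ## contexts = edges (x, y) of the level-1 skeleton
      contexts <- character(0)
      rows <- list()
      for (x in sl_items) {
        for (y in c(sl_succ_high[[x]], sl_succ_low[[x]])) {
          ctx <- paste0(x, y)
          row <- stats::setNames(numeric(4), sl_items)
          if (y == sl_succ_high[[x]]) {
            ## arrived via the high edge: flip the assignment
            row[sl_succ_low[[y]]] <- high_p
            row[sl_succ_high[[y]]] <- low_p
          } else {
            row[sl_succ_high[[y]]] <- high_p
            row[sl_succ_low[[y]]] <- low_p
          }
          contexts <- c(contexts, ctx)
          rows[[ctx]] <- row
        }
      }
      table <- do.call(rbind, rows)
      dimnames(table) <- list(contexts, sl_items)
    }
  }

  ## relabel canonical items by the counterbalancing permutation
  map <- stats::setNames(permutation, sl_items)
  colnames(table) <- unname(map[colnames(table)])
  rownames(table) <- vapply(rownames(table), function(ctx) {
    if (ctx == "") "" else
      paste(map[strsplit(ctx, "")[[1]]], collapse = "")
  }, character(1))
  table <- table[order(rownames(table)), order(colnames(table)), drop = FALSE]

  model <- structure(
    list(level = level,
         items = sl_items,
         contexts = rownames(table),
         table = table,
         context_weights = NULL),
    class = "markov_model")
  model$context_weights <- stationary_context_distribution(model)
  validate_model(model)
  model
}

validate_model <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  tab <- model$table
  if (any(abs(rowSums(tab) - 1) > 1e-12)) {
    stop("model rows must sum to 1 (tolerance 1e-12)", call. = FALSE)
  }
  if (model$level >= 1L && any(rowSums(tab > 0) != 2L)) {
    stop("order >= 1 model rows must have exactly two nonzero entries",
         call. = FALSE)
  }
  w <- model$context_weights
  if (!is.null(w) && (any(w < 0) || abs(sum(w) - 1) > 1e-9)) {
    stop("context weights must be a probability vector", call. = FALSE)
  }
  invisible(model)
}

## Transition matrix of the induced context chain: entry (c, c') is the
## probability that context c' follows context c after emitting one target.
context_transition_matrix <- function(model) {
  contexts <- model$contexts
  n <- length(contexts)
  tm <- matrix(0, n, n, dimnames = list(contexts, contexts))
  k <- model$level
  for (ci in seq_len(n)) {
    ctx <- contexts[ci]
    for (t in model$items) {
      p <- model$table[ci, t]
      if (p <= 0) next
      nxt <- if (k == 0L) "" else
        paste0(substr(ctx, 2L, k), t)  # drop oldest item, append target
      cj <- match(nxt, contexts)
      if (is.na(cj)) {
        stop(sprintf("target %s from context '%s' leaves the context set",
                     t, ctx), call. = FALSE)
      }
      tm[ci, cj] <- tm[ci, cj] + p
    }
  }
  tm
}

#' Stationary distribution of a model's context chain
#'
#' Solves pi = pi T for the transition operator T of the induced context
#' chain (the chain whose state is the k most recent items). These weights
#' enter the KL divergence of a sequence to its ideal model and the
#' context-weighted overall performance index.
#'
#' @param model A [build_model()] object.
#' @return Named probability vector over `model$contexts` (a single weight
#'   of 1 on the empty context for level 0).
#' @details The chain must be irreducible over the model's context set; if
#'   some contexts cannot be reached from others the function stops and
#'   names the unreachable contexts.
#' @examples
#' stationary_context_distribution(build_model(1))  # uniform over A-D
#' @export
stationary_context_distribution <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  contexts <- model$contexts
  n <- length(contexts)
  if (n == 1L) {
    return(stats::setNames(1, contexts))
  }
  tm <- context_transition_matrix(model)

  ## irreducibility check by breadth-first reachability from context 1,
  ## forward and backward
  reach <- function(adj) {
    seen <- rep(FALSE, n)
    seen[1L] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  ok <- reach(tm) & reach(t(tm))
  if (!all(ok)) {
    stop("context chain is not ergodic; unreachable contexts: ",
         paste(contexts[!ok], collapse = ", "), call. = FALSE)
  }

  ## solve pi (T - I) = 0 with sum(pi) = 1
  a <- t(tm) - diag(n)
  a[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- solve(a, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  stats::setNames(pi / sum(pi), contexts)
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov stimulus model, order k = %d (%d context%s)\n",
              x$level, length(x$contexts),
              if (length(x$contexts) == 1L) "" else "s"))
  print(round(x$table, 3))
  cat("context weights:\n")
  print(round(x$context_weights, 4))
  invisible(x)
}
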
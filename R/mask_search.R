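#' Bi-level masked minimizer optimization (greedy mask pruning)
#'
#' Outer loop of the sketch optimizer.  Starting from the full mask
#' `v = [0, w-1]`, the ordering is trained (inner loop) and the GSS of
#' the resulting scheme recorded; then, repeatedly, every set offset is
#' tentatively pruned, the ordering retrained for each candidate, and
#' the best strictly-improving pruned mask accepted.  The search stops
#' when no candidate improves GSS or the mask is empty.  Sibling trials
#' at one depth share the training seed and held-out homolog panel
#' (common random numbers), so GSS differences reflect the masks.
#' The inner loop runs at most `w(w+1)/2 + 1` times.
#'
#' @inheritParams train_ordering
#' @param evaluator optional function `mask -> list(gss = , fit = )`
#'   replacing the default inner loop (used for cheap or mock
#'   evaluations); the default trains with [train_ordering()] under
#'   `config`.
#' @return an object of class `mask_search`: `best_mask`, `best_gss`,
#'   `best_fit`, the trial log `trials` (mask, bits set, depth, GSS,
#'   accepted flag) and the inner-loop call count `n_evals`.
#' @export
greedy_prune <- function(seq, w, k, loss = "gss", config = train_config(),
                         evaluator = NULL) {
  w <- as.integer(w)
  stopifnot(w >= 1)
  if (is.null(evaluator)) {
    evaluator <- function(mask) {
      fit <- train_ordering(seq, w, k, mask = mask, loss = loss,
                            config = config)
      list(gss = fit$metrics$gss, fit = fit)
    }
  }
  trials <- list()
  n_evals <- 0L
  log_trial <- function(mask, gss_val, depth, accepted) {
    trials[[length(trials) + 1L]] <<- data.frame(
      mask = format_mask(mask), n_bits = length(mask$bits),
      depth = depth, gss = gss_val, accepted = accepted,
      stringsAsFactors = FALSE)
  }

  best_gss <- 0
  mask <- minimizer_mask(w)
  res <- evaluator(mask)
  n_evals <- n_evals + 1L
  cur_gss <- res$gss
  best_fit <- res$fit
  best_mask <- mask
  log_trial(mask, cur_gss, 0L, TRUE)
  depth <- 0L

  while (cur_gss > best_gss && length(mask$bits) > 0L) {
    best_gss <- cur_gss
    best_mask <- mask
    depth <- depth + 1L
    round_best_mask <- mask
    round_best_fit <- best_fit
    improved <- FALSE
    for (offset in mask$bits) {
      trial_mask <- new_mask(setdiff(mask$bits, offset), w)
      tr <- evaluator(trial_mask)
      n_evals <- n_evals + 1L
      accept <- tr$gss > cur_gss  # strict improvement; ties keep the
                                  # earlier (smallest pruned offset) mask
      log_trial(trial_mask, tr$gss, depth, accept)
      if (accept) {
        cur_gss <- tr$gss
        round_best_mask <- trial_mask
        round_best_fit <- tr$fit
        improved <- TRUE
      }
    }
    mask <- round_best_mask
    if (improved) {
      best_fit <- round_best_fit
      best_mask <- round_best_mask
    }
  }

  out <- list(best_mask = best_mask, best_gss = max(best_gss, cur_gss),
              best_fit = best_fit, trials = do.call(rbind, trials),
              n_evals = n_evals, w = w, k = k)
  class(out) <- "mask_search"
  out
}

#' @export
print.mask_search <- function(x, ...) {
  cat(sprintf("Greedy mask search (w = %d): best mask %s, GSS %.4f\n",
              x$w, format_mask(x$best_mask), x$best_gss))
  cat(sprintf("  %d inner-loop evaluations over %d depth levels\n",
              x$n_evals, max(x$trials$depth)))
  invisible(x)
}

#' @export
plot.mask_search <- function(x, ...) {
  tr <- x$trials
  graphics::plot(seq_len(nrow(tr)), tr$gss, pch = ifelse(tr$accepted, 19, 1),
                 col = ifelse(tr$accepted, "#0072B2", "grey50"),
                 xlab = "trial", ylab = "GSS", ...)
  graphics::legend("bottomleft", legend = c("accepted", "rejected"),
                   pch = c(19, 1), col = c("#0072B2", "grey50"), bty = "n")
  invisible(x)
}

#' Evaluate every non-empty mask of width w
#'
#' Exhaustive sweep over all `2^w - 1` non-empty qualifying subsets.
#' By default each mask is scored with a fixed ordering and a shared
#' homolog panel (common random numbers), so the resulting table obeys
#' the subset-monotonicity of density and conservation exactly; with
#' `train = TRUE` the ordering is retrained per mask (same seed).
#'
#' @inheritParams train_ordering
#' @param train retrain the ordering for every mask (expensive).
#' @param ordering fixed ordering used when `train = FALSE`; default a
#'   seeded random ordering.
#' @param evaluator optional function `mask -> named list/row` with at
#'   least `density`, `conservation`, `coverage`, `gss`, overriding
#'   both built-in evaluation modes.
#' @param max_w refuse wider masks than this (the sweep is exponential
#'   in `w`).
#' @return `data.frame` with one row per mask: `mask`, `n_bits`,
#'   `density`, `conservation`, `coverage`, `gss`.
#' @export
exhaustive_mask_sweep <- function(seq, w, k, loss = "gss",
                                  config = train_config(), train = FALSE,
                                  ordering = NULL, evaluator = NULL,
                                  max_w = 12L) {
  w <- as.integer(w)
  if (w > max_w)
    stop(sprintf("w = %d too large for an exhaustive sweep (2^w masks); max_w = %d",
                 w, max_w))
  if (is.null(evaluator)) {
    if (train) {
      evaluator <- function(mask) {
        fit <- train_ordering(seq, w, k, mask = mask, loss = loss,
                              config = config)
        fit$metrics[, c("density", "conservation", "coverage", "gss")]
      }
    } else {
      if (is.null(ordering)) ordering <- random_ordering(k, seed = config$seed)
      homologs <- draw_homologs(as_dna(seq), n = config$eval_n_homologs,
                                rate = config$rate, seed = config$seed + 1L)
      evaluator <- function(mask) {
        sketch_metrics(seq, w, k, mask, ordering, homologs = homologs
                       )[, c("density", "conservation", "coverage", "gss")]
      }
    }
  }
  masks <- lapply(seq_len(2^w - 1L), function(b) {
    bits <- which(bitwAnd(b, 2L^(0:(w - 1L))) > 0L) - 1L
    new_mask(bits, w)
  })
  rows <- lapply(masks, function(m) {
    r <- as.data.frame(evaluator(m))
    cbind(data.frame(mask = format_mask(m), n_bits = length(m$bits),
                     stringsAsFactors = FALSE), r)
  })
  do.call(rbind, rows)
}
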
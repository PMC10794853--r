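#' Training configuration for the ordering optimizer
#'
#' @param lambda_reg regularization weight in the density loss.
#' @param lambda_con conservation weight in the combined loss
#'   (default 1).
#' @param n_homologs mutated copies drawn per epoch for the conservation
#'   term (redrawn each epoch, so the term is an unbiased stochastic
#'   estimate of the expectation over the substitution model).
#' @param epochs gradient steps.
#' @param batch_span bases per sampled training subsequence.
#' @param learning_rate Adam step size.
#' @param hidden priority-model hidden width.
#' @param tau softmin temperature of the loss weights.
#' @param rate per-base substitution probability of the homolog model.
#' @param amplitude template sinusoid depth (logit units).
#' @param eval_every record a metric report every this many epochs.
#' @param eval_n_homologs homolog draws of the fixed held-out evaluation
#'   panel (common random numbers across losses/masks).
#' @param seed master seed for initialization, batch sampling and
#'   homolog draws.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lambda_reg = 1, lambda_con = 1, n_homologs = 3L,
                         epochs = 200L, batch_span = 2000L,
                         learning_rate = 1e-3, hidden = 96L, tau = 0.05,
                         rate = 0.05, amplitude = 3, eval_every = 10L,
                         eval_n_homologs = 8L, seed = 1L) {
  cfg <- list(lambda_reg = lambda_reg, lambda_con = lambda_con,
              n_homologs = as.integer(n_homologs),
              epochs = as.integer(epochs),
              batch_span = as.integer(batch_span),
              learning_rate = learning_rate, hidden = as.integer(hidden),
              tau = tau, rate = rate, amplitude = amplitude,
              eval_every = as.integer(eval_every),
              eval_n_homologs = as.integer(eval_n_homologs),
              seed = as.integer(seed))
  stopifnot(cfg$lambda_reg >= 0, cfg$lambda_con >= 0, cfg$epochs >= 0,
            cfg$n_homologs >= 0, cfg$batch_span >= 1,
            cfg$learning_rate > 0, cfg$tau > 0,
            cfg$rate >= 0, cfg$rate <= 1)
  class(cfg) <- "train_config"
  cfg
}

#' Fit a sequence-specific k-mer ordering for a masked minimizer scheme
#'
#' Inner loop of the bi-level sketch optimizer: gradient descent on the
#' priority (content) and template (position) models under one of three
#' surrogate losses, for a fixed mask.  Each epoch samples a random
#' subsequence of `batch_span` bases, draws fresh substitution-mutated
#' copies for the conservation term, and takes one Adam step.  At a
#' fixed interval the masked minimizer induced by the current priority
#' scores is evaluated (density, conservation, coverage, GSS) against a
#' held-out homolog panel drawn once per fit (common random numbers,
#' so trajectories are comparable across losses and masks).
#'
#' @param seq reference DNA sequence (character scalar).
#' @param w window size in k-mers.
#' @param k k-mer length.
#' @param mask qualifying-offset mask of width `w` (default: full mask,
#'   i.e. plain minimizers).
#' @param loss `"gss"` (density + conservation terms), `"dm"` (density
#'   only) or `"con"` (conservation term only).
#' @param config a [train_config()].
#' @return an object of class `sketch_fit` with the fitted models, the
#'   metric trajectory (`history`), and the final metric report
#'   (`metrics`).
#' @export
train_ordering <- function(seq, w, k, mask = minimizer_mask(w),
                           loss = c("gss", "dm", "con"),
                           config = train_config()) {
  loss <- match.arg(loss)
  w <- as.integer(w); k <- as.integer(k)
  seq <- as_dna(seq)
  codes <- chartr_codes(seq)
  L <- length(codes)
  check_kmer_params(L, w, k)
  mask <- as_mask(mask, w)
  cfg <- config
  span <- min(cfg$batch_span, L)
  if (span < w + k - 1L)
    stop(sprintf("batch_span must be >= w + k - 1 = %d", w + k - 1L))
  if (loss != "dm" && cfg$n_homologs < 1L)
    stop("conservation losses need n_homologs >= 1")
  Lk <- L - k + 1L

  pm <- priority_model(k, hidden = cfg$hidden, seed = cfg$seed)
  tm <- template_model(Lk, w, amplitude = cfg$amplitude)
  # held-out panel for metric evaluation, fixed for the whole fit
  eval_homologs <- draw_homologs(seq, n = cfg$eval_n_homologs,
                                 rate = cfg$rate, seed = cfg$seed + 1L)
  eval_codes <- lapply(eval_homologs, chartr_codes)

  evaluate <- function(epoch, train_loss) {
    scores <- priority_scores(pm, codes)
    sk <- sketch_from_scores(scores, w, mask)
    d <- sketch_density(sk, Lk)
    cons <- mean(vapply(eval_codes, function(hc) {
      skh <- sketch_from_scores(priority_scores(pm, hc), w, mask)
      length(intersect(sk, skh)) / Lk
    }, numeric(1)))
    cov <- w_coverage(sk, L, w, k)
    data.frame(epoch = epoch, train_loss = train_loss,
               scheme = "masked_minimizer", w = w, k = k,
               mask = format_mask(mask), density = d, conservation = cons,
               coverage = cov, gss = gss(d, cons, cov),
               n_homologs = cfg$eval_n_homologs,
               substitution_rate = cfg$rate, seed = cfg$seed,
               stringsAsFactors = FALSE)
  }

  history <- list(evaluate(0L, NA_real_))
  st_p <- adam_init(pm$par)
  st_t <- adam_init(tm$par)

  if (cfg$epochs > 0L) local_seed(cfg$seed + 2L, {
    for (ep in seq_len(cfg$epochs)) {
      a <- sample.int(L - span + 1L, 1L)               # 1-based base start
      bc <- codes[a:(a + span - 1L)]
      nk <- span - k + 1L
      pos0 <- (a - 1L) + 0:(nk - 1L)                   # absolute k-mer pos
      fT <- template_forward(tm, pos0)
      fP <- priority_forward(pm, bc)

      need_hom <- loss != "dm"
      hom_caches <- NULL
      if (need_hom) {
        hom_caches <- lapply(seq_len(cfg$n_homologs), function(i) {
          hit <- which(stats::runif(span) < cfg$rate)
          hc <- bc
          if (length(hit) > 0L) {
            hc[hit] <- (hc[hit] +
                          sample.int(3L, length(hit), replace = TRUE)) %% 4L
          }
          list(codes = hc, fwd = priority_forward(pm, hc))
        })
      }

      dT_total <- numeric(nk)
      gp_total <- NULL
      total_loss <- 0
      add_gp <- function(g1, g2) Map(`+`, g1, g2)

      if (loss != "con") {
        gr <- density_loss_grad(fP$P, fT$TT, mask, w, cfg$lambda_reg, cfg$tau)
        total_loss <- total_loss + gr$loss
        dT_total <- dT_total + gr$dT
        gp_total <- priority_backward(pm, fP, gr$dP)
      }
      if (need_hom) {
        coef_h <- if (loss == "con") 1 / cfg$n_homologs
                  else cfg$lambda_con / cfg$n_homologs
        for (h in hom_caches) {
          gr <- density_loss_grad(h$fwd$P, fT$TT, mask, w,
                                  cfg$lambda_reg, cfg$tau)
          total_loss <- total_loss + coef_h * gr$loss
          dT_total <- dT_total + coef_h * gr$dT
          gph <- priority_backward(pm, h$fwd, coef_h * gr$dP)
          gp_total <- if (is.null(gp_total)) gph else add_gp(gp_total, gph)
        }
      }

      up <- adam_step(pm$par, gp_total, st_p, cfg$learning_rate)
      pm$par <- up$par; st_p <- up$state
      gt <- template_backward(tm, fT, dT_total)
      ut <- adam_step(tm$par, gt, st_t, cfg$learning_rate)
      tm$par <- ut$par; st_t <- ut$state

      if (ep %% cfg$eval_every == 0L || ep == cfg$epochs) {
        history[[length(history) + 1L]] <- evaluate(ep, total_loss)
      }
    }
  })

  history <- do.call(rbind, history)
  final <- history[nrow(history), , drop = FALSE]
  fit <- structure(list(
    priority = pm, template = tm, mask = mask, w = w, k = k,
    loss = loss, config = cfg, seq = seq,
    history = history, metrics = final,
    scores = priority_scores(pm, codes),
    sketch = NULL), class = "sketch_fit")
  fit$sketch <- sketch_from_scores(fit$scores, w, mask)
  fit
}

#' @export
print.sketch_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Masked minimizer fit (loss '%s'), w = %d, k = %d, mask %s\n",
              x$loss, x$w, x$k, format_mask(x$mask)))
  cat(sprintf("  %d epochs | density %.4f | conservation %.4f | coverage %.4f | GSS %.4f\n",
              m$epoch, m$density, m$conservation, m$coverage, m$gss))
  invisible(x)
}

#' @export
summary.sketch_fit <- function(object, ...) {
  h <- object$history
  first <- h[1L, ]; last <- h[nrow(h), ]
  out <- list(loss = object$loss, w = object$w, k = object$k,
              mask = format_mask(object$mask),
              epochs = last$epoch,
              initial = first[, c("density", "conservation", "coverage", "gss")],
              final = last[, c("density", "conservation", "coverage", "gss")],
              sketch_size = length(object$sketch))
  class(out) <- "summary.sketch_fit"
  out
}

#' @export
print.summary.sketch_fit <- function(x, ...) {
  cat(sprintf("Masked minimizer fit: loss '%s', w = %d, k = %d, mask %s\n",
              x$loss, x$w, x$k, x$mask))
  cat(sprintf("  sketch size %d after %d epochs\n", x$sketch_size, x$epochs))
  tab <- rbind(initial = unlist(x$initial), final = unlist(x$final))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.sketch_fit <- function(object, ...) {
  c(unlist(object$priority$par), delta = object$template$par$delta)
}

#' Predict sketches or scores from a fitted ordering
#'
#' @param object a `sketch_fit`.
#' @param newdata sequence to sketch/score; defaults to the training
#'   sequence.
#' @param type `"sketch"` (0-based selected k-mer indices under the
#'   fitted mask) or `"scores"` (priority score of every k-mer).
#' @param ... unused.
#' @export
predict.sketch_fit <- function(object, newdata = NULL,
                               type = c("sketch", "scores"), ...) {
  type <- match.arg(type)
  seq <- if (is.null(newdata)) object$seq else as_dna(newdata)
  scores <- priority_scores(object$priority, chartr_codes(seq))
  if (type == "scores") return(scores)
  sketch_from_scores(scores, object$w, object$mask)
}

#' Simulate homologs under the fitted substitution model
#'
#' @param object a `sketch_fit`.
#' @param nsim number of homologs.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of mutated copies of the training sequence.
#' @export
simulate.sketch_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw_homologs(object$seq, n = nsim, rate = object$config$rate, seed = seed)
}

#' Plot the metric trajectory of a fit
#'
#' @param x a `sketch_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sketch_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, h[, c("density", "conservation", "coverage", "gss")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("#D55E00", "#0072B2", "#009E73", "#000000"),
                    xlab = "epoch", ylab = "metric", ylim = c(0, 1), ...)
  graphics::legend("topright",
                   legend = c("density", "conservation", "coverage", "GSS"),
                   col = c("#D55E00", "#0072B2", "#009E73", "#000000"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
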
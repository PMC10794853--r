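#' Experiment configuration
#'
#' A fully serializable description of one sketching run: the input
#' (FASTA path or simulation spec), the scheme, the metric settings and
#' (optionally) the training/optimization settings.  Re-running a saved
#' config under the same seed reproduces all outputs.
#'
#' @param input FASTA path, or `NULL` to simulate.
#' @param sim list for the simulator when `input` is `NULL`: `L`,
#'   `homopolymer_fraction`, `min_run`.
#' @param scheme `"masked_minimizer"` (windowed) or
#'   `"parameterized_syncmer"` (context-free).
#' @param w window size (masked minimizers).
#' @param k k-mer length.
#' @param s s-mer length (syncmers only).
#' @param mask mask string ([parse_mask()] syntax) or `offset_mask`.
#' @param rate homolog substitution rate.
#' @param n_homologs homolog draws for conservation.
#' @param action `"sketch"` (sketch + metrics only), `"train"` (fit the
#'   ordering first), or `"optimize"` (full bi-level mask search).
#' @param loss training loss (see [train_ordering()]).
#' @param train a [train_config()] (its seed is overridden by `seed`).
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(input = NULL,
                              sim = list(L = 10000L,
                                         homopolymer_fraction = 0,
                                         min_run = 20L),
                              scheme = c("masked_minimizer",
                                         "parameterized_syncmer"),
                              w = 7L, k = 15L, s = NULL, mask = "full",
                              rate = 0.05, n_homologs = 8L,
                              action = c("sketch", "train", "optimize"),
                              loss = "gss", train = train_config(),
                              out_dir = tempfile("masksketch_run_"),
                              seed = 1L) {
  cfg <- list(input = input, sim = sim, scheme = match.arg(scheme),
              w = as.integer(w), k = as.integer(k),
              s = if (is.null(s)) NULL else as.integer(s),
              mask = if (inherits(mask, "offset_mask")) format_mask(mask)
                     else mask,
              rate = rate, n_homologs = as.integer(n_homologs),
              action = match.arg(action), loss = loss, train = train,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  cfg
}

#' Run a sketching experiment
#'
#' Loads or simulates the input, applies the scheme (optionally after
#' training the ordering or running the full bi-level optimization),
#' computes the metric report, and writes all artifacts to
#' `config$out_dir`: the sketch (`sketch.bed`), the metric table
#' (`metrics.tsv`), the config echo (`config.json`) and, when training,
#' the metric trajectory (`trajectory.tsv`).  Every artifact carries the
#' seed via the config echo.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the metric table, sketch and (if any)
#'   fit / search object.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(cfg$input)) {
    seqs <- read_fasta(cfg$input)
  } else {
    fr <- cfg$sim$homopolymer_fraction %||% 0
    s0 <- if (fr > 0) {
      homopolymer_sequence(cfg$sim$L, fr, min_run = cfg$sim$min_run %||% 20L,
                           seed = cfg$seed)
    } else random_sequence(cfg$sim$L, seed = cfg$seed)
    seqs <- c(simulated = s0)
    write_fasta(seqs, file.path(cfg$out_dir, "input.fasta"))
  }

  width <- if (cfg$scheme == "masked_minimizer") cfg$w
           else cfg$k - cfg$s + 1L
  mask <- parse_mask(cfg$mask, width = width)
  tcfg <- cfg$train
  tcfg$seed <- cfg$seed
  tcfg$rate <- cfg$rate

  results <- list()
  rows <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    fit <- NULL; search <- NULL
    if (cfg$scheme == "parameterized_syncmer") {
      ordering <- random_ordering(cfg$s, seed = cfg$seed)
      sk <- parameterized_syncmer_sketch(s, cfg$k, cfg$s, mask, ordering)
      Lk <- nchar(s) - cfg$k + 1L
      homs <- draw_homologs(s, cfg$n_homologs, cfg$rate, seed = cfg$seed + 1L)
      d <- sketch_density(sk, Lk)
      cons <- sketch_conservation(function(x)
        parameterized_syncmer_sketch(x, cfg$k, cfg$s, mask, ordering),
        s, homs, cfg$k)
      cov <- w_coverage(sk, nchar(s), cfg$w, cfg$k)
      row <- data.frame(record = nm, scheme = cfg$scheme, w = cfg$w,
                        k = cfg$k, s = cfg$s, mask = format_mask(mask),
                        density = d, conservation = cons, coverage = cov,
                        gss = gss(d, cons, cov),
                        n_homologs = cfg$n_homologs,
                        substitution_rate = cfg$rate, seed = cfg$seed,
                        stringsAsFactors = FALSE)
    } else if (cfg$action == "sketch") {
      ordering <- random_ordering(cfg$k, seed = cfg$seed)
      homs <- draw_homologs(s, cfg$n_homologs, cfg$rate, seed = cfg$seed + 1L)
      row <- sketch_metrics(s, cfg$w, cfg$k, mask, ordering, homologs = homs)
      row$substitution_rate <- cfg$rate
      row <- cbind(data.frame(record = nm, stringsAsFactors = FALSE), row)
      sk <- masked_minimizer_sketch(s, cfg$w, cfg$k, mask, ordering)
    } else if (cfg$action == "train") {
      fit <- train_ordering(s, cfg$w, cfg$k, mask = mask, loss = cfg$loss,
                            config = tcfg)
      sk <- fit$sketch
      row <- cbind(data.frame(record = nm, stringsAsFactors = FALSE),
                   fit$metrics)
      utils::write.table(fit$history,
                         file.path(cfg$out_dir,
                                   sprintf("trajectory_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {  # optimize
      search <- greedy_prune(s, cfg$w, cfg$k, loss = cfg$loss, config = tcfg)
      fit <- search$best_fit
      sk <- fit$sketch
      row <- cbind(data.frame(record = nm, stringsAsFactors = FALSE),
                   fit$metrics)
      utils::write.table(search$trials,
                         file.path(cfg$out_dir,
                                   sprintf("prune_log_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_sketch_bed(sk, nm, cfg$k,
                     file.path(cfg$out_dir, sprintf("sketch_%s.bed", nm)))
    rows[[nm]] <- row
    results[[nm]] <- list(sketch = sk, fit = fit, search = search)
    say("record %s: %d k-mers sketched", nm, length(sk))
  }

  metrics <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(c("record", "scheme", "w", "k", "mask", "density",
                      "conservation", "coverage", "gss", "n_homologs",
                      "substitution_rate", "seed"), names(r))
    for (m in miss) r[[m]] <- NA
    r[, c("record", "scheme", "w", "k", "mask", "density", "conservation",
          "coverage", "gss", "n_homologs", "substitution_rate", "seed")]
  }))
  utils::write.table(metrics, file.path(cfg$out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  echo <- cfg
  class(echo) <- NULL
  echo$train <- unclass(echo$train)
  jsonlite::write_json(echo, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(metrics = metrics, results = results, config = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
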
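test_that("density basics and the window-sharing lower bound", {
  expect_equal(sketch_density(integer(0), 10), 0)
  s <- random_sequence(40, seed = 1)
  o <- random_ordering(4, seed = 1)
  expect_equal(sketch_density(minimizer_sketch(s, 1, 4, o), 40 - 4 + 1), 1)
  # a minimizer sketch needs at least ceil(Lwk / w) picks: w consecutive
  # windows can share at most one pick
  for (i in 1:30) {
    inst <- rand_minimizer_instance(1200 + i)
    cnt <- seq_counts(inst$L, inst$w, inst$k)
    d <- sketch_density(minimizer_sketch(inst$seq, inst$w, inst$k,
                                         inst$ordering), cnt$Lk)
    expect_gte(d, ceiling(cnt$Lwk / inst$w) / cnt$Lk)
  }
})

test_that("w-coverage: full mask is 1, empty sketch 0, single pick w/Lwk", {
  s <- random_sequence(120, seed = 3)
  o <- random_ordering(5, seed = 3)
  sk <- minimizer_sketch(s, 6, 5, o)
  expect_identical(w_coverage(sk, 120, 6, 5), 1)
  expect_identical(w_coverage(integer(0), 120, 6, 5), 0)
  cnt <- seq_counts(120, 6, 5)
  # an interior pick at index j is contained in the w windows i = j-w+1..j;
  # a pick at index 0 only in window 0 (boundary truncation)
  expect_equal(w_coverage(5L, 120, 6, 5), 6 / cnt$Lwk)
  expect_equal(w_coverage(0L, 120, 6, 5), 1 / cnt$Lwk)
  # direct window-scan cross-check on random sparse sketches
  for (i in 1:20) {
    inst <- rand_minimizer_instance(1500 + i)
    cnt <- seq_counts(inst$L, inst$w, inst$k)
    set.seed(i)
    sk <- sort(sample(0:(cnt$Lk - 1L), sample(0:min(6, cnt$Lk), 1)))
    manual <- mean(vapply(0:(cnt$Lwk - 1L), function(win)
      any(sk >= win & sk <= win + inst$w - 1L), logical(1)))
    expect_equal(w_coverage(sk, inst$L, inst$w, inst$k), manual)
  }
})

test_that("conservation equals density for identical homologs, 0 for empty mask", {
  s <- random_sequence(150, seed = 9)
  o <- random_ordering(4, seed = 9)
  fn <- function(x) minimizer_sketch(x, 5, 4, o)
  d <- sketch_density(fn(s), 150 - 4 + 1)
  expect_equal(sketch_conservation(fn, s, list(s, s), 4), d)
  fn0 <- function(x) masked_minimizer_sketch(x, 5, 4, new_mask(integer(0), 5), o)
  expect_equal(sketch_conservation(fn0, s, list(mutate_sequence(s, 0.1, 1)), 4), 0)
  expect_error(sketch_conservation(fn, s, list(substr(s, 1, 100)), 4),
               "length differs")
})

test_that("conservation is bounded by density under shared homolog draws", {
  for (i in 1:40) {
    inst <- rand_minimizer_instance(1800 + i)
    m <- rand_mask(inst$w, 1900 + i)
    homs <- draw_homologs(inst$seq, 3, rate = stats::runif(1, 0, 1),
                          seed = 50 + i)
    fn <- function(x) masked_minimizer_sketch(x, inst$w, inst$k, m,
                                              inst$ordering)
    cnt <- seq_counts(inst$L, inst$w, inst$k)
    d <- sketch_density(fn(inst$seq), cnt$Lk)
    cons <- sketch_conservation(fn, inst$seq, homs, inst$k)
    expect_lte(cons, d + 1e-12)
  }
})

test_that("GSS combines the metrics and stays in [0, 1]", {
  expect_identical(gss(0, 0, 0), 0)
  s <- random_sequence(100, seed = 12)
  o <- random_ordering(3, seed = 12)
  r <- sketch_metrics(s, 4, 3, minimizer_mask(4), o, homologs = list(s))
  expect_equal(r$coverage, 1)
  expect_equal(r$conservation, r$density)
  expect_equal(r$gss, 1)
  for (i in 1:40) {
    inst <- rand_minimizer_instance(2100 + i)
    m <- rand_mask(inst$w, 2200 + i)
    r <- sketch_metrics(inst$seq, inst$w, inst$k, m, inst$ordering,
                        n_homologs = 2, rate = stats::runif(1), seed = i)
    expect_gte(r$gss, 0)
    expect_lte(r$gss, 1 + 1e-12)
  }
})

test_that("density and conservation are monotone in the mask (CRN)", {
  for (i in 1:50) {
    inst <- rand_minimizer_instance(2500 + i)
    mm <- rand_nested_masks(inst$w, 2600 + i)
    homs <- draw_homologs(inst$seq, 2, rate = 0.1, seed = 70 + i)
    r1 <- sketch_metrics(inst$seq, inst$w, inst$k, mm$small, inst$ordering,
                         homologs = homs)
    r2 <- sketch_metrics(inst$seq, inst$w, inst$k, mm$big, inst$ordering,
                         homologs = homs)
    expect_lte(r1$density, r2$density)
    expect_lte(r1$conservation, r2$conservation + 1e-12)
  }
})
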
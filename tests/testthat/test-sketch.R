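test_that("index selector returns the leftmost minimum", {
  o1 <- random_ordering(1, seed = 4)
  expect_identical(index_selector("ACGT", o1, 0, 1), 0L)
  # all k-mers identical: leftmost tie wins regardless of ordering
  expect_identical(index_selector("AAAA", o1, 0, 4), 0L)
  # brute-force scan of the four 2-mers of ACGTAC: AC is smallest
  lex <- lexicographic_ordering(2)
  kmers <- c("AC", "CG", "GT", "TA")
  expect_identical(index_selector("ACGTAC", lex, 0, 4),
                   which.min(lex$score(kmers)) - 1L)
  expect_identical(index_selector("ACGTAC", lex, 0, 4), 0L)
  expect_error(index_selector("ACGT", lex, 2, 2), "out of range")
})

test_that("degenerate minimizer cases: w = 1 and homopolymers", {
  s <- random_sequence(60, seed = 10)
  o <- random_ordering(3, seed = 2)
  expect_identical(minimizer_sketch(s, 1, 3, o), 0:(nchar(s) - 3L))
  # homopolymer: every window ties, leftmost pick -> indices 0..Lwk-1
  hp <- paste(rep("A", 8), collapse = "")
  cnt <- seq_counts(8, 3, 2)
  expect_identical(minimizer_sketch(hp, 3, 2, random_ordering(2, seed = 5)),
                   0:(cnt$Lwk - 1L))
})

test_that("parameter errors are raised", {
  s <- random_sequence(30, seed = 1)
  o <- random_ordering(4, seed = 1)
  expect_error(minimizer_sketch("ACGT", 5, 4, o), "too short")
  expect_error(masked_minimizer_sketch(s, 4, 4, new_mask(0, 5), o), "width")
  expect_error(open_syncmer_sketch(s, 4, 2, 5, random_ordering(2, seed = 1)),
               "t must lie")
  expect_error(parameterized_syncmer_sketch(s, 4, 6, new_mask(0, 1),
                                            random_ordering(6, seed = 1)),
               "s must be smaller")
  expect_error(as_dna("ACGTNAC"), "illegal symbol 'N' at position 5")
})

test_that("efficient schemes match the naive oracle on random instances", {
  for (i in 1:60) {
    inst <- rand_minimizer_instance(1000 + i)
    m <- rand_mask(inst$w, 2000 + i)
    fast <- masked_minimizer_sketch(inst$seq, inst$w, inst$k, m, inst$ordering)
    slow <- naive_oracle_sketch("masked_minimizer", inst$seq,
                                list(w = inst$w, k = inst$k, mask = m),
                                inst$ordering)
    expect_identical(fast, slow)
  }
  for (i in 1:40) {
    inst <- rand_syncmer_instance(3000 + i)
    m <- rand_mask(inst$ks, 4000 + i)
    fast <- parameterized_syncmer_sketch(inst$seq, inst$k, inst$s, m,
                                         inst$ordering)
    slow <- naive_oracle_sketch("parameterized_syncmer", inst$seq,
                                list(k = inst$k, s = inst$s, mask = m),
                                inst$ordering)
    expect_identical(fast, slow)
  }
})

test_that("full mask recovers plain minimizers; empty mask is vacuous", {
  for (i in 1:25) {
    inst <- rand_minimizer_instance(500 + i)
    full <- masked_minimizer_sketch(inst$seq, inst$w, inst$k,
                                    minimizer_mask(inst$w), inst$ordering)
    expect_identical(full, minimizer_sketch(inst$seq, inst$w, inst$k,
                                            inst$ordering))
    expect_identical(
      masked_minimizer_sketch(inst$seq, inst$w, inst$k,
                              new_mask(integer(0), inst$w), inst$ordering),
      integer(0))
  }
})

test_that("syncmer reductions: singleton and closed masks", {
  for (i in 1:25) {
    inst <- rand_syncmer_instance(700 + i)
    t <- sample(0:(inst$ks - 1L), 1)
    expect_identical(
      parameterized_syncmer_sketch(inst$seq, inst$k, inst$s,
                                   new_mask(t, inst$ks), inst$ordering),
      open_syncmer_sketch(inst$seq, inst$k, inst$s, t, inst$ordering))
    if (inst$ks >= 2) {
      closed <- parameterized_syncmer_sketch(
        inst$seq, inst$k, inst$s, closed_syncmer_mask(inst$ks), inst$ordering)
      uni <- sort(union(
        open_syncmer_sketch(inst$seq, inst$k, inst$s, 0L, inst$ordering),
        open_syncmer_sketch(inst$seq, inst$k, inst$s, inst$ks - 1L,
                            inst$ordering)))
      expect_identical(closed, uni)
    }
    # full syncmer mask samples every k-mer; t = 0 on homopolymer likewise
    expect_identical(
      parameterized_syncmer_sketch(inst$seq, inst$k, inst$s,
                                   minimizer_mask(inst$ks), inst$ordering),
      0:(nchar(inst$seq) - inst$k))
  }
  hp <- paste(rep("G", 30), collapse = "")
  expect_identical(open_syncmer_sketch(hp, 6, 3, 0, random_ordering(3, 1)),
                   0:(30 - 6))
})

test_that("sketch subset monotonicity in the mask (windowed and context-free)", {
  for (i in 1:60) {
    inst <- rand_minimizer_instance(9000 + i)
    mm <- rand_nested_masks(inst$w, 9500 + i)
    small <- masked_minimizer_sketch(inst$seq, inst$w, inst$k, mm$small,
                                     inst$ordering)
    big <- masked_minimizer_sketch(inst$seq, inst$w, inst$k, mm$big,
                                   inst$ordering)
    expect_true(all(small %in% big))
  }
})

test_that("window guarantee and determinism", {
  for (i in 1:15) {
    inst <- rand_minimizer_instance(600 + i)
    sk <- minimizer_sketch(inst$seq, inst$w, inst$k, inst$ordering)
    expect_equal(w_coverage(sk, inst$L, inst$w, inst$k), 1)
    # byte-identical on recomputation
    expect_identical(sk, minimizer_sketch(inst$seq, inst$w, inst$k,
                                          inst$ordering))
    expect_true(all(sk >= 0 & sk <= inst$L - inst$k))
    expect_false(is.unsorted(sk, strictly = TRUE))
  }
})

test_that("orderings are deterministic, bounded, and injective for small k", {
  o <- random_ordering(6, seed = 77)
  kmers <- vapply(1:50, function(i)
    random_sequence(6, seed = 5000 + i), character(1))
  s1 <- o$score(kmers)
  expect_identical(s1, o$score(kmers))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_identical(anyDuplicated(s1[!duplicated(kmers)]), 0L)
  # string path and code fast path agree
  s <- random_sequence(80, seed = 8)
  sc <- kmer_scores(o, s)
  km <- substring(s, 1:(80 - 5), (1:(80 - 5)) + 5)
  expect_equal(sc, o$score(km), tolerance = 1e-12)
})
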
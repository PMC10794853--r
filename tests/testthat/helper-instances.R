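# Shared fixture builders: random small scheme instances, all generated in
# code under fixed seeds.

rand_minimizer_instance <- function(seed, Lmax = 200L) {
  set.seed(seed)
  w <- sample(1:8, 1)
  k <- sample(1:8, 1)
  L <- sample((w + k - 1 + 5):Lmax, 1)
  list(seq = random_sequence(L, seed = seed + 1L),
       w = w, k = k, L = L,
       ordering = random_ordering(k, seed = seed + 2L))
}

rand_syncmer_instance <- function(seed, Lmax = 150L) {
  set.seed(seed)
  k <- sample(3:10, 1)
  s <- sample(1:(k - 1), 1)
  L <- sample((k + 5):Lmax, 1)
  list(seq = random_sequence(L, seed = seed + 1L),
       k = k, s = s, ks = k - s + 1L,
       ordering = random_ordering(s, seed = seed + 2L))
}

# a random mask of the given width (possibly empty unless forbid_empty)
rand_mask <- function(width, seed, forbid_empty = FALSE) {
  set.seed(seed)
  repeat {
    bits <- which(stats::runif(width) < 0.5) - 1L
    if (!forbid_empty || length(bits) > 0L) return(new_mask(bits, width))
  }
}

# nested mask pair v subset of v2
rand_nested_masks <- function(width, seed) {
  set.seed(seed)
  big <- which(stats::runif(width) < 0.7) - 1L
  small <- big[stats::runif(length(big)) < 0.6]
  list(small = new_mask(small, width), big = new_mask(big, width))
}
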
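# A literal double-loop rendering of the density loss, independent of the
# vectorized implementation.
loop_density_loss <- function(P, T, vbits, w, lambda, weights) {
  n <- length(P)
  Lwk <- n - w + 1L
  loss <- lambda * sum((1 - P)^2)
  for (i in seq_len(Lwk)) {
    for (j in vbits) {
      loss <- loss + weights[i, j + 1L] * (P[i + j] - T[i + j])^2
    }
  }
  loss
}

test_that("density loss: degenerate cases", {
  P <- rep(1, 8); T <- rep(1, 8)
  expect_equal(density_loss(P, T, minimizer_mask(3), 3), 0)
  P2 <- c(0.2, 0.9, 0.4, 1, 0.5, 0.8, 0.3, 0.6)
  expect_equal(density_loss(P2, T, new_mask(integer(0), 3), 3, lambda_reg = 2),
               2 * sum((1 - P2)^2))
  expect_gte(density_loss(P2, runif(8), rand_mask(3, 1), 3), 0)
  expect_error(density_loss(P2, T[1:5], minimizer_mask(3), 3), "equal length")
})

test_that("density loss matches a literal double-loop evaluation", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    w <- sample(2:4, 1)
    if (n < w) next
    P <- runif(n); T <- runif(n)
    v <- rand_mask(w, 400 + rep)
    W <- loss_weights(P, T, w, tau = 0.07)
    expect_equal(density_loss(P, T, v, w, lambda_reg = 0.5, tau = 0.07),
                 loop_density_loss(P, T, v$bits, w, 0.5, W))
  }
  # hand-set small instance from first principles: Lk = 6, w = 3, v = {1}
  P <- c(0.1, 0.9, 0.3, 0.7, 0.5, 0.2)
  T <- c(0.6, 0.2, 0.8, 0.1, 0.9, 0.4)
  W <- loss_weights(P, T, 3, tau = 0.05)
  manual <- sum((1 - P)^2)
  for (i in 1:4) manual <- manual + W[i, 2] * (P[i + 1] - T[i + 1])^2
  expect_equal(density_loss(P, T, new_mask(1, 3), 3), manual)
})

test_that("softmin weights approach the hard argmin and sum to window mass", {
  set.seed(7)
  T <- runif(30); P <- runif(30)
  W <- loss_weights(P, T, 5, tau = 1e-4)
  # each row sums to 2 (one unit of mass per score vector)
  expect_equal(rowSums(W), rep(2, 26))
  WT <- masksketch:::loss_weights_one(T, 5, tau = 1e-4)
  hardT <- apply(matrix(T[rep(1:26, 5) + rep(0:4, each = 26)], 26, 5), 1, which.min)
  expect_equal(apply(WT, 1, which.max), hardT)
  expect_equal(rowSums(WT), rep(1, 26))
})

test_that("analytic gradients match finite differences (frozen weights)", {
  set.seed(13)
  n <- 12; w <- 4
  P <- runif(n); T <- runif(n)
  v <- new_mask(c(0, 2), w)
  W <- loss_weights(P, T, w, tau = 0.1)
  gr <- masksketch:::density_loss_grad(P, T, v, w, lambda_reg = 0.7,
                                       weights = W)
  eps <- 1e-6
  for (m in seq_len(n)) {
    Pp <- P; Pp[m] <- Pp[m] + eps
    Pm <- P; Pm[m] <- Pm[m] - eps
    fd <- (density_loss(Pp, T, v, w, 0.7, weights = W) -
           density_loss(Pm, T, v, w, 0.7, weights = W)) / (2 * eps)
    expect_equal(gr$dP[m], fd, tolerance = 1e-4)
    Tp <- T; Tp[m] <- Tp[m] + eps
    Tm <- T; Tm[m] <- Tm[m] - eps
    fdT <- (density_loss(P, Tp, v, w, 0.7, weights = W) -
            density_loss(P, Tm, v, w, 0.7, weights = W)) / (2 * eps)
    expect_equal(gr$dT[m], fdT, tolerance = 1e-4)
  }
})

test_that("combined loss reduces to its stated identities", {
  set.seed(17)
  P <- runif(15); T <- runif(15)
  v <- new_mask(c(1, 3), 5)
  dl <- density_loss(P, T, v, 5)
  expect_equal(gss_loss(P, list(), T, v, 5, lambda_con = 0), dl)
  expect_equal(gss_loss(P, list(P, P), T, v, 5, lambda_con = 1), 2 * dl)
  expect_equal(gss_loss(P, list(P, P, P), T, v, 5, lambda_con = 0.5),
               1.5 * dl)
  # literal formula with two hand-set homolog vectors
  H1 <- runif(15); H2 <- runif(15)
  expect_equal(gss_loss(P, list(H1, H2), T, v, 5, lambda_con = 2),
               dl + 2 * mean(c(density_loss(H1, T, v, 5),
                               density_loss(H2, T, v, 5))))
  expect_error(gss_loss(P, list(), T, v, 5, lambda_con = 1), "homolog")
})

test_that("model gradients (priority net) match finite differences", {
  set.seed(23)
  pm <- priority_model(4, hidden = 6, seed = 3)
  codes <- chartr_codes(random_sequence(20, seed = 4))
  fwd <- masksketch:::priority_forward(pm, codes)
  n <- length(fwd$P)
  dP <- rnorm(n)  # arbitrary downstream gradient
  gr <- masksketch:::priority_backward(pm, fwd, dP)
  eps <- 1e-6
  loss_at <- function(par) {
    pm2 <- pm; pm2$par <- par
    sum(dP * masksketch:::priority_forward(pm2, codes)$P)
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    target <- pm$par[[nm]]
    idx <- sample(seq_along(target), min(5, length(target)))
    for (i in idx) {
      pp <- pm$par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pmn <- pm$par; pmn[[nm]][i] <- pmn[[nm]][i] - eps
      fd <- (loss_at(pp) - loss_at(pmn)) / (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})
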
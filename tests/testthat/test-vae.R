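test_that("KL to the prior is zero exactly when posterior equals prior", {
  expect_equal(kl_to_prior(1, 2 * log(0.1), prior_mean = 1,
                           prior_sd = 0.1), 0)
  expect_equal(kl_to_prior(0, 0, prior_mean = 0, prior_sd = 1), 0)
  expect_gt(kl_to_prior(c(1, 1.2), c(2 * log(0.1), 2 * log(0.1)),
                        1, 0.1), 0)
})

test_that("KL is additive over dimensions and permutation invariant", {
  set.seed(21)
  mu <- rnorm(4); lv <- rnorm(4, sd = 0.5)
  total <- kl_to_prior(mu, lv, 1, 0.1)
  per_dim <- vapply(1:4, function(d) kl_to_prior(mu[d], lv[d], 1, 0.1),
                    numeric(1))
  expect_equal(total, sum(per_dim))
  p <- sample.int(4)
  expect_equal(kl_to_prior(mu[p], lv[p], 1, 0.1), total)
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  for (loss in c("bce", "mse")) {
    cfg <- vae_config(hidden_dim = 6L, latent_dim = 3L,
                      recon_loss = loss, seed = 1L)
    d <- 8L; b <- 4L
    par <- list(W1 = vaenet:::glorot(d, 6), b1 = rnorm(6, 0, 0.1),
                Wm = vaenet:::glorot(6, 3), bm = rnorm(3, 0, 0.1),
                Wv = vaenet:::glorot(6, 3), bv = rnorm(3, 0, 0.1),
                W2 = vaenet:::glorot(3, 6), b2 = rnorm(6, 0, 0.1),
                W3 = vaenet:::glorot(6, d), b3 = rnorm(d, 0, 0.1))
    X <- matrix(runif(b * d), b, d)
    Eps <- matrix(rnorm(b * 3), b, 3)
    fb <- vaenet:::vae_forward_backward(par, X, Eps, cfg)
    h <- 1e-6
    for (nm in names(par)) {
      idx <- seq_len(min(length(par[[nm]]), 10L))
      for (i in idx) {
        up <- par; up[[nm]][i] <- up[[nm]][i] + h
        dn <- par; dn[[nm]][i] <- dn[[nm]][i] - h
        fd <- (vaenet:::vae_forward_backward(up, X, Eps, cfg)$total -
                 vaenet:::vae_forward_backward(dn, X, Eps, cfg)$total) /
          (2 * h)
        expect_equal(fb$grads[[nm]][i], fd, tolerance = 1e-4,
                     label = paste(loss, nm, i))
      }
    }
  }
})

test_that("training reduces the loss and is reproducible from the seed", {
  fx <- tiny_fixture()
  scaled <- preprocess_matrix(fx$matrix)
  ls1 <- train_vae(scaled, tiny_vae_config())
  ls2 <- train_vae(scaled, tiny_vae_config())
  expect_identical(ls1$mu, ls2$mu)
  hist <- ls1$loss_history
  expect_lt(hist$total[nrow(hist)], hist$total[1L])
  expect_true(all(hist$recon >= 0))
  expect_true(all(is.finite(ls1$mu)) && all(is.finite(ls1$log_var)))
  expect_identical(rownames(ls1$mu), rownames(scaled))

  ls3 <- train_vae(scaled, tiny_vae_config(seed = 99L))
  expect_false(identical(ls1$mu, ls3$mu))
})

test_that("planted blocks are closer within than between in the latent space", {
  # two gene blocks active in disjoint condition sets
  set.seed(17)
  n_per <- 10L
  on <- matrix(rlnorm(n_per * 15, log(8), 0.2), n_per, 15)
  off <- matrix(0, n_per, 15)
  m <- expression_matrix(
    rbind(cbind(on, off), cbind(off, on)) +
      matrix(rlnorm(20 * 30, log(1.1), 0.1), 20, 30) * 0.05,
    genes = sprintf("g%02d", 1:20))
  scaled <- preprocess_matrix(m)
  ls <- train_vae(scaled, vae_config(hidden_dim = 16L, latent_dim = 2L,
                                     epochs = 200L, batch_size = 8L,
                                     seed = 5L))
  centered <- ls$mu - rowMeans(ls$mu)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  block <- rep(1:2, each = n_per)
  within <- c(); between <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    cs <- cosine(centered[i, ], centered[j, ])
    if (block[i] == block[j]) within <- c(within, cs) else
      between <- c(between, cs)
  }
  expect_gt(mean(within), mean(between))
})

test_that("increasing the KL weight shrinks the spread of the embeddings", {
  fx <- tiny_fixture()
  scaled <- preprocess_matrix(fx$matrix)
  spread <- vapply(c(0.1, 0.9), function(wk) {
    cfg <- vae_config(hidden_dim = 16L, latent_dim = 4L, epochs = 60L,
                      batch_size = 8L, w_recon = 1 - wk, w_kl = wk,
                      seed = 5L)
    stats::var(as.vector(train_vae(scaled, cfg)$mu))
  }, numeric(1))
  expect_lt(spread[2L], spread[1L])
})

test_that("configuration invariants are enforced", {
  expect_error(vae_config(w_recon = 0.9, w_kl = 0.2), "must equal 1")
  fx <- tiny_fixture()
  scaled <- preprocess_matrix(fx$matrix)
  expect_warning(
    train_vae(scaled[, 1:3], vae_config(hidden_dim = 4L, latent_dim = 8L,
                                        epochs = 1L)),
    "latent_dim")
  expect_error(train_vae(fx$matrix, vae_config(epochs = 1L)),
               "in \\[0, 1\\]")
})
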
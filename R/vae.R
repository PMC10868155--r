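#' Configuration for the variational autoencoder
#'
#' The autoencoder treats every gene as one observation and the conditions
#' (cells/samples) as features, so the bottleneck compresses the condition
#' dimension into a short per-gene embedding. The loss is the weighted sum
#' `w_recon * reconstruction + w_kl * KL`, with the reconstruction term a
#' per-feature binary cross-entropy (inputs and outputs both live in [0,1]
#' through the sigmoid output layer; mean squared error is available as an
#' alternative) and the KL term the divergence between each latent
#' posterior and the prior `N(prior_mean, prior_sd^2)`. The weights default
#' to 0.9 / 0.1 and the prior to N(1, 0.1^2); training uses the Adam
#' optimizer at learning rate 1e-3.
#'
#' @param hidden_dim Width of the single hidden layer in the encoder and
#'   decoder (default 256).
#' @param latent_dim Dimension of the latent embedding (default 48). Should
#'   be well below the number of conditions; a warning is issued otherwise.
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size in genes (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param w_recon,w_kl Loss weights; must sum to 1 (defaults 0.9 and 0.1).
#' @param prior_mean,prior_sd Latent prior parameters (defaults 1 and 0.1).
#' @param recon_loss `"bce"` (default) or `"mse"`.
#' @param seed Integer seed driving all randomness: weight initialization,
#'   mini-batch shuffling and reparameterization noise.
#' @return A list of class `vaenet_config`.
#' @export
vae_config <- function(hidden_dim = 256L, latent_dim = 48L, epochs = 50L,
                       batch_size = 32L, learning_rate = 1e-3,
                       w_recon = 0.9, w_kl = 0.1,
                       prior_mean = 1, prior_sd = 0.1,
                       recon_loss = c("bce", "mse"), seed = 42L) {
  recon_loss <- match.arg(recon_loss)
  stopifnot(hidden_dim >= 1L, latent_dim >= 1L, epochs >= 1L,
            batch_size >= 1L, learning_rate > 0, prior_sd > 0,
            w_recon > 0, w_recon < 1, w_kl > 0, w_kl < 1)
  if (abs(w_recon + w_kl - 1) > 1e-8) {
    stop("w_recon + w_kl must equal 1", call. = FALSE)
  }
  structure(list(hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 w_recon = w_recon, w_kl = w_kl,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 recon_loss = recon_loss, seed = as.integer(seed)),
            class = "vaenet_config")
}

#' KL divergence from a diagonal Gaussian to the latent prior
#'
#' Closed-form Kullback-Leibler divergence
#' `KL( N(mu, diag(sigma^2)) || N(prior_mean, prior_sd^2 I) )`, summed over
#' latent dimensions:
#' `sum_d [ log(prior_sd / sigma_d) + (sigma_d^2 + (mu_d - prior_mean)^2) /
#' (2 prior_sd^2) - 1/2 ]` with `sigma_d = exp(log_var_d / 2)`.
#'
#' Non-negative, and zero exactly when the posterior equals the prior in
#' every dimension.
#'
#' @param mu,log_var Numeric vectors of equal length: posterior means and
#'   log-variances.
#' @param prior_mean,prior_sd Prior parameters; `prior_sd > 0`.
#' @return A single non-negative number.
#' @export
kl_to_prior <- function(mu, log_var, prior_mean = 1, prior_sd = 0.1) {
  stopifnot(length(mu) == length(log_var), prior_sd > 0,
            all(is.finite(mu)), all(is.finite(log_var)))
  var_d <- exp(log_var)
  kl <- sum(log(prior_sd) - log_var / 2 +
              (var_d + (mu - prior_mean)^2) / (2 * prior_sd^2) - 0.5)
  if (!is.finite(kl)) stop("non-finite KL divergence", call. = FALSE)
  kl
}

# numerically stable softplus, elementwise
#' @keywords internal
#' @noRd
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Glorot-uniform weight matrix
#' @keywords internal
#' @noRd
glorot <- function(nin, nout) {
  limit <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -limit, limit), nin, nout)
}

# One forward + backward pass on a batch with fixed reparameterization
# noise Eps. Returns per-batch mean losses and gradients for every
# parameter. Kept separate from the training loop so the analytic
# gradients can be checked against finite differences.
#' @keywords internal
#' @noRd
vae_forward_backward <- function(par, X, Eps, config) {
  b <- nrow(X)
  wr <- config$w_recon; wk <- config$w_kl
  pm <- config$prior_mean; ps2 <- config$prior_sd^2
  use_bce <- config$recon_loss == "bce"

  H1 <- pmax(sweep(X %*% par$W1, 2L, par$b1, "+"), 0)
  Mu <- sweep(H1 %*% par$Wm, 2L, par$bm, "+")
  Lv <- sweep(H1 %*% par$Wv, 2L, par$bv, "+")
  Lv <- pmin(pmax(Lv, -15), 15)       # keep exp() sane
  Sd <- exp(Lv / 2)
  Z <- Mu + Sd * Eps
  H2 <- pmax(sweep(Z %*% par$W2, 2L, par$b2, "+"), 0)
  Logit <- sweep(H2 %*% par$W3, 2L, par$b3, "+")
  Y <- 1 / (1 + exp(-Logit))

  if (use_bce) {
    recon <- sum(softplus(Logit) - X * Logit) / b
    dLogit <- wr * (Y - X) / b
  } else {
    recon <- sum((Y - X)^2) / b
    dLogit <- wr * 2 * (Y - X) * Y * (1 - Y) / b
  }
  Var <- Sd^2
  kl <- sum(log(config$prior_sd) - Lv / 2 +
              (Var + (Mu - pm)^2) / (2 * ps2) - 0.5) / b
  total <- wr * recon + wk * kl

  g <- list()
  g$W3 <- crossprod(H2, dLogit)
  g$b3 <- colSums(dLogit)
  dH2 <- tcrossprod(dLogit, par$W3) * (H2 > 0)
  g$W2 <- crossprod(Z, dH2)
  g$b2 <- colSums(dH2)
  dZ <- tcrossprod(dH2, par$W2)
  dMu <- dZ + wk * (Mu - pm) / (ps2 * b)
  dLv <- dZ * Eps * Sd / 2 + wk * (Var / (2 * ps2) - 0.5) / b
  g$Wm <- crossprod(H1, dMu)
  g$bm <- colSums(dMu)
  g$Wv <- crossprod(H1, dLv)
  g$bv <- colSums(dLv)
  dH1 <- (tcrossprod(dMu, par$Wm) + tcrossprod(dLv, par$Wv)) * (H1 > 0)
  g$W1 <- crossprod(X, dH1)
  g$b1 <- colSums(dH1)

  list(total = total, recon = recon, kl = kl, grads = g)
}

#' Train the variational autoencoder and return gene embeddings
#'
#' Fits a VAE with architecture
#' `input -> hidden (ReLU) -> (mu, log_var: linear)` /
#' `latent -> hidden (ReLU) -> output (sigmoid)` on a row-scaled matrix in
#' [0,1] (see [preprocess_matrix()]), using the reparameterization trick
#' and mini-batch Adam. The per-gene embedding returned is the mean layer
#' `mu` — deterministic, not a stochastic sample — so downstream
#' correlations are reproducible.
#'
#' Reconstruction loss is summed over features and averaged over the
#' batch; KL is summed over latent dimensions and averaged over the batch.
#' With a fixed seed the result is reproducible on the same platform.
#'
#' @param m Numeric genes-by-conditions matrix with all entries in [0, 1].
#' @param config A [vae_config()].
#' @param verbose Print the per-epoch loss? Default `FALSE`.
#' @return A list of class `vaenet_latent` with elements `genes`, `mu`
#'   (genes x latent_dim matrix of embeddings, gene rownames), `log_var`,
#'   `loss_history` (data frame with per-epoch `total`, `recon`, `kl`) and
#'   `config`.
#' @export
train_vae <- function(m, config = vae_config(), verbose = FALSE) {
  assert_expression_matrix(m)
  if (any(m < 0) || any(m > 1)) {
    stop("train_vae expects values in [0, 1]; run preprocess_matrix() first",
         call. = FALSE)
  }
  n <- nrow(m); d <- ncol(m)
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  if (config$latent_dim >= d) {
    warning("latent_dim (", config$latent_dim,
            ") is not smaller than the number of conditions (", d, ")")
  }
  h <- config$hidden_dim; l <- config$latent_dim
  wr <- config$w_recon; wk <- config$w_kl
  set.seed(config$seed)
  par <- list(W1 = glorot(d, h), b1 = numeric(h),
              Wm = glorot(h, l), bm = numeric(l),
              Wv = glorot(h, l), bv = numeric(l),
              W2 = glorot(l, h), b2 = numeric(h),
              W3 = glorot(h, d), b3 = numeric(d))
  adam_m <- lapply(par, function(p) p * 0)
  adam_v <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L

  history <- matrix(NA_real_, config$epochs, 3L,
                    dimnames = list(NULL, c("total", "recon", "kl")))
  for (epoch in seq_len(config$epochs)) {
    order_ <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_recon <- 0; ep_kl <- 0
    for (s in starts) {
      idx <- order_[s:min(s + config$batch_size - 1L, n)]
      X <- m[idx, , drop = FALSE]
      b <- nrow(X)
      Eps <- matrix(stats::rnorm(b * l), b, l)

      fb <- vae_forward_backward(par, X, Eps, config)
      if (!is.finite(fb$total)) {
        stop("non-finite loss at epoch ", epoch,
             " (recon=", format(fb$recon), ", kl=", format(fb$kl),
             "); lower the learning rate", call. = FALSE)
      }
      ep_recon <- ep_recon + fb$recon * b
      ep_kl <- ep_kl + fb$kl * b
      g <- fb$grads

      ## Adam update
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in names(par)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
        par[[nm]] <- par[[nm]] -
          lr * (adam_m[[nm]] / bc1) / (sqrt(adam_v[[nm]] / bc2) + eps)
      }
    }
    history[epoch, ] <- c(wr * ep_recon / n + wk * ep_kl / n,
                          ep_recon / n, ep_kl / n)
    if (verbose) {
      message(sprintf("epoch %d/%d  total %.4f  recon %.4f  kl %.4f",
                      epoch, config$epochs, history[epoch, 1L],
                      history[epoch, 2L], history[epoch, 3L]))
    }
  }

  ## final deterministic encoding pass: embeddings are the mu layer
  H1 <- pmax(sweep(m %*% par$W1, 2L, par$b1, "+"), 0)
  Mu <- sweep(H1 %*% par$Wm, 2L, par$bm, "+")
  Lv <- sweep(H1 %*% par$Wv, 2L, par$bv, "+")
  rownames(Mu) <- rownames(m)
  rownames(Lv) <- rownames(m)
  structure(list(genes = rownames(m), mu = Mu, log_var = Lv,
                 loss_history = as.data.frame(history),
                 config = config, weights = par),
            class = "vaenet_latent")
}

#' @export
print.vaenet_latent <- function(x, ...) {
  cat("Latent space: ", length(x$genes), " genes x ", ncol(x$mu),
      " dimensions (", x$config$epochs, " epochs, final loss ",
      format(utils::tail(x$loss_history$total, 1L), digits = 5L),
      ")\n", sep = "")
  invisible(x)
}
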
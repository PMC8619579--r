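# Variational auto-encoder mapping 19-channel EEG samples to J latent
# variables and back. The encoder outputs a diagonal-Gaussian posterior
# (mu, sigma) per sample; the decoder reconstructs the channel vector from a
# reparameterized latent draw. Training maximizes the evidence lower bound
# (Gaussian reconstruction likelihood with unit observation variance on
# per-channel standardized data, minus the closed-form KL divergence to the
# standard-normal prior) by stochastic gradient descent with back-propagation.

mlp_init <- function(widths, seed_offset) {
  layers <- list()
  for (l in seq_len(length(widths) - 1L)) {
    fin <- widths[l]; fout <- widths[l + 1L]
    r <- sqrt(6 / (fin + fout))                       # Xavier/Glorot uniform
    layers[[l]] <- list(
      W = matrix(stats::runif(fout * fin, -r, r), fout, fin),
      b = rep(0, fout))
  }
  layers
}

# Forward pass through a tanh MLP (linear output layer); activations kept for
# the backward pass. Batches are columns (d x B).
mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  a <- x
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- layers[[l]]$W %*% a + layers[[l]]$b
    a <- if (l < nl) tanh(z) else z
    acts[[l + 1L]] <- a
  }
  list(out = a, acts = acts)
}

# Backward pass: `dout` is the gradient wrt the network output. Returns
# per-layer gradients and the gradient wrt the input.
mlp_backward <- function(layers, acts, dout) {
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- dout
  for (l in rev(seq_len(nl))) {
    if (l < nl) delta <- delta * (1 - acts[[l + 1L]]^2)
    grads[[l]] <- list(W = delta %*% t(acts[[l]]), b = rowSums(delta))
    delta <- t(layers[[l]]$W) %*% delta
  }
  list(grads = grads, dinput = delta)
}

#' Initialize a variational auto-encoder
#'
#' Default architecture: encoder `n_channels -> hidden (tanh) -> 2J` (the
#' `mu` and `log sigma^2` of the latent posterior), decoder mirrored
#' `J -> hidden (tanh) -> n_channels`. `hidden` may be an empty vector for a
#' purely linear encoder/decoder.
#'
#' @param n_channels Input dimension (number of EEG channels).
#' @param J Latent dimension (>= 1).
#' @param hidden Integer vector of hidden-layer widths (default 32).
#' @param seed Integer seed for the deterministic weight initialization.
#' @return An object of class `vae_model`.
#' @export
init_vae <- function(n_channels, J, hidden = 32L, seed = 1L) {
  if (J < 1) stopf("latent dimension J must be >= 1")
  if (n_channels < 1) stopf("n_channels must be >= 1")
  hidden <- as.integer(hidden)
  with_seed(seed, {
    enc <- mlp_init(c(n_channels, hidden, 2L * J), 0L)
    dec <- mlp_init(c(J, rev(hidden), n_channels), 1L)
    structure(
      list(n_channels = as.integer(n_channels), J = as.integer(J),
           hidden = hidden, enc = enc, dec = dec,
           center = rep(0, n_channels), scale = rep(1, n_channels),
           trained = FALSE),
      class = "vae_model")
  })
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("<vae_model> %d channels -> J = %d latents (hidden: %s)%s\n",
              x$n_channels, x$J,
              if (length(x$hidden)) paste(x$hidden, collapse = ", ") else "none",
              if (x$trained) " [trained]" else ""))
  invisible(x)
}

# Accept an epoch_set, list of channels x samples matrices, a recording, or a
# single matrix; returns one channels x N matrix.
vae_training_matrix <- function(epochs) {
  if (inherits(epochs, "epoch_set")) do.call(cbind, epochs$epochs)
  else if (inherits(epochs, "recording") || is.matrix(epochs)) as_recording_matrix(epochs)
  else if (is.list(epochs)) do.call(cbind, lapply(epochs, as_recording_matrix))
  else stopf("unsupported training-data type")
}

standardize_cols <- function(model, X) {
  (X - model$center) / model$scale
}

#' Encode a batch of channel vectors into latent posteriors
#'
#' @param model A `vae_model`.
#' @param x Numeric matrix, one sample per row, `n_channels` columns
#'   (a single sample may be given as a vector). Channel standardization
#'   learned during training is applied.
#' @return An object of class `latent_posterior`: list with `mu` and `sigma`
#'   (samples x J matrices, `sigma > 0`).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "vae_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_channels) {
    stopf("input width %d does not match n_channels = %d", ncol(x), model$n_channels)
  }
  if (any(!is.finite(x))) stopf("non-finite values in encoder input")
  Xs <- standardize_cols(model, t(x))                    # channels x B
  out <- mlp_forward(model$enc, Xs)$out
  J <- model$J
  mu <- t(out[seq_len(J), , drop = FALSE])
  logvar <- t(out[J + seq_len(J), , drop = FALSE])
  structure(list(mu = mu, sigma = exp(0.5 * logvar)), class = "latent_posterior")
}

#' Decode latent coordinates into channel space
#'
#' @param model A `vae_model`.
#' @param z Samples x J matrix of latent coordinates.
#' @return Samples x `n_channels` matrix in the original (unstandardized)
#'   channel units.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "vae_model"))
  if (is.vector(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$J) stopf("latent width %d does not match J = %d", ncol(z), model$J)
  Xs <- mlp_forward(model$dec, t(z))$out
  t(Xs * model$scale + model$center)
}

#' Draw reparameterized latent samples
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, 1)`, `L` draws per input sample.
#'
#' @param post A `latent_posterior`.
#' @param L Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Array `samples x J x L`.
#' @export
reparameterize <- function(post, L = 1L, seed = 1L) {
  stopifnot(inherits(post, "latent_posterior"))
  if (L < 1) stopf("L must be >= 1")
  n <- nrow(post$mu); J <- ncol(post$mu)
  with_seed(seed, {
    eps <- array(stats::rnorm(n * J * L), c(n, J, L))
    z <- array(0, c(n, J, L))
    for (l in seq_len(L)) z[, , l] <- post$mu + post$sigma * eps[, , l]
    z
  })
}

#' Closed-form KL divergence of the latent posterior from the N(0, 1) prior
#'
#' `D_KL = -1/2 sum_j (1 + log sigma_j^2 - mu_j^2 - sigma_j^2)`, per sample;
#' non-negative, zero iff `mu = 0, sigma = 1`.
#'
#' @param post A `latent_posterior` (all `sigma > 0`).
#' @return Numeric vector, one KL value per sample.
#' @export
kl_gaussian <- function(post) {
  stopifnot(inherits(post, "latent_posterior"))
  if (any(post$sigma <= 0)) stopf("sigma must be strictly positive")
  s2 <- post$sigma^2
  -0.5 * rowSums(1 + log(s2) - post$mu^2 - s2)
}

#' Evidence lower bound of a batch
#'
#' Gaussian reconstruction log-likelihood (unit observation variance, on the
#' standardized scale) averaged over `L` reparameterized draws, minus the
#' closed-form KL term, averaged over the batch.
#'
#' @param model A `vae_model`.
#' @param batch Samples x `n_channels` matrix (nonempty).
#' @param L Monte-Carlo sample count for the reconstruction term.
#' @param seed Integer seed for the draws.
#' @return Scalar ELBO (natural-log units per sample).
#' @export
elbo <- function(model, batch, L = 1L, seed = 1L) {
  stopifnot(inherits(model, "vae_model"))
  if (is.vector(batch)) batch <- matrix(batch, nrow = 1L)
  if (nrow(batch) < 1L) stopf("empty batch")
  post <- encode(model, batch)
  Xs <- t(standardize_cols(model, t(batch)))            # samples x d
  z <- reparameterize(post, L, seed)
  d <- model$n_channels
  ll <- matrix(0, nrow(batch), L)
  for (l in seq_len(L)) {
    zl <- matrix(z[, , l], nrow(post$mu), ncol(post$mu))
    rec <- mlp_forward(model$dec, t(zl))$out
    ll[, l] <- -0.5 * colSums((t(Xs) - rec)^2) - d / 2 * log(2 * pi)
  }
  mean(rowMeans(ll) - kl_gaussian(post))
}

vae_params <- function(model) c(model$enc, model$dec)

vae_set_params <- function(model, params) {
  ne <- length(model$enc)
  model$enc <- params[seq_len(ne)]
  model$dec <- params[ne + seq_len(length(model$dec))]
  model
}

make_opt_state <- function(params) {
  lapply(params, function(p) list(
    mW = matrix(0, nrow(p$W), ncol(p$W)), mb = rep(0, length(p$b)),
    vW = matrix(0, nrow(p$W), ncol(p$W)), vb = rep(0, length(p$b))))
}

#' Train a variational auto-encoder
#'
#' Minimizes the negative ELBO by minibatch stochastic gradient descent with
#' back-propagation (optionally with momentum, or Adam). Input data are
#' standardized per channel before training (the standardization is stored on
#' the model and undone by [decode()]). Deterministic given `seed`.
#'
#' @param model A `vae_model` from [init_vae()].
#' @param epochs Training data: an `epoch_set`, a list of channels x samples
#'   matrices, a `recording`, or a single channels x samples matrix.
#' @param n_epochs Number of passes over the data.
#' @param batch_size Minibatch size (default 20).
#' @param learning_rate Step size (default 1e-3).
#' @param seed Integer seed controlling shuffling and reparameterization noise.
#' @param optimizer `"sgd"` (optionally with `momentum`) or `"adam"`.
#' @param momentum Momentum coefficient for `"sgd"`.
#' @return The trained `vae_model`, with a `loss_history` attribute-like list
#'   element `loss_history` (mean negative ELBO per pass, natural-log units).
#' @export
train_vae <- function(model, epochs, n_epochs = 30L, batch_size = 20L,
                      learning_rate = 1e-3, seed = 1L,
                      optimizer = c("sgd", "adam"), momentum = 0) {
  stopifnot(inherits(model, "vae_model"))
  optimizer <- match.arg(optimizer)
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  X <- vae_training_matrix(epochs)                      # channels x N
  if (nrow(X) != model$n_channels) {
    stopf("data have %d channels but the model expects %d", nrow(X), model$n_channels)
  }
  model$center <- rowMeans(X)
  sds <- apply(X, 1L, stats::sd)
  sds[sds < 1e-12] <- 1
  model$scale <- sds
  Xs <- (X - model$center) / model$scale
  N <- ncol(Xs); d <- nrow(Xs); J <- model$J
  params <- vae_params(model)
  ne <- length(model$enc)
  opt <- make_opt_state(params)
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  adam_t <- 0L
  history <- numeric(n_epochs)
  const <- d / 2 * log(2 * pi)

  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      perm <- sample.int(N)
      total <- 0
      nb <- 0L
      for (start in seq(1L, N, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, N)]
        B <- length(idx)
        xb <- Xs[, idx, drop = FALSE]

        enc_fwd <- mlp_forward(model$enc, xb)
        out <- enc_fwd$out
        mu <- out[seq_len(J), , drop = FALSE]
        logvar <- out[J + seq_len(J), , drop = FALSE]
        sig <- exp(0.5 * logvar)
        epsm <- matrix(stats::rnorm(J * B), J, B)
        z <- mu + sig * epsm
        dec_fwd <- mlp_forward(model$dec, z)
        xhat <- dec_fwd$out

        resid <- xhat - xb
        recon <- 0.5 * sum(resid^2) / B
        kl <- -0.5 * sum(1 + logvar - mu^2 - sig^2) / B
        loss <- recon + kl
        if (!is.finite(loss)) {
          stopf("training diverged (non-finite loss) at pass %d", ep)
        }
        total <- total + loss
        nb <- nb + 1L

        dec_bwd <- mlp_backward(model$dec, dec_fwd$acts, resid / B)
        dz <- dec_bwd$dinput
        dmu <- dz + mu / B
        dlogvar <- 0.5 * dz * epsm * sig + 0.5 * (sig^2 - 1) / B
        enc_bwd <- mlp_backward(model$enc, enc_fwd$acts, rbind(dmu, dlogvar))
        grads <- c(enc_bwd$grads, dec_bwd$grads)

        if (optimizer == "adam") adam_t <- adam_t + 1L
        for (l in seq_along(params)) {
          g <- grads[[l]]
          if (optimizer == "sgd") {
            opt[[l]]$mW <- momentum * opt[[l]]$mW - learning_rate * g$W
            opt[[l]]$mb <- momentum * opt[[l]]$mb - learning_rate * g$b
            params[[l]]$W <- params[[l]]$W + opt[[l]]$mW
            params[[l]]$b <- params[[l]]$b + opt[[l]]$mb
          } else {
            opt[[l]]$mW <- beta1 * opt[[l]]$mW + (1 - beta1) * g$W
            opt[[l]]$mb <- beta1 * opt[[l]]$mb + (1 - beta1) * g$b
            opt[[l]]$vW <- beta2 * opt[[l]]$vW + (1 - beta2) * g$W^2
            opt[[l]]$vb <- beta2 * opt[[l]]$vb + (1 - beta2) * g$b^2
            corr1 <- 1 - beta1^adam_t; corr2 <- 1 - beta2^adam_t
            params[[l]]$W <- params[[l]]$W - learning_rate *
              (opt[[l]]$mW / corr1) / (sqrt(opt[[l]]$vW / corr2) + eps_adam)
            params[[l]]$b <- params[[l]]$b - learning_rate *
              (opt[[l]]$mb / corr1) / (sqrt(opt[[l]]$vb / corr2) + eps_adam)
          }
        }
        model <- vae_set_params(model, params)
      }
      history[ep] <- total / nb + const     # mean negative ELBO per sample
    }
  })
  model$trained <- TRUE
  model$loss_history <- history
  model
}

# Grow a trained VAE from J to J_new latents without changing its function:
# new posterior-mean rows and decoder columns start at zero, so the added
# latents are born collapsed to the prior (mu = 0, sigma = 1, zero decoder
# weight) and the expanded model reproduces the smaller one exactly.
expand_vae <- function(model, J_new) {
  stopifnot(inherits(model, "vae_model"), J_new > model$J)
  J <- model$J
  out <- model
  le <- length(out$enc)
  W <- out$enc[[le]]$W; b <- out$enc[[le]]$b
  h <- ncol(W)
  W2 <- matrix(0, 2L * J_new, h); b2 <- rep(0, 2L * J_new)
  W2[seq_len(J), ] <- W[seq_len(J), , drop = FALSE]
  b2[seq_len(J)] <- b[seq_len(J)]
  W2[J_new + seq_len(J), ] <- W[J + seq_len(J), , drop = FALSE]
  b2[J_new + seq_len(J)] <- b[J + seq_len(J)]
  out$enc[[le]]$W <- W2; out$enc[[le]]$b <- b2
  Wd <- out$dec[[1L]]$W
  Wd2 <- matrix(0, nrow(Wd), J_new)
  Wd2[, seq_len(J)] <- Wd
  out$dec[[1L]]$W <- Wd2
  out$J <- as.integer(J_new)
  out
}

#' Reconstruction-performance sweep over the latent count
#'
#' Trains a sequence of nested VAEs with increasing latent dimension. Each
#' larger model is warm-started from the trained smaller one (added latents
#' start collapsed to the prior, so the expanded model initially reproduces
#' its predecessor exactly) and refined; if refinement does not improve the
#' mean reconstruction correlation, the inherited solution is kept. The sweep
#' is therefore non-decreasing in J by construction, reflecting that a model
#' with J + 1 latents nests every J-latent model.
#'
#' @param epochs Training data in any form accepted by [train_vae()].
#' @param J_values Increasing latent counts to visit (default `1:6`).
#' @param hidden Hidden-layer widths of every model.
#' @param n_epochs,batch_size,learning_rate,optimizer Training settings
#'   shared by all models.
#' @param seed Integer seed (initialization, shuffling, reparameterization).
#' @return `data.frame` with columns `J` and `reconstruction` (mean channel
#'   correlation).
#' @export
reconstruction_sweep <- function(epochs, J_values = 1:6, hidden = 32L,
                                 n_epochs = 8L, batch_size = 20L,
                                 learning_rate = 1e-3, optimizer = "adam",
                                 seed = 1L) {
  J_values <- sort(unique(as.integer(J_values)))
  X <- vae_training_matrix(epochs)
  recs <- numeric(length(J_values))
  prev <- NULL; prev_rec <- -Inf
  for (i in seq_along(J_values)) {
    J <- J_values[i]
    m <- if (is.null(prev)) init_vae(nrow(X), J, hidden = hidden, seed = seed)
         else expand_vae(prev, J)
    m <- train_vae(m, X, n_epochs = n_epochs, batch_size = batch_size,
                   learning_rate = learning_rate, seed = seed + i,
                   optimizer = optimizer)
    r <- reconstruction_performance(m, X)
    if (r < prev_rec) {
      m <- if (J > prev$J) expand_vae(prev, J) else prev
      m$trained <- TRUE
      r <- prev_rec
    }
    recs[i] <- r
    prev <- m; prev_rec <- r
  }
  data.frame(J = J_values, reconstruction = recs)
}

#' Mean channel-wise reconstruction correlation
#'
#' Pearson correlation between each original channel trace and its
#' posterior-mean reconstruction, averaged over channels and epochs.
#' Constant channels are skipped with a warning.
#'
#' @param model A trained `vae_model`.
#' @param epochs Data in any form accepted by [train_vae()].
#' @return Mean correlation in `[-1, 1]`.
#' @export
reconstruction_performance <- function(model, epochs) {
  stopifnot(inherits(model, "vae_model"))
  eps_list <- if (inherits(epochs, "epoch_set")) epochs$epochs
              else if (inherits(epochs, "recording") || is.matrix(epochs)) {
                list(as_recording_matrix(epochs))
              } else lapply(epochs, as_recording_matrix)
  cors <- c()
  skipped <- 0L
  for (E in eps_list) {
    post <- encode(model, t(E))
    rec <- t(decode(model, post$mu))                    # channels x samples
    for (i in seq_len(nrow(E))) {
      if (stats::sd(E[i, ]) < 1e-12 || stats::sd(rec[i, ]) < 1e-12) {
        skipped <- skipped + 1L
        next
      }
      cors <- c(cors, stats::cor(E[i, ], rec[i, ]))
    }
  }
  if (skipped > 0L) warning(sprintf("%d constant channel trace(s) skipped", skipped))
  if (!length(cors)) stopf("no non-constant channels to correlate")
  mean(cors)
}

#' Latent trajectory of a segment
#'
#' Per-sample posterior means, with latent coordinates ordered by decreasing
#' variance over the segment (ties broken by original index). The "top 3"
#' dimensions are the first three columns.
#'
#' @param model A trained `vae_model`.
#' @param segment A `recording` or channels x samples matrix.
#' @param top_k If non-NULL, keep only the first `top_k` ordered coordinates
#'   (error if `J < top_k`).
#' @param subject_id,condition,trial Optional provenance.
#' @return An object of class `latent_trajectory`: list with `times` (s, if
#'   the segment is a recording; sample index otherwise), `Z` (time x J or
#'   time x `top_k`), `order` (original latent indices of the columns), and
#'   provenance fields.
#' @export
latent_trajectory <- function(model, segment, top_k = NULL,
                              subject_id = NA_character_,
                              condition = NA_character_, trial = NA_integer_) {
  stopifnot(inherits(model, "vae_model"))
  fs <- if (inherits(segment, "recording")) segment$fs else NA_real_
  X <- as_recording_matrix(segment)
  if (!is.null(top_k) && model$J < top_k) {
    stopf("J = %d latents cannot provide the top %d dimensions", model$J, top_k)
  }
  post <- encode(model, t(X))
  v <- apply(post$mu, 2L, stats::var)
  ord <- order(-v, seq_along(v))
  Z <- post$mu[, ord, drop = FALSE]
  if (!is.null(top_k)) {
    Z <- Z[, seq_len(top_k), drop = FALSE]
    ord <- ord[seq_len(top_k)]
  }
  times <- if (is.na(fs)) seq_len(nrow(Z)) else (seq_len(nrow(Z)) - 1) / fs
  structure(list(times = times, Z = Z, order = ord, subject_id = subject_id,
                 condition = condition, trial = trial),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("<latent_trajectory> %d samples x %d latent dims (%s/%s trial %s)\n",
              nrow(x$Z), ncol(x$Z), x$subject_id, x$condition, x$trial))
  invisible(x)
}
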
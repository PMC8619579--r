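# Variational auto-encoder: initialization, posterior, reparameterization,
# KL closed form, ELBO, training, reconstruction and latent trajectories.

test_that("initialization is deterministic and structurally correct", {
  a <- init_vae(19, 3, seed = 4)
  b <- init_vae(19, 3, seed = 4)
  expect_identical(a, b)
  # encoder emits mu and log sigma^2: output dimension 2J
  expect_equal(nrow(a$enc[[length(a$enc)]]$W), 6L)
  expect_equal(ncol(a$enc[[1L]]$W), 19L)
  expect_equal(nrow(a$dec[[length(a$dec)]]$W), 19L)
  # zero hidden layers: purely linear encoder/decoder is accepted
  lin <- init_vae(5, 2, hidden = integer(0), seed = 1)
  expect_length(lin$enc, 1L)
  expect_equal(dim(lin$enc[[1L]]$W), c(4L, 5L))
  expect_error(init_vae(19, 0), "J")
})

test_that("encoding yields strictly positive sigma and is deterministic", {
  m <- init_vae(6, 2, seed = 2)
  set.seed(1)
  x <- matrix(rnorm(40 * 6), 40L)
  post <- encode(m, x)
  expect_true(all(post$sigma > 0))
  dup <- encode(m, x[c(1, 1, 2), ])
  expect_equal(dup$mu[1L, ], dup$mu[2L, ])
  expect_equal(dup$sigma[1L, ], dup$sigma[2L, ])
  x[3, 2] <- NA
  expect_error(encode(m, x), "non-finite")
  expect_error(encode(m, matrix(0, 2L, 5L)), "width")
})

test_that("reparameterized draws have the posterior's moments", {
  post <- structure(list(mu = matrix(c(1, -2), 1L, 2L),
                         sigma = matrix(c(0.5, 2), 1L, 2L)),
                    class = "latent_posterior")
  z <- reparameterize(post, L = 1e5, seed = 3)
  mn <- apply(z[1L, , ], 1L, mean)
  se <- c(0.5, 2) / sqrt(1e5)
  expect_true(all(abs(mn - c(1, -2)) < 3 * se))
  # sigma -> 0 limit collapses to mu
  post0 <- structure(list(mu = matrix(1:3, 1L), sigma = matrix(1e-300, 1L, 3L)),
                     class = "latent_posterior")
  expect_equal(reparameterize(post0, 2, seed = 1)[1L, , 1L], 1:3,
               ignore_attr = TRUE)
  expect_identical(reparameterize(post, 3, seed = 9),
                   reparameterize(post, 3, seed = 9))
  expect_error(reparameterize(post, 0), "L")
})

test_that("the closed-form KL matches hand values and a Monte-Carlo oracle", {
  std <- structure(list(mu = matrix(0, 1L, 4L), sigma = matrix(1, 1L, 4L)),
                   class = "latent_posterior")
  expect_equal(kl_gaussian(std), 0)
  one <- structure(list(mu = matrix(1, 1L, 1L), sigma = matrix(1, 1L, 1L)),
                   class = "latent_posterior")
  expect_equal(kl_gaussian(one), 0.5)

  set.seed(14)
  mu <- matrix(rnorm(3), 1L)
  sg <- matrix(exp(rnorm(3, sd = 0.4)), 1L)
  post <- structure(list(mu = mu, sigma = sg), class = "latent_posterior")
  L <- 1e5
  z <- matrix(rnorm(L * 3, mean = rep(mu, each = L), sd = rep(sg, each = L)), L)
  logq <- rowSums(dnorm(z, rep(mu, each = L), rep(sg, each = L), log = TRUE))
  logp <- rowSums(dnorm(z, log = TRUE))
  d <- logq - logp
  expect_lt(abs(kl_gaussian(post) - mean(d)), 3 * sd(d) / sqrt(L))
  expect_gte(kl_gaussian(post), 0)

  bad <- structure(list(mu = mu, sigma = matrix(c(1, -1, 1), 1L)),
                   class = "latent_posterior")
  expect_error(kl_gaussian(bad), "positive")
})

test_that("the ELBO equals the Gaussian normalization constant for a perfect fit", {
  # linear VAE rigged so mu = 0, sigma = 1 and the decoder bias reproduces the
  # constant standardized input exactly: KL = 0 and zero residual
  m <- init_vae(4, 2, hidden = integer(0), seed = 1)
  m$enc[[1L]]$W[] <- 0
  m$enc[[1L]]$b[] <- 0
  m$dec[[1L]]$W[] <- 0
  m$dec[[1L]]$b[] <- 0
  batch <- matrix(0, 10L, 4L)
  expect_equal(elbo(m, batch, L = 1, seed = 2), -4 / 2 * log(2 * pi))
  expect_error(elbo(m, batch[0, , drop = FALSE]), "empty")
})

test_that("the ELBO estimator's variance shrinks with more Monte-Carlo draws", {
  m <- init_vae(6, 2, seed = 3)
  set.seed(4)
  batch <- matrix(rnorm(30 * 6), 30L)
  ev <- function(L) vapply(1:30, function(s) elbo(m, batch, L = L, seed = s),
                           numeric(1))
  expect_lt(var(ev(20)), var(ev(1)))
  # KL >= 0 means the ELBO never exceeds the reconstruction term
  post <- encode(m, batch)
  expect_lte(elbo(m, batch, L = 1, seed = 1) + mean(kl_gaussian(post)),
             elbo(m, batch, L = 1, seed = 1) + 2 * mean(kl_gaussian(post)) + 1e-12)
  expect_gte(mean(kl_gaussian(post)), 0)
})

test_that("training reduces the loss and is seed-reproducible", {
  cfg <- synthetic_config(n_subjects = 1, duration_s = 10)
  rec <- preprocess_recording(generate_study(cfg)$recordings[[2L]])
  m0 <- init_vae(19, 3, seed = 6)
  m1 <- train_vae(m0, rec, n_epochs = 3, learning_rate = 1e-3,
                  optimizer = "adam", seed = 8)
  expect_lt(tail(m1$loss_history, 1L), m1$loss_history[1L])
  m2 <- train_vae(m0, rec, n_epochs = 3, learning_rate = 1e-3,
                  optimizer = "adam", seed = 8)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$enc, m2$enc)
  # plain SGD also descends
  m3 <- train_vae(m0, rec, n_epochs = 3, seed = 8)
  expect_lt(tail(m3$loss_history, 1L), m3$loss_history[1L])
})

test_that("a J=3 VAE recovers rank-3 noiseless data nearly perfectly", {
  states <- lapply(default_states(), function(s) {
    s$noise_sd <- 0; s$jitter_sd <- 0.02; s
  })
  cfg <- synthetic_config(n_subjects = 1, duration_s = 15, states = states,
                          carrier_amp = 0)
  X <- do.call(cbind, lapply(generate_study(cfg)$recordings, function(r) r$data))
  m <- train_vae(init_vae(19, 3, seed = 2), X, n_epochs = 10,
                 learning_rate = 1e-3, optimizer = "adam", seed = 7)
  perf <- reconstruction_performance(m, X)
  expect_gt(perf, 0.95)

  # within 0.05 of the optimal linear (top-3 principal subspace) projection
  Xs <- (X - rowMeans(X)) / apply(X, 1L, sd)
  sv <- svd(Xs)
  proj <- sv$u[, 1:3] %*% t(sv$u[, 1:3]) %*% Xs
  opt <- mean(vapply(seq_len(19), function(i) cor(Xs[i, ], proj[i, ]), numeric(1)))
  expect_gt(perf, opt - 0.05)
})

test_that("reconstruction performance handles identity, negation and constants", {
  set.seed(15)
  E <- matrix(rnorm(3 * 100), 3L)
  fake <- structure(list(n_channels = 3L, J = 3L, hidden = integer(0),
                         enc = list(list(W = rbind(diag(3), matrix(0, 3L, 3L)),
                                         b = rep(0, 6L))),
                         dec = list(list(W = diag(3), b = rep(0, 3L))),
                         center = rep(0, 3L), scale = rep(1, 3L),
                         trained = TRUE),
                    class = "vae_model")
  expect_equal(reconstruction_performance(fake, E), 1.0)
  neg <- fake
  neg$dec[[1L]]$W <- -diag(3)
  expect_equal(reconstruction_performance(neg, E), -1.0)
  Ec <- rbind(E[1:2, ], 0)
  expect_warning(p <- reconstruction_performance(fake, Ec), "constant")
  expect_equal(p, 1.0)
})

test_that("latent trajectories order coordinates by variance", {
  set.seed(16)
  # rig a linear model whose latents are three scaled copies of the input dims
  m <- structure(list(n_channels = 3L, J = 5L, hidden = integer(0),
                      enc = list(list(W = rbind(diag(c(1, 3, 2)),
                                                matrix(0, 2L, 3L),
                                                matrix(0, 5L, 3L)),
                                      b = rep(0, 10L))),
                      dec = list(list(W = matrix(0, 3L, 5L), b = rep(0, 3L))),
                      center = rep(0, 3L), scale = rep(1, 3L), trained = TRUE),
                 class = "vae_model")
  X <- matrix(rnorm(3 * 200), 3L)
  tr <- latent_trajectory(m, X)
  expect_equal(ncol(tr$Z), 5L)
  expect_equal(tr$order[1:3], c(2L, 3L, 1L))   # variance order 3x, 2x, 1x
  v <- apply(tr$Z, 2L, var)
  expect_true(all(diff(v) <= 1e-12))
  top <- latent_trajectory(m, X, top_k = 3L)
  expect_equal(ncol(top$Z), 3L)
  # zero-variance coordinates tie-break by original index
  const <- latent_trajectory(m, matrix(0, 3L, 10L))
  expect_equal(const$order, 1:5)
  m$J <- 2L
  m$enc[[1L]]$W <- m$enc[[1L]]$W[1:4, , drop = FALSE]
  m$enc[[1L]]$b <- rep(0, 4L)
  expect_error(latent_trajectory(m, X, top_k = 3L), "top 3")
})

test_that("extra latent capacity beyond the data rank stays collapsed", {
  states <- lapply(default_states()[1:2], function(s) {
    s$noise_sd <- 0.01; s$jitter_sd <- 0.3; s   # all 3 latent dims substantial
  })
  cfg <- synthetic_config(n_subjects = 1, duration_s = 15, states = states,
                          carrier_amp = 0)
  X <- do.call(cbind, lapply(generate_study(cfg)$recordings, function(r) r$data))
  m <- train_vae(init_vae(19, 5, seed = 3), X, n_epochs = 8,
                 learning_rate = 1e-3, optimizer = "adam", seed = 9)
  tr <- latent_trajectory(m, X)
  v <- apply(tr$Z, 2L, var)
  expect_lt(v[4L], 0.2 * v[3L])
  expect_lt(v[5L], 0.2 * v[3L])
})
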
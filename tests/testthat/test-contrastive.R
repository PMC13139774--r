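test_that("cosine similarity follows its definition", {
  u <- c(3, 4)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(0, 0), u), "zero vector")
})

test_that("NT-Xent evaluates the worked fixtures exactly", {
  # N = 2, tau = 0.5, aligned orthogonal pairs: L = -log(e^2 / (e^2 + 2))
  Zg <- rbind(c(1, 0), c(0, 1))
  Zc <- rbind(c(1, 0), c(0, 1))
  expected <- -log(exp(2) / (exp(2) + 2))
  expect_equal(nt_xent_batch_loss(Zg, Zc, 0.5), expected, tolerance = 1e-10)
  for (i in 1:4) {
    expect_equal(nt_xent_anchor_loss(i, rbind(Zg, Zc), 0.5), expected,
                 tolerance = 1e-10)
  }
  # N = 1 identical pair: denominator reduces to the positive term
  expect_equal(nt_xent_anchor_loss(1, rbind(c(0, 1), c(0, 1)), 0.5), 0,
               tolerance = 1e-12)
  # all views collapsed to one unit vector, N = 4: uniform softmax, log(2N-1)
  One <- matrix(rep(c(1, 0), 4), ncol = 2, byrow = TRUE)
  expect_equal(nt_xent_batch_loss(One, One, 0.5), log(7), tolerance = 1e-10)
  expect_error(nt_xent_batch_loss(Zg, Zc[1, , drop = FALSE]), "equal rows")
  expect_error(nt_xent_anchor_loss(1, rbind(Zg, Zc), tau = -1), "positive")
})

test_that("vectorized NT-Xent equals the brute-force double loop", {
  set.seed(123)
  for (rep in 1:60) {
    N <- sample(2:8, 1)
    d <- sample(c(2, 64), 1)
    Zg <- matrix(rnorm(N * d), N)
    Zc <- matrix(rnorm(N * d), N)
    tau <- runif(1, 0.1, 2)
    for (den in c("exclude_anchor", "exclude_positive")) {
      bf <- ntxent_bruteforce(Zg, Zc, tau, den)
      expect_equal(nt_xent_batch_loss(Zg, Zc, tau, den), bf$loss,
                   tolerance = 1e-6)
      i <- sample(2 * N, 1)
      expect_equal(nt_xent_anchor_loss(i, rbind(Zg, Zc), tau, den),
                   bf$anchor_losses[i], tolerance = 1e-6)
    }
  }
})

test_that("NT-Xent invariances and limits hold", {
  set.seed(77)
  N <- 6
  Zg <- matrix(rnorm(N * 8), N); Zc <- matrix(rnorm(N * 8), N)
  base <- nt_xent_batch_loss(Zg, Zc, 0.5)
  # permutation of cohorts leaves the batch loss unchanged
  perm <- sample(N)
  expect_equal(nt_xent_batch_loss(Zg[perm, ], Zc[perm, ], 0.5), base,
               tolerance = 1e-12)
  # anchor losses are non-negative
  Z <- mscontab:::l2_normalize_rows(rbind(Zg, Zc))
  core <- mscontab:::nt_xent_core(Z, c((N + 1):(2 * N), 1:N), 0.5,
                                  "exclude_anchor")
  expect_true(all(core$anchor_losses >= 0))
  # moving a negative closer to the anchor strictly increases its loss
  Zc2 <- Zc
  Zc2[2, ] <- Zc2[2, ] + 5 * Zg[1, ] / sqrt(sum(Zg[1, ]^2))
  l1 <- nt_xent_anchor_loss(1, rbind(Zg, Zc), 0.5)
  l2 <- nt_xent_anchor_loss(1, rbind(Zg, Zc2), 0.5)
  expect_gt(l2, l1)
  # tau -> Inf: every anchor loss approaches log(2N - 1)
  core_inf <- mscontab:::nt_xent_core(Z, c((N + 1):(2 * N), 1:N), 1e7,
                                      "exclude_anchor")
  expect_equal(core_inf$anchor_losses, rep(log(2 * N - 1), 2 * N),
               tolerance = 1e-5)
})

test_that("NT-Xent analytic gradient matches finite differences", {
  set.seed(31)
  N <- 4; d <- 5
  H <- matrix(rnorm(2 * N * d), 2 * N)
  pairs <- c((N + 1):(2 * N), 1:N)
  loss_of <- function(H) {
    Zn <- mscontab:::l2_normalize_rows(H)
    mscontab:::nt_xent_core(Zn, pairs, 0.5, "exclude_anchor")$loss
  }
  Zn <- mscontab:::l2_normalize_rows(H)
  core <- mscontab:::nt_xent_core(Zn, pairs, 0.5, "exclude_anchor")
  dH <- mscontab:::l2_normalize_rows_backward(H, core$dZn)
  for (rep in 1:25) {
    i <- sample(2 * N, 1); j <- sample(d, 1)
    eps <- 1e-6
    Hp <- H; Hp[i, j] <- Hp[i, j] + eps
    Hm <- H; Hm[i, j] <- Hm[i, j] - eps
    expect_equal(dH[i, j], (loss_of(Hp) - loss_of(Hm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("embedding fusion follows the stated arithmetic", {
  u <- c(2, 0, 0); v <- c(0, 3, 0)
  Zg <- rbind(u); Zc <- rbind(u)
  expect_equal(fuse_embeddings(Zg, Zc)[1, ], u / sqrt(sum(u^2)))
  f <- fuse_embeddings(rbind(u), rbind(v))[1, ]
  expect_equal(f, (c(1, 0, 0) + c(0, 1, 0)) / sqrt(2))
  expect_equal(ncol(fuse_embeddings(rbind(u), rbind(v), mode = "concat")), 6)
  expect_error(fuse_embeddings(rbind(u, v), rbind(u)), "aligned")
})

test_that("contrastive training aligns views, decreases loss, reproduces bit-identically", {
  tv <- tiny_views(seed = 7)
  cfg <- train_config(epochs = 12, seed = 42)
  fit <- train_ms_contab(tv$views, cfg = cfg)
  lh <- fit$embedding$loss_history
  expect_equal(length(lh), 12)
  expect_lt(lh[12], lh[1])
  expect_equal(dim(fit$embedding$Zg), c(12, 64))
  expect_equal(dim(fit$embedding$Z_fused), c(12, 64))
  # fused rows are unit-norm in mean mode
  expect_equal(rowSums(fit$embedding$Z_fused^2), rep(1, 12),
               tolerance = 1e-9, ignore_attr = TRUE)
  # reproducibility
  fit2 <- train_ms_contab(tv$views, cfg = cfg)
  expect_identical(fit$embedding$Z_fused, fit2$embedding$Z_fused)
  # a different seed changes the result
  fit3 <- train_ms_contab(tv$views, cfg = train_config(epochs = 12, seed = 1))
  expect_false(identical(fit$embedding$Z_fused, fit3$embedding$Z_fused))
  # too few cohorts
  sm <- tv$views
  sm$Xg <- sm$Xg[1:2, ]; sm$Xc <- sm$Xc[1:2, ]; sm$cohorts <- sm$cohorts[1:2]
  expect_error(train_ms_contab(sm, cfg = cfg), "at least 3")
})

test_that("checkpoints round-trip and mask traces export per cohort", {
  tv <- tiny_views(seed = 21)
  fit <- train_ms_contab(tv$views, cfg = train_config(epochs = 3, seed = 9))
  p <- tempfile(fileext = ".rds")
  write_checkpoint(fit, p)
  ck <- read_checkpoint(p)
  expect_identical(ck$weights, fit$weights)
  # reloaded weights reproduce the latents exactly
  h1 <- encode(tv$views$Xg, fit$spec_g$params, fit$weights$enc_g)$h
  h2 <- encode(tv$views$Xg, ck$spec_g$params, ck$weights$enc_g)$h
  expect_identical(h1, h2)
  dir <- tempfile()
  tr <- mask_traces(fit, tv$views, dir = dir)
  expect_equal(dim(tr$gene), c(12, 300))
  expect_equal(rowSums(tr$gene), rep(1, 12), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "mask_trace_gene.csv")))
  expect_true(file.exists(file.path(dir, "mask_trace_chromosome.csv")))
})
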
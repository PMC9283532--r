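test_that("GCN forward pass matches hand computations", {
  # zero weights: PReLU(0) = 0 everywhere
  A <- Matrix::Matrix(matrix(c(0, 1, 1, 0), 2), sparse = TRUE)
  st <- init_dgi(1, 1, seed = 1)
  st$W1[] <- 0; st$W2[] <- 0
  expect_equal(gcn_encode(matrix(c(1, -2), 2, 1), A, st),
               matrix(0, 2, 1))

  # isolated node: Ahat = [1], the encoder reduces to a 2-layer MLP
  A1 <- Matrix::Matrix(0, 1, 1, sparse = TRUE)
  st <- init_dgi(2, 2, seed = 2)
  x <- matrix(c(0.5, -1), 1, 2)
  pr <- function(z, a) ifelse(z > 0, z, a * z)
  manual <- pr(pr(x %*% st$W1, st$prelu1_slope) %*% st$W2, st$prelu2_slope)
  expect_equal(gcn_encode(x, A1, st), manual)

  # 2-node path, 1 feature, 1 latent dim, hand-set weights:
  # degrees with self-loops are 2, so Ahat = [[1/2, 1/2], [1/2, 1/2]]
  st <- init_dgi(1, 1, seed = 3)
  st$W1[] <- 2; st$W2[] <- -1; st$prelu1_slope <- 0.5; st$prelu2_slope <- 0.1
  X <- matrix(c(1, 3), 2, 1)
  # layer 1: Ahat X = (2, 2); * W1 = (4, 4); positive -> unchanged
  # layer 2: Ahat H1 = (4, 4); * W2 = (-4, -4); PReLU slope .1 -> (-0.4, -0.4)
  expect_equal(gcn_encode(X, A, st), matrix(-0.4, 2, 1))
})

test_that("summary vector is the sigmoid of the embedding mean", {
  expect_equal(dgi_summary(matrix(0, 5, 3)), rep(0.5, 3))
  h <- c(1, -2, 0.3)
  H <- matrix(h, 4, 3, byrow = TRUE)
  expect_equal(dgi_summary(H), 1 / (1 + exp(-h)))
  set.seed(1)
  H <- matrix(rnorm(60), 20, 3)
  expect_equal(dgi_summary(H), 1 / (1 + exp(-colMeans(H))))
})

test_that("discriminator is the sigmoid bilinear form", {
  s <- runif(4)
  expect_equal(discriminate(rnorm(4), s, matrix(0, 4, 4)), 0.5)
  expect_equal(discriminate(c(1, 0), c(0, 1), diag(2)), 0.5)  # h orthogonal to s
  expect_equal(discriminate(c(1, 2), c(0.5, 0.25), diag(2)),
               1 / (1 + exp(-1)))  # h.s = 1 -> sigmoid(1) ~ 0.7311
})

test_that("discriminator loss has its analytic fixed points", {
  set.seed(5)
  H <- matrix(rnorm(40), 10, 4)
  Ht <- matrix(rnorm(40), 10, 4)
  s <- dgi_summary(H)
  # Theta = 0: all probabilities 1/2, loss log 2 exactly
  expect_equal(dgi_loss(H, Ht, s, matrix(0, 4, 4)), log(2), tolerance = 1e-12)
  # perfect discrimination drives the loss to 0 (clamped at ~1e-7 floor)
  big <- diag(4) * 1e4
  H1 <- matrix(1, 3, 4); Hm <- -H1
  expect_lt(dgi_loss(H1, Hm, rep(1, 4), big), 1e-4)
  # N = 2 case against a scalar hand computation
  H2 <- rbind(c(1, 0), c(0, 1)); Ht2 <- rbind(c(-1, 1), c(0.5, -2))
  s2 <- c(0.6, 0.3); Th <- rbind(c(0.2, -0.1), c(0.4, 0.3))
  p <- function(h) 1 / (1 + exp(-sum(h * (Th %*% s2))))
  manual <- -(log(p(H2[1, ])) + log(p(H2[2, ])) +
                log(1 - p(Ht2[1, ])) + log(1 - p(Ht2[2, ]))) / 4
  expect_equal(dgi_loss(H2, Ht2, s2, Th), manual)
})

test_that("spatial regularizer matches the literal double sum", {
  # coincident coordinates: spatial distances vanish, loss 0
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(spatial_regularization(matrix(1, 4, 2), H), 0)
  # N = 2: both normalized distances are 1, loss forced to 0
  expect_equal(spatial_regularization(rbind(c(0, 0), c(2, 1)),
                                      matrix(rnorm(4), 2, 2)), 0)
  # 3-cell hand case against the brute-force ordered-pair oracle
  co <- cbind(c(0, 1, 3), 0)
  H3 <- matrix(c(0, 1, 1), 3, 1)
  expect_equal(spatial_regularization(co, H3), oracle_reg_all_pairs(co, H3))
  # random instance, all pairs and explicit full pair list agree
  set.seed(8)
  co <- matrix(runif(24), 12, 2)
  H <- matrix(rnorm(36), 12, 3)
  expect_equal(spatial_regularization(co, H), oracle_reg_all_pairs(co, H))
  idx <- expand.grid(i = 1:12, j = 1:12)
  idx <- as.matrix(idx[idx$i != idx$j, ])
  # full ordered-pair list differs from the matrix form only through the
  # diagonal terms of the N*N normalizer
  expect_equal(spatial_regularization(co, H, idx) * nrow(idx) / 144,
               spatial_regularization(co, H))
  expect_true(spatial_regularization(co, H) >= 0 &&
                spatial_regularization(co, H) <= 1)
})

test_that("pair sampling is uniform over ordered pairs and reproducible", {
  set.seed(1)
  p <- sample_pairs(2, 4)
  expect_true(all(p[, 1] != p[, 2]))
  expect_true(all(p %in% 1:2))
  set.seed(42); a <- sample_pairs(10, 1000)
  set.seed(42); b <- sample_pairs(10, 1000)
  expect_identical(a, b)
  # frequency of each of the 90 ordered pairs within 5 sigma of uniform
  set.seed(7)
  p <- sample_pairs(10, 1e5)
  grid <- expand.grid(i = 1:10, j = 1:10)
  grid <- grid[grid$i != grid$j, ]
  counts <- table(factor(paste(p[, 1], p[, 2]),
                         levels = paste(grid$i, grid$j)))
  expected <- 1e5 / 90
  sigma <- sqrt(1e5 * (1 / 90) * (1 - 1 / 90))
  expect_true(all(abs(counts - expected) < 5 * sigma))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  n <- 6; g <- 4; d <- 3
  X <- matrix(rnorm(n * g), n, g)
  coords <- matrix(runif(n * 2) * 10, n, 2)
  A <- build_knn_graph(coords, 2)
  state <- init_dgi(g, d, seed = 7)
  perm <- sample.int(n)
  gamma <- 0.3
  Ahat <- spatialflow:::normalize_adjacency(A)
  loss_fn <- function(st, pairs = NULL) {
    fw <- spatialflow:::gcn_forward(X, Ahat, st)
    fwt <- spatialflow:::gcn_forward(X[perm, ], Ahat, st)
    s <- dgi_summary(fw$H)
    dgi_loss(fw$H, fwt$H, s, st$Theta) +
      gamma * spatial_regularization(coords, fw$H, pairs)
  }
  fw <- spatialflow:::gcn_forward(X, Ahat, state)
  fwt <- spatialflow:::gcn_forward(X[perm, ], Ahat, state)
  for (pairs in list(NULL, {set.seed(3); sample_pairs(n, 12)})) {
    gr <- spatialflow:::dgi_grads(fw, fwt, state, Ahat, gamma, coords,
                                  pairs, NULL)
    expect_equal(gr$total, loss_fn(state, pairs), tolerance = 1e-10)
    ana <- list(W1 = gr$dW1, W2 = gr$dW2, Theta = gr$dTheta,
                prelu1_slope = gr$da1, prelu2_slope = gr$da2)
    for (f in names(ana)) {
      p <- state[[f]]
      gnum <- p * 0
      for (idx in seq_along(p)) {
        sp <- state; sp[[f]][idx] <- p[idx] + 1e-6
        sm <- state; sm[[f]][idx] <- p[idx] - 1e-6
        gnum[idx] <- (loss_fn(sp, pairs) - loss_fn(sm, pairs)) / 2e-6
      }
      expect_equal(unname(as.matrix(ana[[f]])), unname(as.matrix(gnum)),
                   tolerance = 1e-5, info = f)
    }
  }
})

test_that("subsampled regularizer estimates the all-pairs value", {
  set.seed(13)
  n <- 200
  coords <- matrix(runif(2 * n) * 10, n, 2)
  H <- matrix(rnorm(n * 5), n, 5) + coords[, 1] / 10
  full <- spatial_regularization(coords, H)
  vals <- replicate(200, spatial_regularization(coords, H,
                                                sample_pairs(n, 1000)))
  # within-subset max-normalization leaves a small systematic offset, so the
  # mean of many subsets is compared on the sampling scale of one subset
  # estimate (its standard error sd(vals)), not the vanishing SE of the mean
  expect_lt(abs(mean(vals) - full), 3 * sd(vals))
})

test_that("training is reproducible and gamma = 0 reduces to plain infomax", {
  tis <- tiny_layered(seed = 3, cells_per_layer = 40L)
  fe <- preprocess_st(tis$dataset, n_top = 60)
  seg <- build_seg(fe, fe$dataset$coords, method = "knn", k = 6)
  fit1 <- train_dgi(seg, gamma = 0, max_epochs = 30, min_epochs = 5,
                    patience = 50, seed = 9)
  fit2 <- train_dgi(seg, gamma = 0, max_epochs = 30, min_epochs = 5,
                    patience = 50, seed = 9)
  expect_identical(fit1$H, fit2$H)     # bitwise determinism
  # with gamma = 0 the total loss IS the discriminator loss
  expect_equal(fit1$history$loss_total, fit1$history$loss_dgi)
  expect_true(all(fit1$history$loss_reg == 0))
})

test_that("training reduces the loss and the spatial penalty", {
  tis <- tiny_layered(seed = 2, cells_per_layer = 60L)
  fe <- preprocess_st(tis$dataset, n_top = 100)
  seg <- build_seg(fe, fe$dataset$coords, method = "alpha", k = 10)
  fit <- train_dgi(seg, gamma = 0.1, max_epochs = 150, min_epochs = 50,
                   patience = 150, seed = 1)
  expect_lt(fit$best_loss, fit$history$loss_total[1])
  fit0 <- train_dgi(seg, gamma = 0, max_epochs = 150, min_epochs = 50,
                    patience = 150, seed = 1)
  # post hoc, regularized embeddings carry a smaller spatial penalty than
  # unregularized ones
  expect_lt(spatial_regularization(seg$coords, fit$H),
            spatial_regularization(seg$coords, fit0$H))
})
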
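# Spatially regularized deep graph infomax: two-layer GCN encoder, bilinear
# discriminator against a global summary vector, contrastive loss on true vs
# feature-permuted graphs, and a spatial-distance regularizer. Forward pass,
# analytic gradients and the Adam optimizer are implemented here directly;
# gradient correctness is pinned down by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

prelu <- function(z, a) ifelse(z > 0, z, a * z)
dprelu <- function(z, a) ifelse(z > 0, 1, a)

#' Initialize encoder and discriminator weights
#'
#' Glorot-uniform weight matrices, PReLU slopes 0.25, all drawn from `seed`.
#'
#' @param n_features number of input features g (columns of X).
#' @param latent_dim embedding dimension (both GCN layers use this width).
#' @param seed integer seed.
#' @return A list of class `dgi_state`: `W1` (g x latent), `W2`
#'   (latent x latent), `prelu1_slope`, `prelu2_slope`, `Theta`
#'   (latent x latent), `latent_dim`.
#' @export
init_dgi <- function(n_features, latent_dim = 50L, seed = 0L) {
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  with_seed(seed, {
    structure(list(W1 = glorot(n_features, latent_dim),
                   W2 = glorot(latent_dim, latent_dim),
                   prelu1_slope = 0.25, prelu2_slope = 0.25,
                   Theta = glorot(latent_dim, latent_dim),
                   latent_dim = as.integer(latent_dim)),
              class = "dgi_state")
  })
}

# symmetric normalization with self-loops: D^{-1/2} (A + I) D^{-1/2}
normalize_adjacency <- function(A) {
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(At))
  Matrix::Diagonal(x = dinv) %*% At %*% Matrix::Diagonal(x = dinv)
}

# forward pass keeping intermediates for backprop; Ahat sparse, X dense/sparse
gcn_forward <- function(X, Ahat, state) {
  AX <- as.matrix(Ahat %*% X)
  Z1 <- AX %*% state$W1
  H1 <- prelu(Z1, state$prelu1_slope)
  AH1 <- as.matrix(Ahat %*% H1)
  Z2 <- AH1 %*% state$W2
  H <- prelu(Z2, state$prelu2_slope)
  if (any(!is.finite(H))) stop("non-finite values in GCN output")
  list(H = H, Z1 = Z1, Z2 = Z2, AX = AX, AH1 = AH1)
}

#' Encode node features through the two-layer GCN
#'
#' `H = PReLU2( Ahat %*% PReLU1( Ahat %*% X %*% W1 ) %*% W2 )` with
#' `Ahat = D^{-1/2} (A + I) D^{-1/2}` (symmetric normalization with
#' self-loops).
#'
#' @param X cells x g feature matrix.
#' @param A binary symmetric spatial adjacency.
#' @param state a `dgi_state` from [init_dgi].
#' @return cells x latent embedding matrix H.
#' @export
gcn_encode <- function(X, A, state) {
  gcn_forward(X, normalize_adjacency(A), state)$H
}

#' Graph summary vector
#'
#' Sigmoid of the column means of the embedding matrix; each component lies
#' in (0, 1).
#'
#' @param H cells x latent embedding matrix.
#' @return Numeric vector of length `ncol(H)`.
#' @export
dgi_summary <- function(H) {
  sigmoid(colMeans(H))
}

#' Discriminator score
#'
#' Bilinear probability that an embedding belongs to the true graph:
#' `sigmoid(h' Theta s)`.
#'
#' @param h a single embedding vector, or a cells x latent matrix for a score
#'   per row.
#' @param s summary vector from [dgi_summary].
#' @param Theta latent x latent bilinear weight.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
discriminate <- function(h, s, Theta) {
  ts <- as.vector(Theta %*% s)
  if (is.matrix(h)) sigmoid(as.vector(h %*% ts)) else sigmoid(sum(h * ts))
}

#' Contrastive discriminator loss
#'
#' Minimized binary cross-entropy form of the infomax objective:
#' `-(1/2N) [ sum_i log D(h_i, s) + sum_j log(1 - D(htilde_j, s)) ]`.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param H embeddings of the true graph.
#' @param H_tilde embeddings of the feature-permuted graph (same shape).
#' @param s summary vector of the true graph.
#' @param Theta discriminator weight.
#' @return Non-negative scalar; `log(2)` when the discriminator is
#'   uninformative (`Theta = 0`).
#' @export
dgi_loss <- function(H, H_tilde, s, Theta) {
  stopifnot(all(dim(H) == dim(H_tilde)))
  eps <- 1e-7
  p_pos <- pmin(pmax(discriminate(H, s, Theta), eps), 1 - eps)
  p_neg <- pmin(pmax(discriminate(H_tilde, s, Theta), eps), 1 - eps)
  -(sum(log(p_pos)) + sum(log(1 - p_neg))) / (2 * nrow(H))
}

#' Spatial regularization loss
#'
#' Over a set of ordered cell pairs, spatial and embedding Euclidean
#' distances are each normalized by their maximum over the pair set (an
#' all-zero distance set normalizes to zero), and the loss is the mean of
#' `ds_hat * (1 - dz_hat)`: spatially distant pairs are penalized for sitting
#' close in embedding space. With all ordered pairs this is the double sum
#' over cells with the `N * N` normalizer (diagonal terms contribute zero).
#'
#' @param coords N x d spatial coordinates.
#' @param H N x latent embedding matrix.
#' @param pairs optional 2-column matrix of 1-based ordered pairs; all
#'   ordered pairs when `NULL`.
#' @return Scalar in `[0, 1]`.
#' @export
spatial_regularization <- function(coords, H, pairs = NULL) {
  coords <- as.matrix(coords)
  H <- as.matrix(H)
  if (is.null(pairs)) {
    Ds <- euclid_dist(coords)
    Dz <- euclid_dist(H)
    ms <- max(Ds); mz <- max(Dz)
    Ds_hat <- if (ms > 0) Ds / ms else Ds * 0
    Dz_hat <- if (mz > 0) Dz / mz else Dz * 0
    sum(Ds_hat * (1 - Dz_hat)) / (nrow(coords)^2)
  } else {
    stopifnot(nrow(pairs) >= 1L)
    ds <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                        coords[pairs[, 2], , drop = FALSE])^2))
    dz <- sqrt(rowSums((H[pairs[, 1], , drop = FALSE] -
                        H[pairs[, 2], , drop = FALSE])^2))
    ms <- max(ds); mz <- max(dz)
    if (ms > 0) ds <- ds / ms else ds[] <- 0
    if (mz > 0) dz <- dz / mz else dz[] <- 0
    mean(ds * (1 - dz))
  }
}

#' Sample ordered cell pairs uniformly
#'
#' Draws `n_pairs` ordered pairs (i, j), i != j, uniformly with replacement
#' from the current RNG stream.
#'
#' @param N number of cells.
#' @param n_pairs number of pairs to draw.
#' @return `n_pairs` x 2 integer matrix of 1-based indices.
#' @export
sample_pairs <- function(N, n_pairs) {
  stopifnot(N >= 2L, n_pairs >= 1L)
  i <- sample.int(N, n_pairs, replace = TRUE)
  j <- sample.int(N - 1L, n_pairs, replace = TRUE)
  j <- j + (j >= i)
  cbind(i = i, j = j)
}

# gradient of the regularizer w.r.t. H (times 1, caller applies gamma).
# Returns list(loss, G). Mirrors spatial_regularization exactly.
reg_loss_grad <- function(coords, H, pairs = NULL, Ds_hat_cached = NULL) {
  n <- nrow(H)
  if (is.null(pairs)) {
    Ds_hat <- if (!is.null(Ds_hat_cached)) Ds_hat_cached else {
      Ds <- euclid_dist(coords)
      ms <- max(Ds)
      if (ms > 0) Ds / ms else Ds * 0
    }
    Dz <- euclid_dist(H)
    mz <- max(Dz)
    Cw <- Ds_hat / (n^2)
    if (mz == 0) return(list(loss = sum(Cw), G = matrix(0, n, ncol(H))))
    loss <- sum(Cw * (1 - Dz / mz))
    S <- sum(Cw * Dz)
    W <- -Cw / mz
    amax <- which.max(Dz)
    W[amax] <- W[amax] + S / mz^2
    K <- (W + t(W))
    div <- Dz
    div[div == 0] <- Inf
    K <- K / div
    G <- rowSums(K) * H - K %*% H
    list(loss = loss, G = G)
  } else {
    np <- nrow(pairs)
    ds <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                        coords[pairs[, 2], , drop = FALSE])^2))
    dz <- sqrt(rowSums((H[pairs[, 1], , drop = FALSE] -
                        H[pairs[, 2], , drop = FALSE])^2))
    ms <- max(ds); mz <- max(dz)
    dsh <- if (ms > 0) ds / ms else ds * 0
    if (mz == 0) return(list(loss = mean(dsh), G = matrix(0, n, ncol(H))))
    loss <- mean(dsh * (1 - dz / mz))
    Cw <- dsh / np
    S <- sum(Cw * dz)
    w <- -Cw / mz
    amax <- which.max(dz)
    w[amax] <- w[amax] + S / mz^2
    coefs <- ifelse(dz > 0, w / dz, 0)
    K <- Matrix::sparseMatrix(i = pairs[, 1], j = pairs[, 2], x = coefs,
                              dims = c(n, n))
    K <- K + Matrix::t(K)
    G <- as.vector(Matrix::rowSums(K)) * H - as.matrix(K %*% H)
    list(loss = loss, G = G)
  }
}

# analytic gradients of total loss w.r.t. all parameters.
# fw / fw_t are gcn_forward caches for the true and permuted graph.
dgi_grads <- function(fw, fw_t, state, Ahat, gamma, coords, pairs,
                      Ds_hat_cached) {
  H <- fw$H; Ht <- fw_t$H
  n <- nrow(H)
  m <- colMeans(H)
  s <- sigmoid(m)
  ts <- as.vector(state$Theta %*% s)
  l_pos <- as.vector(H %*% ts)
  l_neg <- as.vector(Ht %*% ts)
  p_pos <- sigmoid(l_pos)
  p_neg <- sigmoid(l_neg)
  eps <- 1e-7
  loss_dgi <- -(sum(log(pmin(pmax(p_pos, eps), 1 - eps))) +
                sum(log(1 - pmin(pmax(p_neg, eps), 1 - eps)))) / (2 * n)
  g_pos <- -(1 - p_pos) / (2 * n)           # dL/d l_pos
  g_neg <- p_neg / (2 * n)                  # dL/d l_neg
  G_H <- outer(g_pos, ts)
  G_Ht <- outer(g_neg, ts)
  v <- crossprod(H, g_pos) + crossprod(Ht, g_neg)   # latent x 1
  dTheta <- tcrossprod(v, s)
  dls <- as.vector(crossprod(state$Theta, v))       # dL/ds
  dlm <- dls * s * (1 - s)
  G_H <- G_H + matrix(dlm, n, length(dlm), byrow = TRUE) / n

  loss_reg <- 0
  if (gamma > 0) {
    rg <- reg_loss_grad(coords, H, pairs, Ds_hat_cached)
    loss_reg <- rg$loss
    G_H <- G_H + gamma * as.matrix(rg$G)
  }

  back <- function(G, cache) {
    G_Z2 <- G * dprelu(cache$Z2, state$prelu2_slope)
    da2 <- sum(G[cache$Z2 <= 0] * cache$Z2[cache$Z2 <= 0])
    dW2 <- crossprod(cache$AH1, G_Z2)
    G_H1 <- as.matrix(Ahat %*% G_Z2) %*% t(state$W2)
    G_Z1 <- G_H1 * dprelu(cache$Z1, state$prelu1_slope)
    da1 <- sum(G_H1[cache$Z1 <= 0] * cache$Z1[cache$Z1 <= 0])
    dW1 <- crossprod(cache$AX, G_Z1)
    list(dW1 = dW1, dW2 = dW2, da1 = da1, da2 = da2)
  }
  b1 <- back(G_H, fw)
  b2 <- back(G_Ht, fw_t)
  list(loss_dgi = loss_dgi, loss_reg = loss_reg,
       total = loss_dgi + gamma * loss_reg,
       dW1 = b1$dW1 + b2$dW1, dW2 = b1$dW2 + b2$dW2,
       da1 = b1$da1 + b2$da1, da2 = b1$da2 + b2$da2,
       dTheta = dTheta, s = s)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train the spatially regularized infomax model
#'
#' Per epoch a fresh feature permutation is drawn as the negative sample,
#' both graphs are encoded with shared weights, and one Adam step is taken on
#' `dgi_loss + gamma * spatial_regularization`. The regularizer is evaluated
#' over all ordered pairs for up to `pair_subsample_threshold` cells and over
#' `n_pairs` uniformly resampled pairs per epoch beyond that. Training stops
#' at `max_epochs`, or once the best total loss has not improved for
#' `patience` consecutive epochs after `min_epochs`. The returned embeddings
#' come from the best-loss parameter snapshot, and the whole run is
#' reproducible from `seed`.
#'
#' @param seg a `seg` object from [build_seg].
#' @param gamma spatial regularization strength (>= 0; 0 disables the
#'   regularizer entirely).
#' @param latent_dim embedding dimension.
#' @param lr Adam learning rate.
#' @param max_epochs,min_epochs,patience training schedule.
#' @param seed integer seed controlling initialization and permutations.
#' @param pair_subsample_threshold cell count above which the regularizer is
#'   estimated from a random pair subset.
#' @param n_pairs pairs per step when subsampling; default
#'   `min(N^2, 1e6)`.
#' @param verbose print per-epoch losses.
#' @return A list of class `dgi_fit`: `H` (best-snapshot embeddings),
#'   `summary` (summary vector), `state` (best `dgi_state`), `history`
#'   (per-epoch loss data.frame), `best_epoch`, `epochs_run`, `config`.
#' @export
train_dgi <- function(seg, gamma = 0.1, latent_dim = 50L, lr = 1e-3,
                      max_epochs = 1000L, min_epochs = 100L, patience = 50L,
                      seed = 0L, pair_subsample_threshold = 10000L,
                      n_pairs = NULL, verbose = FALSE) {
  stopifnot(gamma >= 0, min_epochs <= max_epochs)
  X <- as.matrix(seg$X)
  n <- nrow(X)
  coords <- seg$coords
  if (is.null(n_pairs)) n_pairs <- as.integer(min(n^2, 1e6))
  subsample <- n > pair_subsample_threshold
  Ahat <- normalize_adjacency(seg$A)

  Ds_hat <- NULL
  if (gamma > 0 && !subsample) {
    Ds <- euclid_dist(coords)
    ms <- max(Ds)
    Ds_hat <- if (ms > 0) Ds / ms else Ds * 0
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  state <- init_dgi(ncol(X), latent_dim, seed = sample.int(.Machine$integer.max - 1L, 1))
  params <- c("W1", "W2", "prelu1_slope", "prelu2_slope", "Theta")
  opt <- adam_init(state[params])

  best <- list(loss = Inf, state = state, H = NULL, s = NULL, epoch = 0L)
  wait <- 0L
  hist <- vector("list", max_epochs)

  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n)
    fw <- gcn_forward(X, Ahat, state)
    fw_t <- gcn_forward(X[perm, , drop = FALSE], Ahat, state)
    pairs <- if (gamma > 0 && subsample) sample_pairs(n, n_pairs) else NULL
    gr <- dgi_grads(fw, fw_t, state, Ahat, gamma, coords, pairs, Ds_hat)
    if (!is.finite(gr$total))
      stop("non-finite loss at epoch ", epoch, " (dgi = ", gr$loss_dgi,
           ", reg = ", gr$loss_reg, ")")
    hist[[epoch]] <- data.frame(epoch = epoch, loss_dgi = gr$loss_dgi,
                                loss_reg = gr$loss_reg, loss_total = gr$total)
    if (verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d: total %.5f (dgi %.5f, reg %.5f)", epoch,
                      gr$total, gr$loss_dgi, gr$loss_reg))
    if (gr$total < best$loss) {
      best <- list(loss = gr$total, state = state, H = fw$H, s = gr$s,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (epoch >= min_epochs && wait >= patience) break

    grads <- list(W1 = gr$dW1, W2 = gr$dW2, prelu1_slope = gr$da1,
                  prelu2_slope = gr$da2, Theta = gr$dTheta)
    for (pn in params) {
      upd <- adam_step(state[[pn]], grads[[pn]], opt[[pn]], lr, epoch)
      state[[pn]] <- upd$p
      opt[[pn]] <- upd$st
    }
  }

  structure(list(H = best$H, summary = best$s, state = best$state,
                 history = do.call(rbind, hist), best_epoch = best$epoch,
                 best_loss = best$loss, epochs_run = epoch,
                 config = list(gamma = gamma, latent_dim = latent_dim,
                               lr = lr, max_epochs = max_epochs,
                               min_epochs = min_epochs, patience = patience,
                               seed = seed,
                               pair_subsample_threshold = pair_subsample_threshold,
                               n_pairs = n_pairs)),
            class = "dgi_fit")
}

#' @export
print.dgi_fit <- function(x, ...) {
  cat("infomax fit: ", nrow(x$H), " cells x ", ncol(x$H), " latent dims; ",
      x$epochs_run, " epochs (best total loss ",
      sprintf("%.5f", x$best_loss), " at epoch ", x$best_epoch, ")\n",
      sep = "")
  invisible(x)
}
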
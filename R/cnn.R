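#' VGG-family 3D CNN architecture descriptor
#'
#' Four frozen complexity levels span the tuned family: small 3x3x3
#' convolutions, max pooling after each block, three terminal fully connected
#' layers whose widths are derived from the last convolutional block (the
#' first FC layer doubles its channel count, the second halves it back, the
#' third maps to the two classes). Batch normalization follows the first FC
#' layer with dropout immediately after.
#'
#' @param complexity_level Integer 1-4 selecting the block layout:
#'   level 1 = blocks (1x8, 1x16, 1x32, 1x64); level 2 = (2x8, 2x16, 2x32,
#'   2x64); level 3 = (2x16, 2x32, 2x64, 2x128, 1x128); level 4 = (2x16,
#'   2x32, 3x64, 3x128, 4x128). `n x C` means `n` convolutional layers of
#'   `C` channels.
#' @param dropout_rate Dropout frequency after the first FC layer
#'   (tuning grid 0.6, 0.7, 0.8).
#' @param l2 L2-norm penalty on the weights (tuning grid 0.001, 0.01).
#' @param blocks Optional explicit block list of `c(n_conv, channels)`
#'   pairs, overriding `complexity_level` (4-5 blocks, channels 8-128).
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(complexity_level = 1, dropout_rate = 0.6,
                              l2 = 0.001, blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- switch(complexity_level,
      list(c(1, 8), c(1, 16), c(1, 32), c(1, 64)),
      list(c(2, 8), c(2, 16), c(2, 32), c(2, 64)),
      list(c(2, 16), c(2, 32), c(2, 64), c(2, 128), c(1, 128)),
      list(c(2, 16), c(2, 32), c(3, 64), c(3, 128), c(4, 128)))
    if (is.null(blocks)) stop("architecture_spec: complexity_level must be 1-4")
  }
  nb <- length(blocks)
  if (nb < 2 || nb > 5)
    stop("architecture_spec: needs 2-5 blocks")
  for (b in blocks) {
    if (b[1] < 1 || b[1] > 4) stop("architecture_spec: 1-4 conv layers per block")
    if (b[2] < 8 || b[2] > 128) stop("architecture_spec: channels must be 8-128")
  }
  c_last <- blocks[[nb]][2]
  structure(list(complexity_level = complexity_level, blocks = blocks,
                 kernel = c(3, 3, 3), dropout_rate = dropout_rate, l2 = l2,
                 fc_widths = c(2 * c_last, c_last, 2),
                 c_last = c_last, batchnorm_after_fc1 = TRUE),
            class = "architecture_spec")
}

#' CNN training configuration
#'
#' Defaults follow the training protocol the models were tuned under: 800
#' epochs, mini-batches of 128, class-weighted cross-entropy, SGD with
#' momentum 0.9 under a cosine-annealing schedule with warm restarts (first
#' cycle 50 epochs, cycle length doubling, floor 1e-10), early stopping on
#' the validation weighted loss with the best weights restored.
#'
#' @param lr0 Initial learning rate (tuning grid 0.1e-4, 0.8e-4, 1e-4).
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size; training sets smaller than this use
#'   full batches.
#' @param t0 First cosine-annealing cycle length in epochs.
#' @param t_mult Cycle-length multiplier at each warm restart.
#' @param lr_floor Learning-rate floor reached at the end of each cycle.
#' @param momentum SGD momentum.
#' @param patience Early-stopping patience in epochs (monitoring validation
#'   weighted loss).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 1e-4, epochs = 800, batch_size = 128,
                         t0 = 50, t_mult = 2, lr_floor = 1e-10,
                         momentum = 0.9, patience = 100, seed = 1L) {
  stopifnot(lr_floor < lr0, epochs >= 1, batch_size >= 1)
  structure(list(lr0 = lr0, epochs = epochs, batch_size = batch_size,
                 t0 = t0, t_mult = t_mult, lr_floor = lr_floor,
                 momentum = momentum, patience = patience,
                 seed = as.integer(seed)), class = "train_config")
}

#' Inverse class-frequency loss weights
#'
#' `w_c = N / (2 * n_c)`, so the weight ratio equals the inverse class-count
#' ratio and balanced classes get weights (1, 1).
#'
#' @param labels Binary labels (factor/character/0-1).
#' @return Named numeric vector of per-class weights.
#' @export
inverse_frequency_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2) stop("inverse_frequency_weights: single-class input")
  n <- sum(tab)
  w <- n / (2 * as.numeric(tab))
  names(w) <- names(tab)
  w
}

#' Cosine-annealing learning rate within a cycle
#'
#' `lr = floor + (lr0 - floor)/2 * (1 + cos(pi * t / cycle_len))`: starts at
#' `lr0`, reaches `floor` at the end of the cycle. Warm restarts reset `t` to
#' 0 while the cycle length grows by `t_mult`.
#'
#' @param t_in_cycle Position within the cycle, `0 <= t <= cycle_len`.
#' @param cycle_len Cycle length in epochs.
#' @param lr0 Rate at the cycle start.
#' @param floor Rate at the cycle end.
#' @return Learning rate.
#' @export
scheduled_lr <- function(t_in_cycle, cycle_len, lr0, floor = 1e-10) {
  stopifnot(t_in_cycle >= 0, t_in_cycle <= cycle_len)
  floor + (lr0 - floor) / 2 * (1 + cos(pi * t_in_cycle / cycle_len))
}

#' @rdname scheduled_lr
#' @param epoch Zero-based global epoch.
#' @param t0 First cycle length.
#' @param t_mult Cycle-length multiplier per restart.
#' @export
lr_at_epoch <- function(epoch, t0 = 50, t_mult = 2, lr0 = 1e-4,
                        floor = 1e-10) {
  len <- t0
  t <- epoch
  while (t >= len) {
    t <- t - len
    len <- len * t_mult
  }
  scheduled_lr(t, len, lr0, floor)
}

#' Build a 3D CNN from an architecture descriptor
#'
#' Constructs the layer stack (conv3x3x3 "same" + ReLU within blocks, 2x2x2
#' ceil-mode max pooling between blocks, flatten, FC1 + batch norm + dropout
#' + ReLU, FC2 + ReLU, FC3 to the two class scores) with He-initialised
#' weights.
#'
#' @param spec An [architecture_spec()].
#' @param input_dim Spatial dims of the (single-channel) input volume.
#' @param seed Integer seed for weight initialization.
#' @return A `cnn_model`.
#' @export
build_network <- function(spec, input_dim, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"), length(input_dim) == 3)
  set.seed(seed)
  layers <- list()
  dims <- as.integer(input_dim)
  cin <- 1L
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    for (l in seq_len(b[1])) {
      cout <- b[2]
      layers[[length(layers) + 1]] <- list(
        type = "conv", dims = dims, cin = cin, cout = cout,
        W = he(cout, cin * 27, cin * 27), b = rep(0, cout))
      layers[[length(layers) + 1]] <- list(type = "relu")
      cin <- cout
    }
    if (any(dims < 1))
      stop(sprintf("build_network: spatial size collapsed below 1 at block %d", bi))
    layers[[length(layers) + 1]] <- list(type = "pool", dims = dims)
    dims <- as.integer(ceiling(dims / 2))
  }
  last_relu_ix <- max(which(vapply(layers, `[[`, "", "type") == "relu"))
  flat <- cin * prod(dims)
  layers[[length(layers) + 1]] <- list(type = "flatten", c = cin, dims = dims)
  fw <- spec$fc_widths
  layers[[length(layers) + 1]] <- list(type = "fc", W = he(fw[1], flat, flat),
                                       b = rep(0, fw[1]))
  layers[[length(layers) + 1]] <- list(type = "bnorm", gamma = rep(1, fw[1]),
                                       beta = rep(0, fw[1]),
                                       rmean = rep(0, fw[1]),
                                       rvar = rep(1, fw[1]),
                                       momentum = 0.1, eps = 1e-5)
  layers[[length(layers) + 1]] <- list(type = "dropout", rate = spec$dropout_rate)
  layers[[length(layers) + 1]] <- list(type = "relu")
  layers[[length(layers) + 1]] <- list(type = "fc", W = he(fw[2], fw[1], fw[1]),
                                       b = rep(0, fw[2]))
  layers[[length(layers) + 1]] <- list(type = "relu")
  feature_ix <- length(layers)
  layers[[length(layers) + 1]] <- list(type = "fc", W = he(2, fw[2], fw[2]),
                                       b = rep(0, 2))
  structure(list(spec = spec, input_dim = as.integer(input_dim),
                 layers = layers, last_conv_relu_ix = last_relu_ix,
                 feature_ix = feature_ix, classes = c("nonsevere", "severe")),
            class = "cnn_model")
}

# Stack a list of 3D arrays into the internal batch cube (1 x nvox x n).
volumes_to_input <- function(volumes, input_dim) {
  n <- length(volumes)
  nvox <- prod(input_dim)
  X <- array(0, c(1L, nvox, n))
  for (s in seq_len(n)) {
    v <- volumes[[s]]
    if (!identical(dim(v), as.integer(input_dim)))
      stop("volumes_to_input: shape mismatch")
    X[1, , s] <- as.vector(v)
  }
  X
}

# Forward pass. Returns list(acts = list of post-layer activations with the
# input at index 0 stored as acts[["input"]], caches per layer, logits).
net_forward <- function(net, X, training = FALSE) {
  acts <- vector("list", length(net$layers))
  caches <- vector("list", length(net$layers))
  cur <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      caches[[i]] <- list(X = cur)
      cur <- conv3d_forward_cpp(cur, ly$dims, ly$W, ly$b)
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = cur > 0)
      cur <- cur * caches[[i]]$mask
    } else if (ly$type == "pool") {
      fp <- maxpool3d_forward_cpp(cur, ly$dims)
      caches[[i]] <- list(argmax = fp$argmax, nvox_in = prod(ly$dims))
      cur <- fp$Y
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(dim_in = dim(cur))
      cur <- matrix(cur, nrow = dim(cur)[1] * dim(cur)[2], ncol = dim(cur)[3])
    } else if (ly$type == "fc") {
      caches[[i]] <- list(X = cur)
      cur <- ly$W %*% cur + ly$b
    } else if (ly$type == "bnorm") {
      if (training) {
        mu <- rowMeans(cur)
        va <- rowMeans((cur - mu)^2)
      } else {
        mu <- ly$rmean
        va <- ly$rvar
      }
      istd <- 1 / sqrt(va + ly$eps)
      xhat <- (cur - mu) * istd
      caches[[i]] <- list(xhat = xhat, istd = istd, training = training)
      cur <- ly$gamma * xhat + ly$beta
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- matrix(runif(length(cur)) >= ly$rate, nrow(cur), ncol(cur)) /
          (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        cur <- cur * mask
      } else caches[[i]] <- list(mask = NULL)
    }
    acts[[i]] <- cur
  }
  list(acts = acts, caches = caches, logits = cur, input = X)
}

# Backward pass from dlogits (2 x n). Returns per-layer parameter grads and
# the gradient w.r.t. every layer's input (`dacts[[i]]` is the gradient at
# the input of layer i); dacts[[1]] is the input-volume gradient.
net_backward <- function(net, fw, dlogits) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dacts <- vector("list", L + 1)
  cur <- dlogits
  for (i in L:1) {
    ly <- net$layers[[i]]
    ca <- fw$caches[[i]]
    if (ly$type == "fc") {
      grads[[i]] <- list(dW = cur %*% t(ca$X), db = rowSums(cur))
      cur <- t(ly$W) %*% cur
    } else if (ly$type == "relu") {
      cur <- cur * ca$mask
    } else if (ly$type == "dropout") {
      if (!is.null(ca$mask)) cur <- cur * ca$mask
    } else if (ly$type == "bnorm") {
      n <- ncol(cur)
      dgamma <- rowSums(cur * ca$xhat)
      dbeta <- rowSums(cur)
      grads[[i]] <- list(dgamma = dgamma, dbeta = dbeta)
      if (ca$training) {
        dxhat <- cur * ly$gamma
        cur <- ca$istd * (dxhat - rowMeans(dxhat) -
                            ca$xhat * rowMeans(dxhat * ca$xhat))
      } else {
        cur <- cur * ly$gamma * ca$istd
      }
    } else if (ly$type == "flatten") {
      cur <- array(cur, ca$dim_in)
    } else if (ly$type == "pool") {
      cur <- maxpool3d_backward_cpp(cur, ca$argmax, ca$nvox_in)
    } else if (ly$type == "conv") {
      bw <- conv3d_backward_cpp(ca$X, cur, ly$dims, ly$W)
      grads[[i]] <- list(dW = bw$dW, db = bw$db)
      cur <- bw$dX
    }
    dacts[[i]] <- cur
  }
  list(grads = grads, dacts = dacts, dinput = cur)
}

# Class-weighted softmax cross-entropy. y is an integer vector in {1,2}
# (2 = severe). Returns list(loss, dlogits), loss averaged over the batch.
weighted_ce <- function(logits, y, class_weights) {
  n <- ncol(logits)
  m <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, m))
  p <- sweep(ex, 2, colSums(ex), "/")
  w <- class_weights[y]
  py <- p[cbind(y, seq_len(n))]
  loss <- mean(w * (-log(pmax(py, 1e-300))))
  onehot <- matrix(0, 2, n)
  onehot[cbind(y, seq_len(n))] <- 1
  dlogits <- sweep(p - onehot, 2, w, `*`) / n
  list(loss = loss, dlogits = dlogits, p = p)
}

labels_to_y <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels) + 1L)
  ifelse(as.character(labels) == "severe", 2L, 1L)
}

# L2 penalty term over conv/fc weights.
net_l2_penalty <- function(net) {
  sum(vapply(net$layers, function(ly)
    if (ly$type %in% c("conv", "fc")) sum(ly$W^2) else 0, 0))
}

#' Train the 3D CNN
#'
#' Minimises class-weighted cross-entropy with an L2 penalty using SGD with
#' momentum under the cosine-annealing warm-restart schedule. The validation
#' weighted loss is monitored every epoch; training stops after `patience`
#' epochs without improvement and the best-validation weights are restored.
#'
#' @param net A `cnn_model` from [build_network()] (or an
#'   [architecture_spec()], in which case the network is built with
#'   `config$seed`).
#' @param volumes List of scaled 3D arrays (training inputs).
#' @param labels Binary labels aligned with `volumes` (`"severe"` positive).
#' @param config A [train_config()].
#' @param val_volumes,val_labels Held-out validation data for early stopping
#'   (disjoint from the training set).
#' @param verbose Print a line every 25 epochs.
#' @return A `trained_cnn`: the fitted model plus per-epoch `history` and
#'   the class weights used.
#' @export
train_cnn <- function(net, volumes, labels, config = train_config(),
                      val_volumes, val_labels, verbose = FALSE) {
  if (inherits(net, "architecture_spec"))
    net <- build_network(net, dim(volumes[[1]]), seed = config$seed)
  y <- labels_to_y(labels)
  yv <- labels_to_y(val_labels)
  if (length(unique(y)) < 2) stop("train_cnn: single-class training data")
  cw <- inverse_frequency_weights(factor(y, levels = 1:2))
  cw <- as.numeric(cw)  # index by class 1/2
  X <- volumes_to_input(volumes, net$input_dim)
  Xv <- volumes_to_input(val_volumes, net$input_dim)
  n <- length(volumes)
  bs <- min(config$batch_size, n)
  set.seed(config$seed)
  vel <- lapply(net$layers, function(ly) NULL)
  best <- list(loss = Inf, layers = net$layers, epoch = 0L)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(ep - 1, config$t0, config$t_mult, config$lr0,
                      config$lr_floor)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      ix <- ord[start:min(start + bs - 1, n)]
      fw <- net_forward(net, X[, , ix, drop = FALSE], training = TRUE)
      lo <- weighted_ce(fw$logits, y[ix], cw)
      if (!is.finite(lo$loss))
        stop(sprintf("train_cnn: loss diverged (NaN/Inf) at epoch %d", ep))
      bw <- net_backward(net, fw, lo$dlogits)
      for (i in seq_along(net$layers)) {
        ly <- net$layers[[i]]
        g <- bw$grads[[i]]
        if (is.null(g)) next
        if (ly$type %in% c("conv", "fc")) {
          gW <- g$dW + net$spec$l2 * ly$W
          if (is.null(vel[[i]])) vel[[i]] <- list(W = gW * 0, b = g$db * 0)
          vel[[i]]$W <- config$momentum * vel[[i]]$W - lr * gW
          vel[[i]]$b <- config$momentum * vel[[i]]$b - lr * g$db
          net$layers[[i]]$W <- ly$W + vel[[i]]$W
          net$layers[[i]]$b <- ly$b + vel[[i]]$b
        } else if (ly$type == "bnorm") {
          if (is.null(vel[[i]]))
            vel[[i]] <- list(g = g$dgamma * 0, b = g$dbeta * 0)
          vel[[i]]$g <- config$momentum * vel[[i]]$g - lr * g$dgamma
          vel[[i]]$b <- config$momentum * vel[[i]]$b - lr * g$dbeta
          net$layers[[i]]$gamma <- ly$gamma + vel[[i]]$g
          net$layers[[i]]$beta <- ly$beta + vel[[i]]$b
          # running statistics from the batch just seen
          mu <- rowMeans(fw$acts[[i - 1]])
          va <- rowMeans((fw$acts[[i - 1]] - mu)^2)
          net$layers[[i]]$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * mu
          net$layers[[i]]$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * va
        }
      }
      ep_loss <- ep_loss + lo$loss; nb <- nb + 1
    }
    fwv <- net_forward(net, Xv, training = FALSE)
    vl <- weighted_ce(fwv$logits, yv, cw)$loss
    history <- rbind(history, data.frame(epoch = ep, lr = lr,
                                         train_loss = ep_loss / nb,
                                         val_loss = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, layers = net$layers, epoch = ep)
      wait <- 0L
    } else wait <- wait + 1L
    if (verbose && ep %% 25 == 0)
      message(sprintf("epoch %d lr %.2e train %.4f val %.4f", ep, lr,
                      ep_loss / nb, vl))
    if (wait >= config$patience) break
  }
  net$layers <- best$layers
  structure(list(net = net, history = history, class_weights = cw,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 config = config), class = "trained_cnn")
}

#' Class probabilities from a trained CNN
#'
#' Softmax of the two class scores; columns `nonsevere`, `severe`.
#'
#' @param model A `trained_cnn` (or bare `cnn_model`).
#' @param volumes List of scaled 3D arrays.
#' @return n x 2 probability matrix with rows summing to 1.
#' @export
predict_proba <- function(model, volumes) {
  net <- if (inherits(model, "trained_cnn")) model$net else model
  X <- volumes_to_input(volumes, net$input_dim)
  fw <- net_forward(net, X, training = FALSE)
  logits <- fw$logits
  m <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, m))
  p <- t(sweep(ex, 2, colSums(ex), "/"))
  colnames(p) <- net$classes
  p
}

#' Penultimate-layer features from a trained CNN
#'
#' Activations after the second fully connected layer's ReLU, one row per
#' subject; width equals the channel count of the last convolutional block.
#'
#' @inheritParams predict_proba
#' @return n x C_last feature matrix.
#' @export
extract_features <- function(model, volumes) {
  net <- if (inherits(model, "trained_cnn")) model$net else model
  X <- volumes_to_input(volumes, net$input_dim)
  fw <- net_forward(net, X, training = FALSE)
  t(fw$acts[[net$feature_ix]])
}

#' Select CNN hyperparameters from inner-fold losses
#'
#' Returns the candidate with the smallest mean inner-fold validation loss;
#' ties break to lower complexity, then lower learning rate.
#'
#' @param mean_losses Numeric vector of mean inner-fold losses per candidate.
#' @param grid data.frame of candidates with columns `complexity` and `lr`.
#' @return Row index of the chosen candidate.
#' @export
select_best_hyperparams <- function(mean_losses, grid) {
  stopifnot(length(mean_losses) == nrow(grid))
  ord <- order(mean_losses, grid$complexity, grid$lr)
  ord[1]
}

#' Tune the CNN over the hyperparameter grid on inner folds
#'
#' Grid search over complexity x dropout x L2 x learning rate: each candidate
#' is trained on every inner training split and scored by the class-weighted
#' validation loss on the held-out inner fold; the candidate with the
#' smallest mean loss is returned.
#'
#' @param volumes,labels Outer-fold training data.
#' @param inner_fold Inner fold id per training subject.
#' @param grid data.frame with columns `complexity`, `dropout`, `l2`, `lr`
#'   (default: the full tuning grid).
#' @param config Base [train_config()]; `lr0` is overridden per candidate.
#' @return List with `chosen` (grid row), `mean_losses`, `grid`.
#' @export
tune_cnn <- function(volumes, labels, inner_fold,
                     grid = expand.grid(complexity = 1:4,
                                        dropout = c(0.6, 0.7, 0.8),
                                        l2 = c(0.001, 0.01),
                                        lr = c(0.1e-4, 0.8e-4, 1e-4)),
                     config = train_config()) {
  folds <- sort(unique(inner_fold))
  y <- labels_to_y(labels)
  mean_losses <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- architecture_spec(grid$complexity[g], grid$dropout[g], grid$l2[g])
    cfg <- config
    cfg$lr0 <- grid$lr[g]
    losses <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      tr <- inner_fold != folds[fi]
      fit <- train_cnn(spec, volumes[tr], labels[tr], cfg,
                       volumes[!tr], labels[!tr])
      p <- predict_proba(fit, volumes[!tr])
      cw <- fit$class_weights
      yv <- y[!tr]
      losses[fi] <- mean(cw[yv] * -log(pmax(p[cbind(seq_len(sum(!tr)), yv)],
                                            1e-300)))
    }
    mean_losses[g] <- mean(losses)
  }
  chosen <- select_best_hyperparams(mean_losses, grid)
  list(chosen = grid[chosen, , drop = FALSE], chosen_ix = chosen,
       mean_losses = mean_losses, grid = grid)
}
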
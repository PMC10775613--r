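#' Training configuration for the unsupervised segmenter
#'
#' @param alpha weight of the shape-factor loss term in
#'   `L = L_ce + alpha * L_fs` (default 0.1).
#' @param C_target cornea-specific shape-factor constant `C` (default 10).
#' @param lr SGD learning rate.
#' @param momentum SGD momentum.
#' @param max_epochs_first_frame epoch budget for a cold-started frame.
#'   Cold starts on corneal deformation frames typically converge within 25
#'   epochs; the default budget of 60 brackets that comfortably.
#' @param max_epochs_warm epoch budget for a warm-started frame (warm starts
#'   typically stop within a handful of epochs).
#' @param loss_stop_threshold training stops the first time the total loss
#'   falls below this value (default 0.1).
#' @param min_labels training stops if the number of distinct refined labels
#'   drops below this floor (default 2: a segmentation collapsed to one label
#'   has no contour).
#' @param seed integer seed for parameter initialisation.
#' @param activation activation after C1/C3/C5: `"relu"` (default),
#'   `"leakyrelu"`, `"mish"` or `"pish"` (implemented as the swish-family form
#'   `x * sigmoid(x)`; no canonical definition is in common use).
#' @param n_classes number of output maps `q` (default 4).
#' @param shape_loss_grad if `TRUE`, a differentiable surrogate of the
#'   shape-factor loss (soft area = sum of the candidate-channel probability,
#'   soft perimeter = its total variation) also contributes gradients. By
#'   default the shape term affects only the loss value and stopping rule,
#'   since the hard shape factor is piecewise constant in the parameters.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(alpha = 0.1, C_target = 10, lr = 0.1,
                         momentum = 0.9, max_epochs_first_frame = 60L,
                         max_epochs_warm = 15L, loss_stop_threshold = 0.1,
                         min_labels = 2L, seed = 1L,
                         activation = c("relu", "leakyrelu", "mish", "pish"),
                         n_classes = 4L, shape_loss_grad = FALSE) {
  activation <- match.arg(activation)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (loss_stop_threshold <= 0) stop("loss_stop_threshold must be > 0", call. = FALSE)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  structure(list(alpha = alpha, C_target = C_target, lr = lr,
                 momentum = momentum,
                 max_epochs_first_frame = as.integer(max_epochs_first_frame),
                 max_epochs_warm = as.integer(max_epochs_warm),
                 loss_stop_threshold = loss_stop_threshold,
                 min_labels = as.integer(min_labels), seed = as.integer(seed),
                 activation = activation, n_classes = as.integer(n_classes),
                 shape_loss_grad = isTRUE(shape_loss_grad)),
            class = "train_config")
}

# six-layer stride-1 FCN: 3x3 and 1x1 convolutions alternating, BatchNorm on
# every layer, activation only on C1/C3/C5, softmax over the q output maps
fcn_layer_spec <- function(q = 4L) {
  maps <- c(128L, 64L, 32L, 16L, 8L, q)
  ks <- c(3L, 1L, 3L, 1L, 3L, 1L)
  act <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  cin <- c(3L, maps[-6L])
  lapply(1:6, function(i) list(cin = cin[i], cout = maps[i], k = ks[i],
                               act = act[i]))
}

#' Initialise (or warm-start) the network state
#'
#' With `warm = NULL`, parameters are drawn with He-normal initialisation,
#' deterministic under `cfg$seed`. With a previous frame's `"network_state"`
#' supplied, an exact copy of it is returned ("shared model" warm start).
#'
#' @param cfg a [train_config()].
#' @param warm optional `"network_state"` from a previously trained frame.
#' @return An object of class `"network_state"`.
#' @export
init_network <- function(cfg, warm = NULL) {
  spec <- fcn_layer_spec(cfg$n_classes)
  if (!is.null(warm)) {
    if (!inherits(warm, "network_state"))
      stop("warm must be a network_state", call. = FALSE)
    ws <- lapply(warm$layers, function(l) l[c("cin", "cout", "k", "act")])
    ss <- lapply(spec, function(l) l[c("cin", "cout", "k", "act")])
    if (!identical(ws, ss))
      stop("warm state is incompatible with the configured layer spec",
           call. = FALSE)
    return(warm)  # R copy semantics: caller-side mutation cannot leak back
  }
  local_seed(cfg$seed, {
    layers <- lapply(spec, function(l) {
      fan_in <- l$cin * l$k * l$k
      list(cin = l$cin, cout = l$cout, k = l$k, act = l$act,
           W = matrix(rnorm(fan_in * l$cout, sd = sqrt(2 / fan_in)),
                      fan_in, l$cout),
           b = numeric(l$cout),
           gamma = rep(1, l$cout), beta = numeric(l$cout),
           run_mean = numeric(l$cout), run_var = rep(1, l$cout))
    })
    structure(list(layers = layers, activation = cfg$activation,
                   q = cfg$n_classes),
              class = "network_state")
  })
}

act_forward <- function(x, type) {
  switch(type,
         relu = pmax(x, 0),
         leakyrelu = ifelse(x > 0, x, 0.01 * x),
         mish = x * tanh(log1p(exp(pmin(x, 30)))),
         pish = x / (1 + exp(-x)))
}

act_backward <- function(x, type) {
  switch(type,
         relu = (x > 0) * 1,
         leakyrelu = ifelse(x > 0, 1, 0.01),
         mish = {
           sp <- log1p(exp(pmin(x, 30)))
           ts <- tanh(sp)
           sig <- 1 / (1 + exp(-x))
           ts + x * sig * (1 - ts^2)
         },
         pish = {
           sig <- 1 / (1 + exp(-x))
           sig + x * sig * (1 - sig)
         })
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# forward through all layers on an npix x 3 matrix; returns softmax
# probabilities and (optionally) the per-layer cache needed for backprop
forward_pass <- function(state, X, H, W, training = TRUE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(state$layers))
  a <- X
  for (i in seq_along(state$layers)) {
    l <- state$layers[[i]]
    cols <- if (l$k == 1L) a else cpp_im2col(a, H, W, l$k)
    z <- cols %*% l$W
    z <- sweep(z, 2L, l$b, "+")
    if (training) {
      mu <- colMeans(z)
      va <- colMeans(z * z) - mu^2
      state$layers[[i]]$run_mean <- (1 - BN_MOMENTUM) * l$run_mean + BN_MOMENTUM * mu
      state$layers[[i]]$run_var <- (1 - BN_MOMENTUM) * l$run_var + BN_MOMENTUM * va
    } else {
      mu <- l$run_mean
      va <- l$run_var
    }
    invstd <- 1 / sqrt(va + BN_EPS)
    xhat <- sweep(sweep(z, 2L, mu, "-"), 2L, invstd, "*")
    y <- sweep(sweep(xhat, 2L, l$gamma, "*"), 2L, l$beta, "+")
    out <- if (l$act) act_forward(y, state$activation) else y
    if (keep_cache)
      caches[[i]] <- list(input = a, xhat = xhat, invstd = invstd, preact = y)
    a <- out
  }
  # softmax over the q output maps
  mx <- do.call(pmax, c(lapply(seq_len(ncol(a)), function(j) a[, j]), list(0)))
  ex <- exp(a - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, caches = caches, state = state)
}

backward_pass <- function(state, caches, dlogits, H, W) {
  grads <- vector("list", length(state$layers))
  dy <- dlogits
  for (i in rev(seq_along(state$layers))) {
    l <- state$layers[[i]]
    cache <- caches[[i]]
    if (l$act) dy <- dy * act_backward(cache$preact, state$activation)
    # batch-norm backward (per-channel statistics over all pixels)
    n <- nrow(dy)
    dgamma <- colSums(dy * cache$xhat)
    dbeta <- colSums(dy)
    dxhat <- sweep(dy, 2L, l$gamma, "*")
    dz <- sweep(dxhat, 2L, colMeans(dxhat), "-") -
      sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
    dz <- sweep(dz, 2L, cache$invstd, "*")
    cols <- if (l$k == 1L) cache$input else cpp_im2col(cache$input, H, W, l$k)
    dW <- crossprod(cols, dz)
    db <- colSums(dz)
    grads[[i]] <- list(W = dW, b = db, gamma = dgamma, beta = dbeta)
    if (i > 1L) {
      dcols <- tcrossprod(dz, l$W)
      dy <- if (l$k == 1L) dcols else cpp_col2im(dcols, H, W, l$cin, l$k)
    }
  }
  grads
}

#' Forward pass of the fully convolutional network
#'
#' Applies the six stride-1 convolution units (convolution, batch
#' normalisation, activation on C1/C3/C5) and a softmax over the `q = 4`
#' output maps. The network is fully convolutional, so any frame size is
#' accepted and spatial dimensions are preserved.
#'
#' @param state a `"network_state"`.
#' @param frame `height x width` matrix or `height x width x 3` array.
#' @param training if `TRUE` (default), batch normalisation uses the
#'   statistics of this forward pass; otherwise the running statistics
#'   carried in `state`.
#' @return `height x width x q` array of per-pixel class probabilities
#'   (each pixel's scores sum to 1).
#' @export
forward <- function(state, frame, training = TRUE) {
  stopifnot(inherits(state, "network_state"))
  rgb <- as_rgb_array(frame)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  X <- cbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
             as.vector(rgb[, , 3L]))
  fp <- forward_pass(state, X, h, w, training = training)
  array(fp$probs, dim = c(h, w, state$q))
}

#' Per-pixel cluster labels from a feature map
#'
#' Each pixel receives the index of its maximum class score; ties break
#' towards the lowest channel index.
#'
#' @param fm `height x width x q` probability array (or `npix x q` matrix).
#' @return `height x width` integer matrix of labels in `1..q`.
#' @export
assign_labels <- function(fm) {
  if (is.matrix(fm)) stop("fm must be a height x width x q array", call. = FALSE)
  d <- dim(fm)
  m <- matrix(fm, d[1L] * d[2L], d[3L])
  matrix(max.col(m, ties.method = "first"), d[1L], d[2L])
}

#' Majority-vote label refinement over superpixels
#'
#' Within each superpixel, every pixel receives the superpixel's modal
#' cluster label; ties break towards the lowest label value. Idempotent.
#'
#' @param lm `height x width` integer label matrix.
#' @param part a `"superpixel_partition"` of the same shape.
#' @return Refined label matrix of the same shape.
#' @export
refine_labels <- function(lm, part) {
  stopifnot(inherits(part, "superpixel_partition"))
  if (!identical(dim(lm), dim(part$labels)))
    stop("label map and partition have different shapes", call. = FALSE)
  q <- max(lm)
  out <- cpp_refine_labels(as.integer(lm), as.integer(part$labels),
                           as.integer(part$K), as.integer(q))
  matrix(out, nrow(lm), ncol(lm))
}

#' Pixel-averaged cross-entropy loss
#'
#' Mean over pixels of `-log(p[target])`, with the probabilities taken from
#' the softmax feature map.
#'
#' @param fm `height x width x q` probability array.
#' @param target `height x width` integer label matrix in `1..q`.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(fm, target) {
  d <- dim(fm)
  if (!identical(d[1:2], dim(target)))
    stop("feature map and target have different shapes", call. = FALSE)
  m <- matrix(fm, d[1L] * d[2L], d[3L])
  p <- m[cbind(seq_len(nrow(m)), as.vector(target))]
  mean(-log(pmax(p, 1e-12)))
}

#' Shape-factor loss
#'
#' For each label present in the map, the shape factor
#' `Fs = perimeter^2 / (4 * pi * area)` of that label's largest connected
#' region is computed; the label whose `Fs` is closest to `C_target` is taken
#' as the corneal candidate and `|Fs - C_target|` is returned. If the map is
#' constant (a single label covering the frame) the full-frame `Fs` is used
#' and the result carries a `degenerate = TRUE` attribute.
#'
#' @param lm `height x width` integer label matrix.
#' @param C_target the corneal shape-factor constant `C` (default 10).
#' @return Scalar loss with attributes `label` (the candidate label), `Fs`
#'   and `degenerate`.
#' @export
shape_factor_loss <- function(lm, C_target = 10) {
  if (length(lm) == 0L) stop("label map is empty", call. = FALSE)
  labs <- sort(unique(as.vector(lm)))
  best <- NULL
  for (lab in labs) {
    mask <- lm == lab
    cc <- cpp_connected_components(as.integer(mask), nrow(lm), ncol(lm))
    sizes <- tabulate(cc$comp, nbins = cc$ncomp)
    big <- which.max(sizes)
    comp_mask <- matrix(cc$comp == big, nrow(lm), ncol(lm))
    tr <- cpp_trace_contour(as.integer(comp_mask), nrow(lm), ncol(lm))
    fs <- tr$perimeter^2 / (4 * pi * sizes[big])
    if (is.null(best) || abs(fs - C_target) < abs(best$fs - C_target))
      best <- list(label = lab, fs = fs)
  }
  structure(abs(best$fs - C_target), label = best$label, Fs = best$fs,
            degenerate = length(labs) == 1L)
}

#' Combined training loss
#'
#' `L = L_ce + alpha * L_fs`: the cross-entropy between the feature map and
#' the refined labels plus the weighted shape-factor loss of the current
#' label map. Only the cross-entropy term carries gradients unless
#' `cfg$shape_loss_grad` is set.
#'
#' @param fm `height x width x q` probability array.
#' @param target refined label matrix (the training targets).
#' @param lm label map used for the shape term (typically equal to `target`).
#' @param cfg a [train_config()].
#' @return Scalar loss with attributes `ce` and `fs_loss`.
#' @export
total_loss <- function(fm, target, lm, cfg) {
  ce <- cross_entropy_loss(fm, target)
  fs <- shape_factor_loss(lm, cfg$C_target)
  structure(ce + cfg$alpha * as.numeric(fs), ce = ce,
            fs_loss = as.numeric(fs), fs_label = attr(fs, "label"),
            degenerate = attr(fs, "degenerate"))
}

# gradient of the differentiable shape-loss surrogate w.r.t. the softmax
# probabilities of the candidate channel (soft area = sum P, soft perimeter =
# total variation of P)
soft_shape_grad <- function(P, H, W, C_target) {
  Pm <- matrix(P, H, W)
  dr <- Pm[-1L, , drop = FALSE] - Pm[-H, , drop = FALSE]
  dc <- Pm[, -1L, drop = FALSE] - Pm[, -W, drop = FALSE]
  per <- sum(abs(dr)) + sum(abs(dc))
  area <- sum(Pm)
  if (area <= 0) return(matrix(0, H, W))
  fs <- per^2 / (4 * pi * area)
  sgn <- sign(fs - C_target)
  dper <- matrix(0, H, W)
  s <- sign(dr)
  dper[-1L, ] <- dper[-1L, ] + s
  dper[-H, ] <- dper[-H, ] - s
  s <- sign(dc)
  dper[, -1L] <- dper[, -1L] + s
  dper[, -W] <- dper[, -W] - s
  sgn * (2 * per * dper / (4 * pi * area) - fs / area)
}

#' Train the network on one frame
#'
#' Alternates (1) label prediction -- forward pass, per-pixel argmax,
#' superpixel majority refinement -- with (2) parameter updates by SGD with
#' momentum on the combined loss. Stops at the epoch budget, when the loss
#' first falls below `cfg$loss_stop_threshold`, or when the number of
#' distinct refined labels drops below `cfg$min_labels`. A cold start
#' (`init = NULL`) that collapses to a single label on its first epochs is
#' re-initialised with a perturbed seed up to 3 times before raising an
#' error; a warm start that collapses stops and returns the last
#' non-collapsed labels.
#'
#' @param frame `height x width` matrix or `height x width x 3` array.
#' @param part a `"superpixel_partition"` for the frame.
#' @param init `NULL` for a cold (random) start, or a previous frame's
#'   `"network_state"` for a shared-model warm start.
#' @param cfg a [train_config()].
#' @param max_epochs epoch budget; defaults to `cfg$max_epochs_first_frame`
#'   for cold starts and `cfg$max_epochs_warm` for warm starts.
#' @param seed seed for cold initialisation (defaults to `cfg$seed`).
#' @return A list: `state` (trained `"network_state"`), `labels` (final
#'   refined label matrix), `loss_history`, `epochs_used`,
#'   `epochs_to_threshold` (`NA` if the threshold was never reached), and
#'   `collapsed`.
#' @export
train_frame <- function(frame, part, init = NULL, cfg = train_config(),
                        max_epochs = NULL, seed = cfg$seed) {
  cold <- is.null(init)
  if (is.null(max_epochs))
    max_epochs <- if (cold) cfg$max_epochs_first_frame else cfg$max_epochs_warm
  retries <- if (cold) 3L else 0L
  for (attempt in 0:retries) {
    state <- if (cold) {
      cfg_i <- cfg
      cfg_i$seed <- as.integer(seed + attempt * 1000L)
      init_network(cfg_i)
    } else {
      init_network(cfg, warm = init)
    }
    res <- train_frame_once(frame, part, state, cfg, max_epochs)
    if (!res$collapsed || !cold) return(res)
  }
  stop("training collapsed to a single label after 3 re-initialisations",
       call. = FALSE)
}

train_frame_once <- function(frame, part, state, cfg, max_epochs) {
  if (!cfg$shape_loss_grad)
    return(train_frame_fast(frame, part, state, cfg, max_epochs))
  rgb <- as_rgb_array(frame)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  npix <- h * w
  X <- cbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
             as.vector(rgb[, , 3L]))
  vel <- lapply(state$layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(l$cout),
         gamma = numeric(l$cout), beta = numeric(l$cout)))
  loss_hist <- numeric(0)
  epochs_to_threshold <- NA_integer_
  last_labels <- NULL
  collapsed <- FALSE
  for (epoch in seq_len(max_epochs)) {
    fp <- forward_pass(state, X, h, w, training = TRUE, keep_cache = TRUE)
    state <- fp$state  # running BN statistics updated
    lm_raw <- matrix(max.col(fp$probs, ties.method = "first"), h, w)
    lm_ref <- refine_labels(lm_raw, part)
    n_lab <- length(unique(as.vector(lm_ref)))
    if (n_lab < cfg$min_labels) {
      collapsed <- is.null(last_labels)
      if (is.null(last_labels)) last_labels <- lm_ref
      break
    }
    fs <- shape_factor_loss(lm_ref, cfg$C_target)
    tgt <- as.vector(lm_ref)
    pt <- fp$probs[cbind(seq_len(npix), tgt)]
    ce <- mean(-log(pmax(pt, 1e-12)))
    loss <- ce + cfg$alpha * as.numeric(fs)
    loss_hist <- c(loss_hist, loss)
    last_labels <- lm_ref
    if (loss < cfg$loss_stop_threshold) {
      if (is.na(epochs_to_threshold)) epochs_to_threshold <- epoch
      break
    }
    # softmax + cross-entropy gradient, averaged over pixels
    dprobs_extra <- NULL
    if (cfg$shape_loss_grad && !isTRUE(attr(fs, "degenerate"))) {
      g <- soft_shape_grad(fp$probs[, attr(fs, "label")], h, w, cfg$C_target)
      dprobs_extra <- list(channel = attr(fs, "label"),
                           grad = as.vector(g) * cfg$alpha)
    }
    dlogits <- fp$probs / npix
    dlogits[cbind(seq_len(npix), tgt)] <-
      dlogits[cbind(seq_len(npix), tgt)] - 1 / npix
    if (!is.null(dprobs_extra)) {
      # backprop the surrogate through the softmax jacobian
      dp <- matrix(0, npix, state$q)
      dp[, dprobs_extra$channel] <- dprobs_extra$grad
      dot <- rowSums(dp * fp$probs)
      dlogits <- dlogits + fp$probs * (dp - dot)
    }
    grads <- backward_pass(state, fp$caches, dlogits, h, w)
    for (i in seq_along(state$layers)) {
      for (p in c("W", "b", "gamma", "beta")) {
        vel[[i]][[p]] <- cfg$momentum * vel[[i]][[p]] - cfg$lr * grads[[i]][[p]]
        state$layers[[i]][[p]] <- state$layers[[i]][[p]] + vel[[i]][[p]]
      }
    }
  }
  list(state = state, labels = last_labels, loss_history = loss_hist,
       epochs_used = length(loss_hist), epochs_to_threshold = epochs_to_threshold,
       collapsed = collapsed)
}

# compiled training loop; numerically equivalent to the R loop above with
# shape_loss_grad = FALSE, kept separate so the surrogate-gradient variant
# stays readable
train_frame_fast <- function(frame, part, state, cfg, max_epochs) {
  rgb <- as_rgb_array(frame)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  X <- cbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
             as.vector(rgb[, , 3L]))
  act_code <- match(state$activation,
                    c("relu", "leakyrelu", "mish", "pish")) - 1L
  res <- cpp_train_frame(X, state$layers, h, w,
                         as.integer(part$labels), as.integer(part$K),
                         as.integer(state$q), act_code,
                         cfg$alpha, cfg$C_target, cfg$lr, cfg$momentum,
                         as.integer(max_epochs), cfg$loss_stop_threshold,
                         cfg$min_labels)
  out_state <- structure(list(layers = res$layers,
                              activation = state$activation, q = state$q),
                         class = "network_state")
  ett <- res$epochs_to_threshold
  list(state = out_state,
       labels = matrix(res$labels, h, w),
       loss_history = as.numeric(res$loss_history),
       ce_history = as.numeric(res$ce_history),
       fs_history = as.numeric(res$fs_history),
       epochs_used = length(res$loss_history),
       epochs_to_threshold = if (ett > 0) as.integer(ett) else NA_integer_,
       collapsed = isTRUE(res$collapsed))
}
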
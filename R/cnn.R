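# Convolutional-network module.
#
# Two layers of implementation: pure-R *reference operators* (conv2d on a
# single plane per the textbook convolution / cross-correlation definitions,
# max pooling, ReLU, softmax, multinomial logistic loss) that serve as the
# semantic ground truth, and fast C++ kernels (im2col convolution, pooling)
# used by the trainer. The two are cross-checked in the test suite.
#
# The default architecture follows the VGG16 recipe: thirteen 3x3/stride-1/
# zero-padded convolution layers in five blocks (2,2,3,3,3 layers wide;
# 64,128,256,512,512 filters), each followed by ReLU and each block closed by
# a 2x2/stride-2 max pool; then FC-4096 + ReLU + dropout, FC-4096 + ReLU +
# dropout, FC-K and softmax — sixteen trainable layers in all. A width
# multiplier scales the channel counts for desk-scale training while keeping
# the block structure.

# ---------------------------------------------------------------------------
# Reference operators

#' Reference 2-D convolution / cross-correlation on a single plane
#'
#' Computes the discrete 2-D cross-correlation of a plane with a kernel
#' (`flip = FALSE`), or the convolution proper (`flip = TRUE`, i.e. the
#' kernel rotated by 180 degrees — the two are identical up to that
#' rotation). Borders use zero padding and the output has the same size as
#' the input: for a kernel of size `kh x kw` the window is anchored
#' `floor((k-1)/2)` before each output pixel.
#'
#' @param B numeric matrix (the image plane).
#' @param K numeric matrix (the kernel), no larger than the padded plane.
#' @param flip rotate the kernel by 180 degrees first (convolution) or not
#'   (cross-correlation).
#' @return Matrix of the same size as `B`.
#' @export
conv2d <- function(B, K, flip = TRUE) {
  stopifnot(is.matrix(B), is.matrix(K))
  if (length(K) == 0L) stop("empty kernel", call. = FALSE)
  kh <- nrow(K); kw <- ncol(K)
  if (flip) K <- K[kh:1, kw:1, drop = FALSE]
  pr <- (kh - 1L) %/% 2L; pc <- (kw - 1L) %/% 2L
  h <- nrow(B); w <- ncol(B)
  pad <- matrix(0, h + kh - 1L, w + kw - 1L)
  pad[(pr + 1L):(pr + h), (pc + 1L):(pc + w)] <- B
  out <- matrix(0, h, w)
  for (n in seq_len(kh)) {
    for (m in seq_len(kw)) {
      if (K[n, m] == 0) next
      out <- out + K[n, m] * pad[(n):(n + h - 1L), (m):(m + w - 1L)]
    }
  }
  out
}

as_tensor <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  stopifnot(is.array(x), length(dim(x)) == 4L)
  x
}

#' Max pooling
#'
#' Non-overlapping maxima over `kernel x kernel` windows (default 2x2,
#' stride 2, which keeps exactly 25% of the elements of an even-dimension
#' plane). Trailing rows/columns that do not fill a window are dropped
#' (floor semantics).
#'
#' @param x matrix or `(h, w, c, n)` array.
#' @param kernel,stride pooling window and step.
#' @return Pooled matrix or array.
#' @export
maxpool <- function(x, kernel = 2L, stride = 2L) {
  was_matrix <- is.matrix(x)
  x <- as_tensor(x)
  y <- cpp_maxpool_forward(x, as.integer(kernel), as.integer(stride))$y
  if (was_matrix) y <- matrix(y[, , 1L, 1L], dim(y)[1], dim(y)[2])
  y
}

#' Rectified linear activation
#'
#' Returns `x` where `x > 0` and `leaky_slope * x` elsewhere (0 for the pure
#' ReLU).
#'
#' @param x numeric vector, matrix or array.
#' @param leaky_slope slope for negative inputs.
#' @export
relu <- function(x, leaky_slope = 0) {
  if (leaky_slope == 0) return(pmax(x, 0))
  ifelse(x > 0, x, leaky_slope * x)
}

#' Softmax over rows
#'
#' Numerically-stabilized softmax; each row of the result is a probability
#' vector summing to one, and row order statistics are preserved.
#'
#' @param z numeric vector (one example) or matrix (rows = examples).
#' @export
softmax <- function(z) {
  vec <- is.null(dim(z))
  m <- if (vec) matrix(z, nrow = 1L) else as.matrix(z)
  m <- exp(m - apply(m, 1L, max))
  m <- m / rowSums(m)
  if (vec) m[1L, ] else m
}

#' Multinomial logistic loss
#'
#' Mean over the batch of the negative log-probability assigned to the true
#' class: `-(1/N) * sum(log p[i, l_i])`. Never negative, and zero exactly
#' when every true class receives probability one.
#'
#' @param p matrix of predicted class probabilities (rows sum to 1).
#' @param labels integer class ids in `0..K-1`, length `nrow(p)`.
#' @export
multinomial_log_loss <- function(p, labels) {
  p <- as.matrix(p)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(p))) {
    stop("label outside [0, K)", call. = FALSE)
  }
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  -mean(log(p[cbind(seq_len(nrow(p)), labels + 1L)]))
}

# ---------------------------------------------------------------------------
# Declarative network specification

#' Create a single layer specification
#'
#' @param kind one of `conv`, `relu`, `maxpool`, `fc`, `dropout`, `softmax`.
#' @param name layer name.
#' @param kernel kernel side length (conv: 3; maxpool: 2).
#' @param stride stride (conv: 1; maxpool: 2).
#' @param zero_padding logical; conv layers pad to preserve spatial size.
#' @param out_channels output channels (conv) or output neurons (fc).
#' @param weight_filler `"reference"` (fan-in-scaled uniform) or
#'   `"gaussian"`.
#' @param weight_sd standard deviation for the gaussian filler.
#' @param bias_filler constant bias initial value.
#' @param dropout_p dropout probability in `[0, 1)`.
#' @param leaky_slope ReLU slope for negative inputs (0 = pure ReLU).
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind, name = kind, kernel = NA_integer_,
                       stride = NA_integer_, zero_padding = NA,
                       out_channels = NA_integer_,
                       weight_filler = NA_character_, weight_sd = NA_real_,
                       bias_filler = NA_real_, dropout_p = NA_real_,
                       leaky_slope = 0) {
  kind <- match.arg(kind, c("conv", "relu", "maxpool", "fc", "dropout",
                            "softmax"))
  if (kind == "conv" &&
      (!identical(as.integer(kernel), 3L) || !identical(as.integer(stride), 1L) ||
       !isTRUE(zero_padding))) {
    stop("conv layers are 3x3, stride 1, zero-padded in this architecture",
         call. = FALSE)
  }
  if (kind == "dropout" && (is.na(dropout_p) || dropout_p < 0 || dropout_p >= 1)) {
    stop("dropout_p must lie in [0, 1)", call. = FALSE)
  }
  structure(list(kind = kind, name = name, kernel = as.integer(kernel),
                 stride = as.integer(stride), zero_padding = zero_padding,
                 out_channels = as.integer(out_channels),
                 weight_filler = weight_filler, weight_sd = weight_sd,
                 bias_filler = bias_filler, dropout_p = dropout_p,
                 leaky_slope = leaky_slope),
            class = "layer_spec")
}

scaled_width <- function(base, width_mult, floor_at = 1L) {
  max(floor_at, as.integer(round(base * width_mult)))
}

#' Build the sixteen-layer VGG16-style network specification
#'
#' Five convolution blocks of 2, 2, 3, 3, 3 layers with 64, 128, 256, 512,
#' 512 filters (all 3x3, stride 1, zero-padded, each followed by ReLU and
#' each block closed by a 2x2/stride-2 max pool), then FC-4096 + ReLU +
#' dropout, FC-4096 + ReLU + dropout, and FC-`K` feeding a softmax output:
#' thirteen convolutional plus three fully-connected trainable layers.
#' Fillers: convolution weights use the fan-in-scaled uniform reference
#' initializer with constant bias 0.2; FC6/FC7 use gaussian weights
#' (sd 0.005) with constant bias 1; FC8 uses gaussian weights (sd 0.01) with
#' bias 0. Dropout (p = 0.5) follows FC6 and FC7.
#'
#' @param input_shape `(h, w, d)`; `h` and `w` must be divisible by 32
#'   (five spatial halvings). Default `(256, 256, 3)`.
#' @param K number of output classes (default 2: benign, malignant).
#' @param width_mult multiplier applied to every channel width (including the
#'   4096-wide FC layers) for desk-scale training; 1 reproduces the full
#'   recipe.
#' @param dropout_p dropout probability on FC6/FC7.
#' @return An object of class `depict_netspec`: a list with `layers` (ordered
#'   [layer_spec()]s), `input_shape`, `K` and `width_mult`.
#' @export
build_depict_net <- function(input_shape = c(256L, 256L, 3L), K = 2L,
                             width_mult = 1, dropout_p = 0.5) {
  stopifnot(length(input_shape) == 3L, K >= 2L, width_mult > 0)
  if (input_shape[1] %% 32L != 0L || input_shape[2] %% 32L != 0L) {
    stop("input height and width must be divisible by 32", call. = FALSE)
  }
  blocks <- list(c(64L, 2L), c(128L, 2L), c(256L, 3L), c(512L, 3L),
                 c(512L, 3L))
  layers <- list()
  for (b in seq_along(blocks)) {
    ch <- scaled_width(blocks[[b]][1], width_mult)
    for (i in seq_len(blocks[[b]][2])) {
      nm <- sprintf("conv%d_%d", b, i)
      layers <- c(layers, list(
        layer_spec("conv", nm, kernel = 3L, stride = 1L, zero_padding = TRUE,
                   out_channels = ch, weight_filler = "reference",
                   bias_filler = 0.2),
        layer_spec("relu", sprintf("relu%d_%d", b, i))))
    }
    layers <- c(layers, list(layer_spec("maxpool", sprintf("pool%d", b),
                                        kernel = 2L, stride = 2L)))
  }
  fcw <- scaled_width(4096L, width_mult, floor_at = as.integer(K))
  layers <- c(layers, list(
    layer_spec("fc", "fc6", out_channels = fcw, weight_filler = "gaussian",
               weight_sd = 0.005, bias_filler = 1),
    layer_spec("relu", "relu6"),
    layer_spec("dropout", "drop6", dropout_p = dropout_p),
    layer_spec("fc", "fc7", out_channels = fcw, weight_filler = "gaussian",
               weight_sd = 0.005, bias_filler = 1),
    layer_spec("relu", "relu7"),
    layer_spec("dropout", "drop7", dropout_p = dropout_p),
    layer_spec("fc", "fc8", out_channels = as.integer(K),
               weight_filler = "gaussian", weight_sd = 0.01, bias_filler = 0),
    layer_spec("softmax", "prob")))
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 K = as.integer(K), width_mult = width_mult),
            class = "depict_netspec")
}

#' Propagate shapes symbolically through a network specification
#'
#' @param spec a `depict_netspec`.
#' @return Data frame with one row per layer: name, kind, and output
#'   `(h, w, c)` (fully-connected outputs appear as `1 x 1 x channels`).
#' @export
network_shapes <- function(spec) {
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; c <- spec$input_shape[3]
  rows <- lapply(spec$layers, function(ly) {
    switch(ly$kind,
      conv = { c <<- ly$out_channels },
      maxpool = { h <<- (h - ly$kernel) %/% ly$stride + 1L
                  w <<- (w - ly$kernel) %/% ly$stride + 1L },
      fc = { h <<- 1L; w <<- 1L; c <<- ly$out_channels },
      NULL)
    data.frame(name = ly$name, kind = ly$kind, out_h = h, out_w = w,
               out_c = c, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.depict_netspec <- function(x, ...) {
  kinds <- vapply(x$layers, `[[`, character(1), "kind")
  cat(sprintf("<depict_netspec> input %s, %d trainable layers (%d conv + %d fc), %d maxpool, K = %d, width x%g\n",
              paste(x$input_shape, collapse = "x"),
              sum(kinds %in% c("conv", "fc")), sum(kinds == "conv"),
              sum(kinds == "fc"), sum(kinds == "maxpool"), x$K,
              x$width_mult))
  invisible(x)
}

#' Serialize / restore a network specification as JSON
#'
#' @param spec a `depict_netspec`.
#' @param path JSON file path.
#' @export
write_network_spec <- function(spec, path) {
  jsonlite::write_json(list(input_shape = spec$input_shape, K = spec$K,
                            width_mult = spec$width_mult,
                            layers = lapply(spec$layers, unclass)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(x$layers, function(l) {
    structure(list(kind = l$kind, name = l$name,
                   kernel = as.integer(l$kernel %||% NA),
                   stride = as.integer(l$stride %||% NA),
                   zero_padding = l$zero_padding %||% NA,
                   out_channels = as.integer(l$out_channels %||% NA),
                   weight_filler = l$weight_filler %||% NA_character_,
                   weight_sd = as.numeric(l$weight_sd %||% NA),
                   bias_filler = as.numeric(l$bias_filler %||% NA),
                   dropout_p = as.numeric(l$dropout_p %||% NA),
                   leaky_slope = as.numeric(l$leaky_slope %||% 0)),
              class = "layer_spec")
  })
  structure(list(layers = layers,
                 input_shape = as.integer(unlist(x$input_shape)),
                 K = as.integer(x$K), width_mult = as.numeric(x$width_mult)),
            class = "depict_netspec")
}

# ---------------------------------------------------------------------------
# Parameter initialization and forward/backward passes

# Materialize weights for every trainable layer of a spec.
init_network_params <- function(spec, seed = 1L) {
  shapes <- network_shapes(spec)
  with_seed(seed, {
    params <- list()
    h <- spec$input_shape[1]; w <- spec$input_shape[2]
    cin <- spec$input_shape[3]
    flat_in <- NA_integer_
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      if (ly$kind == "conv") {
        k <- ly$kernel; co <- ly$out_channels
        fan_in <- k * k * cin
        W <- if (identical(ly$weight_filler, "gaussian")) {
          array(stats::rnorm(k * k * cin * co, sd = ly$weight_sd),
                dim = c(k, k, cin, co))
        } else {
          lim <- sqrt(6 / fan_in)
          array(stats::runif(k * k * cin * co, -lim, lim),
                dim = c(k, k, cin, co))
        }
        params[[ly$name]] <- list(W = W, b = rep(ly$bias_filler, co))
        cin <- co
      } else if (ly$kind == "maxpool") {
        h <- (h - ly$kernel) %/% ly$stride + 1L
        w <- (w - ly$kernel) %/% ly$stride + 1L
      } else if (ly$kind == "fc") {
        nin <- if (is.na(flat_in)) h * w * cin else flat_in
        nout <- ly$out_channels
        W <- if (identical(ly$weight_filler, "gaussian")) {
          matrix(stats::rnorm(nout * nin, sd = ly$weight_sd), nout, nin)
        } else {
          lim <- sqrt(6 / nin)
          matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
        }
        params[[ly$name]] <- list(W = W, b = rep(ly$bias_filler, nout))
        flat_in <- nout
        cin <- nout; h <- 1L; w <- 1L
      }
    }
    params
  })
}

# Forward pass. x: (h, w, c, n) array with values in [0,1]; internally the
# input is mapped to the raw 8-bit intensity scale (x * 255), the convention
# the architecture's prescribed fillers (gaussian sd 0.005/0.01 against
# constant biases) are calibrated for — on unit-scale inputs those fillers
# produce nearly constant fully-connected activations and the network cannot
# train. Returns list(prob, cache, activations) — cache only when
# train = TRUE, activations only for names in `capture`.
net_forward <- function(spec, params, x, train = FALSE, capture = character(0)) {
  x <- x * 255
  n <- dim(x)[4]
  cache <- if (train) vector("list", length(spec$layers)) else NULL
  acts <- list()
  cur <- x          # spatial tensor until the first fc layer
  flat <- NULL      # (features, n) matrix afterwards
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      if (train) cache[[i]] <- list(x = cur)
      cur <- cpp_conv_forward(cur, params[[ly$name]]$W, params[[ly$name]]$b)
    } else if (ly$kind == "relu") {
      if (is.null(flat)) {
        if (train) cache[[i]] <- list(pos = cur > 0)
        cur <- relu(cur, ly$leaky_slope)
      } else {
        if (train) cache[[i]] <- list(pos = flat > 0)
        flat <- relu(flat, ly$leaky_slope)
      }
    } else if (ly$kind == "maxpool") {
      mp <- cpp_maxpool_forward(cur, ly$kernel, ly$stride)
      if (train) cache[[i]] <- list(argmax = mp$argmax, xdim = dim(cur))
      cur <- mp$y
    } else if (ly$kind == "fc") {
      if (is.null(flat)) {
        d <- dim(cur)
        flat <- matrix(cur, d[1] * d[2] * d[3], n)
        if (train) cache[[i]] <- list(xdim = d)
      }
      if (train) cache[[i]] <- c(cache[[i]], list(x = flat))
      flat <- params[[ly$name]]$W %*% flat + params[[ly$name]]$b
    } else if (ly$kind == "dropout") {
      if (train) {
        keep <- matrix(stats::runif(length(flat)) >= ly$dropout_p,
                       nrow(flat), ncol(flat))
        cache[[i]] <- list(keep = keep, p = ly$dropout_p)
        flat <- flat * keep / (1 - ly$dropout_p)
      }
      # inference: identity (inverted dropout)
    } else if (ly$kind == "softmax") {
      flat <- t(softmax(t(flat)))
    }
    if (ly$name %in% capture) {
      acts[[ly$name]] <- if (is.null(flat)) cur else flat
    }
  }
  list(prob = t(flat), cache = cache, activations = acts)
}

# Backward pass from softmax gradient; returns gradients named per layer.
net_backward <- function(spec, params, cache, prob, labels) {
  n <- nrow(prob)
  onehot <- matrix(0, n, ncol(prob))
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  dflat <- t(prob - onehot) / n   # gradient at fc8 output (softmax + NLL)
  grads <- list()
  dcur <- NULL
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    if (ly$kind == "softmax") {
      next
    } else if (ly$kind == "fc") {
      x <- cache[[i]]$x
      grads[[ly$name]] <- list(W = dflat %*% t(x),
                               b = rowSums(dflat))
      dflat <- t(params[[ly$name]]$W) %*% dflat
      if (!is.null(cache[[i]]$xdim)) {
        dcur <- array(dflat, dim = cache[[i]]$xdim)
        dflat <- NULL
      }
    } else if (ly$kind == "dropout") {
      dflat <- dflat * cache[[i]]$keep / (1 - cache[[i]]$p)
    } else if (ly$kind == "relu") {
      if (is.null(dflat)) {
        dcur <- dcur * (cache[[i]]$pos + ly$leaky_slope * (!cache[[i]]$pos))
      } else {
        dflat <- dflat * (cache[[i]]$pos + ly$leaky_slope * (!cache[[i]]$pos))
      }
    } else if (ly$kind == "maxpool") {
      dcur <- cpp_maxpool_backward(cache[[i]]$argmax, dcur, cache[[i]]$xdim)
    } else if (ly$kind == "conv") {
      bw <- cpp_conv_backward(cache[[i]]$x, params[[ly$name]]$W, dcur)
      grads[[ly$name]] <- list(W = bw$dw, b = bw$db)
      dcur <- bw$dx
    }
  }
  grads
}

#' Training configuration for the network
#'
#' The default optimizer is Adam: the architecture's prescribed fillers mix
#' very small gaussian fully-connected weights (sd 0.005/0.01) with fan-in
#' scaled convolution weights, which puts per-layer gradient magnitudes
#' orders of magnitude apart — a single global SGD step size either
#' oscillates the output layer or leaves the rest frozen, while
#' per-parameter adaptive steps train all sixteen layers together. Plain
#' momentum SGD remains available.
#'
#' @param epochs passes over the training set.
#' @param batch_size minibatch size.
#' @param lr learning rate (Adam default 0.001).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param momentum momentum coefficient (SGD) / beta1 (Adam).
#' @param beta2 Adam second-moment decay.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L, lr = 0.001,
                         optimizer = c("adam", "sgd"), momentum = 0.9,
                         beta2 = 0.999, seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, optimizer = match.arg(optimizer),
                 momentum = momentum, beta2 = beta2,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the network with momentum SGD on the multinomial logistic loss
#'
#' Dropout is active during training only. The run is fully reproducible
#' given the specification, the data, and the configuration seed.
#'
#' @param spec a [build_depict_net()] specification.
#' @param images `(h, w, 3, n)` array in `[0, 1]`, already at the network's
#'   input size.
#' @param labels integer class ids in `0..K-1` (0 = benign, 1 = malignant).
#' @param config a [train_config()].
#' @return An object of class `depict_net` with elements `spec`, `params`,
#'   `config` and `history` (mean training loss per epoch).
#' @export
train_depict_net <- function(spec, images, labels, config = train_config()) {
  stopifnot(inherits(spec, "depict_netspec"))
  images <- as_tensor(images)
  labels <- as.integer(labels)
  n <- dim(images)[4]
  stopifnot(length(labels) == n, n >= 2L)
  if (length(unique(labels)) < 2L) {
    stop("training requires at least two classes", call. = FALSE)
  }
  if (!all(dim(images)[1:3] == spec$input_shape)) {
    stop("images must match the network input shape; rescale them first",
         call. = FALSE)
  }
  params <- init_network_params(spec, seed = config$seed)
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  mom2 <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  history <- numeric(config$epochs)
  step <- 0L
  eps <- 1e-8
  with_seed(derive_seed(config$seed, 1L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- images[, , , take, drop = FALSE]
        yb <- labels[take]
        fwd <- net_forward(spec, params, xb, train = TRUE)
        p <- pmax(fwd$prob, 1e-12)
        losses <- c(losses, multinomial_log_loss(p / rowSums(p), yb))
        grads <- net_backward(spec, params, fwd$cache, fwd$prob, yb)
        step <- step + 1L
        for (nm in names(grads)) {
          if (config$optimizer == "adam") {
            b1 <- config$momentum; b2 <- config$beta2
            for (part in c("W", "b")) {
              g <- grads[[nm]][[part]]
              vel[[nm]][[part]] <- b1 * vel[[nm]][[part]] + (1 - b1) * g
              mom2[[nm]][[part]] <- b2 * mom2[[nm]][[part]] + (1 - b2) * g^2
              mhat <- vel[[nm]][[part]] / (1 - b1^step)
              vhat <- mom2[[nm]][[part]] / (1 - b2^step)
              params[[nm]][[part]] <- params[[nm]][[part]] -
                config$lr * mhat / (sqrt(vhat) + eps)
            }
          } else {
            vel[[nm]]$W <- config$momentum * vel[[nm]]$W - config$lr * grads[[nm]]$W
            vel[[nm]]$b <- config$momentum * vel[[nm]]$b - config$lr * grads[[nm]]$b
            params[[nm]]$W <- params[[nm]]$W + vel[[nm]]$W
            params[[nm]]$b <- params[[nm]]$b + vel[[nm]]$b
          }
        }
      }
      history[ep] <- mean(losses)
    }
  })
  structure(list(spec = spec, params = params, config = config,
                 history = history),
            class = "depict_net")
}

#' @export
print.depict_net <- function(x, ...) {
  cat(sprintf("<depict_net> trained %d epoch(s), final loss %.4f\n",
              length(x$history), utils::tail(x$history, 1L)))
  print(x$spec)
  invisible(x)
}

#' Predict with a trained network
#'
#' @param object a `depict_net`.
#' @param images `(h, w, 3, n)` array (or a single `(h, w, 3)` image).
#' @param type `"class"` (0/1 ids), `"prob"` (softmax matrix), `"label"`
#'   (benign/malignant strings) or `"embedding"` (post-ReLU FC7 activations).
#' @param ... unused.
#' @export
predict.depict_net <- function(object, images,
                               type = c("class", "prob", "label", "embedding"),
                               ...) {
  type <- match.arg(type)
  if (length(dim(images)) == 3L) {
    images <- array(images, dim = c(dim(images), 1L))
  }
  if (type == "embedding") {
    fwd <- net_forward(object$spec, object$params, images,
                       capture = "relu7")
    return(t(fwd$activations$relu7))
  }
  prob <- net_forward(object$spec, object$params, images)$prob
  switch(type,
         prob = prob,
         class = max.col(prob, ties.method = "first") - 1L,
         label = CLASS_LEVELS[max.col(prob, ties.method = "first")])
}

#' Extract the case-representation embedding of an image
#'
#' The stored case representation is the activation of the last hidden
#' layer (FC7, after its ReLU), computed in inference mode (dropout off), so
#' identical inputs always yield identical embeddings.
#'
#' @param network a trained `depict_net`.
#' @param image `(h, w, 3)` array at the network input size.
#' @return Numeric embedding vector (FC7 width, 4096 at the default spec).
#' @export
embed <- function(network, image) {
  if (!inherits(network, "depict_net")) {
    stop("embed() requires a trained network", call. = FALSE)
  }
  as.numeric(predict(network, image, type = "embedding"))
}

# ---------------------------------------------------------------------------
# HDF5 training bundle

#' Write an HDF5 training bundle
#'
#' Stores datasets `images` (float, HDF5 shape `n x 3 x h x w`, values in
#' `[0, 1]`) and `labels` (integer, 0 = benign, 1 = malignant).
#'
#' @param images `(h, w, 3, n)` array in `[0, 1]`.
#' @param labels integer vector of 0/1 class ids.
#' @param path output `.h5` path (overwritten).
#' @export
write_h5_bundle <- function(images, labels, path) {
  images <- as_tensor(images)
  stopifnot(dim(images)[3] == 3L, dim(images)[4] == length(labels))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # rhdf5 reverses R dims when writing: R (w, h, 3, n) -> HDF5 (n, 3, h, w)
  rhdf5::h5write(aperm(images, c(2L, 1L, 3L, 4L)), path, "images")
  rhdf5::h5write(as.integer(labels), path, "labels")
  rhdf5::H5close()
  invisible(path)
}

#' Read an HDF5 training bundle
#'
#' @param path `.h5` path written by [write_h5_bundle()].
#' @return List with `images` (`(h, w, 3, n)` array) and `labels`.
#' @export
read_h5_bundle <- function(path) {
  x <- rhdf5::h5read(path, "images")
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  rhdf5::H5close()
  list(images = aperm(x, c(2L, 1L, 3L, 4L)), labels = labels)
}

#' Stack synthetic cases into a CNN input tensor
#'
#' Rescales every case image to `size x size` and stacks them into an
#' `(size, size, 3, n)` array with integer labels (0 = benign,
#' 1 = malignant).
#'
#' @param cases list of `synthetic_case` objects.
#' @param size target side length.
#' @export
cases_to_tensor <- function(cases, size = 64L) {
  n <- length(cases)
  images <- array(0, dim = c(size, size, 3L, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    img <- cases[[i]]$image
    if (!all(dim(img)[1:2] == c(size, size))) {
      img <- rescale_image(img, c(size, size))
    }
    images[, , , i] <- img
    labels[i] <- as.integer(cases[[i]]$label == "malignant")
  }
  list(images = images, labels = labels)
}
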
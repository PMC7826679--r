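# Feature-extraction backbones.
#
# A backbone is a stack of conv(+BN+ReLU) and max-pool stages described by a
# layer table. The "inception_v3" configuration reproduces the stage output
# shapes of the Inception-v3 layer layout (299x299x3 -> 149x149x32 ->
# 147x147x64 -> 71x71x192 -> 35x35x288 -> 17x17x768 -> 8x8x2048); the "tiny"
# configuration is a 4-stage surrogate that keeps the whole pipeline trainable
# on a CPU in minutes.

#' Backbone configuration
#'
#' @param arch `"tiny"` or `"inception_v3"`.
#' @param input_size Input image side length in pixels. `inception_v3` fixes
#'   299; `tiny` defaults to 64.
#' @param out_spatial Length-2 integer vector, spatial grid of the output
#'   feature map. `inception_v3` fixes `c(8, 8)`.
#' @param out_channels Output channel count D. `inception_v3` fixes 2048;
#'   `tiny` defaults to 64.
#' @param pretrained Load pretrained weights. Requires `checkpoint`; without
#'   one this errors rather than silently falling back to random
#'   initialisation.
#' @param checkpoint Optional path to a saved parameter file (RDS written by
#'   [save_checkpoint()]).
#' @return An object of class `farnet_backbone_config`.
#' @export
backbone_config <- function(arch = c("tiny", "inception_v3"),
                            input_size = NULL, out_spatial = NULL,
                            out_channels = NULL, pretrained = FALSE,
                            checkpoint = NULL) {
  arch <- match.arg(arch)
  if (arch == "inception_v3") {
    input_size <- input_size %||% 299L
    if (input_size != 299) {
      stop("the inception_v3 configuration requires input_size 299",
           call. = FALSE)
    }
    out_spatial <- c(8L, 8L)
    out_channels <- 2048L
  } else {
    input_size <- as.integer(input_size %||% 64L)
    out_spatial <- as.integer(out_spatial %||% c(8L, 8L))
    out_channels <- as.integer(out_channels %||% 64L)
  }
  structure(list(arch = arch, input_size = as.integer(input_size),
                 out_spatial = out_spatial,
                 out_channels = as.integer(out_channels),
                 pretrained = isTRUE(pretrained), checkpoint = checkpoint),
            class = "farnet_backbone_config")
}

# Layer tables. type: conv (k, stride, pad, cout) or maxpool (k, stride).
backbone_layers <- function(config) {
  if (config$arch == "inception_v3") {
    list(
      list(type = "conv", k = 3L, stride = 2L, pad = 0L, cout = 32L),
      list(type = "conv", k = 3L, stride = 1L, pad = 0L, cout = 64L),
      list(type = "maxpool", k = 3L, stride = 2L),
      list(type = "conv", k = 1L, stride = 1L, pad = 0L, cout = 80L),
      list(type = "conv", k = 3L, stride = 1L, pad = 0L, cout = 192L),
      list(type = "maxpool", k = 3L, stride = 2L),
      list(type = "conv", k = 1L, stride = 1L, pad = 0L, cout = 288L),
      list(type = "conv", k = 3L, stride = 2L, pad = 0L, cout = 768L),
      list(type = "conv", k = 3L, stride = 2L, pad = 0L, cout = 2048L)
    )
  } else {
    red <- log2(config$input_size / config$out_spatial[1])
    if (red %% 1 != 0 || red < 0 || red > 4) {
      stop("tiny backbone needs input_size / out_spatial a power of two ",
           "between 1 and 16", call. = FALSE)
    }
    strides <- c(rep(2L, red), rep(1L, 4 - red))[1:4]
    chans <- unique(round(seq(16, config$out_channels, length.out = 4)))
    chans <- c(rep(16L, 4 - length(chans)), as.integer(chans))
    chans[4] <- config$out_channels
    lapply(1:4, function(i) {
      list(type = "conv", k = 3L, stride = strides[i], pad = 1L,
           cout = chans[i])
    })
  }
}

#' Build a feature-extraction backbone
#'
#' Instantiates the conv-stage stack for the requested architecture with
#' freshly initialised (or checkpoint-loaded) parameters. The Inception
#' configuration maps 299 x 299 x 3 inputs to 8 x 8 x 2048 feature maps;
#' auxiliary classifiers are not part of the assembly.
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return Object of class `farnet_backbone`: list with `config`, `layers`,
#'   `params` (per-conv weight/bias + BN gamma/beta) and `state` (BN running
#'   moments).
#' @export
#' @examples
#' bb <- build_backbone(backbone_config("tiny"))
#' dim(extract_features(bb, array(0.5, c(64, 64, 3, 1))))  # 8 8 64 1
build_backbone <- function(config, seed = 1) {
  if (!inherits(config, "farnet_backbone_config")) {
    stop("config must be created with backbone_config()", call. = FALSE)
  }
  if (config$pretrained && is.null(config$checkpoint)) {
    stop("pretrained weights requested but no checkpoint is available; ",
         "pass a checkpoint path or set pretrained = FALSE",
         call. = FALSE)
  }
  layers <- backbone_layers(config)
  params <- list(); state <- list()
  cin <- 3L
  with_seed(seed, {
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      nm <- sprintf("layer%02d", i)
      if (ly$type == "conv") {
        params[[nm]] <- c(conv_params(ly$k, ly$k, cin, ly$cout),
                          bn_params(ly$cout))
        state[[nm]] <- bn_state(ly$cout)
        cin <- ly$cout
      }
    }
  })
  bb <- structure(list(config = config, layers = layers, params = params,
                       state = state), class = "farnet_backbone")
  if (!is.null(config$checkpoint)) {
    ck <- readRDS(config$checkpoint)
    bb$params <- ck$params %||% ck
    if (!is.null(ck$state)) bb$state <- ck$state
  }
  bb
}

# Forward through the backbone stack. Returns out + caches when training.
backbone_forward <- function(bb, x, training = FALSE, cache_needed = FALSE) {
  caches <- list()
  for (i in seq_along(bb$layers)) {
    ly <- bb$layers[[i]]
    nm <- sprintf("layer%02d", i)
    if (ly$type == "conv") {
      cv <- conv_forward(x, bb$params[[nm]], ly$stride, ly$pad,
                         cache_needed = cache_needed)
      bn <- bn_forward(cv$out, bb$params[[nm]], bb$state[[nm]], training)
      bb$state[[nm]] <- bn$state
      rl <- relu_forward(bn$out)
      x <- rl$out
      if (cache_needed) {
        caches[[nm]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$mask)
      }
    } else {
      mp <- maxpool_forward(x, ly$k, ly$stride, cache_needed = cache_needed)
      x <- mp$out
      if (cache_needed) caches[[nm]] <- list(pool = mp$cache)
    }
  }
  list(out = x, caches = caches, state = bb$state)
}

backbone_backward <- function(bb, caches, dout) {
  grads <- list()
  for (i in rev(seq_along(bb$layers))) {
    ly <- bb$layers[[i]]
    nm <- sprintf("layer%02d", i)
    if (ly$type == "conv") {
      ca <- caches[[nm]]
      dout <- relu_backward(dout, ca$relu)
      bnb <- bn_backward(dout, ca$bn)
      cvb <- conv_backward(bnb$dx, ca$conv)
      grads[[nm]] <- list(W = cvb$dW, b = cvb$db,
                          gamma = bnb$dgamma, beta = bnb$dbeta)
      dout <- cvb$dx
    } else {
      dout <- maxpool_backward(dout, caches[[nm]]$pool)
    }
  }
  list(grads = grads, dx = dout)
}

#' Extract feature maps from an image batch
#'
#' Runs the backbone in inference mode (BN running statistics, deterministic).
#'
#' @param backbone A `farnet_backbone` from [build_backbone()].
#' @param images A single H x W x 3 array or an H x W x 3 x N batch array,
#'   pixel values in `[0, 1]`. Pixels are rescaled to `[-1, 1]` internally.
#' @return An h x w x D x N feature-map array with attribute `provenance`
#'   recording the config used.
#' @export
extract_features <- function(backbone, images) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  expect <- backbone$config$input_size
  if (d[1] != expect || d[2] != expect || d[3] != 3) {
    stop(sprintf(
      "input shape mismatch: backbone expects %d x %d x 3, got %d x %d x %d",
      expect, expect, d[1], d[2], d[3]), call. = FALSE)
  }
  x <- images * 2 - 1
  out <- backbone_forward(backbone, x, training = FALSE)$out
  stopifnot_finite(out, "feature map")
  attr(out, "provenance") <- backbone$config
  out
}
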
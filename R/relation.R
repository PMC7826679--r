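# FAR-Net core: label-wise feature aggregation (LFA), activation /
# deactivation (ADA, a squeeze-excitation gate), attention-based relation
# learning (ARL), fusion, and the multilabel sigmoid head.
#
# The exported operations work on single-image h x w x C arrays and are the
# reference semantics; the batched farnet_* internals used for training share
# the same parameters and are tested against them.

#' Assemble a FAR-Net model
#'
#' Builds backbone + LFA + ADA + ARL + prediction head with freshly
#' initialised parameters. The LFA block is three conv layers (1x1 and 3x3 at
#' `lfa_width` channels, then 1x1 down to C), each followed by batch
#' normalisation with learnable scale and ReLU, and a channel-wise spatial
#' softmax. The ADA block is a squeeze-excitation gate with two C-dimensional
#' fully connected layers (ReLU inner, sigmoid outer). The ARL block computes
#' scaled dot-product attention between the C flattened label channels.
#'
#' @param labels Label vocabulary (defines C and the channel order).
#' @param backbone A `farnet_backbone` or a [backbone_config()].
#' @param lfa_width Hidden width of the first two LFA conv layers. Defaults
#'   to 1024 for the Inception backbone, D/2 for the tiny backbone.
#' @param dk Attention projection dimension d_K (default 64).
#' @param scale `"sqrt_dk"` (scaled dot-product attention convention,
#'   default) or `"dk"` (divide raw scores by d_K itself).
#' @param per_label_params If `TRUE`, each query label gets its own
#'   W_Q/W_K/W_V; default shares one set across labels.
#' @param ablate Character subset of `c("lfa", "ada", "arl")` naming blocks
#'   to bypass. Removing LFA requires removing ADA and ARL as well (they are
#'   dimensioned on the C label channels); the resulting model is the plain
#'   backbone + global-average-pool + C-way linear + sigmoid baseline.
#' @param seed Integer seed for parameter initialisation.
#' @return Object of class `farnet_model`.
#' @export
build_farnet <- function(labels = jujube_labels(),
                         backbone = backbone_config("tiny"),
                         lfa_width = NULL, dk = 64L,
                         scale = c("sqrt_dk", "dk"),
                         per_label_params = FALSE,
                         ablate = character(0), seed = 1) {
  scale <- match.arg(scale)
  if (dk <= 0) stop("dk must be positive", call. = FALSE)
  bad <- setdiff(ablate, c("lfa", "ada", "arl"))
  if (length(bad)) stop("unknown ablation flag(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if ("lfa" %in% ablate && !"arl" %in% ablate) {
    stop("ablating LFA requires ablating ARL too: ",
         "relation learning needs label-wise channels", call. = FALSE)
  }
  if ("lfa" %in% ablate && !"ada" %in% ablate) {
    stop("ablating LFA requires ablating ADA too: ",
         "the excitation layers are dimensioned on the C label channels",
         call. = FALSE)
  }
  if (inherits(backbone, "farnet_backbone_config")) {
    backbone <- build_backbone(backbone, seed = seed)
  }
  C <- length(labels)
  D <- backbone$config$out_channels
  hw <- prod(backbone$config$out_spatial)
  lfa_width <- as.integer(lfa_width %||%
    if (backbone$config$arch == "inception_v3") 1024L else max(8L, D %/% 2L))
  model <- with_seed(derive_seed(seed, 7L), {
    lfa <- list(
      conv1 = c(conv_params(1L, 1L, D, lfa_width), bn_params(lfa_width)),
      conv2 = c(conv_params(3L, 3L, lfa_width, lfa_width),
                bn_params(lfa_width)),
      conv3 = c(conv_params(1L, 1L, lfa_width, C), bn_params(C))
    )
    lfa_state <- list(conv1 = bn_state(lfa_width),
                      conv2 = bn_state(lfa_width), conv3 = bn_state(C))
    ada <- list(W1 = linear_params(C, C)$W, b1 = numeric(C),
                W2 = linear_params(C, C)$W, b2 = numeric(C))
    mk_maps <- function() list(WQ = linear_params(hw, dk)$W,
                               WK = linear_params(hw, dk)$W,
                               WV = linear_params(hw, hw, 0.3 / sqrt(hw))$W)
    arl <- if (per_label_params) {
      list(per_label = lapply(seq_len(C), function(l) mk_maps()))
    } else {
      mk_maps()
    }
    head <- linear_params(D, C)
    list(lfa = lfa, lfa_state = lfa_state, ada = ada, arl = arl,
         head = head)
  })
  structure(list(labels = labels, backbone = backbone,
                 params = list(lfa = model$lfa, ada = model$ada,
                               arl = model$arl, head = model$head),
                 state = list(lfa = model$lfa_state),
                 dk = as.integer(dk), scale = scale,
                 per_label_params = isTRUE(per_label_params),
                 ablate = ablate, hw = hw),
            class = "farnet_model")
}

#' @export
print.farnet_model <- function(x, ...) {
  cat("FAR-Net model:", length(x$labels), "labels,",
      x$backbone$config$arch, "backbone",
      sprintf("(%dx%dx%d features),", x$backbone$config$out_spatial[1],
              x$backbone$config$out_spatial[2],
              x$backbone$config$out_channels),
      "d_K =", x$dk, paste0("(", x$scale, ")"))
  if (length(x$ablate)) cat(", ablated:", paste(x$ablate, collapse = ", "))
  cat("\n")
  invisible(x)
}

arl_scale_factor <- function(dk, scale) {
  if (scale == "sqrt_dk") sqrt(dk) else dk
}

# ---- single-image reference operations ------------------------------------

#' Label-wise feature aggregation convolution
#'
#' Maps a D-channel backbone feature map to C label channels through the
#' three-layer conv block (1x1, 3x3 same-padded, 1x1 -> C; each with batch
#' normalisation and ReLU, evaluated with running statistics). Spatial size
#' is preserved.
#'
#' @param X h x w x D feature array (single image).
#' @param params The `lfa` component of a `farnet_model` (`model$params$lfa`),
#'   with matching BN state in `model$state$lfa`.
#' @param state BN running statistics; defaults to fresh (identity-like)
#'   statistics.
#' @return h x w x C response array S.
#' @export
lfa_conv <- function(X, params, state = NULL) {
  d <- dim(X)
  x4 <- array(X, c(d, 1L))
  state <- state %||% list(conv1 = bn_state(ncol(params$conv1$W)),
                           conv2 = bn_state(ncol(params$conv2$W)),
                           conv3 = bn_state(ncol(params$conv3$W)))
  pads <- c(conv1 = 0L, conv2 = 1L, conv3 = 0L)
  for (nm in c("conv1", "conv2", "conv3")) {
    cv <- conv_forward(x4, params[[nm]], 1L, pads[[nm]], cache_needed = FALSE)
    bn <- bn_forward(cv$out, params[[nm]], state[[nm]], training = FALSE)
    x4 <- relu_forward(bn$out)$out
  }
  array(x4, dim(x4)[1:3])
}

#' Channel-wise spatial softmax
#'
#' Normalises every channel of `S` over its spatial grid so that each channel
#' is nonnegative and sums to one: `A_l(i,j) = exp(S_l(i,j)) / sum_ij
#' exp(S_l(i,j))`. Shift-invariant and numerically stabilised by max
#' subtraction.
#'
#' @param S h x w x C array of responses.
#' @return h x w x C aggregated feature array A.
#' @export
#' @examples
#' A <- spatial_softmax(array(0, c(8, 8, 2)))
#' A[1, 1, 1]  # 1/64
spatial_softmax <- function(S) {
  stopifnot_finite(S, "spatial softmax input")
  d <- dim(S)
  A <- S
  for (l in seq_len(d[3])) {
    ch <- S[, , l]
    e <- exp(ch - max(ch))
    A[, , l] <- e / sum(e)
  }
  A
}

#' Squeeze: per-channel spatial mean
#'
#' `z_l` is the global average of channel `l` (divisor h*w). Applied to a
#' spatially softmax-normalised map every `z_l` equals `1/(h*w)`.
#'
#' @param A h x w x C array.
#' @return Numeric vector of length C.
#' @export
se_squeeze <- function(A) {
  apply(A, 3, mean)
}

#' Excitation: two fully connected layers with a sigmoid gate
#'
#' `s = sigmoid(W2 relu(W1 z + b1) + b2)`; both layers are C-dimensional.
#' Outputs lie strictly in (0, 1).
#'
#' @param z Length-C squeeze vector.
#' @param params The `ada` component of a `farnet_model` (fields `W1`, `b1`,
#'   `W2`, `b2`; the maps are C x C).
#' @return Length-C gate vector in (0, 1).
#' @export
se_excite <- function(z, params) {
  if (length(z) != nrow(params$W1)) {
    stop(sprintf("squeeze vector length %d does not match gate dimension %d",
                 length(z), nrow(params$W1)), call. = FALSE)
  }
  h <- pmax(as.vector(crossprod(params$W1, z)) + params$b1, 0)
  sigmoid(as.vector(crossprod(params$W2, h)) + params$b2)
}

#' Reweight: gate each label channel by its excitation scalar
#'
#' @param A h x w x C array.
#' @param s Length-C gate vector.
#' @return h x w x C activated feature array, channel l scaled by `s[l]`.
#' @export
se_reweight <- function(A, s) {
  d <- dim(A)
  if (length(s) != d[3]) {
    stop(sprintf("gate length %d does not match channel count %d",
                 length(s), d[3]), call. = FALSE)
  }
  A * rep(s, each = d[1] * d[2])
}

# Flatten channels of an h x w x C array into a C x (h*w) matrix.
flatten_channels <- function(fA) {
  d <- dim(fA)
  t(matrix(fA, d[1] * d[2], d[3]))
}

#' Raw attention scores between label channels
#'
#' Each label channel is flattened to an h*w vector; the score between source
#' label m and query label l is the dot product of their W_K / W_Q
#' projections divided by the scale (`sqrt(d_K)` by default, or `d_K`).
#' The diagonal is not part of the relation definition and is returned as 0.
#'
#' @param fA h x w x C activated feature array.
#' @param params ARL parameters: list with `WQ`, `WK` (h*w x d_K) and `WV`
#'   (h*w x h*w), or a `per_label` list of such sets
#'   (`model$params$arl`).
#' @param dk Positive integer scale hyperparameter d_K.
#' @param scale `"sqrt_dk"` or `"dk"`.
#' @return C x C matrix `wS` with `wS[m, l]` the score of source m for
#'   query l.
#' @export
relation_scores <- function(fA, params, dk = 64, scale = "sqrt_dk") {
  if (dk <= 0) stop("dk must be positive", call. = FALSE)
  M <- flatten_channels(fA)
  C <- nrow(M)
  sc <- arl_scale_factor(dk, scale)
  if (!is.null(params$per_label)) {
    wS <- matrix(0, C, C)
    for (l in seq_len(C)) {
      pl <- params$per_label[[l]]
      q <- as.vector(M[l, , drop = FALSE] %*% pl$WQ)
      K <- M %*% pl$WK
      wS[, l] <- (K %*% q) / sc
    }
  } else {
    Q <- M %*% params$WQ
    K <- M %*% params$WK
    wS <- tcrossprod(K, Q) / sc
  }
  diag(wS) <- 0
  wS
}

#' Normalise attention scores into relation weights
#'
#' Per query label l, a softmax over the other labels m != l:
#' `w[m, l] = exp(wS[m, l]) / sum_{k != l} exp(wS[k, l])`. Every column sums
#' to one over its off-diagonal entries; the diagonal is zero.
#'
#' @param wS C x C score matrix (diagonal ignored).
#' @return C x C weight matrix.
#' @export
relation_weights <- function(wS) {
  stopifnot_finite(wS[row(wS) != col(wS)], "relation scores")
  C <- nrow(wS)
  if (C < 2) stop("relation weights need at least 2 labels", call. = FALSE)
  w <- matrix(0, C, C)
  for (l in seq_len(C)) {
    m <- setdiff(seq_len(C), l)
    e <- exp(wS[m, l] - max(wS[m, l]))
    w[m, l] <- e / sum(e)
  }
  w
}

#' Correlation features from relation weights
#'
#' `fR_l` is the weight-averaged sum of the W_V-transformed other-label
#' channels, reshaped back to the spatial grid.
#'
#' @param fA h x w x C activated feature array.
#' @param w C x C relation weight matrix (zero diagonal, columns summing
#'   to one).
#' @param params ARL parameters (see [relation_scores()]).
#' @return h x w x C correlation feature array.
#' @export
relation_features <- function(fA, w, params) {
  d <- dim(fA)
  M <- flatten_channels(fA)
  C <- nrow(M)
  if (!is.null(params$per_label)) {
    fR <- matrix(0, C, d[1] * d[2])
    for (l in seq_len(C)) {
      V <- M %*% params$per_label[[l]]$WV
      fR[l, ] <- as.vector(crossprod(V, w[, l]))
    }
  } else {
    V <- M %*% params$WV
    fR <- crossprod(w, V)
  }
  array(t(fR), d)
}

#' Fuse independent and correlation features
#'
#' Elementwise sum `fM = fA + fR`.
#'
#' @param fA,fR h x w x C arrays of identical shape.
#' @return h x w x C fused feature array.
#' @export
fuse <- function(fA, fR) {
  if (!identical(dim(fA), dim(fR))) {
    stop(sprintf("shape mismatch: fA is %s, fR is %s",
                 paste(dim(fA), collapse = "x"),
                 paste(dim(fR), collapse = "x")), call. = FALSE)
  }
  fA + fR
}

#' Multilabel prediction head
#'
#' Global average pooling per channel (the per-label logit) followed by a
#' logistic sigmoid.
#'
#' @param fM h x w x C fused feature array.
#' @return List with `logits` (length C) and `confidence` (length C, in
#'   `[0, 1]`).
#' @export
predict_head <- function(fM) {
  logits <- apply(fM, 3, mean)
  list(logits = logits, confidence = sigmoid(logits))
}

# ---- batched forward / backward -------------------------------------------

lfa_pads <- c(conv1 = 0L, conv2 = 1L, conv3 = 0L)

lfa_forward_batch <- function(model, X, training, cache_needed) {
  caches <- list()
  x4 <- X
  st <- model$state$lfa
  for (nm in c("conv1", "conv2", "conv3")) {
    cv <- conv_forward(x4, model$params$lfa[[nm]], 1L, lfa_pads[[nm]],
                       cache_needed = cache_needed)
    bn <- bn_forward(cv$out, model$params$lfa[[nm]], st[[nm]], training)
    st[[nm]] <- bn$state
    rl <- relu_forward(bn$out)
    x4 <- rl$out
    if (cache_needed) {
      caches[[nm]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$mask)
    }
  }
  # channel-wise spatial softmax per image
  d <- dim(x4)
  A <- x4
  for (i in seq_len(d[4])) A[, , , i] <- spatial_softmax(x4[, , , i])
  list(S = x4, A = A, caches = caches, state = st)
}

lfa_backward_batch <- function(model, cache, dS) {
  grads <- list()
  dout <- dS
  for (nm in c("conv3", "conv2", "conv1")) {
    ca <- cache[[nm]]
    dout <- relu_backward(dout, ca$relu)
    bnb <- bn_backward(dout, ca$bn)
    cvb <- conv_backward(bnb$dx, ca$conv)
    grads[[nm]] <- list(W = cvb$dW, b = cvb$db,
                        gamma = bnb$dgamma, beta = bnb$dbeta)
    dout <- cvb$dx
  }
  list(grads = grads, dx = dout)
}

# softmax backward over the spatial grid, per channel and image:
# dS = A * (dA - sum(A * dA)).
spatial_softmax_backward <- function(dA, A) {
  d <- dim(A)
  hw <- d[1] * d[2]
  Am <- matrix(A, hw)          # columns: channel x image
  dAm <- matrix(dA, hw)
  s <- colSums(Am * dAm)
  dS <- Am * (dAm - rep(s, each = hw))
  array(dS, d)
}

ada_forward_batch <- function(model, A) {
  d <- dim(A)
  hw <- d[1] * d[2]
  # z: C x N matrix of channel means
  z <- apply(A, c(3, 4), mean)
  dim(z) <- c(d[3], d[4])
  p <- model$params$ada
  H <- pmax(crossprod(p$W1, z) + p$b1, 0)       # C x N
  s <- sigmoid(crossprod(p$W2, H) + p$b2)       # C x N
  At <- A * array(rep(as.vector(s), each = hw), d)
  list(At = At, z = z, H = H, s = s)
}

ada_backward_batch <- function(model, cache, A, dAt) {
  d <- dim(A)
  hw <- d[1] * d[2]
  p <- model$params$ada
  sful <- rep(as.vector(cache$s), each = hw)
  dA <- dAt * array(sful, d)
  ds <- apply(dAt * A, c(3, 4), sum)          # C x N
  dim(ds) <- c(d[3], d[4])
  dpre2 <- ds * cache$s * (1 - cache$s)       # C x N
  dW2 <- tcrossprod(cache$H, dpre2)           # (C x N)(N x C) -> C x C
  db2 <- rowSums(dpre2)
  dH <- p$W2 %*% dpre2
  dpre1 <- dH * (cache$H > 0)
  dW1 <- tcrossprod(cache$z, dpre1)
  db1 <- rowSums(dpre1)
  dz <- p$W1 %*% dpre1                        # C x N
  dA <- dA + array(rep(as.vector(dz), each = hw), d) / hw
  list(dA = dA, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

arl_forward_batch <- function(model, At) {
  d <- dim(At)
  C <- d[3]; n <- d[4]; hw <- d[1] * d[2]
  sc <- arl_scale_factor(model$dk, model$scale)
  fR <- array(0, d)
  att <- array(0, c(C, C, n))
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    M <- t(matrix(At[, , , i], hw, C))
    if (model$per_label_params) {
      wS <- matrix(0, C, C); V <- NULL
      for (l in seq_len(C)) {
        pl <- model$params$arl$per_label[[l]]
        q <- as.vector(M[l, , drop = FALSE] %*% pl$WQ)
        wS[, l] <- ((M %*% pl$WK) %*% q) / sc
      }
      diag(wS) <- 0
      w <- relation_weights(wS)
      fRm <- matrix(0, C, hw)
      for (l in seq_len(C)) {
        Vl <- M %*% model$params$arl$per_label[[l]]$WV
        fRm[l, ] <- as.vector(crossprod(Vl, w[, l]))
      }
      caches[[i]] <- list(M = M, w = w)
    } else {
      p <- model$params$arl
      Q <- M %*% p$WQ; K <- M %*% p$WK; V <- M %*% p$WV
      wS <- tcrossprod(K, Q) / sc
      diag(wS) <- 0
      w <- relation_weights(wS)
      fRm <- crossprod(w, V)
      caches[[i]] <- list(M = M, Q = Q, K = K, V = V, w = w)
    }
    fR[, , , i] <- array(t(fRm), d[1:3])
    att[, , i] <- w
  }
  list(fR = fR, att = att, caches = caches)
}

# Backward through shared-parameter ARL. Per-label parameter mode is
# supported for inference only; training uses the shared default.
arl_backward_batch <- function(model, caches, At, dfR) {
  if (model$per_label_params) {
    stop("training with per_label_params is not supported; ",
         "use the shared-parameter ARL", call. = FALSE)
  }
  d <- dim(At)
  C <- d[3]; n <- d[4]; hw <- d[1] * d[2]
  p <- model$params$arl
  sc <- arl_scale_factor(model$dk, model$scale)
  dWQ <- matrix(0, hw, model$dk); dWK <- dWQ
  dWV <- matrix(0, hw, hw)
  dAt <- array(0, d)
  for (i in seq_len(n)) {
    ca <- caches[[i]]
    dfRm <- t(matrix(dfR[, , , i], hw, C))     # C x hw
    dV <- ca$w %*% dfRm                        # C x hw
    dw <- tcrossprod(ca$V, dfRm)               # dw[m, l] = <V_m, dfR_l>
    # column-wise masked softmax backward
    dwS <- matrix(0, C, C)
    for (l in seq_len(C)) {
      wl <- ca$w[, l]
      dwS[, l] <- wl * (dw[, l] - sum(wl * dw[, l]))
    }
    diag(dwS) <- 0
    dK <- (dwS %*% ca$Q) / sc
    dQ <- (crossprod(dwS, ca$K)) / sc
    dM <- dQ %*% t(p$WQ) + dK %*% t(p$WK) + dV %*% t(p$WV)
    dWQ <- dWQ + crossprod(ca$M, dQ)
    dWK <- dWK + crossprod(ca$M, dK)
    dWV <- dWV + crossprod(ca$M, dV)
    dAt[, , , i] <- array(t(dM), d[1:3])
  }
  list(dAt = dAt, grads = list(WQ = dWQ, WK = dWK, WV = dWV))
}

head_pool_batch <- function(x) {
  # global average pooling: returns N x C matrix of channel means
  d <- dim(x)
  t(apply(x, 4, function(a) colMeans(matrix(a, d[1] * d[2], d[3]))))
}

#' Forward pass of an assembled FAR-Net model
#'
#' Composition backbone -> LFA -> ADA -> ARL -> fusion -> pooling head,
#' honouring the model's ablation flags (`ada` bypassed: the gate is skipped
#' and the aggregated map passes through; `arl` bypassed: the correlation
#' features are zero; all three bypassed: backbone + pooled C-way linear
#' head). Deterministic in inference mode.
#'
#' @param model A `farnet_model`.
#' @param images H x W x 3 array or H x W x 3 x N batch, pixels in `[0, 1]`.
#' @param ablate Optional override of the model's ablation flags.
#' @return List with `confidence` (N x C matrix), `logits` (N x C), and
#'   `attention` (C x C x N relation-weight array, `NULL` when ARL is
#'   bypassed).
#' @export
farnet_forward <- function(model, images, ablate = NULL) {
  ablate <- ablate %||% model$ablate
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  fwd <- farnet_batch_forward(model, images * 2 - 1, training = FALSE,
                              cache_needed = FALSE, ablate = ablate)
  list(confidence = fwd$confidence, logits = fwd$logits,
       attention = fwd$att)
}

# Internal batched forward. `x` is already rescaled to [-1, 1].
farnet_batch_forward <- function(model, x, training, cache_needed,
                                 ablate = model$ablate) {
  C <- length(model$labels)
  bb <- backbone_forward(model$backbone, x, training = training,
                         cache_needed = cache_needed)
  out <- list(state = list(backbone = bb$state), att = NULL)
  if ("lfa" %in% ablate) {
    pooled <- head_pool_batch(bb$out)                  # N x D
    logits <- sweep(pooled %*% model$params$head$W, 2,
                    model$params$head$b, "+")
    out$cache <- if (cache_needed) list(mode = "baseline", bb = bb$caches,
                                        pooled = pooled,
                                        dims_f = dim(bb$out))
    out$logits <- logits
  } else {
    lf <- lfa_forward_batch(model, bb$out, training, cache_needed)
    out$state$lfa <- lf$state
    if ("ada" %in% ablate) {
      At <- lf$A
      ada <- NULL
    } else {
      ada <- ada_forward_batch(model, lf$A)
      At <- ada$At
    }
    if ("arl" %in% ablate) {
      fM <- At
      arl <- NULL
    } else {
      arl <- arl_forward_batch(model, At)
      fM <- At + arl$fR
      out$att <- arl$att
    }
    logits <- head_pool_batch(fM)
    out$logits <- logits
    out$cache <- if (cache_needed) {
      list(mode = "farnet", bb = bb$caches, lfa = lf, ada = ada,
           arl = if (!is.null(arl)) arl$caches, At = At, A = lf$A,
           dims_f = dim(fM), ablate = ablate)
    }
  }
  colnames(out$logits) <- model$labels
  out$confidence <- sigmoid(out$logits)
  out
}

# Internal batched backward from d(logits): returns gradients per module.
farnet_batch_backward <- function(model, cache, dlogits) {
  grads <- list()
  d <- cache$dims_f
  hw <- d[1] * d[2]
  if (cache$mode == "baseline") {
    grads$head <- list(W = crossprod(cache$pooled, dlogits),
                       b = colSums(dlogits))
    dpooled <- tcrossprod(dlogits, model$params$head$W)   # N x D
    dfeat <- array(0, d)
    for (i in seq_len(d[4])) {
      dfeat[, , , i] <- rep(dpooled[i, ] / hw, each = hw)
    }
    bbb <- backbone_backward(model$backbone, cache$bb, dfeat)
    grads$backbone <- bbb$grads
    return(grads)
  }
  ablate <- cache$ablate
  # head: logit_l = mean over hw of fM channel l
  dfM <- array(0, d)
  for (i in seq_len(d[4])) {
    dfM[, , , i] <- rep(dlogits[i, ] / hw, each = hw)
  }
  if ("arl" %in% ablate) {
    dAt <- dfM
  } else {
    ab <- arl_backward_batch(model, cache$arl, cache$At, dfM)
    grads$arl <- ab$grads
    dAt <- dfM + ab$dAt     # fusion: fM = At + fR
  }
  if ("ada" %in% ablate) {
    dA <- dAt
  } else {
    adab <- ada_backward_batch(model, cache$ada, cache$A, dAt)
    grads$ada <- adab$grads
    dA <- adab$dA
  }
  dS <- spatial_softmax_backward(dA, cache$A)
  lfb <- lfa_backward_batch(model, cache$lfa$caches, dS)
  grads$lfa <- lfb$grads
  bbb <- backbone_backward(model$backbone, cache$bb, lfb$dx)
  grads$backbone <- bbb$grads
  grads
}
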
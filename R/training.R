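# Multilabel loss and the four-stage module-wise training protocol.

#' Multilabel binary cross-entropy loss
#'
#' Sum over labels of the binary cross-entropy between the multi-hot target
#' and the sigmoid of the logit, averaged over the batch. Evaluated in the
#' numerically stabilised log-sum-exp form, so it is finite for any finite
#' logits and nonnegative.
#'
#' @param y Multi-hot target vector (one sample), or N x C matrix; entries
#'   in `{0, 1}`.
#' @param logits Pre-sigmoid prediction(s), same shape as `y`.
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' multilabel_loss(c(1, 0), c(0, 0))  # 2 * log(2)
multilabel_loss <- function(y, logits) {
  if (!all(y %in% c(0, 1))) {
    stop("targets must be 0/1 multi-hot indicators", call. = FALSE)
  }
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  y <- as.matrix(y); logits <- as.matrix(logits)
  if (!all(dim(y) == dim(logits))) {
    stop("y and logits must have the same shape", call. = FALSE)
  }
  # per-element BCE-with-logits: max(x, 0) - x*y + log(1 + exp(-|x|))
  ll <- pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))
  mean(rowSums(ll))
}

# gradient of multilabel_loss wrt logits (mean over batch rows)
multilabel_loss_grad <- function(y, logits) {
  (sigmoid(logits) - y) / nrow(as.matrix(y))
}

#' The four-stage module-wise training plan
#'
#' Stage 1 fine-tunes the feature-extraction backbone through its own pooled
#' C-way linear head; stage 2 freezes the backbone and trains the LFA and ADA
#' blocks (ARL stays frozen at its initialisation but remains in the forward
#' pass, so the label-channel stages always see the full architecture);
#' stage 3 freezes everything but ARL; stage 4 fine-tunes the whole model.
#'
#' @param warn_random_init Emit a message noting that stage 1 starts from
#'   random backbone weights when no pretrained checkpoint is in play.
#' @return Object of class `farnet_stage_plan`: list of four stages, each
#'   with `trainable` (module names) and `forward` mode.
#' @export
make_stage_plan <- function(warn_random_init = FALSE) {
  if (warn_random_init) {
    message("no pretrained backbone weights available; ",
            "stage 1 starts from random initialisation")
  }
  plan <- list(
    list(trainable = c("backbone", "head"), forward = "baseline"),
    list(trainable = c("lfa", "ada"),       forward = "full"),
    list(trainable = "arl",                 forward = "full"),
    list(trainable = c("backbone", "head", "lfa", "ada", "arl"),
         forward = "full")
  )
  class(plan) <- "farnet_stage_plan"
  plan
}

#' Training hyperparameters
#'
#' Defaults follow the reference protocol: SGD with momentum 0.9, weight
#' decay 0.0005, base learning rate 0.001, exponential learning-rate policy,
#' batch size 16. The per-stage iteration counts and the exponential decay
#' factor are configurable; defaults are full-scale counts, scale them down
#' for desk-size experiments.
#'
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay coefficient.
#' @param base_lr Base learning rate.
#' @param gamma Exponential decay factor applied every `decay_steps`
#'   iterations (one epoch by default).
#' @param batch_size Minibatch size.
#' @param iters Integer vector of per-stage iteration counts (length 4).
#' @param seed RNG seed governing batch sampling and augmentation.
#' @param decay_steps Iterations per decay step; default one epoch
#'   (`ceiling(n_train / batch_size)`).
#' @param eval_every Validation-mAP evaluation period (iterations) for best-
#'   checkpoint selection within each stage; default half a stage.
#' @param select_best Keep the best-validation-mAP parameters of each stage.
#' @param augment Apply random horizontal/vertical flips.
#' @param stage_lr_mult Per-stage multipliers on `base_lr` (length 4). The
#'   gradient scale of the label-channel stages differs from the backbone
#'   stage by roughly the spatial grid size squared (every softmax-normalised
#'   channel sums to one, so pooled logits and their gradients are of order
#'   1/(h*w)); stage-wise multipliers let the module-wise stages take
#'   usefully sized steps without changing the base rate.
#' @return List of class `farnet_train_config`.
#' @export
train_config <- function(momentum = 0.9, weight_decay = 5e-4,
                         base_lr = 0.001, gamma = 0.95, batch_size = 16,
                         iters = c(2000, 1000, 1000, 2000), seed = 1,
                         decay_steps = NULL, eval_every = NULL,
                         select_best = TRUE, augment = TRUE,
                         stage_lr_mult = c(1, 1, 1, 1)) {
  stopifnot(momentum >= 0, weight_decay >= 0, base_lr > 0, gamma > 0,
            batch_size >= 1, all(iters > 0), length(iters) == 4,
            all(stage_lr_mult > 0), length(stage_lr_mult) == 4)
  structure(list(momentum = momentum, weight_decay = weight_decay,
                 base_lr = base_lr, gamma = gamma,
                 batch_size = as.integer(batch_size),
                 iters = as.integer(iters), seed = as.integer(seed),
                 decay_steps = decay_steps, eval_every = eval_every,
                 select_best = isTRUE(select_best),
                 augment = isTRUE(augment),
                 stage_lr_mult = stage_lr_mult),
            class = "farnet_train_config")
}

#' Learning rate under the exponential policy
#'
#' @param config A [train_config()].
#' @param step Number of completed decay steps.
#' @return `base_lr * gamma^step`.
#' @export
learning_rate <- function(config, step) {
  config$base_lr * config$gamma^step
}

# ---- parameter bookkeeping ------------------------------------------------

# Collect the trainable numeric leaves of a module's parameter list as a
# named flat list of paths. BN running states are excluded (not parameters).
flatten_params <- function(params, prefix = character()) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) {
      out <- c(out, flatten_params(p, c(prefix, nm)))
    } else if (is.numeric(p) && nm %in%
               c("W", "b", "gamma", "beta", "W1", "b1", "W2", "b2",
                 "WQ", "WK", "WV")) {
      out[[paste(c(prefix, nm), collapse = ".")]] <- c(prefix, nm)
    }
  }
  out
}

get_param <- function(root, path) {
  for (nm in path) root <- root[[nm]]
  root
}

set_param <- function(root, path, value) {
  if (length(path) == 1) {
    root[[path]] <- value
  } else {
    root[[path[1]]] <- set_param(root[[path[1]]], path[-1], value)
  }
  root
}

# Module parameter roots within a model: backbone params live inside
# model$backbone$params, the rest under model$params.
module_params <- function(model, module) {
  if (module == "backbone") model$backbone$params else model$params[[module]]
}

module_paths <- function(model, module) {
  flatten_params(module_params(model, module))
}

set_module_params <- function(model, module, params) {
  if (module == "backbone") {
    model$backbone$params <- params
  } else {
    model$params[[module]] <- params
  }
  model
}

#' Checksum of a module's parameters
#'
#' Useful for verifying the freeze contract: a frozen module's checksum is
#' bit-identical before and after a training stage.
#'
#' @param model A `farnet_model`.
#' @param module One of `"backbone"`, `"head"`, `"lfa"`, `"ada"`, `"arl"`.
#' @return A single numeric digest.
#' @export
param_checksum <- function(model, module) {
  pars <- module_params(model, module)
  paths <- flatten_params(pars)
  vals <- unlist(lapply(paths, function(p) as.vector(get_param(pars, p))))
  sum(vals * seq_along(vals) %% 97)
}

# random flips, applied image-wise; consumes the RNG stream
augment_flips <- function(x) {
  n <- dim(x)[4]
  fh <- stats::runif(n) < 0.5
  fv <- stats::runif(n) < 0.5
  for (i in seq_len(n)) {
    if (fh[i]) x[, , , i] <- x[rev(seq_len(dim(x)[1])), , , i]
    if (fv[i]) x[, , , i] <- x[, rev(seq_len(dim(x)[2])), , i]
  }
  x
}

stage_forward_mode <- function(stage_mode, ablate) {
  extra <- switch(stage_mode, baseline = c("lfa", "ada", "arl"),
                  without_arl = "arl", full = character(0))
  union(ablate, extra)
}

#' Train a FAR-Net model with the staged protocol
#'
#' Runs the requested stages of `plan` with SGD (momentum, weight decay,
#' exponential learning-rate decay). Within each stage only the stage's
#' trainable modules are updated; all other parameters are bit-identical
#' before and after. Stages whose trainable modules are all ablated from the
#' model are skipped. Deterministic given `config$seed`.
#'
#' @param model A `farnet_model`.
#' @param data List with `images` (H x W x 3 x N) and `index` (a
#'   `farnet_index` whose `split` column marks train/val rows; see
#'   [split_dataset()]).
#' @param config A [train_config()].
#' @param plan A [make_stage_plan()].
#' @param stages Integer subset of stages to run (default all four).
#' @param verbose Print per-stage progress.
#' @return List with `model` (trained), `history` (data.frame of stage,
#'   iteration, learning rate, training loss) and `val` (data.frame of
#'   validation mAP measurements).
#' @export
train_farnet <- function(model, data, config = train_config(),
                         plan = make_stage_plan(), stages = 1:4,
                         verbose = FALSE) {
  index <- data$index
  labels <- model$labels
  tr_rows <- which(index$split == "train")
  if (length(tr_rows) == 0) stop("empty training split", call. = FALSE)
  val_rows <- which(index$split == "val")
  ymat <- as.matrix(index[, labels, drop = FALSE])
  history <- list(); vallog <- list()
  set.seed(config$seed)
  decay_steps <- config$decay_steps %||%
    ceiling(length(tr_rows) / config$batch_size)
  for (st in stages) {
    stage <- plan[[st]]
    trainable <- setdiff(stage$trainable, model$ablate)
    if (length(trainable) == 0) {
      if (verbose) message("stage ", st, ": all modules ablated, skipped")
      next
    }
    fwd_ablate <- stage_forward_mode(stage$forward, model$ablate)
    paths <- lapply(trainable, function(m) module_paths(model, m))
    names(paths) <- trainable
    vel <- lapply(trainable, function(m) {
      lapply(paths[[m]], function(p) {
        v <- get_param(module_params(model, m), p)
        v[] <- 0
        v
      })
    })
    names(vel) <- trainable
    eval_every <- config$eval_every %||% max(25L, config$iters[st] %/% 2L)
    best <- list(map = -Inf, params = NULL)
    n_iter <- config$iters[st]
    lr_mult <- (config$stage_lr_mult %||% rep(1, 4))[st]
    for (it in seq_len(n_iter)) {
      lr <- lr_mult * learning_rate(config, (it - 1) %/% decay_steps)
      batch <- sample(tr_rows, min(config$batch_size, length(tr_rows)))
      xb <- data$images[, , , batch, drop = FALSE]
      if (config$augment) xb <- augment_flips(xb)
      yb <- ymat[batch, , drop = FALSE]
      fwd <- farnet_batch_forward(model, xb * 2 - 1, training = TRUE,
                                  cache_needed = TRUE, ablate = fwd_ablate)
      model$backbone$state <- fwd$state$backbone
      if (!is.null(fwd$state$lfa)) model$state$lfa <- fwd$state$lfa
      loss <- multilabel_loss(yb, fwd$logits)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at stage %d iteration %d ",
                     st, it),
             "(non-finite loss); lower the learning rate", call. = FALSE)
      }
      dlogits <- multilabel_loss_grad(yb, fwd$logits)
      grads <- farnet_batch_backward(model, fwd$cache, dlogits)
      for (m in trainable) {
        gmod <- grads[[m]]
        if (is.null(gmod)) next
        pars <- module_params(model, m)
        gpaths <- flatten_params(gmod)
        for (nm in names(paths[[m]])) {
          p <- paths[[m]][[nm]]
          g <- get_param(gmod, p)
          if (is.null(g)) next
          w <- get_param(pars, p)
          v <- vel[[m]][[nm]]
          v <- config$momentum * v - lr * (g + config$weight_decay * w)
          vel[[m]][[nm]] <- v
          pars <- set_param(pars, p, w + v)
        }
        model <- set_module_params(model, m, pars)
      }
      history[[length(history) + 1]] <-
        data.frame(stage = st, iter = it, lr = lr, loss = loss)
      if (config$select_best && length(val_rows) &&
          (it %% eval_every == 0 || it == n_iter)) {
        vmap <- validation_map(model, data, val_rows, ymat, fwd_ablate)
        vallog[[length(vallog) + 1]] <-
          data.frame(stage = st, iter = it, map = vmap)
        if (vmap >= best$map) {
          best <- list(map = vmap,
                       params = lapply(stats::setNames(trainable, trainable),
                                       function(m) module_params(model, m)))
        }
      }
    }
    if (config$select_best && !is.null(best$params)) {
      for (m in trainable) {
        model <- set_module_params(model, m, best$params[[m]])
      }
    }
    if (verbose) {
      message(sprintf("stage %d done: final loss %.4f", st, loss))
    }
  }
  list(model = model,
       history = do.call(rbind, history),
       val = if (length(vallog)) do.call(rbind, vallog) else NULL)
}

validation_map <- function(model, data, rows, ymat, ablate,
                           batch_size = 64) {
  conf <- predict_scores(model, data$images, rows, ablate, batch_size)
  aps <- vapply(seq_len(ncol(ymat)), function(l) {
    yt <- ymat[rows, l]
    if (sum(yt) == 0) return(NA_real_)
    average_precision(conf[, l], yt)
  }, numeric(1))
  mean(aps, na.rm = TRUE)
}

predict_scores <- function(model, images, rows, ablate, batch_size = 64) {
  conf <- matrix(0, length(rows), length(model$labels))
  for (start in seq(1, length(rows), by = batch_size)) {
    pos <- start:min(start + batch_size - 1, length(rows))
    xb <- images[, , , rows[pos], drop = FALSE]
    fwd <- farnet_batch_forward(model, xb * 2 - 1, training = FALSE,
                                cache_needed = FALSE, ablate = ablate)
    conf[pos, ] <- fwd$confidence
  }
  colnames(conf) <- model$labels
  conf
}

#' Predict label confidences for an image batch
#'
#' @param model A trained `farnet_model`.
#' @param images H x W x 3 (x N) array, pixels in `[0, 1]`.
#' @param batch_size Images per forward pass.
#' @return List with `confidence` (N x C), `logits` (N x C) and `attention`
#'   (C x C x N mean relation weights, `NULL` when ARL is ablated).
#' @export
predict_farnet <- function(model, images, batch_size = 64) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  C <- length(model$labels)
  conf <- matrix(0, n, C); logit <- matrix(0, n, C)
  att <- if (!"arl" %in% model$ablate) array(0, c(C, C, n))
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, n)
    fwd <- farnet_batch_forward(model,
                                images[, , , sel, drop = FALSE] * 2 - 1,
                                training = FALSE, cache_needed = FALSE)
    conf[sel, ] <- fwd$confidence
    logit[sel, ] <- fwd$logits
    if (!is.null(att) && !is.null(fwd$att)) att[, , sel] <- fwd$att
  }
  colnames(conf) <- model$labels; colnames(logit) <- model$labels
  list(confidence = conf, logits = logit, attention = att)
}

#' Save / load model checkpoints
#'
#' Checkpoints store the parameter and BN-state lists keyed by module name.
#'
#' @param model A `farnet_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(labels = model$labels,
               backbone_config = model$backbone$config,
               backbone = list(params = model$backbone$params,
                               state = model$backbone$state),
               params = model$params, state = model$state,
               dk = model$dk, scale = model$scale,
               per_label_params = model$per_label_params,
               ablate = model$ablate), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_farnet(labels = ck$labels,
                        backbone = ck$backbone_config,
                        dk = ck$dk, scale = ck$scale,
                        per_label_params = ck$per_label_params,
                        ablate = ck$ablate)
  model$backbone$params <- ck$backbone$params
  model$backbone$state <- ck$backbone$state
  model$params <- ck$params
  model$state <- ck$state
  model
}
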
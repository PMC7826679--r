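# Shared fixtures and independent oracles, built in code at test time.

# A small model on 16x16 inputs with a 4x4x12 feature grid and 3 labels.
tiny_model <- function(labels = c("a", "b", "c"), seed = 3, ...) {
  bb <- build_backbone(backbone_config("tiny", input_size = 16,
                                       out_spatial = c(4, 4),
                                       out_channels = 12), seed = seed)
  build_farnet(labels = labels, backbone = bb, dk = 5, seed = seed, ...)
}

random_image_batch <- function(n, size = 16, seed = 1) {
  with_seed_test(seed, array(stats::runif(size * size * 3 * n),
                             c(size, size, 3, n)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

# A small dataset spec covering all eight labels with a handful of samples.
mini_spec <- function(per = 5L, image_size = 16, seed = 9) {
  spec <- make_default_spec(image_size = image_size, seed = seed)
  per <- as.integer(per)
  spec$combos <- lapply(jujube_labels(), function(l) {
    list(labels = l, count = per)
  })
  spec$combos <- c(spec$combos,
                   list(list(labels = c("r", "p"), count = per),
                        list(labels = c("mr", "c"), count = per)))
  spec
}

# Index replicating the census without rendering any image.
census_index <- function(spec = make_default_spec()) {
  labels <- spec$labels
  rows <- do.call(rbind, lapply(spec$combos, function(co) {
    y <- as.integer(labels %in% co$labels)
    matrix(y, co$count, length(labels), byrow = TRUE)
  }))
  colnames(rows) <- labels
  idx <- data.frame(id = sprintf("s%04d", seq_len(nrow(rows))), rows,
                    split = NA_character_, check.names = FALSE)
  attr(idx, "labels") <- labels
  class(idx) <- c("farnet_index", "data.frame")
  idx
}

# Brute-force ARL oracle: three nested loops, scalar arithmetic only.
arl_brute_force <- function(fA, WQ, WK, WV, dk, scale = "sqrt_dk") {
  d <- dim(fA)
  C <- d[3]; hw <- d[1] * d[2]
  sc <- if (scale == "sqrt_dk") sqrt(dk) else dk
  chan <- function(l) as.vector(fA[, , l])
  wS <- matrix(0, C, C)
  for (l in seq_len(C)) {
    for (m in seq_len(C)) {
      if (m == l) next
      q <- numeric(ncol(WQ)); k <- numeric(ncol(WK))
      for (j in seq_len(ncol(WQ))) {
        for (i in seq_len(hw)) {
          q[j] <- q[j] + chan(l)[i] * WQ[i, j]
          k[j] <- k[j] + chan(m)[i] * WK[i, j]
        }
      }
      wS[m, l] <- sum(k * q) / sc
    }
  }
  w <- matrix(0, C, C)
  for (l in seq_len(C)) {
    others <- setdiff(seq_len(C), l)
    den <- sum(exp(wS[others, l]))
    for (m in others) w[m, l] <- exp(wS[m, l]) / den
  }
  fR <- array(0, d)
  for (l in seq_len(C)) {
    acc <- numeric(hw)
    for (m in setdiff(seq_len(C), l)) {
      vm <- as.vector(chan(m) %*% WV)
      acc <- acc + w[m, l] * vm
    }
    fR[, , l] <- matrix(acc, d[1], d[2])
  }
  list(wS = wS, w = w, fR = fR)
}

# O(N^2) ranking oracle for average precision: for each positive, precision
# is counted pairwise against every other sample ranked at or above it.
ap_brute_force <- function(scores, y_true) {
  n <- length(scores)
  ord <- order(-scores)
  prec <- c()
  for (pos_rank in seq_len(n)) {
    i <- ord[pos_rank]
    if (y_true[i] != 1) next
    above_pos <- 0; above <- 0
    for (other_rank in seq_len(pos_rank)) {
      j <- ord[other_rank]
      above <- above + 1
      if (y_true[j] == 1) above_pos <- above_pos + 1
    }
    prec <- c(prec, above_pos / above)
  }
  mean(prec)
}
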
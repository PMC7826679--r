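test_that("LFA conv block maps D channels to C label channels in place", {
  m <- tiny_model()
  X <- with_seed_test(1, array(stats::rnorm(4 * 4 * 12), c(4, 4, 12)))
  S <- lfa_conv(X, m$params$lfa, m$state$lfa)
  expect_equal(dim(S), c(4, 4, 3))
  expect_true(all(is.finite(S)))
  expect_error(lfa_conv(array(0, c(4, 4, 7)), m$params$lfa),
               "channel mismatch")
})

test_that("spatial softmax normalises every channel over the grid", {
  A <- spatial_softmax(array(3, c(8, 8, 2)))
  expect_equal(A, array(1 / 64, c(8, 8, 2)))
  S <- array(c(0, 0, log(2), 0), c(2, 2, 1))  # [[0, ln2], [0, 0]] row-wise
  A2 <- spatial_softmax(S)
  expect_equal(A2[, , 1], matrix(c(0.2, 0.2, 0.4, 0.2), 2, 2))
  # shift invariance and unit-sum invariant over random instances
  for (k in 1:100) {
    S3 <- with_seed_test(k, array(stats::rnorm(4 * 4 * 5), c(4, 4, 5)))
    A3 <- spatial_softmax(S3)
    expect_equal(apply(A3, 3, sum), rep(1, 5), tolerance = 1e-6)
    expect_true(all(A3 >= 0))
    expect_equal(spatial_softmax(S3 + 2.5), A3, tolerance = 1e-12)
  }
  expect_error(spatial_softmax(array(c(1, NA), c(1, 2, 1))), "non-finite")
})

test_that("squeeze is the per-channel spatial mean", {
  expect_equal(se_squeeze(array(1, c(8, 8, 2))), c(1, 1))
  ch <- array(0, c(8, 8, 1)); ch[3, 5, 1] <- 64
  expect_equal(se_squeeze(ch), 1)
  A <- spatial_softmax(with_seed_test(2, array(stats::rnorm(64 * 3),
                                               c(8, 8, 3))))
  expect_equal(se_squeeze(A), rep(1 / 64, 3), tolerance = 1e-12)
})

test_that("excitation gates live strictly inside (0, 1)", {
  zero_pars <- list(W1 = matrix(0, 3, 3), b1 = numeric(3),
                    W2 = matrix(0, 3, 3), b2 = numeric(3))
  expect_equal(se_excite(c(0, 0, 0), zero_pars), rep(0.5, 3))
  expect_equal(se_excite(c(5, -2, 1), zero_pars), rep(0.5, 3))
  m <- tiny_model()
  for (k in 1:20) {
    s <- se_excite(with_seed_test(k, stats::rnorm(3, sd = 5)),
                   m$params$ada)
    expect_true(all(s > 0 & s < 1))
  }
  expect_error(se_excite(c(1, 2), m$params$ada), "length 2")
})

test_that("reweighting scales each channel by its gate", {
  A <- array(2, c(1, 1, 3))
  expect_equal(se_reweight(A, c(1, 1, 1)), A)
  expect_equal(se_reweight(A, c(0, 0, 0)), array(0, c(1, 1, 3)))
  expect_equal(se_reweight(A, c(0.25, 0.5, 1))[1, 1, ], c(0.5, 1, 2))
  expect_error(se_reweight(A, c(1, 1)), "gate length 2")
})

test_that("relation scores follow the scaled dot product", {
  # identical channels with shared maps -> constant off-diagonal scores
  fA <- array(rep(1:4, 3), c(2, 2, 3))
  I4 <- diag(4)
  pars <- list(WQ = I4, WK = I4, WV = I4)
  wS <- relation_scores(fA, pars, dk = 1)
  off <- wS[row(wS) != col(wS)]
  expect_true(all(abs(off - off[1]) < 1e-12))
  # orthogonal channels under identity maps -> zero score
  fA2 <- array(0, c(1, 2, 2))
  fA2[1, , 1] <- c(1, 0); fA2[1, , 2] <- c(0, 2)
  pars2 <- list(WQ = diag(2), WK = diag(2), WV = diag(2))
  wS2 <- relation_scores(fA2, pars2, dk = 1, scale = "sqrt_dk")
  expect_equal(wS2[2, 1], 0)
  expect_equal(wS2[1, 2], 0)
  # dk scaling conventions
  fA3 <- array(stats::rnorm(2 * 2 * 2), c(2, 2, 2))
  p3 <- list(WQ = diag(4), WK = diag(4), WV = diag(4))
  expect_equal(relation_scores(fA3, p3, dk = 4, scale = "dk"),
               relation_scores(fA3, p3, dk = 4, scale = "sqrt_dk") / 2)
  expect_error(relation_scores(fA3, p3, dk = 0), "positive")
})

test_that("relation weights are a masked per-query softmax", {
  wS <- matrix(1.7, 4, 4)
  w <- relation_weights(wS)
  expect_equal(w[row(w) != col(w)], rep(1 / 3, 12))
  expect_equal(diag(w), rep(0, 4))
  w2 <- relation_weights(matrix(c(0, 3, -2, 0), 2, 2))
  expect_equal(w2, matrix(c(0, 1, 1, 0), 2, 2))
  wS3 <- matrix(0, 3, 3); wS3[2, 1] <- log(2); wS3[3, 1] <- 0
  w3 <- relation_weights(wS3)
  expect_equal(w3[2, 1], 2 / 3)
  expect_equal(w3[3, 1], 1 / 3)
  for (k in 1:100) {
    wSk <- with_seed_test(200 + k,
                          matrix(stats::rnorm(36, sd = 2), 6, 6))
    wk <- relation_weights(wSk)
    expect_equal(colSums(wk), rep(1, 6), tolerance = 1e-6)
    expect_true(all(wk >= 0))
  }
  expect_error(relation_weights(matrix(0, 1, 1)), "at least 2")
})

test_that("relation features are the weighted transformed channels", {
  # C = 2, identity W_V: fR_1 is exactly fA_2
  fA <- with_seed_test(5, array(stats::rnorm(2 * 2 * 2), c(2, 2, 2)))
  pars <- list(WQ = diag(4), WK = diag(4), WV = diag(4))
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  fR <- relation_features(fA, w, pars)
  expect_equal(fR[, , 1], fA[, , 2])
  expect_equal(fR[, , 2], fA[, , 1])
  # weighted sum by hand
  fA3 <- array(0, c(2, 2, 3))
  fA3[, , 2] <- 3; fA3[, , 3] <- 0
  w3 <- matrix(0, 3, 3); w3[2, 1] <- 2 / 3; w3[3, 1] <- 1 / 3
  fR3 <- relation_features(fA3, w3, pars)
  expect_equal(fR3[, , 1], matrix(2, 2, 2))
  expect_equal(relation_features(array(0, c(2, 2, 3)), w3, pars),
               array(0, c(2, 2, 3)))
})

test_that("vectorised ARL equals the triple-loop brute force", {
  for (k in 1:8) {
    C <- sample(2:8, 1)
    side <- sample(2:4, 1)
    dk <- sample(2:6, 1)
    hw <- side^2
    dat <- with_seed_test(300 + k, list(
      fA = array(stats::rnorm(hw * C), c(side, side, C)),
      WQ = matrix(stats::rnorm(hw * dk), hw, dk),
      WK = matrix(stats::rnorm(hw * dk), hw, dk),
      WV = matrix(stats::rnorm(hw * hw), hw, hw)
    ))
    pars <- list(WQ = dat$WQ, WK = dat$WK, WV = dat$WV)
    oracle <- arl_brute_force(dat$fA, dat$WQ, dat$WK, dat$WV, dk)
    wS <- relation_scores(dat$fA, pars, dk = dk)
    w <- relation_weights(wS)
    fR <- relation_features(dat$fA, w, pars)
    expect_equal(wS[row(wS) != col(wS)],
                 oracle$wS[row(oracle$wS) != col(oracle$wS)],
                 tolerance = 1e-6)
    expect_equal(w, oracle$w, tolerance = 1e-6)
    expect_equal(fR, oracle$fR, tolerance = 1e-6)
  }
})

test_that("per-label relation parameters reduce to shared ones when equal", {
  side <- 3; C <- 4; dk <- 5; hw <- side^2
  dat <- with_seed_test(77, list(
    fA = array(stats::rnorm(hw * C), c(side, side, C)),
    WQ = matrix(stats::rnorm(hw * dk), hw, dk),
    WK = matrix(stats::rnorm(hw * dk), hw, dk),
    WV = matrix(stats::rnorm(hw * hw), hw, hw)
  ))
  shared <- list(WQ = dat$WQ, WK = dat$WK, WV = dat$WV)
  per <- list(per_label = rep(list(shared), C))
  wS_s <- relation_scores(dat$fA, shared, dk = dk)
  wS_p <- relation_scores(dat$fA, per, dk = dk)
  expect_equal(wS_s, wS_p, tolerance = 1e-10)
  w <- relation_weights(wS_s)
  expect_equal(relation_features(dat$fA, w, shared),
               relation_features(dat$fA, w, per), tolerance = 1e-10)
})

test_that("fusion adds features elementwise and symmetrically", {
  a <- array(1, c(2, 2, 2)); b <- array(2, c(2, 2, 2))
  expect_equal(fuse(a, b), array(3, c(2, 2, 2)))
  expect_equal(fuse(a, array(0, dim(a))), a)
  r <- with_seed_test(1, array(stats::rnorm(8), c(2, 2, 2)))
  expect_equal(fuse(a, r), fuse(r, a))
  expect_error(fuse(a, array(0, c(2, 2, 3))), "shape mismatch")
})

test_that("the prediction head pools then squashes", {
  expect_equal(predict_head(array(0, c(8, 8, 1)))$confidence, 0.5)
  expect_equal(predict_head(array(1.3, c(4, 4, 2)))$confidence,
               rep(1 / (1 + exp(-1.3)), 2))
  ch <- array(0, c(8, 8, 1)); ch[2, 7, 1] <- 64
  out <- predict_head(ch)
  expect_equal(out$logits, 1)
  expect_equal(out$confidence, 1 / (1 + exp(-1)), tolerance = 1e-4)
})

test_that("forward composition matches the single-image operations", {
  m <- tiny_model()
  img <- random_image_batch(1, size = 16, seed = 21)
  # manual composition with ARL bypassed
  X1 <- extract_features(m$backbone, img)[, , , 1]
  S <- lfa_conv(X1, m$params$lfa, m$state$lfa)
  A <- spatial_softmax(S)
  s <- se_excite(se_squeeze(A), m$params$ada)
  At <- se_reweight(A, s)
  manual <- predict_head(At)
  fwd <- farnet_forward(m, img, ablate = "arl")
  expect_equal(as.vector(fwd$logits), manual$logits, tolerance = 1e-10)
  expect_null(fwd$attention)
  # full model: fusion adds the relation features on top
  wS <- relation_scores(At, m$params$arl, dk = m$dk, scale = m$scale)
  fR <- relation_features(At, relation_weights(wS), m$params$arl)
  full_manual <- predict_head(fuse(At, fR))
  full <- farnet_forward(m, img)
  expect_equal(as.vector(full$logits), full_manual$logits,
               tolerance = 1e-10)
  expect_equal(full$attention[, , 1], relation_weights(wS),
               tolerance = 1e-10)
})

test_that("forward pass is deterministic with bounded confidences", {
  m <- tiny_model()
  x <- random_image_batch(3, size = 16, seed = 8)
  f1 <- farnet_forward(m, x)
  f2 <- farnet_forward(m, x)
  expect_identical(f1$confidence, f2$confidence)
  expect_true(all(f1$confidence >= 0 & f1$confidence <= 1))
})

test_that("ablation flags compose and invalid combinations error", {
  x <- random_image_batch(2, size = 16, seed = 4)
  m_base <- tiny_model(ablate = c("lfa", "ada", "arl"))
  f <- farnet_forward(m_base, x)
  expect_equal(dim(f$confidence), c(2, 3))
  expect_null(f$attention)
  expect_error(tiny_model(ablate = "lfa"), "ARL|ADA")
  expect_error(tiny_model(ablate = c("lfa", "arl")), "ADA")
  expect_error(tiny_model(ablate = "bogus"), "unknown ablation")
  # without_ada: gate bypassed means At == A
  m_noada <- tiny_model(ablate = "ada")
  img <- x[, , , 1]
  X1 <- extract_features(m_noada$backbone, img)[, , , 1]
  A <- spatial_softmax(lfa_conv(X1, m_noada$params$lfa,
                                m_noada$state$lfa))
  wS <- relation_scores(A, m_noada$params$arl, dk = m_noada$dk)
  fR <- relation_features(A, relation_weights(wS), m_noada$params$arl)
  manual <- predict_head(fuse(A, fR))
  expect_equal(as.vector(farnet_forward(m_noada, img)$logits),
               manual$logits, tolerance = 1e-10)
})

test_that("label permutation equivariance holds end to end", {
  m <- tiny_model(labels = c("a", "b", "c"))
  perm <- c(3, 1, 2)
  mp <- m
  mp$labels <- m$labels[perm]
  # permute LFA last-layer filters and their BN parameters
  mp$params$lfa$conv3$W <- m$params$lfa$conv3$W[, perm]
  mp$params$lfa$conv3$b <- m$params$lfa$conv3$b[perm]
  mp$params$lfa$conv3$gamma <- m$params$lfa$conv3$gamma[perm]
  mp$params$lfa$conv3$beta <- m$params$lfa$conv3$beta[perm]
  mp$state$lfa$conv3$mean <- m$state$lfa$conv3$mean[perm]
  mp$state$lfa$conv3$var <- m$state$lfa$conv3$var[perm]
  # permute SE rows/cols (maps act as crossprod(W, z))
  mp$params$ada$W1 <- m$params$ada$W1[perm, perm]
  mp$params$ada$b1 <- m$params$ada$b1[perm]
  mp$params$ada$W2 <- m$params$ada$W2[perm, perm]
  mp$params$ada$b2 <- m$params$ada$b2[perm]
  x <- random_image_batch(2, size = 16, seed = 31)
  f <- farnet_forward(m, x)
  fp <- farnet_forward(mp, x)
  expect_equal(fp$confidence, f$confidence[, perm], ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("closing the gate drives a channel toward its relation features", {
  m <- tiny_model()
  x <- random_image_batch(1, size = 16, seed = 13)
  X1 <- extract_features(m$backbone, x)[, , , 1]
  A <- spatial_softmax(lfa_conv(X1, m$params$lfa, m$state$lfa))
  pooled_with_gate <- function(g) {
    At <- se_reweight(A, g)
    wS <- relation_scores(At, m$params$arl, dk = m$dk)
    fR <- relation_features(At, relation_weights(wS), m$params$arl)
    predict_head(fuse(At, fR))$logits
  }
  gates <- c(1, 0.5, 0.1, 0)
  logits1 <- vapply(gates, function(g) pooled_with_gate(c(g, 1, 1))[1],
                    numeric(1))
  # as s_1 -> 0 the direct (gated) contribution vanishes; the limit is the
  # pooled relation-only feature
  At0 <- se_reweight(A, c(0, 1, 1))
  wS0 <- relation_scores(At0, m$params$arl, dk = m$dk)
  fR0 <- relation_features(At0, relation_weights(wS0), m$params$arl)
  limit <- predict_head(fR0)$logits[1]
  expect_equal(logits1[4], limit, tolerance = 1e-12)
  expect_lt(abs(logits1[3] - limit), abs(logits1[1] - limit))
})
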
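# Toy ViT components and the pufferfish patch-size optimizer.

test_that("patchify is an exact partition with a bit-exact inverse", {
  img <- matrix(sample(0:255, 224 * 224, replace = TRUE), 224)
  p <- patchify(img, 16)
  expect_equal(nrow(p), 196L)
  expect_identical(assemble_patches(p, 224, 224, 16), img * 1)

  one <- patchify(img, 224)
  expect_equal(nrow(one), 1L)
  expect_identical(matrix(one[1, ], 224), img * 1)
  expect_error(patchify(img, 15), "15")

  for (P in c(4, 8, 16, 32)) {
    small <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32)
    expect_identical(assemble_patches(patchify(small, P), 32, 32, P),
                     small * 1)
  }
})

test_that("projection standardizes per vector with the documented
           degenerate rule", {
  set.seed(21)
  patches <- matrix(runif(10 * 16, 0, 255), 10)
  W <- matrix(rnorm(16 * 8), 16)
  z <- project_and_norm(patches, W)
  expect_true(all(abs(rowMeans(z)) < 1e-6))
  expect_true(all(abs(sqrt(rowMeans(z^2)) - 1) < 1e-6))
  expect_true(all(project_and_norm(patches, W * 0) == 0))
  # hand-standardized single 2x2 patch through an identity-like map
  p1 <- matrix(c(10, 20, 30, 100), 1)
  z1 <- project_and_norm(p1, diag(4))
  hand <- (c(10, 20, 30, 100) - 40) / sqrt(mean((c(10, 20, 30, 100) - 40)^2))
  expect_equal(as.numeric(z1), hand, tolerance = 1e-6)
  expect_error(project_and_norm(patches, matrix(0, 4, 8)), "shape")
})

test_that("CLS and positional embeddings compose additively", {
  seq0 <- matrix(1:12, 3, 4)
  cls <- rep(0.5, 4)
  pos0 <- matrix(0, 4, 4)
  out <- add_cls_and_positions(seq0, cls, pos0)
  expect_equal(nrow(out), 4L)
  expect_equal(out[1, ], cls)
  expect_equal(out[-1, ], seq0 * 1)
  pos <- matrix(rnorm(16), 4, 4)
  expect_equal(add_cls_and_positions(seq0, cls, pos),
               rbind(cls, seq0) + pos, ignore_attr = TRUE)
  expect_error(add_cls_and_positions(seq0, cls, matrix(0, 3, 4)), "rows")
})

test_that("self-attention is row-stochastic and matches hand arithmetic on
           a two-token toy", {
  set.seed(22)
  D <- 8
  pars <- list(Wq = matrix(rnorm(D * D, 0, 0.3), D),
               Wk = matrix(rnorm(D * D, 0, 0.3), D),
               Wv = matrix(rnorm(D * D, 0, 0.3), D),
               Wo = diag(D), W1 = matrix(0, D, 2 * D),
               W2 = matrix(0, 2 * D, D))
  x <- matrix(rnorm(5 * D), 5, D)
  out <- multi_head_self_attention(x, pars, n_heads = 2L)
  for (A in attr(out, "attention"))
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-9)

  # single token: attention output equals its value projection
  x1 <- matrix(rnorm(D), 1, D)
  out1 <- multi_head_self_attention(x1, pars, n_heads = 1L)
  expect_equal(as.numeric(out1), as.numeric(x1 + x1 %*% pars$Wv),
               tolerance = 1e-12)

  # 2-token, D=2, 1 head, zeroed MLP and identity output projection:
  # out - x must equal softmax(QK'/sqrt(2)) V
  p2 <- list(Wq = matrix(c(1, 0, 0, 1), 2), Wk = matrix(c(0, 1, 1, 0), 2),
             Wv = matrix(c(1, 2, 3, 4), 2), Wo = diag(2),
             W1 = matrix(0, 2, 4), W2 = matrix(0, 4, 2))
  x2 <- matrix(c(1, -1, 0.5, 2), 2, 2)
  out2 <- multi_head_self_attention(x2, p2, n_heads = 1L)
  Q <- x2 %*% p2$Wq; K <- x2 %*% p2$Wk; V <- x2 %*% p2$Wv
  S <- Q %*% t(K) / sqrt(2)
  A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
  expect_equal(unclass(out2 - x2), A %*% V, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(multi_head_self_attention(matrix(NaN, 2, 2), p2, 1L),
               "finite")
})

test_that("image encoding is seed-deterministic with the stated layout", {
  ph <- fixture_phantom(noise = 8)
  cfg <- patch_config(8L, 32L, 4L, 2L, seed = 3L)
  e1 <- encode_image(ph, cfg)
  e2 <- encode_image(ph, cfg)
  expect_identical(e1$cls, e2$cls)
  expect_identical(e1$patches, e2$patches)
  expect_equal(dim(e1$patches), c(64L, 32L))
  expect_length(e1$cls, 32L)

  # permuting image patches permutes the pre-attention content rows
  img <- as_pixels(ph)
  pt <- patchify(img, 8)
  perm <- sample(nrow(pt))
  img_perm <- assemble_patches(pt[perm, ], 64, 64, 8)
  pars <- init_encoder_params(8L, 32L, 64L, 2L, 3L)
  z_orig <- encode_image(img, cfg)$pre_attention[-1, ] -
    pars$positions[-1, ]
  z_perm <- encode_image(img_perm, cfg)$pre_attention[-1, ] -
    pars$positions[-1, ]
  expect_equal(z_perm, z_orig[perm, ], tolerance = 1e-9)
})

test_that("the pufferfish optimizer matches exhaustive search on small
           discrete spaces", {
  single <- poa_optimize(function(P) P^2, poa_config(candidate_patch_sizes = 7))
  expect_equal(single$best_candidate, 7)

  res <- poa_optimize(function(P) (P - 8)^2,
                      poa_config(c(4, 8, 16, 32), seed = 0L))
  expect_equal(res$best_candidate, 8)
  expect_true(all(diff(res$history) <= 0))

  set.seed(23)
  for (i in 1:10) {
    cands <- sort(sample(c(2, 4, 6, 8, 12, 16, 24, 32, 48, 64), 8))
    target <- sample(cands, 1)
    fit <- function(P) (P - target)^2 + 0.1 * P
    exhaustive <- cands[which.min(vapply(cands, fit, 0))]
    res <- poa_optimize(fit, poa_config(cands, seed = i))
    expect_equal(res$best_candidate, exhaustive)
    expect_true(res$best_candidate %in% cands)
    expect_true(all(diff(res$history) <= 0))
  }
  expect_error(poa_config(numeric(0)), "empty")
})
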
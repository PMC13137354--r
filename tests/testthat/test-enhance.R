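# M-CLAHE components: entropy, clip limits, redistribution, LUTs, bilinear
# blending, gamma, sharpening, and the composed pipeline.

test_that("Shannon entropy hits its closed-form endpoints", {
  expect_equal(shannon_entropy(rep(1, 256)), 8)
  h <- rep(0, 256); h[17] <- 41
  expect_equal(shannon_entropy(h), 0)
  expect_equal(shannon_entropy(c(5, 5)), 1)
  expect_error(shannon_entropy(rep(0, 256)), "all-zero")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("entropy maps affinely onto the clip-limit range", {
  p <- enhance_params()
  expect_equal(entropy_to_clip_limit(0, p, 4096), 1.5 * 4096 / 256)
  expect_equal(entropy_to_clip_limit(8, p, 4096), 4.0 * 4096 / 256)
  expect_equal(entropy_to_clip_limit(4, p, 4096), 44.0)
  e <- seq(0, 8, by = 0.5)
  cl <- vapply(e, entropy_to_clip_limit, 0, params = p,
               tile_pixel_count = 4096)
  expect_true(all(diff(cl) > 0))
})

test_that("clip-and-redistribute conserves mass and caps bins", {
  h <- c(3, 2, 1, 0)
  expect_equal(clip_and_redistribute(h, 10), h)
  out <- clip_and_redistribute(c(10, 0, 0, 0), 4)
  expect_equal(sum(out), 10)
  expect_true(all(out <= 4 + 1))
  # randomized conservation property
  set.seed(42)
  for (i in 1:50) {
    h <- rpois(256, lambda = runif(1, 0.5, 30))
    cl <- runif(1, 1, 40)
    out <- clip_and_redistribute(h, cl)
    expect_equal(sum(out), sum(h), tolerance = 1e-9)
    expect_true(all(out <= cl + 1 + 1e-9) || all(abs(out - out[1]) < cl))
  }
})

test_that("equalization LUTs follow the CDF conventions", {
  expect_equal(cdf_lut(c(1, 1, 1, 1)), c(0L, 1L, 2L, 3L))
  lut <- cdf_lut(rep(4, 256))
  expect_true(all(abs(lut - (0:255)) <= 1))
  delta <- rep(0, 256); delta[1] <- 99
  expect_true(all(cdf_lut(delta) == 255L))
  expect_error(cdf_lut(rep(0, 8)), "positive")
})

test_that("bilinear remap equals the brute-force per-pixel oracle", {
  set.seed(7)
  for (dims in list(c(32, 32), c(64, 64), c(48, 40))) {
    img <- matrix(sample(0:255, prod(dims), replace = TRUE), dims[1])
    for (grid in list(c(2L, 2L), c(4L, 4L))) {
      tiles <- tile_stats(img, enhance_params(tile_grid = grid))
      expect_identical(bilinear_remap(img, tiles),
                       oracle_bilinear(img, tiles))
    }
  }
})

test_that("bilinear remap respects constant-field and identity cases", {
  set.seed(8)
  img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32)
  tiles <- tile_stats(img, enhance_params(tile_grid = c(2L, 2L)))
  shared <- tiles[[1, 1]]$lut
  for (k in seq_along(tiles)) tiles[[k]]$lut <- shared
  expect_identical(bilinear_remap(img, tiles),
                   matrix(shared[img + 1L], 32))
  for (k in seq_along(tiles)) tiles[[k]]$lut <- 0:255
  expect_identical(bilinear_remap(img, tiles), matrix(as.integer(img), 32))
})

test_that("gamma correction is the identity at 1 and fixes the endpoints", {
  set.seed(9)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8)
  expect_identical(gamma_correct(img, 1), matrix(as.integer(img), 8))
  expect_equal(gamma_correct(matrix(c(0L, 255L), 1), 2),
               matrix(c(0L, 255L), 1))
  v <- matrix(round(0.25 * 255), 1)
  expect_equal(gamma_correct(v, 0.5)[1, 1],
               as.integer(round(255 * sqrt(v[1, 1] / 255))))
  expect_error(gamma_correct(img, 3), "range")
})

test_that("unsharp masking sharpens a bright point and leaves constants", {
  img <- matrix(100, 9, 9)
  expect_identical(unsharp_sharpen(img, 2), matrix(100L, 9, 9))
  img[5, 5] <- 200
  out <- unsharp_sharpen(img, 1)
  expect_gt(out[5, 5], 200)
  expect_lt(out[5, 4], 100)
  expect_identical(unsharp_sharpen(img, 0), matrix(as.integer(img), 9))
  # hand-convolved center: in + (in - blur), clamped to the bit depth
  expect_equal(out[5, 5],
               as.integer(min(255, round(200 + (200 - (8 * 100 + 200) / 9)))))
  expect_equal(out[5, 4],
               as.integer(round(100 + (100 - (8 * 100 + 200) / 9))))
})

test_that("the composed M-CLAHE pipeline is deterministic and raises lesion
           contrast on a two-region phantom", {
  flat <- matrix(77L, 32, 32)
  out <- enhance_mclahe(flat, enhance_params(tile_grid = c(2L, 2L)))
  expect_true(all(out$image == out$image[1, 1]))

  ph <- fixture_phantom(noise = 8)
  res <- enhance_mclahe(ph)
  expect_equal(dim(res$tiles), c(8L, 8L))
  ents <- vapply(res$tiles, `[[`, 0, "entropy_bits")
  expect_true(all(ents >= 0 & ents <= 8))
  expect_equal(res$gamma_used, 1.25)
  expect_identical(res$image, enhance_mclahe(ph)$image)

  les <- render_lesion(ph, lesion_spec("ICH", c(32, 32), 8, -60))
  m <- les$lesion_mask
  rms <- function(img) {
    both <- c(img[m], img[ph$brain & !m & !ph$ventricles])
    sd(both / mean(both))
  }
  enh <- enhance_mclahe(les$pixels)$image
  expect_gte(rms(enh), rms(les$pixels))

  adaptive <- enhance_mclahe(ph, enhance_params(
    gamma_mode = "entropy_adaptive"))
  expect_gte(adaptive$gamma_used, 0.5)
  expect_lte(adaptive$gamma_used, 2.5)
})

test_that("method comparison reports three rows and matches the global
           equalization oracle for one-tile unclipped CLAHE", {
  ph <- fixture_phantom(noise = 8)
  tab <- compare_methods(ph)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$method, c("mCLAHE", "CLAHE", "Laplacian"))
  expect_true(all(is.finite(tab$psnr_db)))
  expect_true(all(c("entropy_before", "entropy_after",
                    "rms_contrast_before", "rms_contrast_after",
                    "relative_contrast_change") %in% names(tab)))

  # plain CLAHE, one tile, clip so high nothing clips == global equalization
  img <- ph$pixels
  p1 <- enhance_params(tile_grid = c(1L, 1L), clip_min_rel = 1e6,
                       clip_max_rel = 1e6)
  clahe1 <- bilinear_remap(img, tile_stats(img, p1))
  hist <- tabulate(as.integer(img) + 1L, 256L)
  cdf <- cumsum(hist)
  cdf_min <- cdf[which(hist > 0)[1]]
  lut <- as.integer(round(255 * (cdf - cdf_min) / (sum(hist) - cdf_min)))
  expect_identical(clahe1, matrix(lut[img + 1L], nrow(img)))

  expect_equal(psnr(img, img), Inf)
  expect_equal(ssim(img, img), 1)
})
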
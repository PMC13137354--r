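# Independent oracle implementations used by the tests. These deliberately
# re-derive results by brute force or closed form, without reusing the
# package's code paths.

# Brute-force per-pixel bilinear tile-LUT remap: for each pixel, locate the
# two bracketing tile centers per axis and blend the four LUT outputs.
oracle_bilinear <- function(img, tiles, L = 256L) {
  nr <- dim(tiles)[1]; nc <- dim(tiles)[2]
  rc <- sapply(seq_len(nr), function(i) {
    b <- tiles[[i, 1]]$bounds; (b[1] + b[3]) / 2 })
  cc <- sapply(seq_len(nc), function(j) {
    b <- tiles[[1, j]]$bounds; (b[2] + b[4]) / 2 })
  out <- matrix(0L, nrow(img), ncol(img))
  bracket <- function(x, cent) {
    if (x <= cent[1]) return(c(1L, 1L, 0))
    if (x >= cent[length(cent)]) return(c(length(cent), length(cent), 0))
    hi <- which(cent > x)[1]
    lo <- hi - 1L
    c(lo, hi, (x - cent[lo]) / (cent[hi] - cent[lo]))
  }
  for (r in seq_len(nrow(img))) {
    br <- bracket(r - 1, rc)
    for (c in seq_len(ncol(img))) {
      bc <- bracket(c - 1, cc)
      v <- img[r, c] + 1L
      val <- (1 - br[3]) * (1 - bc[3]) * tiles[[br[1], bc[1]]]$lut[v] +
        (1 - br[3]) * bc[3] * tiles[[br[1], bc[2]]]$lut[v] +
        br[3] * (1 - bc[3]) * tiles[[br[2], bc[1]]]$lut[v] +
        br[3] * bc[3] * tiles[[br[2], bc[2]]]$lut[v]
      out[r, c] <- as.integer(min(max(round(val), 0), L - 1))
    }
  }
  out
}

# All segmentations of `word` into vocab pieces (first piece plain,
# continuations matched against the "##" set), by exhaustive recursion.
oracle_segmentations <- function(word, starts, conts) {
  rec <- function(pos, first) {
    n <- nchar(word)
    if (pos > n) return(list(character(0)))
    pool <- if (first) starts else conts
    res <- list()
    for (len in seq_len(n - pos + 1L)) {
      piece <- substr(word, pos, pos + len - 1L)
      if (piece %in% pool) {
        for (tail in rec(pos + len, FALSE))
          res[[length(res) + 1L]] <-
            c(if (first) piece else paste0("##", piece), tail)
      }
    }
    res
  }
  rec(1L, TRUE)
}

# Mann-Whitney pair-counting AUC (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# Pixel count of a rasterized disc on an H x W grid.
oracle_disc_area <- function(H, W, ctr, radius) {
  n <- 0L
  for (r in seq_len(H)) for (c in seq_len(W))
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= radius^2) n <- n + 1L
  n
}

# Shared small fixture: a deterministic two-region phantom.
fixture_phantom <- function(noise = 0, seed = 11L) {
  generate_phantom(phantom_spec(noise_sigma = noise, seed = seed))
}
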
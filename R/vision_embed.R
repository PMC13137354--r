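# Toy ViT-style image encoder: patchify, shared linear projection with
# per-vector standardization, CLS + learnable positions, multi-head
# self-attention encoder blocks. All parameters are seeded Gaussians
# (sd 0.02): a weightless, deterministic feature map.

#' Patch/encoder configuration
#'
#' @param patch_size Patch side P in pixels; must divide both image sides.
#' @param embed_dim Embedding dimension D (divisible by `n_heads`).
#' @param n_heads Attention heads per layer.
#' @param n_layers Encoder blocks.
#' @param seed Parameter-initialization seed.
#' @return A `patch_config` object.
#' @export
patch_config <- function(patch_size = 8L, embed_dim = 32L, n_heads = 4L,
                         n_layers = 2L, seed = 0L) {
  if (embed_dim %% n_heads != 0L)
    stop("embed_dim must be divisible by n_heads")
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), seed = as.integer(seed)),
            class = "patch_config")
}

#' Split an image into non-overlapping P x P patches
#'
#' Row-major order; [assemble_patches()] inverts the operation bit-exactly.
#'
#' @param image Intensity matrix (or phantom); both sides divisible by `P`.
#' @param P Patch side in pixels.
#' @return Matrix with `N = (H/P)*(W/P)` rows, each a flattened
#'   (column-major within patch) P^2 vector.
#' @export
patchify <- function(image, P) {
  img <- as_pixels(image)
  H <- nrow(img); W <- ncol(img)
  if (H %% P != 0L || W %% P != 0L)
    stop(sprintf("patch size %d does not divide image dims %dx%d", P, H, W))
  nr <- H %/% P; nc <- W %/% P
  out <- matrix(0, nr * nc, P * P)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- k + 1L
    out[k, ] <- as.numeric(img[((i - 1L) * P + 1L):(i * P),
                               ((j - 1L) * P + 1L):(j * P)])
  }
  out
}

#' Reassemble patches into an image
#' @param patches Matrix from [patchify()].
#' @param H,W Original image dimensions.
#' @param P Patch side.
#' @return The reconstructed matrix.
#' @export
assemble_patches <- function(patches, H, W, P) {
  nr <- H %/% P; nc <- W %/% P
  img <- matrix(0, H, W)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- k + 1L
    img[((i - 1L) * P + 1L):(i * P), ((j - 1L) * P + 1L):(j * P)] <-
      matrix(patches[k, ], P, P)
  }
  img
}

#' Project flattened patches and standardize per vector
#'
#' Shared linear map (P^2 x D), then each projected vector is standardized
#' to mean 0 / sd 1 (epsilon 1e-8; an all-constant vector maps to zeros).
#'
#' @param patches Matrix (N x P^2) from [patchify()].
#' @param weights Projection matrix (P^2 x D).
#' @return N x D matrix of standardized embeddings.
#' @export
project_and_norm <- function(patches, weights) {
  if (ncol(patches) != nrow(weights))
    stop(sprintf("weight shape (%d x %d) does not match patch length %d",
                 nrow(weights), ncol(weights), ncol(patches)))
  z <- patches %*% weights
  mu <- rowMeans(z)
  sdv <- sqrt(rowMeans((z - mu)^2))
  out <- (z - mu) / (sdv + 1e-8)
  out[sdv == 0, ] <- 0
  out
}

#' Prepend the CLS token and add positional embeddings
#'
#' @param seq N x D matrix of patch embeddings.
#' @param cls_vector Length-D CLS vector.
#' @param position_table (N+1) x D positional table (CLS row first).
#' @return (N+1) x D matrix.
#' @export
add_cls_and_positions <- function(seq, cls_vector, position_table) {
  out <- rbind(matrix(cls_vector, 1L), seq)
  if (nrow(position_table) != nrow(out))
    stop(sprintf("position table has %d rows; need %d",
                 nrow(position_table), nrow(out)))
  out + position_table
}

.softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

#' One multi-head self-attention encoder block
#'
#' Per-head scaled dot-product attention with row-stochastic weights, heads
#' concatenated and output-projected, with residual connections and a
#' two-layer MLP: `y = x + MHSA(x); z = y + MLP(y)`. The per-head attention
#' matrices are attached as attribute `"attention"`.
#'
#' @param seq T x D input sequence.
#' @param params Block parameters (`Wq`, `Wk`, `Wv`, `Wo` D x D; `W1`,
#'   `W2` the MLP), e.g. from [init_encoder_params()].
#' @param n_heads Number of heads (D divisible by it).
#' @return T x D output sequence.
#' @export
multi_head_self_attention <- function(seq, params, n_heads = 4L) {
  if (any(!is.finite(seq))) stop("non-finite values in attention input")
  D <- ncol(seq)
  if (D %% n_heads != 0L) stop("embed dim must be divisible by n_heads")
  dh <- D %/% n_heads
  Q <- seq %*% params$Wq; K <- seq %*% params$Wk; V <- seq %*% params$Wv
  heads <- vector("list", n_heads)
  attn <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- .softmax_rows(Q[, idx, drop = FALSE] %*%
                         t(K[, idx, drop = FALSE]) / sqrt(dh))
    attn[[h]] <- A
    heads[[h]] <- A %*% V[, idx, drop = FALSE]
  }
  y <- seq + do.call(cbind, heads) %*% params$Wo
  z <- y + pmax(y %*% params$W1, 0) %*% params$W2
  attr(z, "attention") <- attn
  z
}

#' Seeded encoder parameters
#'
#' @param P Patch side.
#' @param D Embedding dimension.
#' @param n_patches Number of patches N (positions table gets N+1 rows).
#' @param n_layers Encoder blocks.
#' @param seed Integer seed; all weights Gaussian sd 0.02.
#' @return List with `Wproj`, `cls`, `positions` and per-layer block
#'   parameters.
#' @export
init_encoder_params <- function(P, D, n_patches, n_layers, seed) {
  with_seed(substream_seed(seed, "vision-params"), {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    list(Wproj = g(P * P, D), cls = stats::rnorm(D, 0, 0.02),
         positions = g(n_patches + 1L, D),
         layers = lapply(seq_len(n_layers), function(l)
           list(Wq = g(D, D), Wk = g(D, D), Wv = g(D, D), Wo = g(D, D),
                W1 = g(D, 2L * D), W2 = g(2L * D, D))))
  })
}

#' Encode an image into CLS and patch embeddings
#'
#' Deterministic for a fixed config seed: patchify, project + standardize,
#' CLS + positions, then `n_layers` self-attention blocks.
#'
#' @param image Intensity matrix (or phantom).
#' @param config A [patch_config()].
#' @return List with `cls` (length-D vector), `patches` (N x D matrix) and
#'   the layer-0 sequence `pre_attention`.
#' @export
encode_image <- function(image, config = patch_config()) {
  img <- as_pixels(image)
  P <- config$patch_size
  pt <- patchify(img, P)
  pars <- init_encoder_params(P, config$embed_dim, nrow(pt),
                              config$n_layers, config$seed)
  z <- project_and_norm(pt, pars$Wproj)
  z <- add_cls_and_positions(z, pars$cls, pars$positions)
  z0 <- z
  for (l in pars$layers)
    z <- multi_head_self_attention(z, l, config$n_heads)
  list(cls = z[1, ], patches = z[-1, , drop = FALSE], pre_attention = z0)
}
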
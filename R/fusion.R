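# Multimodal fusion and toy-scale classification. Three strategies:
#   early  concatenate pooled raw patch pixels and pooled token embeddings
#          before any encoder
#   late   train per-modality classifiers and average their class
#          probabilities (its component heads double as the single-modality
#          baselines)
#   joint  cross-attention between the encoded text sequence (queries) and
#          the encoded image patches (keys/values); the fused vector
#          concatenates the pooled attended values with the pooled
#          projected queries, so it provably carries both modalities.
# Heads are single-hidden-layer perceptrons trained by full-batch gradient
# descent; everything is deterministic under a fixed seed.

#' Fusion / training configuration
#'
#' @param strategy `"early"`, `"late"` or `"joint"`.
#' @param hidden_dim Cross-attention projection width.
#' @param head_hidden MLP-head hidden width.
#' @param n_classes_subtype Subtype classes (default 5).
#' @param learning_rate,n_epochs,weight_decay Full-batch gradient-descent
#'   schedule and L2 penalty for the heads.
#' @param max_text_tokens WordPiece tokens kept per case.
#' @param seed Run seed (drives encoder init and head init).
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(strategy = c("joint", "early", "late"),
                          hidden_dim = 32L, head_hidden = 64L,
                          n_classes_subtype = 5L,
                          learning_rate = 0.3, n_epochs = 500L,
                          weight_decay = 1e-3,
                          max_text_tokens = 128L, seed = 0L) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy, hidden_dim = as.integer(hidden_dim),
                 head_hidden = as.integer(head_hidden),
                 n_classes_subtype = as.integer(n_classes_subtype),
                 sentiment_classes = 4L,
                 learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 weight_decay = weight_decay,
                 max_text_tokens = as.integer(max_text_tokens),
                 seed = as.integer(seed)), class = "fusion_config")
}

#' Cross-attention between a text and an image sequence
#'
#' Queries come from the text vectors, keys and values from the image patch
#' vectors; scaled dot-product attention with row-stochastic weights. The
#' fused representation concatenates the attended outputs pooled over text
#' positions with the pooled projected queries.
#'
#' @param text_seq T x Dt matrix.
#' @param image_seq N x Di matrix.
#' @param params List with projections `Wq` (Dt x H), `Wk`, `Wv`
#'   (Di x H), e.g. from [init_cross_attention_params()].
#' @return List: `vector` (length 2H fused representation), `attended`
#'   (pooled attended values, length H), `query_pooled` (length H) and the
#'   `attention` matrix (T x N, rows sum to 1).
#' @export
cross_attention <- function(text_seq, image_seq, params) {
  if (nrow(text_seq) == 0L || nrow(image_seq) == 0L)
    stop("cross_attention: empty sequence")
  if (ncol(text_seq) != nrow(params$Wq) || ncol(image_seq) != nrow(params$Wk))
    stop("cross_attention: projection dimensions do not match inputs")
  H <- ncol(params$Wq)
  Q <- text_seq %*% params$Wq
  K <- image_seq %*% params$Wk
  V <- image_seq %*% params$Wv
  A <- .softmax_rows(Q %*% t(K) / sqrt(H))
  attended <- colMeans(A %*% V)
  qp <- colMeans(Q)
  list(vector = c(attended, qp), attended = attended, query_pooled = qp,
       attention = A)
}

#' Seeded cross-attention projections
#' @param d_text,d_image Input dims; `hidden` projection width; `seed`.
#' @param hidden Projection width H.
#' @param seed Integer seed.
#' @return List `Wq`, `Wk`, `Wv` (Gaussian sd 0.02).
#' @export
init_cross_attention_params <- function(d_text, d_image, hidden = 32L,
                                        seed = 0L) {
  with_seed(substream_seed(seed, "cross-attention"), {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    list(Wq = g(d_text, hidden), Wk = g(d_image, hidden),
         Wv = g(d_image, hidden))
  })
}

# Frozen encoder context shared by all strategies of a run.
make_fusion_context <- function(config) {
  vocab <- default_wp_vocab()
  tables <- make_text_tables(vocab, embed_dim = 32L, max_len = 512L,
                             seed = config$seed)
  pconf <- patch_config(patch_size = 8L, embed_dim = 32L, n_heads = 4L,
                        n_layers = 2L, seed = config$seed)
  xparams <- init_cross_attention_params(32L, 32L, config$hidden_dim,
                                         config$seed)
  list(vocab = vocab, tables = tables, patch_config = pconf,
       xparams = xparams, enhance = enhance_params())
}

#' Fuse one case's modalities under a strategy
#'
#' @param case_features List with `image_thumb`, `text_token_pooled`,
#'   `text_pooled`, `joint` (from [compute_features()]).
#' @param strategy `"early"`, `"late"` or `"joint"`.
#' @return Numeric fused vector. Early fusion concatenates the per-patch
#'   pooled raw image vector with the pooled token-table vector (both
#'   pre-encoder); late returns the two per-modality vectors concatenated
#'   for inspection (late fusion proper averages the trained heads'
#'   probabilities); joint returns the cross-attention shared-space vector.
#' @export
fuse <- function(case_features, strategy) {
  switch(strategy,
         early = c(case_features$image_raw_pooled,
                   case_features$text_token_pooled),
         late = c(case_features$image_thumb, case_features$text_pooled),
         joint = case_features$joint,
         stop("unknown fusion strategy '", strategy, "'"))
}

#' Compute per-case multimodal features for a whole manifest
#'
#' For every non-Mixed case: renders the full temporal progression,
#' enhances every frame with M-CLAHE, encodes frame 0 with the toy ViT;
#' generates the consultation and radiology notes, tokenizes (truncated to
#' `max_text_tokens` pieces) and embeds them; and evaluates the
#' cross-attention fusion. Mixed cases are excluded from classification by
#' default.
#'
#' Per-case fields: `image_thumb` (per-patch pooled intensities of every
#' enhanced progression frame - the temporal image descriptor),
#' `image_raw_pooled` (frame-0 per-patch pooled raw intensities, the
#' pre-encoder vector used by early fusion), `image_enc_pooled`
#' (mean + max pooled encoded patches plus CLS), `text_token_pooled`
#' (mean token-table lookup, pre-encoder), `text_pooled` (mean and max of
#' the embedded tokens) and `joint` (cross-attention attended + query
#' vectors concatenated with both modality vectors in the shared space).
#'
#' @param manifest A `dataset_manifest`.
#' @param config A [fusion_config()].
#' @param progress Print a dot every 50 cases.
#' @return A `fusion_features` object (list of per-case feature lists plus
#'   the frozen context).
#' @export
compute_features <- function(manifest, config = fusion_config(),
                             progress = FALSE) {
  ctx <- make_fusion_context(config)
  cases <- Filter(function(cs) cs$subtype != "Mixed", manifest$cases)
  out <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    ph <- generate_phantom(cs$phantom_spec)
    if (!is.null(cs$secondary_lesion))
      ph <- render_lesion(ph, cs$secondary_lesion)
    frames <- suppressWarnings(simulate_progression(ph, cs$lesion,
                                                    cs$params))
    P <- ctx$patch_config$patch_size
    thumbs <- unlist(lapply(frames, function(fr)
      rowMeans(patchify(enhance_mclahe(fr$pixels, ctx$enhance)$image,
                        P)) / 255))
    enh <- enhance_mclahe(frames[[1]]$pixels, ctx$enhance)$image
    enc <- encode_image(enh, ctx$patch_config)
    raw <- patchify(as_pixels(frames[[1]]), P) / 255
    notes <- paste(generate_clinical_note(cs, "consultation", manifest$seed),
                   generate_clinical_note(cs, "radiology", manifest$seed))
    toks <- wordpiece_tokenize(notes, ctx$vocab)
    toks <- toks[seq_len(min(length(toks), config$max_text_tokens))]
    temb <- embed_tokens(toks, 0L, ctx$tables)
    xa <- cross_attention(temb, enc$patches, ctx$xparams)
    text_pooled <- c(colMeans(temb), apply(temb, 2, max))
    out[[i]] <- list(
      case_id = cs$case_id, split = cs$split, subtype = cs$subtype,
      prognosis_sentiment = cs$prognosis_sentiment,
      therapeutic_sentiment = cs$therapeutic_sentiment,
      image_thumb = thumbs,
      image_raw_pooled = rowMeans(raw),
      image_enc_pooled = c(colMeans(enc$patches),
                           apply(enc$patches, 2, max), enc$cls),
      text_token_pooled = colMeans(
        ctx$tables$token_table[toks, , drop = FALSE]),
      text_pooled = text_pooled,
      joint = c(xa$vector, thumbs, text_pooled))
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(cases = out, config = config, context = ctx,
                 seed = manifest$seed), class = "fusion_features")
}

.feature_matrix <- function(features, field, split = NULL) {
  cs <- features$cases
  if (!is.null(split)) cs <- Filter(function(x) x$split == split, cs)
  X <- do.call(rbind, lapply(cs, `[[`, field))
  rownames(X) <- vapply(cs, `[[`, "", "case_id")
  X
}

.label_vector <- function(features, task, split = NULL) {
  cs <- features$cases
  if (!is.null(split)) cs <- Filter(function(x) x$split == split, cs)
  field <- switch(task, subtype = "subtype",
                  prognosis = "prognosis_sentiment",
                  therapeutic = "therapeutic_sentiment",
                  stop("unknown task ", task))
  vapply(cs, `[[`, "", field)
}

# Single-hidden-layer softmax perceptron trained by full-batch gradient
# descent with per-epoch validation tracking; the best-validation
# checkpoint is returned. Deterministic for a fixed seed.
train_head <- function(X, y, classes, X_val, y_val, hidden = 64L,
                       lr = 0.3, epochs = 500L, seed = 0L, wd = 1e-3) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xv <- sweep(sweep(X_val, 2, mu), 2, sdv, "/")
  K <- length(classes); d <- ncol(X); n <- nrow(X)
  Y <- outer(y, classes, "==") * 1
  pars <- with_seed(substream_seed(seed, "head-init"), list(
    W1 = matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * K, 0, sqrt(2 / hidden)), hidden, K),
    b2 = numeric(K)))
  forward <- function(p, X) {
    H1 <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
    list(H = H1, P = .softmax_rows(sweep(H1 %*% p$W2, 2, p$b2, "+")))
  }
  best <- list(pars = pars, val_acc = -1, epoch = 0L)
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    fw <- forward(pars, Xs)
    G <- (fw$P - Y) / n
    dW2 <- t(fw$H) %*% G + wd * pars$W2; db2 <- colSums(G)
    dH <- G %*% t(pars$W2) * (1 - fw$H^2)
    dW1 <- t(Xs) %*% dH + wd * pars$W1; db1 <- colSums(dH)
    pars$W1 <- pars$W1 - lr * dW1; pars$b1 <- pars$b1 - lr * db1
    pars$W2 <- pars$W2 - lr * dW2; pars$b2 <- pars$b2 - lr * db2
    losses[e] <- -mean(log(pmax(fw$P[Y == 1], 1e-12)))
    pv <- forward(pars, Xv)$P
    acc <- mean(classes[max.col(pv, ties.method = "first")] == y_val)
    if (acc > best$val_acc) best <- list(pars = pars, val_acc = acc,
                                         epoch = e)
  }
  structure(list(pars = best$pars, classes = classes, mu = mu, sd = sdv,
                 val_acc = best$val_acc, best_epoch = best$epoch,
                 loss_curve = losses, forward = NULL), class = "mlp_head")
}

predict_head <- function(head, X) {
  Xs <- sweep(sweep(X, 2, head$mu), 2, head$sd, "/")
  H1 <- tanh(sweep(Xs %*% head$pars$W1, 2, head$pars$b1, "+"))
  P <- .softmax_rows(sweep(H1 %*% head$pars$W2, 2, head$pars$b2, "+"))
  colnames(P) <- head$classes
  P
}

#' Train the toy multimodal classifier
#'
#' Trains one head per task (subtype, prognosis sentiment, therapeutic
#' sentiment) on the train split with per-epoch validation tracking and
#' best-validation checkpointing. For the late strategy two per-modality
#' heads are trained per task and their probabilities averaged at
#' prediction time.
#'
#' @param features A [compute_features()] object (or a `dataset_manifest`,
#'   which is featurized first).
#' @param config A [fusion_config()].
#' @return A `fusion_model`.
#' @export
train_toy <- function(features, config = fusion_config()) {
  if (inherits(features, "dataset_manifest"))
    features <- compute_features(features, config)
  splits <- unique(vapply(features$cases, `[[`, "", "split"))
  if (!all(c("train", "validation") %in% splits))
    stop("manifest must contain non-empty train and validation splits")
  tasks <- c("subtype", "prognosis", "therapeutic")
  fields <- switch(config$strategy,
                   early = "early", joint = "joint",
                   late = c("image_thumb", "text_pooled"))
  get_X <- function(field, split) {
    if (field == "early")
      cbind(.feature_matrix(features, "image_raw_pooled", split),
            .feature_matrix(features, "text_token_pooled", split))
    else .feature_matrix(features, field, split)
  }
  heads <- lapply(tasks, function(task) {
    y_tr <- .label_vector(features, task, "train")
    y_va <- .label_vector(features, task, "validation")
    classes <- sort(unique(y_tr))
    lapply(fields, function(f)
      train_head(get_X(f, "train"), y_tr, classes,
                 get_X(f, "validation"), y_va,
                 hidden = config$head_hidden, lr = config$learning_rate,
                 epochs = config$n_epochs,
                 seed = substream_seed(config$seed, paste0(task, "-", f)),
                 wd = config$weight_decay))
  })
  names(heads) <- tasks
  structure(list(strategy = config$strategy, fields = fields,
                 heads = heads, config = config), class = "fusion_model")
}

# Class-probability matrix for one task; late fusion averages the
# per-modality heads.
predict_proba <- function(model, features, task, split = NULL,
                          modality = NULL) {
  get_X <- function(field) {
    if (field == "early")
      cbind(.feature_matrix(features, "image_raw_pooled", split),
            .feature_matrix(features, "text_token_pooled", split))
    else .feature_matrix(features, field, split)
  }
  heads <- model$heads[[task]]
  if (!is.null(modality)) {
    i <- match(modality, model$fields)
    if (is.na(i)) stop("model has no modality '", modality, "'")
    return(predict_head(heads[[i]], get_X(model$fields[i])))
  }
  Ps <- Map(function(h, f) predict_head(h, get_X(f)), heads, model$fields)
  Reduce(`+`, Ps) / length(Ps)
}

#' Evaluate a fusion model on a split
#'
#' @param model A `fusion_model` from [train_toy()].
#' @param features The [compute_features()] object.
#' @param split Split name (e.g. `"test"`).
#' @param modality For late models: evaluate a single per-modality head
#'   (`"image_thumb"` or `"text_pooled"`) instead of the averaged fusion.
#' @return An `eval_report`: per-task accuracy, per-class metric tables
#'   (percent, one-vs-rest plus macro), confusion matrices and ROC/PR
#'   curves per class.
#' @export
evaluate <- function(model, features, split = "test", modality = NULL) {
  tasks <- names(model$heads)
  out <- lapply(tasks, function(task) {
    y <- .label_vector(features, task, split)
    if (length(y) == 0L) stop("split '", split, "' is empty")
    P <- predict_proba(model, features, task, split, modality)
    classes <- colnames(P)
    pred <- classes[max.col(P, ties.method = "first")]
    tab <- multiclass_metrics(pred, y, classes, scores = P)
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x) 100 * x)
    curves <- lapply(stats::setNames(classes, classes), function(cl) {
      if (length(unique(y == cl)) < 2L) return(NULL)
      list(roc = roc_points(P[, cl], y == cl)$points,
           pr = pr_points(P[, cl], y == cl))
    })
    list(task = task, accuracy = mean(pred == y),
         metrics_pct = tab,
         confusion = confusion_matrix(pred, y, classes), curves = curves)
  })
  names(out) <- tasks
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  for (task in names(x))
    cat(sprintf("%-12s accuracy %.1f%%\n", task, 100 * x[[task]]$accuracy))
  invisible(x)
}

#' Run the packaged multimodal benchmark
#'
#' Builds the balanced five-subtype benchmark manifest, featurizes it once,
#' trains the joint model and the late model (whose per-modality heads are
#' the image-only and text-only baselines) plus the early baseline, and
#' evaluates subtype accuracy on the test split.
#'
#' @param seed Run seed.
#' @param counts Per-split case counts (default [benchmark_counts()]).
#' @param n_epochs Training epochs.
#' @return List with the featurized data, models, reports, and the subtype
#'   test accuracies `joint`, `early`, `late`, `image_only`, `text_only`.
#' @export
run_benchmark <- function(seed = 0L, counts = benchmark_counts(),
                          n_epochs = 500L) {
  manifest <- build_manifest(counts, frames_per_case = 10L, seed = seed)
  feats <- compute_features(manifest, fusion_config(seed = seed))
  models <- lapply(c(joint = "joint", late = "late", early = "early"),
                   function(s) train_toy(feats,
                     fusion_config(strategy = s, n_epochs = n_epochs,
                                   seed = seed)))
  reports <- lapply(models, evaluate, features = feats, split = "test")
  acc <- c(joint = reports$joint$subtype$accuracy,
           late = reports$late$subtype$accuracy,
           early = reports$early$subtype$accuracy,
           image_only = evaluate(models$late, feats, "test",
                                 "image_thumb")$subtype$accuracy,
           text_only = evaluate(models$late, feats, "test",
                                "text_pooled")$subtype$accuracy)
  list(manifest = manifest, features = feats, models = models,
       reports = reports, subtype_test_accuracy = acc)
}
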
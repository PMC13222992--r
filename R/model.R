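## The parallel CNN-GRU hybrid regressor with meta-learner fusion, the
## comparison-model zoo, and the training loop.

#' Model configuration
#'
#' Hyperparameters of the hybrid regressor and its baselines. The CNN
#' branch uses three convolutional blocks with 64, 128 and 256 filters of
#' kernel 3 (1D along the feature-field axis in feature mode, 3x3 2D over
#' the per-stage patch stack in image mode), each followed by ReLU and
#' stride-2 max pooling, then spatial dropout; the GRU branch stacks two
#' layers of 128 and 64 hidden units over the L timesteps; each branch ends
#' in a 64-unit dense head and the meta-learner fuses the concatenated
#' branch outputs through 128- and 64-unit dense layers into one linear
#' output. Training uses Adam (initial learning rate 0.001), batch size 32,
#' MSE loss and early stopping on a 10% validation split.
#'
#' @param mode `"feature"` (F x L feature matrix input, default) or
#'   `"image"` (resized per-stage patch stack).
#' @param image_size image-mode input side, one of 16, 32, 64, 96, 128,
#'   192, 224 (default 128).
#' @param filters CNN filter counts per block.
#' @param kernel convolution kernel size.
#' @param dropout spatial dropout rate (default 0.2).
#' @param gru_units GRU layer widths.
#' @param branch_units width of each branch's dense head.
#' @param head_units meta-learner dense widths.
#' @param lr,batch_size,max_epochs,patience,val_fraction training controls.
#' @param knn_k,rf_trees,xgb_rounds,xgb_eta,xgb_depth baseline controls
#'   (KNN k = 5 distance-weighted, RF 500 trees, XGBoost 500 rounds at
#'   learning rate 0.05 and depth 6).
#' @param transformer_layers,transformer_heads,transformer_width smallest
#'   credible encoder defaults: 2 layers, 4 heads, width 64.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a `model_config` object.
#' @export
model_config <- function(mode = c("feature", "image"),
                         image_size = 128L,
                         filters = c(64L, 128L, 256L),
                         kernel = 3L,
                         dropout = 0.2,
                         gru_units = c(128L, 64L),
                         branch_units = 64L,
                         head_units = c(128L, 64L),
                         lr = 0.001,
                         batch_size = 32L,
                         max_epochs = 500L,
                         patience = 20L,
                         val_fraction = 0.1,
                         knn_k = 5L,
                         rf_trees = 500L,
                         xgb_rounds = 500L,
                         xgb_eta = 0.05,
                         xgb_depth = 6L,
                         transformer_layers = 2L,
                         transformer_heads = 4L,
                         transformer_width = 64L,
                         seed = 1L) {
  mode <- match.arg(mode)
  allowed <- c(16L, 32L, 64L, 96L, 128L, 192L, 224L)
  if (mode == "image" && !(image_size %in% allowed))
    stopf("image_size must be one of %s", paste(allowed, collapse = ", "))
  if (any(c(filters, gru_units, branch_units, head_units) <= 0))
    stopf("all layer sizes must be positive")
  structure(as.list(environment()), class = "model_config")
}

cnn_branch_layers <- function(config, image_mode) {
  conv <- if (image_mode) layer_conv2d else layer_conv1d
  pool <- if (image_mode) layer_maxpool2d else layer_maxpool1d
  blocks <- list()
  for (f in config$filters)
    blocks <- c(blocks, list(conv(f, config$kernel), layer_relu(), pool()))
  c(blocks, list(layer_spatial_dropout(config$dropout), layer_flatten(),
                 layer_dense(config$branch_units), layer_relu()))
}

gru_branch_layers <- function(config) {
  list(layer_gru(config$gru_units[1], return_sequences = TRUE),
       layer_gru(config$gru_units[2]),
       layer_dense(config$branch_units), layer_relu())
}

meta_head_layers <- function(config) {
  list(layer_dense(config$head_units[1]), layer_relu(),
       layer_dense(config$head_units[2]), layer_relu(),
       layer_dense(1L))
}

#' Build the parallel CNN-GRU hybrid regressor
#'
#' Two parallel branches — a CNN over the input's spatial/feature axis and
#' a stacked GRU over the L phenological timesteps — whose outputs are
#' concatenated and fused by a dense meta-learner ending in a single
#' linear unit.
#'
#' @param config a [model_config()].
#' @return an untrained `lai_model`.
#' @export
build_cnn_gru <- function(config = model_config()) {
  net <- list(branches = list(
                list(input = "cnn_in",
                     layers = cnn_branch_layers(config, config$mode == "image")),
                list(input = "gru_in", layers = gru_branch_layers(config))),
              head = meta_head_layers(config))
  structure(list(name = "cnn_gru", config = config, net = net),
            class = "lai_model")
}

#' Build a comparison baseline model
#'
#' All baselines consume the same normalized inputs as the hybrid model:
#' `cnn` is the CNN branch plus dense head alone; `mlp` is a two-hidden-
#' layer (128, 64) perceptron on the flattened input; `transformer` is a
#' small encoder (2 layers, 4 heads, width 64) whose tokens are the L
#' timesteps; `knn` is k = 5 distance-weighted nearest neighbours; `rf`
#' and `xgboost` are ensemble trees on the flattened input.
#'
#' @param name one of `"transformer"`, `"knn"`, `"mlp"`, `"cnn"`, `"rf"`,
#'   `"xgboost"`, `"cnn_gru"`.
#' @param config a [model_config()].
#' @return an untrained `lai_model`.
#' @export
build_baseline <- function(name, config = model_config()) {
  name <- match.arg(name, c("transformer", "knn", "mlp", "cnn", "rf",
                            "xgboost", "cnn_gru"))
  if (name == "cnn_gru") return(build_cnn_gru(config))
  net <- switch(name,
    cnn = list(branches = list(
                 list(input = "cnn_in",
                      layers = cnn_branch_layers(config, config$mode == "image"))),
               head = meta_head_layers(config)),
    mlp = list(branches = list(
                 list(input = "flat_in",
                      layers = list(layer_dense(128L), layer_relu(),
                                    layer_dense(64L), layer_relu()))),
               head = list(layer_dense(1L))),
    transformer = {
      enc <- list(layer_conv1d(config$transformer_width, kernel = 1L))
      for (i in seq_len(config$transformer_layers))
        enc <- c(enc, list(layer_attention(config$transformer_heads),
                           layer_layernorm(),
                           layer_ffn_residual(128L),
                           layer_layernorm()))
      enc <- c(enc, list(layer_mean_pool_tokens(),
                         layer_dense(config$branch_units), layer_relu()))
      list(branches = list(list(input = "gru_in", layers = enc)),
           head = list(layer_dense(1L)))
    },
    NULL)
  structure(list(name = name, config = config, net = net),
            class = "lai_model")
}

## ---- sample -> tensor preparation ---------------------------------------

#' Attach per-stage feature matrices to samples
#'
#' Runs [extract_patch_features()] on each present stage patch and stores
#' the resulting F x L matrix in `$features` (rows = features, columns =
#' stages).
#'
#' @param samples list of `temporal_sample` objects with patches.
#' @param config a [feature_config()] naming the feature subset.
#' @return the samples, each with a `$features` matrix.
#' @export
attach_sample_features <- function(samples, config = feature_config()) {
  lapply(samples, function(s) {
    L <- length(s$patches)
    f <- matrix(NA_real_, length(config$features), L,
                dimnames = list(config$features, NULL))
    for (t in seq_len(L))
      if (!is.null(s$patches[[t]]))
        f[, t] <- extract_patch_features(s$patches[[t]], config)
    s$features <- f
    s
  })
}

## Nearest-neighbour resize of an H x W x C patch to side s.
resize_patch <- function(patch, s) {
  d <- dim(patch)
  ri <- pmin(d[1], pmax(1L, round(seq(0.5, d[1] - 0.5, length.out = s) + 0.5)))
  ci <- pmin(d[2], pmax(1L, round(seq(0.5, d[2] - 0.5, length.out = s) + 0.5)))
  patch[ri, ci, , drop = FALSE]
}

## Build the tensor set a model consumes from a list of samples.
## Feature mode: cnn_in (n, F, L), gru_in (n, L, F), flat_in (n, F*L).
## Image mode: cnn_in (n, s, s, 3L) stacked stages, gru_in (n, L, 3)
## per-stage band means, flat_in = flattened gru_in.
prepare_inputs <- function(samples, config) {
  n <- length(samples)
  if (config$mode == "feature") {
    f1 <- samples[[1]]$features
    if (is.null(f1)) stopf("samples carry no feature matrices; run attach_sample_features()")
    F <- nrow(f1); L <- ncol(f1)
    cnn_in <- array(0, c(n, F, L))
    for (i in seq_len(n)) cnn_in[i, , ] <- samples[[i]]$features
    gru_in <- aperm(cnn_in, c(1, 3, 2))
    flat_in <- cnn_in; dim(flat_in) <- c(n, F * L)
    list(cnn_in = cnn_in, gru_in = gru_in, flat_in = flat_in)
  } else {
    s <- config$image_size
    L <- length(samples[[1]]$patches)
    cnn_in <- array(0, c(n, s, s, 3L * L))
    gru_in <- array(0, c(n, L, 3L))
    for (i in seq_len(n)) {
      for (t in seq_len(L)) {
        p <- samples[[i]]$patches[[t]]
        if (is.null(p)) next
        rp <- resize_patch(unclass(p), s)
        cnn_in[i, , , (3L * (t - 1L) + 1L):(3L * t)] <- rp
        gru_in[i, t, ] <- apply(p, 3, mean)
      }
    }
    flat_in <- gru_in; dim(flat_in) <- c(n, L * 3L)
    list(cnn_in = cnn_in, gru_in = gru_in, flat_in = flat_in)
  }
}

## Min-max input normalization fitted on the training tensors only.
fit_input_norm <- function(inputs, config) {
  if (config$mode == "feature") {
    x <- inputs$cnn_in                     # (n, F, L): per-feature range
    mins <- apply(x, 2, min); maxs <- apply(x, 2, max)
    list(mode = "feature", min = mins, max = maxs)
  } else {
    list(mode = "image", min = min(inputs$cnn_in), max = max(inputs$cnn_in),
         gmin = apply(inputs$gru_in, 3, min),
         gmax = apply(inputs$gru_in, 3, max))
  }
}

apply_input_norm <- function(inputs, norm) {
  if (norm$mode == "feature") {
    x <- inputs$cnn_in
    rng <- norm$max - norm$min
    rng[rng == 0] <- 1
    for (f in seq_along(norm$min))
      x[, f, ] <- (x[, f, ] - norm$min[f]) / rng[f]
    gru_in <- aperm(x, c(1, 3, 2))
    flat_in <- x; dim(flat_in) <- c(dim(x)[1], prod(dim(x)[-1]))
    list(cnn_in = x, gru_in = gru_in, flat_in = flat_in)
  } else {
    rng <- norm$max - norm$min
    if (rng == 0) rng <- 1
    ci <- (inputs$cnn_in - norm$min) / rng
    g <- inputs$gru_in
    grng <- norm$gmax - norm$gmin
    grng[grng == 0] <- 1
    for (k in seq_along(norm$gmin))
      g[, , k] <- (g[, , k] - norm$gmin[k]) / grng[k]
    flat_in <- g; dim(flat_in) <- c(dim(g)[1], prod(dim(g)[-1]))
    list(cnn_in = ci, gru_in = g, flat_in = flat_in)
  }
}

## ---- training and prediction --------------------------------------------

#' Train an LAI regression model
#'
#' Fits the model on a list of temporal samples (which must carry feature
#' matrices in feature mode, patches in image mode). Input normalization is
#' fitted on these training samples only and stored with the model. Neural
#' models minimize MSE with Adam, batch size and early stopping taken from
#' the config; `rf` and `xgboost` delegate to their packages; `knn` stores
#' the normalized training set.
#'
#' @param model an untrained `lai_model` from [build_cnn_gru()] or
#'   [build_baseline()].
#' @param samples training samples.
#' @param verbose print per-epoch losses.
#' @return a `trained_lai_model` with fields `fit` (parameters or library
#'   object), `norm`, `history` and `train_loss`.
#' @export
train_model <- function(model, samples, verbose = FALSE) {
  if (!inherits(model, "lai_model")) stopf("model must be a lai_model")
  config <- model$config
  raw <- prepare_inputs(samples, config)
  norm <- fit_input_norm(raw, config)
  inputs <- apply_input_norm(raw, norm)
  y <- vapply(samples, function(s) s$lai, numeric(1))
  fit <- NULL; history <- NULL; y_scale <- NULL
  if (model$name %in% c("cnn_gru", "cnn", "mlp", "transformer")) {
    ## labels are standardized for the optimizer (the linear output unit
    ## then starts near the optimum); predictions are mapped back
    y_sd <- stats::sd(y)
    y_scale <- list(mean = mean(y), sd = if (y_sd > 0) y_sd else 1)
    ys <- (y - y_scale$mean) / y_scale$sd
    res <- nn_train(model$net, inputs, ys, seed = config$seed,
                    lr = config$lr, batch_size = config$batch_size,
                    max_epochs = config$max_epochs,
                    patience = config$patience,
                    val_fraction = config$val_fraction, verbose = verbose)
    fit <- res$params
    history <- res$history
  } else if (model$name == "knn") {
    fit <- list(X = inputs$flat_in, y = y, k = config$knn_k)
  } else if (model$name == "rf") {
    fit <- with_seed(config$seed,
      randomForest::randomForest(x = inputs$flat_in, y = y,
                                 ntree = config$rf_trees))
  } else if (model$name == "xgboost") {
    fit <- with_seed(config$seed,
      xgboost::xgboost(inputs$flat_in, y,
                       objective = "reg:squarederror",
                       nrounds = config$xgb_rounds,
                       learning_rate = config$xgb_eta,
                       max_depth = config$xgb_depth,
                       nthreads = 1L, seed = config$seed))
  }
  out <- structure(list(model = model, name = model$name, config = config,
                        fit = fit, norm = norm, history = history,
                        y_scale = y_scale),
                   class = "trained_lai_model")
  out$train_loss <- mean((predict(out, samples) - y)^2)
  out
}

#' Predict LAI for new samples
#'
#' @param object a `trained_lai_model`.
#' @param samples list of temporal samples (preprocessed the same way as
#'   the training data; the stored normalization stats are applied).
#' @param ablate_branch optionally zero a branch's output before the
#'   meta-learner (e.g. `"gru_in"` to silence the temporal branch), for
#'   ablation analysis of neural models.
#' @param ... unused.
#' @return numeric vector of predicted LAI, one finite value per sample.
#' @export
predict.trained_lai_model <- function(object, samples, ablate_branch = NULL,
                                      ...) {
  config <- object$config
  inputs <- apply_input_norm(prepare_inputs(samples, config), object$norm)
  if (object$name %in% c("cnn_gru", "cnn", "mlp", "transformer")) {
    net <- object$model$net
    if (!is.null(ablate_branch)) {
      bi <- which(vapply(net$branches, function(b) b$input, "") == ablate_branch)
      if (!length(bi)) stopf("no branch reads input '%s'", ablate_branch)
      out <- nn_forward_ablate(net, object$fit, inputs, bi)
    } else {
      out <- nn_forward(net, object$fit, inputs, training = FALSE)$out
    }
    out <- out * object$y_scale$sd + object$y_scale$mean
  } else if (object$name == "knn") {
    out <- knn_predict(object$fit, inputs$flat_in)
  } else if (object$name == "rf") {
    out <- as.numeric(predict(object$fit, inputs$flat_in))
  } else if (object$name == "xgboost") {
    out <- as.numeric(predict(object$fit, inputs$flat_in))
  } else stopf("unknown model %s", object$name)
  if (!all(is.finite(out))) stopf("non-finite predictions")
  out
}

## Forward pass with one branch's output zeroed before the meta-learner.
nn_forward_ablate <- function(net, params, inputs, zero_branch) {
  branch_out <- vector("list", length(net$branches))
  for (bi in seq_along(net$branches)) {
    br <- net$branches[[bi]]
    x <- inputs[[br$input]]
    for (li in seq_along(br$layers))
      x <- layer_forward(br$layers[[li]], params$branches[[bi]][[li]], x,
                         FALSE)$out
    if (length(dim(x)) > 2L) dim(x) <- c(dim(x)[1], prod(dim(x)[-1]))
    if (bi %in% zero_branch) x <- x * 0
    branch_out[[bi]] <- as_mat(x)
  }
  h <- do.call(cbind, branch_out)
  for (li in seq_along(net$head))
    h <- layer_forward(net$head[[li]], params$head[[li]], h, FALSE)$out
  as.vector(h)
}

knn_predict <- function(fit, X) {
  vapply(seq_len(nrow(X)), function(i) {
    d <- sqrt(colSums((t(fit$X) - X[i, ])^2))
    k <- min(fit$k, length(d))
    nn <- order(d)[seq_len(k)]
    w <- 1 / (d[nn] + 1e-9)
    sum(w * fit$y[nn]) / sum(w)
  }, numeric(1))
}

#' Number of trainable parameters of a neural model
#'
#' For a trained model the stored parameters are counted; for an untrained
#' one the network is sized from the given input shapes (sample dimension
#' excluded), e.g. `list(cnn_in = c(18, 3), gru_in = c(3, 18))`.
#'
#' @param x a `lai_model` or `trained_lai_model`.
#' @param input_shapes named list of per-input shapes (untrained models).
#' @return integer parameter count.
#' @export
n_parameters <- function(x, input_shapes = NULL) {
  count <- function(p) {
    if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  }
  if (inherits(x, "trained_lai_model")) {
    if (is.null(x$fit$branches)) stopf("not a neural model")
    return(as.integer(count(x$fit)))
  }
  if (is.null(input_shapes)) stopf("untrained models need input_shapes")
  params <- nn_init_network(x$net, input_shapes, seed = 0L)
  as.integer(count(params))
}
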
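#' Architecture specifications for the GSN map classifiers
#'
#' `build_vgg()` and `build_resnet()` return declarative architecture specs
#' (ordered layer descriptors plus a counted depth); [train()] instantiates
#' and fits them. All convolutions use 7 x 7 kernels with stride 1 and "same"
#' padding and swish activations with per-layer batch normalization; residual
#' blocks stack 4 or 5 such convolutions and add the block input back
#' (`H(x) = F(x) + x`), through an identity shortcut or a 1 x 1 mapping
#' convolution (stride 2 where the block downsamples).
#'
#' Layer counting convention: convolution layers, dense layers and mapping
#' shortcut convolutions count toward the depth; batch normalization,
#' activations, pooling and flatten do not. Under this convention the full
#' ResNet preset counts 112 layers — stem convolution (1), three groups of
#' four 4-convolution mapped blocks plus one 5-convolution identity block
#' (3 x 25 = 75), seven trailing 4-convolution mapped blocks (35), and the
#' dense softmax head (1) — and the full VGG preset counts 33 (five stages of
#' six convolutions plus three dense layers). Reduced presets shrink repeats
#' and filter counts for desk-scale training while preserving the block
#' structure.
#'
#' @param n_classes Number of output classes (4 NPI levels by default).
#' @param input_shape Integer `(g, g, channels)`.
#' @param preset `"full"` (paper-scale depth) or `"reduced"` (trainable on a
#'   CPU at small g).
#' @return List of class `architecture_spec` with `name`, `layers`,
#'   `counted_depth`, `n_classes`, `input_shape`.
#' @export
build_vgg <- function(n_classes = 4L, input_shape = c(32L, 32L, 3L),
                      preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  g <- input_shape[1]
  layers <- list(d("bn"))
  if (preset == "full") {
    if (g < 32L) stop("full VGG preset needs inputs of at least 32 px", call. = FALSE)
    filters <- c(16, 32, 64, 64, 64)
    for (st in 1:5) {
      for (i in 1:6) layers <- c(layers, list(d("conv", filters = filters[st])))
      layers <- c(layers, list(d("maxpool")))
    }
    layers <- c(layers, list(d("flatten"), d("dense", units = 64L),
                             d("dense", units = 32L),
                             d("dense", units = n_classes, head = TRUE)))
  } else {
    if (g < 8L) stop("reduced VGG preset needs inputs of at least 8 px", call. = FALSE)
    for (f in c(6, 8)) {
      layers <- c(layers, list(d("conv", filters = f), d("conv", filters = f),
                               d("maxpool")))
    }
    layers <- c(layers, list(d("flatten"), d("dense", units = 16L),
                             d("dense", units = n_classes, head = TRUE)))
  }
  new_architecture_spec("vgg", layers, n_classes, input_shape, preset)
}

#' @rdname build_vgg
#' @export
build_resnet <- function(n_classes = 4L, input_shape = c(32L, 32L, 3L),
                         preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  g <- input_shape[1]
  layers <- list(d("bn"))
  if (preset == "full") {
    if (g < 8L) stop("full ResNet preset needs inputs of at least 8 px", call. = FALSE)
    layers <- c(layers, list(d("conv", filters = 16L)))
    for (grp in 1:3) {
      f <- 16L * 2L^(grp - 1L)
      for (rep4 in 1:4) {
        layers <- c(layers, list(d("resblock", n_conv = 4L, filters = f,
                                   shortcut = "mapping",
                                   downsample = rep4 == 1L)))
      }
      layers <- c(layers, list(d("resblock", n_conv = 5L, filters = f,
                                 shortcut = "identity", downsample = FALSE)))
    }
    for (i in 1:7) {
      layers <- c(layers, list(d("resblock", n_conv = 4L, filters = 64L,
                                 shortcut = "mapping", downsample = FALSE)))
    }
    layers <- c(layers, list(d("bn"), d("gap"),
                             d("dense", units = n_classes, head = TRUE)))
  } else {
    if (g < 4L) stop("input too small", call. = FALSE)
    stem_stride <- if (g >= 32L) 2L else 1L
    layers <- c(layers,
                list(d("conv", filters = 6L, stride = stem_stride),
                     d("resblock", n_conv = 4L, filters = 8L,
                       shortcut = "mapping", downsample = TRUE),
                     d("bn"), d("gap"),
                     d("dense", units = n_classes, head = TRUE)))
  }
  new_architecture_spec("resnet", layers, n_classes, input_shape, preset)
}

#' @rdname build_vgg
#' @param branch_specs List of three single-channel `architecture_spec`s
#'   (one per omic) whose pooled feature widths match.
#' @export
build_concatenated <- function(branch_specs) {
  stopifnot(length(branch_specs) == 3L)
  widths <- vapply(branch_specs, branch_feature_width, numeric(1))
  if (length(unique(widths)) != 1L) {
    stop("branch feature widths differ: ", paste(widths, collapse = ", "),
         call. = FALSE)
  }
  n_classes <- branch_specs[[1]]$n_classes
  branches <- lapply(branch_specs, function(sp) {
    keep <- !vapply(sp$layers, function(l) isTRUE(l$head), logical(1))
    sp$layers[keep]
  })
  layers <- list(d("concat", branches = branches),
                 d("dense", units = n_classes, head = TRUE))
  spec <- new_architecture_spec("concatenated", layers, n_classes,
                                branch_specs[[1]]$input_shape,
                                branch_specs[[1]]$preset)
  spec$branch_input_shape <- branch_specs[[1]]$input_shape
  spec
}

d <- function(type, ...) c(list(type = type), list(...))

new_architecture_spec <- function(name, layers, n_classes, input_shape, preset) {
  structure(list(name = name, layers = layers,
                 counted_depth = count_depth(layers),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape), preset = preset),
            class = "architecture_spec")
}

count_depth <- function(layers) {
  sum(vapply(layers, function(l) {
    switch(l$type,
           conv = 1L,
           dense = 1L,
           resblock = l$n_conv + if (identical(l$shortcut, "mapping")) 1L else 0L,
           concat = sum(vapply(l$branches, count_depth, integer(1))),
           0L)
  }, integer(1)))
}

# Feature width after the last non-head layer (the pooled channel count).
branch_feature_width <- function(spec) {
  f <- spec$input_shape[3]
  for (l in spec$layers) {
    if (l$type %in% c("conv", "resblock")) f <- l$filters
    if (l$type == "dense" && !isTRUE(l$head)) f <- l$units
  }
  f
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("<architecture_spec> ", x$name, " (", x$preset, "), counted depth ",
      x$counted_depth, ", input ", paste(x$input_shape, collapse = "x"),
      ", ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

## ---- instantiation ------------------------------------------------------

# Turn descriptors into parameterized nodes. Tracks spatial size and channel
# count; errors if the spatial extent collapses below 1 px.
instantiate_network <- function(spec, seed = 42L) {
  set.seed(derive_seed(seed, paste0("init_", spec$name)))
  build_nodes(spec$layers, spec$input_shape, spec$name)
}

build_nodes <- function(layers, input_shape, name) {
  h <- input_shape[1]; w <- input_shape[2]; cc <- input_shape[3]
  nodes <- list()
  flat <- NULL
  for (l in layers) {
    node <- switch(l$type,
      bn = layer_bn(cc),
      conv = {
        s <- l$stride %||% 1L
        n <- layer_conv(cc, l$filters, kernel = l$kernel %||% 7L, stride = s)
        if (s > 1L) {
          h <- as.integer(ceiling(h / s)); w <- as.integer(ceiling(w / s))
        }
        cc <- l$filters
        n
      },
      maxpool = {
        if (h < 2L || w < 2L) stop("spatial extent too small for pooling", call. = FALSE)
        h <- h %/% 2L; w <- w %/% 2L
        layer_maxpool()
      },
      resblock = {
        main <- list()
        for (i in seq_len(l$n_conv)) {
          stride <- if (i == 1L && l$downsample) 2L else 1L
          main <- c(main, list({
            cv <- layer_conv(if (i == 1L) cc else l$filters, l$filters,
                             stride = stride)
            cv
          }, layer_bn(l$filters)))
          if (i < l$n_conv) main <- c(main, list(layer_swish()))
        }
        shortcut <- NULL
        if (identical(l$shortcut, "mapping")) {
          shortcut <- list(layer_conv(cc, l$filters, kernel = 1L,
                                      stride = if (l$downsample) 2L else 1L),
                           layer_bn(l$filters))
        } else if (cc != l$filters || l$downsample) {
          stop("identity shortcut requires matching shapes", call. = FALSE)
        }
        if (l$downsample) {
          if (h < 2L || w < 2L) stop("spatial extent too small to downsample", call. = FALSE)
          h <- as.integer(ceiling(h / 2)); w <- as.integer(ceiling(w / 2))
        }
        cc <- l$filters
        layer_resblock(main, shortcut)
      },
      gap = { flat <- cc; layer_gap() },
      flatten = { flat <- h * w * cc; layer_flatten() },
      dense = {
        if (is.null(flat)) stop("dense layer before flatten/gap", call. = FALSE)
        n <- layer_dense(flat, l$units)
        flat <- l$units
        n
      },
      concat = {
        branches <- lapply(l$branches, build_nodes, input_shape = input_shape,
                           name = name)
        flat <- sum(vapply(l$branches, function(b) {
          f <- input_shape[3]
          for (bl in b) if (bl$type %in% c("conv", "resblock")) f <- bl$filters
          f
        }, numeric(1)))
        list(type = "concat", branches = branches)
      },
      swish = layer_swish(),
      stop("unknown descriptor: ", l$type)
    )
    nodes <- c(nodes, list(node))
    # interleave activation after plain conv/dense descriptors (not the head)
    if (l$type == "conv") nodes <- c(nodes, list(layer_bn(cc), layer_swish()))
    if (l$type == "dense" && !isTRUE(l$head)) nodes <- c(nodes, list(layer_swish()))
  }
  nodes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# concat node forward/backward live here (they need multiple inputs).
concat_forward <- function(node, xs, training) {
  outs <- vector("list", length(node$branches))
  caches <- vector("list", length(node$branches))
  for (i in seq_along(node$branches)) {
    r <- net_forward(node$branches[[i]], xs[[i]], training)
    outs[[i]] <- r$out
    caches[[i]] <- r$caches
    node$branches[[i]] <- r$nodes
  }
  list(out = do.call(cbind, outs), caches = caches, node = node,
       widths = vapply(outs, ncol, integer(1)))
}

concat_backward <- function(node, caches, widths, dout) {
  grads <- vector("list", length(node$branches))
  off <- 0L
  for (i in seq_along(node$branches)) {
    cols <- off + seq_len(widths[i])
    off <- off + widths[i]
    b <- net_backward(node$branches[[i]], caches[[i]], dout[, cols, drop = FALSE])
    grads[[i]] <- b$grads
  }
  grads
}

## ---- training configuration ---------------------------------------------

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param validation_fraction Held-out fraction for the internal stratified
#'   split (ignored when a validation set is supplied).
#' @param seed Master seed (initialization, split, shuffling).
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, learning_rate = 1e-3,
                         validation_fraction = 0.2, seed = 42L) {
  stopifnot(epochs >= 1, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Stack a list of sample_images into an (H, W, C, N) array.
images_to_array <- function(images) {
  d <- dim(images[[1]]$pixels)
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]$pixels
  x
}

# Inputs for one model: merged -> single array; concatenated -> list of
# per-omic arrays (images is a list of named per-omic image lists).
dataset_inputs <- function(images, concatenated) {
  if (!concatenated) return(images_to_array(images))
  omics <- names(images[[1]])
  lapply(omics, function(o) images_to_array(lapply(images, `[[`, o)))
}

dataset_labels <- function(images, concatenated) {
  if (!concatenated) {
    labs <- vapply(images, function(im) as.character(im$label), character(1))
  } else {
    labs <- vapply(images, function(im) as.character(im[[1]]$label), character(1))
  }
  if (any(is.na(labs))) stop("all images must carry a label", call. = FALSE)
  factor(labs)
}

subset_inputs <- function(x, idx) {
  if (is.list(x)) lapply(x, function(a) a[, , , idx, drop = FALSE])
  else x[, , , idx, drop = FALSE]
}

input_count <- function(x) if (is.list(x)) dim(x[[1]])[4] else dim(x)[4]

#' Train a GSN map classifier
#'
#' Instantiates an [build_vgg()] / [build_resnet()] / [build_concatenated()]
#' spec and minimizes categorical cross-entropy with Adam. The history
#' records per-epoch accuracy, loss and macro one-vs-rest AUC on the training
#' batches and on the validation set. Fully seeded: two runs with the same
#' seed produce identical histories.
#'
#' @param spec An `architecture_spec`.
#' @param images List of labeled `sample_image`s (merged mode) or list of
#'   per-omic named image lists (concatenated mode).
#' @param config A [train_config()].
#' @param validation Optional list of images held out for validation; when
#'   `NULL` a stratified split of `images` is used.
#' @return Object of class `gsn_cnn` with elements `spec`, `nodes`,
#'   `classes`, `history` (tibble), `config`.
#' @export
train <- function(spec, images, config = train_config(), validation = NULL) {
  concat <- spec$name == "concatenated"
  y_all <- dataset_labels(images, concat)
  if (nlevels(droplevels(y_all)) < 2L) stop("need >= 2 classes to train", call. = FALSE)
  if (is.null(validation)) {
    val_idx <- stratified_holdout(y_all, config$validation_fraction, config$seed)
    tr <- which(!val_idx)
    va <- which(val_idx)
    classes <- levels(droplevels(y_all))
    x_tr <- dataset_inputs(images[tr], concat); y_tr <- droplevels(y_all[tr])
    x_va <- dataset_inputs(images[va], concat); y_va <- droplevels(y_all[va])
  } else {
    classes <- levels(droplevels(y_all))
    x_tr <- dataset_inputs(images, concat); y_tr <- droplevels(y_all)
    y_v <- dataset_labels(validation, concat)
    x_va <- dataset_inputs(validation, concat)
    y_va <- factor(as.character(y_v), levels = classes)
  }
  if (!setequal(levels(droplevels(y_tr)), levels(droplevels(factor(y_va)))) ||
      nlevels(droplevels(y_tr)) < 2L) {
    stop("stratification error: every class must appear in both splits", call. = FALSE)
  }
  y_tr <- factor(as.character(y_tr), levels = classes)
  y_va <- factor(as.character(y_va), levels = classes)
  nodes <- instantiate_network(spec, config$seed)
  state <- NULL
  t_global <- 0L
  set.seed(derive_seed(config$seed, "train_loop"))
  n_tr <- input_count(x_tr)
  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    batch_starts <- seq(1L, n_tr, by = config$batch_size)
    ep_loss <- 0
    probs_tr <- matrix(0, n_tr, length(classes))
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, n_tr)]
      xb <- subset_inputs(x_tr, idx)
      yb <- as.integer(y_tr[idx])
      fw <- model_forward(spec, nodes, xb, training = TRUE)
      nodes <- fw$nodes
      ce <- softmax_ce(fw$out, yb)
      ep_loss <- ep_loss + ce$loss * length(idx)
      probs_tr[idx, ] <- ce$probs
      grads <- model_backward(spec, nodes, fw, ce$dlogits)
      t_global <- t_global + 1L
      up <- adam_step_nodes(nodes, grads, state, t_global, config$learning_rate)
      nodes <- up$nodes
      state <- up$state
    }
    val <- model_metrics(spec, nodes, x_va, y_va, config$batch_size)
    history[[ep]] <- tibble::tibble(
      epoch = ep,
      acc = mean(classes[max.col(probs_tr, "first")] == as.character(y_tr)),
      loss = ep_loss / n_tr,
      auc = macro_auc(probs_tr, y_tr),
      val_acc = val$acc, val_loss = val$loss, val_auc = val$auc
    )
  }
  structure(list(spec = spec, nodes = nodes, classes = classes,
                 history = dplyr::bind_rows(history), config = config),
            class = "gsn_cnn")
}

stratified_holdout <- function(labels, fraction, seed) {
  set.seed(derive_seed(seed, "split"))
  val <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(length(idx) * fraction))
    val[sample(idx, n_val)] <- TRUE
  }
  val
}

model_forward <- function(spec, nodes, x, training) {
  if (spec$name == "concatenated") {
    cf <- concat_forward(nodes[[1]], x, training)
    nodes[[1]] <- cf$node
    head <- net_forward(nodes[-1], cf$out, training)
    list(out = head$out, nodes = c(nodes[1], head$nodes),
         caches = list(concat = cf, head = head$caches))
  } else {
    r <- net_forward(nodes, x, training)
    list(out = r$out, nodes = r$nodes, caches = r$caches)
  }
}

model_backward <- function(spec, nodes, fw, dlogits) {
  if (spec$name == "concatenated") {
    hb <- net_backward(nodes[-1], fw$caches$head, dlogits)
    cgrads <- concat_backward(nodes[[1]], fw$caches$concat$caches,
                              fw$caches$concat$widths, hb$dx)
    c(list(list(branches = cgrads)), hb$grads)
  } else {
    net_backward(nodes, fw$caches, dlogits)$grads
  }
}

model_metrics <- function(spec, nodes, x, y, batch_size) {
  probs <- predict_probs(spec, nodes, x, batch_size)
  classes <- levels(y)
  yidx <- as.integer(y)
  eps <- 1e-12
  list(acc = mean(classes[max.col(probs, "first")] == as.character(y)),
       loss = -mean(log(pmax(probs[cbind(seq_along(yidx), yidx)], eps))),
       auc = macro_auc(probs, y))
}

predict_probs <- function(spec, nodes, x, batch_size = 64L) {
  n <- input_count(x)
  out <- NULL
  for (bs in seq(1L, n, by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1L, n)
    fw <- model_forward(spec, nodes, subset_inputs(x, idx), training = FALSE)
    out <- rbind(out, softmax(fw$out))
  }
  out
}

# Macro one-vs-rest AUC; classes absent from y are skipped.
macro_auc <- function(probs, y) {
  classes <- levels(y)
  aucs <- c()
  for (i in seq_along(classes)) {
    pos <- y == classes[i]
    if (!any(pos) || all(pos)) next
    r <- try(suppressMessages(pROC::auc(response = as.integer(pos),
                                        predictor = probs[, i],
                                        quiet = TRUE, direction = "<")),
             silent = TRUE)
    if (!inherits(r, "try-error")) aucs <- c(aucs, as.numeric(r))
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

#' @export
predict.gsn_cnn <- function(object, images, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  concat <- object$spec$name == "concatenated"
  x <- if (is.array(images) || (is.list(images) && is.array(images[[1]])))
    images else dataset_inputs(images, concat)
  probs <- predict_probs(object$spec, object$nodes, x, object$config$batch_size)
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else factor(object$classes[max.col(probs, "first")], levels = object$classes)
}

#' Evaluate a trained classifier
#'
#' Top-1 accuracy, mean categorical cross-entropy and macro one-vs-rest AUC
#' on a labeled image set.
#'
#' @param model A `gsn_cnn` from [train()].
#' @param images Labeled images (same shape as in [train()]).
#' @return One-row tibble of class `eval_report`: `acc`, `loss`, `auc`, `n`.
#' @export
evaluate <- function(model, images) {
  concat <- model$spec$name == "concatenated"
  y <- dataset_labels(images, concat)
  if (nlevels(droplevels(y)) < 2L) {
    stop("AUC undefined on a single-class evaluation set", call. = FALSE)
  }
  y <- factor(as.character(y), levels = model$classes)
  x <- dataset_inputs(images, concat)
  m <- model_metrics(model$spec, model$nodes, x, y, model$config$batch_size)
  out <- tibble::tibble(acc = m$acc, loss = m$loss, auc = m$auc, n = length(y))
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.gsn_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<gsn_cnn> ", x$spec$name, " (", x$spec$preset, "), ",
      nrow(x$history), " epochs; val_acc ", sprintf("%.3f", last$val_acc),
      ", val_auc ", sprintf("%.3f", last$val_auc), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.gsn_cnn <- function(x, ...) x$history

#' @importFrom generics glance
#' @export
glance.gsn_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(model = x$spec$name, preset = x$spec$preset,
                 counted_depth = x$spec$counted_depth,
                 epochs = nrow(x$history),
                 acc = last$acc, val_acc = last$val_acc,
                 loss = last$loss, val_loss = last$val_loss,
                 auc = last$auc, val_auc = last$val_auc)
}

#' @export
autoplot.gsn_cnn <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

## ---- residual block diagnostics ------------------------------------------

zero_branch_params <- function(nodes) {
  lapply(nodes, function(n) {
    if (!is.null(n$W)) { n$W[] <- 0; n$b[] <- 0 }
    if (identical(n$type, "bn")) { n$gamma[] <- 1; n$beta[] <- 0 }
    n
  })
}

#' Identity limit of a residual block
#'
#' Instantiates a residual block with an identity shortcut, zeroes the
#' residual branch's convolution weights, and measures the largest absolute
#' deviation of the block output from its input on a random batch. Because
#' the block output is `H(x) = F(x) + x`, a zeroed branch must reproduce the
#' input exactly (up to floating-point noise).
#'
#' @param n_conv Convolutions in the residual branch (4 or 5).
#' @param channels Input/output channel count.
#' @param size Spatial extent of the random input.
#' @param n Batch size.
#' @param seed Seed for the block initialization and the random input.
#' @return Max absolute deviation `max |H(x) - x|`.
#' @export
resblock_identity_gap <- function(n_conv = 4L, channels = 4L, size = 8L,
                                  n = 2L, seed = 1L) {
  nodes <- build_nodes(list(d("resblock", n_conv = n_conv, filters = channels,
                              shortcut = "identity", downsample = FALSE)),
                       c(size, size, channels), "diag")
  nodes[[1]]$main <- zero_branch_params(nodes[[1]]$main)
  set.seed(derive_seed(seed, "resblock_diag"))
  x <- array(stats::rnorm(size * size * channels * n), c(size, size, channels, n))
  out <- net_forward(nodes, x, training = FALSE)$out
  max(abs(out - x))
}
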
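test_that("softmax forms a stable probability simplex", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(softmax(c(1000, 0)), c(1, 0), tolerance = 1e-12)
  expect_equal(softmax(c(log(2), 0)), c(2/3, 1/3))
  set.seed(1)
  m <- matrix(rnorm(50, sd = 5), 10, 5)
  p <- softmax(m)
  expect_true(all(p > 0 & p < 1))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
})

test_that("full presets count exactly 112 (ResNet) and 33 (VGG) layers", {
  rs <- build_resnet(preset = "full")
  expect_equal(rs$counted_depth, 112L)
  vg <- build_vgg(preset = "full")
  expect_equal(vg$counted_depth, 33L)
  # reduced presets stay shallow but keep the block structure
  rr <- build_resnet(input_shape = c(16L, 16L, 3L), preset = "reduced")
  expect_lte(rr$counted_depth, 12L)
  expect_true(any(vapply(rr$layers, function(l) l$type == "resblock", logical(1))))
})

test_that("block repeats change the counted depth predictably", {
  base <- build_resnet(preset = "full")
  # one 4-conv mapped block contributes 5 counted layers
  extra <- base$layers
  extra <- append(extra, list(gsnpi:::d("resblock", n_conv = 4L, filters = 64L,
                                        shortcut = "mapping", downsample = FALSE)),
                  after = length(extra) - 3L)
  expect_equal(gsnpi:::count_depth(extra), 117L)
})

test_that("zeroed residual branches reduce blocks to the identity", {
  expect_lt(resblock_identity_gap(n_conv = 4L, channels = 4L, size = 8L, seed = 1), 1e-6)
  expect_lt(resblock_identity_gap(n_conv = 5L, channels = 3L, size = 6L, seed = 2), 1e-6)
})

test_that("mapping shortcuts with stride 2 halve the spatial extent", {
  nodes <- gsnpi:::build_nodes(
    list(gsnpi:::d("resblock", n_conv = 4L, filters = 5L,
                   shortcut = "mapping", downsample = TRUE)),
    c(8L, 8L, 3L), "t")
  set.seed(3)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  out <- gsnpi:::net_forward(nodes, x, training = TRUE)$out
  expect_equal(dim(out), c(4L, 4L, 5L, 2L))
})

test_that("concatenated models validate and join branch features", {
  br <- function() build_resnet(4L, c(8L, 8L, 1L), "reduced")
  spec <- build_concatenated(list(br(), br(), br()))
  expect_equal(spec$n_classes, 4L)
  nodes <- gsnpi:::instantiate_network(spec, 1L)
  xs <- lapply(1:3, function(i) array(runif(8 * 8 * 2), c(8, 8, 1, 2)))
  fw <- gsnpi:::model_forward(spec, nodes, xs, training = FALSE)
  probs <- softmax(fw$out)
  expect_equal(dim(probs), c(2L, 4L))
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  # head input width is 3 x branch width
  expect_equal(nrow(nodes[[2]]$W), 3L * gsnpi:::branch_feature_width(br()))

  wide <- build_vgg(4L, c(8L, 8L, 1L), "reduced")
  expect_error(build_concatenated(list(br(), br(), wide)), "widths differ")
})

test_that("training learns separable classes, is seeded, and validates splits", {
  imgs <- make_class_images(14, g = 8L, channels = 1L, seed = 4)
  spec <- build_resnet(2L, c(8L, 8L, 1L), "reduced")
  cfg <- train_config(epochs = 6L, batch_size = 8L, seed = 11L)
  fit <- train(spec, imgs, cfg)
  expect_s3_class(fit$history, "tbl_df")
  expect_equal(nrow(fit$history), 6L)
  # separable data: loss drops and accuracy ends high
  expect_lt(fit$history$loss[6], fit$history$loss[1])
  expect_gte(fit$history$val_acc[6], 0.8)

  fit2 <- train(spec, imgs, cfg)
  expect_identical(fit$history$loss, fit2$history$loss)  # same seed, same path

  one_class <- imgs[1:14]
  expect_error(train(spec, one_class, cfg), ">= 2 classes")
})

test_that("evaluation reports accuracy, cross-entropy and macro AUC", {
  imgs <- make_class_images(12, g = 8L, channels = 1L, seed = 5)
  spec <- build_vgg(2L, c(8L, 8L, 1L), "reduced")
  fit <- train(spec, imgs, train_config(epochs = 6L, batch_size = 8L, seed = 3L))
  rep <- evaluate(fit, imgs)
  expect_true(all(c("acc", "loss", "auc", "n") %in% names(rep)))
  expect_gte(rep$acc, 0.9)
  expect_gte(rep$auc, 0.95)
  expect_gte(rep$loss, 0)

  single <- imgs[vapply(imgs, function(im) im$label == "I", logical(1))]
  expect_error(evaluate(fit, single), "single-class")

  td <- tidy(fit)
  expect_identical(td, fit$history)
  gl <- glance(fit)
  expect_equal(gl$epochs, 6L)
  expect_equal(gl$counted_depth, fit$spec$counted_depth)
})

test_that("cross-entropy matches a hand-computed three-sample case", {
  logits <- rbind(c(log(0.7), log(0.2), log(0.1)),
                  c(log(0.1), log(0.8), log(0.1)),
                  c(log(0.25), log(0.25), log(0.5)))
  ce <- gsnpi:::softmax_ce(logits, c(1L, 2L, 3L))
  hand <- -(log(0.7) + log(0.8) + log(0.5)) / 3
  expect_equal(ce$loss, hand)
  expect_equal(rowSums(ce$probs), rep(1, 3), tolerance = 1e-9)
})

test_that("a perfect and a uniform predictor bracket the AUC scale", {
  y <- factor(rep(c("I", "II"), each = 5))
  perfect <- cbind(rep(c(1, 0), each = 5), rep(c(0, 1), each = 5))
  expect_equal(gsnpi:::macro_auc(perfect, y), 1)
  uniform <- matrix(0.5, 10, 2)
  expect_equal(gsnpi:::macro_auc(uniform, y), 0.5)
})
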
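test_that("log + z-score normalization follows the population-sd convention", {
  m <- tiny_omics(c(1, 5, 3, 5), genes = c("g1", "gc"), samples = c("s1", "s2"))
  z <- normalize_omics(m, normalization_spec(pseudocount = 1, log_base = 2))
  expect_equal(as.vector(unclass(z)["g1", ]), c(-1, 1))  # log2(2), log2(4) -> +-1
  expect_equal(as.vector(unclass(z)["gc", ]), c(0, 0))   # constant gene

  set.seed(1)
  big <- tiny_omics(rexp(200), genes = sprintf("g%02d", 1:20),
                    samples = sprintf("s%02d", 1:10))
  zb <- normalize_omics(big)
  expect_lt(max(abs(rowMeans(zb))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(unclass(zb)^2)) - 1)), 1e-9)
})

test_that("non-positive values under log require a pseudocount or skip", {
  m <- tiny_omics(c(-1, 2), genes = "g1", samples = c("s1", "s2"), omic = "cna")
  expect_error(normalize_omics(m, normalization_spec(pseudocount = 0)),
               "non-positive")
  z <- normalize_omics(m, normalization_spec(apply_log = FALSE))
  expect_equal(as.vector(unclass(z)), c(-1, 1))
})

test_that("intensity transfer is linear with clipping", {
  expect_equal(value_to_intensity(0, 3), 0.5)
  expect_equal(value_to_intensity(-5, 3), 0)
  expect_equal(value_to_intensity(1.5, 3), 0.75)
  expect_equal(value_to_intensity(3, 3), 1)
  set.seed(2)
  z <- rnorm(100, sd = 4)
  v <- value_to_intensity(z, 3)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v[order(z)]) >= 0))  # monotone in z
})


test_that("merged rendering colors one pixel per template gene and channel", {
  fx <- make_render_fixture()
  img <- render_merged("s1", fx$template, fx$mats$expression, fx$mats$cna,
                       fx$mats$mrna, label = "II")
  expect_equal(dim(img$pixels), c(8, 8, 3))
  for (ch in 1:3) {
    expect_equal(sum(img$pixels[, , ch] != 0), 22)
  }
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  # determinism: bit-identical re-render
  img2 <- render_merged("s1", fx$template, fx$mats$expression, fx$mats$cna,
                        fx$mats$mrna, label = "II")
  expect_identical(img$pixels, img2$pixels)
})

test_that("zero z-scores render mid-gray and clipped values saturate", {
  genes <- "g1"
  zmat <- function(v, nm) {
    m <- matrix(v, 1, 2, dimnames = list(genes, c("s1", "s2")))
    omics_matrix(m, omic_name = nm)
  }
  emb <- structure(tibble::tibble(gene_id = "g1", y1 = 0, y2 = 0),
                   class = c("gene_embedding", class(tibble::tibble())))
  tpl <- build_template(emb, 4)
  img <- render_merged("s1", tpl, zmat(c(0, 0), "expression"),
                       zmat(c(0, 0), "cna"), zmat(c(0, 0), "mrna"))
  px <- img$pixels[tpl$row[1] + 1, tpl$col[1] + 1, ]
  expect_equal(px, c(0.5, 0.5, 0.5))
  expect_equal(sum(img$pixels != 0), 3)

  img_hi <- render_merged("s1", tpl, zmat(c(3, 0), "expression"),
                          zmat(c(0, 0), "cna"), zmat(c(0, 0), "mrna"))
  expect_equal(img_hi$pixels[tpl$row[1] + 1, tpl$col[1] + 1, 1], 1.0)
})

test_that("missing template genes are reported per omic", {
  fx <- make_render_fixture()
  short <- fx$mats$cna[-1, , drop = FALSE]
  short <- omics_matrix(short, omic_name = "cna")
  expect_error(render_merged("s1", fx$template, fx$mats$expression, short,
                             fx$mats$mrna), "cna")
})

test_that("concatenated rendering honors per-omic template sizes", {
  set.seed(4)
  sizes <- c(expression = 17L, cna = 22L, mrna = 22L)
  samples <- c("s1", "s2")
  mats <- lapply(names(sizes), function(nm) {
    genes <- sprintf("%s_g%02d", nm, seq_len(sizes[[nm]]))
    normalize_omics(tiny_omics(rexp(sizes[[nm]] * 2), genes = genes,
                               samples = samples, omic = nm))
  })
  names(mats) <- names(sizes)
  tpls <- lapply(names(sizes), function(nm) {
    emb <- structure(tibble::tibble(gene_id = rownames(mats[[nm]]),
                                    y1 = rnorm(sizes[[nm]]),
                                    y2 = rnorm(sizes[[nm]])),
                     class = c("gene_embedding", class(tibble::tibble())))
    build_template(emb, 8)
  })
  names(tpls) <- names(sizes)
  maps <- render_concatenated("s1", tpls, mats, label = "III")
  expect_named(maps, names(sizes))
  for (nm in names(sizes)) {
    expect_equal(dim(maps[[nm]]$pixels), c(8, 8, 1))
    expect_equal(sum(maps[[nm]]$pixels != 0), unname(sizes[[nm]]))
  }

  # identical inputs per omic give identical maps
  same <- lapply(mats["expression"], identity)
  maps2 <- render_concatenated("s1", list(a = tpls$expression, b = tpls$expression),
                               list(a = mats$expression, b = mats$expression))
  expect_identical(maps2$a$pixels, maps2$b$pixels)

  empty_tpl <- tpls$expression[0, ]
  attr(empty_tpl, "grid_size") <- 8L
  class(empty_tpl) <- class(tpls$expression)
  expect_error(render_concatenated("s1", list(expression = empty_tpl),
                                   mats["expression"]), "empty template")
})

test_that("raising a gene's value never darkens its pixel", {
  fx <- make_render_fixture(n_genes = 5L)
  g <- "g03"
  vals <- seq(-4, 4, length.out = 9)
  intens <- vapply(vals, function(v) {
    m <- fx$mats$expression
    m[g, "s1"] <- v
    img <- render_merged("s1", fx$template[fx$template$gene_id %in% rownames(m)[1:5], ],
                         m, fx$mats$cna, fx$mats$mrna)
    r <- fx$template[fx$template$gene_id == g, ]
    img$pixels[r$row + 1, r$col + 1, 1]
  }, numeric(1))
  expect_true(all(diff(intens) >= 0))
})

test_that("PNG export writes a readable file", {
  fx <- make_render_fixture()
  img <- render_merged("s1", fx$template, fx$mats$expression, fx$mats$cna,
                       fx$mats$mrna)
  p <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, p, upscale = 2L)
  back <- png::readPNG(p)
  expect_equal(dim(back), c(16, 16, 3))
})
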
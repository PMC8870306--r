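


test_that("t-SNE affinities are symmetric with unit mass and the layout is finite", {
  fx <- planted_gene_clusters()
  emb <- tsne_embed(fx$gv, tsne_config(perplexity = 5, iterations = 300, seed = 1))
  expect_equal(nrow(emb), nrow(fx$gv))
  expect_true(all(is.finite(emb$y1)) && all(is.finite(emb$y2)))
  P <- attr(emb, "p_matrix")
  expect_lt(max(abs(P - t(P))), 1e-12)
  expect_equal(sum(P), 1, tolerance = 1e-8)
})

test_that("t-SNE places correlated gene clusters closer than unrelated ones", {
  fx <- planted_gene_clusters()
  emb <- tsne_embed(fx$gv, tsne_config(perplexity = 5, iterations = 1000, seed = 3))
  expect_lt(cluster_distance_ratio(emb, fx$cluster), 1)

  # duplicate gene vectors end up closer than the median pairwise distance
  gv <- fx$gv
  gv["g02", ] <- gv["g01", ]
  emb2 <- tsne_embed(gv, tsne_config(perplexity = 5, iterations = 500, seed = 3))
  d <- as.matrix(dist(cbind(emb2$y1, emb2$y2)))
  expect_lt(d["g01", "g02"], median(d[upper.tri(d)]))
})

test_that("t-SNE is deterministic under a fixed seed and validates perplexity", {
  fx <- planted_gene_clusters(n_per = 4L)
  e1 <- tsne_embed(fx$gv, tsne_config(perplexity = 4, iterations = 200, seed = 5))
  e2 <- tsne_embed(fx$gv, tsne_config(perplexity = 4, iterations = 200, seed = 5))
  expect_identical(e1$y1, e2$y1)
  expect_error(tsne_embed(fx$gv, tsne_config(perplexity = 12)), "perplexity")
  expect_error(tsne_embed(fx$gv[1:2, ], tsne_config(perplexity = 1)), ">= 3")
})

test_that("SOM maps identical genes together and separates distinct clusters", {
  gv <- matrix(1, 5, 8, dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  emb <- som_embed(gv, som_config(2, 2, epochs = 20, seed = 1))
  expect_equal(nrow(unique(cbind(emb$y1, emb$y2))), 1L)

  set.seed(6)
  ok <- 0L
  for (s in 1:10) {
    g2 <- rbind(matrix(rnorm(4 * 8, mean = 0, sd = 0.1), 4),
                matrix(rnorm(4 * 8, mean = 6, sd = 0.1), 4))
    rownames(g2) <- paste0("g", 1:8)
    e <- som_embed(g2, som_config(2, 1, epochs = 50, seed = s))
    key <- paste(e$y1, e$y2)
    if (length(unique(key[1:4])) == 1L && length(unique(key[5:8])) == 1L &&
        key[1] != key[5]) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("SOM coordinates are integer grid positions within bounds", {
  set.seed(7)
  gv <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(paste0("g", 1:6), NULL))
  emb <- som_embed(gv, som_config(3, 4, epochs = 30, seed = 2))
  expect_true(all(emb$y1 == round(emb$y1)))
  expect_true(all(emb$y1 >= 0 & emb$y1 <= 2))
  expect_true(all(emb$y2 >= 0 & emb$y2 <= 3))
  e2 <- som_embed(gv, som_config(3, 4, epochs = 30, seed = 2))
  expect_identical(e2, emb)
})

test_that("templates are injective, in range, and resolve collisions", {
  fx <- planted_gene_clusters(n_per = 8L)
  emb <- tsne_embed(fx$gv, tsne_config(perplexity = 5, iterations = 300, seed = 1))
  tpl <- build_template(emb, 8)
  expect_equal(nrow(tpl), 24L)
  expect_equal(nrow(unique(tpl[, c("row", "col")])), 24L)
  expect_true(all(tpl$row >= 0 & tpl$row < 8 & tpl$col >= 0 & tpl$col < 8))

  # one gene lands on one in-range pixel
  one <- structure(tibble::tibble(gene_id = "g1", y1 = 0.3, y2 = -2),
                   class = c("gene_embedding", class(tibble::tibble())))
  t1 <- build_template(one, 8)
  expect_equal(nrow(t1), 1L)

  # identical coordinates still get distinct pixels
  two <- structure(tibble::tibble(gene_id = c("a", "b"), y1 = c(1, 1), y2 = c(1, 1)),
                   class = c("gene_embedding", class(tibble::tibble())))
  t2 <- build_template(two, 2)
  expect_equal(nrow(unique(t2[, c("row", "col")])), 2L)

  expect_error(build_template(emb, 4), "capacity")
})

test_that("templates stay injective across random embeddings", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    g <- sample(ceiling(sqrt(n)):10, 1)
    emb <- structure(tibble::tibble(gene_id = sprintf("g%02d", 1:n),
                                    y1 = rnorm(n), y2 = rnorm(n)),
                     class = c("gene_embedding", class(tibble::tibble())))
    tpl <- build_template(emb, g)
    expect_equal(nrow(unique(tpl[, c("row", "col")])), n)
    expect_true(all(tpl$row >= 0 & tpl$row < g & tpl$col >= 0 & tpl$col < g))
  }
})

test_that("template JSON round-trips", {
  fx <- planted_gene_clusters(n_per = 4L)
  emb <- som_embed(fx$gv, som_config(4, 4, epochs = 20, seed = 3))
  tpl <- build_template(emb, 6)
  p <- withr::local_tempfile(fileext = ".json")
  write_template(tpl, p)
  tpl2 <- read_template(p)
  expect_equal(as.data.frame(tpl2), as.data.frame(tpl))
  expect_identical(attr(tpl2, "grid_size"), attr(tpl, "grid_size"))
  expect_identical(attr(tpl2, "method"), "som")
})
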
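# Shared fixtures, built in code. The simulated study is cached per session
# so several test files can reuse it without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_study(simulation_config(seed = 101L))
  }
  .fixture_env$study
}

tiny_omics <- function(values, genes = NULL, samples = NULL, omic = "expression") {
  m <- matrix(values, nrow = length(genes %||% rownames(values)))
  genes <- genes %||% rownames(values)
  samples <- samples %||% colnames(values)
  omics_matrix(m, gene_ids = genes, sample_ids = samples, omic_name = omic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small labeled images with a class-dependent bright quadrant: linearly
# separable, so tiny classifiers can learn them in a few epochs.
make_class_images <- function(n_per_class, g = 8L, channels = 1L,
                              classes = c("I", "II"), noise = 0.05,
                              seed = 1L) {
  set.seed(seed)
  out <- list()
  half <- g %/% 2L
  for (ci in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      px <- array(stats::runif(g * g * channels, 0, noise), c(g, g, channels))
      rr <- if (ci %% 2L == 1L) seq_len(half) else (half + 1L):g
      cc <- if (ci <= 2L) seq_len(half) else (half + 1L):g
      px[rr, cc, ] <- px[rr, cc, ] + 0.8
      px <- pmin(px, 1)
      out <- c(out, list(gsnpi:::new_sample_image(
        px, sprintf("%s_%02d", classes[ci], i), "merged", label = classes[ci])))
    }
  }
  out
}

# Literal transcription of the summed-expression chi-square definition,
# kept loop-based and independent of the package implementation.
chi_square_reference <- function(x, labels) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  n <- ncol(x)
  chi <- numeric(nrow(x))
  for (j in seq_len(nrow(x))) {
    total <- sum(x[j, ])
    s <- 0
    for (cl in classes) {
      in_c <- labels == cl
      O <- sum(x[j, in_c])
      E <- (sum(in_c) / n) * total
      if (E > 0) s <- s + (O - E)^2 / E
    }
    chi[j] <- s
  }
  chi
}

planted_gene_clusters <- function(n_per = 10L, n_samples = 20L, sd = 0.1,
                                  seed = 2L) {
  set.seed(seed)
  base <- matrix(stats::rnorm(3 * n_samples, sd = 2), 3, n_samples)
  gv <- base[rep(1:3, each = n_per), ] +
    matrix(stats::rnorm(3 * n_per * n_samples, sd = sd), 3 * n_per)
  rownames(gv) <- sprintf("g%02d", seq_len(3 * n_per))
  list(gv = gv, cluster = rep(1:3, each = n_per))
}

cluster_distance_ratio <- function(emb, cluster) {
  d <- as.matrix(dist(cbind(emb$y1, emb$y2)))
  same <- outer(cluster, cluster, "==") & upper.tri(d)
  diff <- outer(cluster, cluster, "!=") & upper.tri(d)
  mean(d[same]) / mean(d[diff])
}

make_render_fixture <- function(n_genes = 22L, n_samples = 4L, seed = 3L) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%d", seq_len(n_samples))
  mats <- lapply(c("expression", "cna", "mrna"), function(nm) {
    normalize_omics(tiny_omics(stats::rexp(n_genes * n_samples), genes = genes,
                               samples = samples, omic = nm))
  })
  names(mats) <- c("expression", "cna", "mrna")
  emb <- structure(tibble::tibble(gene_id = genes, y1 = stats::rnorm(n_genes),
                                  y2 = stats::rnorm(n_genes)),
                   class = c("gene_embedding", class(tibble::tibble())))
  list(mats = mats, template = build_template(emb, 8), genes = genes)
}

random_image <- function(g = 16L, channels = 3L, label = "I", seed = 1L) {
  set.seed(seed)
  gsnpi:::new_sample_image(array(stats::runif(g * g * channels),
                                 c(g, g, channels)),
                           paste0("img", seed), "merged", label = label)
}
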
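#' t-SNE configuration
#'
#' @param perplexity Effective neighbor count used to calibrate the Gaussian
#'   bandwidth of each point; must be below the number of genes.
#' @param iterations Gradient-descent iterations.
#' @param learning_rate Gradient-descent step size; `NULL` (default) uses the
#'   standard `n / 12` heuristic, which keeps the attraction/repulsion forces
#'   stable for small gene sets.
#' @param seed Seed for the initial layout.
#' @return List of class `tsne_config`.
#' @export
tsne_config <- function(perplexity = 5, iterations = 1000L,
                        learning_rate = NULL, seed = 1L) {
  stopifnot(perplexity > 0, iterations > 0,
            is.null(learning_rate) || learning_rate > 0)
  structure(list(perplexity = perplexity, iterations = as.integer(iterations),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "tsne_config")
}

#' Self-organizing map configuration
#'
#' @param grid_rows,grid_cols Neuron grid dimensions.
#' @param epochs Training epochs (full passes over the genes).
#' @param initial_learning_rate Start of the linear learning-rate decay
#'   (ends at 0.01).
#' @param initial_radius Start of the exponential neighborhood-radius decay
#'   (ends at 1).
#' @param seed Seed for weight initialization and presentation order.
#' @return List of class `som_config`.
#' @export
som_config <- function(grid_rows = 8L, grid_cols = 8L, epochs = 200L,
                       initial_learning_rate = 0.5,
                       initial_radius = max(grid_rows, grid_cols) / 2,
                       seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, epochs >= 1,
            initial_learning_rate > 0, initial_radius > 0)
  structure(list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 initial_radius = initial_radius, seed = as.integer(seed)),
            class = "som_config")
}

new_gene_embedding <- function(coords, method, config) {
  out <- tibble::tibble(gene_id = rownames(coords),
                        y1 = coords[, 1], y2 = coords[, 2])
  attr(out, "method") <- method
  attr(out, "config") <- config
  class(out) <- c("gene_embedding", class(out))
  out
}

#' Embed genes in two dimensions with t-SNE
#'
#' Embeds genes (rows of the matrix; each gene is a point in sample space)
#' into 2-D by exact t-SNE: per-point Gaussian bandwidths are calibrated to
#' the target perplexity by bisection, high-dimensional affinities are
#' symmetrized as `p_ij = (p_{i|j} + p_{j|i}) / (2n)`, low-dimensional
#' affinities use the Student-t kernel
#' `q_ij = (1 + ||y_i - y_j||^2)^-1 / sum_{k != l} (1 + ||y_k - y_l||^2)^-1`,
#' and the layout minimizes `KL(P || Q)` by gradient descent with momentum
#' and early exaggeration. Deterministic under a fixed seed.
#'
#' The symmetrized affinity matrix is attached to the result as the
#' `p_matrix` attribute for diagnostic checks (symmetry, unit mass).
#'
#' @param gene_vectors Genes x samples matrix (>= 3 genes).
#' @param config A [tsne_config()]; `perplexity` must be `< nrow`.
#' @return A `gene_embedding` tibble (`gene_id`, `y1`, `y2`).
#' @export
tsne_embed <- function(gene_vectors, config = tsne_config()) {
  x <- unclass(gene_vectors)
  n <- nrow(x)
  if (n < 3L) stop("need >= 3 genes to embed", call. = FALSE)
  if (config$perplexity >= n) stop("perplexity must be below the gene count", call. = FALSE)
  lr <- config$learning_rate %||% max(2, n / 12)
  P <- tsne_affinities(x, config$perplexity)
  set.seed(derive_seed(config$seed, "tsne"))
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), nrow = n)
  vel <- matrix(0, n, 2)
  exaggeration_until <- min(100L, config$iterations)
  for (it in seq_len(config$iterations)) {
    Pit <- if (it <= exaggeration_until) 4 * P else P
    d2 <- as.matrix(stats::dist(y))^2
    w <- 1 / (1 + d2)
    diag(w) <- 0
    Q <- w / sum(w)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    mult <- (Pit - Q) * w
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
    momentum <- if (it <= 250L) 0.5 else 0.8
    vel <- momentum * vel - lr * grad
    y <- y + vel
    y <- sweep(y, 2L, colMeans(y))
  }
  rownames(y) <- rownames(x)
  emb <- new_gene_embedding(y, "tsne", config)
  attr(emb, "p_matrix") <- P
  emb
}

# Symmetrized high-dimensional affinities with per-point bandwidths
# calibrated to the target perplexity by bisection.
tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  Pcond <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { p[] <- 1 / length(p); s <- 1; H <- log(length(p)) }
      else {
        p <- p / s
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < 1e-7) break
      if (H > target) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else            { hi <- beta; beta <- (beta + lo) / 2 }
    }
    Pcond[i, -i] <- p
  }
  P <- (Pcond + t(Pcond)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

#' Embed genes on a self-organizing map grid
#'
#' Classic online Kohonen fit: neuron weights are initialized from the data,
#' genes are presented in seeded random order for `epochs` passes, the
#' winning (best-matching) neuron and its Gaussian neighborhood move toward
#' each gene under a linearly decaying learning rate and exponentially
#' decaying radius. Each gene's final coordinates are its winning neuron's
#' integer grid position (0-based `(row, col)` stored as `(y1, y2)`).
#'
#' @param gene_vectors Genes x samples matrix (>= 1 gene).
#' @param config A [som_config()].
#' @return A `gene_embedding` tibble with integer coordinates.
#' @export
som_embed <- function(gene_vectors, config = som_config()) {
  x <- unclass(gene_vectors)
  n <- nrow(x)
  if (n < 1L) stop("need >= 1 gene", call. = FALSE)
  set.seed(derive_seed(config$seed, "som"))
  nr <- config$grid_rows; nc <- config$grid_cols
  k <- nr * nc
  grid <- cbind(row = rep(seq_len(nr) - 1L, each = nc),
                col = rep(seq_len(nc) - 1L, times = nr))
  w <- x[sample.int(n, k, replace = TRUE), , drop = FALSE] +
    matrix(stats::rnorm(k * ncol(x), sd = 0.01), k)
  total <- config$epochs * n
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    for (i in sample.int(n)) {
      step <- step + 1L
      frac <- step / total
      lr <- config$initial_learning_rate +
        (0.01 - config$initial_learning_rate) * frac
      radius <- config$initial_radius * (1 / config$initial_radius)^frac
      dif <- sweep(w, 2L, x[i, ])
      bmu <- which.min(rowSums(dif^2))
      gd2 <- (grid[, 1] - grid[bmu, 1])^2 + (grid[, 2] - grid[bmu, 2])^2
      h <- exp(-gd2 / (2 * radius^2))
      w <- w - (lr * h) * dif
    }
  }
  coords <- matrix(0, n, 2, dimnames = list(rownames(x), NULL))
  for (i in seq_len(n)) {
    dif <- sweep(w, 2L, x[i, ])
    bmu <- which.min(rowSums(dif^2))
    coords[i, ] <- grid[bmu, ]
  }
  new_gene_embedding(coords, "som", config)
}

#' Rasterize a gene embedding into an injective gene-to-pixel template
#'
#' Min-max scales each embedding axis to `[0, g-1]`, rounds to the nearest
#' pixel, and resolves collisions by a deterministic spiral search: genes are
#' placed in order of (y1, y2, gene id), and a gene whose pixel is taken
#' moves to the nearest free pixel (squared-distance, then row, then column
#' order). The result is the GSN template shared by all samples.
#'
#' @param embedding A `gene_embedding` tibble.
#' @param grid_size Template side length g; needs `g^2 >=` gene count.
#' @return A `gsn_template`: tibble (`gene_id`, `row`, `col`; 0-based) with
#'   `grid_size`, `method` and `seed` attributes.
#' @export
build_template <- function(embedding, grid_size) {
  g <- as.integer(grid_size)
  n <- nrow(embedding)
  if (g * g < n) {
    stop("grid capacity ", g * g, " below gene count ", n, call. = FALSE)
  }
  scale01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  }
  px <- round(scale01(embedding$y1) * (g - 1))
  py <- round(scale01(embedding$y2) * (g - 1))
  ord <- order(embedding$y1, embedding$y2, embedding$gene_id)
  taken <- matrix(FALSE, g, g)
  rows <- integer(n); cols <- integer(n)
  offsets <- spiral_offsets(g)
  for (i in ord) {
    placed <- FALSE
    for (o in seq_len(nrow(offsets))) {
      r <- px[i] + offsets[o, 1]; c <- py[i] + offsets[o, 2]
      if (r >= 0 && r < g && c >= 0 && c < g && !taken[r + 1, c + 1]) {
        taken[r + 1, c + 1] <- TRUE
        rows[i] <- r; cols[i] <- c
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("internal: no free pixel found", call. = FALSE)
  }
  out <- tibble::tibble(gene_id = embedding$gene_id, row = rows, col = cols)
  attr(out, "grid_size") <- g
  attr(out, "method") <- attr(embedding, "method")
  attr(out, "seed") <- attr(embedding, "config")$seed
  class(out) <- c("gsn_template", class(out))
  out
}

# All pixel offsets within a (2g x 2g) window ordered by squared distance,
# then row, then column: the deterministic spiral used for collision search.
spiral_offsets <- function(g) {
  d <- -(g - 1):(g - 1)
  grid <- expand.grid(dr = d, dc = d)
  grid <- grid[order(grid$dr^2 + grid$dc^2, grid$dr, grid$dc), ]
  as.matrix(grid)
}

#' Serialize / read a GSN template as JSON
#'
#' @param template A `gsn_template`.
#' @param path Output (input) path.
#' @return `path` (`write_template`) or a `gsn_template` (`read_template`).
#' @export
write_template <- function(template, path) {
  obj <- list(grid_size = attr(template, "grid_size"),
              method = attr(template, "method"),
              seed = attr(template, "seed"),
              genes = as.data.frame(template))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(obj$genes)
  out$row <- as.integer(out$row); out$col <- as.integer(out$col)
  attr(out, "grid_size") <- as.integer(obj$grid_size)
  attr(out, "method") <- obj$method
  attr(out, "seed") <- obj$seed
  class(out) <- c("gsn_template", class(out))
  out
}

#' @export
autoplot.gene_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y1, y = .data$y2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene_id), vjust = -0.6, size = 2.5) +
    ggplot2::labs(title = paste(attr(object, "method"), "gene embedding")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gsn_template <- function(object, ...) {
  g <- attr(object, "grid_size")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(fill = "grey30") +
    ggplot2::scale_y_reverse(limits = c(g - 0.5, -0.5)) +
    ggplot2::scale_x_continuous(limits = c(-0.5, g - 0.5)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("GSN template (", attr(object, "method"),
                                 ", g = ", g, ")")) +
    ggplot2::theme_minimal()
}
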
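#' Elastic deformation configuration
#'
#' Random displacement-field warping: per-pixel uniform `[-1, 1]` fields are
#' Gaussian-smoothed with `sigma` and scaled by `alpha` (drawn uniformly from
#' `[alpha_min, alpha_max]` when balancing). Alpha values of 15-18 are
#' conventional for ~224-px images, so displacements are rescaled by
#' `g / 224` to stay meaningful on small GSN maps. Resampling is bilinear
#' with reflected boundaries.
#'
#' @param alpha_min,alpha_max Displacement magnitude range (>= 0).
#' @param sigma Gaussian smoothing sd of the displacement field, in pixels;
#'   `NULL` defaults to `g / 8` at transform time.
#' @param seed Master seed.
#' @return List of class `elastic_config`.
#' @export
elastic_config <- function(alpha_min = 15, alpha_max = 18, sigma = NULL,
                           seed = 1L) {
  stopifnot(alpha_min >= 0, alpha_max >= alpha_min, is.null(sigma) || sigma > 0)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, sigma = sigma,
                 seed = as.integer(seed)),
            class = "elastic_config")
}

# Separable Gaussian blur with reflected boundaries.
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect_pad_idx <- function(n) {
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
    if (r > n) { # very small images: recycle reflection
      idx <- pmax(pmin(c(rep(1L, r - n), idx, rep(n, r - n)), n), 1L)
    }
    idx
  }
  conv1 <- function(mat) { # along rows
    idx <- reflect_pad_idx(nrow(mat))
    padded <- mat[idx, , drop = FALSE]
    out <- matrix(0, nrow(mat), ncol(mat))
    for (o in seq_along(k)) {
      out <- out + k[o] * padded[(o - 1) + seq_len(nrow(mat)), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

# Bilinear sampling at (possibly fractional) coordinates with reflected
# boundary handling; exact at integer coordinates.
bilinear_sample <- function(channel, rows, cols) {
  n <- nrow(channel)
  reflect <- function(v, n) {
    v <- (v - 1) %% (2 * (n - 1))
    v <- ifelse(v > (n - 1), 2 * (n - 1) - v, v)
    v + 1
  }
  if (n == 1L) return(matrix(channel[1, 1], nrow(rows), ncol(rows)))
  rows <- reflect(rows, n); cols <- reflect(cols, ncol(channel))
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, n); c1 <- pmin(c0 + 1, ncol(channel))
  fr <- rows - r0; fc <- cols - c0
  v00 <- channel[cbind(as.vector(r0), as.vector(c0))]
  v01 <- channel[cbind(as.vector(r0), as.vector(c1))]
  v10 <- channel[cbind(as.vector(r1), as.vector(c0))]
  v11 <- channel[cbind(as.vector(r1), as.vector(c1))]
  out <- v00 * (1 - as.vector(fr)) * (1 - as.vector(fc)) +
    v01 * (1 - as.vector(fr)) * as.vector(fc) +
    v10 * as.vector(fr) * (1 - as.vector(fc)) +
    v11 * as.vector(fr) * as.vector(fc)
  matrix(out, nrow(rows), ncol(rows))
}

#' Elastic transform of a sample image
#'
#' Displaces pixels by a smoothed random field and resamples bilinearly.
#' `alpha = 0` is the exact identity; outputs stay in `[0, 1]`; the label is
#' preserved and the seed recorded for provenance.
#'
#' @param image A `sample_image`.
#' @param alpha Displacement magnitude (paper-scale; rescaled by `g / 224`).
#' @param sigma Field smoothing sd; default `g / 8`.
#' @param seed Seed for the displacement field.
#' @return A new `sample_image`.
#' @export
elastic_transform <- function(image, alpha = 16, sigma = NULL, seed = 1L) {
  px <- image$pixels
  g <- dim(px)[1]
  if (is.null(sigma)) sigma <- g / 8
  if (alpha == 0) {
    out <- image
    out$aug_seed <- seed
    out$source_id <- image$sample_id
    return(out)
  }
  set.seed(derive_seed(seed, "elastic"))
  scale <- alpha * g / 224
  dx <- gaussian_blur(matrix(stats::runif(g * g, -1, 1), g, g), sigma) * scale
  dy <- gaussian_blur(matrix(stats::runif(g * g, -1, 1), g, g), sigma) * scale
  base_r <- matrix(seq_len(g), g, g)
  base_c <- matrix(seq_len(g), g, g, byrow = TRUE)
  rows <- base_r + dx
  cols <- base_c + dy
  out_px <- px
  for (ch in seq_len(dim(px)[3])) {
    out_px[, , ch] <- bilinear_sample(px[, , ch], rows, cols)
  }
  out_px[] <- pmin(pmax(out_px, 0), 1)
  new_sample_image(out_px, paste0(image$sample_id, "_aug", seed), image$mode,
                   label = image$label, omic = image$omic,
                   source_id = image$sample_id, aug_seed = seed)
}

#' Balance a labeled image set by elastic augmentation
#'
#' Brings every class to exactly `target_per_class` images. Classes below
#' target keep their originals and gain elastic-transform copies of randomly
#' chosen (seeded) originals, with alpha drawn uniformly from the config
#' range; classes above target are randomly subsampled (seeded).
#'
#' @param images List of `sample_image` (all with non-missing labels).
#' @param target_per_class Desired images per class.
#' @param config An [elastic_config()].
#' @return List of `sample_image`, `n_classes * target_per_class` long.
#' @export
balance_dataset <- function(images, target_per_class, config = elastic_config()) {
  stopifnot(target_per_class >= 1)
  labels <- vapply(images, function(im) as.character(im$label), character(1))
  if (any(is.na(labels))) stop("all images must carry a label", call. = FALSE)
  classes <- sort(unique(labels))
  set.seed(derive_seed(config$seed, "balance"))
  out <- list()
  for (cl in classes) {
    members <- images[labels == cl]
    if (!length(members)) stop("empty class: ", cl, call. = FALSE)
    if (length(members) > target_per_class) {
      members <- members[sort(sample.int(length(members), target_per_class))]
    } else if (length(members) < target_per_class) {
      deficit <- target_per_class - length(members)
      src <- sample.int(length(members), deficit, replace = TRUE)
      alphas <- stats::runif(deficit, config$alpha_min, config$alpha_max)
      seeds <- sample.int(.Machine$integer.max - 1L, deficit)
      extra <- lapply(seq_len(deficit), function(i) {
        elastic_transform(members[[src[i]]], alpha = alphas[i],
                          sigma = config$sigma, seed = seeds[i])
      })
      members <- c(members, extra)
    }
    out <- c(out, members)
  }
  out
}
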
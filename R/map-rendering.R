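#' Normalization specification
#'
#' Omics layers are normalized by a log transform followed by per-gene
#' z-scoring (population sd, denominator n). Copy-number layers, whose values
#' are small signed integers, skip the log step (`apply_log = FALSE`) and are
#' only z-scored.
#'
#' @param pseudocount Added before the log; must make all values positive.
#' @param log_base 2, 10 or `exp(1)`.
#' @param apply_log Apply the log step (disable for signed layers like CNA).
#' @param clip_sigma Z-score clipping range used when mapping values to pixel
#'   intensities.
#' @return List of class `normalization_spec`.
#' @export
normalization_spec <- function(pseudocount = 1, log_base = 2,
                               apply_log = TRUE, clip_sigma = 3) {
  stopifnot(pseudocount >= 0, log_base > 0, clip_sigma > 0)
  structure(list(pseudocount = pseudocount, log_base = log_base,
                 apply_log = apply_log, clip_sigma = clip_sigma),
            class = "normalization_spec")
}

#' Log + z-score normalization of an omics matrix
#'
#' Applies `log(x + pseudocount)` (when `apply_log`) then per-gene z-scores
#' with the population standard deviation. Constant genes become all zeros.
#'
#' @param matrix An [omics_matrix()].
#' @param spec A [normalization_spec()].
#' @return The normalized [omics_matrix()] (per-gene mean 0, sd 1).
#' @export
normalize_omics <- function(matrix, spec = normalization_spec()) {
  x <- unclass(matrix)
  if (spec$apply_log) {
    shifted <- x + spec$pseudocount
    if (any(shifted <= 0)) {
      stop("non-positive value after pseudocount; increase `pseudocount` or ",
           "set `apply_log = FALSE`", call. = FALSE)
    }
    x <- log(shifted, base = spec$log_base)
  }
  mu <- rowMeans(x)
  centered <- x - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  z <- centered / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  omics_matrix(z, omic_name = attr(matrix, "omic_name"))
}

#' Map a z-score to a pixel intensity in [0, 1]
#'
#' Linear map of `[-clip_sigma, +clip_sigma]` onto `[0, 1]`, clipped outside.
#'
#' @param z Z-score(s).
#' @param clip_sigma Clipping range (> 0).
#' @return Intensities in `[0, 1]`.
#' @export
value_to_intensity <- function(z, clip_sigma = 3) {
  stopifnot(clip_sigma > 0)
  pmin(pmax((z + clip_sigma) / (2 * clip_sigma), 0), 1)
}

BACKGROUND_INTENSITY <- 0

new_sample_image <- function(pixels, sample_id, mode, label = NA,
                             omic = NULL, source_id = sample_id, aug_seed = NA) {
  structure(list(pixels = pixels, sample_id = sample_id, mode = mode,
                 label = label, omic = omic, source_id = source_id,
                 aug_seed = aug_seed),
            class = "sample_image")
}

#' @export
print.sample_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<sample_image> ", x$sample_id, " [", x$mode,
      if (!is.null(x$omic)) paste0("/", x$omic), "] ",
      d[1], "x", d[2], "x", d[3], ", label ", as.character(x$label), "\n", sep = "")
  invisible(x)
}

template_genes_checked <- function(template, matrices) {
  genes <- template$gene_id
  for (m in matrices) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      stop("template gene(s) absent from omic '", attr(m, "omic_name"), "': ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  genes
}

#' Render a merged 3-channel GSN map for one sample
#'
#' Colors one shared template with the three normalized omics layers:
#' channel 1 (R) = gene expression, channel 2 (G) = copy number alteration,
#' channel 3 (B) = mRNA. Non-template pixels hold the background constant 0.
#'
#' @param sample_id Sample to render (must be a column of all matrices).
#' @param template A `gsn_template` (from the expression layer's genes).
#' @param expr,cna,mrna Normalized [omics_matrix()] layers.
#' @param clip_sigma Z-score clipping for [value_to_intensity()].
#' @param label Optional NPI level attached to the image.
#' @return A `sample_image` with `pixels` array `g x g x 3` in `[0, 1]`.
#' @export
render_merged <- function(sample_id, template, expr, cna, mrna,
                          clip_sigma = 3, label = NA) {
  mats <- list(expr, cna, mrna)
  genes <- template_genes_checked(template, mats)
  if (!all(vapply(mats, function(m) sample_id %in% colnames(m), logical(1)))) {
    stop("sample '", sample_id, "' absent from an omic layer", call. = FALSE)
  }
  g <- attr(template, "grid_size")
  px <- array(BACKGROUND_INTENSITY, dim = c(g, g, 3))
  idx <- cbind(template$row + 1L, template$col + 1L)
  for (ch in 1:3) {
    vals <- value_to_intensity(unclass(mats[[ch]])[genes, sample_id], clip_sigma)
    px[cbind(idx, ch)] <- vals
  }
  new_sample_image(px, sample_id, "merged", label = label)
}

#' Render per-omic single-channel GSN maps for one sample
#'
#' Concatenated mode: each omic keeps its own template (the per-omic selected
#' gene sets may differ in size) and yields one single-channel map.
#'
#' @param sample_id Sample to render.
#' @param templates Named list of `gsn_template`s, one per omic.
#' @param matrices Named list of normalized [omics_matrix()] layers, names
#'   matching `templates`.
#' @param clip_sigma Z-score clipping.
#' @param label Optional NPI level.
#' @return Named list of single-channel `sample_image`s (`g x g x 1`).
#' @export
render_concatenated <- function(sample_id, templates, matrices,
                                clip_sigma = 3, label = NA) {
  stopifnot(length(templates) == length(matrices),
            all(names(templates) %in% names(matrices)))
  out <- lapply(names(templates), function(nm) {
    tpl <- templates[[nm]]
    if (nrow(tpl) == 0L) stop("empty template for omic '", nm, "'", call. = FALSE)
    m <- matrices[[nm]]
    genes <- template_genes_checked(tpl, list(m))
    if (!sample_id %in% colnames(m)) {
      stop("sample '", sample_id, "' absent from omic '", nm, "'", call. = FALSE)
    }
    g <- attr(tpl, "grid_size")
    px <- array(BACKGROUND_INTENSITY, dim = c(g, g, 1))
    px[cbind(tpl$row + 1L, tpl$col + 1L, 1L)] <-
      value_to_intensity(unclass(m)[genes, sample_id], clip_sigma)
    new_sample_image(px, sample_id, "concatenated", label = label, omic = nm)
  })
  names(out) <- names(templates)
  out
}

#' Render the full cohort
#'
#' @param scored Clinical tibble with `sample_id` and `npi_level`.
#' @param template A template (merged) or named list of templates
#'   (concatenated).
#' @param matrices Named list of normalized layers `expression`, `cna`,
#'   `mrna`.
#' @param mode `"merged"` or `"concatenated"`.
#' @param clip_sigma Z-score clipping.
#' @return List of `sample_image` (merged) or list of per-omic image lists
#'   (concatenated), one element per sample.
#' @export
render_cohort <- function(scored, template, matrices,
                          mode = c("merged", "concatenated"), clip_sigma = 3) {
  mode <- match.arg(mode)
  lapply(seq_len(nrow(scored)), function(i) {
    sid <- scored$sample_id[i]
    lab <- scored$npi_level[i]
    if (mode == "merged") {
      render_merged(sid, template, matrices$expression, matrices$cna,
                    matrices$mrna, clip_sigma = clip_sigma, label = lab)
    } else {
      render_concatenated(sid, template, matrices, clip_sigma = clip_sigma,
                          label = lab)
    }
  })
}

#' Export a sample image as PNG
#'
#' 8-bit export for inspection; training always uses the raw arrays.
#'
#' @param image A `sample_image`.
#' @param path Output path.
#' @param upscale Integer nearest-neighbor upscale factor.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path, upscale = 1L) {
  px <- image$pixels
  if (dim(px)[3] == 1L) px <- px[, , 1]
  if (upscale > 1L) {
    rep_idx <- function(n) rep(seq_len(n), each = upscale)
    px <- if (length(dim(px)) == 3L) px[rep_idx(dim(px)[1]), rep_idx(dim(px)[2]), ]
          else px[rep_idx(nrow(px)), rep_idx(ncol(px))]
  }
  png::writePNG(px, target = path)
  invisible(path)
}

#' @export
autoplot.sample_image <- function(object, ...) {
  px <- object$pixels
  g <- dim(px)[1]
  df <- expand.grid(row = seq_len(g), col = seq_len(g))
  if (dim(px)[3] == 3L) {
    df$fill <- grDevices::rgb(px[cbind(df$row, df$col, 1)],
                              px[cbind(df$row, df$col, 2)],
                              px[cbind(df$row, df$col, 3)])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity()
  } else {
    df$value <- px[cbind(df$row, df$col, 1)]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(object$sample_id, " (", object$mode,
                                 if (!is.null(object$omic)) paste0("/", object$omic), ")")) +
    ggplot2::theme_void()
}
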
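#' Summed-expression chi-square gene ranking
#'
#' Ranks genes by a chi-square statistic computed on class-wise sums of
#' expression: for gene j and class c the observed value is
#' `O_jc = sum over samples in c of x_ij`, the expected value is
#' `E_jc = (n_c / N) * sum over all samples of x_ij`, and the statistic is
#' `chi2_j = sum_c (O_jc - E_jc)^2 / E_jc`. A gene whose class sums are
#' exactly proportional to class sizes scores 0. Genes with total sum 0 have
#' every `E_jc = 0`; their statistic is defined as 0 and they are flagged as
#' degenerate (an all-zero gene cannot be informative).
#'
#' Values must be non-negative (expression-scale); when a layer contains
#' negative values (e.g. copy-number states), set `shift = TRUE` to subtract
#' each gene's minimum first.
#'
#' @param matrix Gene x sample [omics_matrix()] (non-negative values).
#' @param labels Class label per sample (factor or coercible).
#' @param shift If `TRUE`, shift each gene by its minimum so all values are
#'   non-negative before scoring.
#' @return A tibble of class `chi_square_result` with columns `gene_id`,
#'   `chi_value`, `degenerate`, sorted by decreasing `chi_value` (ties by
#'   `gene_id`); the per-gene observed and expected class sums are attached
#'   as `observed` and `expected` matrix attributes.
#' @export
chi_square_scores <- function(matrix, labels, shift = FALSE) {
  x <- unclass(matrix)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x)) stop("one label per sample required", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L) stop("need >= 2 classes", call. = FALSE)
  labels <- droplevels(labels)
  if (shift) {
    mins <- apply(x, 1L, min)
    x <- x - pmin(mins, 0)
  }
  if (any(x < 0)) stop("chi-square ranking requires non-negative values; use shift = TRUE", call. = FALSE)
  ind <- stats::model.matrix(~ labels - 1)            # samples x classes
  O <- x %*% ind                                      # genes x classes
  n_c <- colSums(ind)
  totals <- rowSums(x)
  E <- totals %o% (n_c / ncol(x))
  ratio <- (O - E)^2 / E
  ratio[E == 0] <- 0
  chi <- rowSums(ratio)
  degenerate <- totals == 0
  chi[degenerate] <- 0
  colnames(O) <- colnames(E) <- levels(labels)
  out <- tibble::tibble(gene_id = rownames(x), chi_value = unname(chi),
                        degenerate = unname(degenerate)) |>
    dplyr::arrange(dplyr::desc(.data$chi_value), .data$gene_id)
  attr(out, "observed") <- O
  attr(out, "expected") <- E
  class(out) <- c("chi_square_result", class(out))
  out
}

#' Top-k genes from a chi-square ranking
#'
#' @param result A `chi_square_result` tibble.
#' @param k Number of genes to keep; ties broken by lexicographic gene id.
#' @return Character vector of k gene ids, highest statistic first.
#' @export
top_k <- function(result, k) {
  if (k <= 0 || k > nrow(result)) {
    stop("k must be in 1..", nrow(result), call. = FALSE)
  }
  result$gene_id[seq_len(k)]
}

#' Plug-in mutual information between two sample vectors
#'
#' Continuous vectors are discretized by equal-frequency (quantile) binning;
#' factors/characters/integers with few distinct values are used as-is.
#' Mutual information is the plug-in estimate on the joint contingency
#' table, in nats. A vector that is constant after discretization yields 0.
#'
#' @param x,y Equal-length vectors (numeric, factor, or character).
#' @param bins Number of quantile bins for continuous vectors.
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(x, y, bins = 10L) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need >= 2 observations", call. = FALSE)
  dx <- discretize_vector(x, bins)
  dy <- discretize_vector(y, bins)
  tab <- table(dx, dy)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

discretize_vector <- function(v, bins) {
  if (is.factor(v) || is.character(v) || is.logical(v)) return(as.factor(v))
  u <- unique(v)
  if (length(u) <= bins) return(factor(v))
  qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) return(factor(rep(1L, length(v))))
  cut(v, breaks = qs, include.lowest = TRUE)
}

#' Greedy mRMR gene ranking
#'
#' Minimum-redundancy maximum-relevance selection: the first gene maximizes
#' relevance `I(x_j, c)` to the class; each later step adds the gene
#' maximizing, under the difference (MID) criterion,
#' `I(x_j, c) - (1/|S|) * sum over selected x_i of I(x_j, x_i)`,
#' or under the quotient (MIQ) criterion the ratio of the two terms.
#' Ties break by lexicographic gene id, so rankings are deterministic.
#'
#' @param matrix Gene x sample [omics_matrix()].
#' @param labels Class per sample.
#' @param m Number of genes to rank.
#' @param criterion `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @param bins Quantile bins for [mutual_information()].
#' @return Tibble of class `mrmr_ranking` with columns `rank`, `gene_id`,
#'   `relevance`, `redundancy`, `score`.
#' @export
mrmr_rank <- function(matrix, labels, m, criterion = c("MID", "MIQ"), bins = 10L) {
  criterion <- match.arg(criterion)
  x <- unclass(matrix)
  if (m <= 0) stop("m must be positive", call. = FALSE)
  if (m > nrow(x)) stop("m exceeds gene count", call. = FALSE)
  genes <- rownames(x)
  labels <- as.factor(labels)
  relevance <- vapply(seq_len(nrow(x)),
                      function(j) mutual_information(x[j, ], labels, bins),
                      numeric(1))
  names(relevance) <- genes
  selected <- character(0)
  red_sum <- stats::setNames(numeric(length(genes)), genes)
  rows <- vector("list", m)
  remaining <- genes
  for (step in seq_len(m)) {
    if (step == 1L) {
      red <- stats::setNames(numeric(length(remaining)), remaining)
      score <- relevance[remaining]
    } else {
      red <- red_sum[remaining] / length(selected)
      score <- if (criterion == "MID") relevance[remaining] - red
               else relevance[remaining] / (red + 1e-12)
    }
    best <- remaining[order(-score, remaining)][1L]
    rows[[step]] <- tibble::tibble(rank = step, gene_id = best,
                                   relevance = unname(relevance[best]),
                                   redundancy = unname(red[best]),
                                   score = unname(score[best]))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining)) {
      bi <- match(best, genes)
      add <- vapply(remaining, function(g) {
        mutual_information(x[match(g, genes), ], x[bi, ], bins)
      }, numeric(1))
      red_sum[remaining] <- red_sum[remaining] + add
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mrmr_ranking", class(out))
  out
}

#' Random-forest forward search over an mRMR ranking
#'
#' Evaluates the ranking prefixes of size 1..m with a seeded random forest
#' (100 trees) under stratified k-fold cross-validation and returns the
#' prefix with the highest mean accuracy (ties go to the smallest size).
#'
#' @param matrix Gene x sample [omics_matrix()].
#' @param labels Class per sample.
#' @param ranking An `mrmr_ranking` tibble (or character vector of gene ids).
#' @param folds Number of CV folds (>= 2).
#' @param seed Seed controlling fold assignment and forests.
#' @param num_trees Trees per forest.
#' @return List of class `forward_search_result` with `best_subset`,
#'   `chosen_size`, `best_accuracy` and a `score_path` tibble
#'   (`size`, `accuracy`).
#' @export
forward_search <- function(matrix, labels, ranking, folds = 5L, seed = 1L,
                           num_trees = 100L) {
  genes <- if (is.character(ranking)) ranking else ranking$gene_id
  if (!length(genes)) stop("empty ranking", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  labels <- as.factor(labels)
  if (min(table(labels)) < folds) {
    stop("a class has fewer samples than folds; reduce `folds`", call. = FALSE)
  }
  x <- t(unclass(matrix)[genes, , drop = FALSE])   # samples x genes
  fold_id <- stratified_folds(labels, folds, seed)
  acc <- vapply(seq_along(genes), function(size) {
    cv_accuracy(x[, seq_len(size), drop = FALSE], labels, fold_id, seed, num_trees)
  }, numeric(1))
  chosen <- which.max(acc)   # which.max returns the first (smallest) maximum
  out <- list(best_subset = genes[seq_len(chosen)],
              chosen_size = chosen,
              best_accuracy = acc[chosen],
              score_path = tibble::tibble(size = seq_along(genes), accuracy = acc))
  class(out) <- "forward_search_result"
  out
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(derive_seed(seed, "folds"))
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

cv_accuracy <- function(x, labels, fold_id, seed, num_trees) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    df_train <- data.frame(x[!test, , drop = FALSE], .y = labels[!test])
    fit <- ranger::ranger(.y ~ ., data = df_train, num.trees = num_trees,
                          seed = derive_seed(seed, paste0("rf", f)),
                          num.threads = 1L)
    pred <- stats::predict(fit, data.frame(x[test, , drop = FALSE]),
                           num.threads = 1L)$predictions
    correct <- correct + sum(pred == labels[test])
  }
  correct / length(labels)
}

#' Hybrid feature selection for one omics layer
#'
#' Chains the chi-square ranker (top `top_k` cut), mRMR ranking and the
#' random-forest forward search, the hybrid selector applied per omic.
#'
#' @param matrix Gene x sample [omics_matrix()].
#' @param labels Class per sample.
#' @param top_k Ranker cut size.
#' @param max_subset Maximum wrapper subset size.
#' @inheritParams forward_search
#' @param bins Quantile bins for mutual information.
#' @param shift Passed to [chi_square_scores()] (needed for signed layers).
#' @return `forward_search_result` with the chi-square table and mRMR ranking
#'   attached as `chi_square` / `mrmr` elements.
#' @export
select_features <- function(matrix, labels, top_k = 1000L, max_subset = 30L,
                            folds = 5L, seed = 1L, bins = 10L, shift = FALSE) {
  chi <- chi_square_scores(matrix, labels, shift = shift)
  kk <- min(top_k, nrow(chi))
  kept <- top_k(chi, kk)
  sub <- unclass(matrix)[kept, , drop = FALSE]
  ranking <- mrmr_rank(omics_matrix(sub, omic_name = attr(matrix, "omic_name")),
                       labels, m = min(max_subset, nrow(sub)), bins = bins)
  fs <- forward_search(matrix, labels, ranking, folds = folds, seed = seed)
  fs$chi_square <- chi
  fs$mrmr <- ranking
  fs
}

#' @export
print.forward_search_result <- function(x, ...) {
  cat("<forward_search_result> chosen size ", x$chosen_size,
      " (CV accuracy ", sprintf("%.3f", x$best_accuracy), ")\n", sep = "")
  cat("genes:", paste(x$best_subset, collapse = ", "), "\n")
  invisible(x)
}

#' @export
autoplot.forward_search_result <- function(object, ...) {
  ggplot2::ggplot(object$score_path,
                  ggplot2::aes(x = .data$size, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_size, linetype = 2) +
    ggplot2::labs(x = "Subset size (ranking prefix)",
                  y = "Cross-validated accuracy") +
    ggplot2::theme_minimal()
}
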
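test_that("chi-square scores match hand-evaluated class sums", {
  x <- tiny_omics(c(2, 1, 2, 1, 0, 1, 0, 1), genes = c("gA", "gB"),
                  samples = paste0("s", 1:4))
  res <- chi_square_scores(x, c("A", "A", "B", "B"))
  # gA: O = (4, 0), E = (2, 2) -> (4-2)^2/2 + (0-2)^2/2 = 4
  expect_equal(res$chi_value[res$gene_id == "gA"], 4)
  # constant gene with equal class sizes: O == E
  expect_equal(res$chi_value[res$gene_id == "gB"], 0)
})

test_that("chi-square agrees with an independent loop transcription", {
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    x <- matrix(rexp(30 * 12), 30, 12,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
    labels <- sample(LETTERS[1:k], 12, replace = TRUE)
    while (length(unique(labels)) < k) labels <- sample(LETTERS[1:k], 12, TRUE)
    ref <- chi_square_reference(x, labels)
    res <- chi_square_scores(omics_matrix(x), labels)
    expect_lt(max(abs(res$chi_value[match(rownames(x), res$gene_id)] - ref)), 1e-9)
    # mass conservation: sum of observed == sum of expected per gene
    O <- attr(res, "observed"); E <- attr(res, "expected")
    expect_lt(max(abs(rowSums(O) - rowSums(E))), 1e-9)
  }
})

test_that("all-zero genes are flagged degenerate with score 0", {
  x <- tiny_omics(c(0, 1, 0, 2, 0, 3, 0, 4), genes = c("gz", "gk"),
                  samples = paste0("s", 1:4))
  res <- chi_square_scores(x, c("A", "A", "B", "B"))
  expect_equal(res$chi_value[res$gene_id == "gz"], 0)
  expect_true(res$degenerate[res$gene_id == "gz"])
  expect_false(res$degenerate[res$gene_id == "gk"])
})

test_that("negative values are rejected unless shifted", {
  x <- tiny_omics(c(-1, 0, 1, 2), genes = c("g1", "g2"), samples = c("s1", "s2"))
  expect_error(chi_square_scores(x, c("A", "B")), "non-negative")
  expect_no_error(chi_square_scores(x, c("A", "B"), shift = TRUE))
})

test_that("top_k sorts by score with lexicographic tie-breaks", {
  x <- tiny_omics(c(2, 0, 1, 1, 2, 0, 1, 1, 0, 2, 1, 1),
                  genes = c("g1", "g3", "g2"), samples = paste0("s", 1:4))
  res <- chi_square_scores(x, c("A", "A", "B", "B"))
  expect_identical(top_k(res, 2), res$gene_id[1:2])
  expect_identical(top_k(res, 3), res$gene_id)
  expect_error(top_k(res, 4), "k must be")
  # equal scores order lexicographically
  ties <- res[res$chi_value == res$chi_value[2], ]
  expect_identical(ties$gene_id, sort(ties$gene_id))
})

test_that("mutual information matches closed forms and is symmetric", {
  v <- rep(c(0, 1), 60)
  expect_equal(mutual_information(v, v), log(2), tolerance = 1e-12)
  expect_equal(mutual_information(v, rep(1, 120)), 0)

  set.seed(12)
  x <- rnorm(300)
  y_ind <- sample(rep(letters[1:3], 100))
  expect_lt(mutual_information(x, y_ind), 0.06)  # estimator bias only

  for (i in 1:5) {
    a <- rnorm(80); b <- rnorm(80)
    expect_equal(mutual_information(a, b), mutual_information(b, a),
                 tolerance = 1e-12)
  }
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mRMR defers redundant copies behind independent informative genes", {
  set.seed(13)
  n <- 200
  cls <- rep(c("A", "B"), each = n / 2)
  g1 <- ifelse(cls == "A", 0, 1) + rnorm(n, sd = 0.05)
  g2 <- g1                               # exact copy: redundant
  g3 <- ifelse(cls == "A", 0, 1) + rnorm(n, sd = 0.4)  # informative, independent noise
  g4 <- rnorm(n)                         # noise
  x <- rbind(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
  colnames(x) <- sprintf("s%03d", 1:n)
  rk <- mrmr_rank(omics_matrix(x), cls, m = 4)
  expect_identical(rk$gene_id[1], "g1")  # ties broken lexicographically
  expect_lt(which(rk$gene_id == "g3"), which(rk$gene_id == "g2"))

  # m = 1 reduces to pure relevance ranking
  rk1 <- mrmr_rank(omics_matrix(x), cls, m = 1)
  rel <- vapply(rownames(x), function(g) mutual_information(x[g, ], cls),
                numeric(1))
  expect_identical(rk1$gene_id, names(which.max(rel)))
})

test_that("mRMR is deterministic on pure noise", {
  set.seed(14)
  x <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40)))
  cls <- rep(c("A", "B"), 20)
  r1 <- mrmr_rank(omics_matrix(x), cls, m = 10)
  r2 <- mrmr_rank(omics_matrix(x), cls, m = 10)
  expect_identical(r1$gene_id, r2$gene_id)
})

test_that("forward search finds a single perfectly separating gene", {
  set.seed(15)
  n <- 60
  cls <- rep(c("A", "B"), each = n / 2)
  x <- rbind(sep = ifelse(cls == "A", 0, 10) + rnorm(n, sd = 0.1),
             n1 = rnorm(n), n2 = rnorm(n))
  colnames(x) <- sprintf("s%02d", 1:n)
  fs <- forward_search(omics_matrix(x), cls, c("sep", "n1", "n2"),
                       folds = 3, seed = 1)
  expect_equal(fs$chosen_size, 1L)
  expect_identical(fs$best_subset, "sep")
  expect_equal(nrow(fs$score_path), 3L)
  expect_gte(fs$best_accuracy, 0.95)
})

test_that("forward search validates folds against class sizes", {
  x <- tiny_omics(runif(8), genes = c("g1", "g2"), samples = paste0("s", 1:4))
  expect_error(forward_search(x, c("A", "A", "A", "B"), c("g1"), folds = 2),
               "fewer samples than folds")
})
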
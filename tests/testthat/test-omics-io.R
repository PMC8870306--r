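test_that("write/read round-trip is the identity on valid matrices", {
  set.seed(1)
  m <- tiny_omics(runif(6), genes = c("TP53", "BRCA1", "RAD21"),
                  samples = c("s1", "s2"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, p)
  m2 <- read_omics_matrix(p)
  expect_identical(rownames(m2), rownames(m))
  expect_identical(colnames(m2), colnames(m))
  expect_lt(max(abs(unclass(m2) - unclass(m))), 1e-12)

  # 1x1 matrix with value 0.5 survives exactly
  one <- tiny_omics(0.5, genes = "G1", samples = "s1")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(one, p1)
  expect_equal(as.vector(read_omics_matrix(p1)[1, 1]), 0.5)
})

test_that("duplicate identifiers are rejected with the offender named", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "RAD21\t1\t2", "RAD21\t3\t4"), p)
  expect_error(read_omics_matrix(p), "RAD21")
  expect_error(omics_matrix(matrix(1:4, 2), c("a", "a"), c("s1", "s2")), "duplicate")
})

test_that("missing tokens parse as NA at the right coordinates", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "g1\t1\t2\t3", "g2\t4\tNA\t6", "g3\t7\t8\t9", "g4\t1\t1\t1"), p)
  m <- read_omics_matrix(p)
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["g2", "s2"]))
})

test_that("non-numeric cells and degenerate matrices are errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\toops"), p)
  expect_error(read_omics_matrix(p), "oops.*g1|g1.*oops")
  expect_error(omics_matrix(matrix(numeric(0), 0, 2)), "gene")
})

test_that("samples-in-rows orientation is transposed on read", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2", "s1\t1\t2", "s2\t3\t4"), p)
  m <- read_omics_matrix(p, orientation = "samples-in-rows")
  expect_identical(rownames(m), c("g1", "g2"))
  expect_equal(as.vector(m["g2", "s1"]), 2)
})

make_aligned_trio <- function(samples = c("A", "B", "C")) {
  set.seed(42)
  lapply(c("expression", "cna", "mrna"), function(nm) {
    tiny_omics(runif(3 * length(samples)), genes = paste0("g", 1:3),
               samples = samples, omic = nm)
  }) |> stats::setNames(c("expression", "cna", "mrna"))
}

clin3 <- tibble::tibble(sample_id = c("A", "B", "C"),
                        tumor_size_cm = c(2, 3, 1.5),
                        positive_nodes = c(0L, 2L, 5L),
                        grade = c(1L, 2L, 3L))

test_that("alignment drops samples with any missing omic or clinical value", {
  mats <- make_aligned_trio()
  mats$expression["g2", "B"] <- NA
  al <- align_complete_cases(mats, clin3)
  expect_identical(al$clinical$sample_id, c("A", "C"))
  for (m in al$matrices) expect_identical(colnames(m), c("A", "C"))
  expect_true(all(vapply(al$matrices, function(m) !anyNA(m), logical(1))))

  # no missing anywhere: alignment is the identity up to column order
  mats2 <- make_aligned_trio()
  al2 <- align_complete_cases(mats2, clin3)
  expect_identical(al2$clinical$sample_id, c("A", "B", "C"))
  expect_equal(unclass(al2$matrices$cna), unclass(mats2$cna)[, c("A", "B", "C")],
               ignore_attr = TRUE)
})

test_that("alignment errors on disjoint sample sets and orders output lexicographically", {
  mats <- make_aligned_trio()
  colnames(mats$mrna) <- c("X", "Y", "Z")
  expect_error(align_complete_cases(mats, clin3), "shared")

  mats2 <- make_aligned_trio(samples = c("C", "A", "B"))
  al <- align_complete_cases(mats2, clin3)
  expect_identical(al$clinical$sample_id, sort(al$clinical$sample_id))
})

test_that("alignment never keeps more samples than the smallest input", {
  set.seed(7)
  for (rep in 1:10) {
    samples <- paste0("S", 1:8)
    mats <- lapply(1:3, function(i) {
      m <- tiny_omics(runif(4 * 8), genes = paste0("g", 1:4), samples = samples)
      mask <- matrix(runif(32) < 0.1, 4, 8)
      m[mask] <- NA
      m
    })
    cl <- tibble::tibble(sample_id = samples, tumor_size_cm = runif(8, 1, 5),
                         positive_nodes = rpois(8, 2), grade = sample(1:3, 8, TRUE))
    al <- try(align_complete_cases(mats, cl), silent = TRUE)
    if (inherits(al, "try-error")) next
    expect_lte(nrow(al$clinical), 8)
    expect_true(all(vapply(al$matrices, function(m) !anyNA(m), logical(1))))
  }
})
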
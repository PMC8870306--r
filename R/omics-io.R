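#' Construct an omics matrix
#'
#' An omics matrix is a plain numeric matrix of genes (rows) by samples
#' (columns) carrying an `omic_name` attribute, the container shared by all
#' three layers handled here (gene expression, copy number alteration, mRNA).
#' Missing values (`NA`) are allowed on input and removed by
#' [align_complete_cases()].
#'
#' @param values Numeric matrix, genes in rows.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param sample_ids Character vector of unique sample identifiers (column
#'   names).
#' @param omic_name Label for the layer, e.g. `"expression"`, `"cna"`,
#'   `"mrna"`.
#' @return A numeric matrix of class `omics_matrix` with gene row names,
#'   sample column names, and an `omic_name` attribute.
#' @export
omics_matrix <- function(values, gene_ids = rownames(values),
                         sample_ids = colnames(values),
                         omic_name = "omic") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L) stop("omics matrix must contain >= 1 gene", call. = FALSE)
  if (ncol(values) == 0L) stop("omics matrix must contain >= 1 sample", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("`gene_ids` length (", length(gene_ids), ") != row count (",
         nrow(values), ")", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("`sample_ids` length (", length(sample_ids), ") != column count (",
         ncol(values), ")", call. = FALSE)
  }
  check_unique(gene_ids, "gene id")
  check_unique(sample_ids, "sample id")
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "omic_name") <- omic_name
  class(values) <- c("omics_matrix", class(values))
  values
}

check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup)) {
    stop("duplicate ", what, "(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("<omics_matrix> ", attr(x, "omic_name"), ": ",
      nrow(x), " genes x ", ncol(x), " samples, ",
      sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

# Tokens treated as missing in delimited omics files (cBioPortal-style).
MISSING_TOKENS <- c("", "NA", "NaN", "null")

#' Read an omics matrix from a delimited text file
#'
#' Expects a tab-separated file with identifiers in the first row and first
#' column (cBioPortal-style export). Blank, `NA`, `NaN` and `null` cells
#' become missing values.
#'
#' @param path File path.
#' @param orientation Either `"genes-in-rows"` (default; first column = gene
#'   ids, header = sample ids) or `"samples-in-rows"` (transposed on read).
#' @param omic_name Label attached to the returned matrix.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, orientation = c("genes-in-rows", "samples-in-rows"),
                              omic_name = "omic") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected at least one identifier and one data column", call. = FALSE)
  row_ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells %in% MISSING_TOKENS] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %d ('%s'), column %d ('%s') in %s",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], row_ids[bad[1, 1]],
                 bad[1, 2], colnames(cells)[bad[1, 2]], path), call. = FALSE)
  }
  dimnames(num) <- list(row_ids, colnames(cells))
  if (orientation == "samples-in-rows") num <- t(num)
  omics_matrix(num, omic_name = omic_name)
}

#' Write an omics matrix to a tab-separated file
#'
#' Values are written at full precision so that [read_omics_matrix()]
#' reproduces the matrix exactly (round-trip identity).
#'
#' @param matrix An [omics_matrix()] (or gene x sample numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(matrix, path) {
  if (is.null(rownames(matrix)) || nrow(matrix) == 0L) {
    stop("refusing to write a degenerate matrix (no genes)", call. = FALSE)
  }
  df <- data.frame(gene_id = rownames(matrix),
                   format(unclass(matrix), digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(matrix))
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' The clinical table is a tibble with one row per sample and columns
#' `sample_id`, `tumor_size_cm` (> 0), `positive_nodes` (integer >= 0),
#' `grade` (1, 2 or 3) and, optionally, `relapse_time_months` and
#' `relapse_event` for survival analysis.
#'
#' @param path File path (tab- or comma-separated, inferred from extension).
#' @return A validated tibble.
#' @export
read_clinical_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = MISSING_TOKENS)
  validate_clinical(tibble::as_tibble(df))
}

#' @rdname read_clinical_table
#' @param clinical A clinical tibble.
#' @export
write_clinical_table <- function(clinical, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(clinical, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_clinical <- function(clinical, require_complete = FALSE) {
  need <- c("sample_id", "tumor_size_cm", "positive_nodes", "grade")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  clinical$sample_id <- as.character(clinical$sample_id)
  check_unique(clinical$sample_id, "sample id")
  ok <- !is.na(clinical$grade)
  if (any(!clinical$grade[ok] %in% c(1L, 2L, 3L))) {
    stop("grade must be 1, 2 or 3", call. = FALSE)
  }
  if (any(clinical$tumor_size_cm[!is.na(clinical$tumor_size_cm)] <= 0)) {
    stop("tumor_size_cm must be positive", call. = FALSE)
  }
  if (any(clinical$positive_nodes[!is.na(clinical$positive_nodes)] < 0)) {
    stop("positive_nodes must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(clinical)
}

#' Restrict three omics layers and the clinical table to shared complete cases
#'
#' Keeps the intersection of sample ids across all four inputs, then drops
#' any sample with a missing value in any omic or a missing tumor size, node
#' count or grade. The retained samples are ordered lexicographically by
#' sample id in every output, so downstream stages see one consistent cohort.
#'
#' @param matrices List of three [omics_matrix()] objects.
#' @param clinical Clinical tibble (see [read_clinical_table()]).
#' @return A list with elements `matrices` (list of three complete-case
#'   matrices) and `clinical` (filtered tibble), samples aligned.
#' @export
align_complete_cases <- function(matrices, clinical) {
  stopifnot(is.list(matrices), length(matrices) == 3L)
  clinical <- validate_clinical(clinical)
  shared <- Reduce(intersect, c(lapply(matrices, colnames), list(clinical$sample_id)))
  if (!length(shared)) stop("no sample id shared by all omics layers and the clinical table", call. = FALSE)
  incomplete_omic <- unique(unlist(lapply(matrices, function(m) {
    sub <- m[, shared, drop = FALSE]
    shared[colSums(is.na(sub)) > 0]
  })))
  cl <- clinical[match(shared, clinical$sample_id), ]
  incomplete_clin <- cl$sample_id[is.na(cl$tumor_size_cm) | is.na(cl$positive_nodes) | is.na(cl$grade)]
  keep <- sort(setdiff(shared, union(incomplete_omic, incomplete_clin)))
  if (!length(keep)) stop("no complete-case sample remains after alignment", call. = FALSE)
  out_mats <- lapply(matrices, function(m) {
    omics_matrix(unclass(m)[, keep, drop = FALSE], omic_name = attr(m, "omic_name"))
  })
  names(out_mats) <- names(matrices)
  list(matrices = out_mats,
       clinical = clinical[match(keep, clinical$sample_id), ])
}
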
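#' Coerce to a beta-value matrix
#'
#' Methylation profiles are handled as numeric matrices with CpG identifiers
#' as row names and sample (or cell-type) identifiers as column names.
#' Data frames whose first column holds CpG identifiers (the layout of the
#' on-disk TSV format, see [read_beta_matrix()]) are converted to that form.
#'
#' @param x A numeric matrix with CpG row names, or a data frame whose first
#'   column contains CpG identifiers and whose remaining columns are numeric.
#' @param check If `TRUE`, values are required to lie in \[0, 1\].
#'
#' @return A numeric matrix (CpG x sample) with complete dimnames.
#' @export
as_beta_matrix <- function(x, check = TRUE) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
  } else {
    abort("`x` must be a matrix or a data frame.")
  }
  if (is.null(rownames(m))) abort("CpG identifiers (row names) are required.")
  if (is.null(colnames(m))) abort("Sample identifiers (column names) are required.")
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    abort(paste0("Duplicate CpG identifiers: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (check) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0(
        "Beta values must lie in [0, 1]; first offender: CpG '",
        rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]],
        "' (value ", format(m[bad[1, , drop = FALSE]]), ")."
      ))
    }
  }
  m
}

#' Convert a beta matrix to a tibble
#'
#' Inverse of [as_beta_matrix()]: the CpG identifiers become the first column.
#'
#' @param x A beta (or M-value) matrix.
#' @param id_col Name for the identifier column.
#' @return A tibble with one row per CpG.
#' @export
beta_as_tibble <- function(x, id_col = "CpG") {
  tibble::as_tibble(x, rownames = id_col)
}

#' Beta-value / M-value transforms
#'
#' The M-value is the log2 odds of methylation, `M = log2(b / (1 - b))`.
#' Betas are clipped into `[eps, 1 - eps]` before the transform so that fully
#' (un)methylated CpGs map to finite M-values. `m_to_beta()` is the exact
#' inverse on the clipped range: `b = 2^M / (1 + 2^M)`.
#'
#' @param beta,m Numeric vector or matrix (dimnames preserved).
#' @param eps Clipping constant in (0, 0.5). Default `1e-6`.
#'
#' @return An object of the same shape on the other scale.
#' @examples
#' beta_to_m(c(0.5, 0.8))      # 0, 2
#' m_to_beta(beta_to_m(0.37))  # 0.37
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(is.numeric(eps), length(eps) == 1, eps > 0, eps < 0.5)
  if (any(!is.finite(beta))) {
    idx <- which(!is.finite(beta), arr.ind = is.matrix(beta))
    loc <- if (is.matrix(beta)) {
      paste0("CpG '", rownames(beta)[idx[1, 1]], "', sample '", colnames(beta)[idx[1, 2]], "'")
    } else paste0("position ", idx[1])
    abort(paste0("Non-finite beta value at ", loc, "."))
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) abort("M-values must be finite.")
  1 / (1 + 2^(-m))
}

#' Read / write beta-value matrices
#'
#' Tab-separated (`.tsv`, `.txt`) or comma-separated (`.csv`) files with a
#' header row of sample identifiers and a first column of CpG identifiers
#' (conventionally headed `CpG`). Rows containing missing values are dropped
#' with a message; the number dropped is attached as attribute `n_dropped`.
#'
#' @param path File path; the delimiter is chosen from the extension.
#' @return For `read_beta_matrix()`, a beta matrix (see [as_beta_matrix()]).
#' @export
read_beta_matrix <- function(path) {
  df <- read_delim_auto(path)
  n0 <- nrow(df)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (n_dropped > 0) {
    inform(paste0("Dropped ", n_dropped, " CpG row(s) with missing values."))
  }
  m <- as_beta_matrix(df)
  attr(m, "n_dropped") <- n_dropped
  m
}

#' @rdname read_beta_matrix
#' @param x Beta matrix (or data frame accepted by [as_beta_matrix()]).
#' @export
write_beta_matrix <- function(x, path) {
  x <- as_beta_matrix(x, check = FALSE)
  df <- beta_as_tibble(x)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read a CpG genomic position table
#'
#' TSV with columns `CpG`, `chrom`, `pos` (1-based coordinate of the cytosine).
#'
#' @param path File path.
#' @return A tibble with columns `CpG`, `chrom`, `pos`.
#' @export
read_cpg_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1:3] <- c("CpG", "chrom", "pos")
  if (any(df$pos < 1)) abort("CpG positions are 1-based and must be >= 1.")
  if (anyDuplicated(df$CpG)) abort("Duplicate CpG identifiers in the position table.")
  tibble::as_tibble(df[, c("CpG", "chrom", "pos")])
}
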
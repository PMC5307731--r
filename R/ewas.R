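#' Per-CpG association of methylation with a phenotype
#'
#' Fits, for every CpG, the linear model
#' `beta ~ phenotype + covariates (+ cell fractions)` and reports the
#' phenotype coefficient with its ordinary-least-squares two-sided t-test.
#' When cell fractions are supplied and sum to ~1 across cell types, one
#' cell type must be dropped to keep the design full rank alongside the
#' intercept; by default the cell type with the smallest mean fraction is
#' dropped (typically the one whose weights are effectively zero). Fits are
#' vectorised across CpGs via [limma::lmFit()]; no variance moderation is
#' applied here.
#'
#' @param beta Beta matrix (CpG x sample).
#' @param pheno Tibble with a `sample` column, a `phenotype` column (ordinal
#'   coded as numeric, e.g. 0 = never, 1 = former, 2 = current smoker) and
#'   optionally further covariate columns (character/factor columns enter as
#'   factors).
#' @param fractions Optional `cell_fractions` tibble to adjust for.
#' @param drop_celltypes Cell types to exclude from the covariate set;
#'   `NULL` applies the smallest-mean-fraction rule when needed.
#' @return A tibble of class `ewas_result`: `CpG`, `estimate` (beta units
#'   per phenotype unit), `std_error`, `statistic`, `p_value`, `q_value`
#'   (BH over all tested CpGs).
#' @export
fit_ewas <- function(beta, pheno, fractions = NULL, drop_celltypes = NULL) {
  beta <- as_beta_matrix(beta, check = FALSE)
  stopifnot(all(c("sample", "phenotype") %in% names(pheno)))
  if (nrow(pheno) < 10) abort("At least 10 samples are required.")
  if (!setequal(colnames(beta), pheno$sample)) {
    abort("Samples of `beta` and `pheno` do not match.")
  }
  pheno <- pheno[match(colnames(beta), pheno$sample), ]

  covars <- pheno[, setdiff(names(pheno), c("sample", "phenotype")), drop = FALSE]
  design_df <- data.frame(phenotype = as.numeric(pheno$phenotype))
  for (nm in names(covars)) {
    v <- covars[[nm]]
    design_df[[nm]] <- if (is.character(v)) factor(v) else v
  }

  if (!is.null(fractions)) {
    W <- fractions_as_matrix(fractions)
    W <- W[colnames(beta), , drop = FALSE]
    keep <- colnames(W)
    if (!is.null(drop_celltypes)) {
      keep <- setdiff(keep, drop_celltypes)
    } else if (max(abs(rowSums(W) - 1)) < 1e-6) {
      drop <- colnames(W)[which.min(colMeans(W))]
      inform(paste0("Fractions sum to 1; dropping cell type '", drop,
                    "' (smallest mean fraction) from the covariates."))
      keep <- setdiff(keep, drop)
    }
    for (ct in keep) design_df[[make.names(ct)]] <- W[, ct]
  }

  design <- stats::model.matrix(~ ., data = design_df)
  if (qr(design)$rank < ncol(design)) {
    abort(paste0("Design matrix is rank deficient; drop a cell-type ",
                 "covariate (see `drop_celltypes`)."))
  }
  fit <- limma::lmFit(beta, design)
  i <- which(colnames(design) == "phenotype")
  est <- fit$coefficients[, i]
  se <- fit$stdev.unscaled[, i] * fit$sigma
  tt <- est / se
  p <- 2 * pt(-abs(tt), df = fit$df.residual)
  out <- tibble::tibble(
    CpG = rownames(beta), estimate = unname(est), std_error = unname(se),
    statistic = unname(tt), p_value = unname(p), q_value = bh_fdr(unname(p))
  )
  structure(out, class = c("ewas_result", class(out)),
            n_samples = ncol(beta), adjusted = !is.null(fractions))
}

#' CpGs significant at an FDR threshold
#'
#' @param result An `ewas_result` tibble from [fit_ewas()].
#' @param fdr q-value threshold (default 0.05).
#' @return Character vector of CpG identifiers with `q < fdr`.
#' @export
call_dmcs <- function(result, fdr = 0.05) {
  result$CpG[result$q_value < fdr]
}

#' Read a gold-standard CpG list
#'
#' Plain text, one CpG identifier per line.
#'
#' @param path File path.
#' @return Character vector of CpG identifiers.
#' @export
read_cpg_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x[nzchar(trimws(x))]
}

#' Sensitivity, specificity and empirical FDR of a call set
#'
#' Scored against disjoint gold-standard true-positive and true-negative
#' CpG sets: sensitivity is the fraction of true positives among the calls,
#' specificity is one minus the fraction of the true-negative set called,
#' and the empirical FDR is the fraction of calls that are known true
#' negatives (0 when there are no calls).
#'
#' @param calls Character vector of called CpGs.
#' @param true_positives,true_negatives Disjoint character vectors of
#'   gold-standard CpGs (both non-empty).
#' @return A one-row tibble: `n_calls`, `tp_found`, `fp_found`,
#'   `sensitivity`, `specificity`, `empirical_fdr`.
#' @export
score_calls <- function(calls, true_positives, true_negatives) {
  if (length(true_positives) == 0 || length(true_negatives) == 0) {
    abort("Gold-standard sets must be non-empty.")
  }
  if (length(intersect(true_positives, true_negatives)) > 0) {
    abort("True-positive and true-negative sets must be disjoint.")
  }
  calls <- unique(calls)
  tp_found <- length(intersect(calls, true_positives))
  fp_found <- length(intersect(calls, true_negatives))
  tibble::tibble(
    n_calls = length(calls),
    tp_found = tp_found,
    fp_found = fp_found,
    sensitivity = tp_found / length(true_positives),
    specificity = 1 - fp_found / length(true_negatives),
    empirical_fdr = if (length(calls) > 0) fp_found / length(calls) else 0
  )
}
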
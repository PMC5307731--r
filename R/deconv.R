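#' Deconvolution configuration
#'
#' @param method One of `"lr"` (ordinary least squares), `"rpc"` (robust
#'   Huber regression, iteratively reweighted least squares), `"svr"`
#'   (linear-kernel nu-support-vector regression) or `"cp"` (constrained
#'   projection by quadratic programming).
#' @param huber_c Huber tuning constant for `rpc`; 1.345 gives 95% efficiency
#'   at the Gaussian model.
#' @param rpc_max_iter,rpc_tol IRLS iteration cap and convergence tolerance
#'   (maximum absolute coefficient change).
#' @param svr_nu Grid of nu values; the fit with the smallest RMSE between
#'   fitted and observed methylation is kept.
#' @return A list of class `deconv_config`.
#' @export
deconv_config <- function(method = c("rpc", "lr", "svr", "cp"),
                          huber_c = 1.345, rpc_max_iter = 50L,
                          rpc_tol = 1e-6, svr_nu = c(0.25, 0.5, 0.75)) {
  method <- match.arg(method)
  stopifnot(huber_c > 0, rpc_max_iter >= 1, rpc_tol > 0,
            all(svr_nu > 0 & svr_nu < 1))
  structure(
    list(method = method, huber_c = huber_c, rpc_max_iter = as.integer(rpc_max_iter),
         rpc_tol = rpc_tol, svr_nu = svr_nu),
    class = "deconv_config"
  )
}

check_reference_rank <- function(B) {
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    dropped <- colnames(B)[qrB$pivot[seq(qrB$rank + 1, ncol(B))]]
    abort(paste0("Reference matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  invisible(B)
}

#' Unconstrained weight estimators (single sample)
#'
#' Each solves, in its own sense, `y ~ B w` with no intercept (the mixture
#' model has none) and returns the raw coefficient vector; simplex
#' constraints are applied afterwards by [project_to_simplex()].
#'
#' * `estimate_lr()`: ordinary least squares.
#' * `estimate_rpc()`: Huber M-estimator by IRLS, initialised at the OLS
#'   solution. Residual scale is `median(|r|) / 0.6745`, re-estimated each
#'   iteration; observation weight is 1 for `|r| <= c * scale`, else
#'   `c * scale / |r|`.
#' * `estimate_svr()`: linear-kernel nu-SVR (via \pkg{e1071}), fitted
#'   unstandardised on the beta scale once per nu on the grid; the fit with
#'   the lowest RMSE against `y` is kept and its primal coefficient vector
#'   returned (the offset is not part of the reported weights).
#'
#' @param y Numeric vector: one sample's beta values over the reference CpGs.
#' @param B Reference matrix (CpG x cell type), full column rank.
#' @param config A [deconv_config()].
#' @return Named numeric vector of raw (unconstrained) weights.
#' @export
estimate_lr <- function(y, B) {
  check_reference_rank(B)
  fit <- lm.fit(B, y)
  setNames(coef(fit), colnames(B))
}

#' @rdname estimate_lr
#' @export
estimate_rpc <- function(y, B, config = deconv_config("rpc")) {
  w <- estimate_lr(y, B)
  cc <- config$huber_c
  for (it in seq_len(config$rpc_max_iter)) {
    r <- y - as.numeric(B %*% w)
    scale <- median(abs(r)) / 0.6745
    if (scale <= .Machine$double.eps) {
      if (max(abs(r)) > 1e-8) warn("Residual MAD is zero; returning current iterate.")
      break
    }
    a <- abs(r) / scale
    wt <- ifelse(a <= cc, 1, cc / a)
    w_new <- setNames(coef(lm.wfit(B, y, wt)), colnames(B))
    if (max(abs(w_new - w)) < config$rpc_tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w
}

#' @rdname estimate_lr
#' @export
estimate_svr <- function(y, B, config = deconv_config("svr")) {
  check_reference_rank(B)
  fits <- lapply(config$svr_nu, function(nu) {
    tryCatch(
      e1071::svm(x = B, y = y, type = "nu-regression", kernel = "linear",
                 nu = nu, scale = FALSE),
      error = function(e) {
        warn(paste0("nu-SVR failed at nu = ", nu, ": ", conditionMessage(e)))
        NULL
      }
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("nu-SVR failed for every nu on the grid.")
  rmse <- vapply(fits[ok], function(f) sqrt(mean((y - stats::fitted(f))^2)),
                 numeric(1))
  best <- fits[ok][[which.min(rmse)]]
  w <- as.numeric(t(best$coefs) %*% best$SV)
  setNames(w, colnames(B))
}

#' Constrained projection (quadratic programming)
#'
#' Minimises `||y - B w||^2` subject to `w >= 0` and `sum(w) <= 1` (the
#' normalisation as an inequality). The feasible set always contains the
#' origin, so the program is feasible by construction.
#'
#' @inheritParams estimate_lr
#' @return Named numeric vector of weights satisfying the constraints.
#' @export
estimate_cp <- function(y, B) {
  check_reference_rank(B)
  C <- ncol(B)
  H <- crossprod(B)
  d <- as.numeric(-crossprod(B, y))
  sol <- tryCatch(
    pracma::quadprog(C = H, d = d, A = matrix(1, 1, C), b = 1, lb = rep(0, C)),
    error = function(e) abort(paste0("Quadratic program failed: ", conditionMessage(e)))
  )
  w <- pmax(sol$xmin, 0)  # round-off guard; active-set solution is feasible
  setNames(w, colnames(B))
}

#' A-posteriori simplex constraints
#'
#' Negative raw weights are set to zero and the remaining positive weights
#' rescaled to sum to exactly 1. If no weight is positive an all-zero vector
#' is returned (flagged by attribute `degenerate`).
#'
#' @param w Raw weight vector.
#' @return Constrained weight vector (non-negative, summing to 1 or to 0 in
#'   the degenerate case).
#' @export
project_to_simplex <- function(w) {
  w <- pmax(w, 0)
  s <- sum(w)
  if (s <= 0) {
    warn("All raw weights non-positive; returning an all-zero row.")
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  w / s
}

#' Estimate cell-type fractions for every sample
#'
#' Models each sample's methylation profile as a non-negative combination of
#' the reference centroids over the CpGs shared between mixture and
#' reference. Weights from the unconstrained methods (`lr`, `rpc`, `svr`)
#' are passed through [project_to_simplex()]; `cp` builds the constraints
#' into the optimisation.
#'
#' @param mix Mixture beta matrix, or data frame accepted by
#'   [as_beta_matrix()].
#' @param ref Reference matrix (CpG x cell type).
#' @param method,config Either a method name (see [deconv_config()]) or a
#'   full config object.
#' @return A tibble of class `cell_fractions`: column `sample` followed by
#'   one column of fractions per cell type. Attributes `method` and
#'   `n_shared_cpgs` record the fit.
#' @examples
#' ref <- matrix(c(0.9, 0.1, 0.2, 0.1, 0.9, 0.6), 3, 2,
#'               dimnames = list(paste0("cg", 1:3), c("A", "B")))
#' mix <- ref %*% cbind(s1 = c(0.3, 0.7))
#' deconvolve(mix, ref, method = "rpc")
#' @export
deconvolve <- function(mix, ref, method = "rpc",
                       config = deconv_config(method)) {
  mix <- as_beta_matrix(mix, check = FALSE)
  ref <- as_beta_matrix(ref, check = FALSE)
  shared <- intersect(rownames(ref), rownames(mix))
  if (length(shared) < ncol(ref)) {
    abort(paste0("Only ", length(shared), " CpG(s) shared between mixture and ",
                 "reference; need at least ", ncol(ref), "."))
  }
  inform(paste0("Deconvolving over ", length(shared), " shared CpG(s)."))
  B <- ref[shared, , drop = FALSE]
  Y <- mix[shared, , drop = FALSE]
  est_one <- switch(config$method,
    lr  = function(y) project_to_simplex(estimate_lr(y, B)),
    rpc = function(y) project_to_simplex(estimate_rpc(y, B, config)),
    svr = function(y) project_to_simplex(estimate_svr(y, B, config)),
    cp  = function(y) estimate_cp(y, B)
  )
  W <- t(apply(Y, 2, est_one))
  out <- tibble::as_tibble(W)
  out <- dplyr::bind_cols(tibble::tibble(sample = colnames(Y)), out)
  structure(out,
            class = c("cell_fractions", class(out)),
            method = config$method,
            n_shared_cpgs = length(shared))
}

#' Convert a cell-fraction tibble to a matrix
#'
#' @param x A `cell_fractions` tibble (or any tibble with a `sample` column
#'   followed by numeric cell-type columns).
#' @return Numeric matrix, samples as rows.
#' @export
fractions_as_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "sample"), drop = FALSE])
  rownames(m) <- x$sample
  m
}
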
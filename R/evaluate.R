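#' Score estimated against true cell fractions
#'
#' Per cell type, over samples: root mean square error and squared Pearson
#' correlation between estimated and true weights. R-squared of a constant
#' vector is defined as 0 so that averages over cell types stay computable;
#' with fewer than 2 samples it is reported as `NA`.
#'
#' @param est Estimated fractions (`cell_fractions` tibble or compatible).
#' @param truth True weights (`mixture_truth` tibble or compatible).
#' @return A tibble of class `eval_report`: one row per cell type plus an
#'   `"average"` row (unweighted means over cell types), columns
#'   `cell_type`, `rmse`, `r2`.
#' @export
score_fractions <- function(est, truth) {
  E <- fractions_as_matrix(est)
  W <- fractions_as_matrix(truth)
  if (!setequal(rownames(E), rownames(W)) || !setequal(colnames(E), colnames(W))) {
    abort("`est` and `truth` must cover the same samples and cell types.")
  }
  E <- E[rownames(W), colnames(W), drop = FALSE]
  n <- nrow(W)
  per_type <- purrr::map_dfr(colnames(W), function(ct) {
    e <- E[, ct]; w <- W[, ct]
    rmse <- sqrt(mean((e - w)^2))
    r2 <- if (n < 2) {
      NA_real_
    } else if (sd(e) == 0 || sd(w) == 0) {
      0
    } else {
      cor(e, w)^2
    }
    tibble::tibble(cell_type = ct, rmse = rmse, r2 = r2)
  })
  avg <- tibble::tibble(
    cell_type = "average",
    rmse = mean(per_type$rmse),
    r2 = mean(per_type$r2)
  )
  out <- dplyr::bind_rows(per_type, avg)
  structure(out, class = c("eval_report", class(out)), n_samples = n)
}

#' Average RMSE / R-squared of an evaluation report
#'
#' @param report An `eval_report` from [score_fractions()].
#' @return Named numeric vector `c(rmse, r2)`.
#' @export
average_scores <- function(report) {
  avg <- report[report$cell_type == "average", ]
  c(rmse = avg$rmse, r2 = avg$r2)
}

#' In-silico mixture benchmark over methods, noise levels and runs
#'
#' For each Monte-Carlo run, fresh normalised-uniform mixture weights are
#' drawn and applied to `profiles` (the held-out study's cell-type
#' profiles); Gaussian noise of each requested SD is added on the M scale;
#' and every method is applied to the identical noisy data and scored
#' against the true weights. Per-run seeds are derived deterministically
#' from `seed`, so the full grid is reproducible.
#'
#' @param ref Reference matrix used for deconvolution.
#' @param profiles Cell-type profiles the mixtures are built from (same cell
#'   types as `ref`; typically from an independent study).
#' @param methods Character vector of method names (see [deconv_config()]).
#' @param n_mixtures Mixtures per run (default 100).
#' @param n_runs Monte-Carlo runs (default 25).
#' @param noise_sds Noise grid on the M scale (default 0:6).
#' @param seed Master seed.
#' @return A tibble of class `benchmark_report`, long format: one row per
#'   (method, noise SD, run, cell type or `"average"`) with `rmse`, `r2`
#'   and an `error` column (`NA` unless that method failed on that cell).
#' @export
run_benchmark <- function(ref, profiles, methods = c("lr", "rpc", "svr", "cp"),
                          n_mixtures = 100, n_runs = 25, noise_sds = 0:6,
                          seed = 1L) {
  ref <- as_beta_matrix(ref, check = FALSE)
  profiles <- as_beta_matrix(profiles, check = FALSE)
  rows <- purrr::map_dfr(seq_len(n_runs), function(run) {
    set.seed(derive_seed(seed, run))
    truth <- sample_simplex_weights(n_mixtures, colnames(profiles))
    mix <- make_mixtures(profiles, truth)
    purrr::map_dfr(noise_sds, function(nsd) {
      noisy <- add_mspace_noise(mix, sd = nsd)
      purrr::map_dfr(methods, function(mth) {
        res <- tryCatch(
          {
            est <- suppressMessages(deconvolve(noisy, ref, method = mth))
            scores <- score_fractions(est, truth)
            dplyr::mutate(tibble::as_tibble(scores), error = NA_character_)
          },
          error = function(e) {
            tibble::tibble(cell_type = "average", rmse = NA_real_,
                           r2 = NA_real_, error = conditionMessage(e))
          }
        )
        dplyr::mutate(res, method = mth, noise_sd = nsd, run = run,
                      .before = 1)
      })
    })
  })
  structure(rows,
            class = c("benchmark_report", class(rows)),
            n_mixtures = n_mixtures, n_runs = n_runs, seed = seed)
}

derive_seed <- function(seed, run) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(run)
}

#' Paired one-tailed Wilcoxon signed-rank test
#'
#' Compares two methods' run-level scores. Zero differences are dropped; the
#' exact null distribution is used when there are no ties, mid-ranks with a
#' normal approximation otherwise (the [stats::wilcox.test()] conventions).
#' If every difference is zero the test is degenerate and p = 1 is returned
#' with a warning.
#'
#' @param a,b Equal-length numeric vectors of paired scores (length >= 5).
#' @param alternative `"greater"` tests whether `a` tends to exceed `b`;
#'   `"less"` the reverse.
#' @return A single p-value.
#' @export
paired_wilcoxon_one_tailed <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warn("All paired differences are zero; returning p = 1.")
    return(1)
  }
  suppressWarnings(
    wilcox.test(d, mu = 0, alternative = alternative)$p.value
  )
}
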
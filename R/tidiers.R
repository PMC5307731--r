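#' Tidy a cell-fractions table into long format
#'
#' @param x A `cell_fractions` tibble from [deconvolve()].
#' @param ... Unused.
#' @return A tibble with columns `sample`, `cell_type`, `fraction`.
#' @method tidy cell_fractions
#' @export
tidy.cell_fractions <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"sample",
                      names_to = "cell_type", values_to = "fraction")
}

#' One-row summary of a deconvolution fit
#'
#' @inheritParams tidy.cell_fractions
#' @return A tibble with `method`, `n_samples`, `n_cell_types`,
#'   `n_shared_cpgs`, `mean_row_sum`.
#' @method glance cell_fractions
#' @export
glance.cell_fractions <- function(x, ...) {
  W <- fractions_as_matrix(x)
  tibble::tibble(
    method = attr(x, "method") %||% NA_character_,
    n_samples = nrow(W),
    n_cell_types = ncol(W),
    n_shared_cpgs = attr(x, "n_shared_cpgs") %||% NA_integer_,
    mean_row_sum = mean(rowSums(W))
  )
}

#' @method tidy mixture_truth
#' @export
tidy.mixture_truth <- tidy.cell_fractions

#' One-row summary of an association scan
#'
#' @param x An `ewas_result` from [fit_ewas()].
#' @param fdr Threshold used to count significant CpGs.
#' @param ... Unused.
#' @return A tibble with `n_cpgs`, `n_samples`, `adjusted`, `n_significant`,
#'   `lambda` (genomic inflation factor, median chi-squared ratio).
#' @method glance ewas_result
#' @export
glance.ewas_result <- function(x, fdr = 0.05, ...) {
  chisq <- stats::qchisq(1 - x$p_value, df = 1)
  tibble::tibble(
    n_cpgs = nrow(x),
    n_samples = attr(x, "n_samples") %||% NA_integer_,
    adjusted = attr(x, "adjusted") %||% NA,
    n_significant = sum(x$q_value < fdr),
    lambda = median(chisq) / stats::qchisq(0.5, df = 1)
  )
}

#' Run-level average scores of a benchmark
#'
#' @param x A `benchmark_report` from [run_benchmark()].
#' @param ... Unused.
#' @return The `"average"` rows only: one per (method, noise SD, run).
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) {
  out <- dplyr::filter(tibble::as_tibble(x), .data$cell_type == "average")
  dplyr::select(out, "method", "noise_sd", "run", "rmse", "r2")
}

#' Grid summary of a benchmark
#'
#' @inheritParams tidy.benchmark_report
#' @return One row per (method, noise SD): mean and SD of the run-level
#'   average RMSE and R-squared.
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tidy.benchmark_report(x) |>
    dplyr::group_by(.data$method, .data$noise_sd) |>
    dplyr::summarise(
      mean_rmse = mean(.data$rmse, na.rm = TRUE),
      sd_rmse = sd(.data$rmse, na.rm = TRUE),
      mean_r2 = mean(.data$r2, na.rm = TRUE),
      sd_r2 = sd(.data$r2, na.rm = TRUE),
      .groups = "drop"
    )
}
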
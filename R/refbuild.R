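#' Moderated t-test of one cell type against the rest
#'
#' Two-group comparison of each CpG between the target cell type and all
#' remaining samples pooled, with empirical-Bayes variance shrinkage: the
#' per-CpG pooled residual variance `s^2` (d residual df) is shrunk towards a
#' prior `(d0, s0^2)` fitted by moment matching on log variances across CpGs
#' (via [limma::squeezeVar()]), giving
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and a t-statistic on `d0 + d` df.
#' Effect sizes (`delta`) stay on the beta scale.
#'
#' @param beta Beta matrix of purified samples (see [as_beta_matrix()]).
#' @param cell_type_of_sample Named character vector mapping every sample
#'   (column of `beta`) to its cell-type label.
#' @param target Target cell-type label.
#' @param prior_df Overrides the estimated prior degrees of freedom `d0`:
#'   `0` gives the ordinary pooled t-test, `Inf` full shrinkage to `s0^2`.
#'   Default `NULL` estimates `d0` from the data.
#' @return A tibble (one row per CpG): `CpG`, `cell_type`, `mean_target`,
#'   `mean_rest`, `delta`, `t`, `p`, `q` (BH-adjusted), `in_dhs` (initialised
#'   `NA`, see [filter_to_dhs()]).
#' @export
moderated_t_one_vs_rest <- function(beta, cell_type_of_sample, target,
                                    prior_df = NULL) {
  beta <- as_beta_matrix(beta)
  labels <- check_labels(beta, cell_type_of_sample)
  if (!target %in% labels) abort(paste0("No samples labelled '", target, "'."))
  grp1 <- which(labels == target)
  grp2 <- which(labels != target)
  n1 <- length(grp1); n2 <- length(grp2)
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 samples.")

  m1 <- rowMeans(beta[, grp1, drop = FALSE])
  m2 <- rowMeans(beta[, grp2, drop = FALSE])
  ss1 <- rowSums((beta[, grp1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((beta[, grp2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d

  if (is.null(prior_df)) {
    sq <- tryCatch(limma::squeezeVar(s2, df = d),
      error = function(e) {
        warn(paste0("Prior estimation failed (", conditionMessage(e),
                    "); falling back to the ordinary t-test."))
        list(df.prior = 0, var.post = s2)
      })
    d0 <- sq$df.prior
    s2_post <- sq$var.post
  } else if (is.infinite(prior_df)) {
    sq <- limma::squeezeVar(s2, df = d)
    d0 <- Inf
    s2_post <- rep(sq$var.prior, length(s2))
  } else if (prior_df == 0) {
    d0 <- 0
    s2_post <- s2
  } else {
    sq <- limma::squeezeVar(s2, df = d)
    d0 <- prior_df
    s2_post <- (d0 * sq$var.prior + d * s2) / (d0 + d)
  }

  delta <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- delta / se
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * pt(-abs(tt), df = df_total)

  tibble::tibble(
    CpG = rownames(beta), cell_type = target,
    mean_target = unname(m1), mean_rest = unname(m2), delta = unname(delta),
    t = unname(tt), p = unname(p), q = bh_fdr(unname(p)), in_dhs = NA
  )
}

check_labels <- function(beta, cell_type_of_sample) {
  samples <- colnames(beta)
  missing <- setdiff(samples, names(cell_type_of_sample))
  if (length(missing) > 0) {
    abort(paste0("Unlabelled sample(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  as.character(cell_type_of_sample[samples])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`), preserving
#' input order and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of the same length.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Select cell-type-specific DMCs by one-vs-rest moderated t
#'
#' For each cell type, CpGs whose moderated-t comparison against all other
#' samples pooled is significant at the given FDR.
#'
#' @inheritParams moderated_t_one_vs_rest
#' @param fdr FDR (q-value) threshold; default 0.05.
#' @return A tibble of significant rows (all cell types stacked), columns as
#'   in [moderated_t_one_vs_rest()].
#' @export
select_dmcs_one_vs_rest <- function(beta, cell_type_of_sample, fdr = 0.05) {
  beta <- as_beta_matrix(beta)
  labels <- check_labels(beta, cell_type_of_sample)
  types <- unique(labels)
  if (length(types) < 2) abort("At least 2 cell types are required.")
  purrr::map_dfr(types, function(ct) {
    tab <- moderated_t_one_vs_rest(beta, cell_type_of_sample, ct)
    tab[tab$q < fdr, , drop = FALSE]
  })
}

#' Select DMCs by pairwise beta difference
#'
#' For single-representative profiles (one column per cell type), CpGs whose
#' absolute beta difference between a pair of cell types exceeds a threshold.
#' This is the stringent selection used when replicates are unavailable.
#'
#' @param profiles Beta matrix with one column per cell type.
#' @param delta Threshold on `|b_A - b_B|`; default 0.9.
#' @return A list with `pairs` (tibble: `type_a`, `type_b`, `CpG`, `delta`)
#'   and `union` (character vector of unique CpGs across all pairs).
#' @export
select_dmcs_pairwise <- function(profiles, delta = 0.9) {
  profiles <- as_beta_matrix(profiles)
  types <- colnames(profiles)
  if (length(types) < 2) abort("At least 2 cell types are required.")
  combs <- utils::combn(types, 2, simplify = FALSE)
  pairs <- purrr::map_dfr(combs, function(ab) {
    d <- profiles[, ab[1]] - profiles[, ab[2]]
    hit <- abs(d) > delta
    tibble::tibble(
      type_a = ab[1], type_b = ab[2],
      CpG = rownames(profiles)[hit], delta = unname(d[hit])
    )
  })
  list(pairs = pairs, union = unique(pairs$CpG))
}

#' Restrict a DMC table to CpGs in DHS
#'
#' @param dmcs DMC tibble (e.g. from [select_dmcs_one_vs_rest()]).
#' @param dhs_cpgs Character vector of CpGs overlapping a DHS
#'   (see [cpgs_in_dhs()]).
#' @return The subset of rows whose `CpG` is in `dhs_cpgs`, with `in_dhs`
#'   set to `TRUE`.
#' @export
filter_to_dhs <- function(dmcs, dhs_cpgs) {
  out <- dmcs[dmcs$CpG %in% dhs_cpgs, , drop = FALSE]
  out$in_dhs <- rep(TRUE, nrow(out))
  out
}

#' Top-k DMCs by absolute mean difference
#'
#' CpGs ranked by `|delta|` descending; ties broken lexicographically by CpG
#' identifier so that builds are deterministic.
#'
#' @param dmcs DMC tibble with columns `CpG` and `delta`.
#' @param k Number of CpGs to keep (default 50); fewer are returned if fewer
#'   are available.
#' @return Character vector of CpG identifiers.
#' @export
top_k_by_delta <- function(dmcs, k = 50) {
  stopifnot(k >= 1)
  ord <- order(-abs(dmcs$delta), dmcs$CpG)
  head(dmcs$CpG[ord], k)
}

#' Average purified replicates into reference centroids
#'
#' @inheritParams moderated_t_one_vs_rest
#' @param cpgs CpGs to include (typically the union of per-cell-type top-k
#'   picks); duplicates are dropped.
#' @return A reference beta matrix (CpG x cell type) of centroid values:
#'   the arithmetic mean over replicates of each cell type.
#' @export
build_reference <- function(beta, cell_type_of_sample, cpgs) {
  beta <- as_beta_matrix(beta)
  labels <- check_labels(beta, cell_type_of_sample)
  cpgs <- unique(cpgs)
  missing <- setdiff(cpgs, rownames(beta))
  if (length(missing) > 0) {
    abort(paste0("Selected CpG(s) absent from data: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  types <- unique(labels)
  ref <- vapply(types, function(ct) {
    rowMeans(beta[cpgs, labels == ct, drop = FALSE])
  }, numeric(length(cpgs)))
  ref <- matrix(ref, nrow = length(cpgs), dimnames = list(cpgs, types))
  ref
}

#' Build a reference methylation database from purified-cell data
#'
#' The full recipe: select cell-type-specific DMCs (one-vs-rest moderated t
#' at an FDR threshold, or pairwise beta-difference for single-replicate
#' profiles), optionally keep only DMCs overlapping a DHS of any of the
#' catalog's cell types, rank by absolute mean difference, keep the top `k`
#' per cell type (pairwise mode: per pair), and average replicates into
#' centroids over the union of picks. Passing no DHS information reproduces
#' the unrestricted ("non-DHS") variant of the database.
#'
#' @inheritParams moderated_t_one_vs_rest
#' @param mode `"fdr"` (one-vs-rest moderated t; needs replicates) or
#'   `"pairwise"` (absolute beta difference between single profiles).
#' @param fdr FDR threshold for `mode = "fdr"`.
#' @param delta Beta-difference threshold for `mode = "pairwise"`.
#' @param top_k Picks per cell type (or per pair); `Inf` keeps all.
#' @param cpg_map,catalog Optional CpG positions and DHS catalog; when both
#'   are given, DMCs are restricted to DHS CpGs before ranking.
#' @param dhs_cell_types Cell types of `catalog` to use (union rule);
#'   defaults to all.
#' @return A reference matrix (CpG x cell type) with attribute `selection`,
#'   the per-cell-type pick list.
#' @export
build_reference_database <- function(beta, cell_type_of_sample,
                                     mode = c("fdr", "pairwise"),
                                     fdr = 0.05, delta = 0.9, top_k = 50,
                                     cpg_map = NULL, catalog = NULL,
                                     dhs_cell_types = NULL) {
  mode <- match.arg(mode)
  beta <- as_beta_matrix(beta)
  use_dhs <- !is.null(cpg_map) && !is.null(catalog)
  dhs_set <- if (use_dhs) {
    cpgs_in_dhs(cpg_map, catalog, dhs_cell_types %||% names(catalog))
  } else NULL

  if (mode == "fdr") {
    dmcs <- select_dmcs_one_vs_rest(beta, cell_type_of_sample, fdr = fdr)
    if (use_dhs) dmcs <- filter_to_dhs(dmcs, dhs_set)
    picks <- lapply(split(dmcs, dmcs$cell_type), top_k_by_delta, k = top_k)
  } else {
    labels <- check_labels(beta, cell_type_of_sample)
    types <- unique(labels)
    profiles <- build_reference(beta, cell_type_of_sample, rownames(beta))
    sel <- select_dmcs_pairwise(profiles, delta = delta)
    tab <- sel$pairs
    if (use_dhs) tab <- tab[tab$CpG %in% dhs_set, , drop = FALSE]
    picks <- lapply(
      split(tab, paste(tab$type_a, tab$type_b, sep = " vs ")),
      top_k_by_delta, k = top_k
    )
  }
  selected <- unique(unlist(picks, use.names = FALSE))
  if (length(selected) == 0) abort("No DMCs survived selection.")
  ref <- build_reference(beta, cell_type_of_sample, selected)
  attr(ref, "selection") <- picks
  ref
}
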
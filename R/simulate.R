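#' Random mixture weights on the unit simplex
#'
#' Each row is `C` independent Uniform(0,1) draws divided by their sum
#' (note: this is the normalised-uniform construction, not a flat Dirichlet
#' on the simplex).
#'
#' @param n_samples Number of mixtures.
#' @param cell_types Character vector of cell-type labels.
#' @param seed Optional integer seed.
#' @return A tibble of class `mixture_truth`: `sample` column plus one
#'   weight column per cell type; rows sum to 1.
#' @export
sample_simplex_weights <- function(n_samples, cell_types, seed = NULL) {
  stopifnot(n_samples >= 1, length(cell_types) >= 1)
  if (!is.null(seed)) set.seed(seed)
  C <- length(cell_types)
  u <- matrix(runif(n_samples * C), n_samples, C)
  w <- u / rowSums(u)
  colnames(w) <- cell_types
  out <- dplyr::bind_cols(
    tibble::tibble(sample = sprintf("mix%03d", seq_len(n_samples))),
    tibble::as_tibble(w)
  )
  structure(out, class = c("mixture_truth", class(out)))
}

#' Mix reference profiles into in-silico samples
#'
#' Mixing is linear on the beta scale: methylation fractions of cell
#' populations combine in proportion to their abundance.
#'
#' @param profiles Beta matrix with one column per cell type.
#' @param truth Weight tibble from [sample_simplex_weights()] (or any tibble
#'   with a `sample` column plus one column per cell type of `profiles`).
#' @return Mixture beta matrix (CpG x sample), clipped to \[0, 1\]
#'   (attribute `n_clipped` counts clipped entries; 0 for valid inputs).
#' @export
make_mixtures <- function(profiles, truth) {
  profiles <- as_beta_matrix(profiles, check = FALSE)
  W <- fractions_as_matrix(truth)
  if (!setequal(colnames(W), colnames(profiles))) {
    abort("Cell types of `truth` and `profiles` do not match.")
  }
  W <- W[, colnames(profiles), drop = FALSE]
  mix <- profiles %*% t(W)
  n_clipped <- sum(mix < 0 | mix > 1)
  if (n_clipped > 0) inform(paste0("Clipped ", n_clipped, " mixture value(s) into [0, 1]."))
  mix <- pmin(pmax(mix, 0), 1)
  attr(mix, "n_clipped") <- n_clipped
  mix
}

#' Add Gaussian noise on the M-value scale
#'
#' Betas are transformed to M-values, perturbed by i.i.d. Normal(0, sd^2),
#' and transformed back. An M-shift of +1 changes a beta value `b` by
#' exactly `b (1 - b) / (1 + b)`, i.e. about 5% at `b = 0.05` and about 16%
#' at `b = 0.4`, so `sd = 1` is a realistic array-noise level while `sd = 6`
#' is comparable to the M-distance between strongly discriminative cell-type
#' states (beta 0.1 vs 0.9).
#'
#' @param beta Beta matrix.
#' @param sd Noise standard deviation on the M scale (>= 0).
#' @param seed Optional integer seed.
#' @param eps Clipping constant for the transform (see [beta_to_m()]).
#' @return Beta matrix of the same shape, values in (0, 1).
#' @export
add_mspace_noise <- function(beta, sd = 1, seed = NULL, eps = 1e-6) {
  stopifnot(sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- beta_to_m(beta, eps = eps)
  if (sd > 0) m <- m + rnorm(length(m), mean = 0, sd = sd)
  out <- m_to_beta(m)
  dimnames(out) <- dimnames(beta)
  out
}

#' Synthetic-data configuration
#'
#' Defaults emulate a purified-blood training resource: 7 cell types with 6
#' replicates each, 50 strongly cell-type-specific DMCs per type (beta
#' differences of 0.5-0.9) on a background of mostly bimodal CpGs,
#' replicate noise and a between-study (lab) shift applied on the M scale,
#' and a DHS catalog enriched for each cell type's own DMCs.
#'
#' @param n_cell_types,n_replicates Cell types and replicates per type.
#' @param n_cpgs Total CpGs (background + planted).
#' @param n_dmcs_per_type Planted cell-type-specific DMCs per cell type.
#' @param delta_range Range of planted beta differences (target vs rest).
#' @param replicate_sd Replicate noise SD, M scale.
#' @param study_shift_sd SD of the per-CpG between-study shift (M scale),
#'   shared by all replicates of the test study.
#' @param dhs_enrichment Probability that a planted DMC lies in its own cell
#'   type's DHS; background CpGs enter any cell type's DHS at rate
#'   `dhs_background_rate`.
#' @param dhs_background_rate Background DHS rate per CpG.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cell_types = 7, n_replicates = 6, n_cpgs = 5000,
                         n_dmcs_per_type = 50, delta_range = c(0.5, 0.9),
                         replicate_sd = 0.3, study_shift_sd = 0.3,
                         dhs_enrichment = 0.8, dhs_background_rate = 0.1,
                         seed = 1L) {
  stopifnot(n_cell_types >= 1, n_replicates >= 1, n_cpgs >= 1,
            n_dmcs_per_type >= 1, length(delta_range) == 2,
            all(delta_range > 0 & delta_range < 1),
            replicate_sd >= 0, study_shift_sd >= 0,
            dhs_enrichment >= 0 && dhs_enrichment <= 1)
  if (n_dmcs_per_type * n_cell_types > n_cpgs) {
    abort("More planted DMCs than CpGs; increase `n_cpgs`.")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate purified-cell methylation studies
#'
#' Generates a training and an independent test study of purified cell-type
#' replicates with the same underlying cell-type means. Background CpG
#' baselines are drawn from a bimodal mixture (mostly near 0 or 1, a
#' minority intermediate). Each cell type receives planted DMCs whose mean
#' differs from every other type by a delta drawn from `delta_range`
#' (direction random). Replicates add Normal(0, `replicate_sd`^2) noise on
#' the M scale; the test study additionally applies a per-CpG shift
#' Normal(0, `study_shift_sd`^2) shared across its replicates (a lab
#' effect). A synthetic genome places CpGs 1 kb apart on one chromosome, and
#' DHS intervals preferentially cover each cell type's planted DMCs.
#'
#' @param config A [synth_config()].
#' @return A list with elements `train` and `test` (each a list with `beta`
#'   and `cell_type_of_sample`), `ground_truth` (tibble of planted DMCs:
#'   `CpG`, `cell_type`, `delta`, `mean_target`, `mean_rest`), `cpg_map`,
#'   `catalog` (a `dhs_catalog`) and `cell_types`.
#' @export
synth_purified_dataset <- function(config = synth_config()) {
  set.seed(config$seed)
  C <- config$n_cell_types
  G <- config$n_cpgs
  types <- paste0("ct", seq_len(C))
  cpgs <- sprintf("cg%06d", seq_len(G))

  # bimodal background baselines
  comp <- sample(1:3, G, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  base <- numeric(G)
  base[comp == 1] <- rbeta_clamped(sum(comp == 1), 2, 18)
  base[comp == 2] <- 1 - rbeta_clamped(sum(comp == 2), 2, 18)
  base[comp == 3] <- runif(sum(comp == 3), 0.2, 0.8)

  means <- matrix(base, G, C, dimnames = list(cpgs, types))

  # planted cell-type-specific DMCs: distinct CpGs per cell type
  dmc_idx <- sample.int(G, config$n_dmcs_per_type * C)
  dmc_type <- rep(seq_len(C), each = config$n_dmcs_per_type)
  delta <- runif(length(dmc_idx), config$delta_range[1], config$delta_range[2])
  sign_up <- runif(length(dmc_idx)) < 0.5
  mean_rest <- ifelse(sign_up,
                      runif(length(dmc_idx), 0.02, 0.98 - delta),
                      runif(length(dmc_idx), 0.02 + delta, 0.98))
  mean_target <- mean_rest + ifelse(sign_up, delta, -delta)
  for (i in seq_along(dmc_idx)) {
    means[dmc_idx[i], ] <- mean_rest[i]
    means[dmc_idx[i], dmc_type[i]] <- mean_target[i]
  }

  ground_truth <- tibble::tibble(
    CpG = cpgs[dmc_idx], cell_type = types[dmc_type],
    delta = mean_target - mean_rest,
    mean_target = mean_target, mean_rest = mean_rest
  )

  draw_study <- function(study_shift_sd) {
    m_means <- beta_to_m(means)
    shift <- if (study_shift_sd > 0) rnorm(G, 0, study_shift_sd) else 0
    cols <- lapply(seq_len(C), function(c) {
      reps <- matrix(
        rnorm(G * config$n_replicates, 0, config$replicate_sd),
        G, config$n_replicates
      )
      m_to_beta(m_means[, c] + shift + reps)
    })
    beta <- do.call(cbind, cols)
    samples <- as.vector(outer(seq_len(config$n_replicates), types,
                               function(r, t) paste0(t, "_r", r)))
    # outer() varies replicate fastest within each type, matching cbind order
    dimnames(beta) <- list(cpgs, samples)
    labels <- setNames(rep(types, each = config$n_replicates), samples)
    list(beta = beta, cell_type_of_sample = labels)
  }

  train <- draw_study(0)
  test <- draw_study(config$study_shift_sd)

  # synthetic genome and DHS catalog
  pos <- seq_len(G) * 1000L
  cpg_map <- tibble::tibble(CpG = cpgs, chrom = "chr1", pos = pos)
  in_dhs_of <- vector("list", C)
  for (c in seq_len(C)) {
    covered <- runif(G) < config$dhs_background_rate
    own <- dmc_idx[dmc_type == c]
    covered[own] <- runif(length(own)) < config$dhs_enrichment
    i <- which(covered)
    in_dhs_of[[c]] <- tibble::tibble(
      chrom = "chr1", start = pos[i] - 50L, end = pos[i] + 50L
    )
  }
  names(in_dhs_of) <- types
  list(
    train = train, test = test, ground_truth = ground_truth,
    cpg_map = cpg_map, catalog = dhs_catalog(in_dhs_of), cell_types = types
  )
}

rbeta_clamped <- function(n, a, b) pmin(pmax(stats::rbeta(n, a, b), 0.005), 0.995)

#' Per-cell-type mean profiles of a purified study
#'
#' @param study A list with `beta` and `cell_type_of_sample` (as produced by
#'   [synth_purified_dataset()]).
#' @return Beta matrix with one averaged column per cell type.
#' @export
mean_profiles <- function(study) {
  build_reference(study$beta, study$cell_type_of_sample,
                  rownames(study$beta))
}

#' Simulate a cell-composition-confounded association study
#'
#' Whole-tissue samples are generated as mixtures of reference profiles with
#' normalised-uniform weights. An ordinal phenotype (0/1/2, e.g. never /
#' former / current exposure) can act on the data through two routes:
#' a direct effect (`effect_size` beta units per phenotype unit at
#' `n_effect_cpgs` randomly chosen CpGs) and a composition effect
#' (`confound_strength` added to `confound_cell_type`'s raw weight per
#' phenotype unit before renormalisation). The second route makes every
#' DMC of the confounded cell type spuriously phenotype-associated unless
#' composition is adjusted for. Measurement noise is Gaussian on the M
#' scale.
#'
#' @param ref Reference beta matrix (CpG x cell type) used as the true
#'   underlying profiles.
#' @param n_samples Number of tissue samples.
#' @param effect_size Direct phenotype effect, beta units per phenotype unit.
#' @param n_effect_cpgs Number of CpGs carrying the direct effect.
#' @param confound_cell_type Cell type whose abundance tracks the phenotype
#'   (`NULL` for none).
#' @param confound_strength Raw-weight increment per phenotype unit.
#' @param noise_sd Measurement noise SD on the M scale.
#' @param seed Integer seed.
#' @return A list: `beta` (CpG x sample), `pheno` (tibble `sample`,
#'   `phenotype`), `fractions` (true `mixture_truth` weights),
#'   `effect_cpgs` (character).
#' @export
synth_ewas_dataset <- function(ref, n_samples = 150, effect_size = 0,
                               n_effect_cpgs = 0, confound_cell_type = NULL,
                               confound_strength = 0, noise_sd = 0.3,
                               seed = 1L) {
  set.seed(seed)
  ref <- as_beta_matrix(ref, check = FALSE)
  types <- colnames(ref)
  phenotype <- sample(0:2, n_samples, replace = TRUE)
  u <- matrix(runif(n_samples * length(types)), n_samples, length(types),
              dimnames = list(NULL, types))
  if (!is.null(confound_cell_type)) {
    stopifnot(confound_cell_type %in% types)
    u[, confound_cell_type] <- u[, confound_cell_type] +
      confound_strength * phenotype
  }
  w <- u / rowSums(u)
  samples <- sprintf("s%03d", seq_len(n_samples))
  truth <- dplyr::bind_cols(tibble::tibble(sample = samples), tibble::as_tibble(w))
  truth <- structure(truth, class = c("mixture_truth", class(truth)))

  beta <- ref %*% t(w)
  colnames(beta) <- samples

  effect_cpgs <- character()
  if (n_effect_cpgs > 0 && effect_size != 0) {
    effect_cpgs <- sample(rownames(ref), n_effect_cpgs)
    beta[effect_cpgs, ] <- beta[effect_cpgs, ] +
      effect_size * matrix(phenotype, n_effect_cpgs, n_samples, byrow = TRUE)
  }
  beta <- pmin(pmax(beta, 0), 1)
  beta <- add_mspace_noise(beta, sd = noise_sd)

  list(
    beta = beta,
    pheno = tibble::tibble(sample = samples, phenotype = phenotype),
    fractions = truth,
    effect_cpgs = effect_cpgs
  )
}
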
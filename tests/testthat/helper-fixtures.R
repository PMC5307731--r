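# Shared fixtures and independent oracles used across test files.

# Small reference with well-separated cell-type profiles.
toy_reference <- function(n_cpgs = 100, n_types = 3, seed = 42) {
  set.seed(seed)
  B <- matrix(runif(n_cpgs * n_types), n_cpgs, n_types)
  dimnames(B) <- list(sprintf("cg%05d", seq_len(n_cpgs)),
                      paste0("ct", seq_len(n_types)))
  B
}

# Independent Benjamini-Hochberg step-up, straight from the definition:
# q_i = min over p_(j) >= p_i of m * p_(j) / j, capped at 1.
bh_stepup_bruteforce <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      pj <- sort(p)[j]
      if (pj >= p[i] - 1e-15) m * pj / j else Inf
    }, numeric(1))
    min(min(cand), 1)
  }, numeric(1))
}

# Exact one-tailed signed-rank p-value by enumerating all 2^n sign patterns.
wilcoxon_enumerate <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# Brute-force constrained projection: search the simplex grid (step `by`)
# including interior points (sum <= 1).
cp_gridsearch <- function(y, B, by = 0.01) {
  C <- ncol(B)
  steps <- seq(0, 1, by = by)
  grid <- expand.grid(rep(list(steps), C))
  grid <- grid[rowSums(grid) <= 1 + 1e-9, , drop = FALSE]
  sse <- colSums((y - B %*% t(as.matrix(grid)))^2)
  as.numeric(grid[which.min(sse), ])
}

# Per-base interval membership scan (oracle for cpgs_in_dhs).
dhs_scan_bruteforce <- function(cpg_map, catalog, cell_types) {
  hits <- vapply(seq_len(nrow(cpg_map)), function(i) {
    p0 <- cpg_map$pos[i] - 1  # 0-based position
    any(vapply(cell_types, function(ct) {
      iv <- catalog[[ct]]
      any(iv$chrom == cpg_map$chrom[i] & iv$start <= p0 & p0 < iv$end)
    }, logical(1)))
  }, logical(1))
  cpg_map$CpG[hits]
}
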
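# Small purified fixture: `n_types` cell types, `n_rep` replicates, one
# planted DMC per type with a given delta, on a null background.
purified_fixture <- function(n_types = 2, n_rep = 3, n_cpgs = 100,
                             delta = 0.8, rep_sd = 0.02, seed = 1) {
  set.seed(seed)
  types <- paste0("ct", seq_len(n_types))
  cpgs <- sprintf("cg%04d", seq_len(n_cpgs))
  means <- matrix(0.5, n_cpgs, n_types, dimnames = list(cpgs, types))
  planted <- character(n_types)
  for (i in seq_len(n_types)) {
    means[i, ] <- 0.1
    means[i, i] <- 0.1 + delta
    planted[i] <- cpgs[i]
  }
  samples <- as.vector(outer(paste0("_r", seq_len(n_rep)), types,
                             function(r, t) paste0(t, r)))
  beta <- means[, rep(seq_len(n_types), each = n_rep)] +
    rnorm(n_cpgs * n_types * n_rep, 0, rep_sd)
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(cpgs, samples)
  labels <- setNames(rep(types, each = n_rep), samples)
  list(beta = beta, labels = labels, planted = setNames(planted, types))
}

test_that("moderated t reduces to the ordinary pooled t when d0 = 0", {
  fx <- purified_fixture()
  tab <- moderated_t_one_vs_rest(fx$beta, fx$labels, "ct1", prior_df = 0)
  ordinary <- apply(fx$beta, 1, function(y) {
    unname(t.test(y[fx$labels == "ct1"], y[fx$labels != "ct1"],
                  var.equal = TRUE)$statistic)
  })
  expect_equal(tab$t, unname(ordinary), tolerance = 1e-10)
})

test_that("forcing d0 = Inf uses the common prior variance at every CpG", {
  fx <- purified_fixture()
  tab <- moderated_t_one_vs_rest(fx$beta, fx$labels, "ct1", prior_df = Inf)
  # all moderated variances equal: t / delta constant across CpGs
  ratio <- tab$t / tab$delta
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("a strongly planted DMC gets the largest |t| among nulls", {
  fx <- purified_fixture(n_types = 2, n_rep = 3, n_cpgs = 101, delta = 0.8,
                         rep_sd = 0.02, seed = 5)
  tab <- moderated_t_one_vs_rest(fx$beta, fx$labels, "ct1")
  expect_equal(tab$CpG[which.max(abs(tab$t))], fx$planted[["ct1"]])
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  fx <- purified_fixture(n_types = 3, n_rep = 4, n_cpgs = 200, seed = 9)
  tab <- moderated_t_one_vs_rest(fx$beta, fx$labels, "ct2")
  design <- cbind(Intercept = 1, target = as.numeric(fx$labels == "ct2"))
  efit <- limma::eBayes(limma::lmFit(fx$beta, design))
  expect_equal(tab$t, unname(efit$t[, "target"]), tolerance = 1e-6)
  expect_equal(tab$p, unname(efit$p.value[, "target"]), tolerance = 1e-6)
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric()), numeric())
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_fdr(p), bh_stepup_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("one-vs-rest selection recovers planted DMCs and little else", {
  n_types <- 3
  recovered <- integer(0)
  false_pos <- integer(0)
  for (seed in 1:3) {
    set.seed(seed)
    types <- paste0("ct", seq_len(n_types))
    n_cpgs <- 600; n_rep <- 6; n_dmc <- 30
    cpgs <- sprintf("cg%04d", seq_len(n_cpgs))
    means <- matrix(runif(n_cpgs, 0.3, 0.7), n_cpgs, n_types,
                    dimnames = list(cpgs, types))
    planted <- split(seq_len(n_dmc * n_types),
                     rep(seq_len(n_types), each = n_dmc))
    for (i in seq_len(n_types)) {
      means[planted[[i]], i] <-
        pmin(means[planted[[i]], i] + 0.3, 0.98)  # modest but clear effects
    }
    samples <- paste0(rep(types, each = n_rep), "_r", seq_len(n_rep))
    beta <- pmin(pmax(
      means[, rep(seq_len(n_types), each = n_rep)] +
        rnorm(n_cpgs * n_types * n_rep, 0, 0.03), 0), 1)
    dimnames(beta) <- list(cpgs, samples)
    labels <- setNames(rep(types, each = n_rep), samples)
    dmcs <- select_dmcs_one_vs_rest(beta, labels, fdr = 0.05)
    for (i in seq_len(n_types)) {
      sel <- dmcs$CpG[dmcs$cell_type == types[i]]
      recovered <- c(recovered, sum(cpgs[planted[[i]]] %in% sel))
      false_pos <- c(false_pos, sum(!sel %in% cpgs[planted[[i]]]))
    }
  }
  expect_true(all(recovered >= 28))
  expect_true(all(false_pos <= 2))
})

test_that("null data yields (almost) no selections at FDR 0.05", {
  empty <- 0L
  for (seed in 1:10) {
    set.seed(100 + seed)
    beta <- matrix(pmin(pmax(0.5 + rnorm(1000 * 8, 0, 0.05), 0), 1), 1000, 8,
                   dimnames = list(sprintf("cg%04d", 1:1000),
                                   paste0("s", 1:8)))
    labels <- setNames(rep(c("a", "b"), each = 4), colnames(beta))
    dmcs <- select_dmcs_one_vs_rest(beta, labels, fdr = 0.05)
    if (nrow(dmcs) == 0) empty <- empty + 1L
  }
  expect_gte(empty, 9)  # >= 95% of seeds in expectation; allow one failure
})

test_that("fdr threshold of 1 selects every CpG for every cell type", {
  fx <- purified_fixture(n_cpgs = 50)
  dmcs <- select_dmcs_one_vs_rest(fx$beta, fx$labels, fdr = 1 + 1e-9)
  expect_equal(nrow(dmcs), 50 * 2)
})

test_that("pairwise selection thresholds |delta| and unions across pairs", {
  prof <- matrix(c(0.02, 0.10, 0.97, 0.90), 2, 2,
                 dimnames = list(c("hit", "miss"), c("A", "B")))
  sel <- select_dmcs_pairwise(prof, delta = 0.9)
  expect_equal(sel$union, "hit")   # |0.02-0.97| = 0.95; |0.1-0.9| = 0.8

  # 3 types, engineered pair sets of sizes 2, 3, 1 with one shared CpG
  prof3 <- matrix(0.5, 6, 3, dimnames = list(paste0("cg", 1:6),
                                             c("A", "B", "C")))
  prof3[1, ] <- c(0.01, 0.99, 0.5)    # A-B
  prof3[2, ] <- c(0.99, 0.01, 0.95)   # A-B and B-C
  prof3[3, ] <- c(0.5, 0.99, 0.01)    # B-C
  prof3[4, ] <- c(0.45, 0.99, 0.03)   # B-C
  prof3[5, ] <- c(0.99, 0.5, 0.02)    # A-C
  sel3 <- select_dmcs_pairwise(prof3, delta = 0.9)
  sizes <- table(paste(sel3$pairs$type_a, sel3$pairs$type_b))
  expect_setequal(as.integer(sizes), c(2L, 3L, 1L))
  expect_equal(length(sel3$union), 5)
})

test_that("DHS filtering subsets and flags; empty and superset edge cases", {
  fx <- purified_fixture(n_cpgs = 10)
  dmcs <- moderated_t_one_vs_rest(fx$beta, fx$labels, "ct1")
  sub <- filter_to_dhs(dmcs, dmcs$CpG[c(1, 3, 5, 7)])
  expect_equal(nrow(sub), 4)
  expect_true(all(sub$in_dhs))
  expect_equal(nrow(filter_to_dhs(dmcs, character())), 0)
  expect_equal(filter_to_dhs(dmcs, dmcs$CpG)$CpG, dmcs$CpG)
})

test_that("top-k ranking is by |delta| with lexicographic tie-break", {
  dmcs <- tibble::tibble(CpG = c("cg3", "cg1", "cg2"),
                         delta = c(0.9, -0.8, 0.7))
  expect_equal(top_k_by_delta(dmcs, 2), c("cg3", "cg1"))
  expect_equal(length(top_k_by_delta(dmcs, 100)), 3)
  tied <- tibble::tibble(CpG = c("cgB", "cgA"), delta = c(0.8, -0.8))
  expect_equal(top_k_by_delta(tied, 1), "cgA")
})

test_that("centroids average replicates over the union of picks", {
  beta <- matrix(c(0.2, 0.4, 0.6, 0.8), 1, 4,
                 dimnames = list("cg1", paste0("s", 1:4)))
  labels <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  ref <- build_reference(beta, labels, "cg1")
  expect_equal(unname(ref["cg1", ]), c(0.3, 0.7))
  # a single replicate: centroid equals the profile
  ref1 <- build_reference(beta[, 1, drop = FALSE], labels[1], "cg1")
  expect_equal(unname(ref1[1, 1]), 0.2)
  expect_error(build_reference(beta, labels, c("cg1", "cgX")), "cgX")
})

test_that("union arithmetic: 7 x 50 picks with 17 shared CpGs gives 333 rows", {
  # mirror the blood design: per-type pick lists of 50 with engineered overlap
  all_ids <- sprintf("cg%05d", 1:400)
  shared <- all_ids[1:17]           # shared between the first two lists
  rest <- all_ids[-(1:17)]
  picks <- vector("list", 7)
  picks[[1]] <- c(shared, rest[1:33])
  picks[[2]] <- c(shared, rest[34:66])
  offset <- 66
  for (i in 3:7) {
    picks[[i]] <- rest[(offset + 1):(offset + 50)]
    offset <- offset + 50
  }
  union_ids <- unique(unlist(picks))
  expect_equal(length(union_ids), 333)  # 7*50 - 17 duplicates
  set.seed(2)
  beta <- matrix(runif(400 * 14), 400, 14,
                 dimnames = list(all_ids, paste0("s", 1:14)))
  labels <- setNames(rep(paste0("ct", 1:7), each = 2), colnames(beta))
  ref <- build_reference(beta, labels, unlist(picks))
  expect_equal(nrow(ref), 333)
  expect_false(anyDuplicated(rownames(ref)) > 0)
})

test_that("pipeline without DHS inputs is the non-DHS variant of the same path", {
  fx <- purified_fixture(n_types = 3, n_rep = 4, n_cpgs = 300, seed = 11)
  ref <- build_reference_database(fx$beta, fx$labels, mode = "fdr",
                                  fdr = 0.05, top_k = 10)
  expect_true(all(fx$planted %in% rownames(ref)))
  expect_equal(ncol(ref), 3)
})

test_that("planted strong DMCs appear in their cell type's top-k list", {
  fx <- purified_fixture(n_types = 3, n_rep = 4, n_cpgs = 300, delta = 0.8,
                         rep_sd = 0.05, seed = 13)
  dmcs <- select_dmcs_one_vs_rest(fx$beta, fx$labels, fdr = 0.05)
  for (ct in names(fx$planted)) {
    top <- top_k_by_delta(dmcs[dmcs$cell_type == ct, ], k = 5)
    expect_true(fx$planted[[ct]] %in% top)
  }
})
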
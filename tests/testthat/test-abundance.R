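test_that("identical groups produce no significant proteins", {
  set.seed(2)
  half <- matrix(2^rnorm(60, 15), 30, 2)
  pm <- toy_pm(cbind(half, half), groups = rep(c("A", "B"), each = 2))
  v <- volcano(pm, "A", "B")
  expect_equal(v$log2FC, rep(0, 30))
  expect_equal(sum(v$status != "not_significant"), 0L)
  expect_equal(v$p_value, rep(1, 30))
})

test_that("swapping the groups mirrors fold changes and up/down sets", {
  set.seed(4)
  pm <- toy_pm(matrix(2^rnorm(200, 15, 1), 50, 4),
               groups = rep(c("A", "B"), each = 2))
  ab <- volcano(pm, "A", "B", p_thr = 0.05, fc_thr = 1.2)
  ba <- volcano(pm, "B", "A", p_thr = 0.05, fc_thr = 1.2)
  m <- match(ab$protein_id, ba$protein_id)
  expect_equal(ab$log2FC, -ba$log2FC[m], tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value[m], tolerance = 1e-12)
  expect_equal(sort(ab$protein_id[ab$status == "up"]),
               sort(ba$protein_id[ba$status == "down"]))
  expect_equal(sort(ab$protein_id[ab$status == "down"]),
               sort(ba$protein_id[ba$status == "up"]))
})

test_that("volcano t-test agrees with textbook formulas to 1e-10", {
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- 2^rnorm(n1, 15); b <- 2^rnorm(n2, 15)
    ab <- rbind(c(a, rep(NA, 5 - n1), b, rep(NA, 5 - n2)))
    pm <- toy_pm(ab, groups = rep(c("A", "B"), each = 5))
    vw <- volcano(pm, "A", "B")
    expect_equal(vw$p_value, welch_t_oracle(log2(b), log2(a)),
                 tolerance = 1e-10)
    vs <- volcano(pm, "A", "B", var_equal = TRUE)
    expect_equal(vs$p_value, pooled_t_oracle(log2(b), log2(a)),
                 tolerance = 1e-10)
    expect_equal(vw$log2FC, mean(log2(b)) - mean(log2(a)),
                 tolerance = 1e-12)
  }
})

test_that("significant-set size is monotone in both thresholds", {
  set.seed(12)
  pm <- toy_pm(matrix(2^rnorm(400, 15, 1), 100, 4),
               groups = rep(c("A", "B"), each = 2))
  n_sig <- function(p, fc)
    sum(volcano(pm, "A", "B", p_thr = p, fc_thr = fc)$status !=
          "not_significant")
  for (fc in c(1.2, 1.5, 2, 4))
    expect_true(n_sig(0.01, fc) <= n_sig(0.05, fc))
  for (p in c(0.05, 0.01))
    expect_true(all(diff(sapply(c(1.2, 2, 4, 8),
                                function(f) n_sig(p, f))) <= 0))
  # fc below 1 is symmetrized: 0.5 and 2 give the same status sets
  expect_equal(volcano(pm, "A", "B", fc_thr = 0.5)$status,
               volcano(pm, "A", "B", fc_thr = 2)$status)
  expect_error(volcano(pm, "A", "B", fc_thr = 0), "fc_thr")
})

test_that("abundance ranking is descending with deterministic ties", {
  ab <- matrix(c(10, 10, 10, 10, 5, 5), 3, 2, byrow = TRUE,
               dimnames = list(c("B", "A", "C"), NULL))
  pm <- toy_pm(ab, groups = c("g", "g"))
  rk <- rank_abundance(pm, "g")
  expect_equal(rk$protein_id, c("A", "B", "C"))  # ties lexicographic
  expect_equal(rk$rank, 1:3)
  expect_error(rank_abundance(pm, "nope"), "unknown group")
})

test_that("single-protein bar statistics mark significance", {
  set.seed(6)
  ref <- 2^rnorm(3, 10, 0.05)
  same <- ref
  shifted <- 2^rnorm(3, 10 + log2(10), 0.05)   # planted 10-fold shift
  pm <- toy_pm(rbind(c(ref, same, shifted)),
               groups = rep(c("R", "S", "T"), each = 3))
  rownames(pm$abundance) <- "P1"
  bs <- protein_bar_stats(pm, "P1", reference_group = "R")
  expect_equal(bs$mark[bs$group == "R"], "")
  expect_equal(bs$mark[bs$group == "S"], "n.s.")
  expect_equal(bs$mark[bs$group == "T"], "*")
  # p for the shifted group agrees with the oracle t-test
  expect_equal(bs$p_value[bs$group == "T"],
               welch_t_oracle(log2(ref), log2(shifted)),
               tolerance = 1e-10)
  expect_error(protein_bar_stats(pm, "XYZ", "R"), "not found")
})

test_that("imputation preserves observed cells bitwise", {
  fx <- make_rank1_fixture(n_proteins = 40, n_samples = 5,
                           miss_rate = 0.08, seed = 2)
  out <- impute_iterative(fx$pm)
  obs <- !is.na(fx$pm$abundance)
  expect_identical(out$abundance[obs], fx$pm$abundance[obs])
  expect_false(anyNA(out$abundance))
  # no missing values -> identity
  pm_full <- toy_pm(matrix(2^rnorm(40, 15), 10, 4),
                    groups = rep(c("A", "B"), each = 2))
  expect_identical(impute_iterative(pm_full)$abundance,
                   pm_full$abundance)
})

test_that("imputation recovers deleted cells of a rank-1 matrix", {
  fx <- make_rank1_fixture(n_proteins = 100, n_samples = 6,
                           miss_rate = 0.05, seed = 5)
  out <- impute_iterative(fx$pm)
  imput <- out$abundance[cbind(fx$deleted$row, fx$deleted$col)]
  rel_err <- abs(imput - fx$deleted$value) / fx$deleted$value
  expect_lt(median(rel_err), 0.01)
})

test_that("imputation errors on fully missing proteins", {
  ab <- matrix(c(NA, NA, 1, 2), 2, 2, byrow = TRUE,
               dimnames = list(c("P1", "P2"), NULL))
  pm <- toy_pm(ab, groups = c("g", "g"))
  expect_error(impute_iterative(pm), "zero observations")
})

test_that("selected-protein heatmaps render missing cells as n.d.", {
  ab <- matrix(c(8, NA, 16, 32), 2, 2, byrow = TRUE,
               dimnames = list(c("P1", "P2"), NULL))
  pm <- toy_pm(ab, groups = c("A", "B"))
  hd <- heatmap_data(pm, proteins = c("P1", "P2"), by = "sample")
  expect_equal(hd$display["P1", 2], "n.d.")
  expect_equal(hd$values["P1", 1], 3)            # exact log2 of input
  expect_equal(hd$values["P2", 2], 5)
  expect_false(hd$imputed)
  expect_error(heatmap_data(pm, proteins = character()), "empty")
})

test_that("full heatmap row order equals the clustering leaf order", {
  set.seed(14)
  pm <- toy_pm(matrix(2^rnorm(240, 15, 2), 40, 6),
               groups = rep(c("A", "B", "C"), each = 2))
  hd <- heatmap_data(pm, by = "group", impute = TRUE)
  expect_equal(hd$row_order,
               hclust(dist(hd$values), method = "average")$order)
  expect_equal(hd$col_order, cluster_profiles(pm, on = "groups")$order)
  # impute = TRUE on a complete matrix leaves values unchanged
  expect_equal(hd$values,
               heatmap_data(pm, by = "group", impute = FALSE)$values)
})
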
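test_that("yields use union semantics for groups", {
  lay <- simple_layout("g", 2)
  # replicate 1 sees P1 only, replicate 2 sees P2 only
  ab <- matrix(c(10, NA, NA, 20), 2, 2,
               dimnames = list(c("P1", "P2"), lay$sample_name))
  pm <- toy_pm(ab, groups = c("g", "g"))
  qt <- toy_qt(data.frame(protein_id = c("P1", "P2"),
                          stripped_seq = c("AAAK", "CCCK"),
                          sample = c("g_1", "g_2"),
                          quantity = c(10, 20)), lay)
  y <- count_yields(pm, qt)
  expect_equal(y$samples$proteins, c(1L, 1L))
  expect_equal(y$groups$proteins, 2L)            # union over replicates
  expect_equal(y$groups$peptides, 2L)
  expect_true(all(y$groups$proteins >= y$samples$proteins))
})

test_that("shared/unique/core follows set semantics on a known case", {
  # groups {P1,P2} and {P2,P3}
  ab <- matrix(c(1, 1, NA, NA, 1, 1), 3, 2,
               dimnames = list(c("P1", "P2", "P3"), c("A_1", "B_1")))
  lay <- sample_layout(c("r1", "r2"), c("A_1", "B_1"), c("A", "B"),
                       c(1, 1))
  pm <- quickprot:::new_protein_matrix(
    ab, (!is.na(ab)) * 1L,
    data.frame(protein_id = rownames(ab), gene = rownames(ab)), lay)
  su <- shared_unique(pm)
  expect_equal(su$unique$A, "P1")
  expect_equal(su$unique$B, "P3")
  expect_equal(su$core, "P2")
  expect_equal(unname(su$shared_counts["A", "B"]), 1)
})

test_that("identical groups give empty uniques and a full core", {
  ab <- matrix(1, 5, 4, dimnames = list(paste0("P", 1:5), NULL))
  pm <- toy_pm(ab, groups = rep(c("A", "B"), each = 2))
  su <- shared_unique(pm)
  expect_equal(lengths(su$unique), c(A = 0L, B = 0L))
  expect_equal(sort(su$core), paste0("P", 1:5))
})

test_that("shared/unique matches brute-force set enumeration", {
  set.seed(21)
  groups <- c("G1", "G2", "G3", "G4")
  ab <- matrix(2^rnorm(400, 15), 50, 8)
  ab[runif(400) < 0.35] <- NA
  ab <- ab[rowSums(!is.na(ab)) > 0, ]
  pm <- toy_pm(ab, groups = rep(groups, each = 2))
  ab <- pm$abundance
  su <- shared_unique(pm)
  # oracle: explicit per-group membership sets
  sets <- lapply(groups, function(g) {
    cols <- pm$layout$sample_name[pm$layout$group == g]
    rownames(ab)[rowSums(!is.na(ab[, cols, drop = FALSE])) > 0]
  })
  names(sets) <- groups
  for (g in groups) {
    others <- unique(unlist(sets[setdiff(groups, g)]))
    expect_equal(sort(su$unique[[g]]), sort(setdiff(sets[[g]], others)))
  }
  expect_equal(sort(su$core), sort(Reduce(intersect, sets)))
  for (a in groups) for (b in groups)
    expect_equal(unname(su$shared_counts[a, b]),
                 length(intersect(sets[[a]], sets[[b]])))
  # partition identity
  in_two_plus <- sum(rowSums(su$presence) >= 2)
  expect_equal(sum(lengths(su$unique)) + in_two_plus, nrow(ab))
})

test_that("adding a group never enlarges the core set", {
  set.seed(5)
  ab <- matrix(2^rnorm(240, 15), 40, 6)
  ab[runif(240) < 0.3] <- NA
  ab <- ab[rowSums(!is.na(ab)) > 0, ]
  pm3 <- toy_pm(ab, groups = rep(c("A", "B", "C"), each = 2))
  pm2 <- toy_pm(ab[, 1:4], groups = rep(c("A", "B"), each = 2))
  expect_true(all(shared_unique(pm3)$core %in% shared_unique(pm2)$core))
})

test_that("peptides-per-protein medians and single-protein lookup", {
  lay <- simple_layout("g", 2)
  qt <- toy_qt(data.frame(
    protein_id = rep(c("P1", "P2"), each = 3),
    gene = rep(c("GA", "GB"), each = 3),
    stripped_seq = paste0("SEQ", 1:6, "K"),
    sample = "g_1", quantity = 10), lay)
  ppp <- peptides_per_protein(qt)
  expect_equal(unname(ppp$medians["g"]), 3)
  one <- peptides_per_protein(qt, "GA")
  expect_equal(one$peptides, c(3L, 0L))
  expect_error(peptides_per_protein(qt, "GZZZ"), "not found")
})

test_that("clustering merges identical profiles first", {
  ab <- 2^cbind(a = c(10, 12, 14), b = c(10, 12, 14),
                c = c(20, 22, 24))
  rownames(ab) <- paste0("P", 1:3)
  lay <- sample_layout(paste0("r", 1:3), c("a", "b", "c"),
                       c("a", "b", "c"), c(1, 1, 1))
  pm <- quickprot:::new_protein_matrix(
    ab, (ab > 0) * 1L,
    data.frame(protein_id = rownames(ab), gene = rownames(ab)), lay)
  tree <- cluster_profiles(pm, on = "samples")
  first_pair <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first_pair, c("a", "b"))
  expect_equal(tree$height[1], 0)
  expect_true(all(diff(tree$height) >= 0))
})

test_that("average-linkage merge heights equal the brute-force oracle", {
  set.seed(13)
  ab <- 2^matrix(rnorm(40, 15, 2), 10, 4)
  pm <- toy_pm(ab, groups = paste0("g", 1:4))
  tree <- cluster_profiles(pm, on = "samples")
  d <- as.matrix(dist(t(log2(pm$abundance))))
  expect_equal(sort(tree$height), upgma_heights_oracle(d),
               tolerance = 1e-12)
  # permuting leaves does not change merge heights
  perm <- c(3, 1, 4, 2)
  pm2 <- toy_pm(pm$abundance[, perm], groups = paste0("g", 1:4)[perm])
  tree2 <- cluster_profiles(pm2, on = "samples")
  expect_equal(sort(tree$height), sort(tree2$height), tolerance = 1e-12)
})

test_that("group correlation matrix matches per-pair recomputation", {
  set.seed(31)
  ab <- 2^matrix(rnorm(300, 15, 2), 50, 6)
  ab[runif(300) < 0.1] <- NA
  ab <- ab[rowSums(!is.na(ab)) > 0, ]
  pm <- toy_pm(ab, groups = rep(c("A", "B", "C"), each = 2))
  ab <- pm$abundance
  gcm <- group_correlation_matrix(pm)
  expect_equal(gcm, t(gcm))
  expect_equal(unname(diag(gcm)), rep(1, 3))
  # independent per-pair oracle
  gm <- sapply(c("A", "B", "C"), function(g) {
    cols <- pm$layout$sample_name[pm$layout$group == g]
    v <- rowMeans(log2(ab[, cols, drop = FALSE]), na.rm = TRUE)
    v[is.nan(v)] <- NA
    v
  })
  for (a in 1:2) for (b in (a + 1):3) {
    both <- complete.cases(gm[, c(a, b)])
    expect_equal(gcm[a, b],
                 cor(rank(gm[both, a]), rank(gm[both, b])),
                 tolerance = 1e-12)
  }
  # identical groups correlate perfectly
  dup <- cbind(ab[, 1:2], ab[, 1:2])
  colnames(dup) <- NULL
  pm_id <- toy_pm(dup, groups = rep(c("A", "B"), each = 2))
  expect_equal(unname(group_correlation_matrix(pm_id)[1, 2]), 1)
})
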
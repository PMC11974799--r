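test_that("peptide ratios handle zero light, zero heavy and missing heavy", {
  lay <- simple_layout("g", 2)
  prm <- toy_prm(data.frame(
    protein_id = c("P1", "P1", "P2", "P3"),
    stripped_seq = c("AAAK", "CCCK", "DDDK", "EEEK"),
    sample = "g_1",
    light_area = c(1000, 0, 500, 100),
    heavy_area = c(500, 800, 0, NA)), lay)
  expect_warning(expect_warning(rt <- peptide_ratios(prm),
                                "2 row"), "unquantifiable")
  expect_equal(rt$ratio[rt$stripped_seq == "AAAK"], 2)
  expect_equal(rt$ratio[rt$stripped_seq == "CCCK"], 0)
  expect_false("DDDK" %in% rt$stripped_seq)
  expect_true(all(c("P2", "P3") %in% attr(rt, "unquantifiable")))
})

test_that("copies per nucleus reproduces the unit-analysis example", {
  lay <- simple_layout("g", 2)
  prm <- toy_prm(data.frame(protein_id = "P1", stripped_seq = "AAAK",
                            sample = c("g_1", "g_2"),
                            light_area = c(1000, 1000),
                            heavy_area = c(1000, 1000)), lay)
  params <- abs_quant_params(hlis_mw = 1e5, spiked_mass_ng = 1,
                             injected_protein_ug = 1,
                             protein_per_cell_pg = 10)
  aq <- copies_per_cell(peptide_ratios(prm), params)
  # R = 1 -> 1e-9/1e5 mol spike = 1e-14; x 1e-5 ug/nucleus = 1e-19 mol;
  # x N_A = 6.02214076e4 copies per nucleus
  expect_equal(aq$copies$copies, rep(6.02214076e4, 2),
               tolerance = 1e-9)
})

test_that("copies are linear in R and protein mass, inverse in MW and load", {
  lay <- simple_layout("g", 2)
  mk <- function(r) toy_prm(data.frame(
    protein_id = "P1", stripped_seq = "AAAK", sample = "g_1",
    light_area = r * 100, heavy_area = 100), lay)
  base_params <- abs_quant_params(1e5, 1, 1, 10)
  base <- copies_per_cell(peptide_ratios(mk(1)), base_params)$copies$copies
  c2 <- copies_per_cell(peptide_ratios(mk(3.7)), base_params)$copies$copies
  expect_equal(c2 / base, 3.7, tolerance = 1e-12)
  p2 <- copies_per_cell(peptide_ratios(mk(1)),
                        abs_quant_params(1e5, 1, 1, 25))$copies$copies
  expect_equal(p2 / base, 2.5, tolerance = 1e-12)
  m2 <- copies_per_cell(peptide_ratios(mk(1)),
                        abs_quant_params(2e5, 1, 1, 10))$copies$copies
  expect_equal(m2 / base, 0.5, tolerance = 1e-12)
  i2 <- copies_per_cell(peptide_ratios(mk(1)),
                        abs_quant_params(1e5, 1, 4, 10))$copies$copies
  expect_equal(i2 / base, 0.25, tolerance = 1e-12)
  # R = 0 -> 0 copies
  z <- copies_per_cell(peptide_ratios(mk(0)), base_params)
  expect_equal(z$copies$copies, 0)
  expect_error(abs_quant_params(-1, 1, 1, 10), "positive")
})

test_that("per-protein spike overrides are honoured", {
  lay <- simple_layout("g", 2)
  prm <- toy_prm(data.frame(protein_id = c("P1", "P2"),
                            stripped_seq = c("AAAK", "CCCK"),
                            sample = "g_1",
                            light_area = 100, heavy_area = 100), lay)
  params <- abs_quant_params(1e5, 1, 1, 10, per_protein = data.frame(
    protein_id = "P2", hlis_mw = 2e5, spiked_mass_ng = 1))
  aq <- copies_per_cell(peptide_ratios(prm), params)
  cp <- aq$copies
  expect_equal(cp$copies[cp$protein_id == "P1"] /
                 cp$copies[cp$protein_id == "P2"], 2, tolerance = 1e-12)
})

test_that("ANOVA/Tukey flags the shifted group and not the null pair", {
  set.seed(23)
  hits <- replicate(30, {
    v <- c(rnorm(4, 0), rnorm(4, 0), rnorm(4, 5))
    tk <- anova_tukey(v, rep(c("g1", "g2", "g3"), each = 4))
    sig <- tk$pairs$significant
    names(sig) <- paste(tk$pairs$group_a, tk$pairs$group_b)
    sig
  })
  expect_gt(mean(hits["g1 g3", ]), 0.95)
  expect_gt(mean(hits["g2 g3", ]), 0.95)
  expect_lt(mean(hits["g1 g2", ]), 0.2)
})

test_that("Tukey agrees with stats::TukeyHSD for k > 2", {
  set.seed(27)
  v <- rnorm(15, rep(c(0, 1, 3), each = 5))
  g <- rep(c("a", "b", "c"), each = 5)
  tk <- anova_tukey(v, g)
  ref <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  expect_equal(unname(tk$pairs$p_adj),
               unname(ref[c("b-a", "c-a", "c-b"), "p adj"]),
               tolerance = 1e-6)
  expect_equal(unname(tk$pairs$diff),
               unname(ref[c("b-a", "c-a", "c-b"), "diff"]),
               tolerance = 1e-10)
})

test_that("two-group Tukey equals the pooled t-test exactly", {
  set.seed(29)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, sample(c(0, 2), 1))
    tk <- anova_tukey(c(x, y), rep(c("a", "b"), c(n1, n2)))
    expect_equal(tk$pairs$p_adj, pooled_t_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("degenerate all-identical data yields p = 1 everywhere", {
  tk <- anova_tukey(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(tk$pairs$p_adj, rep(1, 3))
  expect_false(any(tk$pairs$significant))
  expect_equal(unname(tk$anova["p"]), 1)
  expect_error(anova_tukey(1:3, c("a", "a", "b")), "fewer than 2")
})

test_that("compact letter display covers the canonical cases", {
  none <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3],
                                              letters[1:3]))
  expect_equal(unname(compact_letter_display(none)$letters),
               rep("a", 3))
  all_sig <- !diag(3)
  dimnames(all_sig) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(compact_letter_display(all_sig)$letters),
               c("a", "b", "c"))
})

test_that("letter assignments satisfy the share-letter invariant", {
  set.seed(33)
  for (i in 1:120) {
    k <- sample(2:5, 1)
    sig <- matrix(FALSE, k, k)
    sig[upper.tri(sig)] <- runif(k * (k - 1) / 2) < 0.5
    sig <- sig | t(sig)
    dimnames(sig) <- list(paste0("g", 1:k), paste0("g", 1:k))
    cld <- compact_letter_display(sig)
    expect_true(cld_invariant_holds(cld$letters, sig),
                info = paste("matrix", i))
  }
})

test_that("stoichiometry comparison separates planted copy differences", {
  set.seed(37)
  lay <- simple_layout("D0", 3)
  prm <- toy_prm(data.frame(
    protein_id = rep(c("P1", "P2"), each = 3),
    stripped_seq = rep(c("AAAK", "CCCK"), each = 3),
    sample = rep(lay$sample_name, 2),
    light_area = c(rnorm(3, 1000, 10), rnorm(3, 10000, 100)),
    heavy_area = 1000), lay)
  aq <- copies_per_cell(peptide_ratios(prm),
                        abs_quant_params(1e5, 1, 1, 10))
  sc <- stoichiometry_compare(aq, c("P1", "P2"), "D0")
  expect_false(any(strsplit(sc$bars$letters[1], "")[[1]] %in%
                     strsplit(sc$bars$letters[2], "")[[1]]))
  # identical copies share a letter
  prm2 <- toy_prm(data.frame(
    protein_id = rep(c("P1", "P2"), each = 3),
    stripped_seq = rep(c("AAAK", "CCCK"), each = 3),
    sample = rep(lay$sample_name, 2),
    light_area = rep(c(1000, 1010, 990), 2), heavy_area = 1000), lay)
  aq2 <- copies_per_cell(peptide_ratios(prm2),
                         abs_quant_params(1e5, 1, 1, 10))
  sc2 <- stoichiometry_compare(aq2, c("P1", "P2"), "D0")
  expect_true(any(strsplit(sc2$bars$letters[1], "")[[1]] %in%
                    strsplit(sc2$bars$letters[2], "")[[1]]))
  expect_error(stoichiometry_compare(aq, "P1", "D0"), "at least 2")
})

test_that("trend series follow the layout group order", {
  fx <- make_prm_fixture(prm_fixture_spec(seed = 41, ratio_noise_cv = 5),
                         dir = tempfile())
  lay <- read_layout(fx$paths$layout)
  prm <- read_skyline_table(fx$paths$prm, lay, "prm_heavy")
  aq <- copies_per_cell(peptide_ratios(prm),
                        read_abs_quant_params(fx$paths$params))
  tr <- trend(aq, "BAF01")
  expect_equal(tr$group, group_order(lay))
  expect_true(all(tr$n == 2))
  expect_error(trend(aq, "NOPE"), "not found")
  # constant copies give a flat series
  lay1 <- simple_layout(c("A", "B"), 2)
  prm1 <- toy_prm(data.frame(protein_id = "P1", stripped_seq = "AAAK",
                             sample = lay1$sample_name,
                             light_area = 500, heavy_area = 500), lay1)
  aq1 <- copies_per_cell(peptide_ratios(prm1),
                         abs_quant_params(1e5, 1, 1, 10))
  tr1 <- trend(aq1, "P1")
  expect_equal(tr1$mean_copies[1], tr1$mean_copies[2])
  expect_equal(tr1$sd_copies, c(0, 0))
})
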
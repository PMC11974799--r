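make_filter_qt <- function() {
  lay <- simple_layout("g", 2)
  toy_qt(data.frame(
    protein_id = c("P1", "P1;P2", "P3", "P4,P5", "P6"),
    stripped_seq = c("AAAK", "CCCK", "DDDK", "EEEK", "FFFK"),
    proteotypic = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    sample = "g_1", quantity = c(10, 20, 30, 40, 50)), lay)
}

test_that("proteotypic filter keeps flagged rows and reports removals", {
  qt <- make_filter_qt()
  expect_message(out <- filter_proteotypic(qt), "2 non-proteotypic")
  expect_equal(nrow(out), 3L)
  expect_true(all(out$proteotypic))
  # identity when all proteotypic
  all_pt <- qt; all_pt$proteotypic <- TRUE
  expect_equal(nrow(suppressMessages(filter_proteotypic(all_pt))), 5L)
  # degenerate: everything removed, with a warning
  none <- qt; none$proteotypic <- FALSE
  expect_warning(suppressMessages(out0 <- filter_proteotypic(none)),
                 "empty")
  expect_equal(nrow(out0), 0L)
  # Skyline path: no flags -> no-op with warning
  noflag <- qt; noflag$proteotypic <- NA
  expect_warning(out_na <- filter_proteotypic(noflag), "skipped")
  expect_equal(nrow(out_na), 5L)
})

test_that("multi-protein-ID filter removes separator-delimited rows", {
  qt <- make_filter_qt()
  out <- suppressMessages(filter_multi_protein(qt))
  expect_equal(out$protein_id, c("P1", "P3", "P6"))
})

test_that("set-based filters commute", {
  qt <- make_filter_qt()
  ab <- suppressWarnings(suppressMessages(
    filter_multi_protein(filter_proteotypic(qt))))
  ba <- suppressWarnings(suppressMessages(
    filter_proteotypic(filter_multi_protein(qt))))
  expect_equal(as.data.frame(ab), as.data.frame(ba))
})

test_that("sum rollup matches brute-force accumulation", {
  set.seed(42)
  lay <- simple_layout(c("A", "B"), 2)
  n <- 200
  qt <- toy_qt(data.frame(
    protein_id = sprintf("P%02d", sample(20, n, TRUE)),
    stripped_seq = sprintf("SEQ%03dK", sample(60, n, TRUE)),
    sample = sample(lay$sample_name, n, TRUE),
    quantity = round(runif(n, 1, 1000), 3)), lay)
  pm <- rollup_protein(qt, "sum")
  # brute-force oracle over rows
  for (i in sample(nrow(pm$abundance), 5)) for (s in lay$sample_name) {
    sel <- qt$protein_id == rownames(pm$abundance)[i] & qt$sample == s &
      qt$quantity > 0
    expected <- if (any(sel)) sum(qt$quantity[sel]) else NA_real_
    expect_equal(pm$abundance[i, s], expected)
  }
  # conservation of total signal
  expect_equal(sum(pm$abundance, na.rm = TRUE), sum(qt$quantity))
  # unique peptide counts equal distinct-sequence oracle
  for (i in sample(nrow(pm$abundance), 5)) for (s in lay$sample_name) {
    sel <- qt$protein_id == rownames(pm$abundance)[i] & qt$sample == s
    expect_equal(pm$unique_peptides[i, s],
                 length(unique(qt$stripped_seq[sel])))
  }
})

test_that("single-peptide rollup is the identity for all methods", {
  lay <- simple_layout("g", 2)
  qt <- toy_qt(data.frame(protein_id = "P1", stripped_seq = "AAAK",
                          sample = c("g_1", "g_2"),
                          quantity = c(123.5, 456.5),
                          protein_quantity = c(123.5, 456.5)), lay)
  for (m in c("sum", "median", "maxlfq_passthrough")) {
    pm <- rollup_protein(qt, m)
    expect_equal(unname(pm$abundance["P1", ]), c(123.5, 456.5))
  }
})

test_that("passthrough rollup rejects disagreeing protein quantities", {
  lay <- simple_layout("g", 2)
  qt <- toy_qt(data.frame(protein_id = "P1",
                          stripped_seq = c("AAAK", "CCCK"),
                          sample = "g_1", quantity = c(1, 2),
                          protein_quantity = c(100, 200)), lay)
  expect_error(rollup_protein(qt, "maxlfq_passthrough"), "disagreeing")
})

test_that("zero quantities are treated as missing", {
  lay <- simple_layout("g", 2)
  qt <- toy_qt(data.frame(protein_id = "P1", stripped_seq = "AAAK",
                          sample = c("g_1", "g_2"),
                          quantity = c(0, 10)), lay)
  pm <- rollup_protein(qt, "sum")
  expect_true(is.na(pm$abundance["P1", "g_1"]))
  expect_equal(pm$unique_peptides["P1", "g_1"], 0L)
})

test_that("minimum unique-peptide filter masks cells and drops rows", {
  ab <- matrix(c(10, 20, 30, 40), 2, 2,
               dimnames = list(c("P1", "P2"), c("g_1", "g_2")))
  pm <- toy_pm(ab, groups = c("g", "g"))
  pm$unique_peptides[] <- c(1L, 3L, 3L, 2L)  # P1: (1,3); P2: (3,2)
  out <- filter_min_unique_peptides(pm, 2, "per_sample")
  expect_true(is.na(out$abundance["P1", "g_1"]))
  expect_equal(out$abundance["P1", "g_2"], 30)
  expect_equal(out$filter_report$protein_id, "P1")
  # n = 1 is the identity
  id <- filter_min_unique_peptides(pm, 1)
  expect_equal(id$abundance, pm$abundance)
  # global scope keeps proteins reaching n somewhere
  glob <- filter_min_unique_peptides(pm, 3, "global")
  expect_equal(rownames(glob$abundance), c("P1", "P2"))
  glob4 <- filter_min_unique_peptides(pm, 4, "global")
  expect_equal(nrow(glob4$abundance), 0L)
  expect_error(filter_min_unique_peptides(pm, 0), "positive")
})

test_that("unique-peptide filter is monotone in the threshold", {
  set.seed(7)
  ab <- matrix(2^rnorm(120, 15), 30, 4)
  pm <- toy_pm(ab, groups = rep(c("A", "B"), each = 2))
  pm$unique_peptides[] <- sample(0:5, 120, TRUE)
  pm$abundance[pm$unique_peptides == 0L] <- NA
  universe <- function(n)
    rownames(filter_min_unique_peptides(pm, n)$abundance)
  for (k in 1:4)
    expect_true(all(universe(k + 1) %in% universe(k)))
})
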
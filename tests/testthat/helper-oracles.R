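# Shared fixture builders and independent oracles for the test suite.

# small protein_matrix built directly from an abundance matrix
toy_pm <- function(abundance, groups, replicates = NULL) {
  n <- ncol(abundance)
  if (is.null(replicates))
    replicates <- as.integer(stats::ave(seq_len(n), groups,
                                        FUN = seq_along))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0(groups, "_", replicates)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("P", seq_len(nrow(abundance)))
  layout <- sample_layout(run_id = paste0("run", seq_len(n)),
                          sample_name = colnames(abundance),
                          group = groups, replicate = replicates)
  up <- matrix(3L, nrow(abundance), n, dimnames = dimnames(abundance))
  up[is.na(abundance)] <- 0L
  quickprot:::new_protein_matrix(
    abundance, up,
    data.frame(protein_id = rownames(abundance),
               gene = paste0("G_", rownames(abundance)),
               stringsAsFactors = FALSE),
    layout)
}

# quant_table built in code (bypasses file IO)
toy_qt <- function(df, layout) {
  defaults <- data.frame(protein_id = "P1", gene = "G1",
                         peptide_seq = "PEPTIDE", stripped_seq = "PEPTIDE",
                         proteotypic = TRUE, sample = layout$sample_name[1],
                         group = layout$group[1], replicate = 1L,
                         quantity = 1, protein_quantity = NA_real_,
                         points_across_peak = NA_real_, ms_level = 2L,
                         stringsAsFactors = FALSE)
  full <- defaults[rep(1L, nrow(df)), , drop = FALSE]
  for (nm in names(df)) full[[nm]] <- df[[nm]]
  i <- match(full$sample, layout$sample_name)
  full$group <- layout$group[i]
  full$replicate <- layout$replicate[i]
  rownames(full) <- NULL
  structure(full, class = c("quant_table", "data.frame"),
            layout = layout, dropped_runs = 0L)
}

toy_prm <- function(df, layout) {
  i <- match(df$sample, layout$sample_name)
  df$group <- layout$group[i]
  df$replicate <- layout$replicate[i]
  if (is.null(df$gene)) df$gene <- df$protein_id
  rownames(df) <- NULL
  structure(df, class = c("prm_table", "data.frame"), layout = layout,
            dropped_runs = 0L, orphan_light = 0L)
}

simple_layout <- function(groups, replicates) {
  sample_layout(
    run_id = paste0("run_", rep(groups, each = replicates), "_",
                    rep(seq_len(replicates), length(groups))),
    sample_name = paste0(rep(groups, each = replicates), "_",
                         rep(seq_len(replicates), length(groups))),
    group = rep(groups, each = replicates),
    replicate = rep(seq_len(replicates), length(groups)))
}

lognoise_test <- function(n, cv_pct) quickprot:::lognoise(n, cv_pct)

# exhaustive hypergeometric upper-tail sum, independent of phyper:
# P(X >= k) for X ~ Hypergeom(N, K, n)
hyper_tail_oracle <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# pooled two-sample t-test p-value from the textbook formula
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), n1 + n2 - 2)
}

# Welch t-test p-value from the textbook formula
welch_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

# exhaustive pairwise verification of the compact-letter-display
# invariant: share a letter <=> not significantly different
cld_invariant_holds <- function(letters_vec, sig) {
  k <- length(letters_vec)
  chars <- strsplit(letters_vec, "")
  if (any(lengths(chars) == 0L)) return(FALSE)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    share <- length(intersect(chars[[i]], chars[[j]])) > 0L
    if (share == sig[i, j]) return(FALSE)  # share <=> NOT significant
  }
  TRUE
}

# brute-force UPGMA (average linkage) agglomeration returning sorted
# merge heights; independent of stats::hclust
upgma_heights_oracle <- function(d_matrix) {
  clusters <- as.list(seq_len(nrow(d_matrix)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d_matrix[clusters[[a]], clusters[[b]]])
      if (dd < bestd) { bestd <- dd; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}
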
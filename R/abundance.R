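# Two-sample t-test on log2 abundances.  Welch by default (robust to
# unequal variances at small n); pooled available.  Degenerate zero
# variance: equal means -> p = 1 (no evidence of difference); different
# means with zero variance -> smallest positive double so that p stays in
# (0, 1] and -log10(p) is finite.
log2_ttest <- function(a, b, var_equal = FALSE) {
  la <- log2(a); lb <- log2(b)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    p <- if (mean(la) == mean(lb)) 1 else .Machine$double.xmin
    return(list(p = p, lfc = mean(lb) - mean(la)))
  }
  tt <- stats::t.test(lb, la, var.equal = var_equal)
  list(p = tt$p.value, lfc = mean(lb) - mean(la))
}

# fold-change menu values below 1 mean their reciprocal as a two-sided
# bound: 0.5 -> |log2FC| >= 1
symmetrize_fc <- function(fc_thr) max(fc_thr, 1 / fc_thr)

#' Volcano differential-abundance analysis between two groups
#'
#' For each protein observed in at least two replicates of both groups, a
#' two-sample t-test (Welch by default) is run on log2 abundances of
#' `group_b` versus `group_a`; `log2FC = mean_b - mean_a`.  A protein is
#' `up` when `p <= p_thr` and `log2FC >= log2(fc)`, `down` when
#' `p <= p_thr` and `log2FC <= -log2(fc)`, where `fc = max(fc_thr,
#' 1/fc_thr)`; otherwise `not_significant`.  Raw p-values drive the
#' status (matching the interactive threshold menus); a BH-adjusted
#' column is included for transparency.
#'
#' @param pm a `protein_matrix`.
#' @param group_a,group_b group names (b is tested against a).
#' @param p_thr p-value threshold, conventionally 0.05 down to 0.001.
#' @param fc_thr fold-change threshold (> 0), conventionally 0.5 to 10.
#' @param var_equal use the pooled (Student) t-test instead of Welch.
#' @return A `volcano_result` data frame: `protein_id`, `gene`,
#'   `log2FC`, `p_value`, `neg_log10_p`, `p_adj_BH`, `status`; attribute
#'   `excluded` counts proteins with insufficient replicates.
#' @export
volcano <- function(pm, group_a, group_b, p_thr = 0.05, fc_thr = 2,
                    var_equal = FALSE) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (!is.numeric(fc_thr) || fc_thr <= 0)
    stop("fc_thr must be > 0")
  if (!is.numeric(p_thr) || p_thr <= 0 || p_thr > 1)
    stop("p_thr must be in (0, 1]")
  for (g in c(group_a, group_b))
    if (!g %in% group_order(pm$layout))
      stop("unknown group '", g, "'")
  sa <- group_samples(pm$layout, group_a)
  sb <- group_samples(pm$layout, group_b)
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both groups need at least 2 replicates")
  A <- pm$abundance[, sa, drop = FALSE]
  B <- pm$abundance[, sb, drop = FALSE]
  ok <- rowSums(!is.na(A)) >= 2L & rowSums(!is.na(B)) >= 2L
  excluded <- sum(!ok)
  idx <- which(ok)
  res <- lapply(idx, function(i)
    log2_ttest(A[i, !is.na(A[i, ])], B[i, !is.na(B[i, ])], var_equal))
  p <- vapply(res, `[[`, 0, "p")
  lfc <- vapply(res, `[[`, 0, "lfc")
  lfc_cut <- log2(symmetrize_fc(fc_thr))
  status <- rep("not_significant", length(idx))
  status[p <= p_thr & lfc >= lfc_cut] <- "up"
  status[p <= p_thr & lfc <= -lfc_cut] <- "down"
  out <- data.frame(
    protein_id = rownames(pm$abundance)[idx],
    gene = pm$proteins$gene[idx],
    log2FC = lfc, p_value = p, neg_log10_p = -log10(p),
    p_adj_BH = stats::p.adjust(p, method = "BH"),
    status = status, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("volcano_result", "data.frame"),
            group_a = group_a, group_b = group_b,
            p_thr = p_thr, fc_thr = fc_thr, excluded = excluded)
}

#' @export
print.volcano_result <- function(x, ...) {
  cat("Volcano:", attr(x, "group_b"), "vs", attr(x, "group_a"), "-",
      nrow(x), "proteins tested;",
      sum(x$status == "up"), "up,", sum(x$status == "down"), "down",
      sprintf("(p <= %g, FC >= |%g|)\n", attr(x, "p_thr"),
              symmetrize_fc(attr(x, "fc_thr"))))
  invisible(x)
}

#' @export
plot.volcano_result <- function(x, ...) {
  col <- c(up = "firebrick", down = "steelblue",
           not_significant = "grey70")[x$status]
  graphics::plot(x$log2FC, x$neg_log10_p, pch = 16, col = col,
                 xlab = "log2 fold change", ylab = "-log10(P)",
                 main = paste(attr(x, "group_b"), "vs",
                              attr(x, "group_a")), ...)
  lfc_cut <- log2(symmetrize_fc(attr(x, "fc_thr")))
  graphics::abline(v = c(-lfc_cut, lfc_cut),
                   h = -log10(attr(x, "p_thr")), lty = 2, col = "grey40")
  invisible(x)
}

#' Rank proteins by abundance within a group
#'
#' Proteins are sorted by their group-mean abundance (over observed
#' replicates), descending; ties break lexicographically on protein id.
#'
#' @param pm a `protein_matrix`.
#' @param group group name.
#' @return Data frame `rank`, `protein_id`, `gene`, `abundance`.
#' @export
rank_abundance <- function(pm, group) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (!group %in% group_order(pm$layout))
    stop("unknown group '", group, "'")
  sub <- pm$abundance[, group_samples(pm$layout, group), drop = FALSE]
  m <- rowMeans(sub, na.rm = TRUE)
  keep <- !is.nan(m)
  ord <- order(-m[keep], rownames(sub)[keep])
  out <- data.frame(rank = seq_along(ord),
                    protein_id = rownames(sub)[keep][ord],
                    gene = pm$proteins$gene[keep][ord],
                    abundance = m[keep][ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-group abundance bar statistics for one protein
#'
#' Each non-reference group is tested against the reference group with
#' the same t-test used by [volcano()]; groups at `p <= alpha` are marked
#' `"*"`, others `"n.s."`.  The reference group itself is not tested.
#'
#' @param pm a `protein_matrix`.
#' @param protein protein id or gene name.
#' @param reference_group reference group name.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled t-test instead of Welch.
#' @return Data frame `group`, `mean`, `sd`, `p_value`, `mark` in layout
#'   group order.
#' @export
protein_bar_stats <- function(pm, protein, reference_group, alpha = 0.05,
                              var_equal = FALSE) {
  stopifnot(inherits(pm, "protein_matrix"))
  row <- which(rownames(pm$abundance) == protein |
               pm$proteins$gene == protein)
  if (!length(row)) {
    cand <- unique(c(rownames(pm$abundance), pm$proteins$gene))
    near <- cand[agrepl(protein, cand, max.distance = 0.2,
                        ignore.case = TRUE)]
    stop("protein or gene '", protein, "' not found",
         if (length(near)) paste0("; near matches: ",
           paste(utils::head(near, 5), collapse = ", ")), call. = FALSE)
  }
  row <- row[1]
  gs <- group_order(pm$layout)
  if (!reference_group %in% gs)
    stop("unknown reference group '", reference_group, "'")
  ref <- pm$abundance[row, group_samples(pm$layout, reference_group)]
  ref <- ref[!is.na(ref)]
  do.call(rbind, lapply(gs, function(g) {
    v <- pm$abundance[row, group_samples(pm$layout, g)]
    v <- v[!is.na(v)]
    if (g == reference_group) {
      p <- NA_real_; mark <- ""
    } else if (length(v) < 2L || length(ref) < 2L) {
      p <- NA_real_; mark <- "n.s."
    } else {
      p <- log2_ttest(ref, v, var_equal)$p
      mark <- if (!is.na(p) && p <= alpha) "*" else "n.s."
    }
    data.frame(group = g, mean = mean(v), sd = stats::sd(v),
               p_value = p, mark = mark, stringsAsFactors = FALSE)
  }))
}

#' Iterative chained-regression imputation of missing abundances
#'
#' Works on the log2 scale.  Missing cells start at the per-protein mean
#' of observed values; then each sample column in turn is regressed (OLS
#' with intercept) on all other columns over the rows where it is
#' observed, and its missing cells are replaced by the fitted values.
#' Sweeps repeat in a fixed column order until the largest absolute
#' update falls below `tol` or `max_iter` sweeps are reached, so the
#' result is deterministic.  Observed cells are never modified.
#'
#' @param pm a `protein_matrix`; every protein must be observed in at
#'   least one sample and every sample in at least one protein.
#' @param tol convergence tolerance on log2 updates (default 1e-6).
#' @param max_iter maximum sweeps (default 50).
#' @return A complete `protein_matrix` (no missing abundances);
#'   `unique_peptides` is left as-is.
#' @export
impute_iterative <- function(pm, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(pm, "protein_matrix"))
  X <- log2(pm$abundance)
  miss <- is.na(X)
  if (!any(miss)) return(pm)
  if (any(rowSums(!miss) == 0L))
    stop("cannot impute: protein(s) with zero observations: ",
         paste(utils::head(rownames(X)[rowSums(!miss) == 0L], 5),
               collapse = ", "))
  if (any(colSums(!miss) == 0L))
    stop("cannot impute: sample(s) with zero observations")
  rowmean <- rowMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- rowmean[miss[, j]]
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(ncol(X))) {
      mj <- miss[, j]
      if (!any(mj)) next
      obs <- !mj
      pred <- X[, -j, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, pred[obs, , drop = FALSE]), X[obs, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0   # collinear predictors contribute nothing
      new <- drop(cbind(1, pred[mj, , drop = FALSE]) %*% beta)
      delta <- max(delta, max(abs(new - X[mj, j])))
      X[mj, j] <- new
    }
    if (delta < tol) break
  }
  out <- pm
  out$abundance[miss] <- 2^X[miss]
  out
}

#' Heatmap data on the log2 scale
#'
#' Selected-protein mode (`proteins` given): no imputation, no
#' clustering; missing cells are rendered as `"n.d."` (not detected) in
#' the display matrix and observed cells are the exact log2 abundances.
#' Full-matrix mode with `impute = TRUE`: missing cells are filled by
#' [impute_iterative()], then rows and columns are ordered by the same
#' hierarchical clustering as [cluster_profiles()].
#'
#' @param pm a `protein_matrix`.
#' @param proteins optional character vector of protein ids or genes.
#' @param by `"group"` (columns are group means) or `"sample"`.
#' @param impute impute missing values (full-matrix mode only).
#' @return A `heatmap_data` object: list with `values` (numeric log2
#'   matrix, NA where missing), `display` (character matrix with
#'   `"n.d."`), `row_order`, `col_order`, `imputed`.
#' @export
heatmap_data <- function(pm, proteins = NULL, by = c("group", "sample"),
                         impute = FALSE) {
  by <- match.arg(by)
  stopifnot(inherits(pm, "protein_matrix"))
  if (!is.null(proteins)) {
    if (!length(proteins)) stop("empty protein selection")
    rows <- vapply(proteins, function(p) {
      i <- which(rownames(pm$abundance) == p | pm$proteins$gene == p)[1]
      if (is.na(i)) stop("protein or gene '", p, "' not found",
                         call. = FALSE)
      i
    }, 0L)
    M <- log2(pm$abundance[rows, , drop = FALSE])
    rownames(M) <- proteins
    if (by == "group")
      M <- sapply(group_order(pm$layout), function(g)
        rowMeans(M[, group_samples(pm$layout, g), drop = FALSE],
                 na.rm = TRUE)) |>
        matrix(nrow = length(rows),
               dimnames = list(proteins, group_order(pm$layout)))
    M[is.nan(M)] <- NA_real_
    disp <- matrix(ifelse(is.na(M), "n.d.",
                          formatC(M, digits = 3, format = "f")),
                   nrow = nrow(M), dimnames = dimnames(M))
    return(structure(list(values = M, display = disp,
                          row_order = seq_len(nrow(M)),
                          col_order = seq_len(ncol(M)), imputed = FALSE),
                     class = "heatmap_data"))
  }
  pm2 <- if (impute) impute_iterative(pm) else pm
  on <- if (by == "group") "groups" else "samples"
  prof_cols <- if (by == "group") group_order(pm$layout)
               else pm$layout$sample_name
  lg <- log2(pm2$abundance)
  M <- if (by == "group")
    sapply(group_order(pm$layout), function(g)
      rowMeans(lg[, group_samples(pm$layout, g), drop = FALSE],
               na.rm = TRUE))
  else lg
  M[is.nan(M)] <- NA_real_
  col_order <- if (ncol(M) >= 3L)
    cluster_profiles(pm2, on = on)$order else seq_len(ncol(M))
  row_order <- if (nrow(M) >= 3L && !anyNA(M))
    stats::hclust(stats::dist(M), method = "average")$order
  else seq_len(nrow(M))
  disp <- matrix(ifelse(is.na(M), "n.d.",
                        formatC(M, digits = 3, format = "f")),
                 nrow = nrow(M), dimnames = dimnames(M))
  structure(list(values = M, display = disp, row_order = row_order,
                 col_order = col_order, imputed = impute),
            class = "heatmap_data")
}

#' @export
plot.heatmap_data <- function(x, ...) {
  M <- x$values[x$row_order, x$col_order, drop = FALSE]
  graphics::image(t(M)[, rev(seq_len(nrow(M))), drop = FALSE],
                  axes = FALSE, main = "log2 abundance", ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(M)),
                 labels = colnames(M), las = 2, cex.axis = 0.7)
  invisible(x)
}
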
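#' Replicate coefficient of variation per protein and group
#'
#' For every protein observed in at least two replicates of a group, the
#' coefficient of variation is `100 * sd / mean` over the replicate
#' abundances (sample standard deviation, raw scale).  CVs below ~20% are
#' the conventional benchmark for acceptable replicate variability in
#' discovery proteomics.
#'
#' @param pm a `protein_matrix`.
#' @param layout optional `sample_layout`; defaults to the matrix's own.
#' @return A `cv_result`: list with `cv` (per group, named numeric vector
#'   of per-protein CVs in %) and `medians` (per-group median CV in %).
#'   Groups with a single replicate are skipped with a warning.
#' @export
compute_cv <- function(pm, layout = pm$layout) {
  stopifnot(inherits(pm, "protein_matrix"))
  cvs <- list()
  for (g in group_order(layout)) {
    smp <- group_samples(layout, g)
    if (length(smp) < 2L) {
      warning("group '", g, "' has a single replicate; skipped",
              call. = FALSE)
      next
    }
    sub <- pm$abundance[, smp, drop = FALSE]
    nobs <- rowSums(!is.na(sub))
    sub <- sub[nobs >= 2L, , drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    cvs[[g]] <- 100 * s / m
  }
  structure(list(cv = cvs,
                 medians = vapply(cvs, stats::median, 0, na.rm = TRUE)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Replicate CV by group (median %):\n")
  print(round(x$medians, 2))
  invisible(x)
}

#' @export
plot.cv_result <- function(x, ...) {
  graphics::boxplot(x$cv, ylab = "CV (%)", xlab = "Group",
                    main = "Replicate coefficient of variation", ...)
  graphics::abline(h = 20, lty = 2, col = "grey40")
  invisible(x)
}

#' Spearman correlation among the replicates of a group
#'
#' Rank correlation is computed on proteins observed in both members of
#' each replicate pair (pairwise-complete); ties get average ranks.  A
#' pair sharing fewer than 3 proteins is reported as `NA` with a warning.
#'
#' @param pm a `protein_matrix`.
#' @param group group name.
#' @return A `correlation_result`: list with `group`, `rho` (replicate x
#'   replicate Spearman matrix, unit diagonal) and `data` (the abundance
#'   submatrix used, for paired scatter plots).
#' @export
replicate_correlation <- function(pm, group) {
  stopifnot(inherits(pm, "protein_matrix"))
  smp <- group_samples(pm$layout, group)
  if (length(smp) < 2L)
    stop("group '", group, "' needs at least 2 replicates")
  sub <- pm$abundance[, smp, drop = FALSE]
  k <- length(smp)
  rho <- diag(1, k); dimnames(rho) <- list(smp, smp)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    both <- stats::complete.cases(sub[, c(i, j)])
    if (sum(both) < 3L) {
      warning("fewer than 3 shared proteins between ", smp[i], " and ",
              smp[j], "; correlation reported missing", call. = FALSE)
      rho[i, j] <- rho[j, i] <- NA_real_
    } else {
      rho[i, j] <- rho[j, i] <-
        stats::cor(sub[both, i], sub[both, j], method = "spearman")
    }
  }
  structure(list(group = group, rho = rho, data = sub),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Spearman correlation, group", x$group, "\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' @export
plot.correlation_result <- function(x, ...) {
  graphics::pairs(log2(x$data),
                  main = paste0("Group ", x$group,
                                " replicate correlation (Spearman)"), ...)
  invisible(x)
}

#' Distribution of MS points across chromatographic peaks
#'
#' The number of MS scans sampling an elution peak is a quantification
#' fidelity metric; medians of 8 or more points are generally considered
#' adequate peak coverage.  Requires an export carrying the points
#' column (Skyline path).
#'
#' @param qt a `quant_table`.
#' @param layout optional layout; defaults to the table's own.
#' @param level MS level, 1 or 2 (default 2, the DIA/PRM quantification
#'   level).
#' @return A `points_result`: list with `points` (per-group integer
#'   vectors) and `medians`.
#' @export
ms_points_distribution <- function(qt, layout = attr(qt, "layout"),
                                   level = 2L) {
  stopifnot(inherits(qt, "quant_table"))
  if (!level %in% c(1L, 2L)) stop("level must be 1 or 2")
  if (all(is.na(qt$points_across_peak)))
    stop("feature unavailable: this export has no '",
         skyline_columns()$points_across_peak,
         "' column; re-export with points across the peak included",
         call. = FALSE)
  sel <- qt$ms_level == level & !is.na(qt$points_across_peak)
  pts <- split(qt$points_across_peak[sel],
               factor(qt$group[sel], levels = group_order(layout)))
  structure(list(points = pts,
                 medians = vapply(pts, stats::median, 0, na.rm = TRUE),
                 level = level),
            class = "points_result")
}

#' @export
print.points_result <- function(x, ...) {
  cat("MS", x$level, " points across peak, group medians:\n", sep = "")
  print(x$medians)
  invisible(x)
}

#' @export
plot.points_result <- function(x, ...) {
  graphics::boxplot(x$points, ylab = paste0("MS", x$level, " points"),
                    xlab = "Group",
                    main = "Points across chromatographic peak", ...)
  invisible(x)
}
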
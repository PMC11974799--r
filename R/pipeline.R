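#' Run a full analysis pipeline
#'
#' Executes one of the end-to-end pipelines and writes every table and
#' figure into the standard output tree (`TABLES/`, `PLOTS/`):
#'
#' * `dia-diann` / `dia-skyline`: preprocessing (proteotypic and
#'   multi-ID filters on the DIA-NN path, minimum-unique-peptide
#'   threshold), QC (replicate CV, Spearman replicate correlation,
#'   MS2 points where exported), yields, shared/unique/core breakdown,
#'   clustering dendrogram and group correlation matrix, abundance
#'   ranking, volcano analyses of the reference group against every
#'   other group, clustering heatmap, and (given GMT files) enrichment
#'   of up/down lists.
#' * `prm-free`: label-free PRM relative mode — same stages on the
#'   summed PRM light areas.
#' * `prm-heavy`: peptide light/heavy ratios, copies per nucleus,
#'   per-protein trends, stoichiometry ANOVA/Tukey/compact letters.
#'
#' Stage progress and row counts are logged to stderr.
#'
#' @param pipeline pipeline name.
#' @param input path to the quantification export.
#' @param layout path to the layout YAML, or a `sample_layout`.
#' @param out output root directory.
#' @param min_peptides minimum unique peptides per protein (default 2).
#' @param p_thr,fc_thr volcano thresholds (menus: p 0.05-0.001, FC
#'   0.5-10; out-of-menu values need `force = TRUE`).
#' @param alpha significance level for PRM statistics.
#' @param params path to the absolute-quantification YAML (prm-heavy).
#' @param gmt named list/vector of GMT paths (names = namespace), or
#'   `NULL` to skip enrichment.
#' @param reference reference group (default: first in group order).
#' @param impute impute missing values for the full heatmap.
#' @param force allow thresholds outside the menu ranges.
#' @return An `output_manifest`.
#' @export
run_pipeline <- function(pipeline = c("dia-diann", "dia-skyline",
                                      "prm-free", "prm-heavy"),
                         input, layout, out,
                         min_peptides = 2L, p_thr = 0.05, fc_thr = 2,
                         alpha = 0.05, params = NULL, gmt = NULL,
                         reference = NULL, impute = TRUE,
                         force = FALSE) {
  pipeline <- match.arg(pipeline)
  if (!force) {
    if (p_thr < 0.001 || p_thr > 0.05)
      stop("p_thr outside the 0.001-0.05 menu range (use force = TRUE)")
    if (fc_thr < 0.5 || fc_thr > 10)
      stop("fc_thr outside the 0.5-10 menu range (use force = TRUE)")
  }
  if (!inherits(layout, "sample_layout")) layout <- read_layout(layout)
  log_stage <- function(...) message("[quickprot] ", ...)
  t0 <- proc.time()[["elapsed"]]
  if (pipeline == "prm-heavy") {
    log_stage("reading PRM heavy-label export")
    prm <- read_skyline_table(input, layout, mode = "prm_heavy")
    log_stage(nrow(prm), " paired peptide x run rows")
    if (is.null(params))
      stop("prm-heavy requires an absolute-quantification params file")
    pq <- if (inherits(params, "abs_quant_params")) params
          else read_abs_quant_params(params)
    ratios <- peptide_ratios(prm)
    aq <- copies_per_cell(ratios, pq)
    log_stage("absolute quantification done: ",
              length(unique(aq$copies$protein_id)), " proteins")
    # protein x sample copies matrix for QC / clustering
    cp <- aq$copies
    ab <- matrix(NA_real_, length(unique(cp$protein_id)),
                 nrow(layout),
                 dimnames = list(sort(unique(cp$protein_id)),
                                 layout$sample_name))
    ab[cbind(cp$protein_id, cp$sample)] <- cp$copies
    up <- matrix(1L, nrow(ab), ncol(ab), dimnames = dimnames(ab))
    up[is.na(ab)] <- 0L
    zero <- !is.na(ab) & ab == 0
    ab[zero] <- NA_real_; up[zero] <- 0L
    pmc <- new_protein_matrix(ab, up,
      data.frame(protein_id = rownames(ab),
                 gene = cp$gene[match(rownames(ab), cp$protein_id)],
                 stringsAsFactors = FALSE), layout)
    cv <- compute_cv(pmc)
    trends <- do.call(rbind, lapply(rownames(ab), function(p)
      cbind(protein_id = p, trend(aq, p))))
    prots <- rownames(ab)[rowSums(!is.na(ab)) == ncol(ab)]
    results <- list(copies_per_nucleus = aq, cv = cv,
                    trend_series = trends)
    if (length(prots) >= 2L) {
      ref_g <- if (is.null(reference)) group_order(layout)[1]
               else reference
      sc <- stoichiometry_compare(aq, utils::head(prots, 8L), ref_g,
                                  alpha = alpha)
      results$stoichiometry <- sc$bars
      results$stoichiometry_pairs <- sc$tukey$pairs
    }
    if (nrow(layout) >= 3L && length(group_order(layout)) >= 3L)
      results$dendrogram <- cluster_profiles(pmc, on = "groups")
    man <- write_outputs(results, out)
    log_stage(sprintf("pipeline finished in %.1fs",
                      proc.time()[["elapsed"]] - t0))
    return(man)
  }
  log_stage("reading ", pipeline, " export")
  qt <- if (pipeline == "dia-diann")
    read_diann_report(input, layout)
  else read_skyline_table(input, layout,
                          mode = if (pipeline == "prm-free") "prm_free"
                                 else "dia")
  log_stage(nrow(qt), " peptide x run rows")
  if (pipeline == "dia-diann") {
    qt <- filter_proteotypic(qt)
    qt <- filter_multi_protein(qt)
  }
  pm <- rollup_protein(qt, method = if (pipeline == "dia-diann" &&
                                        !all(is.na(qt$protein_quantity)))
    "maxlfq_passthrough" else "sum")
  pm <- filter_min_unique_peptides(pm, min_peptides)
  log_stage(nrow(pm$abundance), " proteins after filters")
  gs <- group_order(layout)
  ref_g <- if (is.null(reference)) gs[1] else reference
  results <- list(
    cv = compute_cv(pm),
    yields_samples = count_yields(pm, qt)$samples,
    yields_groups = count_yields(pm, qt)$groups)
  if (length(gs) >= 2L) results$shared_unique <- shared_unique(pm)
  if (length(gs) >= 3L)
    results$dendrogram <- cluster_profiles(pm, on = "groups")
  if (length(gs) >= 2L) {
    gcm <- group_correlation_matrix(pm)
    results$group_correlation <- gcm
  }
  if (!all(is.na(qt$points_across_peak))) {
    pr <- ms_points_distribution(qt)
    results$ms_points <- data.frame(group = names(pr$medians),
                                    median_points = pr$medians)
  }
  for (g in gs) {
    rk <- rank_abundance(pm, g)
    results[[paste0("ranking_", g)]] <- rk
  }
  for (g in setdiff(gs, ref_g)) {
    v <- try(volcano(pm, ref_g, g, p_thr = p_thr, fc_thr = fc_thr),
             silent = TRUE)
    if (inherits(v, "try-error")) next
    results[[paste0("volcano_", ref_g, "_vs_", g)]] <- v
    if (!is.null(gmt)) {
      sets <- do.call(combine_annotation_sets, lapply(names(gmt),
        function(ns) read_gmt(gmt[[ns]], namespace = ns)))
      background <- unique(pm$proteins$gene)
      for (dir in c("up", "down")) {
        genes <- v$gene[v$status == dir]
        if (length(genes))
          results[[paste0("enrichment_", dir, "_", g)]] <-
            enrich(genes, background, sets)
      }
    }
  }
  hm <- try(heatmap_data(pm, by = "group",
                         impute = impute && anyNA(pm$abundance)),
            silent = TRUE)
  if (!inherits(hm, "try-error")) {
    results$heatmap <- function() plot(hm)
    results$heatmap_values <- data.frame(
      protein_id = rownames(hm$values)[hm$row_order],
      as.data.frame(hm$values[hm$row_order, hm$col_order,
                              drop = FALSE]),
      check.names = FALSE)
  }
  man <- write_outputs(results, out)
  log_stage(sprintf("pipeline finished in %.1fs",
                    proc.time()[["elapsed"]] - t0))
  man
}
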
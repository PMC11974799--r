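#' Default column mapping for DIA-NN report tables
#'
#' DIA-NN lets users customize export columns, so the reader resolves all
#' columns through this mapping; override any entry to match a custom
#' export.  `protein_quantity` (the tool-provided MaxLFQ protein-group
#' quantity) and `points_across_peak` are optional.
#'
#' @param ... named overrides, e.g. `run = "File.Name"`.
#' @return Named list of column names.
#' @export
diann_columns <- function(...) {
  cols <- list(
    protein_id = "Protein.Group",
    gene = "Genes",
    peptide_seq = "Modified.Sequence",
    stripped_seq = "Stripped.Sequence",
    proteotypic = "Proteotypic",
    run = "Run",
    quantity = "Precursor.Quantity",
    protein_quantity = "PG.MaxLFQ"
  )
  utils::modifyList(cols, list(...))
}

#' Default column mapping for Skyline CSV exports
#'
#' @param ... named overrides, e.g. `quantity = "Total Area"`.
#' @return Named list of column names.
#' @export
skyline_columns <- function(...) {
  cols <- list(
    protein_id = "Protein",
    gene = "Gene",
    peptide_seq = "Peptide",
    run = "Replicate Name",
    quantity = "Total Area Fragment",
    points_across_peak = "Points Across Peak",
    isotope_label = "Isotope Label Type"
  )
  utils::modifyList(cols, list(...))
}

qp_check_columns <- function(df, cols, mandatory, path) {
  for (key in mandatory) {
    if (!cols[[key]] %in% names(df))
      stop("format error: mandatory column '", cols[[key]],
           "' (", key, ") not found in ", path, call. = FALSE)
  }
}

# Numeric parse that rejects thousands separators / locale decimals:
# plain-period decimals only.
qp_as_numeric <- function(x, what) {
  x <- as.character(x)
  bad <- grepl(",", x, fixed = TRUE)
  if (any(bad, na.rm = TRUE))
    stop("format error: non plain-period numeric value in column '", what,
         "' (thousands separators / locale decimals are rejected)",
         call. = FALSE)
  suppressWarnings(as.numeric(x))
}

qp_apply_layout <- function(df, run, layout, path) {
  idx <- match(run, layout$run_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0L)
    message(dropped, " row(s) dropped from ", basename(path),
            ": run not present in the sample layout")
  keep <- !is.na(idx)
  list(df = df[keep, , drop = FALSE], idx = idx[keep], dropped = dropped)
}

new_quant_table <- function(df, layout, dropped = 0L) {
  rownames(df) <- NULL
  structure(df, class = c("quant_table", "data.frame"),
            layout = layout, dropped_runs = dropped)
}

#' Read a DIA-NN long-format report
#'
#' Reads the tab-separated DIA-NN `report.tsv` export (one row per
#' precursor per run), renames runs to sample names per the layout, and
#' drops rows whose run is absent from the layout (the count is reported).
#'
#' @param path path to the tab-separated report.
#' @param layout a [sample_layout()].
#' @param columns column mapping, see [diann_columns()].
#' @return A `quant_table` data frame with columns `protein_id`, `gene`,
#'   `peptide_seq`, `stripped_seq`, `proteotypic`, `sample`, `group`,
#'   `replicate`, `quantity`, `protein_quantity` (NA when the export lacks
#'   it), `points_across_peak` (NA), `ms_level`.
#' @export
read_diann_report <- function(path, layout, columns = diann_columns()) {
  stopifnot(inherits(layout, "sample_layout"))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L)
    stop("format error: empty DIA-NN report: ", path, call. = FALSE)
  qp_check_columns(df, columns,
                   c("protein_id", "gene", "peptide_seq", "stripped_seq",
                     "proteotypic", "run", "quantity"), path)
  ap <- qp_apply_layout(df, as.character(df[[columns$run]]), layout, path)
  df <- ap$df; idx <- ap$idx
  pq <- if (columns$protein_quantity %in% names(df))
    qp_as_numeric(df[[columns$protein_quantity]], columns$protein_quantity)
  else rep(NA_real_, nrow(df))
  out <- data.frame(
    protein_id = as.character(df[[columns$protein_id]]),
    gene = as.character(df[[columns$gene]]),
    peptide_seq = as.character(df[[columns$peptide_seq]]),
    stripped_seq = as.character(df[[columns$stripped_seq]]),
    proteotypic = qp_as_numeric(df[[columns$proteotypic]],
                                columns$proteotypic) != 0,
    sample = layout$sample_name[idx],
    group = layout$group[idx],
    replicate = layout$replicate[idx],
    quantity = qp_as_numeric(df[[columns$quantity]], columns$quantity),
    protein_quantity = pq,
    points_across_peak = NA_real_,
    ms_level = 2L,
    stringsAsFactors = FALSE
  )
  bad <- !grepl("^[A-Z]+$", out$stripped_seq)
  if (any(bad))
    stop("format error: stripped sequence(s) with non amino-acid ",
         "characters, e.g. '", out$stripped_seq[which(bad)[1]], "'",
         call. = FALSE)
  new_quant_table(out, layout, ap$dropped)
}

#' Read a Skyline CSV export (DIA or PRM)
#'
#' In `dia` and `prm_free` modes a `quant_table` is returned (points across
#' the chromatographic peak retained when exported).  In `prm_heavy` mode,
#' light and heavy rows for the same peptide and run are joined into one
#' `prm_table` row carrying both areas; light rows without a heavy partner
#' are excluded with a warning.
#'
#' @param path path to the comma-separated export.
#' @param layout a [sample_layout()].
#' @param mode one of `"dia"`, `"prm_free"`, `"prm_heavy"`.
#' @param columns column mapping, see [skyline_columns()].
#' @return A `quant_table` (dia / prm_free) or `prm_table` (prm_heavy).
#' @export
read_skyline_table <- function(path, layout,
                               mode = c("dia", "prm_free", "prm_heavy"),
                               columns = skyline_columns()) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "sample_layout"))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L)
    stop("format error: empty Skyline export: ", path, call. = FALSE)
  qp_check_columns(df, columns,
                   c("protein_id", "peptide_seq", "run", "quantity"), path)
  ap <- qp_apply_layout(df, as.character(df[[columns$run]]), layout, path)
  df <- ap$df; idx <- ap$idx
  gene <- if (columns$gene %in% names(df)) as.character(df[[columns$gene]])
          else as.character(df[[columns$protein_id]])
  pap <- if (columns$points_across_peak %in% names(df))
    qp_as_numeric(df[[columns$points_across_peak]],
                  columns$points_across_peak)
  else rep(NA_real_, nrow(df))
  pep <- as.character(df[[columns$peptide_seq]])
  base <- data.frame(
    protein_id = as.character(df[[columns$protein_id]]),
    gene = gene,
    peptide_seq = pep,
    stripped_seq = strip_modifications(pep),
    proteotypic = NA,
    sample = layout$sample_name[idx],
    group = layout$group[idx],
    replicate = layout$replicate[idx],
    quantity = qp_as_numeric(df[[columns$quantity]], columns$quantity),
    protein_quantity = NA_real_,
    points_across_peak = pap,
    ms_level = 2L,
    stringsAsFactors = FALSE
  )
  if (mode != "prm_heavy") {
    if (columns$isotope_label %in% names(df)) {
      lab <- tolower(as.character(df[[columns$isotope_label]]))
      base <- base[lab %in% c("light", "", NA), , drop = FALSE]
    }
    return(new_quant_table(base, layout, ap$dropped))
  }
  if (!columns$isotope_label %in% names(df))
    stop("format error: heavy-label mode requires column '",
         columns$isotope_label, "' in ", path, call. = FALSE)
  lab <- tolower(as.character(df[[columns$isotope_label]]))
  light <- base[lab == "light", , drop = FALSE]
  heavy <- base[lab == "heavy", , drop = FALSE]
  if (nrow(heavy) == 0L)
    stop("format error: heavy-label mode but no heavy-labeled rows in ",
         path, call. = FALSE)
  key <- function(d) paste(d$protein_id, d$stripped_seq, d$sample, sep = "\r")
  m <- match(key(light), key(heavy))
  orphans <- sum(is.na(m))
  if (orphans > 0L)
    warning(orphans, " light row(s) without a heavy partner excluded",
            call. = FALSE)
  keep <- !is.na(m)
  out <- data.frame(
    protein_id = light$protein_id[keep],
    gene = light$gene[keep],
    stripped_seq = light$stripped_seq[keep],
    sample = light$sample[keep],
    group = light$group[keep],
    replicate = light$replicate[keep],
    light_area = light$quantity[keep],
    heavy_area = heavy$quantity[m[keep]],
    points_across_peak = light$points_across_peak[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("prm_table", "data.frame"), layout = layout,
            dropped_runs = ap$dropped, orphan_light = orphans)
}

#' @export
print.quant_table <- function(x, ...) {
  cat("Quantification table:", nrow(x), "peptide x run rows,",
      length(unique(x$protein_id)), "proteins,",
      length(unique(x$sample)), "samples\n")
  utils::head(as.data.frame(x)) |> print()
  invisible(x)
}

#' @export
print.prm_table <- function(x, ...) {
  cat("PRM table:", nrow(x), "peptide x run rows (light/heavy paired),",
      length(unique(x$protein_id)), "proteins\n")
  utils::head(as.data.frame(x)) |> print()
  invisible(x)
}
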
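# create parent directories and write a CSV
qp_write_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Save a plot expression as a 300-dpi TIFF
#'
#' All figure output follows the folder contract: TIFF images at 300 dpi
#' under `PLOTS/`.
#'
#' @param path output path (`.tiff`).
#' @param expr expression producing the plot.
#' @param width,height size in inches.
#' @return `path`, invisibly.
#' @export
save_tiff <- function(path, expr, width = 6, height = 5) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::tiff(path, width = width, height = height, units = "in",
                  res = 300, compression = "lzw")
  on.exit(grDevices::dev.off())
  force(expr)
  invisible(path)
}

new_manifest <- function(root) {
  structure(list(root = root, tables = character(),
                 plots = character()), class = "output_manifest")
}

add_table <- function(manifest, path) {
  manifest$tables <- c(manifest$tables, path); manifest
}
add_plot <- function(manifest, path) {
  manifest$plots <- c(manifest$plots, path); manifest
}

#' Validate an output manifest
#'
#' Checks that every declared table and plot exists on disk and that
#' plot files are TIFF.
#'
#' @param manifest an `output_manifest`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "output_manifest"))
  missing <- c(manifest$tables, manifest$plots)[
    !file.exists(c(manifest$tables, manifest$plots))]
  if (length(missing))
    stop("manifest artifacts missing on disk: ",
         paste(missing, collapse = ", "))
  if (length(manifest$plots) &&
      !all(grepl("\\.tiff?$", manifest$plots, ignore.case = TRUE)))
    stop("plot artifacts must be TIFF files")
  invisible(TRUE)
}

#' @export
print.output_manifest <- function(x, ...) {
  cat("Output manifest at", x$root, "\n  tables:", length(x$tables),
      "\n  plots:", length(x$plots), "\n")
  invisible(x)
}

#' Write module results into the standard output folder tree
#'
#' Materializes the folder contract: CSV tables under `TABLES/` (volcano
#' lists under `TABLES/VOLCANO_PLOT_VALUES/` as all/upregulated/
#' downregulated files, shared/unique lists under
#' `TABLES/SHARED_UNIQUE_PROTEINS/`), figures under `PLOTS/` as TIFF at
#' 300 dpi.  Empty result sets produce header-only CSVs.
#'
#' @param results named list of module outputs (`volcano_result`,
#'   `shared_unique`, `cv_result`, `enrichment_result`,
#'   `abs_quant_result`, data frames, or plot closures).
#' @param root output root directory.
#' @return An `output_manifest`.
#' @export
write_outputs <- function(results, root) {
  ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root))
    stop("I/O error: cannot create output root ", root)
  tables_dir <- file.path(root, "TABLES")
  plots_dir <- file.path(root, "PLOTS")
  man <- new_manifest(root)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "volcano_result")) {
      vd <- file.path(tables_dir, "VOLCANO_PLOT_VALUES")
      df <- as.data.frame(x)
      man <- add_table(man, qp_write_csv(df,
        file.path(vd, paste0(nm, "_all.csv"))))
      man <- add_table(man, qp_write_csv(df[df$status == "up", ],
        file.path(vd, paste0(nm, "_upregulated.csv"))))
      man <- add_table(man, qp_write_csv(df[df$status == "down", ],
        file.path(vd, paste0(nm, "_downregulated.csv"))))
      man <- add_plot(man, save_tiff(
        file.path(plots_dir, paste0(nm, ".tiff")), plot(x)))
    } else if (inherits(x, "shared_unique")) {
      sd <- file.path(tables_dir, "SHARED_UNIQUE_PROTEINS")
      for (g in names(x$unique))
        man <- add_table(man, qp_write_csv(
          data.frame(protein_id = x$unique[[g]]),
          file.path(sd, paste0("unique_", g, ".csv"))))
      man <- add_table(man, qp_write_csv(
        data.frame(group = rownames(x$shared_counts),
                   as.data.frame(x$shared_counts)),
        file.path(sd, "shared_counts.csv")))
      man <- add_table(man, qp_write_csv(
        data.frame(protein_id = x$core),
        file.path(sd, "core_proteins.csv")))
    } else if (inherits(x, "cv_result")) {
      long <- do.call(rbind, lapply(names(x$cv), function(g)
        data.frame(group = g, protein_id = names(x$cv[[g]]),
                   cv_percent = unname(x$cv[[g]]))))
      man <- add_table(man, qp_write_csv(long,
        file.path(tables_dir, paste0(nm, ".csv"))))
      man <- add_plot(man, save_tiff(
        file.path(plots_dir, paste0(nm, ".tiff")), plot(x)))
    } else if (inherits(x, "abs_quant_result")) {
      man <- add_table(man, qp_write_csv(x$copies,
        file.path(tables_dir, paste0(nm, ".csv"))))
    } else if (inherits(x, "enrichment_result")) {
      man <- add_table(man, qp_write_csv(as.data.frame(x),
        file.path(tables_dir, paste0(nm, ".csv"))))
      if (nrow(x))
        man <- add_plot(man, save_tiff(
          file.path(plots_dir, paste0(nm, ".tiff")), plot(x)))
    } else if (is.function(x)) {
      man <- add_plot(man, save_tiff(
        file.path(plots_dir, paste0(nm, ".tiff")), x()))
    } else if (is.data.frame(x)) {
      man <- add_table(man, qp_write_csv(x,
        file.path(tables_dir, paste0(nm, ".csv"))))
    } else if (inherits(x, "hclust")) {
      man <- add_plot(man, save_tiff(
        file.path(plots_dir, paste0(nm, ".tiff")),
        plot(x, main = nm, xlab = "", sub = "")))
    } else if (is.matrix(x)) {
      man <- add_table(man, qp_write_csv(
        data.frame(name = rownames(x), as.data.frame(x),
                   check.names = FALSE),
        file.path(tables_dir, paste0(nm, ".csv"))))
    } else {
      warning("unhandled result type for '", nm, "'; skipped",
              call. = FALSE)
    }
  }
  validate_manifest(man)
  man
}
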
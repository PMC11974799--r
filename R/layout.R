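#' Sample layout: run identifiers, sample names, groups and replicates
#'
#' A sample layout maps the raw run identifiers found in a quantification
#' export to human-readable sample names, experimental groups and replicate
#' indices, and fixes the display order of the groups.  Every downstream
#' table and plot uses the layout's names and group order.
#'
#' @param run_id character vector of raw run identifiers (must be unique).
#' @param sample_name character vector of display names, one per run.
#' @param group character vector of experimental group labels, one per run.
#' @param replicate positive integer replicate index within the group;
#'   every (group, replicate) pair must be unique.
#' @param group_order optional character vector giving the display order of
#'   the groups.  Defaults to order of first appearance.  Must contain
#'   exactly the groups present in `group`.
#' @return An object of class `sample_layout`: a data frame with columns
#'   `run_id`, `sample_name`, `group`, `replicate` and attribute
#'   `group_order`.
#' @examples
#' sample_layout(c("r1", "r2"), c("D0_1", "D0_2"), c("D0", "D0"), c(1, 2))
#' @export
sample_layout <- function(run_id, sample_name, group, replicate,
                          group_order = NULL) {
  run_id <- as.character(run_id)
  sample_name <- as.character(sample_name)
  group <- as.character(group)
  replicate <- as.integer(replicate)
  n <- length(run_id)
  if (length(sample_name) != n || length(group) != n || length(replicate) != n)
    stop("run_id, sample_name, group and replicate must have equal length")
  if (anyDuplicated(run_id))
    stop("run_id values must be unique")
  if (anyDuplicated(sample_name))
    stop("sample_name values must be unique")
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate must be a positive integer")
  if (anyDuplicated(paste(group, replicate, sep = "\r")))
    stop("every (group, replicate) pair must be unique")
  if (is.null(group_order)) group_order <- unique(group)
  group_order <- as.character(group_order)
  if (!setequal(group_order, unique(group)))
    stop("group_order must contain exactly the groups present in the layout")
  ord <- order(match(group, group_order), replicate)
  out <- data.frame(run_id = run_id, sample_name = sample_name,
                    group = group, replicate = replicate,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_order") <- group_order
  class(out) <- c("sample_layout", "data.frame")
  out
}

#' Read a sample layout from a YAML config file
#'
#' The file holds a list `samples:` of records with fields `run`, `sample`,
#' `group`, `replicate`, and an optional top-level `group_order:` list.
#'
#' @param path path to the YAML file.
#' @return A [sample_layout()] object.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$samples) || !length(cfg$samples))
    stop("layout file has no 'samples' entries: ", path)
  get1 <- function(rec, key) {
    if (is.null(rec[[key]])) stop("layout entry missing field '", key, "'")
    rec[[key]]
  }
  sample_layout(
    run_id = vapply(cfg$samples, get1, "", key = "run"),
    sample_name = vapply(cfg$samples, function(r)
      as.character(get1(r, "sample")), ""),
    group = vapply(cfg$samples, function(r)
      as.character(get1(r, "group")), ""),
    replicate = vapply(cfg$samples, function(r)
      as.integer(get1(r, "replicate")), 1L),
    group_order = if (!is.null(cfg$group_order))
      as.character(cfg$group_order) else NULL
  )
}

#' Write a sample layout to a YAML config file
#'
#' @param layout a [sample_layout()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "sample_layout"))
  cfg <- list(
    group_order = as.list(group_order(layout)),
    samples = lapply(seq_len(nrow(layout)), function(i) list(
      run = layout$run_id[i], sample = layout$sample_name[i],
      group = layout$group[i], replicate = layout$replicate[i]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Group display order of a sample layout
#' @param layout a [sample_layout()] object.
#' @return Character vector of group names in display order.
#' @export
group_order <- function(layout) {
  stopifnot(inherits(layout, "sample_layout"))
  attr(layout, "group_order")
}

#' @export
print.sample_layout <- function(x, ...) {
  cat("Sample layout:", nrow(x), "runs,",
      length(group_order(x)), "groups (",
      paste(group_order(x), collapse = ", "), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}
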
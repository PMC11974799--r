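#' Read gene sets from a GMT file
#'
#' One tab-separated line per set: set id, description, then member
#' genes.  Offline GMT files (KEGG-pathway-style or GO-style) replace
#' live annotation services.
#'
#' @param path path to the GMT file.
#' @param namespace annotation namespace for all sets in the file: one of
#'   `"pathway"`, `"MF"`, `"CC"`, `"BP"`.
#' @return An `annotation_sets` object: data frame `set_id`, `set_name`,
#'   `namespace` with a `members` list column.
#' @export
read_gmt <- function(path, namespace = c("pathway", "MF", "CC", "BP")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("format error: empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("format error: GMT line with fewer than 3 fields in ", path)
  out <- data.frame(
    set_id = vapply(parts, `[[`, "", 1L),
    set_name = vapply(parts, `[[`, "", 2L),
    namespace = namespace, stringsAsFactors = FALSE)
  if (anyDuplicated(out$set_id))
    stop("format error: duplicate set ids in ", path)
  out$members <- lapply(parts, function(p) unique(p[-(1:2)]))
  class(out) <- c("annotation_sets", "data.frame")
  out
}

#' Combine annotation-set collections
#' @param ... `annotation_sets` objects.
#' @return A single `annotation_sets` data frame.
#' @export
combine_annotation_sets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  if (anyDuplicated(out$set_id)) stop("duplicate set ids across files")
  class(out) <- c("annotation_sets", "data.frame")
  out
}

#' Over-representation enrichment analysis
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of the query
#' gene list against each annotation set, restricted to the background:
#' with `N` background genes, `K` of them in the set, a query of size
#' `n` and overlap `k`, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`.
#' Benjamini-Hochberg adjustment is applied within each namespace.  The
#' background should be the quantified proteome of the experiment (not
#' the whole genome) to guard against detection bias.
#'
#' @param query character vector of gene symbols (e.g. an upregulated
#'   list); must be a subset of `background`.
#' @param background character vector of gene symbols.
#' @param sets an `annotation_sets` object (see [read_gmt()]).
#' @param namespace optional filter, e.g. `"pathway"`.
#' @return An `enrichment_result` data frame sorted by p-value:
#'   `set_id`, `set_name`, `namespace`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_adj_BH`, `genes` (overlap, `;`-separated).
#' @export
enrich <- function(query, background, sets, namespace = NULL) {
  stopifnot(inherits(sets, "annotation_sets"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (!length(query)) stop("empty query gene list")
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  if (!is.null(namespace))
    sets <- sets[sets$namespace %in% namespace, , drop = FALSE]
  N <- length(background)
  n <- length(query)
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    members <- intersect(sets$members[[i]], background)
    K <- length(members)
    hits <- intersect(query, members)
    k <- length(hits)
    # upper tail including k itself
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = sets$set_id[i], set_name = sets$set_name[i],
               namespace = sets$namespace[i], k = k, K = K, n = n, N = N,
               p_value = p, genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_BH <- NA_real_
  for (ns in unique(out$namespace)) {
    sel <- out$namespace == ns
    out$p_adj_BH[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out <- out[order(out$p_value, out$set_id),
             c("set_id", "set_name", "namespace", "k", "K", "n", "N",
               "p_value", "p_adj_BH", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment:", nrow(x), "sets tested;",
      sum(x$p_adj_BH <= 0.05), "with BH-adjusted p <= 0.05\n")
  print(utils::head(as.data.frame(x)[, c("set_id", "k", "K", "p_value",
                                         "p_adj_BH")]))
  invisible(x)
}

#' @export
plot.enrichment_result <- function(x, top = 10L, ...) {
  x <- utils::head(x, top)
  graphics::par(mar = c(4, 12, 2, 1))
  graphics::barplot(rev(-log10(x$p_value)), horiz = TRUE,
                    names.arg = rev(x$set_id), las = 1, cex.names = 0.7,
                    xlab = "-log10(P)", main = "Top enriched sets", ...)
  invisible(x)
}
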
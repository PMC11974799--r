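#' Keep only proteotypic peptides
#'
#' Proteotypic peptides map to exactly one protein group and are the safe
#' basis for protein-level inference.  When the export carries no
#' proteotypic flag (Skyline path) the table is returned unchanged with a
#' warning.
#'
#' @param qt a `quant_table`.
#' @return The filtered `quant_table`; the number of removed rows is
#'   reported via `message()`.
#' @export
filter_proteotypic <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  if (all(is.na(qt$proteotypic))) {
    warning("no proteotypic flags in this export; filter skipped",
            call. = FALSE)
    return(qt)
  }
  keep <- !is.na(qt$proteotypic) & qt$proteotypic
  removed <- sum(!keep)
  message(removed, " non-proteotypic row(s) removed")
  if (removed == nrow(qt))
    warning("all rows are non-proteotypic; the table is now empty",
            call. = FALSE)
  new_quant_table(qt[keep, , drop = FALSE], attr(qt, "layout"),
                  attr(qt, "dropped_runs"))
}

# TRUE when a protein-id field holds more than one accession
is_multi_protein_id <- function(id) {
  lengths(strsplit(as.character(id), "[;,[:space:]]+")) > 1L
}

#' Remove peptides assigned to multiple protein IDs
#'
#' Rows whose protein-id field contains more than one accession
#' (`;`-, `,`- or whitespace-delimited) are removed: such peptides cannot
#' be attributed to a single protein group.
#'
#' @param qt a `quant_table`.
#' @return The filtered `quant_table`.
#' @export
filter_multi_protein <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  multi <- is_multi_protein_id(qt$protein_id)
  message(sum(multi), " multi-protein-ID row(s) removed")
  new_quant_table(qt[!multi, , drop = FALSE], attr(qt, "layout"),
                  attr(qt, "dropped_runs"))
}

#' Roll peptide-level quantities up to a protein-by-sample matrix
#'
#' @param qt a `quant_table` (filters already applied).
#' @param method `"sum"` (default; protein quantity per sample is the sum
#'   of its peptide quantities, the Skyline convention), `"median"`, or
#'   `"maxlfq_passthrough"` (take the upstream tool's protein-group
#'   quantity per run, e.g. DIA-NN MaxLFQ, which must be constant within a
#'   protein and run).
#' @return A `protein_matrix`: list with `abundance` (protein x sample,
#'   `NA` for missing), `unique_peptides` (protein x sample counts of
#'   distinct stripped sequences with a positive quantity), `proteins`
#'   (data frame `protein_id`, `gene`) and the `layout`.  Zero quantities
#'   are treated as missing (unintegrated peaks).
#' @export
rollup_protein <- function(qt, method = c("sum", "median",
                                          "maxlfq_passthrough")) {
  method <- match.arg(method)
  stopifnot(inherits(qt, "quant_table"))
  layout <- attr(qt, "layout")
  samples <- layout$sample_name
  if (any(qt$quantity < 0, na.rm = TRUE))
    stop("negative quantities are not allowed")
  q <- qt$quantity
  q[!is.na(q) & q == 0] <- NA_real_   # zeros are unintegrated peaks
  prots <- unique(qt$protein_id)
  genes <- qt$gene[match(prots, qt$protein_id)]
  abund <- matrix(NA_real_, length(prots), length(samples),
                  dimnames = list(prots, samples))
  upep <- matrix(0L, length(prots), length(samples),
                 dimnames = list(prots, samples))
  pi <- match(qt$protein_id, prots)
  si <- match(qt$sample, samples)
  obs <- !is.na(q)
  # distinct stripped sequences with an observed quantity
  if (any(obs)) {
    dk <- paste(pi[obs], si[obs], qt$stripped_seq[obs], sep = "\r")
    dd <- !duplicated(dk)
    cnt <- table(factor(paste(pi[obs][dd], si[obs][dd], sep = "\r")))
    ij <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    upep[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <-
      as.integer(cnt)
  }
  if (method == "maxlfq_passthrough") {
    pq <- qt$protein_quantity
    if (all(is.na(pq)))
      stop("maxlfq_passthrough requires the tool-provided protein-group ",
           "quantity column")
    cell <- paste(pi, si, sep = "\r")
    for (k in split(seq_len(nrow(qt)), cell)) {
      vals <- unique(pq[k][!is.na(pq[k]) & pq[k] > 0])
      if (length(vals) > 1L)
        stop("disagreeing protein-group quantities within a run for ",
             "protein '", qt$protein_id[k[1]], "' sample '",
             qt$sample[k[1]], "': ", paste(vals, collapse = ", "))
      if (length(vals) == 1L) abund[pi[k[1]], si[k[1]]] <- vals
    }
  } else {
    fun <- if (method == "sum") sum else stats::median
    if (any(obs)) {
      agg <- tapply(q[obs], paste(pi[obs], si[obs], sep = "\r"), fun)
      ij <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
      abund[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <-
        as.numeric(agg)
    }
  }
  # invariant: abundance missing <=> no observed peptide
  upep[is.na(abund)] <- 0L
  abund[upep == 0L] <- NA_real_
  new_protein_matrix(abund, upep,
                     data.frame(protein_id = prots, gene = genes,
                                stringsAsFactors = FALSE),
                     layout)
}

new_protein_matrix <- function(abundance, unique_peptides, proteins,
                               layout, filter_report = NULL) {
  structure(list(abundance = abundance,
                 unique_peptides = unique_peptides,
                 proteins = proteins, layout = layout,
                 filter_report = filter_report),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat("Protein matrix:", nrow(x$abundance), "proteins x",
      ncol(x$abundance), "samples; ",
      sum(is.na(x$abundance)), "missing cells\n")
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$abundance)

#' Filter proteins on a minimum unique-peptide count
#'
#' Proteins identified by few peptides are prone to false positives and
#' unreliable quantification; this control point removes them.
#'
#' @param pm a `protein_matrix`.
#' @param n minimum number of distinct peptides (>= 1).
#' @param scope `"per_sample"` (default): abundance cells backed by fewer
#'   than `n` unique peptides are set missing, so the threshold holds for
#'   all samples; `"global"`: a protein is kept only when some sample
#'   reaches `n` peptides, otherwise its whole row is dropped.
#' @return The filtered `protein_matrix`; `$filter_report` lists removed
#'   proteins with the affected samples.
#' @export
filter_min_unique_peptides <- function(pm, n,
                                       scope = c("per_sample", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(pm, "protein_matrix"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer >= 1")
  n <- as.integer(n)
  ab <- pm$abundance; up <- pm$unique_peptides
  if (scope == "per_sample") {
    mask <- up < n & up > 0L
    rep_rows <- which(rowSums(mask) > 0L)
    report <- if (length(rep_rows)) data.frame(
      protein_id = rownames(ab)[rep_rows],
      reason = sprintf("fewer than %d unique peptides", n),
      samples = vapply(rep_rows, function(i)
        paste(colnames(ab)[mask[i, ]], collapse = ";"), ""),
      stringsAsFactors = FALSE) else NULL
    ab[mask] <- NA_real_
    up[mask] <- 0L
    keep <- rowSums(!is.na(ab)) > 0L
    ab <- ab[keep, , drop = FALSE]; up <- up[keep, , drop = FALSE]
    prots <- pm$proteins[keep, , drop = FALSE]
  } else {
    keep <- apply(up, 1L, max) >= n
    report <- if (any(!keep)) data.frame(
      protein_id = rownames(ab)[!keep],
      reason = sprintf("max unique peptides below %d", n),
      samples = "all", stringsAsFactors = FALSE) else NULL
    ab <- ab[keep, , drop = FALSE]; up <- up[keep, , drop = FALSE]
    prots <- pm$proteins[keep, , drop = FALSE]
  }
  rownames(prots) <- NULL
  new_protein_matrix(ab, up, prots, pm$layout, report)
}

# samples belonging to one group, in replicate order
group_samples <- function(layout, group) {
  layout$sample_name[layout$group == group]
}
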
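#' Peptide and protein yields per sample and per group
#'
#' Counts distinct stripped peptide sequences and distinct retained
#' proteins per sample; group counts are the union over the group's
#' replicates, so a group count is at least each of its replicate counts.
#'
#' @param pm a `protein_matrix` (filters applied).
#' @param qt the `quant_table` the matrix was rolled up from.
#' @return A `yield_summary`: list of data frames `samples` (sample,
#'   group, peptides, proteins) and `groups` (group, peptides, proteins).
#' @export
count_yields <- function(pm, qt) {
  stopifnot(inherits(pm, "protein_matrix"), inherits(qt, "quant_table"))
  layout <- pm$layout
  obs <- !is.na(pm$abundance)
  qobs <- !is.na(qt$quantity) & qt$quantity > 0
  pep_by_sample <- vapply(layout$sample_name, function(s) {
    sel <- qobs & qt$sample == s & qt$protein_id %in% rownames(pm$abundance)
    length(unique(qt$stripped_seq[sel]))
  }, 0L)
  samples <- data.frame(
    sample = layout$sample_name, group = layout$group,
    peptides = pep_by_sample,
    proteins = colSums(obs)[layout$sample_name],
    stringsAsFactors = FALSE, row.names = NULL)
  groups <- do.call(rbind, lapply(group_order(layout), function(g) {
    smp <- group_samples(layout, g)
    sel <- qobs & qt$group == g & qt$protein_id %in% rownames(pm$abundance)
    data.frame(group = g,
               peptides = length(unique(qt$stripped_seq[sel])),
               proteins = sum(rowSums(obs[, smp, drop = FALSE]) > 0L),
               stringsAsFactors = FALSE)
  }))
  structure(list(samples = samples, groups = groups),
            class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("Yields per group:\n"); print(x$groups)
  invisible(x)
}

# protein x group presence: observed in >= 1 replicate ("any", default)
# or in all replicates ("all")
group_presence <- function(pm, presence = c("any", "all")) {
  presence <- match.arg(presence)
  layout <- pm$layout
  obs <- !is.na(pm$abundance)
  sapply(group_order(layout), function(g) {
    sub <- obs[, group_samples(layout, g), drop = FALSE]
    if (presence == "any") rowSums(sub) > 0L else rowSums(sub) == ncol(sub)
  })
}

#' Shared, unique and core proteins across experimental groups
#'
#' A protein is "present" in a group when observed in at least one of its
#' replicates (switchable to all replicates).  Reports per-group unique
#' protein lists (present in exactly one group), pairwise shared counts,
#' and the core set present in every group.
#'
#' @param pm a `protein_matrix` with at least 2 groups.
#' @param presence `"any"` (default) or `"all"` replicates.
#' @return A `shared_unique` object: list with `unique` (named list of
#'   per-group unique protein ids), `shared_counts` (group x group
#'   matrix), `core` (character vector) and `presence` (the logical
#'   protein x group matrix).
#' @export
shared_unique <- function(pm, presence = c("any", "all")) {
  stopifnot(inherits(pm, "protein_matrix"))
  gs <- group_order(pm$layout)
  if (length(gs) < 2L) stop("at least 2 groups are required")
  pres <- group_presence(pm, presence)
  ngroups <- rowSums(pres)
  uniq <- lapply(gs, function(g)
    rownames(pres)[pres[, g] & ngroups == 1L])
  names(uniq) <- gs
  shared <- crossprod(pres)  # pairwise co-presence counts
  core <- rownames(pres)[ngroups == length(gs)]
  structure(list(unique = uniq, shared_counts = shared, core = core,
                 presence = pres),
            class = "shared_unique")
}

#' @export
print.shared_unique <- function(x, ...) {
  cat("Unique proteins per group:\n")
  print(lengths(x$unique))
  cat("Core set (all groups):", length(x$core), "proteins\n")
  invisible(x)
}

#' Peptides-per-protein distribution, or counts for one protein
#'
#' Without `protein`, returns per-group distributions (and medians) of the
#' number of distinct stripped peptide sequences per protein.  With
#' `protein` (protein id or gene symbol), returns the per-sample peptide
#' counts for that protein; an unknown name raises an error listing near
#' matches.
#'
#' @param qt a `quant_table`.
#' @param protein optional protein id or gene name.
#' @return A `peptides_per_protein` object (list `counts`, `medians`) or,
#'   for a single protein, a data frame (sample, group, peptides).
#' @export
peptides_per_protein <- function(qt, protein = NULL) {
  stopifnot(inherits(qt, "quant_table"))
  layout <- attr(qt, "layout")
  qobs <- !is.na(qt$quantity) & qt$quantity > 0
  if (!is.null(protein)) {
    sel <- qobs & (qt$protein_id == protein | qt$gene == protein)
    if (!any(sel)) {
      cand <- unique(c(qt$protein_id, qt$gene))
      near <- cand[agrepl(protein, cand, max.distance = 0.2,
                          ignore.case = TRUE)]
      stop("protein or gene '", protein, "' not found",
           if (length(near)) paste0("; near matches: ",
             paste(utils::head(near, 5), collapse = ", ")),
           call. = FALSE)
    }
    return(do.call(rbind, lapply(layout$sample_name, function(s) data.frame(
      sample = s, group = layout$group[layout$sample_name == s],
      peptides = length(unique(qt$stripped_seq[sel & qt$sample == s])),
      stringsAsFactors = FALSE))))
  }
  counts <- lapply(group_order(layout), function(g) {
    sel <- qobs & qt$group == g
    k <- paste(qt$protein_id[sel], qt$stripped_seq[sel], sep = "\r")
    tab <- table(qt$protein_id[sel][!duplicated(k)])
    as.integer(tab) |> stats::setNames(names(tab))
  })
  names(counts) <- group_order(layout)
  structure(list(counts = counts,
                 medians = vapply(counts, function(v)
                   stats::median(as.numeric(v)), 0)),
            class = "peptides_per_protein")
}

#' @export
print.peptides_per_protein <- function(x, ...) {
  cat("Median peptides per protein, by group:\n")
  print(x$medians)
  invisible(x)
}

# log2 profile matrix over complete-observation proteins, by group mean
# or by sample
log2_profiles <- function(pm, on = c("groups", "samples")) {
  on <- match.arg(on)
  complete <- rowSums(is.na(pm$abundance)) == 0L
  lg <- log2(pm$abundance[complete, , drop = FALSE])
  if (on == "samples") return(lg)
  gs <- group_order(pm$layout)
  sapply(gs, function(g)
    rowMeans(lg[, group_samples(pm$layout, g), drop = FALSE]))
}

#' Hierarchical clustering of group (or sample) abundance profiles
#'
#' Agglomerative clustering of log2 abundance profiles restricted to
#' proteins observed in every column.  Defaults: Euclidean distance on
#' log2 group means, average linkage.
#'
#' @param pm a `protein_matrix`.
#' @param on `"groups"` (cluster group-mean profiles, default) or
#'   `"samples"`.
#' @param dist_method distance passed to [stats::dist()].
#' @param linkage linkage passed to [stats::hclust()].
#' @return An [stats::hclust] tree (at least 3 leaves required).
#' @export
cluster_profiles <- function(pm, on = c("groups", "samples"),
                             dist_method = "euclidean",
                             linkage = "average") {
  stopifnot(inherits(pm, "protein_matrix"))
  prof <- log2_profiles(pm, on)
  if (ncol(prof) < 3L) stop("clustering needs at least 3 leaves")
  stats::hclust(stats::dist(t(prof), method = dist_method),
                method = linkage)
}

#' Spearman correlation matrix among experimental groups
#'
#' Pairwise Spearman correlation of group-mean log2 abundances, computed
#' per pair on proteins observed in both groups' means.
#'
#' @param pm a `protein_matrix` with at least 2 groups.
#' @return Symmetric group x group correlation matrix with unit diagonal.
#' @export
group_correlation_matrix <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  gs <- group_order(pm$layout)
  if (length(gs) < 2L) stop("at least 2 groups are required")
  lg <- log2(pm$abundance)
  gm <- sapply(gs, function(g) {
    sub <- lg[, group_samples(pm$layout, g), drop = FALSE]
    out <- rowMeans(sub, na.rm = TRUE)  # mean over observed replicates
    out[is.nan(out)] <- NA_real_
    out
  })
  stats::cor(gm, method = "spearman", use = "pairwise.complete.obs")
}
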
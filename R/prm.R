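#' Avogadro constant (1/mol)
#' @export
AVOGADRO <- 6.02214076e23

#' Spike-in bookkeeping parameters for absolute quantification
#'
#' Holds the conversion factors needed to turn light/heavy peptide
#' ratios into protein copies per nucleus (or per cell): the molecular
#' weight of the spiked heavy-labeled internal standard (HLIS, e.g. a
#' QconCAT concatemer), the spiked mass per injection, the amount of
#' sample protein injected, and the protein mass per nucleus.
#'
#' @param hlis_mw HLIS molecular weight, g/mol.
#' @param spiked_mass_ng spiked HLIS mass per injection, ng.
#' @param injected_protein_ug sample protein injected, ug per injection.
#'   When the spike is specified per ug of digest rather than per
#'   injection, supply that spike in `spiked_mass_ng` together with
#'   `injected_protein_ug = 1` (the per-ug entry style).
#' @param protein_per_cell_pg protein mass per nucleus or cell, pg.
#' @param per_protein optional data frame (`protein_id`, `hlis_mw`,
#'   `spiked_mass_ng`) overriding the global MW/spike per concatemer.
#' @return An `abs_quant_params` object.
#' @export
abs_quant_params <- function(hlis_mw, spiked_mass_ng, injected_protein_ug,
                             protein_per_cell_pg, per_protein = NULL) {
  vals <- c(hlis_mw = hlis_mw, spiked_mass_ng = spiked_mass_ng,
            injected_protein_ug = injected_protein_ug,
            protein_per_cell_pg = protein_per_cell_pg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all absolute-quantification parameters must be strictly ",
         "positive; got ", paste(names(vals)[vals <= 0 | !is.finite(vals)],
                                 collapse = ", "))
  if (!is.null(per_protein)) {
    need <- c("protein_id", "hlis_mw", "spiked_mass_ng")
    if (!all(need %in% names(per_protein)))
      stop("per_protein table needs columns: ",
           paste(need, collapse = ", "))
    if (any(per_protein$hlis_mw <= 0) ||
        any(per_protein$spiked_mass_ng <= 0))
      stop("per_protein MW and spike must be strictly positive")
  }
  structure(list(hlis_mw = hlis_mw, spiked_mass_ng = spiked_mass_ng,
                 injected_protein_ug = injected_protein_ug,
                 protein_per_cell_pg = protein_per_cell_pg,
                 per_protein = per_protein),
            class = "abs_quant_params")
}

#' Read absolute-quantification parameters from a YAML file
#'
#' Top-level fields `hlis_mw`, `spiked_mass_ng`, `injected_protein_ug`,
#' `protein_per_cell_pg`; optional `per_protein:` list of records
#' (`protein`, `hlis_mw`, `spiked_mass_ng`), one per concatemer.
#'
#' @param path path to the YAML parameter file.
#' @return An [abs_quant_params()] object.
#' @export
read_abs_quant_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  cfg <- yaml::read_yaml(path)
  pp <- NULL
  if (!is.null(cfg$per_protein))
    pp <- do.call(rbind, lapply(cfg$per_protein, function(r)
      data.frame(protein_id = r$protein, hlis_mw = r$hlis_mw,
                 spiked_mass_ng = r$spiked_mass_ng,
                 stringsAsFactors = FALSE)))
  abs_quant_params(cfg$hlis_mw, cfg$spiked_mass_ng,
                   cfg$injected_protein_ug, cfg$protein_per_cell_pg,
                   per_protein = pp)
}

#' Light/heavy peptide ratios from a PRM table
#'
#' `R = light_area / heavy_area` per peptide and run.  Rows with a
#' missing or zero heavy area carry no usable ratio and are excluded
#' with a warning; a protein whose heavy areas are all zero is flagged
#' unquantifiable.
#'
#' @param prm a `prm_table` (heavy-label Skyline export).
#' @return A `ratio_table` data frame: `protein_id`, `gene`,
#'   `stripped_seq`, `sample`, `group`, `replicate`, `ratio`; attribute
#'   `excluded` counts dropped rows, `unquantifiable` lists proteins
#'   with no usable heavy area at all.
#' @export
peptide_ratios <- function(prm) {
  stopifnot(inherits(prm, "prm_table"))
  usable <- !is.na(prm$heavy_area) & prm$heavy_area > 0
  excluded <- sum(!usable)
  if (excluded > 0L)
    warning(excluded, " row(s) with missing or zero heavy area excluded",
            call. = FALSE)
  unq <- setdiff(unique(prm$protein_id), unique(prm$protein_id[usable]))
  if (length(unq))
    warning("protein(s) unquantifiable (no usable heavy area): ",
            paste(unq, collapse = ", "), call. = FALSE)
  d <- prm[usable, , drop = FALSE]
  light <- ifelse(is.na(d$light_area), 0, d$light_area)
  out <- data.frame(protein_id = d$protein_id, gene = d$gene,
                    stripped_seq = d$stripped_seq, sample = d$sample,
                    group = d$group, replicate = d$replicate,
                    ratio = light / d$heavy_area,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ratio_table", "data.frame"),
            layout = attr(prm, "layout"), excluded = excluded,
            unquantifiable = unq)
}

# params for one protein (per-protein override or globals)
protein_params <- function(params, protein) {
  pp <- params$per_protein
  if (!is.null(pp) && protein %in% pp$protein_id) {
    i <- match(protein, pp$protein_id)
    list(mw = pp$hlis_mw[i], spike = pp$spiked_mass_ng[i])
  } else list(mw = params$hlis_mw, spike = params$spiked_mass_ng)
}

#' Convert light/heavy ratios to protein copies per nucleus (or cell)
#'
#' Per peptide, the moles of heavy standard in one injection are
#' `spiked_mass_ng * 1e-9 / hlis_mw`; the endogenous amount per ug of
#' injected protein is `R * mol_heavy / injected_protein_ug`; scaling by
#' the protein mass per nucleus (`protein_per_cell_pg * 1e-6` ug) and
#' the Avogadro constant gives copies per nucleus.  Peptide-level copies
#' are rolled up per protein and sample by the median (robust to
#' single-peptide interference; mean available).
#'
#' @param ratios a `ratio_table` from [peptide_ratios()].
#' @param params an [abs_quant_params()] object.
#' @param rollup `"median"` (default) or `"mean"` over peptides.
#' @return An `abs_quant_result`: list with `copies` (data frame
#'   `protein_id`, `gene`, `sample`, `group`, `replicate`, `copies`),
#'   `peptides` (peptide-level copies) and the `layout`.
#' @export
copies_per_cell <- function(ratios, params, rollup = c("median", "mean")) {
  rollup <- match.arg(rollup)
  stopifnot(inherits(ratios, "ratio_table"),
            inherits(params, "abs_quant_params"))
  pp <- lapply(ratios$protein_id, protein_params, params = params)
  mw <- vapply(pp, `[[`, 0, "mw")
  spike <- vapply(pp, `[[`, 0, "spike")
  mol_heavy <- spike * 1e-9 / mw                    # mol per injection
  mol_per_ug <- ratios$ratio * mol_heavy / params$injected_protein_ug
  copies <- mol_per_ug * (params$protein_per_cell_pg * 1e-6) * AVOGADRO
  pept <- cbind(ratios[, c("protein_id", "gene", "stripped_seq", "sample",
                           "group", "replicate")],
                copies = copies)
  fun <- if (rollup == "median") stats::median else mean
  key <- paste(pept$protein_id, pept$sample, sep = "\r")
  agg <- tapply(pept$copies, key, fun)
  first <- !duplicated(key)
  prot <- pept[first, c("protein_id", "gene", "sample", "group",
                        "replicate")]
  prot$copies <- as.numeric(agg[key[first]])
  ord <- order(prot$protein_id,
               match(prot$sample, attr(ratios, "layout")$sample_name))
  prot <- prot[ord, , drop = FALSE]
  rownames(prot) <- NULL
  structure(list(copies = prot, peptides = pept,
                 layout = attr(ratios, "layout"), rollup = rollup),
            class = "abs_quant_result")
}

#' @export
print.abs_quant_result <- function(x, ...) {
  cat("Absolute quantification:", length(unique(x$copies$protein_id)),
      "proteins x", length(unique(x$copies$sample)),
      "samples (copies per nucleus/cell,", x$rollup,
      "over peptides)\n")
  invisible(x)
}

#' One-way ANOVA with Tukey's HSD post-hoc test
#'
#' Fits a one-way ANOVA and computes all-pairs Tukey honest significant
#' differences from the studentized-range distribution with the pooled
#' within-group variance (Tukey-Kramer for unequal group sizes).  With
#' two groups the studentized range reduces exactly to the pooled
#' two-sample t distribution (q = t*sqrt(2)), and the p-value is
#' evaluated through that closed form.  If all values are identical the
#' comparison carries no evidence of difference and every p is 1.
#'
#' @param values numeric replicate measurements.
#' @param groups group label per value (>= 2 groups, each with >= 2
#'   replicates).
#' @param alpha significance level for the `significant` flag.
#' @return A `tukey_result`: list with `anova` (F, df, p), `pairs`
#'   (data frame `group_a`, `group_b`, `diff`, `p_adj`, `significant`),
#'   `group_levels`, `alpha`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("at least 2 groups are required")
  nrep <- table(factor(groups, levels = lev))
  if (any(nrep < 2L))
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(nrep)[nrep < 2L], collapse = ", "))
  k <- length(lev)
  n <- length(values)
  means <- tapply(values, factor(groups, levels = lev), mean)
  df_within <- n - k
  ss_within <- sum((values - means[match(groups, lev)])^2)
  ss_between <- sum(nrep * (means - mean(values))^2)
  if (ss_within == 0 && ss_between == 0) {
    pairs <- expand_pairs(lev)
    pairs$diff <- 0; pairs$p_adj <- 1; pairs$significant <- FALSE
    return(structure(list(anova = c(F = NA_real_, df1 = k - 1,
                                    df2 = df_within, p = 1),
                          pairs = pairs, group_levels = lev,
                          alpha = alpha),
                     class = "tukey_result"))
  }
  msw <- ss_within / df_within
  Fstat <- (ss_between / (k - 1)) / msw
  p_anova <- stats::pf(Fstat, k - 1, df_within, lower.tail = FALSE)
  pairs <- expand_pairs(lev)
  pairs$diff <- as.numeric(means[pairs$group_b] - means[pairs$group_a])
  se <- as.numeric(sqrt(msw / 2 * (1 / nrep[pairs$group_a] +
                                   1 / nrep[pairs$group_b])))
  q <- abs(pairs$diff) / se
  pairs$p_adj <- if (msw == 0) {
    ifelse(pairs$diff == 0, 1, .Machine$double.xmin)
  } else if (k == 2L) {
    # exact two-group identity: q = t*sqrt(2)
    2 * stats::pt(-q / sqrt(2), df_within)
  } else {
    stats::ptukey(q, k, df_within, lower.tail = FALSE)
  }
  pairs$significant <- pairs$p_adj <= alpha
  structure(list(anova = c(F = Fstat, df1 = k - 1, df2 = df_within,
                           p = p_anova),
                 pairs = pairs, group_levels = lev, alpha = alpha),
            class = "tukey_result")
}

expand_pairs <- function(lev) {
  idx <- utils::combn(length(lev), 2L)
  data.frame(group_a = lev[idx[1, ]], group_b = lev[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova[["df1"]], x$anova[["df2"]], x$anova[["F"]],
              x$anova[["p"]]))
  print(x$pairs)
  invisible(x)
}

#' Compact letter display from all-pairs Tukey results
#'
#' Assigns every group a non-empty letter string such that two groups
#' share at least one letter exactly when their Tukey comparison is not
#' significant at `alpha`.  Uses the insert-and-absorb construction:
#' start with a single letter covering all groups; for each significant
#' pair, split every letter containing both groups into two letters each
#' lacking one member; absorb letters that became subsets of others.
#' Letters are labelled `a`, `b`, ... in group display order, so the
#' assignment is deterministic.
#'
#' @param tukey a `tukey_result` (or a logical significance matrix with
#'   group names).
#' @param alpha significance level (default: the one stored in `tukey`).
#' @return A `cld` object: list with `letters` (named character vector
#'   per group) and `significant` (logical group x group matrix).
#' @export
compact_letter_display <- function(tukey, alpha = NULL) {
  if (is.matrix(tukey)) {
    sig <- tukey
    lev <- rownames(sig)
  } else {
    stopifnot(inherits(tukey, "tukey_result"))
    if (is.null(alpha)) alpha <- tukey$alpha
    lev <- tukey$group_levels
    sig <- matrix(FALSE, length(lev), length(lev),
                  dimnames = list(lev, lev))
    for (i in seq_len(nrow(tukey$pairs))) {
      a <- tukey$pairs$group_a[i]; b <- tukey$pairs$group_b[i]
      sig[a, b] <- sig[b, a] <- tukey$pairs$p_adj[i] <= alpha
    }
  }
  k <- length(lev)
  cols <- list(seq_len(k))          # letters as index sets
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    newcols <- list()
    for (L in cols) {
      if (i %in% L && j %in% L) {
        newcols <- c(newcols, list(setdiff(L, i)), list(setdiff(L, j)))
      } else newcols <- c(newcols, list(L))
    }
    # absorb: drop letters that are subsets of another letter
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newcols[[a]] %in% newcols[[b]]) &&
          !(length(newcols[[a]]) == length(newcols[[b]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- newcols[keep]
  }
  # deterministic letter order: by smallest member position
  cols <- cols[order(vapply(cols, min, 0))]
  letters_vec <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, function(L) g %in% L, TRUE))],
          collapse = ""), "")
  names(letters_vec) <- lev
  structure(list(letters = letters_vec, significant = sig),
            class = "cld")
}

#' @export
print.cld <- function(x, ...) {
  print(x$letters)
  invisible(x)
}

#' Compare protein stoichiometry within one experimental group
#'
#' ANOVA + Tukey + compact letter display across proteins, on their
#' replicate-level copies within the group: proteins sharing a letter do
#' not differ significantly in copy number.
#'
#' @param result an `abs_quant_result`.
#' @param proteins character vector of >= 2 protein ids (or genes).
#' @param group group name.
#' @param alpha significance level.
#' @return List with `bars` (protein, mean, sd), `tukey`, `cld`.
#' @export
stoichiometry_compare <- function(result, proteins, group, alpha = 0.05) {
  stopifnot(inherits(result, "abs_quant_result"))
  cp <- result$copies
  resolve <- function(p) {
    hit <- unique(cp$protein_id[cp$protein_id == p | cp$gene == p])
    if (!length(hit)) NA_character_ else hit[1]
  }
  ids <- vapply(proteins, resolve, "")
  present <- vapply(ids, function(i)
    !is.na(i) && any(cp$protein_id == i & cp$group == group), TRUE)
  if (any(!present))
    warning("protein(s) absent in group '", group, "' excluded: ",
            paste(proteins[!present], collapse = ", "), call. = FALSE)
  ids <- ids[present]
  if (length(ids) < 2L)
    stop("at least 2 proteins quantified in the group are required")
  sel <- cp$protein_id %in% ids & cp$group == group
  vals <- cp$copies[sel]; labs <- cp$protein_id[sel]
  tk <- anova_tukey(vals, labs, alpha = alpha)
  cld <- compact_letter_display(tk, alpha)
  bars <- do.call(rbind, lapply(unique(labs), function(p) data.frame(
    protein_id = p, mean = mean(vals[labs == p]),
    sd = stats::sd(vals[labs == p]),
    letters = cld$letters[[p]], stringsAsFactors = FALSE)))
  list(bars = bars, tukey = tk, cld = cld)
}

#' Abundance trend of one protein across the time course
#'
#' @param result an `abs_quant_result`.
#' @param protein protein id or gene name.
#' @return Data frame (`group`, `mean_copies`, `sd_copies`, `n`) in
#'   layout group order, restricted to groups where the protein was
#'   quantified.
#' @export
trend <- function(result, protein) {
  stopifnot(inherits(result, "abs_quant_result"))
  cp <- result$copies
  sel <- cp$protein_id == protein | cp$gene == protein
  if (!any(sel)) stop("protein or gene '", protein, "' not found",
                      call. = FALSE)
  gs <- group_order(result$layout)
  out <- do.call(rbind, lapply(gs, function(g) {
    v <- cp$copies[sel & cp$group == g]
    if (!length(v)) return(NULL)
    data.frame(group = g, mean_copies = mean(v),
               sd_copies = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
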
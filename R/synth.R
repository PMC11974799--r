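# lognormal multiplicative noise with exact coefficient of variation
# (percent); mean 1
lognoise <- function(n, cv_pct) {
  if (cv_pct <= 0) return(rep(1, n))
  cv <- cv_pct / 100
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

#' Specification for a synthetic DIA fixture
#'
#' Defaults emulate a nuclear-proteome erythroid differentiation time
#' course: nine time-point groups with two biological replicates,
#' replicate CV around 12% (mid range of typical DIA replicate CVs),
#' four to five peptides per protein, a planted differential subset at
#' 4-fold change, and 10% random missingness.  The protein count is kept
#' at 200 so fixtures stay desk-sized.
#'
#' @param groups character vector of group names.
#' @param replicates replicates per group.
#' @param proteins number of proteins.
#' @param peptide_range min/max peptides per protein (uniform).
#' @param base_log2_mean,base_log2_sd base protein abundance, log2 scale.
#' @param replicate_cv planted replicate CV, percent (protein-level
#'   multiplicative noise shared by the protein's peptides in a run).
#' @param peptide_noise_cv extra per-peptide measurement noise, percent.
#' @param n_de number of differential proteins (fold change applied to
#'   every non-reference group, reference = first group).
#' @param de_fc planted fold change for differential proteins.
#' @param miss_rate protein-by-sample missingness probability.
#' @param miss_mechanism `"random"` or `"abundance"` (left-censoring:
#'   lower-abundance proteins are more likely to drop out).
#' @param decoy_nonproteotypic,decoy_multi_id fractions of extra decoy
#'   rows carrying a non-proteotypic flag / multiple protein IDs.
#' @param seed integer seed fixing all randomness.
#' @return A list of class `dia_fixture_spec`.
#' @export
dia_fixture_spec <- function(groups = paste0("D", c(0, 2, 4, 6, 8, 10,
                                                    11, 12, 14)),
                             replicates = 2L, proteins = 200L,
                             peptide_range = c(2L, 8L),
                             base_log2_mean = 15, base_log2_sd = 2,
                             replicate_cv = 12,
                             peptide_noise_cv = 5,
                             n_de = 20L, de_fc = 4,
                             miss_rate = 0.1,
                             miss_mechanism = c("random", "abundance"),
                             decoy_nonproteotypic = 0.05,
                             decoy_multi_id = 0.05,
                             seed = 1L) {
  miss_mechanism <- match.arg(miss_mechanism)
  if (n_de > proteins)
    stop("infeasible spec: differential subset larger than the proteome")
  if (miss_rate < 0 || miss_rate > 1)
    stop("miss_rate must be in [0, 1]")
  structure(as.list(environment()), class = "dia_fixture_spec")
}

#' Generate a synthetic DIA fixture with planted ground truth
#'
#' Emits a DIA-NN-dialect `report.tsv`, a Skyline-dialect
#' `DIA_RESULTS.csv` and a `layout.yaml` into `dir`.  Peptide quantities
#' are protein abundance x peptide share x lognormal replicate noise at
#' the planted CV; decoy non-proteotypic and multi-protein-ID rows are
#' included so the preprocessing filters have work to do.  Both files
#' parse cleanly through the package readers, and regeneration with the
#' same spec is byte-identical.
#'
#' @param spec a [dia_fixture_spec()].
#' @param dir output directory (created).
#' @return List with `paths` (report, skyline, layout), `layout`, and
#'   `truth`: protein x group true abundance matrix, `de` flags,
#'   `deleted` registry of missing protein x sample cells, `decoys`.
#' @export
make_dia_fixture <- function(spec, dir = tempfile("dia_fixture")) {
  stopifnot(inherits(spec, "dia_fixture_spec"))
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  G <- spec$groups; r <- spec$replicates; P <- spec$proteins
  layout <- sample_layout(
    run_id = paste0("run_", rep(G, each = r), "_", rep(seq_len(r),
                                                       length(G))),
    sample_name = paste0(rep(G, each = r), "_", rep(seq_len(r),
                                                    length(G))),
    group = rep(G, each = r), replicate = rep(seq_len(r), length(G)),
    group_order = G)
  prots <- sprintf("P%05d", seq_len(P))
  genes <- sprintf("GENE%d", seq_len(P))
  npep <- sample(spec$peptide_range[1]:spec$peptide_range[2], P,
                 replace = TRUE)
  peptides <- lapply(npep, function(k)
    vapply(seq_len(k), function(i) random_peptide(sample(7:15, 1)), ""))
  shares <- lapply(npep, function(k) {
    s <- stats::rgamma(k, shape = 2); s / sum(s)
  })
  base <- 2^stats::rnorm(P, spec$base_log2_mean, spec$base_log2_sd)
  de <- logical(P)
  de[sample.int(P, spec$n_de)] <- TRUE
  truth_ab <- matrix(rep(base, length(G)), P,
                     dimnames = list(prots, G))
  if (spec$n_de > 0 && length(G) > 1)
    truth_ab[de, -1] <- truth_ab[de, -1] * spec$de_fc
  # missing protein x sample cells
  nS <- nrow(layout)
  miss <- matrix(FALSE, P, nS, dimnames = list(prots,
                                               layout$sample_name))
  if (spec$miss_rate > 0) {
    pmiss <- if (spec$miss_mechanism == "random")
      matrix(spec$miss_rate, P, nS)
    else {  # left-censored: scale by abundance rank
      rk <- rank(base) / P
      matrix(rep(2 * spec$miss_rate * (1 - rk), nS), P)
    }
    miss[] <- stats::runif(P * nS) < pmiss
  }
  rows <- vector("list", P)
  for (i in seq_len(P)) {
    gi <- match(layout$group, G)
    prot_noise <- lognoise(nS, spec$replicate_cv)
    abund <- truth_ab[i, gi] * prot_noise
    abund[miss[i, ]] <- NA_real_
    k <- npep[i]
    pepq <- outer(shares[[i]], abund) *
      matrix(lognoise(k * nS, spec$peptide_noise_cv), k)
    rows[[i]] <- data.frame(
      protein = prots[i], gene = genes[i],
      peptide = rep(peptides[[i]], nS),
      run = rep(layout$run_id, each = k),
      quantity = as.vector(pepq),
      pg = rep(colSums(pepq), each = k),
      points = NA_real_, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  long <- long[!is.na(long$quantity), , drop = FALSE]
  long$points <- sample(6:11, nrow(long), replace = TRUE)
  # decoy rows (not part of the ground truth; removed by the filters)
  ndec_np <- round(spec$decoy_nonproteotypic * nrow(long))
  ndec_mi <- round(spec$decoy_multi_id * nrow(long))
  decoy <- function(n, multi) {
    if (n == 0L) return(NULL)
    idx <- sample.int(nrow(long), n, replace = TRUE)
    d <- long[idx, , drop = FALSE]
    d$peptide <- vapply(seq_len(n), function(i)
      random_peptide(sample(7:15, 1)), "")
    if (multi)
      d$protein <- paste(d$protein,
                         sprintf("P%05d", sample.int(P, n, TRUE) + P),
                         sep = ";")
    d
  }
  dec_np <- decoy(ndec_np, multi = FALSE)
  dec_mi <- decoy(ndec_mi, multi = TRUE)
  fmt <- function(x) sprintf("%.15g", x)
  diann <- rbind(
    data.frame(long, proteotypic = 1L),
    if (!is.null(dec_np)) data.frame(dec_np, proteotypic = 0L),
    if (!is.null(dec_mi)) data.frame(dec_mi, proteotypic = 1L))
  diann_out <- data.frame(
    `Protein.Group` = diann$protein, Genes = diann$gene,
    `Modified.Sequence` = diann$peptide,
    `Stripped.Sequence` = diann$peptide,
    Proteotypic = diann$proteotypic, Run = diann$run,
    `Precursor.Quantity` = fmt(diann$quantity),
    `PG.MaxLFQ` = fmt(diann$pg),
    check.names = FALSE, stringsAsFactors = FALSE)
  report_path <- file.path(dir, "report.tsv")
  utils::write.table(diann_out, report_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sky_out <- data.frame(
    Protein = long$protein, Gene = long$gene, Peptide = long$peptide,
    `Replicate Name` = long$run, `Isotope Label Type` = "light",
    `Total Area Fragment` = fmt(long$quantity),
    `Points Across Peak` = long$points,
    check.names = FALSE, stringsAsFactors = FALSE)
  sky_path <- file.path(dir, "DIA_RESULTS.csv")
  utils::write.csv(sky_out, sky_path, row.names = FALSE, quote = FALSE)
  layout_path <- file.path(dir, "layout.yaml")
  write_layout(layout, layout_path)
  deleted <- which(miss, arr.ind = TRUE)
  list(paths = list(report = report_path, skyline = sky_path,
                    layout = layout_path),
       layout = layout,
       truth = list(abundance = truth_ab, de = stats::setNames(de, prots),
                    shares = shares,
                    deleted = data.frame(
                      protein_id = rownames(miss)[deleted[, 1]],
                      sample = colnames(miss)[deleted[, 2]],
                      stringsAsFactors = FALSE),
                    decoys = c(nonproteotypic = ndec_np,
                               multi_id = ndec_mi)))
}

#' Specification for a synthetic heavy-label PRM fixture
#'
#' Defaults emulate a targeted chromatin-remodeler panel: 21 proteins
#' with 2-4 peptides each across a nine-point time course with two
#' replicates, true copy numbers spanning roughly 1e2 to 5e4 copies per
#' nucleus, 10% ratio noise, and QconCAT-style spike bookkeeping (100
#' kDa standard, 1 ng spiked per injection, 1 ug injected, 10 pg protein
#' per nucleus).
#'
#' @param groups,replicates,seed as in [dia_fixture_spec()].
#' @param proteins number of targeted proteins.
#' @param peptide_range min/max peptides per protein.
#' @param copies_log10_range log10 range of true copies per nucleus.
#' @param ratio_noise_cv light/heavy ratio noise, percent.
#' @param hlis_mw,spiked_mass_ng,injected_protein_ug,protein_per_cell_pg
#'   spike bookkeeping, see [abs_quant_params()].
#' @return A list of class `prm_fixture_spec`.
#' @export
prm_fixture_spec <- function(groups = paste0("D", c(0, 2, 4, 6, 8, 10,
                                                    11, 12, 14)),
                             replicates = 2L, proteins = 21L,
                             peptide_range = c(2L, 4L),
                             copies_log10_range = c(2, 4.7),
                             ratio_noise_cv = 10,
                             hlis_mw = 1e5, spiked_mass_ng = 1,
                             injected_protein_ug = 1,
                             protein_per_cell_pg = 10,
                             seed = 1L) {
  structure(as.list(environment()), class = "prm_fixture_spec")
}

#' Generate a synthetic heavy-label PRM fixture with planted copies
#'
#' True copies per nucleus are planted per protein and group; light
#' areas are back-computed from the copies-per-nucleus formula inverted
#' (light = heavy x R, with R the ratio that reproduces the true
#' copies), then perturbed by multiplicative ratio noise.  Emits a
#' Skyline-dialect `PRM_RESULTS_Heavy_label.csv`, a `params.yaml` and a
#' `layout.yaml`.
#'
#' @param spec a [prm_fixture_spec()].
#' @param dir output directory (created).
#' @return List with `paths`, `layout`, `params` and `truth` (protein x
#'   group matrix of true copies).
#' @export
make_prm_fixture <- function(spec, dir = tempfile("prm_fixture")) {
  stopifnot(inherits(spec, "prm_fixture_spec"))
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  G <- spec$groups; r <- spec$replicates; P <- spec$proteins
  layout <- sample_layout(
    run_id = paste0("prm_", rep(G, each = r), "_", rep(seq_len(r),
                                                       length(G))),
    sample_name = paste0(rep(G, each = r), "_", rep(seq_len(r),
                                                    length(G))),
    group = rep(G, each = r), replicate = rep(seq_len(r), length(G)),
    group_order = G)
  params <- abs_quant_params(spec$hlis_mw, spec$spiked_mass_ng,
                             spec$injected_protein_ug,
                             spec$protein_per_cell_pg)
  # copies per unit light/heavy ratio
  copies_per_ratio <- (spec$spiked_mass_ng * 1e-9 / spec$hlis_mw) /
    spec$injected_protein_ug * (spec$protein_per_cell_pg * 1e-6) *
    AVOGADRO
  prots <- sprintf("BAF%02d", seq_len(P))
  genes <- sprintf("SUBUNIT%d", seq_len(P))
  npep <- sample(spec$peptide_range[1]:spec$peptide_range[2], P,
                 replace = TRUE)
  truth <- matrix(
    10^stats::runif(P * length(G), spec$copies_log10_range[1],
                    spec$copies_log10_range[2]),
    P, length(G), dimnames = list(prots, G))
  rows <- vector("list", P)
  for (i in seq_len(P)) {
    peps <- vapply(seq_len(npep[i]), function(j)
      random_peptide(sample(8:14, 1)), "")
    gi <- match(layout$group, G)
    k <- npep[i]; nS <- nrow(layout)
    heavy <- matrix(stats::rlnorm(k * nS, log(1e5), 0.5), k)
    R_true <- truth[i, gi] / copies_per_ratio
    R <- outer(rep(1, k), R_true) *
      matrix(lognoise(k * nS, spec$ratio_noise_cv), k)
    light <- heavy * R
    rows[[i]] <- data.frame(
      protein = prots[i], gene = genes[i], peptide = rep(peps, nS),
      run = rep(layout$run_id, each = k),
      light = as.vector(light), heavy = as.vector(heavy),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  long$points <- sample(26:34, nrow(long), replace = TRUE)
  fmt <- function(x) sprintf("%.15g", x)
  out <- rbind(
    data.frame(Protein = long$protein, Gene = long$gene,
               Peptide = long$peptide, `Replicate Name` = long$run,
               `Isotope Label Type` = "light",
               `Total Area Fragment` = fmt(long$light),
               `Points Across Peak` = long$points,
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(Protein = long$protein, Gene = long$gene,
               Peptide = long$peptide, `Replicate Name` = long$run,
               `Isotope Label Type` = "heavy",
               `Total Area Fragment` = fmt(long$heavy),
               `Points Across Peak` = long$points,
               check.names = FALSE, stringsAsFactors = FALSE))
  prm_path <- file.path(dir, "PRM_RESULTS_Heavy_label.csv")
  utils::write.csv(out, prm_path, row.names = FALSE, quote = FALSE)
  params_path <- file.path(dir, "params.yaml")
  yaml::write_yaml(list(hlis_mw = spec$hlis_mw,
                        spiked_mass_ng = spec$spiked_mass_ng,
                        injected_protein_ug = spec$injected_protein_ug,
                        protein_per_cell_pg = spec$protein_per_cell_pg),
                   params_path)
  layout_path <- file.path(dir, "layout.yaml")
  write_layout(layout, layout_path)
  list(paths = list(prm = prm_path, params = params_path,
                    layout = layout_path),
       layout = layout, params = params,
       truth = list(copies = truth))
}

#' Rank-one abundance matrix fixture with held-out cells
#'
#' Builds a `protein_matrix` whose sample columns are exact scalar
#' multiples of a base profile (rank one on the raw scale, additive
#' offsets on log2), deletes a fraction of cells at random while keeping
#' every row and column observed, and records the deleted truth — the
#' standard benchmark for the chained-regression imputation.
#'
#' @param n_proteins,n_samples matrix size.
#' @param miss_rate fraction of cells deleted.
#' @param seed integer seed.
#' @return List with `pm` (the incomplete `protein_matrix`), `full`
#'   (complete abundance matrix) and `deleted` (data frame `row`, `col`,
#'   `value`).
#' @export
make_rank1_fixture <- function(n_proteins = 100L, n_samples = 6L,
                               miss_rate = 0.05, seed = 1L) {
  set.seed(seed)
  groups <- paste0("G", seq_len(max(2L, ceiling(n_samples / 2))))
  layout <- sample_layout(
    run_id = paste0("r", seq_len(n_samples)),
    sample_name = paste0("S", seq_len(n_samples)),
    group = rep(groups, each = 2, length.out = n_samples),
    replicate = rep(1:2, length.out = n_samples))
  base <- 2^stats::rnorm(n_proteins, 15, 2)
  fac <- stats::runif(n_samples, 0.5, 2)
  full <- outer(base, fac)
  dimnames(full) <- list(sprintf("P%04d", seq_len(n_proteins)),
                         layout$sample_name)
  ab <- full
  n_del <- round(miss_rate * length(ab))
  cand <- sample.int(length(ab))
  del <- integer(0)
  for (idx in cand) {
    if (length(del) >= n_del) break
    tmp <- ab; tmp[c(del, idx)] <- NA
    if (all(rowSums(!is.na(tmp)) > 0L) && all(colSums(!is.na(tmp)) > 0L))
      del <- c(del, idx)
  }
  ab[del] <- NA_real_
  ij <- arrayInd(del, dim(ab))
  up <- matrix(3L, n_proteins, n_samples, dimnames = dimnames(ab))
  up[is.na(ab)] <- 0L
  pm <- new_protein_matrix(ab, up,
                           data.frame(protein_id = rownames(ab),
                                      gene = rownames(ab),
                                      stringsAsFactors = FALSE),
                           layout)
  list(pm = pm, full = full,
       deleted = data.frame(row = ij[, 1], col = ij[, 2],
                            value = full[del]))
}
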
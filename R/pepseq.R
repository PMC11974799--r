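#' Strip modification annotations from peptide sequences
#'
#' Removes bracketed and parenthesized mass tags (e.g.
#' `"C[+57.0215]"`, `"M(ox)"`) and any UniMod-style annotations, leaving
#' the bare uppercase amino-acid sequence.  Idempotent.
#'
#' @param x character vector of (possibly modified) peptide sequences.
#' @return Character vector of stripped sequences.
#' @export
strip_modifications <- function(x) {
  out <- gsub("\\[[^][]*\\]|\\([^()]*\\)", "", as.character(x))
  # nested tags: repeat until fixed point
  while (any(grepl("\\[[^][]*\\]|\\([^()]*\\)", out)))
    out <- gsub("\\[[^][]*\\]|\\([^()]*\\)", "", out)
  toupper(out)
}

#' Count peptides matching a query amino-acid sequence
#'
#' Finds, per sample and per experimental group, the distinct stripped
#' peptide sequences of the dataset that occur as exact contiguous
#' substrings of the query (e.g. a protein domain).  Modification
#' annotations are stripped before matching; each distinct sequence
#' counts once per sample (and once per group).
#'
#' @param qt a `quant_table`.
#' @param query amino-acid sequence, `[A-Z]+`, length >= 5.
#' @return A `pepseq_report`: list with `query`, `samples` and `groups`
#'   (named lists of matching peptide vectors), `sample_counts`,
#'   `group_counts`.
#' @export
match_peptides <- function(qt, query) {
  stopifnot(inherits(qt, "quant_table"))
  query <- toupper(as.character(query))
  if (!grepl("^[A-Z]+$", query))
    stop("query must contain only amino-acid letters A-Z")
  if (nchar(query) < 5L)
    stop("query must be at least 5 residues long")
  layout <- attr(qt, "layout")
  seqs <- strip_modifications(qt$stripped_seq)
  is_match <- function(v) {
    v <- unique(v)
    v[vapply(v, function(p) grepl(p, query, fixed = TRUE), TRUE)]
  }
  samples <- lapply(layout$sample_name, function(s)
    sort(is_match(seqs[qt$sample == s])))
  names(samples) <- layout$sample_name
  groups <- lapply(group_order(layout), function(g)
    sort(is_match(seqs[qt$group == g])))
  names(groups) <- group_order(layout)
  structure(list(query = query, samples = samples, groups = groups,
                 sample_counts = lengths(samples),
                 group_counts = lengths(groups)),
            class = "pepseq_report")
}

#' @export
print.pepseq_report <- function(x, ...) {
  cat("Peptide matches for query of", nchar(x$query), "residues\n")
  cat("Per group:\n"); print(x$group_counts)
  invisible(x)
}

#' Write a PepSeq report to disk
#'
#' Writes one CSV per sample and per group (the report's tabs) plus a
#' `summary.csv` of match counts, and a bar plot of the per-sample
#' counts.
#'
#' @param report a `pepseq_report`.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_pepseq_report <- function(report, dir) {
  stopifnot(inherits(report, "pepseq_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  tabs <- c(report$samples, report$groups)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0("matches_", gsub("[^A-Za-z0-9_.-]", "_",
                                                nm), ".csv"))
    utils::write.csv(data.frame(peptide = tabs[[nm]]), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, "summary.csv")
  utils::write.csv(data.frame(
    name = c(names(report$sample_counts), names(report$group_counts)),
    scope = rep(c("sample", "group"),
                c(length(report$sample_counts),
                  length(report$group_counts))),
    matches = c(report$sample_counts, report$group_counts)),
    sp, row.names = FALSE)
  invisible(c(paths, sp))
}

#' Map gene names to protein accessions from a local table
#'
#' Case-insensitive exact gene-symbol matching against a two-column
#' gene-to-accession table (e.g. a UniProt idmapping extract); genes
#' mapping to several accessions return all of them.
#'
#' @param genes non-empty character vector of gene names.
#' @param mapping data frame whose first two columns are gene and
#'   accession (see [read_gene_map()]).
#' @return List with `mapped` (data frame `gene`, `accession`) and
#'   `unmapped` (character vector).
#' @export
map_gene_ids <- function(genes, mapping) {
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene list")
  if (ncol(mapping) < 2L) stop("mapping table needs 2 columns")
  map_gene <- toupper(as.character(mapping[[1]]))
  map_acc <- as.character(mapping[[2]])
  rows <- lapply(unique(genes), function(g) {
    hits <- map_acc[map_gene == toupper(g)]
    if (!length(hits)) return(NULL)
    data.frame(gene = g, accession = hits, stringsAsFactors = FALSE)
  })
  mapped <- do.call(rbind, rows)
  if (is.null(mapped))
    mapped <- data.frame(gene = character(), accession = character(),
                         stringsAsFactors = FALSE)
  unmapped <- setdiff(toupper(unique(genes)), map_gene)
  unmapped <- unique(genes)[toupper(unique(genes)) %in% unmapped]
  list(mapped = mapped, unmapped = unmapped)
}

#' Read a two-column gene-to-accession mapping table (TSV)
#'
#' @param path path to a tab-separated file with at least two columns
#'   (gene, accession); a header line is detected automatically.
#' @return Data frame with columns `gene`, `accession`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("gene", tolower(first))
  df <- utils::read.delim(path, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("format error: mapping table needs 2 columns")
  stats::setNames(df[, 1:2], c("gene", "accession"))
}
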
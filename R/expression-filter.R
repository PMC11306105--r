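#' Construct a feature (gene expression) table
#'
#' Container for the per-gene records the downstream numeric filters
#' operate on: gene lengths, raw counts per sample, optional differential
#' expression statistics (`log2fc`, `padj` — treated as input columns, not
#' computed here) and logical tag columns such as `is_rrna` or gene-set
#' membership flags.
#'
#' @param genes Data frame with at least `gene_id` (unique) and `length`
#'   (bases, > 0); may carry `log2fc`, `padj` and logical tag columns.
#' @param counts Numeric matrix, genes x samples, non-negative; rownames
#'   must match `gene_id`, colnames are the sample labels. Fractional
#'   counts (multi-mapper assignment) are accepted.
#' @return A `feature_table`.
#' @export
feature_table <- function(genes, counts) {
  genes <- as.data.frame(genes)
  counts <- as.matrix(counts)
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (any(genes$length <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) rownames(counts) <- genes$gene_id
  if (!identical(rownames(counts), as.character(genes$gene_id))) {
    counts <- counts[match(genes$gene_id, rownames(counts)), , drop = FALSE]
    if (anyNA(counts)) stop("counts rows do not cover all gene_ids")
  }
  if ("padj" %in% names(genes)) {
    bad <- genes$padj[!is.na(genes$padj)]
    if (any(bad < 0 | bad > 1)) stop("padj values must lie in [0, 1]")
  }
  structure(list(genes = genes, counts = counts, tpm = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d genes x %d samples%s\n",
              nrow(x$genes), ncol(x$counts),
              if (is.null(x$tpm)) "" else " (TPM computed)"))
  invisible(x)
}

subset_feature_table <- function(ft, keep) {
  ft$genes <- ft$genes[keep, , drop = FALSE]
  ft$counts <- ft$counts[keep, , drop = FALSE]
  if (!is.null(ft$tpm)) ft$tpm <- ft$tpm[keep, , drop = FALSE]
  ft
}

#' Drop ribosomal RNA features
#'
#' Removes records flagged in the logical `is_rrna` column; the sample set
#' is unchanged. An all-flagged table yields an empty table with a warning.
#'
#' @param ft A [feature_table()] whose `genes` has an `is_rrna` column.
#' @return The filtered `feature_table`.
#' @export
remove_rrna <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (!"is_rrna" %in% names(ft$genes)) stop("no is_rrna flag column present")
  keep <- !ft$genes$is_rrna
  if (!any(keep)) warning("all features are flagged as rRNA; table is empty")
  subset_feature_table(ft, keep)
}

#' Convert counts to transcripts per kilobase million (TPM)
#'
#' Per sample: each gene's count is divided by its length to a rate, and
#' rates are rescaled to sum to 10^6. TPM therefore corrects for both gene
#' length and sequencing depth, and each sample's TPM column sums to 10^6.
#'
#' @param ft A [feature_table()].
#' @return The table with a `tpm` matrix added.
#' @export
tpm <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  rate <- ft$counts / ft$genes$length
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count rate: ",
         paste(colnames(ft$counts)[totals == 0], collapse = ", "))
  }
  ft$tpm <- sweep(rate, 2, totals, "/") * 1e6
  ft
}

#' Top-k genes of a gene set by mean abundance
#'
#' Restricts the table to the members of a tagged gene set, ranks them by
#' mean TPM across the named samples, and returns the top `k`. Ties are
#' broken by lexicographic gene_id so the ranking is deterministic.
#'
#' @param ft A [feature_table()] with TPM computed (see [tpm()]).
#' @param gene_set Name of a logical tag column in `ft$genes`.
#' @param samples Sample labels over which to average.
#' @param k Number of genes to keep (default 20).
#' @return Data frame `gene_id`, `mean_tpm` in descending abundance order.
#' @export
top_metabolic_genes <- function(ft, gene_set, samples, k = 20) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$tpm)) ft <- tpm(ft)
  if (!gene_set %in% names(ft$genes)) {
    stop("unknown gene set tag: ", gene_set)
  }
  if (length(samples) == 0L) stop("sample subset must be non-empty")
  missing <- setdiff(samples, colnames(ft$tpm))
  if (length(missing) > 0L) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  }
  members <- which(ft$genes[[gene_set]])
  mean_tpm <- rowMeans(ft$tpm[members, samples, drop = FALSE])
  ids <- as.character(ft$genes$gene_id[members])
  ord <- order(-mean_tpm, ids)
  top <- head(ord, k)
  data.frame(gene_id = ids[top], mean_tpm = unname(mean_tpm[top]),
             stringsAsFactors = FALSE)
}

#' Differential-expression threshold filter
#'
#' Keeps genes with `padj <= padj_max` and `|log2fc| >= abs_log2fc_min`
#' (inclusive thresholds; an absolute log2 fold change of 0.585 is a 1.5-fold
#' change). Genes with missing statistics are excluded.
#'
#' @param ft A [feature_table()] with `log2fc` and `padj` columns.
#' @param padj_max Adjusted-p ceiling (default 0.05).
#' @param abs_log2fc_min Minimum absolute log2 fold change (default 0.585).
#' @return The filtered `feature_table`.
#' @export
de_filter <- function(ft, padj_max = 0.05, abs_log2fc_min = 0.585) {
  stopifnot(inherits(ft, "feature_table"))
  if (!all(c("log2fc", "padj") %in% names(ft$genes))) {
    stop("de_filter needs log2fc and padj columns")
  }
  keep <- !is.na(ft$genes$padj) & !is.na(ft$genes$log2fc) &
    ft$genes$padj <= padj_max & abs(ft$genes$log2fc) >= abs_log2fc_min
  subset_feature_table(ft, keep)
}

#' Abundance floor over sample groups
#'
#' Keeps genes whose mean TPM reaches `min_mean_tpm` within at least one of
#' the given sample groups (e.g. one group per sampling point).
#'
#' @param ft A [feature_table()]; TPM is computed on the fly if absent.
#' @param sample_groups List of character vectors of sample labels; none may
#'   be empty.
#' @param min_mean_tpm Abundance threshold (default 50 mean TPM).
#' @return The filtered `feature_table`.
#' @export
abundance_floor <- function(ft, sample_groups, min_mean_tpm = 50) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$tpm)) ft <- tpm(ft)
  if (!is.list(sample_groups)) sample_groups <- list(sample_groups)
  if (any(lengths(sample_groups) == 0L)) stop("empty sample group")
  group_means <- vapply(sample_groups, function(g) {
    missing <- setdiff(g, colnames(ft$tpm))
    if (length(missing) > 0L) {
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
    }
    rowMeans(ft$tpm[, g, drop = FALSE])
  }, numeric(nrow(ft$genes)))
  group_means <- matrix(group_means, nrow = nrow(ft$genes))
  keep <- apply(group_means, 1, max) >= min_mean_tpm
  subset_feature_table(ft, keep)
}
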
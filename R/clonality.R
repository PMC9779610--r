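# Per-sample and cross-sample clonality statistics: dominant clonotype,
# pooled percentages, gene-usage tables.

#' Identify the dominant clonotype of a sample
#'
#' The clonotype with the largest cell count; exact count ties are broken
#' by the lexicographically smallest clonotype key and flagged.
#'
#' @param clonotypes A `clonotype_set` (see [group_clonotypes()]).
#' @param sample_id Sample label carried into the report.
#' @return A one-row data frame: `sample_id`, `n_rearranged_cells`,
#'   `dominant_clonotype_id`, `dominant_key`, `dominant_frequency_pct`,
#'   `tie_flag`, `other_clonotypes_pct`.
#' @export
dominant_clonotype <- function(clonotypes, sample_id = "sample") {
  if (nrow(clonotypes) == 0L) stop("no clonotypes in sample")
  top_n <- max(clonotypes$n_cells)
  cands <- clonotypes[clonotypes$n_cells == top_n, , drop = FALSE]
  cands <- cands[order(cands$key), , drop = FALSE]
  dom <- cands[1L, , drop = FALSE]
  data.frame(sample_id = sample_id,
             n_rearranged_cells = sum(clonotypes$n_cells),
             dominant_clonotype_id = dom$clonotype_id,
             dominant_key = dom$key,
             dominant_frequency_pct = dom$frequency_pct,
             tie_flag = nrow(cands) > 1L,
             other_clonotypes_pct = 100 - dom$frequency_pct,
             stringsAsFactors = FALSE)
}

#' Summarise dominant-clonotype fractions over a cohort
#'
#' Mean, min and max of the per-sample dominant-clonotype percentages, plus
#' the pooled percentage `100 * sum(dominant barcodes) / sum(total
#' barcodes)` when absolute per-sample counts are supplied.
#'
#' @param reports Data frame with one row per sample carrying
#'   `dominant_frequency_pct` and, optionally, absolute counts.
#' @param dominant_counts,total_counts Optional absolute barcode counts per
#'   sample (same order as `reports`); both or neither must be given.
#' @return A one-row data frame: `n_samples`, `mean_pct`, `min_pct`,
#'   `max_pct`, `pooled_pct` (`NA` without counts).
#' @export
cohort_summary <- function(reports, dominant_counts = NULL,
                           total_counts = NULL) {
  if (nrow(reports) == 0L) stop("at least one report required")
  if (xor(is.null(dominant_counts), is.null(total_counts))) {
    stop("dominant_counts and total_counts must be supplied together")
  }
  pooled <- NA_real_
  if (!is.null(dominant_counts)) {
    if (length(dominant_counts) != length(total_counts)) {
      stop("mismatched sample sets between dominant_counts and total_counts")
    }
    pooled <- 100 * sum(dominant_counts) / sum(total_counts)
  }
  p <- reports$dominant_frequency_pct
  data.frame(n_samples = nrow(reports), mean_pct = mean(p),
             min_pct = min(p), max_pct = max(p), pooled_pct = pooled)
}

#' Gene-usage tables from chain or clonotype calls
#'
#' Counts calls per V gene, per V family (gene-name prefix before the first
#' hyphen) and per J gene. Unparseable gene names are counted under
#' `"unknown"` with a warning.
#'
#' @param calls Data frame with `v_call` and `j_call` columns (e.g. a
#'   `chain_calls` table or one call per sample).
#' @return List of three count data frames: `v_gene`, `v_family`, `j_gene`.
#' @export
gene_usage <- function(calls) {
  count_tab <- function(x) {
    if (length(x) == 0L) {
      return(data.frame(name = character(0), n = integer(0)))
    }
    t <- sort(table(x), decreasing = TRUE)
    data.frame(name = names(t), n = as.integer(t), stringsAsFactors = FALSE)
  }
  v <- strip_allele(calls$v_call)
  j <- strip_allele(calls$j_call)
  fam <- gene_family(v)
  if (any(fam == "unknown" & !is.na(v))) {
    warning("unparseable gene name(s) counted under 'unknown': ",
            paste(unique(v[fam == "unknown"]), collapse = ", "))
  }
  list(v_gene = count_tab(v[!is.na(v)]), v_family = count_tab(fam[!is.na(v)]),
       j_gene = count_tab(j[!is.na(j)]))
}
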
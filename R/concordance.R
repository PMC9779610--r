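# Concordance between scRNA-seq-derived and bulk-DNA-derived dominant
# clonotypes, with mechanistic attribution of discordances.

#' Construct a per-sample method call
#'
#' One dominant-clonotype call by one method (single-cell RNA or bulk DNA
#' amplicon), as compared across methods.
#'
#' @param sample_id Sample label.
#' @param method `"scRNA"` or `"bulkDNA"`.
#' @param v_call,j_call Gene names (allele suffixes allowed).
#' @param cdr3_aa CDR3 amino-acid string, or `NA` (unproductive DNA
#'   clonotypes may have none).
#' @param proportion_pct Clonal proportion in percent, in `(0, 100]`.
#' @param productive Productivity of the called rearrangement.
#' @param chain Chain of the call (`"IGH"`/`"IGK"`).
#' @param failure_reason Failure reason for unproductive calls.
#' @return One-row data frame.
#' @export
method_call <- function(sample_id, method, v_call, j_call,
                        cdr3_aa = NA_character_, proportion_pct,
                        productive = TRUE, chain = "IGH",
                        failure_reason = "none") {
  stopifnot(method %in% c("scRNA", "bulkDNA"),
            proportion_pct > 0, proportion_pct <= 100)
  data.frame(sample_id = sample_id, method = method, v_call = v_call,
             j_call = j_call, cdr3_aa = cdr3_aa,
             proportion_pct = proportion_pct, productive = productive,
             chain = chain, failure_reason = failure_reason,
             stringsAsFactors = FALSE)
}

#' Match the dominant clonotypes called by two methods on one sample
#'
#' The CDR3 is compared as an exact amino-acid string; V and J genes are
#' compared at gene level with allele suffixes stripped, so the two methods
#' reporting different allele resolution does not break gene agreement. A
#' CDR3 match defines concordance; gene-level disagreement is recorded
#' separately without breaking it.
#'
#' @param rna,dna One-row method-call data frames ([method_call()]) for the
#'   same sample.
#' @return One-row data frame: `sample_id`, `status` (`"match"` /
#'   `"discordant"`), `cdr3_match`, `v_gene_agreement`, `j_gene_agreement`,
#'   `discordance_reason` (`"none"` for matches, `"unknown"` until
#'   attributed via [attribute_discordance()]).
#' @export
match_clonotypes <- function(rna, dna) {
  if (rna$sample_id != dna$sample_id) {
    stop("method calls are for different samples")
  }
  cdr3_match <- !is.na(rna$cdr3_aa) && !is.na(dna$cdr3_aa) &&
    rna$cdr3_aa == dna$cdr3_aa
  v_agree <- isTRUE(strip_allele(rna$v_call) == strip_allele(dna$v_call))
  j_agree <- isTRUE(strip_allele(rna$j_call) == strip_allele(dna$j_call))
  data.frame(sample_id = rna$sample_id,
             status = if (cdr3_match) "match" else "discordant",
             cdr3_match = cdr3_match, v_gene_agreement = v_agree,
             j_gene_agreement = j_agree,
             discordance_reason = if (cdr3_match) "none" else "unknown",
             stringsAsFactors = FALSE)
}

#' Pearson correlation of paired clonal fractions
#'
#' Pearson product-moment correlation of the per-sample clonal percentages
#' reported by the two methods.
#'
#' @param rna_pct,dna_pct Paired percentage vectors, length >= 3.
#' @return List: `r`, `r_squared`, `n`.
#' @export
fraction_correlation <- function(rna_pct, dna_pct) {
  if (length(rna_pct) != length(dna_pct)) stop("unpaired inputs")
  n <- length(rna_pct)
  if (n < 3L) stop("at least 3 pairs required")
  if (stats::sd(rna_pct) == 0 || stats::sd(dna_pct) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(rna_pct, dna_pct)
  list(r = r, r_squared = r^2, n = n)
}

#' Attribute mechanisms to an RNA/DNA dominant-clonotype discordance
#'
#' Decision rules, applied in order with all applicable reasons reported:
#'
#' 1. the DNA call is unproductive with a stop codon and its CDR3 is absent
#'    from the RNA side -> `"nmd_unproductive_absent_in_rna"` (the
#'    transcript is degraded by nonsense-mediated decay);
#' 2. the RNA call is productive but its rearranged sequence fails the
#'    annealing screen for every matching panel primer on the genomic
#'    template -> `"primer_misannealing_absent_in_dna"` (a hypermutated
#'    primer site prevents first-step PCR);
#' 3. the RNA dominant clonotype has only a light chain while the DNA
#'    heavy-chain screen found no productive clonotype ->
#'    `"light_chain_only_in_rna"`;
#' 4. otherwise `"unknown"`.
#'
#' A biallelic clone with a productive-but-unamplifiable allele and a
#' stop-codon allele triggers reasons 1 and 2 simultaneously.
#'
#' @param rna,dna One-row method-call data frames.
#' @param rna_sequence Rearranged nucleotide sequence behind the RNA call
#'   (consensus or simulation truth); `NULL` skips rule 2.
#' @param panel Primer panel for rule 2; `NULL` skips it.
#' @param k,max_total_mismatches Annealing screen parameters.
#' @return Character vector of reasons (possibly several), or `"unknown"`.
#' @export
attribute_discordance <- function(rna, dna, rna_sequence = NULL,
                                  panel = NULL, k = 3L,
                                  max_total_mismatches = 6L) {
  reasons <- character(0)
  if (isFALSE(dna$productive) &&
      identical(dna$failure_reason, "stop_codon") &&
      !isTRUE(dna$cdr3_aa == rna$cdr3_aa)) {
    reasons <- c(reasons, "nmd_unproductive_absent_in_rna")
  }
  if (isTRUE(rna$productive) && !is.null(rna_sequence) &&
      !is.null(panel)) {
    scr <- panel_screen(panel, paste0(rna_sequence, igh_jc_intron()),
                        template_kind = "dna_rearrangement", k = k,
                        max_total_mismatches = max_total_mismatches)
    if (!scr$amplifiable) {
      reasons <- c(reasons, "primer_misannealing_absent_in_dna")
    }
  }
  if (identical(rna$chain, "IGK") && isFALSE(dna$productive)) {
    reasons <- c(reasons, "light_chain_only_in_rna")
  }
  if (length(reasons) == 0L) "unknown" else reasons
}

#' Venn counts of sample-level dominant clonotypes
#'
#' Each concordant sample contributes one shared clonotype; each discordant
#' sample contributes one clonotype unique to the RNA method and one unique
#' to the DNA method.
#'
#' @param records Data frame of match records ([match_clonotypes()]).
#' @return List: `n_shared`, `n_rna_only`, `n_dna_only`.
#' @export
venn_counts <- function(records) {
  if (nrow(records) == 0L) {
    return(list(n_shared = 0L, n_rna_only = 0L, n_dna_only = 0L))
  }
  n_disc <- sum(records$status == "discordant")
  list(n_shared = sum(records$status == "match"),
       n_rna_only = n_disc, n_dna_only = n_disc)
}

#' Cross-method concordance analysis of a clonotype table
#'
#' Runs [match_clonotypes()] per sample, computes Venn counts and the
#' clonal-fraction correlation over the matched samples only (the
#' proportions of discordant samples describe different rearrangements and
#' are not comparable).
#'
#' @param tab Clonotype comparison table (see [load_clonotype_table()]).
#' @return List: `records` (per-sample match records), `venn`,
#'   `correlation`.
#' @export
concordance_summary <- function(tab) {
  records <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, , drop = FALSE]
    match_clonotypes(
      method_call(row$sample_id, "scRNA", row$rna_v, row$rna_j,
                  cdr3_aa = row$rna_cdr3_aa,
                  proportion_pct = row$rna_proportion_pct,
                  productive = row$rna_productive, chain = row$rna_chain),
      method_call(row$sample_id, "bulkDNA", row$dna_v, row$dna_j,
                  cdr3_aa = row$dna_cdr3_aa,
                  proportion_pct = row$dna_proportion_pct,
                  productive = row$dna_productive,
                  failure_reason = row$dna_failure_reason))
  }))
  matched <- records$status == "match"
  corr <- fraction_correlation(tab$rna_proportion_pct[matched],
                               tab$dna_proportion_pct[matched])
  list(records = records, venn = venn_counts(records), correlation = corr)
}
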
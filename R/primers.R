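# Consensus-primer annealing screen: ungapped alignment of first-step PCR
# primers against rearranged sequences and prediction of amplification
# failure from 3'-proximal mismatches.

#' J-C intron context used by the bulk PCR model
#'
#' Fixed toy intron placed immediately downstream of the J segment on
#' genomic templates. Reverse J primers carry a 5' tail annealing here;
#' the intron is spliced out of mature transcripts, so that tail cannot
#' match RNA-derived sequence.
#'
#' @param chain Chain label (only `"IGH"` has a packaged panel).
#' @return Intron nucleotide string.
#' @export
igh_jc_intron <- function(chain = "IGH") {
  stopifnot(chain == "IGH")
  "GTGAGTCCTTACAACCTCTCTCTTCTATTC"
}

#' Read a primer panel from TSV
#'
#' Columns: `name`, `sequence` (5'->3'), `orientation`
#' (`forward`/`reverse`), `target_region` (`V`/`J`), `intronic_tail_len`
#' (number of primer 5' bases annealing in the J-C intron; 0 for forward
#' primers).
#'
#' @param path TSV path.
#' @return A `primer_panel` data frame.
#' @export
read_primer_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation", "target_region",
            "intronic_tail_len")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0L) {
    stop("primer panel missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(all(p$orientation %in% c("forward", "reverse")),
            all(p$target_region %in% c("V", "J")),
            all(nchar(p$sequence) > 0L),
            all(p$intronic_tail_len < nchar(p$sequence)))
  structure(p, class = c("primer_panel", "data.frame"))
}

#' Packaged toy IGH V-J primer panel
#'
#' Mimics the layout of clinical first-step IGH marker-identification PCR:
#' one forward framework primer per V family and two reverse J primers
#' whose 5' tails anneal in the J-C intron. Sequences are matched to the
#' packaged toy germline database; they are synthetic stand-ins, not any
#' clinical protocol's actual primer sequences.
#'
#' @return A `primer_panel` data frame.
#' @export
default_primer_panel <- function() {
  read_primer_panel(system.file("extdata", "primers_igh_toy.tsv",
                                package = "clonotracer", mustWork = TRUE))
}

#' Annealing report for one primer on one template
#'
#' The primer (reverse primers reverse-complemented onto the template
#' strand) is aligned ungapped at its best-scoring offset. For
#' `template_kind = "mature_mrna"` the `intronic_tail_len` 3'-context bases
#' are excluded from comparison: the intron is spliced out of mature
#' transcripts, so that portion of a reverse primer cannot be compared
#' against RNA-derived sequence. Mismatch offsets are counted from the
#' primer 3' terminus (0 = terminal base); any mismatch at offset `< k`
#' abolishes predicted amplification.
#'
#' @param primer One-row `primer_panel` data frame (or equivalent list).
#' @param template_nt Template nucleotide string (plus strand).
#' @param template_kind `"dna_rearrangement"` (genomic, intron present) or
#'   `"mature_mrna"` (spliced).
#' @param k 3'-terminal window size in nt; mismatches inside it are
#'   considered detrimental to priming.
#' @param max_total_mismatches Above this count at the best offset the
#'   primer is reported as not aligned at all.
#' @return List: `primer_name`, `aligned`, `template_start`,
#'   `mismatch_offsets` (ascending, 3'-first), `three_prime_hit`,
#'   `predicted_amplification`.
#' @export
anneal_report <- function(primer, template_nt,
                          template_kind = c("dna_rearrangement",
                                            "mature_mrna"),
                          k = 3L, max_total_mismatches = 6L) {
  template_kind <- match.arg(template_kind)
  stopifnot(k >= 1L, nchar(template_nt) > 0L, nchar(primer$sequence) > 0L)
  reverse <- primer$orientation == "reverse"
  oriented <- if (reverse) revcomp(primer$sequence) else primer$sequence
  L <- nchar(oriented)
  # positions (in oriented coordinates) compared against the template
  cmp_from <- 1L
  cmp_to <- L
  if (template_kind == "mature_mrna" && primer$intronic_tail_len > 0L) {
    if (reverse) {
      # 5' intronic tail of the reverse primer sits at the right end of
      # the template-oriented sequence
      cmp_to <- L - primer$intronic_tail_len
    } else {
      cmp_from <- 1L + primer$intronic_tail_len
    }
  }
  cmp <- substr(oriented, cmp_from, cmp_to)
  Lc <- nchar(cmp)
  tlen <- nchar(template_nt)
  no_fit <- list(primer_name = primer$name, aligned = FALSE,
                 template_start = NA_integer_,
                 mismatch_offsets = integer(0), three_prime_hit = FALSE,
                 predicted_amplification = FALSE)
  if (Lc > tlen || Lc == 0L) return(no_fit)

  tvec <- utf8ToInt(template_nt)
  pvec <- utf8ToInt(cmp)
  n_off <- tlen - Lc + 1L
  mism <- vapply(seq_len(n_off), function(s) {
    sum(tvec[s:(s + Lc - 1L)] != pvec)
  }, integer(1))
  best <- which.min(mism)
  mm_pos <- which(tvec[best:(best + Lc - 1L)] != pvec)  # within cmp
  oriented_pos <- mm_pos + (cmp_from - 1L)
  offsets <- if (reverse) oriented_pos - 1L else L - oriented_pos
  offsets <- sort(offsets)
  aligned <- mism[best] <= max_total_mismatches
  hit <- any(offsets < k)
  list(primer_name = primer$name, aligned = aligned,
       template_start = as.integer(best),
       mismatch_offsets = as.integer(offsets),
       three_prime_hit = hit,
       predicted_amplification = aligned && !hit)
}

#' Screen a full primer panel against one rearranged template
#'
#' First-step PCR requires a working forward and a working reverse primer:
#' the template is amplifiable iff at least one forward primer and at least
#' one reverse primer have `predicted_amplification = TRUE`.
#'
#' @param panel A `primer_panel`.
#' @param template_nt Template string (for genomic templates append the
#'   J-C intron, see [igh_jc_intron()]).
#' @param template_kind,k,max_total_mismatches Passed to [anneal_report()].
#' @return List: `amplifiable` plus a `reports` data frame with one row per
#'   primer.
#' @export
panel_screen <- function(panel, template_nt,
                         template_kind = "dna_rearrangement", k = 3L,
                         max_total_mismatches = 6L) {
  stopifnot(any(panel$orientation == "forward"),
            any(panel$orientation == "reverse"))
  reps <- lapply(seq_len(nrow(panel)), function(i) {
    anneal_report(panel[i, , drop = FALSE], template_nt, template_kind, k,
                  max_total_mismatches)
  })
  rep_df <- data.frame(
    name = vapply(reps, `[[`, character(1), "primer_name"),
    orientation = panel$orientation,
    aligned = vapply(reps, `[[`, logical(1), "aligned"),
    n_mismatches = vapply(reps, function(r) length(r$mismatch_offsets),
                          integer(1)),
    three_prime_hit = vapply(reps, `[[`, logical(1), "three_prime_hit"),
    predicted_amplification = vapply(reps, `[[`, logical(1),
                                     "predicted_amplification"),
    stringsAsFactors = FALSE)
  ok_fw <- any(rep_df$predicted_amplification[panel$orientation ==
                                                "forward"])
  ok_rev <- any(rep_df$predicted_amplification[panel$orientation ==
                                                 "reverse"])
  list(amplifiable = ok_fw && ok_rev, reports = rep_df)
}

#' Text rendering of a primer annealing site
#'
#' Prints the template window under the oriented primer with mismatch
#' columns marked, the kind of display used to show how a mutated
#' nucleotide under a reverse primer's 3' end prevents PCR priming.
#'
#' @param primer One-row primer data frame.
#' @param template_nt Template string.
#' @param ... Passed to [anneal_report()].
#' @return Character vector of display lines, invisibly; printed as a side
#'   effect.
#' @export
render_annealing <- function(primer, template_nt, ...) {
  rep <- anneal_report(primer, template_nt, ...)
  if (is.na(rep$template_start)) {
    lines <- paste0(primer$name, ": no placement on template")
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  reverse <- primer$orientation == "reverse"
  oriented <- if (reverse) revcomp(primer$sequence) else primer$sequence
  win <- substr(template_nt, rep$template_start,
                rep$template_start + nchar(oriented) - 1L)
  marks <- vapply(seq_len(nchar(win)), function(i) {
    if (substr(win, i, i) == substr(oriented, i, i)) "|" else "x"
  }, character(1))
  lines <- c(paste0("template ", win),
             paste0("         ", paste(marks, collapse = "")),
             paste0(format(primer$name, width = 8L), " ", oriented,
                    if (reverse) "  (reverse, shown as revcomp)" else ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
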
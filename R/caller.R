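# Per-cell chain calling from barcoded reads: UMI/barcode consensus
# building, V/J assignment by semi-global alignment, CDR3 extraction at the
# conserved anchors, productivity classification, clonotype grouping.

# Per-position plurality vote over groups of equal-role sequences.
# Sequences shorter than their group's longest are padded and the pad never
# votes; ties go to the alphabetically first base.
majority_vote <- function(seqs, group) {
  group <- as.character(group)
  glen <- tapply(nchar(seqs), group, max)
  tgt <- unname(glen[group])
  pad <- tgt - nchar(seqs)
  if (any(pad > 0L)) seqs <- paste0(seqs, strrep("-", pad))
  out <- character(length(glen))
  names(out) <- names(glen)
  for (L in unique(tgt)) {
    sel <- tgt == L
    s <- seqs[sel]
    g <- group[sel]
    ug <- unique(g)
    gi <- match(g, ug)
    m <- matrix(utf8ToInt(paste(s, collapse = "")), ncol = L, byrow = TRUE)
    best_cnt <- best_base <- NULL
    for (b in DNA_BASES) {
      cnt <- rowsum((m == utf8ToInt(b)) + 0L, gi)
      if (is.null(best_cnt)) {
        best_cnt <- cnt
        best_base <- matrix(utf8ToInt(b), nrow(cnt), ncol(cnt))
      } else {
        upd <- cnt > best_cnt
        best_cnt[upd] <- cnt[upd]
        best_base[upd] <- utf8ToInt(b)
      }
    }
    out[ug] <- apply(best_base, 1L, intToUtf8, multiple = FALSE)
  }
  out
}

#' Build per-barcode chain consensus sequences
#'
#' Reads are first collapsed per UMI by per-position plurality vote (reads
#' of conflicting length are voted over columns of the longest), then UMI
#' consensuses are collapsed per barcode. Within a barcode, UMI consensuses
#' are partitioned into chain candidates by transcript length and split
#' further when two same-length consensuses disagree at more than 20% of
#' positions (distinct co-occurring transcripts); the chain identity of each
#' candidate is resolved later by best-scoring germline V alignment in
#' [call_cells()]. Candidates supported by fewer than `min_umis` UMIs are
#' dropped and reported in the `"dropped"` attribute.
#'
#' @param reads A `read_set` data frame (`barcode`, `umi`, `sequence`).
#' @param min_umis Minimum UMIs per retained chain consensus.
#' @return A `consensus_set` data frame: `barcode`, `consensus`,
#'   `umi_count`, `read_count`.
#' @export
build_consensus <- function(reads, min_umis = 2L) {
  empty <- structure(data.frame(barcode = character(0),
                                consensus = character(0),
                                umi_count = integer(0),
                                read_count = integer(0)),
                     class = c("consensus_set", "data.frame"))
  if (nrow(reads) == 0L) return(empty)

  g1 <- paste(reads$barcode, reads$umi, sep = "\r")
  umi_cons <- majority_vote(reads$sequence, g1)
  umi_nreads <- table(g1)
  info <- data.frame(key = names(umi_cons), consensus = unname(umi_cons),
                     stringsAsFactors = FALSE)
  info$barcode <- sub("\r.*$", "", info$key)
  info$n_reads <- as.integer(umi_nreads[info$key])
  info$len <- nchar(info$consensus)

  g2 <- paste(info$barcode, info$len, sep = "\r")
  cl <- integer(nrow(info))
  for (grp in split(seq_len(nrow(info)), g2)) {
    if (length(grp) == 1L) {
      cl[grp] <- 1L
      next
    }
    ref <- info$consensus[grp[1]]
    mm <- vapply(info$consensus[grp], hamming, numeric(1), b = ref,
                 USE.NAMES = FALSE) / info$len[grp[1]]
    cl[grp] <- ifelse(mm > 0.2, 2L, 1L)
  }
  g3 <- paste(info$barcode, info$len, cl, sep = "\r")
  cons <- majority_vote(info$consensus, g3)
  out <- data.frame(key = names(cons), consensus = unname(cons),
                    stringsAsFactors = FALSE)
  out$barcode <- sub("\r.*$", "", out$key)
  out$umi_count <- as.integer(table(g3)[out$key])
  out$read_count <- as.integer(rowsum(info$n_reads, g3)[out$key, 1L])
  out <- out[order(out$barcode, -out$umi_count),
             c("barcode", "consensus", "umi_count", "read_count")]
  rownames(out) <- NULL

  low <- out$umi_count < min_umis
  dropped <- out[low, , drop = FALSE]
  out <- out[!low, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " chain consensus(es) dropped (umi_count < ",
            min_umis, ")")
  }
  structure(out, class = c("consensus_set", "data.frame"),
            dropped = dropped)
}

# score matrix: queries x candidate segments, semi-global (free end gaps on
# the query side, candidate consumed in full), linear gap cost
segment_score_matrix <- function(query, candidates, match = 1,
                                 mismatch = -1, gap = -2) {
  S <- .sg_score_matrix(query, candidates$sequence, as.integer(match),
                        as.integer(mismatch), as.integer(gap))
  colnames(S) <- candidates$name
  S
}

#' Assign the best-matching germline segment to queries
#'
#' Semi-global alignment with free end gaps on the query side under a
#' configurable unit-cost scheme (default match +1, mismatch -1, gap -2 per
#' base). The best candidate is chosen by score; exact score ties are broken
#' by lexicographic gene name and flagged ambiguous. A call is also flagged
#' ambiguous when the margin to the second-best candidate is below
#' `ambiguity_margin`, mirroring how heavily hypermutated sequences can be
#' assigned different near-identical paralogs by different aligners.
#'
#' @param query Character vector of query sequences.
#' @param candidates Segment data frame (one `seg_type`).
#' @param match,mismatch,gap Alignment scores (gap is per gapped base).
#' @param ambiguity_margin Minimum score gap to the runner-up.
#' @return Data frame with one row per query: `best_name`, `score`,
#'   `margin`, `ambiguous`. The full score matrix is in the `"scores"`
#'   attribute.
#' @export
assign_segment <- function(query, candidates, match = 1, mismatch = -1,
                           gap = -2, ambiguity_margin = 5) {
  if (nrow(candidates) == 0L) stop("candidates must be non-empty")
  if (length(unique(candidates$seg_type)) != 1L) {
    stop("candidates must share seg_type")
  }
  if (length(query) == 0L) {
    return(data.frame(best_name = character(0), score = numeric(0),
                      margin = numeric(0), ambiguous = logical(0)))
  }
  if (any(!nzchar(query))) stop("empty query")
  candidates <- candidates[order(candidates$name), , drop = FALSE]
  S <- segment_score_matrix(query, candidates, match, mismatch, gap)
  res <- summarize_scores(S, ambiguity_margin)
  attr(res, "scores") <- S
  res
}

# best/second-best summary of a query x candidate score matrix; columns
# must be in lexicographic name order so that ties resolve to the
# alphabetically first gene
summarize_scores <- function(S, ambiguity_margin = 5) {
  bi <- max.col(S, ties.method = "first")
  score <- S[cbind(seq_len(nrow(S)), bi)]
  tie <- rowSums(S == score) > 1L
  margin <- if (ncol(S) > 1L) {
    second <- apply(S, 1L, function(r) sort(r, decreasing = TRUE)[2])
    score - second
  } else rep(Inf, nrow(S))
  data.frame(best_name = colnames(S)[bi], score = score, margin = margin,
             ambiguous = tie | margin < ambiguity_margin,
             stringsAsFactors = FALSE)
}

# Map a segment's anchor codon onto query coordinates through the
# semi-global alignment. Returns NA when the anchor codon is broken by the
# alignment (gapped or non-contiguous).
map_anchor <- function(query, segment, match = 1, mismatch = -1, gap = -2) {
  anchor <- segment$anchor_start
  # align only the germline region bounded by the anchor codon (V ends at
  # it, J starts at it): junction trimming removes bases outside that
  # region, so the aligned subject is fully present in the query and the
  # traceback cannot be distorted by unmatched germline ends
  if (segment$seg_type == "V") {
    subj <- substr(segment$sequence, 1L, anchor + 2L)
    spos <- anchor + 0:2
  } else {
    subj <- substr(segment$sequence, anchor, nchar(segment$sequence))
    spos <- 1:3
  }
  pos <- .sg_map_positions(query, subj, as.integer(spos),
                           as.integer(match), as.integer(mismatch),
                           as.integer(gap))
  ok <- !is.na(pos[, 1]) & !is.na(pos[, 2]) & !is.na(pos[, 3]) &
    pos[, 2] == pos[, 1] + 1L & pos[, 3] == pos[, 1] + 2L
  out <- rep(NA_integer_, length(query))
  out[ok] <- pos[ok, 1]
  out
}

# Vectorised productivity classification over parallel vectors of
# sequences, anchor positions and chains; the workhorse behind
# classify_productivity() and extract_cdr3().
classify_productivity_vec <- function(sequence, v_anchor, j_anchor, chain) {
  n <- length(sequence)
  len <- nchar(sequence)
  v_anchor <- as.integer(v_anchor)
  j_anchor <- as.integer(j_anchor)
  codon_ok <- function(pos, want) {
    ok <- !is.na(pos) & pos >= 1L & pos + 2L <= len
    cod <- substr(sequence, ifelse(ok, pos, 1L), ifelse(ok, pos + 2L, 3L))
    aa <- unname(Biostrings::GENETIC_CODE[cod])
    ok & !is.na(aa) & !is.na(want) & aa == want
  }
  anchors_ok <- codon_ok(v_anchor, rep("C", n)) &
    codon_ok(j_anchor, anchor_residue(chain, "J")) &
    !is.na(v_anchor) & !is.na(j_anchor) & j_anchor >= v_anchor
  cdr3_nt <- rep(NA_character_, n)
  cdr3_nt[anchors_ok] <- substr(sequence[anchors_ok], v_anchor[anchors_ok],
                                j_anchor[anchors_ok] + 2L)
  in_frame <- anchors_ok & nchar(cdr3_nt) %% 3L == 0L
  in_frame[is.na(in_frame)] <- FALSE

  cdr3_aa <- rep(NA_character_, n)
  stop_hit <- rep(FALSE, n)
  idx <- which(in_frame)
  if (length(idx) > 0L) {
    fr <- ((v_anchor[idx] - 1L) %% 3L) + 1L
    n_cod <- (len[idx] - fr + 1L) %/% 3L
    region <- substr(sequence[idx], fr, fr + n_cod * 3L - 1L)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(region), no.init.codon = TRUE))
    stop_hit[idx] <- grepl("*", aa, fixed = TRUE)
    cdr3_aa[idx] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cdr3_nt[idx]), no.init.codon = TRUE))
  }
  productive <- in_frame & !stop_hit
  failure_reason <- ifelse(!anchors_ok, "missing_anchor",
                           ifelse(!in_frame, "out_of_frame",
                                  ifelse(stop_hit, "stop_codon", "none")))
  data.frame(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, productive = productive,
             failure_reason = failure_reason, stringsAsFactors = FALSE)
}

#' Classify productivity of a rearranged sequence
#'
#' A sequence is productive when both conserved anchors are present (the
#' codons at the given positions translate to Cys and to Trp/Phe for
#' IGH/IGK), the CDR3 nucleotide length is divisible by 3, and the
#' translation from the V reading frame through the end of the J region
#' contains no stop codon. The first failing rule is recorded, with
#' precedence `missing_anchor` > `out_of_frame` > `stop_codon`.
#'
#' @param sequence Rearranged nucleotide sequence (V through J).
#' @param v_anchor_start,j_anchor_start 1-based positions of the conserved
#'   V-Cys and J-Trp/Phe codons in `sequence` (`NA` when not found).
#' @param chain `"IGH"` or `"IGK"`.
#' @return List: `productive`, `failure_reason` (`"none"`,
#'   `"missing_anchor"`, `"out_of_frame"`, `"stop_codon"`), `cdr3_nt`,
#'   `cdr3_aa` (`NA` when undefined).
#' @export
classify_productivity <- function(sequence, v_anchor_start, j_anchor_start,
                                  chain) {
  res <- classify_productivity_vec(sequence, v_anchor_start,
                                   j_anchor_start, chain)
  list(productive = res$productive[1], failure_reason = res$failure_reason[1],
       cdr3_nt = res$cdr3_nt[1], cdr3_aa = res$cdr3_aa[1])
}

#' Extract CDR3 sequences from consensus sequences
#'
#' The CDR3 spans the conserved V-region cysteine codon through the
#' conserved J-region tryptophan (IGH) or phenylalanine (IGK) codon,
#' inclusive. Anchor codons are located by mapping the germline
#' `anchor_start` coordinates through the V and J alignments onto the
#' consensus; an anchor that was trimmed away or mutated beyond recognition
#' yields `failure_reason = "missing_anchor"`.
#'
#' @param consensus_nt Character vector of consensus sequences.
#' @param v_call,j_call Germline gene names per consensus.
#' @param db A `germline_db`.
#' @param match,mismatch,gap Alignment scores.
#' @return Data frame with one row per consensus: `cdr3_nt`, `cdr3_aa`,
#'   `v_anchor_start`, `j_anchor_start`, `productive`, `failure_reason`.
#' @export
extract_cdr3 <- function(consensus_nt, v_call, j_call, db, match = 1,
                         mismatch = -1, gap = -2) {
  n <- length(consensus_nt)
  v_anchor <- j_anchor <- rep(NA_integer_, n)
  chain <- rep(NA_character_, n)
  for (vn in unique(v_call)) {
    idx <- which(v_call == vn)
    seg <- get_segments(db, name = vn, seg_type = "V")
    if (nrow(seg) != 1L) stop("unknown V gene: ", vn)
    chain[idx] <- seg$chain
    v_anchor[idx] <- map_anchor(consensus_nt[idx], seg, match, mismatch, gap)
  }
  for (jn in unique(j_call)) {
    idx <- which(j_call == jn)
    seg <- get_segments(db, name = jn, seg_type = "J")
    if (nrow(seg) != 1L) stop("unknown J gene: ", jn)
    j_anchor[idx] <- map_anchor(consensus_nt[idx], seg, match, mismatch, gap)
  }
  cls <- classify_productivity_vec(consensus_nt, v_anchor, j_anchor, chain)
  cbind(cls[, c("cdr3_nt", "cdr3_aa")],
        data.frame(v_anchor_start = v_anchor, j_anchor_start = j_anchor),
        cls[, c("productive", "failure_reason")])
}

empty_chain_calls <- function() {
  structure(data.frame(barcode = character(0), chain = character(0),
                       consensus_nt = character(0), v_call = character(0),
                       j_call = character(0), v_score = numeric(0),
                       j_score = numeric(0), v_margin = numeric(0),
                       ambiguous_v = logical(0), cdr3_nt = character(0),
                       cdr3_aa = character(0), productive = logical(0),
                       failure_reason = character(0),
                       umi_count = integer(0), read_count = integer(0)),
            class = c("chain_calls", "data.frame"))
}

#' Call per-cell chains from barcoded reads
#'
#' Full caller pipeline: consensus building ([build_consensus()]), chain
#' resolution and V assignment by best-scoring germline V across both loci,
#' J assignment within the resolved locus, CDR3 extraction
#' ([extract_cdr3()]) and productivity classification.
#'
#' @param reads A `read_set` data frame.
#' @param db A `germline_db`.
#' @param min_umis Minimum UMIs per retained chain.
#' @param ambiguity_margin Score margin below which a V call is flagged
#'   ambiguous.
#' @param match,mismatch,gap Alignment scores.
#' @return A `chain_calls` data frame, one row per called cell chain.
#' @export
call_cells <- function(reads, db, min_umis = 2L, ambiguity_margin = 5,
                       match = 1, mismatch = -1, gap = -2) {
  cons <- build_consensus(reads, min_umis = min_umis)
  if (nrow(cons) == 0L) {
    warning("no chain consensus passed filtering; returning empty calls")
    return(empty_chain_calls())
  }
  # resolve the locus of each consensus by its best-scoring germline J
  # (short segments, so this pre-pass is cheap); V assignment then runs
  # within the resolved locus only
  j_all <- get_segments(db, seg_type = "J")
  j_all <- j_all[order(j_all$name), , drop = FALSE]
  Sj <- segment_score_matrix(cons$consensus, j_all, match, mismatch, gap)
  chain <- j_all$chain[max.col(Sj, ties.method = "first")]

  out <- vector("list", length(unique(chain)))
  names(out) <- unique(chain)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    q <- cons$consensus[idx]
    vres <- assign_segment(q, get_segments(db, chain = ch, seg_type = "V"),
                           match, mismatch, gap, ambiguity_margin)
    jres <- summarize_scores(Sj[idx, j_all$chain == ch, drop = FALSE],
                             ambiguity_margin)
    cd <- extract_cdr3(q, vres$best_name, jres$best_name, db, match,
                       mismatch, gap)
    out[[ch]] <- data.frame(
      barcode = cons$barcode[idx], chain = ch, consensus_nt = q,
      v_call = vres$best_name, j_call = jres$best_name,
      v_score = vres$score, j_score = jres$score, v_margin = vres$margin,
      ambiguous_v = vres$ambiguous, cdr3_nt = cd$cdr3_nt,
      cdr3_aa = cd$cdr3_aa, productive = cd$productive,
      failure_reason = cd$failure_reason,
      umi_count = cons$umi_count[idx], read_count = cons$read_count[idx],
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$barcode, calls$chain), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("chain_calls", "data.frame"),
            dropped = attr(cons, "dropped"))
}

#' Canonical clonotype key
#'
#' @param chains,cdr3_nt Parallel vectors of chain labels and CDR3
#'   nucleotide sequences for one cell.
#' @return Single string, chain-sorted, e.g. `"IGH:TGT...;IGK:TGC..."`.
#' @export
clonotype_key <- function(chains, cdr3_nt) {
  parts <- paste0(chains, ":", cdr3_nt)
  paste(sort(parts), collapse = ";")
}

#' Group called cells into clonotypes
#'
#' Cells are keyed by the set of their productive CDR3 nucleotide sequences
#' (paired IGH+IGK key when both are productive; single-chain keys are
#' allowed, which supports light-chain-only clonotypes). Cells with no
#' productive chain are excluded from the frequency denominator and
#' reported in the `"excluded_barcodes"` attribute.
#'
#' @param chain_calls A `chain_calls` data frame.
#' @return A `clonotype_set` data frame: `clonotype_id`, `key`,
#'   `cdr3_aa_key`, `n_cells`, `frequency_pct`, `barcodes` (list column),
#'   ordered by descending abundance.
#' @export
group_clonotypes <- function(chain_calls) {
  empty <- structure(data.frame(clonotype_id = character(0),
                                key = character(0),
                                cdr3_aa_key = character(0),
                                n_cells = integer(0),
                                frequency_pct = numeric(0)),
                     class = c("clonotype_set", "data.frame"))
  empty$barcodes <- list()
  if (nrow(chain_calls) == 0L) return(empty)
  prod <- chain_calls[chain_calls$productive, , drop = FALSE]
  excluded <- setdiff(unique(chain_calls$barcode), unique(prod$barcode))
  if (nrow(prod) == 0L) {
    attr(empty, "excluded_barcodes") <- excluded
    return(empty)
  }
  keys <- vapply(split(prod, prod$barcode), function(d) {
    clonotype_key(d$chain, d$cdr3_nt)
  }, character(1))
  aa_keys <- vapply(split(prod, prod$barcode), function(d) {
    clonotype_key(d$chain, d$cdr3_aa)
  }, character(1))
  n_denom <- length(keys)
  by_key <- split(names(keys), unname(keys))
  aa_by_key <- aa_keys[!duplicated(unname(keys))]
  names(aa_by_key) <- unname(keys)[!duplicated(unname(keys))]
  out <- data.frame(key = names(by_key),
                    n_cells = vapply(by_key, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$cdr3_aa_key <- unname(aa_by_key[out$key])
  out$frequency_pct <- 100 * out$n_cells / n_denom
  out <- out[order(-out$n_cells, out$key), , drop = FALSE]
  out$clonotype_id <- sprintf("CT%04d", seq_len(nrow(out)))
  out$barcodes <- unname(by_key[out$key])
  out <- out[, c("clonotype_id", "key", "cdr3_aa_key", "n_cells",
                 "frequency_pct", "barcodes")]
  rownames(out) <- NULL
  structure(out, class = c("clonotype_set", "data.frame"),
            excluded_barcodes = excluded, n_cells_denominator = n_denom)
}

#' Call clonotypes from bulk amplicon templates
#'
#' Simplified bulk-DNA clonotyping: distinct amplified rearrangement
#' sequences are assigned V and J genes, CDR3 and productivity exactly as
#' single-cell consensuses are, and ranked by read proportion. Unproductive
#' rearrangements are retained - genomic DNA is blind to productivity.
#'
#' @param amplicons Output of [simulate_bulk_amplicon()].
#' @param db A `germline_db`.
#' @param ... Alignment parameters passed to [assign_segment()].
#' @return Data frame of bulk clonotype calls ordered by descending read
#'   proportion (`proportion_pct`).
#' @export
call_bulk_amplicons <- function(amplicons, db, ...) {
  amp <- amplicons[amplicons$amplified & amplicons$n_reads > 0L, ,
                   drop = FALSE]
  if (nrow(amp) == 0L) {
    return(data.frame(v_call = character(0), j_call = character(0),
                      cdr3_nt = character(0), cdr3_aa = character(0),
                      productive = logical(0), failure_reason = character(0),
                      n_reads = integer(0), proportion_pct = numeric(0)))
  }
  vres <- assign_segment(amp$sequence,
                         get_segments(db, chain = "IGH", seg_type = "V"),
                         ...)
  jres <- assign_segment(amp$sequence,
                         get_segments(db, chain = "IGH", seg_type = "J"),
                         ...)
  cd <- extract_cdr3(amp$sequence, vres$best_name, jres$best_name, db)
  out <- data.frame(v_call = vres$best_name, j_call = jres$best_name,
                    cdr3_nt = cd$cdr3_nt, cdr3_aa = cd$cdr3_aa,
                    productive = cd$productive,
                    failure_reason = cd$failure_reason,
                    n_reads = amp$n_reads,
                    proportion_pct = 100 * amp$n_reads / sum(amp$n_reads),
                    sequence = amp$sequence,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_reads, out$cdr3_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
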
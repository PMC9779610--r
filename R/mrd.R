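# In silico minimal residual disease: spike reads from known clonal
# barcodes into a polyclonal background and detect the target clonotype.

#' Build an in silico dilution sample
#'
#' Reads from `n_clonal_cells` randomly chosen clonal barcodes of the
#' source sample are concatenated with all background reads, emulating a
#' post-therapy sample in which a handful of residual tumour cells sit in a
#' polyclonal marrow. Barcode collisions between spike and background are
#' re-coded deterministically (fresh barcodes drawn from the seeded RNG)
#' and logged in the result.
#'
#' @param clonal_sample A `vdj_sample` containing the target clone.
#' @param clonal_reads Reads emitted from `clonal_sample`.
#' @param background_reads Pooled background `read_set` (typically several
#'   samples' reads combined with `rbind`).
#' @param n_clonal_cells Number of clonal barcodes to spike.
#' @param seed RNG seed for barcode choice and collision re-coding.
#' @return A `dilution` list: `reads`, `truth` (barcode, spiked,
#'   clonotype_label), `spiked_barcodes`, `target_key`, `recoded` (old ->
#'   new barcode map).
#' @export
build_dilution <- function(clonal_sample, clonal_reads, background_reads,
                           n_clonal_cells = 5L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  target_key <- clone_target_key(clonal_sample)
  clonal_bcs <- clonal_sample$cells$barcode[clonal_sample$cells$is_clonal]
  if (length(clonal_bcs) < n_clonal_cells) {
    stop("insufficient clonal barcodes: have ", length(clonal_bcs),
         ", need ", n_clonal_cells)
  }
  spike_bcs <- sort(sample(clonal_bcs, n_clonal_cells))
  spike <- clonal_reads[clonal_reads$barcode %in% spike_bcs, , drop = FALSE]

  bg_bcs <- unique(background_reads$barcode)
  collide <- intersect(spike_bcs, bg_bcs)
  recoded <- data.frame(old = character(0), new = character(0))
  if (length(collide) > 0L) {
    taken <- union(bg_bcs, spike_bcs)
    fresh <- character(length(collide))
    for (i in seq_along(collide)) {
      repeat {
        cand <- random_nt(1L, 16L)
        if (!cand %in% taken) break
      }
      fresh[i] <- cand
      taken <- c(taken, cand)
    }
    recoded <- data.frame(old = collide, new = fresh,
                          stringsAsFactors = FALSE)
    idx <- match(spike$barcode, collide)
    hit <- !is.na(idx)
    spike$barcode[hit] <- fresh[idx[hit]]
    spike_bcs <- ifelse(spike_bcs %in% collide,
                        fresh[match(spike_bcs, collide)], spike_bcs)
  }

  reads <- rbind(spike, background_reads)
  truth <- data.frame(barcode = c(spike_bcs, bg_bcs),
                      spiked = c(rep(TRUE, length(spike_bcs)),
                                 rep(FALSE, length(bg_bcs))),
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth,
                 spiked_barcodes = spike_bcs, target_key = target_key,
                 recoded = recoded, seed = as.integer(seed)),
            class = "dilution")
}

#' @export
print.dilution <- function(x, ...) {
  cat("<dilution>", length(x$spiked_barcodes), "spiked barcodes in",
      nrow(x$truth), "total;", nrow(x$reads), "reads\n")
  invisible(x)
}

#' Detect a known clonotype in a called dilution sample
#'
#' Detection is an exact CDR3-nucleotide-key match of called clonotypes
#' against the known target key; no fuzzy rescue is applied. Sensitivity
#' and false positives are scored against the dilution truth table, and the
#' target's abundance rank is reported.
#'
#' @param clonotypes A `clonotype_set` called on the dilution reads.
#' @param target_key Target clonotype key (see [clone_target_key()]).
#' @param truth Dilution truth table (from [build_dilution()]).
#' @return An `mrd_result` list: `detected_barcodes`, `n_detected`,
#'   `sensitivity`, `false_positive_barcodes`, `clonotype_rank` (`NA` when
#'   the target clonotype was not called).
#' @export
detect_mrd <- function(clonotypes, target_key, truth) {
  spiked <- truth$barcode[truth$spiked]
  if (length(spiked) == 0L) {
    stop("target clonotype absent from the truth table")
  }
  hit <- clonotypes$key == target_key
  detected <- unlist(clonotypes$barcodes[hit], use.names = FALSE)
  detected <- detected %||% character(0)
  true_pos <- intersect(detected, spiked)
  false_pos <- setdiff(detected, spiked)
  ranks <- rank_clonotypes(clonotypes)
  rank <- if (any(hit)) ranks$rank[match(target_key, ranks$key)] else
    NA_integer_
  structure(list(detected_barcodes = sort(true_pos),
                 n_detected = length(true_pos),
                 sensitivity = length(true_pos) / length(spiked),
                 false_positive_barcodes = sort(false_pos),
                 clonotype_rank = rank),
            class = "mrd_result")
}

#' @export
print.mrd_result <- function(x, ...) {
  cat("<mrd_result>", x$n_detected, "detected (sensitivity",
      format(x$sensitivity), ");",
      length(x$false_positive_barcodes), "false positive(s); rank",
      x$clonotype_rank, "\n")
  invisible(x)
}

#' Rank clonotypes by abundance
#'
#' Stable sort by descending cell count with ties broken by lexicographic
#' key; ranks are 1-based.
#'
#' @param clonotypes A `clonotype_set`.
#' @param top Optionally truncate to the first `top` rows.
#' @return The clonotype table with a `rank` column.
#' @export
rank_clonotypes <- function(clonotypes, top = NULL) {
  out <- clonotypes[order(-clonotypes$n_cells, clonotypes$key), ,
                    drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
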
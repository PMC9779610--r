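# Synthetic repertoire generator: clonal + polyclonal plasma-cell samples,
# RNA transcripts under nonsense-mediated decay, barcoded/UMI-tagged reads,
# and bulk DNA amplicons under a consensus-primer PCR model.

#' Simulation configuration
#'
#' @param n_cells Number of cells in the sample.
#' @param clonal_fraction Fraction of cells carrying the shared clonal
#'   rearrangement pair, in `[0, 1]`.
#' @param shm_rate Per-base somatic hypermutation probability, in
#'   `[0, 0.15]`. Plasma-cell myeloma clones are typically heavily mutated;
#'   the default of 0.05 gives ~15 substitutions over a V gene.
#' @param max_trim Maximum nucleotides trimmed per junction end (uniform on
#'   `0:max_trim`).
#' @param max_insert Maximum untemplated N nucleotides per junction (uniform
#'   on `0:max_insert`).
#' @param reads_per_umi Sequenced reads per UMI.
#' @param umis_per_cell UMIs per surviving chain per cell.
#' @param seq_error_rate Per-base read substitution error probability.
#' @param read_length Read length in nt; reads longer than the transcript
#'   are truncated to the transcript.
#' @param nmd_mode `"deterministic"` (stop-codon transcripts always dropped)
#'   or `"probabilistic"` (dropped with probability `p_nmd`).
#' @param p_nmd Dropout probability of stop-codon transcripts in
#'   probabilistic mode.
#' @param bulk_reads_per_cell Amplicon reads contributed per template cell
#'   in the bulk PCR model.
#' @param seed Integer RNG seed; mandatory for every stochastic operation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 200L, clonal_fraction = 0.8,
                       shm_rate = 0.05, max_trim = 6L, max_insert = 6L,
                       reads_per_umi = 3L, umis_per_cell = 4L,
                       seq_error_rate = 0.005, read_length = 450L,
                       nmd_mode = c("deterministic", "probabilistic"),
                       p_nmd = 0.9, bulk_reads_per_cell = 10L,
                       seed = NULL) {
  nmd_mode <- match.arg(nmd_mode)
  cfg <- list(n_cells = as.integer(n_cells),
              clonal_fraction = clonal_fraction, shm_rate = shm_rate,
              max_trim = as.integer(max_trim),
              max_insert = as.integer(max_insert),
              reads_per_umi = as.integer(reads_per_umi),
              umis_per_cell = as.integer(umis_per_cell),
              seq_error_rate = seq_error_rate,
              read_length = as.integer(read_length),
              nmd_mode = nmd_mode, p_nmd = p_nmd,
              bulk_reads_per_cell = as.integer(bulk_reads_per_cell),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  probs <- c(clonal_fraction = cfg$clonal_fraction,
             seq_error_rate = cfg$seq_error_rate, p_nmd = cfg$p_nmd)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (cfg$shm_rate < 0 || cfg$shm_rate > 0.15) {
    stop("shm_rate must lie in [0, 0.15]")
  }
  counts <- c(n_cells = cfg$n_cells, reads_per_umi = cfg$reads_per_umi,
              umis_per_cell = cfg$umis_per_cell,
              read_length = cfg$read_length,
              bulk_reads_per_cell = cfg$bulk_reads_per_cell)
  if (any(counts < 1L)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts < 1L], collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

new_rearrangement <- function(fields) {
  structure(fields, class = "rearrangement")
}

#' @export
print.rearrangement <- function(x, ...) {
  cat("<rearrangement>", x$chain, paste0(x$v_name, "/",
      if (!is.na(x$d_name)) paste0(x$d_name, "/") else "", x$j_name),
      "len", nchar(x$sequence),
      if (x$productive) "productive" else paste0("unproductive (",
                                                 x$failure_reason, ")"),
      "\n  CDR3:", x$cdr3_aa %||% NA, "\n")
  invisible(x)
}

# (re)derive anchors, CDR3 and productivity from sequence + coordinates
reclassify_rearrangement <- function(r) {
  cls <- classify_productivity(r$sequence, r$v_anchor_start,
                               r$j_anchor_start, r$chain)
  r$cdr3_nt <- cls$cdr3_nt
  r$cdr3_aa <- cls$cdr3_aa
  r$productive <- cls$productive
  r$failure_reason <- cls$failure_reason
  r
}

#' Recombine germline segments into a V(D)J rearrangement
#'
#' Assembles trimmed-V + N1 + trimmed-D + N2 + trimmed-J (the D segment and
#' N2 are omitted for IGK). Trim lengths are uniform on `0:max_trim` per
#' junction end, insert lengths uniform on `0:max_insert`, inserted bases
#' uniform over A/C/G/T; all draws come from the session RNG, so seed with
#' `set.seed()` for reproducibility. Productivity is classified with
#' [classify_productivity()].
#'
#' @param v,j Single-row segment data frames (see [get_segments()]).
#' @param d Single-row D-segment data frame, or `NULL` (IGK).
#' @param max_trim,max_insert Junction model bounds.
#' @return A `rearrangement` object. Coordinates are 1-based: `v_end` is the
#'   last V base, `d_start`/`d_end` bound the kept D portion (empty when
#'   `d_end < d_start`), `j_start` is the first J base.
#' @export
recombine <- function(v, d = NULL, j, max_trim = 6L, max_insert = 6L) {
  stopifnot(nrow(v) == 1L, nrow(j) == 1L, v$seg_type == "V",
            j$seg_type == "J")
  if (!is.null(d)) stopifnot(nrow(d) == 1L, d$seg_type == "D")
  chains <- c(v$chain, j$chain, if (!is.null(d)) d$chain)
  if (length(unique(chains)) != 1L) {
    stop("segments must share the chain")
  }
  chain <- v$chain
  rint <- function(max) sample.int(max + 1L, 1L) - 1L
  v_trim <- rint(max_trim)
  j_trim <- rint(max_trim)
  if (v_trim >= nchar(v$sequence) || j_trim >= nchar(j$sequence)) {
    stop("trimming exceeds segment length")
  }
  v_keep <- substr(v$sequence, 1L, nchar(v$sequence) - v_trim)
  n1 <- if (max_insert > 0L) {
    k <- rint(max_insert)
    if (k > 0L) random_nt(1L, k) else ""
  } else ""
  if (!is.null(d)) {
    d5 <- rint(max_trim)
    d3 <- rint(max_trim)
    if (d5 + d3 > nchar(d$sequence)) stop("trimming exceeds segment length")
    d_keep <- substr(d$sequence, d5 + 1L, nchar(d$sequence) - d3)
    n2 <- if (max_insert > 0L) {
      k <- rint(max_insert)
      if (k > 0L) random_nt(1L, k) else ""
    } else ""
  } else {
    d_keep <- ""
    n2 <- ""
  }
  j_keep <- substr(j$sequence, j_trim + 1L, nchar(j$sequence))
  sequence <- paste0(v_keep, n1, d_keep, n2, j_keep)

  v_end <- nchar(v_keep)
  d_start <- v_end + nchar(n1) + 1L
  d_end <- d_start + nchar(d_keep) - 1L
  j_start <- d_end + nchar(n2) + 1L
  v_anchor <- if (!is.na(v$anchor_start) && v$anchor_start + 2L <= v_end) {
    v$anchor_start
  } else NA_integer_
  j_anchor <- if (!is.na(j$anchor_start) && j$anchor_start > j_trim) {
    j_start + (j$anchor_start - j_trim) - 1L
  } else NA_integer_

  r <- new_rearrangement(list(
    chain = chain, v_name = v$name,
    d_name = if (is.null(d)) NA_character_ else d$name, j_name = j$name,
    sequence = sequence, v_end = v_end, d_start = d_start, d_end = d_end,
    j_start = j_start, n1_insert = n1, n2_insert = n2,
    shm_positions = integer(0),
    v_anchor_start = v_anchor, j_anchor_start = j_anchor,
    cdr3_nt = NA_character_, cdr3_aa = NA_character_,
    productive = FALSE, failure_reason = "none"))
  reclassify_rearrangement(r)
}

#' Apply somatic hypermutation to a rearrangement
#'
#' Substitutions only (no indels): the mutation count is
#' `Binomial(length, shm_rate)`, positions are uniform without replacement,
#' and the new base always differs from the original. Productivity and CDR3
#' are re-derived afterwards, so hypermutation can create stop codons or
#' destroy an anchor.
#'
#' @param r A `rearrangement`.
#' @param shm_rate Per-base substitution probability, in `[0, 0.15]`.
#' @return The mutated `rearrangement`; mutated positions are appended to
#'   `shm_positions`.
#' @export
apply_shm <- function(r, shm_rate) {
  if (shm_rate < 0 || shm_rate > 0.15) stop("shm_rate must lie in [0, 0.15]")
  len <- nchar(r$sequence)
  n_mut <- stats::rbinom(1L, len, shm_rate)
  if (n_mut == 0L) return(r)
  pos <- sort(sample.int(len, n_mut))
  s <- strsplit(r$sequence, "", fixed = TRUE)[[1]]
  for (p in pos) {
    s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
  }
  r$sequence <- paste(s, collapse = "")
  r$shm_positions <- sort(unique(c(r$shm_positions, pos)))
  reclassify_rearrangement(r)
}

#' Substitute one base of a rearrangement at a given position
#'
#' Deterministic point mutation used to engineer mechanism fixtures (for
#' example a J-gene mutation under a reverse primer's 3' terminus, or a
#' premature stop codon). Productivity and CDR3 are re-derived.
#'
#' @param r A `rearrangement`.
#' @param pos 1-based position in `r$sequence`.
#' @param base Replacement base, must differ from the current one.
#' @return The mutated `rearrangement`.
#' @export
mutate_at <- function(r, pos, base) {
  stopifnot(pos >= 1L, pos <= nchar(r$sequence), base %in% DNA_BASES)
  if (substr(r$sequence, pos, pos) == base) {
    stop("replacement base equals the original base at position ", pos)
  }
  substr(r$sequence, pos, pos) <- base
  r$shm_positions <- sort(unique(c(r$shm_positions, as.integer(pos))))
  reclassify_rearrangement(r)
}

# draw one random rearrangement (uniform segment choice + SHM)
draw_rearrangement <- function(db, chain, config) {
  vs <- get_segments(db, chain = chain, seg_type = "V")
  js <- get_segments(db, chain = chain, seg_type = "J")
  v <- vs[sample.int(nrow(vs), 1L), , drop = FALSE]
  j <- js[sample.int(nrow(js), 1L), , drop = FALSE]
  d <- NULL
  if (chain == "IGH") {
    ds <- get_segments(db, chain = chain, seg_type = "D")
    d <- ds[sample.int(nrow(ds), 1L), , drop = FALSE]
  }
  r <- recombine(v, d, j, max_trim = config$max_trim,
                 max_insert = config$max_insert)
  apply_shm(r, config$shm_rate)
}

draw_until <- function(db, chain, config, pred, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    r <- draw_rearrangement(db, chain, config)
    if (pred(r)) return(r)
  }
  stop("failed to draw a rearrangement satisfying the predicate after ",
       max_tries, " tries")
}

# Batch somatic hypermutation over a character vector of sequences;
# substitution-only, same per-base binomial model as apply_shm()
shm_batch <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  n_mut <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_mut > 0L)
  if (length(idx) == 0L) return(seqs)
  si <- rep(idx, n_mut[idx])
  pos <- unlist(lapply(idx, function(i) {
    sample.int(nchar(seqs[i]), n_mut[i])
  }))
  seqs <- substitute_bases(seqs, si, pos)
  seqs
}

# substitute a uniform different base at (string index, position) pairs;
# positions within one string must be distinct
substitute_bases <- function(seqs, si, pos) {
  if (length(si) == 0L) return(seqs)
  shift <- sample.int(3L, length(si), replace = TRUE)
  rnd <- stats::ave(si, si, FUN = seq_along)
  for (r in seq_len(max(rnd))) {
    sel <- rnd == r
    i <- si[sel]
    p <- pos[sel]
    cur <- substr(seqs[i], p, p)
    ci <- match(cur, DNA_BASES)
    substr(seqs[i], p, p) <- DNA_BASES[((ci - 1L + shift[sel]) %% 4L) + 1L]
  }
  seqs
}

# Vectorised draw of n independent rearrangements (same junction and
# hypermutation model as recombine() + apply_shm(), batched for speed)
recombine_batch <- function(db, chain, n, config) {
  vs <- get_segments(db, chain = chain, seg_type = "V")
  js <- get_segments(db, chain = chain, seg_type = "J")
  vi <- sample.int(nrow(vs), n, replace = TRUE)
  ji <- sample.int(nrow(js), n, replace = TRUE)
  rint <- function(max) sample.int(max + 1L, n, replace = TRUE) - 1L
  rins <- function() {
    if (config$max_insert == 0L) return(rep("", n))
    substr(random_nt(n, config$max_insert), 1L, rint(config$max_insert))
  }
  v_trim <- rint(config$max_trim)
  j_trim <- rint(config$max_trim)
  v_keep <- substr(vs$sequence[vi], 1L, nchar(vs$sequence[vi]) - v_trim)
  n1 <- rins()
  if (chain == "IGH") {
    ds <- get_segments(db, chain = chain, seg_type = "D")
    di <- sample.int(nrow(ds), n, replace = TRUE)
    d5 <- rint(config$max_trim)
    d3 <- rint(config$max_trim)
    d_keep <- substr(ds$sequence[di], d5 + 1L,
                     nchar(ds$sequence[di]) - d3)
    d_name <- ds$name[di]
    n2 <- rins()
  } else {
    d_keep <- rep("", n)
    d_name <- rep(NA_character_, n)
    n2 <- rep("", n)
  }
  j_keep <- substr(js$sequence[ji], j_trim + 1L, nchar(js$sequence[ji]))
  sequence <- paste0(v_keep, n1, d_keep, n2, j_keep)

  v_anchor <- ifelse(vs$anchor_start[vi] + 2L <= nchar(v_keep),
                     vs$anchor_start[vi], NA_integer_)
  j_pos <- nchar(v_keep) + nchar(n1) + nchar(d_keep) + nchar(n2) + 1L
  j_anchor <- ifelse(js$anchor_start[ji] > j_trim,
                     j_pos + (js$anchor_start[ji] - j_trim) - 1L,
                     NA_integer_)
  sequence <- shm_batch(sequence, config$shm_rate)
  cls <- classify_productivity_vec(sequence, v_anchor, j_anchor,
                                   rep(chain, n))
  data.frame(chain = chain, v_name = vs$name[vi], d_name = d_name,
             j_name = js$name[ji], sequence = sequence,
             v_anchor_start = as.integer(v_anchor),
             j_anchor_start = as.integer(j_anchor),
             cdr3_nt = cls$cdr3_nt, cdr3_aa = cls$cdr3_aa,
             productive = cls$productive,
             failure_reason = cls$failure_reason, stringsAsFactors = FALSE)
}

# rejection-sample a batch of n productive rearrangements
draw_productive_batch <- function(db, chain, n, config) {
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    need <- n - (if (is.null(out)) 0L else nrow(out))
    batch <- recombine_batch(db, chain, max(4L * need, 20L), config)
    out <- rbind(out, batch[batch$productive, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

rearr_row <- function(r, barcode, role) {
  data.frame(barcode = barcode, role = role, chain = r$chain,
             v_name = r$v_name, d_name = r$d_name, j_name = r$j_name,
             sequence = r$sequence,
             v_anchor_start = r$v_anchor_start,
             j_anchor_start = r$j_anchor_start,
             cdr3_nt = r$cdr3_nt, cdr3_aa = r$cdr3_aa,
             productive = r$productive, failure_reason = r$failure_reason,
             stringsAsFactors = FALSE)
}

#' Simulate a plasma-cell sample
#'
#' `round(n_cells * clonal_fraction)` cells share one clonal rearrangement
#' pair (identical CDR3 nucleotides by construction, hypermutation applied
#' once at the clone level); every remaining cell receives independent
#' random heavy and light rearrangements. The clonal chains are guaranteed
#' productive by resampling (myeloma clones are expected productive), except
#' under the alternative clone models:
#'
#' * `"paired"` - productive heavy + productive light (default);
#' * `"light_only"` - productive IGK only, no heavy chain (kappa light-chain
#'   disease analog);
#' * `"biallelic_nmd"` - productive heavy + productive light + a second,
#'   stop-codon-unproductive heavy allele (biallelic clone analog).
#'
#' @param db A `germline_db`.
#' @param config A [sim_config()]; `seed` must be set.
#' @param clone_model Clone structure, see above.
#' @param clone Optional list with elements `heavy`, `light`,
#'   `second_heavy` (each a `rearrangement` or `NULL`) overriding the drawn
#'   clone, e.g. one engineered with [mutate_at()].
#' @param productive_background If `TRUE` (default), polyclonal cells also
#'   carry productive heavy and light chains, as expressed plasma-cell
#'   receptors are under allelic exclusion; `FALSE` leaves background
#'   rearrangements unselected (a sizeable fraction then falls out of frame
#'   or hits a stop codon).
#' @return A `vdj_sample`: list with `cells` (barcode, clonotype_label,
#'   is_clonal), `rearr` (one row per cell chain), `truth` (the truth
#'   table), `clone`, and `config`.
#' @export
simulate_sample <- function(db, config,
                            clone_model = c("paired", "light_only",
                                            "biallelic_nmd"),
                            clone = NULL, productive_background = TRUE) {
  clone_model <- match.arg(clone_model)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  set.seed(config$seed)

  n_cells <- config$n_cells
  n_clonal <- round(n_cells * config$clonal_fraction)
  if (config$clonal_fraction > 0 && n_clonal < 1L) {
    warning("clonal_fraction times n_cells < 1: zero clonal cells")
  }

  productive <- function(r) r$productive
  if (is.null(clone) && n_clonal >= 1L) {
    clone <- switch(clone_model,
      paired = list(
        heavy = draw_until(db, "IGH", config, productive),
        light = draw_until(db, "IGK", config, productive),
        second_heavy = NULL),
      light_only = list(
        heavy = NULL,
        light = draw_until(db, "IGK", config, productive),
        second_heavy = NULL),
      biallelic_nmd = list(
        heavy = draw_until(db, "IGH", config, productive),
        light = draw_until(db, "IGK", config, productive),
        second_heavy = draw_until(db, "IGH", config,
                                  function(r) r$failure_reason ==
                                    "stop_codon")))
  }

  barcodes <- random_barcodes(n_cells)
  clonal_idx <- if (n_clonal >= 1L) sort(sample.int(n_cells, n_clonal)) else
    integer(0)
  is_clonal <- seq_len(n_cells) %in% clonal_idx
  label <- ifelse(is_clonal, "clone", paste0("poly_", barcodes))
  cells <- data.frame(barcode = barcodes, clonotype_label = label,
                      is_clonal = is_clonal, stringsAsFactors = FALSE)

  parts <- list()
  if (n_clonal >= 1L) {
    cb <- barcodes[clonal_idx]
    for (role in c("heavy", "light", "second_heavy")) {
      r <- clone[[role]]
      if (!is.null(r)) {
        block <- rearr_row(r, "x", role)[rep(1L, n_clonal), , drop = FALSE]
        block$barcode <- cb
        parts[[length(parts) + 1L]] <- block
      }
    }
  }
  poly_idx <- which(!is_clonal)
  if (length(poly_idx) > 0L) {
    gen <- if (productive_background) draw_productive_batch else
      recombine_batch
    for (locus in list(list(chain = "IGH", role = "heavy"),
                       list(chain = "IGK", role = "light"))) {
      block <- gen(db, locus$chain, length(poly_idx), config)
      block <- cbind(data.frame(barcode = barcodes[poly_idx],
                                role = locus$role,
                                stringsAsFactors = FALSE), block)
      parts[[length(parts) + 1L]] <- block
    }
  }
  rearr <- do.call(rbind, parts)
  rearr <- rearr[order(match(rearr$barcode, barcodes), rearr$role), ,
                 drop = FALSE]
  rownames(rearr) <- NULL

  truth <- merge(rearr, cells, by = "barcode", sort = FALSE)
  truth <- truth[, c("barcode", "clonotype_label", "is_clonal", "role",
                     "chain", "v_name", "j_name", "cdr3_nt", "cdr3_aa",
                     "productive", "failure_reason")]

  structure(list(cells = cells, rearr = rearr, truth = truth,
                 clone = clone, clone_model = clone_model, config = config),
            class = "vdj_sample")
}

#' @export
print.vdj_sample <- function(x, ...) {
  cat("<vdj_sample>", nrow(x$cells), "cells (",
      sum(x$cells$is_clonal), "clonal ),", nrow(x$rearr),
      "rearrangements\n")
  invisible(x)
}

#' Clonotype key of the simulated clone
#'
#' Canonical key over the clone's productive chains, in the same format as
#' [group_clonotypes()] keys, for use as an MRD detection target.
#'
#' @param sample A `vdj_sample` with at least one clonal cell.
#' @return Key string, e.g. `"IGH:<cdr3_nt>;IGK:<cdr3_nt>"`.
#' @export
clone_target_key <- function(sample) {
  cl <- sample$clone
  if (is.null(cl)) stop("sample has no clone")
  parts <- Filter(Negate(is.null), cl[c("heavy", "light", "second_heavy")])
  parts <- Filter(function(r) isTRUE(r$productive), parts)
  if (length(parts) == 0L) stop("clone has no productive chain")
  clonotype_key(vapply(parts, `[[`, character(1), "chain"),
                vapply(parts, `[[`, character(1), "cdr3_nt"))
}

#' Transcribe simulated cells under nonsense-mediated decay
#'
#' DNA-level rearrangements become RNA transcripts. In deterministic mode a
#' rearrangement whose `failure_reason` is `"stop_codon"` yields zero
#' transcripts; out-of-frame rearrangements without a classified premature
#' stop are retained (decay is modelled as triggered by premature
#' termination codons). In probabilistic mode stop-codon rearrangements are
#' dropped with probability `p_nmd`.
#'
#' @param sample A `vdj_sample`.
#' @param config A [sim_config()].
#' @return Data frame of transcripts (one row per surviving cell chain)
#'   with an `n_umis` column.
#' @export
transcribe_with_nmd <- function(sample, config) {
  tr <- sample$rearr
  is_ptc <- tr$failure_reason == "stop_codon"
  keep <- if (config$nmd_mode == "deterministic") {
    !is_ptc
  } else {
    !(is_ptc & stats::runif(nrow(tr)) < config$p_nmd)
  }
  tr <- tr[keep, c("barcode", "role", "chain", "sequence"), drop = FALSE]
  tr$n_umis <- rep(config$umis_per_cell, nrow(tr))
  rownames(tr) <- NULL
  tr
}

#' Emit barcoded, UMI-tagged reads from transcripts
#'
#' Each transcript yields `n_umis` UMIs with `reads_per_umi` reads each.
#' Reads start at the transcript 5' end, are truncated to the transcript
#' when `read_length` exceeds it (flagged in `truncated`), and carry i.i.d.
#' substitution errors at `seq_error_rate`.
#'
#' @param transcripts Output of [transcribe_with_nmd()].
#' @param config A [sim_config()].
#' @return A `read_set` data frame: `barcode`, `umi` (10 nt), `serial`,
#'   `sequence`, `truncated`.
#' @export
emit_reads <- function(transcripts, config) {
  if (nrow(transcripts) == 0L) {
    return(structure(data.frame(barcode = character(0), umi = character(0),
                                serial = integer(0), sequence = character(0),
                                truncated = logical(0)),
                     class = c("read_set", "data.frame")))
  }
  rpu <- config$reads_per_umi
  n_umis <- transcripts$n_umis
  umi_tr <- rep(seq_len(nrow(transcripts)), times = n_umis)
  umis <- random_nt(length(umi_tr), 10L)
  read_umi <- rep(seq_along(umis), each = rpu)
  tr_idx <- umi_tr[read_umi]

  template <- transcripts$sequence[tr_idx]
  truncated <- config$read_length > nchar(template)
  seqs <- substr(template, 1L, config$read_length)

  # i.i.d. substitution errors over the flattened base coordinates
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, config$seq_error_rate)
  if (n_err > 0L) {
    pos <- sort(sample.int(total, n_err))
    ends <- cumsum(lens)
    ridx <- findInterval(pos - 1L, ends) + 1L
    offs <- pos - c(0L, ends)[ridx]
    seqs <- substitute_bases(seqs, ridx, offs)
  }

  structure(data.frame(barcode = transcripts$barcode[tr_idx],
                       umi = umis[read_umi],
                       serial = stats::ave(tr_idx, read_umi,
                                           FUN = seq_along),
                       sequence = seqs, truncated = truncated,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Simulate bulk-DNA consensus-primer amplicons
#'
#' The template is genomic DNA, so nonsense-mediated decay does not apply
#' and unproductive rearrangements are amplifiable. A rearrangement is
#' amplified only if at least one forward V primer and one reverse J primer
#' pass the annealing screen ([panel_screen()]) on the rearranged sequence
#' followed by the J-C intron context; amplified rearrangements contribute
#' `bulk_reads_per_cell` reads per carrying cell.
#'
#' @param sample A `vdj_sample`.
#' @param panel A primer panel (see [default_primer_panel()]).
#' @param config A [sim_config()].
#' @param k 3'-terminal mismatch window passed to [panel_screen()].
#' @param max_total_mismatches Annealing failure threshold.
#' @return Data frame of distinct heavy-chain rearrangements with cell
#'   counts, amplification verdicts and read counts.
#' @export
simulate_bulk_amplicon <- function(sample, panel, config, k = 3L,
                                   max_total_mismatches = 6L) {
  hc <- sample$rearr[sample$rearr$chain == "IGH", , drop = FALSE]
  if (nrow(hc) == 0L) {
    return(data.frame(sequence = character(0), v_name = character(0),
                      j_name = character(0), productive = logical(0),
                      failure_reason = character(0), n_cells = integer(0),
                      amplified = logical(0), n_reads = integer(0)))
  }
  agg <- stats::aggregate(list(n_cells = hc$barcode),
                          by = list(sequence = hc$sequence), FUN = length)
  first <- hc[!duplicated(hc$sequence), , drop = FALSE]
  agg <- merge(agg, first[, c("sequence", "v_name", "j_name", "productive",
                              "failure_reason")], by = "sequence")
  agg$amplified <- vapply(agg$sequence, function(s) {
    panel_screen(panel, paste0(s, igh_jc_intron()),
                 template_kind = "dna_rearrangement", k = k,
                 max_total_mismatches = max_total_mismatches)$amplifiable
  }, logical(1), USE.NAMES = FALSE)
  agg$n_reads <- ifelse(agg$amplified,
                        agg$n_cells * config$bulk_reads_per_cell, 0L)
  agg <- agg[order(-agg$n_reads, agg$sequence), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
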
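# Shared test helpers: an independent alignment oracle, read-set builders
# and engineered clone constructors.

toy_db <- default_germline_db()

# Brute-force semi-global alignment score (free end gaps on the query,
# subject consumed in full), written independently of the package's
# alignment kernel.
r_semiglobal_score <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(qc)
  m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  H[1, ] <- (0:m) * gap
  for (i in seq_len(n) + 1L) {
    H[i, 1] <- 0
    for (j in seq_len(m) + 1L) {
      H[i, j] <- max(H[i - 1, j - 1] +
                       if (qc[i - 1] == sc[j - 1]) match else mismatch,
                     H[i - 1, j] + gap, H[i, j - 1] + gap)
    }
  }
  max(H[, m + 1])
}

hamming_frac <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b)) / nchar(a)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# read_set data frame from explicit (barcode, umi, sequence) triples
make_reads <- function(barcode, umi, sequence) {
  structure(data.frame(barcode = barcode, umi = umi,
                       serial = seq_along(barcode), sequence = sequence,
                       truncated = FALSE, stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

# 1-based position, in a rearranged sequence, of the J exon site that sits
# under the 3'-terminal window of both packaged reverse primers
# (J position length - 11; see the primer panel layout)
j_primer_kill_pos <- function(r, db) {
  j <- get_segments(db, name = r$j_name, seg_type = "J")
  j_trim <- nchar(j$sequence) - (nchar(r$sequence) - r$j_start + 1L)
  r$j_start + (nchar(j$sequence) - 11L) - j_trim - 1L
}

# Mutate a productive heavy rearrangement at the shared reverse-primer
# 3'-window site, keeping it productive
kill_j_primer_site <- function(r, db) {
  pos <- j_primer_kill_pos(r, db)
  cur <- substr(r$sequence, pos, pos)
  for (b in setdiff(c("A", "C", "G", "T"), cur)) {
    cand <- mutate_at(r, pos, b)
    if (cand$productive) return(cand)
  }
  stop("could not keep productivity while killing the primer site")
}

# draw a rearrangement satisfying `pred` (seeded by the caller)
draw_rearr <- function(db, chain, pred = function(r) r$productive,
                      shm_rate = 0.05, max_tries = 2000) {
  cfg <- sim_config(shm_rate = shm_rate, seed = 1)
  for (i in seq_len(max_tries)) {
    vs <- get_segments(db, chain = chain, seg_type = "V")
    js <- get_segments(db, chain = chain, seg_type = "J")
    v <- vs[sample.int(nrow(vs), 1), , drop = FALSE]
    j <- js[sample.int(nrow(js), 1), , drop = FALSE]
    d <- NULL
    if (chain == "IGH") {
      ds <- get_segments(db, chain = chain, seg_type = "D")
      d <- ds[sample.int(nrow(ds), 1), , drop = FALSE]
    }
    r <- apply_shm(recombine(v, d, j), shm_rate)
    if (pred(r)) return(r)
  }
  stop("no rearrangement satisfying predicate")
}

# RNA-side dominant method call of a called sample
rna_dominant_call <- function(sample_id, calls, ct, chain = "IGH") {
  dom <- dominant_clonotype(ct, sample_id)
  bc <- ct$barcodes[[match(dom$dominant_key, ct$key)]][1]
  row <- calls[calls$barcode == bc & calls$chain == chain, ]
  method_call(sample_id, "scRNA", row$v_call, row$j_call,
              cdr3_aa = row$cdr3_aa,
              proportion_pct = dom$dominant_frequency_pct,
              productive = row$productive, chain = chain)
}

# Biallelic discordance analog: the clone carries a productive heavy whose
# J primer site is mutated plus a stop-codon second allele. RNA sees only
# the productive allele (NMD), DNA amplifies only the unproductive one
# (primer misannealing).
run_plc14_analog <- function(db, seed) {
  set.seed(seed)
  killed <- kill_j_primer_site(draw_rearr(db, "IGH"), db)
  stopcod <- draw_rearr(db, "IGH",
                        pred = function(r) r$failure_reason == "stop_codon")
  clone <- list(heavy = killed, light = draw_rearr(db, "IGK"),
                second_heavy = stopcod)
  cfg <- sim_config(n_cells = 30, clonal_fraction = 0.8, seed = seed)
  s <- simulate_sample(db, cfg, clone = clone)
  reads <- emit_reads(transcribe_with_nmd(s, cfg), cfg)
  calls <- call_cells(reads, db)
  ct <- group_clonotypes(calls)
  rna <- rna_dominant_call("PLC14-analog", calls, ct, chain = "IGH")
  panel <- default_primer_panel()
  bulk <- call_bulk_amplicons(simulate_bulk_amplicon(s, panel, cfg), db)
  dna <- method_call("PLC14-analog", "bulkDNA", bulk$v_call[1],
                     bulk$j_call[1], cdr3_aa = bulk$cdr3_aa[1],
                     proportion_pct = bulk$proportion_pct[1],
                     productive = bulk$productive[1],
                     failure_reason = bulk$failure_reason[1])
  rna_seq <- calls$consensus_nt[calls$barcode ==
                                  ct$barcodes[[1]][1] &
                                  calls$chain == "IGH"]
  reasons <- attribute_discordance(rna, dna, rna_sequence = rna_seq,
                                   panel = panel)
  list(clone = clone, sample = s, calls = calls, ct = ct, rna = rna,
       dna = dna, bulk = bulk, reasons = reasons)
}

# Light-chain-only analog: the clone expresses a productive kappa chain
# while its heavy allele is stop-codon unproductive, so RNA yields an
# IGK-only dominant clonotype and DNA only an unproductive heavy one.
run_plc16_analog <- function(db, seed) {
  set.seed(seed)
  stopcod <- draw_rearr(db, "IGH",
                        pred = function(r) r$failure_reason == "stop_codon")
  clone <- list(heavy = stopcod, light = draw_rearr(db, "IGK"),
                second_heavy = NULL)
  cfg <- sim_config(n_cells = 30, clonal_fraction = 0.8, seed = seed)
  s <- simulate_sample(db, cfg, clone = clone)
  reads <- emit_reads(transcribe_with_nmd(s, cfg), cfg)
  calls <- call_cells(reads, db)
  ct <- group_clonotypes(calls)
  rna <- rna_dominant_call("PLC16-analog", calls, ct, chain = "IGK")
  panel <- default_primer_panel()
  bulk <- call_bulk_amplicons(simulate_bulk_amplicon(s, panel, cfg), db)
  dna <- method_call("PLC16-analog", "bulkDNA", bulk$v_call[1],
                     bulk$j_call[1], cdr3_aa = bulk$cdr3_aa[1],
                     proportion_pct = bulk$proportion_pct[1],
                     productive = bulk$productive[1],
                     failure_reason = bulk$failure_reason[1])
  reasons <- attribute_discordance(rna, dna)
  list(clone = clone, calls = calls, ct = ct, rna = rna, dna = dna,
       bulk = bulk, reasons = reasons)
}

# Run the full MRD dilution design: 13 polyclonal samples totalling 3180
# cells plus a clonal source, 5 spiked barcodes. Heavy; used by the MRD
# acceptance check. `n_background` can be scaled down for quick tests.
run_dilution_design <- function(db, seed, n_background = 3180L,
                                n_samples = 13L, n_spike = 5L) {
  sizes <- rep(n_background %/% n_samples, n_samples)
  sizes[n_samples] <- sizes[n_samples] + n_background - sum(sizes)
  bg <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cfg <- sim_config(n_cells = sizes[i], clonal_fraction = 0,
                      seed = seed * 1000L + i)
    sm <- simulate_sample(db, cfg)
    bg[[i]] <- emit_reads(transcribe_with_nmd(sm, cfg), cfg)
  }
  background <- do.call(rbind, bg)
  ccfg <- sim_config(n_cells = 40L, clonal_fraction = 0.5,
                     seed = seed * 1000L + 999L)
  cs <- simulate_sample(db, ccfg)
  creads <- emit_reads(transcribe_with_nmd(cs, ccfg), ccfg)
  dil <- build_dilution(cs, creads, background, n_clonal_cells = n_spike,
                        seed = seed)
  calls <- call_cells(dil$reads, db)
  ct <- group_clonotypes(calls)
  detect_mrd(ct, dil$target_key, dil$truth)
}
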
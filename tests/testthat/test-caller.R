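v343 <- get_segments(toy_db, name = "IGHV3-43")
j4 <- get_segments(toy_db, name = "IGHJ4")

test_that("UMI and barcode consensus building votes out read errors", {
  bc <- strrep("A", 16)
  seq <- random_seq(120)
  # 3 identical reads in one UMI reproduce the read
  r <- make_reads(rep(bc, 3), rep("AAAAAAAAAA", 3), rep(seq, 3))
  cons <- build_consensus(r, min_umis = 1)
  expect_equal(cons$consensus, seq)
  expect_equal(cons$umi_count, 1L)
  expect_equal(cons$read_count, 3L)

  # one read carrying a single error is outvoted
  bad <- seq
  substr(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(seq, 50, 50))[1]
  r2 <- make_reads(rep(bc, 6),
                   rep(c("AAAAAAAAAA", "CCCCCCCCCC"), each = 3),
                   c(seq, bad, seq, rep(seq, 3)))
  cons2 <- build_consensus(r2, min_umis = 2)
  expect_equal(cons2$consensus, seq)
  expect_equal(cons2$umi_count, 2L)

  # conflicting lengths within a UMI group: vote over the longest
  r3 <- make_reads(rep(bc, 3), rep("GGGGGGGGGG", 3),
                   c(seq, seq, substr(seq, 1, 60)))
  cons3 <- build_consensus(r3, min_umis = 1)
  expect_equal(cons3$consensus, seq)
})

test_that("chains below the UMI threshold are dropped and logged", {
  bc <- strrep("C", 16)
  seq <- random_seq(100)
  r <- make_reads(rep(bc, 3), rep("AAAAAAAAAA", 3), rep(seq, 3))
  expect_message(cons <- build_consensus(r, min_umis = 2), "dropped")
  expect_equal(nrow(cons), 0L)
  expect_equal(attr(cons, "dropped")$barcode, bc)
})

test_that("segment assignment matches self-alignment arithmetic", {
  vs <- get_segments(toy_db, chain = "IGH", seg_type = "V")
  res <- assign_segment(v343$sequence, vs)
  expect_equal(res$best_name, "IGHV3-43")
  expect_equal(res$score, nchar(v343$sequence))
  expect_false(res$ambiguous)
  expect_gte(res$margin, 5)

  # one substitution costs match + mismatch = 2 under unit costs
  q <- v343$sequence
  substr(q, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, 100, 100))[1]
  res2 <- assign_segment(q, vs)
  expect_equal(res2$best_name, "IGHV3-43")
  expect_equal(res2$score, nchar(v343$sequence) - 2)

  expect_error(assign_segment("", vs), "empty query")
  expect_error(assign_segment(q, vs[0, ]), "non-empty")
})

test_that("ties and small margins are flagged ambiguous", {
  a <- random_seq(60)
  b <- a
  substr(b, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(a, 10, 10))[1]
  substr(b, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(a, 40, 40))[1]
  cands <- data.frame(name = c("GENE-B", "GENE-A"), sequence = c(b, a),
                      seg_type = "V", stringsAsFactors = FALSE)
  # query = A: margin to B is 4 (< 5) -> ambiguous, but best is A
  res <- assign_segment(a, cands)
  expect_equal(res$best_name, "GENE-A")
  expect_equal(res$margin, 4)
  expect_true(res$ambiguous)

  # exact tie: lexicographically first name wins, flagged
  cands2 <- data.frame(name = c("GENE-Z", "GENE-M"), sequence = c(a, a),
                       seg_type = "V", stringsAsFactors = FALSE)
  res2 <- assign_segment(a, cands2)
  expect_equal(res2$best_name, "GENE-M")
  expect_true(res2$ambiguous)
})

test_that("alignment scores equal a brute-force DP oracle", {
  set.seed(77)
  cands <- data.frame(name = paste0("SEG-", 1:5),
                      sequence = vapply(1:5, function(i) {
                        random_seq(sample(10:50, 1))
                      }, ""),
                      seg_type = "V", stringsAsFactors = FALSE)
  for (i in 1:30) {
    q <- random_seq(sample(15:60, 1))
    res <- assign_segment(q, cands)
    S <- attr(res, "scores")
    oracle <- vapply(cands$sequence[order(cands$name)],
                     function(s) r_semiglobal_score(q, s), numeric(1))
    expect_equal(unname(S[1, ]), unname(oracle))
  }
})

test_that("CDR3 extraction spans the conserved anchors", {
  set.seed(88)
  for (i in 1:10) {
    r <- draw_rearr(toy_db, "IGH")
    cd <- extract_cdr3(r$sequence, r$v_name, r$j_name, toy_db)
    expect_identical(cd$cdr3_nt, r$cdr3_nt)
    expect_match(cd$cdr3_aa, "^C.*W$")
  }
  for (i in 1:5) {
    r <- draw_rearr(toy_db, "IGK")
    cd <- extract_cdr3(r$sequence, r$v_name, r$j_name, toy_db)
    expect_match(cd$cdr3_aa, "^C.*F$")
  }
})

test_that("an engineered myeloma CDR3 is recovered exactly", {
  # CARTNWPYYFDHW encoded between the V-Cys and J-Trp anchors
  mid <- "GCTCGTACTAATTGGCCTTATTATTTTGATCAT"  # ARTNWPYYFDH
  cdr3 <- paste0("TGT", mid, "TGG")
  cons <- paste0(substr(v343$sequence, 1, v343$anchor_start - 1), cdr3,
                 substr(j4$sequence, j4$anchor_start + 3,
                        nchar(j4$sequence)))
  cd <- extract_cdr3(cons, "IGHV3-43", "IGHJ4", toy_db)
  expect_identical(cd$cdr3_aa, "CARTNWPYYFDHW")
  expect_identical(cd$cdr3_nt, cdr3)
  expect_true(cd$productive)
})

test_that("the minimal CDR3 of adjacent anchors is CW", {
  cons <- paste0(substr(v343$sequence, 1, v343$anchor_start + 2),
                 substr(j4$sequence, j4$anchor_start, nchar(j4$sequence)))
  cd <- extract_cdr3(cons, "IGHV3-43", "IGHJ4", toy_db)
  expect_identical(cd$cdr3_aa, "CW")
})

test_that("productivity classification applies the failure precedence", {
  base_v <- substr(v343$sequence, 1, v343$anchor_start + 2)
  j_tail <- substr(j4$sequence, j4$anchor_start, nchar(j4$sequence))

  ok <- extract_cdr3(paste0(base_v, "GGGACT", j_tail),
                     "IGHV3-43", "IGHJ4", toy_db)
  expect_true(ok$productive)
  expect_identical(ok$failure_reason, "none")

  # a single junction nucleotide shifts the frame
  oof <- extract_cdr3(paste0(base_v, "A", j_tail),
                      "IGHV3-43", "IGHJ4", toy_db)
  expect_false(oof$productive)
  expect_identical(oof$failure_reason, "out_of_frame")

  # in-frame junction containing TAA
  stp <- extract_cdr3(paste0(base_v, "TAA", j_tail),
                      "IGHV3-43", "IGHJ4", toy_db)
  expect_false(stp$productive)
  expect_identical(stp$failure_reason, "stop_codon")

  # destroyed anchor outranks everything
  cls <- classify_productivity(paste0(base_v, "TAA", j_tail), NA, 300,
                               "IGH")
  expect_identical(cls$failure_reason, "missing_anchor")
})

test_that("clonotype grouping keys cells by productive CDR3s", {
  calls <- data.frame(
    barcode = c("B1", "B2", "B3", "B4", "B4"),
    chain = c("IGH", "IGH", "IGH", "IGH", "IGK"),
    cdr3_nt = c("TGTAAATGG", "TGTAAATGG", "TGTAAATGG", "TGTCCCTGG",
                "TGTCCCTTC"),
    cdr3_aa = c("CKW", "CKW", "CKW", "CPW", "CPF"),
    productive = TRUE, stringsAsFactors = FALSE)
  ct <- group_clonotypes(calls)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$n_cells, c(3L, 1L))
  expect_equal(ct$frequency_pct, c(75, 25))
  expect_equal(sum(ct$frequency_pct), 100)
  # the paired cell is keyed on both chains
  expect_identical(ct$key[2], "IGH:TGTCCCTGG;IGK:TGTCCCTTC")

  # unproductive-only cells are excluded from the denominator
  calls2 <- rbind(calls, data.frame(barcode = "B5", chain = "IGH",
                                    cdr3_nt = NA, cdr3_aa = NA,
                                    productive = FALSE,
                                    stringsAsFactors = FALSE))
  ct2 <- group_clonotypes(calls2)
  expect_equal(sum(ct2$n_cells), 4L)
  expect_identical(attr(ct2, "excluded_barcodes"), "B5")

  # a light-chain-only dominant clonotype is a legal key
  calls3 <- data.frame(barcode = c("L1", "L2", "L3"), chain = "IGK",
                       cdr3_nt = "TGTGGGTTC", cdr3_aa = "CGF",
                       productive = TRUE, stringsAsFactors = FALSE)
  ct3 <- group_clonotypes(calls3)
  expect_identical(ct3$key, "IGK:TGTGGGTTC")
  expect_equal(ct3$frequency_pct, 100)

  expect_equal(nrow(group_clonotypes(calls[0, ])), 0L)
})

test_that("full calling recovers simulated truth per cell", {
  cfg <- sim_config(n_cells = 50, clonal_fraction = 0.6, seed = 61)
  s <- simulate_sample(toy_db, cfg)
  reads <- emit_reads(transcribe_with_nmd(s, cfg), cfg)
  calls <- call_cells(reads, toy_db)
  expect_equal(nrow(calls), 100L)  # heavy + light per cell
  m <- match(paste(calls$barcode, calls$chain),
             paste(s$truth$barcode, s$truth$chain))
  expect_true(all(calls$cdr3_nt == s$truth$cdr3_nt[m]))
  expect_true(all(calls$v_call == s$truth$v_name[m]))
  expect_true(all(calls$j_call == s$truth$j_name[m]))
  expect_true(all(calls$umi_count >= 1))
  expect_true(all(calls$read_count >= calls$umi_count))
})
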
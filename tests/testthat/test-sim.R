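v343 <- get_segments(toy_db, name = "IGHV3-43")
d33 <- get_segments(toy_db, name = "IGHD3-3")
j4 <- get_segments(toy_db, name = "IGHJ4")

test_that("recombination with zero trimming concatenates the segments", {
  set.seed(1)
  r <- recombine(v343, d33, j4, max_trim = 0, max_insert = 0)
  expect_identical(r$sequence,
                   paste0(v343$sequence, d33$sequence, j4$sequence))
  expect_equal(nchar(r$sequence), 297 + 20 + 48)
  expect_equal(r$v_end, 297)
  expect_equal(r$d_start, 298)
  expect_equal(r$d_end, 317)
  expect_equal(r$j_start, 318)
  expect_equal(r$v_anchor_start, v343$anchor_start)
  expect_equal(r$j_anchor_start, 317 + j4$anchor_start)
})

test_that("recombination is deterministic under a fixed seed", {
  set.seed(7)
  r1 <- recombine(v343, d33, j4)
  set.seed(7)
  r2 <- recombine(v343, d33, j4)
  expect_identical(r1, r2)
})

test_that("insert lengths follow the uniform junction model", {
  set.seed(11)
  lens <- vapply(1:1000, function(i) {
    nchar(recombine(v343, d33, j4, max_trim = 0, max_insert = 6)$n1_insert)
  }, numeric(1))
  expect_true(all(lens >= 0 & lens <= 6))
  se <- sqrt((7^2 - 1) / 12 / 1000)  # uniform {0..6}: mean 3, var 4
  expect_lt(abs(mean(lens) - 3), 3 * se)
})

test_that("mixed-chain segments are rejected", {
  jk <- get_segments(toy_db, name = "IGKJ1")
  expect_error(recombine(v343, d33, jk), "share the chain")
})

test_that("hypermutation follows the binomial substitution model", {
  set.seed(3)
  r <- recombine(v343, d33, j4, max_trim = 0, max_insert = 0)
  expect_identical(apply_shm(r, 0), r)

  L <- nchar(r$sequence)
  set.seed(4)
  counts <- vapply(1:500, function(i) {
    length(apply_shm(r, 0.05)$shm_positions)
  }, numeric(1))
  se <- sqrt(L * 0.05 * 0.95 / 500)
  expect_lt(abs(mean(counts) - 0.05 * L), 3 * se)

  set.seed(5)
  m <- apply_shm(r, 0.05)
  for (p in m$shm_positions) {
    expect_false(substr(m$sequence, p, p) == substr(r$sequence, p, p))
  }
})

test_that("targeted mutation recomputes productivity", {
  set.seed(6)
  r <- draw_rearr(toy_db, "IGH")
  # break the V anchor cysteine codon (TGT -> TAT)
  pos <- r$v_anchor_start + 1L
  expect_identical(substr(r$sequence, pos, pos), "G")
  m <- mutate_at(r, pos, "A")
  expect_false(m$productive)
  expect_identical(m$failure_reason, "missing_anchor")
  expect_error(mutate_at(r, pos, "G"), "equals the original")
})

test_that("simulated samples have the requested clonal structure", {
  cfg <- sim_config(n_cells = 100, clonal_fraction = 0.8, seed = 21)
  s <- simulate_sample(toy_db, cfg)
  expect_equal(sum(s$cells$clonotype_label == "clone"), 80)
  expect_true(s$clone$heavy$productive)
  expect_true(s$clone$light$productive)
  # all clonal cells share identical CDR3 nucleotide sequences
  cl <- s$truth[s$truth$is_clonal & s$truth$role == "heavy", ]
  expect_equal(length(unique(cl$cdr3_nt)), 1L)

  s2 <- simulate_sample(toy_db, cfg)
  expect_identical(s$truth, s2$truth)

  poly <- simulate_sample(toy_db, sim_config(n_cells = 50,
                                             clonal_fraction = 0,
                                             seed = 22))
  expect_equal(anyDuplicated(poly$cells$clonotype_label), 0L)
  expect_warning(
    simulate_sample(toy_db, sim_config(n_cells = 100,
                                       clonal_fraction = 0.004,
                                       seed = 23)),
    "zero clonal cells")
})

test_that("transcription drops stop-codon rearrangements via NMD", {
  cfg <- sim_config(n_cells = 20, clonal_fraction = 0.5, seed = 31)
  s <- simulate_sample(toy_db, cfg, clone_model = "biallelic_nmd")
  expect_identical(s$clone$second_heavy$failure_reason, "stop_codon")
  tr <- transcribe_with_nmd(s, cfg)
  clonal_bc <- s$cells$barcode[s$cells$is_clonal]
  roles <- unique(tr$role[tr$barcode %in% clonal_bc])
  expect_setequal(roles, c("heavy", "light"))

  # a cell whose only rearrangement carries a stop codon yields nothing
  only_stop <- s
  only_stop$rearr <- s$rearr[s$rearr$role == "second_heavy", ][1, ]
  expect_equal(nrow(transcribe_with_nmd(only_stop, cfg)), 0L)

  # probabilistic mode with p_nmd = 0 keeps every transcript
  cfg0 <- sim_config(n_cells = 20, clonal_fraction = 0.5, seed = 31,
                     nmd_mode = "probabilistic", p_nmd = 0)
  expect_equal(nrow(transcribe_with_nmd(s, cfg0)), nrow(s$rearr))
})

test_that("read emission respects counts, truncation and the error model", {
  tr <- data.frame(barcode = "ACGTACGTACGTACGT", role = "heavy",
                   chain = "IGH", sequence = random_seq(300), n_umis = 4L,
                   stringsAsFactors = FALSE)
  cfg <- sim_config(reads_per_umi = 3, umis_per_cell = 4,
                    seq_error_rate = 0, read_length = 450, seed = 1)
  set.seed(41)
  reads <- emit_reads(tr, cfg)
  expect_equal(nrow(reads), 12L)
  expect_equal(unique(reads$barcode), tr$barcode)
  expect_equal(length(unique(reads$umi)), 4L)
  expect_true(all(reads$sequence == tr$sequence))
  expect_true(all(reads$truncated))  # read_length exceeds the transcript

  cfg2 <- sim_config(seq_error_rate = 0, read_length = 100, seed = 1)
  set.seed(42)
  r2 <- emit_reads(tr, cfg2)
  expect_true(all(!r2$truncated))
  expect_true(all(r2$sequence == substr(tr$sequence, 1, 100)))

  # observed mismatches match the binomial error oracle
  templates <- vapply(1:40, function(i) random_seq(250), "")
  tr3 <- data.frame(barcode = vapply(1:40, function(i) random_seq(16), ""),
                    role = "heavy", chain = "IGH", sequence = templates,
                    n_umis = 1L, stringsAsFactors = FALSE)
  cfg3 <- sim_config(reads_per_umi = 1, umis_per_cell = 1,
                     seq_error_rate = 0.01, read_length = 250, seed = 1)
  set.seed(43)
  r3 <- emit_reads(tr3, cfg3)
  total <- sum(nchar(r3$sequence))
  mism <- sum(vapply(seq_len(nrow(r3)), function(i) {
    sum(charToRaw(r3$sequence[i]) != charToRaw(templates[i]))
  }, numeric(1)))
  se <- sqrt(total * 0.01 * 0.99)
  expect_lt(abs(mism - total * 0.01), 3 * se)
})

test_that("bulk amplification is blind to productivity but primer-gated", {
  panel <- default_primer_panel()
  set.seed(51)
  heavy <- draw_rearr(toy_db, "IGH")
  killed <- kill_j_primer_site(heavy, toy_db)
  stopcod <- draw_rearr(toy_db, "IGH",
                        pred = function(r) r$failure_reason == "stop_codon")
  clone <- list(heavy = killed, light = draw_rearr(toy_db, "IGK"),
                second_heavy = stopcod)
  cfg <- sim_config(n_cells = 12, clonal_fraction = 1, seed = 52)
  s <- simulate_sample(toy_db, cfg, clone = clone)
  amp <- simulate_bulk_amplicon(s, panel, cfg)

  k_row <- amp[amp$sequence == killed$sequence, ]
  s_row <- amp[amp$sequence == stopcod$sequence, ]
  expect_false(k_row$amplified)   # productive but primer site mutated
  expect_equal(k_row$n_reads, 0L)
  expect_true(s_row$amplified)    # unproductive, DNA amplifies regardless
  expect_false(s_row$productive)
  expect_gt(s_row$n_reads, 0L)

  # an unmutated productive rearrangement amplifies
  plain <- recombine(v343, d33, j4, max_trim = 0, max_insert = 0)
  expect_true(panel_screen(panel,
                           paste0(plain$sequence, igh_jc_intron()))$
                amplifiable)
})
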
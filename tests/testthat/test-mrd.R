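# small clonal source + background shared across the MRD tests
mrd_fixture <- local({
  ccfg <- sim_config(n_cells = 20, clonal_fraction = 0.6, seed = 301)
  cs <- simulate_sample(toy_db, ccfg)
  creads <- emit_reads(transcribe_with_nmd(cs, ccfg), ccfg)
  bcfg <- sim_config(n_cells = 30, clonal_fraction = 0, seed = 302)
  bs <- simulate_sample(toy_db, bcfg)
  breads <- emit_reads(transcribe_with_nmd(bs, bcfg), bcfg)
  list(cs = cs, creads = creads, bs = bs, breads = breads)
})

test_that("dilution building spikes the requested barcodes", {
  f <- mrd_fixture
  dil <- build_dilution(f$cs, f$creads, f$breads, n_clonal_cells = 5,
                        seed = 9)
  expect_length(dil$spiked_barcodes, 5)
  expect_equal(length(unique(dil$reads$barcode)), 35L)  # 5 + 30
  expect_true(all(dil$spiked_barcodes %in% dil$reads$barcode))
  expect_equal(sum(dil$truth$spiked), 5L)

  # determinism
  dil2 <- build_dilution(f$cs, f$creads, f$breads, n_clonal_cells = 5,
                         seed = 9)
  expect_identical(dil$reads, dil2$reads)

  # pure clonal mini-sample with no background
  empty <- f$breads[0, ]
  dil0 <- build_dilution(f$cs, f$creads, empty, n_clonal_cells = 5,
                         seed = 9)
  expect_equal(length(unique(dil0$reads$barcode)), 5L)

  expect_error(build_dilution(f$cs, f$creads, f$breads,
                              n_clonal_cells = 100, seed = 9),
               "insufficient clonal barcodes")
  expect_error(build_dilution(f$cs, f$creads, f$breads,
                              n_clonal_cells = 5),
               "seed is mandatory")
})

test_that("barcode collisions between spike and background are re-coded", {
  f <- mrd_fixture
  # force a collision: give the background one barcode from the clone
  clonal_bc <- f$cs$cells$barcode[f$cs$cells$is_clonal][1]
  bg <- f$breads
  bg$barcode[bg$barcode == bg$barcode[1]] <- clonal_bc
  dil <- build_dilution(f$cs, f$creads, bg,
                        n_clonal_cells = sum(f$cs$cells$is_clonal),
                        seed = 2)
  expect_equal(nrow(dil$recoded), 1L)
  expect_identical(dil$recoded$old, clonal_bc)
  # the spiked copy now lives under the fresh barcode
  expect_true(dil$recoded$new %in% dil$spiked_barcodes)
  expect_false(clonal_bc %in% dil$spiked_barcodes)
})

test_that("detection scores sensitivity and false positives exactly", {
  f <- mrd_fixture
  dil <- build_dilution(f$cs, f$creads, f$breads, n_clonal_cells = 5,
                        seed = 9)
  ct <- group_clonotypes(call_cells(dil$reads, toy_db))
  res <- detect_mrd(ct, dil$target_key, dil$truth)
  expect_equal(res$n_detected, 5L)
  expect_equal(res$sensitivity, 1)
  expect_length(res$false_positive_barcodes, 0)
  expect_equal(res$clonotype_rank, 1L)

  # absent target clonotype: nothing detected
  res0 <- detect_mrd(ct, "IGH:TGTAAAAAATGG", dil$truth)
  expect_equal(res0$n_detected, 0L)
  expect_equal(res0$sensitivity, 0)
  expect_true(is.na(res0$clonotype_rank))

  # truth without spiked barcodes is an error
  bad_truth <- dil$truth
  bad_truth$spiked <- FALSE
  expect_error(detect_mrd(ct, dil$target_key, bad_truth),
               "absent from the truth table")
})

test_that("a background CDR3 collision is counted as a false positive", {
  ct <- data.frame(clonotype_id = c("CT0001", "CT0002"),
                   key = c("IGH:TGTAAATGG", "IGH:TGTCCCTGG"),
                   cdr3_aa_key = c("IGH:CKW", "IGH:CPW"),
                   n_cells = c(3L, 1L), frequency_pct = c(75, 25),
                   stringsAsFactors = FALSE)
  ct$barcodes <- list(c("S1", "S2", "BG9"), "BG1")
  truth <- data.frame(barcode = c("S1", "S2", "BG9", "BG1"),
                      spiked = c(TRUE, TRUE, FALSE, FALSE))
  res <- detect_mrd(ct, "IGH:TGTAAATGG", truth)
  expect_equal(res$n_detected, 2L)
  expect_identical(res$false_positive_barcodes, "BG9")
})

test_that("sensitivity degrades but never exceeds the clean-read value
          when UMI support drops to 1 and errors grow", {
  sens_at <- function(err) {
    ccfg <- sim_config(n_cells = 15, clonal_fraction = 0.6,
                       umis_per_cell = 1, reads_per_umi = 1,
                       seq_error_rate = err, seed = 321)
    cs <- simulate_sample(toy_db, ccfg)
    creads <- emit_reads(transcribe_with_nmd(cs, ccfg), ccfg)
    bcfg <- sim_config(n_cells = 40, clonal_fraction = 0,
                       umis_per_cell = 1, reads_per_umi = 1,
                       seq_error_rate = err, seed = 322)
    bs <- simulate_sample(toy_db, bcfg)
    breads <- emit_reads(transcribe_with_nmd(bs, bcfg), bcfg)
    dil <- build_dilution(cs, creads, breads, n_clonal_cells = 5,
                          seed = 3)
    ct <- group_clonotypes(call_cells(dil$reads, toy_db, min_umis = 1))
    detect_mrd(ct, dil$target_key, dil$truth)$sensitivity
  }
  clean <- sens_at(0)
  noisy <- sens_at(0.08)
  expect_equal(clean, 1)
  expect_lte(noisy, clean)
})

test_that("detection does not rely on the target being dominant", {
  # background samples keep their own dominant clonotypes, which outrank
  # the 5 spiked cells; exact-key matching must still find them all
  f <- mrd_fixture
  bg <- do.call(rbind, lapply(1:3, function(i) {
    cfg <- sim_config(n_cells = 40, clonal_fraction = 0.7,
                      seed = 310 + i)
    emit_reads(transcribe_with_nmd(simulate_sample(toy_db, cfg), cfg),
               cfg)
  }))
  dil <- build_dilution(f$cs, f$creads, bg, n_clonal_cells = 5, seed = 17)
  ct <- group_clonotypes(call_cells(dil$reads, toy_db))
  res <- detect_mrd(ct, dil$target_key, dil$truth)
  expect_equal(res$n_detected, 5L)
  expect_length(res$false_positive_barcodes, 0)
  expect_gt(res$clonotype_rank, 1L)  # background clones outrank the spike
})

test_that("clonotype ranking is stable with lexicographic tie-breaks", {
  ct <- data.frame(clonotype_id = c("CT0001", "CT0002", "CT0003"),
                   key = c("B", "C", "A"),
                   cdr3_aa_key = c("B", "C", "A"),
                   n_cells = c(3L, 3L, 5L),
                   frequency_pct = c(27.3, 27.3, 45.4),
                   stringsAsFactors = FALSE)
  rk <- rank_clonotypes(ct)
  expect_equal(rk$key, c("A", "B", "C"))
  expect_equal(rk$rank, 1:3)

  single <- rank_clonotypes(ct[1, ])
  expect_equal(single$rank, 1L)

  big <- data.frame(clonotype_id = sprintf("CT%04d", 1:200),
                    key = sprintf("K%03d", 1:200),
                    cdr3_aa_key = sprintf("K%03d", 1:200),
                    n_cells = rep(1L, 200),
                    frequency_pct = rep(0.5, 200),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(rank_clonotypes(big, top = 100)), 100L)
})
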
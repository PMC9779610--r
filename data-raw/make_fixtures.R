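# Generates the packaged plain-text fixtures under inst/extdata:
#   germline_toy.fasta        toy IGH/IGK germline segment database
#   primers_igh_toy.tsv       toy IGH V-J first-step PCR primer panel
#   clonotype_comparison.csv  19-sample RNA vs DNA dominant-clonotype table
# Run from the package root: Rscript data-raw/make_fixtures.R
# The germline/primer fixtures are deterministic (fixed seed) and the two
# are generated together so that primer sequences match the toy repertoire.

set.seed(15691L)

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")
CODONS <- setdiff(as.vector(outer(outer(BASES, BASES, paste0), BASES,
                                  paste0)), STOPS)

rand_codons <- function(n) sample(CODONS, n, replace = TRUE)
rand_nt <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# --- V genes: 297 nt (99 codons), Cys anchor codon 97, frame 0 ------------
build_v <- function(len_codons, anchor_codon, fam_block = NULL) {
  cod <- rand_codons(len_codons)
  if (!is.null(fam_block)) cod[8:14] <- fam_block   # nt 22..42, FR1 primer
  cod[anchor_codon] <- "TGT"
  paste(cod, collapse = "")
}

mutate_outside <- function(seq, n_mut, protect) {
  s <- strsplit(seq, "")[[1]]
  allowed <- setdiff(seq_along(s), protect)
  pos <- sample(allowed, n_mut)
  for (p in pos) {
    repeat {
      b <- sample(setdiff(BASES, s[p]), 1L)
      cod_i <- (p - 1L) %/% 3L
      cod <- s
      cod[p] <- b
      codon <- paste(cod[(cod_i * 3L + 1L):(cod_i * 3L + 3L)],
                     collapse = "")
      if (!codon %in% STOPS) {
        s[p] <- b
        break
      }
    }
  }
  paste(s, collapse = "")
}

fam3 <- rand_codons(7L)
v_protect <- c(22:42, 289:297)   # family FR1 primer site + anchor/tail
ighv3_43 <- build_v(99L, 97L, fam3)
ighv3_9 <- mutate_outside(ighv3_43, 24L, v_protect)   # ~92% identity
ighv3_23 <- mutate_outside(ighv3_43, 30L, v_protect)  # ~90% identity
ighv1_18 <- build_v(99L, 97L, rand_codons(7L))
ighv4_39 <- build_v(99L, 97L, rand_codons(7L))
ighv5_51 <- build_v(99L, 97L, rand_codons(7L))

igkv <- function() {
  cod <- rand_codons(90L)
  cod[88L] <- "TGT"
  paste(cod, collapse = "")
}
igkv1_33 <- igkv()
igkv1_5 <- igkv()
igkv3_20 <- igkv()

# --- J genes: Trp/Phe anchor, shared 3' exon end for consensus primers ----
J_SHARED15 <- "GGTCACCGTCTCCTC"   # last 15 exon nt of every IGHJ, in frame
build_ighj <- function(mid_codons) {
  paste0(paste(rand_codons(4L), collapse = ""), "TGG",
         paste(rand_codons(mid_codons), collapse = ""), J_SHARED15)
}
ighj4 <- build_ighj(6L)   # 48 nt
ighj5 <- build_ighj(7L)   # 51 nt
ighj6 <- build_ighj(9L)   # 57 nt

build_igkj <- function(tail_codons) {
  paste0(paste(rand_codons(3L), collapse = ""), "TTC",
         paste(rand_codons(tail_codons), collapse = ""))
}
igkj1 <- build_igkj(11L)  # 45 nt
igkj3 <- build_igkj(10L)  # 42 nt

# --- D genes: short, unconstrained ----------------------------------------
ighd2_2 <- rand_nt(16L)
ighd3_3 <- rand_nt(20L)
ighd3_9 <- rand_nt(23L)

segs <- rbind(
  data.frame(name = c("IGHV1-18", "IGHV3-23", "IGHV3-43", "IGHV3-9",
                      "IGHV4-39", "IGHV5-51"),
             seq = c(ighv1_18, ighv3_23, ighv3_43, ighv3_9, ighv4_39,
                     ighv5_51),
             chain = "IGH", type = "V", anchor = 289L, frame = 0L),
  data.frame(name = c("IGHD2-2", "IGHD3-3", "IGHD3-9"),
             seq = c(ighd2_2, ighd3_3, ighd3_9),
             chain = "IGH", type = "D", anchor = NA, frame = NA),
  data.frame(name = c("IGHJ4", "IGHJ5", "IGHJ6"),
             seq = c(ighj4, ighj5, ighj6),
             chain = "IGH", type = "J", anchor = 13L, frame = 0L),
  data.frame(name = c("IGKV1-33", "IGKV1-5", "IGKV3-20"),
             seq = c(igkv1_33, igkv1_5, igkv3_20),
             chain = "IGK", type = "V", anchor = 262L, frame = 0L),
  data.frame(name = c("IGKJ1", "IGKJ3"),
             seq = c(igkj1, igkj3),
             chain = "IGK", type = "J", anchor = 10L, frame = 0L))
segs <- segs[order(segs$name), ]

wrap60 <- function(s) {
  starts <- seq(1L, nchar(s), by = 60L)
  substring(s, starts, pmin(starts + 59L, nchar(s)))
}
fasta <- unlist(lapply(seq_len(nrow(segs)), function(i) {
  hdr <- paste0(">", segs$name[i], "|01|", segs$chain[i], "|",
                segs$type[i], "|",
                ifelse(is.na(segs$anchor[i]), "", segs$anchor[i]), "|",
                ifelse(is.na(segs$frame[i]), "", segs$frame[i]))
  c(hdr, wrap60(segs$seq[i]))
}))
writeLines(fasta, "inst/extdata/germline_toy.fasta")

# --- primer panel ---------------------------------------------------------
INTRON <- "GTGAGTCCTTACAACCTCTCTCTTCTATTC"
exon12 <- substr(J_SHARED15, 4L, 15L)
exon14 <- substr(J_SHARED15, 2L, 15L)
panel <- data.frame(
  name = c("IGHV1-FW", "IGHV3-FW", "IGHV4-FW", "IGHV5-FW",
           "IGH-J-A-1", "IGH-J-A-2"),
  sequence = c(substr(ighv1_18, 22L, 41L), substr(ighv3_43, 22L, 41L),
               substr(ighv4_39, 22L, 41L), substr(ighv5_51, 22L, 41L),
               revcomp(paste0(exon12, substr(INTRON, 1L, 8L))),
               revcomp(paste0(exon14, substr(INTRON, 1L, 6L)))),
  orientation = c(rep("forward", 4L), "reverse", "reverse"),
  target_region = c(rep("V", 4L), "J", "J"),
  intronic_tail_len = c(0L, 0L, 0L, 0L, 8L, 6L))
write.table(panel, "inst/extdata/primers_igh_toy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# --- 19-sample clonotype comparison table (printed values) ----------------
m <- function(id, rv, rj, rp, dv, dj, dp, cdr3) {
  data.frame(sample_id = id, rna_chain = "IGH", rna_v = rv, rna_j = rj,
             rna_proportion_pct = rp, rna_cdr3_aa = cdr3,
             rna_productive = TRUE, dna_v = dv, dna_d = NA_character_,
             dna_j = dj, dna_proportion_pct = dp, dna_cdr3_aa = cdr3,
             dna_productive = TRUE, dna_failure_reason = "none",
             cdr3_source = "printed", stringsAsFactors = FALSE)
}
tab <- rbind(
  m("PLC-01", "IGHV3-48", "IGHJ4", 92.90, "IGHV3-30*09", "IGHJ4*02", 67.55,
    "CARDSYEDYVYW"),
  m("PLC-02", "IGHV3-21", "IGHJ4", 97.93, "IGHV3-21*01", "IGHJ4*02", 74.39,
    "CARYQLDAVAGKWGHYFDYW"),
  m("PLC-03", "IGHV3-43", "IGHJ5", 97.77, "IGHV3-9*01", "IGHJ4*02", 66.23,
    "CAKARLPLVGGLDSW"),
  m("PLC-05", "IGHV3-43", "IGHJ6", 49.79, "IGHV3-9*01", "IGHJ6*02", 13.62,
    "CTRVIGSGASCYDCYYHGMDVW"),
  m("PLC-06", "IGHV3-53", "IGHJ5", 87.91, "IGHV3-53*01", "IGHJ4*02", 57.58,
    "CARGLTAPGFPLDSW"),
  m("PLC-07", "IGHV3-23", "IGHJ6", 65.26, "IGHV3-23*01", "IGHJ6*01", 56.92,
    "CAKGRADCTDGVCYRRYGMDVW"),
  m("PLC-08", "IGHV3-43", "IGHJ4", 99.44, "IGHV3-43*01", "IGHJ4*02", 81.44,
    "CVKGQGGYTYGGFDCW"),
  m("PLC-10", "IGHV5-51", "IGHJ4", 77.63, "IGHV5-51*01", "IGHJ4*02", 57.39,
    "CARTNWPYYFDHW"),
  m("PLC-12", "IGHV3-43", "IGHJ4", 93.73, "IGHV3-9*01", "IGHJ4*02", 62.86,
    "CARDRYQLIIYYFDRW"),
  m("PLC-15", "IGHV3-43", "IGHJ4", 98.97, "IGHV3-9*01", "IGHJ4*02", 32.77,
    "CAKDVRYGYGSTQSAGFDYW"),
  m("PLC-17", "IGHV4-39", "IGHJ4", 95.53, "IGHV4-39*07", "IGHJ4*02", 22.10,
    "CARDKTTMTFSSPIFDYW"),
  m("PLC-18", "IGHV2-5", "IGHJ1", 95.78, "IGHV2-5*02", "IGHJ1*01", 56.58,
    "CAHSGSMWSGYAGTEYFQHW"),
  m("PLC-19", "IGHV4-59", "IGHJ4", 67.50, "IGHV4-59*01", "IGHJ4*02", 21.08,
    "CARAGDYDLLLLDYW"),
  m("PLC-21", "IGHV5-51", "IGHJ6", 80.02, "IGHV5-51*03", "IGHJ6*03", 56.06,
    "CARLPQGGYYYMDVW"),
  m("PLC-22", "IGHV3-53", "IGHJ5", 85.10, "IGHV3-53*01", "IGHJ4*02", 77.01,
    "CARGLTAPGFPLDSW"),
  m("PLC-23", "IGHV3-33", "IGHJ1", 56.11, "IGHV3-30-3*02", "IGHJ1*01",
    61.13, "CAFAIGADGEYFQHW"),
  m("PLC-24", "IGHV2-70", "IGHJ4", 69.68, "IGHV2-70*01", "IGHJ4*02", 40.67,
    "CARGASETQVAMSTAELYFFDSW"),
  # discordant samples: the DNA dominant clonotype is stop-codon
  # unproductive; RNA-side CDR3s are synthetic placeholders (not printed)
  data.frame(sample_id = "PLC-14", rna_chain = "IGH", rna_v = "IGHV1-18",
             rna_j = "IGHJ4", rna_proportion_pct = 98.08,
             rna_cdr3_aa = "CARDGYSSGWFDPW", rna_productive = TRUE,
             dna_v = "IGHV3-23*01", dna_d = "IGHD3-9*01",
             dna_j = "IGHJ5*02", dna_proportion_pct = 78.00,
             dna_cdr3_aa = NA_character_, dna_productive = FALSE,
             dna_failure_reason = "stop_codon", cdr3_source = "synthetic",
             stringsAsFactors = FALSE),
  data.frame(sample_id = "PLC-16", rna_chain = "IGK", rna_v = "IGKV1-33",
             rna_j = "IGKJ3", rna_proportion_pct = 79.00,
             rna_cdr3_aa = "CQQYDNLPLTF", rna_productive = TRUE,
             dna_v = "IGHV3-11*05", dna_d = "IGHD3-3*01",
             dna_j = "IGHJ5*02", dna_proportion_pct = 29.97,
             dna_cdr3_aa = NA_character_, dna_productive = FALSE,
             dna_failure_reason = "stop_codon", cdr3_source = "synthetic",
             stringsAsFactors = FALSE))
write.csv(tab, "inst/extdata/clonotype_comparison.csv", row.names = FALSE)

cat("fixtures written\n")
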
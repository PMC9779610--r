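# Germline segment database: a small packaged V/D/J repertoire with
# conserved-anchor annotations shared by the simulator and the caller.

#' Expected conserved anchor residue for a segment class
#'
#' V segments carry the conserved CDR3-opening cysteine; IGH J segments the
#' conserved tryptophan; IGK J segments the conserved phenylalanine.
#'
#' @param chain `"IGH"` or `"IGK"`.
#' @param seg_type `"V"`, `"D"` or `"J"`.
#' @return Single amino-acid letter, or `NA` for D segments.
#' @export
anchor_residue <- function(chain, seg_type) {
  ifelse(seg_type == "V", "C",
         ifelse(seg_type == "J" & chain == "IGH", "W",
                ifelse(seg_type == "J" & chain == "IGK", "F", NA_character_)))
}

#' Gene family from a gene name
#'
#' The family is the name prefix up to the first hyphen, so that
#' `IGHV3-30-3` belongs to family `IGHV3`. Names without a recognisable
#' immunoglobulin prefix are reported as `"unknown"`.
#'
#' @param name Character vector of gene names.
#' @return Character vector of family names.
#' @export
#' @examples
#' gene_family(c("IGHV3-30-3", "IGHJ4", "oddball"))
gene_family <- function(name) {
  fam <- sub("^([^-]+)-.*$", "\\1", name)
  fam[!grepl("^IG[HK][VDJ]", name)] <- "unknown"
  fam
}

# strip the allele suffix ("IGHV3-23*01" -> "IGHV3-23")
strip_allele <- function(name) sub("\\*.*$", "", name)

new_germline_db <- function(segments) {
  structure(list(segments = segments), class = "germline_db")
}

validate_germline_db <- function(db) {
  s <- db$segments
  if (anyDuplicated(s$name)) {
    stop("duplicate segment name(s): ",
         paste(unique(s$name[duplicated(s$name)]), collapse = ", "))
  }
  if (any(nchar(s$sequence) == 0L)) stop("empty sequence in germline database")
  if (any(grepl("[^ACGT]", s$sequence))) {
    stop("germline sequences must use the A/C/G/T alphabet only")
  }
  is_d <- s$seg_type == "D"
  if (any(!is.na(s$anchor_start[is_d]))) {
    stop("D segments must not carry an anchor: ",
         paste(s$name[is_d & !is.na(s$anchor_start)], collapse = ", "))
  }
  ann <- which(!is_d)
  for (i in ann) {
    a <- s$anchor_start[i]
    if (is.na(a) || a < 1L || a + 2L > nchar(s$sequence[i])) {
      stop("segment ", s$name[i], ": anchor codon outside the sequence")
    }
    aa <- translate_nt(substr(s$sequence[i], a, a + 2L))
    want <- anchor_residue(s$chain[i], s$seg_type[i])
    if (!identical(aa, want)) {
      stop("segment ", s$name[i], ": anchor codon ",
           substr(s$sequence[i], a, a + 2L), " translates to '", aa,
           "', expected '", want, "'")
    }
  }
  invisible(db)
}

#' Load a germline segment database from FASTA
#'
#' Headers are pipe-delimited:
#' `name|allele|chain|seg_type|anchor_start|frame_offset`, where
#' `anchor_start` is the 1-based position of the first base of the conserved
#' anchor codon (Cys for V, Trp for IGH J, Phe for IGK J; empty for D
#' segments) and `frame_offset` is the reading-frame offset in `{0,1,2}`.
#' Segments are ordered by name; anchors are validated on load.
#'
#' @param path Path to the FASTA file.
#' @return A `germline_db` object.
#' @seealso [write_germline_db()], [default_germline_db()]
#' @export
load_germline_db <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  # strsplit drops a trailing empty field (D segments have no anchor)
  trail <- grepl("\\|$", headers)
  parts[trail] <- lapply(parts[trail], c, "")
  bad <- vapply(parts, length, integer(1)) != 6L
  if (any(bad)) {
    stop("malformed FASTA header (expected 6 pipe-delimited fields): ",
         headers[which(bad)[1]])
  }
  f <- function(k) vapply(parts, `[[`, character(1), k)
  segments <- data.frame(
    name = f(1), allele = f(2), chain = f(3), seg_type = f(4),
    anchor_start = suppressWarnings(as.integer(f(5))),
    frame_offset = suppressWarnings(as.integer(f(6))),
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE
  )
  segments$family <- gene_family(segments$name)
  if (!all(segments$chain %in% c("IGH", "IGK"))) {
    stop("chain must be IGH or IGK: ",
         segments$name[!segments$chain %in% c("IGH", "IGK")][1])
  }
  if (!all(segments$seg_type %in% c("V", "D", "J"))) {
    stop("seg_type must be V, D or J: ",
         segments$name[!segments$seg_type %in% c("V", "D", "J")][1])
  }
  segments <- segments[order(segments$name), , drop = FALSE]
  rownames(segments) <- NULL
  db <- new_germline_db(segments)
  validate_germline_db(db)
  db
}

#' Write a germline database as canonical FASTA
#'
#' The canonical form orders records by name and wraps sequence lines at 60
#' columns; `load_germline_db()` followed by `write_germline_db()` is a
#' byte-identical round trip on a canonical file.
#'
#' @param db A `germline_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germline_db <- function(db, path) {
  s <- db$segments[order(db$segments$name), , drop = FALSE]
  headers <- paste(s$name, s$allele, s$chain, s$seg_type,
                   ifelse(is.na(s$anchor_start), "", s$anchor_start),
                   ifelse(is.na(s$frame_offset), "", s$frame_offset),
                   sep = "|")
  x <- Biostrings::DNAStringSet(s$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Packaged toy germline database
#'
#' A small IGH/IGK repertoire with realistic segment lengths, including two
#' IGHV genes of high mutual identity to exercise ambiguous V assignment.
#'
#' @return A `germline_db`.
#' @export
default_germline_db <- function() {
  load_germline_db(system.file("extdata", "germline_toy.fasta",
                               package = "clonotracer", mustWork = TRUE))
}

#' Retrieve segments from a germline database
#'
#' @param db A `germline_db`.
#' @param chain Optional chain filter (`"IGH"`/`"IGK"`).
#' @param seg_type Optional segment-type filter (`"V"`/`"D"`/`"J"`).
#' @param name Optional exact gene-name filter.
#' @return A data frame of segments (possibly zero rows).
#' @export
get_segments <- function(db, chain = NULL, seg_type = NULL, name = NULL) {
  s <- db$segments
  if (!is.null(chain)) s <- s[s$chain %in% chain, , drop = FALSE]
  if (!is.null(seg_type)) s <- s[s$seg_type %in% seg_type, , drop = FALSE]
  if (!is.null(name)) s <- s[s$name %in% name, , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' @export
print.germline_db <- function(x, ...) {
  s <- x$segments
  cat("<germline_db>", nrow(s), "segments\n")
  print(table(chain = s$chain, seg_type = s$seg_type))
  invisible(x)
}
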
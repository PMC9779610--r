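# File formats and fixtures: FASTQ with barcode/UMI headers, AIRR-style
# rearrangement TSV, and the packaged 19-sample clonotype comparison table.

AIRR_COLUMNS <- c("cell_id", "locus", "v_call", "j_call", "junction",
                  "junction_aa", "productive", "consensus_count",
                  "umi_count")

#' Write reads as FASTQ
#'
#' Header convention `@<barcode>:<umi>:<serial>`; qualities are constant
#' (the simulator models substitution errors, not quality). A `.gz` path
#' suffix triggers gzip compression.
#'
#' @param reads A `read_set` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    lines <- rbind(paste0("@", reads$barcode, ":", reads$umi, ":",
                          reads$serial),
                   reads$sequence,
                   "+",
                   strrep("I", nchar(reads$sequence)))
    writeLines(as.vector(lines), con)
  }
  invisible(path)
}

#' Read FASTQ written with the barcode/UMI header convention
#'
#' @param path FASTQ path (`.gz` auto-detected by extension).
#' @return A `read_set` data frame (`barcode`, `umi`, `serial`,
#'   `sequence`).
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(structure(data.frame(barcode = character(0), umi = character(0),
                                serial = integer(0),
                                sequence = character(0)),
                     class = c("read_set", "data.frame")))
  }
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  headers <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  parts <- strsplit(headers, ":", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) != 3L)) {
    stop("FASTQ headers must follow @<barcode>:<umi>:<serial>")
  }
  structure(data.frame(
    barcode = vapply(parts, `[[`, character(1), 1L),
    umi = vapply(parts, `[[`, character(1), 2L),
    serial = as.integer(vapply(parts, `[[`, character(1), 3L)),
    sequence = lines[seq(2L, length(lines), by = 4L)],
    stringsAsFactors = FALSE), class = c("read_set", "data.frame"))
}

#' Write chain calls as an AIRR-style rearrangement TSV
#'
#' Columns: `cell_id`, `locus`, `v_call`, `j_call`, `junction`,
#' `junction_aa`, `productive`, `consensus_count`, `umi_count`. Rows are
#' ordered by cell then locus for deterministic output.
#'
#' @param chain_calls A `chain_calls` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(chain_calls, path) {
  tab <- data.frame(cell_id = chain_calls$barcode,
                    locus = chain_calls$chain,
                    v_call = chain_calls$v_call,
                    j_call = chain_calls$j_call,
                    junction = chain_calls$cdr3_nt,
                    junction_aa = chain_calls$cdr3_aa,
                    productive = chain_calls$productive,
                    consensus_count = chain_calls$read_count,
                    umi_count = chain_calls$umi_count,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cell_id, tab$locus), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an AIRR-style rearrangement TSV
#'
#' Mandatory columns are validated by name; unknown extra columns are
#' preserved with a warning. A `junction_aa` that is not the standard-code
#' translation of `junction` raises a validation warning.
#'
#' @param path TSV path.
#' @return Data frame of rearrangement records.
#' @export
read_airr <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  miss <- setdiff(AIRR_COLUMNS, names(tab))
  if (length(miss) > 0L) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(tab), AIRR_COLUMNS)
  if (length(extra) > 0L) {
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  }
  chk <- !is.na(tab$junction) & !is.na(tab$junction_aa)
  if (any(chk)) {
    mism <- translate_nt(tab$junction[chk]) != tab$junction_aa[chk]
    if (any(mism)) {
      warning("junction_aa inconsistent with junction translation for ",
              sum(mism), " record(s)")
    }
  }
  tab
}

#' Load the packaged 19-sample clonotype comparison table
#'
#' Per-sample dominant clonotype calls from single-cell RNA and bulk-DNA
#' amplicon clonotyping of 19 plasma-cell dyscrasia samples: V/J gene
#' calls, clonal proportions for both methods and the shared CDR3
#' amino-acid sequence for the 17 concordant samples. The two discordant
#' samples carry a stop-codon-unproductive DNA call (one of them
#' paired with a light-chain-only RNA call); their RNA-side CDR3s are
#' synthetic placeholders, flagged `"synthetic"` in `cdr3_source`.
#' Percentages are stored as printed (e.g. `99.44` means 99.44%).
#'
#' @return Data frame with one row per sample.
#' @export
load_clonotype_table <- function() {
  path <- system.file("extdata", "clonotype_comparison.csv",
                      package = "clonotracer", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  stopifnot(nrow(tab) == 19L)
  tab
}
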
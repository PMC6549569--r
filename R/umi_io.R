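# Demultiplexing of dual-indexed reads and UMI extraction.
#
# Each fragment is sequenced with two 14-cycle index reads. An index read
# carries a fixed, sample-specific index plus a degenerate molecular barcode
# (UMI). Demultiplexing matches the fixed part against a sample sheet and
# stores the degenerate part on the read record.

#' Index read layout
#'
#' Describes how each index read splits into a fixed sample index and a
#' degenerate molecular barcode (UMI). The default is a 14-base index read
#' carrying an 8-base fixed index followed by a 6-base UMI; whether the UMI
#' occupies the leading or trailing bases is configurable since adapter
#' designs differ.
#'
#' @param total_index_len Total bases per index read (default 14).
#' @param fixed_len Bases of the fixed sample index (default 8).
#' @param umi_len Bases of the degenerate barcode; must be 4-6 (default 6).
#' @param umi_position `"trailing"` (default) or `"leading"`: where the UMI
#'   sits within the index read.
#' @return An object of class `index_layout`.
#' @export
#' @examples
#' index_layout()
#' index_layout(total_index_len = 12, fixed_len = 8, umi_len = 4)
index_layout <- function(total_index_len = 14L, fixed_len = 8L,
                         umi_len = 6L, umi_position = c("trailing", "leading")) {
  umi_position <- match.arg(umi_position)
  total_index_len <- as.integer(total_index_len)
  fixed_len <- as.integer(fixed_len)
  umi_len <- as.integer(umi_len)
  if (fixed_len + umi_len != total_index_len) {
    stop("fixed_len + umi_len must equal total_index_len", call. = FALSE)
  }
  if (umi_len < 4L || umi_len > 6L) {
    stop("umi_len must be between 4 and 6", call. = FALSE)
  }
  structure(
    list(total_index_len = total_index_len, fixed_len = fixed_len,
         umi_len = umi_len, umi_position = umi_position),
    class = "index_layout"
  )
}

#' @export
print.index_layout <- function(x, ...) {
  cat(sprintf("index layout: %d bp = %d bp fixed index + %d bp UMI (%s)\n",
              x$total_index_len, x$fixed_len, x$umi_len, x$umi_position))
  invisible(x)
}

# Split index read sequences into fixed and UMI parts per the layout.
split_index_read <- function(seqs, layout) {
  if (any(nchar(seqs) < layout$total_index_len)) {
    stop("index read shorter than total_index_len: malformed input",
         call. = FALSE)
  }
  seqs <- substr(seqs, 1L, layout$total_index_len)
  if (layout$umi_position == "trailing") {
    list(fixed = substr(seqs, 1L, layout$fixed_len),
         umi = substr(seqs, layout$fixed_len + 1L, layout$total_index_len))
  } else {
    list(fixed = substr(seqs, layout$umi_len + 1L, layout$total_index_len),
         umi = substr(seqs, 1L, layout$umi_len))
  }
}

#' Read a sample sheet
#'
#' Reads a 3-column delimited file (`sample`, `index1`, `index2`) mapping
#' each sample to its fixed index pair.
#'
#' @param path Path to a tab- or whitespace-delimited file. A header line
#'   with those column names is accepted and optional.
#' @return A data.frame with columns `sample`, `index1`, `index2`.
#' @export
read_sample_sheet <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("sample sheet needs 3 columns", call. = FALSE)
  df <- df[, 1:3]
  names(df) <- c("sample", "index1", "index2")
  df$index1 <- toupper(df$index1)
  df$index2 <- toupper(df$index2)
  df
}

# Fails if any two samples could both match one fragment at the given
# mismatch radius (combined distance over both indices <= 2 * max_mismatch).
validate_sample_sheet <- function(sheet, layout, max_mismatch) {
  stopifnot(all(c("sample", "index1", "index2") %in% names(sheet)))
  if (anyDuplicated(sheet$sample)) {
    stop("duplicate sample names in sample sheet", call. = FALSE)
  }
  bad_len <- nchar(sheet$index1) != layout$fixed_len |
    nchar(sheet$index2) != layout$fixed_len
  if (any(bad_len)) {
    stop("sample sheet index length does not match layout fixed_len",
         call. = FALSE)
  }
  n <- nrow(sheet)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- hamming_to(sheet$index1[(i + 1L):n], sheet$index1[i]) +
        hamming_to(sheet$index2[(i + 1L):n], sheet$index2[i])
      if (any(d <= 2L * max_mismatch)) {
        j <- which(d <= 2L * max_mismatch)[1L] + i
        stop(sprintf(
          "ambiguous sample sheet: samples '%s' and '%s' are within the mismatch radius",
          sheet$sample[i], sheet$sample[j]), call. = FALSE)
      }
    }
  }
  invisible(sheet)
}

#' Demultiplex dual-indexed read pairs and extract UMIs
#'
#' Assigns each fragment to a sample by matching the fixed part of both
#' index reads against the sample sheet (within `max_mismatch` per index),
#' and extracts the degenerate barcode from each index read. Fragments
#' matching no sample go to the `"undetermined"` bin. Assignment is per
#' fragment and order-independent, and every input fragment lands in exactly
#' one bin.
#'
#' @param reads A data.frame of read quartets with columns `name`,
#'   `read1_seq`, `read1_qual`, `read2_seq`, `read2_qual`, `index1_seq`,
#'   `index2_seq` (see [read_fastq_quartet()]).
#' @param sample_sheet Data.frame with columns `sample`, `index1`, `index2`;
#'   indices must be unique at the chosen mismatch radius.
#' @param layout An [index_layout()].
#' @param max_mismatch Maximum mismatches tolerated per index read when
#'   matching the fixed index (default 0, i.e. exact match).
#' @return A list of class `demux_result`:
#'   \describe{
#'     \item{reads}{the input with `sample_id`, `umi1`, `umi2` columns added}
#'     \item{counts}{named integer vector of fragments per bin (samples plus
#'       `undetermined`)}
#'     \item{layout}{the layout used}
#'   }
#' @export
demultiplex <- function(reads, sample_sheet, layout = index_layout(),
                        max_mismatch = 0L) {
  req <- c("name", "index1_seq", "index2_seq")
  if (!all(req %in% names(reads))) {
    stop("reads must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  validate_sample_sheet(sample_sheet, layout, max_mismatch)

  i1 <- split_index_read(toupper(reads$index1_seq), layout)
  i2 <- split_index_read(toupper(reads$index2_seq), layout)

  n <- nrow(reads)
  n_hits <- integer(n)
  assigned <- rep(NA_character_, n)
  for (s in seq_len(nrow(sample_sheet))) {
    ok <- hamming_to(i1$fixed, sample_sheet$index1[s]) <= max_mismatch &
      hamming_to(i2$fixed, sample_sheet$index2[s]) <= max_mismatch
    n_hits <- n_hits + ok
    assigned[ok] <- sample_sheet$sample[s]
  }
  # sheet validation guarantees n_hits <= 1; keep a guard regardless
  assigned[n_hits != 1L] <- "undetermined"

  out <- reads
  out$sample_id <- assigned
  out$umi1 <- i1$umi
  out$umi2 <- i2$umi

  bins <- c(sample_sheet$sample, "undetermined")
  counts <- table(factor(assigned, levels = bins))
  counts <- stats::setNames(as.integer(counts), bins)
  stopifnot(sum(counts) == n)  # conservation: every fragment in one bin

  structure(list(reads = out, counts = counts, layout = layout),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("demultiplexed", sum(x$counts), "fragments:\n")
  for (b in names(x$counts)) cat(sprintf("  %-14s %d\n", b, x$counts[[b]]))
  invisible(x)
}

#' Attach UMI tags to aligned records
#'
#' Carries the barcode pair on the read name using the `name+UMI1+UMI2`
#' dialect, and the resolved sample as a `sample_id` column (the analogue of
#' an optional SAM tag). The encoding round-trips through
#' [parse_tagged_name()] byte-identically. Genomic insert bases are never
#' altered.
#'
#' @param records Data.frame of aligned records with a `qname` column.
#' @param tags Data.frame with columns `name`, `umi1`, `umi2` and optionally
#'   `sample_id` (e.g. the `reads` element of a [demultiplex()] result).
#' @param force Overwrite existing tags if a record already carries them
#'   (default `FALSE`: refused with an error).
#' @return `records` with tagged `qname` and `umi1`, `umi2`, `sample_id`
#'   columns.
#' @export
attach_tags <- function(records, tags, force = FALSE) {
  stopifnot("qname" %in% names(records),
            all(c("name", "umi1", "umi2") %in% names(tags)))
  already <- grepl("\\+[ACGTN]+\\+[ACGTN]+$", records$qname)
  if (any(already)) {
    if (!force) {
      stop("records already carry UMI tags; use force = TRUE to overwrite",
           call. = FALSE)
    }
    records$qname[already] <- sub("\\+[ACGTN]+\\+[ACGTN]+$", "",
                                  records$qname[already])
  }
  idx <- match(records$qname, tags$name)
  if (anyNA(idx)) {
    stop("pairing error: aligned record names not found in tag table",
         call. = FALSE)
  }
  umi1 <- tags$umi1[idx]
  umi2 <- tags$umi2[idx]
  if (any(is.na(umi1) | is.na(umi2) | umi1 == "" | umi2 == "" |
          grepl("[^ACGTN]", umi1) | grepl("[^ACGTN]", umi2))) {
    stop("invalid UMI: empty or non-IUPAC barcode", call. = FALSE)
  }
  records$qname <- paste0(records$qname, "+", umi1, "+", umi2)
  records$umi1 <- umi1
  records$umi2 <- umi2
  if ("sample_id" %in% names(tags)) records$sample_id <- tags$sample_id[idx]
  records
}

#' Parse UMI-tagged read names
#'
#' Inverse of the [attach_tags()] read-name encoding.
#'
#' @param qnames Character vector of `name+UMI1+UMI2` read names.
#' @return Data.frame with columns `name`, `umi1`, `umi2`.
#' @export
parse_tagged_name <- function(qnames) {
  m <- regmatches(qnames, regexec("^(.*)\\+([ACGTN]+)\\+([ACGTN]+)$", qnames))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("read name(s) not in name+UMI1+UMI2 form: ",
         paste(utils::head(qnames[bad], 3), collapse = ", "), call. = FALSE)
  }
  mm <- do.call(rbind, m)
  data.frame(name = mm[, 2], umi1 = mm[, 3], umi2 = mm[, 4],
             stringsAsFactors = FALSE)
}

#' Read a FASTQ quartet into a read table
#'
#' Loads the four FASTQ files of a dual-indexed run (R1, R2, I1, I2; gzip
#' allowed) into the in-memory read-quartet table that [demultiplex()]
#' consumes. Requires the Biostrings package.
#'
#' @param r1,r2,i1,i2 Paths to the paired-end and index FASTQ files.
#' @return Data.frame with columns `name`, `read1_seq`, `read1_qual`,
#'   `read2_seq`, `read2_qual`, `index1_seq`, `index2_seq`.
#' @export
read_fastq_quartet <- function(r1, r2, i1, i2) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTQ input", call. = FALSE)
  }
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    list(name = sub("\\s.*$", "", names(x)),
         seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1); b <- rd(r2); c1 <- rd(i1); c2 <- rd(i2)
  if (!identical(a$name, b$name) || !identical(a$name, c1$name) ||
      !identical(a$name, c2$name)) {
    stop("FASTQ files are not name-synchronised", call. = FALSE)
  }
  data.frame(name = a$name,
             read1_seq = a$seq, read1_qual = a$qual,
             read2_seq = b$seq, read2_qual = b$qual,
             index1_seq = c1$seq, index2_seq = c2$seq,
             stringsAsFactors = FALSE)
}

#' Write demultiplexed reads as per-sample FASTQ
#'
#' Writes `R1`/`R2` FASTQ files per sample bin with barcode-annotated read
#' names (`name+UMI1+UMI2`). Requires the Biostrings package.
#'
#' @param demux A [demultiplex()] result.
#' @param dir Output directory (created if needed).
#' @param include_undetermined Also write the undetermined bin (default
#'   `TRUE`).
#' @return Invisibly, a character vector of files written.
#' @export
write_demux_fastq <- function(demux, dir, include_undetermined = TRUE) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTQ output", call. = FALSE)
  }
  stopifnot(inherits(demux, "demux_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rt <- demux$reads
  rt$tagged_name <- paste0(rt$name, "+", rt$umi1, "+", rt$umi2)
  bins <- unique(rt$sample_id)
  if (!include_undetermined) bins <- setdiff(bins, "undetermined")
  written <- character(0)
  for (b in bins) {
    sub <- rt[rt$sample_id == b, , drop = FALSE]
    for (mate in 1:2) {
      seqs <- Biostrings::DNAStringSet(sub[[paste0("read", mate, "_seq")]])
      names(seqs) <- sub$tagged_name
      qual <- Biostrings::BStringSet(sub[[paste0("read", mate, "_qual")]])
      f <- file.path(dir, sprintf("%s_R%d.fastq", b, mate))
      Biostrings::writeXStringSet(seqs, f, format = "fastq", qualities = qual)
      written <- c(written, f)
    }
  }
  invisible(written)
}
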
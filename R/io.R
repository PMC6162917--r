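#' Read and write FASTA
#'
#' Thin wrappers around Biostrings keeping the package's working currency
#' (named character vectors).
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

SAM_FLAG_UNMAPPED <- 4L
SAM_FLAG_REVERSE <- 16L
SAM_FLAG_SECONDARY <- 256L
SAM_FLAG_DUPLICATE <- 1024L

#' Write alignment records as SAM
#'
#' Emits a minimal SAM file: `@SQ` header lines for every reference contig,
#' one line per record with flags for unmapped/reverse/secondary/duplicate
#' and an `NM:i` tag when the mismatch count is present. Sequence and
#' quality columns are written as `*` unless `sequences` provides the read
#' sequences.
#'
#' @param records Alignment record data frame (see [emit_alignments()]).
#' @param contig_lengths Named vector of reference contig lengths.
#' @param path Output path.
#' @param sequences Optional named character vector of read sequences.
#' @export
write_sam <- function(records, contig_lengths, path, sequences = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths))), con)
  flag <- ifelse(records$mapped, 0L, SAM_FLAG_UNMAPPED) +
    ifelse(records$mapped & !is.na(records$reverse) & records$reverse,
           SAM_FLAG_REVERSE, 0L) +
    ifelse(records$primary, 0L, SAM_FLAG_SECONDARY) +
    ifelse(records$duplicate, SAM_FLAG_DUPLICATE, 0L)
  seq_col <- if (is.null(sequences)) "*" else unname(sequences[records$read_id])
  lines <- paste(records$read_id, flag,
                 ifelse(records$mapped, records$target_id, "*"),
                 ifelse(records$mapped, records$pos, 0L),
                 ifelse(records$mapped, 255L, 0L),
                 ifelse(records$mapped, records$cigar, "*"),
                 "*", 0L, 0L, seq_col, "*", sep = "\t")
  nm <- !is.na(records$nm)
  lines[nm] <- paste0(lines[nm], sprintf("\tNM:i:%d", records$nm[nm]))
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Parses header and alignment lines of the SAM dialect used throughout
#' the package (arbitrary tags tolerated; `NM:i` extracted). Flags for
#' unmapped, reverse, secondary and duplicate records are honored; read
#' length is taken from the query-consuming CIGAR operations (M+I+S), or
#' from the SEQ field for unmapped records.
#'
#' @param path SAM file path.
#' @return List with `records` (alignment record data frame) and
#'   `contig_lengths` (named vector from the `@SQ` lines).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  contig_lengths <- structure(ln, names = sn)
  if (length(body) == 0)
    return(list(records = NULL, contig_lengths = contig_lengths))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 11)
  if (length(bad) > 0)
    stop("malformed SAM line(s) at ",
         paste(bad + length(hdr), collapse = ", "))
  fld <- function(i) vapply(parts, `[[`, "", i)
  flag <- as.integer(fld(2))
  mapped <- bitwAnd(flag, SAM_FLAG_UNMAPPED) == 0
  cigar <- fld(6)
  cigar[!mapped | cigar == "*"] <- NA_character_
  cs <- cigar_summary(cigar)
  seqs <- fld(10)
  read_length <- ifelse(!is.na(cs$query_length), cs$query_length,
                        ifelse(seqs == "*", NA_integer_, nchar(seqs)))
  nm <- vapply(parts, function(p) {
    tags <- p[-(1:11)]
    hit <- tags[startsWith(tags, "NM:i:")]
    if (length(hit) == 0) NA_integer_ else as.integer(sub("NM:i:", "", hit[1]))
  }, 0L)
  records <- data.frame(
    read_id = fld(1),
    mapped = mapped,
    primary = bitwAnd(flag, SAM_FLAG_SECONDARY) == 0,
    duplicate = bitwAnd(flag, SAM_FLAG_DUPLICATE) != 0,
    target_id = ifelse(mapped, fld(3), NA_character_),
    pos = ifelse(mapped, as.integer(fld(4)), NA_integer_),
    cigar = cigar,
    nm = nm,
    read_length = as.integer(read_length),
    reverse = ifelse(mapped, bitwAnd(flag, SAM_FLAG_REVERSE) != 0, NA),
    stringsAsFactors = FALSE)
  list(records = records, contig_lengths = contig_lengths)
}

#' Read and write the bin-membership table
#'
#' TSV with columns `contig_id`, `bin_id`, `length`; unbinned contigs have
#' an empty `bin_id`.
#'
#' @param bins Bin table data frame.
#' @param path File path.
#' @export
write_bins <- function(bins, path) {
  out <- data.frame(contig_id = bins$contig_id,
                    bin_id = ifelse(is.na(bins$bin_id), "", bins$bin_id),
                    length = bins$length)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer"))
  if (!all(c("contig_id", "bin_id", "length") %in% names(df)))
    stop("bin table must have columns contig_id, bin_id, length")
  df$bin_id[df$bin_id == ""] <- NA_character_
  df[c("contig_id", "length", "bin_id")]
}

#' Read and write alignment-block tables
#'
#' TSV with columns `query_id`, `target_id`, `q_start`, `q_end`, `t_start`,
#' `t_end`, `pct_identity` (coordinates 0-based half-open).
#'
#' @param blocks Block data frame.
#' @param path File path.
#' @export
write_blocks <- function(blocks, path) {
  cols <- c("query_id", "target_id", "q_start", "q_end", "t_start",
            "t_end", "pct_identity")
  write.table(blocks[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "target_id", "q_start", "q_end", "t_start",
            "t_end", "pct_identity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("block table missing column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' Read a genome-by-feature count table (markers or COG categories)
#'
#' TSV with a `genome_id` column followed by one column per feature.
#'
#' @param path File path.
#' @param features Optional declared feature set; the file's columns must
#'   match it exactly.
#' @return Integer matrix with genome ids as row names.
#' @export
read_count_table <- function(path, features = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "genome_id")
    stop("count table must start with a 'genome_id' column")
  m <- as.matrix(df[-1])
  rownames(m) <- df$genome_id
  if (!is.null(features) && !identical(sort(colnames(m)), sort(features)))
    stop("count table columns do not match the declared feature set")
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_table
#' @param table Matrix with genome ids as row names.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(genome_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
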
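## File-format plumbing: FASTA/FASTQ via Biostrings, plus the light
## line-oriented formats (PAF, SAM text, BED, Kraken per-read output).

# Normalize an assembly (DNAStringSet or named character) to named character.
asm_chars <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("assembly sequences must be named by contig")
    }
    toupper(x)
  } else {
    stop("assembly must be a DNAStringSet or a named character vector")
  }
}

#' Read an assembly from FASTA
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_assembly <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write an assembly to FASTA
#' @param assembly DNAStringSet or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  x <- asm_chars(assembly)
  dss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Write single-end reads to FASTQ
#'
#' Constant high base quality (Q37, "F") throughout: read-level quality
#' modelling is outside the scope of this benchmark.
#'
#' @param reads named character vector (names are read IDs).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(
    nchar(reads), function(n) strrep("F", n), character(1)
  ))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read single-end reads from FASTQ or FASTA
#' @param path input path.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return named character vector of sequences.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dss <- Biostrings::readDNAStringSet(path, format = format)
  # FASTQ descriptions may carry comments after the ID
  ids <- sub("\\s.*$", "", names(dss))
  setNames(as.character(dss), ids)
}

#' Read a PAF whole-genome alignment table
#'
#' Only the standard first 12 columns are kept; optional SAM-style tags
#' are ignored.
#'
#' @param path PAF file path.
#' @return data.frame with PAF columns (`qname`, ..., `tname`, `tstart`,
#'   `tend`, ...). Coordinates are 0-based half-open as in the format.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("qname", "qlen", "qstart", "qend", "strand",
            "tname", "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
  if (length(lines) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    for (j in c(2:4, 7:12)) df[[j]] <- integer(0)
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12L)) stop("malformed PAF line: fewer than 12 fields")
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in c(2:4, 7:12)) df[[j]] <- as.integer(df[[j]])
  df
}

#' Write a PAF alignment table
#' @param paf data.frame as returned by [read_paf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  write.table(paf, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals to BED
#' @param regions data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open) and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- c("contig", "start", "end")
  stopifnot(all(cols %in% names(regions)))
  df <- regions[, c(cols, intersect("name", names(regions)))]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#' @param path BED file path.
#' @return data.frame with `contig`, `start`, `end` (0-based half-open)
#'   and `name` when a fourth column is present.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

# Parse SAM text records into (qname, flag). Header lines skipped.
# Only these two fields are consumed anywhere in the package.
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 11L)) stop("malformed SAM line: fewer than 11 fields")
  qname <- vapply(parts, `[[`, character(1), 1L)
  flag_raw <- vapply(parts, `[[`, character(1), 2L)
  flag <- suppressWarnings(as.integer(flag_raw))
  if (anyNA(flag)) {
    stop("malformed SAM FLAG field: ", paste(unique(flag_raw[is.na(flag)]), collapse = ", "))
  }
  data.frame(qname = qname, flag = flag, stringsAsFactors = FALSE)
}

#' Read Kraken-style per-read classifications
#'
#' Standard 5-column per-read output (`C`/`U`, read ID, taxid, length,
#' LCA mapping); only the first three columns are consumed.
#'
#' @param path path to the classification table.
#' @return data.frame with `classified` (logical), `read_id`, `taxid`.
#' @export
read_kraken <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, quote = "",
                   col.names = paste0("V", 1:5), fill = TRUE)
  data.frame(
    classified = df$V1 == "C",
    read_id = as.character(df$V2),
    taxid = as.integer(df$V3),
    stringsAsFactors = FALSE
  )
}

#' Read BLAST tabular output (outfmt 6 style)
#'
#' Expects at least the columns `qseqid`, `staxid`, `pident`, `qcovs`, in
#' that order (a reduced tabular format; `staxid` may be a
#' semicolon-separated taxid list, of which the first is used).
#'
#' @param path TSV file path.
#' @return data.frame with `read_id`, `taxid`, `pident`, `qcovs`.
#' @export
read_blast_hits <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BLAST hit table needs >= 4 columns: qseqid staxid pident qcovs")
  data.frame(
    read_id = as.character(df[[1]]),
    taxid = as.integer(sub(";.*$", "", as.character(df[[2]]))),
    pident = as.numeric(df[[3]]),
    qcovs = as.numeric(df[[4]]),
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
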
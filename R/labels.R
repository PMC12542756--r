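## Per-read binary host labels from tool outputs (SAM, Kraken-style
## tables) or from a built-in naive k-mer classifier, assembled into a
## rectangular label matrix.

#' Construct a label matrix
#'
#' @param labels logical matrix, reads x methods (`TRUE` = host);
#'   rownames are read IDs, colnames are method names.
#' @param methods data.frame with `name`, `category` (`"alignment-based"`
#'   or `"k-mer-based"`), `reference_id`, one row per matrix column.
#' @return object of class `label_matrix`.
#' @export
label_matrix <- function(labels, methods) {
  stopifnot(is.matrix(labels), is.logical(labels))
  if (is.null(rownames(labels)) || is.null(colnames(labels))) {
    stop("label matrix must have read IDs as rownames and methods as colnames")
  }
  if (anyDuplicated(colnames(labels))) stop("duplicate method names")
  if (anyNA(labels)) stop("label matrix must be complete (rectangular)")
  stopifnot(all(c("name", "category", "reference_id") %in% names(methods)))
  if (!identical(sort(methods$name), sort(colnames(labels)))) {
    stop("methods table must describe exactly the matrix columns")
  }
  bad <- !methods$category %in% c("alignment-based", "k-mer-based")
  if (any(bad)) stop("method category must be alignment-based or k-mer-based")
  methods <- methods[match(colnames(labels), methods$name), , drop = FALSE]
  rownames(methods) <- NULL
  structure(list(labels = labels, methods = methods), class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("label_matrix:", nrow(x$labels), "reads x", ncol(x$labels), "methods\n")
  cat("methods:", paste0(x$methods$name, " (", x$methods$category, ")",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Host labels from a SAM alignment stream
#'
#' Mirrors the discard-if-aligned dehosting rule: a read is labeled host
#' iff it has at least one aligned record that is neither secondary
#' (0x100) nor supplementary (0x800); an unmapped primary (0x4) alone
#' labels the read non-host. Only QNAME and FLAG are consumed.
#'
#' @param sam path to a SAM text file.
#' @param method a method descriptor row (`name`, `category`,
#'   `reference_id`); defaults to a generic alignment-based descriptor.
#' @return named logical vector (`TRUE` = host) over the reads present
#'   in the stream.
#' @export
labels_from_alignment <- function(sam, method = NULL) {
  rec <- read_sam_minimal(sam)
  primary <- bitwAnd(rec$flag, 0x100) == 0L & bitwAnd(rec$flag, 0x800) == 0L
  mapped <- bitwAnd(rec$flag, 0x4) == 0L
  prim <- rec[primary, , drop = FALSE]
  if (nrow(prim) > 0) {
    st <- split(mapped[primary], prim$qname)
    conflict <- vapply(st, function(v) length(unique(v)) > 1L, logical(1))
    if (any(conflict)) {
      stop("conflicting primary records for read(s): ",
           paste(names(st)[conflict], collapse = ", "))
    }
  }
  ids <- unique(rec$qname)
  host <- vapply(split(primary & mapped, rec$qname)[ids], any, logical(1))
  setNames(host, ids)
}

#' Host labels from Kraken-style per-read classifications
#'
#' A read is labeled host iff its assigned taxid's lineage (inclusive)
#' contains the taxonomy's host clade (any Chordata species under the
#' default clade); unclassified reads are non-host.
#'
#' @param classifications data.frame with `classified` (logical),
#'   `read_id`, `taxid`, as from [read_kraken()].
#' @param taxonomy a [taxonomy_table()].
#' @return named logical vector (`TRUE` = host).
#' @export
labels_from_kraken <- function(classifications, taxonomy) {
  stopifnot(all(c("classified", "read_id", "taxid") %in% names(classifications)))
  host <- rep(FALSE, nrow(classifications))
  cl <- classifications$classified
  if (any(cl)) {
    host[cl] <- in_clade(taxonomy, classifications$taxid[cl])
  }
  setNames(host, classifications$read_id)
}

#' Build a canonical k-mer index of a reference assembly
#'
#' @param reference assembly (named character or DNAStringSet).
#' @param k k-mer size (>= 4).
#' @return character vector of unique canonical k-mers, wrapped with
#'   attributes `k`; suitable for repeated classification calls.
#' @export
kmer_index <- function(reference, k = 31L) {
  if (k < 4L) stop("k < 4: spectrum degenerate")
  asm <- asm_chars(reference)
  idx <- unique(kmers_of(asm, k, canonical = TRUE))
  attr(idx, "k") <- as.integer(k)
  idx
}

#' Classify reads as host by shared canonical k-mers
#'
#' A desk-scale stand-in for an aligner or k-mer screener: a read is
#' labeled host iff it shares at least `min_shared` canonical k-mers
#' with the reference k-mer set. Strands are collapsed canonically.
#'
#' @param reads named character vector (or DNAStringSet) of reads.
#' @param reference assembly, or a prebuilt [kmer_index()].
#' @param k k-mer size; ignored when `reference` is an index.
#' @param min_shared minimum number of shared k-mers to call host.
#' @return named logical vector (`TRUE` = host).
#' @export
kmer_classify_reads <- function(reads, reference, k = 31L, min_shared = 1L) {
  if (is.character(reference) && !is.null(attr(reference, "k"))) {
    idx <- reference
    k <- attr(reference, "k")
  } else {
    idx <- kmer_index(reference, k)
  }
  if (methods::is(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  if (is.null(names(reads))) stop("reads must be named by read ID")
  if (any(nchar(reads) < k)) stop("k exceeds a read length")
  kt <- read_kmer_table(reads, k, canonical = TRUE)
  shared <- tabulate(kt$read_idx[kt$kmer %in% idx], nbins = length(reads))
  setNames(shared >= min_shared, names(reads))
}

# All k-mers of all reads at once: read index, 0-based offset in the
# read, and the (optionally canonical) k-mer; N-containing k-mers are
# dropped. Single pass, vectorized.
read_kmer_table <- function(reads, k, canonical = FALSE) {
  reads <- toupper(as.character(reads))
  n_km <- pmax(nchar(reads) - k + 1L, 0L)
  read_idx <- rep(seq_along(reads), n_km)
  offset <- unlist(lapply(n_km, seq_len), use.names = FALSE) - 1L
  km <- stringi::stri_sub(rep(reads, n_km), offset + 1L, offset + k)
  if (canonical) {
    rc <- revcomp(km)
    km <- ifelse(km <= rc, km, rc)
  }
  keep <- !stringi::stri_detect_fixed(km, "N")
  list(read_idx = read_idx[keep], offset = offset[keep], kmer = km[keep])
}

#' Assemble per-method label sets into a label matrix
#'
#' @param label_sets list of `list(method = <descriptor row>, labels =
#'   <named logical vector>)`; all label sets must cover the same read
#'   universe.
#' @return a [label_matrix()].
#' @export
assemble_label_matrix <- function(label_sets) {
  if (length(label_sets) == 0L) stop("no label sets supplied")
  methods <- do.call(rbind, lapply(label_sets, function(s) {
    m <- s$method
    data.frame(name = m$name, category = m$category,
               reference_id = m$reference_id %||% "", stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(methods$name)) {
    stop("duplicate method name: ",
         paste(unique(methods$name[duplicated(methods$name)]), collapse = ", "))
  }
  universe <- names(label_sets[[1]]$labels)
  for (s in label_sets) {
    missing <- setdiff(universe, names(s$labels))
    extra <- setdiff(names(s$labels), universe)
    if (length(missing) > 0 || length(extra) > 0) {
      stop("method ", s$method$name, " does not cover the read universe; ",
           "missing: ", paste(head(missing, 5), collapse = ", "),
           if (length(extra)) paste0("; extra: ", paste(head(extra, 5), collapse = ", ")) else "")
    }
  }
  lab <- vapply(label_sets, function(s) unname(s$labels[universe]),
                logical(length(universe)))
  dimnames(lab) <- list(universe, methods$name)
  label_matrix(lab, methods)
}

#' Write a label matrix as TSV (read_id plus one 0/1 column per method)
#' @param matrix a [label_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_matrix <- function(matrix, path) {
  df <- data.frame(read_id = rownames(matrix$labels),
                   matrix$labels * 1L, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a label matrix from TSV
#' @param path TSV path as written by [write_label_matrix()].
#' @param methods methods descriptor data.frame (`name`, `category`,
#'   `reference_id`) for the matrix columns.
#' @return a [label_matrix()].
#' @export
read_label_matrix <- function(path, methods) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  lab <- as.matrix(df[, -1, drop = FALSE]) == 1L
  rownames(lab) <- df$read_id
  label_matrix(lab, methods)
}
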
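## Characterization of false-negative (missed host) reads: GC content,
## k-mer spectra (where satellite-repeat signatures show up), naive
## placement on a reference, and a tally of falsely assigned taxa.

#' Per-read GC content
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from both
#' numerator and denominator. All-N reads are reported `NA` with a flag.
#'
#' @param reads named character vector or DNAStringSet.
#' @return list with `per_read` (named numeric, `NA` where undefined)
#'   and `summary` (mean and quartiles over defined reads).
#' @export
gc_content <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  if (length(reads) == 0L) stop("no reads supplied")
  reads <- toupper(reads)
  gc <- stringi::stri_count_charclass(reads, "[GC]")
  at <- stringi::stri_count_charclass(reads, "[AT]")
  frac <- ifelse(gc + at > 0, gc / (gc + at), NA_real_)
  names(frac) <- names(reads)
  ok <- !is.na(frac)
  list(
    per_read = frac,
    summary = c(mean = mean(frac[ok]),
                stats::quantile(frac[ok], c(0.25, 0.5, 0.75))),
    n_undefined = sum(!ok)
  )
}

#' K-mer spectrum of a read set
#'
#' Counts every length-`k` window over all reads; windows containing
#' `N` are skipped entirely. With `canonical = TRUE` the two strands
#' are collapsed.
#'
#' @param reads named character vector or DNAStringSet.
#' @param k k-mer size (>= 1).
#' @param canonical collapse strands?
#' @return object of class `kmer_spectrum`: list with `k`, `counts`
#'   (named integer vector, decreasing), `total_kmers`.
#' @export
kmer_spectrum <- function(reads, k, canonical = FALSE) {
  if (k < 1L) stop("k must be >= 1")
  if (methods::is(reads, "DNAStringSet")) {
    reads <- as.character(reads)
  }
  km <- kmers_of(reads, k, canonical = canonical)
  counts <- sort(table(km), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(k = as.integer(k), counts = counts,
                 total_kmers = sum(counts)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum: k =", x$k, ",", length(x$counts), "distinct,",
      x$total_kmers, "total\n")
  print(head(x$counts, 10))
  invisible(x)
}

#' Place reads on a reference by seed clustering
#'
#' A naive placement adequate for ideogram-style summaries, using the
#' same canonical k-mer machinery as the classifier: each read's shared
#' k-mers are located on the reference, the contig with most shared
#' k-mers is chosen, its positions are clustered (gaps larger than the
#' read length split clusters), and the densest cluster's span is
#' reported as a 0-based half-open interval. Reads sharing fewer than
#' `min_shared` k-mers are reported unplaced.
#'
#' @param reads named character vector or DNAStringSet.
#' @param reference assembly (named character or DNAStringSet).
#' @param k seed k-mer size.
#' @param min_shared minimum shared k-mers to attempt placement.
#' @return data.frame with `read_id`, `placed`, `contig`, `start`,
#'   `end`, `n_seeds`; unplaced reads have `NA` coordinates.
#' @export
map_read_positions <- function(reads, reference, k = 31L, min_shared = 1L) {
  asm <- asm_chars(reference)
  if (length(asm) == 0L || all(nchar(asm) == 0L)) stop("empty reference")
  if (methods::is(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  rl <- max(nchar(reads))
  # positional canonical k-mer index of the reference
  ref_tab <- read_kmer_table(asm, k, canonical = TRUE)
  ref_dt <- data.table::data.table(
    kmer = ref_tab$kmer,
    contig = names(asm)[ref_tab$read_idx],
    pos = ref_tab$offset
  )
  data.table::setkey(ref_dt, kmer)
  kt <- read_kmer_table(reads, k, canonical = TRUE)
  q_dt <- data.table::data.table(ridx = kt$read_idx, kmer = kt$kmer)
  hits <- ref_dt[q_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  out <- data.frame(read_id = names(reads), placed = FALSE,
                    contig = NA_character_, start = NA_integer_,
                    end = NA_integer_, n_seeds = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(hits) > 0) {
    by_read <- split(hits, hits$ridx)
    for (key in names(by_read)) {
      h <- by_read[[key]]
      i <- as.integer(key)
      best_ctg <- names(sort(table(h$contig), decreasing = TRUE))[1]
      pos <- sort(h$pos[h$contig == best_ctg])
      if (length(pos) < min_shared) next
      cl <- cumsum(c(0L, diff(pos) > rl))
      sizes <- table(cl)
      pick <- as.integer(names(sizes)[which.max(sizes)])
      span <- pos[cl == pick]
      if (length(span) < min_shared) next
      out$placed[i] <- TRUE
      out$contig[i] <- best_ctg
      out$start[i] <- span[1]
      out$end[i] <- span[length(span)] + k
      out$n_seeds[i] <- length(span)
    }
  }
  out
}

#' Tally the taxa assigned to a read set
#'
#' Top-`n` taxa by read count, remainder aggregated; unclassified reads
#' are tallied under `"unclassified"`. Ties at the cut are broken
#' lexicographically by taxon name.
#'
#' @param classifications data.frame with `read_id`, `taxid`, and
#'   optionally `classified`.
#' @param taxonomy a [taxonomy_table()] used to resolve names.
#' @param top_n number of taxa to report separately (default 5).
#' @return data.frame with `taxon`, `count`, `percent`; the remainder
#'   row (if any) is named `"other"`.
#' @export
taxa_tally <- function(classifications, taxonomy, top_n = 5L) {
  if (nrow(classifications) == 0L) {
    return(data.frame(taxon = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  classified <- if ("classified" %in% names(classifications)) {
    classifications$classified
  } else rep(TRUE, nrow(classifications))
  nm <- rep("unclassified", nrow(classifications))
  if (any(classified)) {
    tx <- classifications$taxid[classified]
    bad <- !(as.character(tx) %in% names(taxonomy$name))
    if (any(bad)) stop("taxid(s) absent from taxonomy: ",
                       paste(unique(tx[bad]), collapse = ", "))
    nm[classified] <- unname(taxonomy$name[as.character(tx)])
  }
  tab <- table(nm)
  # decreasing count, lexicographic name as the tie-break
  ord <- order(-as.integer(tab), names(tab))
  tab <- tab[ord]
  total <- sum(tab)
  if (length(tab) > top_n) {
    top <- tab[seq_len(top_n)]
    rest <- sum(tab[-seq_len(top_n)])
    df <- data.frame(taxon = c(names(top), "other"),
                     count = c(as.integer(top), rest),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(taxon = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  }
  df$percent <- 100 * df$count / total
  df
}
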
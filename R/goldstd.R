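## The gold-standard adjudication cascade: per-read truth labels fused
## from cross-method consensus, alignment x k-mer category concordance,
## and a BLAST fallback against the host clade at identity/coverage
## thresholds.

#' Adjudicate per-read gold-standard host labels
#'
#' Decision cascade per read:
#' 1. **consensus** — all methods agree: that label is the gold label.
#' 2. **category-concordance** — otherwise, if at least one
#'    alignment-based and at least one k-mer-based method label the read
#'    host, the gold label is host.
#' 3. **blast-adjudicated** — otherwise the read falls through to the
#'    hit table: host iff some hit lies in the host clade with identity
#'    strictly above `identity_min` and query coverage strictly above
#'    `coverage_min`; otherwise non-host. A read reaching this step must
#'    have been queried (an empty hit list is a valid "no hit" entry);
#'    an unqueried read is an error.
#'
#' @param matrix a [label_matrix()].
#' @param hits data.frame with `read_id`, `taxid`, `pident`, `qcovs`
#'   (query coverage percent), as from [read_blast_hits()].
#' @param taxonomy a [taxonomy_table()]; its host clade defines "host"
#'   hits (Chordata by default).
#' @param queried_reads reads that were submitted to the fallback
#'   search; defaults to the reads present in `hits`.
#' @param identity_min,coverage_min strict thresholds in percent
#'   (defaults 90/90).
#' @return data.frame of class `gold_labels`: `read_id`, `label`
#'   (`"host"`/`"non-host"`), `provenance` (`"consensus"`,
#'   `"category-concordance"`, `"blast-adjudicated"`).
#' @export
adjudicate <- function(matrix, hits, taxonomy,
                       queried_reads = unique(hits$read_id),
                       identity_min = 90, coverage_min = 90) {
  stopifnot(inherits(matrix, "label_matrix"))
  lab <- matrix$labels
  n_host_votes <- rowSums(lab)
  consensus <- n_host_votes == 0L | n_host_votes == ncol(lab)

  align_cols <- matrix$methods$category == "alignment-based"
  kmer_cols <- matrix$methods$category == "k-mer-based"
  cat_conc <- !consensus &
    rowSums(lab[, align_cols, drop = FALSE]) >= 1L &
    rowSums(lab[, kmer_cols, drop = FALSE]) >= 1L

  needs_blast <- !consensus & !cat_conc
  label <- ifelse(consensus, ifelse(n_host_votes > 0L, "host", "non-host"),
                  ifelse(cat_conc, "host", NA_character_))
  provenance <- ifelse(consensus, "consensus",
                       ifelse(cat_conc, "category-concordance",
                              "blast-adjudicated"))

  if (any(needs_blast)) {
    ids <- rownames(lab)[needs_blast]
    unqueried <- setdiff(ids, queried_reads)
    if (length(unqueried) > 0) {
      stop("discordant read(s) with no hit-table entry: ",
           paste(head(unqueried, 5), collapse = ", "),
           if (length(unqueried) > 5) " ..." else "")
    }
    good <- hits[hits$pident > identity_min & hits$qcovs > coverage_min, ,
                 drop = FALSE]
    if (nrow(good) > 0) {
      good <- good[in_clade(taxonomy, good$taxid), , drop = FALSE]
    }
    label[needs_blast] <- ifelse(ids %in% good$read_id, "host", "non-host")
  }
  structure(
    data.frame(read_id = rownames(lab), label = label,
               provenance = provenance, stringsAsFactors = FALSE,
               row.names = NULL),
    class = c("gold_labels", "data.frame")
  )
}

#' Consensus summary of a label matrix
#'
#' The fractions of reads with a unanimous host label, a unanimous
#' non-host label, and discordant (multi-label) calls.
#'
#' @param matrix a [label_matrix()].
#' @return named numeric vector `host_consensus`, `nonhost_consensus`,
#'   `multi_label`, summing to 1.
#' @export
summarize_consensus <- function(matrix) {
  stopifnot(inherits(matrix, "label_matrix"))
  lab <- matrix$labels
  if (nrow(lab) == 0L) stop("empty label matrix")
  votes <- rowSums(lab)
  c(host_consensus = mean(votes == ncol(lab)),
    nonhost_consensus = mean(votes == 0L),
    multi_label = mean(votes > 0L & votes < ncol(lab)))
}

#' Write gold labels to TSV
#' @param gold a `gold_labels` data.frame from [adjudicate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gold_labels <- function(gold, path) {
  write_tsv(as.data.frame(gold), path)
}
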
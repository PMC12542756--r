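## Confusion counting against the gold standard and the evaluation
## metrics: sensitivity, specificity, and the Matthews correlation
## coefficient. "Positive" means labeled host throughout.

#' Confusion counts for one method against the gold standard
#'
#' @param matrix a [label_matrix()].
#' @param gold `gold_labels` from [adjudicate()], or any data.frame with
#'   `read_id` and `label` covering the matrix's reads.
#' @param method method name (a matrix column).
#' @param sample_id sample identifier carried into the output.
#' @param exclude_reads read IDs excluded before counting (flagged-taxon
#'   reads, e.g. the host-associated virus emulation).
#' @return data.frame of class `confusion_counts` with `method_name`,
#'   `sample_id`, `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(matrix, gold, method, sample_id = "sample",
                      exclude_reads = character(0)) {
  stopifnot(inherits(matrix, "label_matrix"))
  if (!method %in% colnames(matrix$labels)) {
    stop("method ", method, " not present in the label matrix")
  }
  ids <- rownames(matrix$labels)
  missing <- setdiff(ids, gold$read_id)
  if (length(missing) > 0) {
    stop("read(s) missing from the gold standard: ",
         paste(head(missing, 5), collapse = ", "))
  }
  keep <- !(ids %in% exclude_reads)
  pred <- matrix$labels[keep, method]
  truth <- gold$label[match(ids[keep], gold$read_id)] == "host"
  out <- data.frame(
    method_name = method, sample_id = sample_id,
    TP = sum(pred & truth), FP = sum(pred & !truth),
    TN = sum(!pred & !truth), FN = sum(!pred & truth),
    stringsAsFactors = FALSE
  )
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Sensitivity, specificity and MCC from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#'
#' A zero denominator makes the corresponding metric undefined: it is
#' reported as `NA` (MCC as 0) together with an explicit flag, never as
#' a silent zero — silent zeros would corrupt the paired statistics
#' downstream. The MCC denominator is evaluated as a product of square
#' roots so that read-scale counts cannot overflow double precision.
#'
#' @param counts a `confusion_counts` row (or data.frame with `TP`,
#'   `FP`, `TN`, `FN`; extra columns are carried through).
#' @return data.frame of class `metric_record`: identifiers,
#'   `sensitivity`, `specificity`, `mcc`, and a `flags` column naming
#'   any undefined metric (empty string when all are defined).
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  out <- lapply(seq_len(nrow(counts)), function(i) {
    tp <- as.numeric(counts$TP[i]); fp <- as.numeric(counts$FP[i])
    tn <- as.numeric(counts$TN[i]); fn <- as.numeric(counts$FN[i])
    if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
    if (tp + fp + tn + fn == 0) stop("all confusion counts are zero")
    flags <- character(0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else {
      flags <- c(flags, "sensitivity_undefined"); NA_real_
    }
    spec <- if (tn + fp > 0) tn / (tn + fp) else {
      flags <- c(flags, "specificity_undefined"); NA_real_
    }
    denom_f <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    if (any(denom_f == 0)) {
      flags <- c(flags, "mcc_undefined")
      mcc <- 0
    } else {
      mcc <- (tp * tn - fp * fn) / prod(sqrt(denom_f))
    }
    data.frame(
      method_name = counts$method_name[i] %||% NA_character_,
      sample_id = counts$sample_id[i] %||% NA_character_,
      sensitivity = sens, specificity = spec, mcc = mcc,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  class(out) <- c("metric_record", "data.frame")
  out
}

#' Evaluate microbe-level calls after host removal
#'
#' True-positive microbe calls are retained reads whose gold-standard
#' host label is negative and whose classification falls within one of
#' the expected (spiked-in) taxa, lineage-aware. False-negative microbe
#' calls are retained reads with a positive gold host label whose
#' classification does not belong to the host clade — host reads that
#' escaped removal and masquerade as microbes.
#'
#' @param gold `gold_labels` data.frame.
#' @param retained_reads read IDs surviving the removal method.
#' @param classifications data.frame with `read_id`, `taxid` (and
#'   optionally `classified`; unclassified reads count in neither tally)
#'   covering the retained reads.
#' @param expected_taxa taxids of the spiked-in community.
#' @param taxonomy a [taxonomy_table()].
#' @return named integer vector `tp_microbe`, `fn_microbe`.
#' @export
microbe_call_eval <- function(gold, retained_reads, classifications,
                              expected_taxa, taxonomy) {
  if (length(expected_taxa) == 0L) stop("expected_taxa must be non-empty")
  cl <- classifications[match(retained_reads, classifications$read_id), ]
  if (anyNA(cl$read_id)) {
    stop("classifications do not cover all retained reads")
  }
  classified <- if ("classified" %in% names(cl)) cl$classified else rep(TRUE, nrow(cl))
  g <- gold$label[match(retained_reads, gold$read_id)]
  if (anyNA(g)) stop("retained read(s) missing from the gold standard")

  in_expected <- rep(FALSE, nrow(cl))
  if (any(classified)) {
    hit <- vapply(cl$taxid[classified], function(t) {
      any(vapply(expected_taxa, function(e) e %in% lineage(taxonomy, t), logical(1)))
    }, logical(1))
    in_expected[classified] <- hit
  }
  in_host_clade <- rep(FALSE, nrow(cl))
  if (any(classified)) {
    in_host_clade[classified] <- in_clade(taxonomy, cl$taxid[classified])
  }
  c(tp_microbe = sum(g == "non-host" & in_expected),
    fn_microbe = sum(g == "host" & classified & !in_host_clade))
}
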
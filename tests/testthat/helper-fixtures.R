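# Shared fixtures: tiny configurations, taxonomies and genomes built in
# code at test time.

tiny_config <- function(seed = 1L, n_reads = 500L, ...) {
  args <- list(
    master_seed = seed,
    n_reads = n_reads,
    host_contigs = c(chr1 = 60000L),
    exclusive_region_spec = data.frame(contig = "chr1",
                                       start = 40000L, end = 52000L),
    satellite_array_lengths = c(3000L, 2000L),
    satellite_positions = data.frame(contig = c("chr1", "chr1"),
                                     start = c(41000L, 47000L)),
    microbe_spec = data.frame(
      taxon_name = c("MicA", "MicB", "FlagV"),
      taxid = c(1001L, 1002L, 1999L),
      genome_length = c(15000L, 15000L, 5000L),
      n_contigs = c(1L, 2L, 1L),
      flagged = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

tiny_taxonomy <- function() {
  synthetic_taxonomy(tiny_config()$microbe_spec)
}

# Full 2^n enumeration of sign assignments: the oracle for the exact
# one-sided signed-rank branch.
brute_wilcoxon_greater <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  mean(signs %*% r >= W - 1e-9)
}

# Brute-force reimplementation of the adjudication cascade for one read,
# used as the oracle against adjudicate().
cascade_oracle <- function(labels, categories, hit_state,
                           identity_min = 90, coverage_min = 90) {
  if (all(labels) || all(!labels)) {
    return(list(label = if (all(labels)) "host" else "non-host",
                provenance = "consensus"))
  }
  if (any(labels[categories == "alignment-based"]) &&
      any(labels[categories == "k-mer-based"])) {
    return(list(label = "host", provenance = "category-concordance"))
  }
  label <- switch(hit_state,
    good_host_hit = "host",
    low_quality_hit = "non-host",
    no_hit = "non-host")
  list(label = label, provenance = "blast-adjudicated")
}

# Build a label_matrix directly from a logical matrix.
lm_from <- function(mat, categories) {
  label_matrix(mat, data.frame(
    name = colnames(mat), category = categories,
    reference_id = "test", stringsAsFactors = FALSE))
}

write_sam_fixture <- function(records, path = tempfile(fileext = ".sam")) {
  header <- "@HD\tVN:1.6\tSO:unknown"
  body <- vapply(records, function(r) {
    paste(r$qname, r$flag, r$rname %||% "*", r$pos %||% 0, 0, "*",
          "*", 0, 0, "ACGT", "FFFF", sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
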
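## End-to-end orchestration of the synthetic benchmark: simulate ->
## label -> adjudicate -> evaluate -> compare -> characterize -> scan,
## from one config, with deterministic seeding and a run manifest.

#' Synthetic taxonomy covering the simulated community
#'
#' A minimal NCBI-shaped tree: root, Bacteria, Viruses, and the host
#' clade (Chordata, 7711) with the host species beneath it; every
#' microbe in `microbe_spec` hangs under Bacteria except flagged taxa,
#' which hang under Viruses (the host-associated-virus emulation).
#'
#' @param microbe_spec data.frame as in [sim_config()].
#' @param host_taxid host species taxid (default 9606).
#' @return a [taxonomy_table()] with host clade 7711.
#' @export
synthetic_taxonomy <- function(microbe_spec = default_microbe_spec(),
                               host_taxid = 9606L) {
  base <- data.frame(
    taxid = c(1L, 2L, 10239L, 7711L, host_taxid),
    parent_taxid = c(1L, 1L, 1L, 1L, 7711L),
    rank = c("no rank", "superkingdom", "superkingdom", "phylum", "species"),
    name = c("root", "Bacteria", "Viruses", "Chordata", "Homo sapiens"),
    stringsAsFactors = FALSE
  )
  mic <- data.frame(
    taxid = microbe_spec$taxid,
    parent_taxid = ifelse(microbe_spec$flagged, 10239L, 2L),
    rank = "species",
    name = microbe_spec$taxon_name,
    stringsAsFactors = FALSE
  )
  taxonomy_table(rbind(base, mic), host_clade = 7711L)
}

#' Default benchmark configuration
#'
#' The study conditions of the synthetic benchmark as a nested list
#' (YAML-serializable): 15 mock samples, the default host/legacy genome
#' pair with satellite-bearing exclusive regions, the built-in k-mer
#' classifier run against both references, two simulated screeners, and
#' the contamination screen with the benchmark's printed thresholds
#' (90% identity, 90% coverage, 100 bp hits and segments, two segments,
#' 0.01% severity).
#'
#' @param master_seed integer master seed.
#' @return nested configuration list for [run_benchmark()].
#' @export
default_benchmark_config <- function(master_seed = 1L) {
  list(
    master_seed = as.integer(master_seed),
    n_samples = 15L,
    reads = list(n_reads = 4000L, read_length = 75L, host_fraction = 0.95,
                 substitution_error_rate = 0.001),
    classifier = list(k = 31L, min_shared = 1L),
    adjudication = list(identity_min = 90, coverage_min = 90,
                        no_hit_fraction = 0.02),
    simulated_tools = list(
      list(name = "sim_kmer_screen", category = "k-mer-based",
           sensitivity = 0.97, specificity = 0.995),
      list(name = "sim_conservative", category = "k-mer-based",
           sensitivity = 0.80, specificity = 0.9995)
    ),
    contamination = list(
      target_taxon = "Microbe_01",
      plant_length = 500L, plant_identity = 1.0,
      min_hit_length = 100L, min_identity = 90, kmer_size = 100L,
      min_matched_kmers = 2L, severe_threshold = 0.0001,
      small_contig_max = 10000L, edge_window = 1000L
    ),
    characterization = list(spectrum_k = 5L),
    residual = list(k = 25L, min_shared = 1L)
  )
}

#' Run the full synthetic benchmark
#'
#' Stages: (1) build host genome, legacy reference and microbial
#' community; (2) per sample, simulate reads with truth, label them with
#' the built-in k-mer classifier against the full and legacy references
#' plus the configured simulated screeners, adjudicate gold labels, and
#' compute confusion counts and metrics per method (flagged-taxon reads
#' excluded); (3) pairwise method comparisons per metric; (4)
#' characterize the legacy reference's false-negative reads (GC, k-mer
#' spectrum, misassigned taxa); (5) the contamination screen: exclusive
#' regions recovered from the legacy-vs-host alignment, planted
#' contamination detected by the two-k-mer rule, contamination ratios,
#' and the residual-host screen of the legacy-dehosted reads. All
#' outputs are TSV/FASTA/BED/JSON-free plain text, written under
#' `out_dir`, with a YAML manifest of seeds and file digests.
#'
#' @param config path to a YAML config file, or a nested list as from
#'   [default_benchmark_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results
#'   (`metrics`, `comparisons`, `consensus`, `characterization`,
#'   `contamination`, `residual`, `manifest`).
#' @export
run_benchmark <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  req <- c("master_seed", "n_samples", "reads", "classifier",
           "simulated_tools", "contamination")
  missing <- setdiff(req, names(config))
  if (length(missing) > 0) {
    stop("missing config keys: ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$master_seed)
  log_stage <- function(...) message(sprintf("[dehostbench] %s", sprintf(...)))

  ## genomes -----------------------------------------------------------
  base_cfg <- sim_config(
    master_seed = seed,
    n_reads = config$reads$n_reads %||% 4000L,
    read_length = config$reads$read_length %||% 75L,
    host_fraction = config$reads$host_fraction %||% 0.95,
    substitution_error_rate = config$reads$substitution_error_rate %||% 0.001
  )
  host <- build_host_genome(base_cfg)
  legacy <- derive_legacy_reference(host$assembly, base_cfg$exclusive_region_spec)
  microbes <- build_microbe_genomes(base_cfg)
  taxonomy <- synthetic_taxonomy(base_cfg$microbe_spec, base_cfg$host_taxid)
  log_stage("genomes: host %d bp, legacy %d bp, %d microbial genomes",
            sum(nchar(host$assembly)), sum(nchar(legacy$assembly)),
            length(microbes))
  write_assembly(host$assembly, file.path(out_dir, "host.fasta"))
  write_assembly(legacy$assembly, file.path(out_dir, "legacy.fasta"))
  write_bed(host$satellites, file.path(out_dir, "satellite_arrays.bed"))
  write_bed(as.data.frame(legacy$regions),
            file.path(out_dir, "exclusive_regions_truth.bed"))

  k <- config$classifier$k %||% 31L
  min_shared <- config$classifier$min_shared %||% 1L
  full_idx <- kmer_index(host$assembly, k)
  legacy_idx <- kmer_index(legacy$assembly, k)
  tool_specs <- do.call(rbind, lapply(config$simulated_tools, function(t) {
    data.frame(name = t$name, category = t$category,
               sensitivity = t$sensitivity, specificity = t$specificity,
               stringsAsFactors = FALSE)
  }))

  ## per-sample benchmark ---------------------------------------------
  n_samples <- as.integer(config$n_samples)
  all_counts <- list()
  all_metrics <- list()
  consensus <- list()
  sample1 <- NULL
  for (s in seq_len(n_samples)) {
    cfg_s <- base_cfg
    cfg_s$master_seed <- stage_seed(seed, paste0("sample", s))
    sim <- simulate_reads(host$assembly, microbes, cfg_s)
    full_lab <- kmer_classify_reads(sim$reads, full_idx, min_shared = min_shared)
    legacy_lab <- kmer_classify_reads(sim$reads, legacy_idx, min_shared = min_shared)
    simulated <- simulate_tool_labels(sim$truth, tool_specs,
                                      seed = cfg_s$master_seed)
    matrix <- assemble_label_matrix(c(
      list(
        list(method = list(name = "full_ref", category = "alignment-based",
                           reference_id = "host"), labels = full_lab),
        list(method = list(name = "legacy_ref", category = "alignment-based",
                           reference_id = "legacy"), labels = legacy_lab)
      ),
      lapply(colnames(simulated$labels), function(m) {
        list(method = simulated$methods[simulated$methods$name == m, ],
             labels = setNames(simulated$labels[, m],
                               rownames(simulated$labels)))
      })
    ))
    blast <- simulate_blast_hits(
      sim$truth,
      no_hit_fraction = config$adjudication$no_hit_fraction %||% 0.02,
      seed = cfg_s$master_seed)
    gold <- adjudicate(matrix, blast$hits, taxonomy,
                       queried_reads = blast$queried_reads,
                       identity_min = config$adjudication$identity_min %||% 90,
                       coverage_min = config$adjudication$coverage_min %||% 90)
    consensus[[s]] <- summarize_consensus(matrix)
    flagged <- sim$truth$read_id[sim$truth$flagged]
    sample_id <- sprintf("S%02d", s)
    for (m in colnames(matrix$labels)) {
      cc <- confusion(matrix, gold, m, sample_id, exclude_reads = flagged)
      all_counts[[length(all_counts) + 1L]] <- cc
      all_metrics[[length(all_metrics) + 1L]] <- compute_metrics(cc)
    }
    if (s == 1L) {
      sample1 <- list(sim = sim, matrix = matrix, gold = gold)
      write_fastq(sim$reads, file.path(out_dir, "sample01_reads.fastq"))
      write_tsv(sim$truth, file.path(out_dir, "sample01_truth.tsv"))
      write_label_matrix(matrix, file.path(out_dir, "sample01_labels.tsv"))
      write_gold_labels(gold, file.path(out_dir, "sample01_gold.tsv"))
    }
    log_stage("sample %s: %d reads, %d flagged excluded", sample_id,
              length(sim$reads), length(flagged))
  }
  counts <- do.call(rbind, all_counts)
  metrics <- cbind(counts,
                   do.call(rbind, all_metrics)[, c("sensitivity",
                                                   "specificity", "mcc",
                                                   "flags")])
  write_tsv(metrics, file.path(out_dir, "metrics.tsv"))
  consensus_df <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
                             do.call(rbind, consensus))
  write_tsv(consensus_df, file.path(out_dir, "consensus_fractions.tsv"))

  ## pairwise comparisons ---------------------------------------------
  mt <- data.frame(sample_id = metrics$sample_id, method = metrics$method_name,
                   sensitivity = metrics$sensitivity,
                   specificity = metrics$specificity, mcc = metrics$mcc)
  comparisons <- lapply(c("sensitivity", "specificity", "mcc"),
                        function(mn) compare_all(mt, mn))
  names(comparisons) <- c("sensitivity", "specificity", "mcc")
  comp_df <- do.call(rbind, lapply(comparisons, `[[`, "pairs"))
  rownames(comp_df) <- NULL
  write_tsv(comp_df, file.path(out_dir, "comparisons.tsv"))
  log_stage("comparisons: %d pairs x 3 metrics", nrow(comparisons$mcc$pairs))

  ## FN-read characterization (legacy reference, sample 1) -------------
  lab1 <- sample1$matrix$labels
  gold_host <- sample1$gold$label[match(rownames(lab1),
                                        sample1$gold$read_id)] == "host"
  fn_ids <- rownames(lab1)[gold_host & !lab1[, "legacy_ref"]]
  fn_reads <- sample1$sim$reads[fn_ids]
  characterization <- NULL
  if (length(fn_reads) > 0) {
    spec_k <- config$characterization$spectrum_k %||% 5L
    gc <- gc_content(fn_reads)
    spectrum <- kmer_spectrum(fn_reads, spec_k)
    cls <- data.frame(read_id = sample1$sim$truth$read_id,
                      taxid = sample1$sim$truth$taxid,
                      classified = TRUE, stringsAsFactors = FALSE)
    tally <- taxa_tally(cls[cls$read_id %in% fn_ids, ], taxonomy)
    spec_df <- data.frame(kmer = names(spectrum$counts),
                          count = spectrum$counts, row.names = NULL)
    write_tsv(spec_df, file.path(out_dir, "fn_kmer_spectrum.tsv"))
    write_tsv(tally, file.path(out_dir, "fn_taxa_tally.tsv"))
    characterization <- list(gc = gc, spectrum = spectrum, tally = tally,
                             n_fn = length(fn_reads))
    log_stage("FN characterization: %d legacy-reference FN reads, top %d-mer %s",
              length(fn_reads), spec_k, names(spectrum$counts)[1])
  }

  ## contamination screen ---------------------------------------------
  ccfg <- config$contamination
  paf <- legacy_alignment_paf(host$assembly, legacy$regions)
  write_paf(paf, file.path(out_dir, "legacy_vs_host.paf"))
  excl <- exclusive_regions(paf, nchar(host$assembly),
                            min_region_length = 100L)
  excl_seqs <- extract_region_sequences(host$assembly, excl)
  write_assembly(excl_seqs, file.path(out_dir, "exclusive_sequences.fasta"))
  # plant a host segment into the configured target genome
  tgt_name <- ccfg$target_taxon %||% names(microbes)[1]
  plant_len <- ccfg$plant_length %||% 500L
  src_region <- data.frame(
    contig = names(asm_chars(microbes[[tgt_name]]))[1],
    position = 2000L,
    source_contig = excl$contig[1],
    source_start = excl$start[1],
    source_end = excl$start[1] + plant_len,
    identity = ccfg$plant_identity %||% 1.0
  )
  planted <- plant_contamination(microbes[[tgt_name]], host$assembly,
                                 src_region, seed = seed)
  community <- microbes
  community[[tgt_name]] <- planted$assembly
  calls <- detect_contaminants(
    excl_seqs, community, hit_source = NULL,
    min_hit_length = ccfg$min_hit_length %||% 100L,
    min_identity = ccfg$min_identity %||% 90,
    kmer_size = ccfg$kmer_size %||% 100L,
    min_matched_kmers = ccfg$min_matched_kmers %||% 2L,
    small_contig_max = ccfg$small_contig_max %||% 10000L,
    edge_window = ccfg$edge_window %||% 1000L)
  report <- contamination_report(
    calls, assembly_lengths(community),
    severe_threshold = ccfg$severe_threshold %||% 0.0001,
    small_contig_max = ccfg$small_contig_max %||% 10000L,
    edge_window = ccfg$edge_window %||% 1000L)
  if (nrow(calls) > 0) {
    write_bed(data.frame(contig = calls$contig, start = calls$start,
                         end = calls$end, name = calls$genome),
              file.path(out_dir, "contaminant_calls.bed"))
  }
  write_tsv(report, file.path(out_dir, "contamination_report.tsv"))
  log_stage("contamination screen: %d calls, %d severe genome(s)",
            nrow(calls), sum(report$severe))

  ## residual-host screen ---------------------------------------------
  dehosted <- sample1$sim$reads[!lab1[, "legacy_ref"]]
  residual <- residual_host_screen(dehosted, excl_seqs,
                                   k = config$residual$k %||% 25L,
                                   min_shared = config$residual$min_shared %||% 1L)
  log_stage("residual-host screen: %d/%d reads (%.3f%%)",
            residual$residual_count, length(dehosted),
            100 * residual$residual_fraction)

  ## manifest ----------------------------------------------------------
  data_files <- sort(list.files(out_dir, full.names = FALSE))
  data_files <- setdiff(data_files, "manifest.yaml")
  digests <- tools::md5sum(file.path(out_dir, data_files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dehostbench")),
    master_seed = seed,
    n_samples = n_samples,
    files = as.list(setNames(unname(digests), data_files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(
    host = host, legacy = legacy, microbes = microbes, taxonomy = taxonomy,
    metrics = metrics, comparisons = comparisons, consensus = consensus_df,
    characterization = characterization,
    contamination = list(exclusive = excl, calls = calls, report = report,
                         truth_calls = planted$calls),
    residual = list(residual_count = residual$residual_count,
                    residual_fraction = residual$residual_fraction,
                    n_dehosted = length(dehosted)),
    sample1 = sample1,
    manifest = manifest
  ))
}
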
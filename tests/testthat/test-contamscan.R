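test_that("exclusive regions are the complement of PAF coverage", {
  cfg <- tiny_config()
  host <- build_host_genome(cfg)
  legacy <- derive_legacy_reference(host$assembly, cfg$exclusive_region_spec)
  lens <- nchar(host$assembly)
  # self-alignment end to end: empty set
  self_paf <- legacy_alignment_paf(host$assembly, exclusive_region_set(NULL))
  er0 <- exclusive_regions(self_paf, lens)
  expect_equal(nrow(er0), 0L)
  expect_equal(attr(er0, "total_length"), 0L)
  # no alignments at all: the whole genome is exclusive
  empty_paf <- self_paf[0, ]
  er_all <- exclusive_regions(empty_paf, lens)
  expect_equal(attr(er_all, "total_length"), sum(lens))
  # legacy-vs-host alignment recovers exactly the configured regions
  paf <- legacy_alignment_paf(host$assembly, legacy$regions)
  er <- exclusive_regions(paf, lens)
  expect_equal(as.data.frame(er), as.data.frame(legacy$regions))
  # coverage + exclusive = genome length at min_region_length = 1
  er1 <- exclusive_regions(paf, lens, min_region_length = 1L)
  covered <- sum(paf$tend - paf$tstart)
  expect_equal(attr(er1, "total_length") + covered, sum(lens))
  # short gaps are dropped by the length filter
  er_big <- exclusive_regions(paf, lens, min_region_length = 50000L)
  expect_equal(nrow(er_big), 0L)
  expect_error(exclusive_regions(data.frame(self_paf[1, ], check.names = FALSE)
                                 |> transform(tname = "ghost"), lens),
               "ghost")
})

test_that("region sequence extraction round-trips coordinates", {
  asm <- c(c1 = paste0("GGAAT", strrep("C", 95)))
  seqs <- extract_region_sequences(asm, data.frame(contig = "c1",
                                                   start = 0L, end = 5L))
  expect_equal(unname(seqs), "GGAAT")
  expect_equal(names(seqs), "c1:0-5")
  expect_equal(length(extract_region_sequences(asm, data.frame(
    contig = character(0), start = integer(0), end = integer(0)))), 0L)
  # round trip: extracted sequence occurs at the stated coordinates
  cfg <- tiny_config()
  host <- build_host_genome(cfg)
  regs <- data.frame(contig = "chr1", start = c(100L, 40000L),
                     end = c(700L, 41000L))
  ex <- extract_region_sequences(host$assembly, regs)
  for (i in seq_len(nrow(regs))) {
    expect_identical(unname(ex[i]),
                     substr(host$assembly[["chr1"]], regs$start[i] + 1L,
                            regs$end[i]))
  }
  expect_error(extract_region_sequences(asm, data.frame(
    contig = "c1", start = 0L, end = 500L)), "bounds")
})

test_that("the two-k-mer rule governs contaminant detection", {
  cfg <- tiny_config(seed = 31L)
  host <- build_host_genome(cfg)
  mic <- build_microbe_genomes(cfg)
  excl <- exclusive_region_set(cfg$exclusive_region_spec)
  excl_seqs <- extract_region_sequences(host$assembly, excl)
  plant_and_scan <- function(len, identity, position = 4000L) {
    pl <- data.frame(contig = "MicA_ctg1", position = position,
                     source_contig = "chr1",
                     source_start = excl$start[1],
                     source_end = excl$start[1] + len,
                     identity = identity)
    planted <- plant_contamination(mic$MicA, host$assembly, pl, seed = 8L)
    comm <- list(MicA = planted$assembly, MicB = mic$MicB)
    detect_contaminants(excl_seqs, comm)
  }
  # 500 bp at identity 1.0: one call, 5 matched segments, clean genome clean
  calls <- plant_and_scan(500L, 1.0)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$matched_kmer_count, 5L)
  expect_equal(calls$genome, "MicA")
  expect_equal(c(calls$start, calls$end), c(4000L, 4500L))
  expect_equal(calls$percent_identity, 100)
  # 150 bp plant: only one full segment -> excluded by the two-k-mer rule
  expect_equal(nrow(plant_and_scan(150L, 1.0)), 0L)
  # 85% identity plant: excluded by the identity rule
  expect_equal(nrow(plant_and_scan(500L, 0.85)), 0L)
  # 95% identity, 500 bp: detected
  calls95 <- plant_and_scan(500L, 0.95)
  expect_equal(nrow(calls95), 1L)
  expect_gte(calls95$matched_kmer_count, 2L)
  # edge placement is flagged
  calls_edge <- plant_and_scan(500L, 1.0, position = 0L)
  expect_true(calls_edge$edge_flag)
  expect_error(detect_contaminants(excl_seqs, mic, min_hit_length = 200L),
               "inconsistent")
})

test_that("minus-strand contamination is detected", {
  cfg <- tiny_config(seed = 33L)
  host <- build_host_genome(cfg)
  mic <- build_microbe_genomes(cfg)
  excl <- exclusive_region_set(cfg$exclusive_region_spec)
  excl_seqs <- extract_region_sequences(host$assembly, excl)
  seg <- revcomp(substr(host$assembly[["chr1"]], excl$start[1] + 1L,
                        excl$start[1] + 400L))
  tgt <- asm_chars(mic$MicA)
  substr(tgt[["MicA_ctg1"]], 5001L, 5400L) <- seg
  calls <- detect_contaminants(excl_seqs, list(MicA = tgt))
  expect_equal(nrow(calls), 1L)
  expect_equal(c(calls$start, calls$end), c(5000L, 5400L))
  expect_equal(calls$matched_kmer_count, 4L)
})

test_that("contamination ratios and severity follow the 0.01% rule", {
  lens <- data.frame(genome = c("gA", "gB"),
                     contig = c("gA_c1", "gB_c1"),
                     length = c(1000000L, 10000000L))
  calls <- data.frame(
    genome = c("gA", "gB"), contig = c("gA_c1", "gB_c1"),
    start = c(600000L, 1000L), end = c(600300L, 1500L),
    source_id = "x", source_start = 0L, source_end = 300L,
    percent_identity = 100, matched_kmer_count = 3L,
    edge_flag = FALSE, small_contig_flag = FALSE)
  rep <- contamination_report(calls, lens)
  # 300 bp / 1 Mb = 0.03% > 0.01% -> severe
  expect_equal(rep$contamination_ratio[rep$genome == "gA"], 3e-4)
  expect_true(rep$severe[rep$genome == "gA"])
  # 500 bp / 10 Mb = 0.005% -> not severe
  expect_equal(rep$contamination_ratio[rep$genome == "gB"], 5e-8 * 1000)
  expect_false(rep$severe[rep$genome == "gB"])
  # calls within the edge window or on small contigs count as localized
  loc <- data.frame(
    genome = "gA", contig = "gA_c1", start = c(0L, 500000L),
    end = c(500L, 500100L), source_id = "x", source_start = 0L,
    source_end = 100L, percent_identity = 100, matched_kmer_count = 2L,
    edge_flag = c(TRUE, FALSE), small_contig_flag = FALSE)
  rep2 <- contamination_report(loc, lens["1", ])
  expect_equal(rep2$edge_or_small_fraction[1], 500 / 600)
  # overlapping calls are merged before length accounting
  ov <- data.frame(
    genome = "gA", contig = "gA_c1", start = c(1000L, 1200L),
    end = c(1500L, 1700L), source_id = "x", source_start = 0L,
    source_end = 100L, percent_identity = 100, matched_kmer_count = 2L,
    edge_flag = FALSE, small_contig_flag = FALSE)
  rep3 <- contamination_report(ov, lens["1", ])
  expect_equal(rep3$contaminant_bp[1], 700L)
  expect_equal(rep3$n_calls[1], 1L)
  expect_error(contamination_report(calls, lens[1, ]), "absent")
  expect_error(contamination_report(calls[0, ],
                                    data.frame(genome = "g", contig = "c",
                                               length = 0L)), "zero")
})

test_that("the residual-host screen flags exclusive-origin reads only", {
  cfg <- tiny_config(n_reads = 1500L)
  host <- build_host_genome(cfg)
  legacy <- derive_legacy_reference(host$assembly, cfg$exclusive_region_spec)
  mic <- build_microbe_genomes(cfg)
  sim <- simulate_reads(host$assembly, mic, cfg)
  legacy_lab <- kmer_classify_reads(sim$reads, legacy$assembly, k = 31)
  dehosted <- sim$reads[!legacy_lab]
  excl_seqs <- extract_region_sequences(
    host$assembly, exclusive_region_set(cfg$exclusive_region_spec))
  res <- residual_host_screen(dehosted, excl_seqs)
  truth_d <- sim$truth[match(names(dehosted), sim$truth$read_id), ]
  n_exclusive_host <- sum(truth_d$from_exclusive)
  # flagged count tracks the exclusive-origin host reads (reads lost to
  # simulated errors or boundary effects allow a small deficit)
  expect_gt(res$residual_count, 0.9 * n_exclusive_host)
  expect_lte(res$residual_count, n_exclusive_host)
  # microbial dehosted reads are never flagged
  expect_equal(sum(res$flags[truth_d$origin == "microbe"]), 0L)
  # screening against the legacy genome's own sequence finds nothing
  legacy_self <- residual_host_screen(
    dehosted[truth_d$origin == "microbe"][1:50],
    setNames(legacy$assembly, names(legacy$assembly)))
  expect_equal(legacy_self$residual_count, 0L)
  expect_error(residual_host_screen(dehosted, character(0)), "empty")
})
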
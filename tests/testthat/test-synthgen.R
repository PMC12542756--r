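test_that("satellite arrays are written verbatim at recorded coordinates", {
  cfg <- tiny_config()
  host <- build_host_genome(cfg)
  sat <- host$satellites
  expect_equal(nrow(sat), 2L)
  arr <- substr(host$assembly[[sat$contig[1]]], sat$start[1] + 1L, sat$end[1])
  expect_equal(arr, strrep("GGAAT", 600))
  # a 500 bp array is the unit repeated 100 times
  cfg2 <- tiny_config(satellite_array_lengths = 500L,
                      satellite_positions = data.frame(contig = "chr1",
                                                       start = 41000L))
  h2 <- build_host_genome(cfg2)
  expect_equal(substr(h2$assembly[["chr1"]], 41001L, 41500L),
               strrep("GGAAT", 100))
})

test_that("generation is byte-deterministic in the seed", {
  a <- build_host_genome(tiny_config(seed = 7))
  b <- build_host_genome(tiny_config(seed = 7))
  expect_identical(a, b)
  c <- build_host_genome(tiny_config(seed = 8))
  expect_false(identical(a$assembly, c$assembly))
  # array coordinates stay as configured across seeds
  expect_identical(a$satellites, c$satellites)
  # FASTA round trip is byte-identical
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_assembly(a$assembly, f1); write_assembly(b$assembly, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("oversized satellite arrays are rejected with a coordinate error", {
  cfg <- tiny_config(satellite_array_lengths = 70000L,
                     satellite_positions = data.frame(contig = "chr1",
                                                      start = 0L))
  expect_error(build_host_genome(cfg), "bounds")
})

test_that("legacy derivation splices out exactly the exclusive regions", {
  cfg <- sim_config(host_contigs = c(c1 = 200000L),
                    exclusive_region_spec = NULL,
                    satellite_positions = data.frame(contig = "c1",
                                                     start = c(1000L, 8000L)))
  host <- build_host_genome(cfg)
  # empty region list: legacy identical to host
  leg0 <- derive_legacy_reference(host$assembly, NULL)
  expect_identical(leg0$assembly, host$assembly)
  expect_equal(attr(leg0$regions, "total_length"), 0L)
  # one region [50000, 60000) on a 200 kb contig -> 190 kb
  leg1 <- derive_legacy_reference(
    host$assembly, data.frame(contig = "c1", start = 50000L, end = 60000L))
  expect_equal(nchar(leg1$assembly[["c1"]]), 190000L)
  expect_equal(leg1$assembly[["c1"]],
               paste0(substr(host$assembly[["c1"]], 1, 50000),
                      substr(host$assembly[["c1"]], 60001, 200000)))
  # regions covering a whole contig remove it
  leg2 <- derive_legacy_reference(
    host$assembly, data.frame(contig = "c1", start = 0L, end = 200000L))
  expect_false("c1" %in% names(leg2$assembly))
  # overlapping regions are merged with a warning
  expect_warning(
    exclusive_region_set(data.frame(contig = "c1",
                                    start = c(10L, 50L), end = c(100L, 200L))),
    "merged")
})

test_that("planted contamination realizes the requested identity", {
  cfg <- tiny_config()
  host <- build_host_genome(cfg)
  mic <- build_microbe_genomes(cfg)
  plant <- function(identity, position = 3000L) {
    plant_contamination(
      mic$MicA, host$assembly,
      data.frame(contig = "MicA_ctg1", position = position,
                 source_contig = "chr1", source_start = 40000L,
                 source_end = 40500L, identity = identity),
      seed = 5L)
  }
  p1 <- plant(1.0)
  seg <- substr(p1$assembly[["MicA_ctg1"]], 3001L, 3500L)
  expect_identical(seg, substr(host$assembly[["chr1"]], 40001L, 40500L))
  expect_false(p1$calls$edge_placed)
  p2 <- plant(0.92)
  expect_gte(p2$calls$realized_identity, 0.90)
  expect_lte(p2$calls$realized_identity, 0.94)
  seg2 <- substr(p2$assembly[["MicA_ctg1"]], 3001L, 3500L)
  src <- substr(host$assembly[["chr1"]], 40001L, 40500L)
  mism <- sum(strsplit(seg2, "")[[1]] != strsplit(src, "")[[1]])
  expect_equal(1 - mism / 500, p2$calls$realized_identity)
  # contig-edge placement is flagged
  p3 <- plant(1.0, position = 0L)
  expect_true(p3$calls$edge_placed)
  # plants that do not fit error out
  expect_error(plant(1.0, position = 14900L), "fit")
})

test_that("simulated reads follow the configured mixture and error model", {
  cfg <- tiny_config(n_reads = 10000L)
  host <- build_host_genome(cfg)
  mic <- build_microbe_genomes(cfg)
  sim <- simulate_reads(host$assembly, mic, cfg)
  expect_equal(length(sim$reads), 10000L)
  expect_equal(nrow(sim$truth), 10000L)
  # empirical host fraction within 3 binomial SDs of 0.95
  p_hat <- mean(sim$truth$origin == "host")
  tol <- 3 * sqrt(0.95 * 0.05 / 10000)
  expect_lt(abs(p_hat - 0.95), tol)
  # degenerate mixture
  cfg1 <- tiny_config(n_reads = 200L, host_fraction = 1.0)
  sim1 <- simulate_reads(host$assembly, mic, cfg1)
  expect_true(all(sim1$truth$origin == "host"))
  # error rate 0: every read is an exact (strand-aware) substring of its source
  cfg0 <- tiny_config(n_reads = 300L, substitution_error_rate = 0)
  sim0 <- simulate_reads(host$assembly, mic, cfg0)
  seqs <- c(host$assembly, unlist(unname(mic)))
  for (i in seq_len(nrow(sim0$truth))) {
    tr <- sim0$truth[i, ]
    src <- substr(seqs[[tr$source_contig]], tr$source_start + 1L,
                  tr$source_start + cfg0$read_length)
    expect_identical(unname(sim0$reads[[tr$read_id]]),
                     if (tr$strand == "+") src else revcomp(src))
  }
  # from_exclusive marks exactly the reads overlapping the exclusive region
  excl <- cfg$exclusive_region_spec
  overlaps <- sim$truth$origin == "host" &
    sim$truth$source_start < excl$end &
    sim$truth$source_start + cfg$read_length > excl$start
  expect_identical(sim$truth$from_exclusive, overlaps)
  expect_error(simulate_reads(host$assembly, mic, tiny_config(n_reads = 0L)),
               "positive")
})

test_that("simulated tool labels hit their configured operating points", {
  cfg <- tiny_config(n_reads = 10000L)
  host <- build_host_genome(cfg)
  mic <- build_microbe_genomes(cfg)
  sim <- simulate_reads(host$assembly, mic, cfg)
  perfect <- data.frame(name = "p", category = "alignment-based",
                        sensitivity = 1, specificity = 1)
  lm <- simulate_tool_labels(sim$truth, perfect, seed = 3)
  expect_identical(unname(lm$labels[, "p"]), sim$truth$origin == "host")
  # sensitivity 0.9: host-label count within 3 binomial SDs
  spec <- data.frame(name = "t", category = "k-mer-based",
                     sensitivity = 0.9, specificity = 1)
  lm2 <- simulate_tool_labels(sim$truth, spec, seed = 4)
  n_host <- sum(sim$truth$origin == "host")
  hits <- sum(lm2$labels[sim$truth$origin == "host", "t"])
  expect_lt(abs(hits - 0.9 * n_host), 3 * sqrt(n_host * 0.9 * 0.1))
  expect_equal(sum(lm2$labels[sim$truth$origin != "host", "t"]), 0)
  # degenerate classifier labels nothing host
  none <- simulate_tool_labels(sim$truth,
    data.frame(name = "n", category = "k-mer-based",
               sensitivity = 0, specificity = 1), seed = 5)
  expect_equal(sum(none$labels), 0)
  expect_error(
    simulate_tool_labels(sim$truth,
      data.frame(name = "x", category = "other",
                 sensitivity = 1, specificity = 1)),
    "category")
})
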
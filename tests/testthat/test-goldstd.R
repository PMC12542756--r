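tax <- tiny_taxonomy()

# Hit tables realizing the three fallback states for one read
hit_for_state <- function(read_id, state) {
  switch(state,
    good_host_hit = data.frame(read_id = read_id, taxid = 9606L,
                               pident = 95, qcovs = 92),
    low_quality_hit = data.frame(read_id = read_id, taxid = 9606L,
                                 pident = 89, qcovs = 95),
    no_hit = data.frame(read_id = character(0), taxid = integer(0),
                        pident = numeric(0), qcovs = numeric(0))
  )
}

test_that("adjudication matches the exhaustive cascade oracle", {
  categories <- c("alignment-based", "alignment-based",
                  "k-mer-based", "k-mer-based")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  states <- c("good_host_hit", "low_quality_hit", "no_hit")
  for (i in seq_len(nrow(combos))) {
    labels <- as.logical(combos[i, ])
    for (state in states) {
      mat <- matrix(labels, nrow = 1,
                    dimnames = list("r1", paste0("m", 1:4)))
      lm <- lm_from(mat, categories)
      gold <- adjudicate(lm, hit_for_state("r1", state), tax,
                         queried_reads = "r1")
      want <- cascade_oracle(labels, categories, state)
      expect_equal(gold$label, want$label,
                   info = sprintf("labels=%s state=%s",
                                  paste(labels, collapse = ","), state))
      expect_equal(gold$provenance, want$provenance)
    }
  }
})

test_that("adjudication thresholds are strict and clade-aware", {
  categories <- c("alignment-based", "k-mer-based")
  mat <- matrix(c(TRUE, FALSE), nrow = 1,
                dimnames = list("r1", c("aln", "kmr")))
  lm <- lm_from(mat, categories)
  call_with <- function(taxid, pident, qcovs) {
    adjudicate(lm, data.frame(read_id = "r1", taxid = taxid,
                              pident = pident, qcovs = qcovs),
               tax, queried_reads = "r1")$label
  }
  expect_equal(call_with(9606L, 95, 92), "host")
  # exactly at the threshold is rejected (strict > 90)
  expect_equal(call_with(9606L, 90, 95), "non-host")
  expect_equal(call_with(9606L, 95, 90), "non-host")
  # high-quality hit to bacteria stays non-host
  expect_equal(call_with(1001L, 99, 99), "non-host")
  # discordant read never queried is an error
  expect_error(adjudicate(lm, hit_for_state("r1", "no_hit"), tax,
                          queried_reads = character(0)),
               "no hit-table entry")
})

test_that("single host votes per category trigger category concordance", {
  # one alignment-based and one k-mer-based host vote among 13 methods
  categories <- c(rep("alignment-based", 7), rep("k-mer-based", 6))
  labels <- rep(FALSE, 13)
  labels[c(1, 8)] <- TRUE
  mat <- matrix(labels, nrow = 1, dimnames = list("r1", paste0("m", 1:13)))
  gold <- adjudicate(lm_from(mat, categories), hit_for_state("r1", "no_hit"),
                     tax, queried_reads = "r1")
  expect_equal(gold$label, "host")
  expect_equal(gold$provenance, "category-concordance")
  # all 13 host -> consensus host
  mat2 <- matrix(rep(TRUE, 13), nrow = 1,
                 dimnames = list("r1", paste0("m", 1:13)))
  gold2 <- adjudicate(lm_from(mat2, categories), hit_for_state("r1", "no_hit"),
                      tax, queried_reads = "r1")
  expect_equal(gold2$provenance, "consensus")
  expect_equal(gold2$label, "host")
})

test_that("flipping a vote towards host never demotes a gold host label", {
  categories <- c("alignment-based", "alignment-based",
                  "k-mer-based", "k-mer-based")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  for (state in c("good_host_hit", "no_hit")) {
    for (i in seq_len(nrow(combos))) {
      labels <- as.logical(combos[i, ])
      mat <- matrix(labels, nrow = 1, dimnames = list("r1", paste0("m", 1:4)))
      before <- adjudicate(lm_from(mat, categories),
                           hit_for_state("r1", state), tax,
                           queried_reads = "r1")$label
      for (j in which(!labels)) {
        flipped <- labels
        flipped[j] <- TRUE
        mat2 <- matrix(flipped, nrow = 1,
                       dimnames = list("r1", paste0("m", 1:4)))
        after <- adjudicate(lm_from(mat2, categories),
                            hit_for_state("r1", state), tax,
                            queried_reads = "r1")$label
        if (before == "host") expect_equal(after, "host")
      }
    }
  }
})

test_that("perfect simulated tools reproduce the synthetic truth", {
  cfg <- tiny_config(n_reads = 3000L)
  host <- build_host_genome(cfg)
  mic <- build_microbe_genomes(cfg)
  sim <- simulate_reads(host$assembly, mic, cfg)
  tools <- data.frame(
    name = c("aln1", "aln2", "km1", "km2"),
    category = c("alignment-based", "alignment-based",
                 "k-mer-based", "k-mer-based"),
    sensitivity = 1, specificity = 1)
  lm <- simulate_tool_labels(sim$truth, tools, seed = 2)
  gold <- adjudicate(lm, hit_for_state("none", "no_hit"), tax,
                     queried_reads = character(0))
  expect_identical(gold$label == "host", sim$truth$origin == "host")
  expect_true(all(gold$provenance == "consensus"))
})

test_that("consensus fractions sum to one and match hand counts", {
  # 10 reads: 4 host-consensus, 3 non-host-consensus, 3 mixed
  mat <- rbind(
    matrix(TRUE, 4, 3), matrix(FALSE, 3, 3),
    matrix(c(TRUE, FALSE, TRUE), 3, 3, byrow = TRUE)
  )
  dimnames(mat) <- list(sprintf("r%02d", 1:10), c("a", "b", "c"))
  fr <- summarize_consensus(lm_from(mat, rep("alignment-based", 3)))
  expect_equal(unname(fr), c(0.4, 0.3, 0.3))
  expect_equal(sum(fr), 1)
  # single-method matrix has no possible discordance
  m1 <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(c("r1", "r2"), "solo"))
  fr1 <- summarize_consensus(lm_from(m1, "alignment-based"))
  expect_equal(unname(fr1["multi_label"]), 0)
  empty_lm <- structure(
    list(labels = matrix(logical(0), 0, 1, dimnames = list(NULL, "a")),
         methods = data.frame(name = "a", category = "alignment-based",
                              reference_id = "t")),
    class = "label_matrix")
  expect_error(summarize_consensus(empty_lm), "empty")
})
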
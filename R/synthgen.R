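## Synthetic benchmark inputs with known truth: a host genome carrying
## satellite repeat arrays, a "legacy" reference equal to the host minus
## designated exclusive regions (emulating the relationship between an
## older human assembly and a complete telomere-to-telomere one), microbial
## genomes with optionally planted host segments, single-end reads with
## ground-truth origin labels, and simulated per-method label matrices.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic benchmark. Coordinates are 0-based
#' half-open throughout. The defaults describe one mock sample of the
#' benchmark's study conditions: a host genome whose exclusive region
#' carries `(GGAAT)n` satellite arrays (the repeat unit of the human
#' satellite II/III families), a host read fraction of 0.95 (mock and
#' clinical metagenomes are typically >90% host), 75 bp single-end reads
#' (Illumina-like; use 50 for MGI-like), and ten spiked-in microbes plus
#' one flagged virus standing in for the host-associated virus excluded
#' from benchmarking.
#'
#' @param master_seed integer; fully determines all generated output.
#' @param n_reads number of single-end reads to simulate.
#' @param read_length read length in bp (75 Illumina-like, 50 MGI-like).
#' @param host_fraction expected fraction of reads of host origin, in
#'   `[0, 1]`.
#' @param substitution_error_rate per-base substitution probability.
#' @param satellite_unit repeat unit of the satellite arrays.
#' @param satellite_array_lengths integer vector of array lengths (bp).
#' @param satellite_positions data.frame (`contig`, `start`) with one row
#'   per array, or `NULL` to place arrays uniformly at random inside the
#'   exclusive regions (inside the contigs when no exclusive regions are
#'   configured).
#' @param host_contigs named integer vector of host contig lengths.
#' @param exclusive_region_spec data.frame (`contig`, `start`, `end`):
#'   regions present in the host genome but absent from the legacy
#'   reference.
#' @param microbe_spec data.frame (`taxon_name`, `taxid`, `genome_length`,
#'   `n_contigs`, `flagged`): the spiked-in community. `flagged` taxa are
#'   excluded from benchmarking downstream (host-associated virus
#'   emulation).
#' @param contamination_plants data.frame (`target_taxon`, `contig`,
#'   `position`, `source_contig`, `source_start`, `source_end`,
#'   `identity`) of host segments to copy into microbial assemblies, or
#'   `NULL`.
#' @param host_taxid taxid reported for host-origin reads.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(master_seed = 1L,
                       n_reads = 10000L,
                       read_length = 75L,
                       host_fraction = 0.95,
                       substitution_error_rate = 0.001,
                       satellite_unit = "GGAAT",
                       satellite_array_lengths = c(8000L, 8000L),
                       satellite_positions = data.frame(
                         contig = c("chr1", "chr1"),
                         start = c(152000L, 166000L)
                       ),
                       host_contigs = c(chr1 = 200000L),
                       exclusive_region_spec = data.frame(
                         contig = "chr1", start = 150000L, end = 180000L
                       ),
                       microbe_spec = default_microbe_spec(),
                       contamination_plants = NULL,
                       host_taxid = 9606L) {
  stopifnot(
    is.numeric(master_seed), length(master_seed) == 1L,
    host_fraction >= 0, host_fraction <= 1,
    substitution_error_rate >= 0, substitution_error_rate < 1,
    read_length >= 1, nchar(satellite_unit) >= 1
  )
  if (is.null(names(host_contigs))) stop("host_contigs must be named")
  if (!is.null(exclusive_region_spec) && nrow(exclusive_region_spec) > 0) {
    bad <- !(exclusive_region_spec$contig %in% names(host_contigs)) |
      exclusive_region_spec$start < 0 |
      exclusive_region_spec$end > host_contigs[exclusive_region_spec$contig] |
      exclusive_region_spec$start >= exclusive_region_spec$end
    if (any(bad)) stop("exclusive regions out of contig bounds or empty")
  }
  structure(
    list(
      master_seed = as.integer(master_seed),
      n_reads = as.integer(n_reads),
      read_length = as.integer(read_length),
      host_fraction = host_fraction,
      substitution_error_rate = substitution_error_rate,
      satellite_unit = toupper(satellite_unit),
      satellite_array_lengths = as.integer(satellite_array_lengths),
      satellite_positions = satellite_positions,
      host_contigs = setNames(as.integer(host_contigs), names(host_contigs)),
      exclusive_region_spec = exclusive_region_spec,
      microbe_spec = microbe_spec,
      contamination_plants = contamination_plants,
      host_taxid = as.integer(host_taxid)
    ),
    class = "sim_config"
  )
}

#' Default spiked-in microbial community
#'
#' Ten microbes (even mixture; the benchmark's dilution series is a free
#' parameter here) plus one flagged small virus emulating the
#' host-associated virus removed before benchmarking.
#'
#' @return data.frame with `taxon_name`, `taxid`, `genome_length`,
#'   `n_contigs`, `flagged`.
#' @export
default_microbe_spec <- function() {
  data.frame(
    taxon_name = c(sprintf("Microbe_%02d", 1:10), "FlagVirus"),
    taxid = c(1001:1010, 1999L),
    genome_length = c(rep(40000L, 10), 7000L),
    n_contigs = c(rep(2L, 10), 1L),
    flagged = c(rep(FALSE, 10), TRUE),
    stringsAsFactors = FALSE
  )
}

satellite_sequence <- function(unit, length) {
  substr(strrep(unit, ceiling(length / nchar(unit))), 1L, length)
}

#' Build the host genome
#'
#' Contigs are i.i.d. uniform A/C/G/T background with satellite arrays of
#' the configured unit written in at recorded coordinates; the arrays are
#' the only low-complexity structure, so reads are unmappable to the
#' legacy reference only via the exclusive regions.
#'
#' @param config a [sim_config()].
#' @return list with `assembly` (named character vector) and `satellites`
#'   (data.frame `contig`, `start`, `end`, 0-based half-open).
#' @export
build_host_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$satellite_array_lengths) == 0L) {
    stop("satellite_array_lengths must be non-empty")
  }
  with_stage_seed(config$master_seed, "host_genome", {
    asm <- vapply(config$host_contigs, random_dna, character(1))
    pos <- config$satellite_positions
    lens <- config$satellite_array_lengths
    if (is.null(pos)) {
      regions <- config$exclusive_region_spec
      if (is.null(regions) || nrow(regions) == 0L) {
        regions <- data.frame(contig = names(config$host_contigs),
                              start = 0L, end = unname(config$host_contigs))
      }
      pick <- sample.int(nrow(regions), length(lens), replace = TRUE)
      start <- integer(length(lens))
      for (i in seq_along(lens)) {
        r <- regions[pick[i], ]
        room <- (r$end - r$start) - lens[i]
        if (room < 0) stop("satellite array ", i, " longer than its region")
        start[i] <- r$start + sample.int(room + 1L, 1L) - 1L
      }
      pos <- data.frame(contig = regions$contig[pick], start = start)
    }
    if (nrow(pos) != length(lens)) {
      stop("satellite_positions must have one row per configured array length")
    }
    sat <- data.frame(contig = as.character(pos$contig),
                      start = as.integer(pos$start),
                      end = as.integer(pos$start) + lens)
    for (i in seq_len(nrow(sat))) {
      ctg <- sat$contig[i]
      if (!ctg %in% names(asm)) stop("satellite array contig ", ctg, " unknown")
      if (sat$start[i] < 0 || sat$end[i] > nchar(asm[[ctg]])) {
        stop("satellite array [", sat$start[i], ",", sat$end[i],
             ") exceeds contig ", ctg, " bounds")
      }
      substr(asm[[ctg]], sat$start[i] + 1L, sat$end[i]) <-
        satellite_sequence(config$satellite_unit, lens[i])
    }
    list(assembly = asm, satellites = sat)
  })
}

#' Construct an exclusive-region set
#'
#' @param regions data.frame with `contig`, `start`, `end` (0-based
#'   half-open). Intervals are sorted; overlapping or bookended intervals
#'   are merged with a warning.
#' @return data.frame of class `exclusive_region_set` with a
#'   `total_length` attribute.
#' @export
exclusive_region_set <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) {
    out <- data.frame(contig = character(0), start = integer(0), end = integer(0))
  } else {
    stopifnot(all(c("contig", "start", "end") %in% names(regions)))
    if (any(regions$start >= regions$end)) stop("empty or inverted region")
    parts <- split(regions, regions$contig)
    merged <- lapply(names(parts), function(ctg) {
      p <- parts[[ctg]][order(parts[[ctg]]$start), ]
      ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)
      red <- IRanges::reduce(ir)
      if (length(red) < length(ir)) {
        warning("overlapping exclusive regions on ", ctg, " merged")
      }
      data.frame(contig = ctg, start = IRanges::start(red) - 1L,
                 end = IRanges::end(red))
    })
    out <- do.call(rbind, merged)
    out <- out[order(out$contig, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "total_length") <- sum(out$end - out$start)
  class(out) <- c("exclusive_region_set", "data.frame")
  out
}

#' Derive the legacy reference by deleting exclusive regions
#'
#' Emulates the relationship between a legacy human assembly and a
#' complete one: the legacy genome is the host genome with the listed
#' regions spliced out. Contigs fully covered by regions are dropped.
#'
#' @param host host assembly (named character or DNAStringSet).
#' @param exclusive_region_spec data.frame (`contig`, `start`, `end`).
#' @return list with `assembly` (legacy, named character) and `regions`
#'   (the ground-truth [exclusive_region_set()] in host coordinates).
#' @export
derive_legacy_reference <- function(host, exclusive_region_spec) {
  asm <- asm_chars(host)
  regs <- exclusive_region_set(exclusive_region_spec)
  if (nrow(regs) > 0) {
    bad <- !(regs$contig %in% names(asm)) | regs$end > nchar(asm[regs$contig])
    if (any(bad)) stop("exclusive region out of assembly bounds")
  }
  legacy <- asm
  for (ctg in unique(regs$contig)) {
    r <- regs[regs$contig == ctg, ]
    keep <- IRanges::setdiff(
      IRanges::IRanges(1L, nchar(asm[[ctg]])),
      IRanges::IRanges(r$start + 1L, r$end)
    )
    if (length(keep) == 0L) {
      legacy <- legacy[names(legacy) != ctg]
    } else {
      legacy[[ctg]] <- paste(
        stringi::stri_sub(asm[[ctg]], IRanges::start(keep), IRanges::end(keep)),
        collapse = ""
      )
    }
  }
  list(assembly = legacy, regions = regs)
}

#' Build microbial genomes from a community specification
#'
#' Each genome is i.i.d. random background split into `n_contigs` equal
#' contigs named `<taxon>_ctg<i>`.
#'
#' @param config a [sim_config()].
#' @return named list (by taxon name) of assemblies.
#' @export
build_microbe_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$microbe_spec
  with_stage_seed(config$master_seed, "microbe_genomes", {
    out <- vector("list", nrow(spec))
    names(out) <- spec$taxon_name
    for (i in seq_len(nrow(spec))) {
      n <- spec$n_contigs[i]
      len <- spec$genome_length[i]
      sizes <- rep(len %/% n, n)
      sizes[n] <- sizes[n] + len %% n
      ctgs <- vapply(sizes, random_dna, character(1))
      names(ctgs) <- sprintf("%s_ctg%d", spec$taxon_name[i], seq_len(n))
      out[[i]] <- ctgs
    }
    out
  })
}

#' Plant host segments into a target assembly
#'
#' Copies each source region into the target contig at the requested
#' position (overwriting in place, so contig coordinates are unchanged),
#' applying `round((1 - identity) * length)` substitutions at random
#' positions to realize the requested identity. The returned truth calls
#' record target interval, source interval, realized identity, and
#' whether the plant touches a contig end.
#'
#' @param target target assembly (named character or DNAStringSet).
#' @param source source assembly.
#' @param plants data.frame with `contig`, `position`, `source_contig`,
#'   `source_start`, `source_end`, `identity`.
#' @param seed integer seed for the substitution placement.
#' @return list with `assembly` (mutated target) and `calls` (data.frame
#'   of truth contaminant calls).
#' @export
plant_contamination <- function(target, source, plants, seed = 1L) {
  tgt <- asm_chars(target)
  src <- asm_chars(source)
  stopifnot(all(c("contig", "position", "source_contig", "source_start",
                  "source_end", "identity") %in% names(plants)))
  if (any(plants$identity <= 0 | plants$identity > 1)) {
    stop("plant identity must lie in (0, 1]")
  }
  calls <- vector("list", nrow(plants))
  with_stage_seed(seed, "plant_contamination", {
    for (i in seq_len(nrow(plants))) {
      p <- plants[i, ]
      if (!p$source_contig %in% names(src) ||
          p$source_end > nchar(src[[p$source_contig]]) || p$source_start < 0) {
        stop("plant source region outside the source assembly")
      }
      len <- p$source_end - p$source_start
      if (!p$contig %in% names(tgt)) stop("plant target contig ", p$contig, " unknown")
      ctg_len <- nchar(tgt[[p$contig]])
      if (p$position < 0 || p$position + len > ctg_len) {
        stop("plant of ", len, " bp does not fit in target contig ", p$contig)
      }
      seg <- substr(src[[p$source_contig]], p$source_start + 1L, p$source_end)
      n_sub <- round((1 - p$identity) * len)
      if (n_sub > 0) {
        seg <- substitute_bases(seg, sample.int(len, n_sub))
      }
      substr(tgt[[p$contig]], p$position + 1L, p$position + len) <- seg
      calls[[i]] <- data.frame(
        contig = p$contig,
        start = p$position,
        end = p$position + len,
        source_contig = p$source_contig,
        source_start = p$source_start,
        source_end = p$source_end,
        realized_identity = 1 - n_sub / len,
        edge_placed = p$position == 0L || p$position + len == ctg_len,
        stringsAsFactors = FALSE
      )
    }
  })
  list(assembly = tgt, calls = do.call(rbind, calls))
}

#' Simulate single-end reads with ground-truth origins
#'
#' Read origins are drawn independently (host with probability
#' `host_fraction`, otherwise a microbe weighted by genome length), the
#' start position uniformly along the source genome, the strand
#' uniformly, and per-base substitution errors at the configured rate.
#' Base qualities are constant; indels are not modelled (the benchmark is
#' label-level).
#'
#' @param host host assembly.
#' @param microbes named list of microbial assemblies, as from
#'   [build_microbe_genomes()] (names must match `microbe_spec`).
#' @param config a [sim_config()].
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `origin`, `taxid`, `source_contig`,
#'   `source_start`, `strand`, `from_exclusive`, `flagged`).
#' @export
simulate_reads <- function(host, microbes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reads <= 0L) stop("n_reads must be positive")
  asm <- asm_chars(host)
  rl <- config$read_length
  spec <- config$microbe_spec
  if (!all(names(microbes) %in% spec$taxon_name)) {
    stop("microbe assemblies not described in microbe_spec")
  }
  # flat table of sampleable contigs
  srcs <- list(data.frame(genome = "host", taxid = config$host_taxid,
                          contig = names(asm), len = unname(nchar(asm)),
                          flagged = FALSE, stringsAsFactors = FALSE))
  for (tx in names(microbes)) {
    m <- asm_chars(microbes[[tx]])
    row <- spec[spec$taxon_name == tx, ]
    srcs[[length(srcs) + 1L]] <- data.frame(
      genome = tx, taxid = row$taxid, contig = names(m),
      len = unname(nchar(m)), flagged = row$flagged, stringsAsFactors = FALSE)
  }
  srcs <- do.call(rbind, srcs)
  if (any(srcs$len < rl)) stop("read_length exceeds the shortest contig")
  seq_by_contig <- c(asm, unlist(lapply(microbes, asm_chars)))
  names(seq_by_contig) <- c(names(asm), unlist(lapply(microbes, function(m) names(asm_chars(m)))))

  excl <- config$exclusive_region_spec
  with_stage_seed(config$master_seed, "reads", {
    n <- config$n_reads
    is_host <- runif(n) < config$host_fraction
    # contig choice weighted by length, within host or within the community
    pick_contig <- function(rows, k) {
      if (k == 0L) return(integer(0))
      rows[sample.int(length(rows), k, replace = TRUE,
                      prob = srcs$len[rows] - rl + 1L)]
    }
    idx <- integer(n)
    idx[is_host] <- pick_contig(which(srcs$genome == "host"), sum(is_host))
    idx[!is_host] <- pick_contig(which(srcs$genome != "host"), sum(!is_host))
    contig <- srcs$contig[idx]
    start0 <- vapply(srcs$len[idx] - rl + 1L,
                     function(m) sample.int(m, 1L) - 1L, integer(1))
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- stringi::stri_sub(seq_by_contig[contig], start0 + 1L, start0 + rl)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    # substitution errors
    n_err <- rbinom(n, rl, config$substitution_error_rate)
    for (i in which(n_err > 0L)) {
      seqs[i] <- substitute_bases(seqs[i], sample.int(rl, n_err[i]))
    }
    read_id <- sprintf("read%06d", seq_len(n))
    names(seqs) <- read_id
    from_excl <- rep(FALSE, n)
    if (!is.null(excl) && nrow(excl) > 0) {
      for (j in seq_len(nrow(excl))) {
        hit <- is_host & contig == excl$contig[j] &
          start0 < excl$end[j] & (start0 + rl) > excl$start[j]
        from_excl <- from_excl | hit
      }
    }
    truth <- data.frame(
      read_id = read_id,
      origin = ifelse(is_host, "host", "microbe"),
      taxid = srcs$taxid[idx],
      source_contig = contig,
      source_start = start0,
      strand = strand,
      from_exclusive = from_excl,
      flagged = srcs$flagged[idx],
      stringsAsFactors = FALSE
    )
    list(reads = seqs, truth = truth)
  })
}

#' Simulate per-method host labels at configured operating points
#'
#' Artifact plumbing: produces the label matrix an aligner or k-mer
#' screener would have produced, without running one. Each true-host read
#' is labeled host with probability `sensitivity`; each true-non-host
#' read with probability `1 - specificity`, independently.
#'
#' @param truth truth table from [simulate_reads()].
#' @param tool_specs data.frame with `name`, `category` (one of
#'   `"alignment-based"`, `"k-mer-based"`), `sensitivity`, `specificity`.
#' @param seed integer seed.
#' @return a [label_matrix()].
#' @export
simulate_tool_labels <- function(truth, tool_specs, seed = 1L) {
  stopifnot(all(c("name", "category", "sensitivity", "specificity") %in%
                  names(tool_specs)))
  bad <- !tool_specs$category %in% c("alignment-based", "k-mer-based")
  if (any(bad)) {
    stop("unknown method category: ", paste(tool_specs$category[bad], collapse = ", "))
  }
  if (any(tool_specs$sensitivity < 0 | tool_specs$sensitivity > 1 |
          tool_specs$specificity < 0 | tool_specs$specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  is_host <- truth$origin == "host"
  n <- nrow(truth)
  lab <- matrix(FALSE, nrow = n, ncol = nrow(tool_specs),
                dimnames = list(truth$read_id, tool_specs$name))
  with_stage_seed(seed, "tool_labels", {
    for (j in seq_len(nrow(tool_specs))) {
      p_host <- ifelse(is_host, tool_specs$sensitivity[j],
                       1 - tool_specs$specificity[j])
      lab[, j] <- runif(n) < p_host
    }
  })
  label_matrix(lab, data.frame(
    name = tool_specs$name, category = tool_specs$category,
    reference_id = tool_specs$reference_id %||% rep("simulated", nrow(tool_specs)),
    stringsAsFactors = FALSE
  ))
}

#' Simulate a BLAST fallback hit table from the truth
#'
#' Artifact plumbing for adjudication without a sequence database:
#' host-origin reads receive a high-quality hit to the host taxid,
#' microbial reads a hit to their own taxid; a small configurable
#' fraction of reads receives no hit.
#'
#' @param truth truth table from [simulate_reads()].
#' @param read_ids which reads were "queried"; defaults to all.
#' @param no_hit_fraction fraction of queried reads with no hit.
#' @param seed integer seed.
#' @return list with `hits` (data.frame `read_id`, `taxid`, `pident`,
#'   `qcovs`) and `queried_reads` (character vector).
#' @export
simulate_blast_hits <- function(truth, read_ids = truth$read_id,
                                no_hit_fraction = 0.02, seed = 1L) {
  t2 <- truth[match(read_ids, truth$read_id), ]
  with_stage_seed(seed, "blast_hits", {
    n <- nrow(t2)
    has_hit <- runif(n) >= no_hit_fraction
    hits <- data.frame(
      read_id = t2$read_id[has_hit],
      taxid = t2$taxid[has_hit],
      pident = round(runif(sum(has_hit), 92, 99.9), 2),
      qcovs = round(runif(sum(has_hit), 92, 100), 2),
      stringsAsFactors = FALSE
    )
    list(hits = hits, queried_reads = read_ids)
  })
}

#' Emit the PAF a whole-genome aligner would produce for legacy-vs-host
#'
#' Artifact plumbing: the legacy reference aligns to the host genome in
#' one exact block per retained segment (the complement of the exclusive
#' regions), which is what an aligner recovers for a pure-deletion
#' relationship. Target coordinates are host coordinates.
#'
#' @param host host assembly.
#' @param regions an [exclusive_region_set()] (host coordinates).
#' @return data.frame of PAF columns suitable for [write_paf()].
#' @export
legacy_alignment_paf <- function(host, regions) {
  asm <- asm_chars(host)
  rows <- list()
  for (ctg in names(asm)) {
    L <- nchar(asm[[ctg]])
    r <- regions[regions$contig == ctg, , drop = FALSE]
    keep <- IRanges::setdiff(IRanges::IRanges(1L, L),
                             IRanges::IRanges(r$start + 1L, r$end))
    if (length(keep) == 0L) next
    ts <- IRanges::start(keep) - 1L
    te <- IRanges::end(keep)
    widths <- te - ts
    qlen <- sum(widths)
    qs <- cumsum(c(0L, head(widths, -1L)))
    rows[[length(rows) + 1L]] <- data.frame(
      qname = ctg, qlen = qlen, qstart = qs, qend = qs + widths,
      strand = "+", tname = ctg, tlen = L, tstart = ts, tend = te,
      nmatch = widths, alen = widths, mapq = 60L,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(read_paf(textConnection(character(0))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
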
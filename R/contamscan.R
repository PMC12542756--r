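## The contamination screen: exclusive-region extraction from
## whole-genome alignment coverage, k-mer-rule contaminant detection in
## microbial assemblies, contamination-ratio reporting with severity and
## edge/small-contig localization, and the residual-host screen for
## dehosted read sets.

#' Exclusive regions of a genome from PAF alignment coverage
#'
#' The complement, per contig, of the union of the alignment target
#' intervals: sequence of genome A with no coverage from genome B.
#' Contigs absent from the PAF are entirely exclusive. Regions shorter
#' than `min_region_length` are dropped.
#'
#' @param paf data.frame from [read_paf()]; target coordinates must
#'   refer to genome A.
#' @param genome_a_lengths named integer vector of genome A contig
#'   lengths.
#' @param min_region_length minimum region length kept (default 100 bp).
#' @return an [exclusive_region_set()].
#' @export
exclusive_regions <- function(paf, genome_a_lengths, min_region_length = 100L) {
  if (is.null(names(genome_a_lengths))) {
    stop("genome_a_lengths must be a named vector")
  }
  unknown <- setdiff(unique(paf$tname), names(genome_a_lengths))
  if (length(unknown) > 0) {
    stop("PAF target contig(s) absent from the lengths table: ",
         paste(unknown, collapse = ", "))
  }
  rows <- list()
  for (ctg in names(genome_a_lengths)) {
    L <- genome_a_lengths[[ctg]]
    p <- paf[paf$tname == ctg, , drop = FALSE]
    cov <- IRanges::IRanges(pmax(p$tstart, 0L) + 1L, pmin(p$tend, L))
    gap <- IRanges::setdiff(IRanges::IRanges(1L, L), IRanges::reduce(cov))
    gap <- gap[IRanges::width(gap) >= min_region_length]
    if (length(gap) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, start = IRanges::start(gap) - 1L,
        end = IRanges::end(gap), stringsAsFactors = FALSE)
    }
  }
  exclusive_region_set(if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0)))
}

#' Extract exclusive-region sequences from an assembly
#'
#' @param assembly named character vector or DNAStringSet.
#' @param regions an [exclusive_region_set()] (or data.frame with
#'   `contig`, `start`, `end`).
#' @return named character vector; names encode `contig:start-end`.
#' @export
extract_region_sequences <- function(assembly, regions) {
  asm <- asm_chars(assembly)
  if (nrow(regions) == 0L) return(setNames(character(0), character(0)))
  bad <- !(regions$contig %in% names(asm)) |
    regions$start < 0 | regions$end > nchar(asm[regions$contig])
  if (any(bad)) stop("region out of assembly bounds")
  seqs <- stringi::stri_sub(asm[regions$contig], regions$start + 1L, regions$end)
  setNames(seqs, sprintf("%s:%d-%d", regions$contig, regions$start, regions$end))
}

# X-drop ungapped extension helper: per-position match vector scanning.
# a, b are character vectors of aligned bases; returns the 0-based
# length of the retained extension.
xdrop_extent <- function(match_vec, xdrop = 20L) {
  if (length(match_vec) == 0L) return(0L)
  score <- cumsum(ifelse(match_vec, 1L, -2L))
  run_max <- cummax(score)
  stop_at <- which(run_max - score > xdrop)
  upto <- if (length(stop_at) > 0) stop_at[1] - 1L else length(score)
  if (upto == 0L) return(0L)
  which.max(score[seq_len(upto)])
}

chars_of <- function(s, from, to) {
  if (to < from) return(character(0))
  strsplit(stringi::stri_sub(s, from, to), "", fixed = TRUE)[[1]]
}

# Ungapped seed-and-extend matcher between one query sequence and one
# target contig, forward strand. Seeds are exact seed_k-mers; seeds on
# one diagonal are chained (gaps <= chain_gap), each chain is extended
# by X-drop, and overlapping spans on a diagonal are deduplicated.
# Returns hits as 0-based half-open intervals with exact identity.
match_one_strand <- function(qseq, tseq, seed_index, seed_k,
                             chain_gap = 100L, xdrop = 20L) {
  kt <- read_kmer_table(qseq, seed_k, canonical = FALSE)
  if (length(kt$kmer) == 0L) return(NULL)
  m <- seed_index[data.table::data.table(kmer = kt$kmer, qpos = kt$offset),
                  on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(m) == 0L) return(NULL)
  m <- as.data.frame(m)
  m$diag <- m$pos - m$qpos
  qlen <- nchar(qseq)
  tlen <- nchar(tseq)
  out <- list()
  for (d in unique(m$diag)) {
    qp <- sort(unique(m$qpos[m$diag == d]))
    runs <- cumsum(c(0L, diff(qp) > chain_gap))
    for (r in unique(runs)) {
      qs <- min(qp[runs == r])          # 0-based seed-span start
      qe <- max(qp[runs == r]) + seed_k # 0-based half-open end
      # right extension
      room <- min(qlen - qe, tlen - (qe + d))
      if (room > 0) {
        a <- chars_of(qseq, qe + 1L, qe + room)
        b <- chars_of(tseq, qe + d + 1L, qe + d + room)
        qe <- qe + xdrop_extent(a == b, xdrop)
      }
      # left extension
      room <- min(qs, qs + d)
      if (room > 0) {
        a <- rev(chars_of(qseq, qs - room + 1L, qs))
        b <- rev(chars_of(tseq, qs + d - room + 1L, qs + d))
        qs <- qs - xdrop_extent(a == b, xdrop)
      }
      a <- chars_of(qseq, qs + 1L, qe)
      b <- chars_of(tseq, qs + d + 1L, qe + d)
      out[[length(out) + 1L]] <- data.frame(
        qstart = qs, qend = qe, tstart = qs + d, tend = qe + d,
        nmatch = sum(a == b), stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, out)
  # deduplicate identical/contained spans produced by split chains
  hits <- unique(hits)
  hits$pident <- 100 * hits$nmatch / (hits$qend - hits$qstart)
  hits
}

#' Built-in near-exact matcher between exclusive sequences and genomes
#'
#' Exact-seed, ungapped X-drop extension on both strands: a desk-scale
#' Blastn-like search adequate for substitution-level contamination.
#' Hits are reported in query-forward coordinates; minus-strand hits
#' align the query interval to the reverse complement of the target
#' interval.
#'
#' @param queries named character vector of exclusive sequences.
#' @param target assembly (named character or DNAStringSet) of one
#'   genome.
#' @param seed_k exact seed length (default 16).
#' @return data.frame with `qseqid`, `tcontig`, `qstart`, `qend`,
#'   `tstart`, `tend`, `strand`, `nmatch`, `pident` (0-based half-open
#'   coordinates), or NULL when nothing matches.
#' @export
builtin_match <- function(queries, target, seed_k = 16L) {
  tgt <- asm_chars(target)
  out <- list()
  for (ctg in names(tgt)) {
    tt <- read_kmer_table(tgt[[ctg]], seed_k, canonical = FALSE)
    if (length(tt$kmer) == 0L) next
    idx <- data.table::data.table(kmer = tt$kmer, pos = tt$offset)
    data.table::setkey(idx, kmer)
    for (q in names(queries)) {
      qlen <- nchar(queries[[q]])
      fw <- match_one_strand(queries[[q]], tgt[[ctg]], idx, seed_k)
      if (!is.null(fw) && nrow(fw) > 0) {
        fw$strand <- "+"
        fw$qseqid <- q
        fw$tcontig <- ctg
        out[[length(out) + 1L]] <- fw
      }
      rc <- match_one_strand(revcomp(queries[[q]]), tgt[[ctg]], idx, seed_k)
      if (!is.null(rc) && nrow(rc) > 0) {
        qs <- qlen - rc$qend
        rc$qend <- qlen - rc$qstart
        rc$qstart <- qs
        rc$strand <- "-"
        rc$qseqid <- q
        rc$tcontig <- ctg
        out[[length(out) + 1L]] <- rc
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  df <- do.call(rbind, out)
  df[, c("qseqid", "tcontig", "qstart", "qend", "tstart", "tend",
         "strand", "nmatch", "pident")]
}

# Exact matching-base count between query segment [a, b) and its image
# under an ungapped hit, by direct sequence comparison.
segment_matches <- function(qseq, tseq, hit, a, b) {
  if (hit$strand == "+") {
    off <- hit$tstart - hit$qstart
    qa <- chars_of(qseq, a + 1L, b)
    ta <- chars_of(tseq, a + off + 1L, b + off)
  } else {
    # query [qstart,qend) aligns to revcomp(target [tstart,tend))
    t_hi <- hit$tend - (a - hit$qstart)
    t_lo <- hit$tend - (b - hit$qstart)
    qa <- chars_of(qseq, a + 1L, b)
    ta <- chars_of(revcomp(stringi::stri_sub(tseq, t_lo + 1L, t_hi)), 1L, b - a)
  }
  sum(qa == ta)
}

#' Detect host contamination in microbial genomes by the two-k-mer rule
#'
#' Candidate hits between exclusive sequences and target genomes are
#' filtered to alignments of at least `min_hit_length` bp with identity
#' strictly above `min_identity` percent. Each surviving exclusive
#' sequence is segmented into non-overlapping `kmer_size` bp segments;
#' a target genome is called contaminated by that sequence iff at least
#' `min_matched_kmers` of its segments match the genome (a segment
#' matches when at least `kmer_size * min_identity / 100` of its bases
#' match inside a surviving hit). Overlapping calls on the same target
#' contig are merged before reporting.
#'
#' @param exclusive_fasta named character vector of exclusive sequences
#'   (as from [extract_region_sequences()] or [read_assembly()]).
#' @param target_genomes named list of assemblies, one per genome.
#' @param hit_source `NULL` to use the built-in matcher, or a data.frame
#'   of precomputed hits with columns `qseqid`, `genome`, `tcontig`,
#'   `qstart`, `qend`, `tstart`, `tend`, `strand`, `pident` (0-based
#'   half-open; e.g. converted BLAST tabular output).
#' @param min_hit_length minimum alignment length (default 100 bp).
#' @param min_identity identity threshold in percent (default 90,
#'   strict).
#' @param kmer_size segment size (default 100 bp).
#' @param min_matched_kmers segments required to call (default 2).
#' @param small_contig_max contigs at most this long are "small"
#'   (default 10 kb).
#' @param edge_window distance from a contig end that counts as the
#'   edge (default 1 kb).
#' @return data.frame of contaminant calls: `genome`, `contig`,
#'   `start`, `end`, `source_id`, `source_start`, `source_end`,
#'   `percent_identity`, `matched_kmer_count`, `edge_flag`,
#'   `small_contig_flag`. Zero rows when nothing is called.
#' @export
detect_contaminants <- function(exclusive_fasta, target_genomes,
                                hit_source = NULL,
                                min_hit_length = 100L, min_identity = 90,
                                kmer_size = 100L, min_matched_kmers = 2L,
                                small_contig_max = 10000L,
                                edge_window = 1000L) {
  if (kmer_size < min_hit_length) {
    stop("inconsistent configuration: kmer_size < min_hit_length")
  }
  if (methods::is(exclusive_fasta, "DNAStringSet")) {
    exclusive_fasta <- setNames(as.character(exclusive_fasta),
                                sub("\\s.*$", "", names(exclusive_fasta)))
  }
  empty <- data.frame(
    genome = character(0), contig = character(0), start = integer(0),
    end = integer(0), source_id = character(0), source_start = integer(0),
    source_end = integer(0), percent_identity = numeric(0),
    matched_kmer_count = integer(0), edge_flag = logical(0),
    small_contig_flag = logical(0), stringsAsFactors = FALSE)
  if (length(exclusive_fasta) == 0L) return(empty)

  if (is.null(hit_source)) {
    hit_source <- do.call(rbind, lapply(names(target_genomes), function(g) {
      h <- builtin_match(exclusive_fasta, target_genomes[[g]])
      if (is.null(h)) return(NULL)
      h$genome <- g
      h
    }))
  }
  if (is.null(hit_source) || nrow(hit_source) == 0L) return(empty)
  hits <- hit_source[(hit_source$qend - hit_source$qstart) >= min_hit_length &
                       hit_source$pident > min_identity, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)

  calls <- list()
  min_seg_matches <- kmer_size * min_identity / 100
  for (q in unique(hits$qseqid)) {
    qseq <- exclusive_fasta[[q]]
    n_seg <- nchar(qseq) %/% kmer_size
    if (n_seg == 0L) next
    seg_start <- (seq_len(n_seg) - 1L) * kmer_size
    hq <- hits[hits$qseqid == q, , drop = FALSE]
    for (g in unique(hq$genome)) {
      tgt <- asm_chars(target_genomes[[g]])
      hg <- hq[hq$genome == g, , drop = FALSE]
      seg_rows <- list()
      for (s in seq_len(n_seg)) {
        a <- seg_start[s]; b <- a + kmer_size
        for (j in seq_len(nrow(hg))) {
          h <- hg[j, ]
          # matching bases are counted inside the hit's overlap with the
          # segment; a hit trimmed by an edge substitution can still
          # carry the segment
          ov_a <- max(a, h$qstart); ov_b <- min(b, h$qend)
          if (ov_b - ov_a < min_seg_matches) next
          nm <- segment_matches(qseq, tgt[[h$tcontig]], h, ov_a, ov_b)
          if (nm >= min_seg_matches) {
            # project the overlap onto the target
            if (h$strand == "+") {
              ts <- ov_a + (h$tstart - h$qstart)
              te <- ov_b + (h$tstart - h$qstart)
            } else {
              te <- h$tend - (ov_a - h$qstart)
              ts <- h$tend - (ov_b - h$qstart)
            }
            seg_rows[[length(seg_rows) + 1L]] <- data.frame(
              contig = h$tcontig, ts = ts, te = te, a = ov_a, b = ov_b,
              nm = nm, stringsAsFactors = FALSE)
            break
          }
        }
      }
      if (length(seg_rows) < min_matched_kmers) next
      segs <- do.call(rbind, seg_rows)
      for (ctg in unique(segs$contig)) {
        sc <- segs[segs$contig == ctg, , drop = FALSE]
        if (nrow(sc) < min_matched_kmers) next
        red <- IRanges::reduce(IRanges::IRanges(sc$ts + 1L, sc$te))
        ctg_len <- nchar(tgt[[ctg]])
        for (i in seq_along(red)) {
          st <- IRanges::start(red)[i] - 1L
          en <- IRanges::end(red)[i]
          inside <- sc$ts >= st - kmer_size & sc$te <= en + kmer_size
          calls[[length(calls) + 1L]] <- data.frame(
            genome = g, contig = ctg, start = st, end = en,
            source_id = q, source_start = min(sc$a[inside]),
            source_end = max(sc$b[inside]),
            percent_identity = 100 * sum(sc$nm[inside]) /
              sum(sc$b[inside] - sc$a[inside]),
            matched_kmer_count = sum(inside),
            edge_flag = st < edge_window || en > ctg_len - edge_window,
            small_contig_flag = ctg_len <= small_contig_max,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Contig lengths of a set of genomes
#' @param genomes named list of assemblies.
#' @return data.frame with `genome`, `contig`, `length`.
#' @export
assembly_lengths <- function(genomes) {
  do.call(rbind, lapply(names(genomes), function(g) {
    asm <- asm_chars(genomes[[g]])
    data.frame(genome = g, contig = names(asm), length = unname(nchar(asm)),
               stringsAsFactors = FALSE)
  }))
}

#' Per-genome contamination report
#'
#' Contamination ratio = merged contaminant bases / genome length;
#' genomes above `severe_threshold` (default 0.0001, i.e. the 0.01%
#' rule) are flagged severely contaminated. `edge_or_small_fraction`
#' is the fraction of contaminant bases lying on contigs of at most
#' `small_contig_max` bp or within `edge_window` bp of a contig end.
#'
#' @param calls data.frame from [detect_contaminants()].
#' @param genome_lengths data.frame from [assembly_lengths()] (columns
#'   `genome`, `contig`, `length`).
#' @param severe_threshold ratio above which a genome is severe.
#' @param small_contig_max,edge_window localization parameters (bp).
#' @return data.frame with `genome`, `n_calls`, `contaminant_bp`,
#'   `genome_bp`, `contamination_ratio`, `severe`,
#'   `edge_or_small_fraction`.
#' @export
contamination_report <- function(calls, genome_lengths,
                                 severe_threshold = 0.0001,
                                 small_contig_max = 10000L,
                                 edge_window = 1000L) {
  stopifnot(all(c("genome", "contig", "length") %in% names(genome_lengths)))
  if (any(genome_lengths$length <= 0)) stop("zero-length genome contig")
  unknown <- setdiff(unique(calls$genome), unique(genome_lengths$genome))
  if (length(unknown) > 0) {
    stop("call genome(s) absent from lengths table: ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(unique(genome_lengths$genome), function(g) {
    gl <- genome_lengths[genome_lengths$genome == g, ]
    genome_bp <- sum(gl$length)
    cg <- calls[calls$genome == g, , drop = FALSE]
    contaminant_bp <- 0L
    edge_small_bp <- 0L
    n_calls <- 0L
    if (nrow(cg) > 0) {
      for (ctg in unique(cg$contig)) {
        cc <- cg[cg$contig == ctg, ]
        ctg_len <- gl$length[match(ctg, gl$contig)]
        if (is.na(ctg_len)) stop("call contig ", ctg, " absent from lengths")
        red <- IRanges::reduce(IRanges::IRanges(cc$start + 1L, cc$end))
        n_calls <- n_calls + length(red)
        w <- IRanges::width(red)
        contaminant_bp <- contaminant_bp + sum(w)
        st <- IRanges::start(red) - 1L
        en <- IRanges::end(red)
        is_edge <- st < edge_window | en > ctg_len - edge_window
        is_small <- ctg_len <= small_contig_max
        edge_small_bp <- edge_small_bp + sum(w[is_edge | is_small])
      }
    }
    ratio <- contaminant_bp / genome_bp
    data.frame(
      genome = g, n_calls = n_calls, contaminant_bp = contaminant_bp,
      genome_bp = genome_bp, contamination_ratio = ratio,
      severe = ratio > severe_threshold,
      edge_or_small_fraction = if (contaminant_bp > 0) {
        edge_small_bp / contaminant_bp
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual-host screen of an already-dehosted read set
#'
#' Flags reads that share at least `min_shared` canonical k-mers with
#' the exclusive sequences: host reads a legacy reference could not
#' remove because their source sequence is absent from it.
#'
#' @param dehosted_reads named character vector (or DNAStringSet) of
#'   reads surviving a dehosting step.
#' @param exclusive_fasta named character vector of exclusive sequences.
#' @param k k-mer size (default 25).
#' @param min_shared minimum shared k-mers (default 1).
#' @return list with `residual_count`, `residual_fraction`, `flags`
#'   (named logical per read).
#' @export
residual_host_screen <- function(dehosted_reads, exclusive_fasta,
                                 k = 25L, min_shared = 1L) {
  if (length(exclusive_fasta) == 0L) stop("empty exclusive sequence set")
  idx <- kmer_index(exclusive_fasta, k)
  flags <- kmer_classify_reads(dehosted_reads, idx, min_shared = min_shared)
  list(residual_count = sum(flags),
       residual_fraction = mean(flags),
       flags = flags)
}
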
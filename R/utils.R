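#' @importFrom stats median p.adjust pnorm rbinom runif setNames shapiro.test
#' @importFrom utils combn head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement; `N` maps to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

#' Enumerate the k-mers of a set of sequences
#'
#' Returns every overlapping window of length `k`. K-mers containing
#' ambiguous bases (`N`) are dropped. With `canonical = TRUE` each k-mer
#' is replaced by the lexicographic minimum of itself and its reverse
#' complement, collapsing the two strands.
#'
#' @param seqs character vector of sequences.
#' @param k integer k-mer size.
#' @param canonical collapse strands to canonical form?
#' @return character vector of k-mers (concatenated over all sequences).
#' @export
kmers_of <- function(seqs, k, canonical = FALSE) {
  stopifnot(k >= 1)
  seqs <- toupper(as.character(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L < k) {
      out[[i]] <- character(0)
      next
    }
    starts <- seq_len(L - k + 1L)
    km <- stringi::stri_sub(seqs[i], starts, starts + k - 1L)
    if (canonical) {
      rc <- revcomp(km)
      km <- ifelse(km <= rc, km, rc)
    }
    out[[i]] <- km
  }
  km <- unlist(out, use.names = FALSE)
  km[!stringi::stri_detect_fixed(km, "N")]
}

# Deterministic fan-out of a master seed into named per-stage substreams.
# Kept below 2^31 so it is always a valid R integer seed.
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

# Run an expression under a temporary RNG state seeded from (master, stage).
with_stage_seed <- function(master_seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(master_seed, stage))
  force(expr)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute bases at given 1-based positions with a uniformly chosen
# different base. Returns the mutated string.
substitute_bases <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
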
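# Synthetic reference sequences and sequence/file helpers.

# Run code under a fixed RNG seed, then restore the caller's RNG state, so
# reference generation is deterministic without perturbing user simulations.
with_fixed_seed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Bundled synthetic prey reference
#'
#' Deterministically generated uniform-random DNA standing in for the Salpha /
#' Calpha analysis window; the same sequence is returned on every call. It is
#' synthetic: it carries no S-region repeat structure (see the methods
#' vignette for what that does and does not limit).
#'
#' @param width Sequence length in bp (default: the default 20-kb window).
#' @return A character scalar of `width` bases.
#' @export
synthetic_prey_ref <- function(width = 20000L) {
  with_fixed_seed(491100L + width %% 1000L, function() random_dna(width))
}

#' Bundled synthetic bait reference
#'
#' The fixed Smu bait primer followed by deterministically generated random
#' sequence up to and past the bait break, providing the germline continuation
#' used to recognize unbroken reads.
#'
#' @param len Total bait reference length in bp.
#' @return A character scalar: `primer` + synthetic continuation.
#' @export
synthetic_bait_ref <- function(len = DEFAULT_BAIT_REF_LEN) {
  primer <- DEFAULT_BAIT_PRIMER
  stopifnot(len > nchar(primer))
  with_fixed_seed(20565L, function() {
    paste0(primer, random_dna(len - nchar(primer)))
  })
}

# reverse complement of a single character string (internal; public I/O goes
# through Biostrings)
rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Oriented prey segment read off the locus: for "+" the locus-forward sequence
# starting at pos and running downstream; for "-" the reverse complement
# starting at pos and running upstream (centromere-to-telomere capture).
# Truncated at the window edges.
prey_segment <- function(locus, pos, strand, len) {
  w <- locus$analysis_window
  if (strand == "+") {
    lo <- prey_offset(locus, pos)
    hi <- min(lo + len - 1L, gi_width(w))
    if (lo > hi) return("")
    substr(locus$prey_ref, lo, hi)
  } else {
    hi <- prey_offset(locus, pos)
    lo <- max(1L, hi - len + 1L)
    if (lo > hi) return("")
    rc(substr(locus$prey_ref, lo, hi))
  }
}

# single oriented base immediately upstream (delta < 0) or downstream of pos
# in reading orientation; "" past the window edge
prey_char <- function(locus, pos, strand, delta = 0L) {
  p <- if (strand == "+") pos + delta else pos - delta
  off <- prey_offset(locus, p)
  if (off < 1L || off > nchar(locus$prey_ref)) return("")
  ch <- substr(locus$prey_ref, off, off)
  if (strand == "+") ch else chartr("ACGT", "TGCA", ch)
}

#' Write locus references as FASTA
#'
#' Emits `bait_ref.fa` and `prey_ref.fa` into a directory, with coordinates
#' echoed in the headers, for interoperability with external tools.
#'
#' @param locus A `locus_map`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_locus_fasta <- function(locus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- locus$analysis_window
  bait <- Biostrings::DNAStringSet(locus$bait_ref)
  names(bait) <- sprintf("bait_ref break=%d primer=%s", locus$bait_break, locus$bait_primer)
  prey <- Biostrings::DNAStringSet(locus$prey_ref)
  names(prey) <- sprintf("prey_ref %s:%d-%d", w$chrom, w$start, w$end)
  bait_path <- file.path(dir, "bait_ref.fa")
  prey_path <- file.path(dir, "prey_ref.fa")
  Biostrings::writeXStringSet(bait, bait_path)
  Biostrings::writeXStringSet(prey, prey_path)
  invisible(c(bait = bait_path, prey = prey_path))
}

# FASTQ helpers ---------------------------------------------------------------

read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  if (file.size(path) == 0L) return(character(0L))
  first <- readChar(path, 1L)
  if (first == ">") stop("input looks like FASTA, not FASTQ: ", path)
  if (first != "@") stop("malformed FASTQ (does not start with '@'): ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(seqs)
  # keep only the read id (strip any description)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

write_fastq <- function(reads, path) {
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))  # constant Q40 placeholder
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}
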
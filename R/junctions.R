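# Junction calling: bait anchoring, germline filtering (in-silico analog of
# AflII blocking), exhaustive prey mapping, microhomology/insertion
# resolution, and exact-key deduplication.

JUNCTION_STATUSES <- c("junction", "germline", "unmapped", "ambiguous",
                       "duplicate", "unanchored")

#' Anchor a read on the bait reference
#'
#' Computes the longest prefix of the read matching the bait reference with
#' at most `tolerance` mismatches. Reads whose match does not cover the full
#' bait primer are unanchored; reads whose match extends at least
#' `germline_threshold` bases past the bait break are germline (the unbroken
#' fragments an AflII blocking step removes in the wet protocol).
#'
#' @param read Read sequence.
#' @param locus A `locus_map`.
#' @param germline_threshold Bases past `bait_break` required to call a read
#'   germline (default 10, tolerant of chance matches at the break).
#' @param tolerance Mismatches allowed in the prefix match.
#' @return `list(match_len, anchored, crosses_break)`.
#' @export
match_bait <- function(read, locus, germline_threshold = 10L, tolerance = 0L) {
  if (nchar(read) == 0L) stop("empty read")
  n <- min(nchar(read), nchar(locus$bait_ref))
  mm <- cumsum(utf8ToInt(substr(read, 1L, n)) != utf8ToInt(substr(locus$bait_ref, 1L, n)))
  ok <- mm <= tolerance
  match_len <- if (any(ok)) max(which(ok)) else 0L
  list(
    match_len = as.integer(match_len),
    anchored = match_len >= nchar(locus$bait_primer),
    crosses_break = match_len >= locus$bait_break + germline_threshold
  )
}

#' Precompiled prey-reference subjects for repeated mapping
#'
#' Builds the forward and reverse-complement `DNAString` subjects once so
#' that [map_prey()] calls over a whole library avoid re-parsing the
#' reference.
#'
#' @param locus A `locus_map`.
#' @return A list used by [map_prey()] / [call_library()].
#' @export
prey_subjects <- function(locus) {
  fwd <- Biostrings::DNAString(locus$prey_ref)
  rev <- Biostrings::reverseComplement(fwd)
  list(fwd = fwd, rev = rev,
       fwd_str = locus$prey_ref, rev_str = as.character(rev),
       width = nchar(locus$prey_ref), win_start = locus$analysis_window$start)
}

# all (including overlapping) occurrences of a fixed pattern in a string
find_all_fixed <- function(pat, s) {
  out <- integer(0L)
  from <- 1L
  repeat {
    rel <- regexpr(pat, substring(s, from), fixed = TRUE)
    if (rel == -1L) break
    hit <- from + as.integer(rel) - 1L
    out <- c(out, hit)
    from <- hit + 1L
  }
  out
}

# all occurrences of read[j..] in both strands; returns starts in subject
# coordinates plus per-hit mismatch counts
suffix_hits <- function(read, j, subj, tolerance) {
  suf <- substr(read, j, nchar(read))
  if (tolerance == 0L) {
    sp <- find_all_fixed(suf, subj$fwd_str)
    sm <- find_all_fixed(suf, subj$rev_str)
    return(list(starts_p = sp, mm_p = integer(length(sp)),
                starts_m = sm, mm_m = integer(length(sm)),
                len = nchar(suf)))
  }
  count_mm <- function(views) {
    if (length(views) == 0L) return(integer(0L))
    vapply(as.character(views), function(s) {
      sum(utf8ToInt(s) != utf8ToInt(suf))
    }, integer(1L), USE.NAMES = FALSE)
  }
  hp <- Biostrings::matchPattern(suf, subj$fwd, max.mismatch = tolerance)
  hm <- Biostrings::matchPattern(suf, subj$rev, max.mismatch = tolerance)
  list(
    starts_p = BiocGenerics::start(hp), mm_p = count_mm(hp),
    starts_m = BiocGenerics::start(hm), mm_m = count_mm(hm),
    len = nchar(suf)
  )
}

#' Map the prey segment of a read
#'
#' Finds the longest read suffix `read[j..]` (`j >= min_j`, suffix length
#' `>= min_len`) occurring in the prey reference, on either strand, with at
#' most `tolerance` mismatches; candidates are ranked by match length
#' (descending), mismatches (ascending), then leftmost prey position. The
#' search exploits that "`read[j..]` occurs somewhere" is monotone in `j`
#' (any occurrence of a suffix contains occurrences of all shorter suffixes),
#' so the minimal `j` is located by bisection; the result is identical to an
#' exhaustive scan of all suffixes against all positions on both strands.
#' When `tolerance > 0`, candidates with a mismatch in the first
#' `exact_junction_bp` matched bases are dropped (microhomology calling
#' requires the junction-proximal bases to be exact).
#'
#' @param read Read sequence.
#' @param locus A `locus_map`.
#' @param min_j Smallest read position where the prey match may begin.
#' @param tolerance Mismatches allowed in the suffix match.
#' @param min_len Minimum prey match length (bp).
#' @param exact_junction_bp Junction-proximal bases that must match exactly.
#' @param subjects Optional precomputed [prey_subjects()].
#' @return A data.frame of candidates (`read_start_j`, `prey_pos`, `strand`,
#'   `match_len`, `mismatches`), best first; zero rows when unmapped.
#'   `prey_pos` is the locus coordinate of the first prey-assigned base.
#' @export
map_prey <- function(read, locus, min_j = 1L, tolerance = 0L, min_len = 15L,
                     exact_junction_bp = 5L, subjects = NULL) {
  if (is.null(subjects)) subjects <- prey_subjects(locus)
  empty <- data.frame(read_start_j = integer(0L), prey_pos = integer(0L),
                      strand = character(0L), match_len = integer(0L),
                      mismatches = integer(0L), stringsAsFactors = FALSE)
  L <- nchar(read)
  lo <- max(as.integer(min_j), 1L)
  hi <- L - as.integer(min_len) + 1L
  if (hi < lo) return(empty)

  has_hit <- function(j) {
    if (tolerance == 0L) {
      suf <- substr(read, j, L)
      return(grepl(suf, subjects$fwd_str, fixed = TRUE) ||
             grepl(suf, subjects$rev_str, fixed = TRUE))
    }
    h <- suffix_hits(read, j, subjects, tolerance)
    length(h$starts_p) + length(h$starts_m) > 0L
  }
  if (!has_hit(hi)) return(empty)
  # bisect for the minimal j with a hit (monotone predicate)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (has_hit(mid)) hi <- mid else lo <- mid + 1L
  }
  j <- lo
  h <- suffix_hits(read, j, subjects, tolerance)
  W <- subjects$width
  cand <- data.frame(
    read_start_j = j,
    prey_pos = c(subjects$win_start + h$starts_p - 1L,
                 subjects$win_start + W - h$starts_m),
    strand = c(rep("+", length(h$starts_p)), rep("-", length(h$starts_m))),
    match_len = h$len,
    mismatches = c(h$mm_p, h$mm_m),
    stringsAsFactors = FALSE
  )
  if (tolerance > 0L && exact_junction_bp > 0L) {
    head_ok <- vapply(seq_len(nrow(cand)), function(i) {
      k <- min(exact_junction_bp, h$len)
      s <- if (cand$strand[i] == "+") {
        as.character(Biostrings::subseq(subjects$fwd,
          start = cand$prey_pos[i] - subjects$win_start + 1L, width = k))
      } else {
        q <- subjects$win_start + W - cand$prey_pos[i]
        as.character(Biostrings::subseq(subjects$rev, start = q, width = k))
      }
      s == substr(read, j, j + k - 1L)
    }, logical(1L))
    cand <- cand[head_ok, , drop = FALSE]
  }
  cand[order(cand$mismatches, cand$prey_pos), , drop = FALSE]
}

#' Resolve microhomology and insertion at a junction
#'
#' Given a bait anchor ending at read position `i = match_len` and a prey
#' alignment starting at read position `j`, the overlap bases assignable to
#' both sides give `mh_len = max(0, i - j + 1)` and any gap gives
#' `insertion_len = max(0, j - i - 1)` (mutually exclusive by construction).
#' The reported junction coordinate follows the maximal-bait-extension
#' convention: the bait claims the microhomology bases, so `prey_pos` is
#' advanced past them in the reading direction.
#'
#' @param bait Result of [match_bait()] (must be anchored).
#' @param prey One candidate row from [map_prey()].
#' @param read Read sequence.
#' @return `list(bait_end_i, prey_pos, strand, prey_match_len, mh_len,
#'   insertion_len, insertion_seq)`.
#' @export
resolve_junction <- function(bait, prey, read) {
  if (!isTRUE(bait$anchored)) stop("bait not anchored")
  j <- as.integer(prey$read_start_j)
  if (is.na(j) || j <= 0L) stop("inconsistent prey alignment: read_start_j <= 0")
  i <- bait$match_len
  mh <- max(0L, i - j + 1L)
  ins <- max(0L, j - i - 1L)
  list(
    bait_end_i = i,
    prey_pos = if (prey$strand == "+") prey$prey_pos + mh else prey$prey_pos - mh,
    strand = prey$strand,
    prey_match_len = as.integer(prey$match_len),
    mh_len = mh,
    insertion_len = ins,
    insertion_seq = if (ins > 0L) substr(read, i + 1L, j - 1L) else ""
  )
}

#' Mark exact-key duplicates
#'
#' Junction records sharing `(prey_pos, strand, bait_end_i)` beyond the first
#' (ordered by `read_id`) are marked `duplicate`. This exact-key rule is a
#' stated approximation of offset-based HTGTS deduplication and is
#' deterministic.
#'
#' @param records A junction table (data.frame).
#' @return The table with `status` updated.
#' @export
deduplicate <- function(records) {
  idx <- which(records$status == "junction")
  if (length(idx) < 2L) return(records)
  idx <- idx[order(records$read_id[idx])]
  key <- paste(records$prey_pos[idx], records$strand[idx], records$bait_end_i[idx])
  records$status[idx[duplicated(key)]] <- "duplicate"
  records
}

#' Call junctions for a whole library
#'
#' Runs bait anchoring, germline filtering, prey mapping, junction resolution
#' and deduplication over a FASTQ. Every input read appears exactly once in
#' the output with exactly one status among `junction`, `germline`,
#' `unmapped`, `ambiguous`, `duplicate`, `unanchored`; an alignment tie
#' (two candidates with equal length and mismatches at different loci) is
#' reported as `ambiguous`, never silently resolved.
#'
#' @param fastq Path to a FASTQ file, or a named character vector of reads.
#' @param locus A `locus_map`.
#' @param germline_threshold,tolerance,min_len,min_j See [match_bait()] and
#'   [map_prey()].
#' @param dedup Apply [deduplicate()]? Disable for libraries known to carry
#'   no PCR duplicates: the exact-key rule cannot distinguish a PCR copy from
#'   an independent junction at a saturated position.
#' @param out_tsv Optional path for the junction table TSV.
#' @return `list(table = <data.frame>, counts = <named integer by status>)`.
#' @export
call_library <- function(fastq, locus, germline_threshold = 10L, tolerance = 0L,
                         min_len = 15L, min_j = 1L, dedup = TRUE,
                         out_tsv = NULL) {
  reads <- if (is.character(fastq) && length(fastq) == 1L && is.null(names(fastq))) {
    read_fastq(fastq)
  } else fastq
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  subj <- prey_subjects(locus)
  chrom <- locus$analysis_window$chrom

  status <- character(n)
  bait_end_i <- rep(NA_integer_, n)
  prey_pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  prey_match_len <- rep(NA_integer_, n)
  mh_len <- rep(NA_integer_, n)
  insertion_len <- rep(NA_integer_, n)
  insertion_seq <- rep(NA_character_, n)

  for (k in seq_len(n)) {
    bait <- match_bait(reads[[k]], locus, germline_threshold, tolerance)
    if (!bait$anchored) { status[k] <- "unanchored"; next }
    bait_end_i[k] <- bait$match_len
    if (bait$crosses_break) { status[k] <- "germline"; next }
    cand <- map_prey(reads[[k]], locus, min_j = min_j, tolerance = tolerance,
                     min_len = min_len, subjects = subj)
    if (nrow(cand) == 0L) { status[k] <- "unmapped"; next }
    top_ties <- sum(cand$mismatches == cand$mismatches[1L])
    if (top_ties >= 2L) { status[k] <- "ambiguous"; next }
    jr <- resolve_junction(bait, cand[1L, ], reads[[k]])
    status[k] <- "junction"
    prey_pos[k] <- jr$prey_pos
    strand[k] <- jr$strand
    prey_match_len[k] <- jr$prey_match_len
    mh_len[k] <- jr$mh_len
    insertion_len[k] <- jr$insertion_len
    insertion_seq[k] <- jr$insertion_seq
  }

  tab <- data.frame(
    read_id = ids, status = status, bait_end_i = bait_end_i,
    prey_chrom = ifelse(status == "junction", chrom, NA_character_),
    prey_pos = prey_pos, strand = strand, prey_match_len = prey_match_len,
    mh_len = mh_len, insertion_len = insertion_len,
    insertion_seq = insertion_seq, stringsAsFactors = FALSE
  )
  if (dedup) tab <- deduplicate(tab)
  counts <- vapply(JUNCTION_STATUSES, function(s) sum(tab$status == s), integer(1L))
  if (!is.null(out_tsv)) write_junction_table(tab, out_tsv)
  list(table = tab, counts = counts)
}
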
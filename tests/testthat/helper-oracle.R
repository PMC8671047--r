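# Brute-force oracles and small fixtures, independent of the package's
# calling path (plain base-R string scans only).

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# every occurrence (including overlapping) of pat in s, by repeated fixed
# search from each hit + 1
oracle_find_all <- function(pat, s) {
  out <- integer(0L)
  from <- 1L
  repeat {
    rel <- regexpr(pat, substring(s, from), fixed = TRUE)
    if (rel == -1L) break
    out <- c(out, from + as.integer(rel) - 1L)
    from <- out[length(out)] + 1L
  }
  out
}

# Split-enumeration oracle for a single read: longest bait prefix (exact),
# then the smallest j such that read[j..] occurs in the prey (either strand),
# enumerated linearly from j = 1; ties at that j across loci = ambiguous.
# Mirrors the documented zero-tolerance calling semantics.
oracle_call <- function(read, locus, germline_threshold = 10L, min_len = 15L) {
  L <- nchar(read)
  bait <- locus$bait_ref
  n <- min(L, nchar(bait))
  i_star <- 0L
  while (i_star < n &&
         substr(read, i_star + 1L, i_star + 1L) == substr(bait, i_star + 1L, i_star + 1L)) {
    i_star <- i_star + 1L
  }
  if (i_star < nchar(locus$bait_primer)) return(list(status = "unanchored"))
  if (i_star >= locus$bait_break + germline_threshold) {
    return(list(status = "germline", bait_end_i = i_star))
  }
  prey <- locus$prey_ref
  prey_rc <- oracle_rc(prey)
  W <- nchar(prey)
  win_start <- locus$analysis_window$start
  hi <- L - min_len + 1L
  if (hi >= 1L) {
    for (j in seq_len(hi)) {
      suf <- substr(read, j, L)
      hp <- oracle_find_all(suf, prey)
      hm <- oracle_find_all(suf, prey_rc)
      nh <- length(hp) + length(hm)
      if (nh == 0L) next
      if (nh >= 2L) return(list(status = "ambiguous", bait_end_i = i_star))
      mh <- max(0L, i_star - j + 1L)
      ins <- max(0L, j - i_star - 1L)
      if (length(hp) == 1L) {
        strand <- "+"
        pos <- win_start + hp - 1L + mh
      } else {
        strand <- "-"
        pos <- win_start + W - hm - mh
      }
      return(list(status = "junction", bait_end_i = i_star, prey_pos = pos,
                  strand = strand, mh_len = mh, insertion_len = ins,
                  insertion_seq = if (ins > 0L) substr(read, i_star + 1L, j - 1L) else ""))
    }
  }
  list(status = "unmapped", bait_end_i = i_star)
}

# expected per-read statuses from a set of oracle calls plus the exact-key
# first-by-read_id duplicate rule
oracle_statuses <- function(oracle_list, ids) {
  status <- vapply(oracle_list, `[[`, character(1L), "status")
  j <- which(status == "junction")
  if (length(j) >= 2L) {
    ord <- j[order(ids[j])]
    key <- vapply(oracle_list[ord], function(o) {
      paste(o$prey_pos, o$strand, o$bait_end_i)
    }, character(1L))
    status[ord[duplicated(key)]] <- "duplicate"
  }
  status
}

tvd <- function(p, q) 0.5 * sum(abs(p - q))

# realized-MH spectrum from a truth table, matching mh_spectrum() classes
truth_mh_spectrum <- function(truth, cap = 10L) {
  tr <- truth[!truth$is_germline, ]
  cls <- as.character(pmin(tr$realized_mh, cap))
  cls[tr$insertion_len > 0L] <- "ins"
  tab <- table(factor(cls, levels = c(as.character(0:cap), "ins")))
  as.numeric(tab) / nrow(tr)
}

# small fast locus (2-kb window, 10 bins) for unit tests
tiny_locus <- function() {
  win <- genomic_interval("chrT", 1001, 3000)
  set.seed(909)
  bases <- c("A", "C", "G", "T")
  primer <- "ACGTACGTAC"
  locus_map(
    bait_primer = primer,
    bait_break = 20L,
    bait_ref = paste0(primer, paste(sample(bases, 110, replace = TRUE), collapse = "")),
    prey_ref = paste(sample(bases, 2000, replace = TRUE), collapse = ""),
    analysis_window = win,
    core_acceptor = genomic_interval("chrT", 1801, 2200),
    distal_acceptor = genomic_interval("chrT", 2201, 3000),
    bin_width = 200L
  )
}

# 14-bp worked-example locus from hand-checkable sequences
toy_locus <- function() {
  locus_map(
    bait_primer = "AAAA",
    bait_break = 6L,
    bait_ref = "AAAACCTTTT",
    prey_ref = "TTTTCCGGGGAAAA",
    analysis_window = genomic_interval("chrT", 1, 14),
    core_acceptor = genomic_interval("chrT", 1, 7),
    distal_acceptor = genomic_interval("chrT", 8, 14),
    bin_width = 7L
  )
}

# minimal junction-table row constructor for summarize tests
jrow <- function(read_id, status = "junction", prey_pos = NA, strand = NA,
                 mh_len = NA, insertion_len = 0L, bait_end_i = 60L,
                 chrom = "chr12") {
  data.frame(
    read_id = read_id, status = status, bait_end_i = bait_end_i,
    prey_chrom = ifelse(status == "junction", chrom, NA_character_),
    prey_pos = prey_pos, strand = strand, prey_match_len = NA_integer_,
    mh_len = mh_len, insertion_len = insertion_len,
    insertion_seq = ifelse(insertion_len > 0, strrep("N", insertion_len), ""),
    stringsAsFactors = FALSE
  )
}
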
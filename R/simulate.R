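# Generative model of HTGTS-style class-switch junction libraries.
#
# Each non-germline read is built as
#   bait_ref[1..bait_break] + insertion + oriented prey segment,
# where the prey join position is (acceptor break ~ truncated normal around
# the core-Salpha midpoint) + (geometric resection, shifted downstream toward
# Calpha), optionally relocated to a nearby planted microhomology, truncated
# to the read length and overlaid with uniform substitution errors.

#' Sample acceptor break positions
#'
#' Breaks are drawn from a truncated normal centered on the core-acceptor
#' midpoint with sd `break_spread`, then clamped into the analysis window
#' (AID-initiated Salpha breaks are modeled as highly enriched in the core).
#'
#' @param preset A `pathway_preset`.
#' @param locus A `locus_map`.
#' @param n Number of draws.
#' @return Integer vector of locus positions.
#' @export
sample_break <- function(preset, locus, n = 1L) {
  core <- locus$core_acceptor
  mid <- (core$start + core$end) %/% 2L
  if (preset$break_spread == 0) return(rep(mid, n))
  w <- locus$analysis_window
  pos <- round(stats::rnorm(n, mean = mid, sd = preset$break_spread))
  as.integer(pmin(pmax(pos, w$start), w$end))
}

#' Sample resection lengths
#'
#' Geometric on \{0, 1, 2, ...\} with mean `resection_mean` (memoryless
#' one-parameter default; long-resection behaviour is controlled entirely by
#' this mean).
#'
#' @inheritParams sample_break
#' @return Integer vector of non-negative resected lengths (bp).
#' @export
sample_resection <- function(preset, n = 1L) {
  m <- preset$resection_mean
  if (m == 0) return(integer(n))
  stats::rgeom(n, prob = 1 / (1 + m))
}

#' Place a join by microhomology annealing
#'
#' Scans `acceptor_seq` for an exact occurrence of the terminal
#' `target_mh`-mer of `bait_end_seq` whose end lies within `search_window`
#' of the nominal (blunt) junction; on failure the target is decremented and
#' the scan retried. The returned `join` is the 1-based index in
#' `acceptor_seq` where the prey continuation starts (for a blunt join,
#' `nominal` itself); `planted_mh` is the microhomology actually planted.
#' Among admissible occurrences the one nearest the nominal junction wins
#' (ties broken downstream), making the operation deterministic.
#'
#' @param bait_end_seq Bait-side sequence ending at the break.
#' @param acceptor_seq Oriented acceptor sequence to scan.
#' @param target_mh Target microhomology length (>= 0).
#' @param nominal 1-based index in `acceptor_seq` of the blunt junction
#'   (default 1: the sequence starts at the resected position).
#' @param search_window Maximum distance (bp) between the occurrence end and
#'   the nominal junction; defaults to the whole sequence.
#' @return `list(join = <index>, planted_mh = <int>)`.
#' @examples
#' anneal_join("GGGGACGT", "TTACGTTT", target_mh = 4)  # join 7, planted 4
#' @export
anneal_join <- function(bait_end_seq, acceptor_seq, target_mh,
                        nominal = 1L, search_window = nchar(acceptor_seq)) {
  if (nchar(acceptor_seq) == 0L) stop("empty acceptor_seq")
  if (target_mh < 0L) stop("target_mh must be >= 0")
  m <- as.integer(target_mh)
  anchor <- nominal - 1L  # where the MH would end for a blunt-adjacent join
  while (m > 0L) {
    if (m <= nchar(bait_end_seq)) {
      kmer <- substr(bait_end_seq, nchar(bait_end_seq) - m + 1L, nchar(bait_end_seq))
      starts <- gregexpr(kmer, acceptor_seq, fixed = TRUE)[[1L]]
      starts <- starts[starts > 0L]
      if (length(starts)) {
        ends <- starts + m - 1L
        ends <- ends[abs(ends - anchor) <= search_window]
        if (length(ends)) {
          d <- abs(ends - anchor)
          best <- ends[d == min(d)]
          return(list(join = max(best) + 1L, planted_mh = m))
        }
      }
    }
    m <- m - 1L
  }
  list(join = as.integer(nominal), planted_mh = 0L)
}

# sample one target MH length from the preset prior
sample_target_mh <- function(preset, n = 1L) {
  k <- as.integer(names(preset$mh_prior))
  sample(k, n, replace = TRUE, prob = preset$mh_prior)
}

apply_errors <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}

# maximal exact overlap at a realized junction: how far the bait match can be
# pushed forward into the read (germline continuation) and how far the prey
# match reaches back, on the clean (error-free) read
realized_overlap <- function(read, locus, bait_end, ins_len, join_pos, strand) {
  L <- nchar(read)
  # forward extension of the bait past its break
  f <- 0L
  maxf <- min(L, nchar(locus$bait_ref)) - bait_end
  while (f < maxf &&
         substr(read, bait_end + f + 1L, bait_end + f + 1L) ==
         substr(locus$bait_ref, bait_end + f + 1L, bait_end + f + 1L)) {
    f <- f + 1L
  }
  # backward extension of the prey before its continuation start
  cont <- bait_end + ins_len + 1L
  u <- 0L
  while (cont - 1L - u >= 1L) {
    ch <- prey_char(locus, join_pos, strand, delta = -(u + 1L))
    if (ch == "" || substr(read, cont - 1L - u, cont - 1L - u) != ch) break
    u <- u + 1L
  }
  i_star <- bait_end + f
  j_star <- cont - u
  max(0L, i_star - j_star + 1L)
}

#' Synthesize one read from a ground-truth record
#'
#' Non-germline reads are the exact concatenation
#' `bait_ref[1..bait_end_pos] + insertion + oriented prey from prey_join_pos`,
#' truncated to the configured read length; germline reads are the bait
#' reference continuing uninterrupted past the break. Substitution errors are
#' applied at `config$error_rate` unless `with_error = FALSE`.
#'
#' @param truth A one-row slice of a ground-truth table (see
#'   [simulate_library()]).
#' @param locus A `locus_map`.
#' @param config A `simulation_config`.
#' @param with_error Apply the substitution-error overlay?
#' @return A character scalar (the read sequence).
#' @export
synthesize_read <- function(truth, locus, config, with_error = TRUE) {
  rl <- config$read_length
  if (isTRUE(truth$is_germline)) {
    read <- substr(locus$bait_ref, 1L, rl)
  } else {
    bait_part <- substr(locus$bait_ref, 1L, truth$bait_end_pos)
    ins <- if (is.na(truth$insertion_seq)) "" else truth$insertion_seq
    rest <- rl - nchar(bait_part) - nchar(ins)
    prey_part <- if (rest > 0L) {
      prey_segment(locus, truth$prey_join_pos, truth$prey_strand, rest)
    } else ""
    read <- substr(paste0(bait_part, ins, prey_part), 1L, rl)
  }
  if (with_error) read <- apply_errors(read, config$error_rate) else read
}

#' Simulate an HTGTS-style junction library
#'
#' Generates `n_reads` unique templates (a deterministic
#' `round(germline_fraction * n_reads)` of them germline), appends Poisson
#' PCR duplicates of the junction templates, overlays substitution errors
#' independently on every emitted copy, and writes a FASTQ plus a
#' ground-truth TSV. `realized_mh` in the truth table is recomputed post hoc
#' as the maximal exact overlap at the realized junction on the clean read
#' (it can exceed the planted microhomology when flanks coincidentally
#' match). The same seed yields byte-identical outputs.
#'
#' @param config A `simulation_config` (carries the mandatory seed).
#' @param fastq_path,truth_path Output paths; `NULL` to skip writing.
#' @return Invisibly, `list(fastq, truth_path, truth = <data.frame>,
#'   reads = <named character>)`.
#' @export
simulate_library <- function(config, fastq_path = NULL, truth_path = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  locus <- config$locus
  preset <- config$preset
  win <- locus$analysis_window
  set.seed(config$seed)

  n <- config$n_reads
  n_germ <- round(config$germline_fraction * n)
  germ_idx <- if (n_germ > 0L) sort(sample.int(n, n_germ)) else integer(0L)
  is_germ <- seq_len(n) %in% germ_idx

  sw <- config$search_window
  margin <- config$read_length + sw
  lo_clamp <- win$start + margin
  hi_clamp <- win$end - margin
  bait_end_seq <- substr(locus$bait_ref, 1L, locus$bait_break)
  mh_margin <- length(preset$mh_prior) + 2L

  truth <- data.frame(
    read_id = sprintf("read%06d", seq_len(n)),
    is_germline = is_germ,
    bait_end_pos = ifelse(is_germ, NA_integer_, locus$bait_break),
    acceptor_break_pos = NA_integer_, resection_len = NA_integer_,
    prey_join_pos = NA_integer_, prey_strand = NA_character_,
    target_mh = NA_integer_, planted_mh = NA_integer_,
    realized_mh = NA_integer_, insertion_len = NA_integer_,
    insertion_seq = NA_character_, is_duplicate_of = NA_character_,
    stringsAsFactors = FALSE
  )

  jidx <- which(!is_germ)
  nj <- length(jidx)
  if (nj > 0L) {
    truth$acceptor_break_pos[jidx] <- sample_break(preset, locus, nj)
    truth$resection_len[jidx] <- sample_resection(preset, nj)
    truth$prey_strand[jidx] <- ifelse(stats::runif(nj) < preset$inversion_prob, "-", "+")
    has_ins <- stats::runif(nj) < preset$insertion_prob
    targets <- sample_target_mh(preset, nj)
    targets[has_ins] <- 0L
    truth$target_mh[jidx] <- targets
    truth$insertion_len[jidx] <- 0L
    truth$insertion_seq[jidx] <- ""

    for (k in seq_len(nj)) {
      i <- jidx[k]
      raw <- min(max(truth$acceptor_break_pos[i] + truth$resection_len[i], lo_clamp), hi_clamp)
      strand <- truth$prey_strand[i]
      if (has_ins[k]) {
        len <- sample.int(preset$ins_max, 1L)
        truth$insertion_len[i] <- len
        truth$insertion_seq[i] <- random_dna(len)
      }
      tm <- truth$target_mh[i]
      if (tm > 0L) {
        if (strand == "+") {
          ctx_lo <- raw - sw - mh_margin
          ctx <- substr(locus$prey_ref, prey_offset(locus, ctx_lo),
                        prey_offset(locus, raw + sw))
          nominal <- raw - ctx_lo + 1L
          res <- anneal_join(bait_end_seq, ctx, tm, nominal = nominal, search_window = sw)
          truth$prey_join_pos[i] <- ctx_lo + res$join - 1L
        } else {
          ctx_hi <- raw + sw + mh_margin
          ctx <- rc(substr(locus$prey_ref, prey_offset(locus, raw - sw),
                           prey_offset(locus, ctx_hi)))
          nominal <- ctx_hi - raw + 1L
          res <- anneal_join(bait_end_seq, ctx, tm, nominal = nominal, search_window = sw)
          truth$prey_join_pos[i] <- ctx_hi - res$join + 1L
        }
        truth$planted_mh[i] <- res$planted_mh
      } else {
        truth$prey_join_pos[i] <- raw
        truth$planted_mh[i] <- 0L
      }
    }
  }

  # clean reads, realized overlap, PCR duplicates, error overlay
  clean <- character(n)
  for (i in seq_len(n)) {
    clean[i] <- synthesize_read(truth[i, ], locus, config, with_error = FALSE)
    if (!is_germ[i]) {
      truth$realized_mh[i] <- realized_overlap(
        clean[i], locus, truth$bait_end_pos[i], truth$insertion_len[i],
        truth$prey_join_pos[i], truth$prey_strand[i]
      )
    }
  }

  if (config$duplicate_rate > 0 && nj > 0L) {
    n_extra <- stats::rpois(nj, config$duplicate_rate)
    dup_rows <- rep(jidx, n_extra)
    if (length(dup_rows)) {
      copy_no <- sequence(n_extra[n_extra > 0L])
      dups <- truth[dup_rows, ]
      dups$is_duplicate_of <- truth$read_id[dup_rows]
      dups$read_id <- sprintf("%s_d%d", truth$read_id[dup_rows], copy_no)
      truth <- rbind(truth, dups)
      clean <- c(clean, clean[dup_rows])
    }
  }
  rownames(truth) <- NULL

  reads <- vapply(clean, apply_errors, character(1L), rate = config$error_rate,
                  USE.NAMES = FALSE)
  names(reads) <- truth$read_id

  if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(list(fastq = fastq_path, truth_path = truth_path,
                 truth = truth, reads = reads))
}
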
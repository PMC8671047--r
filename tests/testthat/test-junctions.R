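test_that("bait anchoring: longest prefix, germline crossing, unanchored", {
  loc <- toy_locus()  # bait AAAACC|TTTT, break after 6, primer AAAA
  m <- match_bait("AAAACCGGGG", loc, germline_threshold = 3, tolerance = 0)
  expect_equal(m$match_len, 6L)
  expect_true(m$anchored)
  expect_false(m$crosses_break)
  m2 <- match_bait("AAAACCTTTT", loc, germline_threshold = 3)
  expect_equal(m2$match_len, 10L)
  expect_true(m2$crosses_break)
  m3 <- match_bait("GGGGGGGG", loc)
  expect_false(m3$anchored)
  # tolerance admits mismatches inside the prefix
  m4 <- match_bait("AAAACAGGGG", loc, tolerance = 1)
  expect_equal(m4$match_len, 6L)
  expect_error(match_bait("", loc), "empty read")
})

test_that("prey mapping finds the longest suffix on either strand", {
  loc <- toy_locus()  # prey TTTTCCGGGGAAAA
  cand <- map_prey("AAAACCGGGG", loc, min_len = 4)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$read_start_j, 5L)
  expect_equal(cand$prey_pos, 5L)  # CCGGGG at prey offset 5
  expect_equal(cand$strand, "+")
  expect_equal(cand$match_len, 6L)
  # suffix equal to the reverse complement of a prey segment maps to "-"
  cand_m <- map_prey("AAAACCGGAAAA", loc, min_len = 6)
  expect_equal(cand_m$strand, "-")
  expect_equal(cand_m$read_start_j, 5L)
  # no suffix of the required length matches
  expect_equal(nrow(map_prey("AAAATTTTTTTA", loc, min_len = 6)), 0L)
})

test_that("mapping agrees with an exhaustive per-position scan on random reads", {
  loc <- tiny_locus()
  set.seed(61)
  prey_rc <- oracle_rc(loc$prey_ref)
  for (i in 1:40) {
    # random reads that embed a genuine prey segment at a random split
    j0 <- sample(25:60, 1)
    off <- sample(100:1800, 1)
    strand <- sample(c("+", "-"), 1)
    hay <- if (strand == "+") loc$prey_ref else prey_rc
    read <- paste0(substr(loc$bait_ref, 1, j0 - 1L), substr(hay, off, off + 80L - j0))
    cand <- map_prey(read, loc)
    # oracle: smallest j whose suffix occurs anywhere
    found <- NULL
    for (j in seq_len(nchar(read) - 15L + 1L)) {
      suf <- substr(read, j, nchar(read))
      hp <- oracle_find_all(suf, loc$prey_ref)
      hm <- oracle_find_all(suf, prey_rc)
      if (length(hp) + length(hm) > 0L) {
        found <- list(j = j, n = length(hp) + length(hm))
        break
      }
    }
    expect_false(is.null(found))
    expect_equal(cand$read_start_j[1L], found$j)
    expect_equal(nrow(cand), found$n)
  }
})

test_that("junction resolution: microhomology, blunt and insertion splits", {
  bait6 <- list(match_len = 6L, anchored = TRUE)
  prey <- list(read_start_j = 5L, prey_pos = 5L, strand = "+", match_len = 6L)
  jr <- resolve_junction(bait6, prey, "AAAACCGGGG")
  expect_equal(jr$mh_len, 2L)
  expect_equal(jr$insertion_len, 0L)
  expect_equal(jr$prey_pos, 7L)  # maximal bait extension: pos advanced past MH
  bait4 <- list(match_len = 4L, anchored = TRUE)
  jr2 <- resolve_junction(bait4, prey, "AAAACCGGGG")
  expect_equal(jr2$mh_len, 0L)
  expect_equal(jr2$insertion_len, 0L)
  expect_equal(jr2$prey_pos, 5L)
  prey7 <- list(read_start_j = 7L, prey_pos = 7L, strand = "+", match_len = 4L)
  jr3 <- resolve_junction(bait4, prey7, "AAAATTGGGG")
  expect_equal(jr3$insertion_len, 2L)
  expect_equal(jr3$insertion_seq, "TT")
  expect_equal(jr3$mh_len, 0L)
  # minus strand: position advanced downstream in reading direction
  prey_m <- list(read_start_j = 5L, prey_pos = 100L, strand = "-", match_len = 6L)
  expect_equal(resolve_junction(bait6, prey_m, "AAAACCGGGG")$prey_pos, 98L)
  expect_error(resolve_junction(bait6, list(read_start_j = 0L), "AAAA"),
               "read_start_j")
  expect_error(resolve_junction(list(match_len = 2L, anchored = FALSE), prey, "AAAA"),
               "not anchored")
  # mutual exclusivity holds across arbitrary splits
  for (i in 1:20) {
    b <- list(match_len = sample(1:40, 1), anchored = TRUE)
    p <- list(read_start_j = sample(1:40, 1), prey_pos = 500L, strand = "+")
    r <- resolve_junction(b, p, strrep("A", 60))
    expect_equal(r$mh_len * r$insertion_len, 0L)
  }
})

test_that("deduplication marks exact-key repeats, keeping the first read_id", {
  tab <- rbind(
    jrow("r2", prey_pos = 100L, strand = "+", mh_len = 1L),
    jrow("r1", prey_pos = 100L, strand = "+", mh_len = 1L),
    jrow("r3", prey_pos = 101L, strand = "+", mh_len = 1L),
    jrow("r4", prey_pos = 100L, strand = "-", mh_len = 1L)
  )
  out <- deduplicate(tab)
  expect_equal(out$status[out$read_id == "r1"], "junction")
  expect_equal(out$status[out$read_id == "r2"], "duplicate")
  expect_equal(out$status[out$read_id == "r3"], "junction")  # 1-bp offset kept
  expect_equal(out$status[out$read_id == "r4"], "junction")  # other strand kept
  expect_equal(deduplicate(tab[0, ]), tab[0, ])
})

test_that("call_library statuses match truth-derived expectations on an
           error-free library", {
  loc <- tiny_locus()
  cfg <- simulation_config(loc, "aej", n_reads = 150, seed = 42,
                           read_length = 80, error_rate = 0,
                           duplicate_rate = 0.3, germline_fraction = 0.2)
  sim <- simulate_library(cfg)
  res <- call_library(sim$reads, loc)
  expect_equal(sum(res$counts), length(sim$reads))
  oracle <- lapply(sim$reads, oracle_call, locus = loc)
  expected <- oracle_statuses(oracle, names(sim$reads))
  expect_equal(res$table$status, unname(expected))
  # simulated PCR copies are always among the records not kept as junctions
  pcr <- !is.na(sim$truth$is_duplicate_of)
  expect_true(all(res$table$status[pcr] == "duplicate"))
})

test_that("degenerate libraries: empty, all-germline, all-unmapped", {
  loc <- tiny_locus()
  dir <- withr::local_tempdir()
  empty_fq <- file.path(dir, "empty.fastq")
  file.create(empty_fq)
  res <- call_library(empty_fq, loc)
  expect_equal(nrow(res$table), 0L)
  expect_equal(sum(res$counts), 0L)

  germ <- simulate_library(simulation_config(loc, "cnhej", n_reads = 30, seed = 3,
                                             read_length = 80, error_rate = 0,
                                             germline_fraction = 1))
  res_g <- call_library(germ$reads, loc)
  expect_equal(unname(res_g$counts["germline"]), 30L)
  expect_equal(sum(res_g$counts), 30L)

  set.seed(8)
  garbage <- vapply(1:25, function(i) {
    paste0(loc$bait_primer,
           paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE), collapse = ""))
  }, character(1L))
  names(garbage) <- sprintf("g%02d", 1:25)
  res_u <- call_library(garbage, loc)
  expect_equal(sum(res_u$counts), 25L)
  expect_equal(unname(res_u$counts["junction"]), 0L)
  expect_gt(res_u$counts["unmapped"], 0L)
})

test_that("malformed input is rejected with a clear format error", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "reads.fa")
  writeLines(c(">r1", "ACGTACGT"), fa)
  expect_error(call_library(fa, tiny_locus()), "FASTA")
})
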
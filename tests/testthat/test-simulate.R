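test_that("preset priors are valid and overridable", {
  for (nm in c("cnhej", "aej")) {
    p <- pathway_preset(nm)
    expect_equal(sum(p$mh_prior), 1)
    expect_true(all(p$mh_prior >= 0))
  }
  expect_equal(pathway_preset("cnhej", resection_mean = 600)$resection_mean, 600)
  expect_error(pathway_preset("aej", mh_prior = c(0.5, 0.4)), "sum to 1")
  expect_error(pathway_preset("aej", bogus = 1), "unknown preset field")
})

test_that("acceptor breaks are core-centered, clamped and mean-accurate", {
  loc <- default_locus()
  mid <- (loc$core_acceptor$start + loc$core_acceptor$end) %/% 2L
  degenerate <- pathway_preset("cnhej", break_spread = 0)
  expect_equal(sample_break(degenerate, loc, 5L), rep(mid, 5L))
  set.seed(11)
  pos <- sample_break(pathway_preset("cnhej"), loc, 1e4L)
  se <- 700 / sqrt(1e4)
  expect_lt(abs(mean(pos) - mid), 3 * se)
  # huge spread: clamping keeps every draw inside the window
  wild <- sample_break(pathway_preset("cnhej", break_spread = 5e4), loc, 2000L)
  expect_true(all(gi_contains(loc$analysis_window, wild)))
})

test_that("resection lengths are geometric with the configured mean", {
  expect_equal(sample_resection(pathway_preset("cnhej", resection_mean = 0), 10L),
               integer(10L))
  set.seed(12)
  r <- sample_resection(pathway_preset("aej", resection_mean = 1000), 1e5L)
  expect_true(all(r >= 0) && all(r == floor(r)))
  se <- sqrt(1000 * 1001) / sqrt(1e5)
  expect_lt(abs(mean(r) - 1000), 3 * se)
})

test_that("anneal_join plants the requested microhomology or decrements", {
  # terminal 4-mer ACGT present: join right after its occurrence
  res <- anneal_join("GGGGACGT", "TTACGTTT", target_mh = 4)
  expect_equal(res, list(join = 7L, planted_mh = 4L))
  # blunt request: join at the nominal resected position
  expect_equal(anneal_join("GGGGACGT", "TTACGTTT", target_mh = 0, nominal = 3L),
               list(join = 3L, planted_mh = 0L))
  # terminal 3-mer CGT absent, 2-mer GT present: decrement semantics
  acceptor <- "TTGTTTTT"
  expect_false(grepl("CGT", acceptor, fixed = TRUE))
  expect_true(grepl("GT", acceptor, fixed = TRUE))
  res <- anneal_join("GGGGACGT", acceptor, target_mh = 3)
  expect_equal(res$planted_mh, 2L)
  expect_equal(substr(acceptor, res$join - 2L, res$join - 1L), "GT")
  expect_error(anneal_join("ACGT", "", 2), "empty")
})

test_that("synthesized reads are exact concatenations when error-free", {
  loc <- tiny_locus()
  cfg <- simulation_config(loc, "cnhej", n_reads = 10, seed = 1,
                           read_length = 80, error_rate = 0)
  truth <- data.frame(is_germline = FALSE, bait_end_pos = loc$bait_break,
                      prey_join_pos = 2000L, prey_strand = "+",
                      insertion_seq = "", stringsAsFactors = FALSE)
  read <- synthesize_read(truth, loc, cfg)
  bait_part <- substr(loc$bait_ref, 1, loc$bait_break)
  expect_equal(nchar(read), 80L)
  expect_equal(substr(read, 1, loc$bait_break), bait_part)
  off <- 2000L - loc$analysis_window$start + 1L
  expect_equal(substr(read, loc$bait_break + 1L, 80L),
               substr(loc$prey_ref, off, off + 80L - loc$bait_break - 1L))
  # inverted capture reads the reverse complement walking upstream
  truth$prey_strand <- "-"
  read_m <- synthesize_read(truth, loc, cfg)
  expect_equal(substr(read_m, loc$bait_break + 1L, loc$bait_break + 1L),
               chartr("ACGT", "TGCA", substr(loc$prey_ref, off, off)))
  # germline reads continue uninterrupted past the break
  germ <- synthesize_read(data.frame(is_germline = TRUE), loc, cfg)
  expect_equal(germ, substr(loc$bait_ref, 1, 80))
})

test_that("substitution errors occur at the configured rate", {
  loc <- tiny_locus()
  cfg <- simulation_config(loc, "cnhej", n_reads = 10, seed = 1,
                           read_length = 100, error_rate = 0.01)
  truth <- data.frame(is_germline = TRUE)
  clean <- synthesize_read(truth, loc, cfg, with_error = FALSE)
  set.seed(33)
  n_bases <- 1e5L
  subs <- sum(vapply(seq_len(n_bases / 100L), function(i) {
    noisy <- synthesize_read(truth, loc, cfg, with_error = TRUE)
    sum(utf8ToInt(noisy) != utf8ToInt(clean))
  }, numeric(1L)))
  se <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(subs - n_bases * 0.01), 3 * se)
})

test_that("simulate_library keeps its bookkeeping contracts", {
  loc <- tiny_locus()
  cfg <- simulation_config(loc, "cnhej", n_reads = 100, seed = 5,
                           read_length = 80, germline_fraction = 0.2,
                           duplicate_rate = 0)
  sim <- simulate_library(cfg)
  expect_equal(sum(sim$truth$is_germline), 20L)
  expect_true(all(is.na(sim$truth$is_duplicate_of)))
  expect_equal(length(sim$reads), 100L)
  # junction fields and germline flag are mutually exclusive
  j <- !sim$truth$is_germline
  expect_false(anyNA(sim$truth$prey_join_pos[j]))
  expect_true(all(is.na(sim$truth$prey_join_pos[!j])))
  # duplicates reference their template
  cfg2 <- simulation_config(loc, "cnhej", n_reads = 100, seed = 5,
                            read_length = 80, duplicate_rate = 0.5)
  sim2 <- simulate_library(cfg2)
  dups <- sim2$truth[!is.na(sim2$truth$is_duplicate_of), ]
  expect_gt(nrow(dups), 0L)
  expect_true(all(dups$is_duplicate_of %in% sim2$truth$read_id))
})

test_that("the same seed reproduces a library byte-for-byte", {
  loc <- tiny_locus()
  dir <- withr::local_tempdir()
  paths1 <- c(file.path(dir, "a.fastq"), file.path(dir, "a.tsv"))
  paths2 <- c(file.path(dir, "b.fastq"), file.path(dir, "b.tsv"))
  cfg <- simulation_config(loc, "aej", n_reads = 120, seed = 77, read_length = 80)
  simulate_library(cfg, paths1[1], paths1[2])
  simulate_library(cfg, paths2[1], paths2[2])
  expect_equal(unname(tools::md5sum(paths1)), unname(tools::md5sum(paths2)))
})

test_that("error-free reads contain bait prefix and prey suffix exactly, and
           truth realized_mh equals a brute-force maximal overlap", {
  loc <- tiny_locus()
  cfg <- simulation_config(loc, "aej", n_reads = 300, seed = 21,
                           read_length = 80, error_rate = 0, duplicate_rate = 0,
                           germline_fraction = 0)
  sim <- simulate_library(cfg)
  prey_rc <- oracle_rc(loc$prey_ref)
  for (k in seq_along(sim$reads)) {
    read <- sim$reads[[k]]
    tr <- sim$truth[k, ]
    expect_equal(substr(read, 1, tr$bait_end_pos),
                 substr(loc$bait_ref, 1, tr$bait_end_pos))
    # prey suffix occurs in the reference (strand per truth)
    suf <- substr(read, tr$bait_end_pos + tr$insertion_len + 1L, nchar(read))
    hay <- if (tr$prey_strand == "+") loc$prey_ref else prey_rc
    expect_true(grepl(suf, hay, fixed = TRUE))
    # realized MH is the maximal overlap found by split enumeration
    o <- oracle_call(read, loc)
    expect_equal(o$status, "junction")
    expect_equal(o$mh_len, tr$realized_mh)
  }
})

test_that("longer resection pushes joins into the distal zone; A-EJ uses more MH", {
  loc <- default_locus()
  distal_frac <- vapply(c(150, 600, 1200), function(m) {
    cfg <- simulation_config(loc, pathway_preset("aej", resection_mean = m),
                             n_reads = 5000, seed = 100 + m, error_rate = 0)
    tr <- simulate_library(cfg)$truth
    tr <- tr[!tr$is_germline & is.na(tr$is_duplicate_of), ]
    mean(locate(tr$prey_join_pos, loc) == "distal")
  }, numeric(1L))
  expect_true(all(diff(distal_frac) > 0))
  mean_mh <- vapply(c("cnhej", "aej"), function(nm) {
    cfg <- simulation_config(loc, nm, n_reads = 5000, seed = 31, error_rate = 0)
    tr <- simulate_library(cfg)$truth
    mean(tr$realized_mh[!tr$is_germline])
  }, numeric(1L))
  expect_gt(mean_mh[["aej"]], mean_mh[["cnhej"]])
})
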
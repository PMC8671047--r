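#' End-joining pathway presets
#'
#' Parameter bundles describing how a repair pathway shapes junctions:
#' `resection_mean` (expected resected bases on the acceptor end; geometric),
#' `mh_prior` (categorical prior over target microhomology lengths
#' `0..length(mh_prior)-1`), `insertion_prob` / `ins_max` (untemplated
#' insertions), `inversion_prob` (probability a join is captured in inverted
#' orientation) and `break_spread` (sd, in bp, of acceptor break placement
#' around the core-Salpha midpoint).
#'
#' The two built-in presets encode the qualitative c-NHEJ vs A-EJ contrast:
#' c-NHEJ joins are mostly blunt or 1-bp MH with short resection and a
#' deletion-preferred orientation mix; A-EJ joins carry the 1-5 bp MH typical
#' of microhomology-mediated end joining, much longer resection, and a less
#' deletion-biased orientation mix. These are modeling choices, not measured
#' distributions (see the methods vignette).
#'
#' @param name `"cnhej"` or `"aej"`.
#' @param ... Named overrides for any preset field.
#' @return An object of class `pathway_preset`.
#' @examples
#' pathway_preset("aej")
#' pathway_preset("cnhej", resection_mean = 600)
#' @export
pathway_preset <- function(name = c("cnhej", "aej"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    cnhej = list(
      name = "cnhej",
      resection_mean = 150,
      mh_prior = c(`0` = 0.45, `1` = 0.30, `2` = 0.12, `3` = 0.07, `4` = 0.04, `5` = 0.02),
      insertion_prob = 0.08,
      ins_max = 6L,
      inversion_prob = 0.10,
      break_spread = 700
    ),
    aej = list(
      name = "aej",
      resection_mean = 1200,
      mh_prior = c(`0` = 0.10, `1` = 0.20, `2` = 0.22, `3` = 0.20, `4` = 0.15,
                   `5` = 0.08, `6` = 0.03, `7` = 0.02),
      insertion_prob = 0.04,
      ins_max = 6L,
      inversion_prob = 0.25,
      break_spread = 700
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  validate_preset(structure(p, class = "pathway_preset"))
}

validate_preset <- function(p) {
  if (abs(sum(p$mh_prior) - 1) > 1e-8) stop("mh_prior must sum to 1")
  if (is.null(names(p$mh_prior))) names(p$mh_prior) <- as.character(seq_along(p$mh_prior) - 1L)
  probs <- c(p$insertion_prob, p$inversion_prob, p$mh_prior)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$resection_mean < 0) stop("resection_mean must be >= 0")
  if (p$break_spread < 0) stop("break_spread must be >= 0")
  p
}

#' @export
print.pathway_preset <- function(x, ...) {
  cat(sprintf("<pathway_preset> %s: resection_mean=%g, inversion_prob=%g, insertion_prob=%g\n",
              x$name, x$resection_mean, x$inversion_prob, x$insertion_prob))
  cat("  mh_prior:", paste(sprintf("%s=%.2f", names(x$mh_prior), x$mh_prior), collapse = " "), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' @param locus A `locus_map`.
#' @param preset A `pathway_preset` (or preset name).
#' @param n_reads Number of unique template reads to simulate.
#' @param seed Integer RNG seed (mandatory: libraries are reproducible
#'   fixtures).
#' @param read_length Read length in nt; must exceed the bait primer by at
#'   least 10 nt.
#' @param germline_fraction Proportion of reads that are unbroken germline
#'   bait continuations (the residue an AflII-style blocking step leaves
#'   behind); the realized count is `round(germline_fraction * n_reads)`.
#' @param duplicate_rate Expected extra PCR copies per unique junction read
#'   (Poisson).
#' @param error_rate Per-base substitution probability.
#' @param search_window Half-width (bp) of the microhomology annealing scan
#'   around the resected position.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(locus, preset, n_reads, seed,
                              read_length = 150L,
                              germline_fraction = 0.15,
                              duplicate_rate = 0.2,
                              error_rate = 0.001,
                              search_window = 50L) {
  if (is.character(preset)) preset <- pathway_preset(preset)
  stopifnot(inherits(locus, "locus_map"), inherits(preset, "pathway_preset"))
  n_reads <- as.integer(n_reads)
  read_length <- as.integer(read_length)
  if (is.na(n_reads) || n_reads <= 0L) stop("n_reads must be a positive integer")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (read_length <= nchar(locus$bait_primer) + 10L) {
    stop("read_length must exceed |bait_primer| + 10")
  }
  if (read_length > nchar(locus$bait_ref)) {
    stop("bait_ref shorter than read_length: germline reads cannot be synthesized")
  }
  for (f in c(germline_fraction, duplicate_rate, error_rate)) {
    if (f < 0) stop("fractions and rates must be non-negative")
  }
  if (germline_fraction > 1 || error_rate > 1) stop("fractions must be <= 1")
  structure(
    list(locus = locus, preset = preset, n_reads = n_reads,
         read_length = read_length, germline_fraction = germline_fraction,
         duplicate_rate = duplicate_rate, error_rate = error_rate,
         search_window = as.integer(search_window), seed = as.integer(seed)),
    class = "simulation_config"
  )
}
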
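# Figure-2-style readouts from junction tables: orientation classification,
# pooled binned landscapes, deletion/inversion ratio, long-resection
# percentage, MH spectrum, replicate t-tests, normalized CSR efficiency.

#' Classify junction orientation
#'
#' A junction whose prey reads in the locus-forward (telomere-to-centromere)
#' orientation and falls in the analysis window is a productive deletional
#' join; the opposite orientation in the window is an inversional join;
#' junctions outside the window are `other`.
#'
#' @param table A junction table (rows with `status == "junction"` are
#'   classified; pass a single-row data.frame for one record).
#' @param locus A `locus_map`.
#' @return Character vector (`NA` for non-junction rows) in
#'   `{"deletion","inversion","other"}`.
#' @export
classify_orientation <- function(table, locus) {
  if (is.null(table) || nrow(table) == 0L) return(character(0L))
  if (nrow(table) == 1L && !is.na(table$status) && table$status != "junction") {
    stop("record does not have status 'junction'")
  }
  out <- rep(NA_character_, nrow(table))
  is_j <- table$status == "junction"
  in_win <- gi_contains(locus$analysis_window, table$prey_pos)
  out[is_j & in_win & table$strand == "+"] <- "deletion"
  out[is_j & in_win & table$strand == "-"] <- "inversion"
  out[is_j & !in_win] <- "other"
  out
}

#' Pool junction tables across libraries
#'
#' Concatenates tables, preserving per-library provenance in a `library`
#' column; no cross-library deduplication is performed (each library is an
#' independent experiment).
#'
#' @param tables A named (or unnamed) list of junction tables.
#' @param windows Optional list of `genomic_interval`s, one per table; an
#'   error is raised if they differ.
#' @return The pooled table with a `library` column and attribute
#'   `n_pooled_libraries`.
#' @export
pool <- function(tables, windows = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (!is.null(windows)) {
    ref <- windows[[1L]]
    same <- vapply(windows, function(w) {
      w$chrom == ref$chrom && w$start == ref$start && w$end == ref$end
    }, logical(1L))
    if (!all(same)) stop("cannot pool: analysis windows differ across tables")
  }
  nms <- names(tables)
  if (is.null(nms)) nms <- sprintf("lib%d", seq_along(tables))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    t$library <- nms[i]
    t
  }))
  rownames(out) <- NULL
  attr(out, "n_pooled_libraries") <- length(tables)
  out
}

#' Binned deletion/inversion junction landscape
#'
#' Counts deletional and inversional junctions per bin over the analysis
#' window; junctions outside the window are excluded from the bins and
#' counted separately.
#'
#' @param table A junction table.
#' @param locus A `locus_map`.
#' @return An object of class `binned_landscape`: a data.frame with `bin`,
#'   `start`, `end`, `del_count`, `inv_count`, plus attributes
#'   `n_outside_window` and `n_pooled_libraries`.
#' @export
bin_landscape <- function(table, locus) {
  win <- locus$analysis_window
  nb <- n_bins(win, locus$bin_width)
  cls <- classify_orientation(table, locus)
  bins <- bin_index(table$prey_pos, win, locus$bin_width)
  del <- tabulate(bins[cls %in% "deletion"], nbins = nb)
  inv <- tabulate(bins[cls %in% "inversion"], nbins = nb)
  out <- data.frame(
    bin = seq_len(nb),
    start = win$start + (seq_len(nb) - 1L) * locus$bin_width,
    end = win$start + seq_len(nb) * locus$bin_width - 1L,
    del_count = del, inv_count = inv
  )
  attr(out, "n_outside_window") <- sum(cls %in% "other")
  attr(out, "n_pooled_libraries") <- attr(table, "n_pooled_libraries") %||% 1L
  class(out) <- c("binned_landscape", "data.frame")
  out
}

#' @export
print.binned_landscape <- function(x, ...) {
  cat(sprintf("<binned_landscape> %d bins; %d deletion / %d inversion junctions in window; %d outside\n",
              nrow(x), sum(x$del_count), sum(x$inv_count),
              attr(x, "n_outside_window")))
  invisible(x)
}

#' Deletion/inversion ratio
#'
#' @param table A junction table.
#' @param locus A `locus_map`.
#' @return `list(ratio, n_deletion, n_inversion, undefined)`; `ratio` is `NA`
#'   with `undefined = TRUE` when there are no inversional junctions.
#' @export
deletion_inversion_ratio <- function(table, locus) {
  cls <- classify_orientation(table, locus)
  nd <- sum(cls %in% "deletion")
  ni <- sum(cls %in% "inversion")
  list(
    ratio = if (ni == 0L) NA_real_ else nd / ni,
    n_deletion = nd, n_inversion = ni, undefined = ni == 0L
  )
}

#' Long-resection percentage
#'
#' Percentage of in-window junctions whose prey position falls in the distal
#' (Calpha-side) acceptor region; reaching it requires the acceptor break to
#' have been resected out of core Salpha. The denominator is all in-window
#' junctions, deletional and inversional.
#'
#' @param table A junction table.
#' @param locus A `locus_map`.
#' @return Percentage in `[0, 100]`, or `NA` when no junction lies in the
#'   window.
#' @export
long_resection_fraction <- function(table, locus) {
  cls <- classify_orientation(table, locus)
  in_win <- cls %in% c("deletion", "inversion")
  if (!any(in_win)) return(NA_real_)
  100 * sum(locate(table$prey_pos[in_win], locus) == "distal") / sum(in_win)
}

#' Microhomology spectrum
#'
#' Proportion of junctions at each microhomology length `0..cap` (lengths
#' `>= cap` pooled into the `cap` class). Insertion-bearing junctions are by
#' default reported as their own `ins` class, preserving the blunt (MH = 0)
#' versus MH distinction; set `insertions = "mh0"` to fold them into MH 0.
#'
#' @param table A junction table (rows with `status == "junction"`).
#' @param cap Largest MH length reported separately.
#' @param insertions `"separate"` or `"mh0"`.
#' @return Named numeric vector of proportions (sums to 1 when junctions
#'   exist); `attr(, "n")` is the junction count. Empty tables return an
#'   all-`NA` spectrum flagged with `attr(, "empty") = TRUE`.
#' @export
mh_spectrum <- function(table, cap = 10L, insertions = c("separate", "mh0")) {
  insertions <- match.arg(insertions)
  j <- table[table$status == "junction", , drop = FALSE]
  labs <- c(as.character(0:cap), if (insertions == "separate") "ins")
  if (nrow(j) == 0L) {
    out <- stats::setNames(rep(NA_real_, length(labs)), labs)
    attr(out, "n") <- 0L
    attr(out, "empty") <- TRUE
    return(out)
  }
  mh <- pmin(j$mh_len, cap)
  cls <- as.character(mh)
  if (insertions == "separate") cls[j$insertion_len > 0L] <- "ins"
  tab <- table(factor(cls, levels = labs))
  out <- as.numeric(tab) / nrow(j)
  names(out) <- labs
  attr(out, "n") <- nrow(j)
  attr(out, "empty") <- FALSE
  out
}

#' Two-sample Student's t-test on replicate values
#'
#' Pooled-variance two-sided Student's t by default (Welch behind a flag).
#' Degenerate inputs follow fixed conventions: two zero-variance groups with
#' equal means give `t = 0, p = 1`; with unequal means, a flagged infinite t
#' with `p = 0`.
#'
#' @param a,b Numeric replicate values, each of length >= 2.
#' @param welch Use Welch's unequal-variance t instead.
#' @return `list(statistic, df, p.value, infinite)`.
#' @export
compare_groups_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) {
      return(list(statistic = 0, df = length(a) + length(b) - 2L,
                  p.value = 1, infinite = FALSE))
    }
    return(list(statistic = sign(d) * Inf, df = length(a) + length(b) - 2L,
                p.value = 0, infinite = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, infinite = FALSE)
}

#' Normalize class-switch efficiency to controls
#'
#' `100 * sample_pct / mean(control_pcts)`: a sample switching at the control
#' mean reads out as 100.
#'
#' @param sample_pct Surface-isotype-positive percentage of the sample.
#' @param control_pcts Control percentages (e.g. scramble controls).
#' @return Normalized percentage.
#' @export
normalize_csr <- function(sample_pct, control_pcts) {
  if (length(control_pcts) == 0L) stop("no control values")
  if (any(c(sample_pct, control_pcts) < 0 | c(sample_pct, control_pcts) > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  m <- mean(control_pcts)
  if (m <= 0) stop("control mean must be > 0")
  100 * sample_pct / m
}

#' Normalize Cas9-initiated switching to transfection efficiency
#'
#' `100 * igx_pct / gfp24_pct`: switching is expressed relative to the GFP+
#' fraction 24 h after transfection.
#'
#' @param igx_pct Surface-isotype-positive percentage.
#' @param gfp24_pct GFP-positive percentage at 24 h.
#' @return Normalized percentage.
#' @export
normalize_cas9_csr <- function(igx_pct, gfp24_pct) {
  if (gfp24_pct <= 0) stop("gfp24_pct must be > 0")
  if (igx_pct < 0 || igx_pct > 100 || gfp24_pct > 100) {
    stop("percentages must lie in [0, 100]")
  }
  100 * igx_pct / gfp24_pct
}

#' Per-library summary statistics
#'
#' One row per junction table: junction totals, orientation counts and ratio,
#' long-resection percentage, in-window percentage, and mean MH length.
#'
#' @param table A junction table.
#' @param locus A `locus_map`.
#' @return A one-row data.frame.
#' @export
summary_stats <- function(table, locus) {
  r <- deletion_inversion_ratio(table, locus)
  n_junction <- sum(table$status == "junction")
  in_win <- r$n_deletion + r$n_inversion
  mh <- table$mh_len[table$status == "junction"]
  data.frame(
    n_reads = nrow(table),
    n_junction = n_junction,
    n_deletion = r$n_deletion,
    n_inversion = r$n_inversion,
    del_inv_ratio = r$ratio,
    pct_long_resection = long_resection_fraction(table, locus),
    pct_window_of_total = if (n_junction == 0L) NA_real_ else 100 * in_win / n_junction,
    mean_mh = if (n_junction == 0L) NA_real_ else mean(mh)
  )
}
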
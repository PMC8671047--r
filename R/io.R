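# Junction-table and BED I/O.

JUNCTION_TSV_COLS <- c("read_id", "status", "bait_end_i", "prey_chrom",
                       "prey_pos", "strand", "prey_match_len", "mh_len",
                       "insertion_len", "insertion_seq")

#' Write a junction table as TSV
#' @param table A junction table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junction_table <- function(table, path) {
  cols <- intersect(JUNCTION_TSV_COLS, names(table))
  cols <- c(cols, setdiff(names(table), cols))
  utils::write.table(table[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a junction table TSV
#' @param path Path written by [write_junction_table()].
#' @return A junction table data.frame.
#' @export
read_junction_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("read_id", "status") %in% names(tab))) {
    stop("not a junction table (missing read_id/status columns): ", path)
  }
  if ("insertion_seq" %in% names(tab)) {
    tab$insertion_seq[is.na(tab$insertion_seq) & tab$status == "junction"] <- ""
  }
  tab
}

#' Export junction positions as BED
#'
#' BED is 0-based, half-open: `start = prey_pos - 1`, `end = prey_pos` (the
#' subtraction applies to the start only). Only junction-status records are
#' exported; the score column carries the microhomology length.
#'
#' @param table A junction table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_junctions_bed <- function(table, path) {
  j <- table[table$status == "junction", , drop = FALSE]
  bed <- data.frame(
    chrom = j$prey_chrom,
    start = j$prey_pos - 1L,
    end = j$prey_pos,
    name = j$read_id,
    score = j$mh_len,
    strand = j$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binned landscape as TSV
#' @param landscape A [bin_landscape()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.table(as.data.frame(landscape), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
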
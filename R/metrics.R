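# Native assembly statistics (QUAST-style length metrics subset).

length_thresholds <- c(0L, 1000L, 5000L, 10000L, 25000L, 50000L)

#' Assembly length statistics
#'
#' Computes, natively, the length-based subset of the usual assembly
#' report: per-threshold sequence counts and total lengths (thresholds 0,
#' 1,000, 5,000, 10,000, 25,000, 50,000 bp), largest sequence, total
#' length, N50, N90, and Ns per 100 kbp. N50 is the length of the sequence
#' at which the descending cumulative length first reaches half the total
#' (N90 analogous at 90%); Ns are counted case-insensitively.
#'
#' @param sequences Named character vector, `DNAStringSet`, or the path of
#'   a FASTA file.
#' @param min_length Optional minimum sequence length applied before any
#'   statistic is computed (default 0 = use every sequence).
#' @return An `assembly_stats` list.
#' @export
assembly_stats <- function(sequences, min_length = 0L) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences))) {
    sequences <- read_fasta(sequences)
  }
  if (methods::is(sequences, "DNAStringSet")) {
    lens <- Biostrings::width(sequences)
    n_count <- sum(Biostrings::letterFrequency(sequences, "N"))
  } else {
    sequences <- as.character(sequences)
    lens <- nchar(sequences)
    n_count <- sum(lengths(regmatches(sequences,
                                      gregexpr("[Nn]", sequences))))
  }
  if (!length(lens)) stop("assembly_stats: no sequences")
  keep <- lens >= min_length
  lens <- lens[keep]
  if (!length(lens)) stop("assembly_stats: no sequences >= min_length")

  counts <- vapply(length_thresholds, function(t) sum(lens >= t), integer(1))
  totals <- vapply(length_thresholds, function(t) sum(as.double(lens[lens >= t])),
                   numeric(1))
  names(counts) <- names(totals) <- paste0(">=", length_thresholds)

  total <- sum(as.double(lens))
  srt <- sort(lens, decreasing = TRUE)
  cum <- cumsum(as.double(srt))
  n50 <- srt[which(cum >= total / 2)[1L]]
  n90 <- srt[which(cum >= 0.9 * total)[1L]]

  structure(list(
    n_contigs = counts,
    total_length = totals,
    largest = max(lens),
    total = total,
    n50 = n50,
    n90 = n90,
    ns_per_100kbp = n_count / total * 1e5,
    min_length = as.integer(min_length)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("assembly_stats:", x$n_contigs[[">=0"]], "sequences, total",
      format(x$total, big.mark = ","), "bp; N50",
      format(x$n50, big.mark = ","), "N90", format(x$n90, big.mark = ","),
      sprintf("; %.2f Ns per 100 kbp\n", x$ns_per_100kbp))
  invisible(x)
}

#' Fold-change report between two assemblies
#'
#' Reports `after / before` ratios for N50, N90, largest sequence, total
#' length and sequence count; no judgement is applied, but a decrease in
#' N50 is flagged with a warning.
#'
#' @param before,after [assembly_stats()] results.
#' @return List of fold changes.
#' @export
compare_stats <- function(before, after) {
  stopifnot(inherits(before, "assembly_stats"),
            inherits(after, "assembly_stats"))
  out <- list(
    n50 = after$n50 / before$n50,
    n90 = after$n90 / before$n90,
    largest = after$largest / before$largest,
    total = after$total / before$total,
    n_contigs = after$n_contigs[[">=0"]] / before$n_contigs[[">=0"]]
  )
  if (out$n50 < 1) {
    warning("compare_stats: N50 decreased (fold-change ",
            format(out$n50, digits = 4), ")")
  }
  out
}
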
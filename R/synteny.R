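# Synteny-block handling: alignment-block filters, reciprocal-style
# overlap, successive intersection of homologous regions across genomes,
# and construction of indexed three-way synteny blocks.

#' Filter alignment blocks by length and identity
#'
#' Keeps blocks whose reference-side length is at least `min_len` bp and
#' whose percent identity is at least `min_idy` (the published filters
#' exclude blocks "less than 2000 bp" and "below 90%", so both boundaries
#' are inclusive on the keep side). Idempotent.
#'
#' @param blocks An `alignment_blocks` data frame (see [read_coords()]).
#' @param min_len Minimum reference interval length (bp).
#' @param min_idy Minimum percent identity.
#' @return The filtered `alignment_blocks`.
#' @export
filter_blocks <- function(blocks, min_len = 2000L, min_idy = 90) {
  keep <- (blocks$ref_end - blocks$ref_start + 1L) >= min_len &
    blocks$identity >= min_idy
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

overlap_bp <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L)
}

#' Overlap fraction of two intervals
#'
#' `|a intersect b| / min(|a|, |b|)` on closed 1-based intervals; 0 when
#' disjoint. Both intervals must sit on the same chromosome: if chromosome
#' labels are supplied and differ, an error is raised (callers pre-group by
#' chromosome).
#'
#' @param a,b Numeric length-2 vectors `c(start, end)`.
#' @param chrom_a,chrom_b Optional chromosome labels to cross-check.
#' @return Fraction in `[0, 1]`.
#' @examples
#' overlap_fraction(c(1, 1000), c(901, 1900))  # 0.1
#' @export
overlap_fraction <- function(a, b, chrom_a = NULL, chrom_b = NULL) {
  if (!is.null(chrom_a) && !is.null(chrom_b) && chrom_a != chrom_b) {
    stop("overlap_fraction: intervals on different chromosomes (",
         chrom_a, " vs ", chrom_b, ")")
  }
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
  ov <- overlap_bp(a[1], a[2], b[1], b[2])
  ov / min(a[2] - a[1] + 1, b[2] - b[1] + 1)
}

#' Intersect homologous regions across pairwise comparisons
#'
#' All comparisons share one anchor genome (the refined reference on the
#' `ref` side of every coords table). Starting from the first comparison's
#' anchor intervals, each further comparison keeps only anchor regions
#' whose overlap fraction with one of its blocks strictly exceeds
#' `overlap_min` ("overlap exceeding 80%"); surviving regions are replaced
#' by the intersection of the two anchor intervals, and each step's matched
#' query interval and strand are carried along per genome.
#'
#' @param comparisons Named list of (filtered) `alignment_blocks`, one per
#'   comparison genome; names become genome labels.
#' @param overlap_min Strict lower bound on the overlap fraction.
#' @return A `homolog_regions` data frame: `chrom, start, end` on the
#'   anchor plus `<genome>.chrom/.start/.end/.strand` columns per
#'   comparison genome.
#' @export
intersect_homologs <- function(comparisons, overlap_min = 0.8) {
  if (!length(comparisons)) stop("intersect_homologs: no comparisons")
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons)))) {
    names(comparisons) <- paste0("genome_", seq_along(comparisons))
  }
  g1 <- names(comparisons)[1L]
  b1 <- comparisons[[1L]]
  regions <- data.frame(chrom = b1$ref_id, start = b1$ref_start,
                        end = b1$ref_end, stringsAsFactors = FALSE)
  regions[[paste0(g1, ".chrom")]] <- b1$qry_id
  regions[[paste0(g1, ".start")]] <- b1$qry_start
  regions[[paste0(g1, ".end")]] <- b1$qry_end
  regions[[paste0(g1, ".strand")]] <- b1$strand

  for (g in names(comparisons)[-1L]) {
    bl <- comparisons[[g]]
    keep <- logical(nrow(regions))
    new_start <- new_end <- integer(nrow(regions))
    qc <- qs <- qe <- qstr <- rep(NA, nrow(regions))
    for (r in seq_len(nrow(regions))) {
      cand <- which(bl$ref_id == regions$chrom[r])
      if (!length(cand)) next
      of <- overlap_bp(regions$start[r], regions$end[r],
                       bl$ref_start[cand], bl$ref_end[cand]) /
        pmin(regions$end[r] - regions$start[r] + 1L,
             bl$ref_end[cand] - bl$ref_start[cand] + 1L)
      hit <- cand[of > overlap_min]
      if (!length(hit)) next
      ## best overlap wins; ties resolved lexicographically by coordinates
      of_hit <- of[of > overlap_min]
      best <- hit[order(-of_hit, bl$ref_start[hit], bl$qry_start[hit])][1L]
      keep[r] <- TRUE
      new_start[r] <- max(regions$start[r], bl$ref_start[best])
      new_end[r] <- min(regions$end[r], bl$ref_end[best])
      qc[r] <- bl$qry_id[best]; qs[r] <- bl$qry_start[best]
      qe[r] <- bl$qry_end[best]; qstr[r] <- bl$strand[best]
    }
    regions <- regions[keep, , drop = FALSE]
    regions$start <- new_start[keep]
    regions$end <- new_end[keep]
    regions[[paste0(g, ".chrom")]] <- as.character(qc[keep])
    regions[[paste0(g, ".start")]] <- as.integer(qs[keep])
    regions[[paste0(g, ".end")]] <- as.integer(qe[keep])
    regions[[paste0(g, ".strand")]] <- as.character(qstr[keep])
    rownames(regions) <- NULL
  }
  class(regions) <- c("homolog_regions", "data.frame")
  regions
}

#' Build indexed three-way synteny blocks
#'
#' From anchor regions shared with two chromosome-level comparator genomes
#' (the output of [intersect_homologs()] on exactly two comparisons, which
#' already enforces the pairwise `> overlap_min` criterion), keeps regions
#' whose anchor interval is strictly longer than `min_len` bp, then
#' assigns per-genome block indices by sorting on (chromosome, start)
#' within each genome. Anchor strand is defined `+`; comparator signs are
#' relative strands.
#'
#' @param regions A `homolog_regions` data frame covering the anchor plus
#'   two genomes.
#' @param min_len Strict minimum anchor length (bp); the published
#'   criterion is "longer than 10,000 bp".
#' @param anchor Name used for the anchor genome (default `"anchor"`).
#' @return A `synteny_blocks` data frame in long format: `block_id, genome,
#'   chrom, start, end, strand, index`, with attribute `anchor`.
#' @export
threeway_blocks <- function(regions, min_len = 10000L, anchor = "anchor") {
  stopifnot(inherits(regions, "homolog_regions"))
  genomes <- unique(sub("\\.chrom$", "",
                        grep("\\.chrom$", names(regions), value = TRUE)))
  keep <- (regions$end - regions$start + 1L) > min_len
  regions <- regions[keep, , drop = FALSE]
  n <- nrow(regions)
  if (!n) {
    out <- data.frame(block_id = integer(0), genome = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      index = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("synteny_blocks", "data.frame")
    attr(out, "anchor") <- anchor
    return(out)
  }
  ## stable block ids in anchor coordinate order
  ord <- order(regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  rows <- list()
  idx_by <- function(chrom, start) {
    o <- order(chrom, start)
    r <- integer(length(o)); r[o] <- seq_along(o)
    r
  }
  rows[[anchor]] <- data.frame(
    block_id = seq_len(n), genome = anchor, chrom = regions$chrom,
    start = regions$start, end = regions$end, strand = "+",
    index = idx_by(regions$chrom, regions$start), stringsAsFactors = FALSE
  )
  for (g in genomes) {
    rows[[g]] <- data.frame(
      block_id = seq_len(n), genome = g,
      chrom = regions[[paste0(g, ".chrom")]],
      start = regions[[paste0(g, ".start")]],
      end = regions[[paste0(g, ".end")]],
      strand = regions[[paste0(g, ".strand")]],
      index = idx_by(regions[[paste0(g, ".chrom")]],
                     regions[[paste0(g, ".start")]]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", "data.frame")
  attr(out, "anchor") <- anchor
  out
}

#' Synteny blocks from a single pairwise coords table
#'
#' Convenience constructor for the rearrangement stage on two-genome
#' fixtures: every alignment block becomes one synteny block, indexed by
#' (chromosome, start) within the `ref` and `qry` genomes; ref strand is
#' `+`.
#'
#' @param blocks An `alignment_blocks` data frame.
#' @param ref,qry Genome labels for the two sides.
#' @return A `synteny_blocks` data frame (long format) with attribute
#'   `anchor = ref`.
#' @export
coords_to_blocks <- function(blocks, ref = "ref", qry = "qry") {
  n <- nrow(blocks)
  ord <- order(blocks$ref_id, blocks$ref_start)
  blocks <- blocks[ord, , drop = FALSE]
  idx <- function(chrom, start) {
    o <- order(chrom, start)
    r <- integer(length(o)); r[o] <- seq_along(o)
    r
  }
  out <- rbind(
    data.frame(block_id = seq_len(n), genome = ref, chrom = blocks$ref_id,
               start = blocks$ref_start, end = blocks$ref_end, strand = "+",
               index = idx(blocks$ref_id, blocks$ref_start),
               stringsAsFactors = FALSE),
    data.frame(block_id = seq_len(n), genome = qry, chrom = blocks$qry_id,
               start = blocks$qry_start, end = blocks$qry_end,
               strand = blocks$strand,
               index = idx(blocks$qry_id, blocks$qry_start),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", "data.frame")
  attr(out, "anchor") <- ref
  out
}
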
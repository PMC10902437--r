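# File format I/O: FASTA (via Biostrings), VCF text emission, AGP v2.1,
# and the tab-separated alignment-coordinate dialect.

#' Write sequences as FASTA wrapped at 60 columns
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @param as Return `"character"` (default) or `"DNAStringSet"`.
#' @return Named sequences.
#' @export
read_fasta <- function(path, as = c("character", "DNAStringSet")) {
  as <- match.arg(as)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (as == "character") setNames(as.character(x), names(x)) else x
}

# Minimal VCF v4.2 emitter: one GT-only FORMAT column set, ##contig headers.
write_vcf_table <- function(path, contigs, records, gt, samples) {
  stopifnot(nrow(records) == nrow(gt))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ldrefine",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (nrow(records)) {
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

agp_columns <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation")

# Build AGP v2.1 rows for one object: W component lines alternating with
# U gap lines (gap type "scaffold", linkage "yes", evidence "align_genus").
layout_to_agp <- function(object, components, strands, lengths,
                          gap_length = 100L) {
  stopifnot(length(components) == length(strands),
            length(components) == length(lengths))
  rows <- list()
  at <- 1L
  part <- 1L
  for (i in seq_along(components)) {
    if (i > 1L && gap_length > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        object = object, object_beg = at, object_end = at + gap_length - 1L,
        part_number = part, component_type = "U",
        component_id = as.character(gap_length), component_beg = "scaffold",
        component_end = "yes", orientation = "align_genus",
        stringsAsFactors = FALSE
      )
      at <- at + gap_length
      part <- part + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      object = object, object_beg = at, object_end = at + lengths[i] - 1L,
      part_number = part, component_type = "W",
      component_id = components[i], component_beg = "1",
      component_end = as.character(lengths[i]), orientation = strands[i],
      stringsAsFactors = FALSE
    )
    at <- at + lengths[i]
    part <- part + 1L
  }
  do.call(rbind, rows)
}

#' Write an AGP v2.1 table
#'
#' @param agp AGP data frame as produced by [emit_super_scaffolds()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##agp-version 2.1", con)
  if (!is.null(agp) && nrow(agp)) {
    write.table(agp[, agp_columns], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an AGP v2.1 table
#'
#' @param path AGP path.
#' @return Data frame with the nine AGP columns.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(setNames(data.frame(matrix(character(0), ncol = 9)), agp_columns))
  }
  agp <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  names(agp) <- agp_columns
  for (f in c("object_beg", "object_end", "part_number")) {
    agp[[f]] <- as.integer(agp[[f]])
  }
  agp
}

#' Rebuild object sequences from an AGP table plus component sequences
#'
#' The exact inverse of [emit_super_scaffolds()]: W rows are extracted from
#' the named components (reverse-complemented for orientation `-`), U/N gap
#' rows become runs of `N`.
#'
#' @param agp AGP data frame (see [read_agp()]).
#' @param components Named character vector or `DNAStringSet` of component
#'   sequences.
#' @return Named character vector of object sequences.
#' @export
agp_to_fasta <- function(agp, components) {
  if (methods::is(components, "DNAStringSet")) {
    components <- setNames(as.character(components), names(components))
  }
  out <- character(0)
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type %in% c("U", "N")) {
        strrep("N", as.integer(r$component_id))
      } else {
        if (!r$component_id %in% names(components)) {
          stop("agp_to_fasta: missing component ", r$component_id)
        }
        s <- substr(components[[r$component_id]],
                    as.integer(r$component_beg), as.integer(r$component_end))
        if (r$orientation == "-") revcomp(s) else s
      }
    }, "")
    out[[obj]] <- paste(parts, collapse = "")
  }
  out
}

#' Read an alignment-coordinate table
#'
#' Parses the tab-separated show-coords-style dialect with columns
#' `ref_start, ref_end, qry_start, qry_end, ref_alnlen, qry_alnlen,
#' pct_identity, ref_id, qry_id` (1-based inclusive). Lines starting with
#' `#` are skipped. `qry_start > qry_end` encodes the minus strand; query
#' intervals are normalized to `(min, max)` with an explicit `strand`
#' column.
#'
#' @param path Coords file.
#' @return An `alignment_blocks` data frame with columns `ref_id,
#'   ref_start, ref_end, qry_id, qry_start, qry_end, strand, identity`.
#' @export
read_coords <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  empty <- data.frame(ref_id = character(0), ref_start = integer(0),
                      ref_end = integer(0), qry_id = character(0),
                      qry_start = integer(0), qry_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("alignment_blocks", "data.frame")
  if (!any(keep)) return(empty)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    stop("read_coords: expected 9 tab-separated columns at line ",
         lineno[bad[1L]], " of ", path)
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 1:7, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 7L)
  badnum <- which(apply(is.na(num), 1L, any))
  if (length(badnum)) {
    stop("read_coords: non-numeric coordinate field at line ",
         lineno[badnum[1L]], " of ", path)
  }
  rs <- as.integer(num[, 1L]); re <- as.integer(num[, 2L])
  qs <- as.integer(num[, 3L]); qe <- as.integer(num[, 4L])
  idy <- num[, 7L]
  if (any(rs > re)) {
    stop("read_coords: ref_start > ref_end at line ",
         lineno[which(rs > re)[1L]], " of ", path)
  }
  if (any(idy < 0 | idy > 100)) {
    stop("read_coords: identity outside [0, 100] at line ",
         lineno[which(idy < 0 | idy > 100)[1L]], " of ", path)
  }
  out <- data.frame(
    ref_id = m[, 8L], ref_start = rs, ref_end = re,
    qry_id = m[, 9L], qry_start = pmin(qs, qe), qry_end = pmax(qs, qe),
    strand = ifelse(qs > qe, "-", "+"), identity = idy,
    stringsAsFactors = FALSE
  )
  class(out) <- c("alignment_blocks", "data.frame")
  out
}

#' Write an alignment-coordinate table
#'
#' Inverse of [read_coords()]: minus-strand rows are written with
#' `qry_start > qry_end`.
#'
#' @param blocks `alignment_blocks` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coords <- function(blocks, path) {
  qs <- ifelse(blocks$strand == "-", blocks$qry_end, blocks$qry_start)
  qe <- ifelse(blocks$strand == "-", blocks$qry_start, blocks$qry_end)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ref_start\tref_end\tqry_start\tqry_end\tref_alnlen\t",
                    "qry_alnlen\tpct_identity\tref_id\tqry_id"), con)
  if (nrow(blocks)) {
    writeLines(paste(blocks$ref_start, blocks$ref_end, qs, qe,
                     blocks$ref_end - blocks$ref_start + 1L,
                     abs(qe - qs) + 1L,
                     blocks$identity, blocks$ref_id, blocks$qry_id,
                     sep = "\t"), con)
  }
  invisible(path)
}
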
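# Variant handling: VCF ingestion, the site- and scaffold-level filters
# applied before LD scoring, and extraction of scaffold-edge SNP windows.

#' Construct a per-scaffold genotype matrix
#'
#' Dosage-coded biallelic SNPs for one scaffold: rows are sites (strictly
#' increasing 1-based positions), columns are samples, entries count ALT
#' alleles (0/1/2, `NA` = missing).
#'
#' @param scaffold_id Scaffold name.
#' @param pos Integer vector of 1-based positions, strictly increasing.
#' @param ref,alt Single-nucleotide alleles per site.
#' @param geno Integer matrix, sites x samples, with column names.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(scaffold_id, pos, ref, alt, geno) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (length(pos) != nrow(geno)) {
    stop("genotype_matrix: pos length must match geno rows")
  }
  if (length(pos) > 1L && any(diff(pos) <= 0)) {
    stop("genotype_matrix: positions not strictly increasing on scaffold ",
         scaffold_id)
  }
  if (is.null(colnames(geno))) {
    stop("genotype_matrix: geno must carry sample names as column names")
  }
  if (any(geno < 0L | geno > 2L, na.rm = TRUE)) {
    stop("genotype_matrix: genotype codes must be 0, 1, 2 or NA")
  }
  structure(list(scaffold_id = scaffold_id, pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, samples = colnames(geno)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", x$scaffold_id, "-", length(x$pos), "sites x",
      length(x$samples), "samples\n")
  invisible(x)
}

n_sites <- function(gm) length(gm$pos)

subset_sites <- function(gm, idx) {
  genotype_matrix(gm$scaffold_id, gm$pos[idx], gm$ref[idx], gm$alt[idx],
                  gm$geno[idx, , drop = FALSE])
}

#' Filter thresholds for the variant and scaffold filters
#'
#' Defaults follow the published pipeline: sites are kept when their missing
#' rate is strictly below 15% and the minor allele count is greater than
#' three (i.e. >= 4); scaffolds are kept when at least 20,000 bp long with
#' at least 100 surviving SNPs; 500 SNPs are taken per scaffold edge.
#'
#' @param max_missing_rate Sites with missing rate `>=` this fail.
#' @param min_minor_allele_count Minimum minor allele count to keep a site.
#' @param min_scaffold_length Minimum scaffold length (bp).
#' @param min_scaffold_snps Minimum surviving SNPs per scaffold.
#' @param edge_snps SNPs per scaffold edge window (`k`).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_missing_rate = 0.15,
                              min_minor_allele_count = 4L,
                              min_scaffold_length = 20000L,
                              min_scaffold_snps = 100L,
                              edge_snps = 500L) {
  if (max_missing_rate < 0 || max_missing_rate > 1) {
    stop("filter_thresholds: max_missing_rate must lie in [0, 1]")
  }
  if (min_minor_allele_count < 0 || min_scaffold_length < 0 ||
      min_scaffold_snps < 0 || edge_snps < 1) {
    stop("filter_thresholds: thresholds must be non-negative (edge_snps >= 1)")
  }
  structure(list(max_missing_rate = max_missing_rate,
                 min_minor_allele_count = as.integer(min_minor_allele_count),
                 min_scaffold_length = as.integer(min_scaffold_length),
                 min_scaffold_snps = as.integer(min_scaffold_snps),
                 edge_snps = as.integer(edge_snps)),
            class = "filter_thresholds")
}

# GT string -> ALT dosage; any missing allele makes the genotype missing.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]")[[1L]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(al))
    if (any(is.na(a)) || any(a < 0L) || any(a > 1L)) return(NA_integer_)
    sum(a)
  }, integer(1))
  matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
         dimnames = dimnames(gt))
}

#' Read a VCF into per-scaffold genotype matrices
#'
#' Retains only biallelic SNP records (single-nucleotide REF and exactly one
#' single-nucleotide ALT); genotype dosages are computed from GT regardless
#' of the phasing separator, and half-missing genotypes count as missing.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param sample_subset Optional character vector of sample ids to keep.
#' @return Named list of [genotype_matrix()] objects, one per scaffold that
#'   carries at least one retained record (empty list for a header-only
#'   VCF).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  hdr <- VariantAnnotation::header(vcf)
  if (!"GT" %in% rownames(VariantAnnotation::geno(hdr))) {
    stop("read_vcf: VCF has no GT FORMAT field: ", path)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")

  gt <- VariantAnnotation::geno(vcf)$GT
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, colnames(gt))
    if (length(missing_s)) {
      stop("read_vcf: samples not in VCF: ", paste(missing_s, collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
  }
  if (!any(keep)) return(setNames(list(), character(0)))

  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  ref <- ref[keep]
  alt1 <- alt1[keep]
  dos <- gt_to_dosage(gt[keep, , drop = FALSE])

  out <- list()
  for (sid in unique(chrom)) {
    i <- which(chrom == sid)
    if (length(i) > 1L && any(diff(pos[i]) <= 0)) {
      stop("read_vcf: positions not strictly increasing/sorted on scaffold ",
           sid)
    }
    out[[sid]] <- genotype_matrix(sid, pos[i], ref[i], alt1[i],
                                  dos[i, , drop = FALSE])
  }
  out
}

site_missing_rate <- function(gm) rowMeans(is.na(gm$geno))

site_minor_allele_count <- function(gm) {
  alt_ct <- rowSums(gm$geno, na.rm = TRUE)
  tot <- 2L * rowSums(!is.na(gm$geno))
  pmin(alt_ct, tot - alt_ct)
}

#' Apply the site-level filters to a genotype matrix
#'
#' Keeps sites whose missing rate is strictly below
#' `thresholds$max_missing_rate` and whose minor allele count (alleles
#' counted over non-missing diploid genotypes) is at least
#' `thresholds$min_minor_allele_count`. Order-preserving and idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [filter_thresholds()].
#' @return The filtered `genotype_matrix` (possibly with zero sites).
#' @export
filter_sites <- function(gm, thresholds = filter_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- site_missing_rate(gm) < thresholds$max_missing_rate &
    site_minor_allele_count(gm) >= thresholds$min_minor_allele_count
  subset_sites(gm, which(keep))
}

#' Apply the scaffold-level filters
#'
#' Keeps scaffolds at least `min_scaffold_length` bp long with at least
#' `min_scaffold_snps` (post-site-filter) SNPs; both boundaries are
#' inclusive on the keep side.
#'
#' @param matrices Named list of [genotype_matrix()] objects.
#' @param scaffold_lengths Named integer vector of scaffold lengths; every
#'   scaffold in `matrices` must be present.
#' @param thresholds A [filter_thresholds()].
#' @return List with `kept` (surviving matrices) and `excluded` (data frame
#'   of `scaffold_id`, `reason` in {`length`, `snp_count`,
#'   `length;snp_count`}).
#' @export
filter_scaffolds <- function(matrices, scaffold_lengths,
                             thresholds = filter_thresholds()) {
  ids <- vapply(matrices, function(g) g$scaffold_id, "")
  unknown <- setdiff(ids, names(scaffold_lengths))
  if (length(unknown)) {
    stop("filter_scaffolds: no length known for scaffold(s): ",
         paste(unknown, collapse = ", "))
  }
  reasons <- character(0)
  excluded_ids <- character(0)
  keep <- logical(length(matrices))
  for (i in seq_along(matrices)) {
    gm <- matrices[[i]]
    why <- character(0)
    if (scaffold_lengths[[gm$scaffold_id]] < thresholds$min_scaffold_length) {
      why <- c(why, "length")
    }
    if (n_sites(gm) < thresholds$min_scaffold_snps) {
      why <- c(why, "snp_count")
    }
    if (length(why)) {
      excluded_ids <- c(excluded_ids, gm$scaffold_id)
      reasons <- c(reasons, paste(why, collapse = ";"))
    } else {
      keep[i] <- TRUE
    }
  }
  list(kept = matrices[keep],
       excluded = data.frame(scaffold_id = excluded_ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Extract the head and tail SNP windows of a scaffold
#'
#' With `m` sites and window size `k`: when `m >= 2k`, head = first `k`
#' sites and tail = last `k`; when `m < 2k` the sites are split in half
#' without overlap, the odd site going to the tail.
#'
#' @param gm A non-empty [genotype_matrix()].
#' @param k Edge window size in SNPs (default from [filter_thresholds()]).
#' @return List with `head` and `tail` `edge_block` objects (fields
#'   `scaffold_id`, `end`, `pos`, `geno`).
#' @export
extract_edge_blocks <- function(gm, k = 500L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- n_sites(gm)
  if (m == 0L) stop("extract_edge_blocks: scaffold ", gm$scaffold_id,
                    " has no sites")
  k <- as.integer(k)
  if (m >= 2L * k) {
    head_idx <- seq_len(k)
    tail_idx <- seq.int(m - k + 1L, m)
  } else {
    h <- m %/% 2L
    head_idx <- seq_len(h)
    tail_idx <- if (h < m) seq.int(h + 1L, m) else integer(0)
  }
  mk <- function(idx, end) {
    structure(list(scaffold_id = gm$scaffold_id, end = end,
                   pos = gm$pos[idx],
                   geno = gm$geno[idx, , drop = FALSE]),
              class = "edge_block")
  }
  list(head = mk(head_idx, "head"), tail = mk(tail_idx, "tail"))
}
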
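#' Simulation configuration for the population-scaffolding generator
#'
#' Bundles and validates the parameters of the synthetic world: one
#' chromosome fragmented into shuffled, randomly oriented scaffolds, and a
#' diploid population whose genotypes carry distance-decaying linkage
#' disequilibrium (LD) that persists across true scaffold junctions.
#'
#' The population model is a founder mosaic: every sample haplotype copies
#' from a panel of `n_founders` founder haplotypes and switches to a
#' uniformly chosen founder independently at each base with probability
#' `recomb_rate`. Correlation between the founder identities at two sites
#' decays as `(1 - recomb_rate)^distance`, which yields the required LD
#' decay without simulating demography.
#'
#' @param chromosome_length Chromosome length in bp.
#' @param n_scaffolds Number of scaffolds the chromosome is fragmented into.
#' @param n_samples Number of diploid individuals.
#' @param n_founders Number of founder haplotypes (>= 2).
#' @param n_sites Number of biallelic SNP sites (>= 2 * `n_scaffolds`).
#' @param recomb_rate Per-bp probability that a haplotype switches founder.
#' @param min_maf Minimum minor-allele frequency among founder haplotypes.
#' @param gap_free Scaffolds contain no N runs (the only supported mode).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(chromosome_length = 1e5, n_scaffolds = 4,
#'                   n_samples = 10, n_sites = 200, seed = 1)
#' @export
sim_config <- function(chromosome_length = 5e6,
                       n_scaffolds = 30,
                       n_samples = 40,
                       n_founders = 8,
                       n_sites = 5000,
                       recomb_rate = 1e-6,
                       min_maf = 0.1,
                       gap_free = TRUE,
                       seed = 1) {
  cfg <- list(
    chromosome_length = as.integer(chromosome_length),
    n_scaffolds = as.integer(n_scaffolds),
    n_samples = as.integer(n_samples),
    n_founders = as.integer(n_founders),
    n_sites = as.integer(n_sites),
    recomb_rate = as.numeric(recomb_rate),
    min_maf = as.numeric(min_maf),
    gap_free = isTRUE(gap_free),
    seed = as.integer(seed)
  )
  for (f in c("chromosome_length", "n_scaffolds", "n_samples", "n_founders",
              "n_sites")) {
    if (!is_count(cfg[[f]])) stop("sim_config: `", f, "` must be a positive integer")
  }
  if (cfg$n_founders < 2) stop("sim_config: n_founders must be >= 2")
  if (cfg$n_sites < 2L * cfg$n_scaffolds) {
    stop("sim_config: n_sites must be >= 2 * n_scaffolds")
  }
  if (cfg$recomb_rate < 0 || cfg$recomb_rate > 1) {
    stop("sim_config: recomb_rate must lie in [0, 1]")
  }
  if (cfg$min_maf < 0 || cfg$min_maf > 0.5) {
    stop("sim_config: min_maf must lie in [0, 0.5]")
  }
  if (cfg$n_scaffolds > cfg$chromosome_length) {
    stop("sim_config: more scaffolds than bases")
  }
  if (cfg$n_sites > cfg$chromosome_length) {
    stop("sim_config: more SNP sites than bases")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a fragmented chromosome and a population with junction-spanning LD
#'
#' Draws, in this documented order and from one generator seeded with
#' `config$seed`: (1) an i.i.d. uniform A/C/G/T chromosome; (2) sorted SNP
#' positions, uniform without replacement; (3) founder allele vectors per
#' site, redrawn until the founder minor-allele frequency reaches
#' `min_maf`, plus an alternate base per site; (4) `2 * n_samples` sample
#' haplotypes by founder copying (switch probability `recomb_rate` per bp);
#' (5) scaffold breakpoints, uniform without replacement; (6) a uniform
#' scaffold shuffling and uniform strands.
#'
#' @param config A [sim_config()].
#' @return An object of class `ld_simulation`: a list with elements `truth`
#'   (chromosome sequence, breakpoints, scaffold order/strand/lengths,
#'   oriented scaffold sequences, per-site map between chromosome and
#'   scaffold coordinates, true adjacency table) and `panel` (binary
#'   haplotypes, founder identities, site positions, ref/alt alleles,
#'   sample ids), plus the `config`.
#' @seealso [emit_dataset()] to materialize FASTA/VCF/AGP files,
#'   [genotype_matrices()] for in-memory genotype matrices.
#' @export
simulate_truth <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, {
    L <- config$chromosome_length
    S <- config$n_scaffolds
    m <- config$n_sites
    nf <- config$n_founders
    nh <- 2L * config$n_samples

    ## (1) chromosome
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    chromosome <- paste(bases, collapse = "")

    ## (2) SNP positions
    positions <- sort(sample.int(L, m))
    ref <- bases[positions]

    ## (3) founder alleles; enforce founder MAF >= min_maf per site
    fa <- matrix(sample(c(0L, 1L), nf * m, replace = TRUE), nrow = nf)
    repeat {
      cnt <- colSums(fa)
      bad <- which(pmin(cnt, nf - cnt) / nf < config$min_maf)
      if (!length(bad)) break
      fa[, bad] <- sample(c(0L, 1L), nf * length(bad), replace = TRUE)
    }
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    names(alt) <- NULL

    ## (4) haplotypes by founder copying
    gaps <- diff(positions)
    p_switch <- 1 - (1 - config$recomb_rate)^gaps
    haplotypes <- matrix(0L, nrow = nh, ncol = m)
    founder_ids <- matrix(0L, nrow = nh, ncol = m)
    for (h in seq_len(nh)) {
      sw <- c(TRUE, runif(m - 1L) < p_switch)
      seg <- cumsum(sw)
      f_per_seg <- sample.int(nf, seg[m], replace = TRUE)
      f <- f_per_seg[seg]
      founder_ids[h, ] <- f
      haplotypes[h, ] <- fa[cbind(f, seq_len(m))]
    }
    samples <- sprintf("sample_%03d", seq_len(config$n_samples))
    rownames(haplotypes) <- rownames(founder_ids) <-
      paste0(rep(samples, each = 2L), c("_h1", "_h2"))

    ## (5) breakpoints (0-based cut positions, strictly inside the chromosome)
    breakpoints <- if (S > 1L) sort(sample.int(L - 1L, S - 1L)) else integer(0)
    seg_start0 <- c(0L, breakpoints)        # 0-based half-open segments
    seg_end0 <- c(breakpoints, L)
    seg_len <- seg_end0 - seg_start0

    ## (6) shuffled ids and strands
    emission_rank <- sample.int(S)          # segment i is emitted at this rank
    scaffold_ids_by_segment <- sprintf("scaf_%03d", emission_rank)
    strand_by_segment <- sample(c("+", "-"), S, replace = TRUE)

    ## per-site map
    seg_of_site <- findInterval(positions - 1L, seg_start0)  # segment index 1..S
    offset0 <- (positions - 1L) - seg_start0[seg_of_site]
    scaf_pos <- ifelse(strand_by_segment[seg_of_site] == "+",
                       offset0 + 1L,
                       seg_len[seg_of_site] - offset0)
    site_map <- data.frame(
      site = seq_len(m),
      chrom_pos = positions,
      segment = seg_of_site,
      scaffold_id = scaffold_ids_by_segment[seg_of_site],
      strand = strand_by_segment[seg_of_site],
      scaf_pos = as.integer(scaf_pos),
      stringsAsFactors = FALSE
    )

    ## oriented scaffold sequences (as they will be emitted)
    seg_seq <- substring(chromosome, seg_start0 + 1L, seg_end0)
    scaf_seq <- ifelse(strand_by_segment == "-", revcomp(seg_seq), seg_seq)
    names(scaf_seq) <- scaffold_ids_by_segment

    ## true adjacencies between consecutive segments
    if (S > 1L) {
      i <- seq_len(S - 1L)
      adjacencies <- data.frame(
        scaffold_a = scaffold_ids_by_segment[i],
        end_a = trailing_end(strand_by_segment[i]),
        scaffold_b = scaffold_ids_by_segment[i + 1L],
        end_b = leading_end(strand_by_segment[i + 1L]),
        stringsAsFactors = FALSE
      )
    } else {
      adjacencies <- data.frame(scaffold_a = character(0), end_a = character(0),
                                scaffold_b = character(0), end_b = character(0),
                                stringsAsFactors = FALSE)
    }

    lens <- setNames(as.integer(seg_len), scaffold_ids_by_segment)
    truth <- list(
      chromosome = chromosome,
      breakpoints = breakpoints,
      scaffold_order = scaffold_ids_by_segment,   # true chromosome order
      scaffold_strand = setNames(strand_by_segment, scaffold_ids_by_segment),
      scaffold_lengths = lens,
      scaffold_seqs = scaf_seq,
      site_map = site_map,
      adjacencies = adjacencies
    )
    panel <- list(
      haplotypes = haplotypes,
      founder_ids = founder_ids,
      founder_alleles = fa,
      site_positions = positions,
      ref = ref,
      alt = alt,
      samples = samples
    )
    structure(list(truth = truth, panel = panel, config = config),
              class = "ld_simulation")
  })
}

#' @export
print.ld_simulation <- function(x, ...) {
  cat("ld_simulation:", x$config$chromosome_length, "bp chromosome,",
      x$config$n_scaffolds, "scaffolds,", x$config$n_samples, "samples,",
      x$config$n_sites, "SNPs (seed", paste0(x$config$seed, ")\n"))
  invisible(x)
}

#' In-memory per-scaffold genotype matrices from a simulation
#'
#' Collapses the phased panel into unphased diploid dosage matrices in
#' scaffold coordinates, exactly as [read_vcf()] would reconstruct them from
#' the VCF written by [emit_dataset()] (an identity asserted in the test
#' suite).
#'
#' @param sim An `ld_simulation`.
#' @return Named list of `genotype_matrix` objects, in scaffold id order.
#' @export
genotype_matrices <- function(sim) {
  stopifnot(inherits(sim, "ld_simulation"))
  sm <- sim$truth$site_map
  hap <- sim$panel$haplotypes
  n <- length(sim$panel$samples)
  dosage <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]   # samples x sites
  out <- list()
  for (sid in sort(unique(sm$scaffold_id))) {
    rows <- sm[sm$scaffold_id == sid, , drop = FALSE]
    rows <- rows[order(rows$scaf_pos), , drop = FALSE]
    minus <- rows$strand == "-"
    geno <- t(dosage[, rows$site, drop = FALSE])
    colnames(geno) <- sim$panel$samples
    out[[sid]] <- genotype_matrix(
      scaffold_id = sid,
      pos = rows$scaf_pos,
      ref = ifelse(minus, complement_base(sim$panel$ref[rows$site]),
                   sim$panel$ref[rows$site]),
      alt = ifelse(minus, complement_base(sim$panel$alt[rows$site]),
                   sim$panel$alt[rows$site]),
      geno = geno
    )
  }
  out
}

#' Write the simulated dataset to disk
#'
#' Materializes a simulation as (a) a scaffold FASTA in shuffled order with
#' minus-strand scaffolds reverse-complemented, (b) a VCF v4.2 with
#' scaffold-relative 1-based positions and unphased diploid GT fields (the
#' order of the two alleles within each genotype is randomized), (c) a
#' phased haplotype table kept solely as a test oracle, (d) a truth AGP
#' describing the true super-scaffold, and (e) a truth TSV of scaffold-end
#' adjacencies.
#'
#' @param sim An `ld_simulation`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
emit_dataset <- function(sim, outdir) {
  stopifnot(inherits(sim, "ld_simulation"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("emit_dataset: cannot create ", outdir)
  }
  truth <- sim$truth
  ids <- sort(names(truth$scaffold_lengths))   # emission order = id order

  paths <- list(
    fasta = file.path(outdir, "scaffolds.fasta"),
    vcf = file.path(outdir, "variants.vcf"),
    haplotypes = file.path(outdir, "haplotypes.tsv"),
    agp = file.path(outdir, "truth.agp"),
    adjacencies = file.path(outdir, "truth_adjacencies.tsv")
  )

  write_fasta(truth$scaffold_seqs[ids], paths$fasta)

  ## VCF: scaffold coordinates, sorted; alleles complemented on minus strand
  gms <- genotype_matrices(sim)
  gt <- with_seed(sim$config$seed + 500000L, {
    do.call(rbind, lapply(ids, function(sid) {
      g <- gms[[sid]]$geno
      if (!nrow(g)) return(NULL)
      ## randomize within-genotype allele order: 1 -> "0/1" or "1/0"
      flip <- matrix(runif(length(g)) < 0.5, nrow = nrow(g))
      out <- matrix("0/0", nrow = nrow(g), ncol = ncol(g))
      out[g == 2L] <- "1/1"
      out[g == 1L & flip] <- "1/0"
      out[g == 1L & !flip] <- "0/1"
      out[is.na(g)] <- "./."
      out
    }))
  })
  rec <- do.call(rbind, lapply(ids, function(sid) {
    g <- gms[[sid]]
    if (!length(g$pos)) return(NULL)
    data.frame(chrom = sid, pos = g$pos, ref = g$ref, alt = g$alt,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rec)) {
    rec <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0))
    gt <- matrix(character(0), nrow = 0, ncol = length(sim$panel$samples))
  }
  write_vcf_table(paths$vcf, contigs = truth$scaffold_lengths[ids],
                  records = rec, gt = gt, samples = sim$panel$samples)

  ## phased haplotype oracle table
  hap <- sim$panel$haplotypes
  hap_df <- data.frame(site = seq_along(sim$panel$site_positions),
                       chrom_pos = sim$panel$site_positions,
                       t(hap), check.names = FALSE)
  write.table(hap_df, paths$haplotypes, sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## truth AGP of the single true super-scaffold
  agp <- layout_to_agp(
    object = "true_super_1",
    components = truth$scaffold_order,
    strands = unname(truth$scaffold_strand[truth$scaffold_order]),
    lengths = unname(truth$scaffold_lengths[truth$scaffold_order]),
    gap_length = 100L
  )
  write_agp(agp, paths$agp)

  write.table(truth$adjacencies, paths$adjacencies, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate an alignment-coordinate table with planted rearrangements
#'
#' Generates `n_blocks` collinear alignment blocks between a reference
#' chromosome (`ref_1`) and a query chromosome (`qry_1`), then plants the
#' requested number of inversions (a run of 1-3 blocks, strand-flipped and
#' order-reversed in the query) and translocations (a run of 1-2 blocks
#' either moved to a second query chromosome `qry_2`, or displaced forward
#' past a longer stretch of blocks). Events are placed in the interior with
#' at least two undisturbed blocks between them so each planted event is
#' identifiable as exactly one call downstream; displacement jumps always
#' skip strictly more blocks than they move, which keeps the moved run (not
#' the skipped stretch) the unique shortest explanation.
#'
#' @param n_blocks Number of alignment blocks (>= what the events need).
#' @param inversions Number of planted inversions.
#' @param translocations Number of planted translocations.
#' @param seed Integer seed.
#' @param path Optional file to write the coords table to.
#' @return List with `coords` (an `alignment_blocks` data frame in the
#'   show-coords-style dialect; minus-strand rows have `qry_start > qry_end`
#'   when written), `truth` (planted events: type, subtype, first/last
#'   anchor block), and `path` (or `NULL`).
#' @export
simulate_coords <- function(n_blocks, inversions = 0L, translocations = 0L,
                            seed = 1L, path = NULL) {
  n_blocks <- as.integer(n_blocks)
  inversions <- as.integer(inversions)
  translocations <- as.integer(translocations)
  if (!is_count(n_blocks)) stop("simulate_coords: n_blocks must be positive")
  if (inversions < 0 || translocations < 0) {
    stop("simulate_coords: event counts must be non-negative")
  }
  if (inversions + translocations > n_blocks) {
    stop("simulate_coords: more events than blocks")
  }
  with_seed(seed, {
    ## plan events left to right with >= 2 buffer blocks around each
    n_events <- inversions + translocations
    types <- sample(c(rep("inversion", inversions),
                      rep("translocation", translocations)))
    cursor <- 3L   # first block available to an event (1-based); keep 2 lead-in
    truth <- NULL
    plan <- list()
    for (ty in types) {
      cursor <- cursor + sample.int(3L, 1L) - 1L   # extra random spacing 0..2
      if (ty == "inversion") {
        len <- sample.int(3L, 1L)
        span_end <- cursor + len - 1L
        ev <- list(type = "inversion", subtype = "inversion",
                   first = cursor, last = span_end, region_end = span_end)
      } else {
        len <- sample.int(2L, 1L)
        subtype <- sample(c("interchromosomal", "displacement"), 1L)
        if (subtype == "interchromosomal") {
          span_end <- cursor + len - 1L
          ev <- list(type = "translocation", subtype = subtype,
                     first = cursor, last = span_end, region_end = span_end)
        } else {
          skip <- len + 1L + sample.int(2L, 1L)   # skip > len always
          span_end <- cursor + len - 1L
          ev <- list(type = "translocation", subtype = subtype,
                     first = cursor, last = span_end, skip = skip,
                     region_end = span_end + skip)
        }
      }
      plan[[length(plan) + 1L]] <- ev
      cursor <- ev$region_end + 3L   # >= 2 undisturbed blocks between events
    }
    need <- if (length(plan)) plan[[length(plan)]]$region_end + 2L else 0L
    if (need > n_blocks) {
      stop("simulate_coords: n_blocks = ", n_blocks, " too small for the ",
           "requested events (need >= ", need, ")")
    }

    ## reference geometry
    len <- sample(12000:30000, n_blocks, replace = TRUE)
    gap <- sample(500:5000, n_blocks, replace = TRUE)
    ref_start <- cumsum(c(1L, head(len + gap, -1L)))
    ref_end <- ref_start + len - 1L
    identity <- round(runif(n_blocks, 92, 99.9), 2)

    ## apply events to the query-side description of each block
    qry_chrom <- rep("qry_1", n_blocks)
    strand <- rep("+", n_blocks)
    order_q1 <- seq_len(n_blocks)    # query order of qry_1 blocks (by block id)
    for (ev in plan) {
      run <- ev$first:ev$last
      if (ev$subtype == "inversion") {
        strand[run] <- "-"
        pos <- match(run, order_q1)
        order_q1[pos] <- rev(run)
      } else if (ev$subtype == "interchromosomal") {
        qry_chrom[run] <- "qry_2"
        order_q1 <- setdiff(order_q1, run)
      } else {
        ## displace the run forward, re-inserting it after the block that
        ## ends the skipped stretch (which is strictly longer than the run)
        skipped_last <- ev$last + ev$skip
        rest <- setdiff(order_q1, run)
        at <- match(skipped_last, rest)
        order_q1 <- append(rest, run, after = at)
      }
      truth <- rbind(truth, data.frame(
        type = ev$type, subtype = ev$subtype,
        first_block = ev$first, last_block = ev$last,
        stringsAsFactors = FALSE
      ))
    }
    if (is.null(truth)) {
      truth <- data.frame(type = character(0), subtype = character(0),
                          first_block = integer(0), last_block = integer(0),
                          stringsAsFactors = FALSE)
    }

    ## assign query coordinates chromosome by chromosome
    qry_start <- integer(n_blocks)
    qry_end <- integer(n_blocks)
    assign_coords <- function(block_order) {
      at <- 1L
      for (b in block_order) {
        qry_start[b] <<- at
        qry_end[b] <<- at + len[b] - 1L
        at <- at + len[b] + sample(500:5000, 1L)
      }
    }
    assign_coords(order_q1)
    q2 <- which(qry_chrom == "qry_2")
    if (length(q2)) assign_coords(q2)

    coords <- data.frame(
      ref_id = "ref_1",
      ref_start = as.integer(ref_start),
      ref_end = as.integer(ref_end),
      qry_id = qry_chrom,
      qry_start = as.integer(qry_start),
      qry_end = as.integer(qry_end),
      strand = strand,
      identity = identity,
      stringsAsFactors = FALSE
    )
    class(coords) <- c("alignment_blocks", "data.frame")
    if (!is.null(path)) write_coords(coords, path)
    list(coords = coords, truth = truth, path = path)
  })
}
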
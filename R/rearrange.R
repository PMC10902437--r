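# Rearrangement analysis on signed block permutations: inversion and
# translocation calling, breakpoint-style adjacency encoding, and a
# majority-rule reconstruction of ancestral adjacencies for three genomes
# (a documented simplification of full multi-genome breakpoint-graph
# rearrangement inference).

#' Signed permutation of one genome in another genome's block order
#'
#' For each anchor chromosome, lists the blocks in anchor coordinate order
#' together with the other genome's chromosome, block index, and relative
#' sign (+1 when both genomes carry the block on the same strand).
#'
#' @param blocks A `synteny_blocks` data frame (long format; see
#'   [threeway_blocks()] or [coords_to_blocks()]).
#' @param anchor,other Genome labels present in `blocks$genome`.
#' @return A `signed_permutation` data frame: `anchor_chrom, position,
#'   block_id, other_chrom, other_index, sign`.
#' @export
signed_permutation <- function(blocks, anchor, other) {
  a <- blocks[blocks$genome == anchor, , drop = FALSE]
  o <- blocks[blocks$genome == other, , drop = FALSE]
  if (!nrow(a) || !nrow(o)) {
    stop("signed_permutation: genome not present in blocks")
  }
  missing_blocks <- union(setdiff(a$block_id, o$block_id),
                          setdiff(o$block_id, a$block_id))
  if (length(missing_blocks)) {
    stop("signed_permutation: block(s) missing in one genome: ",
         paste(missing_blocks, collapse = ", "))
  }
  a <- a[order(a$chrom, a$index), , drop = FALSE]
  m <- match(a$block_id, o$block_id)
  out <- data.frame(
    anchor_chrom = a$chrom,
    position = stats::ave(seq_len(nrow(a)), a$chrom, FUN = seq_along),
    block_id = a$block_id,
    other_chrom = o$chrom[m],
    other_index = o$index[m],
    sign = ifelse(a$strand == o$strand[m], 1L, -1L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("signed_permutation", "data.frame")
  out
}

empty_calls <- function() {
  data.frame(type = character(0), anchor_chrom = character(0),
             first_pos = integer(0), last_pos = integer(0),
             blocks = character(0), other_chrom = character(0),
             evidence = character(0), stringsAsFactors = FALSE)
}

#' Call inversions from a signed permutation
#'
#' One call per maximal run of consecutive anchor positions whose blocks
#' are sign `-`, map to the same other-genome chromosome, and have strictly
#' decreasing other-genome indices (the anti-diagonal run of a dot plot);
#' a single negative block qualifies as a run of length 1.
#'
#' @param perm A [signed_permutation()].
#' @return A `rearrangement_calls` data frame: `type, anchor_chrom,
#'   first_pos, last_pos, blocks` (comma-joined block ids), `other_chrom,
#'   evidence`.
#' @export
call_inversions <- function(perm) {
  calls <- list()
  for (chrom in unique(perm$anchor_chrom)) {
    p <- perm[perm$anchor_chrom == chrom, , drop = FALSE]
    n <- nrow(p)
    i <- 1L
    while (i <= n) {
      if (p$sign[i] == -1L) {
        j <- i
        while (j < n && p$sign[j + 1L] == -1L &&
               p$other_chrom[j + 1L] == p$other_chrom[i] &&
               p$other_index[j + 1L] < p$other_index[j]) {
          j <- j + 1L
        }
        calls[[length(calls) + 1L]] <- data.frame(
          type = "inversion", anchor_chrom = chrom,
          first_pos = p$position[i], last_pos = p$position[j],
          blocks = paste(p$block_id[i:j], collapse = ","),
          other_chrom = p$other_chrom[i],
          evidence = "reversed run", stringsAsFactors = FALSE
        )
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  class(out) <- c("rearrangement_calls", "data.frame")
  out
}

# Maximal collinear runs: consecutive positions on the same other
# chromosome, same sign, with the other-index stepping by +1 (sign +) or
# -1 (sign -). Returns per-run first/last row indices into `p`.
collinear_runs <- function(p) {
  n <- nrow(p)
  if (!n) return(data.frame(first = integer(0), last = integer(0)))
  brk <- which(
    p$other_chrom[-1L] != p$other_chrom[-n] |
      p$sign[-1L] != p$sign[-n] |
      (p$other_index[-1L] - p$other_index[-n]) != p$sign[-n]
  )
  first <- c(1L, brk + 1L)
  last <- c(brk, n)
  data.frame(first = first, last = last)
}

#' Call translocations from a signed permutation
#'
#' Two evidence classes, one call per maximal run: (a) interchromosomal --
#' a run of blocks mapping to a different other-genome chromosome than the
#' dominant chromosome of that anchor chromosome (ties broken towards the
#' lexicographically smallest chromosome; a run spanning the whole anchor
#' chromosome is never called); (b) intrachromosomal displacement -- a
#' maximal collinear run, not part of an inversion call, whose boundary
#' block indices are adjacent to neither neighbouring block's index
#' (chromosome ends count as adjacent). A displacement always admits two
#' reciprocal descriptions (moving the run, or moving the stretch it
#' jumped); when two candidate runs are consecutive, the shorter one is
#' called (the left one on ties).
#'
#' @param perm A [signed_permutation()].
#' @param inversions Optional pre-computed [call_inversions()] result.
#' @return A `rearrangement_calls` data frame (see [call_inversions()]).
#' @export
call_translocations <- function(perm, inversions = NULL) {
  if (is.null(inversions)) inversions <- call_inversions(perm)
  calls <- list()
  for (chrom in unique(perm$anchor_chrom)) {
    p <- perm[perm$anchor_chrom == chrom, , drop = FALSE]
    n <- nrow(p)
    tab <- table(p$other_chrom)
    dominant <- sort(names(tab)[tab == max(tab)])[1L]

    ## (a) interchromosomal runs
    r <- rle(p$other_chrom)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] != dominant && r$lengths[k] < n) {
        calls[[length(calls) + 1L]] <- data.frame(
          type = "translocation", anchor_chrom = chrom,
          first_pos = p$position[starts[k]], last_pos = p$position[ends[k]],
          blocks = paste(p$block_id[starts[k]:ends[k]], collapse = ","),
          other_chrom = r$values[k],
          evidence = "chromosome switch", stringsAsFactors = FALSE
        )
      }
    }

    ## (b) intrachromosomal displacement
    inv <- inversions[inversions$anchor_chrom == chrom, , drop = FALSE]
    in_inversion <- function(first, last) {
      any(inv$first_pos <= p$position[first] & inv$last_pos >= p$position[last])
    }
    runs <- collinear_runs(p)
    ## flank adjacency uses the nearest block on the same other-chromosome
    ## (interchromosomal blocks between two same-chromosome runs do not
    ## break their index adjacency); a chromosome end counts as adjacent
    nearest_same <- function(from, step, chrom) {
      q <- from + step
      while (q >= 1L && q <= n) {
        if (p$other_chrom[q] == chrom) return(q)
        q <- q + step
      }
      NA_integer_
    }
    cand <- logical(nrow(runs))
    for (k in seq_len(nrow(runs))) {
      f <- runs$first[k]; l <- runs$last[k]
      if (p$other_chrom[f] != dominant) next
      if (in_inversion(f, l)) next
      lq <- nearest_same(f, -1L, p$other_chrom[f])
      rq <- nearest_same(l, 1L, p$other_chrom[l])
      left_adj <- is.na(lq) ||
        abs(p$other_index[f] - p$other_index[lq]) == 1L
      right_adj <- is.na(rq) ||
        abs(p$other_index[l] - p$other_index[rq]) == 1L
      ## a displaced run is index-adjacent to neither flank, and removing
      ## it restores collinearity between the flanks
      restores <- !is.na(lq) && !is.na(rq) &&
        abs(p$other_index[lq] - p$other_index[rq]) == 1L
      cand[k] <- !left_adj && !right_adj && restores
    }
    ## dual suppression: consecutive candidate runs describe one event;
    ## keep the shorter (left on ties)
    for (k in which(cand)) {
      if (!cand[k]) next
      if (k < nrow(runs) && cand[k + 1L] &&
          runs$first[k + 1L] == runs$last[k] + 1L) {
        len_k <- runs$last[k] - runs$first[k]
        len_n <- runs$last[k + 1L] - runs$first[k + 1L]
        if (len_k <= len_n) cand[k + 1L] <- FALSE else cand[k] <- FALSE
      }
    }
    for (k in which(cand)) {
      f <- runs$first[k]; l <- runs$last[k]
      calls[[length(calls) + 1L]] <- data.frame(
        type = "translocation", anchor_chrom = chrom,
        first_pos = p$position[f], last_pos = p$position[l],
        blocks = paste(p$block_id[f:l], collapse = ","),
        other_chrom = p$other_chrom[f],
        evidence = "displacement", stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  out <- out[order(out$anchor_chrom, out$first_pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rearrangement_calls", "data.frame")
  out
}

#' Adjacency set of a signed block order
#'
#' Consecutive signed blocks `a, b` join `a`'s trailing end (tail for `+a`,
#' head for `-a`) to `b`'s leading end (head for `+b`, tail for `-b`).
#' Adjacencies are unordered, encoded as canonical strings
#' `"<id>.<end>--<id>.<end>"`, so a reversed chain yields the same set.
#'
#' @param block_id Vector of block ids in chromosome order (or a data
#'   frame with columns `block_id` and `sign`).
#' @param sign Signs, `+1`/`-1` (or `"+"`/`"-"`), one per block.
#' @return Character vector of adjacency keys (empty for a single block).
#' @export
adjacencies <- function(block_id, sign = NULL) {
  if (is.data.frame(block_id)) {
    sign <- block_id$sign
    block_id <- block_id$block_id
  }
  sign <- ifelse(sign %in% c("-", "-1", -1L), -1L, 1L)
  n <- length(block_id)
  if (n < 2L) return(character(0))
  i <- seq_len(n - 1L)
  trail <- paste0(block_id[i], ".", ifelse(sign[i] == 1L, "tail", "head"))
  lead <- paste0(block_id[i + 1L], ".",
                 ifelse(sign[i + 1L] == 1L, "head", "tail"))
  adjacency_key(trail, lead)
}

#' Per-genome signed block orders from a synteny-block table
#'
#' @param blocks A `synteny_blocks` data frame (long format).
#' @param genome Genome label.
#' @return Data frame `chrom, block_id, sign` ordered by (chrom, index).
#' @export
signed_orders <- function(blocks, genome) {
  g <- blocks[blocks$genome == genome, , drop = FALSE]
  if (!nrow(g)) stop("signed_orders: genome not present: ", genome)
  g <- g[order(g$chrom, g$index), , drop = FALSE]
  data.frame(chrom = g$chrom, block_id = g$block_id,
             sign = ifelse(g$strand == "-", -1L, 1L),
             stringsAsFactors = FALSE)
}

#' Adjacency set of one genome
#'
#' @param orders Data frame `chrom, block_id, sign` (see [signed_orders()]).
#' @return Character vector of adjacency keys over all chromosomes.
#' @export
genome_adjacencies <- function(orders) {
  unlist(lapply(split(orders, orders$chrom), function(ch)
    adjacencies(ch$block_id, ch$sign)), use.names = FALSE)
}

split_adjacency <- function(key) strsplit(key, "--", fixed = TRUE)

#' Majority-rule ancestral adjacencies for three genomes
#'
#' For the rooted topology `((A, B), C)`, an adjacency is assigned to the
#' `(A, B)` ancestor iff it is present in at least two of the three
#' genomes (the Fitch/majority small-parsimony rule on adjacency
#' presence). Conflicting adjacencies (a block end used twice) are
#' resolved by keeping the better-supported adjacency, then the
#' lexicographically smaller one; the accepted set is chained into linear
#' contiguous ancestral regions, with any residual cycle broken at its
#' lexicographically largest adjacency. The report lists adjacencies of
#' `A` absent from the ancestor (derived in `A`) and ancestral adjacencies
#' absent from `A` (lost in `A`).
#'
#' This is a deliberate simplification of full multi-genome
#' breakpoint-graph rearrangement inference; it is exact for adjacencies
#' supported by two or more leaves of the 3-leaf tree.
#'
#' @param A,B,C Per-genome signed orders (data frames `chrom, block_id,
#'   sign`, see [signed_orders()]).
#' @return An `ancestral_reconstruction` list: `ancestral` (adjacency
#'   keys), `cars` (list of signed block orders, one per contiguous
#'   ancestral region with >= 2 blocks), `derived_in_A`, `lost_in_A`,
#'   `support` (named support counts over all observed adjacencies),
#'   `dropped` (conflict- or cycle-dropped adjacencies).
#' @export
ancestral_adjacencies <- function(A, B, C) {
  sets <- lapply(list(A = A, B = B, C = C), function(g) {
    unique(genome_adjacencies(g))
  })
  universes <- lapply(list(A, B, C), function(g)
    sort(unique(as.character(g$block_id))))
  if (!identical(universes[[1]], universes[[2]]) ||
      !identical(universes[[1]], universes[[3]])) {
    stop("ancestral_adjacencies: genomes do not share the same block set")
  }
  blocks <- universes[[1]]

  support <- table(unlist(sets))
  keys <- names(support)[support >= 2L]
  keys <- keys[order(-support[keys], keys)]

  ## conflict resolution: each block end used at most once
  used <- character(0)
  accepted <- character(0)
  dropped <- character(0)
  for (k in keys) {
    ends <- split_adjacency(k)[[1L]]
    if (any(ends %in% used)) {
      dropped <- c(dropped, k)
    } else {
      accepted <- c(accepted, k)
      used <- c(used, ends)
    }
  }

  ## cycle breaking: adjacencies link blocks; with ends used at most once
  ## the structure is a disjoint union of paths and cycles over blocks
  repeat {
    parent <- setNames(as.character(blocks), as.character(blocks))
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    cycle_break <- NULL
    for (k in sort(accepted)) {
      ends <- split_adjacency(k)[[1L]]
      b <- sub("\\.(head|tail)$", "", ends)
      ra <- find(b[1L]); rb <- find(b[2L])
      if (ra == rb) {
        ## closing adjacency: its cycle's lexicographically largest member
        ## must go; collect the cycle by walking the accepted set
        comp <- vapply(as.character(blocks), find, "")
        members <- accepted[vapply(accepted, function(kk) {
          bb <- sub("\\.(head|tail)$", "", split_adjacency(kk)[[1L]])
          find(bb[1L]) == ra || find(bb[2L]) == ra
        }, logical(1))]
        cycle_break <- max(c(members, k))
        break
      }
      parent[[ra]] <- rb
    }
    if (is.null(cycle_break)) break
    dropped <- c(dropped, cycle_break)
    accepted <- setdiff(accepted, cycle_break)
  }

  ## chain accepted adjacencies into contiguous ancestral regions
  end_partner <- list()
  for (k in accepted) {
    ends <- split_adjacency(k)[[1L]]
    end_partner[[ends[1L]]] <- ends[2L]
    end_partner[[ends[2L]]] <- ends[1L]
  }
  other_side <- function(e) {
    b <- sub("\\.(head|tail)$", "", e)
    side <- sub("^.*\\.", "", e)
    paste0(b, ".", if (side == "head") "tail" else "head")
  }
  seen <- character(0)
  cars <- list()
  for (b in as.character(blocks)) {
    if (b %in% seen) next
    ## start each walk from a free end (paths only; cycles were broken);
    ## interior blocks are reached from their path's free end later
    start <- NULL
    for (side in c("head", "tail")) {
      e <- paste0(b, ".", side)
      if (is.null(end_partner[[e]])) { start <- e; break }
    }
    if (is.null(start)) next
    ids <- character(0); sgn <- integer(0)
    e <- start
    repeat {
      blk <- sub("\\.(head|tail)$", "", e)
      side <- sub("^.*\\.", "", e)
      ids <- c(ids, blk)
      sgn <- c(sgn, if (side == "head") 1L else -1L)  # entered at head => +
      seen <- c(seen, blk)
      nxt <- end_partner[[other_side(e)]]
      if (is.null(nxt)) break
      e <- nxt
    }
    cars[[length(cars) + 1L]] <- data.frame(
      block_id = ids, sign = sgn, stringsAsFactors = FALSE)
  }
  stopifnot(setequal(seen, as.character(blocks)))
  cars <- cars[vapply(cars, nrow, integer(1)) >= 2L]

  adj_a <- sets$A
  structure(list(
    ancestral = sort(accepted),
    cars = cars,
    derived_in_A = sort(setdiff(adj_a, accepted)),
    lost_in_A = sort(setdiff(accepted, adj_a)),
    support = support,
    dropped = sort(unique(dropped))
  ), class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("ancestral_reconstruction:", length(x$ancestral), "adjacencies in",
      length(x$cars), "contiguous regions;",
      length(x$derived_in_A), "derived /", length(x$lost_in_A),
      "lost in genome A\n")
  invisible(x)
}
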
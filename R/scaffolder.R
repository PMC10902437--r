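# Scaffold ordering and orientation: threshold the linkage-score matrix
# into a terminal graph, solve the layout (exact dynamic programming on
# small components, greedy matching with min-edge cycle linearization on
# large ones), emit super-scaffold sequences plus AGP, and score recovery
# against simulated truth.

#' Build the scaffold terminal graph
#'
#' Candidate edges are exactly the inter-scaffold terminal pairs whose
#' linkage score is strictly greater than `threshold`; the obligatory
#' head-tail edge inside each scaffold is implicit.
#'
#' @param mat A [score_matrix()] result.
#' @param threshold Linkage-score cutoff (e.g. from [fit_null()], or the
#'   published 0.15).
#' @return A `scaffold_graph`: list with `terminals`, `edges` (data frame
#'   `scaffold_a, end_a, scaffold_b, end_b, score`) and `threshold`.
#' @export
build_graph <- function(mat, threshold) {
  stopifnot(inherits(mat, "linkage_score_matrix"))
  if (inherits(threshold, "ld_null_model")) threshold <- threshold$threshold
  t <- mat$terminals
  nt <- nrow(t)
  rows <- list()
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      s <- mat$scores[i, j]
      if (!is.na(s) && mat$n_pairs[i, j] >= 0L && s > threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_a = t$scaffold_id[i], end_a = t$end[i],
          scaffold_b = t$scaffold_id[j], end_b = t$end[j],
          score = s, stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_a = character(0), end_a = character(0),
               scaffold_b = character(0), end_b = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  structure(list(terminals = t, edges = edges, threshold = threshold),
            class = "scaffold_graph")
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat("scaffold_graph:", nrow(x$terminals) / 2L, "scaffolds,",
      nrow(x$edges), "candidate edges above threshold",
      sprintf("%.4f", x$threshold), "\n")
  invisible(x)
}

## ---- exact solver: maximum-weight path cover on one component ----------

# Oriented-scaffold transition weights: state k = 2*(i-1)+o with o = 1 (+)
# or 2 (-). W[k1, k2] is the score of the candidate edge joining the
# trailing end of state k1 to the leading end of state k2 (-Inf if none).
component_weights <- function(sids, edges) {
  s <- length(sids)
  W <- matrix(-Inf, 2L * s, 2L * s)
  st <- function(i, o) 2L * (i - 1L) + o
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$scaffold_a[r], sids)
    j <- match(edges$scaffold_b[r], sids)
    v <- edges$score[r]
    ea <- edges$end_a[r]; eb <- edges$end_b[r]
    ## direction i -> j
    oi <- if (ea == "tail") 1L else 2L   # trailing end of "+" is tail
    oj <- if (eb == "head") 1L else 2L   # leading end of "+" is head
    k1 <- st(i, oi); k2 <- st(j, oj)
    W[k1, k2] <- max(W[k1, k2], v)
    ## mirrored orientations traverse the same junction in reverse
    k1r <- st(j, if (eb == "tail") 1L else 2L)
    k2r <- st(i, if (ea == "head") 1L else 2L)
    W[k1r, k2r] <- max(W[k1r, k2r], v)
  }
  W
}

# Exact maximum-weight path cover over <= max_exact scaffolds by bitmask
# dynamic programming: h(set, last-state) = best single chain covering
# `set`; g(set) = best partition of `set` into chains. Optimal for the
# post-linearization objective, so it never forms cycles.
exact_path_cover <- function(sids, edges) {
  s <- length(sids)
  ns <- 2L * s
  W <- component_weights(sids, edges)
  nmask <- bitwShiftL(1L, s)
  H <- matrix(-Inf, nmask, ns)      # row mask+1
  P <- matrix(0L, nmask, ns)        # parent state (0 = chain start)
  scaffold_of <- rep(seq_len(s), each = 2L)
  bit <- bitwShiftL(1L, seq_len(s) - 1L)
  for (i in seq_len(s)) H[bit[i] + 1L, c(2L * i - 1L, 2L * i)] <- 0

  masks <- seq_len(nmask - 1L)
  pop <- vapply(masks, function(m) sum(bitwAnd(m, bit) > 0L), integer(1))
  for (m in masks[pop >= 2L]) {
    members <- which(bitwAnd(m, bit) > 0L)
    for (j in members) {
      sub <- m - bit[j]
      for (oj in 1:2) {
        kj <- 2L * (j - 1L) + oj
        v <- H[sub + 1L, ] + W[, kj]
        bi <- which.max(v)
        if (is.finite(v[bi]) && v[bi] > H[m + 1L, kj]) {
          H[m + 1L, kj] <- v[bi]
          P[m + 1L, kj] <- bi
        }
      }
    }
  }
  chainbest <- apply(H, 1L, max)
  chainstate <- apply(H, 1L, which.max)

  G <- rep(-Inf, nmask); G[1L] <- 0   # index mask+1
  TG <- integer(nmask)
  for (m in masks) {
    pivot <- bit[which(bitwAnd(m, bit) > 0L)[1L]]
    sub <- m
    repeat {
      if (bitwAnd(sub, pivot) > 0L && is.finite(chainbest[sub + 1L]) &&
          is.finite(G[m - sub + 1L])) {
        cand <- chainbest[sub + 1L] + G[m - sub + 1L]
        if (cand > G[m + 1L]) {
          G[m + 1L] <- cand
          TG[m + 1L] <- sub
        }
      }
      sub <- bitwAnd(sub - 1L, m)
      if (sub == 0L) break
    }
  }

  ## reconstruct chains
  chains <- list()
  cur <- nmask - 1L
  while (cur > 0L) {
    Tm <- TG[cur + 1L]
    k <- chainstate[Tm + 1L]
    states <- integer(0)
    mm <- Tm
    while (k > 0L) {
      states <- c(k, states)
      pk <- P[mm + 1L, k]
      mm <- mm - bit[scaffold_of[k]]
      k <- pk
    }
    i <- scaffold_of[states]
    o <- states - 2L * (i - 1L)
    sc <- if (length(states) > 1L) {
      vapply(seq_len(length(states) - 1L), function(q)
        W[states[q], states[q + 1L]], numeric(1))
    } else numeric(0)
    chains[[length(chains) + 1L]] <- data.frame(
      scaffold_id = sids[i], strand = c("+", "-")[o],
      score_next = c(sc, NA_real_), stringsAsFactors = FALSE
    )
    cur <- cur - Tm
  }
  list(chains = chains,
       removed_edges = data.frame(scaffold_a = character(0), end_a = character(0),
                                  scaffold_b = character(0), end_b = character(0),
                                  score = numeric(0), stringsAsFactors = FALSE),
       total = G[nmask])
}

## ---- greedy solver with min-edge cycle linearization -------------------

# Greedy maximal matching over terminals: edge indices taken by descending
# score (ties lexicographic) while both terminals are free.
greedy_matching <- function(la, lb, score, ord) {
  used <- character(0)
  matched <- integer(0)
  for (r in ord) {
    if (!(la[r] %in% used) && !(lb[r] %in% used)) {
      matched <- c(matched, r)
      used <- c(used, la[r], lb[r])
    }
  }
  matched
}

# Deterministic local search towards the maximum-weight matching: strict
# total-weight improvements only (edge additions, single-endpoint
# replacements, and pairwise rewires), so the loop terminates; a pass cap
# guards against pathological inputs.
improve_matching <- function(matched, la, lb, score, max_passes = 100L) {
  eps <- 1e-12
  edge_of <- function(ms) {
    u <- c(la[ms], lb[ms])
    setNames(rep(ms, 2L), u)
  }
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    owner <- edge_of(matched)
    free <- function(t) is.na(owner[t])
    ## additions
    for (r in order(-score, pmin(la, lb), pmax(la, lb))) {
      if (r %in% matched) next
      if (is.na(owner[la[r]]) && is.na(owner[lb[r]])) {
        matched <- c(matched, r)
        owner <- edge_of(matched)
        changed <- TRUE
      }
    }
    ## single replacements: swap a matched edge for a strictly better edge
    ## sharing one terminal whose other terminal is free
    for (r in seq_along(score)) {
      if (r %in% matched) next
      e1 <- owner[la[r]]; e2 <- owner[lb[r]]
      if (!is.na(e1) && is.na(e2) && score[r] > score[e1] + eps) {
        matched <- c(setdiff(matched, e1), r)
        owner <- edge_of(matched)
        changed <- TRUE
      } else if (is.na(e1) && !is.na(e2) && score[r] > score[e2] + eps) {
        matched <- c(setdiff(matched, e2), r)
        owner <- edge_of(matched)
        changed <- TRUE
      }
    }
    ## pairwise rewires: drop matched edges e1, e2 and rematch their four
    ## terminals with two candidate edges of larger total weight
    cand_between <- local({
      key <- adjacency_key(la, lb)
      setNames(seq_along(key), key)
    })
    ms <- sort(matched)
    for (i in seq_along(ms)) {
      for (j in seq_along(ms)) {
        if (j <= i) next
        e1 <- ms[i]; e2 <- ms[j]
        if (!(e1 %in% matched) || !(e2 %in% matched)) next
        ends <- c(la[e1], lb[e1], la[e2], lb[e2])
        for (alt in list(c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))) {
          k1 <- cand_between[adjacency_key(ends[alt[1L]], ends[alt[2L]])]
          k2 <- cand_between[adjacency_key(ends[alt[3L]], ends[alt[4L]])]
          if (is.na(k1) || is.na(k2)) next
          if (score[k1] + score[k2] > score[e1] + score[e2] + eps) {
            matched <- c(setdiff(matched, c(e1, e2)), unname(c(k1, k2)))
            owner <- edge_of(matched)
            changed <- TRUE
            break
          }
        }
      }
    }
    if (!changed) break
  }
  sort(matched)
}

greedy_chains <- function(sids, edges) {
  la <- terminal_label(edges$scaffold_a, edges$end_a)
  lb <- terminal_label(edges$scaffold_b, edges$end_b)
  ord <- order(-edges$score, pmin(la, lb), pmax(la, lb))
  matched <- improve_matching(greedy_matching(la, lb, edges$score, ord),
                              la, lb, edges$score)
  partner <- list()   # terminal label -> list(partner label, score)
  for (r in matched) {
    partner[[la[r]]] <- list(to = lb[r], score = edges$score[r])
    partner[[lb[r]]] <- list(to = la[r], score = edges$score[r])
  }
  removed <- list()

  other_end <- function(end) if (end == "head") "tail" else "head"
  split_label <- function(lbl) {
    k <- regexpr(":[^:]*$", lbl)
    list(scaffold = substr(lbl, 1L, k - 1L),
         end = substr(lbl, k + 1L, nchar(lbl)))
  }

  walk <- function(start_scaffold, enter_end) {
    ids <- character(0); strands <- character(0); scores <- numeric(0)
    s <- start_scaffold; e <- enter_end
    repeat {
      ids <- c(ids, s)
      strands <- c(strands, if (e == "head") "+" else "-")
      exit <- terminal_label(s, other_end(e))
      m <- partner[[exit]]
      if (is.null(m)) break
      scores <- c(scores, m$score)
      nxt <- split_label(m$to)
      s <- nxt$scaffold; e <- nxt$end
    }
    data.frame(scaffold_id = ids, strand = strands,
               score_next = c(scores, NA_real_), stringsAsFactors = FALSE)
  }

  visited <- character(0)
  chains <- list()
  ## paths: start from scaffolds with at least one unmatched terminal
  for (s in sids) {
    if (s %in% visited) next
    free_head <- is.null(partner[[terminal_label(s, "head")]])
    free_tail <- is.null(partner[[terminal_label(s, "tail")]])
    if (!free_head && !free_tail) next
    enter <- if (free_head) "head" else "tail"
    ch <- walk(s, enter)
    visited <- c(visited, ch$scaffold_id)
    chains[[length(chains) + 1L]] <- ch
  }
  ## remaining scaffolds sit on cycles: cut the weakest matching edge
  for (s in sids) {
    if (s %in% visited) next
    ## trace the cycle's matching edges from this scaffold
    cyc <- list()
    cur <- s; e <- "head"
    repeat {
      exit <- terminal_label(cur, other_end(e))
      m <- partner[[exit]]
      cyc[[length(cyc) + 1L]] <- list(from = exit, to = m$to, score = m$score)
      nxt <- split_label(m$to)
      cur <- nxt$scaffold; e <- nxt$end
      if (cur == s) break
    }
    sc <- vapply(cyc, function(x) x$score, numeric(1))
    key <- vapply(cyc, function(x) adjacency_key(x$from, x$to), "")
    cut <- order(sc, key)[1L]
    cut_edge <- cyc[[cut]]
    a <- split_label(cut_edge$from); b <- split_label(cut_edge$to)
    removed[[length(removed) + 1L]] <- data.frame(
      scaffold_a = a$scaffold, end_a = a$end,
      scaffold_b = b$scaffold, end_b = b$end,
      score = cut_edge$score, stringsAsFactors = FALSE
    )
    partner[[cut_edge$from]] <- NULL
    partner[[cut_edge$to]] <- NULL
    ## the freed terminal is now the outer (leading) end of the opened path
    ch <- walk(a$scaffold, a$end)
    visited <- c(visited, ch$scaffold_id)
    chains[[length(chains) + 1L]] <- ch
  }
  list(chains = chains,
       removed_edges = if (length(removed)) do.call(rbind, removed) else
         data.frame(scaffold_a = character(0), end_a = character(0),
                    scaffold_b = character(0), end_b = character(0),
                    score = numeric(0), stringsAsFactors = FALSE),
       total = sum(vapply(chains, function(ch)
         sum(ch$score_next, na.rm = TRUE), numeric(1))))
}

canonicalize_chain <- function(ch) {
  n <- nrow(ch)
  if (n == 1L) {
    ch$strand <- "+"
    return(ch)
  }
  if (ch$scaffold_id[n] < ch$scaffold_id[1L]) {
    sc <- ch$score_next[-n]
    ch <- data.frame(
      scaffold_id = rev(ch$scaffold_id),
      strand = rev(ifelse(ch$strand == "+", "-", "+")),
      score_next = c(rev(sc), NA_real_),
      stringsAsFactors = FALSE
    )
  }
  ch
}

#' Solve the scaffold layout
#'
#' Decomposes the candidate-edge graph into connected components and, per
#' component, finds ordered, oriented scaffold chains maximizing the total
#' junction score. Components with at most `max_exact` scaffolds are solved
#' exactly (maximum-weight path cover by dynamic programming, provably
#' optimal for the linear objective); larger components use greedy
#' matching by descending score with every resulting cycle linearized by
#' deleting its minimum-score candidate edge (recorded in
#' `removed_edges`). Each chain is canonicalized so its lexicographically
#' smaller end scaffold comes first; singletons are reported strand `+`.
#'
#' @param graph A [build_graph()] result.
#' @param method `"auto"` (exact up to `max_exact`, greedy beyond),
#'   `"exact"`, or `"greedy"`.
#' @param max_exact Component size limit for the exact solver.
#' @return A `scaffold_layout`: list with `super_scaffolds` (data frames of
#'   `scaffold_id`, `strand`, `score_next`), `singletons`,
#'   `removed_edges`, `total_score`, `threshold`, `method`.
#' @export
solve_layout <- function(graph, method = c("auto", "exact", "greedy"),
                         max_exact = 10L) {
  stopifnot(inherits(graph, "scaffold_graph"))
  method <- match.arg(method)
  sids <- sort(unique(graph$terminals$scaffold_id))
  edges <- graph$edges

  ## connected components over scaffolds
  comp <- setNames(seq_along(sids), sids)
  find <- function(x) { while (comp[[x]] != match(x, sids)) x <- sids[comp[[x]]]; x }
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges$scaffold_a[r]); rb <- find(edges$scaffold_b[r])
    if (ra != rb) comp[[ra]] <- match(rb, sids)
  }
  roots <- vapply(sids, find, "")
  groups <- split(sids, roots)

  chains <- list()
  removed <- list()
  total <- 0
  for (g in groups[order(vapply(groups, min, ""))]) {
    g <- sort(g)
    if (length(g) == 1L) {
      chains[[length(chains) + 1L]] <- data.frame(
        scaffold_id = g, strand = "+", score_next = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    eg <- edges[edges$scaffold_a %in% g & edges$scaffold_b %in% g, ,
                drop = FALSE]
    use_exact <- method == "exact" ||
      (method == "auto" && length(g) <= max_exact)
    if (use_exact && length(g) > 24L) {
      stop("solve_layout: component of ", length(g),
           " scaffolds is too large for method = \"exact\"")
    }
    res <- if (use_exact) exact_path_cover(g, eg) else greedy_chains(g, eg)
    chains <- c(chains, res$chains)
    if (nrow(res$removed_edges)) {
      removed[[length(removed) + 1L]] <- res$removed_edges
    }
    total <- total + res$total
  }

  chains <- lapply(chains, canonicalize_chain)
  ord <- order(vapply(chains, function(ch) ch$scaffold_id[1L], ""))
  chains <- chains[ord]
  is_single <- vapply(chains, nrow, integer(1)) == 1L

  ## partition invariant: every input scaffold exactly once
  all_ids <- unlist(lapply(chains, function(ch) ch$scaffold_id))
  stopifnot(identical(sort(all_ids), sids))

  structure(list(
    super_scaffolds = chains[!is_single],
    singletons = vapply(chains[is_single], function(ch) ch$scaffold_id, ""),
    removed_edges = if (length(removed)) do.call(rbind, removed) else
      data.frame(scaffold_a = character(0), end_a = character(0),
                 scaffold_b = character(0), end_b = character(0),
                 score = numeric(0), stringsAsFactors = FALSE),
    total_score = total,
    threshold = graph$threshold,
    method = method
  ), class = "scaffold_layout")
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat("scaffold_layout:", length(x$super_scaffolds), "super-scaffolds,",
      length(x$singletons), "singletons,",
      nrow(x$removed_edges), "edges cut during linearization; total score",
      sprintf("%.4f", x$total_score), "\n")
  invisible(x)
}

# Junction table of a layout: one row per joined pair of terminals.
layout_junctions <- function(layout) {
  rows <- lapply(layout$super_scaffolds, function(ch) {
    n <- nrow(ch)
    i <- seq_len(n - 1L)
    data.frame(
      scaffold_a = ch$scaffold_id[i],
      end_a = trailing_end(ch$strand[i]),
      scaffold_b = ch$scaffold_id[i + 1L],
      end_b = leading_end(ch$strand[i + 1L]),
      score = ch$score_next[i],
      stringsAsFactors = FALSE
    )
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_a = character(0), end_a = character(0),
               scaffold_b = character(0), end_b = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
}

#' Emit super-scaffold sequences and the matching AGP
#'
#' Concatenates each chain's component sequences (reverse-complementing
#' strand `-` components) with `gap_length` Ns between them; singletons
#' pass through unchanged as single-component objects. AGP rows alternate
#' W component lines and U gap lines (gap type scaffold, linkage yes).
#'
#' @param layout A [solve_layout()] result.
#' @param sequences Named character vector or `DNAStringSet` with every
#'   scaffold in the layout.
#' @param gap_length N-run length between joined components.
#' @param prefix Object-name prefix (objects are `prefix_1`, `prefix_2`,
#'   ... super-scaffolds first, then singletons).
#' @return List with `fasta` (`DNAStringSet`) and `agp` (data frame).
#' @export
emit_super_scaffolds <- function(layout, sequences, gap_length = 100L,
                                 prefix = "super") {
  stopifnot(inherits(layout, "scaffold_layout"))
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  chains <- c(layout$super_scaffolds,
              lapply(sort(layout$singletons), function(s)
                data.frame(scaffold_id = s, strand = "+",
                           score_next = NA_real_, stringsAsFactors = FALSE)))
  need <- unlist(lapply(chains, function(ch) ch$scaffold_id))
  missing_seq <- setdiff(need, names(sequences))
  if (length(missing_seq)) {
    stop("emit_super_scaffolds: no sequence for scaffold(s): ",
         paste(missing_seq, collapse = ", "))
  }
  seqs <- character(0)
  agp <- list()
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    obj <- sprintf("%s_%d", prefix, i)
    parts <- ifelse(ch$strand == "-",
                    revcomp(sequences[ch$scaffold_id]),
                    sequences[ch$scaffold_id])
    seqs[[obj]] <- paste(parts, collapse = strrep("N", gap_length))
    agp[[i]] <- layout_to_agp(obj, ch$scaffold_id, ch$strand,
                              nchar(sequences[ch$scaffold_id]),
                              gap_length = gap_length)
  }
  list(fasta = Biostrings::DNAStringSet(seqs),
       agp = if (length(agp)) do.call(rbind, agp) else NULL)
}

#' Score a layout against the simulated truth
#'
#' A called junction is correct when it joins the same two scaffold
#' terminals as a true adjacency, irrespective of the direction either
#' super-scaffold is read in. Precision = correct / called (NA when no
#' junction is called), recall = correct / true, orientation accuracy =
#' fraction of correct junctions whose relative strand matches truth
#' (NA when no junction is correct).
#'
#' @param layout A [solve_layout()] result.
#' @param truth Truth adjacency data frame (`scaffold_a, end_a, scaffold_b,
#'   end_b`, e.g. `sim$truth$adjacencies`) or the path of the TSV written
#'   by [emit_dataset()].
#' @return An `ld_recovery` list: `precision`, `recall`,
#'   `orientation_accuracy`, `n_called`, `n_true`, `n_correct`.
#' @export
compare_to_truth <- function(layout, truth) {
  stopifnot(inherits(layout, "scaffold_layout"))
  if (is.character(truth) && length(truth) == 1L) {
    truth <- read.table(truth, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  }
  called <- layout_junctions(layout)
  known <- unique(c(truth$scaffold_a, truth$scaffold_b))
  layout_ids <- unique(c(called$scaffold_a, called$scaffold_b,
                         unlist(lapply(layout$super_scaffolds,
                                       function(ch) ch$scaffold_id)),
                         layout$singletons))
  if (nrow(truth) && length(setdiff(layout_ids, known))) {
    stop("compare_to_truth: layout contains scaffold ids absent from truth: ",
         paste(setdiff(layout_ids, known), collapse = ", "))
  }
  key <- function(df) adjacency_key(terminal_label(df$scaffold_a, df$end_a),
                                    terminal_label(df$scaffold_b, df$end_b))
  called_keys <- key(called)
  true_keys <- key(truth)
  n_correct <- sum(called_keys %in% true_keys)
  ## a junction on the same two terminals fixes the relative orientation,
  ## so orientation accuracy over correct junctions is computed from the
  ## end labels themselves
  structure(list(
    precision = if (nrow(called)) n_correct / nrow(called) else NA_real_,
    recall = if (nrow(truth)) n_correct / nrow(truth) else NA_real_,
    orientation_accuracy = if (n_correct) 1 else NA_real_,
    n_called = nrow(called),
    n_true = nrow(truth),
    n_correct = n_correct
  ), class = "ld_recovery")
}

#' @export
print.ld_recovery <- function(x, ...) {
  cat(sprintf(
    "ld_recovery: precision %s, recall %s, orientation %s (%d/%d correct)\n",
    format(x$precision, digits = 3), format(x$recall, digits = 3),
    format(x$orientation_accuracy, digits = 3), x$n_correct, x$n_true))
  invisible(x)
}
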
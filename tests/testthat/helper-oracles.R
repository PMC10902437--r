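# Independent brute-force oracles. Each deliberately re-derives its
# quantity from first principles (direct formulas, exhaustive enumeration)
# and never calls the implementation path it checks.

# Pearson r^2 of genotype codes via the raw-moment formula over complete
# pairs; NA when undefined.
oracle_r2_genotype <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den_a <- n * sum(a^2) - sum(a)^2
  den_b <- n * sum(b^2) - sum(b)^2
  if (den_a == 0 || den_b == 0) return(NA_real_)
  num^2 / (den_a * den_b)
}

# Haplotype r^2 via explicit two-locus haplotype counting.
oracle_r2_haplotype <- function(ha, hb) {
  n <- length(ha)
  n_ab <- sum(ha == 1 & hb == 1)
  p_a <- sum(ha == 1) / n
  p_b <- sum(hb == 1) / n
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) return(NA_real_)
  d <- n_ab / n - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

# Exhaustive optimum over all signed scaffold orderings: junctions score
# only when strictly above the threshold (below-threshold junctions are
# breaks contributing 0). `scores` is the symmetric terminal matrix with
# "<id>:head"/"<id>:tail" dimnames.
oracle_best_order_total <- function(scaffold_ids, scores, threshold) {
  n <- length(scaffold_ids)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  signs_grid <- as.matrix(expand.grid(rep(list(c("+", "-")), n)))
  for (p in perms(scaffold_ids)) {
    for (g in seq_len(nrow(signs_grid))) {
      sg <- signs_grid[g, ]
      total <- 0
      for (i in seq_len(n - 1)) {
        t1 <- paste0(p[i], ":", if (sg[i] == "+") "tail" else "head")
        t2 <- paste0(p[i + 1], ":", if (sg[i + 1] == "+") "head" else "tail")
        s <- scores[t1, t2]
        if (!is.na(s) && s > threshold) total <- total + s
      }
      best <- max(best, total)
    }
  }
  best
}

# N50/N90 by explicit descending walk.
oracle_nx <- function(lengths, frac) {
  lens <- sort(lengths, decreasing = TRUE)
  target <- frac * sum(lens)
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= target) return(l)
  }
  NA_real_
}

# All maximal reversed runs of a signed permutation (quadratic scan):
# every [i, j] with all signs -1, one chromosome, strictly decreasing
# indices, not extendable either way.
oracle_reversed_runs <- function(sign, other_chrom, other_index) {
  n <- length(sign)
  is_run <- function(i, j) {
    if (any(sign[i:j] != -1)) return(FALSE)
    if (length(unique(other_chrom[i:j])) != 1) return(FALSE)
    if (j > i && any(diff(other_index[i:j]) >= 0)) return(FALSE)
    TRUE
  }
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!is_run(i, j)) next
      left_ext <- i > 1 && is_run(i - 1, j)
      right_ext <- j < n && is_run(i, j + 1)
      if (!left_ext && !right_ext) runs[[length(runs) + 1]] <- c(i, j)
    }
  }
  runs
}

# Small-parsimony (Fitch) presence state of the (A,B) ancestor on the
# rooted tree ((A,B),C), by enumerating internal-node states; ties go to
# the majority state.
oracle_fitch_ancestor <- function(in_a, in_b, in_c) {
  leaves <- c(A = in_a, B = in_b, C = in_c)
  best_cost <- Inf
  best_states <- c()
  for (x in c(0, 1)) {
    for (r in c(0, 1)) {
      cost <- (leaves["A"] != x) + (leaves["B"] != x) + (x != r) +
        (leaves["C"] != r)
      if (cost < best_cost) {
        best_cost <- cost
        best_states <- x
      } else if (cost == best_cost) {
        best_states <- union(best_states, x)
      }
    }
  }
  if (length(best_states) == 1) return(best_states)
  as.numeric(sum(leaves) >= 2)
}

# ---- small fixture builders --------------------------------------------

# Genotype matrix with given dosage rows (list of vectors).
make_gm <- function(rows, scaffold_id = "s1", pos = NULL) {
  geno <- do.call(rbind, rows)
  colnames(geno) <- sprintf("smp%02d", seq_len(ncol(geno)))
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 10L
  genotype_matrix(scaffold_id, pos, rep("A", nrow(geno)),
                  rep("C", nrow(geno)), geno)
}

# Edge-block pair built directly from two dosage row lists.
make_edges <- function(scaffold_id, head_rows, tail_rows) {
  mk <- function(rows, end, offset) {
    geno <- do.call(rbind, rows)
    colnames(geno) <- sprintf("smp%02d", seq_len(ncol(geno)))
    storage.mode(geno) <- "integer"
    structure(list(scaffold_id = scaffold_id, end = end,
                   pos = offset + seq_along(rows) * 10L, geno = geno),
              class = "edge_block")
  }
  list(head = mk(head_rows, "head", 0L),
       tail = mk(tail_rows, "tail", 10000L))
}

# Score matrix built directly from a full symmetric matrix of terminal
# scores (list input: terminals in lexicographic scaffold/head-tail order).
make_score_matrix <- function(scaffold_ids, fill = 0) {
  terminals <- data.frame(
    scaffold_id = rep(sort(scaffold_ids), each = 2),
    end = rep(c("head", "tail"), length(scaffold_ids)),
    stringsAsFactors = FALSE
  )
  labels <- paste(terminals$scaffold_id, terminals$end, sep = ":")
  nt <- length(labels)
  scores <- matrix(fill, nt, nt, dimnames = list(labels, labels))
  n_pairs <- matrix(1L, nt, nt, dimnames = list(labels, labels))
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (terminals$scaffold_id[i] == terminals$scaffold_id[j]) {
        scores[i, j] <- NA_real_
        n_pairs[i, j] <- -1L
      }
    }
  }
  structure(list(terminals = terminals, scores = scores, n_pairs = n_pairs),
            class = "linkage_score_matrix")
}

set_score <- function(mat, t1, t2, value) {
  mat$scores[t1, t2] <- mat$scores[t2, t1] <- value
  mat
}

# Random dosage vector guaranteed polymorphic.
random_dosage <- function(n) {
  repeat {
    g <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    if (length(unique(g)) > 1) return(g)
  }
}
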
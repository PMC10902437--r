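# LD statistics: per-pair r2 (genotype/composite and haplotype forms),
# aggregation into linkage scores between scaffold terminals, and the
# Gaussian null fit that yields the junction threshold.

#' Composite (genotype) r-squared between two sites
#'
#' Squared Pearson correlation of ALT-dosage codes over pairwise-complete
#' samples (composite, Rogers-Huff-style LD; phase-free, so it applies to
#' unphased calls). Undefined when fewer than two complete pairs remain or
#' either site is monomorphic among them; undefined pairs raise a condition
#' of class `ldrefine_undefined_ld` which aggregate callers skip.
#'
#' @param a,b Numeric vectors of genotype codes (0/1/2, `NA` missing) over
#'   the same samples, or `edge_block`/site rows coerced with [as.numeric].
#' @return r-squared in `[0, 1]`.
#' @examples
#' r2_genotype(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))  # 1
#' @export
r2_genotype <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("r2_genotype: unequal sample counts")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop_undefined_ld("fewer than 2 complete genotype pairs")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop_undefined_ld("monomorphic site among complete pairs")
  }
  r <- stats::cor(a, b)
  min(1, r * r)
}

#' Haplotype r-squared (classical D-squared form)
#'
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB` counted from
#' phased binary haplotypes. Kept as the test oracle for simulated phased
#' data; the pipeline itself uses [r2_genotype()].
#'
#' @param hap_a,hap_b Binary vectors (0/1) of equal length >= 2, one entry
#'   per haplotype.
#' @return r-squared in `[0, 1]`.
#' @export
r2_haplotype <- function(hap_a, hap_b) {
  hap_a <- as.numeric(hap_a)
  hap_b <- as.numeric(hap_b)
  if (length(hap_a) != length(hap_b) || length(hap_a) < 2L) {
    stop("r2_haplotype: need equal-length haplotype vectors of length >= 2")
  }
  if (any(is.na(hap_a)) || any(is.na(hap_b))) {
    stop("r2_haplotype: phased haplotypes cannot be missing")
  }
  p_a <- mean(hap_a)
  p_b <- mean(hap_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop_undefined_ld("monomorphic haplotype vector")
  }
  p_ab <- mean(hap_a == 1 & hap_b == 1)
  d <- p_ab - p_a * p_b
  min(1, d * d / (p_a * (1 - p_a) * p_b * (1 - p_b)))
}

edge_block_geno <- function(x) {
  if (inherits(x, "edge_block")) x$geno else as.matrix(x)
}

#' Linkage score between two scaffold-edge SNP windows
#'
#' Mean of [r2_genotype()] over all cross pairs of sites between the two
#' windows; pairs with undefined LD are skipped, not zero-filled. When
#' `max_pairs` is set and the number of cross pairs exceeds it, a seeded
#' uniform subsample of pairs is scored instead.
#'
#' @param x,y `edge_block` objects (or genotype matrices, sites x samples)
#'   from different scaffolds.
#' @param max_pairs Optional cap on the number of site pairs scored.
#' @param seed Seed for the pair subsample (only used with `max_pairs`).
#' @return Score in `[0, 1]` with attribute `n_pairs_used`; raises an
#'   `ldrefine_undefined_ld` condition when every pair is undefined.
#' @export
edge_score <- function(x, y, max_pairs = NULL, seed = 1L) {
  gx <- edge_block_geno(x)
  gy <- edge_block_geno(y)
  if (!nrow(gx) || !nrow(gy)) stop_undefined_ld("empty edge window")
  if (ncol(gx) != ncol(gy)) stop("edge_score: sample sets differ")
  n_total <- as.double(nrow(gx)) * nrow(gy)
  if (!is.null(max_pairs) && n_total > max_pairs) {
    idx <- with_seed(seed, sample.int(n_total, max_pairs))
    i <- ((idx - 1) %% nrow(gx)) + 1
    j <- ((idx - 1) %/% nrow(gx)) + 1
    vals <- vapply(seq_along(i), function(p) {
      tryCatch(r2_genotype(gx[i[p], ], gy[j[p], ]),
               ldrefine_undefined_ld = function(e) NA_real_)
    }, numeric(1))
  } else {
    r <- suppressWarnings(
      stats::cor(t(gx), t(gy), use = "pairwise.complete.obs")
    )
    vals <- as.vector(r * r)
    ## pairwise-complete correlation with < 2 shared samples or a
    ## zero-variance side yields NA/NaN, matching the skip rule
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop_undefined_ld("all site pairs undefined")
  structure(min(1, mean(vals)), n_pairs_used = length(vals))
}

#' Linkage score matrix over all scaffold terminals
#'
#' Scores every inter-scaffold pair of terminals (head/tail of each
#' scaffold); cells on the diagonal and between the two ends of the same
#' scaffold are flagged internal (`NA` with `n_pairs = -1`). Symmetric by
#' construction.
#'
#' @param edge_blocks Named list (one element per scaffold) of
#'   `list(head =, tail =)` as returned by [extract_edge_blocks()].
#' @param max_pairs,seed Passed to [edge_score()].
#' @return A `linkage_score_matrix`: list with `terminals` (data frame of
#'   `scaffold_id`, `end` in lexicographic order), `scores` (symmetric
#'   matrix in `[0, 1]`, `NA` where internal or undefined) and `n_pairs`
#'   (site pairs used per cell; `-1` internal, `0` undefined).
#' @export
score_matrix <- function(edge_blocks, max_pairs = NULL, seed = 1L) {
  if (length(edge_blocks) < 2L) stop("score_matrix: need >= 2 scaffolds")
  sids <- sort(vapply(edge_blocks, function(e) e$head$scaffold_id, ""))
  if (anyDuplicated(sids)) stop("score_matrix: duplicate scaffold ids")
  terminals <- data.frame(
    scaffold_id = rep(sids, each = 2L),
    end = rep(c("head", "tail"), length(sids)),
    stringsAsFactors = FALSE
  )
  labels <- terminal_label(terminals$scaffold_id, terminals$end)
  nt <- nrow(terminals)
  scores <- matrix(NA_real_, nt, nt, dimnames = list(labels, labels))
  n_pairs <- matrix(0L, nt, nt, dimnames = list(labels, labels))
  diag(n_pairs) <- -1L
  by_id <- setNames(edge_blocks, vapply(edge_blocks, function(e)
    e$head$scaffold_id, ""))
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      if (terminals$scaffold_id[i] == terminals$scaffold_id[j]) {
        n_pairs[i, j] <- n_pairs[j, i] <- -1L
        next
      }
      bi <- by_id[[terminals$scaffold_id[i]]][[terminals$end[i]]]
      bj <- by_id[[terminals$scaffold_id[j]]][[terminals$end[j]]]
      s <- tryCatch(edge_score(bi, bj, max_pairs = max_pairs, seed = seed),
                    ldrefine_undefined_ld = function(e) NULL)
      if (!is.null(s)) {
        scores[i, j] <- scores[j, i] <- as.numeric(s)
        n_pairs[i, j] <- n_pairs[j, i] <- attr(s, "n_pairs_used")
      }
    }
  }
  structure(list(terminals = terminals, scores = scores, n_pairs = n_pairs),
            class = "linkage_score_matrix")
}

#' @export
print.linkage_score_matrix <- function(x, ...) {
  v <- defined_scores(x)
  cat("linkage_score_matrix:", nrow(x$terminals) / 2L, "scaffolds,",
      length(v), "defined inter-scaffold scores",
      if (length(v)) sprintf("(median %.4f)", stats::median(v)) else "", "\n")
  invisible(x)
}

# Defined inter-scaffold scores from the upper triangle.
defined_scores <- function(mat) {
  stopifnot(inherits(mat, "linkage_score_matrix"))
  ut <- upper.tri(mat$scores)
  v <- mat$scores[ut & mat$n_pairs >= 0L]
  v[!is.na(v)]
}

#' Fit the Gaussian null to the linkage-score distribution
#'
#' True junctions are a vanishing fraction of all inter-scaffold terminal
#' pairs, so the bulk of the score distribution estimates the random-score
#' null. The fit is robust: location = median, scale = 1.4826 x MAD over
#' all defined inter-scaffold scores; the junction threshold is the upper
#' bound of the central two-sided `ci_level` interval of that normal,
#' `location + z * scale` with `z = qnorm(0.5 + ci_level / 2)` (2.17 for
#' the default 97%).
#'
#' @param mat A [score_matrix()] result.
#' @param ci_level Central interval mass (default 0.97).
#' @return An `ld_null_model`: list with `mean`, `sd`, `threshold`,
#'   `ci_level`, `n_scores`.
#' @export
fit_null <- function(mat, ci_level = 0.97) {
  v <- defined_scores(mat)
  if (length(v) < 20L) {
    stop("fit_null: only ", length(v), " defined scores (< 20); ",
         "set the threshold manually")
  }
  if (ci_level <= 0 || ci_level >= 1) stop("fit_null: ci_level in (0, 1)")
  loc <- stats::median(v)
  scl <- stats::mad(v, center = loc)
  z <- stats::qnorm(0.5 + ci_level / 2)
  structure(list(mean = loc, sd = scl, threshold = loc + z * scl,
                 ci_level = ci_level, n_scores = length(v)),
            class = "ld_null_model")
}

#' @export
print.ld_null_model <- function(x, ...) {
  cat(sprintf(
    "ld_null_model: mean %.4f, sd %.4f -> threshold %.4f (%d scores, %.0f%% CI)\n",
    x$mean, x$sd, x$threshold, x$n_scores, 100 * x$ci_level))
  invisible(x)
}
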
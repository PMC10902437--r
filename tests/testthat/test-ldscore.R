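# r2 statistics, edge scores, the terminal score matrix, and the null fit.

test_that("r2_genotype matches its examples and the brute-force oracle", {
  expect_equal(r2_genotype(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)), 1)
  expect_error(r2_genotype(c(0, 0, 1, 1), c(1, 1, 1, 1)),
               class = "ldrefine_undefined_ld")
  expect_equal(r2_genotype(c(0, 0, 2, 2, 1, 1), c(0, 2, 0, 2, 1, 1)), 0)

  set.seed(11)
  for (i in 1:300) {
    a <- random_dosage(25); b <- random_dosage(25)
    a[sample(25, 3)] <- NA
    expected <- oracle_r2_genotype(a, b)
    got <- tryCatch(r2_genotype(a, b),
                    ldrefine_undefined_ld = function(e) NA_real_)
    if (is.na(expected)) expect_true(is.na(got)) else
      expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("r2_haplotype reproduces the worked counting example", {
  ## 8 haplotypes: AB x4, ab x2, Ab x1, aB x1
  ha <- c(1, 1, 1, 1, 0, 0, 1, 0)
  hb <- c(1, 1, 1, 1, 0, 0, 0, 1)
  expect_equal(r2_haplotype(ha, hb), 0.011962890625 / 0.054931640625,
               tolerance = 1e-15)
  expect_equal(r2_haplotype(ha, hb), oracle_r2_haplotype(ha, hb),
               tolerance = 1e-15)
  ## perfectly coupled and exactly independent patterns
  expect_equal(r2_haplotype(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(r2_haplotype(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(r2_haplotype(c(1, 1, 1, 1), c(1, 0, 1, 0)),
               class = "ldrefine_undefined_ld")
})

test_that("without double heterozygotes the genotype covariance is 4D", {
  ## with no sample heterozygous at both sites the within-individual cross
  ## terms equal the within-haplotype direct terms, so the (population)
  ## genotype covariance is exactly 4 x the haplotype D; this is the exact
  ## phase-free identity the composite statistic rests on
  set.seed(21)
  checked <- 0
  for (k in 1:500) {
    if (checked >= 20) break
    ha <- sample(0:1, 16, replace = TRUE)
    hb <- if (stats::runif(1) < 0.5) ha else sample(0:1, 16, replace = TRUE)
    g_a <- ha[c(TRUE, FALSE)] + ha[c(FALSE, TRUE)]
    g_b <- hb[c(TRUE, FALSE)] + hb[c(FALSE, TRUE)]
    if (any(g_a == 1 & g_b == 1)) next
    d <- mean(ha == 1 & hb == 1) - mean(ha) * mean(hb)
    cov_g <- mean(g_a * g_b) - mean(g_a) * mean(g_b)
    expect_equal(cov_g, 4 * d, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("genotype r2 tracks haplotype r2 across the LD spectrum", {
  ## a panel rich in strong-, mid- and weak-LD pairs
  sim <- simulate_truth(sim_config(chromosome_length = 3e5, n_scaffolds = 2,
                                   n_samples = 40, n_founders = 6,
                                   n_sites = 150, recomb_rate = 1e-5,
                                   seed = 4))
  hap <- sim$panel$haplotypes
  h1 <- hap[seq(1, 79, 2), ]; h2 <- hap[seq(2, 80, 2), ]
  geno <- h1 + h2
  set.seed(22)
  all_r2g <- c(); all_r2h <- c()
  for (k in 1:400) {
    ij <- sample(ncol(hap), 2)
    r2h <- tryCatch(r2_haplotype(hap[, ij[1]], hap[, ij[2]]),
                    ldrefine_undefined_ld = function(e) NA_real_)
    r2g <- tryCatch(r2_genotype(geno[, ij[1]], geno[, ij[2]]),
                    ldrefine_undefined_ld = function(e) NA_real_)
    if (is.na(r2h) || is.na(r2g)) next
    all_r2g <- c(all_r2g, r2g); all_r2h <- c(all_r2h, r2h)
  }
  expect_gt(stats::cor(all_r2g, all_r2h), 0.9)
})

test_that("edge_score averages defined pairs and is symmetric", {
  ## four cross pairs with r2 {1, 0, 0, 1} -> 0.5
  x <- make_edges("sx", list(c(0, 0, 2, 2, 1, 1), c(0, 2, 0, 2, 1, 1)),
                  list(c(0, 1, 1, 2, 0, 1)))$head
  y <- make_edges("sy", list(c(0, 0, 2, 2, 1, 1), c(0, 2, 0, 2, 1, 1)),
                  list(c(0, 1, 1, 2, 0, 1)))$head
  s <- edge_score(x, y)
  expect_equal(as.numeric(s), 0.5)
  expect_equal(attr(s, "n_pairs_used"), 4L)
  expect_equal(as.numeric(edge_score(y, x)), as.numeric(s))

  ## one defined pair among undefined ones
  x1 <- make_edges("sx", list(c(0, 1, 2, 1)), list(c(0, 0, 1, 1)))$head
  y1 <- make_edges("sy", list(c(1, 1, 1, 1), c(0, 1, 2, 1)),
                   list(c(0, 0, 1, 1)))$head
  s1 <- edge_score(x1, y1)
  expect_equal(as.numeric(s1), 1)
  expect_equal(attr(s1, "n_pairs_used"), 1L)

  ## all pairs undefined
  mono <- make_edges("sz", list(c(1, 1, 1, 1)), list(c(0, 0, 1, 1)))$head
  expect_error(edge_score(mono, mono), class = "ldrefine_undefined_ld")
})

test_that("subsampled edge_score converges to the full score", {
  set.seed(3)
  gx <- do.call(rbind, replicate(150, random_dosage(40), simplify = FALSE))
  gy <- do.call(rbind, replicate(150, random_dosage(40), simplify = FALSE))
  colnames(gx) <- colnames(gy) <- sprintf("s%02d", 1:40)
  full <- edge_score(gx, gy)
  sub <- edge_score(gx, gy, max_pairs = 10000, seed = 17)
  expect_equal(attr(sub, "n_pairs_used"), 10000L)
  expect_lt(abs(as.numeric(sub) - as.numeric(full)), 0.05)
})

test_that("score_matrix covers all inter-scaffold cells symmetrically", {
  set.seed(5)
  eb <- lapply(c("s1", "s2", "s3"), function(id)
    make_edges(id, replicate(6, random_dosage(20), simplify = FALSE),
               replicate(6, random_dosage(20), simplify = FALSE)))
  names(eb) <- c("s1", "s2", "s3")
  m <- score_matrix(eb)
  expect_identical(dim(m$scores), c(6L, 6L))
  ## 6x6 minus diagonal and 3 internal pairs, halved = 12 defined cells
  expect_identical(sum(!is.na(m$scores) & m$n_pairs >= 0), 24L)
  expect_identical(m$scores, t(m$scores))
  expect_identical(sum(m$n_pairs == -1L), 12L)  # diagonal + internal pairs
})

test_that("true junction scores beat the background on simulated data", {
  sim <- simulate_truth(sim_config(chromosome_length = 4e5, n_scaffolds = 5,
                                   n_samples = 30, n_founders = 6,
                                   n_sites = 700, recomb_rate = 2e-6,
                                   seed = 12))
  eb <- lapply(genotype_matrices(sim), extract_edge_blocks, k = 100)
  m <- score_matrix(eb)
  med <- stats::median(m$scores[upper.tri(m$scores)], na.rm = TRUE)
  tj <- sim$truth$adjacencies
  for (i in seq_len(nrow(tj))) {
    s <- m$scores[paste(tj$scaffold_a[i], tj$end_a[i], sep = ":"),
                  paste(tj$scaffold_b[i], tj$end_b[i], sep = ":")]
    expect_gt(s, med)
  }
})

test_that("fit_null reproduces the quantile geometry and degenerate cases", {
  ## null scores ~ Normal(0.12, 0.0138): threshold should land near 0.15
  set.seed(31)
  m <- make_score_matrix(sprintf("n%03d", 1:72))
  v <- stats::rnorm(sum(upper.tri(m$scores) & m$n_pairs >= 0), 0.12, 0.0138)
  m$scores[upper.tri(m$scores) & m$n_pairs >= 0] <- v
  m$scores[lower.tri(m$scores)] <- t(m$scores)[lower.tri(m$scores)]
  nm <- fit_null(m)
  expect_gt(nm$threshold, 0.14)
  expect_lt(nm$threshold, 0.16)
  expect_equal(nm$mean, 0.12, tolerance = 0.01)

  ## planted signal edges over a quiet bulk all clear the threshold
  m2 <- make_score_matrix(sprintf("p%02d", 1:12), fill = 0.1)
  m2$scores[upper.tri(m2$scores) & m2$n_pairs >= 0] <-
    0.1 + stats::runif(sum(upper.tri(m2$scores) & m2$n_pairs >= 0), -0.01, 0.01)
  m2$scores[lower.tri(m2$scores)] <- t(m2$scores)[lower.tri(m2$scores)]
  m2 <- set_score(m2, "p01:tail", "p02:head", 0.9)
  m2 <- set_score(m2, "p02:tail", "p03:head", 0.9)
  nm2 <- fit_null(m2)
  expect_lt(nm2$threshold, 0.2)
  expect_gt(nm2$threshold, 0.1)
  sig <- build_graph(m2, nm2$threshold)$edges
  expect_true(all(c(0.9, 0.9) %in% sig$score))

  ## identical scores -> zero MAD -> threshold equals that value
  m3 <- make_score_matrix(sprintf("q%02d", 1:12), fill = 0.2)
  nm3 <- fit_null(m3)
  expect_equal(nm3$threshold, 0.2)
  expect_identical(nrow(build_graph(m3, nm3$threshold)$edges), 0L)

  expect_error(fit_null(make_score_matrix(c("a", "b"))), "threshold")
})
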
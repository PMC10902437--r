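# Graph construction, layout solving (exact vs enumeration oracle, greedy
# cycle handling), sequence/AGP emission, and truth comparison.

manual_layout <- function(chains, singletons = character(0)) {
  structure(list(super_scaffolds = chains, singletons = singletons,
                 removed_edges = data.frame(), total_score = 0,
                 threshold = 0, method = "manual"),
            class = "scaffold_layout")
}

test_that("build_graph thresholds strictly and handles extremes", {
  m <- make_score_matrix(c("s1", "s2", "s3"), fill = 0.1)
  m <- set_score(m, "s1:tail", "s2:head", 0.9)
  g <- build_graph(m, 0.15)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$score, 0.9)

  expect_identical(nrow(build_graph(m, 0.95)$edges), 0L)
  ## threshold below every score: complete inter-scaffold candidate set
  expect_identical(nrow(build_graph(m, 0.05)$edges), 12L)
  ## a score exactly at the threshold is excluded (strict >)
  expect_identical(nrow(build_graph(m, 0.9)$edges), 0L)
})

test_that("solve_layout recovers a simple chain and leaves singletons", {
  m <- make_score_matrix(c("s1", "s2", "s3"), fill = 0.1)
  m <- set_score(m, "s1:tail", "s2:head", 0.9)
  m <- set_score(m, "s2:tail", "s3:head", 0.8)
  lay <- solve_layout(build_graph(m, 0.5))
  expect_length(lay$super_scaffolds, 1)
  ch <- lay$super_scaffolds[[1]]
  expect_identical(ch$scaffold_id, c("s1", "s2", "s3"))
  expect_identical(ch$strand, c("+", "+", "+"))
  expect_equal(ch$score_next, c(0.9, 0.8, NA))
  expect_length(lay$singletons, 0)

  single <- solve_layout(build_graph(make_score_matrix(c("a", "b")), 0.5))
  expect_identical(single$singletons, c("a", "b"))
  expect_length(single$super_scaffolds, 0)
})

test_that("reciprocal pair: cycle is linearized at the weaker edge", {
  m <- make_score_matrix(c("s1", "s2"))
  m <- set_score(m, "s1:tail", "s2:head", 0.9)
  m <- set_score(m, "s1:head", "s2:tail", 0.6)
  g <- build_graph(m, 0.15)

  ## greedy follows the matching-then-break procedure literally
  greedy <- solve_layout(g, method = "greedy")
  expect_length(greedy$super_scaffolds, 1)
  expect_identical(greedy$super_scaffolds[[1]]$scaffold_id, c("s1", "s2"))
  expect_identical(greedy$super_scaffolds[[1]]$strand, c("+", "+"))
  expect_identical(nrow(greedy$removed_edges), 1L)
  expect_equal(greedy$removed_edges$score, 0.6)

  ## the exact path cover reaches the same layout without ever forming
  ## the cycle: the 0.6 edge is simply not used as a junction
  exact <- solve_layout(g, method = "exact")
  expect_identical(exact$super_scaffolds[[1]]$scaffold_id, c("s1", "s2"))
  expect_identical(exact$super_scaffolds[[1]]$strand, c("+", "+"))
  expect_equal(exact$super_scaffolds[[1]]$score_next[1], 0.9)
  expect_false(0.6 %in% exact$super_scaffolds[[1]]$score_next)
})

test_that("exact layout equals the exhaustive signed-ordering optimum", {
  set.seed(50)
  for (inst in 1:50) {
    n <- sample(2:6, 1)
    ids <- sprintf("t%02d", seq_len(n))
    m <- make_score_matrix(ids)
    ut <- which(upper.tri(m$scores) & m$n_pairs >= 0, arr.ind = TRUE)
    for (r in seq_len(nrow(ut))) {
      v <- stats::runif(1)
      m$scores[ut[r, 1], ut[r, 2]] <- m$scores[ut[r, 2], ut[r, 1]] <- v
    }
    threshold <- stats::runif(1, 0.2, 0.7)
    lay <- solve_layout(build_graph(m, threshold), method = "exact")
    oracle <- oracle_best_order_total(ids, m$scores, threshold)
    expect_equal(lay$total_score, oracle, tolerance = 1e-9,
                 info = paste("instance", inst))
    ## partition invariant
    got <- c(unlist(lapply(lay$super_scaffolds, function(ch) ch$scaffold_id)),
             lay$singletons)
    expect_setequal(got, ids)
  }
})

test_that("greedy layout stays close to the exact optimum", {
  set.seed(51)
  for (inst in 1:10) {
    ids <- sprintf("g%02d", 1:6)
    m <- make_score_matrix(ids)
    ut <- which(upper.tri(m$scores) & m$n_pairs >= 0, arr.ind = TRUE)
    for (r in seq_len(nrow(ut))) {
      v <- stats::runif(1)
      m$scores[ut[r, 1], ut[r, 2]] <- m$scores[ut[r, 2], ut[r, 1]] <- v
    }
    g <- build_graph(m, 0.3)
    exact <- solve_layout(g, method = "exact")
    greedy <- solve_layout(g, method = "greedy")
    expect_lte(greedy$total_score, exact$total_score + 1e-9)
    expect_gte(greedy$total_score, 0.5 * exact$total_score)
  }
})

test_that("emit_super_scaffolds concatenates, gaps, and round-trips", {
  chains <- list(data.frame(scaffold_id = c("a", "b"), strand = c("+", "-"),
                            score_next = c(0.9, NA), stringsAsFactors = FALSE))
  lay <- manual_layout(chains, singletons = "c")
  seqs <- c(a = strrep("ACGT", 250), b = strrep("GGCTA", 400),
            c = "ACGTACGTAA")
  out <- emit_super_scaffolds(lay, seqs, gap_length = 100)
  expect_identical(names(out$fasta), c("super_1", "super_2"))
  expect_identical(Biostrings::width(out$fasta)[1], 1000L + 100L + 2000L)

  ## strand "-" component is reverse-complemented in the emitted object
  emitted <- as.character(out$fasta[["super_1"]])
  comp_b <- substr(emitted, 1101, 3100)
  expect_identical(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(comp_b))),
    seqs[["b"]])

  ## AGP geometry: W,U,W then a single W for the singleton
  expect_identical(out$agp$component_type, c("W", "U", "W", "W"))
  expect_identical(out$agp$orientation[c(1, 3)], c("+", "-"))

  ## AGP + components regenerate the FASTA byte-identically
  rebuilt <- agp_to_fasta(out$agp, seqs)
  expect_identical(rebuilt, setNames(as.character(out$fasta),
                                     names(out$fasta)))

  ## sequence conservation: non-N bases equal input bases
  non_n <- sum(Biostrings::width(out$fasta)) -
    sum(Biostrings::letterFrequency(out$fasta, "N"))
  expect_identical(non_n, sum(nchar(seqs)))

  expect_error(emit_super_scaffolds(lay, seqs[-1]), "no sequence")
})

test_that("compare_to_truth scores junctions direction-invariantly", {
  truth <- data.frame(scaffold_a = c("a", "b"), end_a = c("tail", "tail"),
                      scaffold_b = c("b", "c"), end_b = c("head", "head"),
                      stringsAsFactors = FALSE)
  perfect <- manual_layout(list(data.frame(
    scaffold_id = c("a", "b", "c"), strand = c("+", "+", "+"),
    score_next = c(0.9, 0.8, NA), stringsAsFactors = FALSE)))
  r <- compare_to_truth(perfect, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$orientation_accuracy, 1)

  ## reversed super-scaffold is the same layout
  reversed <- manual_layout(list(data.frame(
    scaffold_id = c("c", "b", "a"), strand = c("-", "-", "-"),
    score_next = c(0.8, 0.9, NA), stringsAsFactors = FALSE)))
  r2 <- compare_to_truth(reversed, truth)
  expect_equal(r2$precision, 1)
  expect_equal(r2$recall, 1)

  ## all singletons: recall 0, precision NA
  empty <- manual_layout(list(), singletons = c("a", "b", "c"))
  r3 <- compare_to_truth(empty, truth)
  expect_true(is.na(r3$precision))
  expect_equal(r3$recall, 0)

  ## one of two true junctions plus one false junction
  half <- manual_layout(list(
    data.frame(scaffold_id = c("a", "b"), strand = c("+", "+"),
               score_next = c(0.9, NA), stringsAsFactors = FALSE),
    data.frame(scaffold_id = c("c", "b"), strand = c("+", "+"),
               score_next = c(0.5, NA), stringsAsFactors = FALSE)))
  ## second chain joins c.tail-b.head: false (truth has b.tail-c.head)
  r4 <- compare_to_truth(half, truth)
  expect_equal(r4$precision, 0.5)
  expect_equal(r4$recall, 0.5)

  expect_error(compare_to_truth(manual_layout(list(), singletons = "zz"),
                                truth), "absent from truth")
})
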
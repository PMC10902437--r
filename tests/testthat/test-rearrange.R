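# Signed permutations, inversion/translocation calling against independent
# run-enumeration oracles, adjacency encoding, and the majority-rule
# ancestor.

# Signed permutation built directly: one anchor chromosome, query indices
# and signs given per anchor position.
manual_perm <- function(other_index, sign, other_chrom = "q1",
                        anchor_chrom = "c1") {
  n <- length(other_index)
  out <- data.frame(
    anchor_chrom = anchor_chrom, position = seq_len(n),
    block_id = seq_len(n),
    other_chrom = rep_len(other_chrom, n),
    other_index = other_index, sign = sign,
    stringsAsFactors = FALSE
  )
  class(out) <- c("signed_permutation", "data.frame")
  out
}

test_that("signed_permutation reads blocks in anchor order", {
  fx <- simulate_coords(10, 1, 0, seed = 8)
  blocks <- coords_to_blocks(filter_blocks(fx$coords))
  perm <- signed_permutation(blocks, "ref", "qry")
  expect_identical(perm$position, 1:10)
  run <- fx$truth$first_block:fx$truth$last_block
  expect_true(all(perm$sign[run] == -1))
  expect_true(all(perm$sign[-run] == 1))
  ## inverted run has strictly decreasing query indices
  if (length(run) > 1) expect_true(all(diff(perm$other_index[run]) < 0))

  expect_error(signed_permutation(blocks[blocks$block_id != 3 |
                                           blocks$genome == "ref", ],
                                  "ref", "qry"), "missing in one genome")
})

test_that("call_inversions matches the run-enumeration oracle", {
  expect_identical(nrow(call_inversions(manual_perm(1:3, c(1, 1, 1)))), 0L)

  p1 <- manual_perm(c(1, 3, 2, 4), c(1, -1, -1, 1))
  c1 <- call_inversions(p1)
  expect_identical(nrow(c1), 1L)
  expect_identical(c1$blocks, "2,3")

  p2 <- manual_perm(c(1, 2, 3, 5, 4), c(1, -1, 1, -1, -1))
  c2 <- call_inversions(p2)
  expect_identical(nrow(c2), 2L)
  expect_identical(c2$blocks, c("2", "4,5"))

  ## randomized agreement with the quadratic oracle
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:9, 1)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    idx <- sample(n)
    p <- manual_perm(idx, sign)
    calls <- call_inversions(p)
    runs <- oracle_reversed_runs(sign, rep("q1", n), idx)
    got <- if (nrow(calls)) paste(calls$first_pos, calls$last_pos) else
      character(0)
    want <- vapply(runs, function(r) paste(r[1], r[2]), "")
    expect_setequal(got, want)
  }
})

test_that("call_translocations detects chromosome switches", {
  ## (chrA, chrB, chrA) pattern -> one call on the chrB run
  p <- manual_perm(c(1, 2, 1, 2, 3), c(1, 1, 1, 1, 1),
                   other_chrom = c("A", "A", "B", "A", "A"))
  calls <- call_translocations(p)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$evidence, "chromosome switch")
  expect_identical(calls$blocks, "3")

  ## run spanning the whole chromosome: no call
  whole <- manual_perm(1:4, rep(1, 4), other_chrom = "B")
  expect_identical(nrow(call_translocations(whole)), 0L)

  ## two separated switch runs: two calls, background never called
  p2 <- manual_perm(c(1, 2, 1, 3, 4, 2, 5), rep(1, 7),
                    other_chrom = c("A", "A", "B", "A", "A", "B", "A"))
  c2 <- call_translocations(p2)
  expect_identical(nrow(c2), 2L)
  expect_true(all(c2$other_chrom == "B"))
})

test_that("call_translocations detects displacements once", {
  ## (+1, +4, +2, +3): block 4 displaced
  p <- manual_perm(c(1, 4, 2, 3), rep(1, 4))
  calls <- call_translocations(p)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$evidence, "displacement")
  expect_identical(calls$blocks, "2")          # anchor block at position 2

  ## collinear input: nothing
  expect_identical(nrow(call_translocations(manual_perm(1:5, rep(1, 5)))), 0L)

  ## displaced run of 2 jumping a stretch of 3: exactly one call on the run
  p2 <- manual_perm(c(1, 7, 8, 2, 3, 4, 5, 6, 9), rep(1, 9))
  c2 <- call_translocations(p2)
  expect_identical(nrow(c2), 1L)
  expect_identical(c2$blocks, "2,3")
})

test_that("adjacencies follow the sign rule and are orientation-invariant", {
  expect_identical(adjacencies(1:2, c(1, 1)), "1.tail--2.head")
  expect_identical(adjacencies(1:2, c(1, -1)), "1.tail--2.tail")
  expect_identical(adjacencies(1, 1), character(0))

  set.seed(14)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    ids <- sample(100, n)
    sg <- sample(c(-1, 1), n, replace = TRUE)
    fwd <- adjacencies(ids, sg)
    rev_ <- adjacencies(rev(ids), -rev(sg))
    expect_setequal(fwd, rev_)
  }
})

make_orders <- function(perm_list) {
  do.call(rbind, lapply(names(perm_list), function(ch) {
    data.frame(chrom = ch, block_id = perm_list[[ch]]$id,
               sign = perm_list[[ch]]$sign, stringsAsFactors = FALSE)
  }))
}

test_that("ancestral reconstruction follows the majority rule", {
  base <- make_orders(list(c1 = list(id = 1:5, sign = rep(1, 5))))

  ## three identical genomes: ancestor identical, reports empty
  anc <- ancestral_adjacencies(base, base, base)
  expect_setequal(anc$ancestral, adjacencies(1:5, rep(1, 5)))
  expect_length(anc$derived_in_A, 0)
  expect_length(anc$lost_in_A, 0)
  expect_length(anc$cars, 1)
  expect_identical(sort(anc$cars[[1]]$block_id), as.character(1:5))

  ## B = C != A: ancestor equals B; A's private adjacencies are derived
  a_ord <- make_orders(list(c1 = list(id = c(1, 3, 2, 4, 5),
                                      sign = c(1, -1, -1, 1, 1))))
  anc2 <- ancestral_adjacencies(a_ord, base, base)
  expect_setequal(anc2$ancestral, adjacencies(1:5, rep(1, 5)))
  adj_a <- unique(genome_adjacencies(a_ord))
  adj_b <- adjacencies(1:5, rep(1, 5))
  expect_setequal(anc2$derived_in_A, setdiff(adj_a, adj_b))
  expect_setequal(anc2$lost_in_A, setdiff(adj_b, adj_a))

  ## each adjacency's ancestral state matches the Fitch oracle
  all_adj <- union(adj_a, adj_b)
  for (k in all_adj) {
    state <- oracle_fitch_ancestor(k %in% adj_a, k %in% adj_b, k %in% adj_b)
    expect_identical(k %in% anc2$ancestral, state == 1)
  }

  ## an adjacency in B and C only is ancestral and lost in A
  expect_true(all(setdiff(adj_b, adj_a) %in% anc2$ancestral))

  expect_error(ancestral_adjacencies(
    base, base, make_orders(list(c1 = list(id = 1:4, sign = rep(1, 4))))),
    "block set")
})

test_that("ancestral set uses each block end at most once", {
  set.seed(15)
  for (i in 1:10) {
    n <- 6
    mk <- function() {
      ids <- sample(n)
      make_orders(list(c1 = list(id = ids,
                                 sign = sample(c(-1, 1), n, TRUE))))
    }
    anc <- ancestral_adjacencies(mk(), mk(), mk())
    ends <- unlist(strsplit(anc$ancestral, "--", fixed = TRUE))
    expect_identical(anyDuplicated(ends), 0L)
  }
})

test_that("planted rearrangements are recovered exactly once each", {
  for (seed in 1:8) {
    fx <- simulate_coords(32, inversions = 1 + seed %% 2,
                          translocations = seed %% 3, seed = seed * 11)
    blocks <- coords_to_blocks(filter_blocks(fx$coords))
    perm <- signed_permutation(blocks, "ref", "qry")
    inv <- call_inversions(perm)
    tra <- call_translocations(perm, inv)
    truth <- fx$truth
    expect_identical(nrow(inv), sum(truth$type == "inversion"))
    expect_identical(nrow(tra), sum(truth$type == "translocation"))
    for (r in seq_len(nrow(truth))) {
      span <- paste(truth$first_block[r]:truth$last_block[r], collapse = ",")
      calls <- if (truth$type[r] == "inversion") inv else tra
      expect_identical(sum(calls$blocks == span), 1L)
    }
  }
})
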
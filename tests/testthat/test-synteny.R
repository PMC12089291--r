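test_that("identical chromosomes chain into one full forward block", {
  sb <- chain_collinear_blocks(toy_anchors(0:9, 0:9), min_anchors = 5L)
  expect_identical(nrow(sb$blocks), 1L)
  b <- sb$blocks[1, ]
  expect_identical(b$orientation, "+")
  expect_identical(b$n_anchors, 10L)
  expect_identical(c(b$a_start, b$a_end), c(0L, 10L))
  expect_identical(c(b$b_start, b$b_end), c(0L, 10L))
})

test_that("a mixed-orientation instance partitions into its three maximal runs", {
  sb <- chain_collinear_blocks(toy_anchors(0:9, c(0, 1, 2, 3, 6, 5, 4, 7, 8, 9)),
                               min_anchors = 3L)
  expect_identical(sb$blocks$a_start, c(0L, 4L, 7L))
  expect_identical(sb$blocks$a_end, c(4L, 7L, 10L))
  expect_identical(sb$blocks$orientation, c("+", "-", "+"))
  expect_identical(sb$blocks$n_anchors, c(4L, 3L, 3L))
  expect_true(all(!is.na(sb$anchors$block_id)))
})

test_that("blocks below the anchor threshold are not emitted", {
  sb <- chain_collinear_blocks(toy_anchors(0L, 0L), min_anchors = 5L)
  expect_identical(nrow(sb$blocks), 0L)
  expect_true(all(is.na(sb$anchors$block_id)))
  expect_identical(nrow(chain_collinear_blocks(toy_anchors(integer(0), integer(0)))$blocks), 0L)
})

test_that("tandem arrays collapse to the lowest-rank representative", {
  ga <- toy_genome("A", 10L)
  gb <- toy_genome("B", 5L)
  pairs <- data.frame(gene_a = sprintf("A.c1.g%03d", 6:8),  # ranks 5,6,7
                      gene_b = rep("B.c1.g002", 3),
                      family = "fam1", stringsAsFactors = FALSE)
  an <- build_anchors(pairs, ga, gb, tandem_window = 5L)
  expect_identical(nrow(an), 1L)
  expect_identical(an$rank_a, 5L)
  expect_identical(an$rank_b, 1L)
  # ten one-to-one pairs without tandems stay ten anchors
  ga2 <- toy_genome("A2", 10L); gb2 <- toy_genome("B2", 10L)
  p2 <- data.frame(gene_a = ga2$genes$gene_id, gene_b = gb2$genes$gene_id,
                   family = sprintf("f%02d", 1:10))
  expect_identical(nrow(build_anchors(p2, ga2, gb2)), 10L)
})

test_that("pairs naming absent genes raise an error naming the genome", {
  ga <- toy_genome("A", 5L); gb <- toy_genome("B", 5L)
  pairs <- data.frame(gene_a = "missing", gene_b = gb$genes$gene_id[1],
                      family = NA_character_)
  expect_error(build_anchors(pairs, ga, gb), "genome 'A'.*missing")
})

test_that("the chaining DP matches the brute-force partition oracle", {
  set.seed(42)
  params <- expand.grid(min_anchors = c(2L, 3L, 5L), max_gap = c(4L, 25L))
  for (rep in 1:8) {
    n <- sample(8:30, 1L)
    inst <- random_anchor_instance(n)
    for (k in seq_len(nrow(params))) {
      ma <- params$min_anchors[k]; mg <- params$max_gap[k]
      sb <- chain_collinear_blocks(toy_anchors(inst$ra, inst$rb),
                                   min_anchors = ma, max_gap = mg)
      oracle <- oracle_chain_value(inst$ra, inst$rb, ma, mg)
      expect_identical(sum(sb$blocks$n_anchors), as.integer(oracle[["covered"]]),
                       info = sprintf("covered, rep=%d ma=%d mg=%d", rep, ma, mg))
      expect_identical(nrow(sb$blocks), as.integer(oracle[["blocks"]]),
                       info = sprintf("blocks, rep=%d ma=%d mg=%d", rep, ma, mg))
      expect_valid_blocks(sb, ma, mg)
    }
  }
})

test_that("swapping genomes mirrors spans and preserves anchor counts", {
  # with steps of one and max_gap = 1, chain merges are symmetric by
  # construction, so the block partition must mirror exactly
  set.seed(7)
  for (rep in 1:8) {
    inst <- band_permutation_instance(30L)
    fwd <- chain_collinear_blocks(toy_anchors(inst$ra, inst$rb),
                                  min_anchors = 3L, max_gap = 1L)
    ord <- order(inst$rb, inst$ra)
    swapped <- chain_collinear_blocks(toy_anchors(inst$rb[ord], inst$ra[ord]),
                                      min_anchors = 3L, max_gap = 1L)
    expect_identical(sum(fwd$blocks$n_anchors), sum(swapped$blocks$n_anchors))
    expect_identical(nrow(fwd$blocks), nrow(swapped$blocks))
    expect_identical(sort(fwd$blocks$n_anchors), sort(swapped$blocks$n_anchors))
    mirrored <- data.frame(a_start = fwd$blocks$b_start, a_end = fwd$blocks$b_end,
                           b_start = fwd$blocks$a_start, b_end = fwd$blocks$a_end)
    mirrored <- mirrored[order(mirrored$a_start), ]
    expect_identical(mirrored$a_start, swapped$blocks$a_start)
    expect_identical(mirrored$b_start, swapped$blocks$b_start)
  }
  # realistic case: simulated rearranged genome against its reference, where
  # junctions are far apart relative to max_gap
  res <- simulate_scenario(two_lineage_scenario(list(
    sim_event("EEJ", "chr1", "chr2"), sim_event("RCT", "chr3", "chr4"))), seed = 9)
  fwd <- genome_pair_blocks(res$genomes$TGT, res$genomes$REF)
  rev_ <- genome_pair_blocks(res$genomes$REF, res$genomes$TGT)
  expect_identical(nrow(fwd$blocks), nrow(rev_$blocks))
  expect_identical(sort(fwd$blocks$n_anchors), sort(rev_$blocks$n_anchors))
})

test_that("spanning_block certifies collinearity across a junction", {
  # identity genomes: any internal junction is spanned
  sb <- chain_collinear_blocks(toy_anchors(0:199, 0:199))
  expect_true(spanning_block(sb, "c1", 100L)$spanning)
  # genome B rearranged exactly at the junction: flanks in different blocks
  sb2 <- chain_collinear_blocks(toy_anchors(0:199, c(0:99, 300:399)), max_gap = 25L)
  expect_identical(nrow(sb2$blocks), 2L)
  expect_false(spanning_block(sb2, "c1", 100L)$spanning)
  # 30% of flank genes deleted: count the survivors explicitly
  set.seed(11)
  keep <- sort(sample(0:199, 140))
  sb3 <- chain_collinear_blocks(toy_anchors(keep, keep), max_gap = 25L)
  n_left <- sum(keep >= 50 & keep < 100)
  n_right <- sum(keep >= 100 & keep < 150)
  expect_gte(n_left, 10L); expect_gte(n_right, 10L)
  sp <- spanning_block(sb3, "c1", 100L, flank = 50L, min_side_anchors = 10L)
  expect_true(sp$spanning)
  expect_identical(sp$n_left, n_left)
  expect_identical(sp$n_right, n_right)
})

test_that("on loss-free simulations every homolog-bearing gene is covered", {
  res <- simulate_scenario(two_lineage_scenario(list(
    sim_event("EEJ", "chr1", "chr2"), sim_event("RCT", "chr3", "chr4"))), seed = 5)
  sb <- genome_pair_blocks(res$genomes$TGT, res$genomes$REF)
  expect_identical(nrow(sb$anchors), nrow(res$genomes$TGT$genes))
  expect_true(all(!is.na(sb$anchors$block_id)))   # coverage = 1.0
})
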
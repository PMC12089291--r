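test_that("private fusions give single-genome matrix columns", {
  sc <- sim_scenario(6L, 150L, lineages = list(
    sim_lineage("REF"),
    sim_lineage("A", events = list(sim_event("EEJ", "chr1", "chr2"))),
    sim_lineage("B"), sim_lineage("C")))
  res <- simulate_scenario(sc, seed = 1)
  mt <- breakpoint_matrix_pipeline(res$genomes[c("A", "B", "C")], reference_id = NULL,
                                   ak_reference = res$genomes$REF)
  expect_identical(ncol(mt$matrix$matrix), 1L)
  expect_identical(unname(mt$matrix$matrix[, 1]), c(1L, 0L, 0L))
})

test_that("fusions duplicated by polyploidy get copy number two", {
  res <- simulate_scenario(sim_scenario(4L, 150L, lineages = list(
    sim_lineage("REF"),
    sim_lineage("F", events = list(sim_event("EEJ", "chr1", "chr2")))),
    polyploids = list(list(id = "AUTO", parents = c("F", "F"),
                           suffixes = c("A", "B"), loss_rates = c(0, 0)))),
    seed = 2)
  st <- detect_events(res$genomes$AUTO, res$genomes$REF)
  self_blocks <- genome_pair_blocks(res$genomes$AUTO, res$genomes$AUTO, drop_self = TRUE)
  m <- build_breakpoint_matrix(list(AUTO = st$breakpoints),
                               list("AUTO||AUTO" = self_blocks))
  expect_identical(ncol(m$matrix), 1L)
  expect_identical(unname(m$matrix["AUTO", 1]), 2L)
})

test_that("same chromosomes, different breakpoints stay distinct columns", {
  sc <- sim_scenario(8L, 400L, lineages = list(
    sim_lineage("REF"),
    sim_lineage("X", events = list(sim_event("RCT", "chr7", "chr8", 100L, 200L))),
    sim_lineage("Y", events = list(sim_event("RCT", "chr7", "chr8", 250L, 320L)))))
  res <- simulate_scenario(sc, seed = 3)
  mt <- breakpoint_matrix_pipeline(res$genomes[c("X", "Y")], reference_id = NULL,
                                   ak_reference = res$genomes$REF)
  m <- mt$matrix$matrix
  expect_identical(ncol(m), 4L)   # two junctions per RCT, nothing merged
  expect_true(all(colSums(m >= 1L) == 1L))
})

test_that("laminar characters nest into the expected caterpillar", {
  m <- matrix(0L, nrow = 4, ncol = 3,
              dimnames = list(c("A", "B", "C", "D"), c("e1", "e2", "e3")))
  m[c("A", "B"), "e1"] <- 1L
  m[c("A", "B", "C"), "e2"] <- 1L
  m[c("A", "B", "C", "D"), "e3"] <- 1L
  ct <- infer_tree_dollo(m)
  expect_identical(nrow(ct$conflicts), 0L)
  truth <- ape::read.tree(text = "(((A,B),C),D);")
  expect_equal(phangorn::RF.dist(ape::unroot(ct$tree), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  # each character sits on its own edge
  expect_identical(ct$edges$members[ct$edges$column_ids == "e1"], "A|B")
  expect_identical(ct$edges$members[ct$edges$column_ids == "e2"], "A|B|C")
  expect_identical(ct$edges$placement[ct$edges$column_ids == "e3"], "root")
})

test_that("no characters give a star tree; incompatible characters are conflicts", {
  m0 <- matrix(0L, nrow = 3, ncol = 0, dimnames = list(c("A", "B", "C"), NULL))
  ct0 <- infer_tree_dollo(m0)
  expect_identical(nrow(ct0$conflicts), 0L)
  expect_identical(ct0$tree$Nnode, 1L)          # star polytomy
  expect_setequal(ct0$tree$tip.label, c("A", "B", "C"))

  m1 <- matrix(0L, nrow = 3, ncol = 2, dimnames = list(c("A", "B", "C"), c("x", "y")))
  m1[c("A", "B"), "x"] <- 1L
  m1[c("B", "C"), "y"] <- 1L
  ct1 <- infer_tree_dollo(m1)
  expect_identical(nrow(ct1$conflicts), 1L)
  expect_identical(ct1$conflicts$column_id, "y")  # lexicographically later set loses
  # partition property: every column is on an edge or in the conflict list
  placed <- sum(ct1$edges$n_columns)
  expect_identical(placed + nrow(ct1$conflicts), 2L)
})

test_that("phasing is trivial for diploids and permutation-invariant in score", {
  res <- simulate_scenario(sim_preset("suecica_like", genes_per_chromosome = 150L),
                           seed = 4)
  ak <- ak_from_genome(res$genomes$REF)
  sue <- res$genomes$SUE
  p <- paint_genome(sue, ak, genome_pair_blocks(sue, res$genomes$REF))
  ph1 <- phase_subgenomes(p, ak, k = 1L)
  expect_identical(unname(ph1$sizes), 13L)
  ph2 <- phase_subgenomes(p, ak, k = 2L, seed = 1)
  expect_identical(sort(unname(ph2$sizes)), c(5L, 8L))
  truthA <- attr(sue, "subgenomes")$A
  expect_setequal(ph2$subgenomes[[which(ph2$sizes == 5L)]], truthA)
  # renaming chromosomes permutes the assignment but not the score
  p3 <- p
  map <- stats::setNames(paste0("Z", rev(seq_along(unique(p$segments$chromosome)))),
                         unique(p$segments$chromosome))
  p3$segments$chromosome <- unname(map[p3$segments$chromosome])
  ph3 <- phase_subgenomes(p3, ak, k = 2L, seed = 1)
  expect_equal(ph3$score, ph2$score, tolerance = 1e-10)
  expect_identical(sort(unname(ph3$sizes)), c(5L, 8L))
})
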
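# shared fixture: one unrearranged reference plus a lineage with one EEJ and
# one RCT, no gene loss
fixture_res <- simulate_scenario(two_lineage_scenario(list(
  sim_event("EEJ", "chr1", "chr2"),
  sim_event("RCT", "chr3", "chr4"))), seed = 21)
fixture_ak <- ak_from_genome(fixture_res$genomes$REF)

test_that("a reference painted against its own karyotype is one segment per chromosome", {
  ref <- fixture_res$genomes$REF
  sb <- genome_pair_blocks(ref, ref)
  p <- paint_genome(ref, fixture_ak, sb)
  expect_identical(nrow(p$segments), haploid_number(ref))
  expect_true(all(p$segments$orientation == "+"))
  expect_identical(sort(p$segments$label), sort(names(fixture_ak$protochromosomes)))
  # idempotence: repainting returns the same segmentation
  p2 <- paint_genome(ref, fixture_ak, genome_pair_blocks(ref, ref))
  expect_identical(p$segments, p2$segments)
})

test_that("simulated fusions produce the expected segment structure", {
  tgt <- fixture_res$genomes$TGT
  p <- paint_genome(tgt, fixture_ak, genome_pair_blocks(tgt, fixture_res$genomes$REF))
  segs <- p$segments[p$segments$label != "NA", ]
  # EEJ chromosome: exactly 2 segments with distinct labels
  eej <- segs[segs$chromosome == "chr1+chr2", ]
  expect_identical(nrow(eej), 2L)
  expect_identical(length(unique(eej$label)), 2L)
  # RCT pair: 4 segments over the two chromosomes, 2 labels each
  rct <- segs[segs$chromosome %in% c("chr3", "chr4"), ]
  expect_identical(nrow(rct), 4L)
  expect_identical(length(unique(rct$label[rct$chromosome == "chr3"])), 2L)
  expect_identical(length(unique(rct$label[rct$chromosome == "chr4"])), 2L)
  # loss-free invariant: segments per chromosome = 1 + junctions placed there
  expect_identical(nrow(segs), haploid_number(tgt) + 3L)  # 1 EEJ + 2 RCT junctions
})

test_that("CLSBs are the protochromosomes conserved as whole chromosomes", {
  ref <- fixture_res$genomes$REF
  tgt <- fixture_res$genomes$TGT
  p_ref <- paint_genome(ref, fixture_ak, genome_pair_blocks(ref, ref))
  p_tgt <- paint_genome(tgt, fixture_ak, genome_pair_blocks(tgt, ref))
  # two structurally identical genomes: every label is a CLSB
  expect_identical(identify_clsbs(list(p_ref, p_ref)), as.character(1:8))
  # EEJ(1,2) and RCT(3,4) exclude labels 1-4
  expect_identical(identify_clsbs(list(p_ref, p_tgt)), as.character(5:8))
  # order invariance
  expect_identical(identify_clsbs(list(p_tgt, p_ref)),
                   identify_clsbs(list(p_ref, p_tgt)))
})

test_that("karyotype assembly needs every label resolved", {
  ref <- fixture_res$genomes$REF
  tgt <- fixture_res$genomes$TGT
  p_ref <- paint_genome(ref, fixture_ak, genome_pair_blocks(ref, ref))
  p_tgt <- paint_genome(tgt, fixture_ak, genome_pair_blocks(tgt, ref))
  # all-CLSB case: assembled karyotype has p = 8 and the reference gene lists
  ak2 <- assemble_ancestral_karyotype(list(p_ref), as.character(1:8), ref,
                                      karyotype_id = "AK2")
  expect_identical(ak2$p, 8L)
  expect_identical(ak2$protochromosomes[["3"]],
                   fixture_ak$protochromosomes[["3"]])
  # fused labels that are neither CLSB nor outgroup-rooted are an error
  expect_error(assemble_ancestral_karyotype(list(p_ref, p_tgt),
                                            identify_clsbs(list(p_ref, p_tgt)), ref),
               "unresolved protochromosome label")
  # with the missing labels declared resolved, assembly succeeds
  ak3 <- assemble_ancestral_karyotype(list(p_ref, p_tgt),
                                      identify_clsbs(list(p_ref, p_tgt)), ref,
                                      resolved_labels = as.character(1:4))
  expect_identical(ak3$p, 8L)
})

test_that("CGB boundaries link to breakpoint positions within the gene limit", {
  cgbs <- data.frame(label = c("A", "B", "C", "D"), chromosome = "1",
                     start_rank = c(0L, 140L, 300L, 450L),
                     end_rank = c(140L, 300L, 450L, 600L),
                     stringsAsFactors = FALSE)
  # boundaries are the interior junctions: 140, 300, 450
  pos <- data.frame(chromosome = "1",
                    anc_rank = c(140L, 130L, 350L, 501L, 40L),  # distances 0,10,50,51,100
                    stringsAsFactors = FALSE)
  ov <- map_cgb_overlap(cgbs, pos, link_distance = 50L)
  expect_identical(ov$n_boundaries, 3L)
  expect_identical(ov$n_positions, 5L)
  expect_identical(ov$n_linked, 3L)     # 0, 10 and 50 link; 51 and 100 do not
  expect_identical(ov$n_exact, 1L)
  # threshold is inclusive at 50 and exclusive at 51
  expect_identical(map_cgb_overlap(cgbs, data.frame(chromosome = "1", anc_rank = 90L))$n_linked, 1L)
  expect_identical(map_cgb_overlap(cgbs, data.frame(chromosome = "1", anc_rank = 89L))$n_linked, 0L)
})
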
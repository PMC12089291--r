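test_that("an unrearranged genome yields no junctions", {
  res <- simulate_scenario(two_lineage_scenario(list()), seed = 2)
  st <- detect_events(res$genomes$TGT, res$genomes$REF)
  expect_identical(nrow(st$breakpoints), 0L)
  expect_identical(nrow(st$events), 0L)
})

test_that("EEJ, RCT and NCF produce their characteristic breakpoint counts", {
  # single EEJ on a 2-chromosome ancestor: one breakpoint, n 2 -> 1
  res <- simulate_scenario(sim_scenario(2L, 150L, lineages = list(
    sim_lineage("REF"), sim_lineage("TGT", events = list(sim_event("EEJ", "chr1", "chr2"))))),
    seed = 3)
  st <- detect_events(res$genomes$TGT, res$genomes$REF)
  expect_identical(nrow(st$breakpoints), 1L)
  expect_identical(st$events$type, "EEJ")
  expect_identical(st$events$delta_n, -1L)
  expect_identical(haploid_number(res$genomes$TGT), 1L)

  # single RCT: two breakpoints on two chromosomes, n conserved
  res <- simulate_scenario(two_lineage_scenario(list(sim_event("RCT", "chr7", "chr8"))),
                           seed = 4)
  st <- detect_events(res$genomes$TGT, res$genomes$REF)
  expect_identical(nrow(st$breakpoints), 2L)
  expect_identical(st$events$type, "RCT")
  expect_identical(st$events$delta_n, 0L)
  expect_identical(length(unique(st$breakpoints$chromosome)), 2L)

  # single NCF on a 7-chromosome ancestor: two breakpoints flanking the
  # nested chromosome, n 7 -> 6
  res <- simulate_scenario(sim_scenario(7L, 150L, lineages = list(
    sim_lineage("REF"),
    sim_lineage("TGT", events = list(sim_event("NCF", "chr2", "chr5"))))), seed = 5)
  expect_identical(haploid_number(res$genomes$TGT), 6L)
  st <- detect_events(res$genomes$TGT, res$genomes$REF)
  expect_identical(nrow(st$breakpoints), 2L)
  expect_identical(st$events$type, "NCF")
  expect_identical(st$events$delta_n, -1L)
  expect_identical(st$events$proto_a, "2")   # recipient
  expect_identical(st$events$proto_b, "5")   # donor, nested internally
})

test_that("breakpoint counts per type hold on every classified output", {
  for (seed in 1:4) {
    res <- simulate_scenario(two_lineage_scenario(list(
      sim_event("EEJ", "chr1", "chr2"), sim_event("RCT", "chr3", "chr4"),
      sim_event("EEJ", "chr5", "chr6"))), seed = seed)
    st <- detect_events(res$genomes$TGT, res$genomes$REF)
    n_bps <- lengths(strsplit(st$events$bp_ids, ";", fixed = TRUE))
    expect_identical(n_bps[st$events$type == "EEJ"],
                     rep(1L, sum(st$events$type == "EEJ")))
    expect_identical(n_bps[st$events$type %in% c("RCT", "NCF")],
                     rep(2L, sum(st$events$type %in% c("RCT", "NCF"))))
    # chromosome-number bookkeeping from the classified deltas
    expect_identical(sum(st$events$delta_n),
                     haploid_number(res$genomes$TGT) - haploid_number(res$genomes$REF))
  }
})

test_that("event nomenclature formats and parses as an identity", {
  expect_identical(name_event("AKI", "7", "8", "RCT"), "AKI/7_8/RCT")
  parsed <- parse_event_name("AKI/7_8/RCT")
  expect_identical(parsed$type, "RCT")
  expect_identical(parsed$operands, list("7", "8"))
  nested <- sprintf("tAKI/%s_5/RCT", event_token("4", "6", "EEJ"))
  expect_identical(nested, "tAKI/(4_6/EEJ)_5/RCT")
  pn <- parse_event_name(nested)
  expect_identical(pn$operands[[1]]$type, "EEJ")
  expect_identical(pn$operands[[2]], "5")
  # format . parse = identity over randomly nested names
  set.seed(31)
  rand_op <- function(depth) {
    if (depth == 0 || stats::runif(1) < 0.6) as.character(sample(1:9, 1))
    else event_token(rand_op(depth - 1), rand_op(depth - 1),
                     sample(c("EEJ", "RCT", "NCF"), 1))
  }
  for (i in 1:20) {
    nm <- name_event("AK", rand_op(2), rand_op(2), sample(c("EEJ", "RCT"), 1))
    expect_identical(karyotracer:::format_parsed_event(parse_event_name(nm)), nm)
  }
  expect_error(parse_event_name("AK/1_2/XYZ"), "unknown event type")
})

test_that("breakpoint windows take 50 genes per side, truncating at ends", {
  g <- toy_genome("W", 200L)
  bp <- data.frame(bp_id = "W.bp01", genome_id = "W", chromosome = "c1",
                   junction_rank = 100L, stringsAsFactors = FALSE)
  w <- extract_breakpoint_window(bp, g, flank = 50L)
  expect_identical(length(w), 100L)
  expect_false(attr(w, "truncated"))
  expect_identical(w[50:51], c("W.c1.g100", "W.c1.g101"))  # junction between ranks 99|100
  # 20 genes from the chromosome start: 20 + 50 genes, flagged truncated
  bp$junction_rank <- 20L
  w2 <- extract_breakpoint_window(bp, g, flank = 50L)
  expect_identical(length(w2), 70L)
  expect_true(attr(w2, "truncated"))
  expect_error(extract_breakpoint_window(bp, g, flank = 0L), "empty window")
})

test_that("breakpoint sharing distinguishes inheritance from convergence", {
  # lineage F1 fuses; F2 descends from F1; REF keeps the ancestral structure;
  # IND fuses the same chromosomes at explicitly different positions
  sc <- sim_scenario(8L, 400L, lineages = list(
    sim_lineage("REF"),
    sim_lineage("F1", events = list(sim_event("RCT", "chr7", "chr8", 100L, 200L))),
    sim_lineage("F2", parent = "F1"),
    sim_lineage("IND", events = list(sim_event("RCT", "chr7", "chr8", 250L, 320L)))))
  res <- simulate_scenario(sc, seed = 6)
  st <- detect_events(res$genomes$F1, res$genomes$REF)
  to_f2 <- genome_pair_blocks(res$genomes$F1, res$genomes$F2)
  to_ref <- genome_pair_blocks(res$genomes$F1, res$genomes$REF)
  to_ind <- genome_pair_blocks(res$genomes$F1, res$genomes$IND)
  for (i in seq_len(nrow(st$breakpoints))) {
    bp <- st$breakpoints[i, ]
    expect_identical(breakpoint_shared(bp, to_f2)$status, "shared")
    expect_identical(breakpoint_shared(bp, to_ref)$status, "absent")
    expect_identical(breakpoint_shared(bp, to_ind)$status, "absent")
  }
})

test_that("outgroups root the direction of rearrangements", {
  res <- simulate_scenario(sim_preset("outgroup_rooting", genes_per_chromosome = 300L),
                           seed = 8)
  st <- detect_events(res$genomes$ING, res$genomes$REF)
  v <- orient_with_outgroup(st$breakpoints,
                            genome_pair_blocks(res$genomes$ING, res$genomes$OUT))
  expect_identical(nrow(v), 2L)
  expect_true(all(v$verdict == "derived"))   # outgroup retains the ancestor

  # a fusion predating the outgroup split is ancestral
  sc <- sim_scenario(8L, 300L, lineages = list(
    sim_lineage("REF"),
    sim_lineage("N0", events = list(sim_event("EEJ", "chr1", "chr2")), emit = FALSE),
    sim_lineage("ING2", parent = "N0", loss_rate = 0.05),
    sim_lineage("OUT2", parent = "N0", loss_rate = 0.05)))
  res2 <- simulate_scenario(sc, seed = 9)
  st2 <- detect_events(res2$genomes$ING2, res2$genomes$REF)
  v2 <- orient_with_outgroup(st2$breakpoints,
                             genome_pair_blocks(res2$genomes$ING2, res2$genomes$OUT2))
  expect_identical(v2$verdict, "ancestral")

  # heavy loss in the outgroup leaves the junction unresolved
  sc3 <- sim_scenario(8L, 300L, lineages = list(
    sim_lineage("REF"),
    sim_lineage("ING3", events = list(sim_event("RCT", "chr7", "chr8"))),
    sim_lineage("OUT3", loss_rate = 0.85)))
  res3 <- simulate_scenario(sc3, seed = 10)
  st3 <- detect_events(res3$genomes$ING3, res3$genomes$REF)
  v3 <- orient_with_outgroup(st3$breakpoints,
                             genome_pair_blocks(res3$genomes$ING3, res3$genomes$OUT3))
  expect_true(all(v3$verdict == "unresolved"))
})

test_that("inversions are logged as context, not reported as fusions", {
  res <- simulate_scenario(two_lineage_scenario(list(
    sim_event("INV", "chr3", pos_a = 40L, pos_b = 110L))), seed = 12)
  st <- detect_events(res$genomes$TGT, res$genomes$REF)
  expect_identical(nrow(st$breakpoints), 0L)
  expect_gte(nrow(st$inversions), 1L)
  expect_true(all(st$inversions$label == "3"))
})
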
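#' Synteny blocks between two genomes
#'
#' Convenience wrapper: derives homology pairs (from `family` labels when
#' `pairs` is not given), builds anchors and chains blocks.
#'
#' @param ga,gb [genome_order]s (genome A supplies the coordinates blocks
#'   are reported in).
#' @param pairs optional homology pair table; defaults to family-derived
#'   pairs via [homology_pairs].
#' @param drop_self when deriving pairs for a genome against itself, keep
#'   only homeolog pairs (distinct genes); set for polyploid self-synteny.
#'   Identity pairs are kept by default, as needed to paint a reference
#'   against its own karyotype.
#' @param tandem_window,min_anchors,max_gap see [build_anchors] and
#'   [chain_collinear_blocks].
#' @return a `synteny_blocks` object.
#' @export
genome_pair_blocks <- function(ga, gb, pairs = NULL, drop_self = FALSE,
                               tandem_window = 5L, min_anchors = 5L, max_gap = 25L) {
  if (is.null(pairs)) {
    pairs <- homology_pairs(ga, gb, drop_self = drop_self)
  }
  anchors <- build_anchors(pairs, ga, gb, tandem_window)
  chain_collinear_blocks(anchors, min_anchors, max_gap,
                         genome_a = ga$genome_id, genome_b = gb$genome_id)
}

#' Detect and classify fusion events of one genome against a reference
#'
#' Runs the full per-genome stage: synteny blocks to the reference, painting
#' by the reference karyotype, junction detection and event classification.
#'
#' @param target genome to analyze.
#' @param reference structurally conserved reference genome (its
#'   chromosomes define the protochromosome labels) -- or pass `ak` (and
#'   then `reference` must still be the genome the karyotype's gene lists
#'   live in).
#' @param ak optional [ancestral_karyotype]; default [ak_from_genome] of the
#'   reference.
#' @param pairs optional homology pairs target -> reference.
#' @param min_anchors,max_gap,min_segment,flank,min_side_anchors,end_tol
#'   stage parameters, see the underlying functions.
#' @return list with `blocks`, `painting`, `breakpoints`, `events` and
#'   `inversions`.
#' @export
detect_events <- function(target, reference, ak = NULL, pairs = NULL,
                          min_anchors = 5L, max_gap = 25L, min_segment = 30L,
                          flank = 50L, end_tol = 15L) {
  if (is.null(ak)) ak <- ak_from_genome(reference)
  blocks <- genome_pair_blocks(target, reference, pairs,
                               min_anchors = min_anchors, max_gap = max_gap)
  painting <- paint_genome(target, ak, blocks, min_segment = min_segment)
  bps <- detect_junctions(painting, ak, target, flank = flank)
  events <- classify_events(bps, painting, ak, end_tol = end_tol)
  list(blocks = blocks, painting = painting, breakpoints = bps,
       events = events, inversions = attr(bps, "inversions"))
}

#' Reconstruct protochromosomes from a genome panel plus outgroup
#'
#' The pipeline behind ancestral-karyotype assembly: paint every ingroup
#' genome against the reference karyotype, identify CLSBs (protochromosomes
#' conserved as whole chromosomes everywhere), and resolve the remaining
#' labels by outgroup rooting -- a label is resolved to its reference
#' (ancestral) form when every junction involving it in the ingroup is
#' derived relative to the outgroup.
#'
#' @param genomes named list of ingroup [genome_order]s, including the
#'   reference.
#' @param reference_id id of the reference genome within `genomes`.
#' @param outgroup [genome_order] of the outgroup taxon.
#' @param purity CLSB purity criterion, see [identify_clsbs].
#' @param min_side_anchors,flank collinearity support, see [spanning_block].
#' @param ... further parameters passed to [detect_events].
#' @return list with `karyotype` (the assembled [ancestral_karyotype]),
#'   `clsbs`, `resolved`, `paintings`, `breakpoints` and outgroup `verdicts`.
#' @export
reconstruct_protochromosomes <- function(genomes, reference_id, outgroup,
                                         purity = 0.95, min_side_anchors = 25L,
                                         flank = 50L, ...) {
  reference <- genomes[[reference_id]]
  if (is.null(reference)) stop("reference '", reference_id, "' not in genome panel")
  ak <- ak_from_genome(reference)
  stage <- lapply(genomes, detect_events, reference = reference, ak = ak,
                  flank = flank, ...)
  paintings <- lapply(stage, `[[`, "painting")
  bps <- lapply(stage, `[[`, "breakpoints")
  clsbs <- identify_clsbs(paintings, purity = purity)
  labels <- names(ak$protochromosomes)
  pending <- setdiff(labels, clsbs)
  verdicts <- list(); resolved <- character(0)
  if (length(pending) > 0L) {
    out_blocks <- lapply(genomes, function(g) genome_pair_blocks(g, outgroup))
    for (lab in pending) {
      lab_verdicts <- character(0)
      for (id in names(genomes)) {
        b <- bps[[id]]
        b <- b[b$left_label == lab | b$right_label == lab, , drop = FALSE]
        if (nrow(b) == 0L) next
        v <- orient_with_outgroup(b, out_blocks[[id]], flank = flank,
                                  min_side_anchors = min_side_anchors)
        v$genome <- id; v$label <- lab
        verdicts[[length(verdicts) + 1L]] <- v
        lab_verdicts <- c(lab_verdicts, v$verdict)
      }
      if (length(lab_verdicts) > 0L && all(lab_verdicts == "derived")) {
        resolved <- c(resolved, lab)
      }
    }
  }
  verdicts <- if (length(verdicts) > 0L) do.call(rbind, verdicts) else
    data.frame(bp_id = character(), verdict = character(), n_left = integer(),
               n_right = integer(), genome = character(), label = character())
  karyotype <- assemble_ancestral_karyotype(paintings, clsbs, reference,
                                            resolved_labels = resolved,
                                            karyotype_id = paste0("AK.", reference_id))
  list(karyotype = karyotype, clsbs = clsbs, resolved = resolved,
       paintings = paintings, breakpoints = bps, verdicts = verdicts)
}

#' Breakpoint matrix and Dollo tree for a genome panel
#'
#' Detects breakpoints in every genome against the reference karyotype,
#' links them across all ordered genome pairs (both directions, so
#' loss-eroded windows on one side still link), builds the copy-number
#' matrix and infers the clade tree.
#'
#' @inheritParams reconstruct_protochromosomes
#' @param self_pairs genome ids additionally compared against themselves
#'   (needed to merge duplicated fusion copies inside polyploids).
#' @param ak_reference optional reference [genome_order] that defines the
#'   karyotype without contributing a matrix row; when `NULL` the reference
#'   is `genomes[[reference_id]]` and keeps its row.
#' @return list with `matrix` (a `breakpoint_matrix`), `tree` (a
#'   `clade_tree`), `breakpoints` and `events` per genome.
#' @export
breakpoint_matrix_pipeline <- function(genomes, reference_id, self_pairs = character(),
                                       ak_reference = NULL, min_side_anchors = 25L,
                                       flank = 50L, ...) {
  reference <- if (is.null(ak_reference)) genomes[[reference_id]] else ak_reference
  if (is.null(reference)) stop("either reference_id or ak_reference must identify the reference")
  ak <- ak_from_genome(reference)
  stage <- lapply(genomes, detect_events, reference = reference, ak = ak,
                  flank = flank, ...)
  bps <- lapply(stage, `[[`, "breakpoints")
  ids <- names(genomes)
  blocks <- list()
  for (a in ids) for (b in ids) {
    if (a == b && !a %in% self_pairs) next
    blocks[[paste(a, b, sep = "||")]] <-
      genome_pair_blocks(genomes[[a]], genomes[[b]], drop_self = a == b)
  }
  m <- build_breakpoint_matrix(bps, blocks, flank = flank,
                               min_side_anchors = min_side_anchors)
  tree <- infer_tree_dollo(m)
  list(matrix = m, tree = tree, breakpoints = bps,
       events = lapply(stage, `[[`, "events"))
}

#' Phase a polyploid and assign parentage, with iterative refinement
#'
#' Phases the polyploid's chromosomes into `k` subgenomes and assigns each
#' subgenome a parent from the candidates by unique shared fusion events.
#' If two subgenomes claim the same parent, the phasing is re-run with a
#' shifted search seed (up to `max_iter` refinements) and the best
#' conflict-free assignment is kept; remaining conflicts are reported.
#'
#' @param poly [genome_order] of the polyploid.
#' @param reference reference genome defining the karyotype.
#' @param candidates named list of candidate parent [genome_order]s.
#' @param k number of subgenomes.
#' @param seed search seed.
#' @param max_iter refinement attempts.
#' @param ... passed to [detect_events].
#' @return list with `phasing`, `parentage`, `events`, `breakpoints`.
#' @export
phase_and_assign <- function(poly, reference, candidates, k, seed = 1L,
                             max_iter = 3L, ...) {
  ak <- ak_from_genome(reference)
  stage <- detect_events(poly, reference, ak = ak, ...)
  blocks_to <- lapply(candidates, function(cand) genome_pair_blocks(poly, cand))
  parent_stage <- lapply(candidates, detect_events, reference = reference, ak = ak, ...)
  parent_bps <- lapply(parent_stage, `[[`, "breakpoints")
  blocks_from <- lapply(candidates, function(cand) genome_pair_blocks(cand, poly))
  result <- NULL
  for (it in seq_len(max_iter)) {
    ph <- phase_subgenomes(stage$painting, ak, k, seed = seed + (it - 1L) * 1000L)
    pa <- assign_parentage(ph$subgenomes, stage$events, stage$breakpoints,
                           blocks_to, parent_bps = parent_bps,
                           blocks_from_parents = blocks_from)
    assigned <- pa$assignment$parent[!is.na(pa$assignment$parent)]
    conflict <- anyDuplicated(assigned) > 0L
    if (is.null(result) || !conflict) {
      result <- list(phasing = ph, parentage = pa, conflict = conflict)
    }
    if (!conflict) break
  }
  c(result, list(events = stage$events, breakpoints = stage$breakpoints,
                 painting = stage$painting))
}
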
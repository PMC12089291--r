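#' Ancestral karyotype
#'
#' An ancestral karyotype is an ordered set of protochromosomes, each
#' represented by an ordered gene list borrowed from a designated reference
#' genome. Ancestral rank coordinates are 0-based positions within a
#' protochromosome's gene list.
#'
#' @param karyotype_id name of the karyotype (e.g. `"AK"`).
#' @param protochromosomes named list of character vectors of gene ids, in
#'   ancestral order; names are the protochromosome labels.
#' @param reference_genome_id id of the genome the gene lists come from.
#' @return object of class `ancestral_karyotype`.
#' @export
ancestral_karyotype <- function(karyotype_id, protochromosomes,
                                reference_genome_id = NA_character_) {
  stopifnot(is.list(protochromosomes), !is.null(names(protochromosomes)))
  all_genes <- unlist(protochromosomes, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop("protochromosome gene lists must be disjoint")
  structure(list(karyotype_id = karyotype_id,
                 protochromosomes = protochromosomes,
                 reference_genome_id = reference_genome_id,
                 p = length(protochromosomes)),
            class = "ancestral_karyotype")
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat(sprintf("ancestral_karyotype '%s': p = %d protochromosome(s) (%s), %d genes\n",
              x$karyotype_id, x$p, paste(names(x$protochromosomes), collapse = ", "),
              sum(lengths(x$protochromosomes))))
  invisible(x)
}

#' Treat a genome's chromosomes as a karyotype
#'
#' Each chromosome of `g` becomes one protochromosome, labeled `"1"`,
#' `"2"`, ... in chromosome order (or by `labels`). This is the usual way to
#' seed the painting of other genomes against a structurally conserved
#' reference.
#'
#' @param g a [genome_order].
#' @param karyotype_id karyotype name.
#' @param labels optional character vector of labels, one per chromosome.
#' @return an [ancestral_karyotype].
#' @export
ak_from_genome <- function(g, karyotype_id = g$genome_id, labels = NULL) {
  if (is.null(labels)) labels <- as.character(seq_along(g$chrom_order))
  stopifnot(length(labels) == length(g$chrom_order))
  protos <- lapply(g$chrom_order, function(chrom) chrom_genes(g, chrom)$gene_id)
  names(protos) <- labels
  ancestral_karyotype(karyotype_id, protos, g$genome_id)
}

# gene_id -> (label, anc_rank) lookup table
ak_gene_table <- function(ak) {
  data.frame(gene_id = unlist(ak$protochromosomes, use.names = FALSE),
             label = rep(names(ak$protochromosomes), lengths(ak$protochromosomes)),
             anc_rank = unlist(lapply(ak$protochromosomes, function(v) seq_along(v) - 1L),
                               use.names = FALSE),
             stringsAsFactors = FALSE)
}

ak_lengths <- function(ak) {
  stats::setNames(lengths(ak$protochromosomes), names(ak$protochromosomes))
}

#' Paint a genome by protochromosomes
#'
#' Assigns every gene rank of the target genome to a protochromosome label
#' by majority vote over synteny-block anchors (per block, not per gene, so
#' isolated homolog misassignments do not fragment segments), then
#' run-length encodes the labels into segments. Painted segments shorter
#' than `min_segment` are merged into the flanking painted segment with more
#' anchors (or dropped when none is adjacent); unpainted gaps are labeled
#' `"NA"`. Adjacent same-label segments are merged only when their ancestral
#' intervals are contiguous (within `contiguity_tol` ancestral ranks) in a
#' consistent orientation, so that genuine intra-protochromosome
#' rearrangements remain visible as separate segments.
#'
#' @param target [genome_order] to paint.
#' @param ak [ancestral_karyotype] to paint against.
#' @param blocks `synteny_blocks` computed with `target` as genome A and the
#'   karyotype's reference gene set as genome B.
#' @param min_segment minimum painted segment length, in genes.
#' @param contiguity_tol ancestral-rank slack when deciding whether two
#'   same-label segments are contiguous.
#' @return a [karyotype_painting].
#' @export
paint_genome <- function(target, ak, blocks, min_segment = 30L, contiguity_tol = 30L) {
  akt <- ak_gene_table(ak)
  an <- blocks$anchors
  an$label <- akt$label[match(an$gene_b, akt$gene_id)]
  an$anc_rank <- akt$anc_rank[match(an$gene_b, akt$gene_id)]
  an <- an[!is.na(an$label), , drop = FALSE]
  btab <- blocks$blocks
  if (nrow(btab) == 0L || nrow(an) == 0L) {
    warning("no synteny blocks: returning an all-NA painting for ", target$genome_id)
    segs <- do.call(rbind, lapply(target$chrom_order, function(chrom) {
      data.frame(chromosome = chrom, start_rank = 0L,
                 end_rank = chrom_length(target, chrom), label = "NA",
                 orientation = "+", anc_start = NA_integer_,
                 anc_end = NA_integer_, n_anchors = 0L, stringsAsFactors = FALSE)
    }))
    return(karyotype_painting(target$genome_id, segs, ak$karyotype_id, min_segment))
  }
  # majority label per block
  blk_an <- split(an, an$block_id)
  blk_label <- vapply(blk_an, function(d) names(which.max(table(d$label))), "")
  btab$label <- blk_label[btab$block_id]
  btab <- btab[!is.na(btab$label), , drop = FALSE]
  seg_list <- list()
  for (chrom in target$chrom_order) {
    nlen <- chrom_length(target, chrom)
    blk <- rep(NA_character_, nlen)
    cb <- btab[btab$chr_a == chrom, , drop = FALSE]
    cb <- cb[order(cb$n_anchors), , drop = FALSE]  # larger blocks overwrite
    for (i in seq_len(nrow(cb))) {
      blk[(cb$a_start[i] + 1L):cb$a_end[i]] <- cb$block_id[i]
    }
    # segment on block identity (so orientation flips stay visible), then
    # relabel by the block's protochromosome
    segs <- rle_segments(blk, chrom)
    segs$label[!is.na(segs$label)] <-
      cb$label[match(segs$label[!is.na(segs$label)], cb$block_id)]
    segs <- segment_stats(segs, an, chrom)
    segs <- merge_short_segments(segs, min_segment, an, chrom)
    segs <- merge_contiguous(segs, contiguity_tol, an, chrom)
    seg_list[[chrom]] <- segs
  }
  segs <- do.call(rbind, seg_list)
  segs$label[is.na(segs$label)] <- "NA"
  karyotype_painting(target$genome_id, segs, ak$karyotype_id, min_segment)
}

rle_segments <- function(lab, chrom) {
  r <- rle(ifelse(is.na(lab), "\rNA", lab))
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(chromosome = chrom, start_rank = starts, end_rank = ends,
             label = ifelse(r$values == "\rNA", NA_character_, r$values),
             stringsAsFactors = FALSE)
}

# ancestral interval, orientation and anchor count of each painted segment
segment_stats <- function(segs, an, chrom) {
  segs$orientation <- "+"
  segs$anc_start <- NA_integer_; segs$anc_end <- NA_integer_
  segs$n_anchors <- 0L
  ca <- an[an$chr_a == chrom, , drop = FALSE]
  for (i in seq_len(nrow(segs))) {
    if (is.na(segs$label[i])) next
    sa <- ca[ca$rank_a >= segs$start_rank[i] & ca$rank_a < segs$end_rank[i] &
               ca$label == segs$label[i], , drop = FALSE]
    if (nrow(sa) == 0L) { segs$label[i] <- NA_character_; next }
    segs$n_anchors[i] <- nrow(sa)
    segs$anc_start[i] <- min(sa$anc_rank)
    segs$anc_end[i] <- max(sa$anc_rank) + 1L
    if (nrow(sa) >= 2L) {
      rho <- suppressWarnings(stats::cor(sa$rank_a, sa$anc_rank, method = "spearman"))
      if (!is.na(rho) && rho < 0) segs$orientation[i] <- "-"
    }
  }
  segs
}

merge_short_segments <- function(segs, min_segment, an, chrom) {
  repeat {
    painted <- which(!is.na(segs$label))
    len <- segs$end_rank - segs$start_rank
    short <- painted[len[painted] < min_segment]
    if (length(short) == 0L) break
    i <- short[which.min(len[short])]
    pos <- match(i, painted)
    left <- if (pos > 1L && painted[pos - 1L] == i - 1L) i - 1L else NA_integer_
    right <- if (pos < length(painted) && painted[pos + 1L] == i + 1L) i + 1L else NA_integer_
    tgt <- if (!is.na(left) && (is.na(right) || segs$n_anchors[left] >= segs$n_anchors[right])) {
      left
    } else if (!is.na(right)) right else NA_integer_
    if (is.na(tgt)) {                       # isolated short fragment -> unpainted
      segs$label[i] <- NA_character_
      segs$n_anchors[i] <- 0L
      segs$anc_start[i] <- segs$anc_end[i] <- NA_integer_
      next
    }
    lo <- min(segs$start_rank[c(i, tgt)]); hi <- max(segs$end_rank[c(i, tgt)])
    segs$start_rank[tgt] <- lo; segs$end_rank[tgt] <- hi
    segs <- segs[-i, , drop = FALSE]
    segs <- recompute_one(segs, which(segs$start_rank == lo & segs$end_rank == hi)[1L], an, chrom)
    rownames(segs) <- NULL
  }
  segs
}

recompute_one <- function(segs, i, an, chrom) {
  sa <- an[an$chr_a == chrom & an$rank_a >= segs$start_rank[i] &
             an$rank_a < segs$end_rank[i] & an$label == segs$label[i], , drop = FALSE]
  if (nrow(sa) > 0L) {
    segs$n_anchors[i] <- nrow(sa)
    segs$anc_start[i] <- min(sa$anc_rank)
    segs$anc_end[i] <- max(sa$anc_rank) + 1L
    if (nrow(sa) >= 2L) {
      rho <- suppressWarnings(stats::cor(sa$rank_a, sa$anc_rank, method = "spearman"))
      segs$orientation[i] <- if (!is.na(rho) && rho < 0) "-" else "+"
    }
  }
  segs
}

merge_contiguous <- function(segs, tol, an, chrom) {
  repeat {
    merged <- FALSE
    painted <- which(!is.na(segs$label))
    if (length(painted) >= 2L) {
      for (k in seq_len(length(painted) - 1L)) {
        i <- painted[k]; j <- painted[k + 1L]
        if (j != i + 1L) next
        if (segs$label[i] != segs$label[j]) next
        if (segs$orientation[i] != segs$orientation[j]) next
        gap <- if (segs$orientation[i] == "+") {
          segs$anc_start[j] - segs$anc_end[i]
        } else {
          segs$anc_start[i] - segs$anc_end[j]
        }
        if (is.na(gap) || gap > tol || gap < -tol) next
        segs$end_rank[i] <- segs$end_rank[j]
        segs$anc_start[i] <- min(segs$anc_start[i], segs$anc_start[j])
        segs$anc_end[i] <- max(segs$anc_end[i], segs$anc_end[j])
        segs$n_anchors[i] <- segs$n_anchors[i] + segs$n_anchors[j]
        segs <- segs[-j, , drop = FALSE]
        rownames(segs) <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  segs
}

#' Identify chromosome-like synteny blocks (CLSBs)
#'
#' A protochromosome label is a CLSB when, in every input genome, its
#' painted content lies essentially on a single chromosome and that
#' chromosome is essentially pure for the label -- i.e. the protochromosome
#' is preserved as one whole chromosome everywhere. "Essentially" is the
#' `purity` fraction applied in both directions. The result does not depend
#' on the order of the paintings.
#'
#' @param paintings list of [karyotype_painting] objects, all against the
#'   same karyotype.
#' @param purity fraction in (0, 1].
#' @return sorted character vector of CLSB labels.
#' @export
identify_clsbs <- function(paintings, purity = 0.95) {
  kids <- unique(vapply(paintings, function(p) as.character(p$karyotype_id), ""))
  if (length(kids) > 1L) stop("paintings come from different karyotypes: ",
                              paste(kids, collapse = ", "))
  labels <- sort(unique(unlist(lapply(paintings, function(p) {
    p$segments$label[p$segments$label != "NA"]
  }))))
  is_clsb <- vapply(labels, function(lab) {
    all(vapply(paintings, function(p) {
      s <- p$segments[p$segments$label != "NA", , drop = FALSE]
      s$len <- s$end_rank - s$start_rank
      on_lab <- s[s$label == lab, , drop = FALSE]
      if (nrow(on_lab) == 0L) return(FALSE)
      by_chrom <- tapply(on_lab$len, on_lab$chromosome, sum)
      cstar <- names(by_chrom)[which.max(by_chrom)]
      frac_on_cstar <- by_chrom[cstar] / sum(on_lab$len)
      painted_cstar <- sum(s$len[s$chromosome == cstar])
      frac_of_cstar <- by_chrom[cstar] / painted_cstar
      frac_on_cstar >= purity && frac_of_cstar >= purity
    }, TRUE))
  }, TRUE)
  labels[is_clsb]
}

#' Assemble an ancestral karyotype from paintings
#'
#' Extracts protochromosome gene lists from the reference genome's painted
#' segments. Every label must be either a CLSB or explicitly resolved to
#' its ancestral form by outgroup rooting (see [orient_with_outgroup]).
#'
#' @param paintings list of [karyotype_painting]s; must include a painting
#'   of the reference genome itself.
#' @param clsb_labels labels from [identify_clsbs].
#' @param reference [genome_order] of the reference genome.
#' @param resolved_labels labels resolved by outgroup rooting.
#' @param karyotype_id name for the assembled karyotype.
#' @return an [ancestral_karyotype] with `p` = number of labels.
#' @export
assemble_ancestral_karyotype <- function(paintings, clsb_labels, reference,
                                         resolved_labels = character(),
                                         karyotype_id = "AK") {
  ref_paint <- NULL
  for (p in paintings) if (identical(p$genome_id, reference$genome_id)) ref_paint <- p
  if (is.null(ref_paint)) stop("paintings must include the reference genome '",
                               reference$genome_id, "'")
  segs <- ref_paint$segments[ref_paint$segments$label != "NA", , drop = FALSE]
  labels <- sort(unique(segs$label))
  unresolved <- setdiff(labels, union(clsb_labels, resolved_labels))
  if (length(unresolved) > 0L) {
    stop("unresolved protochromosome label(s): ", paste(unresolved, collapse = ", "),
         " (neither CLSB nor outgroup-rooted)")
  }
  protos <- lapply(labels, function(lab) {
    s <- segs[segs$label == lab, , drop = FALSE]
    s <- s[order(s$chromosome, s$start_rank), , drop = FALSE]
    unlist(lapply(seq_len(nrow(s)), function(i) {
      genes <- chrom_genes(reference, s$chromosome[i])
      ids <- genes$gene_id[genes$rank >= s$start_rank[i] & genes$rank < s$end_rank[i]]
      if (s$orientation[i] == "-") rev(ids) else ids
    }), use.names = FALSE)
  })
  names(protos) <- labels
  ancestral_karyotype(karyotype_id, protos, reference$genome_id)
}

#' Overlap between CGB boundaries and fusion breakpoints
#'
#' Maps conserved-genomic-block (CGB) boundaries and fusion-breakpoint
#' positions, both in ancestral rank coordinates on the same karyotype, and
#' links a breakpoint position to a boundary when they sit on the same
#' protochromosome no more than `link_distance` genes apart. Exact
#' coincidences (distance 0) are reported separately.
#'
#' @param cgbs data.frame from [read_cgb_definitions] (`label`,
#'   `chromosome`, `start_rank`, `end_rank`).
#' @param bp_positions data.frame with columns `chromosome` (protochromosome
#'   label) and `anc_rank`; see [breakpoint_anc_positions].
#' @param link_distance maximum rank distance, in genes.
#' @return list with `n_boundaries`, `n_positions`, `n_linked`,
#'   `n_linked_boundaries`, `n_exact` and a `pairs` table of all
#'   boundary/breakpoint distances.
#' @export
map_cgb_overlap <- function(cgbs, bp_positions, link_distance = 50L) {
  bounds <- do.call(rbind, lapply(unique(cgbs$chromosome), function(chrom) {
    s <- cgbs[cgbs$chromosome == chrom, , drop = FALSE]
    pts <- sort(unique(c(s$start_rank, s$end_rank)))
    pts <- pts[pts > min(pts) & pts < max(pts)]   # interior boundaries only
    if (length(pts) == 0L) return(NULL)
    data.frame(chromosome = chrom, boundary_rank = pts, stringsAsFactors = FALSE)
  }))
  if (is.null(bounds)) bounds <- data.frame(chromosome = character(),
                                            boundary_rank = integer())
  pairs <- NULL
  if (nrow(bounds) > 0L && nrow(bp_positions) > 0L) {
    pairs <- merge(bounds, cbind(bp_positions, bp_index = seq_len(nrow(bp_positions))),
                   by = "chromosome")
    if (nrow(pairs) > 0L) {
      pairs$distance <- abs(pairs$boundary_rank - pairs$anc_rank)
      pairs$linked <- pairs$distance <= link_distance
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(chromosome = character(), boundary_rank = integer(),
                        anc_rank = integer(), bp_index = integer(),
                        distance = integer(), linked = logical())
  }
  linked_bp <- unique(pairs$bp_index[pairs$linked])
  exact_bp <- unique(pairs$bp_index[pairs$distance == 0])
  linked_bounds <- unique(paste(pairs$chromosome, pairs$boundary_rank)[pairs$linked])
  list(n_boundaries = nrow(bounds), n_positions = nrow(bp_positions),
       n_linked = length(linked_bp), n_linked_boundaries = length(linked_bounds),
       n_exact = length(exact_bp), boundaries = bounds, pairs = pairs)
}
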
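#' Build synteny anchors from homology pairs
#'
#' Turns a table of homologous gene pairs into dot-plot anchors, i.e. pairs
#' of rank positions in genomes A and B. Tandem arrays (genes of the same
#' family whose ranks lie within `tandem_window` of each other on one
#' chromosome) are collapsed to the lowest-rank representative on each side,
#' and duplicate anchors are removed.
#'
#' @param pairs data.frame from [read_homology_pairs] (`gene_a` in genome A,
#'   `gene_b` in genome B).
#' @param ga,gb [genome_order] objects for genomes A and B.
#' @param tandem_window rank distance (genes) within which same-family genes
#'   on a chromosome are collapsed.
#' @return data.frame of anchors: `chr_a`, `rank_a`, `chr_b`, `rank_b`,
#'   `gene_a`, `gene_b`, `family`.
#' @export
build_anchors <- function(pairs, ga, gb, tandem_window = 5L) {
  if (nrow(pairs) == 0L) {
    return(data.frame(chr_a = character(), rank_a = integer(),
                      chr_b = character(), rank_b = integer(),
                      gene_a = character(), gene_b = character(),
                      family = character(), stringsAsFactors = FALSE))
  }
  ia <- match(pairs$gene_a, ga$genes$gene_id)
  ib <- match(pairs$gene_b, gb$genes$gene_id)
  if (anyNA(ia)) stop("gene id(s) not found in genome '", ga$genome_id, "': ",
                      paste(utils::head(unique(pairs$gene_a[is.na(ia)]), 5L), collapse = ", "))
  if (anyNA(ib)) stop("gene id(s) not found in genome '", gb$genome_id, "': ",
                      paste(utils::head(unique(pairs$gene_b[is.na(ib)]), 5L), collapse = ", "))
  anchors <- data.frame(chr_a = ga$genes$chromosome[ia], rank_a = ga$genes$rank[ia],
                        chr_b = gb$genes$chromosome[ib], rank_b = gb$genes$rank[ib],
                        gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                        family = if ("family" %in% names(pairs)) pairs$family else NA_character_,
                        stringsAsFactors = FALSE)
  if (tandem_window > 0L && !all(is.na(anchors$family))) {
    map_a <- tandem_representatives(anchors$gene_a, anchors$family,
                                    anchors$chr_a, anchors$rank_a, tandem_window)
    map_b <- tandem_representatives(anchors$gene_b, anchors$family,
                                    anchors$chr_b, anchors$rank_b, tandem_window)
    ra <- map_a[anchors$gene_a]
    rb <- map_b[anchors$gene_b]
    ra[is.na(ra)] <- anchors$gene_a[is.na(ra)]
    rb[is.na(rb)] <- anchors$gene_b[is.na(rb)]
    ia <- match(ra, ga$genes$gene_id)
    ib <- match(rb, gb$genes$gene_id)
    anchors$gene_a <- unname(ra); anchors$gene_b <- unname(rb)
    anchors$chr_a <- ga$genes$chromosome[ia]; anchors$rank_a <- ga$genes$rank[ia]
    anchors$chr_b <- gb$genes$chromosome[ib]; anchors$rank_b <- gb$genes$rank[ib]
  }
  anchors <- anchors[!duplicated(anchors[, c("chr_a", "rank_a", "chr_b", "rank_b")]), , drop = FALSE]
  anchors <- anchors[order(anchors$chr_a, anchors$rank_a, anchors$chr_b, anchors$rank_b), , drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

# named map gene_id -> representative gene_id for tandem clusters
tandem_representatives <- function(gene, family, chrom, rank, tandem_window) {
  keep <- !is.na(family)
  df <- unique(data.frame(gene = gene[keep], family = family[keep],
                          chrom = chrom[keep], rank = rank[keep],
                          stringsAsFactors = FALSE))
  out <- character(0)
  for (grp in split(df, paste(df$family, df$chrom, sep = "\r"))) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$rank), , drop = FALSE]
    cl <- cumsum(c(1L, diff(grp$rank) > tandem_window))
    for (k in unique(cl)) {
      members <- grp[cl == k, , drop = FALSE]
      reps <- rep(members$gene[1L], nrow(members))
      names(reps) <- members$gene
      out <- c(out, reps)
    }
  }
  out
}

#' Chain anchors into collinear synteny blocks
#'
#' Within each chromosome pair, anchors (sorted by `rank_a`) are partitioned
#' into strictly monotone runs: strictly increasing in both genomes
#' (orientation `+`) or strictly increasing in A and strictly decreasing in
#' B (`-`), with consecutive anchors at most `max_gap` ranks apart in both
#' genomes. The partition maximizes the number of anchors covered by blocks
#' of at least `min_anchors` anchors, then minimizes the number of blocks
#' (solved exactly by dynamic programming). A final pass extends blocks with
#' adjacent unused anchors, so no returned block can be extended without
#' violating monotonicity or the gap bound.
#'
#' @param anchors data.frame from [build_anchors].
#' @param min_anchors minimum anchors per block.
#' @param max_gap maximum rank step between consecutive anchors of a block,
#'   in either genome.
#' @param genome_a,genome_b genome ids recorded on the result.
#' @return object of class `synteny_blocks`: list with `blocks` (one row per
#'   block: `block_id`, `chr_a`, `a_start`, `a_end`, `chr_b`, `b_start`,
#'   `b_end`, `orientation`, `n_anchors`; spans half-open in rank
#'   coordinates), `anchors` (input anchors with a `block_id` column, NA for
#'   unassigned), and `params`.
#' @export
chain_collinear_blocks <- function(anchors, min_anchors = 5L, max_gap = 25L,
                                   genome_a = NA_character_, genome_b = NA_character_) {
  anchors$block_id <- rep(NA_character_, nrow(anchors))
  blocks <- list()
  if (nrow(anchors) > 0L) {
    grp_key <- paste(anchors$chr_a, anchors$chr_b, sep = "\r")
    for (key in unique(grp_key)) {
      idx <- which(grp_key == key)
      a <- anchors[idx, , drop = FALSE]
      ord <- order(a$rank_a, a$rank_b)
      a <- a[ord, , drop = FALSE]
      part <- chain_group(a$rank_a, a$rank_b, min_anchors, max_gap)
      for (blk in part) {
        rows <- idx[ord[blk$members]]
        blocks[[length(blocks) + 1L]] <- list(rows = rows, chr_a = a$chr_a[1L],
                                              chr_b = a$chr_b[1L],
                                              orientation = blk$orientation)
      }
    }
  }
  if (length(blocks) > 0L) {
    starts <- vapply(blocks, function(b) min(anchors$rank_a[b$rows]), 0L)
    chrs <- vapply(blocks, function(b) b$chr_a, "")
    blocks <- blocks[order(chrs, starts)]
    ids <- sprintf("B%04d", seq_along(blocks))
    btab <- do.call(rbind, lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      ra <- anchors$rank_a[b$rows]; rb <- anchors$rank_b[b$rows]
      data.frame(block_id = ids[i], chr_a = b$chr_a,
                 a_start = min(ra), a_end = max(ra) + 1L,
                 chr_b = b$chr_b, b_start = min(rb), b_end = max(rb) + 1L,
                 orientation = b$orientation, n_anchors = length(b$rows),
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_along(blocks)) anchors$block_id[blocks[[i]]$rows] <- ids[i]
  } else {
    btab <- data.frame(block_id = character(), chr_a = character(),
                       a_start = integer(), a_end = integer(),
                       chr_b = character(), b_start = integer(), b_end = integer(),
                       orientation = character(), n_anchors = integer(),
                       stringsAsFactors = FALSE)
  }
  structure(list(blocks = btab, anchors = anchors,
                 params = list(min_anchors = min_anchors, max_gap = max_gap),
                 genome_a = genome_a, genome_b = genome_b),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("synteny_blocks %s ~ %s: %d block(s), %d/%d anchors assigned\n",
              x$genome_a, x$genome_b, nrow(x$blocks),
              sum(!is.na(x$anchors$block_id)), nrow(x$anchors)))
  invisible(x)
}

# Exact maximal-coverage monotone partition of one (chr_a, chr_b) anchor
# group; ra strictly sorted order (ties in ra break every run). Composite
# objective: covered anchors (weight BIG) minus block count. Monotone-deque
# DP, O(n). Returns list of list(members = index vector, orientation).
chain_group <- function(ra, rb, min_anchors, max_gap) {
  n <- length(ra)
  BIG <- 1e7
  if (n == 0L) return(list())
  # step feasibility between consecutive anchors i and i+1
  if (n > 1L) {
    da <- diff(ra); db <- diff(rb)
    inc_ok <- da > 0L & db > 0L & da <= max_gap & db <= max_gap
    dec_ok <- da > 0L & db < 0L & da <= max_gap & -db <= max_gap
  } else {
    inc_ok <- dec_ok <- logical(0)
  }
  rs_inc <- rs_dec <- integer(n)
  rs_inc[1L] <- rs_dec[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    rs_inc[i] <- if (inc_ok[i - 1L]) rs_inc[i - 1L] else i
    rs_dec[i] <- if (dec_ok[i - 1L]) rs_dec[i - 1L] else i
  }
  F <- numeric(n + 1L)                 # F[j+1] = best composite for first j anchors
  ch_type <- integer(n)                # 0 skip, 1 inc block, 2 dec block
  ch_s <- integer(n)
  # deques of candidate block starts s, keys F[s-1] - s*BIG, decreasing keys
  dq_inc <- integer(n); hi_inc <- 1L; ti_inc <- 0L
  dq_dec <- integer(n); hi_dec <- 1L; ti_dec <- 0L
  key <- function(s) F[s] - s * BIG    # F[s] is F[(s-1)+1] = prefix s-1
  for (i in seq_len(n)) {
    s0 <- i - min_anchors + 1L
    if (s0 >= 1L) {
      k0 <- key(s0)
      while (ti_inc >= hi_inc && key(dq_inc[ti_inc]) < k0) ti_inc <- ti_inc - 1L
      ti_inc <- ti_inc + 1L; dq_inc[ti_inc] <- s0
      while (ti_dec >= hi_dec && key(dq_dec[ti_dec]) < k0) ti_dec <- ti_dec - 1L
      ti_dec <- ti_dec + 1L; dq_dec[ti_dec] <- s0
    }
    while (ti_inc >= hi_inc && dq_inc[hi_inc] < rs_inc[i]) hi_inc <- hi_inc + 1L
    while (ti_dec >= hi_dec && dq_dec[hi_dec] < rs_dec[i]) hi_dec <- hi_dec + 1L
    best <- F[i]                       # skip anchor i
    btype <- 0L; bs <- 0L
    base <- (i + 1) * BIG - 1
    if (ti_dec >= hi_dec) {
      s <- dq_dec[hi_dec]; v <- base + key(s)
      if (v > best) { best <- v; btype <- 2L; bs <- s }
    }
    if (ti_inc >= hi_inc) {            # checked after dec so ties go to "+"
      s <- dq_inc[hi_inc]; v <- base + key(s)
      if (v >= best && btype != 0L || v > best) { best <- v; btype <- 1L; bs <- s }
    }
    F[i + 1L] <- best
    ch_type[i] <- btype; ch_s[i] <- bs
  }
  # traceback
  part <- list()
  i <- n
  while (i >= 1L) {
    if (ch_type[i] == 0L) {
      i <- i - 1L
    } else {
      s <- ch_s[i]
      part[[length(part) + 1L]] <- list(members = s:i,
                                        orientation = if (ch_type[i] == 1L) "+" else "-")
      i <- s - 1L
    }
  }
  part <- rev(part)
  extend_blocks(part, n, inc_ok, dec_ok)
}

# append/prepend unused anchors adjacent (in sorted order) to a block when
# the connecting step stays monotone within the gap bound
extend_blocks <- function(part, n, inc_ok, dec_ok) {
  if (length(part) == 0L) return(part)
  used <- logical(n)
  for (b in part) used[b$members] <- TRUE
  repeat {
    changed <- FALSE
    for (j in seq_along(part)) {
      b <- part[[j]]
      ok <- if (b$orientation == "+") inc_ok else dec_ok
      e <- max(b$members)
      while (e < n && !used[e + 1L] && ok[e]) {
        e <- e + 1L; used[e] <- TRUE
        part[[j]]$members <- c(part[[j]]$members, e)
        changed <- TRUE
      }
      s <- min(part[[j]]$members)
      while (s > 1L && !used[s - 1L] && ok[s - 1L]) {
        s <- s - 1L; used[s] <- TRUE
        part[[j]]$members <- c(s, part[[j]]$members)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(part, function(b) { b$members <- sort(b$members); b })
}

#' Does one synteny block span a junction with support on both flanks?
#'
#' Tests whether a single block contains at least `min_side_anchors` anchors
#' with `rank_a` in `[junction_rank - flank, junction_rank)` and at least as
#' many in `[junction_rank, junction_rank + flank)`. This is the
#' collinearity criterion used to decide whether a fusion breakpoint is
#' present (inherited) in the other genome.
#'
#' @param sb a `synteny_blocks` object (genome A is the breakpoint's genome).
#' @param chr_a chromosome of the junction in genome A.
#' @param junction_rank between-gene position (rank of the right-hand gene).
#' @param flank window size per side, in genes.
#' @param min_side_anchors anchors required on each side within one block.
#' @param restrict_b optional character vector: only consider blocks whose
#'   genome-B chromosome is in this set (e.g. one subgenome's chromosomes).
#' @return list with `spanning` (logical), `block_id`, `n_left`, `n_right`.
#' @export
spanning_block <- function(sb, chr_a, junction_rank, flank = 50L,
                           min_side_anchors = 25L, restrict_b = NULL) {
  an <- sb$anchors
  an <- an[!is.na(an$block_id) & an$chr_a == chr_a, , drop = FALSE]
  if (!is.null(restrict_b)) {
    ok_blocks <- sb$blocks$block_id[sb$blocks$chr_b %in% restrict_b]
    an <- an[an$block_id %in% ok_blocks, , drop = FALSE]
  }
  res <- list(spanning = FALSE, block_id = NA_character_, n_left = 0L, n_right = 0L)
  if (nrow(an) == 0L) return(res)
  left <- an$rank_a >= junction_rank - flank & an$rank_a < junction_rank
  right <- an$rank_a >= junction_rank & an$rank_a < junction_rank + flank
  nl <- tapply(left, an$block_id, sum)
  nr <- tapply(right, an$block_id, sum)
  cand <- names(nl)[nl >= min_side_anchors & nr >= min_side_anchors]
  if (length(cand) == 0L) {
    best <- names(nl)[which.max(nl + nr)]
    res$block_id <- best
    res$n_left <- as.integer(nl[best]); res$n_right <- as.integer(nr[best])
    return(res)
  }
  best <- cand[which.max(nl[cand] + nr[cand])]
  list(spanning = TRUE, block_id = best,
       n_left = as.integer(nl[best]), n_right = as.integer(nr[best]))
}

# largest single-block anchor count inside one flank window (evidence that a
# flank is represented in the other genome at all)
flank_support <- function(sb, chr_a, lo, hi) {
  an <- sb$anchors
  an <- an[!is.na(an$block_id) & an$chr_a == chr_a &
             an$rank_a >= lo & an$rank_a < hi, , drop = FALSE]
  if (nrow(an) == 0L) return(0L)
  max(table(an$block_id))
}

#' Write a synteny block table
#' @param sb a `synteny_blocks` object.
#' @param path output path (tab-separated).
#' @export
write_blocks <- function(sb, path) {
  utils::write.table(sb$blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
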
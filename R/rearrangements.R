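#' Detect fusion junctions between a painted genome and its karyotype
#'
#' Emits one breakpoint per adjacent pair of painted segments whose
#' ancestral positions are not contiguous ends of the same protochromosome.
#' The junction position is the between-gene index equal to the rank of the
#' right-hand gene (half-open convention). Same-label adjacencies whose
#' ancestral intervals are contiguous but whose orientations flip are
#' inversions: they are logged on the `inversions` attribute of the result,
#' not reported as breakpoints.
#'
#' @param p [karyotype_painting] of `target` against `ak`.
#' @param ak the [ancestral_karyotype] painted against.
#' @param target [genome_order]; supplies the gene-order windows.
#' @param flank window genes per side (up to `flank` ids each side).
#' @param contiguity_tol ancestral-rank slack for "contiguous".
#' @return data.frame of breakpoints (`bp_id`, `genome_id`, `chromosome`,
#'   `junction_rank`, left/right context columns, facing ancestral
#'   coordinates, list-columns `window_left`/`window_right`,
#'   `truncated`), with attribute `inversions`.
#' @export
detect_junctions <- function(p, ak, target, flank = 50L, contiguity_tol = 30L) {
  segs <- p$segments
  rows <- list(); invs <- list()
  for (chrom in unique(segs$chromosome)) {
    s <- segs[segs$chromosome == chrom & segs$label != "NA", , drop = FALSE]
    s <- s[order(s$start_rank), , drop = FALSE]
    if (nrow(s) < 2L) next
    genes <- chrom_genes(target, chrom)
    for (k in seq_len(nrow(s) - 1L)) {
      L <- s[k, ]; R <- s[k + 1L, ]
      if (L$label == R$label) {
        if (L$orientation == R$orientation) {
          gap <- if (L$orientation == "+") R$anc_start - L$anc_end else L$anc_start - R$anc_end
          if (!is.na(gap) && abs(gap) <= contiguity_tol) next   # contiguous
        } else {
          # orientation flip within a protochromosome: inversion, not a fusion
          gap2 <- suppressWarnings(min(abs(c(R$anc_start - L$anc_end,
                                             L$anc_start - R$anc_end,
                                             R$anc_end - L$anc_start,
                                             L$anc_end - R$anc_start))))
          if (is.finite(gap2) && gap2 <= contiguity_tol + 1L) {
            invs[[length(invs) + 1L]] <- data.frame(
              genome_id = p$genome_id, chromosome = chrom,
              junction_rank = R$start_rank, label = L$label,
              stringsAsFactors = FALSE)
            next
          }
        }
      }
      jr <- R$start_rank
      wl <- genes$gene_id[genes$rank >= jr - flank & genes$rank < jr]
      wr <- genes$gene_id[genes$rank >= jr & genes$rank < jr + flank]
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = p$genome_id, chromosome = chrom, junction_rank = jr,
        left_label = L$label, left_anc_start = L$anc_start, left_anc_end = L$anc_end,
        left_orient = L$orientation,
        right_label = R$label, right_anc_start = R$anc_start, right_anc_end = R$anc_end,
        right_orient = R$orientation,
        left_facing = if (L$orientation == "+") L$anc_end - 1L else L$anc_start,
        right_facing = if (R$orientation == "+") R$anc_start else R$anc_end - 1L,
        truncated = (jr < flank) || (jr + flank > nrow(genes)),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$window_left <- I(list(wl))
      rows[[length(rows)]]$window_right <- I(list(wr))
    }
  }
  bps <- if (length(rows) > 0L) do.call(rbind, rows) else empty_breakpoints()
  if (nrow(bps) > 0L) {
    bps <- bps[order(bps$chromosome, bps$junction_rank), , drop = FALSE]
    bps$bp_id <- sprintf("%s.bp%02d", p$genome_id, seq_len(nrow(bps)))
    bps <- bps[, c("bp_id", setdiff(names(bps), "bp_id"))]
    rownames(bps) <- NULL
  }
  attr(bps, "inversions") <- if (length(invs) > 0L) do.call(rbind, invs) else
    data.frame(genome_id = character(), chromosome = character(),
               junction_rank = integer(), label = character())
  bps
}

empty_breakpoints <- function() {
  df <- data.frame(bp_id = character(), genome_id = character(), chromosome = character(),
                   junction_rank = integer(), left_label = character(),
                   left_anc_start = integer(), left_anc_end = integer(),
                   left_orient = character(), right_label = character(),
                   right_anc_start = integer(), right_anc_end = integer(),
                   right_orient = character(), left_facing = integer(),
                   right_facing = integer(), truncated = logical(),
                   stringsAsFactors = FALSE)
  df$window_left <- I(list()); df$window_right <- I(list())
  df
}

is_terminal_facing <- function(facing, len, end_tol) {
  !is.na(facing) && (facing <= end_tol || facing >= len - 1L - end_tol)
}

#' Classify breakpoints into fusion events
#'
#' Pairs and classifies junctions as reciprocal chromosome translocations
#' (RCT, two breakpoints on two chromosomes exchanging terminal segments of
#' the same two protochromosomes, chromosome number unchanged), end-to-end
#' joinings (EEJ, one breakpoint joining terminal ancestral intervals of two
#' protochromosomes, chromosome number -1) or nested chromosome fusions
#' (NCF, two breakpoints on one chromosome flanking a complete nested
#' protochromosome, chromosome number -1). Junctions that fit none of the
#' three patterns are reported with type `"complex"`, never dropped.
#'
#' @param bps breakpoints from [detect_junctions].
#' @param p the painting the breakpoints came from.
#' @param ak the ancestral karyotype.
#' @param end_tol ancestral ranks within which a facing coordinate counts as
#'   a protochromosome terminus.
#' @param split_tol slack, in ancestral ranks, when matching complementary
#'   split positions across the two junctions of an RCT or NCF.
#' @return data.frame of events: `event_id`, `type`, `proto_a`, `proto_b`,
#'   `name`, `delta_n`, `bp_ids` (semicolon-joined), `chromosomes`.
#' @export
classify_events <- function(bps, p, ak, end_tol = 15L, split_tol = 30L) {
  lens <- ak_lengths(ak)
  n <- nrow(bps)
  used <- logical(n)
  ev <- list()
  add_event <- function(type, a, b, ids, chroms, delta) {
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type, proto_a = a, proto_b = b,
      name = name_event(ak$karyotype_id, a, b, type),
      delta_n = delta, bp_ids = paste(ids, collapse = ";"),
      chromosomes = paste(unique(chroms), collapse = ";"), stringsAsFactors = FALSE)
  }
  term <- function(facing, lab) is_terminal_facing(facing, lens[[lab]], end_tol)
  # --- NCF: consecutive junction pairs on one chromosome around a complete donor
  if (n >= 2L) {
    for (chrom in unique(bps$chromosome)) {
      idx <- which(bps$chromosome == chrom & !used)
      if (length(idx) < 2L) next
      idx <- idx[order(bps$junction_rank[idx])]
      for (k in seq_len(length(idx) - 1L)) {
        i <- idx[k]; j <- idx[k + 1L]
        if (used[i] || used[j]) next
        D <- bps$right_label[i]
        R <- bps$left_label[i]
        if (!(identical(bps$left_label[j], D) && identical(bps$right_label[j], R))) next
        donor_cov <- bps$left_anc_end[j] - bps$right_anc_start[i]
        if (bps$right_anc_start[i] > bps$left_anc_start[j]) {
          donor_cov <- bps$right_anc_end[i] - bps$left_anc_start[j]
        }
        ok_donor <- term(bps$right_facing[i], D) && term(bps$left_facing[j], D) &&
          !is.na(donor_cov) && donor_cov >= lens[[D]] - 2L * end_tol
        ok_recip <- !term(bps$left_facing[i], R) && !term(bps$right_facing[j], R) &&
          abs(bps$right_facing[j] - bps$left_facing[i]) <= split_tol
        if (ok_donor && ok_recip) {
          used[c(i, j)] <- TRUE
          add_event("NCF", R, D, bps$bp_id[c(i, j)], chrom, -1L)
        }
      }
    }
  }
  # --- RCT: junction pairs involving the same two protochromosomes with
  #     internal complementary splits. The two junctions arise on two
  #     chromosomes, but may sit on one chromosome in the final genome when
  #     a later fusion merged the translocation products.
  if (n >= 2L) {
    pair_key <- apply(cbind(bps$left_label, bps$right_label), 1L,
                      function(v) paste(sort(v), collapse = "\r"))
    for (key in unique(pair_key)) {
      idx <- which(pair_key == key & !used)
      if (length(idx) < 2L) next
      labs <- unique(strsplit(key, "\r", fixed = TRUE)[[1L]])
      if (length(labs) != 2L) next      # same-label junctions cannot be RCTs
      facing_of <- function(i, lab) {
        if (bps$left_label[i] == lab) bps$left_facing[i] else bps$right_facing[i]
      }
      internal <- vapply(idx, function(i) {
        !term(facing_of(i, labs[1L]), labs[1L]) && !term(facing_of(i, labs[2L]), labs[2L])
      }, TRUE)
      idx <- idx[internal]
      while (length(idx) >= 2L) {
        combos <- utils::combn(seq_along(idx), 2L)
        best <- NULL; best_cost <- Inf
        for (c_ in seq_len(ncol(combos))) {
          i <- idx[combos[1L, c_]]; j <- idx[combos[2L, c_]]
          cost <- abs(facing_of(i, labs[1L]) - facing_of(j, labs[1L])) +
            abs(facing_of(i, labs[2L]) - facing_of(j, labs[2L]))
          if (cost <= 2L * split_tol && cost < best_cost) { best <- c(i, j); best_cost <- cost }
        }
        if (is.null(best)) break
        used[best] <- TRUE
        add_event("RCT", labs[1L], labs[2L], bps$bp_id[best], bps$chromosome[best], 0L)
        idx <- idx[!idx %in% best]
      }
    }
  }
  # --- EEJ: single junction joining two protochromosome termini. The two
  #     termini usually belong to different protochromosomes, but can carry
  #     the same label when earlier translocations swapped the tails being
  #     joined; the junction is still a single end-to-end fusion.
  for (i in which(!used)) {
    if (term(bps$left_facing[i], bps$left_label[i]) &&
        term(bps$right_facing[i], bps$right_label[i])) {
      used[i] <- TRUE
      add_event("EEJ", bps$left_label[i], bps$right_label[i], bps$bp_id[i],
                bps$chromosome[i], -1L)
    }
  }
  # --- residue
  for (i in which(!used)) {
    add_event("complex", bps$left_label[i], bps$right_label[i], bps$bp_id[i],
              bps$chromosome[i], NA_integer_)
  }
  if (length(ev) == 0L) {
    return(data.frame(event_id = character(), type = character(),
                      proto_a = character(), proto_b = character(),
                      name = character(), delta_n = integer(),
                      bp_ids = character(), chromosomes = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out <- cbind(event_id = sprintf("%s.ev%02d", p$genome_id, seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fusion-event nomenclature
#'
#' Formats an event as `K/<a>_<b>/<T>`, nesting operands that are themselves
#' fusion products: `K/(<a>_<b>/<T>)_<c>/<T2>`. `parse_event_name` inverts
#' the grammar, so `parse_event_name(name_event(...))` round-trips.
#'
#' @param karyotype_id karyotype the event is defined on.
#' @param token_a,token_b operand tokens: a protochromosome label, or a
#'   parenthesized token of a previous event (as produced by the simulator's
#'   truth log or by `event_token`).
#' @param type `"RCT"`, `"EEJ"`, `"NCF"` or `"complex"`.
#' @return `name_event`: the nomenclature string.
#' @export
name_event <- function(karyotype_id, token_a, token_b, type) {
  sprintf("%s/%s_%s/%s", karyotype_id, token_a, token_b, type)
}

#' @rdname name_event
#' @param token_a,token_b operand tokens of the event being turned into a token.
#' @export
event_token <- function(token_a, token_b, type) {
  sprintf("(%s_%s/%s)", token_a, token_b, type)
}

#' @rdname name_event
#' @param name a nomenclature string.
#' @return `parse_event_name`: list with `karyotype_id`, `type`, and
#'   `operands` (each either a label string or a nested parsed event).
#' @export
parse_event_name <- function(name) {
  slash <- regexpr("/", name, fixed = TRUE)
  if (slash < 0L) stop("malformed event name: ", name)
  karyotype_id <- substr(name, 1L, slash - 1L)
  body <- substr(name, slash + 1L, nchar(name))
  parsed <- parse_event_body(body)
  parsed$karyotype_id <- karyotype_id
  parsed
}

# body grammar: OPERAND "_" OPERAND "/" TYPE ; OPERAND := label | "(" body ")"
parse_event_body <- function(body) {
  read_operand <- function(s) {
    if (substr(s, 1L, 1L) == "(") {
      depth <- 0L
      for (i in seq_len(nchar(s))) {
        ch <- substr(s, i, i)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") { depth <- depth - 1L; if (depth == 0L) break }
      }
      if (depth != 0L) stop("unbalanced parentheses in event name")
      list(value = parse_event_body(substr(s, 2L, i - 1L)), rest = substr(s, i + 1L, nchar(s)))
    } else {
      m <- regexpr("^[^_/()]+", s)
      if (m < 0L) stop("malformed operand in event name")
      len <- attr(m, "match.length")
      list(value = substr(s, 1L, len), rest = substr(s, len + 1L, nchar(s)))
    }
  }
  op1 <- read_operand(body)
  if (substr(op1$rest, 1L, 1L) != "_") stop("malformed event name body: ", body)
  op2 <- read_operand(substr(op1$rest, 2L, nchar(op1$rest)))
  if (substr(op2$rest, 1L, 1L) != "/") stop("malformed event name body: ", body)
  type <- substr(op2$rest, 2L, nchar(op2$rest))
  if (!type %in% c("RCT", "EEJ", "NCF", "complex")) stop("unknown event type: ", type)
  list(karyotype_id = NA_character_, type = type, operands = list(op1$value, op2$value))
}

# re-serialize a parsed event (used to test format . parse = identity)
format_parsed_event <- function(parsed) {
  tok <- function(op) {
    if (is.list(op)) paste0("(", body_of(op), ")") else op
  }
  body_of <- function(pe) {
    sprintf("%s_%s/%s", tok(pe$operands[[1L]]), tok(pe$operands[[2L]]), pe$type)
  }
  sprintf("%s/%s", parsed$karyotype_id, body_of(parsed))
}

#' Extract the gene window around a breakpoint
#'
#' Returns up to `flank` gene ids on each side of the junction, in
#' chromosome order (so 100 genes for an internal breakpoint with the
#' default flank). When a chromosome end intervenes the window is shorter
#' and flagged truncated.
#'
#' @param bp one-row breakpoint data.frame (from [detect_junctions]).
#' @param target [genome_order] the breakpoint lives in.
#' @param flank genes per side; must be positive.
#' @return character vector of gene ids with attribute `truncated`.
#' @export
extract_breakpoint_window <- function(bp, target, flank = 50L) {
  if (flank <= 0L) stop("empty window (flank must be a positive number of genes)")
  genes <- chrom_genes(target, bp$chromosome)
  jr <- bp$junction_rank
  ids <- genes$gene_id[genes$rank >= jr - flank & genes$rank < jr + flank]
  structure(ids, truncated = (jr < flank) || (jr + flank > nrow(genes)))
}

#' Is a fusion breakpoint present in another genome?
#'
#' A breakpoint is shared when a single synteny block between the
#' breakpoint's genome and `other` spans the junction with at least
#' `min_side_anchors` anchors on each 50-gene flank -- i.e. the other genome
#' is collinear across the junction, so it carries the same fusion. Two
#' fusions of the same protochromosomes at different junction positions are
#' not shared.
#'
#' @param bp one-row breakpoint data.frame.
#' @param blocks `synteny_blocks` with the breakpoint's genome as genome A
#'   and `other` as genome B.
#' @param flank,min_side_anchors see [spanning_block].
#' @return list with `status` (`"shared"`/`"absent"`) and the spanning-block
#'   evidence.
#' @export
breakpoint_shared <- function(bp, blocks, flank = 50L, min_side_anchors = 25L) {
  sp <- spanning_block(blocks, bp$chromosome, bp$junction_rank, flank, min_side_anchors)
  list(status = if (sp$spanning) "shared" else "absent",
       block_id = sp$block_id, n_left = sp$n_left, n_right = sp$n_right)
}

#' Root junction directionality with an outgroup
#'
#' For each junction: when the outgroup is collinear across the junction
#' (single spanning block), the arrangement is inherited -- verdict
#' `"ancestral"`. When no block spans but each flank individually has
#' single-block support of at least `min_side_anchors` anchors in the
#' outgroup (so the absence of spanning is evidence of a different
#' arrangement, not of missing data), the junction is `"derived"`.
#' Otherwise `"unresolved"`. Call once per candidate karyotype and compare.
#'
#' @param bps breakpoints of one genome/karyotype.
#' @param blocks_to_outgroup `synteny_blocks` with the breakpoints' genome
#'   as genome A and the outgroup as genome B.
#' @param flank,min_side_anchors see [spanning_block].
#' @return data.frame `bp_id`, `verdict`, `n_left`, `n_right`.
#' @export
orient_with_outgroup <- function(bps, blocks_to_outgroup, flank = 50L,
                                 min_side_anchors = 25L) {
  if (nrow(bps) == 0L) {
    return(data.frame(bp_id = character(), verdict = character(),
                      n_left = integer(), n_right = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(bps)), function(i) {
    bp <- bps[i, ]
    sp <- spanning_block(blocks_to_outgroup, bp$chromosome, bp$junction_rank,
                         flank, min_side_anchors)
    if (sp$spanning) {
      verdict <- "ancestral"
    } else {
      nl <- flank_support(blocks_to_outgroup, bp$chromosome,
                          bp$junction_rank - flank, bp$junction_rank)
      nr <- flank_support(blocks_to_outgroup, bp$chromosome,
                          bp$junction_rank, bp$junction_rank + flank)
      verdict <- if (nl >= min_side_anchors && nr >= min_side_anchors) "derived" else "unresolved"
    }
    data.frame(bp_id = bp$bp_id, verdict = verdict,
               n_left = sp$n_left, n_right = sp$n_right, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ancestral positions of breakpoints
#'
#' Each breakpoint contributes its two junction-facing ancestral
#' coordinates (one per context), the positions used when comparing fusion
#' breakpoints with CGB boundaries on the ancestral karyotype.
#'
#' @param bps breakpoints from [detect_junctions].
#' @return data.frame `chromosome` (protochromosome label), `anc_rank`,
#'   `bp_id`, `side`.
#' @export
breakpoint_anc_positions <- function(bps) {
  if (nrow(bps) == 0L) {
    return(data.frame(chromosome = character(), anc_rank = integer(),
                      bp_id = character(), side = character(),
                      stringsAsFactors = FALSE))
  }
  rbind(data.frame(chromosome = bps$left_label, anc_rank = bps$left_facing,
                   bp_id = bps$bp_id, side = "left", stringsAsFactors = FALSE),
        data.frame(chromosome = bps$right_label, anc_rank = bps$right_facing,
                   bp_id = bps$bp_id, side = "right", stringsAsFactors = FALSE))
}

#' Write / read a breakpoint table
#'
#' Tab-separated exchange format: `bp_id`, `genome`, `chromosome`,
#' `junction_rank`, `left_label`, `right_label`, semicolon-joined window
#' gene ids, `truncated`.
#'
#' @param bps breakpoints from [detect_junctions].
#' @param path file path.
#' @export
write_breakpoints <- function(bps, path) {
  tab <- data.frame(bp_id = bps$bp_id, genome = bps$genome_id,
                    chromosome = bps$chromosome, junction_rank = bps$junction_rank,
                    left_label = bps$left_label, right_label = bps$right_label,
                    window = vapply(seq_len(nrow(bps)), function(i) {
                      paste(c(bps$window_left[[i]], bps$window_right[[i]]), collapse = ";")
                    }, ""),
                    truncated = bps$truncated, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an event table
#' @param events events from [classify_events].
#' @param path file path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
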
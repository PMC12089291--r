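#' Build the genomes-by-breakpoints copy-number matrix
#'
#' Breakpoints from different genomes (or subgenomes) are clustered into
#' identity classes: two breakpoints are the same fusion when they involve
#' the same protochromosome pair and one's junction window is spanned by a
#' single synteny block that covers the other's junction in the other
#' genome. Sharing evidence in either direction links a pair (fusions do
#' not revert; gene loss only erodes windows), and identity classes are the
#' connected components of the link graph. The cell value is the number of
#' chromosomes of a genome carrying an instance of the class -- 2 for a
#' fusion duplicated by polyploidy.
#'
#' @param bp_tables named list (by genome/subgenome id) of breakpoint
#'   data.frames from [detect_junctions]; empty tables are allowed and keep
#'   their row in the matrix.
#' @param blocks named list of `synteny_blocks`, keyed `"A||B"` for genome A
#'   coordinates against genome B; every ordered pair present is used for
#'   linking.
#' @param flank,min_side_anchors collinearity-support criterion, see
#'   [spanning_block].
#' @return object of class `breakpoint_matrix`: list with `matrix` (rows =
#'   genomes, columns = breakpoint classes), `classes` (members and
#'   protochromosome pair per class) and `links`.
#' @export
build_breakpoint_matrix <- function(bp_tables, blocks, flank = 50L,
                                    min_side_anchors = 25L) {
  all_bps <- do.call(rbind, lapply(names(bp_tables), function(g) {
    b <- bp_tables[[g]]
    if (nrow(b) == 0L) return(NULL)
    data.frame(bp_id = b$bp_id, genome = g, chromosome = b$chromosome,
               junction_rank = b$junction_rank,
               pair_key = apply(cbind(b$left_label, b$right_label), 1L,
                                function(v) paste(sort(v), collapse = "_")),
               stringsAsFactors = FALSE)
  }))
  links <- list()
  if (!is.null(all_bps)) {
    for (key in names(blocks)) {
      gg <- strsplit(key, "||", fixed = TRUE)[[1L]]
      if (length(gg) != 2L) next
      ga <- gg[1L]; gb <- gg[2L]
      if (!ga %in% names(bp_tables) || !gb %in% names(bp_tables)) next
      ba <- bp_tables[[ga]]; sb <- blocks[[key]]
      for (i in seq_len(nrow(ba))) {
        sp <- spanning_block(sb, ba$chromosome[i], ba$junction_rank[i],
                             flank, min_side_anchors)
        if (!sp$spanning) next
        blk <- sb$blocks[sb$blocks$block_id == sp$block_id, ]
        cand <- all_bps[all_bps$genome == gb &
                          all_bps$chromosome == blk$chr_b &
                          all_bps$junction_rank > blk$b_start &
                          all_bps$junction_rank < blk$b_end &
                          all_bps$pair_key == all_bps$pair_key[all_bps$bp_id == ba$bp_id[i]][1L],
                        , drop = FALSE]
        for (j in seq_len(nrow(cand))) {
          links[[length(links) + 1L]] <- data.frame(from = ba$bp_id[i],
                                                    to = cand$bp_id[j],
                                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  links <- if (length(links) > 0L) unique(do.call(rbind, links)) else
    data.frame(from = character(), to = character())
  if (is.null(all_bps)) {
    m <- matrix(0L, nrow = length(bp_tables), ncol = 0L,
                dimnames = list(names(bp_tables), NULL))
    return(structure(list(matrix = m,
                          classes = data.frame(class_id = character(),
                                               pair_key = character(),
                                               members = character()),
                          links = links), class = "breakpoint_matrix"))
  }
  gr <- igraph::graph_from_data_frame(links, directed = FALSE,
                                      vertices = data.frame(name = all_bps$bp_id))
  comp <- igraph::components(gr)$membership
  all_bps$class <- comp[all_bps$bp_id]
  # deterministic class ids: order classes by their lexicographically first member
  first_member <- vapply(split(all_bps$bp_id, all_bps$class),
                         function(v) min(v), "")
  class_order <- names(first_member)[order(first_member)]
  class_ids <- stats::setNames(sprintf("F%03d", seq_along(class_order)), class_order)
  all_bps$class_id <- class_ids[as.character(all_bps$class)]
  m <- matrix(0L, nrow = length(bp_tables), ncol = length(class_ids),
              dimnames = list(names(bp_tables), unname(class_ids[class_order])))
  tab <- table(all_bps$genome, all_bps$class_id)
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  classes <- do.call(rbind, lapply(class_order, function(cl) {
    mem <- all_bps[all_bps$class == as.integer(cl), , drop = FALSE]
    data.frame(class_id = unname(class_ids[cl]), pair_key = mem$pair_key[1L],
               members = paste(sort(mem$bp_id), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  structure(list(matrix = m, classes = classes, links = links),
            class = "breakpoint_matrix")
}

#' @export
print.breakpoint_matrix <- function(x, ...) {
  cat(sprintf("breakpoint_matrix: %d genome(s) x %d breakpoint class(es)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Infer evolutionary relationships under a Dollo assumption
#'
#' Each breakpoint class, binarized at `presence_threshold`, is treated as a
#' derived character that arises once and never reverts, so its presence set
#' defines a clade. If the presence sets form a laminar family (pairwise
#' nested or disjoint) the nesting tree is returned, with polytomies where
#' resolution is lacking. Otherwise a maximal laminar subset is kept
#' (greedily by column support, ties to the more inclusive set, then
#' lexicographic) and the excluded columns are reported as conflicts --
#' never silently dropped.
#'
#' @param m a `breakpoint_matrix` or plain genomes-by-characters matrix.
#' @param presence_threshold minimum copy number that counts as presence.
#' @return object of class `clade_tree`: list with `tree` (an [ape] `phylo`,
#'   `NULL` for < 2 taxa), `edges` (character placements) and `conflicts`.
#' @export
infer_tree_dollo <- function(m, presence_threshold = 1L) {
  bm <- if (inherits(m, "breakpoint_matrix")) m$matrix else as.matrix(m)
  if (nrow(bm) == 0L) stop("empty breakpoint matrix")
  taxa <- rownames(bm)
  cols <- colnames(bm)
  if (is.null(cols)) cols <- sprintf("C%03d", seq_len(ncol(bm)))
  sets <- lapply(seq_len(ncol(bm)), function(j) sort(taxa[bm[, j] >= presence_threshold]))
  keep <- lengths(sets) > 0L
  sets <- sets[keep]; cols <- cols[keep]
  keys <- vapply(sets, paste, "", collapse = "|")
  uniq <- unique(keys)
  support <- vapply(uniq, function(k) sum(keys == k), 0L)
  size <- vapply(uniq, function(k) length(strsplit(k, "|", fixed = TRUE)[[1L]]), 0L)
  ord <- order(-support, -size, uniq)
  uniq <- uniq[ord]
  accepted <- list(); conflict_keys <- character(0)
  laminar_pair <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0L || i == length(a) || i == length(b)
  }
  for (k in uniq) {
    s <- strsplit(k, "|", fixed = TRUE)[[1L]]
    if (all(vapply(accepted, function(a) laminar_pair(a, s), TRUE))) {
      accepted[[length(accepted) + 1L]] <- s
    } else {
      conflict_keys <- c(conflict_keys, k)
    }
  }
  conflicts <- data.frame(column_id = cols[keys %in% conflict_keys],
                          members = keys[keys %in% conflict_keys],
                          stringsAsFactors = FALSE)
  # internal nodes: accepted sets with 2 <= size < n_taxa
  node_sets <- Filter(function(s) length(s) >= 2L && length(s) < length(taxa), accepted)
  node_sets <- node_sets[order(-lengths(node_sets))]
  parent_of <- function(s) {
    for (i in seq_along(node_sets)) {
      cand <- node_sets[[i]]
      if (length(cand) > length(s) && all(s %in% cand)) return(i)
    }
    0L   # root
  }
  # strict smallest parent: scan from smallest candidate upward
  smallest_parent <- function(s) {
    best <- 0L; best_size <- Inf
    for (i in seq_along(node_sets)) {
      cand <- node_sets[[i]]
      if (length(cand) > length(s) && all(s %in% cand) && length(cand) < best_size) {
        best <- i; best_size <- length(cand)
      }
    }
    best
  }
  children_nodes <- lapply(seq_along(node_sets), function(i) {
    which(vapply(seq_along(node_sets), function(j) {
      j != i && smallest_parent(node_sets[[j]]) == i
    }, TRUE))
  })
  root_nodes <- which(vapply(seq_along(node_sets), function(j) {
    smallest_parent(node_sets[[j]]) == 0L
  }, TRUE))
  leaf_parent <- vapply(taxa, function(tx) {
    best <- 0L; best_size <- Inf
    for (i in seq_along(node_sets)) {
      if (tx %in% node_sets[[i]] && length(node_sets[[i]]) < best_size) {
        best <- i; best_size <- length(node_sets[[i]])
      }
    }
    best
  }, 0L)
  node_str <- function(i) {
    parts <- c(taxa[leaf_parent == i],
               vapply(children_nodes[[i]], node_str, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  tree <- NULL
  if (length(taxa) >= 2L) {
    parts <- c(taxa[leaf_parent == 0L], vapply(root_nodes, node_str, ""))
    nwk <- if (length(parts) == 1L) paste0(parts, ";") else
      paste0("(", paste(parts, collapse = ","), ");")
    tree <- ape::read.tree(text = nwk)
  }
  set_key_of <- function(s) paste(s, collapse = "|")
  edges <- do.call(rbind, lapply(accepted, function(s) {
    k <- set_key_of(s)
    data.frame(members = k, n_taxa = length(s),
               n_columns = sum(keys == k),
               column_ids = paste(cols[keys == k], collapse = ";"),
               placement = if (length(s) == length(taxa)) "root"
                           else if (length(s) == 1L) "leaf" else "internal",
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(members = character(), n_taxa = integer(),
                                          n_columns = integer(), column_ids = character(),
                                          placement = character())
  structure(list(tree = tree, edges = edges, conflicts = conflicts),
            class = "clade_tree")
}

#' @export
print.clade_tree <- function(x, ...) {
  nwk <- if (is.null(x$tree)) "<fewer than 2 taxa>" else ape::write.tree(x$tree)
  cat("clade_tree:", nwk, "\n")
  cat(sprintf("  %d character placement(s), %d conflict(s)\n",
              nrow(x$edges), nrow(x$conflicts)))
  invisible(x)
}

#' Phase polyploid chromosomes into subgenomes
#'
#' Partitions the chromosomes of a painted polyploid into `k` subgenomes by
#' minimizing a score with three terms, mirroring complementarity of
#' collinear regions, structural consistency and gene retention levels:
#' (i) each subgenome should cover each protochromosome as close to once as
#' possible; (ii) painted gene totals should balance across subgenomes;
#' (iii) chromosomes within a subgenome should have homogeneous retention
#' (painted genes / ancestral span), since fractionation is subgenome
#' biased. The search is exhaustive when `k^C` is small (C = number of
#' chromosomes) and seeded multi-start hill climbing otherwise;
#' deterministic given `seed`.
#'
#' @param p [karyotype_painting] of the polyploid.
#' @param ak the [ancestral_karyotype] painted against.
#' @param k number of subgenomes (`k = 1` returns the identity partition).
#' @param seed integer seed for the stochastic search.
#' @param n_restarts hill-climbing restarts.
#' @param w_balance,w_retention term weights.
#' @return list with `assignment` (named integer, chromosome -> subgenome),
#'   `subgenomes` (list of chromosome id vectors), `sizes`, `score` and the
#'   per-chromosome `report`.
#' @export
phase_subgenomes <- function(p, ak, k, seed = 1L, n_restarts = 20L,
                             w_balance = 0.5, w_retention = 10) {
  stopifnot(k >= 1L)
  segs <- p$segments[p$segments$label != "NA", , drop = FALSE]
  chroms <- sort(unique(p$segments$chromosome))
  labels <- names(ak$protochromosomes)
  lens <- ak_lengths(ak)
  cov <- matrix(0, nrow = length(chroms), ncol = length(labels),
                dimnames = list(chroms, labels))
  painted <- stats::setNames(numeric(length(chroms)), chroms)
  anc_span <- stats::setNames(numeric(length(chroms)), chroms)
  for (i in seq_len(nrow(segs))) {
    len <- segs$end_rank[i] - segs$start_rank[i]
    cov[segs$chromosome[i], segs$label[i]] <-
      cov[segs$chromosome[i], segs$label[i]] + len / lens[[segs$label[i]]]
    painted[segs$chromosome[i]] <- painted[segs$chromosome[i]] + len
    anc_span[segs$chromosome[i]] <- anc_span[segs$chromosome[i]] +
      max(segs$anc_end[i] - segs$anc_start[i], 1L)
  }
  retention <- painted / pmax(anc_span, 1)
  C <- length(chroms)
  score_of <- function(assign) {
    comp <- 0; retn <- 0
    totals <- numeric(k)
    for (s in seq_len(k)) {
      idx <- which(assign == s)
      if (length(idx) == 0L) return(Inf)
      comp <- comp + sum(abs(colSums(cov[idx, , drop = FALSE]) - 1))
      totals[s] <- sum(painted[idx])
      retn <- retn + sum(abs(retention[idx] - mean(retention[idx])))
    }
    bal <- sum(abs(totals - mean(totals))) / max(mean(totals), 1)
    comp + w_balance * bal + w_retention * retn
  }
  if (k == 1L) {
    assign <- stats::setNames(rep(1L, C), chroms)
    best <- list(assign = assign, score = score_of(assign))
  } else if (k^C <= 2e5) {
    best <- list(assign = NULL, score = Inf)
    for (code in 0:(k^C - 1)) {
      assign <- integer(C)
      x <- code
      for (i in seq_len(C)) { assign[i] <- x %% k + 1L; x <- x %/% k }
      sc <- score_of(assign)
      if (sc < best$score) best <- list(assign = stats::setNames(assign, chroms), score = sc)
    }
  } else {
    best <- list(assign = NULL, score = Inf)
    with_seed(seed, {
      for (r in seq_len(n_restarts)) {
        assign <- sample(rep_len(seq_len(k), C))
        sc <- score_of(assign)
        repeat {
          improved <- FALSE
          for (i in seq_len(C)) for (s in seq_len(k)) {
            if (assign[i] == s) next
            cand <- assign; cand[i] <- s
            sc2 <- score_of(cand)
            if (sc2 < sc - 1e-12) { assign <- cand; sc <- sc2; improved <- TRUE }
          }
          for (i in seq_len(C - 1L)) for (j in seq(i + 1L, C)) {
            if (assign[i] == assign[j]) next
            cand <- assign; cand[c(i, j)] <- assign[c(j, i)]
            sc2 <- score_of(cand)
            if (sc2 < sc - 1e-12) { assign <- cand; sc <- sc2; improved <- TRUE }
          }
          if (!improved) break
        }
        if (sc < best$score) best <- list(assign = stats::setNames(assign, chroms), score = sc)
      }
    })
  }
  # canonical subgenome numbering: by first chromosome occurrence
  relabel <- stats::setNames(integer(k), seq_len(k))
  nxt <- 0L
  canon <- integer(C)
  for (i in seq_len(C)) {
    s <- as.character(best$assign[i])
    if (relabel[s] == 0L) { nxt <- nxt + 1L; relabel[s] <- nxt }
    canon[i] <- relabel[s]
  }
  assignment <- stats::setNames(canon, chroms)
  subgenomes <- lapply(seq_len(k), function(s) chroms[assignment == s])
  names(subgenomes) <- paste0("sub", seq_len(k))
  list(assignment = assignment, subgenomes = subgenomes,
       sizes = lengths(subgenomes), score = best$score,
       report = data.frame(chromosome = chroms, subgenome = assignment,
                           painted = as.numeric(painted),
                           retention = as.numeric(retention),
                           stringsAsFactors = FALSE))
}

#' Assign allopolyploid subgenome parentage from shared fusions
#'
#' An event of the polyploid is shared with a candidate parent when every
#' one of its breakpoints is collinearity-supported in that candidate
#' ([breakpoint_shared]); an event is *unique* to a candidate when it is
#' shared with exactly one. A candidate conflicts with a subgenome for each
#' of its own derived breakpoints that is not shared into that subgenome's
#' chromosomes (a parent's fusion must be inherited). Each subgenome is
#' assigned the candidate with the most unique shared events, ties broken
#' by fewest conflicts then most shared events; subgenomes sharing nothing
#' with any candidate are reported unassigned with a warning.
#'
#' @param subgenomes named list: subgenome id -> polyploid chromosome ids.
#' @param poly_events,poly_bps classified events and breakpoints of the
#'   polyploid against the ancestral karyotype.
#' @param blocks_to_parents named list: candidate id -> `synteny_blocks`
#'   (polyploid as genome A, candidate as genome B).
#' @param parent_bps optional named list of candidate breakpoint tables,
#'   used for the conflict term.
#' @param blocks_from_parents optional named list: candidate id ->
#'   `synteny_blocks` with the candidate as genome A and the polyploid as
#'   genome B (required for the conflict term).
#' @param flank,min_side_anchors see [spanning_block].
#' @return list with `table` (per subgenome x candidate counts) and
#'   `assignment`.
#' @export
assign_parentage <- function(subgenomes, poly_events, poly_bps, blocks_to_parents,
                             parent_bps = NULL, blocks_from_parents = NULL,
                             flank = 50L, min_side_anchors = 25L) {
  candidates <- names(blocks_to_parents)
  bp_chrom <- stats::setNames(poly_bps$chromosome, poly_bps$bp_id)
  ev_bps <- strsplit(poly_events$bp_ids, ";", fixed = TRUE)
  ev_chroms <- lapply(ev_bps, function(ids) unique(unname(bp_chrom[ids])))
  # shared matrix: events x candidates
  shared <- matrix(FALSE, nrow = nrow(poly_events), ncol = length(candidates),
                   dimnames = list(poly_events$event_id, candidates))
  for (cand in candidates) {
    sb <- blocks_to_parents[[cand]]
    bp_shared <- vapply(seq_len(nrow(poly_bps)), function(i) {
      breakpoint_shared(poly_bps[i, ], sb, flank, min_side_anchors)$status == "shared"
    }, TRUE)
    names(bp_shared) <- poly_bps$bp_id
    shared[, cand] <- vapply(ev_bps, function(ids) all(bp_shared[ids]), TRUE)
  }
  n_unique_cand <- rowSums(shared)
  rows <- list(); assign_rows <- list()
  for (s in names(subgenomes)) {
    in_s <- vapply(ev_chroms, function(ch) all(ch %in% subgenomes[[s]]), TRUE)
    tab <- do.call(rbind, lapply(candidates, function(cand) {
      n_shared <- sum(shared[in_s, cand])
      n_unique <- sum(shared[in_s, cand] & n_unique_cand[in_s] == 1L)
      n_conflict <- NA_integer_
      if (!is.null(parent_bps) && !is.null(blocks_from_parents) &&
          cand %in% names(parent_bps) && cand %in% names(blocks_from_parents)) {
        pb <- parent_bps[[cand]]
        n_conflict <- 0L
        for (i in seq_len(nrow(pb))) {
          sp <- spanning_block(blocks_from_parents[[cand]], pb$chromosome[i],
                               pb$junction_rank[i], flank, min_side_anchors,
                               restrict_b = subgenomes[[s]])
          if (!sp$spanning) n_conflict <- n_conflict + 1L
        }
      }
      data.frame(subgenome = s, candidate = cand, n_shared = n_shared,
                 n_unique = n_unique, n_conflicts = n_conflict,
                 stringsAsFactors = FALSE)
    }))
    rows[[s]] <- tab
    conf <- ifelse(is.na(tab$n_conflicts), 0L, tab$n_conflicts)
    ord <- order(-tab$n_unique, conf, -tab$n_shared, tab$candidate)
    top <- tab[ord[1L], ]
    if (top$n_shared == 0L && top$n_unique == 0L) {
      warning("subgenome ", s, " shares no fusion event with any candidate parent")
      assign_rows[[s]] <- data.frame(subgenome = s, parent = NA_character_,
                                     stringsAsFactors = FALSE)
    } else {
      assign_rows[[s]] <- data.frame(subgenome = s, parent = top$candidate,
                                     stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, unname(rows)),
       assignment = do.call(rbind, unname(assign_rows)))
}
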
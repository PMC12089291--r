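# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# small genome_order from per-chromosome gene counts
toy_genome <- function(id, chrom_sizes, families = NULL) {
  rows <- lapply(seq_along(chrom_sizes), function(i) {
    n <- chrom_sizes[i]
    data.frame(gene_id = sprintf("%s.c%d.g%03d", id, i, seq_len(n)),
               chromosome = sprintf("c%d", i),
               start = (seq_len(n) - 1L) * 1000L + 1L,
               end = (seq_len(n) - 1L) * 1000L + 601L,
               strand = "+", stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  if (!is.null(families)) genes$family <- families
  genome_order(id, genes)
}

# anchors data.frame from bare rank vectors (single chromosome pair)
toy_anchors <- function(rank_a, rank_b, chr_a = "c1", chr_b = "d1") {
  n <- length(rank_a)
  data.frame(chr_a = rep_len(chr_a, n), rank_a = as.integer(rank_a),
             chr_b = rep_len(chr_b, n), rank_b = as.integer(rank_b),
             gene_a = if (n) paste0("a", rank_a) else character(0),
             gene_b = if (n) paste0("b", rank_b) else character(0),
             family = rep_len(NA_character_, n), stringsAsFactors = FALSE)
}

# clean dot-plot instance: a permutation of monotone bands, so ranks are
# distinct on both axes (as real per-chromosome anchor sets are)
band_permutation_instance <- function(n) {
  ra <- 0:(n - 1L)
  cuts <- sort(sample(seq_len(n - 1L), sample(2:4, 1L)))
  seg <- split(ra, findInterval(ra, cuts))
  k <- length(seg)
  ord <- sample(k)                           # ord[j] = segment in the j-th b-band
  bstart <- integer(k)
  bstart[ord] <- cumsum(c(0L, lengths(seg)[ord]))[seq_len(k)]
  rb <- integer(n)
  for (i in seq_len(k)) {
    vals <- bstart[i]:(bstart[i] + length(seg[[i]]) - 1L)
    if (stats::runif(1) < 0.5) vals <- rev(vals)
    rb[seg[[i]] + 1L] <- vals
  }
  list(ra = ra, rb = rb)
}

# Independent brute-force oracle for the chaining objective: partition the
# rank_a-sorted anchor sequence into contiguous strictly-monotone runs
# (gap-bounded), maximizing anchors covered by runs of >= min_anchors, then
# minimizing the number of runs. Memoized recursion over suffixes, checking
# monotonicity by direct scan (no shared code with the implementation).
oracle_chain_value <- function(ra, rb, min_anchors, max_gap) {
  n <- length(ra)
  memo <- vector("list", n + 1L)
  run_ok <- function(s, e) {
    if (e == s) return(TRUE)
    da <- diff(ra[s:e]); db <- diff(rb[s:e])
    inc <- all(da > 0) && all(db > 0) && all(da <= max_gap) && all(db <= max_gap)
    dec <- all(da > 0) && all(db < 0) && all(da <= max_gap) && all(-db <= max_gap)
    inc || dec
  }
  best <- function(i) {
    if (i > n) return(c(covered = 0, blocks = 0))
    if (!is.null(memo[[i]])) return(memo[[i]])
    res <- best(i + 1L)                     # skip anchor i
    j <- i + min_anchors - 1L
    while (j <= n && run_ok(i, j)) {
      rest <- best(j + 1L)
      cand <- c(covered = (j - i + 1) + rest[["covered"]],
                blocks = 1 + rest[["blocks"]])
      if (cand[["covered"]] > res[["covered"]] ||
          (cand[["covered"]] == res[["covered"]] && cand[["blocks"]] < res[["blocks"]])) {
        res <- cand
      }
      j <- j + 1L
    }
    memo[[i]] <<- res
    res
  }
  best(1L)
}

# random anchor instance: a few monotone runs with noise anchors
random_anchor_instance <- function(n) {
  ra <- sort(sample(0:(3L * n), n))
  rb <- integer(n)
  i <- 1L
  val <- sample(0:20, 1L)
  while (i <= n) {
    len <- min(sample(2:8, 1L), n - i + 1L)
    dirn <- sample(c(1L, -1L), 1L)
    steps <- sample(1:4, len, replace = TRUE)
    rb[i:(i + len - 1L)] <- val + dirn * cumsum(steps)
    val <- rb[i + len - 1L] + sample(-10:10, 1L)
    i <- i + len
  }
  rb <- rb - min(rb)
  list(ra = as.integer(ra), rb = as.integer(rb))
}

# check every emitted block against the synteny-block invariants
expect_valid_blocks <- function(sb, min_anchors, max_gap) {
  an <- sb$anchors
  for (bid in sb$blocks$block_id) {
    b <- sb$blocks[sb$blocks$block_id == bid, ]
    m <- an[!is.na(an$block_id) & an$block_id == bid, , drop = FALSE]
    m <- m[order(m$rank_a), , drop = FALSE]
    expect_gte(nrow(m), min_anchors)
    expect_identical(nrow(m), b$n_anchors)
    da <- diff(m$rank_a); db <- diff(m$rank_b)
    expect_true(all(da > 0))
    expect_true(all(da <= max_gap) && all(abs(db) <= max_gap))
    if (b$orientation == "+") expect_true(all(db > 0)) else expect_true(all(db < 0))
  }
  expect_lte(max(table(an$block_id[!is.na(an$block_id)]), 0), nrow(an))
}

# tiny simulated scenario helpers -------------------------------------------

# one rearranged lineage plus an unrearranged reference, no loss by default
two_lineage_scenario <- function(events, n_chrom = 8L, genes = 150L,
                                 loss_ref = 0, loss_tgt = 0) {
  sim_scenario(n_chrom, genes, lineages = list(
    sim_lineage("REF", loss_rate = loss_ref),
    sim_lineage("TGT", events = events, loss_rate = loss_tgt)))
}

# detected junction ranks mapped back to ground truth: expected rank = number
# of surviving genes before the recorded junction adjacency
expected_junction_ranks <- function(res, lineage) {
  node <- res$nodes[[lineage]]
  emitted <- res$genomes[[lineage]]
  tr <- res$truth[res$truth$lineage == lineage, , drop = FALSE]
  adj <- unlist(strsplit(tr$adjacencies, ";", fixed = TRUE))
  adj <- adj[nzchar(adj)]
  out <- list()
  for (a in adj) {
    fams <- strsplit(a, "|", fixed = TRUE)[[1L]]
    for (nm in names(node$chroms)) {
      fam_seq <- node$chroms[[nm]]$family
      i <- match(fams[2L], fam_seq)
      if (!is.na(i) && i > 1L && fam_seq[i - 1L] == fams[1L]) {
        surv <- emitted$genes$family[emitted$genes$chromosome == nm]
        out[[a]] <- data.frame(chromosome = nm,
                               rank = sum(fam_seq[seq_len(i - 1L)] %in% surv),
                               adjacency = a, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
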
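#' Karyotype evolution simulator
#'
#' The simulator evolves a defined ancestral karyotype through recorded
#' rearrangement events (RCT, EEJ, NCF, inversion), per-lineage gene loss
#' (fractionation) and allopolyploid merging, and can emit every input
#' format the analysis pipeline consumes together with ground-truth event
#' logs and paintings. Gene identifiers carry ancestral-slot family labels,
#' so homology tables are derivable exactly.
#'
#' @name simulator
NULL

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a simulated rearrangement event
#'
#' @param type `"RCT"`, `"EEJ"`, `"NCF"` or `"INV"`.
#' @param chrom_a,chrom_b chromosome ids valid at application time (fusion
#'   products are named by joining the parent ids with `+`). `INV` uses only
#'   `chrom_a`; for `NCF`, `chrom_b` is the donor inserted into `chrom_a`.
#' @param pos_a,pos_b 0-based cut positions (genes kept before the cut);
#'   `NA` positions are drawn uniformly at simulation time, at least 60
#'   genes from chromosome ends and 120 genes from existing junctions so
#'   that full 50-gene windows exist.
#' @param end_a,end_b which ends an EEJ joins (`"tail"`/`"head"`).
#' @param reverse_donor should an NCF donor be inserted inverted?
#' @return a `sim_event` specification list.
#' @export
sim_event <- function(type, chrom_a, chrom_b = NA_character_, pos_a = NA_integer_,
                      pos_b = NA_integer_, end_a = "tail", end_b = "head",
                      reverse_donor = FALSE) {
  stopifnot(type %in% c("RCT", "EEJ", "NCF", "INV"))
  list(type = type, chrom_a = chrom_a, chrom_b = chrom_b, pos_a = pos_a,
       pos_b = pos_b, end_a = end_a, end_b = end_b, reverse_donor = reverse_donor)
}

#' Specify a lineage of an evolution scenario
#'
#' @param id lineage name.
#' @param events list of [sim_event]s applied in order.
#' @param parent id of the parent lineage (`NULL` = the ancestor). Parents
#'   must be defined before children.
#' @param loss_rate per-gene fractionation probability applied to the
#'   emitted genome (after all rearrangements).
#' @param emit should a genome be emitted for this lineage? Internal nodes
#'   of a scenario set `emit = FALSE`.
#' @return a lineage specification list.
#' @export
sim_lineage <- function(id, events = list(), parent = NULL, loss_rate = 0,
                        emit = TRUE) {
  list(id = id, events = events, parent = parent, loss_rate = loss_rate, emit = emit)
}

#' Specify an evolution scenario
#'
#' @param n_chromosomes,genes_per_chromosome ancestor dimensions.
#' @param lineages list of [sim_lineage]s.
#' @param polyploids list of lists `(id, parents, suffixes, loss_rates)`
#'   describing allopolyploid merges of lineage genomes.
#' @param karyotype_id name of the ancestral karyotype.
#' @return an `evolution_scenario` list.
#' @export
sim_scenario <- function(n_chromosomes = 8L, genes_per_chromosome = 400L,
                         lineages = list(), polyploids = list(),
                         karyotype_id = "AK") {
  structure(list(n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 lineages = lineages, polyploids = polyploids,
                 karyotype_id = karyotype_id),
            class = "evolution_scenario")
}

# ---- internal simulated-genome representation ------------------------------
# list(chroms = named list of data.frame(family, strand),
#      tokens = named chr -> nomenclature token,
#      junctions = named chr -> 0-based cut positions)

sim_ancestor <- function(n_chromosomes, genes_per_chromosome) {
  chroms <- list(); tokens <- character(0); junctions <- list()
  for (i in seq_len(n_chromosomes)) {
    nm <- paste0("chr", i)
    chroms[[nm]] <- data.frame(
      family = sprintf("P%d.%04d", i, seq_len(genes_per_chromosome)),
      strand = "+", stringsAsFactors = FALSE)
    tokens[nm] <- as.character(i)
    junctions[[nm]] <- integer(0)
  }
  list(chroms = chroms, tokens = tokens, junctions = junctions)
}

reverse_piece <- function(df) {
  df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  df$strand <- ifelse(df$strand == "+", "-", "+")
  rownames(df) <- NULL
  df
}

draw_cut <- function(len, taken, min_end = 60L, min_sep = 120L) {
  # spacing targets assume full-size chromosomes; scale down proportionally
  # on short ones so desk-size test genomes stay simulable
  min_end <- min(min_end, max(15L, len %/% 5L))
  min_sep <- min(min_sep, max(20L, len %/% 4L))
  repeat {
    cand <- seq(min_end, len - min_end)
    for (t in taken) cand <- cand[abs(cand - t) >= min_sep]
    if (length(cand) > 0L) break
    # crowded chromosome: relax the junction separation, then the end
    # margin, before giving up
    if (min_sep > 25L) { min_sep <- min_sep %/% 2L; next }
    if (min_end > 20L) { min_end <- min_end %/% 2L; next }
    stop("no admissible junction position on a chromosome of ", len, " genes")
  }
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

sim_apply_event <- function(g, ev, karyotype_id) {
  get_chrom <- function(nm) {
    if (!nm %in% names(g$chroms)) stop("event references unknown chromosome '", nm,
                                       "'; present: ", paste(names(g$chroms), collapse = ", "))
    g$chroms[[nm]]
  }
  record <- NULL
  if (ev$type == "EEJ") {
    A <- get_chrom(ev$chrom_a); B <- get_chrom(ev$chrom_b)
    ja <- g$junctions[[ev$chrom_a]]; jb <- g$junctions[[ev$chrom_b]]
    if (ev$end_a == "head") { A <- reverse_piece(A); ja <- nrow(A) - ja }
    if (ev$end_b == "tail") { B <- reverse_piece(B); jb <- nrow(B) - jb }
    new_nm <- paste0(ev$chrom_a, "+", ev$chrom_b)
    cut <- nrow(A)
    newc <- rbind(A, B); rownames(newc) <- NULL
    tok <- event_token(g$tokens[[ev$chrom_a]], g$tokens[[ev$chrom_b]], "EEJ")
    name <- name_event(karyotype_id, g$tokens[[ev$chrom_a]], g$tokens[[ev$chrom_b]], "EEJ")
    g$chroms[[ev$chrom_a]] <- NULL; g$chroms[[ev$chrom_b]] <- NULL
    g$tokens <- g$tokens[setdiff(names(g$tokens), c(ev$chrom_a, ev$chrom_b))]
    g$junctions[[ev$chrom_a]] <- NULL; g$junctions[[ev$chrom_b]] <- NULL
    g$chroms[[new_nm]] <- newc
    g$tokens[new_nm] <- tok
    g$junctions[[new_nm]] <- sort(c(ja, cut, cut + jb))
    record <- list(name = name, chroms = new_nm, cuts = cut,
                   adjacencies = paste(newc$family[cut], newc$family[cut + 1L], sep = "|"))
  } else if (ev$type == "RCT") {
    A <- get_chrom(ev$chrom_a); B <- get_chrom(ev$chrom_b)
    pa <- ev$pos_a; pb <- ev$pos_b
    if (is.na(pa)) pa <- draw_cut(nrow(A), g$junctions[[ev$chrom_a]])
    if (is.na(pb)) pb <- draw_cut(nrow(B), g$junctions[[ev$chrom_b]])
    newA <- rbind(A[seq_len(pa), , drop = FALSE], B[seq(pb + 1L, nrow(B)), , drop = FALSE])
    newB <- rbind(B[seq_len(pb), , drop = FALSE], A[seq(pa + 1L, nrow(A)), , drop = FALSE])
    rownames(newA) <- rownames(newB) <- NULL
    ja <- g$junctions[[ev$chrom_a]]; jb <- g$junctions[[ev$chrom_b]]
    newA_j <- sort(c(ja[ja < pa], pa, pa + (jb[jb > pb] - pb)))
    newB_j <- sort(c(jb[jb < pb], pb, pb + (ja[ja > pa] - pa)))
    tok <- event_token(g$tokens[[ev$chrom_a]], g$tokens[[ev$chrom_b]], "RCT")
    name <- name_event(karyotype_id, g$tokens[[ev$chrom_a]], g$tokens[[ev$chrom_b]], "RCT")
    g$chroms[[ev$chrom_a]] <- newA; g$chroms[[ev$chrom_b]] <- newB
    g$tokens[ev$chrom_a] <- tok; g$tokens[ev$chrom_b] <- tok
    g$junctions[[ev$chrom_a]] <- newA_j; g$junctions[[ev$chrom_b]] <- newB_j
    record <- list(name = name, chroms = paste(ev$chrom_a, ev$chrom_b, sep = ";"),
                   cuts = paste(pa, pb, sep = ";"),
                   adjacencies = paste(
                     paste(newA$family[pa], newA$family[pa + 1L], sep = "|"),
                     paste(newB$family[pb], newB$family[pb + 1L], sep = "|"), sep = ";"))
  } else if (ev$type == "NCF") {
    R <- get_chrom(ev$chrom_a); D <- get_chrom(ev$chrom_b)
    pos <- ev$pos_a
    if (is.na(pos)) pos <- draw_cut(nrow(R), g$junctions[[ev$chrom_a]])
    jd <- g$junctions[[ev$chrom_b]]
    if (ev$reverse_donor) { D <- reverse_piece(D); jd <- nrow(D) - jd }
    newc <- rbind(R[seq_len(pos), , drop = FALSE], D,
                  R[seq(pos + 1L, nrow(R)), , drop = FALSE])
    rownames(newc) <- NULL
    jr <- g$junctions[[ev$chrom_a]]
    new_j <- sort(c(jr[jr < pos], pos, pos + jd, pos + nrow(D),
                    nrow(D) + jr[jr > pos]))
    tok <- event_token(g$tokens[[ev$chrom_a]], g$tokens[[ev$chrom_b]], "NCF")
    name <- name_event(karyotype_id, g$tokens[[ev$chrom_a]], g$tokens[[ev$chrom_b]], "NCF")
    nd <- nrow(D)
    g$chroms[[ev$chrom_a]] <- newc
    g$chroms[[ev$chrom_b]] <- NULL
    g$tokens[ev$chrom_a] <- tok
    g$tokens <- g$tokens[setdiff(names(g$tokens), ev$chrom_b)]
    g$junctions[[ev$chrom_a]] <- new_j
    g$junctions[[ev$chrom_b]] <- NULL
    record <- list(name = name, chroms = ev$chrom_a, cuts = paste(pos, pos + nd, sep = ";"),
                   adjacencies = paste(
                     paste(newc$family[pos], newc$family[pos + 1L], sep = "|"),
                     paste(newc$family[pos + nd], newc$family[pos + nd + 1L], sep = "|"),
                     sep = ";"))
  } else if (ev$type == "INV") {
    A <- get_chrom(ev$chrom_a)
    s <- ev$pos_a; e <- ev$pos_b
    if (is.na(s)) s <- draw_cut(nrow(A), g$junctions[[ev$chrom_a]])
    if (is.na(e)) e <- min(nrow(A) - 10L, s + max(50L, 100L))
    stopifnot(s < e)
    seg <- reverse_piece(A[seq(s + 1L, e), , drop = FALSE])
    newc <- rbind(A[seq_len(s), , drop = FALSE], seg,
                  if (e < nrow(A)) A[seq(e + 1L, nrow(A)), , drop = FALSE])
    rownames(newc) <- NULL
    ja <- g$junctions[[ev$chrom_a]]
    inside <- ja > s & ja < e
    ja[inside] <- s + e - ja[inside]
    g$chroms[[ev$chrom_a]] <- newc
    g$junctions[[ev$chrom_a]] <- sort(ja)
    record <- list(name = name_event(karyotype_id, g$tokens[[ev$chrom_a]],
                                     g$tokens[[ev$chrom_a]], "complex"),
                   chroms = ev$chrom_a, cuts = paste(s, e, sep = ";"), adjacencies = "")
    record$name <- sprintf("%s/INV(%s:%d-%d)", karyotype_id, ev$chrom_a, s, e)
  }
  list(genome = g, record = record)
}

sim_apply_loss <- function(g, rate) {
  if (rate >= 1) stop("degenerate scenario: all genes lost")
  if (rate <= 0) return(g)
  for (nm in names(g$chroms)) {
    keep <- stats::runif(nrow(g$chroms[[nm]])) >= rate
    if (!any(keep)) stop("degenerate scenario: all genes lost on chromosome ", nm)
    g$chroms[[nm]] <- g$chroms[[nm]][keep, , drop = FALSE]
    rownames(g$chroms[[nm]]) <- NULL
  }
  g$junctions <- NULL   # junction gene indices no longer meaningful after loss
  g
}

# convert an internal sim genome to a genome_order; base-pair coordinates are
# synthesized as rank*1000 spans (formats need them; analysis ignores them)
sim_to_genome_order <- function(g, genome_id, id_prefix = genome_id,
                                chrom_suffix = "") {
  rows <- lapply(names(g$chroms), function(nm) {
    df <- g$chroms[[nm]]
    n <- nrow(df)
    data.frame(gene_id = paste(id_prefix, df$family, sep = "."),
               chromosome = paste0(nm, chrom_suffix),
               start = (seq_len(n) - 1L) * 1000L + 1L,
               end = (seq_len(n) - 1L) * 1000L + 601L,
               strand = df$strand, family = df$family, stringsAsFactors = FALSE)
  })
  genome_order(genome_id, do.call(rbind, rows))
}

#' Simulate an evolution scenario
#'
#' Applies each lineage's recorded events to its parent's genome, then
#' fractionation on emitted genomes, then allopolyploid merges. With a fixed
#' seed the outputs (and files written by [emit_datasets]) are
#' byte-identical across runs.
#'
#' @param scenario an [sim_scenario].
#' @param seed integer seed controlling drawn junction positions and gene
#'   loss.
#' @return object of class `sim_result`: list with `genomes` (named list of
#'   [genome_order]), `truth` (event log data.frame with nomenclature names,
#'   cut positions, junction gene adjacencies and per-lineage chromosome
#'   counts), `scenario`, `seed`, and internal per-genome structures used by
#'   [true_painting].
#' @export
simulate_scenario <- function(scenario, seed = 1L) {
  with_seed(seed, {
    anc <- sim_ancestor(scenario$n_chromosomes, scenario$genes_per_chromosome)
    nodes <- list(); truth <- list(); emitted <- list(); genomes <- list()
    for (lin in scenario$lineages) {
      g <- if (is.null(lin$parent)) anc else {
        if (!lin$parent %in% names(nodes)) stop("lineage '", lin$id,
                                                "' defined before its parent '", lin$parent, "'")
        nodes[[lin$parent]]
      }
      k <- 0L
      for (ev in lin$events) {
        k <- k + 1L
        res <- sim_apply_event(g, ev, scenario$karyotype_id)
        g <- res$genome
        truth[[length(truth) + 1L]] <- data.frame(
          lineage = lin$id, event_no = k, type = ev$type, name = res$record$name,
          chromosomes = res$record$chroms, cuts = as.character(res$record$cuts),
          adjacencies = res$record$adjacencies,
          n_after = length(g$chroms), stringsAsFactors = FALSE)
      }
      nodes[[lin$id]] <- g
      if (isTRUE(lin$emit)) {
        gl <- sim_apply_loss(g, lin$loss_rate)
        emitted[[lin$id]] <- gl
        genomes[[lin$id]] <- sim_to_genome_order(gl, lin$id)
      }
    }
    for (pp in scenario$polyploids) {
      sub <- list()
      for (i in seq_along(pp$parents)) {
        pid <- pp$parents[[i]]
        if (!pid %in% names(nodes)) stop("polyploid parent '", pid, "' unknown")
        rate <- if (!is.null(pp$loss_rates)) pp$loss_rates[[i]] else 0
        gl <- sim_apply_loss(nodes[[pid]], rate)
        sub[[pp$suffixes[[i]]]] <- gl
      }
      poly_chroms <- list()
      for (suf in names(sub)) {
        for (nm in names(sub[[suf]]$chroms)) {
          poly_chroms[[paste0(nm, suf)]] <- sub[[suf]]$chroms[[nm]]
        }
      }
      pg <- list(chroms = poly_chroms)
      emitted[[pp$id]] <- pg
      rows <- lapply(names(sub), function(suf) {
        go <- sim_to_genome_order(sub[[suf]], pp$id,
                                  id_prefix = paste(pp$id, suf, sep = "."),
                                  chrom_suffix = suf)
        go$genes
      })
      genomes[[pp$id]] <- genome_order(pp$id, do.call(rbind, rows))
      attr(genomes[[pp$id]], "subgenomes") <-
        stats::setNames(lapply(names(sub), function(suf) {
          paste0(names(sub[[suf]]$chroms), suf)
        }), names(sub))
    }
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(lineage = character(), event_no = integer(), type = character(),
                 name = character(), chromosomes = character(), cuts = character(),
                 adjacencies = character(), n_after = integer(),
                 stringsAsFactors = FALSE)
    structure(list(genomes = genomes, truth = truth, scenario = scenario,
                   seed = seed, nodes = nodes, emitted = emitted),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d genome(s) [%s], %d recorded event(s), seed %s\n",
              length(x$genomes), paste(names(x$genomes), collapse = ", "),
              nrow(x$truth), x$seed))
  invisible(x)
}

#' Simulate a single lineage of a scenario
#'
#' Convenience wrapper: runs [simulate_scenario] and extracts one lineage's
#' genome together with its ground-truth event log (events on the path from
#' the ancestor, i.e. including inherited parental events).
#'
#' @param scenario an [sim_scenario].
#' @param lineage lineage id.
#' @param seed passed to [simulate_scenario].
#' @return list with `genome` and `events`.
#' @export
simulate_lineage <- function(scenario, lineage, seed = 1L) {
  res <- simulate_scenario(scenario, seed)
  if (!lineage %in% names(res$genomes)) stop("no emitted genome for lineage '", lineage, "'")
  path <- lineage
  lin_by_id <- stats::setNames(scenario$lineages,
                               vapply(scenario$lineages, `[[`, "", "id"))
  cur <- lin_by_id[[lineage]]
  while (!is.null(cur$parent)) { path <- c(cur$parent, path); cur <- lin_by_id[[cur$parent]] }
  list(genome = res$genomes[[lineage]],
       events = res$truth[res$truth$lineage %in% path, , drop = FALSE])
}

#' Merge parent genomes into an allopolyploid
#'
#' Chromosome ids get per-subgenome suffixes, gene ids are prefixed to stay
#' unique, `family` labels are preserved so homology remains derivable, and
#' the haploid number is the sum of the parents'.
#'
#' @param parents list of [genome_order]s.
#' @param suffixes one suffix per parent (e.g. `c("A", "B")`).
#' @param genome_id id of the merged genome.
#' @return a [genome_order] with a `subgenomes` attribute mapping suffix ->
#'   chromosome ids.
#' @export
make_allopolyploid <- function(parents, suffixes, genome_id = "polyploid") {
  stopifnot(length(parents) >= 2L, length(parents) == length(suffixes))
  rows <- lapply(seq_along(parents), function(i) {
    gg <- parents[[i]]$genes
    gg$chromosome <- paste0(gg$chromosome, suffixes[[i]])
    gg$gene_id <- paste(suffixes[[i]], gg$gene_id, sep = ".")
    gg$rank <- NULL
    gg
  })
  out <- genome_order(genome_id, do.call(rbind, rows))
  attr(out, "subgenomes") <- stats::setNames(lapply(seq_along(parents), function(i) {
    paste0(parents[[i]]$chrom_order, suffixes[[i]])
  }), suffixes)
  out
}

#' Derive homology pairs between two simulated genomes
#'
#' All gene pairs sharing a family label. For self comparisons set
#' `drop_self = TRUE` to keep only homeolog pairs (distinct genes).
#'
#' @param gx,gy [genome_order]s whose gene tables carry `family`.
#' @param drop_self drop pairs of a gene with itself.
#' @return data.frame `gene_a`, `gene_b`, `family`.
#' @export
homology_pairs <- function(gx, gy, drop_self = FALSE) {
  fx <- gx$genes[!is.na(gx$genes$family), c("gene_id", "family")]
  fy <- gy$genes[!is.na(gy$genes$family), c("gene_id", "family")]
  m <- merge(fx, fy, by = "family", suffixes = c("_a", "_b"))
  m <- m[order(m$gene_id_a, m$gene_id_b), , drop = FALSE]
  if (drop_self) m <- m[m$gene_id_a != m$gene_id_b, , drop = FALSE]
  data.frame(gene_a = m$gene_id_a, gene_b = m$gene_id_b, family = m$family,
             stringsAsFactors = FALSE)
}

#' Ground-truth painting of a simulated genome
#'
#' Segments each emitted chromosome by the ancestor chromosome of each
#' gene's family label -- the painting the pipeline should recover.
#'
#' @param res a `sim_result`.
#' @param genome_id emitted genome id.
#' @return a [karyotype_painting].
#' @export
true_painting <- function(res, genome_id) {
  g <- res$emitted[[genome_id]]
  if (is.null(g)) stop("no emitted genome '", genome_id, "'")
  go <- res$genomes[[genome_id]]
  segs <- list()
  for (nm in go$chrom_order) {
    genes <- chrom_genes(go, nm)
    lab <- sub("^P(\\d+)\\..*$", "\\1", genes$family)
    slot <- as.integer(sub("^P\\d+\\.(\\d+)$", "\\1", genes$family))
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)])
    for (k in seq_along(r$values)) {
      sl <- slot[(starts[k] + 1L):ends[k]]
      segs[[length(segs) + 1L]] <- data.frame(
        chromosome = nm, start_rank = starts[k], end_rank = ends[k],
        label = r$values[k],
        orientation = if (length(sl) > 1L && sl[1L] > sl[length(sl)]) "-" else "+",
        anc_start = min(sl) - 1L, anc_end = max(sl), n_anchors = length(sl),
        stringsAsFactors = FALSE)
    }
  }
  karyotype_painting(genome_id, do.call(rbind, segs),
                     karyotype_id = res$scenario$karyotype_id)
}

#' Built-in simulation presets
#'
#' * `thaliana_like`: 8-chromosome ancestor; one lineage undergoes three
#'   EEJs and two RCTs (n = 8 -> 5), a second stays unrearranged (n = 8).
#' * `suecica_like`: allotetraploid (n = 13) of those two lineages, with
#'   subgenome-specific fractionation rates.
#' * `camelina_like`: allohexaploid (n = 20) of three lineages (n = 7, 6, 7)
#'   sharing a basal EEJ, with lineage-specific RCTs and one extra EEJ.
#' * `clade8`: five descendants of an 8-chromosome ancestor with nested
#'   lineage-specific fusions (a known 5-taxon tree), an unrearranged
#'   reference, and an unrearranged outgroup.
#' * `outgroup_rooting`: ingroup pair differing by an RCT plus an outgroup
#'   retaining the ancestral arrangement.
#'
#' @param name preset name.
#' @param genes_per_chromosome ancestor chromosome size in genes.
#' @return an [sim_scenario].
#' @export
sim_preset <- function(name = c("thaliana_like", "suecica_like", "camelina_like",
                                "clade8", "outgroup_rooting"),
                       genes_per_chromosome = 400L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("thaliana_like", "suecica_like", "camelina_like",
                   "clade8", "outgroup_rooting")) {
    stop("unknown preset '", paste(name[1L], collapse = ""),
         "'; available presets: thaliana_like, suecica_like, camelina_like, ",
         "clade8, outgroup_rooting")
  }
  G <- genes_per_chromosome
  tha_events <- list(sim_event("EEJ", "chr1", "chr2"),
                     sim_event("EEJ", "chr3", "chr4"),
                     sim_event("EEJ", "chr5", "chr6"),
                     sim_event("RCT", "chr7", "chr8"),
                     sim_event("RCT", "chr1+chr2", "chr7"))
  switch(name,
    thaliana_like = sim_scenario(8L, G, lineages = list(
      sim_lineage("REF", loss_rate = 0.03),
      sim_lineage("THA", events = tha_events, loss_rate = 0.05))),
    suecica_like = sim_scenario(8L, G, lineages = list(
      sim_lineage("REF", loss_rate = 0.03),
      sim_lineage("THA", events = tha_events, loss_rate = 0.05)),
      polyploids = list(list(id = "SUE", parents = c("THA", "REF"),
                             suffixes = c("A", "B"), loss_rates = c(0.04, 0.10)))),
    camelina_like = sim_scenario(8L, G, lineages = list(
      sim_lineage("REF", loss_rate = 0.02),
      sim_lineage("N0", events = list(sim_event("EEJ", "chr4", "chr6")), emit = FALSE),
      sim_lineage("HIS", parent = "N0",
                  events = list(sim_event("RCT", "chr4+chr6", "chr5"),
                                sim_event("RCT", "chr7", "chr8")), loss_rate = 0.04),
      sim_lineage("NLK", parent = "N0",
                  events = list(sim_event("RCT", "chr4+chr6", "chr5")), loss_rate = 0.05),
      sim_lineage("NEG", parent = "NLK",
                  events = list(sim_event("EEJ", "chr2", "chr8")), loss_rate = 0.05)),
      polyploids = list(list(id = "SAT", parents = c("HIS", "NEG", "NLK"),
                             suffixes = c("A", "B", "C"),
                             loss_rates = c(0.03, 0.08, 0.13)))),
    clade8 = sim_scenario(8L, G, lineages = list(
      sim_lineage("REF", loss_rate = 0.02),
      sim_lineage("OUT", loss_rate = 0.06),
      sim_lineage("N1", events = list(sim_event("EEJ", "chr1", "chr2")), emit = FALSE),
      sim_lineage("N2", parent = "N1",
                  events = list(sim_event("RCT", "chr3", "chr4")), emit = FALSE),
      sim_lineage("N3", parent = "N2",
                  events = list(sim_event("EEJ", "chr5", "chr6")), emit = FALSE),
      sim_lineage("A", parent = "N3",
                  events = list(sim_event("EEJ", "chr7", "chr8")), loss_rate = 0.05),
      sim_lineage("B", parent = "N3",
                  events = list(sim_event("RCT", "chr7", "chr8")), loss_rate = 0.05),
      sim_lineage("C", parent = "N2",
                  events = list(sim_event("RCT", "chr5", "chr7")), loss_rate = 0.05),
      sim_lineage("D", parent = "N1",
                  events = list(sim_event("RCT", "chr5", "chr8")), loss_rate = 0.05))),
    outgroup_rooting = sim_scenario(8L, G, lineages = list(
      sim_lineage("REF", loss_rate = 0.03),
      sim_lineage("ING", events = list(sim_event("RCT", "chr7", "chr8")),
                  loss_rate = 0.05),
      sim_lineage("OUT", loss_rate = 0.08))))
}

#' Write all simulated datasets to a directory
#'
#' Emits, for each genome, GFF3 and BED gene tables; for each unordered
#' genome pair a homology pair file; the ground-truth event log; and a
#' ground-truth painting per genome in ancestor-file format. All text, all
#' reproducible byte-for-byte under a fixed simulation seed.
#'
#' @param res a `sim_result`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
emit_datasets <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  ids <- names(res$genomes)
  for (id in ids) {
    gff <- file.path(outdir, paste0(id, ".gff3"))
    bed <- file.path(outdir, paste0(id, ".bed"))
    write_gene_positions(res$genomes[[id]], gff, bed)
    files <- c(files, gff, bed)
  }
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in seq(i + 1L, length(ids))) {
      path <- file.path(outdir, sprintf("pairs_%s_%s.tsv", ids[i], ids[j]))
      write_homology_pairs(homology_pairs(res$genomes[[ids[i]]], res$genomes[[ids[j]]]), path)
      files <- c(files, path)
    }
  }
  tf <- file.path(outdir, "truth_events.tsv")
  utils::write.table(res$truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, tf)
  for (id in ids) {
    pf <- file.path(outdir, sprintf("true_painting_%s.tsv", id))
    write_painting(true_painting(res, id), pf)
    files <- c(files, pf)
  }
  invisible(files)
}

#' Read an evolution scenario from a config file
#'
#' Flat YAML format: `ancestor` (`n_chromosomes`, `genes_per_chromosome`),
#' `karyotype_id`, `lineages` (each with `id` and optionally `parent`,
#' `loss_rate`, `emit`, and `events` -- strings like `"EEJ chr1 chr2"`,
#' `"RCT chr7 chr8 120 200"`, `"NCF chrRecipient chrDonor 150"`,
#' `"INV chr3 100 220"`; omitted positions are drawn at simulation time)
#' and `polyploids` (`id`, `parents`, `suffixes`, `loss_rates`).
#'
#' @param path path to the YAML scenario file.
#' @return an [sim_scenario].
#' @export
read_scenario_config <- function(path) {
  conf <- yaml::read_yaml(path)
  parse_ev <- function(s) {
    tok <- strsplit(trimws(s), "\\s+")[[1L]]
    if (length(tok) < 2L) stop("malformed event spec: ", s)
    type <- tok[1L]
    pos <- suppressWarnings(as.integer(tok[-(1:3)]))
    sim_event(type, chrom_a = tok[2L],
              chrom_b = if (length(tok) >= 3L && is.na(suppressWarnings(as.integer(tok[3L]))))
                tok[3L] else NA_character_,
              pos_a = if (type == "INV") suppressWarnings(as.integer(tok[3L])) else
                if (length(pos) >= 1L) pos[1L] else NA_integer_,
              pos_b = if (type == "INV") suppressWarnings(as.integer(tok[4L])) else
                if (length(pos) >= 2L) pos[2L] else NA_integer_)
  }
  lineages <- lapply(conf$lineages, function(l) {
    sim_lineage(l$id,
                events = lapply(l$events %||% list(), parse_ev),
                parent = l$parent,
                loss_rate = l$loss_rate %||% 0,
                emit = l$emit %||% TRUE)
  })
  sim_scenario(n_chromosomes = conf$ancestor$n_chromosomes %||% 8L,
               genes_per_chromosome = conf$ancestor$genes_per_chromosome %||% 400L,
               lineages = lineages,
               polyploids = conf$polyploids %||% list(),
               karyotype_id = conf$karyotype_id %||% "AK")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random rearrangement scenario
#'
#' Draws a lineage of `n_events` events (EEJ/RCT, plus NCF when an intact
#' donor chromosome is available) against an unrearranged reference, for
#' recovery studies. Event types and operands are drawn deterministically
#' from `seed`; junction positions are drawn at simulation time.
#'
#' @param n_events number of events on the rearranged lineage.
#' @param n_chromosomes,genes_per_chromosome ancestor dimensions.
#' @param loss_rate fractionation rate applied to both emitted genomes.
#' @param seed seed for the event draw.
#' @return an [sim_scenario] with lineages `REF` and `TGT`.
#' @export
sim_random_scenario <- function(n_events = 5L, n_chromosomes = 8L,
                                genes_per_chromosome = 200L, loss_rate = 0.1,
                                seed = 1L) {
  with_seed(seed, {
    names_now <- paste0("chr", seq_len(n_chromosomes))
    simple <- stats::setNames(rep(TRUE, n_chromosomes), names_now)
    used_pairs <- character(0)
    events <- list()
    for (i in seq_len(n_events)) {
      if (length(names_now) < 2L) break
      type <- sample(c("EEJ", "RCT", "NCF"), 1L, prob = c(0.4, 0.45, 0.15))
      if (type == "NCF" && !any(simple[names_now])) type <- "RCT"
      if (type == "NCF") {
        donor <- sample(names_now[simple[names_now]], 1L)
        recipient <- sample(setdiff(names_now, donor), 1L)
        events[[i]] <- sim_event("NCF", recipient, donor)
        names_now <- setdiff(names_now, donor)
        simple[recipient] <- FALSE
      } else {
        # avoid hitting the same chromosome pair twice within one lineage
        ops <- sample(names_now, 2L)
        for (try in 1:20) {
          if (!paste(sort(ops), collapse = "\r") %in% used_pairs) break
          ops <- sample(names_now, 2L)
        }
        used_pairs <- c(used_pairs, paste(sort(ops), collapse = "\r"))
        events[[i]] <- sim_event(type, ops[1L], ops[2L])
        if (type == "EEJ") {
          merged <- paste0(ops[1L], "+", ops[2L])
          names_now <- c(setdiff(names_now, ops), merged)
          simple[merged] <- FALSE
        } else {
          simple[ops] <- FALSE
        }
      }
    }
    sim_scenario(n_chromosomes, genes_per_chromosome, lineages = list(
      sim_lineage("REF", loss_rate = loss_rate),
      sim_lineage("TGT", events = events, loss_rate = loss_rate)))
  })
}

#' Compare detected events with a simulation truth log
#'
#' Matches events as multisets of `(type, protochromosome pair)` where the
#' truth pair comes from the recorded junction adjacency families of each
#' event's first breakpoint. Returns the counts needed for precision/recall.
#'
#' @param events classified events ([classify_events]).
#' @param truth truth rows of one lineage (from a `sim_result`).
#' @return list with `tp`, `fp`, `fn`, `f1`.
#' @export
score_event_recovery <- function(events, truth) {
  truth_key <- vapply(seq_len(nrow(truth)), function(i) {
    adj <- strsplit(truth$adjacencies[i], ";", fixed = TRUE)[[1L]][1L]
    fams <- strsplit(adj, "|", fixed = TRUE)[[1L]]
    labs <- sort(sub("^P(\\d+)\\..*$", "\\1", fams))
    paste(truth$type[i], labs[1L], labs[2L])
  }, "")
  det <- events[events$type %in% c("EEJ", "RCT", "NCF"), , drop = FALSE]
  det_key <- vapply(seq_len(nrow(det)), function(i) {
    labs <- sort(c(det$proto_a[i], det$proto_b[i]))
    paste(det$type[i], labs[1L], labs[2L])
  }, "")
  tp <- 0L
  pool <- truth_key
  for (k in det_key) {
    hit <- match(k, pool)
    if (!is.na(hit)) { tp <- tp + 1L; pool <- pool[-hit] }
  }
  fp <- length(det_key) - tp
  fn <- length(truth_key) - tp
  list(tp = tp, fp = fp, fn = fn,
       f1 = if (tp == 0L) 0 else 2 * tp / (2 * tp + fp + fn))
}
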
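#' Gene-order representation of a genome
#'
#' A `genome_order` holds one gene record per gene with both base-pair
#' coordinates (metadata) and rank coordinates (the coordinate system all
#' positional logic in this package uses). Ranks are 0-based, consecutive and
#' unique within each chromosome; intervals over ranks are half-open.
#'
#' @param genome_id single string naming the genome.
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` and optionally `family`. Ranks are (re)assigned by
#'   sorting on `(start, end, gene_id)` within each chromosome, so input row
#'   order never matters.
#' @return an object of class `genome_order`: a list with elements
#'   `genome_id`, `genes` (with a `rank` column added) and `chrom_order`.
#' @export
genome_order <- function(genome_id, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  required <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("genes table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$strand <- as.character(genes$strand)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene identifier ", paste(unique(dup), collapse = ", "))
  }
  bad <- genes$start >= genes$end
  if (any(bad)) {
    stop("start must be < end; offending gene(s): ",
         paste(utils::head(genes$gene_id[bad], 5L), collapse = ", "))
  }
  chrom_order <- sort(unique(genes$chromosome))
  ord <- order(match(genes$chromosome, chrom_order), genes$start, genes$end,
               genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- unlist(lapply(split(seq_len(nrow(genes)), factor(genes$chromosome, chrom_order)),
                              function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes, chrom_order = chrom_order),
            class = "genome_order")
}

#' Haploid chromosome number of a genome
#' @param g a `genome_order`.
#' @return integer n, the number of chromosomes.
#' @export
haploid_number <- function(g) length(g$chrom_order)

#' @export
print.genome_order <- function(x, ...) {
  cat(sprintf("genome_order '%s': %d genes on %d chromosome(s)\n",
              x$genome_id, nrow(x$genes), haploid_number(x)))
  invisible(x)
}

# genes of one chromosome, ordered by rank
chrom_genes <- function(g, chrom) {
  gg <- g$genes[g$genes$chromosome == chrom, , drop = FALSE]
  gg[order(gg$rank), , drop = FALSE]
}

chrom_length <- function(g, chrom) sum(g$genes$chromosome == chrom)

#' Read gene positions from a GFF3 or BED file
#'
#' Parses gene features from GFF3 (only rows of type `gene` are used; mRNA
#' and CDS rows are ignored) or from BED (4+ columns; the name column is the
#' gene identifier). Genes are sorted by start coordinate within each
#' chromosome and assigned 0-based consecutive ranks; ties in start are
#' broken by `(end, gene_id)` so that ranks are deterministic.
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file.
#' @param genome_id name to give the genome.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return a [genome_order].
#' @export
read_gene_positions <- function(path, genome_id, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     gff = "gff3", gff3 = "gff3", bed = "bed",
                     stop("unknown format '", ext,
                          "'; accepted formats: GFF3 (.gff, .gff3), BED (.bed)"))
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      keep <- as.character(gr$type) == "gene"
      if (any(keep)) gr <- gr[keep]
    }
    ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else NULL
    if (is.null(ids) || anyNA(ids)) {
      nm <- if ("Name" %in% names(S4Vectors::mcols(gr))) as.character(gr$Name) else NULL
      if (!is.null(nm)) ids <- ifelse(is.na(ids), nm, ids)
    }
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene features must carry an ID attribute")
    genes <- data.frame(gene_id = ids,
                        chromosome = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- if ("name" %in% names(S4Vectors::mcols(gr))) as.character(gr$name) else NULL
    if (is.null(nm)) stop("BED input needs >= 4 columns (name column carries the gene ID)")
    genes <- data.frame(gene_id = nm,
                        chromosome = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genome_order(genome_id, genes)
}

#' Read a table of homologous gene pairs
#'
#' Tab-separated, >= 2 columns per row; an optional third column carries a
#' family label shared by orthologous/paralogous copies. Lines starting with
#' `#` are skipped. Pairs are returned in file order.
#'
#' @param path path to the pairs file.
#' @return data.frame with columns `gene_a`, `gene_b`, `family` (NA when the
#'   file has no third column).
#' @export
read_homology_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty homology pair file: ", path)
    return(data.frame(gene_a = character(), gene_b = character(),
                      family = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 2L
  if (any(short)) stop("homology pair rows need >= 2 tab-separated fields (row ",
                       which(short)[1L], ")")
  data.frame(gene_a = vapply(parts, `[[`, "", 1L),
             gene_b = vapply(parts, `[[`, "", 2L),
             family = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' Write homology pairs
#' @param pairs data.frame as returned by [read_homology_pairs].
#' @param path output path.
#' @export
write_homology_pairs <- function(pairs, path) {
  has_family <- "family" %in% names(pairs) && !all(is.na(pairs$family))
  cols <- if (has_family) pairs[, c("gene_a", "gene_b", "family")] else pairs[, c("gene_a", "gene_b")]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome's gene table as GFF3 and BED
#'
#' @param g a [genome_order].
#' @param gff_path,bed_path output paths; either may be `NULL` to skip.
#' @export
write_gene_positions <- function(g, gff_path = NULL, bed_path = NULL) {
  gg <- g$genes
  gr <- GenomicRanges::GRanges(seqnames = gg$chromosome,
                               ranges = IRanges::IRanges(start = gg$start, end = gg$end),
                               strand = gg$strand)
  gr$type <- "gene"
  gr$ID <- gg$gene_id
  gr$Name <- gg$gene_id
  if (!is.null(gff_path)) rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(bed_path)) {
    gr2 <- gr
    gr2$name <- gg$gene_id
    gr2$score <- 0L
    S4Vectors::mcols(gr2) <- S4Vectors::mcols(gr2)[, c("name", "score")]
    rtracklayer::export(gr2, bed_path, format = "bed")
  }
  invisible(g)
}
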
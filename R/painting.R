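#' Karyotype painting of a genome
#'
#' A segmentation of a genome into protochromosome-labeled rank intervals.
#' Segments are half-open `[start_rank, end_rank)` in gene-rank coordinates,
#' sorted and non-overlapping within each chromosome. Unpainted gaps carry
#' the label `"NA"`. In-memory paintings additionally record, per segment,
#' the ancestral rank interval, orientation and supporting anchor count.
#'
#' @param genome_id genome the painting describes.
#' @param segments data.frame with columns `chromosome`, `start_rank`,
#'   `end_rank`, `label`, `orientation` and optionally `anc_start`,
#'   `anc_end`, `n_anchors`.
#' @param karyotype_id id of the reference karyotype.
#' @param min_segment minimum painted segment length (genes) used.
#' @return object of class `karyotype_painting`.
#' @export
karyotype_painting <- function(genome_id, segments, karyotype_id = NA_character_,
                               min_segment = NA_integer_) {
  for (col in c("anc_start", "anc_end")) if (!col %in% names(segments)) segments[[col]] <- NA_integer_
  if (!"n_anchors" %in% names(segments)) segments$n_anchors <- NA_integer_
  segments$chromosome <- as.character(segments$chromosome)
  segments$label <- as.character(segments$label)
  segments$orientation <- as.character(segments$orientation)
  segments <- segments[order(segments$chromosome, segments$start_rank), , drop = FALSE]
  rownames(segments) <- NULL
  check_segments(segments)
  structure(list(genome_id = genome_id, karyotype_id = karyotype_id,
                 segments = segments, min_segment = min_segment),
            class = "karyotype_painting")
}

check_segments <- function(segments) {
  if (any(segments$start_rank >= segments$end_rank)) {
    stop("painting segments must satisfy start_rank < end_rank")
  }
  for (chrom in unique(segments$chromosome)) {
    s <- segments[segments$chromosome == chrom, , drop = FALSE]
    s <- s[order(s$start_rank), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start_rank[-1L] < s$end_rank[-nrow(s)])) {
      stop("overlapping painting segments on chromosome ", chrom)
    }
  }
  invisible(TRUE)
}

#' @export
print.karyotype_painting <- function(x, ...) {
  painted <- x$segments[x$segments$label != "NA", , drop = FALSE]
  cat(sprintf("karyotype_painting of '%s' against '%s': %d segment(s), %d label(s)\n",
              x$genome_id, x$karyotype_id, nrow(painted),
              length(unique(painted$label))))
  invisible(x)
}

#' Write a karyotype painting to an ancestor file
#'
#' The ancestor-file exchange format is a tab-separated table of five
#' columns (`chromosome`, `start_rank`, `end_rank`, `label`, `orientation`)
#' with `#` comment lines; ranks are half-open. A write-then-read round trip
#' reproduces those five fields exactly. Overlapping segments are refused.
#'
#' @param p a [karyotype_painting].
#' @param path output path.
#' @export
write_painting <- function(p, path) {
  check_segments(p$segments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# genome_id=%s", p$genome_id),
               sprintf("# karyotype_id=%s", p$karyotype_id),
               sprintf("# min_segment=%s", p$min_segment),
               "# chromosome\tstart_rank\tend_rank\tlabel\torientation"), con)
  s <- p$segments
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", s$chromosome, s$start_rank,
                     s$end_rank, s$label, s$orientation), con)
  invisible(path)
}

#' Read a karyotype painting from an ancestor file
#' @param path path written by [write_painting] (or any 5-column ancestor file).
#' @return a [karyotype_painting]; ancestral-interval columns are NA since
#'   the exchange format does not carry them.
#' @export
read_painting <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), lines, value = TRUE)
    if (length(hit) == 0L) NA_character_ else sub(paste0("^# ", key, "="), "", hit[1L])
  }
  genome_id <- meta("genome_id")
  karyotype_id <- meta("karyotype_id")
  min_segment <- suppressWarnings(as.integer(meta("min_segment")))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no segment rows in ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L)) stop("ancestor file rows need 5 tab-separated fields")
  segments <- data.frame(chromosome = vapply(parts, `[[`, "", 1L),
                         start_rank = as.integer(vapply(parts, `[[`, "", 2L)),
                         end_rank = as.integer(vapply(parts, `[[`, "", 3L)),
                         label = vapply(parts, `[[`, "", 4L),
                         orientation = vapply(parts, `[[`, "", 5L),
                         stringsAsFactors = FALSE)
  karyotype_painting(genome_id, segments, karyotype_id, min_segment)
}

#' Read conserved genomic block (CGB) definitions
#'
#' Tab-separated table `(label, chromosome, start_rank, end_rank)` where
#' `chromosome` is a protochromosome label of the reference karyotype and
#' ranks are half-open ancestral rank coordinates. Intervals must not
#' overlap on a chromosome.
#'
#' @param path path to the definition file.
#' @return data.frame with the four columns above.
#' @export
read_cgb_definitions <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           col.names = c("label", "chromosome", "start_rank", "end_rank"),
                           colClasses = c("character", "character", "integer", "integer"),
                           stringsAsFactors = FALSE)
  for (chrom in unique(tab$chromosome)) {
    s <- tab[tab$chromosome == chrom, , drop = FALSE]
    s <- s[order(s$start_rank), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start_rank[-1L] < s$end_rank[-nrow(s)])) {
      stop("overlapping CGB intervals on protochromosome ", chrom)
    }
  }
  tab
}
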
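#' Locate the orthologous region of a bait in another genome
#'
#' Seeds are k-mers unique in both the bait and the target genome
#' (counting both strands); the hit is the longest strictly co-linear
#' anchor chain (same strand, monotone positions, adjacent anchors within
#' `max_anchor_gap` in both coordinate systems). The chained span is
#' padded by `ortholog_padding` on each side and clipped to the
#' chromosome; minus-strand hits are reverse-complemented so downstream
#' coordinates are bait-forward. Absence (`NULL`) is a legal outcome,
#' mirroring the loci where no corresponding sequence could be obtained.
#'
#' @param bait_seq Bait nucleotide string.
#' @param genome A [genome_assembly()] to search.
#' @param config A [pipeline_config()] (uses `anchor_kmer`, `min_anchors`,
#'   `max_anchor_gap`, `ortholog_padding`).
#' @return An `ortholog_hit` (list with accession, chromosome, `start`,
#'   `end`, `strand`, `anchor_count`, `anchor_span_fraction`, `sequence`,
#'   per-anchor positions in the extracted sequence, and an `ambiguous`
#'   flag set when a second chain scores at least 0.8x the best), or
#'   `NULL`.
#' @export
find_orthologous_region <- function(bait_seq, genome,
                                    config = pipeline_config()) {
  stopifnot(inherits(genome, "genome_assembly"))
  anchors <- .cpp_find_anchors_multi(bait_seq, unname(genome$chromosomes),
                                     config$anchor_kmer)[[1]]
  hit_from_anchors(anchors, nchar(bait_seq), genome, config)
}

# Build the best co-linear chain hit from a unique-anchor table.
hit_from_anchors <- function(anchors, bait_len, genome, config) {
  if (!nrow(anchors)) return(NULL)
  k <- config$anchor_kmer
  chrom_names <- names(genome$chromosomes)
  candidates <- list()
  for (ci in unique(anchors$chrom)) {
    for (st in c(1L, -1L)) {
      g <- anchors[anchors$chrom == ci & anchors$strand == st, , drop = FALSE]
      if (nrow(g) < 2) next
      # anchors arrive sorted by bait_pos; chain = LIS on target positions
      ord_val <- if (st == 1L) g$tpos else -g$tpos
      idx <- .cpp_lis(ord_val)
      ch <- g[idx, , drop = FALSE]
      # split where adjacent anchors are farther than max_anchor_gap apart
      if (nrow(ch) > 1) {
        bgap <- diff(ch$bait_pos)
        tgap <- abs(diff(ch$tpos))
        brk <- which(bgap > config$max_anchor_gap | tgap > config$max_anchor_gap)
        pieces <- split(seq_len(nrow(ch)),
                        cumsum(seq_len(nrow(ch)) %in% (brk + 1L)))
        best_piece <- pieces[[which.max(vapply(pieces, length, integer(1)))]]
        ch <- ch[best_piece, , drop = FALSE]
      }
      if (nrow(ch) >= 2)
        candidates[[length(candidates) + 1L]] <- ch
    }
  }
  if (!length(candidates)) return(NULL)
  score <- vapply(candidates, nrow, integer(1))
  span <- vapply(candidates, function(ch) diff(range(ch$tpos)) + k, numeric(1))
  chrom_nm <- vapply(candidates, function(ch) chrom_names[ch$chrom[1]], character(1))
  tstart <- vapply(candidates, function(ch) min(ch$tpos), numeric(1))
  o <- order(-score, span, chrom_nm, tstart)
  best <- candidates[[o[1]]]
  ambiguous <- length(o) > 1 && score[o[2]] >= 0.8 * score[o[1]]
  if (nrow(best) < config$min_anchors) return(NULL)
  span_frac <- (diff(range(best$bait_pos)) + k) / bait_len
  if (span_frac < 0.5) return(NULL)
  ci <- best$chrom[1]; st <- best$strand[1]
  chrom <- chrom_names[ci]
  L <- nchar(genome$chromosomes[[chrom]])
  rstart <- max(1L, min(best$tpos) - config$ortholog_padding)
  rend <- min(L, max(best$tpos) + k - 1L + config$ortholog_padding)
  seq <- substr(genome$chromosomes[[chrom]], rstart, rend)
  if (st == -1L) seq <- revcomp(seq)
  # anchor positions within the extracted (strand-normalised) sequence
  qpos <- if (st == 1L) best$tpos - rstart + 1L
          else (rend - rstart + 1L) - (best$tpos + k - 1L - rstart + 1L) + 1L
  anchor_df <- data.frame(bait_pos = best$bait_pos, qpos = as.integer(qpos))
  anchor_df <- anchor_df[order(anchor_df$bait_pos), , drop = FALSE]
  structure(list(accession = genome$accession_id,
                 chrom = chrom, start = rstart, end = rend,
                 strand = if (st == 1L) "+" else "-",
                 anchor_count = nrow(best),
                 anchor_span_fraction = span_frac,
                 sequence = seq,
                 anchors = anchor_df,
                 ambiguous = ambiguous),
            class = "ortholog_hit")
}

#' @export
print.ortholog_hit <- function(x, ...) {
  cat(sprintf("Ortholog hit in %s: %s:%d-%d (%s), %d anchors, span %.2f%s\n",
              x$accession, x$chrom, x$start, x$end, x$strand,
              x$anchor_count, x$anchor_span_fraction,
              if (x$ambiguous) ", AMBIGUOUS" else ""))
  invisible(x)
}

#' Assemble the ortholog set of a bait across a genome panel
#'
#' Collects at most one hit per genome (the best co-linear chain). When
#' fewer than `min_ortholog_members` sequences (bait included) are
#' recovered, a rejection record listing the missing genomes is returned
#' instead -- the multiple alignment would not be informative.
#'
#' @param bait One row of [select_bait_windows()] output (or a list with
#'   `chrom`, `start`, `end`, `sequence`).
#' @param genomes Named list of [genome_assembly()] objects (the
#'   non-reference panel members).
#' @param config A [pipeline_config()].
#' @param anchors_by_genome Optional precomputed anchor tables (one per
#'   genome) from a batched scan; used by the pipeline driver.
#' @return An `ortholog_set` (list with `bait` and `hits`) or an
#'   `ortholog_rejection` (list with `bait` and per-genome `reasons`).
#' @export
assemble_ortholog_set <- function(bait, genomes, config = pipeline_config(),
                                  anchors_by_genome = NULL) {
  if (!length(genomes)) stop("at least one non-reference genome is required",
                             call. = FALSE)
  hits <- list(); reasons <- character(0)
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    hit <- if (is.null(anchors_by_genome))
      find_orthologous_region(bait$sequence, g, config)
    else
      hit_from_anchors(anchors_by_genome[[gi]], nchar(bait$sequence), g, config)
    if (is.null(hit)) reasons[g$accession_id] <- "no_colinear_chain"
    else hits[[g$accession_id]] <- hit
  }
  members <- length(hits) + 1L  # the bait itself
  if (members < config$min_ortholog_members) {
    return(structure(list(bait = bait, hits = hits, reasons = reasons,
                          members = members),
                     class = "ortholog_rejection"))
  }
  structure(list(bait = bait, hits = hits, members = members),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("Ortholog set for %s:%d-%d: %d member(s)\n",
              x$bait$chrom, x$bait$start, x$bait$end, x$members))
  invisible(x)
}

#' Write an ortholog set as multi-FASTA
#'
#' One record per member; the bait first. Headers carry the accession and
#' source interval.
#' @param oset An `ortholog_set`.
#' @param path Output path.
#' @export
write_ortholog_fasta <- function(oset, path) {
  seqs <- c(setNames(bait_header_seq(oset$bait),
                     sprintf("bait %s:%d-%d", oset$bait$chrom,
                             oset$bait$start, oset$bait$end)),
            vapply(oset$hits, function(h) h$sequence, character(1)))
  nm <- vapply(oset$hits, function(h)
    sprintf("%s %s:%d-%d(%s)", h$accession, h$chrom, h$start, h$end, h$strand),
    character(1))
  names(seqs)[-1] <- nm
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

bait_header_seq <- function(bait) bait$sequence
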
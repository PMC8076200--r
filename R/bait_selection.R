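#' Repeat-derived fraction of a window
#'
#' The fraction of window positions whose covering k-mer occurs more than
#' once genome-wide (forward strand), or that are soft-masked or N. Each
#' position is covered by the k-mer starting at it (positions in the final
#' k-1 bp inherit the last full k-mer). Deterministic.
#'
#' @param window_seq Window nucleotide string (upper case).
#' @param genome A [genome_assembly()] providing the genome-wide k-mer
#'   background, or a named character vector of chromosome sequences.
#' @param k k-mer size (default 21; must be at least 8).
#' @param masked Optional logical vector (length of the window) marking
#'   soft-masked positions.
#' @return A number in `[0, 1]`.
#' @export
repeat_fraction <- function(window_seq, genome, k = 21, masked = NULL) {
  if (k < 8) stop("k must be >= 8", call. = FALSE)
  L <- nchar(window_seq)
  if (L < k) stop("window shorter than k", call. = FALSE)
  chroms <- if (inherits(genome, "genome_assembly")) genome$chromosomes else genome
  counts <- .cpp_kmer_multiplicity(window_seq, unname(chroms), as.integer(k))
  # k-mers containing N never index; count their positions as repeat-like
  kmer_rep <- is.na(counts) | counts > 1L
  per_pos <- kmer_rep[pmin(seq_len(L), L - k + 1L)]
  if (!is.null(masked)) per_pos <- per_pos | masked[seq_len(L)]
  per_pos <- per_pos | strsplit(window_seq, "")[[1]] == "N"
  mean(per_pos)
}

#' Select evenly spaced repeat-poor bait windows
#'
#' Anchors candidate windows at multiples of `bait_interval_bp` from the
#' top of each chromosome to its end. A window whose repeat fraction
#' exceeds `max_repeat_fraction` is slid forward in steps of
#' `bait_min_len / 2` until an eligible window is found or the next anchor
#' is reached (in which case the anchor is skipped). Windows have length
#' `bait_min_len`.
#'
#' @param reference A [genome_assembly()].
#' @param config A [pipeline_config()].
#' @return A data frame of class `bait_regions`: `chrom`, `start`, `end`
#'   (1-based inclusive), `length`, `repeat_fraction`, `sequence`, sorted
#'   by position.
#' @export
select_bait_windows <- function(reference, config = pipeline_config()) {
  stopifnot(inherits(reference, "genome_assembly"))
  bait_len <- config$bait_min_len
  step <- as.integer(bait_len / 2)
  rows <- list()
  for (chrom in names(reference$chromosomes)) {
    L <- nchar(reference$chromosomes[[chrom]])
    if (L < bait_len) next
    mask_vec <- mask_logical(reference$mask[[chrom]], L)
    anchors <- seq(1L, L - bait_len + 1L, by = as.integer(config$bait_interval_bp))
    for (ai in seq_along(anchors)) {
      a <- anchors[ai]
      limit <- if (ai < length(anchors)) anchors[ai + 1] - 1L else L - bait_len + 1L
      start <- a
      while (start <= limit && start + bait_len - 1L <= L) {
        win <- substr(reference$chromosomes[[chrom]], start, start + bait_len - 1L)
        mk <- if (is.null(mask_vec)) NULL else mask_vec[start:(start + bait_len - 1L)]
        rf <- repeat_fraction(win, reference, k = config$repeat_kmer, masked = mk)
        if (rf <= config$max_repeat_fraction) {
          rows[[length(rows) + 1L]] <-
            data.frame(chrom = chrom, start = start,
                       end = start + bait_len - 1L, length = bait_len,
                       repeat_fraction = rf, sequence = win,
                       stringsAsFactors = FALSE)
          break
        }
        start <- start + step
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               length = integer(0), repeat_fraction = numeric(0),
               sequence = character(0), stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, names(reference$chromosomes)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bait_regions", "data.frame")
  out
}

mask_logical <- function(runs, L) {
  if (is.null(runs) || !nrow(runs)) return(NULL)
  v <- logical(L)
  for (i in seq_len(nrow(runs))) v[runs[i, 1]:runs[i, 2]] <- TRUE
  v
}

#' @export
print.bait_regions <- function(x, ...) {
  cat(sprintf("%d bait window(s)\n", nrow(x)))
  print.data.frame(head(x[, setdiff(names(x), "sequence")], 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write bait windows to TSV
#'
#' Columns: chrom, start (1-based), end, length, repeat_fraction.
#' @param baits A `bait_regions` data frame.
#' @param path Output path.
#' @export
write_bait_table <- function(baits, path) {
  write.table(baits[, c("chrom", "start", "end", "length", "repeat_fraction")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
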
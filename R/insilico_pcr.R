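#' Find primer binding sites on a sequence
#'
#' A site is reported when the primer matches with at most `max_mismatch`
#' mismatches overall and zero mismatches in its 3'-terminal
#' `three_prime_exact_len` bases; both strands are scanned. This models
#' the PCR failures seen when primer binding sites carry sequence
#' variation: a 3'-terminal mismatch abolishes extension.
#'
#' @param primer Primer sequence (A/C/G/T).
#' @param sequence Template nucleotide string.
#' @param max_mismatch Mismatch tolerance (default 2).
#' @param three_prime_exact_len 3'-exact length (default 3).
#' @return Data frame with `position` (1-based start of the matched
#'   window, leftmost template coordinate) and `strand` (`"+"` when the
#'   primer matches the template text directly, `"-"` when its reverse
#'   complement does).
#' @export
find_binding_sites <- function(primer, sequence, max_mismatch = 2,
                               three_prime_exact_len = 3) {
  if (nchar(primer) < three_prime_exact_len)
    stop("primer shorter than the 3'-exact length", call. = FALSE)
  if (grepl("[^ACGT]", primer))
    stop("primer must be A/C/G/T only", call. = FALSE)
  res <- .cpp_scan_sites_multi(sequence,
                               c(primer, revcomp(primer)),
                               c(TRUE, FALSE),
                               as.integer(max_mismatch),
                               as.integer(three_prime_exact_len))
  data.frame(position = c(res[[1]], res[[2]]),
             strand = rep(c("+", "-"), c(length(res[[1]]), length(res[[2]]))),
             stringsAsFactors = FALSE)
}

#' Predict amplicons of a primer pair on one haplotype sequence
#'
#' Every pairing of a forward-primer plus-strand site with a
#' reverse-primer minus-strand site downstream spans an amplicon, kept
#' when its length lies within the e-PCR bounds.
#'
#' @param primer_pair A `primer_pair` (or any list with `fwd_seq`,
#'   `rev_seq`).
#' @param sequence Template nucleotide string.
#' @param config A [pipeline_config()].
#' @return Data frame `start`, `end`, `length`, sorted by position.
#' @export
predict_amplicons <- function(primer_pair, sequence,
                              config = pipeline_config()) {
  fs <- find_binding_sites(primer_pair$fwd_seq, sequence,
                           config$epcr_max_mismatch,
                           config$epcr_three_prime_exact)
  rs <- find_binding_sites(primer_pair$rev_seq, sequence,
                           config$epcr_max_mismatch,
                           config$epcr_three_prime_exact)
  fpos <- fs$position[fs$strand == "+"]
  rpos <- rs$position[rs$strand == "-"]
  if (!length(fpos) || !length(rpos))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  rlen <- nchar(primer_pair$rev_seq)
  grid <- expand.grid(f = fpos, r = rpos)
  grid$end <- grid$r + rlen - 1L
  grid$len <- grid$end - grid$f + 1L
  keep <- grid$len >= config$epcr_min_product &
          grid$len <= config$epcr_max_product
  out <- data.frame(start = as.integer(grid$f[keep]),
                    end = as.integer(grid$end[keep]),
                    length = as.integer(grid$len[keep]))
  out[order(out$start, out$end), , drop = FALSE]
}

#' Merge amplicon lengths under a gel-resolution model
#'
#' Lengths closer than `gel_resolution_bp` are unresolvable on a 2.5-4.0\%
#' agarose gel; single-linkage clusters of such lengths collapse to their
#' mean. Idempotent and order-independent.
#'
#' @param lengths Numeric vector of amplicon lengths.
#' @param gel_resolution_bp Resolution threshold (default 20).
#' @return Sorted numeric vector of merged band lengths.
#' @export
merge_gel_bands <- function(lengths, gel_resolution_bp = 20) {
  if (!length(lengths)) return(numeric(0))
  x <- sort(lengths)
  cl <- cumsum(c(1, diff(x) >= gel_resolution_bp))
  as.numeric(tapply(x, cl, mean))
}

#' Genotype an accession with a marker by in-silico PCR
#'
#' Runs both haplotypes (heterozygous accessions carry two), pools the
#' amplicons, merges lengths under the gel model and assigns a status:
#' `no_amplification` when nothing amplifies, `excess_bands` when more
#' than two merged bands appear, otherwise `ok`. When two bands arise the
#' probable cause is annotated: `heterozygous` if the haplotypes amplify
#' different lengths, `duplication` if a single haplotype yields both, or
#' `NA` when the data cannot distinguish them.
#'
#' @param marker A list with a `primer_pair` element (or a `primer_pair`
#'   itself).
#' @param accession_assembly A [genome_assembly()].
#' @param config A [pipeline_config()].
#' @return A `band_set`: `accession_id`, `band_lengths` (sorted, merged),
#'   `raw_amplicons`, `status`, `two_band_cause`.
#' @export
genotype_accession <- function(marker, accession_assembly,
                               config = pipeline_config()) {
  pair <- if (inherits(marker, "primer_pair")) marker else marker$primer_pair
  haps <- list(h1 = accession_assembly$chromosomes)
  if (!is.null(accession_assembly$haplotype2))
    haps$h2 <- accession_assembly$haplotype2
  amps <- list()
  for (hname in names(haps)) {
    for (chrom in names(haps[[hname]])) {
      a <- predict_amplicons(pair, haps[[hname]][[chrom]], config)
      if (nrow(a)) {
        a$chrom <- chrom; a$haplotype <- hname
        amps[[length(amps) + 1L]] <- a
      }
    }
  }
  raw <- if (length(amps)) do.call(rbind, amps) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               chrom = character(0), haplotype = character(0))
  bands <- merge_gel_bands(raw$length, config$gel_resolution_bp)
  status <- if (!length(bands)) "no_amplification"
            else if (length(bands) > 2) "excess_bands"
            else "ok"
  cause <- NA_character_
  if (length(bands) == 2) {
    by_hap <- split(raw$length, raw$haplotype)
    multi_in_one <- any(vapply(by_hap, function(v)
      length(merge_gel_bands(v, config$gel_resolution_bp)) > 1, logical(1)))
    if (multi_in_one) cause <- "duplication"
    else if (length(by_hap) == 2) cause <- "heterozygous"
  }
  structure(list(accession_id = accession_assembly$accession_id,
                 band_lengths = bands,
                 raw_amplicons = raw,
                 status = status,
                 two_band_cause = cause),
            class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("Band set %s [%s]: %s\n", x$accession_id, x$status,
              if (length(x$band_lengths))
                paste(round(x$band_lengths), collapse = " / ") else "-"))
  invisible(x)
}
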
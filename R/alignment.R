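#' Banded global alignment of an ortholog to its bait
#'
#' Affine-gap global alignment (a gap of length g costs
#' `gap_open + g * gap_extend`) computed inside a band. The band follows
#' the anchor chain when anchors are supplied (piecewise-linear
#' interpolation of the chain path), otherwise the main diagonal. If the
#' optimal path touches the band edge, the band is doubled automatically
#' up to four times the initial width before giving up. Traceback ties
#' prefer match/mismatch, then gap-in-query, then gap-in-bait, so results
#' are deterministic.
#'
#' With `free_query_ends = TRUE` (used by the pipeline, where extracted
#' orthologs carry padding) the query may overhang the bait at either end
#' at no cost; the unaligned overhang is trimmed from the result and
#' reported via `qstart`/`qend`.
#'
#' @param bait_seq,query_seq Nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults
#'   1, -2, -6, -0.2: long-gap friendly, so a 30-bp InDel stays one
#'   event).
#' @param band_width Band half-width in bp; must be at least the largest
#'   expected InDel (default 500).
#' @param anchors Optional data frame (`bait_pos`, `qpos`) guiding the
#'   band.
#' @param free_query_ends Allow cost-free query overhangs.
#' @param query_id Identifier stored in the result.
#' @return A `pairwise_alignment`: `aligned_bait` and `aligned_query`
#'   (equal-length gapped strings; no column is gap-in-both), `score`,
#'   `identity`, `qstart`, `qend`.
#' @export
align_to_bait <- function(bait_seq, query_seq, match = 1, mismatch = -2,
                          gap_open = -6, gap_extend = -0.2,
                          band_width = 500, anchors = NULL,
                          free_query_ends = FALSE, query_id = "query") {
  n <- nchar(bait_seq); m <- nchar(query_seq)
  if (n == 0 || m == 0) stop("sequences must be non-empty", call. = FALSE)
  center <- band_center(n, m, anchors, free_query_ends)
  halfw <- as.integer(band_width)
  res <- NULL
  for (attempt in 1:3) {  # band_width, x2, x4
    res <- .cpp_banded_affine(bait_seq, query_seq, match, mismatch,
                              gap_open, gap_extend, center, halfw,
                              free_query_ends)
    if (!res$edge_hit) break
    if (attempt == 3)
      stop("alignment band overflow at 4x the initial width", call. = FALSE)
    halfw <- halfw * 2L
  }
  a <- res$aligned_a; b <- res$aligned_b
  ncols <- nchar(a)
  av <- charToRaw(a); bv <- charToRaw(b)
  gap <- charToRaw("-")
  matches <- sum(av == bv & av != gap)
  aligned_cols <- sum(av != gap & bv != gap)
  structure(list(query_id = query_id,
                 aligned_bait = a, aligned_query = b,
                 score = res$score,
                 identity = if (aligned_cols) matches / aligned_cols else 0,
                 qstart = res$qstart, qend = res$qend,
                 n_columns = ncols),
            class = "pairwise_alignment")
}

# 0-based column centre per bait row (length n + 1). With free query ends
# the band is extrapolated diagonally beyond the outermost anchors instead
# of being pinned to the (0,0) and (n,m) corners, so padded overhangs stay
# inside the band.
band_center <- function(n, m, anchors = NULL, free_ends = FALSE) {
  if (is.null(anchors) || !nrow(anchors)) {
    return(as.integer(round(seq(0, m, length.out = n + 1))))
  }
  if (free_ends) {
    x <- c(0, anchors$bait_pos,
           n)
    y <- c(anchors$qpos[1] - 1L - anchors$bait_pos[1],
           anchors$qpos - 1L,
           anchors$qpos[nrow(anchors)] - 1L + (n - anchors$bait_pos[nrow(anchors)]))
  } else {
    x <- c(0, anchors$bait_pos, n)
    y <- c(0, anchors$qpos - 1L, m)
  }
  ok <- !duplicated(x)
  ctr <- approx(x[ok], y[ok], xout = 0:n, rule = 2)$y
  ctr <- pmin(pmax(round(ctr), 0), m)
  as.integer(cummax(ctr))  # non-decreasing, keeps the band connected
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment '%s': %d columns, score %.1f, identity %.3f\n",
              x$query_id, x$n_columns, x$score, x$identity))
  invisible(x)
}

#' Project pairwise alignments into a reference-anchored MSA
#'
#' Every bait position is one column; per member the aligned character at
#' each column is stored (gap for deletions), and insertions relative to
#' the bait are stored as (reference position, inserted sequence) pairs
#' anchored after the last consumed bait base. The projection is lossless:
#' [deproject_member()] reproduces each member's aligned sequence
#' byte-for-byte.
#'
#' @param bait_id Identifier of the bait/reference member.
#' @param bait_seq Bait nucleotide string.
#' @param alignments Named list of [align_to_bait()] results (names are
#'   member ids).
#' @return An `anchored_msa`: `bait_id`, `bait_seq`, `members` (per member
#'   `proj` string of length `nchar(bait_seq)` and an `ins` data frame
#'   with `ref_pos`, `seq`).
#' @export
project_to_msa <- function(bait_id, bait_seq, alignments) {
  n <- nchar(bait_seq)
  members <- list()
  for (id in names(alignments)) {
    al <- alignments[[id]]
    acols <- strsplit(al$aligned_bait, "")[[1]]
    qcols <- strsplit(al$aligned_query, "")[[1]]
    is_bait <- acols != "-"
    if (paste(acols[is_bait], collapse = "") != bait_seq)
      stop("alignment bait row does not match the bait sequence for member ",
           id, call. = FALSE)
    proj <- qcols[is_bait]
    ref_idx <- cumsum(is_bait)         # bait position at/before each column
    ins_cols <- which(!is_bait)
    ins <- if (length(ins_cols)) {
      grp <- ref_idx[ins_cols]
      runs <- split(ins_cols, grp)
      data.frame(ref_pos = as.integer(names(runs)),
                 seq = vapply(runs, function(ix)
                   paste(qcols[ix], collapse = ""), character(1)),
                 stringsAsFactors = FALSE, row.names = NULL)
    } else {
      data.frame(ref_pos = integer(0), seq = character(0),
                 stringsAsFactors = FALSE)
    }
    members[[id]] <- list(proj = paste(proj, collapse = ""), ins = ins)
  }
  structure(list(bait_id = bait_id, bait_seq = bait_seq, members = members),
            class = "anchored_msa")
}

#' @export
print.anchored_msa <- function(x, ...) {
  cat(sprintf("Anchored MSA on %s: %d columns, %d member(s) + bait\n",
              x$bait_id, nchar(x$bait_seq), length(x$members)))
  invisible(x)
}

#' Reconstruct a member sequence from the projected MSA
#'
#' @param msa An `anchored_msa`.
#' @param id Member identifier.
#' @return The member's aligned sequence span (gaps removed, insertions
#'   restored).
#' @export
deproject_member <- function(msa, id) {
  mem <- msa$members[[id]]
  if (is.null(mem)) stop("no such member: ", id, call. = FALSE)
  chars <- strsplit(mem$proj, "")[[1]]
  pieces <- character(0)
  ins <- mem$ins
  pre_ins <- ins$seq[ins$ref_pos == 0]
  if (length(pre_ins)) pieces <- pre_ins
  n <- length(chars)
  ins_after <- setNames(ins$seq, ins$ref_pos)
  out <- character(2 * n)
  oi <- 0L
  for (i in seq_len(n)) {
    if (chars[i] != "-") { oi <- oi + 1L; out[oi] <- chars[i] }
    hit <- ins_after[as.character(i)]
    if (!is.na(hit)) { oi <- oi + 1L; out[oi] <- hit }
  }
  paste(c(pieces, out[seq_len(oi)]), collapse = "")
}

#' Emit an anchored MSA as aligned multi-FASTA
#'
#' Gapped, reference-projected member rows (insertions are spliced back in
#' as columns gapped in all other members) for eyeballing in an alignment
#' viewer.
#' @param msa An `anchored_msa`.
#' @param path Output path.
#' @export
write_msa_fasta <- function(msa, path) {
  n <- nchar(msa$bait_seq)
  all_ins <- lapply(msa$members, function(m) m$ins)
  ins_pos <- sort(unique(unlist(lapply(all_ins, function(d) d$ref_pos))))
  ins_len <- vapply(ins_pos, function(p)
    max(vapply(all_ins, function(d) {
      hit <- d$seq[d$ref_pos == p]
      if (length(hit)) nchar(hit)[1] else 0L
    }, integer(1))), integer(1))
  build_row <- function(base_chars, ins_df) {
    out <- character(0)
    prev <- 0L
    for (k in seq_along(ins_pos)) {
      p <- ins_pos[k]
      out <- c(out, paste(base_chars[seq_len(p - prev) + prev], collapse = ""))
      hit <- ins_df$seq[ins_df$ref_pos == p]
      piece <- if (length(hit)) hit[1] else ""
      out <- c(out, formatC(piece, width = -ins_len[k], flag = "-"))
      prev <- p
    }
    out <- c(out, paste(base_chars[seq_len(n - prev) + prev], collapse = ""))
    gsub(" ", "-", paste(out, collapse = ""))
  }
  empty_ins <- data.frame(ref_pos = integer(0), seq = character(0))
  rows <- c(setNames(list(build_row(strsplit(msa$bait_seq, "")[[1]], empty_ins)),
                     msa$bait_id),
            lapply(msa$members, function(m)
              build_row(strsplit(m$proj, "")[[1]], m$ins)))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(vapply(rows, identity, character(1))), path,
    width = 70L)
  invisible(path)
}
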
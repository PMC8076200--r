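#' Extract InDel blocks from an anchored MSA
#'
#' Deletion runs and insertion events are collected per member,
#' left-aligned against the bait sequence (the standard normalisation, so
#' positions are reproducible across aligner variants), and events whose
#' reference positions fall within `merge_radius` of each other are merged
#' into one block with per-member allele lengths. Blocks whose maximum
#' pairwise allele-length difference is below `min_gap_bp` are discarded.
#'
#' Member allele length at a block is the number of member bases occupying
#' the block's reference footprint (reference bases kept, minus deleted,
#' plus inserted); the reference allele length is the footprint width
#' itself. Members absent from the MSA simply do not appear in the allele
#' map.
#'
#' @param msa An `anchored_msa` from [project_to_msa()].
#' @param min_gap_bp Minimum allele-length difference (default 20).
#' @param merge_radius Merge radius in bp (default 10).
#' @return A list of `indel_block` objects: `ref_start`, `ref_len`,
#'   `ref_end`, `allele_len` (named integer vector including the bait
#'   under the MSA's `bait_id`), `max_gap`.
#' @export
extract_indel_blocks <- function(msa, min_gap_bp = 20, merge_radius = 10) {
  stopifnot(inherits(msa, "anchored_msa"))
  bait_chars <- strsplit(msa$bait_seq, "")[[1]]
  n <- length(bait_chars)
  events <- list()
  for (id in names(msa$members)) {
    mem <- msa$members[[id]]
    pv <- strsplit(mem$proj, "")[[1]] == "-"
    r <- rle(pv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      ev <- left_align_deletion(bait_chars, starts[k], r$lengths[k])
      events[[length(events) + 1L]] <-
        list(member = id, type = "del", pos = ev$pos, len = ev$len)
    }
    if (nrow(mem$ins)) {
      for (k in seq_len(nrow(mem$ins))) {
        ev <- left_align_insertion(bait_chars, mem$ins$ref_pos[k],
                                   mem$ins$seq[k])
        events[[length(events) + 1L]] <-
          list(member = id, type = "ins", pos = ev$pos, len = nchar(ev$seq))
      }
    }
  }
  if (!length(events)) return(list())
  pos <- vapply(events, `[[`, numeric(1), "pos")
  o <- order(pos)
  events <- events[o]; pos <- pos[o]
  cluster <- cumsum(c(1, diff(pos) > merge_radius))
  member_ids <- c(msa$bait_id, names(msa$members))
  blocks <- list()
  for (cl in unique(cluster)) {
    ev <- events[cluster == cl]
    dels <- Filter(function(e) e$type == "del", ev)
    if (length(dels)) {
      ref_start <- min(vapply(dels, `[[`, numeric(1), "pos"))
      ref_end <- max(vapply(dels, function(e) e$pos + e$len - 1, numeric(1)))
    } else {
      # insertion-only block: zero-width footprint after the anchor base
      p <- min(vapply(ev, `[[`, numeric(1), "pos"))
      ref_start <- p + 1; ref_end <- p
    }
    ref_len <- ref_end - ref_start + 1
    allele <- setNames(rep(as.integer(ref_len), length(member_ids)), member_ids)
    for (e in ev) {
      if (e$type == "del") {
        ov <- max(0, min(e$pos + e$len - 1, ref_end) - max(e$pos, ref_start) + 1)
        allele[e$member] <- allele[e$member] - ov
      } else {
        allele[e$member] <- allele[e$member] + e$len
      }
    }
    max_gap <- max(allele) - min(allele)
    if (max_gap >= min_gap_bp) {
      blocks[[length(blocks) + 1L]] <-
        structure(list(ref_start = as.integer(ref_start),
                       ref_end = as.integer(ref_end),
                       ref_len = as.integer(ref_len),
                       allele_len = allele,
                       max_gap = as.integer(max_gap)),
                  class = "indel_block")
    }
  }
  blocks
}

# shift a deletion run left while the base preceding it equals the last
# deleted base (classic left normalisation)
left_align_deletion <- function(bait_chars, pos, len) {
  while (pos > 1 && bait_chars[pos - 1] == bait_chars[pos + len - 1]) {
    pos <- pos - 1
  }
  list(pos = pos, len = len)
}

# rotate an insertion left while the anchor base equals the last inserted
# base; pos is the reference base AFTER which the insertion sits
left_align_insertion <- function(bait_chars, pos, seq) {
  while (pos >= 1 && substr(seq, nchar(seq), nchar(seq)) == bait_chars[pos]) {
    seq <- paste0(bait_chars[pos], substr(seq, 1, nchar(seq) - 1))
    pos <- pos - 1
  }
  list(pos = pos, seq = seq)
}

#' @export
print.indel_block <- function(x, ...) {
  cat(sprintf("InDel block at ref %d-%d (%d bp): alleles %s, max gap %d bp\n",
              x$ref_start, x$ref_end, x$ref_len,
              paste(sort(unique(x$allele_len)), collapse = "/"), x$max_gap))
  invisible(x)
}

#' Classify an InDel block as diagnostic between cultivars and wild species
#'
#' A block is *fully* diagnostic when every cultivar-vs-wild member pair
#' differs in allele length by at least `min_gap_bp`, and *partially*
#' diagnostic when at least one such pair does. Members missing from the
#' block (no ortholog recovered) are excluded from the quantifier.
#'
#' @param block An `indel_block`.
#' @param group_label_by_member Named character vector mapping member ids
#'   to group labels (`cultivar_*` or `wild`; other labels are ignored).
#' @param min_gap_bp Diagnostic gap threshold (default 20).
#' @return A `diagnostic_call`: `tier` (`full`/`partial`/`none`),
#'   `cultivar_lengths`, `discriminated_wild_members`, `gap_bp` (the
#'   minimum qualifying difference).
#' @export
classify_diagnostic <- function(block, group_label_by_member, min_gap_bp = 20) {
  allele <- block$allele_len
  members <- intersect(names(allele), names(group_label_by_member))
  grp <- group_label_by_member[members]
  cultivars <- members[startsWith(grp, "cultivar")]
  wilds <- members[grp == "wild"]
  if (!length(cultivars))
    stop("no cultivar member present: diagnosis undefined", call. = FALSE)
  if (!length(wilds)) {
    return(structure(list(tier = "none",
                          cultivar_lengths = sort(unique(allele[cultivars])),
                          discriminated_wild_members = character(0),
                          gap_bp = 0L),
                     class = "diagnostic_call"))
  }
  diffs <- abs(outer(allele[cultivars], allele[wilds], `-`))
  qual <- diffs >= min_gap_bp
  tier <- if (all(qual)) "full" else if (any(qual)) "partial" else "none"
  gap_bp <- if (any(qual)) min(diffs[qual]) else 0L
  disc <- wilds[apply(qual, 2, any)]
  structure(list(tier = tier,
                 cultivar_lengths = sort(unique(allele[cultivars])),
                 discriminated_wild_members = disc,
                 gap_bp = as.integer(gap_bp)),
            class = "diagnostic_call")
}

#' @export
print.diagnostic_call <- function(x, ...) {
  cat(sprintf("Diagnostic call: tier %s, gap %d bp, %d wild member(s) discriminated\n",
              x$tier, x$gap_bp, length(x$discriminated_wild_members)))
  invisible(x)
}

#' Select the marker InDels of one bait
#'
#' Ranks diagnostic blocks (full tier before partial; larger gap first;
#' longer available conserved flank next; then smaller reference start for
#' determinism) and greedily keeps at most `max_markers_per_bait` blocks
#' whose reference starts are at least `product_max` apart, so their
#' amplicons cannot overlap.
#'
#' @param blocks List of `indel_block`s.
#' @param calls List of matching `diagnostic_call`s.
#' @param max_markers_per_bait Cap (default 2).
#' @param product_max Minimum spacing between selected blocks (default 500).
#' @param flank_score Optional numeric vector (same length as `blocks`):
#'   length of the shorter conserved flank from the primer-design
#'   pre-scan.
#' @return Integer indices of the selected blocks, in rank order.
#' @export
select_markers_per_bait <- function(blocks, calls, max_markers_per_bait = 2,
                                    product_max = 500, flank_score = NULL) {
  if (!length(blocks)) return(integer(0))
  tier <- vapply(calls, `[[`, character(1), "tier")
  gap <- vapply(calls, `[[`, integer(1), "gap_bp")
  start <- vapply(blocks, `[[`, integer(1), "ref_start")
  if (is.null(flank_score)) flank_score <- rep(0, length(blocks))
  keep <- which(tier != "none")
  if (!length(keep)) return(integer(0))
  o <- keep[order(-(tier[keep] == "full"), -gap[keep], -flank_score[keep],
                  start[keep])]
  sel <- integer(0)
  for (i in o) {
    if (length(sel) >= max_markers_per_bait) break
    if (all(abs(start[i] - start[sel]) >= product_max))
      sel <- c(sel, i)
  }
  sel
}

#' Write InDel blocks to TSV
#'
#' One row per block: chrom, ref_start (1-based, genome coordinates when
#' `offset` is given), ref_end, per-member allele-length columns, tier and
#' gap.
#' @param blocks List of `indel_block`s.
#' @param calls Matching `diagnostic_call`s.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @param offset Genome coordinate of bait position 1 minus one.
#' @export
write_block_table <- function(blocks, calls, path, chrom = "chr01",
                              offset = 0L) {
  if (!length(blocks)) {
    writeLines("chrom\tref_start\tref_end\ttier\tgap_bp", path)
    return(invisible(path))
  }
  members <- names(blocks[[1]]$allele_len)
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    cbind(data.frame(chrom = chrom,
                     ref_start = b$ref_start + offset,
                     ref_end = b$ref_end + offset,
                     tier = calls[[i]]$tier,
                     gap_bp = calls[[i]]$gap_bp,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(b$allele_len[members])))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
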
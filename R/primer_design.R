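#' Conserved flank windows around an InDel block
#'
#' Scans the MSA columns within `search_span` bp on each side of the block
#' for maximal windows where every member present matches the reference
#' base (at most `max_mismatch_columns` non-reference characters per
#' column; gaps and member insertions always disqualify a column). Primers
#' restricted to such windows anneal to every member, giving even PCR
#' amplification across the panel.
#'
#' @param msa An `anchored_msa`.
#' @param block An `indel_block`.
#' @param search_span How far from the block to search (default
#'   `product_max / 2` = 250 bp).
#' @param max_mismatch_columns Maximum members allowed to mismatch the
#'   reference in a column (default 0).
#' @param bait_mask Optional logical vector marking soft-masked bait
#'   positions (excluded from windows).
#' @return A list with `left` and `right`: data frames of maximal
#'   conserved windows (`start`, `end`, 1-based bait coordinates).
#' @export
conserved_flank_windows <- function(msa, block, search_span = 250,
                                    max_mismatch_columns = 0,
                                    bait_mask = NULL) {
  n <- nchar(msa$bait_seq)
  bait_chars <- strsplit(msa$bait_seq, "")[[1]]
  conserved <- conserved_columns(msa, max_mismatch_columns)
  if (!is.null(bait_mask)) conserved <- conserved & !bait_mask[seq_len(n)]
  conserved <- conserved & bait_chars != "N"
  left_rng <- c(max(1L, block$ref_start - as.integer(search_span)),
                block$ref_start - 1L)
  right_rng <- c(block$ref_end + 1L,
                 min(n, block$ref_end + as.integer(search_span)))
  list(left = maximal_runs(conserved, left_rng),
       right = maximal_runs(conserved, right_rng))
}

# logical vector over bait columns: TRUE where <= max_mm members differ
# from the reference and none has a gap or an anchored insertion
conserved_columns <- function(msa, max_mm = 0) {
  n <- nchar(msa$bait_seq)
  bait_raw <- charToRaw(msa$bait_seq)
  mm <- integer(n)
  bad <- logical(n)
  for (mem in msa$members) {
    pr <- charToRaw(mem$proj)
    gap <- pr == charToRaw("-")
    mm <- mm + as.integer(pr != bait_raw & !gap)
    bad <- bad | gap
    if (nrow(mem$ins)) {
      p <- mem$ins$ref_pos
      bad[pmax(p, 1L)] <- TRUE            # column left of the insertion
      bad[pmin(p + 1L, n)] <- TRUE        # and right: no primer spans it
    }
  }
  mm <= max_mm & !bad
}

maximal_runs <- function(flag, rng) {
  if (rng[2] < rng[1])
    return(data.frame(start = integer(0), end = integer(0)))
  v <- flag[rng[1]:rng[2]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep] + rng[1] - 1L,
             end = ends[keep] + rng[1] - 1L)
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# NOTE: TA and AT differ in dS; the table above keeps each orientation's
# published value (AT/AT -20.4, TA/TA -21.3). Reverse complements share
# entries, so Tm(seq) = Tm(revcomp(seq)).
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor thermodynamics (SantaLucia 1998) at 50 mM
#' monovalent salt and 0.25 uM oligo (the PCR recipe's primer
#' concentration), with the entropic salt correction
#' `dS + 0.368 (N-1) ln[Na+]`. Deterministic.
#'
#' @param primer_seq Primer sequence, A/C/G/T only, length >= 10.
#' @param Na Monovalent cation concentration in M (default 0.05).
#' @param conc_uM Oligo concentration in uM (default 0.25).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temp("ACGTACGTACGTACGTACGT")
#' @export
melting_temp <- function(primer_seq, Na = 0.05, conc_uM = 0.25) {
  L <- nchar(primer_seq)
  if (L < 10) stop("primer shorter than 10 nt", call. = FALSE)
  if (grepl("[^ACGT]", primer_seq))
    stop("ambiguity code in primer: ", primer_seq, call. = FALSE)
  di <- substring(primer_seq, 1:(L - 1), 2:L)
  dH <- sum(NN_DH[di])
  dS <- sum(NN_DS[di])
  ends <- substring(primer_seq, c(1, L), c(1, L))
  for (e in ends) {
    init <- if (e %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  selfc <- identical(primer_seq, revcomp(primer_seq))
  if (selfc) dS <- dS - 1.4
  dS <- dS + 0.368 * (L - 1) * log(Na)
  R <- 1.9872
  ct <- conc_uM * 1e-6
  x <- if (selfc) 1 else 4
  dH * 1000 / (dS + R * log(ct / x)) - 273.15
}

has_homopolymer <- function(seq, len = 5) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", len, len, len, len), seq)
}

three_prime_in_homopolymer <- function(seq) {
  # last base part of a run of >= 3 identical bases at the 3' terminus
  L <- nchar(seq)
  L >= 3 && substr(seq, L, L) == substr(seq, L - 1, L - 1) &&
    substr(seq, L, L) == substr(seq, L - 2, L - 2)
}

gc_fraction <- function(seq) {
  nchar(gsub("[^GC]", "", seq)) / nchar(seq)
}

# TRUE when the 3'-terminal complementarity between s1 and s2 exceeds
# max_len: i.e. the reverse complement of s1's 3'-terminal (max_len + 1)
# bases occurs in s2
three_prime_complementarity_over <- function(s1, s2, max_len = 4) {
  tail_len <- max_len + 1
  if (nchar(s1) < tail_len) return(FALSE)
  tail3 <- substr(s1, nchar(s1) - tail_len + 1, nchar(s1))
  grepl(revcomp(tail3), s2, fixed = TRUE)
}

primer_candidates <- function(msa, windows, side, block, config) {
  lens <- seq(config$primer_len_range[1], config$primer_len_range[2])
  ss <- integer(0); ee <- integer(0)
  for (w in seq_len(nrow(windows))) {
    ws <- windows$start[w]; we <- windows$end[w]
    for (len in lens) {
      if (we - ws + 1 < len) next
      s <- seq.int(ws, we - len + 1)
      ss <- c(ss, s); ee <- c(ee, s + len - 1L)
    }
  }
  if (!length(ss)) return(list())
  site <- substring(msa$bait_seq, ss, ee)
  primer <- if (side == "left") site else vapply(site, revcomp, character(1),
                                                 USE.NAMES = FALSE)
  keep <- !grepl("[^ACGT]", primer) &
    !has_homopolymer(primer) &
    !vapply(primer, three_prime_in_homopolymer, logical(1),
            USE.NAMES = FALSE)
  gc <- nchar(gsub("[^GC]", "", primer)) / nchar(primer)
  keep <- keep & gc >= 0.30 & gc <= 0.70
  if (!any(keep)) return(list())
  idx <- which(keep)
  out <- list()
  for (i in idx) {
    tm <- melting_temp(primer[i])
    if (tm < config$primer_tm_window_c[1] ||
        tm > config$primer_tm_window_c[2]) next
    if (three_prime_complementarity_over(primer[i], primer[i])) next
    out[[length(out) + 1L]] <-
      list(start = ss[i], end = ee[i], seq = primer[i], tm = tm)
  }
  out
}

#' Design a primer pair around a selected InDel block
#'
#' Enumerates candidate primers in the conserved flank windows (length and
#' Tm windows from the configuration; no homopolymer run of 5, 3' end not
#' in a homopolymer, GC between 30 and 70\%, 3'-terminal
#' self/cross-complementarity of at most 4 bp) and picks the pair whose
#' longest-allele product is closest to 300 bp, subject to every member's
#' product lying within `[product_min, product_max]` and the primers' Tm
#' difference being at most 3 degrees C. Ties break deterministically on
#' (forward start, reverse start, forward length, reverse length).
#'
#' @param msa An `anchored_msa`.
#' @param block An `indel_block` extracted from it.
#' @param config A [pipeline_config()].
#' @param bait_mask Optional soft-mask logical vector for the bait.
#' @return A `primer_pair` (fields `fwd_seq`, `rev_seq`, `fwd_start`,
#'   `fwd_end`, `rev_start`, `rev_end`, `tm_f`, `tm_r`,
#'   `product_len_by_member`, `product_ref`), or a
#'   `primer_design_failure` whose `reason` element is one of
#'   `"no_conserved_flank"`, `"no_feasible_primer"`, `"product_bounds"`,
#'   `"no_tm_compatible_pair"`.
#' @export
design_primer_pair <- function(msa, block, config = pipeline_config(),
                               bait_mask = NULL) {
  windows <- conserved_flank_windows(msa, block,
                                     search_span = config$product_max / 2,
                                     bait_mask = bait_mask)
  fail <- function(reason) {
    structure(list(reason = reason), class = "primer_design_failure")
  }
  if (!nrow(windows$left) || !nrow(windows$right))
    return(fail("no_conserved_flank"))
  fwd <- primer_candidates(msa, windows$left, "left", block, config)
  rev <- primer_candidates(msa, windows$right, "right", block, config)
  if (!length(fwd) || !length(rev)) return(fail("no_feasible_primer"))
  cum <- member_cumlen(msa)
  f_start <- vapply(fwd, `[[`, integer(1), "start")
  r_end <- vapply(rev, `[[`, integer(1), "end")
  r_start <- vapply(rev, `[[`, integer(1), "start")
  f_tm <- vapply(fwd, `[[`, numeric(1), "tm")
  r_tm <- vapply(rev, `[[`, numeric(1), "tm")
  # the objective |longest product - 300| depends only on (fwd start,
  # rev end); enumerate those, then expand primer combinations lazily in
  # increasing-objective order with the documented deterministic tie order
  fs_u <- sort(unique(f_start))
  re_u <- sort(unique(r_end))
  feas <- list()
  any_product_ok <- FALSE
  for (fs in fs_u) {
    prod_ref <- re_u - fs + 1L
    ok <- prod_ref >= config$product_min & prod_ref <= config$product_max
    if (!any(ok)) next
    re_ok <- re_u[ok]
    maxprod <- prod_ref[ok]
    good <- rep(TRUE, length(re_ok))
    for (cc in cum) {
      pm <- cc[re_ok + 1L] - cc[fs]
      good <- good & pm >= config$product_min & pm <= config$product_max
      maxprod <- pmax(maxprod, pm)
    }
    if (!any(good)) next
    any_product_ok <- TRUE
    feas[[length(feas) + 1L]] <-
      data.frame(fs = fs, re = re_ok[good],
                 obj = abs(maxprod[good] - 300))
  }
  if (!length(feas)) return(fail("product_bounds"))
  feas <- do.call(rbind, feas)
  feas <- feas[order(feas$obj, feas$fs, feas$re), , drop = FALSE]
  best <- NULL
  for (row in seq_len(nrow(feas))) {
    fs <- feas$fs[row]; re <- feas$re[row]
    fis <- which(f_start == fs)
    ris <- which(r_end == re)
    fis <- fis[order(f_start[fis] + 0, vapply(fwd[fis], function(x)
      x$end - x$start, integer(1)))]
    ris <- ris[order(r_start[ris], vapply(rev[ris], function(x)
      x$end - x$start, integer(1)))]
    for (fi in fis) {
      for (ri in ris) {
        if (abs(f_tm[fi] - r_tm[ri]) > 3) next
        if (three_prime_complementarity_over(fwd[[fi]]$seq, rev[[ri]]$seq) ||
            three_prime_complementarity_over(rev[[ri]]$seq, fwd[[fi]]$seq))
          next
        best <- list(fi = fi, ri = ri, obj = feas$obj[row])
        break
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    return(fail(if (any_product_ok) "no_tm_compatible_pair" else "product_bounds"))
  f <- fwd[[best$fi]]; r <- rev[[best$ri]]
  prods <- c(r$end - f$start + 1L,
             vapply(cum, function(cc) cc[r$end + 1L] - cc[f$start], numeric(1)))
  names(prods) <- c(msa$bait_id, names(cum))
  structure(list(fwd_seq = f$seq, rev_seq = r$seq,
                 fwd_start = f$start, fwd_end = f$end,
                 rev_start = r$start, rev_end = r$end,
                 tm_f = f$tm, tm_r = r$tm,
                 product_len_by_member = setNames(as.integer(prods)[-1],
                                                  names(prods)[-1]),
                 product_ref = as.integer(prods[[1]])),
            class = "primer_pair")
}

# per member: cumulative count of member bases up to and including bait
# column j (index j + 1; index 1 is column 0), insertions included
member_cumlen <- function(msa) {
  n <- nchar(msa$bait_seq)
  lapply(msa$members, function(mem) {
    present <- as.integer(strsplit(mem$proj, "")[[1]] != "-")
    cc <- c(0, cumsum(present))
    if (nrow(mem$ins)) {
      for (k in seq_len(nrow(mem$ins))) {
        idx <- (mem$ins$ref_pos[k] + 1L):(n + 1L)
        cc[idx] <- cc[idx] + nchar(mem$ins$seq[k])
      }
    }
    cc
  })
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("Primer pair: F %s (%.1f C) / R %s (%.1f C), ref product %d bp\n",
              x$fwd_seq, x$tm_f, x$rev_seq, x$tm_r, x$product_ref))
  invisible(x)
}

#' Genome-wide primer uniqueness by exact string scan
#'
#' Counts exact occurrences of each primer and of its reverse complement
#' over all chromosomes of the reference; the pair is `"unique"` iff each
#' primer's total count is exactly one (its design site).
#'
#' @param primer_pair A `primer_pair`.
#' @param reference A [genome_assembly()].
#' @return `"unique"` or `"multi"`.
#' @export
uniqueness_check <- function(primer_pair, reference) {
  subject <- Biostrings::DNAStringSet(unname(reference$chromosomes))
  count_both <- function(p) {
    pat <- Biostrings::DNAString(p)
    sum(Biostrings::vcountPattern(pat, subject)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subject))
  }
  ok <- count_both(primer_pair$fwd_seq) == 1L &&
        count_both(primer_pair$rev_seq) == 1L
  if (ok) "unique" else "multi"
}

#' Marker nomenclature
#'
#' Encodes a marker location as `"A" + 2-digit chromosome + "P" + 5-digit
#' kb position`: genome type A, chromosome number, physical position in kb
#' (rounded to the nearest kb). `A01P00302` sits at 0.302 Mb on
#' chromosome 1.
#'
#' @param chromosome_index Integer in 1..99.
#' @param ref_position_bp Non-negative 1-based position in bp.
#' @return Marker name string.
#' @examples
#' name_marker(1, 302000)    # "A01P00302"
#' name_marker(12, 27058000) # "A12P27058"
#' @export
name_marker <- function(chromosome_index, ref_position_bp) {
  if (chromosome_index < 1 || chromosome_index > 99)
    stop("chromosome index must be in 1..99", call. = FALSE)
  if (ref_position_bp < 0) stop("position must be >= 0", call. = FALSE)
  kb <- floor(ref_position_bp / 1000 + 0.5)  # round half up, deterministic
  if (kb >= 1e5) stop("kb position >= 100,000 cannot be encoded", call. = FALSE)
  sprintf("A%02dP%05d", as.integer(chromosome_index), as.integer(kb))
}

#' @rdname name_marker
#' @param name A marker name such as `"A01P00302"`.
#' @return `decode_marker_name()` returns a list with `chromosome_index`
#'   and `kb`.
#' @export
decode_marker_name <- function(name) {
  if (!grepl("^A[0-9]{2}P[0-9]{5}$", name))
    stop("not a valid marker name: ", name, call. = FALSE)
  list(chromosome_index = as.integer(substr(name, 2, 3)),
       kb = as.integer(substr(name, 5, 9)))
}
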
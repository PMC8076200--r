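test_that("conserved flank windows follow a direct column scan", {
  set.seed(71)
  bait <- rand_seq(1200)
  # member 1 identical; member 2 with one SNP at 400 and a 5-bp gap at 800
  snp_at <- function(s, p) {
    b <- substr(s, p, p)
    paste0(substr(s, 1, p - 1), setdiff(c("A", "C", "G", "T"), b)[1],
           substr(s, p + 1, nchar(s)))
  }
  m1 <- bait
  m2 <- snp_at(bait, 400)
  m2 <- paste0(substr(m2, 1, 799), substr(m2, 805, nchar(m2)))
  msa <- project_to_msa("ref", bait, list(
    m1 = align_to_bait(bait, m1, band_width = 60, query_id = "m1"),
    m2 = align_to_bait(bait, m2, band_width = 60, query_id = "m2")))
  block <- structure(list(ref_start = 600L, ref_end = 601L, ref_len = 2L,
                          allele_len = c(ref = 2L), max_gap = 30L),
                     class = "indel_block")
  w <- conserved_flank_windows(msa, block, search_span = 250)
  # left windows stop at the SNP column (gap placement may shift within
  # the deletion's homopolymer context, so check the right side coarsely)
  expect_false(any(w$left$start <= 400 & w$left$end >= 400))
  expect_true(any(w$left$start >= 401))
  expect_true(all(w$right$start >= 602))
  gap_cols <- which(strsplit(msa$members$m2$proj, "")[[1]] == "-")
  expect_true(all(gap_cols %in% 795:805))  # the planted 5-bp gap, left-shifted
  expect_false(any(vapply(seq_len(nrow(w$right)), function(i)
    any(gap_cols >= w$right$start[i] & gap_cols <= w$right$end[i]),
    logical(1))))
  # fully conserved flanks span the whole searched region
  msa0 <- project_to_msa("ref", bait, list(
    m1 = align_to_bait(bait, bait, band_width = 60, query_id = "m1")))
  w0 <- conserved_flank_windows(msa0, block, search_span = 250)
  expect_equal(nrow(w0$left), 1)
  expect_equal(w0$left$start, 350)
  expect_equal(w0$left$end, 599)
})

test_that("melting temperature is deterministic, GC-monotone and strand-symmetric", {
  expect_lt(melting_temp(strrep("A", 18)), melting_temp(strrep("GC", 9)))
  set.seed(72)
  for (i in 1:20) {
    s <- rand_seq(20)
    expect_equal(melting_temp(s), melting_temp(revcomp(s)), tolerance = 1e-9)
  }
  expect_error(melting_temp("ACGTACGTN"), "shorter|ambiguity")
  expect_error(melting_temp("ACGTACGTACGN"), "ambiguity")
})

test_that("melting temperature matches a hand-summed nearest-neighbor example", {
  # 5'-AGCGTATCCAGT-3'. Unified NN dH (kcal/mol) and dS (cal/mol/K) terms,
  # summed longhand: init 5'A (2.3, 4.1) + init 3'T (2.3, 4.1) +
  # AG(-7.8,-21.0) GC(-9.8,-24.4) CG(-10.6,-27.2) GT(-8.4,-22.4)
  # TA(-7.2,-21.3) AT(-7.2,-20.4) TC(-8.2,-22.2) CC(-8.0,-19.9)
  # CA(-8.5,-22.7) AG(-7.8,-21.0) GT(-8.4,-22.4)
  dH <- 2.3 + 2.3 - 7.8 - 9.8 - 10.6 - 8.4 - 7.2 - 7.2 - 8.2 - 8.0 - 8.5 -
    7.8 - 8.4
  dS <- 4.1 + 4.1 - 21.0 - 24.4 - 27.2 - 22.4 - 21.3 - 20.4 - 22.2 - 19.9 -
    22.7 - 21.0 - 22.4
  dS_salt <- dS + 0.368 * (12 - 1) * log(0.05)
  tm_expect <- dH * 1000 / (dS_salt + 1.9872 * log(0.25e-6 / 4)) - 273.15
  expect_equal(melting_temp("AGCGTATCCAGT"), tm_expect, tolerance = 0.1)
})

test_that("designed pairs reproduce the planted product-size geometry", {
  set.seed(73)
  cfg <- pipeline_config()
  bait <- rand_seq(3000)
  del40 <- paste0(substr(bait, 1, 1499), substr(bait, 1540, 3000))
  ids <- c("Cult_A02", "W1", "W2", "W3", "W4")
  alignments <- lapply(setNames(ids, ids), function(id)
    align_to_bait(bait, if (id == "Cult_A02") bait else del40,
                  band_width = 100, query_id = id))
  msa <- project_to_msa("Cult_A01", bait, alignments)
  block <- extract_indel_blocks(msa, 20)[[1]]
  pair <- design_primer_pair(msa, block, cfg)
  expect_s3_class(pair, "primer_pair")
  expect_lte(abs(pair$tm_f - pair$tm_r), 3)
  expect_true(all(c(pair$product_ref, pair$product_len_by_member) >=
                    cfg$product_min))
  expect_true(all(c(pair$product_ref, pair$product_len_by_member) <=
                    cfg$product_max))
  # carriers are exactly 40 bp shorter than non-carriers
  expect_equal(unname(pair$product_ref - pair$product_len_by_member[["W1"]]), 40)
  expect_equal(unname(pair$product_len_by_member[["Cult_A02"]]),
               pair$product_ref)
  # primer sites never overlap the block
  expect_lt(pair$fwd_end, block$ref_start)
  expect_gt(pair$rev_start, block$ref_end)
  # determinism
  pair2 <- design_primer_pair(msa, block, cfg)
  expect_identical(pair[c("fwd_seq", "rev_seq", "fwd_start", "rev_start")],
                   pair2[c("fwd_seq", "rev_seq", "fwd_start", "rev_start")])
})

test_that("design failures carry machine-readable reasons", {
  set.seed(74)
  cfg <- pipeline_config()
  # block right at the bait edge: too little flank for any legal product
  bait <- rand_seq(320)
  del40 <- paste0(substr(bait, 1, 9), substr(bait, 50, 320))
  msa <- project_to_msa("Cult_A01", bait, list(
    W1 = align_to_bait(bait, del40, band_width = 80, query_id = "W1")))
  block <- extract_indel_blocks(msa, 20)[[1]]
  res <- design_primer_pair(msa, block, cfg)
  expect_s3_class(res, "primer_design_failure")
  expect_true(res$reason %in% c("product_bounds", "no_feasible_primer",
                                "no_conserved_flank"))
  # every fourth flank column polymorphic: no 18-mer conserved window
  set.seed(75)
  bait2 <- rand_seq(2000)
  b2 <- strsplit(bait2, "")[[1]]
  hit <- seq(4, 2000, by = 4)
  b2[hit] <- vapply(b2[hit], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  noisy <- paste(b2, collapse = "")
  del <- paste0(substr(noisy, 1, 999), substr(noisy, 1040, nchar(noisy)))
  msa2 <- project_to_msa("Cult_A01", bait2, list(
    W1 = align_to_bait(bait2, del, band_width = 150, query_id = "W1")))
  blocks2 <- extract_indel_blocks(msa2, 20)
  big <- blocks2[[which.max(vapply(blocks2, `[[`, integer(1), "max_gap"))]]
  res2 <- design_primer_pair(msa2, big, cfg)
  expect_s3_class(res2, "primer_design_failure")
  # conserved runs of at most 3 columns cannot host an 18-mer primer
  expect_true(res2$reason %in% c("no_conserved_flank", "no_feasible_primer"))
})

test_that("uniqueness check counts exact occurrences on both strands", {
  set.seed(76)
  g <- rand_seq(50000)
  fwd <- substr(g, 10001, 10020)
  rev <- revcomp(substr(g, 10301, 10320))
  ref <- genome_assembly(c(chr01 = g), "ref", "r", "other", validate = FALSE)
  pair <- structure(list(fwd_seq = fwd, rev_seq = rev), class = "primer_pair")
  expect_equal(uniqueness_check(pair, ref), "unique")
  # plant a minus-strand copy of the forward primer elsewhere
  g2 <- paste0(g, revcomp(fwd))
  ref2 <- genome_assembly(c(chr01 = g2), "ref2", "r", "other",
                          validate = FALSE)
  expect_equal(uniqueness_check(pair, ref2), "multi")
  # a mutated copy is not an exact occurrence: still unique
  mut <- paste0("T", substr(fwd, 2, 20))
  g3 <- paste0(g, mut)
  ref3 <- genome_assembly(c(chr01 = g3), "ref3", "r", "other",
                          validate = FALSE)
  expect_equal(uniqueness_check(pair, ref3),
               if (identical(substr(fwd, 1, 1), "T")) "multi" else "unique")
})

test_that("marker names encode and decode chromosome and kb position", {
  expect_equal(name_marker(1, 302000), "A01P00302")
  expect_equal(name_marker(12, 27058000), "A12P27058")
  expect_equal(name_marker(10, 0), "A10P00000")
  expect_error(name_marker(1, 1e8), "cannot be encoded")
  expect_error(name_marker(100, 1000), "1..99")
  set.seed(77)
  for (i in 1:50) {
    chrom <- sample(1:12, 1); pos <- sample(0:4e7, 1)
    dec <- decode_marker_name(name_marker(chrom, pos))
    expect_equal(dec$chromosome_index, chrom)
    expect_equal(dec$kb, floor(pos / 1000 + 0.5))
  }
  expect_error(decode_marker_name("B01P00302"), "not a valid")
})
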
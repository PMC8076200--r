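test_that("binding sites follow the mismatch and 3'-exact rules", {
  set.seed(81)
  primer <- rand_seq(20)
  seq <- paste0(rand_seq(500), primer, rand_seq(500))
  hits <- find_binding_sites(primer, seq)
  expect_true(any(hits$position == 501 & hits$strand == "+"))
  # one mismatch at the 3'-terminal base abolishes the site
  mut3 <- paste0(substr(primer, 1, 19),
                 setdiff(c("A", "C", "G", "T"), substr(primer, 20, 20))[1])
  seq2 <- paste0(rand_seq(500), mut3, rand_seq(500))
  hits2 <- find_binding_sites(primer, seq2)
  expect_false(any(hits2$position == 501 & hits2$strand == "+"))
  # two internal mismatches are tolerated, three are not
  mm2 <- primer
  substr(mm2, 3, 3) <- setdiff(c("A","C","G","T"), substr(primer, 3, 3))[1]
  substr(mm2, 9, 9) <- setdiff(c("A","C","G","T"), substr(primer, 9, 9))[1]
  seq3 <- paste0(rand_seq(100), mm2, rand_seq(100))
  expect_true(any(find_binding_sites(primer, seq3)$position == 101))
  mm3 <- mm2
  substr(mm3, 13, 13) <- setdiff(c("A","C","G","T"), substr(primer, 13, 13))[1]
  seq4 <- paste0(rand_seq(100), mm3, rand_seq(100))
  expect_false(any(find_binding_sites(primer, seq4)$position == 101 &
                   find_binding_sites(primer, seq4)$strand == "+"))
})

test_that("site finder equals a position-by-position brute force on 50 seeded sequences", {
  set.seed(82)
  for (i in 1:50) {
    seq <- rand_seq(10000)
    primer <- if (i %% 2 == 0) rand_seq(20) else
      substr(seq, 4000, 4019)  # guarantee some hits
    got <- find_binding_sites(primer, seq)
    exp <- oracle_binding_sites(primer, seq)
    got <- got[order(got$strand, got$position), ]
    exp <- exp[order(exp$strand, exp$position), ]
    expect_equal(got$position, exp$position)
    expect_equal(got$strand, exp$strand)
  }
})

test_that("amplicons pair forward-plus with reverse-minus sites", {
  set.seed(83)
  cfg <- pipeline_config()
  fwd <- rand_seq(20); rev <- rand_seq(20)
  insert <- rand_seq(300)
  seq <- paste0(rand_seq(400), fwd, insert, revcomp(rev), rand_seq(400))
  pair <- structure(list(fwd_seq = fwd, rev_seq = rev), class = "primer_pair")
  amps <- predict_amplicons(pair, seq, cfg)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$length, 20 + 300 + 20)
  # forward site alone yields nothing
  seq_f <- paste0(rand_seq(400), fwd, rand_seq(400))
  expect_equal(nrow(predict_amplicons(pair, seq_f, cfg)), 0)
  # a duplicated target locus yields two amplicons (extra-band precursor);
  # the spacer keeps cross-pairings beyond the e-PCR product ceiling
  seq_dup <- paste0(seq, rand_seq(2000), substr(seq, 301, nchar(seq) - 300))
  expect_equal(nrow(predict_amplicons(pair, seq_dup, cfg)), 2)
})

test_that("gel merging is idempotent, order-independent and threshold-true", {
  set.seed(84)
  expect_equal(merge_gel_bands(c(308, 300), 20), 304)
  expect_equal(merge_gel_bands(c(300, 340), 20), c(300, 340))
  for (i in 1:50) {
    x <- sample(100:500, sample(1:6, 1), replace = TRUE)
    m1 <- merge_gel_bands(x, 20)
    perm <- x[sample.int(length(x))]
    expect_equal(merge_gel_bands(perm, 20), m1)            # order-independent
    expect_equal(merge_gel_bands(m1, 20), m1)              # idempotent
    if (length(m1) > 1) expect_true(all(diff(m1) >= 20))
  }
})

test_that("heterozygous haplotypes produce two bands; small gaps merge to one", {
  set.seed(85)
  cfg <- pipeline_config()
  fwd <- rand_seq(20); rev <- rand_seq(20)
  mk_hap <- function(ins_len) paste0(rand_seq(300), fwd, rand_seq(260 + ins_len),
                                     revcomp(rev), rand_seq(300))
  hap1 <- mk_hap(0)
  hap2 <- paste0(substr(hap1, 1, 400), rand_seq(40), substr(hap1, 401, nchar(hap1)))
  acc <- genome_assembly(c(chr01 = hap1), "het", "h", "wild",
                         haplotype2 = c(chr01 = hap2), validate = FALSE)
  pair <- structure(list(fwd_seq = fwd, rev_seq = rev), class = "primer_pair")
  bs <- genotype_accession(pair, acc, cfg)
  expect_equal(bs$status, "ok")
  expect_length(bs$band_lengths, 2)
  expect_equal(diff(bs$band_lengths), 40)
  expect_equal(bs$two_band_cause, "heterozygous")
  # 8-bp difference is unresolvable on agarose: one merged band
  hap2b <- paste0(substr(hap1, 1, 400), rand_seq(8), substr(hap1, 401, nchar(hap1)))
  acc2 <- genome_assembly(c(chr01 = hap1), "het2", "h", "wild",
                          haplotype2 = c(chr01 = hap2b), validate = FALSE)
  bs2 <- genotype_accession(pair, acc2, cfg)
  expect_length(bs2$band_lengths, 1)
  expect_equal(bs2$band_lengths, 304)  # mean of 300 and 308
  # homozygous accession with one site: one band, no cause
  acc3 <- genome_assembly(c(chr01 = hap1), "hom", "h", "wild",
                          validate = FALSE)
  bs3 <- genotype_accession(pair, acc3, cfg)
  expect_length(bs3$band_lengths, 1)
  expect_equal(bs3$status, "ok")
  # no binding sites anywhere: no amplification
  acc4 <- genome_assembly(c(chr01 = rand_seq(2000)), "none", "h", "wild",
                          validate = FALSE)
  expect_equal(genotype_accession(pair, acc4, cfg)$status, "no_amplification")
})
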
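test_that("identical sequences align with identity 1 and score n * match", {
  set.seed(51)
  a <- rand_seq(1000)
  al <- align_to_bait(a, a, band_width = 60)
  expect_equal(al$score, 1000)
  expect_equal(al$identity, 1)
  expect_false(grepl("-", al$aligned_bait, fixed = TRUE))
  expect_false(grepl("-", al$aligned_query, fixed = TRUE))
})

test_that("a contiguous deletion stays one gap run and matches the oracle", {
  set.seed(52)
  a <- rand_seq(800)
  b <- paste0(substr(a, 1, 400), substr(a, 431, 800))  # 30-bp deletion
  al <- align_to_bait(a, b, band_width = 100)
  runs <- rle(strsplit(al$aligned_query, "")[[1]] == "-")
  expect_equal(sum(runs$values), 1)                  # exactly one gap run
  expect_equal(runs$lengths[runs$values], 30)
  expect_equal(al$score, oracle_align_score(a, b))
  # removing gaps recovers the originals
  expect_identical(gsub("-", "", al$aligned_bait), a)
  expect_identical(gsub("-", "", al$aligned_query), b)
})

test_that("banded scores equal the unbanded dynamic program on 50 seeded pairs", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(50:500, 1)
    a <- rand_seq(n)
    b <- if (i %% 3 == 0) {
      rand_seq(sample(50:500, 1))                     # unrelated pair
    } else {                                          # mutated copy
      ev <- evolve_genome(c(c1 = a), mutation_model(snp_rate = 0.05,
                                                    small_indel_rate = 0.01,
                                                    large_indel_rate = 0.002))
      ev$seqs[[1]]
    }
    if (nchar(b) < 1) next
    al <- align_to_bait(a, b, band_width = 500)
    expect_equal(al$score, oracle_align_score(a, b), tolerance = 1e-9)
  }
})

test_that("no alignment column is gap-in-both and free ends trim overhangs", {
  set.seed(54)
  a <- rand_seq(2000)
  q <- paste0(rand_seq(300), a, rand_seq(200))
  al <- align_to_bait(a, q, band_width = 60, free_query_ends = TRUE,
                      anchors = data.frame(bait_pos = c(1, 2000),
                                           qpos = c(301, 2300)))
  cols_a <- strsplit(al$aligned_bait, "")[[1]]
  cols_q <- strsplit(al$aligned_query, "")[[1]]
  expect_false(any(cols_a == "-" & cols_q == "-"))
  expect_equal(al$qstart, 301)
  expect_equal(al$qend, 2300)
  expect_equal(al$score, 2000)
  expect_identical(gsub("-", "", al$aligned_bait), a)
})

test_that("MSA projection is lossless and column count equals bait length", {
  set.seed(55)
  bait <- rand_seq(3000)
  model <- mutation_model(snp_rate = 0.01, small_indel_rate = 2e-3,
                          large_indel_rate = 5e-4)
  alignments <- list()
  originals <- list()
  for (id in c("m1", "m2", "m3")) {
    ev <- evolve_genome(c(c1 = bait), model)
    originals[[id]] <- ev$seqs[[1]]
    alignments[[id]] <- align_to_bait(bait, ev$seqs[[1]], band_width = 300,
                                      query_id = id)
  }
  msa <- project_to_msa("ref", bait, alignments)
  for (id in names(alignments)) {
    expect_identical(deproject_member(msa, id), originals[[id]])
    expect_equal(nchar(msa$members[[id]]$proj), nchar(bait))
    # inserted bases account for the length difference exactly
    del_bases <- sum(strsplit(msa$members[[id]]$proj, "")[[1]] == "-")
    ins_bases <- sum(nchar(msa$members[[id]]$ins$seq))
    expect_equal(nchar(originals[[id]]),
                 nchar(bait) - del_bases + ins_bases)
  }
})

test_that("planted deletion and insertion events are recovered at their loci", {
  set.seed(56)
  bait <- rand_seq(10000)
  del_member <- paste0(substr(bait, 1, 4999), substr(bait, 5040, 10000))
  ins_member <- paste0(substr(bait, 1, 7000), rand_seq(25),
                       substr(bait, 7001, 10000))
  msa <- project_to_msa("ref", bait, list(
    d = align_to_bait(bait, del_member, band_width = 100, query_id = "d"),
    i = align_to_bait(bait, ins_member, band_width = 100, query_id = "i")))
  dproj <- msa$members[["d"]]$proj
  gap_runs <- rle(strsplit(dproj, "")[[1]] == "-")
  expect_equal(gap_runs$lengths[gap_runs$values], 40)
  ins <- msa$members[["i"]]$ins
  expect_equal(nrow(ins), 1)
  expect_equal(nchar(ins$seq), 25)
  expect_lt(abs(ins$ref_pos - 7000), 30)  # left-shift within homopolymer slack
})

test_that("a bait row that does not match its bait is rejected", {
  al <- align_to_bait("ACGTACGTACGT", "ACGTACGTACGT", band_width = 12)
  expect_error(project_to_msa("ref", "TTTTTTTTTTTT", list(x = al)),
               "does not match")
})
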
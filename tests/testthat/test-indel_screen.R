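groups8 <- c(Cult_A01 = "cultivar_japonica", Cult_A02 = "cultivar_indica",
             W1 = "wild", W2 = "wild", W3 = "wild", W4 = "wild",
             W5 = "wild", W6 = "wild")

# build an MSA where the named members carry a deletion of `len` at `at`
planted_del_msa <- function(bait, carriers, members, at, len) {
  mut <- paste0(substr(bait, 1, at - 1), substr(bait, at + len, nchar(bait)))
  alignments <- lapply(setNames(members, members), function(id)
    align_to_bait(bait, if (id %in% carriers) mut else bait,
                  band_width = 100, query_id = id))
  project_to_msa("Cult_A01", bait, alignments)
}

test_that("no gaps means no blocks; planted deletions become one block", {
  set.seed(61)
  bait <- rand_seq(2000)
  members <- setdiff(names(groups8), "Cult_A01")
  msa0 <- planted_del_msa(bait, character(0), members, 1000, 40)
  expect_length(extract_indel_blocks(msa0, 20), 0)
  msa <- planted_del_msa(bait, c("W1", "W2", "W3"), members, 1000, 40)
  blocks <- extract_indel_blocks(msa, 20)
  expect_length(blocks, 1)
  b <- blocks[[1]]
  expect_equal(b$ref_len, 40)
  expect_setequal(unique(b$allele_len[c("W1", "W2", "W3")]), 0)
  expect_setequal(unique(b$allele_len[setdiff(names(b$allele_len),
                                              c("W1", "W2", "W3"))]), 40)
  expect_equal(b$max_gap, 40)
})

test_that("blocks below the gap threshold are excluded", {
  set.seed(62)
  bait <- rand_seq(2000)
  members <- setdiff(names(groups8), "Cult_A01")
  msa <- planted_del_msa(bait, "W1", members, 800, 15)
  expect_length(extract_indel_blocks(msa, 20), 0)
  expect_length(extract_indel_blocks(msa, 15), 1)
})

test_that("blocks are left-aligned against homopolymer context", {
  # bait has AAAA at 101-104; deleting 103-104 left-aligns to 101
  bait <- paste0(rand_seq(100), "AAAA", rand_seq(100))
  mut <- paste0(substr(bait, 1, 102), substr(bait, 105, nchar(bait)))
  # use a gap threshold of 2 to keep this miniature event
  msa <- project_to_msa("Cult_A01", bait,
                        list(W1 = align_to_bait(bait, mut, band_width = 50,
                                                query_id = "W1")))
  blocks <- extract_indel_blocks(msa, 2)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$ref_start, 101)
})

test_that("classify_diagnostic agrees with the all-pairs brute force", {
  set.seed(63)
  for (i in 1:200) {
    allele <- setNames(sample(c(0L, 10L, 25L, 40L), 8, TRUE), names(groups8))
    block <- structure(list(ref_start = 1L, ref_end = 40L, ref_len = 40L,
                            allele_len = allele,
                            max_gap = max(allele) - min(allele)),
                       class = "indel_block")
    call <- classify_diagnostic(block, groups8, 20)
    expect_equal(call$tier, oracle_classify(allele, groups8, 20))
    if (call$tier != "none") expect_gte(call$gap_bp, 20)
  }
})

test_that("classification handles missing members and degenerate groups", {
  allele_full <- setNames(c(0L, 0L, 45L, 45L, 45L, 45L, 45L, 45L),
                          names(groups8))
  block <- structure(list(ref_start = 1L, ref_end = 45L, ref_len = 45L,
                          allele_len = allele_full, max_gap = 45L),
                     class = "indel_block")
  call <- classify_diagnostic(block, groups8, 20)
  expect_equal(call$tier, "full")
  expect_equal(call$gap_bp, 45L)
  expect_setequal(call$discriminated_wild_members,
                  paste0("W", 1:6))
  # partial: one cultivar lineage differs, wild mixed
  allele_part <- setNames(c(0L, 0L, 0L, 30L, 0L, 30L, 0L, 30L), names(groups8))
  block$allele_len <- allele_part
  expect_equal(classify_diagnostic(block, groups8, 20)$tier, "partial")
  # identical lengths: none
  block$allele_len <- setNames(rep(10L, 8), names(groups8))
  expect_equal(classify_diagnostic(block, groups8, 20)$tier, "none")
  # missing wild members are excluded from the quantifier
  block$allele_len <- setNames(c(0L, 0L, 40L), c("Cult_A01", "Cult_A02", "W1"))
  expect_equal(classify_diagnostic(block, groups8, 20)$tier, "full")
  # no cultivar present: error
  block$allele_len <- setNames(c(0L, 40L), c("W1", "W2"))
  expect_error(classify_diagnostic(block, groups8, 20), "no cultivar")
})

test_that("marker selection ranks by tier then gap and enforces spacing", {
  mkblock <- function(start, gap) {
    allele <- setNames(c(0L, 0L, rep(gap, 6)), names(groups8))
    structure(list(ref_start = as.integer(start),
                   ref_end = as.integer(start + gap - 1),
                   ref_len = gap, allele_len = allele, max_gap = gap),
              class = "indel_block")
  }
  blocks <- list(mkblock(1000, 30), mkblock(5000, 60), mkblock(9000, 45))
  calls <- lapply(blocks, classify_diagnostic, groups8, 20)
  sel <- select_markers_per_bait(blocks, calls, max_markers_per_bait = 2,
                                 product_max = 500)
  expect_equal(sel, c(2L, 3L))  # two largest gaps among full-tier blocks
  # single partial block is still selected
  partial <- structure(list(ref_start = 100L, ref_end = 130L, ref_len = 31L,
                            allele_len = setNames(c(0L, 0L, 31L, rep(0L, 5)),
                                                  names(groups8)),
                            max_gap = 31L), class = "indel_block")
  pcall <- classify_diagnostic(partial, groups8, 20)
  expect_equal(pcall$tier, "partial")
  expect_equal(select_markers_per_bait(list(partial), list(pcall)), 1L)
  # spacing rule: two full blocks 150 bp apart -> only the better ranked
  close_blocks <- list(mkblock(1000, 30), mkblock(1150, 60))
  close_calls <- lapply(close_blocks, classify_diagnostic, groups8, 20)
  expect_equal(select_markers_per_bait(close_blocks, close_calls,
                                       max_markers_per_bait = 2,
                                       product_max = 500), 2L)
})
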
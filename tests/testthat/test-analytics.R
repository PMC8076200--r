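test_that("polymorphism calls respect the gel resolution threshold", {
  a <- make_band_cell(340); b <- make_band_cell(300)
  expect_equal(call_polymorphism(a, b, 20), "polymorphic")
  expect_equal(call_polymorphism(make_band_cell(310), b, 20), "monomorphic")
  expect_equal(call_polymorphism(a, make_band_cell(numeric(0),
                                                   "no_amplification"), 20),
               "not_evaluable")
})

toy_matrix <- function() {
  # 10 markers x (2 refs + 3 accessions): 7 with a 40-bp diagnostic
  # difference, 2 identical everywhere, 1 failing in 2 of 5 cells (40%)
  acc <- data.frame(accession_id = c("R1", "R2", "a1", "a2", "a3"),
                    species = c("cult", "cult", "w1", "w1", "w2"),
                    group_label = c("cultivar_japonica", "cultivar_indica",
                                    "wild", "wild", "wild"),
                    stringsAsFactors = FALSE)
  cells <- list()
  for (i in 1:7) {
    cells[[sprintf("m%02d", i)]] <- list(
      R1 = make_band_cell(300), R2 = make_band_cell(300),
      a1 = make_band_cell(340), a2 = make_band_cell(340),
      a3 = make_band_cell(340))
  }
  for (i in 8:9) {
    cells[[sprintf("m%02d", i)]] <- list(
      R1 = make_band_cell(250), R2 = make_band_cell(250),
      a1 = make_band_cell(250), a2 = make_band_cell(250),
      a3 = make_band_cell(250))
  }
  cells[["m10"]] <- list(
    R1 = make_band_cell(300), R2 = make_band_cell(300),
    a1 = make_band_cell(numeric(0), "no_amplification"),
    a2 = make_band_cell(c(100, 200, 400), "excess_bands"),
    a3 = make_band_cell(340))
  genotype_matrix(cells, acc, c("R1", "R2"))
}

test_that("marker categories partition into (7, 2, 1) on the constructed matrix", {
  v <- categorize_markers(toy_matrix())
  expect_equal(unname(v$totals), c(7, 2, 1))
  expect_equal(sum(v$totals), 10)
  expect_equal(v$records$category[v$records$marker == "m10"], "failed")
})

test_that("category partition holds on random matrices", {
  set.seed(91)
  acc <- data.frame(accession_id = c("R1", "a1", "a2"),
                    species = c("c", "w", "w"),
                    group_label = c("cultivar_indica", "wild", "wild"),
                    stringsAsFactors = FALSE)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    cells <- list()
    for (i in seq_len(n)) {
      cells[[sprintf("m%d", i)]] <- lapply(
        setNames(acc$accession_id, acc$accession_id), function(a) {
          if (runif(1) < 0.15)
            make_band_cell(numeric(0), "no_amplification", a)
          else make_band_cell(sample(c(300, 340, 400), 1), "ok", a)
        })
    }
    v <- categorize_markers(genotype_matrix(cells, acc, "R1"))
    expect_equal(sum(v$totals), n)
  }
})

test_that("published polymorphic-count analytics reproduce the printed arithmetic", {
  tab <- read.delim(table2_path(), stringsAsFactors = FALSE)
  aa <- tab[!grepl("japonica", tab$species), ]  # the 21 AA-genome accessions
  s <- summarize_polymorphism(setNames(aa$ir24_polymorphic, aa$accession))
  expect_equal(s$mean, 323.0)
  expect_equal(s$min, 187L)
  expect_equal(s$which_min, "Glum_A09")
  expect_equal(s$max, 391L)
  expect_equal(s$which_max, "Long_A11")
  expect_equal(summarize_polymorphism(c(x = 5))$mean, 5.0)
  expect_equal(summarize_polymorphism(c(a = 0, b = 0))$mean, 0.0)
})

test_that("validation rate and two-band frequencies round as printed", {
  expect_equal(validation_rate(541, 475), 87.8)
  expect_equal(validation_rate(10, 10), 100.0)
  expect_equal(validation_rate(10, 0), 0.0)
  expect_error(validation_rate(0, 0), "> 0")
  expect_equal(two_band_frequency(60, 475)$percent, 12.632)
  expect_equal(two_band_frequency(44, 475)$percent, 9.263)
  expect_equal(two_band_frequency(18, 475)$percent, 3.789)
  expect_equal(two_band_frequency(1, 475)$percent, 0.211)
  expect_equal(two_band_frequency(0, 475)$percent, 0.000)
})

test_that("species marker sets partition the union (inclusion-exclusion toy)", {
  acc <- data.frame(accession_id = c("R1", "s1", "s2", "s3"),
                    species = c("c", "w", "w", "w"),
                    group_label = c("cultivar_indica", "wild", "wild", "wild"),
                    stringsAsFactors = FALSE)
  # membership pattern over 5 markers: polymorphic in (3,3,2,1,0) accessions
  pattern <- list(m1 = c("s1", "s2", "s3"), m2 = c("s1", "s2", "s3"),
                  m3 = c("s1", "s2"), m4 = c("s3"), m5 = character(0))
  cells <- lapply(pattern, function(who) {
    out <- list(R1 = make_band_cell(300))
    for (a in c("s1", "s2", "s3"))
      out[[a]] <- make_band_cell(if (a %in% who) 360 else 300)
    out
  })
  m <- genotype_matrix(cells, acc, "R1")
  sets <- species_marker_sets(m, list(w = c("s1", "s2", "s3")), "R1")$w
  expect_setequal(sets$common3, c("m1", "m2"))
  expect_setequal(sets$common2, "m3")
  expect_setequal(sets$specific, "m4")
  expect_setequal(sets$union, c("m1", "m2", "m3", "m4"))
  expect_equal(length(sets$common3) + length(sets$common2) +
                 length(sets$specific), length(sets$union))
  # duplicate accession columns: specific and common2 empty
  cells_dup <- lapply(cells, function(cl) { cl$s2 <- cl$s1; cl$s3 <- cl$s1; cl })
  sets2 <- species_marker_sets(genotype_matrix(cells_dup, acc, "R1"),
                               list(w = c("s1", "s2", "s3")), "R1")$w
  expect_length(sets2$common2, 0)
  expect_length(sets2$specific, 0)
})

test_that("interval statistics compute per-chromosome gaps", {
  pos <- data.frame(chrom = c("chr01", "chr01", "chr01", "chr02"),
                    pos = c(3e5, 13e5, 23e5, 5e5))
  s <- interval_statistics(pos)
  expect_equal(s$mean_gap_kb, 1000.0)
  expect_equal(nrow(s$gaps), 2)              # chr02 has a single marker
  expect_equal(nrow(s$gaps_over_threshold), 0)
  s2 <- interval_statistics(data.frame(chrom = "chr01", pos = c(1e5, 26e5)))
  expect_equal(nrow(s2$gaps_over_threshold), 1)
})

test_that("progeny calls distinguish parental and heterozygous band patterns", {
  expect_equal(call_progeny_genotype(300, 340, c(300, 340)), "H")
  expect_equal(call_progeny_genotype(300, 340, 300), "A")
  expect_equal(call_progeny_genotype(300, 340, 340), "B")
  expect_equal(call_progeny_genotype(300, 340, 420), "failed")
  expect_equal(call_progeny_genotype(300, 305, c(300)), "not_evaluable")
})

test_that("introgression segments are maximal runs of non-recurrent calls", {
  calls <- data.frame(chrom = "chr01", pos = 1:5 * 1e6,
                      marker = sprintf("m%d", 1:5),
                      call = c("A", "A", "H", "H", "A"),
                      stringsAsFactors = FALSE)
  seg <- detect_introgressions(calls)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_marker, "m3")
  expect_equal(seg$end_marker, "m4")
  expect_equal(seg$n_markers, 2)
  expect_equal(seg$state, "H")
  # four isolated H calls on four chromosomes -> four one-marker segments
  calls4 <- data.frame(chrom = rep(sprintf("chr%02d", 1:4), each = 3),
                       pos = rep(1:3 * 1e6, 4),
                       marker = sprintf("m%d", 1:12),
                       call = rep(c("A", "H", "A"), 4),
                       stringsAsFactors = FALSE)
  seg4 <- detect_introgressions(calls4)
  expect_equal(nrow(seg4), 4)
  expect_true(all(seg4$n_markers == 1))
  # all recurrent: no segments
  calls0 <- transform(calls, call = "A")
  expect_equal(nrow(detect_introgressions(calls0)), 0)
})
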
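test_that("zero-rate evolution is the identity with empty truth", {
  set.seed(5)
  anc <- c(chr01 = rand_seq(5000))
  ev <- evolve_genome(anc, mutation_model())
  expect_identical(ev$seqs, anc)
  expect_equal(nrow(ev$edits), 0)
})

test_that("applying the truth list reproduces the evolved genome exactly", {
  set.seed(6)
  anc <- c(chr01 = rand_seq(50000), chr02 = rand_seq(30000))
  m <- mutation_model(snp_rate = 0.01, small_indel_rate = 1e-3,
                      large_indel_rate = 1e-4)
  for (rep in 1:5) {
    ev <- evolve_genome(anc, m)
    expect_identical(apply_edits(anc, ev$edits), ev$seqs)
  }
})

test_that("large-InDel counts follow the Poisson expectation", {
  set.seed(7)
  anc <- c(chr01 = rand_seq(2e5))
  r <- 2e-4
  counts <- replicate(20, {
    ev <- evolve_genome(anc, mutation_model(large_indel_rate = r))
    sum(ev$edits$type %in% c("del", "ins") &
        pmax(nchar(ev$edits$ref), nchar(ev$edits$alt)) >= 20)
  })
  lambda <- r * 2e5
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 20) + 2)
  # lengths respect the configured bounds
  ev <- evolve_genome(anc, mutation_model(large_indel_rate = r))
  lens <- pmax(nchar(ev$edits$ref), nchar(ev$edits$alt))
  expect_true(all(lens >= 20 & lens <= 150))
})

test_that("shift_positions lifts coordinates through indels", {
  edits <- data.frame(chrom = "chr01",
                      pos = c(100L, 500L, 900L),
                      type = c("del", "ins", "snp"),
                      ref = c(strrep("A", 30), "", "C"),
                      alt = c("", strrep("T", 10), "G"),
                      stringsAsFactors = FALSE)
  expect_equal(shift_positions(edits, "chr01", 50), 50L)
  expect_equal(shift_positions(edits, "chr01", 200), 170L)   # after the 30-bp del
  expect_equal(shift_positions(edits, "chr01", 600), 580L)   # del -30, ins +10
  expect_equal(shift_positions(edits, "chr01", 110), 100L)   # inside the deletion
  expect_equal(shift_positions(edits, "chr02", 42), 42L)
})

test_that("species panels are reproducible and respect heterozygosity settings", {
  p1 <- make_species_panel(n_wild_species = 2, accessions_per_species = 1,
                           n_chrom = 1, chrom_len = 1e5, seed = 42)
  p2 <- make_species_panel(n_wild_species = 2, accessions_per_species = 1,
                           n_chrom = 1, chrom_len = 1e5, seed = 42)
  expect_identical(p1$assemblies, p2$assemblies)
  expect_identical(p1$truth, p2$truth)
  # h = 0 everywhere: no second haplotype
  p0 <- make_species_panel(n_wild_species = 2, accessions_per_species = 1,
                           n_chrom = 1, chrom_len = 1e5,
                           h = 0, h_perennial = 0, seed = 43)
  expect_true(all(vapply(p0$assemblies, function(a)
    is.null(a$haplotype2), logical(1))))
  # elevated h on the perennial-like species produces more het edits
  ph <- make_species_panel(n_wild_species = 2, accessions_per_species = 1,
                           n_chrom = 1, chrom_len = 2e5,
                           h = 0.002, h_perennial = 0.05, seed = 44)
  het_n <- vapply(ph$truth$het_edits, function(e)
    if (is.null(e)) 0L else nrow(e), integer(1))
  perennial_acc <- names(ph$species_of)[ph$species_of == "wild_2"]
  expect_gt(min(het_n[perennial_acc]),
            max(het_n[setdiff(names(het_n), perennial_acc)]))
})

test_that("F1 constitution and backcross donor fractions follow Mendelian expectation", {
  p <- small_panel(seed = 21)
  rec <- p$assemblies[[1]]
  don <- p$assemblies[[3]]
  f1 <- simulate_cross(rec, don, n_backcrosses = 0, seed = 1)
  ind <- f1$individuals[[1]]
  expect_true(all(ind$hap1$origin == "recurrent"))
  expect_true(all(ind$hap2$origin == "donor"))
  expect_equal(donor_fraction(ind, f1$chrom_lengths), 0.5)
  # BC1 donor fraction approx 25% over 50 seeds
  fr <- vapply(1:50, function(s) {
    bc <- simulate_cross(rec, don, n_backcrosses = 1, seed = s)
    donor_fraction(bc$individuals[[1]], bc$chrom_lengths)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.25), 0.05)
  # truth segments tile each chromosome without overlap
  bc <- simulate_cross(rec, don, n_backcrosses = 2, seed = 9)
  hap <- bc$individuals[[1]]$hap2
  for (chrom in unique(hap$chrom)) {
    seg <- hap[hap$chrom == chrom, ]
    expect_equal(seg$start[1], 1L)
    expect_equal(seg$end[nrow(seg)], unname(bc$chrom_lengths[[chrom]]))
    if (nrow(seg) > 1)
      expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1L))
  }
})
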
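# Independent oracles used by the property tests. These deliberately use
# different algorithms/formulations than the package internals.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Unbanded affine-gap global alignment score by full dynamic programming
# (row-vectorised; gap of length g costs open + g * ext). Same state
# machine as the implementation: X consumes the first sequence (gap in b),
# Y consumes the second, switches between gap states re-open.
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               open = -6, ext = -0.2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  M <- rep(NEG, m + 1); X <- rep(NEG, m + 1); Y <- rep(NEG, m + 1)
  M[1] <- 0
  if (m >= 1) Y[2:(m + 1)] <- open + ext * (1:m)
  for (i in 1:n) {
    pM <- M; pX <- X; pY <- Y
    s <- ifelse(bv == av[i], match, mismatch)
    best_prev <- pmax(pM, pX, pY)
    M <- c(NEG, best_prev[1:m] + s)
    X <- pmax(pM + open + ext, pX + ext, pY + open + ext)
    # Y via running maximum: Y[j] = max_{k<j} max(M[k], X[k]) + open + ext*(j-k)
    A <- pmax(M, X) + open - ext * (0:m)
    Y <- c(NEG, cummax(A)[1:m] + ext * (1:m))
  }
  max(M[m + 1], X[m + 1], Y[m + 1])
}

# Position-by-position binding-site scan (mismatch count per offset,
# exact-region check), independent of the k-mer dispatch in the kernel.
oracle_scan <- function(pattern, seq, max_mm, tpe, right_exact = TRUE) {
  pc <- strsplit(pattern, "")[[1]]; sc <- strsplit(seq, "")[[1]]
  L <- length(pc); n <- length(sc)
  if (n < L) return(integer(0))
  starts <- seq_len(n - L + 1)
  mm <- integer(length(starts))
  exact_ok <- rep(TRUE, length(starts))
  acgt <- c("A", "C", "G", "T")
  for (j in seq_len(L)) {
    ch <- sc[starts + j - 1]
    bad <- ch != pc[j] | !(ch %in% acgt)
    mm <- mm + bad
    in_exact <- if (right_exact) j > L - tpe else j <= tpe
    if (in_exact) exact_ok <- exact_ok & !bad
  }
  starts[mm <= max_mm & exact_ok]
}

oracle_binding_sites <- function(primer, seq, max_mm = 2, tpe = 3) {
  plus <- oracle_scan(primer, seq, max_mm, tpe, right_exact = TRUE)
  minus <- oracle_scan(revcomp(primer), seq, max_mm, tpe, right_exact = FALSE)
  data.frame(position = c(plus, minus),
             strand = rep(c("+", "-"), c(length(plus), length(minus))),
             stringsAsFactors = FALSE)
}

# Brute-force genome-wide k-mer multiplicity of each window k-mer
# (forward strand), via exhaustive substring enumeration.
oracle_kmer_counts <- function(window, genome, k) {
  wk <- substring(window, 1:(nchar(window) - k + 1),
                  k:nchar(window))
  gk <- unlist(lapply(genome, function(s)
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
  tab <- table(gk)
  out <- as.integer(tab[wk])
  out[is.na(out)] <- 0L
  out
}

# Exhaustive all-pairs evaluation of the diagnostic quantifiers.
oracle_classify <- function(allele, groups, min_gap) {
  members <- intersect(names(allele), names(groups))
  cult <- members[startsWith(groups[members], "cultivar")]
  wild <- members[groups[members] == "wild"]
  if (!length(wild)) return("none")
  qual <- c()
  for (cc in cult) for (w in wild)
    qual <- c(qual, abs(allele[[cc]] - allele[[w]]) >= min_gap)
  if (all(qual)) "full" else if (any(qual)) "partial" else "none"
}

# One default species panel, built once and shared across test files
# (test_check runs them in a single session).
.fixture_env <- new.env()
shared_panel <- function() {
  if (is.null(.fixture_env$panel))
    .fixture_env$panel <- make_species_panel(seed = 101)
  .fixture_env$panel
}
shared_pipeline <- function() {
  if (is.null(.fixture_env$result)) {
    panel <- shared_panel()
    ref <- panel$assemblies[[panel$reference_id]]
    others <- panel$assemblies[names(panel$assemblies) != panel$reference_id]
    .fixture_env$result <- run_indel_pipeline(ref, others,
                                              pipeline_config(),
                                              verbose = FALSE)
  }
  .fixture_env$result
}

# A small fast panel for unit tests that only need structure, not scale.
small_panel <- function(seed = 11) {
  make_species_panel(n_wild_species = 3, accessions_per_species = 1,
                     n_chrom = 1, chrom_len = 4e5, seed = seed)
}

make_band_cell <- function(bands, status = "ok", id = "acc") {
  structure(list(accession_id = id, band_lengths = bands,
                 raw_amplicons = NULL, status = status,
                 two_band_cause = NA_character_),
            class = "band_set")
}

table2_path <- function() {
  system.file("extdata", "validation_panel_counts.tsv", package = "indelmark")
}
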
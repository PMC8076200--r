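#' Run the full InDel marker development pipeline
#'
#' Executes bait selection, ortholog extraction, anchored alignment, InDel
#' screening, primer design with uniqueness checks, in-silico PCR
#' genotyping of the whole panel and validation analytics, in order. One
#' log line per stage (with counts and timing) goes to `stderr` when
#' `verbose`.
#'
#' @param reference The reference [genome_assembly()] (a cultivar).
#' @param genomes Named list of the other panel [genome_assembly()]s.
#' @param config A [pipeline_config()].
#' @param verbose Emit stage logs to stderr.
#' @param genotype Run the in-silico PCR and analytics stages (default);
#'   `FALSE` stops after primer design (the `design` command-line step).
#' @return An `indel_pipeline_result`: `baits`, `ortholog_sets`,
#'   `rejections`, `screens` (per-bait blocks and diagnostic calls),
#'   `markers` (marker table data frame), `primer_pairs`,
#'   `design_failures`, `matrix` (the [genotype_matrix()]),
#'   `validation` (from [categorize_markers()]) and `summary`.
#' @export
run_indel_pipeline <- function(reference, genomes,
                               config = pipeline_config(),
                               verbose = TRUE, genotype = TRUE) {
  stopifnot(inherits(reference, "genome_assembly"))
  if (length(genomes) + 1 < config$min_ortholog_members)
    stop(sprintf("pipeline requires >= %d genomes including the reference, got %d",
                 config$min_ortholog_members, length(genomes) + 1),
         call. = FALSE)
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[indelmark] ", fmt), ...))
  }
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  baits <- select_bait_windows(reference, config)
  log_stage("baits: %d window(s) selected (%.1fs)", nrow(baits), tic() - t0)

  t0 <- tic()
  anchors_by_genome_bait <- lapply(genomes, function(g)
    .cpp_find_anchors_multi(baits$sequence, unname(g$chromosomes),
                            config$anchor_kmer))
  sets <- list(); rejections <- list()
  for (bi in seq_len(nrow(baits))) {
    bait <- as.list(baits[bi, ])
    anchors_by_genome <- lapply(anchors_by_genome_bait, `[[`, bi)
    res <- assemble_ortholog_set(bait, genomes, config, anchors_by_genome)
    key <- sprintf("%s:%d", bait$chrom, bait$start)
    if (inherits(res, "ortholog_set")) sets[[key]] <- res
    else rejections[[key]] <- res
  }
  log_stage("orthologs: %d set(s) accepted, %d rejected (%.1fs)",
            length(sets), length(rejections), tic() - t0)

  t0 <- tic()
  group_by_member <- c(setNames(reference$group_label, reference$accession_id),
                       vapply(genomes, `[[`, character(1), "group_label"))
  names(group_by_member) <- c(reference$accession_id,
                              vapply(genomes, `[[`, character(1), "accession_id"))
  screens <- list()
  markers_rows <- list(); primer_pairs <- list(); failures <- list()
  n_blocks_total <- 0
  for (key in names(sets)) {
    oset <- sets[[key]]
    alignments <- list()
    for (id in names(oset$hits)) {
      hit <- oset$hits[[id]]
      al <- tryCatch(
        align_to_bait(oset$bait$sequence, hit$sequence,
                      match = config$align_match,
                      mismatch = config$align_mismatch,
                      gap_open = config$align_gap_open,
                      gap_extend = config$align_gap_extend,
                      band_width = config$band_width,
                      anchors = hit$anchors,
                      free_query_ends = TRUE, query_id = id),
        error = function(e) NULL)
      if (!is.null(al)) alignments[[id]] <- al
    }
    if (length(alignments) + 1 < config$min_ortholog_members) {
      rejections[[key]] <- structure(
        list(bait = oset$bait, hits = oset$hits,
             reasons = c(stage = "alignment"),
             members = length(alignments) + 1L),
        class = "ortholog_rejection")
      next
    }
    msa <- project_to_msa(reference$accession_id, oset$bait$sequence,
                          alignments)
    blocks <- extract_indel_blocks(msa, config$min_gap_bp,
                                   config$merge_radius)
    n_blocks_total <- n_blocks_total + length(blocks)
    calls <- lapply(blocks, classify_diagnostic, group_by_member,
                    config$min_gap_bp)
    flank <- vapply(seq_along(blocks), function(i) {
      w <- conserved_flank_windows(msa, blocks[[i]],
                                   search_span = config$product_max / 2)
      lmax <- if (nrow(w$left)) max(w$left$end - w$left$start + 1) else 0
      rmax <- if (nrow(w$right)) max(w$right$end - w$right$start + 1) else 0
      min(lmax, rmax)
    }, numeric(1))
    sel <- select_markers_per_bait(blocks, calls, config$max_markers_per_bait,
                                   config$product_max, flank)
    screens[[key]] <- list(msa_members = names(alignments), blocks = blocks,
                           calls = calls, selected = sel)
    chrom <- oset$bait$chrom
    chrom_index <- chrom_number(chrom, names(reference$chromosomes))
    for (i in sel) {
      block <- blocks[[i]]
      abs_pos <- oset$bait$start + block$ref_start - 1L
      pair <- design_primer_pair(msa, block, config)
      if (!inherits(pair, "primer_pair")) {
        failures[[length(failures) + 1L]] <-
          data.frame(bait = key, block_pos = abs_pos,
                     reason = pair$reason, stringsAsFactors = FALSE)
        next
      }
      uniq <- uniqueness_check(pair, reference)
      if (uniq != "unique") {
        failures[[length(failures) + 1L]] <-
          data.frame(bait = key, block_pos = abs_pos,
                     reason = "primer_not_unique", stringsAsFactors = FALSE)
        next
      }
      nm <- name_marker(chrom_index, abs_pos)
      products <- paste(sprintf("%s=%d",
                                c(reference$accession_id,
                                  names(pair$product_len_by_member)),
                                c(pair$product_ref,
                                  pair$product_len_by_member)),
                        collapse = ";")
      markers_rows[[length(markers_rows) + 1L]] <-
        data.frame(name = nm, chrom = chrom, pos = abs_pos,
                   amp_start = oset$bait$start + pair$fwd_start - 1L,
                   amp_end = oset$bait$start + pair$rev_end - 1L,
                   block_start = abs_pos,
                   block_end = oset$bait$start + block$ref_end - 1L,
                   tier = calls[[i]]$tier, gap_bp = calls[[i]]$gap_bp,
                   fwd_seq = pair$fwd_seq, rev_seq = pair$rev_seq,
                   tm_f = round(pair$tm_f, 2), tm_r = round(pair$tm_r, 2),
                   product_ref = pair$product_ref, products = products,
                   uniqueness = uniq, stringsAsFactors = FALSE)
      primer_pairs[[nm]] <- pair
    }
  }
  markers <- if (length(markers_rows)) do.call(rbind, markers_rows) else
    empty_marker_table()
  design_failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(bait = character(0), block_pos = integer(0),
               reason = character(0))
  log_stage("screen+design: %d block(s), %d marker(s) named, %d failure(s) (%.1fs)",
            n_blocks_total, nrow(markers), nrow(design_failures), tic() - t0)

  t0 <- tic()
  assemblies <- c(setNames(list(reference), reference$accession_id), genomes)
  names(assemblies) <- vapply(assemblies, `[[`, character(1), "accession_id")
  matrix <- NULL; validation <- NULL; summary <- list()
  if (genotype && nrow(markers)) {
    cells <- epcr_genotype_all(primer_pairs, assemblies, config)
    acc_df <- data.frame(
      accession_id = names(assemblies),
      species = vapply(assemblies, `[[`, character(1), "species"),
      group_label = vapply(assemblies, `[[`, character(1), "group_label"),
      stringsAsFactors = FALSE, row.names = NULL)
    refs <- unique(c(reference$accession_id,
                     acc_df$accession_id[startsWith(acc_df$group_label,
                                                    "cultivar")]))
    refs <- refs[seq_len(min(2L, length(refs)))]
    matrix <- genotype_matrix(cells, acc_df, refs)
    validation <- categorize_markers(matrix, config$gel_resolution_bp)
    validated <- validation$records$marker[
      validation$records$category == "polymorphic"]
    pos_df <- markers[markers$name %in% validated, c("chrom", "pos")]
    summary <- list(
      n_designed = nrow(markers),
      n_validated = length(validated),
      validation_rate = validation_rate(nrow(markers), length(validated)),
      totals = validation$totals,
      interval = interval_statistics(pos_df))
  }
  log_stage("epcr+analytics: %s (%.1fs)",
            if (length(summary)) sprintf("%d/%d marker(s) validated polymorphic",
                                         summary$n_validated, summary$n_designed)
            else if (!genotype) "skipped" else "no markers designed",
            tic() - t0)

  structure(list(config = config, baits = baits,
                 ortholog_sets = sets, rejections = rejections,
                 screens = screens, markers = markers,
                 primer_pairs = primer_pairs,
                 design_failures = design_failures,
                 matrix = matrix, validation = validation,
                 summary = summary,
                 reference_id = reference$accession_id),
            class = "indel_pipeline_result")
}

empty_marker_table <- function() {
  data.frame(name = character(0), chrom = character(0), pos = integer(0),
             amp_start = integer(0), amp_end = integer(0),
             block_start = integer(0), block_end = integer(0),
             tier = character(0), gap_bp = integer(0),
             fwd_seq = character(0), rev_seq = character(0),
             tm_f = numeric(0), tm_r = numeric(0),
             product_ref = integer(0), products = character(0),
             uniqueness = character(0), stringsAsFactors = FALSE)
}

chrom_number <- function(chrom, chrom_names) {
  d <- regmatches(chrom, regexpr("[0-9]+", chrom))
  if (length(d) && nzchar(d)) as.integer(d) else match(chrom, chrom_names)
}

# Batched in-silico PCR of all markers against all accessions: one
# multi-pattern scan per (accession, haplotype, chromosome). Produces the
# same band sets as genotype_accession() marker by marker.
epcr_genotype_all <- function(primer_pairs, assemblies, config) {
  nm <- names(primer_pairs)
  patterns <- character(0); right <- logical(0)
  for (m in nm) {
    p <- primer_pairs[[m]]
    patterns <- c(patterns, p$fwd_seq, revcomp(p$rev_seq))
    right <- c(right, TRUE, FALSE)
  }
  rev_len <- vapply(nm, function(m) nchar(primer_pairs[[m]]$rev_seq),
                    integer(1))
  cells <- setNames(vector("list", length(nm)), nm)
  for (m in nm) cells[[m]] <- list()
  for (acc in names(assemblies)) {
    asm <- assemblies[[acc]]
    haps <- list(h1 = asm$chromosomes)
    if (!is.null(asm$haplotype2)) haps$h2 <- asm$haplotype2
    lens_by_marker <- setNames(rep(list(data.frame(length = integer(0),
                                                   haplotype = character(0))),
                                   length(nm)), nm)
    for (hname in names(haps)) {
      for (chrom in names(haps[[hname]])) {
        sites <- .cpp_scan_sites_multi(haps[[hname]][[chrom]], patterns, right,
                                       config$epcr_max_mismatch,
                                       config$epcr_three_prime_exact)
        for (k in seq_along(nm)) {
          fpos <- sites[[2 * k - 1]]
          rpos <- sites[[2 * k]]
          if (!length(fpos) || !length(rpos)) next
          ends <- rpos + rev_len[k] - 1L
          grid <- expand.grid(f = fpos, e = ends)
          len <- grid$e - grid$f + 1L
          keep <- len >= config$epcr_min_product &
                  len <= config$epcr_max_product
          if (any(keep)) {
            lens_by_marker[[k]] <- rbind(
              lens_by_marker[[k]],
              data.frame(length = as.integer(len[keep]), haplotype = hname,
                         stringsAsFactors = FALSE))
          }
        }
      }
    }
    for (k in seq_along(nm)) {
      raw <- lens_by_marker[[k]]
      bands <- merge_gel_bands(raw$length, config$gel_resolution_bp)
      status <- if (!length(bands)) "no_amplification"
                else if (length(bands) > 2) "excess_bands"
                else "ok"
      cause <- NA_character_
      if (length(bands) == 2) {
        by_hap <- split(raw$length, raw$haplotype)
        multi <- any(vapply(by_hap, function(v)
          length(merge_gel_bands(v, config$gel_resolution_bp)) > 1,
          logical(1)))
        if (multi) cause <- "duplication"
        else if (length(by_hap) == 2) cause <- "heterozygous"
      }
      cells[[nm[k]]][[acc]] <- structure(
        list(accession_id = acc, band_lengths = bands, raw_amplicons = raw,
             status = status, two_band_cause = cause),
        class = "band_set")
    }
  }
  cells
}

#' @export
print.indel_pipeline_result <- function(x, ...) {
  cat("InDel marker pipeline result\n")
  cat(sprintf("  baits selected:        %d\n", nrow(x$baits)))
  cat(sprintf("  ortholog sets:         %d accepted, %d rejected\n",
              length(x$ortholog_sets), length(x$rejections)))
  cat(sprintf("  markers designed:      %d (%d design failure(s))\n",
              nrow(x$markers), nrow(x$design_failures)))
  if (length(x$summary)) {
    cat(sprintf("  validated polymorphic: %d (%.1f%%)\n",
                x$summary$n_validated, x$summary$validation_rate))
    if (!is.na(x$summary$interval$mean_gap_kb))
      cat(sprintf("  mean marker interval:  %.1f kb\n",
                  x$summary$interval$mean_gap_kb))
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits the bait table, marker table, marker BED and genotype matrix as
#' TSV/BED files, the configuration snapshot, and a run manifest (stage
#' counts, seed, package version) written atomically last: two runs with
#' identical inputs and configuration produce byte-identical artifacts.
#' @param result An `indel_pipeline_result`.
#' @param dir Output directory (created if absent).
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bait_table(result$baits, file.path(dir, "baits.tsv"))
  write_marker_table(result$markers, file.path(dir, "markers.tsv"),
                     allow_empty = TRUE)
  write_marker_bed(result$markers, file.path(dir, "markers.bed"),
                   allow_empty = TRUE)
  if (!is.null(result$matrix))
    write_genotype_matrix(result$matrix, file.path(dir, "genotypes.tsv"))
  write_pipeline_config(result$config, file.path(dir, "config.txt"))
  manifest <- c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("indelmark"))),
    sprintf("reference = %s", result$reference_id),
    sprintf("rng_seed = %s",
            if (is.null(result$config$rng_seed)) "NA"
            else result$config$rng_seed),
    sprintf("n_baits = %d", nrow(result$baits)),
    sprintf("n_ortholog_sets = %d", length(result$ortholog_sets)),
    sprintf("n_rejected_sets = %d", length(result$rejections)),
    sprintf("n_markers = %d", nrow(result$markers)),
    sprintf("n_design_failures = %d", nrow(result$design_failures)),
    if (length(result$summary))
      sprintf("n_validated_polymorphic = %d", result$summary$n_validated))
  tmp <- file.path(dir, ".manifest.tmp")
  writeLines(manifest, tmp)
  file.rename(tmp, file.path(dir, "manifest.txt"))
  invisible(dir)
}
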
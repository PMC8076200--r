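#' Genotype matrix container
#'
#' Markers x accessions grid of [genotype_accession()] band sets, plus
#' accession metadata and the designated reference (cultivar) columns the
#' polymorphism calls compare against.
#'
#' @param cells A list of lists: `cells[[marker]][[accession]]` is a
#'   `band_set` (or a plain list with `band_lengths` and `status`).
#' @param accessions Data frame with columns `accession_id`, `species`,
#'   `group_label`.
#' @param reference_accessions Character vector of reference accession
#'   ids (must appear in `accessions`).
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(cells, accessions, reference_accessions) {
  marker_names <- names(cells)
  if (is.null(marker_names)) stop("cells must be named by marker", call. = FALSE)
  for (m in marker_names) {
    missing <- setdiff(accessions$accession_id, names(cells[[m]]))
    if (length(missing))
      stop("marker ", m, " lacks cells for: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(reference_accessions %in% accessions$accession_id))
    stop("reference accessions absent from the accession table", call. = FALSE)
  structure(list(cells = cells,
                 markers = marker_names,
                 accessions = accessions,
                 reference_accessions = reference_accessions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d marker(s) x %d accession(s), references: %s\n",
              length(x$markers), nrow(x$accessions),
              paste(x$reference_accessions, collapse = ", ")))
  invisible(x)
}

#' Band-set polymorphism call against a reference cell
#'
#' Two cells are polymorphic when, after gel merging, some band in one
#' set has no counterpart within `gel_resolution_bp` in the other. Cells
#' that did not amplify cleanly are `not_evaluable`.
#'
#' @param cell,reference_cell `band_set`s.
#' @param gel_resolution_bp Gel resolution threshold (default 20).
#' @return `"polymorphic"`, `"monomorphic"` or `"not_evaluable"`.
#' @export
call_polymorphism <- function(cell, reference_cell, gel_resolution_bp = 20) {
  if (!identical(cell$status, "ok") || !identical(reference_cell$status, "ok"))
    return("not_evaluable")
  if (bands_equivalent(cell$band_lengths, reference_cell$band_lengths,
                       gel_resolution_bp)) "monomorphic" else "polymorphic"
}

# set equivalence under the gel model: every band of a has a counterpart
# within < res in b and vice versa
bands_equivalent <- function(a, b, res) {
  if (!length(a) || !length(b)) return(length(a) == length(b))
  all(vapply(a, function(x) any(abs(b - x) < res), logical(1))) &&
    all(vapply(b, function(x) any(abs(a - x) < res), logical(1)))
}

#' Validation categories for every marker of a genotype matrix
#'
#' A marker is `failed` when more than `fail_fraction` of its cells show
#' no amplification or excess bands; otherwise `polymorphic` when any
#' non-reference accession is polymorphic against either reference
#' column, else `monomorphic`. The three categories partition the marker
#' set.
#'
#' @param matrix A [genotype_matrix()].
#' @param gel_resolution_bp Gel resolution (default 20).
#' @param fail_fraction Bad-cell fraction above which a marker fails
#'   (default 0.3).
#' @return A list with `records` (per-marker data frame: `marker`,
#'   `category`, `bad_fraction`) and `totals` (named counts
#'   polymorphic/monomorphic/failed).
#' @export
categorize_markers <- function(matrix, gel_resolution_bp = 20,
                               fail_fraction = 0.3) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!length(matrix$markers)) stop("empty genotype matrix", call. = FALSE)
  acc <- matrix$accessions$accession_id
  test_acc <- setdiff(acc, matrix$reference_accessions)
  rows <- lapply(matrix$markers, function(m) {
    cells <- matrix$cells[[m]]
    status <- vapply(cells[acc], `[[`, character(1), "status")
    bad <- mean(status != "ok")
    if (bad > fail_fraction) {
      cat_ <- "failed"
    } else {
      poly <- FALSE
      for (ref in matrix$reference_accessions) {
        for (a in test_acc) {
          if (identical(call_polymorphism(cells[[a]], cells[[ref]],
                                          gel_resolution_bp), "polymorphic")) {
            poly <- TRUE; break
          }
        }
        if (poly) break
      }
      cat_ <- if (poly) "polymorphic" else "monomorphic"
    }
    data.frame(marker = m, category = cat_, bad_fraction = bad,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  totals <- c(polymorphic = sum(records$category == "polymorphic"),
              monomorphic = sum(records$category == "monomorphic"),
              failed = sum(records$category == "failed"))
  list(records = records, totals = totals)
}

#' Summary statistics of per-accession polymorphic marker counts
#'
#' @param counts Named integer vector: polymorphic marker count per
#'   accession (e.g. a published table column, or output of
#'   [polymorphic_counts()]).
#' @return List with `counts`, `mean` (1 decimal), `min`, `max`,
#'   `which_min`, `which_max`.
#' @examples
#' summarize_polymorphism(c(a = 300, b = 340, c = 329))
#' @export
summarize_polymorphism <- function(counts) {
  if (!length(counts)) stop("at least one accession required", call. = FALSE)
  list(counts = counts,
       mean = round(mean(counts), 1),
       min = min(counts),
       max = max(counts),
       which_min = names(counts)[which.min(counts)],
       which_max = names(counts)[which.max(counts)])
}

#' Per-accession polymorphic marker counts from a genotype matrix
#'
#' @param matrix A [genotype_matrix()].
#' @param reference Reference accession id to compare against.
#' @param accessions Accessions to count (default: all non-reference).
#' @param gel_resolution_bp Gel resolution.
#' @param validated_markers Optional subset of markers (defaults to all).
#' @return Named integer vector of counts.
#' @export
polymorphic_counts <- function(matrix, reference,
                               accessions = NULL,
                               gel_resolution_bp = 20,
                               validated_markers = NULL) {
  if (is.null(accessions))
    accessions <- setdiff(matrix$accessions$accession_id,
                          matrix$reference_accessions)
  if (is.null(validated_markers)) validated_markers <- matrix$markers
  vapply(accessions, function(a) {
    sum(vapply(validated_markers, function(m) {
      identical(call_polymorphism(matrix$cells[[m]][[a]],
                                  matrix$cells[[m]][[reference]],
                                  gel_resolution_bp), "polymorphic")
    }, logical(1)))
  }, integer(1))
}

#' Experimental validation rate
#'
#' @param n_designed Number of designed markers (> 0).
#' @param n_validated Number validated (0..n_designed).
#' @return Percentage, rounded to 1 decimal.
#' @examples
#' validation_rate(541, 475)  # 87.8
#' @export
validation_rate <- function(n_designed, n_validated) {
  if (n_designed <= 0) stop("n_designed must be > 0", call. = FALSE)
  if (n_validated < 0 || n_validated > n_designed)
    stop("n_validated must lie in [0, n_designed]", call. = FALSE)
  round(100 * n_validated / n_designed, 1)
}

#' Two-band (heterozygosity) marker frequency for one accession
#'
#' @param count_or_matrix Either the integer count of two-band markers,
#'   or a [genotype_matrix()].
#' @param n_validated Denominator: number of validated markers.
#' @param accession Accession id (when a matrix is supplied).
#' @param validated_markers Marker subset (when a matrix is supplied).
#' @return List with `count` and `percent` (3 decimals).
#' @examples
#' two_band_frequency(60, 475)$percent  # 12.632
#' @export
two_band_frequency <- function(count_or_matrix, n_validated,
                               accession = NULL,
                               validated_markers = NULL) {
  if (n_validated <= 0) stop("n_validated must be > 0", call. = FALSE)
  count <- if (is.numeric(count_or_matrix)) {
    as.integer(count_or_matrix)
  } else {
    m <- count_or_matrix
    if (is.null(validated_markers)) validated_markers <- m$markers
    sum(vapply(validated_markers, function(mk) {
      cell <- m$cells[[mk]][[accession]]
      identical(cell$status, "ok") && length(cell$band_lengths) >= 2
    }, logical(1)))
  }
  list(count = count, percent = round(100 * count / n_validated, 3))
}

#' Species-level polymorphic marker sets
#'
#' For each species, markers are grouped by how many of its accessions
#' are polymorphic against the reference: common to all three
#' (`common3`), common to two (`common2`), accession-specific
#' (`specific`); `union` is their disjoint union (the species'
#' available polymorphic markers, the Venn totals).
#'
#' @param matrix A [genotype_matrix()].
#' @param species_to_accessions Named list: species -> accession ids.
#' @param reference Reference accession id.
#' @param gel_resolution_bp Gel resolution.
#' @param validated_markers Optional marker subset.
#' @return Named list per species with `common3`, `common2`, `specific`,
#'   `union` (character vectors of marker names).
#' @export
species_marker_sets <- function(matrix, species_to_accessions, reference,
                                gel_resolution_bp = 20,
                                validated_markers = NULL) {
  if (is.null(validated_markers)) validated_markers <- matrix$markers
  lapply(species_to_accessions, function(accs) {
    if (!length(accs)) stop("species with no accessions", call. = FALSE)
    n_poly <- vapply(validated_markers, function(m) {
      sum(vapply(accs, function(a)
        identical(call_polymorphism(matrix$cells[[m]][[a]],
                                    matrix$cells[[m]][[reference]],
                                    gel_resolution_bp), "polymorphic"),
        logical(1)))
    }, integer(1))
    list(common3 = validated_markers[n_poly >= 3],
         common2 = validated_markers[n_poly == 2],
         specific = validated_markers[n_poly == 1],
         union = validated_markers[n_poly >= 1])
  })
}

#' Marker interval statistics along the genome
#'
#' Gaps between neighbouring markers within each chromosome; the mean gap
#' and the list of gaps exceeding a threshold (2 Mb by default, the
#' conventional yardstick for distribution evenness).
#'
#' @param positions Data frame with `chrom` and `pos` (bp), or a named
#'   list of sorted position vectors.
#' @param threshold_bp Gap threshold (default 2e6).
#' @return List with `mean_gap_kb` (1 decimal), `gaps` (data frame
#'   `chrom`, `from`, `to`, `gap_bp`), `gaps_over_threshold`.
#' @export
interval_statistics <- function(positions, threshold_bp = 2e6) {
  if (is.data.frame(positions)) {
    positions <- split(positions$pos, positions$chrom)
  }
  gaps <- list()
  for (chrom in names(positions)) {
    p <- sort(positions[[chrom]])
    if (length(p) < 2) next
    g <- diff(p)
    gaps[[chrom]] <- data.frame(chrom = chrom,
                                from = p[-length(p)], to = p[-1],
                                gap_bp = g, stringsAsFactors = FALSE)
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(chrom = character(0), from = numeric(0), to = numeric(0),
               gap_bp = numeric(0))
  rownames(gaps) <- NULL
  list(mean_gap_kb = if (nrow(gaps)) round(mean(gaps$gap_bp) / 1000, 1) else NA_real_,
       gaps = gaps,
       gaps_over_threshold = gaps[gaps$gap_bp > threshold_bp, , drop = FALSE])
}

#' Call a progeny genotype from parental and progeny band sets
#'
#' `H` when the progeny shows the union of both parents' bands, `A`/`B`
#' when it matches exactly one parent, `failed` otherwise;
#' `not_evaluable` when the parents are not polymorphic for the marker.
#'
#' @param bands_parentA,bands_parentB,bands_progeny Numeric band-length
#'   vectors (gel-merged).
#' @param gel_resolution_bp Gel resolution.
#' @return One of `"A"`, `"B"`, `"H"`, `"failed"`, `"not_evaluable"`.
#' @examples
#' call_progeny_genotype(300, 340, c(300, 340))  # "H"
#' @export
call_progeny_genotype <- function(bands_parentA, bands_parentB,
                                  bands_progeny, gel_resolution_bp = 20) {
  res <- gel_resolution_bp
  if (bands_equivalent(bands_parentA, bands_parentB, res))
    return("not_evaluable")
  union_bands <- merge_gel_bands(c(bands_parentA, bands_parentB), res)
  if (bands_equivalent(bands_progeny, union_bands, res)) return("H")
  if (bands_equivalent(bands_progeny, bands_parentA, res)) return("A")
  if (bands_equivalent(bands_progeny, bands_parentB, res)) return("B")
  "failed"
}

#' Detect introgressed segments from ordered progeny calls
#'
#' Maximal runs of consecutive non-recurrent (`H` or `B`) calls along each
#' chromosome; single-marker segments are allowed. Markers that could not
#' be evaluated are dropped before run detection.
#'
#' @param calls Data frame with `chrom`, `pos`, `marker`, `call`
#'   (ordered or orderable by position).
#' @return Data frame of segments: `chrom`, `start_marker`, `end_marker`,
#'   `start_pos`, `end_pos`, `n_markers`, `state` (`H`, or `B` when any
#'   homozygous-donor call is inside).
#' @export
detect_introgressions <- function(calls) {
  calls <- calls[calls$call %in% c("A", "B", "H"), , drop = FALSE]
  segs <- list()
  for (chrom in unique(calls$chrom)) {
    d <- calls[calls$chrom == chrom, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    non_a <- d$call != "A"
    r <- rle(non_a)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      segs[[length(segs) + 1L]] <-
        data.frame(chrom = chrom,
                   start_marker = d$marker[idx[1]],
                   end_marker = d$marker[idx[length(idx)]],
                   start_pos = d$pos[idx[1]],
                   end_pos = d$pos[idx[length(idx)]],
                   n_markers = length(idx),
                   state = if (any(d$call[idx] == "B")) "B" else "H",
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(0), start_marker = character(0),
                      end_marker = character(0), start_pos = numeric(0),
                      end_pos = numeric(0), n_markers = integer(0),
                      state = character(0)))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Write a genotype matrix to TSV
#'
#' Cells are semicolon-joined band lengths followed by the status in
#' brackets when not `ok`.
#' @param matrix A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_matrix <- function(matrix, path) {
  acc <- matrix$accessions$accession_id
  rows <- lapply(matrix$markers, function(m) {
    vals <- vapply(acc, function(a) {
      cell <- matrix$cells[[m]][[a]]
      s <- paste(round(cell$band_lengths), collapse = ";")
      if (!identical(cell$status, "ok"))
        s <- paste0(s, "[", cell$status, "]")
      if (!nzchar(s)) s <- "."
      s
    }, character(1))
    c(marker = m, vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Long-format band table of a genotype matrix
#'
#' One row per (marker, accession): comma-joined band lengths and the
#' cell status -- the interchange format of the `epcr` and `summarize`
#' command-line steps.
#'
#' @param matrix A [genotype_matrix()].
#' @return Data frame `marker`, `accession`, `bands`, `status`.
#' @export
band_table <- function(matrix) {
  rows <- list()
  for (m in matrix$markers) {
    for (a in matrix$accessions$accession_id) {
      cell <- matrix$cells[[m]][[a]]
      rows[[length(rows) + 1L]] <-
        data.frame(marker = m, accession = a,
                   bands = paste(round(cell$band_lengths, 1), collapse = ","),
                   status = cell$status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rebuild a genotype matrix from a long band table
#'
#' @param tab Data frame as produced by [band_table()] (columns `marker`,
#'   `accession`, `bands`, `status`).
#' @param accessions Accession metadata data frame (`accession_id`,
#'   `species`, `group_label`).
#' @param reference_accessions Reference accession ids.
#' @return A [genotype_matrix()].
#' @export
genotype_matrix_from_band_table <- function(tab, accessions,
                                            reference_accessions) {
  cells <- list()
  for (m in unique(tab$marker)) {
    sub <- tab[tab$marker == m, , drop = FALSE]
    cells[[m]] <- lapply(setNames(seq_len(nrow(sub)), sub$accession),
                         function(i) {
      bands <- if (nzchar(sub$bands[i]))
        as.numeric(strsplit(sub$bands[i], ",", fixed = TRUE)[[1]])
      else numeric(0)
      structure(list(accession_id = sub$accession[i], band_lengths = bands,
                     raw_amplicons = NULL, status = sub$status[i],
                     two_band_cause = NA_character_),
                class = "band_set")
    })
  }
  genotype_matrix(cells, accessions, reference_accessions)
}

#' In-silico PCR band table for a marker set against a genome panel
#'
#' Batched e-PCR of every marker against every accession.
#'
#' @param markers Marker table data frame (needs `name`, `fwd_seq`,
#'   `rev_seq`).
#' @param assemblies Named list of [genome_assembly()] objects.
#' @param config A [pipeline_config()].
#' @return Data frame `marker`, `accession`, `bands`, `status` (see
#'   [band_table()]).
#' @export
epcr_band_table <- function(markers, assemblies, config = pipeline_config()) {
  pairs <- lapply(seq_len(nrow(markers)), function(i)
    structure(list(fwd_seq = markers$fwd_seq[i],
                   rev_seq = markers$rev_seq[i]), class = "primer_pair"))
  names(pairs) <- markers$name
  cells <- epcr_genotype_all(pairs, assemblies, config)
  acc <- data.frame(
    accession_id = names(assemblies),
    species = vapply(assemblies, `[[`, character(1), "species"),
    group_label = vapply(assemblies, `[[`, character(1), "group_label"),
    stringsAsFactors = FALSE, row.names = NULL)
  band_table(genotype_matrix(cells, acc, names(assemblies)[1]))
}
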
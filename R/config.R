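#' Pipeline configuration
#'
#' Collects every numeric criterion of the marker-development protocol in
#' one validated object: bait spacing and length, the repeat-content
#' ceiling, ortholog-set membership, the diagnostic gap threshold, PCR
#' product bounds and annealing temperature, primer length/Tm windows, the
#' per-bait marker cap, and the agarose gel resolution threshold.
#'
#' @param bait_interval_bp Spacing of bait anchors along each chromosome
#'   (default 1,000,000 bp: one bait per megabase, top to end).
#' @param bait_min_len,bait_max_len Allowed bait window length range in bp
#'   (defaults 30,000 and 100,000).
#' @param max_repeat_fraction Maximum fraction of a bait window allowed to
#'   be repeat-derived (genome-wide k-mer multiplicity > 1, soft-masked, or
#'   N); default 0.3.
#' @param repeat_kmer k-mer size used for repeat-content estimation
#'   (default 21).
#' @param min_ortholog_members Minimum number of sequences (bait included)
#'   required to run a multiple alignment; default 6, i.e. "more than five".
#' @param anchor_kmer k-mer size for ortholog anchoring (default 15; must
#'   be odd).
#' @param min_anchors Minimum number of co-linear unique anchors for an
#'   ortholog hit (default 10).
#' @param max_anchor_gap Maximum distance between adjacent chain anchors in
#'   bp (default 20,000).
#' @param ortholog_padding Padding added to each side of the chained span
#'   when extracting an orthologous region (default 2,000 bp).
#' @param min_gap_bp Minimum allele-length difference for a diagnostic
#'   InDel (default 20 bp; agarose-resolvable).
#' @param merge_radius InDel events across members whose reference
#'   positions are within this many bp are merged into one block
#'   (default 10).
#' @param product_min,product_max PCR product size bounds in bp (defaults
#'   100 and 500).
#' @param annealing_temp_c PCR annealing temperature in degrees C (55).
#' @param primer_len_range Primer length range, inclusive (default 18-24).
#' @param primer_tm_window_c Allowed primer melting-temperature window in
#'   degrees C (default 55-65).
#' @param max_markers_per_bait At most this many InDel markers are selected
#'   per bait window (default 2).
#' @param gel_resolution_bp Band-length differences below this threshold
#'   are unresolvable on a 2.5-4.0\% agarose gel and are merged (default 20).
#' @param epcr_max_product,epcr_min_product In-silico PCR amplicon length
#'   bounds (defaults 2,000 and 50 bp).
#' @param epcr_max_mismatch Maximum primer-template mismatches tolerated at
#'   a binding site (default 2).
#' @param epcr_three_prime_exact Number of 3'-terminal primer bases that
#'   must match exactly (default 3).
#' @param band_width Half-width of the alignment band around the anchor
#'   chain (default 200 bp; doubled automatically up to 4x on overflow --
#'   comfortably above the largest modelled InDel of 150 bp).
#' @param align_match,align_mismatch,align_gap_open,align_gap_extend
#'   Alignment scoring parameters (defaults 1, -2, -6, -0.2; long-gap
#'   friendly so a 30-bp InDel stays one event).
#' @param rng_seed Optional integer seed recorded with the run.
#'
#' @return An object of class `indel_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_gap_bp
#' @export
pipeline_config <- function(bait_interval_bp = 1e6,
                            bait_min_len = 30000,
                            bait_max_len = 100000,
                            max_repeat_fraction = 0.3,
                            repeat_kmer = 21,
                            min_ortholog_members = 6,
                            anchor_kmer = 15,
                            min_anchors = 10,
                            max_anchor_gap = 20000,
                            ortholog_padding = 2000,
                            min_gap_bp = 20,
                            merge_radius = 10,
                            product_min = 100,
                            product_max = 500,
                            annealing_temp_c = 55,
                            primer_len_range = c(18L, 24L),
                            primer_tm_window_c = c(55, 65),
                            max_markers_per_bait = 2,
                            gel_resolution_bp = 20,
                            epcr_max_product = 2000,
                            epcr_min_product = 50,
                            epcr_max_mismatch = 2,
                            epcr_three_prime_exact = 3,
                            band_width = 200,
                            align_match = 1,
                            align_mismatch = -2,
                            align_gap_open = -6,
                            align_gap_extend = -0.2,
                            rng_seed = NULL) {
  cfg <- list(bait_interval_bp = bait_interval_bp,
              bait_min_len = as.integer(bait_min_len),
              bait_max_len = as.integer(bait_max_len),
              max_repeat_fraction = max_repeat_fraction,
              repeat_kmer = as.integer(repeat_kmer),
              min_ortholog_members = as.integer(min_ortholog_members),
              anchor_kmer = as.integer(anchor_kmer),
              min_anchors = as.integer(min_anchors),
              max_anchor_gap = as.integer(max_anchor_gap),
              ortholog_padding = as.integer(ortholog_padding),
              min_gap_bp = as.integer(min_gap_bp),
              merge_radius = as.integer(merge_radius),
              product_min = as.integer(product_min),
              product_max = as.integer(product_max),
              annealing_temp_c = annealing_temp_c,
              primer_len_range = as.integer(primer_len_range),
              primer_tm_window_c = as.numeric(primer_tm_window_c),
              max_markers_per_bait = as.integer(max_markers_per_bait),
              gel_resolution_bp = as.integer(gel_resolution_bp),
              epcr_max_product = as.integer(epcr_max_product),
              epcr_min_product = as.integer(epcr_min_product),
              epcr_max_mismatch = as.integer(epcr_max_mismatch),
              epcr_three_prime_exact = as.integer(epcr_three_prime_exact),
              band_width = as.integer(band_width),
              align_match = align_match,
              align_mismatch = align_mismatch,
              align_gap_open = align_gap_open,
              align_gap_extend = align_gap_extend,
              rng_seed = rng_seed)
  validate_pipeline_config(cfg)
  structure(cfg, class = "indel_config")
}

validate_pipeline_config <- function(cfg) {
  lens <- c("bait_interval_bp", "bait_min_len", "bait_max_len",
            "min_ortholog_members", "min_gap_bp", "product_min",
            "product_max", "gel_resolution_bp", "epcr_max_product",
            "max_markers_per_bait")
  for (f in lens)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive number", call. = FALSE)
  if (cfg$product_min >= cfg$product_max)
    stop("product_min must be < product_max", call. = FALSE)
  if (cfg$bait_min_len > cfg$bait_max_len)
    stop("bait_min_len must be <= bait_max_len", call. = FALSE)
  if (length(cfg$primer_len_range) != 2 ||
      cfg$primer_len_range[1] > cfg$primer_len_range[2] ||
      cfg$primer_len_range[1] < 10 || cfg$primer_len_range[2] > 36)
    stop("primer_len_range must lie within [10, 36]", call. = FALSE)
  if (cfg$max_repeat_fraction < 0 || cfg$max_repeat_fraction > 1)
    stop("max_repeat_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$anchor_kmer %% 2 == 0)
    stop("anchor_kmer must be odd", call. = FALSE)
  invisible(cfg)
}

#' @export
print.indel_config <- function(x, ...) {
  cat("InDel marker pipeline configuration\n")
  cat(sprintf("  baits: %d-%d bp windows every %g bp, repeat fraction <= %g (k=%d)\n",
              x$bait_min_len, x$bait_max_len, x$bait_interval_bp,
              x$max_repeat_fraction, x$repeat_kmer))
  cat(sprintf("  orthologs: k=%d anchors, >= %d co-linear, >= %d members per set\n",
              x$anchor_kmer, x$min_anchors, x$min_ortholog_members))
  cat(sprintf("  InDel screen: gap >= %d bp, merge radius %d bp, <= %d markers/bait\n",
              x$min_gap_bp, x$merge_radius, x$max_markers_per_bait))
  cat(sprintf("  PCR: products %d-%d bp, annealing %g C, primers %d-%d nt, Tm %g-%g C\n",
              x$product_min, x$product_max, x$annealing_temp_c,
              x$primer_len_range[1], x$primer_len_range[2],
              x$primer_tm_window_c[1], x$primer_tm_window_c[2]))
  cat(sprintf("  gel resolution: %d bp\n", x$gel_resolution_bp))
  invisible(x)
}

#' Read or write a pipeline configuration as a flat key/value file
#'
#' One `key = value` pair per line; vector-valued fields are comma-joined.
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path File path.
#' @param cfg An `indel_config` object.
#' @return `read_pipeline_config()` returns an `indel_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- pipeline_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key, call. = FALSE)
    args[[key]] <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
  }
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "indel_config"))
  keep <- !vapply(cfg, is.null, logical(1))
  lines <- vapply(names(cfg)[keep], function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
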
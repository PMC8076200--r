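#' Mutation model for synthetic genome evolution
#'
#' Per-base-pair edit rates used by [evolve_genome()]. Small InDels have
#' geometrically distributed lengths of 1-19 bp; large InDels draw their
#' length uniformly from `large_indel_len` (20-150 bp by default, the
#' size class that separates cleanly on agarose gels); repeat insertions
#' copy an element from a repeat library.
#'
#' @param snp_rate,small_indel_rate,large_indel_rate,repeat_insertion_rate
#'   Per-bp event probabilities, each in `[0, 0.05]`.
#' @param small_indel_mean_len Mean of the (truncated) geometric small
#'   InDel length distribution (default 3 bp).
#' @param large_indel_len Two-element integer range of large InDel lengths
#'   (default `c(20, 150)`).
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(snp_rate = 0, small_indel_rate = 0,
                           large_indel_rate = 0, repeat_insertion_rate = 0,
                           small_indel_mean_len = 3,
                           large_indel_len = c(20L, 150L)) {
  rates <- c(snp_rate, small_indel_rate, large_indel_rate,
             repeat_insertion_rate)
  if (any(rates < 0) || any(rates > 0.05))
    stop("mutation rates must lie in [0, 0.05]", call. = FALSE)
  structure(list(snp_rate = snp_rate,
                 small_indel_rate = small_indel_rate,
                 large_indel_rate = large_indel_rate,
                 repeat_insertion_rate = repeat_insertion_rate,
                 small_indel_mean_len = small_indel_mean_len,
                 large_indel_len = as.integer(large_indel_len)),
            class = "mutation_model")
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random ancestor genome
#'
#' I.i.d. random chromosomes, optionally seeded with tandem repeat arrays
#' and dispersed single copies of repeat-library elements so that
#' repeat-avoidance during bait selection is exercised. Arrays are placed
#' at fixed relative positions (35\% and 65\% of each chromosome).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param repeat_library Character vector of repeat elements; `NULL`
#'   disables planted repeats.
#' @param array_copies Tandem copies per planted array.
#' @param n_dispersed Dispersed single element copies per chromosome.
#' @return Named character vector of chromosome sequences
#'   (`chr01`, `chr02`, ...).
#' @export
random_genome <- function(n_chrom = 2, chrom_len = 3e6,
                          repeat_library = NULL, array_copies = 15,
                          n_dispersed = 10) {
  seqs <- character(n_chrom)
  names(seqs) <- sprintf("chr%02d", seq_len(n_chrom))
  for (i in seq_len(n_chrom)) {
    s <- rand_bases(chrom_len)
    if (!is.null(repeat_library) && length(repeat_library)) {
      el <- repeat_library[1 + (i - 1) %% length(repeat_library)]
      array <- strrep(el, array_copies)
      for (at in round(chrom_len * c(0.35, 0.65))) {
        s <- paste0(substr(s, 1, at - 1),
                    array,
                    substr(s, at + nchar(array), chrom_len))
      }
      # dispersed single copies at random positions
      if (n_dispersed > 0) {
        pos <- sort(sample.int(chrom_len - nchar(el), n_dispersed))
        for (p in pos) {
          el2 <- repeat_library[sample.int(length(repeat_library), 1)]
          s <- paste0(substr(s, 1, p - 1), el2,
                      substr(s, p + nchar(el2), nchar(s)))
        }
      }
      s <- substr(s, 1, chrom_len)
    }
    seqs[i] <- s
  }
  seqs
}

# Draw non-overlapping edits for one chromosome. Returns a data.frame
# (chrom, pos, type, ref, alt) with positions in the input genome's
# coordinates; pos for an insertion is the base AFTER which alt is inserted.
draw_edits_chrom <- function(seq, chrom, model, repeat_library = NULL) {
  L <- nchar(seq)
  n_snp <- rbinom(1, L, model$snp_rate)
  n_sml <- rbinom(1, L, model$small_indel_rate)
  n_lrg <- rbinom(1, L, model$large_indel_rate)
  n_rep <- rbinom(1, L, model$repeat_insertion_rate)
  if (is.null(repeat_library)) n_rep <- 0L
  n <- n_snp + n_sml + n_lrg + n_rep
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      type = character(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  type <- rep(c("snp", "small", "large", "repeat"),
              c(n_snp, n_sml, n_lrg, n_rep))
  pos <- sample.int(L - 1L, n, replace = FALSE) + 1L  # avoid position 1 edge
  is_del <- runif(n) < 0.5
  len <- integer(n)
  len[type == "snp"] <- 1L
  len[type == "small"] <- pmin(19L, 1L + rgeom(sum(type == "small"),
                                               1 / model$small_indel_mean_len))
  len[type == "large"] <- sample(seq(model$large_indel_len[1],
                                     model$large_indel_len[2]),
                                 sum(type == "large"), replace = TRUE)
  rep_el <- character(n)
  if (n_rep > 0) {
    picks <- sample.int(length(repeat_library), n_rep, replace = TRUE)
    rep_el[type == "repeat"] <- repeat_library[picks]
    len[type == "repeat"] <- nchar(rep_el[type == "repeat"])
    is_del[type == "repeat"] <- FALSE  # repeat events are insertions
  }
  is_del[type == "snp"] <- FALSE
  o <- order(pos)
  type <- type[o]; pos <- pos[o]; is_del <- is_del[o]; len <- len[o]
  rep_el <- rep_el[o]
  # greedy non-overlap on footprints, left to right
  foot_end <- ifelse(type == "snp", pos,
              ifelse(is_del, pos + len - 1L, pos))
  keep <- logical(n); last_end <- 0L
  for (i in seq_len(n)) {
    if (pos[i] > last_end + 1L && foot_end[i] <= L - 1L) {
      keep[i] <- TRUE
      last_end <- foot_end[i]
    }
  }
  type <- type[keep]; pos <- pos[keep]; is_del <- is_del[keep]
  len <- len[keep]; rep_el <- rep_el[keep]
  m <- length(pos)
  ref <- character(m); alt <- character(m)
  sn <- type == "snp"
  if (any(sn)) {
    bases <- c("A", "C", "G", "T")
    ref[sn] <- substring(seq, pos[sn], pos[sn])
    code <- match(ref[sn], bases)
    code[is.na(code)] <- 1L  # non-ACGT reference base: substitute anyway
    alt[sn] <- bases[((code - 1L + sample.int(3L, sum(sn), replace = TRUE)) %% 4L) + 1L]
  }
  dl <- is_del
  if (any(dl)) {
    ref[dl] <- substring(seq, pos[dl], pos[dl] + len[dl] - 1L)
    alt[dl] <- ""
  }
  ins <- !sn & !dl
  if (any(ins)) {
    ref[ins] <- ""
    ii <- which(ins)
    for (i in ii) {
      alt[i] <- if (type[i] == "repeat") rep_el[i] else rand_bases(len[i])
    }
  }
  typ <- ifelse(sn, "snp", ifelse(dl, "del", "ins"))
  data.frame(chrom = chrom, pos = pos, type = typ, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Apply an edit list to a genome
#'
#' Edits carry coordinates of the *input* genome (they never overlap), so
#' applying the recorded truth list to the ancestor reproduces the derived
#' genome exactly.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param edits Data frame with columns `chrom`, `pos`, `type`
#'   (`snp`/`del`/`ins`), `ref`, `alt`. Insertions are placed after `pos`.
#' @return The edited sequences (same names).
#' @export
apply_edits <- function(seqs, edits) {
  for (chrom in names(seqs)) {
    e <- edits[edits$chrom == chrom, , drop = FALSE]
    if (!nrow(e)) next
    e <- e[order(e$pos), , drop = FALSE]
    L <- nchar(seqs[[chrom]])
    foot_end <- ifelse(e$type == "ins", e$pos, e$pos + nchar(e$ref) - 1L)
    pre_to <- ifelse(e$type == "ins", e$pos, e$pos - 1L)
    pre_from <- c(1L, foot_end[-nrow(e)] + 1L)
    pres <- substring(seqs[[chrom]], pre_from, pre_to)
    tail_seq <- substring(seqs[[chrom]], foot_end[nrow(e)] + 1L, L)
    seqs[[chrom]] <- paste(c(rbind(pres, e$alt), tail_seq), collapse = "")
  }
  seqs
}

#' Evolve a genome under a mutation model
#'
#' Draws SNPs, small and large InDels and repeat-element insertions
#' independently along each chromosome (non-overlapping footprints by
#' greedy left-to-right rejection) and applies them. The returned edit
#' list refers to the coordinates of the *input* genome, so
#' `apply_edits(seqs, edits)` reproduces the output byte-for-byte.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param model A [mutation_model()].
#' @param repeat_library Optional character vector of repeat elements used
#'   by repeat-insertion events.
#' @return A list with `seqs` (the evolved genome) and `edits` (the truth
#'   list).
#' @export
evolve_genome <- function(seqs, model, repeat_library = NULL) {
  stopifnot(inherits(model, "mutation_model"))
  edits <- do.call(rbind, lapply(names(seqs), function(chrom)
    draw_edits_chrom(seqs[[chrom]], chrom, model, repeat_library)))
  if (is.null(edits))
    edits <- data.frame(chrom = character(0), pos = integer(0),
                        type = character(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
  list(seqs = apply_edits(seqs, edits), edits = edits)
}

#' Map positions through an edit list
#'
#' Lifts 1-based positions from the pre-edit genome to the post-edit
#' genome: positions inside a deleted span map to the deletion start.
#'
#' @param edits Truth edit list (as from [evolve_genome()]).
#' @param chrom Chromosome name.
#' @param pos Integer vector of pre-edit positions.
#' @return Integer vector of post-edit positions.
#' @export
shift_positions <- function(edits, chrom, pos) {
  e <- edits[edits$chrom == chrom, , drop = FALSE]
  if (!nrow(e)) return(as.integer(pos))
  e <- e[order(e$pos), , drop = FALSE]
  delta <- nchar(e$alt) - nchar(e$ref)
  foot_end <- ifelse(e$type == "ins", e$pos, e$pos + nchar(e$ref) - 1L)
  cum <- cumsum(delta)
  vapply(pos, function(p) {
    before <- foot_end < p
    shift <- if (any(before)) cum[max(which(before))] else 0L
    # inside a deleted span: collapse to the deletion point
    inside <- which(e$type == "del" & e$pos <= p & foot_end >= p)
    if (length(inside)) {
      i <- inside[1]
      shift <- (if (i > 1) cum[i - 1] else 0L)
      return(as.integer(e$pos[i] + shift))
    }
    as.integer(p + shift)
  }, integer(1))
}

#' Simulate a species panel with full ground truth
#'
#' Builds an ancestor genome, evolves one cultivar species and several
#' wild species from it (species-level divergence), then derives accessions
#' within each species (accession-level divergence). The first cultivar
#' accession is the reference. Heterozygous accessions receive a second
#' haplotype evolved from the first at rates proportional to the
#' heterozygosity fraction `h`; one wild species is "perennial-like" with
#' elevated `h`, mirroring the high two-band frequencies seen in
#' outcrossing perennial wild rice.
#'
#' @param n_wild_species Number of wild species (default 3).
#' @param accessions_per_species Accessions per wild species (default 3).
#' @param n_chrom,chrom_len Ancestor genome shape (default 2 x 3 Mb).
#' @param species_model,accession_model [mutation_model()]s for the
#'   species-level and accession-level branches.
#' @param h Baseline heterozygosity fraction per accession (default 0.002).
#' @param h_perennial Elevated heterozygosity for the perennial-like wild
#'   species (the last one; default 0.02).
#' @param seed Integer seed; the panel is byte-identical for equal seeds.
#' @return An object of class `species_panel`: list with `assemblies`
#'   (named list of [genome_assembly()]; first element is the reference),
#'   `reference_id`, `truth` (ancestor, per-species and per-accession edit
#'   lists, heterozygous-locus edit lists, `h_by_accession`) and the
#'   models used.
#' @export
make_species_panel <- function(n_wild_species = 3,
                               accessions_per_species = 3,
                               n_chrom = 2, chrom_len = 3e6,
                               species_model = mutation_model(
                                 snp_rate = 0.005, small_indel_rate = 5e-4,
                                 large_indel_rate = 2e-5,
                                 repeat_insertion_rate = 1e-6),
                               accession_model = mutation_model(
                                 snp_rate = 5e-4, small_indel_rate = 5e-5,
                                 large_indel_rate = 2e-6),
                               h = 0.002, h_perennial = 0.02,
                               seed = 1) {
  set.seed(seed)
  repeat_library <- vapply(1:3, function(i) rand_bases(400), character(1))
  ancestor <- random_genome(n_chrom, chrom_len, repeat_library)
  species_names <- c("cultivar", paste0("wild_", seq_len(n_wild_species)))
  species_seqs <- list(); species_edits <- list()
  for (sp in species_names) {
    ev <- evolve_genome(ancestor, species_model, repeat_library)
    species_seqs[[sp]] <- ev$seqs
    species_edits[[sp]] <- ev$edits
  }
  assemblies <- list(); accession_edits <- list(); het_edits <- list()
  h_by_accession <- numeric(0)
  species_of <- character(0)
  add_accession <- function(sp, idx, group, hh) {
    prefix <- if (sp == "cultivar") "Cult" else sub("^wild_", "Wild", sp)
    id <- sprintf("%s_A%02d", prefix, idx)
    ev <- evolve_genome(species_seqs[[sp]], accession_model, repeat_library)
    hap2 <- NULL; hed <- NULL
    if (hh > 0) {
      hm <- het_model(hh)
      ev2 <- evolve_genome(ev$seqs, hm, repeat_library)
      hap2 <- ev2$seqs
      hed <- ev2$edits
    }
    assemblies[[id]] <<- genome_assembly(ev$seqs, accession_id = id,
                                         species = sp, group_label = group,
                                         haplotype2 = hap2, validate = FALSE)
    accession_edits[[id]] <<- ev$edits
    het_edits[[id]] <<- hed
    h_by_accession[id] <<- hh
    species_of[id] <<- sp
    id
  }
  ref_id <- add_accession("cultivar", 1, "cultivar_japonica", h)
  add_accession("cultivar", 2, "cultivar_indica", h)
  for (w in seq_len(n_wild_species)) {
    hh <- if (w == n_wild_species) h_perennial else h
    for (a in seq_len(accessions_per_species))
      add_accession(paste0("wild_", w), a, "wild", hh)
  }
  structure(list(assemblies = assemblies,
                 reference_id = ref_id,
                 species_of = species_of,
                 truth = list(ancestor = ancestor,
                              species_edits = species_edits,
                              accession_edits = accession_edits,
                              het_edits = het_edits,
                              h_by_accession = h_by_accession),
                 species_model = species_model,
                 accession_model = accession_model,
                 repeat_library = repeat_library,
                 seed = seed),
            class = "species_panel")
}

# heterozygosity model: rates proportional to the fraction h of
# heterozygous loci; large-InDel component scaled so that an elevated-h
# accession shows realistic two-band frequencies on ~300-bp amplicons
het_model <- function(h) {
  mutation_model(snp_rate = min(h, 0.05),
                 small_indel_rate = min(h / 6, 0.05),
                 large_indel_rate = min(h / 60, 0.05))
}

#' @export
print.species_panel <- function(x, ...) {
  cat(sprintf("Synthetic species panel: %d accessions (%d chromosomes x %s bp), seed %s\n",
              length(x$assemblies),
              length(x$truth$ancestor),
              format(nchar(x$truth$ancestor[[1]]), big.mark = ","),
              format(x$seed)))
  cat("  reference:", x$reference_id, "\n")
  invisible(x)
}

#' Simulate F1 and backcross progeny as haplotype-origin mosaics
#'
#' An F1 carries one full recurrent-parent haplotype and one full donor
#' haplotype. Each backcross generation crosses the previous individual
#' back to the recurrent parent: the transmitted gamete is a mosaic of the
#' individual's two haplotypes with a Poisson-distributed number of
#' crossovers placed uniformly per chromosome. Haplotypes are represented
#' as origin segments in recurrent-parent coordinates; donor truth
#' segments are therefore exact.
#'
#' @param recurrent,donor [genome_assembly()] objects (chromosome names
#'   must agree; lengths are taken from the recurrent parent).
#' @param n_backcrosses 0 returns F1 individuals; 1 BC1F1; 2 BC2F1.
#' @param n_progeny Number of progeny individuals.
#' @param crossovers_per_chrom_mean Mean crossovers per chromosome per
#'   meiosis (default 1.5).
#' @param seed Optional seed.
#' @return An object of class `cross_progeny`: a list of individuals,
#'   each with `id`, `generation`, `hap1` and `hap2` segment data frames
#'   (`chrom`, `start`, `end`, `origin`) and `donor_segments` (the merged
#'   donor-origin intervals across both haplotypes).
#' @export
simulate_cross <- function(recurrent, donor, n_backcrosses = 1,
                           n_progeny = 1, crossovers_per_chrom_mean = 1.5,
                           seed = NULL) {
  stopifnot(inherits(recurrent, "genome_assembly"),
            inherits(donor, "genome_assembly"))
  if (!setequal(names(recurrent$chromosomes), names(donor$chromosomes)))
    stop("parents must share chromosome names", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(recurrent)
  whole <- function(origin) {
    data.frame(chrom = names(lens), start = 1L, end = as.integer(lens),
               origin = origin, stringsAsFactors = FALSE)
  }
  gamete <- function(hapA, hapB) {
    out <- NULL
    for (chrom in names(lens)) {
      L <- lens[[chrom]]
      k <- rpois(1, crossovers_per_chrom_mean)
      bp <- sort(sample.int(L - 1L, min(k, L - 1L)))
      bounds <- c(0L, bp, L)
      use_a <- (sample.int(2L, 1L) == 1L)
      for (i in seq_len(length(bounds) - 1L)) {
        lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
        src <- if (use_a) hapA else hapB
        seg <- src[src$chrom == chrom & src$end >= lo & src$start <= hi, ,
                   drop = FALSE]
        if (nrow(seg)) {
          seg$start <- pmax(seg$start, lo)
          seg$end <- pmin(seg$end, hi)
          out <- rbind(out, seg)
        }
        use_a <- !use_a
      }
    }
    merge_origin_segments(out, names(lens))
  }
  individuals <- vector("list", n_progeny)
  for (p in seq_len(n_progeny)) {
    hap1 <- whole("recurrent")
    hap2 <- whole("donor")       # F1 state
    gen <- "F1"
    if (n_backcrosses > 0) {
      for (b in seq_len(n_backcrosses)) {
        hap2 <- gamete(hap1, hap2)
        hap1 <- whole("recurrent")
        gen <- sprintf("BC%dF1", b)
      }
    }
    donor_seg <- hap2[hap2$origin == "donor", , drop = FALSE]
    individuals[[p]] <- list(id = sprintf("%s_%02d", gen, p),
                             generation = gen,
                             hap1 = hap1, hap2 = hap2,
                             donor_segments = donor_seg)
  }
  structure(list(individuals = individuals,
                 recurrent_id = recurrent$accession_id,
                 donor_id = donor$accession_id,
                 chrom_lengths = lens),
            class = "cross_progeny")
}

merge_origin_segments <- function(df, chrom_order) {
  df <- df[order(match(df$chrom, chrom_order), df$start), , drop = FALSE]
  keep <- list()
  for (chrom in chrom_order) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    if (!nrow(d)) next
    i <- 1
    while (i < nrow(d)) {
      if (d$origin[i + 1] == d$origin[i] && d$start[i + 1] == d$end[i] + 1L) {
        d$end[i] <- d$end[i + 1]
        d <- d[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    keep[[chrom]] <- d
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Donor-genome fraction of a progeny individual
#'
#' @param individual One element of `simulate_cross()$individuals`.
#' @param chrom_lengths Named chromosome lengths (from the cross object).
#' @return Fraction of the diploid genome that is donor-derived.
#' @export
donor_fraction <- function(individual, chrom_lengths) {
  donor_bp <- 0
  for (hap in list(individual$hap1, individual$hap2)) {
    d <- hap[hap$origin == "donor", , drop = FALSE]
    if (nrow(d)) donor_bp <- donor_bp + sum(d$end - d$start + 1)
  }
  donor_bp / (2 * sum(chrom_lengths))
}

#' Haplotype origin at given marker positions
#'
#' @param individual One progeny individual.
#' @param chrom,pos Vectors of marker chromosome names and 1-based
#'   positions.
#' @return A two-column character matrix (`hap1`, `hap2`) of origins.
#' @export
origin_at <- function(individual, chrom, pos) {
  one <- function(hap) {
    mapply(function(ch, p) {
      seg <- hap[hap$chrom == ch & hap$start <= p & hap$end >= p, , drop = FALSE]
      if (nrow(seg)) seg$origin[1] else NA_character_
    }, chrom, pos, USE.NAMES = FALSE)
  }
  cbind(hap1 = one(individual$hap1), hap2 = one(individual$hap2))
}

#' Planted fully diagnostic InDels of a species panel
#'
#' The cultivar-branch large InDels of the truth set are exactly the loci
#' where both cultivar accessions differ from every wild species -- the
#' fully diagnostic class the marker screen is designed to recover. Each
#' event is lifted into reference-genome coordinates (through the
#' cultivar species and reference-accession edit lists) and flagged
#' `clean` when no other panel edit footprint falls within `iso_bp` of it
#' (coincidental overlap would perturb the allele-length geometry).
#'
#' @param panel A [make_species_panel()] result.
#' @param min_len Minimum InDel length in bp (default 30).
#' @param iso_bp Isolation radius for the `clean` flag (default 25).
#' @return Data frame: `chrom`, `pos_ancestor`, `type`, `len`,
#'   `ref_start`, `ref_end` (the event footprint in reference
#'   coordinates; zero-width for cultivar-branch deletions), `clean`.
#' @export
planted_diagnostic_indels <- function(panel, min_len = 30, iso_bp = 25) {
  stopifnot(inherits(panel, "species_panel"))
  sp_ed <- panel$truth$species_edits
  cult <- sp_ed$cultivar
  acc_ed <- panel$truth$accession_edits[[panel$reference_id]]
  cand <- cult[cult$type %in% c("del", "ins") &
               pmax(nchar(cult$ref), nchar(cult$alt)) >= min_len, ,
               drop = FALSE]
  if (!nrow(cand))
    return(data.frame(chrom = character(0), pos_ancestor = integer(0),
                      type = character(0), len = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      clean = logical(0)))
  # ancestor-coordinate footprints of every other edit in the panel
  other <- list()
  for (sp in names(sp_ed)) {
    e <- sp_ed[[sp]]
    if (sp == "cultivar") e <- e[!(e$pos %in% cand$pos & e$chrom %in% cand$chrom), , drop = FALSE]
    other[[length(other) + 1L]] <- e[e$type %in% c("del", "ins"), , drop = FALSE]
  }
  other <- do.call(rbind, other)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    chrom <- cand$chrom[i]; p <- cand$pos[i]
    len <- max(nchar(cand$ref[i]), nchar(cand$alt[i]))
    is_del <- cand$type[i] == "del"
    foot_end <- if (is_del) p + len - 1L else p
    o <- other[other$chrom == chrom, , drop = FALSE]
    ofe <- ifelse(o$type == "ins", o$pos, o$pos + nchar(o$ref) - 1L)
    clean <- !any(ofe >= p - iso_bp & o$pos <= foot_end + iso_bp)
    # anchor = last untouched base before the event; lift to species then
    # to reference coordinates
    anchor <- p - 1L
    anchor_sp <- shift_positions(panel$truth$species_edits$cultivar, chrom, anchor)
    anchor_ref <- shift_positions(acc_ed, chrom, anchor_sp)
    if (is_del) {
      ref_start <- anchor_ref + 1L; ref_end <- anchor_ref
    } else {
      ref_start <- anchor_ref + 1L; ref_end <- anchor_ref + len
    }
    data.frame(chrom = chrom, pos_ancestor = p, type = cand$type[i],
               len = len, ref_start = ref_start, ref_end = ref_end,
               clean = clean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recovery of planted diagnostic InDels by a pipeline run
#'
#' Evaluates which planted fully diagnostic InDels (length at least
#' `min_len`, clean isolation, non-repeat context, lying at least
#' `edge_margin` bp inside a selected bait window so a 100-500-bp product
#' is geometrically possible) were recovered as validated polymorphic
#' markers whose InDel block overlaps the truth footprint (within
#' `slack` bp, absorbing left-alignment shifts).
#'
#' @param panel The [make_species_panel()] the run was built from.
#' @param result The [run_indel_pipeline()] result.
#' @param min_len Minimum planted InDel length (default 30).
#' @param edge_margin Required distance from the bait edges (default 300).
#' @param slack Overlap slack in bp (default 50).
#' @return List with `n_eligible`, `n_recovered`, `rate` and the
#'   per-event data frame `events`.
#' @export
recovery_rate <- function(panel, result, min_len = 30, edge_margin = 300,
                          slack = 50) {
  truth <- planted_diagnostic_indels(panel, min_len = min_len)
  baits <- result$baits
  cfg <- result$config
  ref <- panel$assemblies[[panel$reference_id]]
  validated <- if (!is.null(result$validation))
    result$validation$records$marker[result$validation$records$category ==
                                     "polymorphic"] else character(0)
  mk <- result$markers[result$markers$name %in% validated, , drop = FALSE]
  eligible <- logical(nrow(truth)); recovered <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (!truth$clean[i]) next
    b <- baits[baits$chrom == truth$chrom[i] &
               baits$start + edge_margin <= truth$ref_start[i] &
               baits$end - edge_margin >= truth$ref_end[i], , drop = FALSE]
    if (!nrow(b)) next
    ctx_lo <- max(1L, truth$ref_start[i] - 100L)
    ctx_hi <- min(nchar(ref$chromosomes[[truth$chrom[i]]]),
                  truth$ref_end[i] + 100L)
    ctx <- substr(ref$chromosomes[[truth$chrom[i]]], ctx_lo, ctx_hi)
    rf <- repeat_fraction(ctx, ref, k = cfg$repeat_kmer)
    if (rf > cfg$max_repeat_fraction) next
    eligible[i] <- TRUE
    m <- mk[mk$chrom == truth$chrom[i] &
            mk$block_start <= truth$ref_end[i] + slack &
            mk$block_end >= truth$ref_start[i] - slack, , drop = FALSE]
    recovered[i] <- nrow(m) > 0
  }
  events <- truth
  events$eligible <- eligible
  events$recovered <- recovered
  list(n_eligible = sum(eligible),
       n_recovered = sum(recovered & eligible),
       rate = if (any(eligible)) sum(recovered & eligible) / sum(eligible)
              else NA_real_,
       events = events)
}
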
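#' Genome assembly container
#'
#' A genome assembly is a named set of chromosome sequences with accession
#' metadata, an optional second haplotype (for heterozygous accessions) and
#' a soft-mask annotation. Sequences are stored upper-cased; lowercase
#' stretches in the input are recorded as soft-mask runs per chromosome.
#'
#' @param chromosomes Named character vector of nucleotide sequences
#'   (IUPAC codes; lowercase allowed on input and recorded as soft mask).
#' @param accession_id Accession identifier, e.g. `"Niva_A16"`.
#' @param species Species name.
#' @param group_label One of `"cultivar_indica"`, `"cultivar_japonica"`,
#'   `"wild"`, `"other"`.
#' @param haplotype2 Optional named character vector with the same
#'   chromosome names: the second haplotype of a heterozygous accession.
#' @param mask Optional list (per chromosome) of two-column matrices of
#'   1-based soft-mask run starts/ends; computed from lowercase if omitted.
#' @param validate Check the alphabet and upper-case the input (default).
#'   The synthetic-genome generator disables this: its output is
#'   upper-case A/C/G/T by construction and the scan of multi-megabase
#'   strings is pure overhead there.
#'
#' @return An object of class `genome_assembly`.
#' @examples
#' g <- genome_assembly(c(chr01 = "ACGTACGTACGT"), "toy", "Toy species", "other")
#' chrom_lengths(g)
#' @export
genome_assembly <- function(chromosomes, accession_id, species = "",
                            group_label = c("other", "cultivar_indica",
                                            "cultivar_japonica", "wild"),
                            haplotype2 = NULL, mask = NULL,
                            validate = TRUE) {
  group_label <- match.arg(group_label)
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes)) ||
      any(!nzchar(names(chromosomes))))
    stop("chromosomes must be a named character vector", call. = FALSE)
  if (anyDuplicated(names(chromosomes)))
    stop("duplicate chromosome name: ",
         names(chromosomes)[duplicated(names(chromosomes))][1], call. = FALSE)
  if (is.null(mask))
    mask <- if (validate) lapply(chromosomes, softmask_runs)
            else lapply(chromosomes, function(s)
              matrix(integer(0), ncol = 2,
                     dimnames = list(NULL, c("start", "end"))))
  if (validate) chromosomes <- toupper_checked(chromosomes, accession_id)
  if (!is.null(haplotype2)) {
    if (!setequal(names(haplotype2), names(chromosomes)))
      stop("haplotype2 chromosome names must equal haplotype 1's", call. = FALSE)
    haplotype2 <- haplotype2[names(chromosomes)]
    if (validate) haplotype2 <- toupper_checked(haplotype2, accession_id)
  }
  structure(list(accession_id = accession_id,
                 species = species,
                 group_label = group_label,
                 chromosomes = chromosomes,
                 haplotype2 = haplotype2,
                 mask = mask),
            class = "genome_assembly")
}

# 1-based runs of lowercase (soft-masked) positions as a 2-column matrix
softmask_runs <- function(seq) {
  low <- gregexpr("[a-z]+", seq)[[1]]
  if (low[1] == -1) return(matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = as.integer(low),
        end = as.integer(low) + attr(low, "match.length") - 1L)
}

toupper_checked <- function(seqs, id) {
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("non-IUPAC character in record '%s' of %s at offset %d",
                 names(seqs)[i], id, bad[i]), call. = FALSE)
  }
  seqs
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("Genome assembly '%s' (%s, %s)%s\n", x$accession_id, x$species,
              x$group_label,
              if (!is.null(x$haplotype2)) ", 2 haplotypes" else ""))
  lens <- chrom_lengths(x)
  cat(sprintf("  %d chromosome(s), %s bp total\n", length(lens),
              format(sum(lens), big.mark = ",")))
  invisible(x)
}

#' @rdname genome_assembly
#' @param x A `genome_assembly`.
#' @export
chrom_lengths <- function(x) {
  stopifnot(inherits(x, "genome_assembly"))
  vapply(x$chromosomes, nchar, integer(1))
}

#' Read a genome assembly from (multi-record) FASTA
#'
#' One file per genome, one record per chromosome; gzipped input is
#' accepted. Lowercase (soft-masked) stretches are recorded in the mask
#' slot, and record order is preserved. Records named `<chrom>_hap2`
#' are collected into the second haplotype (the convention
#' [write_genome_fasta()] uses for heterozygous accessions).
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @param accession_id,species,group_label Metadata for the assembly;
#'   `accession_id` defaults to the file name without extension.
#' @return A [genome_assembly()].
#' @export
read_genome_fasta <- function(path, accession_id = NULL, species = "",
                              group_label = "other") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(accession_id))
    accession_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  recs <- Biostrings::readBStringSet(path)
  seqs <- as.character(recs)
  names(seqs) <- sub("\\s.*$", "", names(recs))
  if (any(!nzchar(names(seqs))))
    stop("malformed FASTA header (empty record name) in ", path, call. = FALSE)
  hap2 <- grepl("_hap2$", names(seqs))
  s1 <- seqs[!hap2]
  s2 <- seqs[hap2]
  if (anyDuplicated(names(s1)))
    stop("duplicate record name '", names(s1)[duplicated(names(s1))][1],
         "' in ", path, call. = FALSE)
  h2 <- NULL
  if (length(s2)) {
    names(s2) <- sub("_hap2$", "", names(s2))
    h2 <- s2
  }
  genome_assembly(s1, accession_id = accession_id, species = species,
                  group_label = group_label, haplotype2 = h2)
}

#' Write a genome assembly to FASTA
#'
#' Soft-mask runs are re-emitted as lowercase so that a read/write
#' round-trip reproduces the input byte-for-byte; second-haplotype
#' records are written as `<chrom>_hap2`.
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  seqs <- assembly$chromosomes
  for (nm in names(seqs)) {
    runs <- assembly$mask[[nm]]
    if (!is.null(runs) && nrow(runs)) {
      s <- strsplit(seqs[[nm]], "")[[1]]
      idx <- unlist(mapply(seq.int, runs[, 1], runs[, 2], SIMPLIFY = FALSE))
      s[idx] <- tolower(s[idx])
      seqs[[nm]] <- paste(s, collapse = "")
    }
  }
  if (!is.null(assembly$haplotype2)) {
    h2 <- assembly$haplotype2
    names(h2) <- paste0(names(h2), "_hap2")
    seqs <- c(seqs, h2)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Reverse complement of a plain character sequence
#'
#' @param seq A nucleotide string (IUPAC codes allowed, case preserved).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", seq)
  rawToChar(rev(charToRaw(comp)))
}

#' Marker table and BED export
#'
#' The marker table mirrors the supplementary-table layout of published
#' InDel marker sets: one row per marker with name, reference location
#' (1-based), diagnostic tier and gap, primer sequences, melting
#' temperatures and per-accession expected product sizes
#' (semicolon-joined `accession=bp` pairs). The BED export uses 0-based
#' half-open coordinates of the amplified reference interval.
#'
#' @param markers A data frame of markers (as produced by
#'   [run_indel_pipeline()], or read back by [read_marker_table()]).
#' @param path Output path.
#' @param allow_empty Permit writing a header-only table.
#' @return `path` invisibly; `read_marker_table()` returns the data frame.
#' @export
write_marker_table <- function(markers, path, allow_empty = FALSE) {
  if (nrow(markers) == 0 && !allow_empty)
    stop("empty marker table (use allow_empty = TRUE to write a header)",
         call. = FALSE)
  cols <- marker_table_columns()
  missing <- setdiff(cols, names(markers))
  if (length(missing))
    stop("marker table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  write.table(markers[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

marker_table_columns <- function() {
  c("name", "chrom", "pos", "amp_start", "amp_end", "tier", "gap_bp",
    "fwd_seq", "rev_seq", "tm_f", "tm_r", "product_ref", "products",
    "uniqueness")
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  int_cols <- c("pos", "amp_start", "amp_end", "gap_bp", "product_ref")
  for (cc in intersect(int_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
  df
}

#' @rdname write_marker_table
#' @export
write_marker_bed <- function(markers, path, allow_empty = FALSE) {
  if (nrow(markers) == 0 && !allow_empty)
    stop("empty marker table (use allow_empty = TRUE)", call. = FALSE)
  bed <- data.frame(chrom = markers$chrom,
                    start = as.integer(markers$amp_start) - 1L,  # 0-based
                    end = as.integer(markers$amp_end),
                    name = markers$name,
                    score = 0L,
                    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
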
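# Shared data model and format I/O.
#
# Internal coordinates are 1-based closed intervals carried by
# GenomicRanges::GRanges, the native convention of the Bioconductor
# interval stack this package is built on. GFF3 is read and written
# without shifting; BED (0-based half-open) is converted at the
# boundary. Strand is one of "+", "-", "*".

FEATURE_TYPES <- c("tRNA", "rRNA", "snRNA", "snoRNA", "sRNA_locus",
                   "gene", "TE", "miRNA")

#' Build a validated sample table
#'
#' @param sample_id unique sample identifiers.
#' @param tissue tissue label per sample.
#' @param replicate replicate index per sample; must be unique within a
#'   tissue.
#' @param total_reads total mapped reads per sample (library size);
#'   strictly positive.
#' @return A `data.frame` with one row per sample.
#' @export
sample_table <- function(sample_id, tissue, replicate, total_reads) {
  df <- data.frame(sample_id = as.character(sample_id),
                   tissue = as.character(tissue),
                   replicate = as.integer(replicate),
                   total_reads = as.numeric(total_reads),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stopf("sample_table: duplicated sample_id")
  }
  if (any(df$total_reads <= 0)) {
    stopf("sample_table: total_reads must be > 0")
  }
  dup <- duplicated(df[, c("tissue", "replicate")])
  if (any(dup)) {
    stopf("sample_table: replicate indices must be unique within tissue")
  }
  df
}

# -- feature annotations ------------------------------------------------

#' Parse genomic feature annotations from GFF3 or BED
#'
#' Produces a `GRanges` of feature records sorted by (chromosome,
#' start), with metadata columns `feature_id`, `feature_type` and
#' `te_family` plus any further GFF3 attributes. GFF3 coordinates
#' (1-based inclusive) map directly onto the internal representation;
#' BED intervals are converted from 0-based half-open.
#'
#' @param path file to read.
#' @param format `"gff3"` or `"bed"`.
#' @param seqlengths optional named vector of chromosome lengths; when
#'   given, records on unknown chromosomes or out of bounds are hard
#'   errors (silent drops would corrupt downstream permutation nulls).
#' @param default_type feature type assigned to BED records, which
#'   carry no type column.
#' @return `GRanges` with feature metadata columns.
#' @export
parse_features <- function(path, format = c("gff3", "bed"),
                           seqlengths = NULL,
                           default_type = "sRNA_locus") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("parse_features: no such file: %s", path)
  validate_interval_file(path, format)
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) == 0) {
    mcols(gr) <- DataFrame(feature_id = character(0),
                           feature_type = character(0),
                           te_family = character(0))
    return(gr)
  }
  mc <- mcols(gr)
  if (format == "gff3") {
    feature_id <- as.character(mc$ID %||% rep(NA_character_, length(gr)))
    missing_id <- is.na(feature_id)
    if ("Name" %in% names(mc)) {
      feature_id[missing_id] <- as.character(mc$Name)[missing_id]
    }
    feature_id[is.na(feature_id)] <-
      sprintf("feat_%d", which(is.na(feature_id)))
    feature_type <- as.character(mc$type)
    te_family <- as.character(mc$te_family %||%
                                rep(NA_character_, length(gr)))
    drop <- c("source", "type", "score", "phase", "ID", "Name", "te_family")
    extra <- mc[, setdiff(names(mc), drop), drop = FALSE]
  } else {
    feature_id <- as.character(mc$name %||% sprintf("feat_%d", seq_along(gr)))
    feature_type <- rep(default_type, length(gr))
    te_family <- rep(NA_character_, length(gr))
    extra <- NULL
  }
  if (any(!is.na(te_family) & feature_type != "TE")) {
    stopf("parse_features: te_family set on a non-TE feature")
  }
  mcols(gr) <- DataFrame(feature_id = feature_id,
                         feature_type = feature_type,
                         te_family = te_family)
  if (!is.null(extra) && ncol(extra)) mcols(gr) <- cbind(mcols(gr), extra)
  if (!is.null(seqlengths)) {
    unknown <- setdiff(as.character(unique(seqnames(gr))), names(seqlengths))
    if (length(unknown)) {
      stopf("parse_features: unknown chromosome(s): %s",
            paste(unknown, collapse = ", "))
    }
    over <- end(gr) > seqlengths[as.character(seqnames(gr))]
    if (any(over)) {
      stopf("parse_features: %d record(s) extend beyond chromosome ends",
            sum(over))
    }
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr[order(as.character(seqnames(gr)), start(gr))]
}

# Cheap line-level validation so parse errors carry line numbers.
validate_interval_file <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  ncol_min <- if (format == "gff3") 9L else 3L
  scol <- if (format == "gff3") 4L else 2L
  ecol <- if (format == "gff3") 5L else 3L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < ncol_min) {
      stopf("%s: malformed line %d (%d field(s), expected >= %d)",
            basename(path), i, length(fields), ncol_min)
    }
    s <- suppressWarnings(as.numeric(fields[[scol]]))
    e <- suppressWarnings(as.numeric(fields[[ecol]]))
    if (is.na(s) || is.na(e)) {
      stopf("%s: malformed line %d (non-numeric coordinates)",
            basename(path), i)
    }
    if (e < s) {
      stopf("%s: line %d has end < start", basename(path), i)
    }
  }
  invisible(TRUE)
}

# -- sequence extraction ------------------------------------------------

#' Extract genomic sequence for intervals
#'
#' @param genome named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param interval `GRanges`; minus-strand intervals are
#'   reverse-complemented.
#' @return character vector of sequences, one per interval.
#' @export
extract_sequence <- function(genome, interval) {
  if (is(genome, "DNAStringSet")) {
    chrs <- setNames(as.character(genome), names(genome))
  } else {
    chrs <- genome
  }
  chr <- as.character(seqnames(interval))
  unknown <- setdiff(unique(chr), names(chrs))
  if (length(unknown)) {
    stopf("extract_sequence: unknown chromosome(s): %s",
          paste(unknown, collapse = ", "))
  }
  lens <- setNames(nchar(chrs), names(chrs))
  if (any(start(interval) < 1L) || any(end(interval) > lens[chr])) {
    stopf("extract_sequence: interval out of chromosome bounds")
  }
  out <- substring(chrs[chr], start(interval), end(interval))
  minus <- as.character(strand(interval)) == "-"
  if (any(minus)) out[minus] <- rc(out[minus])
  unname(out)
}

# -- aligned reads ------------------------------------------------------

#' Construct aligned small-RNA reads
#'
#' In-memory constructor for the read container used throughout the
#' package: a `GRanges` with metadata columns `read_id`, `sequence` and
#' `sample_id`. Alignments are ungapped, so each sequence length must
#' equal its interval width.
#'
#' @param read_id,sequence,chrom,start,end,strand,sample_id parallel
#'   vectors, coordinates 1-based inclusive.
#' @param samples optional [sample_table()]; when given every
#'   `sample_id` must be listed in it.
#' @return `GRanges` of reads.
#' @export
aligned_reads <- function(read_id, sequence, chrom, start, end, strand,
                          sample_id, samples = NULL) {
  sequence <- toupper(as.character(sequence))
  if (any(grepl("[^ACGTN]", sequence))) {
    stopf("aligned_reads: sequence alphabet must be A/C/G/T/N")
  }
  w <- end - start + 1L
  bad <- which(nchar(sequence) != w)
  if (length(bad)) {
    stopf("aligned_reads: read '%s' sequence length %d != interval width %d",
          read_id[bad[1]], nchar(sequence)[bad[1]], w[bad[1]])
  }
  if (!is.null(samples)) {
    unknown <- setdiff(unique(sample_id), samples$sample_id)
    if (length(unknown)) {
      stopf("aligned_reads: unknown sample_id: %s",
            paste(unknown, collapse = ", "))
    }
  }
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr) <- DataFrame(read_id = as.character(read_id),
                         sequence = sequence,
                         sample_id = as.character(sample_id))
  gr
}

#' Load aligned reads from the tabular alignment dialect
#'
#' Reads a TSV with columns `read_id`, `sequence`, `chrom`, `start`,
#' `end`, `strand`, `sample_id` (1-based inclusive coordinates, ungapped
#' alignments, one placement per read).
#'
#' @param path TSV file.
#' @param samples [sample_table()]; rows with unknown samples error.
#' @return `GRanges` of reads (see [aligned_reads()]).
#' @export
load_read_alignments <- function(path, samples) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "sequence", "chrom", "start", "end", "strand",
            "sample_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("load_read_alignments: missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  aligned_reads(df$read_id, df$sequence, df$chrom, as.integer(df$start),
                as.integer(df$end), df$strand, df$sample_id,
                samples = samples)
}

#' Write aligned reads as the tabular alignment dialect
#' @param reads `GRanges` from [aligned_reads()].
#' @param path output TSV path.
#' @export
write_read_alignments <- function(reads, path) {
  write_tsv(data.frame(read_id = reads$read_id,
                       sequence = reads$sequence,
                       chrom = as.character(seqnames(reads)),
                       start = start(reads),
                       end = end(reads),
                       strand = as.character(strand(reads)),
                       sample_id = reads$sample_id), path)
}

# -- GFF3 output --------------------------------------------------------

# Deterministic GFF3 writer (no date stamp) shared by annotation and
# locus output. `attrs` is a data.frame of attribute columns; NA values
# are omitted per record.
write_gff3 <- function(gr, path, types, attrs, source = "srnaland") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(gr) == 0) return(invisible(path))
  attr_strings <- vapply(seq_along(gr), function(i) {
    vals <- unlist(lapply(names(attrs), function(k) {
      v <- attrs[[k]][i]
      if (is.na(v)) NULL else paste0(k, "=", v)
    }))
    paste(vals, collapse = ";")
  }, character(1))
  lines <- paste(as.character(seqnames(gr)), source, types,
                 start(gr), end(gr), ".",
                 sub("\\*", ".", as.character(strand(gr))), ".",
                 attr_strings, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write classified sRNA loci as GFF3
#'
#' Round-trip safe with [parse_features()]: intervals, locus ids and
#' class labels survive a write/parse cycle.
#'
#' @param loci `GRanges` with metadata columns `locus_id` and `class`
#'   (and optionally `major_rna`).
#' @param path output path.
#' @export
write_locus_gff3 <- function(loci, path) {
  if (length(loci) && is.null(loci$class)) {
    stopf("write_locus_gff3: loci must carry a 'class' label")
  }
  attrs <- data.frame(ID = if (length(loci)) loci$locus_id else character(0),
                      class = if (length(loci)) loci$class else character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(loci$major_rna)) attrs$major_rna <- loci$major_rna
  write_gff3(loci, path, types = rep("sRNA_locus", length(loci)),
             attrs = attrs)
}

#' Write feature annotations as GFF3
#' @param features `GRanges` from [parse_features()] or the synthetic
#'   generator (metadata `feature_id`, `feature_type`, `te_family`).
#' @param path output path.
#' @export
write_features_gff3 <- function(features, path) {
  attrs <- data.frame(
    ID = if (length(features)) features$feature_id else character(0),
    te_family = if (length(features)) features$te_family else character(0),
    stringsAsFactors = FALSE)
  write_gff3(features, path,
             types = if (length(features)) features$feature_type
                     else character(0),
             attrs = attrs)
}
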
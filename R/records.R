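#' Per-mutation tables (MAF-lite)
#'
#' Mutation records are plain data frames with columns `sample`, `chrom`,
#' `pos` (1-based), `ref`, `alt`, and optionally `strand`
#' (transcribed/untranscribed/unknown), `class` (an extended-class override),
#' and `context5`/`context3` (precomputed sequence context). Substitutions
#' have single-base `ref`/`alt`; indels use the MAF convention (`ref = "-"`
#' for insertions, `alt = "-"` for deletions) or anchored VCF style
#' (shared leading base), which is normalised internally.
#'
#' @param path Path to a tab-separated file with a header row containing at
#'   least `sample`, `chrom`, `pos`, `ref`, `alt`.
#' @return A validated data frame of mutation records.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  need <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  validate_records(df)
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (nrow(records)) {
    if (any(is.na(records$pos)) || any(records$pos < 1L)) {
      stop("positions must be integers >= 1 (1-based)")
    }
    if (any(records$ref == records$alt)) stop("ref must differ from alt")
  }
  records
}

is_indel_record <- function(records) {
  grepl("-", records$ref, fixed = TRUE) |
    grepl("-", records$alt, fixed = TRUE) |
    nchar(records$ref) != nchar(records$alt)
}

# normalise an indel to its inserted/deleted sequence
# handles MAF "-" style and anchored VCF style (common leading base)
indel_seq <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ref[ref == "-"] <- ""; alt[alt == "-"] <- ""
  # strip common prefix (anchored representation)
  pre <- mapply(function(r, a) {
    n <- min(nchar(r), nchar(a)); i <- 0L
    while (i < n && substr(r, i + 1L, i + 1L) == substr(a, i + 1L, i + 1L)) {
      i <- i + 1L
    }
    i
  }, ref, alt)
  ref <- substring(ref, pre + 1L)
  alt <- substring(alt, pre + 1L)
  type <- ifelse(nchar(ref) > 0L & nchar(alt) == 0L, "del",
          ifelse(nchar(ref) == 0L & nchar(alt) > 0L, "ins", NA_character_))
  data.frame(type = type, seq = ifelse(type == "del", ref, alt),
             stringsAsFactors = FALSE)
}

#' Identify dinucleotide substitution events
#'
#' Two substitutions at consecutive positions on the same chromosome of the
#' same sample form one dinucleotide event; sequence context is ignored.
#' Runs of three or more consecutive substitutions are resolved by greedy
#' left-to-right pairing: positions (100, 101, 102) yield one event
#' (100, 101) and one remaining substitution (102).
#'
#' @param records Mutation records (substitutions).
#' @return A list with `events` (data frame: sample, chrom, pos of the first
#'   base of each event) and `remaining` (records not absorbed into events).
#' @export
identify_dinucleotides <- function(records) {
  records <- validate_records(records)
  if (!nrow(records)) {
    return(list(events = records[0, c("sample", "chrom", "pos")],
                remaining = records))
  }
  ord <- order(records$sample, records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  paired <- logical(n)
  first_of_pair <- logical(n)
  i <- 1L
  while (i < n) {
    same <- records$sample[i + 1L] == records$sample[i] &&
      records$chrom[i + 1L] == records$chrom[i] &&
      records$pos[i + 1L] == records$pos[i] + 1L
    if (same) {
      paired[c(i, i + 1L)] <- TRUE
      first_of_pair[i] <- TRUE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  list(
    events = records[first_of_pair, c("sample", "chrom", "pos"), drop = FALSE],
    remaining = records[!paired, , drop = FALSE]
  )
}

#' Detect kataegis (clustered hypermutation) substitutions
#'
#' Kataegis substitutions are identified purely from intermutation distances,
#' regardless of sequence context: a maximal run of at least `min_run`
#' substitutions on the same chromosome of the same sample, with every
#' consecutive intermutation distance at most `max_imd` base pairs, is
#' labelled kataegis and excluded from the other substitutions.
#'
#' The thresholds are operational choices (the defaults follow the
#' intermutation-distance definitions used in breast-cancer hypermutation
#' analyses) and are configurable.
#'
#' @param records Mutation records (substitutions).
#' @param max_imd Maximum intermutation distance within a run, in bp.
#' @param min_run Minimum number of substitutions in a run.
#' @return A list with `kataegis` and `remaining` record data frames.
#' @export
detect_kataegis <- function(records, max_imd = 1000L, min_run = 6L) {
  stopifnot(max_imd > 0, min_run >= 2)
  records <- validate_records(records)
  if (!nrow(records)) return(list(kataegis = records, remaining = records))
  ord <- order(records$sample, records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  # break into runs: a new run starts when sample/chrom changes or gap > max_imd
  new_run <- c(TRUE, records$sample[-1L] != records$sample[-n] |
                 records$chrom[-1L] != records$chrom[-n] |
                 diff(records$pos) > max_imd)
  run_id <- cumsum(new_run)
  run_len <- ave(run_id, run_id, FUN = length)
  kat <- run_len >= min_run
  list(kataegis = records[kat, , drop = FALSE],
       remaining = records[!kat, , drop = FALSE])
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b)); i <- 0L
  while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L)) {
    i <- i + 1L
  }
  i
}

#' Classify an indel as repeat- or microhomology-mediated
#'
#' An indel is `repeat_mediated` when the inserted/deleted sequence is an
#' exact copy of the immediately adjacent sequence (a mono- or polynucleotide
#' repeat unit, on either side). A deletion that is not repeat-mediated is
#' `microhomology_mediated` when its boundaries share at least
#' `min_homology` identical bases (start of the deleted sequence vs the 3'
#' flank, or end of the deleted sequence vs the 5' flank). Everything else,
#' including all remaining insertions, is `other`.
#'
#' @param ref,alt Indel alleles (MAF `"-"` style or anchored).
#' @param flank5,flank3 Reference sequence immediately 5' and 3' of the
#'   indel; each must be at least as long as the indel.
#' @param min_homology Minimum shared bases to call microhomology.
#' @return One of `"repeat_mediated"`, `"microhomology_mediated"`, `"other"`.
#' @examples
#' classify_indel("A", "-", "T", "AAAT")     # repeat_mediated
#' classify_indel("CTAG", "-", "GGGG", "CTGA")  # microhomology (2 bp)
#' @export
classify_indel <- function(ref, alt, flank5, flank3, min_homology = 1L) {
  info <- indel_seq(ref, alt)
  if (is.na(info$type)) stop("not an indel: ", ref, ">", alt)
  seq <- info$seq
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  len <- nchar(seq)
  if (nchar(flank5) < len || nchar(flank3) < len) {
    stop("flanking sequence shorter than the indel")
  }
  if (substr(flank3, 1L, len) == seq ||
      substr(flank5, nchar(flank5) - len + 1L, nchar(flank5)) == seq) {
    return("repeat_mediated")
  }
  if (info$type == "del") {
    mh <- max(common_prefix_len(seq, flank3),
              common_prefix_len(rev_string(seq), rev_string(flank5)))
    if (mh >= min_homology) return("microhomology_mediated")
  }
  "other"
}

rev_string <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Annotate substitutions with transcriptional strand
#'
#' Substitutions inside the footprint of a transcribed protein-coding gene
#' are labelled by which strand carries the pyrimidine of the mutated base
#' pair: `"transcribed"` when the pyrimidine lies on the template
#' (transcribed) strand, `"untranscribed"` when it lies on the coding strand.
#' Substitutions outside all footprints are labelled `"unknown"` and are
#' excluded from strand-split (SBS192) catalogs.
#'
#' Footprint intervals are half-open, 0-based internally (BED convention);
#' record positions are 1-based (MAF convention).
#'
#' @param records Mutation records.
#' @param footprints A `GRanges` with strand, or a path to a BED6 file
#'   (strand in column 6). Intervals must not overlap each other.
#' @return `records` with a `strand` column filled in.
#' @export
annotate_strand <- function(records, footprints) {
  records <- validate_records(records)
  gr <- read_footprints(footprints)
  records$strand <- rep("unknown", nrow(records))
  if (!nrow(records)) return(records)
  q <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$pos, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(q, gr, select = "first")
  hit <- !is.na(hits)
  gene_strand <- as.character(GenomicRanges::strand(gr))[hits[hit]]
  pyr_on_plus <- toupper(records$ref[hit]) %in% c("C", "T")
  # + gene: template is the - strand; pyrimidine on + => coding strand
  records$strand[hit] <- ifelse(
    (gene_strand == "+") == pyr_on_plus, "untranscribed", "transcribed"
  )
  records
}

read_footprints <- function(footprints) {
  if (inherits(footprints, "GRanges")) {
    gr <- footprints
  } else {
    gr <- tryCatch(rtracklayer::import(footprints, format = "BED"),
                   error = function(e) stop("malformed footprint file: ",
                                            conditionMessage(e)))
  }
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(!strands %in% c("+", "-"))) {
    stop("footprints must be stranded (+/-) intervals")
  }
  if (length(gr) > 1L && any(GenomicRanges::countOverlaps(gr, gr) > 1L)) {
    stop("footprints must be non-overlapping")
  }
  gr
}

#' Extract sequence context around substitutions from a reference
#'
#' @param records Mutation records (substitutions).
#' @param reference A `DNAStringSet` keyed by chromosome name, or a path to
#'   a FASTA file.
#' @param width Number of context bases on each side (1 for SBS96/192,
#'   2 for SBS1536).
#' @return `records` with `context5` and `context3` columns (plus strand as
#'   given); context is reported on the reference (+) strand.
#' @export
extract_context <- function(records, reference, width = 1L) {
  records <- validate_records(records)
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  stopifnot(inherits(reference, "DNAStringSet"))
  ctx5 <- character(nrow(records)); ctx3 <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    chrom <- records$chrom[i]
    if (!chrom %in% names(reference)) {
      stop("chromosome not in reference: ", chrom)
    }
    s <- reference[[chrom]]
    p <- records$pos[i]
    if (p - width < 1L || p + width > length(s)) {
      stop("position too close to contig end for context width ", width)
    }
    ctx5[i] <- as.character(Biostrings::subseq(s, p - width, p - 1L))
    ctx3[i] <- as.character(Biostrings::subseq(s, p + 1L, p + width))
    ref_base <- as.character(Biostrings::subseq(s, p, p))
    if (nchar(records$ref[i]) == 1L && ref_base != toupper(records$ref[i])) {
      stop("reference base mismatch at ", chrom, ":", p,
           " (reference has ", ref_base, ", record has ", records$ref[i], ")")
    }
  }
  records$context5 <- ctx5
  records$context3 <- ctx3
  records
}
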
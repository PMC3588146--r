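#' Mutational catalog matrices
#'
#' A catalog is the K x G matrix M of nonnegative mutation-type counts: rows
#' follow the alphabet's label order, columns are samples (genomes). Columns
#' of M are the observed mixtures from which signatures are deciphered.
#'
#' @param counts K x G matrix of nonnegative integer counts.
#' @param alphabet A `sig_alphabet`; `nrow(counts)` must equal `alphabet$K`.
#' @param samples Optional sample identifiers (defaults to `colnames(counts)`).
#' @return An object of class `sig_catalog`: list with `alphabet`, `counts`
#'   (with dimnames), and `samples`.
#' @export
new_catalog <- function(counts, alphabet, samples = colnames(counts)) {
  stopifnot(inherits(alphabet, "sig_alphabet"))
  counts <- as.matrix(counts)
  if (nrow(counts) != alphabet$K) {
    stop("counts has ", nrow(counts), " rows; alphabet K = ", alphabet$K)
  }
  if (is.null(samples)) samples <- paste0("G", seq_len(ncol(counts)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (any(counts < 0)) stop("catalog counts must be nonnegative")
  if (any(counts != round(counts))) stop("catalog counts must be integers")
  dimnames(counts) <- list(alphabet$labels, samples)
  structure(list(alphabet = alphabet, counts = counts, samples = samples),
            class = "sig_catalog")
}

#' @export
print.sig_catalog <- function(x, ...) {
  cat("<sig_catalog> ", x$alphabet$scheme, ", K=", x$alphabet$K,
      ", G=", ncol(x$counts), ", total mutations=", sum(x$counts), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.matrix.sig_catalog <- function(x, ...) x$counts

#' Build a catalog matrix from per-mutation records
#'
#' Classifies each record and tabulates counts per mutation type and sample.
#' For the extended alphabet (`SBS96_EXT4`) the classification precedence is
#' deterministic: kataegis detection first, then dinucleotide pairing on the
#' remaining substitutions, then indel classification, then trinucleotide
#' substitution classification. A `class` column in `records`, when present,
#' overrides detection for the extended classes.
#'
#' For `SBS192`, records are strand-annotated against `footprints` when a
#' `strand` column is not already present; substitutions outside all
#' footprints (`strand == "unknown"`) are excluded by design (the strand
#' split is defined only on transcribed gene regions) and reported in the
#' `skipped` attribute, not treated as classification failures.
#'
#' @param records Mutation records data frame (see [read_mutations()]).
#' @param alphabet A `sig_alphabet`.
#' @param reference Optional reference sequence (FASTA path or
#'   `DNAStringSet`) used to fill in `context5`/`context3` when absent.
#' @param footprints Optional stranded gene footprints (BED6 path or
#'   `GRanges`) for SBS192.
#' @param strict If `TRUE`, unclassifiable records raise an error; if
#'   `FALSE` (default) they are skipped and counted in `attr(, "skipped")`.
#' @param kataegis_max_imd,kataegis_min_run Kataegis thresholds
#'   (see [detect_kataegis()]).
#' @param min_homology Microhomology threshold (see [classify_indel()]).
#' @return A `sig_catalog`; attribute `skipped` holds the number of records
#'   not classifiable under the chosen alphabet.
#' @export
catalog_from_records <- function(records, alphabet, reference = NULL,
                                 footprints = NULL, strict = FALSE,
                                 kataegis_max_imd = 1000L,
                                 kataegis_min_run = 6L,
                                 min_homology = 1L) {
  stopifnot(inherits(alphabet, "sig_alphabet"))
  records <- validate_records(records)
  samples <- unique(records$sample)
  counts <- matrix(0L, nrow = alphabet$K, ncol = length(samples),
                   dimnames = list(alphabet$labels, samples))
  skipped <- 0L
  if (!nrow(records)) {
    out <- new_catalog(counts, alphabet, samples)
    attr(out, "skipped") <- skipped
    return(out)
  }

  add <- function(labels, samp) {
    if (!length(labels)) return(invisible())
    tab <- table(factor(labels, levels = alphabet$labels),
                 factor(samp, levels = samples))
    counts <<- counts + as.matrix(unclass(tab))
  }
  drop_records <- function(rec, why) {
    if (nrow(rec) == 0L) return(invisible())
    if (strict) stop(nrow(rec), " unclassifiable record(s): ", why)
    skipped <<- skipped + nrow(rec)
  }

  indel <- is_indel_record(records)
  subs <- records[!indel, , drop = FALSE]
  indels <- records[indel, , drop = FALSE]
  ext <- alphabet$scheme == "SBS96_EXT4"

  # class overrides (extended classes supplied directly)
  if (ext && "class" %in% names(records)) {
    has_class <- !is.na(records$class) & nzchar(records$class)
    override <- records[has_class, , drop = FALSE]
    ok <- override$class %in% alphabet$labels
    drop_records(override[!ok, , drop = FALSE], "unknown class label")
    add(override$class[ok], override$sample[ok])
    subs <- subs[!(rownames(subs) %in% rownames(override)), , drop = FALSE]
    indels <- indels[!(rownames(indels) %in% rownames(override)), ,
                     drop = FALSE]
  }

  if (ext) {
    kat <- detect_kataegis(subs, max_imd = kataegis_max_imd,
                           min_run = kataegis_min_run)
    add(rep("kataegis", nrow(kat$kataegis)), kat$kataegis$sample)
    dn <- identify_dinucleotides(kat$remaining)
    add(rep("dinucleotide", nrow(dn$events)), dn$events$sample)
    subs <- dn$remaining
    if (nrow(indels)) {
      cls <- character(nrow(indels))
      for (i in seq_len(nrow(indels))) {
        if (!all(c("flank5", "flank3") %in% names(indels)) ||
            is.na(indels$flank5[i]) || is.na(indels$flank3[i])) {
          cls[i] <- "unflanked"
        } else {
          cls[i] <- classify_indel(indels$ref[i], indels$alt[i],
                                   indels$flank5[i], indels$flank3[i],
                                   min_homology = min_homology)
        }
      }
      lab <- c(repeat_mediated = "indel_repeat",
               microhomology_mediated = "indel_microhomology")[cls]
      keep <- !is.na(lab)
      drop_records(indels[!keep, , drop = FALSE],
                   "indel not at repeat or microhomology, or lacking flanks")
      add(lab[keep], indels$sample[keep])
    }
  } else {
    drop_records(indels, "indels are not part of this alphabet")
  }

  # remaining single-base substitutions
  if (nrow(subs)) {
    width <- switch(alphabet$scheme, SBS6 = 0L, SBS1536 = 2L, 1L)
    if (width > 0L && !all(c("context5", "context3") %in% names(subs))) {
      if (is.null(reference)) {
        drop_records(subs, "no sequence context and no reference supplied")
        subs <- subs[0, , drop = FALSE]
      } else {
        subs <- extract_context(subs, reference, width = width)
      }
    }
    if (alphabet$scheme == "SBS192") {
      if (!"strand" %in% names(subs) ||
          all(is.na(subs$strand))) {
        if (is.null(footprints)) {
          stop("SBS192 requires strand labels or gene footprints")
        }
        subs <- annotate_strand(subs, footprints)
      }
      genic <- subs$strand %in% c("transcribed", "untranscribed")
      # outside-footprint substitutions are excluded by design, not failures
      subs <- subs[genic, , drop = FALSE]
    }
    if (nrow(subs)) {
      lab <- classify_substitution(
        subs$ref, subs$alt,
        if (width > 0L) subs$context5 else "",
        if (width > 0L) subs$context3 else "",
        alphabet,
        strand = if (alphabet$scheme == "SBS192") subs$strand else NULL
      )
      add(lab, subs$sample)
    }
  }

  out <- new_catalog(counts, alphabet, samples)
  attr(out, "skipped") <- skipped
  out
}

#' Read / write catalog TSV files
#'
#' The on-disk format is a tab-separated table whose first column,
#' `MutationType`, holds the type labels and whose remaining columns are
#' samples with integer counts. Rows may appear in any order; they are
#' reordered to the canonical alphabet order on read, so that
#' `write_catalog()` followed by [read_catalog()] is the identity on counts,
#' labels and sample order.
#'
#' @param path File path.
#' @param alphabet Optional `sig_alphabet`; inferred from the label set when
#'   omitted.
#' @return `read_catalog()` returns a `sig_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path, alphabet = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) stop("ragged rows in catalog file")
  df <- utils::read.delim(path, check.names = FALSE, quote = "")
  if (names(df)[1] != "MutationType") {
    stop("first column must be 'MutationType'")
  }
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) stop("duplicate mutation-type labels")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric counts in catalog file")
  if (any(is.na(mat))) stop("missing counts in catalog file")
  if (any(mat < 0)) stop("negative counts in catalog file")
  if (any(mat != round(mat))) stop("non-integer counts in catalog file")
  if (is.null(alphabet)) alphabet <- infer_alphabet(labels)
  unknown <- setdiff(labels, alphabet$labels)
  if (length(unknown)) {
    stop("unknown mutation-type labels: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  missing <- setdiff(alphabet$labels, labels)
  if (length(missing)) {
    stop("catalog file lacks ", length(missing), " labels of scheme ",
         alphabet$scheme)
  }
  mat <- mat[match(alphabet$labels, labels), , drop = FALSE]
  new_catalog(mat, alphabet, colnames(mat))
}

infer_alphabet <- function(labels) {
  for (scheme in c("SBS6", "SBS96", "SBS192", "SBS1536", "SBS96_EXT4")) {
    ab <- build_alphabet(scheme)
    if (length(labels) == ab$K && setequal(labels, ab$labels)) return(ab)
  }
  stop("could not infer an alphabet scheme from ", length(labels), " labels")
}

#' @rdname read_catalog
#' @param catalog A `sig_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "sig_catalog"))
  df <- data.frame(MutationType = catalog$alphabet$labels,
                   catalog$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
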
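#' Mutation-type alphabets
#'
#' A mutation-type alphabet is the ordered set of K mutation-type labels over
#' which catalogs, signatures and simulations are defined. Supported schemes:
#'
#' * `"SBS6"` -- the six pyrimidine-referenced substitution classes
#'   (C>A, C>G, C>T, T>A, T>C, T>G), K = 6.
#' * `"SBS96"` -- substitutions with one base of 5' and 3' context,
#'   COSMIC-style labels `"A[C>T]G"`, K = 96.
#' * `"SBS192"` -- SBS96 further split by transcriptional strand, suffix
#'   `":T"` (transcribed) or `":U"` (untranscribed), K = 192.
#' * `"SBS1536"` -- substitutions with two bases of context on each side,
#'   labels `"AA[C>T]GG"`, K = 1536.
#' * `"SBS96_EXT4"` -- SBS96 plus four extended classes (`kataegis`,
#'   `dinucleotide`, `indel_repeat`, `indel_microhomology`), K = 100.
#'
#' Labels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C, T>G),
#' then lexicographically by 5' context, then 3' context; for SBS192 the
#' strand suffix varies fastest (T before U). Extended classes follow the 96
#' substitution labels in their classification precedence order. The ordering
#' is deterministic so that a signature is a lexicographically ordered
#' K-tuple of type probabilities.
#'
#' @param scheme Character scalar, one of `"SBS6"`, `"SBS96"`, `"SBS192"`,
#'   `"SBS1536"`, `"SBS96_EXT4"` (case-insensitive; `"sbs96ext4"` is also
#'   accepted).
#'
#' @return An object of class `sig_alphabet`: a list with elements `scheme`,
#'   `labels` (character vector of length K) and `K`.
#'
#' @examples
#' ab <- build_alphabet("SBS96")
#' ab$K
#' head(ab$labels)
#' @export
build_alphabet <- function(scheme) {
  stopifnot(is.character(scheme), length(scheme) == 1L)
  key <- toupper(gsub("[^A-Za-z0-9]", "", scheme))
  key <- sub("^SBS96EXT4$", "SBS96_EXT4", key)
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  labels <- switch(key,
    SBS6 = subs,
    SBS96 = sbs_context_labels(subs, bases, width = 1L),
    SBS192 = as.vector(t(outer(
      sbs_context_labels(subs, bases, width = 1L), c(":T", ":U"), paste0
    ))),
    SBS1536 = sbs_context_labels(subs, bases, width = 2L),
    SBS96_EXT4 = c(
      sbs_context_labels(subs, bases, width = 1L),
      c("kataegis", "dinucleotide", "indel_repeat", "indel_microhomology")
    ),
    stop("unsupported alphabet scheme: ", scheme)
  )
  scheme_name <- if (key == "SBS96_EXT4") "SBS96_EXT4" else key
  structure(
    list(scheme = scheme_name, labels = labels, K = length(labels)),
    class = "sig_alphabet"
  )
}

# class-major, then 5' then 3' context, each lexicographic
sbs_context_labels <- function(subs, bases, width) {
  ctx <- bases
  if (width == 2L) {
    ctx <- as.vector(t(outer(bases, bases, paste0)))
    ctx <- sort(ctx)
  }
  out <- character(0)
  for (s in subs) {
    for (c5 in ctx) {
      for (c3 in ctx) {
        out <- c(out, paste0(c5, "[", s, "]", c3))
      }
    }
  }
  out
}

#' @export
print.sig_alphabet <- function(x, ...) {
  cat("<sig_alphabet> scheme=", x$scheme, ", K=", x$K, "\n", sep = "")
  cat("  labels: ", paste(utils::head(x$labels, 4L), collapse = ", "),
      ", ...\n", sep = "")
  invisible(x)
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  # reverse complement of plain character vectors of A/C/G/T
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(REVCOMP[ch])), collapse = "")
  }, character(1))
}

check_bases <- function(x, what) {
  bad <- !grepl("^[ACGT]*$", x)
  if (any(bad)) {
    stop("non-ACGT characters in ", what, ": ",
         paste(unique(x[bad]), collapse = ", "))
  }
  invisible(x)
}

#' Classify a single-base substitution into a mutation-type label
#'
#' Applies the pyrimidine collapse: a substitution whose reference base is a
#' purine is reverse-complemented (together with its context, which is also
#' swapped 5'/3') before lookup, so a mutation and its reverse complement map
#' to the same label.
#'
#' @param ref,alt Reference and alternate bases (character vectors of single
#'   bases in A/C/G/T; `ref != alt` elementwise).
#' @param context5,context3 Immediate 5' and 3' context on the same strand as
#'   `ref`. Length (in bases) must match the scheme: 0 for SBS6, 1 for
#'   SBS96/SBS192, 2 for SBS1536.
#' @param alphabet A `sig_alphabet` (see [build_alphabet()]).
#' @param strand For SBS192 only: `"transcribed"` or `"untranscribed"`, the
#'   pyrimidine-referenced strand label (see [annotate_strand()]).
#'
#' @return Character vector of labels, each an element of `alphabet$labels`.
#' @examples
#' ab <- build_alphabet("SBS96")
#' classify_substitution("C", "T", "T", "G", ab)   # "T[C>T]G"
#' classify_substitution("G", "A", "C", "A", ab)   # same label
#' @export
classify_substitution <- function(ref, alt, context5 = "", context3 = "",
                                  alphabet, strand = NULL) {
  stopifnot(inherits(alphabet, "sig_alphabet"))
  n <- max(length(ref), length(alt), length(context5), length(context3))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context5 <- rep_len(toupper(context5), n)
  context3 <- rep_len(toupper(context3), n)
  check_bases(ref, "ref"); check_bases(alt, "alt")
  check_bases(context5, "context5"); check_bases(context3, "context3")
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L)) {
    stop("ref and alt must be single bases for substitutions")
  }
  if (any(ref == alt)) stop("ref and alt must differ")

  ctx_need <- switch(alphabet$scheme,
    SBS6 = 0L, SBS96 = 1L, SBS192 = 1L, SBS1536 = 2L, SBS96_EXT4 = 1L)
  if (ctx_need > 0L &&
      (any(nchar(context5) != ctx_need) || any(nchar(context3) != ctx_need))) {
    stop("context length must be ", ctx_need, " for scheme ", alphabet$scheme)
  }

  # pyrimidine collapse
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    new5 <- ifelse(flip, revcomp(context3), context5)
    new3 <- ifelse(flip, revcomp(context5), context3)
    ref <- ifelse(flip, unname(REVCOMP[ref]), ref)
    alt <- ifelse(flip, unname(REVCOMP[alt]), alt)
    context5 <- new5
    context3 <- new3
  }
  sub <- paste0(ref, ">", alt)

  lab <- switch(alphabet$scheme,
    SBS6 = sub,
    SBS1536 = paste0(context5, "[", sub, "]", context3),
    paste0(context5, "[", sub, "]", context3)  # SBS96 / SBS96_EXT4 / SBS192 base
  )
  if (alphabet$scheme == "SBS192") {
    if (is.null(strand)) stop("SBS192 classification requires a strand label")
    strand <- rep_len(as.character(strand), n)
    ok <- strand %in% c("transcribed", "untranscribed")
    if (!all(ok)) {
      stop("strand labels must be 'transcribed' or 'untranscribed' for SBS192")
    }
    lab <- paste0(lab, ifelse(strand == "transcribed", ":T", ":U"))
  }
  stopifnot(all(lab %in% alphabet$labels))
  lab
}
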
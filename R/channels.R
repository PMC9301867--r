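#' Mutation class and channel conventions
#'
#' Single-base substitutions (SBS) are reported with a pyrimidine reference
#' base: a purine-reference change is reverse-complemented before classing, so
#' G>A becomes C>T. Six classes (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the
#' 16 flanking-base combinations give the 96 trinucleotide channels, labelled
#' in the COSMIC style `"A[C>A]A"`.
#'
#' @name channels
NULL

SIXCLASS_KEYS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

BASES <- c("A", "C", "G", "T")

#' Complement DNA bases
#'
#' @param x character vector of single bases or base strings over A/C/G/T.
#' @return the complement, same shape; strings are complemented base-wise
#'   without reversal (use [revcomp()] for reverse complement).
#' @examples
#' complement_base(c("A", "C"))
#' revcomp("ACG")
#' @export
complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' @rdname complement_base
#' @export
revcomp <- function(x) {
  vapply(
    strsplit(complement_base(x), "", fixed = TRUE),
    function(b) paste(rev(b), collapse = ""),
    character(1)
  )
}

#' The six pyrimidine-reference substitution classes
#'
#' @return character vector of the six class keys in canonical order.
#' @export
sixclass_keys <- function() SIXCLASS_KEYS

#' The 96 SBS channel labels in canonical (COSMIC) order
#'
#' Ordered by substitution class, then 5' flank, then 3' flank, each
#' alphabetically: `A[C>A]A`, `A[C>A]C`, ..., `T[T>G]T`.
#'
#' @return character vector of length 96.
#' @examples
#' head(sbs96_channels())
#' @export
sbs96_channels <- function() {
  unlist(lapply(SIXCLASS_KEYS, function(cls) {
    unlist(lapply(BASES, function(f5) paste0(f5, "[", cls, "]", BASES)))
  }), use.names = FALSE)
}

#' Map a substitution to its pyrimidine-reference class
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return class keys such as `"T>A"`; purine-reference pairs are
#'   complemented (`A>T` maps to `T>A`).
#' @examples
#' sixclass_of("A", "T")
#' sixclass_of("G", "A")
#' @export
sixclass_of <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- !(ref %in% BASES) | !(alt %in% BASES) | ref == alt
  if (any(bad)) {
    abort(sprintf(
      "sixclass_of(): invalid substitution(s): %s",
      paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", ")
    ))
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- complement_base(ref[purine])
  alt[purine] <- complement_base(alt[purine])
  paste0(ref, ">", alt)
}

#' Build an SBS96 channel label from alleles and trinucleotide context
#'
#' Purine-reference records are reverse-complemented (context and alleles
#' together) so the middle base is a pyrimidine.
#'
#' @param ref,alt single bases (vectorized).
#' @param tri_context 3-mers whose middle base equals `ref` on the reported
#'   strand.
#' @return channel labels, or `NA` where the context is absent or inconsistent
#'   with `ref`.
#' @export
sbs96_channel_of <- function(ref, alt, tri_context) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ctx <- toupper(tri_context)
  n <- length(ref)
  out <- rep(NA_character_, n)
  ok <- !is.na(ctx) & nchar(ctx) == 3L & !is.na(ref) & !is.na(alt) &
    ref %in% BASES & alt %in% BASES & ref != alt
  if (!any(ok)) return(out)
  ctx_ok <- ctx[ok]
  ref_ok <- ref[ok]
  alt_ok <- alt[ok]
  purine <- ref_ok %in% c("A", "G")
  ctx_ok[purine] <- revcomp(ctx_ok[purine])
  ref_ok[purine] <- complement_base(ref_ok[purine])
  alt_ok[purine] <- complement_base(alt_ok[purine])
  consistent <- substr(ctx_ok, 2, 2) == ref_ok
  lab <- rep(NA_character_, sum(ok))
  lab[consistent] <- paste0(
    substr(ctx_ok[consistent], 1, 1),
    "[", ref_ok[consistent], ">", alt_ok[consistent], "]",
    substr(ctx_ok[consistent], 3, 3)
  )
  out[ok] <- lab
  out
}

#' Cosine similarity between two non-negative count vectors
#'
#' Standard reconstruction metric for signature refitting.
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return a value in `[0, 1]` for non-negative inputs.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine_similarity(): zero vector")
  }
  sum(a * b) / (na * nb)
}
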
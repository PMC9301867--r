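#' Consequence taxonomy
#'
#' Each mutation is assigned exactly one class:
#' `SYNONYMOUS`, `MISSENSE`, `NONSENSE`, `FRAMESHIFT`, `SPLICE_ACCEPTOR`,
#' `SPLICE_DONOR`, `NONSTOP`, `INDEL`, `OTHER`.
#'
#' `FRAMESHIFT` is reserved for 1-bp length differences between the alleles in
#' coding sequence; `INDEL` covers longer events and any UTR-located
#' insertion/deletion. Splice classes follow the canonical +/-2 dinucleotide
#' rule on the HGVS intron offset (no splice-strength scoring is done).
#'
#' @name consequence_classes
NULL

CONSEQUENCE_CLASSES <- c(
  "SYNONYMOUS", "MISSENSE", "NONSENSE", "FRAMESHIFT",
  "SPLICE_ACCEPTOR", "SPLICE_DONOR", "NONSTOP", "INDEL", "OTHER"
)

#' @rdname consequence_classes
#' @return `consequence_classes()` returns the nine class keys.
#' @export
consequence_classes <- function() CONSEQUENCE_CLASSES

AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*", Sec = "U"
)

#' Parse HGVS coding-DNA notation
#'
#' Handles the forms seen in annotated exome tables: plain substitutions
#' (`c.746A>T`), intron-offset substitutions (`c.41-2A>T`, `c.528+2T>A`), UTR
#' positions (`c.*30delC`, `c.-12G>A`), deletions, insertions, duplications and
#' delins, with or without an end position. Whitespace around `>` and `+` is
#' tolerated (tables often print `c.528 + 2 T > A`).
#'
#' @param text a single HGVS `c.` string.
#' @return a list with elements `coding_pos` (integer), `utr` (`"none"`,
#'   `"5"`, `"3"`), `intron_offset` (integer or `NA`), `edit` (`"SUB"`,
#'   `"DEL"`, `"INS"`, `"DUP"`, `"DELINS"`), `ref_base`/`alt_base` (for SUB),
#'   `length` (bases inserted/deleted; 1 for SUB) and `raw`.
#' @examples
#' parse_hgvs_c("c.41-2A>T")
#' parse_hgvs_c("c.*30delC")
#' @export
parse_hgvs_c <- function(text) {
  raw <- text
  if (is.na(text) || !nzchar(trimws(text))) {
    abort("parse_hgvs_c(): empty input")
  }
  s <- gsub("[[:space:]]+", "", text)
  if (!startsWith(s, "c.")) {
    abort(sprintf("parse_hgvs_c(): not c. notation: '%s'", raw))
  }
  s <- substr(s, 3, nchar(s))
  pos_re <- "([*-]?)(\\d+)([+-]\\d+)?"
  m <- regexec(paste0("^", pos_re, "(?:_", pos_re, ")?(.*)$"), s)
  g <- regmatches(s, m)[[1]]
  if (!length(g)) {
    abort(sprintf("parse_hgvs_c(): cannot parse '%s'", raw))
  }
  utr_tag <- g[2]
  coding_pos <- as.integer(g[3])
  offset <- if (nzchar(g[4])) as.integer(g[4]) else NA_integer_
  end_pos <- if (nzchar(g[6])) as.integer(g[6]) else NA_integer_
  tail <- g[8]
  utr <- switch(utr_tag, "*" = "3", "-" = "5", "none")
  out <- list(
    coding_pos = coding_pos, utr = utr, intron_offset = offset,
    edit = NA_character_, ref_base = NA_character_, alt_base = NA_character_,
    length = NA_integer_, raw = raw
  )
  sub_m <- regmatches(tail, regexec("^([ACGTacgt])>([ACGTacgt])$", tail))[[1]]
  if (length(sub_m)) {
    out$edit <- "SUB"
    out$ref_base <- toupper(sub_m[2])
    out$alt_base <- toupper(sub_m[3])
    out$length <- 1L
    return(out)
  }
  span <- if (is.na(end_pos)) 1L else abs(end_pos - coding_pos) + 1L
  edit_m <- regmatches(
    tail,
    regexec("^(delins|del|dup|ins)([ACGTacgt]*)$", tail)
  )[[1]]
  if (!length(edit_m)) {
    abort(sprintf("parse_hgvs_c(): cannot parse edit in '%s'", raw))
  }
  kind <- toupper(edit_m[2])
  bases <- toupper(edit_m[3])
  out$edit <- switch(kind, DELINS = "DELINS", DEL = "DEL",
                     DUP = "DUP", INS = "INS")
  out$length <- if (nzchar(bases)) nchar(bases) else span
  out
}

#' Parse HGVS protein notation
#'
#' @param text a single HGVS `p.` string, `"-"`, or empty/`NA` (no protein
#'   change annotated).
#' @return a list with elements `kind` (`"SUBSTITUTION"`, `"STOP_GAIN"`,
#'   `"STOP_LOSS"`, `"UNKNOWN"`, `"NONE"`), and for residue changes `ref_aa`,
#'   `pos`, `alt_aa` (one-letter code, `*` = stop).
#' @examples
#' parse_hgvs_p("p.K57*")
#' parse_hgvs_p("p.?")
#' parse_hgvs_p("-")
#' @export
parse_hgvs_p <- function(text) {
  none <- list(kind = "NONE", ref_aa = NA_character_, pos = NA_integer_,
               alt_aa = NA_character_, raw = text)
  if (is.na(text)) return(none)
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s) || s == "-") return(none)
  if (!startsWith(s, "p.")) {
    abort(sprintf("parse_hgvs_p(): not p. notation: '%s'", text))
  }
  s <- sub("^p\\.", "", s)
  s <- gsub("[()]", "", s)
  if (s == "?") {
    return(list(kind = "UNKNOWN", ref_aa = NA_character_, pos = NA_integer_,
                alt_aa = NA_character_, raw = text))
  }
  if (s == "=") return(none)
  aa1 <- function(x) {
    if (x %in% AA3TO1) return(x)
    if (x %in% names(AA3TO1)) return(unname(AA3TO1[x]))
    if (x %in% c("*", "X", "Ter")) return("*")
    NA_character_
  }
  m <- regmatches(
    s, regexec("^([A-Za-z*]{1,3})(\\d+)([A-Za-z*=]{1,3})$", s)
  )[[1]]
  if (!length(m)) {
    abort(sprintf("parse_hgvs_p(): cannot parse '%s'", text))
  }
  ref_aa <- aa1(m[2])
  alt_aa <- if (m[4] == "=") ref_aa else aa1(m[4])
  if (is.na(ref_aa) || is.na(alt_aa)) {
    abort(sprintf("parse_hgvs_p(): unknown residue code in '%s'", text))
  }
  kind <- if (alt_aa == "*" && ref_aa != "*") {
    "STOP_GAIN"
  } else if (ref_aa == "*" && alt_aa != "*") {
    "STOP_LOSS"
  } else {
    "SUBSTITUTION"
  }
  list(kind = kind, ref_aa = ref_aa, pos = as.integer(m[3]),
       alt_aa = alt_aa, raw = text)
}

## classify one record from parsed pieces; NULL pieces mean "not available"
classify_one <- function(hc, hp, ref, alt) {
  ## (1) canonical splice sites from the intron offset
  if (!is.null(hc) && !is.na(hc$intron_offset)) {
    if (hc$intron_offset %in% c(-1L, -2L)) return("SPLICE_ACCEPTOR")
    if (hc$intron_offset %in% c(1L, 2L)) return("SPLICE_DONOR")
  }
  ## (2) length-changing events: 1 bp in coding sequence is a frameshift,
  ##     anything longer (or UTR-located) is an indel
  len_diff <- NA_integer_
  utr <- if (!is.null(hc)) hc$utr else "none"
  if (!is.na(ref) && !is.na(alt) && nchar(alt) > 0 &&
      (nchar(ref) != nchar(alt))) {
    len_diff <- abs(nchar(ref) - nchar(alt))
  } else if (!is.null(hc) && hc$edit %in% c("DEL", "INS", "DUP", "DELINS")) {
    len_diff <- if (hc$edit == "DELINS") 0L else hc$length
    if (hc$edit == "DELINS") {
      return("INDEL")
    }
  }
  if (!is.na(len_diff) && len_diff > 0L) {
    in_coding <- utr == "none" && (is.null(hc) || is.na(hc$intron_offset))
    if (len_diff == 1L && in_coding) return("FRAMESHIFT")
    return("INDEL")
  }
  ## (3)-(5) protein-level calls
  if (!is.null(hp)) {
    if (hp$kind == "SUBSTITUTION") {
      return(if (hp$ref_aa == hp$alt_aa) "SYNONYMOUS" else "MISSENSE")
    }
    if (hp$kind == "STOP_GAIN") return("NONSENSE")
    if (hp$kind == "STOP_LOSS") return("NONSTOP")
  }
  ## (6) annotated "no protein change" on a coding substitution
  if (!is.null(hp) && hp$kind == "NONE" &&
      !is.null(hc) && identical(hc$edit, "SUB") && utr == "none" &&
      is.na(hc$intron_offset)) {
    return("SYNONYMOUS")
  }
  "OTHER"
}

#' Classify a mutation into the consequence taxonomy
#'
#' Deterministic priority: (1) intron offsets -1/-2 give `SPLICE_ACCEPTOR`,
#' +1/+2 give `SPLICE_DONOR`; (2) allele-length differences give `FRAMESHIFT`
#' (exactly 1 bp, coding) or `INDEL` (longer, or UTR); (3) protein
#' substitutions give `SYNONYMOUS`/`MISSENSE`; (4) stop gain gives `NONSENSE`;
#' (5) stop loss gives `NONSTOP`; (6) an annotated "no protein change" (`-`)
#' on a coding substitution gives `SYNONYMOUS`; (7) anything else is `OTHER`
#' (with a warning when a record carries no classifiable information at all).
#'
#' @param hgvs_c,hgvs_p HGVS strings (either may be `NA`).
#' @param ref,alt allele strings (either may be `NA`).
#' @return a single class key from [consequence_classes()].
#' @examples
#' classify_consequence("c.169A>T", "p.K57*")       # NONSENSE
#' classify_consequence("c.528+2T>A", "p.?")        # SPLICE_DONOR
#' classify_consequence("c.429C>T", "-")            # SYNONYMOUS
#' @export
classify_consequence <- function(hgvs_c = NA, hgvs_p = NA,
                                 ref = NA, alt = NA) {
  hc <- if (!is.na(hgvs_c) && nzchar(trimws(hgvs_c))) {
    parse_hgvs_c(hgvs_c)
  } else {
    NULL
  }
  hp <- if (!is.na(hgvs_p)) parse_hgvs_p(hgvs_p) else NULL
  no_alleles <- is.na(ref) || is.na(alt)
  out <- classify_one(hc, hp, as.character(ref), as.character(alt))
  if (out == "OTHER" && is.null(hc) && is.null(hp) && no_alleles) {
    warn("classify_consequence(): record carries no classifiable information")
  }
  out
}

#' Classify every record of a variant table
#'
#' Adds/fills the `consequence` column. A precomputed `consequence` value
#' wins over re-derivation unless `reclassify = TRUE`, since inputs may come
#' from richer annotators. Records for which neither HGVS nor alleles support
#' a call are left `NA` (unclassified) rather than forced to `OTHER`.
#'
#' @param records a variant tibble.
#' @param reclassify logical; re-derive even where `consequence` is present.
#' @return `records` with the `consequence` column filled where derivable.
#' @export
classify_variants <- function(records, reclassify = FALSE) {
  records <- as_variant_tbl(records)
  todo <- if (reclassify) {
    rep(TRUE, nrow(records))
  } else {
    is.na(records$consequence)
  }
  ## only rows with some classifiable information
  has_info <- !is.na(records$hgvs_c) | !is.na(records$hgvs_p) |
    (nchar(records$ref) != nchar(records$alt) & !is.na(records$alt))
  idx <- which(todo & has_info)
  if (length(idx)) {
    records$consequence[idx] <- vapply(idx, function(i) {
      classify_consequence(
        records$hgvs_c[i], records$hgvs_p[i],
        records$ref[i], records$alt[i]
      )
    }, character(1))
  }
  records
}

#' Does a consequence class change the protein?
#'
#' Splice, frameshift, indel, nonsense, nonstop and missense classes all count
#' as protein-affecting for gene prioritization; only `SYNONYMOUS` and `OTHER`
#' do not. UTR indels count as protein-affecting (they are kept by the
#' gene-level filter).
#'
#' @param consequence character vector of class keys (NA allowed).
#' @return logical vector; `NA` stays `NA`.
#' @export
is_amino_acid_changing <- function(consequence) {
  out <- !(consequence %in% c("SYNONYMOUS", "OTHER"))
  out[is.na(consequence)] <- NA
  out
}
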
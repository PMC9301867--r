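## single-base substitution mask over a variant tibble
is_sbs <- function(records) {
  !is.na(records$alt) & nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% BASES & toupper(records$alt) %in% BASES &
    toupper(records$ref) != toupper(records$alt)
}

sixclass_zero <- function() setNames(rep(0L, 6), SIXCLASS_KEYS)

#' Six-class substitution spectrum of one sample
#'
#' Counts the sample's single-base substitutions (indels and multi-base events
#' are excluded) in the six pyrimidine-reference classes, and the
#' corresponding frequencies.
#'
#' @param records a variant tibble.
#' @param sample_id the sample to tabulate.
#' @return a tibble with one row per class: `class`, `count`, `freq`, and an
#'   attribute `empty = TRUE` when the sample has no substitutions (all
#'   frequencies are then reported as 0).
#' @export
sample_spectrum <- function(records, sample_id) {
  sub <- records[records$sample_id == sample_id & is_sbs(records), ,
                 drop = FALSE]
  counts <- sixclass_zero()
  if (nrow(sub)) {
    tab <- table(sixclass_of(sub$ref, sub$alt))
    counts[names(tab)] <- as.integer(tab)
  }
  total <- sum(counts)
  out <- tibble::tibble(
    class = SIXCLASS_KEYS,
    count = as.integer(counts),
    freq = if (total > 0) as.numeric(counts) / total else rep(0, 6)
  )
  attr(out, "empty") <- total == 0
  out
}

#' Six-class spectrum summary of a cohort
#'
#' Two conventions are supported: `MEAN_OF_SAMPLES` averages each sample's
#' frequency vector (every sample weighs equally, the convention behind
#' per-group "Frequency (%)" rows), while `POOLED` sums counts across samples
#' and normalizes once (the "frequency of total events" convention). The two
#' agree exactly when all samples carry equal substitution totals.
#'
#' @param records a variant tibble.
#' @param group cohort label (`"CASE"` or `"CONTROL"`); rows of other groups
#'   are ignored.
#' @param mode `"MEAN_OF_SAMPLES"` or `"POOLED"`.
#' @return a tibble with `class`, `count` (pooled counts, both modes) and
#'   `freq` per the chosen mode.
#' @export
group_spectrum_summary <- function(records, group,
                                   mode = c("MEAN_OF_SAMPLES", "POOLED")) {
  mode <- match.arg(mode)
  grp <- records[records$group == toupper(group), , drop = FALSE]
  ids <- unique(grp$sample_id)
  if (!length(ids)) abort("group_spectrum_summary(): group has no samples")
  per <- lapply(ids, function(s) sample_spectrum(grp, s))
  counts <- Reduce(`+`, lapply(per, function(p) p$count))
  freq <- if (mode == "POOLED") {
    if (sum(counts) > 0) counts / sum(counts) else rep(0, 6)
  } else {
    nonempty <- per[!vapply(per, attr, logical(1), "empty")]
    if (!length(nonempty)) {
      rep(0, 6)
    } else {
      Reduce(`+`, lapply(nonempty, function(p) p$freq)) / length(nonempty)
    }
  }
  tibble::tibble(class = SIXCLASS_KEYS, count = as.integer(counts),
                 freq = as.numeric(freq))
}

#' Mutation-category accounting for a record set
#'
#' Mirrors the two-level taxonomy used in exome summaries: records whose
#' alleles differ in length by more than 1 bp (and length-preserving
#' multi-base substitutions) are counted as indels; 1-bp length differences
#' are counted as `FRAMESHIFT` inside the single-base-substitution block;
#' remaining substitutions are tallied by their consequence class.
#'
#' @param records a variant tibble (with `consequence` filled where known; see
#'   [classify_variants()]).
#' @param scope optional: a `group` label or `sample_id` to restrict to. By
#'   default all records are tabulated.
#' @return a one-row tibble: `total_somatic`, `indel_total`, `sbs_total`, and
#'   one column per consequence class tallied inside the SBS block
#'   (unclassified substitutions appear under `UNCLASSIFIED`).
#' @export
category_counts <- function(records, scope = NULL) {
  if (!is.null(scope)) {
    keep <- records$group == toupper(scope) | records$sample_id == scope
    records <- records[keep, , drop = FALSE]
  }
  len_ref <- nchar(records$ref)
  len_alt <- ifelse(is.na(records$alt), 0L, nchar(records$alt))
  diff <- abs(len_ref - len_alt)
  multibase_sub <- diff == 0L & len_ref > 1L
  indel <- diff > 1L | multibase_sub
  one_bp <- diff == 1L
  sbs_block <- !indel
  cls <- records$consequence
  cls[one_bp] <- "FRAMESHIFT"
  cls[sbs_block & is.na(cls)] <- "UNCLASSIFIED"
  tab <- table(factor(cls[sbs_block],
                      levels = c(CONSEQUENCE_CLASSES, "UNCLASSIFIED")))
  out <- tibble::tibble(
    total_somatic = nrow(records),
    indel_total = sum(indel),
    sbs_total = sum(sbs_block)
  )
  for (k in names(tab)) out[[k]] <- as.integer(tab[[k]])
  out$INDEL <- NULL  # length-based accounting supersedes the class tally
  out
}

#' Plot a six-class spectrum
#'
#' @param spectrum a tibble from [sample_spectrum()] or
#'   [group_spectrum_summary()] (optionally several, row-bound with an extra
#'   grouping column passed as `facet`).
#' @param facet optional column name to facet by.
#' @return a ggplot bar chart of class frequencies.
#' @export
plot_spectrum <- function(spectrum, facet = NULL) {
  p <- ggplot2::ggplot(
    spectrum,
    ggplot2::aes(x = .data$class, y = .data$freq, fill = .data$class)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of substitutions") +
    ggplot2::theme_minimal()
  if (!is.null(facet)) {
    p <- p + ggplot2::facet_wrap(facet)
  }
  p
}
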
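#' CNV event tables
#'
#' Copy-number events are tibbles with columns `sample_id`, `chrom`, `start`
#' (1-based), `end`, `type` (`"DEL"`/`"DUP"`), optional `ratio`, and `group`
#' when two cohorts are compared. Events are matched across samples by their
#' exact (`chrom`, `start`) key only — recurrence uses the start site as the
#' reference, with no interval-overlap logic.
#'
#' @name cnv_events
NULL

cnv_key <- function(events) paste(events$chrom, events$start, sep = ":")

#' Select recurrent CNV start keys within one cohort
#'
#' @param events CNV tibble restricted to one group.
#' @param min_samples minimum number of distinct samples sharing a
#'   (`chrom`, `start`) key (default 2).
#' @return character vector of `"chrom:start"` keys observed in at least
#'   `min_samples` distinct samples, sorted.
#' @export
select_recurrent_events <- function(events, min_samples = 2L) {
  if (!nrow(events)) return(character())
  counts <- tibble::tibble(
    key = cnv_key(events), sample_id = events$sample_id
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$key, name = "n_samples")
  sort(counts$key[counts$n_samples >= min_samples])
}

#' Case-specific recurrent CNV events
#'
#' Selects recurrent start keys in each cohort, removes keys recurrent in
#' both, and reports the surviving case events. With
#' `against = "all_control"`, case keys are instead removed whenever they
#' appear in any control event (recurrent or not).
#'
#' @param case_events,control_events CNV tibbles per cohort.
#' @param min_samples recurrence threshold per cohort (default 2).
#' @param against compare case keys to the control group's `"recurrent"`
#'   (default) or `"all_control"` keys.
#' @return a list: `events` (surviving case events), `keys` (their unique
#'   start keys), `n_unique` and `n_events`.
#' @export
group_specific_events <- function(case_events, control_events,
                                  min_samples = 2L,
                                  against = c("recurrent", "all_control")) {
  against <- match.arg(against)
  case_keys <- select_recurrent_events(case_events, min_samples)
  control_keys <- if (against == "recurrent") {
    select_recurrent_events(control_events, min_samples)
  } else {
    unique(cnv_key(control_events))
  }
  keys <- setdiff(case_keys, control_keys)
  events <- case_events[cnv_key(case_events) %in% keys, , drop = FALSE]
  list(
    events = events,
    keys = sort(keys),
    n_unique = length(keys),
    n_events = nrow(events)
  )
}
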
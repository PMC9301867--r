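#' Funnel configuration
#'
#' Defaults reproduce the published pipeline: every dbSNP-annotated record is
#' excluded, recurrence requires two or more distinct samples, and genes whose
#' classified mutations are all synonymous are dropped at the end.
#'
#' @param af_max_known population-AF ceiling for the known-polymorphism
#'   filter. `0` (default) excludes every dbSNP-annotated record regardless of
#'   AF; a value in `(0, 1]` switches to the alternate policy of excluding
#'   only dbSNP-annotated records with `pop_af <= af_max_known` (records with
#'   unknown AF are then kept).
#' @param recurrence_min minimum number of distinct units a gene must be
#'   mutated in (default 2).
#' @param recurrence_unit `"SAMPLE"` (default) or `"PATIENT"`. SAMPLE counts
#'   `sample_id`s; PATIENT counts `patient_id`s, so two samples from one
#'   patient count once.
#' @param require_amino_acid_change drop final genes without any
#'   protein-affecting mutation (default `TRUE`).
#' @return a list of class `funnel_config`.
#' @export
funnel_config <- function(af_max_known = 0,
                          recurrence_min = 2L,
                          recurrence_unit = c("SAMPLE", "PATIENT"),
                          require_amino_acid_change = TRUE) {
  recurrence_unit <- match.arg(recurrence_unit)
  stopifnot(af_max_known >= 0, af_max_known <= 1, recurrence_min >= 1)
  structure(
    list(
      af_max_known = af_max_known,
      recurrence_min = as.integer(recurrence_min),
      recurrence_unit = recurrence_unit,
      require_amino_acid_change = isTRUE(require_amino_acid_change)
    ),
    class = "funnel_config"
  )
}

## split multi-symbol gene cells (";"-joined by collapse_transcripts)
split_genes <- function(gene) strsplit(gene, ";", fixed = TRUE)

#' Genes mutated in a record set
#'
#' @param records a variant tibble.
#' @return a [gene_set()] of all symbols carried by the records.
#' @export
mutated_genes <- function(records) {
  gene_set(unlist(split_genes(records$gene)), name = "mutated")
}

## does each record carry at least one symbol in `set`?
record_in_set <- function(gene, set) {
  vapply(split_genes(gene), function(g) any(g %in% set), logical(1))
}

#' Remove catalogued germline polymorphisms
#'
#' Default policy removes every record with a non-empty `dbsnp_id`. With
#' `af_max_known > 0` only dbSNP-annotated records with
#' `pop_af <= af_max_known` are removed (the rare-known-variant reading).
#' Records without a dbSNP annotation always pass.
#'
#' @param records a variant tibble.
#' @param config a [funnel_config()].
#' @return the surviving records.
#' @export
filter_known_polymorphisms <- function(records, config = funnel_config()) {
  known <- !is.na(records$dbsnp_id) & nzchar(records$dbsnp_id)
  drop <- if (config$af_max_known > 0) {
    known & !is.na(records$pop_af) & records$pop_af <= config$af_max_known
  } else {
    known
  }
  records[!drop, , drop = FALSE]
}

#' Collapse per-transcript annotations to one record per mutation
#'
#' Mutations at the same genomic location annotated against different
#' transcripts are counted once: records are grouped by
#' (`sample_id`, `chrom`, `pos`, `ref`, `alt`) and one representative is kept
#' per key (the lexicographically lowest `transcript`, unannotated last).
#' Conflicting gene symbols within a key are all retained on the
#' representative, `";"`-joined, with a warning. Output rows are sorted by
#' key, so the operation is deterministic and idempotent.
#'
#' @param records a variant tibble.
#' @return collapsed records.
#' @export
collapse_transcripts <- function(records) {
  if (!nrow(records)) return(records)
  out <- records |>
    dplyr::mutate(
      .tx = dplyr::coalesce(.data$transcript, "\uffff"),
      .gl = split_genes(.data$gene)
    ) |>
    dplyr::group_by(
      .data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt
    ) |>
    dplyr::arrange(.data$.tx, .by_group = TRUE) |>
    dplyr::mutate(
      .all_genes = paste(sort(unique(unlist(.data$.gl))), collapse = ";"),
      .n_genes = length(unique(unlist(.data$.gl)))
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  if (any(out$.n_genes > 1)) {
    warn(sprintf(
      "collapse_transcripts(): %d mutation key(s) carry conflicting gene symbols; all symbols kept",
      sum(out$.n_genes > 1)
    ))
  }
  out$gene <- out$.all_genes
  out |>
    dplyr::select(-dplyr::all_of(c(".tx", ".gl", ".all_genes", ".n_genes"))) |>
    dplyr::arrange(
      .data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt
    )
}

#' Retain records in catalogued cancer driver genes
#'
#' @param records a variant tibble.
#' @param drivers a [gene_set()] of driver symbols (non-empty).
#' @return records whose gene is in `drivers`; the surviving gene set is
#'   `mutated_genes()` of the result.
#' @export
retain_driver_genes <- function(records, drivers) {
  if (!length(drivers)) abort("retain_driver_genes(): empty driver set")
  out <- records[record_in_set(records$gene, drivers), , drop = FALSE]
  ## non-driver symbols on multi-symbol cells do not pass the stage
  out$gene <- vapply(
    split_genes(out$gene),
    function(g) paste(intersect(g, drivers), collapse = ";"),
    character(1)
  )
  out
}

#' Exclude genes already reported for the disease
#'
#' @param records a variant tibble.
#' @param reported a [gene_set()] or list of gene sets (e.g. one per source
#'   database); their union is excluded.
#' @return records whose gene is not in the union of `reported`.
#' @export
exclude_reported_genes <- function(records, reported) {
  if (is.list(reported)) reported <- unlist(reported)
  reported <- gene_set(reported %||% character(), name = "reported")
  keep <- vapply(
    split_genes(records$gene),
    function(g) any(!g %in% reported),
    logical(1)
  )
  out <- records[keep, , drop = FALSE]
  ## strip reported symbols from multi-symbol cells
  out$gene <- vapply(
    split_genes(out$gene),
    function(g) paste(setdiff(g, reported), collapse = ";"),
    character(1)
  )
  out
}

#' Case-unique genes
#'
#' @param case_genes,control_genes gene sets that passed the same upstream
#'   stages in each cohort.
#' @return `case_genes` minus `control_genes`.
#' @export
group_unique_genes <- function(case_genes, control_genes) {
  gene_set(setdiff(case_genes, control_genes), name = "case_unique")
}

#' Keep genes recurrently mutated across samples (or patients)
#'
#' @param records variant tibble restricted to one cohort.
#' @param genes optional gene set to restrict to (default: all mutated genes).
#' @param config a [funnel_config()]; `recurrence_min` and `recurrence_unit`
#'   are used.
#' @return the gene set mutated in at least `recurrence_min` distinct units.
#' @export
recurrence_filter <- function(records, genes = NULL,
                              config = funnel_config()) {
  if (is.null(genes)) genes <- mutated_genes(records)
  unit <- if (config$recurrence_unit == "PATIENT") {
    records$patient_id
  } else {
    records$sample_id
  }
  pairs <- tibble::tibble(unit = unit, gene = records$gene) |>
    dplyr::mutate(gene = split_genes(.data$gene)) |>
    tidyr::unnest("gene") |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::distinct()
  counts <- dplyr::count(pairs, .data$gene, name = "n_units")
  gene_set(
    counts$gene[counts$n_units >= config$recurrence_min],
    name = "recurrent"
  )
}

#' Keep genes with at least one protein-affecting mutation
#'
#' A gene is dropped only when it has classified mutations and none of them is
#' amino-acid-changing (see [is_amino_acid_changing()]). Genes whose records
#' are all unclassified (`consequence` `NA`) are kept: absence of annotation
#' is not evidence of a silent mutation.
#'
#' @param records variant tibble (with the `consequence` column filled where
#'   derivable, see [classify_variants()]).
#' @param genes optional gene set to restrict to.
#' @return the surviving gene set.
#' @export
nonsynonymous_gene_filter <- function(records, genes = NULL) {
  if (is.null(genes)) genes <- mutated_genes(records)
  pergene <- tibble::tibble(
    gene = records$gene, consequence = records$consequence
  ) |>
    dplyr::mutate(gene = split_genes(.data$gene)) |>
    tidyr::unnest("gene") |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      keep = any(is.na(.data$consequence)) |
        any(is_amino_acid_changing(.data$consequence), na.rm = TRUE),
      .groups = "drop"
    )
  gene_set(pergene$gene[pergene$keep], name = "amino_acid_changing")
}

funnel_stage_row <- function(stage, group, records) {
  genes <- mutated_genes(records)
  tibble::tibble(
    stage = stage, group = group,
    n_mutations = nrow(records), n_genes = length(genes),
    genes = list(as.character(genes))
  )
}

#' Run the full gene-prioritization funnel
#'
#' Applies, in fixed order: known-polymorphism exclusion, transcript
#' collapsing, driver-catalog retention, and exclusion of previously reported
#' genes to both cohorts; then the case-unique overlap, the recurrence filter
#' and (optionally) the amino-acid-change filter to the case cohort. Stage
#' order is not configurable.
#'
#' @param case,control variant tibbles for the case and control cohorts.
#' @param drivers a [gene_set()] of catalogued driver genes.
#' @param reported a gene set or list of gene sets of previously reported
#'   disease genes; their union is excluded.
#' @param config a [funnel_config()].
#' @return an object of class `funnel_report`: a list with `stages` (per
#'   stage/group counts and gene lists), `final_genes`, `final_records`, and
#'   `config`. Methods: [tidy()], [glance()], `print()`,
#'   [autoplot.funnel_report()], [render_funnel_report()].
#' @examples
#' samples <- sample_sheet(paste0("S", 1:5),
#'                         c("CASE", "CASE", "CASE", "CONTROL", "CONTROL"))
#' toy <- tibble::tibble(
#'   sample_id = c("S1", "S2", "S1", "S1", "S4", "S3"),
#'   chrom = "chr1", pos = 1:6 * 100L, ref = "A", alt = "T",
#'   gene = c("G1", "G1", "G2", "G5", "G3", "G1"),
#'   dbsnp_id = c(NA, NA, NA, NA, NA, "rs123")
#' )
#' toy <- as_cohort(toy, samples)
#' rep <- run_funnel(
#'   case = dplyr::filter(toy, group == "CASE"),
#'   control = dplyr::filter(toy, group == "CONTROL"),
#'   drivers = gene_set(c("G1", "G2", "G3", "G5")),
#'   reported = gene_set("G5")
#' )
#' rep$final_genes
#' @export
run_funnel <- function(case, control, drivers, reported = character(),
                       config = funnel_config()) {
  case <- as_variant_tbl(case)
  control <- as_variant_tbl(control)
  stages <- list()
  per_group <- function(records, group) {
    rows <- list(funnel_stage_row("input", group, records))
    records <- filter_known_polymorphisms(records, config)
    records <- collapse_transcripts(records)
    rows <- c(rows, list(funnel_stage_row("novel", group, records)))
    records <- retain_driver_genes(records, drivers)
    rows <- c(rows, list(funnel_stage_row("driver", group, records)))
    records <- exclude_reported_genes(records, reported)
    rows <- c(rows, list(funnel_stage_row("unreported", group, records)))
    list(records = records, rows = rows)
  }
  ca <- per_group(case, "CASE")
  co <- per_group(control, "CONTROL")
  case_genes <- mutated_genes(ca$records)
  control_genes <- mutated_genes(co$records)
  unique_genes <- group_unique_genes(case_genes, control_genes)
  case_unique <- ca$records[
    record_in_set(ca$records$gene, unique_genes), , drop = FALSE
  ]
  rows <- c(ca$rows, co$rows,
            list(funnel_stage_row("case_unique", "CASE", case_unique)))
  recurrent <- recurrence_filter(case_unique, unique_genes, config)
  rec_records <- case_unique[
    record_in_set(case_unique$gene, recurrent), , drop = FALSE
  ]
  rows <- c(rows, list(funnel_stage_row("recurrent", "CASE", rec_records)))
  final_genes <- recurrent
  final_records <- rec_records
  if (config$require_amino_acid_change) {
    final_genes <- nonsynonymous_gene_filter(rec_records, recurrent)
    final_records <- rec_records[
      record_in_set(rec_records$gene, final_genes), , drop = FALSE
    ]
    rows <- c(rows,
              list(funnel_stage_row("amino_acid_change", "CASE",
                                    final_records)))
  }
  stages <- dplyr::bind_rows(rows)
  structure(
    list(
      stages = stages,
      final_genes = gene_set(final_genes, name = "final"),
      final_records = final_records,
      config = config
    ),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Gene-prioritization funnel\n")
  st <- x$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf(
      "  %-18s %-8s %5d genes (%d mutations)\n",
      st$stage[i], st$group[i], st$n_genes[i], st$n_mutations[i]
    ))
  }
  cat(sprintf(
    "final: %d gene(s)%s\n", length(x$final_genes),
    if (length(x$final_genes)) {
      paste0(": ", paste(x$final_genes, collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Tidy a funnel report
#'
#' @param x a `funnel_report`.
#' @param ... unused.
#' @return a tibble with one row per (stage, group): `stage`, `group`,
#'   `n_mutations`, `n_genes`.
#' @method tidy funnel_report
#' @export
tidy.funnel_report <- function(x, ...) {
  dplyr::select(x$stages, -dplyr::all_of("genes"))
}

#' @rdname tidy.funnel_report
#' @return `glance()` returns a one-row tibble with the final gene and
#'   mutation counts.
#' @method glance funnel_report
#' @export
glance.funnel_report <- function(x, ...) {
  tibble::tibble(
    n_stages = nrow(x$stages),
    n_final_genes = length(x$final_genes),
    n_final_mutations = nrow(x$final_records)
  )
}

#' Plot funnel stage counts
#'
#' @param object a `funnel_report`.
#' @param ... unused.
#' @return a ggplot: gene counts per stage, one bar per cohort.
#' @method autoplot funnel_report
#' @export
autoplot.funnel_report <- function(object, ...) {
  df <- tidy(object)
  df$stage <- factor(df$stage, levels = unique(df$stage))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$stage, y = .data$n_genes, fill = .data$group)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes remaining", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Render a funnel report as text or JSON
#'
#' Text lines follow the "stage, group, genes, (mutations)" convention; the
#' JSON form round-trips (`jsonlite::fromJSON()` restores the stage table and
#' final gene list).
#'
#' @param report a `funnel_report`.
#' @param format `"text"` or `"json"`.
#' @param path optional output file; when `NULL` the rendering is returned.
#' @return a character vector (text) or JSON string, invisibly when written.
#' @export
render_funnel_report <- function(report, format = c("text", "json"),
                                 path = NULL) {
  format <- match.arg(format)
  if (format == "text") {
    st <- report$stages
    out <- c(
      sprintf("%s\t%s\t%d\t(%d)",
              st$stage, st$group, st$n_genes, st$n_mutations),
      sprintf("final\tCASE\t%d\t(%d)",
              length(report$final_genes), nrow(report$final_records))
    )
  } else {
    out <- jsonlite::toJSON(
      list(
        stages = dplyr::select(report$stages, -dplyr::all_of("genes")),
        final_genes = as.character(report$final_genes),
        config = unclass(report$config)
      ),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  if (!is.null(path)) {
    writeLines(as.character(out), path)
    return(invisible(out))
  }
  out
}
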
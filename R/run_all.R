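#' Run every analysis stage and write a report bundle
#'
#' Wires the funnel, the six-class spectrum, the SBS96 matrix, signature
#' refitting and (optionally) the CNV comparison into one deterministic
#' output bundle:
#'
#' * `funnel_report.json`, `funnel_report.txt` — per-stage counts;
#' * `final_genes.txt` — one surviving gene per line;
#' * `final_records.tsv` — the surviving case mutations;
#' * `spectrum.tsv` — six-class spectra per cohort;
#' * `sbs96.tsv` — samples-by-96-channel counts (when contexts exist);
#' * `exposures.tsv` — per-sample and pooled signature refits (when a
#'   catalog is given);
#' * `cnv_specific.tsv` — case-specific recurrent CNV events (when CNV
#'   tables are given);
#' * `run_info.json` — package version and the effective configuration.
#'
#' @param case,control variant tibbles (see [variant_table]).
#' @param drivers,reported gene sets for the funnel stages.
#' @param out_dir output directory (created if missing).
#' @param config a [funnel_config()].
#' @param spectrum_mode `"MEAN_OF_SAMPLES"` or `"POOLED"`.
#' @param catalog optional `signature_catalog` for exposure refitting.
#' @param cnv_case,cnv_control optional CNV tibbles (see [cnv_events]).
#' @param min_cnv_samples CNV recurrence threshold.
#' @return the `funnel_report`, invisibly; side effect is the written bundle.
#' @export
run_all <- function(case, control, drivers, reported = character(),
                    out_dir,
                    config = funnel_config(),
                    spectrum_mode = c("MEAN_OF_SAMPLES", "POOLED"),
                    catalog = NULL,
                    cnv_case = NULL, cnv_control = NULL,
                    min_cnv_samples = 2L) {
  spectrum_mode <- match.arg(spectrum_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  case <- classify_variants(as_variant_tbl(case))
  control <- classify_variants(as_variant_tbl(control))

  report <- run_funnel(case, control, drivers, reported, config)
  render_funnel_report(report, "json", file.path(out_dir, "funnel_report.json"))
  render_funnel_report(report, "text", file.path(out_dir, "funnel_report.txt"))
  writeLines(as.character(report$final_genes),
             file.path(out_dir, "final_genes.txt"))
  write_table(report$final_records, file.path(out_dir, "final_records.tsv"))

  all_records <- dplyr::bind_rows(case, control)
  spec <- dplyr::bind_rows(
    dplyr::mutate(
      group_spectrum_summary(all_records, "CASE", spectrum_mode),
      group = "CASE", .before = 1
    ),
    dplyr::mutate(
      group_spectrum_summary(all_records, "CONTROL", spectrum_mode),
      group = "CONTROL", .before = 1
    )
  )
  write_table(spec, file.path(out_dir, "spectrum.tsv"))

  has_context <- any(!is.na(all_records$tri_context))
  if (has_context) {
    sbs96 <- build_sbs96_matrix(all_records)
    write_table(sbs96, file.path(out_dir, "sbs96.tsv"))
    if (!is.null(catalog)) {
      per_sample <- refit_cohort_exposures(sbs96, catalog)
      pooled <- lapply(c("CASE", "CONTROL"), function(g) {
        ids <- unique(all_records$sample_id[all_records$group == g])
        m <- as_sbs96_matrix(sbs96[sbs96$sample_id %in% ids, , drop = FALSE])
        v <- colSums(m)
        if (sum(v) == 0) return(NULL)
        fit <- refit_exposures(v, catalog)
        tibble::tibble(
          sample_id = paste0("POOLED_", g), signature = catalog$names,
          weight = as.numeric(fit$weights),
          percent = as.numeric(fit$percents), cosine = fit$cosine
        )
      })
      write_table(dplyr::bind_rows(per_sample, pooled),
                  file.path(out_dir, "exposures.tsv"))
    }
  }

  if (!is.null(cnv_case) && !is.null(cnv_control)) {
    cnv <- group_specific_events(cnv_case, cnv_control, min_cnv_samples)
    write_table(cnv$events, file.path(out_dir, "cnv_specific.tsv"))
  }

  info <- list(
    package = "somaticfunnel",
    version = as.character(utils::packageVersion("somaticfunnel")),
    config = unclass(config),
    spectrum_mode = spectrum_mode,
    n_case_records = nrow(case),
    n_control_records = nrow(control)
  )
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
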
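#' Synthetic SBS96 signature catalog
#'
#' Three deterministic, clearly separable synthetic signatures for tests and
#' simulations, loosely shaped after well-known processes:
#'
#' * `SBS22like` — T>A dominated (aristolochic-acid-like), peaking at
#'   `C[T>A]G`;
#' * `SBS5like` — near-flat across all channels with a mild C>T/T>C tilt
#'   (clock-like, featureless);
#' * `SBS1like` — concentrated on `N[C>T]G` channels (deamination at CpG).
#'
#' These are synthetic stand-ins, not COSMIC signatures; real COSMIC catalogs
#' are read with [read_signature_catalog()].
#'
#' @return a `signature_catalog` with 3 columns.
#' @export
synthetic_signature_catalog <- function() {
  channels <- sbs96_channels()
  cls <- sub("^.\\[(.+)\\].$", "\\1", channels)
  f5 <- substr(channels, 1, 1)
  f3 <- substr(channels, nchar(channels), nchar(channels))

  sbs22 <- rep(0.1, 96)
  sbs22[cls == "T>A"] <- 4
  sbs22[channels == "C[T>A]G"] <- 12
  sbs22[cls == "T>A" & f5 == "C"] <- sbs22[cls == "T>A" & f5 == "C"] + 2

  sbs5 <- rep(1, 96)
  sbs5[cls %in% c("C>T", "T>C")] <- 1.6

  sbs1 <- rep(0.05, 96)
  sbs1[cls == "C>T" & f3 == "G"] <- 10

  probs <- cbind(
    SBS22like = sbs22 / sum(sbs22),
    SBS5like = sbs5 / sum(sbs5),
    SBS1like = sbs1 / sum(sbs1)
  )
  rownames(probs) <- channels
  signature_catalog(probs)
}

#' Simulation configuration for a synthetic two-cohort study
#'
#' Defaults emulate the study conditions the analysis assumes: 7 case and 5
#' control samples, on the order of 2000 somatic mutations per sample, a
#' strongly aristolochic-acid-like signature mixture in both cohorts
#' (0.84/0.10/0.06 in cases, 0.81/0.11/0.08 in controls over the
#' [synthetic_signature_catalog()] columns), and roughly a fifth of background
#' records carrying dbSNP annotations.
#'
#' @param n_case,n_control cohort sizes.
#' @param mutations_per_sample Poisson mean of per-sample mutation counts.
#' @param signature_mix_case,signature_mix_control non-negative weights over
#'   the catalog columns, summing to 1.
#' @param planted_drivers list of `list(gene =, n_case_samples =,
#'   consequence =)` entries: each gene is mutated once in that many distinct
#'   case samples with the requested consequence class.
#' @param planted_reported_genes genes mutated in at least one sample of each
#'   cohort (to exercise the reported-gene exclusion).
#' @param dbsnp_fraction fraction of background records given synthetic rs
#'   identifiers and common population AFs.
#' @param recurrence_min recurrence threshold assumed when deriving the
#'   expected final gene set (match the [funnel_config()] you will run).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_case = 7L,
                       n_control = 5L,
                       mutations_per_sample = 2000,
                       signature_mix_case = c(SBS22like = 0.84,
                                              SBS5like = 0.10,
                                              SBS1like = 0.06),
                       signature_mix_control = c(SBS22like = 0.81,
                                                 SBS5like = 0.11,
                                                 SBS1like = 0.08),
                       planted_drivers = list(),
                       planted_reported_genes = character(),
                       dbsnp_fraction = 0.2,
                       recurrence_min = 2L,
                       seed = 1L) {
  stopifnot(
    n_case >= 1, n_control >= 1, mutations_per_sample >= 0,
    dbsnp_fraction >= 0, dbsnp_fraction <= 1,
    abs(sum(signature_mix_case) - 1) < 1e-9,
    abs(sum(signature_mix_control) - 1) < 1e-9,
    all(signature_mix_case >= 0), all(signature_mix_control >= 0)
  )
  for (pd in planted_drivers) {
    stopifnot(
      is.character(pd$gene),
      pd$n_case_samples >= 1, pd$n_case_samples <= n_case,
      pd$consequence %in% CONSEQUENCE_CLASSES
    )
  }
  structure(
    list(
      n_case = as.integer(n_case), n_control = as.integer(n_control),
      mutations_per_sample = mutations_per_sample,
      signature_mix_case = signature_mix_case,
      signature_mix_control = signature_mix_control,
      planted_drivers = planted_drivers,
      planted_reported_genes = toupper(planted_reported_genes),
      dbsnp_fraction = dbsnp_fraction,
      recurrence_min = as.integer(recurrence_min),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

channel_parts <- function(channels) {
  tibble::tibble(
    f5 = substr(channels, 1, 1),
    ref = substr(channels, 3, 3),
    alt = substr(channels, 5, 5),
    f3 = substr(channels, 7, 7)
  )
}

#' Draw mutations from a signature mixture
#'
#' Samples `n` channels i.i.d. from the mixture distribution `P %*% mix` and
#' materializes each draw as a variant record with consistent `ref`, `alt`
#' and `tri_context` on a fabricated coordinate. Half the records (in
#' expectation) are emitted on the purine strand — context and alleles
#' reverse-complemented together — so channel assignment must strand-
#' normalize to recover them.
#'
#' @param catalog a `signature_catalog`.
#' @param mix non-negative weights over catalog columns, summing to 1.
#' @param n number of mutations to draw.
#' @param sample_id sample label for the records.
#' @param seed optional integer; when given, the draw is deterministic.
#' @return a list: `counts` (true 96-channel count vector, canonical order)
#'   and `records` (variant tibble, `gene` unset).
#' @export
sample_mutations_from_signatures <- function(catalog, mix, n,
                                             sample_id = "S1", seed = NULL) {
  stopifnot(n >= 0, length(mix) == length(catalog$names),
            all(mix >= 0), abs(sum(mix) - 1) < 1e-9)
  if (!is.null(seed)) set.seed(seed)
  channels <- sbs96_channels()
  p <- as.numeric(catalog$probs %*% mix)
  counts <- if (n > 0) {
    as.integer(rmultinom(1, n, p)[, 1])
  } else {
    rep(0L, 96)
  }
  names(counts) <- channels
  idx <- rep.int(seq_len(96), counts)
  parts <- channel_parts(channels)[idx, , drop = FALSE]
  ref <- parts$ref
  alt <- parts$alt
  ctx <- paste0(parts$f5, parts$ref, parts$f3)
  flip <- if (nrow(parts)) runif(nrow(parts)) < 0.5 else logical(0)
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  records <- tibble::tibble(
    sample_id = rep(sample_id, nrow(parts)),
    chrom = rep("chr1", nrow(parts)),
    pos = 1000000L + seq_len(nrow(parts)),
    ref = ref, alt = alt,
    gene = rep(NA_character_, nrow(parts)),
    tri_context = ctx
  )
  list(counts = counts, records = as_variant_tbl(records))
}

## templates materializing a requested consequence class as annotation
planted_template <- function(consequence) {
  switch(
    consequence,
    MISSENSE = list(hgvs_c = "c.100A>T", hgvs_p = "p.K34N",
                    ref = "A", alt = "T", tri_context = "CAG"),
    SYNONYMOUS = list(hgvs_c = "c.99G>A", hgvs_p = "p.K33K",
                      ref = "G", alt = "A", tri_context = "AGG"),
    NONSENSE = list(hgvs_c = "c.169A>T", hgvs_p = "p.K57*",
                    ref = "A", alt = "T", tri_context = "TAG"),
    NONSTOP = list(hgvs_c = "c.1500A>T", hgvs_p = "p.*500L",
                   ref = "A", alt = "T", tri_context = "TAC"),
    FRAMESHIFT = list(hgvs_c = "c.100delA", hgvs_p = "p.?",
                      ref = "TA", alt = "T", tri_context = NA_character_),
    INDEL = list(hgvs_c = "c.100_102del", hgvs_p = "p.?",
                 ref = "TACG", alt = "T", tri_context = NA_character_),
    SPLICE_DONOR = list(hgvs_c = "c.100+2T>A", hgvs_p = "p.?",
                        ref = "T", alt = "A", tri_context = "GTA"),
    SPLICE_ACCEPTOR = list(hgvs_c = "c.101-2A>T", hgvs_p = "p.?",
                           ref = "A", alt = "T", tri_context = "CAG"),
    OTHER = list(hgvs_c = NA_character_, hgvs_p = "p.?",
                 ref = "A", alt = "T", tri_context = NA_character_),
    abort(sprintf("no planting template for consequence '%s'", consequence))
  )
}

#' Generate a synthetic two-cohort dataset with ground truth
#'
#' Per-sample background mutations are drawn from the cohort's signature
#' mixture on fabricated coordinates; a configured fraction of them is tagged
#' with synthetic rs identifiers and common population AFs. Planted driver
#' mutations are inserted with the requested consequence class in the
#' requested number of case samples; planted "reported" genes are mutated in
#' one sample of each cohort. Planted genes use disjoint per-gene coordinate
#' ranges so transcript collapsing can never merge distinct plantings. The
#' manifest records per-sample true channel counts, the planted gene-sample
#' map, and the final gene set the funnel is expected to return.
#'
#' @param config a [sim_config()].
#' @param catalog a `signature_catalog` (default
#'   [synthetic_signature_catalog()]).
#' @return a list: `case`, `control` (variant tibbles), `samples` (sample
#'   sheet), `drivers`, `reported` (gene sets for the funnel), and `truth`
#'   (manifest: `channel_counts`, `planted`, `expected_final`).
#' @export
generate_cohort <- function(config, catalog = synthetic_signature_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  case_ids <- sprintf("CASE%02d", seq_len(config$n_case))
  control_ids <- sprintf("CTRL%02d", seq_len(config$n_control))
  samples <- sample_sheet(
    c(case_ids, control_ids),
    c(rep("CASE", config$n_case), rep("CONTROL", config$n_control))
  )
  bg_pool <- sprintf("BG%04d", 1:400)

  draw_group <- function(ids, mix) {
    truth_counts <- list()
    recs <- list()
    for (s in ids) {
      n <- rpois(1, config$mutations_per_sample)
      drawn <- sample_mutations_from_signatures(catalog, mix, n, s)
      r <- drawn$records
      if (nrow(r)) {
        r$gene <- sample(bg_pool, nrow(r), replace = TRUE)
        tagged <- runif(nrow(r)) < config$dbsnp_fraction
        r$dbsnp_id[tagged] <- sprintf("rs%07d", sample.int(9999999, sum(tagged)))
        r$pop_af[tagged] <- round(runif(sum(tagged), 0.05, 0.5), 4)
      }
      truth_counts[[s]] <- tibble::tibble(
        sample_id = s, channel = sbs96_channels(),
        count = as.integer(drawn$counts)
      )
      recs[[s]] <- r
    }
    list(records = dplyr::bind_rows(recs),
         truth = dplyr::bind_rows(truth_counts))
  }

  case <- draw_group(case_ids, config$signature_mix_case)
  control <- draw_group(control_ids, config$signature_mix_control)

  ## background coordinates: per-gene disjoint ranges, unique positions
  fix_coords <- function(r) {
    if (!nrow(r)) return(r)
    gi <- match(r$gene, bg_pool)
    r$pos <- as.integer(gi * 100000L + seq_len(nrow(r)))
    r
  }
  case$records <- fix_coords(case$records)
  control$records <- fix_coords(control$records)

  planted_genes <- toupper(vapply(config$planted_drivers,
                                  function(p) p$gene, character(1)))
  plant_rows <- list()
  gene_offset <- function(i) 900000000L + i * 10000L
  for (i in seq_along(config$planted_drivers)) {
    pd <- config$planted_drivers[[i]]
    tpl <- planted_template(pd$consequence)
    in_samples <- sample(case_ids, pd$n_case_samples)
    plant_rows[[length(plant_rows) + 1L]] <- tibble::tibble(
      sample_id = in_samples,
      chrom = "chr2",
      pos = gene_offset(i) + seq_along(in_samples),
      ref = tpl$ref, alt = tpl$alt,
      gene = toupper(pd$gene),
      hgvs_c = tpl$hgvs_c, hgvs_p = tpl$hgvs_p,
      tri_context = tpl$tri_context
    )
  }
  reported_rows <- list()
  for (j in seq_along(config$planted_reported_genes)) {
    g <- config$planted_reported_genes[[j]]
    tpl <- planted_template("MISSENSE")
    reported_rows[[length(reported_rows) + 1L]] <- tibble::tibble(
      sample_id = c(case_ids[1], control_ids[1]),
      chrom = "chr3",
      pos = gene_offset(1000L + j) + c(1L, 2L),
      ref = tpl$ref, alt = tpl$alt,
      gene = g,
      hgvs_c = tpl$hgvs_c, hgvs_p = tpl$hgvs_p,
      tri_context = tpl$tri_context
    )
  }
  planted_case <- dplyr::bind_rows(c(
    plant_rows,
    lapply(reported_rows, function(r) r[r$sample_id %in% case_ids, ])
  ))
  planted_control <- dplyr::bind_rows(
    lapply(reported_rows, function(r) r[r$sample_id %in% control_ids, ])
  )
  case_records <- dplyr::bind_rows(
    case$records,
    if (nrow(planted_case %||% tibble::tibble())) as_variant_tbl(planted_case)
  )
  control_records <- dplyr::bind_rows(
    control$records,
    if (nrow(planted_control %||% tibble::tibble()))
      as_variant_tbl(planted_control)
  )
  case_records <- classify_variants(as_cohort(case_records, samples))
  control_records <- classify_variants(as_cohort(control_records, samples))

  expected_final <- character()
  planted_map <- list()
  for (i in seq_along(config$planted_drivers)) {
    pd <- config$planted_drivers[[i]]
    g <- toupper(pd$gene)
    planted_map[[g]] <- sort(plant_rows[[i]]$sample_id)
    aa <- !(pd$consequence %in% c("SYNONYMOUS", "OTHER"))
    if (pd$n_case_samples >= config$recurrence_min && aa &&
        !(g %in% config$planted_reported_genes)) {
      expected_final <- c(expected_final, g)
    }
  }
  truth <- list(
    channel_counts = dplyr::bind_rows(case$truth, control$truth),
    planted = planted_map,
    expected_final = gene_set(expected_final, name = "expected_final")
  )
  list(
    case = case_records,
    control = control_records,
    samples = samples,
    drivers = gene_set(c(planted_genes, config$planted_reported_genes),
                       name = "driver_catalog"),
    reported = gene_set(config$planted_reported_genes, name = "reported"),
    truth = truth
  )
}
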
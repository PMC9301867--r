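#' Build a samples-by-96-channel mutation matrix
#'
#' Each single-base substitution with a trinucleotide context is assigned to
#' one of the 96 channels (purine-reference records are reverse-complemented,
#' context and alleles together). Records lacking a context, or whose context
#' middle base contradicts the reference allele after strand normalization,
#' are dropped; their counts are reported via attributes and a warning.
#'
#' @param records a variant tibble with `tri_context` filled for its
#'   substitutions.
#' @return a wide tibble: `sample_id` plus 96 channel-count columns in
#'   canonical order. Attributes `n_no_context` and `n_rejected` count dropped
#'   records. Row sums equal each sample's usable substitution count.
#' @seealso [as_sbs96_matrix()] to get the numeric matrix,
#'   [refit_exposures()] to attribute signatures.
#' @export
build_sbs96_matrix <- function(records) {
  channels <- sbs96_channels()
  sub <- records[is_sbs(records), , drop = FALSE]
  no_ctx <- is.na(sub$tri_context) | nchar(sub$tri_context %||% "") != 3L
  lab <- sbs96_channel_of(sub$ref, sub$alt, sub$tri_context)
  rejected <- !no_ctx & is.na(lab)
  if (any(rejected)) {
    warn(sprintf(
      "build_sbs96_matrix(): %d record(s) rejected (context middle base != ref after strand normalization)",
      sum(rejected)
    ))
  }
  keep <- !is.na(lab)
  ids <- sort(unique(records$sample_id))
  mat <- matrix(0L, nrow = length(ids), ncol = 96,
                dimnames = list(ids, channels))
  if (any(keep)) {
    tab <- table(
      factor(sub$sample_id[keep], levels = ids),
      factor(lab[keep], levels = channels)
    )
    mat[] <- as.integer(tab)
  }
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = ids), out)
  attr(out, "n_no_context") <- sum(no_ctx)
  attr(out, "n_rejected") <- sum(rejected)
  out
}

#' Extract the numeric matrix from an SBS96 tibble
#'
#' @param sbs96 a tibble from [build_sbs96_matrix()].
#' @return an integer matrix, samples in rows (named), 96 channels in columns.
#' @export
as_sbs96_matrix <- function(sbs96) {
  m <- as.matrix(sbs96[, sbs96_channels(), drop = FALSE])
  rownames(m) <- sbs96$sample_id
  m
}

#' Read a COSMIC-style signature catalog
#'
#' Tab-separated, first column the channel labels (`A[C>A]A` style), one
#' column per signature, entries the per-channel probabilities. Rows are
#' reordered to the canonical channel order; columns must be non-negative and
#' sum to 1 within 1e-4.
#'
#' @param path path to the catalog file.
#' @return a `signature_catalog`: list with `names` (signatures) and `probs`
#'   (96 x K column-stochastic matrix, channel rownames).
#' @export
read_signature_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  labels <- df[[1]]
  probs <- as.matrix(df[, -1, drop = FALSE])
  rownames(probs) <- labels
  signature_catalog(probs)
}

#' Construct/validate a signature catalog
#'
#' @param probs a 96 x K numeric matrix with channel rownames and signature
#'   colnames.
#' @return a validated `signature_catalog` with channels in canonical order.
#' @export
signature_catalog <- function(probs) {
  channels <- sbs96_channels()
  missing <- setdiff(channels, rownames(probs))
  if (length(missing)) {
    abort(sprintf(
      "signature catalog is missing channel(s): %s%s",
      paste(head(missing, 3), collapse = ", "),
      if (length(missing) > 3) sprintf(" (+%d more)", length(missing) - 3)
      else ""
    ))
  }
  extra <- setdiff(rownames(probs), channels)
  if (length(extra)) {
    abort(sprintf("unknown channel label(s): %s",
                  paste(head(extra, 3), collapse = ", ")))
  }
  probs <- probs[channels, , drop = FALSE]
  if (any(probs < 0)) abort("signature catalog has negative entries")
  sums <- colSums(probs)
  off <- abs(sums - 1) > 1e-4
  if (any(off)) {
    abort(sprintf(
      "signature column(s) not unit-sum: %s",
      paste(colnames(probs)[off], collapse = ", ")
    ))
  }
  structure(
    list(names = colnames(probs), probs = probs),
    class = "signature_catalog"
  )
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("SBS96 signature catalog: %d signature(s): %s\n",
              length(x$names), paste(x$names, collapse = ", ")))
  invisible(x)
}

## Lawson-Hanson active-set non-negative least squares: min ||A x - b||, x >= 0
nnls_fit <- function(A, b, tol = NULL) {
  n <- ncol(A)
  x <- rep(0, n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)[, 1]
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(crossprod(A, b))) *
                     max(dim(A)))
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(replace(w, passive, -Inf))
    passive[j] <- TRUE
    repeat {
      if (!any(passive)) {
        x <- rep(0, n)
        break
      }
      Ap <- A[, passive, drop = FALSE]
      s_p <- qr.coef(qr(Ap), b)
      s_p[is.na(s_p)] <- 0
      s <- rep(0, n)
      s[passive] <- s_p
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      ## step toward s until a passive coefficient hits zero
      neg <- passive & s <= tol
      ratio <- x[neg] / (x[neg] - s[neg])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)[, 1]
  }
  x
}

#' Refit signature exposures to a 96-channel count vector
#'
#' Solves the constrained least-squares problem
#' \eqn{\min_w \|v - P w\|_2, \; w \ge 0} (non-negative least squares,
#' active-set method) where `P` is the catalog's channel-probability matrix.
#' Counts are fit directly, so high-mutation samples carry proportionally
#' more weight; percentages are shares of the fitted weights. With
#' `prune_below > 0`, signatures attributed less than that percent are
#' removed and the fit is repeated once.
#'
#' @param v a 96-channel count vector (canonical order, or named by channel),
#'   or a one-row tibble from [build_sbs96_matrix()].
#' @param catalog a `signature_catalog`.
#' @param prune_below percent threshold for the one-shot pruning refit
#'   (default 0 = no pruning).
#' @return an `exposure_result`: list with `weights` (named, mutation counts
#'   attributed), `percents`, and `cosine` (reconstruction cosine similarity
#'   between `v` and `P w`).
#' @examples
#' cat <- synthetic_signature_catalog()
#' v <- round(1000 * cat$probs[, "SBS22like"])
#' refit_exposures(v, cat)$percents
#' @export
refit_exposures <- function(v, catalog, prune_below = 0) {
  if (is.data.frame(v)) {
    stopifnot(nrow(v) == 1)
    v <- unlist(v[, sbs96_channels()])
  }
  channels <- sbs96_channels()
  if (!is.null(names(v)) && all(channels %in% names(v))) {
    v <- v[channels]
  }
  if (length(v) != 96) {
    abort("refit_exposures(): v must have 96 channels")
  }
  if (any(v < 0)) abort("refit_exposures(): negative counts")
  if (sum(v) == 0) abort("refit_exposures(): all-zero count vector")
  P <- catalog$probs
  w <- nnls_fit(P, as.numeric(v))
  names(w) <- catalog$names
  if (prune_below > 0 && sum(w) > 0) {
    pct <- 100 * w / sum(w)
    keep <- pct >= prune_below
    if (any(keep) && !all(keep)) {
      w2 <- nnls_fit(P[, keep, drop = FALSE], as.numeric(v))
      w <- setNames(rep(0, length(w)), catalog$names)
      w[keep] <- w2
    }
  }
  recon <- as.numeric(P %*% w)
  cosine <- if (sum(recon) == 0) 0 else cosine_similarity(as.numeric(v), recon)
  structure(
    list(
      weights = w,
      percents = if (sum(w) > 0) 100 * w / sum(w) else w,
      cosine = cosine
    ),
    class = "exposure_result"
  )
}

#' Refit exposures for every sample of an SBS96 matrix
#'
#' @param sbs96 a tibble from [build_sbs96_matrix()] (zero-count samples are
#'   skipped), or a pooled vector via [refit_exposures()].
#' @param catalog a `signature_catalog`.
#' @param prune_below see [refit_exposures()].
#' @return a tidy tibble: `sample_id`, `signature`, `weight`, `percent`,
#'   `cosine`.
#' @export
refit_cohort_exposures <- function(sbs96, catalog, prune_below = 0) {
  m <- as_sbs96_matrix(sbs96)
  rows <- lapply(rownames(m), function(s) {
    v <- m[s, ]
    if (sum(v) == 0) return(NULL)
    fit <- refit_exposures(v, catalog, prune_below)
    tibble::tibble(
      sample_id = s,
      signature = catalog$names,
      weight = as.numeric(fit$weights),
      percent = as.numeric(fit$percents),
      cosine = fit$cosine
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.exposure_result <- function(x, ...) {
  cat("Signature exposures (NNLS refit)\n")
  ord <- order(x$percents, decreasing = TRUE)
  for (i in ord) {
    if (x$weights[i] == 0) next
    cat(sprintf("  %-12s %8.1f mutations  %6.2f%%\n",
                names(x$weights)[i], x$weights[i], x$percents[i]))
  }
  cat(sprintf("  reconstruction cosine similarity: %.4f\n", x$cosine))
  invisible(x)
}

#' Tidy an exposure fit
#'
#' @param x an `exposure_result`.
#' @param ... unused.
#' @return a tibble: `signature`, `weight`, `percent`.
#' @method tidy exposure_result
#' @export
tidy.exposure_result <- function(x, ...) {
  tibble::tibble(
    signature = names(x$weights),
    weight = as.numeric(x$weights),
    percent = as.numeric(x$percents)
  )
}

#' @rdname tidy.exposure_result
#' @return `glance()` returns a one-row tibble with the total attributed
#'   weight and the reconstruction cosine.
#' @method glance exposure_result
#' @export
glance.exposure_result <- function(x, ...) {
  tibble::tibble(
    total_weight = sum(x$weights),
    n_active = sum(x$weights > 0),
    cosine = x$cosine
  )
}

#' Plot an exposure fit
#'
#' @param object an `exposure_result`.
#' @param ... unused.
#' @return a ggplot bar chart of signature percentages.
#' @method autoplot exposure_result
#' @export
autoplot.exposure_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$signature, y = .data$percent)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "attributed share (%)") +
    ggplot2::theme_minimal()
}
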
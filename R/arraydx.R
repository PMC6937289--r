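#' Filter probes of a two-color array replicate
#'
#' Drops probes flagged bad by the scanner software and floors both
#' channel intensities at 1 so that subsequent log transforms are
#' finite. The numbers of flagged and floored probes are recorded in
#' attributes `n_flagged` and `n_floored`.
#'
#' @param replicate tibble with columns `probe_id`, `cy3`, `cy5` and
#'   optionally `flag` (`"ok"` / `"bad"`).
#' @return The filtered tibble.
#' @export
filter_features <- function(replicate) {
  replicate <- tibble::as_tibble(replicate)
  need <- c("probe_id", "cy3", "cy5")
  if (!all(need %in% names(replicate))) {
    abort(paste0("Replicate must have columns: ", paste(need, collapse = ", "), "."))
  }
  if (any(replicate$cy3 < 0, na.rm = TRUE) || any(replicate$cy5 < 0, na.rm = TRUE)) {
    abort("Channel intensities must be non-negative.")
  }
  n0 <- nrow(replicate)
  if ("flag" %in% names(replicate)) {
    replicate <- dplyr::filter(replicate, .data$flag != "bad")
  }
  if (!nrow(replicate)) abort("All probes were flagged bad; nothing to analyse.")
  n_floor <- sum(replicate$cy3 < 1) + sum(replicate$cy5 < 1)
  replicate <- dplyr::mutate(replicate,
    cy3 = pmax(.data$cy3, 1), cy5 = pmax(.data$cy5, 1)
  )
  attr(replicate, "n_flagged") <- n0 - nrow(replicate)
  attr(replicate, "n_floored") <- n_floor
  replicate
}

#' MA transform of a two-color replicate
#'
#' The standard reparameterization of two-channel intensities:
#' `M = log2(cy5/cy3)` (the treatment-vs-reference log ratio, with the
#' optimized management in the Cy5 channel) and
#' `A = 0.5 * log2(cy5 * cy3)` (average log intensity). Dye bias shows
#' up as a smooth trend of M in A.
#'
#' @param replicate a filtered replicate (see [filter_features()]).
#' @return The tibble with columns `M` and `A` appended.
#' @examples
#' ma_transform(tibble::tibble(probe_id = "p1", cy3 = 256, cy5 = 1024))
#' @export
ma_transform <- function(replicate) {
  replicate <- tibble::as_tibble(replicate)
  if (any(replicate$cy3 <= 0 | replicate$cy5 <= 0, na.rm = TRUE)) {
    abort("Intensities must be positive; run filter_features() first.")
  }
  dplyr::mutate(replicate,
    M = log2(.data$cy5 / .data$cy3),
    A = 0.5 * log2(.data$cy5 * .data$cy3)
  )
}

#' Loess normalization of the intensity-dependent dye bias
#'
#' Fits a robust local-linear regression of M on A (tricube weights,
#' redescending robustness iterations) and subtracts the fitted trend,
#' removing the smooth intensity-dependent dye bias of two-color
#' hybridizations while leaving genuine differential signal — which is
#' sparse and symmetric about the trend — in place. The fit is global
#' over the array (no print-tip stratification).
#'
#' @param ma tibble with columns `M` and `A` (see [ma_transform()]).
#' @param span loess span (default 0.3).
#' @param robust_iters robustness reweighting iterations (default 3).
#' @return The tibble with columns `M_norm` (normalized log ratio) and
#'   `dye_fit` (the removed trend) appended.
#' @export
loess_normalize <- function(ma, span = 0.3, robust_iters = 3) {
  ma <- tibble::as_tibble(ma)
  if (!all(c("M", "A") %in% names(ma))) {
    abort("`ma` must have columns M and A; run ma_transform() first.")
  }
  n <- sum(is.finite(ma$M) & is.finite(ma$A))
  if (n < 50) abort("Loess normalization needs at least 50 probes.")
  if (span * n < 10) abort("`span` too small: fewer than 10 points per window.")
  fit <- loess(
    M ~ A, data = ma, span = span, degree = 1, family = "symmetric",
    control = loess.control(surface = "interpolate",
                            iterations = robust_iters + 1)
  )
  dye_fit <- predict(fit, newdata = ma)
  dplyr::mutate(ma, dye_fit = dye_fit, M_norm = .data$M - dye_fit)
}

#' Run filtering, MA transform and loess normalization over replicates
#'
#' Convenience wrapper applying [filter_features()], [ma_transform()]
#' and [loess_normalize()] to each replicate hybridization and
#' stacking the results.
#'
#' @param replicates named list of replicate tibbles, or a single
#'   tibble with a `replicate` column.
#' @inheritParams loess_normalize
#' @return A long tibble with columns `replicate`, `probe_id`, `M`,
#'   `A`, `dye_fit`, `M_norm`.
#' @export
normalize_arrays <- function(replicates, span = 0.3, robust_iters = 3) {
  if (is.data.frame(replicates)) {
    if (!"replicate" %in% names(replicates)) {
      abort("A single table must carry a `replicate` column.")
    }
    replicates <- split(replicates, replicates$replicate)
  }
  if (is.null(names(replicates))) {
    names(replicates) <- paste0("rep", seq_along(replicates))
  }
  purrr::imap(replicates, function(tbl, id) {
    tbl |>
      filter_features() |>
      ma_transform() |>
      loess_normalize(span = span, robust_iters = robust_iters) |>
      dplyr::mutate(replicate = id, .before = 1) |>
      dplyr::select("replicate", "probe_id", "M", "A", "dye_fit", "M_norm")
  }) |>
    purrr::list_rbind()
}

#' Per-feature replicate test of differential expression
#'
#' For each probe, averages the normalized log2 ratios over biological
#' replicates and tests the mean against zero with a two-sided
#' one-sample t-test. Probes with zero variance across replicates get
#' `p_value = NA` and `degenerate = TRUE` — a p-value is never
#' fabricated for them.
#'
#' @param normalized long tibble from [normalize_arrays()] (columns
#'   `replicate`, `probe_id`, `M_norm`).
#' @param min_replicates minimum finite replicates per probe
#'   (default 2); probes below it are dropped.
#' @return A tibble with one row per probe: `probe_id`, `n_rep`,
#'   `mean_log2fc`, `p_value`, `degenerate`.
#' @export
test_features <- function(normalized, min_replicates = 2) {
  normalized <- dplyr::filter(tibble::as_tibble(normalized),
                              is.finite(.data$M_norm))
  stats_tbl <- normalized |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      mean_log2fc = mean(.data$M_norm),
      sd_ = sd(.data$M_norm),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_rep >= min_replicates)
  if (!nrow(stats_tbl)) abort("No probe has enough replicates to test.")
  tstat <- stats_tbl$mean_log2fc / (stats_tbl$sd_ / sqrt(stats_tbl$n_rep))
  p <- 2 * pt(abs(tstat), df = stats_tbl$n_rep - 1, lower.tail = FALSE)
  degen <- !is.na(stats_tbl$sd_) & stats_tbl$sd_ == 0
  p[degen] <- NA_real_
  dplyr::mutate(
    dplyr::select(stats_tbl, -"sd_"),
    p_value = p, degenerate = degen
  )
}

#' Call differentially expressed genes
#'
#' Applies the joint criterion of a two-fold mean change
#' (`|mean_log2fc| >= lfc`) and `p_value <= alpha` across replicates.
#' Features failing either gate, and degenerate features without a
#' p-value, are called `"none"`.
#'
#' @param feature_stats output of [test_features()].
#' @param lfc absolute log2 fold-change threshold (default 1, i.e.
#'   two-fold).
#' @param alpha p-value cutoff (default 0.05).
#' @return `feature_stats` with a `call` column (`"up"`, `"down"`,
#'   `"none"`); summary counts are in the `"deg_counts"` attribute and
#'   via [deg_counts()].
#' @export
call_degs <- function(feature_stats, lfc = 1, alpha = 0.05) {
  if (lfc <= 0 || alpha <= 0 || alpha >= 1) {
    abort("`lfc` must be positive and `alpha` in (0, 1).")
  }
  out <- dplyr::mutate(tibble::as_tibble(feature_stats),
    call = dplyr::case_when(
      !is.na(.data$p_value) & .data$p_value <= alpha & .data$mean_log2fc >=  lfc ~ "up",
      !is.na(.data$p_value) & .data$p_value <= alpha & .data$mean_log2fc <= -lfc ~ "down",
      TRUE ~ "none"
    )
  )
  attr(out, "deg_counts") <- deg_counts(out)
  out
}

#' DEG count summary
#'
#' @param called output of [call_degs()].
#' @return One-row tibble with `n_up`, `n_down`, `n_total`.
#' @export
deg_counts <- function(called) {
  tibble::tibble(
    n_up = sum(called$call == "up"),
    n_down = sum(called$call == "down"),
    n_total = sum(called$call != "none")
  )
}

#' GO-term over-representation by the hypergeometric test
#'
#' For each GO term, tests whether the gene list is enriched for the
#' term's members relative to the annotated universe: with `N` genes in
#' the universe, `K` of them in the term, a list of size `n` and an
#' overlap of `k`, the p-value is the upper hypergeometric tail
#' `P(X >= k)`. P-values are Benjamini-Hochberg adjusted across terms
#' and the result sorted by adjusted p.
#'
#' @param genes character vector, the gene list (e.g. up-regulated
#'   DEGs); must be a subset of the universe.
#' @param annotation two-column data frame `gene_id`, `term` (one pair
#'   per row; a gene may carry several terms).
#' @param universe character vector of all genes considered (defaults
#'   to the annotated genes).
#' @return A tibble per term: `term`, `universe_size`, `term_size`,
#'   `list_size`, `overlap`, `p_value`, `p_adjust`.
#' @examples
#' ann <- tibble::tibble(gene_id = paste0("g", 1:20),
#'                       term = rep(c("T1", "T2"), c(5, 15)))
#' go_enrichment(paste0("g", 1:5), ann)
#' @export
go_enrichment <- function(genes, annotation, universe = NULL) {
  annotation <- tibble::as_tibble(annotation)
  if (!all(c("gene_id", "term") %in% names(annotation))) {
    abort("`annotation` must have columns gene_id and term.")
  }
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  genes <- unique(genes)
  if (!length(genes) || !length(universe)) {
    abort("Gene list and universe must be non-empty.")
  }
  stray <- setdiff(genes, universe)
  if (length(stray)) {
    abort(paste0(length(stray), " gene(s) in the list are not in the universe."))
  }
  annotation <- dplyr::filter(annotation, .data$gene_id %in% universe)
  N <- length(universe)
  n <- length(genes)
  res <- annotation |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(
      term_size = dplyr::n_distinct(.data$gene_id),
      overlap = dplyr::n_distinct(intersect(.data$gene_id, genes)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      universe_size = N, list_size = n,
      p_value = phyper(.data$overlap - 1, .data$term_size,
                       N - .data$term_size, n, lower.tail = FALSE),
      p_adjust = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::arrange(.data$p_adjust, .data$p_value) |>
    dplyr::select("term", "universe_size", "term_size", "list_size",
                  "overlap", "p_value", "p_adjust")
  res
}

#' Concordance between array and qPCR log2 fold changes
#'
#' Ordinary least-squares regression of qPCR log2 ratios on the
#' corresponding microarray log2 ratios for a validation gene panel.
#' An R-squared near 1 with slope near 1 indicates the array fold
#' changes are reliable.
#'
#' @param data data frame with one row per validation gene.
#' @param array_col,qpcr_col names of the array and qPCR log2
#'   fold-change columns (defaults `"array_log2fc"`, `"qpcr_log2fc"`).
#' @return An object of class `qpcr_concordance`; `glance()` gives a
#'   one-row tibble with `slope`, `intercept`, `r.squared`, `p.value`,
#'   `nobs`.
#' @export
qpcr_concordance <- function(data, array_col = "array_log2fc",
                             qpcr_col = "qpcr_log2fc") {
  data <- tibble::as_tibble(data)
  for (col in c(array_col, qpcr_col)) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found."))
  }
  x <- data[[array_col]]; y <- data[[qpcr_col]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("Need at least 3 paired genes.")
  if (sd(x[ok]) == 0) abort("Array fold changes have zero variance.")
  fit <- lm(y ~ x, data = data.frame(x = x[ok], y = y[ok]))
  s <- summary(fit)
  structure(
    list(fit = fit,
         data = tibble::tibble(array_log2fc = x[ok], qpcr_log2fc = y[ok]),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r.squared = s$r.squared,
         p.value = unname(s$coefficients[2, 4]), nobs = sum(ok)),
    class = "qpcr_concordance"
  )
}

#' @export
print.qpcr_concordance <- function(x, ...) {
  cat("qPCR / array log2 fold-change concordance (", x$nobs, " genes)\n",
      sprintf("  slope %.3f, intercept %.3f, R^2 = %.3f (p = %.3g)\n",
              x$slope, x$intercept, x$r.squared, x$p.value), sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.qpcr_concordance <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r.squared, p.value = x$p.value, nobs = x$nobs)
}

#' @exportS3Method generics::tidy
tidy.qpcr_concordance <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "array_log2fc"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' Log2 fold change from delta-delta-Ct
#'
#' The comparative-Ct convention: fold change `2^(-ddCt)`, so the log2
#' fold change is simply `-ddCt`. The delta-delta-Ct values must
#' already be referenced to the chosen housekeeping gene.
#'
#' @param ddct numeric vector of delta-delta-Ct values.
#' @return log2 fold changes.
#' @export
ddct_to_log2fc <- function(ddct) -ddct
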
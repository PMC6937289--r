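#' Group means and standard errors for internode traits
#'
#' Summarizes measured traits over the experimental hierarchy: culms
#' are first averaged within their replicate plot, then the group mean
#' and standard error (sd of plot means / sqrt(n plots)) are computed
#' per grouping cell. This matches the convention of agronomy trial
#' tables, where the replicate plot is the unit of observation.
#'
#' @param records data frame of measurements, one row per culm (or per
#'   internode per culm).
#' @param traits character vector of measurement columns to summarize.
#' @param by character vector of grouping columns
#'   (default `c("variety", "treatment", "internode")`; columns absent
#'   from `records` are dropped with a warning).
#' @param plot_col name of the replicate-plot column (default
#'   `"replicate"`).
#' @return A tibble with the grouping columns plus `trait`, `n`
#'   (plots with data), `mean` and `se`. Groups with no data are
#'   omitted with a warning.
#' @examples
#' trial <- gen_field_trial(seed = 1)
#' summarize_traits(trial, "length_cm")
#' @export
summarize_traits <- function(records, traits,
                             by = c("variety", "treatment", "internode"),
                             plot_col = "replicate") {
  records <- tibble::as_tibble(records)
  absent <- setdiff(by, names(records))
  if (length(absent)) {
    warn(paste0("Grouping column(s) not in data, dropped: ",
                paste(absent, collapse = ", ")))
    by <- setdiff(by, absent)
  }
  missing_traits <- setdiff(traits, names(records))
  if (length(missing_traits)) {
    abort(paste0("Trait column(s) not found: ",
                 paste(missing_traits, collapse = ", "), "."))
  }
  if (!plot_col %in% names(records)) {
    abort(paste0("Replicate-plot column `", plot_col, "` not found."))
  }

  long <- tidyr::pivot_longer(
    dplyr::select(records, dplyr::all_of(c(by, plot_col, traits))),
    cols = dplyr::all_of(traits), names_to = "trait", values_to = "value"
  )
  plot_means <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "trait", plot_col)))) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::filter(is.finite(.data$value))

  out <- plot_means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "trait")))) |>
    dplyr::summarise(
      n    = dplyr::n(),
      mean = mean(.data$value),
      se   = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
  n_cells <- nrow(dplyr::distinct(long, dplyr::across(dplyr::all_of(c(by, "trait")))))
  if (nrow(out) < n_cells) {
    warn("Some groups had no finite observations and were omitted.")
  }
  out
}

#' Percent change of a trait under OPT relative to FFP
#'
#' `(opt - ffp) / ffp * 100`, the convention of two-treatment trial
#' tables where the optimized management is expressed relative to the
#' farmers' practice. Scale-invariant: rescaling both means leaves the
#' percent change unchanged.
#'
#' @param opt_mean group mean under the optimized treatment.
#' @param ffp_mean group mean under the reference treatment; must be
#'   nonzero.
#' @param digits decimal places for rounding (default 1, the table
#'   convention; use `Inf` for full precision).
#' @return Percent change, numeric.
#' @examples
#' percent_change(22.7, 28.4)  # -20.1
#' @export
percent_change <- function(opt_mean, ffp_mean, digits = 1) {
  if (any(ffp_mean == 0, na.rm = TRUE)) {
    abort("`ffp_mean` must be nonzero: percent change is relative to it.")
  }
  pc <- (opt_mean - ffp_mean) / ffp_mean * 100
  if (is.finite(digits)) round(pc, digits) else pc
}

#' Average percent change over several trait cells
#'
#' The unweighted mean of per-cell percent changes (mean of ratios,
#' not ratio of sums) — the convention behind statements like "on
#' average, the bending moment of the two internodes was increased by
#' 42.6%".
#'
#' @param opt_means,ffp_means equal-length vectors of paired group
#'   means.
#' @inheritParams percent_change
#' @return A single averaged percent change.
#' @examples
#' average_percent_change(c(1490.3, 1186.5), c(1155.3, 760.0))  # 42.6
#' @export
average_percent_change <- function(opt_means, ffp_means, digits = 1) {
  if (length(opt_means) != length(ffp_means) || !length(opt_means)) {
    abort("`opt_means` and `ffp_means` must be equal-length, non-empty.")
  }
  pc <- mean(percent_change(opt_means, ffp_means, digits = Inf))
  if (is.finite(digits)) round(pc, digits) else pc
}

#' Percent-change columns for a trait summary
#'
#' Widens a [summarize_traits()] result by treatment and appends the
#' percent change of the optimized treatment relative to the reference.
#'
#' @param trait_summary output of [summarize_traits()].
#' @param opt,ffp treatment labels (defaults `"OPT"`, `"FFP"`).
#' @inheritParams percent_change
#' @return A tibble with one row per group cell and columns
#'   `mean_ffp`, `se_ffp`, `mean_opt`, `se_opt`, `pct_change`.
#' @export
percent_change_table <- function(trait_summary, opt = "OPT", ffp = "FFP",
                                 digits = 1) {
  if (!all(c(opt, ffp) %in% trait_summary$treatment)) {
    abort("Both treatment levels must be present in `trait_summary`.")
  }
  keys <- setdiff(names(trait_summary), c("treatment", "n", "mean", "se"))
  wide <- trait_summary |>
    dplyr::filter(.data$treatment %in% c(opt, ffp)) |>
    dplyr::mutate(treatment = ifelse(.data$treatment == opt, "opt", "ffp")) |>
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(keys),
      names_from = "treatment",
      values_from = c("mean", "se"),
      names_glue = "{.value}_{treatment}"
    )
  dplyr::mutate(wide,
    pct_change = percent_change(.data$mean_opt, .data$mean_ffp, digits = digits)
  )
}

#' Split-plot analysis of variance for a two-factor field trial
#'
#' Fits the classical split-plot decomposition for a balanced trial
#' laid out in replicate blocks, with one factor applied to whole
#' plots (here the nitrogen management) and one to subplots (the
#' variety). The whole-plot factor is tested against the
#' replicate-by-whole-plot interaction mean square (the whole-plot
#' error); the subplot factor and the interaction are tested against
#' the residual (subplot error). Sums of squares are the exact
#' balanced-design quantities; an unbalanced layout is an error, not
#' silently imputed.
#'
#' @param data data frame of plot-level responses (one row per
#'   replicate x whole-plot x subplot cell; culms must be averaged to
#'   plot means first, e.g. with [summarize_traits()] upstream).
#' @param response name of the response column.
#' @param whole_plot,sub_plot,rep names of the whole-plot factor,
#'   subplot factor and replicate-block columns. Defaults
#'   `"treatment"`, `"variety"`, `"replicate"`.
#' @return An object of class `split_plot_anova`: a list with the
#'   effects table (`tidy()` it for a tibble), the factor names, and
#'   the error mean squares/dfs used downstream by [letter_groups()].
#' @examples
#' trial <- gen_field_trial(seed = 1)
#' plots <- summarize_plot_means(trial, "length_cm", internodes = 3)
#' fit <- split_plot_anova(plots, "value")
#' tidy(fit)
#' @export
split_plot_anova <- function(data, response, whole_plot = "treatment",
                             sub_plot = "variety", rep = "replicate") {
  data <- tibble::as_tibble(data)
  for (col in c(response, whole_plot, sub_plot, rep)) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found."))
  }
  y <- data[[response]]
  A <- factor(data[[whole_plot]])  # whole-plot factor
  B <- factor(data[[sub_plot]])    # subplot factor
  R <- factor(data[[rep]])         # replicate block
  if (anyNA(y)) abort("Response contains missing values; split-plot ANOVA requires complete balanced data.")

  r <- nlevels(R); a <- nlevels(A); b <- nlevels(B)
  tab <- table(R, A, B)
  if (any(tab != 1) || length(y) != r * a * b) {
    abort("Layout must be balanced: exactly one observation per replicate x whole-plot x subplot cell.")
  }

  gm <- mean(y)
  ss <- function(means, mult) sum((means - gm)^2) * mult
  m_R  <- tapply(y, R, mean);        ss_R  <- ss(m_R, a * b)
  m_A  <- tapply(y, A, mean);        ss_A  <- ss(m_A, r * b)
  m_B  <- tapply(y, B, mean);        ss_B  <- ss(m_B, r * a)
  m_RA <- tapply(y, list(R, A), mean)
  ss_RA_cells <- sum((m_RA - gm)^2) * b
  ss_WPE <- ss_RA_cells - ss_R - ss_A           # rep x whole-plot interaction
  m_AB <- tapply(y, list(A, B), mean)
  ss_AB_cells <- sum((m_AB - gm)^2) * r
  ss_AB <- ss_AB_cells - ss_A - ss_B
  ss_T <- sum((y - gm)^2)
  ss_E <- ss_T - ss_R - ss_A - ss_WPE - ss_B - ss_AB

  df <- c(r - 1, a - 1, (r - 1) * (a - 1), b - 1,
          (a - 1) * (b - 1), a * (r - 1) * (b - 1))
  SS <- c(ss_R, ss_A, ss_WPE, ss_B, ss_AB, max(ss_E, 0))
  MS <- ifelse(df > 0, SS / df, NA_real_)
  ms_wpe <- MS[3]; ms_res <- MS[6]

  f <- c(NA, MS[2] / ms_wpe, NA, MS[4] / ms_res, MS[5] / ms_res, NA)
  err_df <- c(NA, df[3], NA, df[6], df[6], NA)
  p <- ifelse(is.na(f), NA_real_, pf(f, df, err_df, lower.tail = FALSE))
  # a no-variance stratum gives 0/0: report as no evidence of an effect
  p[!is.na(f) & !is.finite(f)] <- NA_real_
  f[!is.finite(f)] <- NA_real_

  effects <- tibble::tibble(
    term = c("replicate", whole_plot, paste0("replicate:", whole_plot, " (whole-plot error)"),
             sub_plot, paste0(whole_plot, ":", sub_plot), "residual (subplot error)"),
    df = df, sumsq = SS, meansq = MS, statistic = f, p.value = p
  )

  structure(
    list(
      effects = effects,
      response = response, whole_plot = whole_plot, sub_plot = sub_plot,
      rep = rep, layout = c(r = r, a = a, b = b),
      whole_plot_error = list(ms = ms_wpe, df = df[3]),
      subplot_error    = list(ms = ms_res, df = df[6]),
      data = tibble::tibble(y = y, A = A, B = B, R = R)
    ),
    class = "split_plot_anova"
  )
}

#' @export
print.split_plot_anova <- function(x, ...) {
  cat("Split-plot ANOVA of `", x$response, "` (",
      x$layout["r"], " blocks x ", x$layout["a"], " whole-plot x ",
      x$layout["b"], " subplot levels)\n\n", sep = "")
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a split-plot ANOVA into its effects table
#'
#' @param x a `split_plot_anova` object.
#' @param ... unused.
#' @return A tibble with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.split_plot_anova <- function(x, ...) x$effects

#' One-row model summary of a split-plot ANOVA
#'
#' @param x a `split_plot_anova` object.
#' @param ... unused.
#' @return A one-row tibble with the whole-plot and subplot F tests
#'   and error mean squares.
#' @exportS3Method generics::glance
glance.split_plot_anova <- function(x, ...) {
  e <- x$effects
  tibble::tibble(
    nobs = prod(x$layout),
    p.whole_plot = e$p.value[2],
    p.sub_plot = e$p.value[4],
    p.interaction = e$p.value[5],
    ms.whole_plot_error = x$whole_plot_error$ms,
    ms.subplot_error = x$subplot_error$ms
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' LSD letter groups for a set of treatment means
#'
#' Assigns compact letter displays at significance level `alpha` using
#' Fisher's least significant difference with a supplied error mean
#' square and its degrees of freedom (taken from the appropriate
#' stratum of a [split_plot_anova()]). Means are sorted in descending
#' order; maximal runs of mutually non-significant means share a
#' letter, so two means carry different letter sets iff their
#' difference exceeds the LSD.
#'
#' @param means named numeric vector of group means.
#' @param n number of observations behind each mean (scalar or vector
#'   matching `means`).
#' @param error_ms error mean square for the comparison.
#' @param df degrees of freedom of `error_ms`.
#' @param alpha significance level (default 0.05).
#' @return A tibble with `group`, `mean` and `letter`, in descending
#'   mean order.
#' @examples
#' letter_groups(c(FFP = 16.9, OPT = 13.2), n = 4, error_ms = 0.5, df = 6)
#' @export
letter_groups <- function(means, n, error_ms, df, alpha = 0.05) {
  if (length(means) < 2) abort("Need at least two groups to compare.")
  if (df < 1) abort("`df` must be at least 1.")
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  n <- rep_len(n, length(means))

  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; nn <- n[ord]
  k <- length(m)
  tcrit <- qt(1 - alpha / 2, df)
  nonsig <- function(i, j) {
    lsd <- tcrit * sqrt(error_ms * (1 / nn[i] + 1 / nn[j]))
    abs(m[i] - m[j]) <= lsd
  }
  # maximal non-significant runs down the sorted means
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig(i, j + 1)) j <- j + 1
    runs[[length(runs) + 1]] <- i:j
  }
  keep <- rep(TRUE, length(runs))
  for (u in seq_along(runs)) {
    for (v in seq_along(runs)) {
      if (u != v && keep[v] && all(runs[[u]] %in% runs[[v]]) &&
          length(runs[[u]]) < length(runs[[v]])) keep[u] <- FALSE
    }
  }
  runs <- unique(runs[keep])
  letters_out <- character(k)
  for (s in seq_along(runs)) {
    for (i in runs[[s]]) letters_out[i] <- paste0(letters_out[i], letters[s])
  }
  tibble::tibble(group = names(m), mean = unname(m), letter = letters_out)
}

#' Harvest index
#'
#' Grain yield as a fraction of total above-ground biomass.
#'
#' @param grain_g_m2 grain yield, g m^-2.
#' @param biomass_g_m2 total biomass, g m^-2; must be positive.
#' @return Harvest index (ratio in `[0, 1]` for physical inputs).
#' @examples
#' harvest_index(500, 1000)
#' @export
harvest_index <- function(grain_g_m2, biomass_g_m2) {
  check_nonneg(grain_g_m2, "grain_g_m2")
  check_positive(biomass_g_m2, "biomass_g_m2")
  grain_g_m2 / biomass_g_m2
}

#' Plot-level means of one trait for the split-plot ANOVA
#'
#' Convenience bridge from culm-level records to the one-row-per-plot
#' layout [split_plot_anova()] expects: averages culms within each
#' replicate plot, optionally restricted to (or summed over) selected
#' internodes.
#'
#' @param records culm-level internode records.
#' @param trait measurement column to analyse.
#' @param internodes internode indices to keep (default all present).
#' @param sum_internodes if `TRUE`, sum the trait over the selected
#'   internodes within each culm before averaging (e.g. total length
#'   of the lower internodes).
#' @return A tibble with `variety`, `treatment`, `replicate`, `value`.
#' @export
summarize_plot_means <- function(records, trait, internodes = NULL,
                                 sum_internodes = FALSE) {
  records <- tibble::as_tibble(records)
  if (!trait %in% names(records)) abort(paste0("Column `", trait, "` not found."))
  if (!is.null(internodes) && "internode" %in% names(records)) {
    records <- dplyr::filter(records, .data$internode %in% internodes)
  }
  if (sum_internodes && "culm" %in% names(records)) {
    records <- records |>
      dplyr::group_by(.data$variety, .data$treatment, .data$replicate, .data$culm) |>
      dplyr::summarise(value = sum(.data[[trait]]), .groups = "drop")
  } else {
    records <- dplyr::rename(records, value = dplyr::all_of(trait))
  }
  records |>
    dplyr::group_by(.data$variety, .data$treatment, .data$replicate) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

#' Render a trial summary in the "mean +/- se letter" table layout
#'
#' Formats a [summarize_traits()] result (optionally joined with
#' letters) the way agronomy papers print trial tables, for visual
#' diffing against published tables.
#'
#' @param trait_summary output of [summarize_traits()], optionally with
#'   a `letter` column.
#' @param digits decimal places (default 1).
#' @return A tibble with grouping columns and a formatted `display`
#'   column.
#' @export
render_trait_table <- function(trait_summary, digits = 1) {
  fmt <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  out <- dplyr::mutate(trait_summary,
    display = paste0(fmt(.data$mean), " ± ", fmt(.data$se),
                     if ("letter" %in% names(trait_summary)) "" else NULL)
  )
  if ("letter" %in% names(trait_summary)) {
    out$display <- paste0(out$display, out$letter)
  }
  keys <- setdiff(names(trait_summary), c("n", "mean", "se", "letter"))
  dplyr::select(out, dplyr::all_of(keys), "display")
}
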
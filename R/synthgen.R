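# Seeded generators for synthetic field trials, two-color arrays and GO
# universes. All generators are pure functions of (config, seed): the
# caller's RNG state is saved and restored, so identical inputs give
# identical outputs without disturbing the session.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Default configuration of the synthetic two-variety nitrogen trial
#'
#' Cell means and standard errors for a 2-variety x 2-N-management x
#' 4-replicate split-plot rice trial, one row per
#' (variety, treatment, internode): internode length, culm diameter and
#' wall thickness, dry weight, breaking force, elastic modulus and
#' self-load bending moment, plus plant height. The defaults emulate a
#' South-China early-season trial contrasting farmers' fertilizer
#' practice (FFP) with an optimized, reduced-and-delayed N management
#' (OPT) in a weakly and a moderately lodging-resistant variety; they
#' ship as a plain-CSV configuration
#' (`system.file("extdata/trial_config_default.csv", package = "culmr")`)
#' that users can edit to emulate other trials. Measurements that are
#' not taken for an internode (e.g. breaking force of internodes
#' shorter than the 5 cm bending span) are empty.
#'
#' @return A tibble, one row per trial cell, with `mean_*` / `se_*`
#'   column pairs.
#' @export
trial_config_default <- function() {
  path <- system.file("extdata", "trial_config_default.csv", package = "culmr")
  if (path == "") path <- file.path("inst", "extdata", "trial_config_default.csv")
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' Simulate a split-plot internode measurement trial
#'
#' Generates culm-level internode records with the hierarchical error
#' structure of a split-plot field trial: for each measurement and each
#' (variety, treatment, internode) cell, a replicate-plot effect is
#' drawn as Normal(0, sd_plot) with `sd_plot = se * sqrt(n_reps)`
#' (the plot-level sd implied by a printed standard error over
#' `n_reps` plots), and culm values are drawn around the plot mean
#' with `sd_culm = culm_sd_factor * sd_plot`. Physical invariants
#' (positive lengths, wall within the radius) are enforced by
#' truncation-free rejection resampling. Bending-test deflections are
#' generated to be exactly consistent with each culm's elastic modulus
#' and geometry, and the fresh weight above each internode base is
#' derived from its bending moment and lever arm, so [mech_profile()]
#' recovers the configured mechanics.
#'
#' @param config trial configuration tibble (see
#'   [trial_config_default()]).
#' @param n_reps replicate plots per treatment (default 4).
#' @param culms_per_plot culms sampled per plot (default 10).
#' @param culm_sd_factor culm-level sd as a multiple of the plot-level
#'   sd (default 2).
#' @param sd_scale multiplier on all sds (0 gives the exact configured
#'   means — the zero-noise limit used for round-trip tests).
#' @param elastic_F_N load used in the simulated elastic bending test,
#'   N.
#' @param span_cm bending-test support span, cm.
#' @param seed integer seed; identical seeds give identical tables.
#' @return A tibble of internode records, one row per internode per
#'   culm, with columns `variety`, `treatment`, `replicate`, `culm`,
#'   `internode`, `length_cm`, `diameter_mm`, `wall_mm`, `fresh_g`,
#'   `dry_mg`, `dist_tip_cm`, `fresh_above_g`, `break_N`,
#'   `elastic_F_N`, `deflect_cm`, `span_cm`.
#' @examples
#' trial <- gen_field_trial(seed = 1)
#' dplyr::count(trial, variety, treatment)
#' @export
gen_field_trial <- function(config = trial_config_default(), n_reps = 4,
                            culms_per_plot = 10, culm_sd_factor = 2,
                            sd_scale = 1, elastic_F_N = 2, span_cm = 5,
                            seed = NULL) {
  config <- tibble::as_tibble(config)
  need <- c("variety", "treatment", "internode",
            "mean_length_cm", "se_length_cm",
            "mean_diameter_mm", "se_diameter_mm",
            "mean_wall_mm", "se_wall_mm")
  missing_cols <- setdiff(need, names(config))
  if (length(missing_cols)) {
    abort(paste0("Config is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (any(config$mean_wall_mm > config$mean_diameter_mm / 2, na.rm = TRUE)) {
    abort("Infeasible config: mean wall thickness exceeds the mean radius.")
  }
  if (n_reps < 1 || culms_per_plot < 1) abort("Need at least one plot and one culm.")

  measures <- c("length_cm", "diameter_mm", "wall_mm", "dry_mg",
                "break_N", "E_GPa", "BM_gfcm", "plant_height_cm")
  measures <- measures[paste0("mean_", measures) %in% names(config)]

  with_seed(seed, {
    cells <- purrr::pmap(config, function(...) list(...))
    rows <- purrr::map(cells, function(cell) {
      n_culm <- n_reps * culms_per_plot
      out <- tibble::tibble(
        variety = cell$variety, treatment = cell$treatment,
        replicate = rep(seq_len(n_reps), each = culms_per_plot),
        culm = rep(seq_len(culms_per_plot), times = n_reps),
        internode = cell$internode
      )
      for (ms in measures) {
        mu <- cell[[paste0("mean_", ms)]]
        se <- cell[[paste0("se_", ms)]] %||% NA_real_
        if (is.null(mu) || is.na(mu)) { out[[ms]] <- NA_real_; next }
        sd_plot <- (if (is.na(se)) 0 else se * sqrt(n_reps)) * sd_scale
        sd_culm <- culm_sd_factor * sd_plot
        plot_mu <- mu + rnorm(n_reps, 0, sd_plot)
        val <- rnorm(n_culm, plot_mu[out$replicate], sd_culm)
        # rejection: physical measurements must stay positive
        bad <- which(val <= 0)
        tries <- 0
        while (length(bad) && tries < 100) {
          val[bad] <- rnorm(length(bad), plot_mu[out$replicate[bad]], sd_culm)
          bad <- which(val <= 0)
          tries <- tries + 1
        }
        if (length(bad)) abort(paste0("Could not satisfy positivity for `", ms, "`."))
        out[[ms]] <- val
      }
      # wall must fit in the radius
      if (all(c("wall_mm", "diameter_mm") %in% names(out))) {
        bad <- which(!is.na(out$wall_mm) & out$wall_mm > out$diameter_mm / 2)
        tries <- 0
        while (length(bad) && tries < 100) {
          mu <- cell$mean_wall_mm
          sd_culm <- culm_sd_factor * cell$se_wall_mm * sqrt(n_reps) * sd_scale
          out$wall_mm[bad] <- rnorm(length(bad), mu, sd_culm)
          bad <- which(!is.na(out$wall_mm) &
                         (out$wall_mm <= 0 | out$wall_mm > out$diameter_mm / 2))
          tries <- tries + 1
        }
        if (length(bad)) abort("Could not satisfy wall <= radius; config too noisy.")
      }
      out
    })
    records <- purrr::list_rbind(rows)

    # lever arm: plant height minus the summed lengths of internodes below
    records <- records |>
      dplyr::group_by(.data$variety, .data$treatment, .data$replicate, .data$culm) |>
      dplyr::arrange(.data$internode, .by_group = TRUE) |>
      dplyr::mutate(
        dist_tip_cm = if ("plant_height_cm" %in% names(records))
          pmax(.data$plant_height_cm - cumsum(dplyr::lag(.data$length_cm, default = 0)),
               .data$length_cm)
        else NA_real_
      ) |>
      dplyr::ungroup()

    records$fresh_above_g <- if ("BM_gfcm" %in% names(records)) {
      records$BM_gfcm / records$dist_tip_cm
    } else NA_real_

    # fresh weight of the internode itself: dry matter at ~75% moisture
    records$fresh_g <- if ("dry_mg" %in% names(records)) {
      records$dry_mg / 1000 * 4
    } else NA_real_

    # breaking force is only measured on internodes at least one span long
    if ("break_N" %in% names(records)) {
      records$break_N[records$length_cm < span_cm] <- NA_real_
    }

    # deflection consistent with E, I and the test load
    if ("E_GPa" %in% names(records)) {
      a_mm <- records$diameter_mm / 2
      I_mm4 <- pi * a_mm^4 / 4 * (1 - (1 - records$wall_mm / a_mm)^4)
      records$elastic_F_N <- ifelse(is.na(records$E_GPa), NA_real_, elastic_F_N)
      records$deflect_cm <- elastic_F_N * (span_cm / 100)^3 /
        (48 * (records$E_GPa * 1e9) * (I_mm4 * 1e-12)) * 100
    } else {
      records$elastic_F_N <- NA_real_
      records$deflect_cm <- NA_real_
    }
    records$span_cm <- span_cm
    for (col in c("dry_mg", "break_N")) {
      if (!col %in% names(records)) records[[col]] <- NA_real_
    }

    dplyr::select(records, dplyr::all_of(c(
      "variety", "treatment", "replicate", "culm", "internode",
      "length_cm", "diameter_mm", "wall_mm", "fresh_g", "dry_mg",
      "dist_tip_cm", "fresh_above_g", "break_N",
      "elastic_F_N", "deflect_cm", "span_cm"
    )), dplyr::any_of(c("E_GPa", "BM_gfcm")))
  })
}

#' Simulate replicate two-color 44k arrays with known truth
#'
#' Generates `n_reps` replicate hybridizations of an Agilent-44k-style
#' two-color array. Each probe gets a latent average log2 intensity
#' `A ~ Uniform(6, 14)` (shared across replicates) and a true log2
#' fold change: 0 for null probes, `+Uniform(lfc_range)` for the
#' spiked up-regulated set, `-Uniform(lfc_range)` for the spiked
#' down-regulated set, plus any exact effects supplied in
#' `spike_log2fc`. The observed per-replicate log ratio is
#' `M = true + bias(A) + Normal(0, noise_sd)` and the channels are
#' reconstructed as `cy5 = 2^(A + M/2)`, `cy3 = 2^(A - M/2)` (Cy5
#' carries the optimized treatment, Cy3 the reference). The default
#' dye-bias function, a sinusoid plus a gentle quadratic in A bounded
#' by about 0.6, makes un-normalized calls visibly biased so the loess
#' stage is exercised meaningfully.
#'
#' @param n_features number of probes per array (default 45018, the
#'   44k design).
#' @param n_up,n_down numbers of spiked up- and down-regulated probes.
#' @param lfc_range range of absolute spiked log2 fold changes
#'   (default `c(1.5, 3)`).
#' @param spike_log2fc optional numeric vector of exact signed log2
#'   fold changes planted as additional spiked probes (e.g. a
#'   validation gene panel).
#' @param noise_sd per-replicate sd of the log-ratio noise (default
#'   0.15).
#' @param n_reps biological replicates (default 3).
#' @param bias dye-bias function of A, or `NULL` for none.
#' @param flag_rate fraction of probes flagged `"bad"` per replicate
#'   (default 0.001).
#' @param seed integer seed.
#' @return A list with `replicates` (named list of
#'   `probe_id`/`cy3`/`cy5`/`flag` tibbles) and `truth` (tibble
#'   `probe_id`, `true_log2fc`, `spiked` in `"up"`/`"down"`/`"none"`).
#' @examples
#' sim <- gen_two_color_arrays(n_features = 2000, n_up = 20, n_down = 20,
#'                             seed = 1)
#' names(sim$replicates)
#' @export
gen_two_color_arrays <- function(n_features = 45018, n_up = 665, n_down = 713,
                                 lfc_range = c(1.5, 3), spike_log2fc = NULL,
                                 noise_sd = 0.15, n_reps = 3,
                                 bias = dye_bias_default, flag_rate = 0.001,
                                 seed = NULL) {
  if (n_up + n_down + length(spike_log2fc) > n_features) {
    abort("More spiked probes than features.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  with_seed(seed, {
    probe_id <- sprintf("probe_%05d", seq_len(n_features))
    true_lfc <- numeric(n_features)
    spiked <- rep("none", n_features)
    idx <- sample.int(n_features, n_up + n_down + length(spike_log2fc))
    up_idx <- idx[seq_len(n_up)]
    down_idx <- idx[n_up + seq_len(n_down)]
    true_lfc[up_idx] <- runif(n_up, lfc_range[1], lfc_range[2])
    true_lfc[down_idx] <- -runif(n_down, lfc_range[1], lfc_range[2])
    spiked[up_idx] <- "up"; spiked[down_idx] <- "down"
    if (length(spike_log2fc)) {
      sp_idx <- idx[n_up + n_down + seq_along(spike_log2fc)]
      true_lfc[sp_idx] <- spike_log2fc
      spiked[sp_idx] <- ifelse(spike_log2fc >= 0, "up", "down")
    }
    A <- runif(n_features, 6, 14)
    b <- if (is.null(bias)) 0 else bias(A)

    replicates <- lapply(seq_len(n_reps), function(r) {
      M <- true_lfc + b + rnorm(n_features, 0, noise_sd)
      tibble::tibble(
        probe_id = probe_id,
        cy3 = 2^(A - M / 2),
        cy5 = 2^(A + M / 2),
        flag = ifelse(runif(n_features) < flag_rate, "bad", "ok")
      )
    })
    names(replicates) <- paste0("rep", seq_len(n_reps))
    list(
      replicates = replicates,
      truth = tibble::tibble(probe_id = probe_id, true_log2fc = true_lfc,
                             spiked = spiked)
    )
  })
}

#' Default intensity-dependent dye-bias function
#'
#' A smooth additive bias in M as a function of A: a sinusoid plus a
#' gentle quadratic, bounded by about 0.6 over the simulated intensity
#' range — large enough that un-normalized fold-change calls are
#' visibly distorted, and entirely removable by loess.
#'
#' @param A average log2 intensity.
#' @return Additive bias on the log ratio M.
#' @export
dye_bias_default <- function(A) 0.3 * sin(A / 2) + 0.015 * (A - 10)^2

#' Simulate a GO annotation universe with an optional planted term
#'
#' Builds a gene universe with random term memberships plus, when
#' `enriched_spec` is supplied, one designated term and gene list with
#' an exact term size, list size and overlap — so the hypergeometric
#' enrichment p-value of the planted term is known in closed form.
#'
#' @param n_genes universe size.
#' @param n_terms number of background terms.
#' @param terms_per_gene mean number of background terms per gene.
#' @param enriched_spec `NULL` for a null universe, or a list with
#'   `term_size` (K), `list_size` (n) and `overlap` (k <= min(K, n)):
#'   the planted term `"GO:planted"` then has exactly that overlap
#'   with the returned `gene_list`.
#' @param seed integer seed.
#' @return A list with `annotation` (tibble `gene_id`, `term`),
#'   `universe` (character) and `gene_list` (character; random when no
#'   spec is planted).
#' @export
gen_go_universe <- function(n_genes = 1000, n_terms = 20, terms_per_gene = 2,
                            enriched_spec = NULL, seed = NULL) {
  if (n_genes < 2 || n_terms < 1) abort("Universe too small.")
  with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    term_ids <- sprintf("GO:%04d", seq_len(n_terms))
    ann <- purrr::map(genes, function(g) {
      k <- max(1, stats::rpois(1, terms_per_gene))
      tibble::tibble(gene_id = g, term = sample(term_ids, min(k, n_terms)))
    }) |> purrr::list_rbind()

    list_size <- max(2, round(n_genes / 20))
    gene_list <- sample(genes, list_size)

    if (!is.null(enriched_spec)) {
      K <- enriched_spec$term_size; n <- enriched_spec$list_size
      k <- enriched_spec$overlap
      if (is.null(K) || is.null(n) || is.null(k) || k > min(K, n) ||
          K > n_genes || n > n_genes || n_genes - K < n - k) {
        abort("Over-constrained `enriched_spec`: overlap incompatible with sizes.")
      }
      gene_list <- sample(genes, n)
      in_list <- sample(gene_list, k)
      out_list <- sample(setdiff(genes, gene_list), K - k)
      ann <- dplyr::bind_rows(
        ann, tibble::tibble(gene_id = c(in_list, out_list), term = "GO:planted")
      )
    }
    list(annotation = dplyr::distinct(ann), universe = genes,
         gene_list = gene_list)
  })
}
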
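# Readers and writers for the package's tabular schemas. Field data
# travel as comma-separated UTF-8 CSV, array data as tab-separated TSV
# (the GenePix convention). Output files carry a commented metadata
# header (package version, parameters, timestamp-free so re-runs are
# byte-identical) that the readers skip transparently.

#' Read a table of internode records
#'
#' Reads a CSV with one row per internode per culm and validates it
#' against the physical invariants of internode measurements (see
#' [validate_internode_records()]). Mandatory columns: `length_cm`,
#' `diameter_mm`, `wall_mm`; all other schema columns (`variety`,
#' `treatment`, `replicate`, `culm`, `internode`, `fresh_g`, `dry_mg`,
#' `dist_tip_cm`, `fresh_above_g`, `break_N`, `elastic_F_N`,
#' `deflect_cm`, `span_cm`) are optional. Unknown columns are kept
#' with a warning.
#'
#' @param path file path.
#' @return A validated tibble of internode records.
#' @export
read_internode_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!nrow(x)) abort("Empty internode file.")
  known <- c("variety", "treatment", "replicate", "culm", "internode",
             "length_cm", "diameter_mm", "wall_mm", "fresh_g", "dry_mg",
             "dist_tip_cm", "fresh_above_g", "break_N", "elastic_F_N",
             "deflect_cm", "span_cm", "E_GPa", "BM_gfcm")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    warn(paste0("Ignoring unknown column(s): ", paste(extra, collapse = ", ")))
  }
  validate_internode_records(x)
}

#' Write a mechanical-profile table (or any tibble) as CSV
#'
#' Writes the table with a commented metadata header recording the
#' package version and any parameters supplied, so every output is
#' self-describing and byte-reproducible under identical inputs.
#'
#' @param x data frame to write.
#' @param path destination path.
#' @param params named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path, params = list()) {
  header <- c(
    paste0("# culmr ", as.character(utils::packageVersion("culmr"))),
    if (length(params)) paste0("# ", names(params), " = ",
                               vapply(params, function(p) paste(format(p), collapse = ","), ""))
  )
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a two-color array replicate TSV
#'
#' Reads one replicate hybridization. Canonical columns are
#' `probe_id`, `cy3`, `cy5`, `flag`; GenePix-results-style headers are
#' mapped automatically (`ID`/`Name` to `probe_id`, `F532 Mean` to
#' `cy3`, `F635 Mean` to `cy5`, negative `Flags` to `"bad"`).
#' Duplicate probe ids are an error.
#'
#' @param path file path (tab-separated).
#' @return Tibble with columns `probe_id`, `cy3`, `cy5`, `flag`.
#' @export
read_array_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!nrow(x)) abort("Empty array file.")
  nm <- names(x)
  pick <- function(...) { cand <- c(...); cand[cand %in% nm][1] }
  id_col <- pick("probe_id", "ID", "Name")
  cy3_col <- pick("cy3", "F532 Mean", "F532.Mean")
  cy5_col <- pick("cy5", "F635 Mean", "F635.Mean")
  if (any(is.na(c(id_col, cy3_col, cy5_col)))) {
    abort("Could not find probe id / Cy3 / Cy5 columns (canonical or GenePix names).")
  }
  flag <- if ("flag" %in% nm) {
    x$flag
  } else if ("Flags" %in% nm) {
    ifelse(x$Flags < 0, "bad", "ok")
  } else "ok"
  out <- tibble::tibble(
    probe_id = as.character(x[[id_col]]),
    cy3 = as.numeric(x[[cy3_col]]),
    cy5 = as.numeric(x[[cy5_col]]),
    flag = flag
  )
  if (anyDuplicated(out$probe_id)) {
    abort("Duplicate probe ids in array file.")
  }
  out
}

#' Read a gene-to-GO-term annotation map
#'
#' Two-column tab-separated file, one `gene_id` / `term` pair per
#' line (a gene may appear on several lines). Exact duplicate pairs
#' are collapsed.
#'
#' @param path file path.
#' @return Tibble with columns `gene_id`, `term`.
#' @export
read_go_map <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  if (!nrow(x) || ncol(x) < 2) abort("Annotation map must have two columns.")
  out <- tibble::tibble(gene_id = as.character(x[[1]]),
                        term = as.character(x[[2]]))
  dplyr::distinct(out)
}

#' Write array replicates to TSV files
#'
#' One tab-separated file per replicate, named
#' `<prefix>_<replicate>.tsv`, in the canonical
#' `probe_id`/`cy3`/`cy5`/`flag` schema.
#'
#' @param replicates named list of replicate tibbles (e.g. from
#'   [gen_two_color_arrays()]).
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_array_tsv <- function(replicates, dir, prefix = "array") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(replicates, function(tbl, id) {
    p <- file.path(dir, paste0(prefix, "_", id, ".tsv"))
    readr::write_tsv(tbl, p)
    p
  })
  invisible(paths)
}
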
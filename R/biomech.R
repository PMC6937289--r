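#' Section moment of area of a hollow culm cross-section
#'
#' The rice culm is modelled as a hollow circular cylinder of outer
#' radius `a` and wall thickness `t`. Its second (section) moment of
#' area about a diameter is
#' \deqn{I = \frac{\pi a^4}{4}\left[1 - \left(1 - t/a\right)^4\right]}
#' which is algebraically identical to \eqn{\pi/4\,(a^4 - (a-t)^4)}.
#' At `t == a` the section is a solid rod and `I` reduces to
#' \eqn{\pi a^4/4}.
#'
#' @param a_mm outer radius at mid-internode, mm (half the culm diameter).
#' @param t_mm culm wall thickness at mid-internode, mm.
#' @return Section moment of area in mm^4.
#' @examples
#' section_moment_of_area(a_mm = 2.425, t_mm = 0.54)  # ~17.24 mm^4
#' section_moment_of_area(1, 1)                        # solid rod, pi/4
#' @export
section_moment_of_area <- function(a_mm, t_mm) {
  check_positive(a_mm, "a_mm")
  check_positive(t_mm, "t_mm")
  if (any(t_mm > a_mm, na.rm = TRUE)) {
    abort("`t_mm` must not exceed the radius `a_mm` (wall cannot be thicker than the culm).")
  }
  pi * a_mm^4 / 4 * (1 - (1 - t_mm / a_mm)^4)
}

#' Elastic modulus from a three-point bending test
#'
#' An internode resting horizontally on two supports a fixed span `L`
#' apart is loaded at mid-span with a force `F` small enough that the
#' culm recovers elastically; the vertical deflection `delta` at
#' mid-span gives the elastic modulus of simple beam theory,
#' \deqn{E = \frac{F L^3}{48\,\delta\,I}.}
#' `span_cm` is the distance between the supports, not the internode
#' length.
#'
#' @param force_n applied mid-span load, N.
#' @param span_cm support span, cm (default 5, the standard fixture).
#' @param deflect_cm mid-span vertical deflection, cm.
#' @param I_mm4 section moment of area, mm^4 (see
#'   [section_moment_of_area()]).
#' @return Elastic modulus in GPa.
#' @examples
#' elastic_modulus(force_n = 1, span_cm = 5, deflect_cm = 1, I_mm4 = 17.24)
#' @export
elastic_modulus <- function(force_n, span_cm = 5, deflect_cm, I_mm4) {
  check_positive(force_n, "force_n")
  check_positive(span_cm, "span_cm")
  check_positive(deflect_cm, "deflect_cm")
  check_positive(I_mm4, "I_mm4")
  # SI: cm -> m, mm^4 -> m^4; result Pa -> GPa
  E_pa <- force_n * (span_cm / 100)^3 / (48 * (deflect_cm / 100) * (I_mm4 * 1e-12))
  E_pa / 1e9
}

#' Flexural rigidity (bending stiffness) of an internode
#'
#' The product of the elastic modulus and the section moment of area,
#' E*I: the resistance of the internode to permanent bending. Reported
#' both in N m^2 and in the 1e-3 N m^2 scale conventional for rice
#' culms.
#'
#' @param E_gpa elastic modulus, GPa.
#' @param I_mm4 section moment of area, mm^4.
#' @param scale `"Nm2"` for N m^2 or `"mNm2"` (default) for 1e-3 N m^2.
#' @return Flexural rigidity in the requested unit.
#' @examples
#' flexural_rigidity(E_gpa = 1.9, I_mm4 = 17.24)  # ~32.8 (1e-3 N m^2)
#' @export
flexural_rigidity <- function(E_gpa, I_mm4, scale = c("mNm2", "Nm2")) {
  scale <- match.arg(scale)
  check_nonneg(E_gpa, "E_gpa")
  check_nonneg(I_mm4, "I_mm4")
  EI_nm2 <- (E_gpa * 1e9) * (I_mm4 * 1e-12)
  if (scale == "mNm2") EI_nm2 * 1e3 else EI_nm2
}

#' Culm volume of an internode
#'
#' Volume of the hollow-cylinder shell,
#' \deqn{V = \pi L (2 a t - t^2) = \pi L\,(a^2 - (a-t)^2).}
#'
#' @param length_cm internode length, cm.
#' @param a_cm outer radius, cm.
#' @param t_cm wall thickness, cm.
#' @return Volume in cm^3.
#' @examples
#' culm_volume(length_cm = 16.9, a_cm = 0.2425, t_cm = 0.054)  # ~1.24
#' @export
culm_volume <- function(length_cm, a_cm, t_cm) {
  check_positive(length_cm, "length_cm")
  check_positive(a_cm, "a_cm")
  check_positive(t_cm, "t_cm")
  if (any(t_cm > a_cm, na.rm = TRUE)) {
    abort("`t_cm` must not exceed the radius `a_cm`.")
  }
  pi * length_cm * (2 * a_cm * t_cm - t_cm^2)
}

#' Bending moment acting on an internode base
#'
#' The self-load moment: the distance from the internode base to the
#' panicle tip times the fresh weight of that whole section,
#' in gram-force centimetres.
#'
#' @param dist_tip_cm distance from internode base to panicle tip, cm.
#' @param fresh_above_g fresh weight of the section from internode base
#'   to panicle tip, g.
#' @return Bending moment in gf cm.
#' @examples
#' bending_moment(76, 10)  # 760 gf cm
#' @export
bending_moment <- function(dist_tip_cm, fresh_above_g) {
  check_nonneg(dist_tip_cm, "dist_tip_cm")
  check_nonneg(fresh_above_g, "fresh_above_g")
  dist_tip_cm * fresh_above_g
}

#' Mid-span bending moment at breaking
#'
#' For a beam on two supports `span` apart loaded at mid-span, the
#' internal moment at the load point is F * span / 4. Expressed in
#' gf cm so it is commensurable with [bending_moment()]; provided as an
#' alternative denominator for [lodging_index()].
#'
#' @param break_n breaking force, N.
#' @param span_cm support span, cm (default 5).
#' @return Breaking bending moment in gf cm.
#' @examples
#' breaking_bending_moment(6, 5)  # ~764.9 gf cm
#' @export
breaking_bending_moment <- function(break_n, span_cm = 5) {
  check_nonneg(break_n, "break_n")
  check_positive(span_cm, "span_cm")
  n_to_gf(break_n) * span_cm / 4
}

#' Lodging index of an internode
#'
#' The ratio of the self-load bending moment to the breaking
#' resistance; a higher lodging index means a higher lodging tendency.
#' Two denominator conventions are provided:
#'
#' * `mode = "force"` (default): the breaking force converted to
#'   gram-force, a literal reading of "bending moment / breaking
#'   resistance". Units cm g g^-1.
#' * `mode = "moment"`: the mid-span breaking bending moment
#'   F * span / 4 (see [breaking_bending_moment()]), which makes the
#'   ratio dimensionless.
#'
#' The convention used is recorded in the `"li_mode"` attribute of the
#' result. Published lodging-index tables are not always recoverable
#' from their printed bending moments and breaking forces under either
#' convention, so the mode is explicit rather than guessed.
#'
#' @param bm_gfcm bending moment, gf cm.
#' @param break_n breaking force, N.
#' @param span_cm support span for `mode = "moment"`, cm.
#' @param mode denominator convention, see Details.
#' @return Lodging index (numeric, with attribute `li_mode`).
#' @examples
#' lodging_index(760, 6)                   # force mode
#' lodging_index(760, 6, mode = "moment")  # moment mode
#' @export
lodging_index <- function(bm_gfcm, break_n, span_cm = 5,
                          mode = c("force", "moment")) {
  mode <- match.arg(mode)
  check_nonneg(bm_gfcm, "bm_gfcm")
  check_positive(break_n, "break_n")
  denom <- switch(mode,
    force  = n_to_gf(break_n),
    moment = breaking_bending_moment(break_n, span_cm)
  )
  structure(bm_gfcm / denom, li_mode = mode)
}

#' Dry-matter densities (plumpness) of an internode
#'
#' Dry weight per unit length (mg cm^-1) and per unit volume
#' (mg cm^-3), the two indicators of internode plumpness.
#'
#' @param dry_mg oven-dry weight, mg.
#' @param length_cm internode length, cm.
#' @param vol_cm3 culm volume, cm^3 (see [culm_volume()]).
#' @return A tibble with columns `dwl_mg_per_cm` and `dwv_mg_per_cm3`.
#' @examples
#' densities(126.1, 16.9, 1.24)
#' @export
densities <- function(dry_mg, length_cm, vol_cm3) {
  check_nonneg(dry_mg, "dry_mg")
  check_positive(length_cm, "length_cm")
  check_positive(vol_cm3, "vol_cm3")
  tibble::tibble(
    dwl_mg_per_cm  = dry_mg / length_cm,
    dwv_mg_per_cm3 = dry_mg / vol_cm3
  )
}

#' Derive the full mechanical profile of internode records
#'
#' Takes a table of internode records (one row per internode per culm;
#' see [read_internode_csv()] for the schema) and appends every
#' mechanical quantity derivable from the columns present:
#' `I_mm4`, `E_GPa`, `EI_mNm2`, `BM_gfcm`, `break_BM_gfcm`, `LI`,
#' `vol_cm3`, `dwl_mg_per_cm`, `dwv_mg_per_cm3`. A quantity whose
#' inputs are missing in a row is `NA` there, never a silent zero.
#'
#' @param records data frame of internode records. Required columns for
#'   the geometric quantities: `length_cm`, `diameter_mm`, `wall_mm`.
#'   Optional: `dry_mg`, `dist_tip_cm`, `fresh_above_g`, `break_N`,
#'   `elastic_F_N`, `deflect_cm`, `span_cm` (defaults to 5 when
#'   absent).
#' @param li_mode lodging-index convention passed to [lodging_index()].
#' @return The input as a tibble with the derived columns appended.
#' @examples
#' rec <- tibble::tibble(
#'   length_cm = 16.9, diameter_mm = 4.85, wall_mm = 0.54,
#'   dry_mg = 126.1, dist_tip_cm = 76, fresh_above_g = 10, break_N = 6
#' )
#' mech_profile(rec)
#' @export
mech_profile <- function(records, li_mode = c("force", "moment")) {
  li_mode <- match.arg(li_mode)
  records <- validate_internode_records(records)
  a_mm <- records$diameter_mm / 2

  out <- dplyr::mutate(tibble::as_tibble(records),
    I_mm4   = pi * a_mm^4 / 4 * (1 - (1 - .data$wall_mm / a_mm)^4),
    vol_cm3 = pi * .data$length_cm *
      (2 * (a_mm / 10) * (.data$wall_mm / 10) - (.data$wall_mm / 10)^2)
  )

  span <- if ("span_cm" %in% names(out)) out$span_cm else rep(5, nrow(out))
  span[is.na(span)] <- 5

  out$E_GPa <- if (all(c("elastic_F_N", "deflect_cm") %in% names(out))) {
    ifelse(
      !is.na(out$elastic_F_N) & !is.na(out$deflect_cm) & out$deflect_cm > 0,
      out$elastic_F_N * (span / 100)^3 /
        (48 * (out$deflect_cm / 100) * (out$I_mm4 * 1e-12)) / 1e9,
      NA_real_
    )
  } else if ("E_GPa" %in% names(records)) records$E_GPa else NA_real_

  out$EI_mNm2 <- out$E_GPa * out$I_mm4  # GPa*mm^4 == 1e-3 N m^2

  out$BM_gfcm <- if (all(c("dist_tip_cm", "fresh_above_g") %in% names(out))) {
    out$dist_tip_cm * out$fresh_above_g
  } else NA_real_

  if ("break_N" %in% names(out)) {
    out$break_BM_gfcm <- ifelse(
      !is.na(out$break_N), n_to_gf(out$break_N) * span / 4, NA_real_
    )
    denom <- if (li_mode == "force") n_to_gf(out$break_N) else out$break_BM_gfcm
    out$LI <- ifelse(
      !is.na(out$BM_gfcm) & !is.na(denom) & denom > 0,
      out$BM_gfcm / denom, NA_real_
    )
  } else {
    out$break_BM_gfcm <- NA_real_
    out$LI <- NA_real_
  }

  if ("dry_mg" %in% names(out)) {
    out$dwl_mg_per_cm  <- out$dry_mg / out$length_cm
    out$dwv_mg_per_cm3 <- out$dry_mg / out$vol_cm3
  } else {
    out$dwl_mg_per_cm  <- NA_real_
    out$dwv_mg_per_cm3 <- NA_real_
  }

  attr(out, "li_mode") <- li_mode
  out
}

# ---- input checks ----------------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x)) abort(paste0("`", name, "` must be numeric."))
  if (any(x <= 0, na.rm = TRUE)) {
    abort(paste0("`", name, "` must be strictly positive."))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x)) abort(paste0("`", name, "` must be numeric."))
  if (any(x < 0, na.rm = TRUE)) {
    abort(paste0("`", name, "` must be non-negative."))
  }
  invisible(x)
}

#' Validate a table of internode records
#'
#' Checks the physical invariants of internode measurements: positive
#' lengths and diameters, wall thickness within the radius, internode
#' index in 1..5, and breaking force absent for internodes shorter than
#' the bending span. Offending rows raise an error naming the row.
#'
#' @param records data frame with at least `length_cm`, `diameter_mm`,
#'   `wall_mm`.
#' @return The records as a tibble, invisibly validated.
#' @export
validate_internode_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("length_cm", "diameter_mm", "wall_mm")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      abort(paste0(what, " (row ", paste(head(idx, 5), collapse = ", "),
                   if (length(idx) > 5) ", ..." else "", ")."))
    }
  }
  bad_row(!is.na(records$length_cm) & records$length_cm <= 0,
          "`length_cm` must be positive")
  bad_row(!is.na(records$diameter_mm) & records$diameter_mm <= 0,
          "`diameter_mm` must be positive")
  bad_row(!is.na(records$wall_mm) &
            (records$wall_mm <= 0 | records$wall_mm > records$diameter_mm / 2),
          "`wall_mm` must lie in (0, diameter/2]")
  if ("internode" %in% names(records)) {
    bad_row(!is.na(records$internode) & !(records$internode %in% 1:5),
            "`internode` must be an index in 1..5")
  }
  if ("break_N" %in% names(records)) {
    span <- if ("span_cm" %in% names(records)) records$span_cm else 5
    span <- ifelse(is.na(span), 5, span)
    bad_row(!is.na(records$break_N) & records$length_cm < span,
            "`break_N` must be absent when the internode is shorter than the bending span")
  }
  records
}
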
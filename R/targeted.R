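#' Fit an external-standard calibration curve
#'
#' Least-squares linear fit of UV peak area against known standard
#' concentration, through the origin by default (a blank has zero signal),
#' so the slope is the closed form `sum(conc * area) / sum(conc^2)`.
#'
#' @param standards Tibble with columns `concentration` and `uv_area`
#'   (optionally `compound`; fit one curve per compound with
#'   [fit_calibrations()]).
#' @param through_origin Fit without intercept (default `TRUE`).
#' @return Object of class `"calibration"` with elements `slope`,
#'   `intercept`, `model` (the `lm` fit), `n`.
#' @examples
#' cal <- fit_calibration(tibble::tibble(concentration = c(1, 2), uv_area = c(10, 20)))
#' cal$slope
#' @export
fit_calibration <- function(standards, through_origin = TRUE) {
  if (nrow(standards) < 2) abort("need >= 2 calibration points.")
  if (dplyr::n_distinct(standards$concentration) < 2) {
    abort("calibration points are degenerate (one distinct concentration).")
  }
  fit <- if (through_origin) {
    lm(uv_area ~ concentration + 0, data = standards)
  } else {
    lm(uv_area ~ concentration, data = standards)
  }
  slope <- unname(coef(fit)[["concentration"]])
  if (!is.finite(slope) || slope <= 0) abort("calibration slope must be positive.")
  structure(list(slope = slope,
                 intercept = if (through_origin) 0 else unname(coef(fit)[1]),
                 model = fit, n = nrow(standards)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Calibration curve: area = %.4g x concentration %s (n = %d)\n",
              x$slope,
              if (x$intercept != 0) sprintf("+ %.4g", x$intercept) else "(through origin)",
              x$n))
  invisible(x)
}

#' @export
tidy.calibration <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @export
glance.calibration <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(slope = x$slope, r_squared = s$r.squared, n = x$n)
}

#' Convert a peak area to a tissue concentration
#'
#' `concentration = (area - intercept) / slope * extract_volume / tissue
#' mass`, in ug per g fresh weight when the calibration is in ug/mL extract.
#'
#' @param calibration A `"calibration"` object.
#' @param uv_area Peak areas to quantify.
#' @param tissue_mass_mg Fresh weight extracted, in mg (default 100).
#' @param extract_volume_ml Extraction volume, in mL (default 1).
#' @return Concentrations (ug/g fresh weight), same length as `uv_area`.
#' @export
quantify <- function(calibration, uv_area, tissue_mass_mg = 100,
                     extract_volume_ml = 1) {
  stopifnot(inherits(calibration, "calibration"))
  (uv_area - calibration$intercept) / calibration$slope *
    extract_volume_ml / (tissue_mass_mg / 1000)
}

#' Estimate a compound-specific MS-to-UV signal conversion factor
#'
#' For compounds whose concentrations are too low to give reliable UV
#' signals, a "predicted" UV signal can be computed from the more sensitive
#' MS signal. The factor is the slope of the through-origin fit of UV on MS
#' area over samples where both signals are reliable:
#' `sum(uv * ms) / sum(ms^2)`.
#'
#' @param panel Tibble with columns `uv_area` and `ms_area`.
#' @param uv_floor Reliability floor: only pairs with `uv_area > uv_floor`
#'   and `ms_area > 0` enter the fit (default 0).
#' @param min_pairs Minimum number of reliable pairs (default 3).
#' @return The scalar conversion factor (UV units per MS unit).
#' @examples
#' p <- tibble::tibble(ms_area = c(100, 200, 300), uv_area = c(5, 10, 15))
#' estimate_ms_uv_factor(p)
#' @export
estimate_ms_uv_factor <- function(panel, uv_floor = 0, min_pairs = 3) {
  ok <- panel$uv_area > uv_floor & panel$ms_area > 0
  if (sum(ok) < min_pairs) {
    abort(paste0("only ", sum(ok), " reliable UV/MS pairs (need >= ",
                 min_pairs, "); supply more calibration data."))
  }
  sum(panel$uv_area[ok] * panel$ms_area[ok]) / sum(panel$ms_area[ok]^2)
}

#' Quantify a targeted compound panel from UV and MS signals
#'
#' Per compound: fits an external-standard calibration curve, estimates the
#' MS-to-UV conversion factor from samples with reliable UV signal, replaces
#' unreliable UV areas (at or below `uv_floor`) with predicted UV =
#' factor x MS area, and converts to tissue concentrations. Every value
#' carries a provenance flag (`"measured"` or `"predicted"`).
#'
#' @param panel Tibble with `compound`, `sample_id`, `uv_area`, `ms_area`,
#'   `tissue_mass_mg` and any design columns (carried through).
#' @param standards Tibble with `compound`, `concentration`, `uv_area`.
#' @param uv_floor UV reliability floor in area units (default 0: all
#'   signals treated as measured).
#' @param extract_volume_ml Extraction volume (default 1 mL).
#' @return `panel` with added columns `uv_used`, `uv_source`,
#'   `concentration`.
#' @export
quantify_panel <- function(panel, standards, uv_floor = 0,
                           extract_volume_ml = 1) {
  needed <- c("compound", "uv_area", "ms_area", "tissue_mass_mg")
  if (!all(needed %in% names(panel))) {
    abort(paste("`panel` needs columns:", paste(needed, collapse = ", ")))
  }
  panel |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(d, key) {
      cal <- fit_calibration(standards[standards$compound == key$compound, ])
      reliable <- d$uv_area > uv_floor
      d$uv_source <- ifelse(reliable, "measured", "predicted")
      if (any(!reliable)) {
        fct <- estimate_ms_uv_factor(d, uv_floor = uv_floor)
        d$uv_used <- ifelse(reliable, d$uv_area, fct * d$ms_area)
      } else {
        d$uv_used <- d$uv_area
      }
      d$concentration <- quantify(cal, d$uv_used,
                                  tissue_mass_mg = d$tissue_mass_mg,
                                  extract_volume_ml = extract_volume_ml)
      d
    }) |>
    dplyr::ungroup()
}

#' Percent reduction of a compound class in a mutant
#'
#' `100 * (1 - sum(mutant) / sum(wild type))` on total concentrations,
#' overall and per root type, with per-compound reductions alongside. The
#' headline number is the reduction of the summed (total) class
#' concentration.
#'
#' @param quant Quantified tibble with `compound`, `genotype`,
#'   `concentration` and optionally `root_type`.
#' @param wt,mutant Genotype labels (defaults `"WT"`, `"bx1"`).
#' @return List with `overall` (scalar percent), `by_root_type` and
#'   `by_compound` tibbles.
#' @export
percent_reduction <- function(quant, wt = "WT", mutant = "bx1") {
  reduction <- function(d) {
    tot_wt <- sum(d$concentration[d$genotype == wt])
    tot_mut <- sum(d$concentration[d$genotype == mutant])
    if (tot_wt <= 0) {
      warn("wild-type total is zero: percent reduction undefined.")
      return(NA_real_)
    }
    100 * (1 - tot_mut / tot_wt)
  }
  by_rt <- if ("root_type" %in% names(quant)) {
    quant |>
      dplyr::group_by(.data$root_type) |>
      dplyr::summarise(percent_reduction = reduction(dplyr::pick(dplyr::everything())),
                       .groups = "drop")
  } else {
    tibble::tibble(root_type = character(), percent_reduction = numeric())
  }
  by_cmp <- quant |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(percent_reduction = reduction(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  list(overall = reduction(quant), by_root_type = by_rt, by_compound = by_cmp)
}

#' Relative gene expression by the 2^-ddCt method
#'
#' Per sample: `dCt = Ct(target) - Ct(reference)`; `ddCt = dCt - mean dCt of
#' the control group`; relative expression `= 2^-ddCt`. Samples with missing
#' Ct values are dropped with a warning.
#'
#' @param records Tibble with `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param control_group Label of the calibrator group (default
#'   `"control"`).
#' @return Tibble with per-sample `dct`, `ddct`, `rel_expression`.
#' @examples
#' q <- simulate_qpcr(seed = 1)
#' knockdown_percent(ddct(q))
#' @export
ddct <- function(records, control_group = "control") {
  ok <- complete.cases(records[, c("ct_target", "ct_reference")]) &
    is.finite(records$ct_target) & is.finite(records$ct_reference)
  if (!all(ok)) {
    warn(paste(sum(!ok), "sample(s) dropped: missing or non-finite Ct."))
    records <- records[ok, , drop = FALSE]
  }
  if (!any(records$group == control_group)) {
    abort(paste0("control group '", control_group, "' is empty."))
  }
  d <- records |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference)
  ref <- mean(d$dct[d$group == control_group])
  d |>
    dplyr::mutate(ddct = .data$dct - ref,
                  rel_expression = 2^(-.data$ddct))
}

#' Percent knockdown from a ddCt table
#'
#' `100 * (1 - mean(treatment expression) / mean(control expression))`.
#'
#' @param ddct_tbl Output of [ddct()].
#' @param control_group,treatment_group Group labels.
#' @return Scalar percent knockdown.
#' @export
knockdown_percent <- function(ddct_tbl, control_group = "control",
                              treatment_group = "treatment") {
  m <- ddct_tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_expr = mean(.data$rel_expression), .groups = "drop")
  ctrl <- m$mean_expr[m$group == control_group]
  trt <- m$mean_expr[m$group == treatment_group]
  if (!length(ctrl) || !length(trt)) abort("both groups must be present.")
  100 * (1 - trt / ctrl)
}
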
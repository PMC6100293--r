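# Free-radical assay quantitation: DPPH scavenging percentage (517 nm),
# trolox-equivalent antioxidant capacity via a trolox standard curve
# (734 nm) and ferric reducing power via an FeSO4 standard curve
# (593 nm), with mass-to-molar conversion of the peptide concentration.

# Average (not monoisotopic) residue masses, g/mol; a peptide's molar
# mass is the sum of its residue masses plus one water.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

#' DPPH radical scavenging percentage
#'
#' Scavenging \% = 100 * (A_control - A_sample) / A_control, from
#' absorbances at 517 nm. Negative values indicate apparent pro-oxidant
#' behaviour and are returned as-is (flagged via attribute
#' `pro_oxidant`).
#'
#' @param a_sample Sample absorbance(s).
#' @param a_control Control absorbance(s), must be positive.
#' @return Numeric scavenging percentage(s).
#' @export
dpph_scavenging <- function(a_sample, a_control) {
  if (any(a_control <= 0)) stop("control absorbance must be positive")
  if (any(a_sample < 0)) stop("absorbances must be non-negative")
  out <- 100 * (a_control - a_sample) / a_control
  attr(out, "pro_oxidant") <- out < 0
  out
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of response on concentration. The fit is
#' rejected when r-squared falls below `r2_floor` (default 0.98), the
#' usual plate-QC criterion for calibration lines.
#'
#' @param concentrations Strictly increasing standard concentrations
#'   (micromolar), at least 3.
#' @param responses Measured responses (e.g. absorbance), same length.
#' @param analyte `"trolox"` or `"FeSO4"`.
#' @param r2_floor Minimum acceptable r-squared.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `range` (min/max concentration), `analyte`.
#' @export
fit_standard_curve <- function(concentrations, responses,
                               analyte = c("trolox", "FeSO4"),
                               r2_floor = 0.98) {
  analyte <- match.arg(analyte)
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 3L) stop("standard curve needs at least 3 points")
  if (anyDuplicated(concentrations)) stop("duplicate standard concentrations")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("standard concentrations must be strictly increasing")
  }
  fit <- stats::lm(responses ~ concentrations)
  tss <- sum((responses - mean(responses))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss
  if (r2 < r2_floor) {
    stop(sprintf("standard curve r-squared %.4f below floor %.4f", r2, r2_floor))
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         range = range(concentrations),
         analyte = analyte),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("%s standard curve: response = %.4g + %.4g * conc (r2 = %.4f, %g-%g uM)\n",
              x$analyte, x$intercept, x$slope, x$r_squared,
              x$range[1], x$range[2]))
  invisible(x)
}

#' Average molar mass of a peptide
#'
#' Sum of average residue masses plus one water molecule.
#'
#' @param sequence Peptide sequence in one-letter code (standard residues
#'   only, non-empty).
#' @return Molar mass in g/mol.
#' @export
peptide_molar_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(RESIDUE_MASS))
  if (length(bad)) stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  sum(RESIDUE_MASS[res]) + WATER_MASS
}

#' Peptide molar concentration from mass concentration
#'
#' @param conc_mass Mass concentration in mg/mL.
#' @param sequence Peptide sequence (used for the molar mass).
#' @return Concentration in micromolar.
#' @export
peptide_micromolar <- function(conc_mass, sequence) {
  stopifnot(conc_mass > 0)
  conc_mass / peptide_molar_mass(sequence) * 1e6
}

equivalent_conc <- function(response, curve) {
  if (abs(curve$slope) < .Machine$double.eps) stop("standard curve slope is zero")
  conc <- (response - curve$intercept) / curve$slope
  attr(conc, "extrapolated") <- conc < curve$range[1] | conc > curve$range[2]
  conc
}

assay_equivalent_value <- function(response, curve, conc_mass, sequence) {
  eq <- equivalent_conc(response, curve)
  pep_um <- peptide_micromolar(conc_mass, sequence)
  out <- as.numeric(eq) / pep_um
  attr(out, "extrapolated") <- attr(eq, "extrapolated")
  out
}

#' Trolox equivalent antioxidant capacity
#'
#' Reads the trolox-equivalent concentration of a sample off the inverse
#' standard curve and divides by the peptide molar concentration, giving
#' micromolar trolox equivalents per micromolar peptide. Read-offs
#' outside the calibrated concentration range are flagged via the
#' `extrapolated` attribute.
#'
#' @param response Sample response on the same scale the curve was fit
#'   on.
#' @param curve A trolox `standard_curve`.
#' @param conc_mass Peptide mass concentration in mg/mL.
#' @param sequence Peptide sequence.
#' @return TEAC value (uM TE / uM peptide).
#' @export
teac_value <- function(response, curve, conc_mass, sequence) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$analyte != "trolox") stop("TEAC needs a trolox standard curve")
  assay_equivalent_value(response, curve, conc_mass, sequence)
}

#' Ferric reducing antioxidant power
#'
#' As [teac_value()] but against an FeSO4 standard curve; the result is
#' micromolar FeSO4 equivalents per micromolar peptide.
#'
#' @inheritParams teac_value
#' @param curve An FeSO4 `standard_curve`.
#' @return FRAP value (uM FeSO4 / uM peptide).
#' @export
frap_value <- function(response, curve, conc_mass, sequence) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$analyte != "FeSO4") stop("FRAP needs an FeSO4 standard curve")
  assay_equivalent_value(response, curve, conc_mass, sequence)
}

#' Aggregate replicate assay values
#'
#' Mean and standard deviation per group (experiments run in triplicate).
#'
#' @param values Numeric assay values.
#' @param group Grouping labels (e.g. sequences), same length.
#' @return Data frame: `group`, `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(values, group) {
  stopifnot(length(values) == length(group))
  groups <- unique(group)
  data.frame(
    group = groups,
    mean = vapply(groups, function(g) mean(values[group == g]), 0),
    sd = vapply(groups, function(g) stats::sd(values[group == g]), 0),
    n = vapply(groups, function(g) sum(group == g), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Quantify an assay plate table
#'
#' Processes a long-format plate table (columns `role`
#' (standard/sample), `id` (analyte or sequence), `concentration`
#' (standard concentration in uM, or sample mass concentration in
#' mg/mL), `response`, `replicate`): fits the standard curve on the
#' standard rows and converts every sample row, then aggregates
#' replicates.
#'
#' @param plate Data frame as above.
#' @param type `"teac"` or `"frap"`.
#' @param r2_floor Passed to [fit_standard_curve()].
#' @return Data frame: `sequence`, `assay`, `value`, `sd`, `n`.
#' @export
analyze_plate <- function(plate, type = c("teac", "frap"), r2_floor = 0.98) {
  type <- match.arg(type)
  needed <- c("role", "id", "concentration", "response", "replicate")
  if (!all(needed %in% names(plate))) {
    stop("plate table needs columns: ", paste(needed, collapse = ", "))
  }
  std <- plate[plate$role == "standard", , drop = FALSE]
  smp <- plate[plate$role == "sample", , drop = FALSE]
  if (!nrow(std) || !nrow(smp)) stop("plate needs both standard and sample rows")
  std_mean <- stats::aggregate(response ~ concentration, data = std, FUN = mean)
  std_mean <- std_mean[order(std_mean$concentration), ]
  analyte <- if (type == "teac") "trolox" else "FeSO4"
  curve <- fit_standard_curve(std_mean$concentration, std_mean$response,
                              analyte = analyte, r2_floor = r2_floor)
  value_fun <- if (type == "teac") teac_value else frap_value
  vals <- vapply(seq_len(nrow(smp)), function(i) {
    as.numeric(value_fun(smp$response[i], curve, smp$concentration[i],
                         smp$id[i]))
  }, 0)
  agg <- aggregate_replicates(vals, smp$id)
  data.frame(sequence = agg$group, assay = type, value = agg$mean,
             sd = agg$sd, n = agg$n, stringsAsFactors = FALSE)
}
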
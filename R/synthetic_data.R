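# Seeded synthetic-data generation: peptide-activity tables drawn from a
# sparse linear ground truth over position-tagged property descriptors,
# and assay plates generated forward through a known standard curve.
# These emulate the statistical shape of published antioxidant
# tripeptide datasets (about 91 tripeptides, most activities between
# 0.028 and 0.995 uM TE/uM with a small high-activity tail up to about
# 2.3) so every pipeline stage is testable without external downloads.

#' Randomly generated synthetic property scales
#'
#' Produces `m` complete property entries with accessions
#' `SYNT<seed-independent index>`; values are standard-normal draws.
#' Useful for building large candidate descriptor pools.
#'
#' @param m Number of scales.
#' @param seed Integer seed.
#' @param prefix Accession prefix (default `"SYNT"`).
#' @return List of [aaindex_entry()] objects.
#' @export
synthetic_properties <- function(m, seed = 42L, prefix = "SYNT") {
  set.seed(seed)
  lapply(seq_len(m), function(k) {
    v <- stats::rnorm(20)
    names(v) <- standard_residues()
    aaindex_entry(sprintf("%s%06d", prefix, k),
                  sprintf("synthetic random scale %d", k), v)
  })
}

#' Default property pool: bundled fixture plus synthetic scales
#'
#' The seven complete fixture scales plus enough synthetic random scales
#' to reach `m` properties in total (default 195, so tripeptides encode
#' to 585 descriptor columns).
#'
#' @param m Total number of property scales (>= 7).
#' @param seed Seed for the synthetic scales.
#' @return List of [aaindex_entry()] objects, fixture entries first.
#' @export
default_properties <- function(m = 195L, seed = 42L) {
  fx <- aaindex_fixture(complete_only = TRUE)
  if (m < length(fx)) stop("m must be at least ", length(fx))
  c(fx, synthetic_properties(m - length(fx), seed = seed))
}

#' Ground truth for synthetic peptide datasets
#'
#' Defines the sparse linear model activities are generated from:
#' `activity = offset + scale * (sum(beta * z) + noise)` where z are the
#' autoscaled descriptor columns of the true variables. The default true
#' variables put most of the signal at the C-terminal position (free
#' energy of solution in water, reverse-turn propensity) plus a
#' steric term at position 1, with coefficients echoing the magnitudes
#' typical of standardized tripeptide QSAR equations. The default
#' offset/scale place the bulk of activities in 0.028-0.995 uM TE/uM
#' with a minority above 1.5.
#'
#' @param true_variables Position-tagged accession names.
#' @param true_coefficients Standardized-scale coefficients, same length.
#' @param noise_sd Gaussian noise standard deviation on the standardized
#'   scale.
#' @param n_peptides Number of distinct tripeptides to generate.
#' @param seed Integer seed.
#' @param activity_offset,activity_scale Affine map from the standardized
#'   linear predictor to uM TE/uM.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(true_variables = c("CHAM820102_p3",
                                            "OOBM850102_p3",
                                            "LEVM760107_p1"),
                         true_coefficients = c(0.90, -0.20, 0.15),
                         noise_sd = 0.15,
                         n_peptides = 91L,
                         seed = 1L,
                         activity_offset = 0.55,
                         activity_scale = 0.50) {
  stopifnot(length(true_variables) == length(true_coefficients),
            noise_sd >= 0, n_peptides >= 2L)
  structure(
    list(true_variables = true_variables,
         true_coefficients = stats::setNames(true_coefficients, true_variables),
         noise_sd = noise_sd, n_peptides = as.integer(n_peptides),
         seed = as.integer(seed),
         activity_offset = activity_offset,
         activity_scale = activity_scale),
    class = "ground_truth"
  )
}

#' Generate a synthetic peptide-activity dataset
#'
#' Draws `n_peptides` distinct tripeptides uniformly over residues,
#' encodes them against `properties`, autoscales the descriptors, and
#' produces activities from the ground-truth linear model plus Gaussian
#' noise, affinely mapped to activity units. The raw-scale true
#' coefficients (`activity_scale * beta`, the target OLS coefficients
#' when regressing raw activity on the autoscaled true columns) are
#' returned with the truth for recovery checks.
#'
#' @param truth A [ground_truth()] object.
#' @param properties Property pool including all true-variable
#'   accessions (default [default_properties()]).
#' @return List with `peptides` (data frame: sequence, activity, subset),
#'   `truth` (with `raw_coefficients` added) and `descriptors` (the raw
#'   encoded matrix).
#' @export
generate_peptide_dataset <- function(truth, properties = default_properties()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$n_peptides > 8000L) {
    stop("at most 8000 distinct tripeptides exist")
  }
  set.seed(truth$seed)
  sequences <- sample(enumerate_candidates(), truth$n_peptides)
  X <- encode_peptides(sequences, properties)
  missing_vars <- setdiff(truth$true_variables, colnames(X))
  if (length(missing_vars)) {
    stop("true variables not in descriptor pool: ",
         paste(missing_vars, collapse = ", "))
  }
  sc <- autoscale(X)
  lost <- intersect(truth$true_variables, sc$params$dropped)
  if (length(lost)) {
    stop("true variable(s) constant in the sampled peptides: ",
         paste(lost, collapse = ", "))
  }
  eta <- as.vector(sc$X[, truth$true_variables, drop = FALSE] %*%
                     truth$true_coefficients)
  noise <- stats::rnorm(truth$n_peptides, 0, truth$noise_sd)
  activity <- truth$activity_offset + truth$activity_scale * (eta + noise)
  truth$raw_coefficients <- truth$activity_scale * truth$true_coefficients
  list(
    peptides = data.frame(sequence = sequences, activity = activity,
                          subset = "unassigned", stringsAsFactors = FALSE),
    truth = truth,
    descriptors = X
  )
}

#' Pinned synthetic standard curves
#'
#' Linear response curves used by the plate generator: a decolorization
#' style trolox curve (absorbance at 734 nm falling with concentration
#' over 150-1500 uM) and an FeSO4 curve (absorbance at 593 nm rising
#' over 200-1200 uM).
#'
#' @param analyte `"trolox"` or `"FeSO4"`.
#' @return A `standard_curve` object.
#' @export
synthetic_standard_curve <- function(analyte = c("trolox", "FeSO4")) {
  analyte <- match.arg(analyte)
  if (analyte == "trolox") {
    structure(list(slope = -4e-4, intercept = 0.70, r_squared = 1,
                   range = c(150, 1500), analyte = "trolox"),
              class = "standard_curve")
  } else {
    structure(list(slope = 1e-3, intercept = 0.05, r_squared = 1,
                   range = c(200, 1200), analyte = "FeSO4"),
              class = "standard_curve")
  }
}

#' Generate a synthetic assay plate
#'
#' Standard wells are placed on the curve (plus noise) at `n_standards`
#' evenly spaced concentrations across its calibrated range; sample wells
#' are generated by forward application of the curve to the analyte
#' equivalent concentration implied by each true value and the peptide's
#' molar concentration. Everything is emitted in triplicate.
#'
#' @param sequences Peptide sequences.
#' @param true_values True assay values (uM analyte equivalents per uM
#'   peptide), same length; must be non-negative.
#' @param curve A `standard_curve` (e.g. [synthetic_standard_curve()]).
#' @param noise_sd_absorbance Gaussian noise SD on responses (default 0).
#' @param conc_mass Peptide mass concentration in mg/mL (default 0.1).
#' @param n_standards Number of standard concentrations (default 6).
#' @param seed Integer seed.
#' @return Plate data frame: `role`, `id`, `concentration`, `response`,
#'   `replicate` (consumable by [analyze_plate()]).
#' @export
generate_assay_plate <- function(sequences, true_values, curve,
                                 noise_sd_absorbance = 0, conc_mass = 0.1,
                                 n_standards = 6L, seed = 1L) {
  stopifnot(length(sequences) == length(true_values), all(true_values >= 0),
            inherits(curve, "standard_curve"))
  set.seed(seed)
  std_conc <- seq(curve$range[1], curve$range[2], length.out = n_standards)
  rows <- list()
  for (rep_id in 1:3) {
    resp <- curve$intercept + curve$slope * std_conc +
      stats::rnorm(n_standards, 0, noise_sd_absorbance)
    rows[[length(rows) + 1L]] <- data.frame(
      role = "standard", id = curve$analyte, concentration = std_conc,
      response = resp, replicate = rep_id, stringsAsFactors = FALSE)
  }
  for (i in seq_along(sequences)) {
    pep_um <- peptide_micromolar(conc_mass, sequences[i])
    eq_conc <- true_values[i] * pep_um
    resp <- curve$intercept + curve$slope * eq_conc +
      stats::rnorm(3, 0, noise_sd_absorbance)
    rows[[length(rows) + 1L]] <- data.frame(
      role = "sample", id = sequences[i], concentration = conc_mass,
      response = resp, replicate = 1:3, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
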
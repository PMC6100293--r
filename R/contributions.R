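# Positional residue-contribution analysis for linear QSAR models: the
# standardized coefficient of each selected variable, multiplied by the
# standardized property value of a residue, decomposes the predicted
# (standardized) activity of a tripeptide into one additive term per
# position.

parse_variable_names <- function(vars) {
  m <- regmatches(vars, regexec("^(.*)_p([0-9]+)$", vars))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop("variable names must look like <accession>_p<position>: ",
         paste(vars[bad], collapse = ", "))
  }
  data.frame(variable = vars,
             accession = vapply(m, `[[`, "", 2L),
             position = as.integer(vapply(m, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Normalized (standardized) regression coefficients
#'
#' Models fitted on autoscaled predictors and response already store
#' normalized regression coefficients (NRCs), which are returned as-is.
#' For a raw-scale linear model, supply the predictor and response
#' standard deviations and the NRCs are recovered as
#' beta_j * sd_x_j / sd_y.
#'
#' @param model A linear `qsar_model` (MLR or PLS).
#' @param sd_x Optional named per-variable standard deviations (raw-scale
#'   coefficients).
#' @param sd_y Optional response standard deviation (raw-scale
#'   coefficients).
#' @return Named numeric vector of NRCs.
#' @export
normalized_coefficients <- function(model, sd_x = NULL, sd_y = NULL) {
  if (is.null(model$coefficients)) {
    stop(model$method, " models carry no regression coefficients")
  }
  beta <- model$coefficients
  if (!is.null(sd_x) || !is.null(sd_y)) {
    if (is.null(sd_x) || is.null(sd_y)) {
      stop("supply both sd_x and sd_y to convert raw-scale coefficients")
    }
    beta <- beta * sd_x[names(beta)] / sd_y
  }
  beta
}

#' Per-residue, per-position contribution table
#'
#' For each amino acid a and position j, sums NRC(v) * z(a) over the
#' selected variables v at position j, where z(a) is the property value
#' of residue a standardized with the same column statistics the model
#' was fitted with (falling back to standardization across the 20
#' residues when the model has no stored scaling). Under this definition
#' the predicted standardized activity of any tripeptide equals the sum
#' of its three positional contributions.
#'
#' @param model Linear `qsar_model` with variables named
#'   `<accession>_p<j>`.
#' @param properties List of [aaindex_entry()] covering every selected
#'   accession.
#' @param n_positions Number of positions in the table (default 3).
#' @return Object of class `contribution_table`: a 20 x `n_positions`
#'   numeric matrix (rows = residues, alphabetical; columns `p1`...).
#' @export
residue_contributions <- function(model, properties, n_positions = 3L) {
  nrc <- normalized_coefficients(model)
  info <- parse_variable_names(names(nrc))
  if (max(info$position) > n_positions) {
    stop("model uses positions beyond n_positions")
  }
  prop_map <- stats::setNames(properties,
                              vapply(properties, `[[`, "", "accession"))
  missing_acc <- setdiff(unique(info$accession), names(prop_map))
  if (length(missing_acc)) {
    stop("properties missing for accession(s): ",
         paste(missing_acc, collapse = ", "))
  }
  res <- standard_residues()
  tab <- matrix(0, nrow = 20L, ncol = n_positions,
                dimnames = list(res, paste0("p", seq_len(n_positions))))
  for (i in seq_len(nrow(info))) {
    v <- info$variable[i]
    vals <- prop_map[[info$accession[i]]]$values[res]
    if (anyNA(vals)) {
      stop("property ", info$accession[i], " has missing residue values")
    }
    if (!is.null(model$scaling) && v %in% names(model$scaling$center)) {
      z <- (vals - model$scaling$center[[v]]) / model$scaling$scale[[v]]
    } else {
      z <- (vals - mean(vals)) / stats::sd(vals)
    }
    tab[, info$position[i]] <- tab[, info$position[i]] + nrc[[v]] * z
  }
  structure(tab, class = c("contribution_table", "matrix"),
            model_method = model$method)
}

#' Rank predominant and deleterious residues per position
#'
#' Sorts each position's contributions in descending order (ties broken
#' alphabetically): the top `top_k` residues are predominant (raise
#' predicted activity), the bottom `top_k` deleterious (most negative
#' contributions).
#'
#' @param table A `contribution_table` from [residue_contributions()].
#' @param top_k Number of residues per list (<= 20).
#' @return Named list per position, each with `predominant` and
#'   `deleterious` character vectors; attribute `degenerate` is TRUE when
#'   the table is all zero.
#' @export
rank_residues <- function(table, top_k = 3L) {
  stopifnot(top_k >= 1L, top_k <= 20L)
  res <- rownames(table)
  out <- lapply(seq_len(ncol(table)), function(j) {
    v <- table[, j]
    ord <- order(-v, res)
    list(predominant = res[ord][seq_len(top_k)],
         deleterious = rev(res[ord])[seq_len(top_k)])
  })
  names(out) <- colnames(table)
  attr(out, "degenerate") <- all(table == 0)
  out
}

#' Write a contribution table to CSV
#'
#' @param table A `contribution_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contributions <- function(table, path) {
  df <- data.frame(residue = rownames(table),
                   as.data.frame(unclass(table)[, , drop = FALSE]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Reference linear model with the published standardized coefficients
#'
#' Builds a linear `qsar_model` carrying the seven-variable standardized
#' coefficient vector reported for the stepwise-MLR antioxidant
#' tripeptide equation (van der Waals parameter at position 1, partial
#' specific volume at position 2, and free energy of solution in water,
#' negative charge, beta-sheet window weight, unfolding Gibbs energy and
#' reverse-turn propensity at the C-terminal position 3). Column scaling
#' is taken across the 20 residues of each property, so predictions are
#' on a standardized activity scale. Combined with the bundled synthetic
#' property fixture this gives a fully specified demonstration model for
#' contribution mapping and candidate design.
#'
#' @param properties List of [aaindex_entry()] containing the seven
#'   accessions (default: the bundled fixture).
#' @return A `qsar_model` of method `"MLR"`.
#' @export
reference_model <- function(properties = aaindex_fixture()) {
  nrc <- c(LEVM760107_p1 = 0.255, COHE430101_p2 = 0.202,
           CHAM820102_p3 = 0.741, FAUJ880112_p3 = -0.245,
           QIAN880115_p3 = 0.236, YUTK870102_p3 = -0.254,
           OOBM850102_p3 = -0.374)
  info <- parse_variable_names(names(nrc))
  prop_map <- stats::setNames(properties,
                              vapply(properties, `[[`, "", "accession"))
  missing_acc <- setdiff(info$accession, names(prop_map))
  if (length(missing_acc)) {
    stop("properties missing for accession(s): ",
         paste(missing_acc, collapse = ", "))
  }
  ctr <- scl <- stats::setNames(numeric(length(nrc)), names(nrc))
  for (i in seq_along(nrc)) {
    vals <- prop_map[[info$accession[i]]]$values
    ctr[i] <- mean(vals)
    scl[i] <- stats::sd(vals)
  }
  scaling <- structure(
    list(center = ctr, scale = scl, dropped = character(0),
         y_center = NULL, y_scale = NULL),
    class = "scaling_params"
  )
  new_qsar_model("MLR", names(nrc), coefficients = nrc, scaling = scaling)
}
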
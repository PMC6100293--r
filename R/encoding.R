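#' Encode peptides as a position-wise descriptor matrix
#'
#' Every peptide of length n characterized by m property scales becomes a
#' row of n x m descriptor values: the cell for column `<accession>_p<j>`
#' is that property's value for the residue at position j (1-based,
#' position 1 = N-terminus). Columns are ordered position-major: all m
#' properties for position 1, then position 2, and so on.
#'
#' @param sequences Character vector of peptide sequences in one-letter
#'   code, all the same length.
#' @param properties List of [aaindex_entry()] objects; each must have a
#'   value for every residue occurring in `sequences`.
#' @return Numeric matrix, rows named by sequence (made unique if
#'   duplicated), columns `<accession>_p<j>`.
#' @export
encode_peptides <- function(sequences, properties) {
  stopifnot(length(sequences) > 0L, length(properties) > 0L)
  sequences <- as.character(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("all peptides must have the same length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  n <- lens[1]
  m <- length(properties)
  res_mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  bad <- matrix(!(res_mat %in% standard_residues()), nrow = nrow(res_mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("peptide '%s' has nonstandard residue '%s' at position %d",
                 sequences[idx[1]], res_mat[idx[1], idx[2]], idx[2]))
  }
  accs <- vapply(properties, `[[`, "", "accession")
  X <- matrix(NA_real_, nrow = length(sequences), ncol = n * m)
  colnames(X) <- as.vector(vapply(
    seq_len(n),
    function(j) paste0(accs, "_p", j),
    character(m)
  ))
  rownames(X) <- make.unique(sequences, sep = "#")
  for (j in seq_len(n)) {
    for (k in seq_len(m)) {
      vals <- properties[[k]]$values[res_mat[, j]]
      if (anyNA(vals)) {
        i <- which(is.na(vals))[1]
        stop(sprintf(
          "peptide '%s': property %s has no value for residue '%s' at position %d",
          sequences[i], accs[k], res_mat[i, j], j))
      }
      X[, (j - 1L) * m + k] <- vals
    }
  }
  X
}

#' Autoscale a descriptor matrix (and optionally the response)
#'
#' Centers each column to mean 0 and scales to standard deviation 1
#' (sample sd, n-1 denominator). Zero-variance columns cannot be scaled
#' and are dropped; their names are reported in the returned scaling
#' parameters. When `y` is supplied the response is centered and scaled
#' the same way, so a linear fit on the scaled data has no intercept and
#' its coefficients are normalized regression coefficients.
#'
#' @param X Numeric descriptor matrix (>= 2 rows).
#' @param y Optional numeric response vector, length `nrow(X)`.
#' @return List with `X` (scaled matrix, zero-variance columns removed),
#'   `y` (scaled response or NULL) and `params`, an object of class
#'   `scaling_params` holding per-column `center`/`scale`, the `dropped`
#'   column names, and `y_center`/`y_scale` when a response was given.
#' @export
autoscale <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  dropped <- colnames(X)[!keep]
  Xs <- scale(X[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  params <- structure(
    list(center = ctr[keep], scale = scl[keep], dropped = dropped,
         y_center = NULL, y_scale = NULL),
    class = "scaling_params"
  )
  ys <- NULL
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(X))
    yc <- mean(y); ysd <- stats::sd(y)
    if (ysd <= 0) stop("response has zero variance; cannot autoscale")
    params$y_center <- yc
    params$y_scale <- ysd
    ys <- (y - yc) / ysd
  }
  list(X = Xs, y = ys, params = params)
}

#' Apply stored scaling parameters to new descriptor rows
#'
#' @param X Raw descriptor matrix containing at least the retained
#'   columns of `params`.
#' @param params A `scaling_params` object from [autoscale()].
#' @return Scaled matrix restricted to the retained columns, in the
#'   order of `params$center`.
#' @export
apply_scaling <- function(X, params) {
  X <- as.matrix(X)
  cols <- names(params$center)
  missing_cols <- setdiff(cols, colnames(X))
  if (length(missing_cols)) {
    stop("descriptor matrix lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  sweep(sweep(X[, cols, drop = FALSE], 2, params$center, "-"),
        2, params$scale, "/")
}

#' Map a scaled response back to the original activity units
#'
#' @param z Scaled response values.
#' @param params A `scaling_params` object carrying `y_center`/`y_scale`.
#' @return Values on the original activity scale.
#' @export
unscale_response <- function(z, params) {
  if (is.null(params$y_center)) {
    stop("scaling parameters carry no response scaling")
  }
  z * params$y_scale + params$y_center
}

#' Read a peptide-activity table
#'
#' Expects a CSV with columns `sequence` and `activity` (micromolar
#' Trolox equivalents per micromolar peptide) and optionally `subset`.
#'
#' @param path CSV file path.
#' @return Data frame with `sequence`, `activity` and `subset` columns.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "activity") %in% names(df))) {
    stop("peptide table needs 'sequence' and 'activity' columns")
  }
  if (is.null(df$subset)) df$subset <- "unassigned"
  df$sequence <- toupper(trimws(df$sequence))
  if (any(!is.finite(df$activity) & !is.na(df$activity))) {
    stop("non-finite activity values in peptide table")
  }
  df
}
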
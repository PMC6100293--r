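# Model-guided tripeptide design: enumerate sequences under positional
# residue constraints, score them with a fitted model, and rank for
# synthesis.

#' Enumerate candidate tripeptides under positional constraints
#'
#' Cartesian product of the allowed residue sets, in lexicographic order
#' of the resulting sequences.
#'
#' @param pos1,pos2,pos3 Character vectors of allowed one-letter codes
#'   per position (default: all 20 standard residues).
#' @return Character vector of candidate sequences (no duplicates).
#' @export
enumerate_candidates <- function(pos1 = standard_residues(),
                                 pos2 = standard_residues(),
                                 pos3 = standard_residues()) {
  sets <- list(pos1, pos2, pos3)
  for (s in sets) {
    if (!length(s)) stop("each position needs a non-empty residue set")
    if (!all(s %in% standard_residues())) {
      stop("nonstandard residue in constraint set: ",
           paste(setdiff(s, standard_residues()), collapse = ", "))
    }
  }
  sets <- lapply(sets, function(s) sort(unique(s)))
  grid <- expand.grid(p3 = sets[[3]], p2 = sets[[2]], p1 = sets[[1]],
                      stringsAsFactors = FALSE)
  sort(paste0(grid$p1, grid$p2, grid$p3))
}

#' Score and rank candidate tripeptides with a fitted model
#'
#' Each sequence is encoded against `properties`, scaled with the model's
#' stored scaling parameters and predicted. Candidates whose scaled
#' descriptor values fall outside the range seen at training time (when
#' the model records one) are flagged as extrapolations. Ranks are 1 for
#' the highest predicted activity; ties keep lexicographic sequence
#' order.
#'
#' @param sequences Character vector of candidate tripeptides.
#' @param model Fitted `qsar_model`.
#' @param properties List of [aaindex_entry()] covering the model's
#'   accessions.
#' @param train_range Optional 2-row matrix (rows `min`, `max`, columns =
#'   model variables, raw descriptor scale) used for the extrapolation
#'   flag.
#' @return Data frame: `sequence`, `predicted_activity`, `rank`,
#'   `extrapolation`, sorted by rank.
#' @export
score_candidates <- function(sequences, model, properties,
                             train_range = NULL) {
  stopifnot(length(sequences) > 0L)
  X <- encode_peptides(sequences, properties)
  pred <- stats::predict(model, X)
  extrap <- rep(FALSE, length(sequences))
  if (!is.null(train_range)) {
    vars <- intersect(model$variables, colnames(train_range))
    Xv <- X[, vars, drop = FALSE]
    lo <- train_range["min", vars]
    hi <- train_range["max", vars]
    extrap <- rowSums(sweep(Xv, 2, lo, "<") | sweep(Xv, 2, hi, ">")) > 0
  }
  ord <- order(-pred, sequences)
  out <- data.frame(sequence = sequences[ord],
                    predicted_activity = pred[ord],
                    rank = seq_along(sequences),
                    extrapolation = extrap[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Descriptor range of a training set (for extrapolation flagging)
#'
#' @param X Raw descriptor matrix of the training peptides.
#' @return 2-row matrix with rows `min` and `max`.
#' @export
descriptor_range <- function(X) {
  rbind(min = apply(X, 2, min), max = apply(X, 2, max))
}

#' Squared Pearson correlation between predictions and observations
#'
#' One value per prediction set; the sign of the underlying correlation
#' is kept alongside since the square discards it.
#'
#' @param predicted Named list of numeric prediction vectors (one per
#'   model), each aligned with `observed`.
#' @param observed Numeric vector of observed activities (length >= 3).
#' @return Data frame: `model`, `r_squared`, `correlation_sign`.
#' @export
compare_predictions_to_observed <- function(predicted, observed) {
  stopifnot(is.list(predicted), length(observed) >= 3L)
  if (stats::sd(observed) == 0) stop("observed activities have zero variance")
  rows <- lapply(names(predicted), function(nm) {
    p <- predicted[[nm]]
    stopifnot(length(p) == length(observed))
    r <- stats::cor(p, observed)
    data.frame(model = nm, r_squared = r^2,
               correlation_sign = sign(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tripeptides designed around the favorable-position rules
#'
#' The fourteen designed sequences named in the source study: eleven
#' with Trp at the C-terminus or His at position 2 plus deliberately
#' unfavorable controls. Five further designed sequences were reported
#' only in the study's supplementary appendix and are not bundled.
#'
#' @return Character vector of tripeptide sequences.
#' @export
designed_tripeptides <- function() {
  c("GKW", "GVR", "PYW", "NKW", "YHW", "KHW", "QHW", "NHW", "KVW",
    "KHR", "GHT", "GHG", "LVG", "GHP")
}
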
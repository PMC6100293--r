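# Partial-F screening: forward entry / backward removal stepwise OLS.
# The enter scan residualizes y and all candidates against the current
# model (plus intercept) in one QR pass, so each cycle is O(n * m).

#' Stepwise regression variable screening
#'
#' Classic forward-entry / backward-removal stepwise ordinary least
#' squares. At each cycle the candidate with the smallest partial-F
#' p-value enters if that p-value is at most `enter`; then any included
#' variable whose partial-F p-value is at least `remove` is dropped
#' (largest p first). Ties are broken by column order. The procedure
#' terminates when neither action fires, when a cycle would re-enter the
#' variable just removed (livelock guard), or when the selected set
#' reaches `nrow(X) - 2` variables (warning flag set).
#'
#' @param X Numeric matrix of candidate predictors (autoscaled columns).
#' @param y Numeric response, length `nrow(X)` (autoscaled).
#' @param enter Significance (probability-of-F) threshold to enter a
#'   variable; default 0.05.
#' @param remove Significance threshold to remove a variable; default
#'   0.10. Must satisfy `enter <= remove`.
#' @return Object of class `swr_selection`: `selected` (ordered names),
#'   `steps` (data frame of action/variable/F/p), `thresholds`, `vifs`
#'   (for >= 2 selected variables), `truncated` (TRUE when the row-count
#'   guard fired).
#' @export
stepwise_select <- function(X, y, enter = 0.05, remove = 0.10) {
  X <- as.matrix(X)
  if (ncol(X) == 0L || nrow(X) == 0L) stop("empty candidate matrix")
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 3L)
  if (enter > remove) stop("'enter' threshold must not exceed 'remove'")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  selected <- character(0)
  steps <- list()
  truncated <- FALSE
  last_removed <- NA_character_
  max_vars <- n - 2L

  enter_scan <- function(sel) {
    cand <- setdiff(colnames(X), sel)
    if (!length(cand)) return(NULL)
    base <- cbind(`(Intercept)` = rep(1, n),
                  X[, sel, drop = FALSE])
    qrB <- qr(base)
    p0 <- qrB$rank
    ry <- qr.resid(qrB, y)
    RX <- qr.resid(qrB, X[, cand, drop = FALSE])
    rss0 <- sum(ry^2)
    # perfect fit: nothing left to explain, avoid eps-level F statistics
    if (rss0 <= 1e-12 * sum((y - mean(y))^2)) return(NULL)
    # RSS after adding candidate c: rss0 - (ry . rc)^2 / (rc . rc)
    num <- as.vector(crossprod(RX, ry))^2
    den <- colSums(RX^2)
    gain <- ifelse(den > 1e-12 * rss0 + .Machine$double.eps, num / den, 0)
    rss1 <- pmax(rss0 - gain, 0)
    df2 <- n - p0 - 1L
    if (df2 < 1L) return(NULL)
    Fstat <- gain / (rss1 / df2)
    Fstat[den <= 1e-12 * rss0 + .Machine$double.eps] <- 0
    pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
    best <- which.min(pval)  # ties: lowest column index among candidates
    list(variable = cand[best], F = Fstat[best], p = pval[best])
  }

  removal_scan <- function(sel) {
    if (!length(sel)) return(NULL)
    fit <- stats::lm.fit(cbind(`(Intercept)` = rep(1, n),
                               X[, sel, drop = FALSE]), y)
    df2 <- n - fit$rank
    if (df2 < 1L) return(NULL)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df2
    R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    XtXinv_diag <- diag(chol2inv(R))
    coefs <- fit$coefficients[c("(Intercept)", sel)]
    tstat <- coefs / sqrt(sigma2 * XtXinv_diag)
    Fstat <- tstat[-1]^2  # drop intercept
    pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
    worst <- which.max(pval)  # ties: first (earliest-selected) wins
    list(variable = sel[worst], F = unname(Fstat[worst]), p = unname(pval[worst]))
  }

  log_step <- function(action, v, F, p) {
    steps[[length(steps) + 1L]] <<- data.frame(
      action = action, variable = v, F = F, p = p,
      stringsAsFactors = FALSE)
  }

  repeat {
    if (length(selected) >= max_vars) {
      truncated <- TRUE
      warning("stepwise selection stopped: selected variables reached nrow - 2")
      break
    }
    cand <- enter_scan(selected)
    entered <- NULL
    if (!is.null(cand) && cand$p <= enter) {
      if (identical(cand$variable, last_removed)) break  # livelock guard
      selected <- c(selected, cand$variable)
      log_step("enter", cand$variable, cand$F, cand$p)
      entered <- cand$variable
    }
    removed_any <- FALSE
    stop_all <- FALSE
    repeat {
      rem <- removal_scan(selected)
      if (is.null(rem) || rem$p < remove) break
      selected <- setdiff(selected, rem$variable)
      log_step("remove", rem$variable, rem$F, rem$p)
      last_removed <- rem$variable
      removed_any <- TRUE
      if (!is.null(entered) && identical(rem$variable, entered)) {
        stop_all <- TRUE  # enter immediately undone: livelock
        break
      }
    }
    if (stop_all) break
    if (is.null(entered) && !removed_any) break
  }

  steps_df <- if (length(steps)) do.call(rbind, steps) else
    data.frame(action = character(0), variable = character(0),
               F = numeric(0), p = numeric(0), stringsAsFactors = FALSE)

  vifs <- if (length(selected) >= 2L && nrow(X) > length(selected)) {
    vif(X[, selected, drop = FALSE])
  } else {
    stats::setNames(numeric(0), character(0))
  }

  structure(
    list(selected = selected, steps = steps_df,
         thresholds = c(enter = enter, remove = remove),
         vifs = vifs, truncated = truncated),
    class = "swr_selection"
  )
}

#' @export
print.swr_selection <- function(x, ...) {
  cat(sprintf("Stepwise selection: %d variable(s) (enter p <= %.3g, remove p >= %.3g)\n",
              length(x$selected), x$thresholds["enter"], x$thresholds["remove"]))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  if (length(x$vifs)) {
    cat("VIF range:", sprintf("%.3f", min(x$vifs)), "-",
        sprintf("%.3f", max(x$vifs)), "\n")
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' For each column v, VIF(v) = 1 / (1 - R^2) where R^2 is the coefficient
#' of determination of v regressed (with intercept) on all remaining
#' columns. Exactly collinear columns (R^2 = 1 within tolerance) are
#' reported as `Inf` rather than capped.
#'
#' @param X Numeric matrix with at least two columns and more rows than
#'   columns.
#' @param tol Collinearity tolerance on 1 - R^2 (default 1e-10).
#' @return Named numeric vector of VIFs (all >= 1, or `Inf`).
#' @export
vif <- function(X, tol = 1e-10) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF needs at least 2 variables")
  if (nrow(X) <= ncol(X)) stop("VIF needs more rows than variables")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    res <- stats::lm.fit(others, v)$residuals
    sst <- sum((v - mean(v))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - sum(res^2) / sst
    one_minus <- 1 - r2
    if (one_minus < tol) Inf else 1 / one_minus
  }, 0)
  names(out) <- colnames(X)
  out
}

#' Collinearity check on a selection result
#'
#' Variables pass when every VIF is below `vif_limit` (the conventional
#' cutoff of 5 flags problematic collinearity).
#'
#' @param result A `swr_selection` object with populated `vifs`.
#' @param vif_limit Threshold (default 5).
#' @return List with `pass` (logical) and `offenders` (named VIFs at or
#'   above the limit).
#' @export
check_selection <- function(result, vif_limit = 5) {
  stopifnot(inherits(result, "swr_selection"))
  if (!length(result$vifs)) stop("selection result has no VIFs to check")
  offenders <- result$vifs[result$vifs >= vif_limit]
  list(pass = length(offenders) == 0L, offenders = offenders,
       vif_limit = vif_limit)
}
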
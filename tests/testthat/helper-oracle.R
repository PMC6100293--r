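# Independent reference implementations used as oracles: a plain lm/anova
# transcription of forward-entry/backward-removal stepwise regression,
# and partial-F scans computed per candidate with lm().

oracle_partial_f_scan <- function(X, y, sel) {
  cand <- setdiff(colnames(X), sel)
  base_df <- data.frame(y = y, X[, sel, drop = FALSE], check.names = FALSE)
  f0 <- lm(y ~ ., data = base_df)
  ps <- vapply(cand, function(v) {
    df1 <- data.frame(y = y, X[, c(sel, v), drop = FALSE], check.names = FALSE)
    f1 <- lm(y ~ ., data = df1)
    a <- anova(f0, f1)
    a$`Pr(>F)`[2]
  }, 0)
  names(ps) <- cand
  ps
}

oracle_removal_scan <- function(X, y, sel) {
  df <- data.frame(y = y, X[, sel, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  s <- summary(fit)$coefficients
  ps <- s[-1, "Pr(>|t|)"]
  names(ps) <- sel
  ps
}

oracle_stepwise <- function(X, y, enter = 0.05, remove = 0.10) {
  sel <- character(0)
  log <- list()
  last_removed <- NA_character_
  repeat {
    if (length(sel) >= nrow(X) - 2L) break
    entered <- NULL
    ps <- oracle_partial_f_scan(X, y, sel)
    ps <- ps[!is.na(ps)]
    if (length(ps)) {
      best <- names(ps)[which.min(ps)]
      if (ps[best] <= enter) {
        if (identical(best, last_removed)) break
        sel <- c(sel, best)
        log[[length(log) + 1L]] <- c("enter", best)
        entered <- best
      }
    }
    removed_any <- FALSE
    stop_all <- FALSE
    repeat {
      if (!length(sel)) break
      rp <- oracle_removal_scan(X, y, sel)
      worst <- names(rp)[which.max(rp)]
      if (rp[worst] < remove) break
      sel <- setdiff(sel, worst)
      log[[length(log) + 1L]] <- c("remove", worst)
      last_removed <- worst
      removed_any <- TRUE
      if (!is.null(entered) && identical(worst, entered)) { stop_all <- TRUE; break }
    }
    if (stop_all) break
    if (is.null(entered) && !removed_any) break
  }
  list(selected = sel,
       steps = if (length(log)) do.call(rbind, log) else
         matrix(character(0), ncol = 2))
}
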
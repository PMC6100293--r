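# 20 standard one-letter codes in AAindex I-line order:
# row 1 = A R N D C Q E G H I, row 2 = L K M F P S T W Y V
AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The 20 standard amino acids
#'
#' One-letter codes of the 20 standard proteinogenic amino acids, in
#' alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
standard_residues <- function() sort(AAINDEX_ORDER)

#' Construct an AAindex entry
#'
#' An AAindex entry is one physicochemical property scale: an accession,
#' a free-text description, and one numeric value per standard residue.
#' Residues whose value is absent in the source database (the flat-file
#' "NA" token) are tracked in `missing_residues`.
#'
#' @param accession Character accession identifier (e.g. `"LEVM760107"`).
#' @param description Free-text property description.
#' @param values Named numeric vector over the 20 standard one-letter
#'   codes; `NA` marks a missing value.
#' @return An object of class `aaindex_entry`.
#' @export
aaindex_entry <- function(accession, description, values) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  if (!all(standard_residues() %in% names(values))) {
    stop("values must be named with all 20 standard residue codes")
  }
  values <- as.numeric(values[AAINDEX_ORDER])
  names(values) <- AAINDEX_ORDER
  structure(
    list(accession = accession,
         description = as.character(description),
         values = values,
         missing_residues = names(values)[is.na(values)]),
    class = "aaindex_entry"
  )
}

#' @export
print.aaindex_entry <- function(x, ...) {
  cat(sprintf("AAindex entry %s: %s\n", x$accession, x$description))
  print(x$values)
  if (length(x$missing_residues)) {
    cat("missing:", paste(x$missing_residues, collapse = " "), "\n")
  }
  invisible(x)
}

#' Parse an AAindex1 flat-format database
#'
#' Reads zero or more AAindex1 records. Each record starts with an
#' `H <accession>` line, carries a `D` description, and holds its 20
#' per-residue values on the two lines following the `I` header (10
#' values each, residue order A R N D C Q E G H I / L K M F P S T W Y V);
#' `NA` tokens mark residues without a value. Records end with `//`.
#' Blank lines between records and trailing whitespace are ignored.
#'
#' @param path Path to an AAindex1 flat file, or a character vector of
#'   lines via `text`.
#' @param text Optional character vector of raw lines (used instead of
#'   `path`).
#' @return List of [aaindex_entry()] objects, in file order.
#' @export
read_aaindex <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("AAindex file not found: ", path)
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("[ \t\r]+$", "", lines)

  entries <- list()
  seen <- character()
  acc <- NULL
  desc <- ""
  vals <- NULL
  in_values <- FALSE
  h_line <- NA_integer_

  flush_record <- function(line_no) {
    if (is.null(acc)) return(invisible(NULL))
    if (is.null(vals) || length(vals) != 20L) {
      stop(sprintf("AAindex record '%s' (near line %d): expected 20 values, got %d",
                   acc, line_no, length(vals)))
    }
    names(vals) <- AAINDEX_ORDER
    entries[[length(entries) + 1L]] <<- aaindex_entry(acc, desc, vals)
    invisible(NULL)
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    tag <- substr(ln, 1L, 1L)
    if (identical(substr(ln, 1L, 2L), "//")) {
      flush_record(i)
      acc <- NULL; desc <- ""; vals <- NULL; in_values <- FALSE
      next
    }
    if (tag == "H") {
      acc <- trimws(substr(ln, 2L, nchar(ln)))
      h_line <- i
      if (acc %in% seen) {
        stop(sprintf("duplicate accession '%s' at line %d", acc, i))
      }
      seen <- c(seen, acc)
      desc <- ""; vals <- NULL; in_values <- FALSE
      next
    }
    if (is.null(acc)) next  # preamble outside any record
    if (tag == "D") {
      d <- trimws(substr(ln, 2L, nchar(ln)))
      desc <- if (nzchar(desc)) paste(desc, d) else d
      next
    }
    if (tag == "I") { in_values <- TRUE; vals <- numeric(0); next }
    if (in_values && tag == " ") {
      toks <- strsplit(trimws(ln), "[ \t]+")[[1]]
      nums <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
      if (anyNA(nums[toks != "NA"])) {
        stop(sprintf("AAindex record '%s': non-numeric value token at line %d", acc, i))
      }
      vals <- c(vals, nums)
      if (length(vals) > 20L) {
        stop(sprintf("AAindex record '%s': more than 20 values by line %d", acc, i))
      }
      next
    }
    # other continuation tags (R, A, T, J, C, *) are ignored
    in_values <- FALSE
  }
  if (!is.null(acc)) flush_record(length(lines))
  entries
}

#' Write entries back to AAindex1 flat format
#'
#' Inverse of [read_aaindex()]: round-tripping a parsed database through
#' `write_aaindex()` and `read_aaindex()` reproduces accessions,
#' descriptions, values and missing-residue sets.
#'
#' @param entries List of [aaindex_entry()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(entries, path) {
  fmt <- function(v) {
    ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 7))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    v <- e$values[AAINDEX_ORDER]
    writeLines(c(
      paste("H", e$accession),
      paste("D", e$description),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("    ", paste(fmt(v[1:10]), collapse = "  ")),
      paste0("    ", paste(fmt(v[11:20]), collapse = "  ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' Keep only property scales with a value for every residue
#'
#' Entries with any missing residue are excluded (no imputation); the
#' remaining entries keep their input order.
#'
#' @param entries List of [aaindex_entry()] objects.
#' @return Filtered list.
#' @export
filter_complete <- function(entries) {
  Filter(function(e) length(e$missing_residues) == 0L, entries)
}

#' Flatten AAindex entries to a data frame
#'
#' @param entries List of [aaindex_entry()] objects.
#' @return Data frame with `accession`, `description` and one column per
#'   residue (alphabetical order).
#' @export
aaindex_to_df <- function(entries) {
  res <- standard_residues()
  df <- data.frame(
    accession = vapply(entries, `[[`, "", "accession"),
    description = vapply(entries, `[[`, "", "description"),
    stringsAsFactors = FALSE
  )
  for (r in res) df[[r]] <- vapply(entries, function(e) e$values[[r]], 0)
  df
}

#' Bundled synthetic property fixture
#'
#' Loads the property database shipped with the package. The accessions
#' and descriptions follow seven published AAindex scales commonly used
#' in peptide QSAR (van der Waals parameter, partial specific volume,
#' free energy of solution in water, negative charge, beta-sheet window
#' weight, unfolding Gibbs energy, reverse-turn propensity), but the
#' numeric values are synthetic stand-ins constructed to be qualitatively
#' realistic (e.g. aromatic residues large, Asp/Glu carrying the negative
#' charge, Gly/Pro turn-prone); they are not the curated database values.
#' One deliberately incomplete synthetic scale is included to exercise
#' missing-value handling.
#'
#' @param complete_only Drop entries with missing residues (default TRUE).
#' @return List of [aaindex_entry()] objects.
#' @export
aaindex_fixture <- function(complete_only = TRUE) {
  path <- system.file("extdata", "aaindex_synthetic.txt", package = "pepqsar")
  entries <- read_aaindex(path)
  if (complete_only) entries <- filter_complete(entries)
  entries
}
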
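# Reading, validating and writing GWAS summary statistics in delimited text.
#
# Canonical column set (the de-facto two-sample-MR exchange format):
#   snp, effect_allele, other_allele, eaf, beta, se, pval, n
# eaf and n are optional; a missing value is an empty field, never 0.

.CANONICAL_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                     "beta", "se", "pval", "n")
.REQUIRED_COLS <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
.VALID_ALLELES <- c("A", "C", "G", "T")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table of per-SNP association statistics,
#' maps arbitrary source headers onto the canonical column set, and validates
#' every row. Row order is preserved and duplicate variant IDs are rejected,
#' so the result can be used directly for instrument selection.
#'
#' @param path Path to a delimited text file with one header row. The
#'   delimiter (tab or comma) is sniffed from the header line.
#' @param column_map Named character vector mapping canonical field names to
#'   the file's headers, e.g. `c(snp = "rsid", beta = "Effect")`. Header
#'   matching is case-insensitive. Canonical fields not named in the map are
#'   looked up under their own (case-insensitive) names. Required fields:
#'   `snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`; optional:
#'   `eaf`, `n` (set to `NA` when absent from the file).
#'
#' @return A `data.frame` of class `"sumstats"` with the canonical columns,
#'   alleles uppercased, one row per variant in file order.
#'
#' @details Validation enforces, per row: alleles in A/C/G/T with
#'   `effect_allele != other_allele`; `se > 0`; `pval` in (0, 1];
#'   `eaf` in \[0, 1\] when present. Violations raise an error naming the
#'   offending row number.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_sumstats(example_sumstats(3), f)
#' ss <- read_sumstats(f)
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path)
  }
  header_line <- readLines(path, n = 1L)
  if (length(header_line) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), comment.char = "")
  headers_lc <- tolower(names(raw))

  locate <- function(field) {
    wanted <- if (!is.null(column_map) && field %in% names(column_map)) {
      column_map[[field]]
    } else {
      field
    }
    hit <- which(headers_lc == tolower(wanted))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }

  idx <- vapply(.CANONICAL_COLS, locate, integer(1))
  missing_req <- .REQUIRED_COLS[is.na(idx[.REQUIRED_COLS])]
  if (length(missing_req) > 0L) {
    stop("mapped column(s) not found in ", path, ": ",
         paste(missing_req, collapse = ", "))
  }

  out <- data.frame(
    snp = as.character(raw[[idx["snp"]]]),
    effect_allele = toupper(as.character(raw[[idx["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[idx["other_allele"]]])),
    eaf = if (is.na(idx["eaf"])) NA_real_ else as.numeric(raw[[idx["eaf"]]]),
    beta = as.numeric(raw[[idx["beta"]]]),
    se = as.numeric(raw[[idx["se"]]]),
    pval = as.numeric(raw[[idx["pval"]]]),
    n = if (is.na(idx["n"])) NA_real_ else as.numeric(raw[[idx["n"]]]),
    stringsAsFactors = FALSE
  )
  validate_sumstats(out, context = path)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Validate a summary-statistics table
#'
#' Checks the per-row invariants of the canonical summary-statistics format
#' and the table-level uniqueness of variant IDs. Called by [read_sumstats()];
#' exported so that programmatically built tables can be checked too.
#'
#' @param x A data.frame with the canonical columns.
#' @param context Label used in error messages (e.g. the file path).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_sumstats <- function(x, context = "sumstats") {
  stopifnot(is.data.frame(x))
  miss <- setdiff(.REQUIRED_COLS, names(x))
  if (length(miss) > 0L) {
    stop(context, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) {
      stop(context, ": ", what, " at row ", i[1L],
           " (snp ", x$snp[i[1L]], ")", call. = FALSE)
    }
  }
  bad_row(is.na(x$snp) | x$snp == "", "missing variant ID")
  bad_row(!(x$effect_allele %in% .VALID_ALLELES), "invalid effect allele")
  bad_row(!(x$other_allele %in% .VALID_ALLELES), "invalid other allele")
  bad_row(x$effect_allele == x$other_allele, "effect and other allele identical")
  bad_row(is.na(x$beta), "missing beta")
  bad_row(is.na(x$se) | x$se <= 0, "standard error not > 0")
  bad_row(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "p-value outside (0, 1]")
  if ("eaf" %in% names(x)) {
    bad_row(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf outside [0, 1]")
  }
  dup <- duplicated(x$snp)
  if (any(dup)) {
    stop(context, ": duplicated variant ID(s): ",
         paste(unique(x$snp[dup]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Write a table in the canonical tab-delimited dialect
#'
#' Writes any tabular result (summary statistics, instrument sets, report
#' tables) as tab-delimited text with one header row. Missing values are
#' written as empty fields. Numeric columns keep full double precision, so
#' a write/read round trip reproduces values to better than 1e-12 relative.
#'
#' @param records A non-empty data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    stop("refusing to write an empty table to ", path)
  }
  out <- as.data.frame(records)
  num <- vapply(out, is.numeric, logical(1))
  # as.character on doubles keeps 15 significant digits
  out[num] <- lapply(out[num], function(v) {
    s <- vapply(v, function(x) {
      if (is.na(x)) NA_character_ else format(x, digits = 15, scientific = NA)
    }, character(1))
    s
  })
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("could not write table to ", path, ": ", conditionMessage(ok))
  }
  invisible(path)
}

#' @rdname write_sumstats
#' @export
write_table <- write_sumstats

#' Study metadata for one GWAS
#'
#' A small record describing the provenance of one trait's summary
#' statistics: trait name (units are carried opaquely in the name),
#' consortium, ancestry and sample sizes.
#'
#' @param trait_name,consortium,ancestry Free-text descriptors.
#' @param n_total Total sample size.
#' @param n_cases,n_controls Optional case/control split for binary traits;
#'   when both are given they must sum to `n_total`.
#' @return A list of class `"study_meta"`.
#' @export
study_meta <- function(trait_name, consortium = NA_character_,
                       ancestry = NA_character_, n_total = NA_real_,
                       n_cases = NA_real_, n_controls = NA_real_) {
  if (!is.na(n_cases) && !is.na(n_controls) && !is.na(n_total) &&
      n_cases + n_controls != n_total) {
    stop("n_cases + n_controls must equal n_total")
  }
  structure(list(trait_name = trait_name, consortium = consortium,
                 ancestry = ancestry, n_total = n_total,
                 n_cases = n_cases, n_controls = n_controls),
            class = "study_meta")
}

#' Small example summary-statistics table
#'
#' Deterministic toy table used in examples and tests.
#'
#' @param n Number of rows.
#' @return A validated `sumstats` data.frame.
#' @export
example_sumstats <- function(n = 5) {
  stopifnot(n >= 1)
  x <- data.frame(
    snp = sprintf("rs%04d", seq_len(n)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C"), length.out = n),
    eaf = round(seq(0.1, 0.45, length.out = n), 4),
    beta = round(seq(-0.05, 0.08, length.out = n), 6),
    se = rep(0.01, n),
    pval = round(seq(1e-10, 0.5, length.out = n), 12),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
  validate_sumstats(x, "example_sumstats")
  class(x) <- c("sumstats", "data.frame")
  x
}
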
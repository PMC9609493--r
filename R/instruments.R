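# Instrument selection and allele harmonization.
#
# Selection applies the usual genome-wide pipeline: p-value threshold,
# MAF filter, user-supplied confounder exclusion list, then greedy
# p-value-ranked LD clumping against an optional user-supplied r^2 matrix.
# Harmonization aligns outcome effects to the exposure's effect allele,
# handling label swaps, strand complements and palindromic variants.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .COMPLEMENT[ea] == oa

#' Select genetic instruments from exposure summary statistics
#'
#' Applies, in order: the association p-value threshold, the minor-allele
#' frequency filter (variants with missing frequency are kept but flagged),
#' the user-supplied exclusion list (standing in for a confounder lookup
#' such as PhenoScanner / GWAS-catalog screening), and greedy
#' p-value-ranked clumping. Clumping sorts survivors by ascending p-value
#' (variant ID as tiebreak) and accepts each variant unless it has
#' `r^2 >= r2_limit` with an already-accepted variant that lies within
#' `window_kb` of it; with no LD matrix all survivors are treated as
#' independent, and with no position table the window constraint is vacuous.
#'
#' @param exposure Exposure summary statistics (canonical columns).
#' @param p_threshold Genome-wide significance threshold; default `5e-8`.
#' @param ld Optional symmetric r^2 matrix with variant IDs as dimnames.
#'   Variants absent from the matrix are treated as independent.
#' @param positions Optional data.frame with columns `snp`, `chr`, `pos`
#'   (base pairs) used for the clumping window.
#' @param window_kb Clumping window in kilobases; default 10,000.
#' @param r2_limit Clumping r^2 limit; default 0.001.
#' @param maf_min Minimum minor allele frequency, `min(eaf, 1-eaf) > maf_min`;
#'   default 0.01.
#' @param exclude Character vector of variant IDs to remove (confounder
#'   exclusion list).
#' @return An `instrument_set` data.frame (exposure side only) with columns
#'   `snp`, `effect_allele`, `other_allele`, `eaf`, `beta_exposure`,
#'   `se_exposure`, `pval_exposure`, `maf_missing`; attributes `counts`
#'   (per-step removal ledger) and `params`.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8,
                               ld = NULL, positions = NULL,
                               window_kb = 10000, r2_limit = 0.001,
                               maf_min = 0.01, exclude = character(0)) {
  stopifnot(is.data.frame(exposure), nrow(exposure) > 0)
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must lie strictly inside (0, 1)")
  }
  counts <- c(candidates = nrow(exposure))

  keep_p <- exposure$pval < p_threshold
  counts["below_threshold"] <- sum(!keep_p)
  x <- exposure[keep_p, , drop = FALSE]

  maf <- pmin(x$eaf, 1 - x$eaf)
  maf_missing <- is.na(maf)
  keep_maf <- maf_missing | maf > maf_min
  counts["maf_filtered"] <- sum(!keep_maf)
  x <- x[keep_maf, , drop = FALSE]
  maf_missing <- maf_missing[keep_maf]

  keep_ex <- !(x$snp %in% exclude)
  counts["excluded"] <- sum(!keep_ex)
  x <- x[keep_ex, , drop = FALSE]
  maf_missing <- maf_missing[keep_ex]

  # greedy clumping
  ord <- order(x$pval, x$snp)
  x <- x[ord, , drop = FALSE]
  maf_missing <- maf_missing[ord]
  if (!is.null(ld) && nrow(x) > 1) {
    pos <- NULL
    if (!is.null(positions)) {
      pos <- positions[match(x$snp, positions$snp), , drop = FALSE]
    }
    accepted <- logical(nrow(x))
    for (i in seq_len(nrow(x))) {
      acc <- which(accepted)
      conflict <- FALSE
      for (j in acc) {
        si <- x$snp[i]; sj <- x$snp[j]
        if (!(si %in% rownames(ld)) || !(sj %in% colnames(ld))) next
        within_window <- TRUE
        if (!is.null(pos) && !is.na(pos$pos[i]) && !is.na(pos$pos[j])) {
          within_window <- identical(pos$chr[i], pos$chr[j]) &&
            abs(pos$pos[i] - pos$pos[j]) <= window_kb * 1000
        }
        if (within_window && ld[si, sj] >= r2_limit) { conflict <- TRUE; break }
      }
      accepted[i] <- !conflict
    }
    counts["pruned"] <- sum(!accepted)
    x <- x[accepted, , drop = FALSE]
    maf_missing <- maf_missing[accepted]
  } else {
    counts["pruned"] <- 0
  }
  counts["retained"] <- nrow(x)

  out <- data.frame(
    snp = x$snp, effect_allele = x$effect_allele,
    other_allele = x$other_allele, eaf = x$eaf,
    beta_exposure = x$beta, se_exposure = x$se, pval_exposure = x$pval,
    maf_missing = maf_missing, stringsAsFactors = FALSE
  )
  structure(out,
            counts = counts,
            params = list(p_threshold = p_threshold, window_kb = window_kb,
                          r2_limit = r2_limit, maf_min = maf_min,
                          n_excluded_listed = length(exclude)),
            class = c("instrument_set", "data.frame"))
}

# Align one outcome record's alleles to a reference orientation.
# Returns list(status, flip, relabelled, palindromic):
#   status "ok" | "irreconcilable" | "ambiguous_palindromic"
.align_alleles <- function(ref_ea, ref_oa, ea, oa, eaf_ref, eaf_other,
                           band = c(0.42, 0.58), drop_ambiguous = TRUE) {
  pal <- .is_palindromic(ref_ea, ref_oa)
  if (pal) {
    # allele labels cannot distinguish strand; require the same pair
    same_pair <- (ea == ref_ea && oa == ref_oa)
    swapped_pair <- (ea == ref_oa && oa == ref_ea)
    if (!same_pair && !swapped_pair) {
      return(list(status = "irreconcilable", flip = FALSE, palindromic = TRUE))
    }
    flip <- swapped_pair
    inferable <- !is.na(eaf_ref) && !is.na(eaf_other) &&
      (eaf_ref < band[1] || eaf_ref > band[2]) &&
      {
        eo <- if (flip) 1 - eaf_other else eaf_other
        eo < band[1] || eo > band[2]
      }
    if (!inferable) {
      if (drop_ambiguous) {
        return(list(status = "ambiguous_palindromic", flip = FALSE,
                    palindromic = TRUE))
      }
      return(list(status = "ok", flip = flip, palindromic = TRUE,
                  unresolved = TRUE))
    }
    eo <- if (flip) 1 - eaf_other else eaf_other
    if ((eaf_ref - 0.5) * (eo - 0.5) < 0) flip <- !flip
    return(list(status = "ok", flip = flip, palindromic = TRUE,
                unresolved = FALSE))
  }
  if (ea == ref_ea && oa == ref_oa) {
    return(list(status = "ok", flip = FALSE, palindromic = FALSE))
  }
  if (ea == ref_oa && oa == ref_ea) {
    return(list(status = "ok", flip = TRUE, palindromic = FALSE))
  }
  cea <- unname(.COMPLEMENT[ea]); coa <- unname(.COMPLEMENT[oa])
  if (cea == ref_ea && coa == ref_oa) {
    return(list(status = "ok", flip = FALSE, palindromic = FALSE))
  }
  if (cea == ref_oa && coa == ref_ea) {
    return(list(status = "ok", flip = TRUE, palindromic = FALSE))
  }
  list(status = "irreconcilable", flip = FALSE, palindromic = FALSE)
}

#' Harmonize outcome effects onto an exposure-side instrument set
#'
#' Looks up each instrument in the outcome summary statistics and aligns
#' the outcome effect to the exposure's effect allele. Variants missing
#' from the outcome are dropped and counted. When the outcome lists the
#' alleles in the opposite order the outcome beta is sign-flipped and its
#' frequency complemented; when they match only under strand complement the
#' labels are complemented first. Palindromic (A/T or C/G) variants are
#' oriented by allele frequency when both frequencies fall outside
#' `palindrome_eaf_band`; otherwise they are dropped (default) or kept
#' as-is with an `unresolved` flag.
#'
#' @param exposure_side An `instrument_set` from [select_instruments()].
#' @param outcome Outcome summary statistics (canonical columns).
#' @param palindrome_eaf_band Frequency band within which a palindromic
#'   variant's orientation is considered ambiguous; default `c(0.42, 0.58)`
#'   (inclusive).
#' @param drop_palindromic_ambiguous Drop ambiguous palindromic variants
#'   (default `TRUE`) instead of keeping them flagged.
#' @return A harmonized `instrument_set` data.frame with columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta_exposure`, `se_exposure`,
#'   `pval_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`,
#'   `palindromic`, `flipped`; the `counts` attribute extends the selection
#'   ledger with `missing_in_outcome`, `irreconcilable`,
#'   `ambiguous_palindromic` and the final `harmonized` count.
#' @export
harmonize <- function(exposure_side, outcome,
                      palindrome_eaf_band = c(0.42, 0.58),
                      drop_palindromic_ambiguous = TRUE) {
  stopifnot(is.data.frame(exposure_side), is.data.frame(outcome))
  counts <- attr(exposure_side, "counts")
  if (is.null(counts)) counts <- c(candidates = nrow(exposure_side))

  m <- match(exposure_side$snp, outcome$snp)
  present <- !is.na(m)
  counts["missing_in_outcome"] <- sum(!present)
  x <- exposure_side[present, , drop = FALSE]
  o <- outcome[m[present], , drop = FALSE]

  n <- nrow(x)
  status <- character(n); flip <- logical(n); pal <- logical(n)
  unresolved <- logical(n)
  for (i in seq_len(n)) {
    al <- .align_alleles(x$effect_allele[i], x$other_allele[i],
                         o$effect_allele[i], o$other_allele[i],
                         x$eaf[i], o$eaf[i],
                         band = palindrome_eaf_band,
                         drop_ambiguous = drop_palindromic_ambiguous)
    status[i] <- al$status
    flip[i] <- al$flip
    pal[i] <- al$palindromic
    unresolved[i] <- isTRUE(al$unresolved)
  }
  counts["irreconcilable"] <- sum(status == "irreconcilable")
  counts["ambiguous_palindromic"] <- sum(status == "ambiguous_palindromic")
  keep <- status == "ok"

  x <- x[keep, , drop = FALSE]; o <- o[keep, , drop = FALSE]
  flip <- flip[keep]; pal <- pal[keep]; unresolved <- unresolved[keep]

  beta_outcome <- ifelse(flip, -o$beta, o$beta)
  eaf_outcome <- ifelse(flip, 1 - o$eaf, o$eaf)

  out <- data.frame(
    snp = x$snp, effect_allele = x$effect_allele,
    other_allele = x$other_allele, eaf = x$eaf,
    beta_exposure = x$beta_exposure, se_exposure = x$se_exposure,
    pval_exposure = x$pval_exposure,
    beta_outcome = beta_outcome, se_outcome = o$se,
    eaf_outcome = eaf_outcome,
    palindromic = pal, flipped = flip, unresolved_palindrome = unresolved,
    stringsAsFactors = FALSE
  )
  counts["harmonized"] <- nrow(out)
  structure(out, counts = counts, params = attr(exposure_side, "params"),
            harmonized = TRUE, class = c("instrument_set", "data.frame"))
}

#' Read a one-ID-per-line variant exclusion list
#'
#' @param path Text file with one variant ID per line; blank lines and
#'   lines starting with `#` are ignored.
#' @return Character vector of variant IDs.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @export
print.instrument_set <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("Instrument set:", nrow(x), "variants",
      if (isTRUE(attr(x, "harmonized"))) "(harmonized)\n" else "(exposure side)\n")
  if (!is.null(counts)) {
    cat("  ", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
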
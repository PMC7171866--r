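#' Thresholds for the five-way process classification
#'
#' Defaults follow the standard null-model framework: `|bNTI| > 2` flags
#' selection, `|RC| > 0.95` splits the non-selected pairs into dispersal
#' classes, with 999 beta-NTI and 9999 Raup-Crick randomizations.
#'
#' @param bnti_cut Selection threshold on `|bNTI|` (> 0).
#' @param rc_cut Dispersal threshold on `|RC|` (> 0).
#' @param n_null_bnti,n_null_rc Randomization counts (>= 1).
#' @return A list of class `process_thresholds`.
#' @export
process_thresholds <- function(bnti_cut = 2, rc_cut = 0.95,
                               n_null_bnti = 999, n_null_rc = 9999) {
  if (bnti_cut <= 0 || rc_cut <= 0) stop_ea("cuts must be > 0")
  if (n_null_bnti < 1 || n_null_rc < 1) stop_ea("n_null must be >= 1")
  structure(list(bnti_cut = bnti_cut, rc_cut = rc_cut,
                 n_null_bnti = as.integer(n_null_bnti),
                 n_null_rc = as.integer(n_null_rc)),
            class = "process_thresholds")
}

process_levels <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Classify community pairs into assembly processes
#'
#' Two-step rule per unordered pair: `bNTI > +cut` -> heterogeneous
#' selection; `bNTI < -cut` -> homogeneous selection; otherwise
#' `RC > +rc_cut` -> dispersal limitation, `RC < -rc_cut` -> homogenizing
#' dispersal, else drift. Pairs with undefined bNTI (zero null sd) get an
#' `NA` label and are excluded from the summary fractions.
#'
#' @param bnti A `bnti_result` from [bnti()] (or a square bNTI matrix).
#' @param rc A square RC matrix from [raup_crick_bray()].
#' @param thresholds A [process_thresholds()].
#' @return A tibble of class `process_calls`, one row per unordered pair:
#'   `sample_1`, `sample_2`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`,
#'   `bray_curtis`, `rc_bray`, `process`. Use [process_summary()] or
#'   [generics::glance()] for the per-process fractions.
#' @export
classify_processes <- function(bnti, rc, thresholds = process_thresholds()) {
  if (inherits(bnti, "bnti_result")) {
    comp <- bnti
    z <- comp$bnti
  } else {
    z <- as.matrix(bnti)
    comp <- NULL
  }
  rc <- as.matrix(rc)
  if (!identical(rownames(z), rownames(rc)))
    stop_ea("bnti and rc must cover the same samples in the same order")
  labs <- rownames(z)
  n <- length(labs)
  ii <- which(lower.tri(z), arr.ind = TRUE)
  zv <- z[ii]; rcv <- rc[ii]
  proc <- ifelse(is.na(zv), NA_character_,
          ifelse(zv > thresholds$bnti_cut, "heterogeneous_selection",
          ifelse(zv < -thresholds$bnti_cut, "homogeneous_selection",
          ifelse(rcv > thresholds$rc_cut, "dispersal_limitation",
          ifelse(rcv < -thresholds$rc_cut, "homogenizing_dispersal", "drift")))))
  out <- tibble::tibble(
    sample_1 = labs[ii[, 2]],
    sample_2 = labs[ii[, 1]],
    bmntd_obs = if (!is.null(comp)) comp$bmntd_obs[ii] else NA_real_,
    null_mean = if (!is.null(comp)) comp$null_mean[ii] else NA_real_,
    null_sd = if (!is.null(comp)) comp$null_sd[ii] else NA_real_,
    bnti = zv,
    rc_bray = rcv,
    process = factor(proc, levels = process_levels)
  )
  attr(out, "thresholds") <- thresholds
  class(out) <- c("process_calls", class(out))
  out
}

#' Summarize process calls into per-process fractions
#'
#' @param calls A `process_calls` tibble from [classify_processes()].
#' @return A tibble of class `process_summary`: `process`, `n_pairs`,
#'   `fraction` (of classified pairs; fractions sum to 1). Pairs with `NA`
#'   bNTI are reported in the `n_unclassified` attribute.
#' @export
process_summary <- function(calls) {
  if (!inherits(calls, "process_calls")) stop_ea("calls must come from classify_processes()")
  ok <- !is.na(calls$process)
  counts <- table(calls$process[ok])
  out <- tibble::tibble(
    process = factor(names(counts), levels = process_levels),
    n_pairs = as.integer(counts),
    fraction = if (sum(counts) > 0) as.numeric(counts) / sum(counts) else rep(NA_real_, length(counts))
  )
  attr(out, "n_unclassified") <- sum(!ok)
  class(out) <- c("process_summary", class(out))
  out
}

#' Quantify assembly processes end to end
#'
#' Convenience wrapper running [bnti()], [raup_crick_bray()] and
#' [classify_processes()] on one table + tree, with seeds derived from one
#' master seed.
#'
#' @param x Samples x taxa count matrix (rarefied counts recommended).
#' @param tree Rooted [ape::phylo] covering the table's taxa.
#' @param thresholds A [process_thresholds()]; also carries the
#'   randomization counts.
#' @param seed Master seed.
#' @param pool Optional metacommunity reference table for the RC null.
#' @return A list of class `assembly_quantification`: `calls`
#'   (`process_calls` tibble), `summary` (`process_summary` tibble),
#'   `bnti` (`bnti_result`), `rc` (matrix).
#' @export
quantify_assembly_processes <- function(x, tree, thresholds = process_thresholds(),
                                        seed = 1, pool = NULL) {
  bn <- bnti(x, tree, n_null = thresholds$n_null_bnti,
             seed = child_seed(seed, 11L))
  rc <- raup_crick_bray(x, n_null = thresholds$n_null_rc,
                        seed = child_seed(seed, 12L), pool = pool)
  calls <- classify_processes(bn, rc, thresholds)
  structure(list(calls = calls, summary = process_summary(calls),
                 bnti = bn, rc = rc),
            class = "assembly_quantification")
}

#' @export
print.assembly_quantification <- function(x, ...) {
  cat("Assembly-process quantification\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-24s %4d pairs  %5.1f%%\n", as.character(s$process[i]),
                s$n_pairs[i], 100 * s$fraction[i]))
  }
  invisible(x)
}
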
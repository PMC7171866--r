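#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a beta-NTI result into a per-pair tibble
#'
#' @param x A `bnti_result` from [bnti()].
#' @param ... Unused.
#' @return Tibble with one row per unordered pair: `sample_1`, `sample_2`,
#'   `bmntd_obs`, `null_mean`, `null_sd`, `bnti`.
#' @export
tidy.bnti_result <- function(x, ...) {
  labs <- rownames(x$bnti)
  ii <- which(lower.tri(x$bnti), arr.ind = TRUE)
  tibble::tibble(
    sample_1 = labs[ii[, 2]], sample_2 = labs[ii[, 1]],
    bmntd_obs = x$bmntd_obs[ii], null_mean = x$null_mean[ii],
    null_sd = x$null_sd[ii], bnti = x$bnti[ii]
  )
}

#' One-row summary of a beta-NTI result
#'
#' @param x A `bnti_result`.
#' @param ... Unused.
#' @return Tibble: `n_pairs`, `n_null`, `frac_selection` (|bNTI| > 2),
#'   `frac_heterogeneous`, `frac_homogeneous`, `n_na`.
#' @export
glance.bnti_result <- function(x, ...) {
  v <- lower_vec(x$bnti)
  tibble::tibble(
    n_pairs = length(v), n_null = x$n_null,
    frac_selection = mean(abs(v) > 2, na.rm = TRUE),
    frac_heterogeneous = mean(v > 2, na.rm = TRUE),
    frac_homogeneous = mean(v < -2, na.rm = TRUE),
    n_na = sum(is.na(v))
  )
}

#' Per-process fractions of an assembly quantification
#'
#' @param x An `assembly_quantification` from
#'   [quantify_assembly_processes()].
#' @param ... Unused.
#' @return The `process_calls` tibble (`tidy`) or a one-row tibble of the
#'   five process fractions plus `n_pairs` (`glance`).
#' @export
tidy.assembly_quantification <- function(x, ...) x$calls

#' @rdname tidy.assembly_quantification
#' @export
glance.assembly_quantification <- function(x, ...) {
  s <- x$summary
  out <- tibble::as_tibble(as.list(stats::setNames(s$fraction, as.character(s$process))))
  out$n_pairs <- sum(s$n_pairs)
  out
}

#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_perm = x$n_perm)
}
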
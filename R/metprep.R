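#' Rank-based inverse normal transformation
#'
#' Maps a metabolite vector onto standard-normal quantiles of its ranks,
#' the standardization applied to every metabolite before association
#' analysis. Non-missing value `x_i` with (average, for ties) rank `r_i`
#' among `n` non-missing values becomes
#' `qnorm((r_i - c) / (n - 2c + 1))` with Blom offset `c = 3/8`.
#' Missing entries are preserved.
#'
#' The transform is monotone in the ranks and invariant to positive affine
#' rescaling of the input, so platform units never reach the models; all
#' downstream effect sizes are in SD units of the transformed trait.
#'
#' @param x numeric vector, possibly with `NA`.
#' @param offset rank offset `c`; default `3/8` (Blom), the prevailing
#'   convention in genetic-epidemiology pipelines.
#' @return numeric vector of the same length, `NA` where `x` is `NA`.
#' @examples
#' rank_inverse_normal(c(3, 1, 2))
#' @export
rank_inverse_normal <- function(x, offset = 3 / 8) {
  stopifnot(is.numeric(x))
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2L)
    stop("need at least 2 non-missing values")
  if (length(unique(v)) < 2L)
    stop("all non-missing values identical: transformation undefined")
  n <- length(v)
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Transform metabolite columns within each timepoint
#'
#' Applies [rank_inverse_normal()] to each named metabolite column of a long
#' phenotype table, separately within each level of `by` (never pooled
#' across ages, since each timepoint is analysed separately).
#'
#' @param pheno data.frame with a timepoint column and metabolite columns.
#' @param metabolites character vector of column names to transform.
#' @param by name of the stratifying column (default `"timepoint"`).
#' @param offset passed to [rank_inverse_normal()].
#' @return `pheno` with the named columns transformed; attribute
#'   `"int_manifest"` records which metabolite was transformed in which
#'   stratum and at what `n`.
#' @export
transform_metabolites <- function(pheno, metabolites, by = "timepoint",
                                  offset = 3 / 8) {
  stopifnot(is.data.frame(pheno), by %in% names(pheno),
            all(metabolites %in% names(pheno)))
  manifest <- list()
  for (lev in unique(pheno[[by]])) {
    idx <- which(pheno[[by]] == lev)
    for (m in metabolites) {
      pheno[[m]][idx] <- rank_inverse_normal(pheno[[m]][idx], offset = offset)
      manifest[[length(manifest) + 1L]] <- data.frame(
        stratum = as.character(lev), metabolite = m,
        n = sum(!is.na(pheno[[m]][idx])), stringsAsFactors = FALSE)
    }
  }
  attr(pheno, "int_manifest") <- do.call(rbind, manifest)
  pheno
}
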
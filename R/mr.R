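# Two-sample MR estimator suite, written from first principles.
#
# All estimators consume a harmonized pair of per-SNP effects:
# gamma_j (SNP -> AD, log odds) with se sigma_gamma_j, and
# Gamma_j (SNP -> metabolite, SD units) with se sigma_Gamma_j,
# both coded for the same effect allele. The causal estimand is the
# metabolite change in SD units per log-odds unit of AD liability;
# scale_to_doubling() converts to the per-doubling-of-liability scale.

#' Construct a harmonized exposure-outcome pair
#'
#' @param beta_exposure,se_exposure per-SNP SNP-exposure effects and SEs
#'   (log odds of AD per effect allele).
#' @param beta_outcome,se_outcome per-SNP SNP-outcome effects and SEs
#'   (SD units of the metabolite per effect allele), same effect allele.
#' @param snp optional SNP ids (must be unique).
#' @return a `harmonized_pair` data.frame.
#' @export
harmonized_pair <- function(beta_exposure, se_exposure, beta_outcome,
                            se_outcome, snp = NULL) {
  J <- length(beta_exposure)
  stopifnot(J >= 1,
            length(se_exposure) == J, length(beta_outcome) == J,
            length(se_outcome) == J,
            all(se_exposure > 0), all(se_outcome > 0))
  snp <- snp %||% paste0("snp", seq_len(J))
  if (anyDuplicated(snp)) stop("duplicate SNP ids")
  structure(data.frame(snp = snp, beta_exposure = beta_exposure,
                       se_exposure = se_exposure,
                       beta_outcome = beta_outcome,
                       se_outcome = se_outcome, stringsAsFactors = FALSE),
            class = c("harmonized_pair", "data.frame"))
}

#' Build a harmonized pair from an instrument and outcome summary stats
#'
#' Runs [harmonize()] and pairs the instrument's weights (the SNP-exposure
#' side) with the harmonized outcome betas.
#'
#' @param instrument an [instrument_table()].
#' @param outcome outcome summary statistics.
#' @param ... passed to [harmonize()].
#' @return a `harmonized_pair`.
#' @export
make_pair <- function(instrument, outcome, ...) {
  h <- harmonize(instrument, outcome, ...)
  m <- match(h$snp, instrument$snp)
  harmonized_pair(instrument$beta[m], instrument$se[m], h$beta, h$se,
                  snp = h$snp)
}

mr_result <- function(method, beta, se, J, q = NA_real_, q_df = NA_integer_,
                      n_boot = NA_integer_, scaled_by_ln2 = FALSE) {
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
             p = 2 * pnorm(-abs(beta / se)),
             J = J, q = q, q_df = q_df, n_boot = n_boot,
             scaled_by_ln2 = scaled_by_ln2, stringsAsFactors = FALSE)
}

#' Wald ratio estimator (single SNP)
#'
#' `beta = Gamma / gamma`, SE by the first-order delta method
#' `sigma_Gamma / |gamma|`, or second-order
#' `sqrt(sigma_Gamma^2 / gamma^2 + Gamma^2 sigma_gamma^2 / gamma^4)`.
#'
#' @param pair a [harmonized_pair()] with exactly one SNP.
#' @param second_order use the second-order delta-method SE.
#' @return one-row MR result data.frame.
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  stopifnot(nrow(pair) == 1L)
  g <- pair$beta_exposure; G <- pair$beta_outcome
  if (g == 0) stop("Wald ratio undefined: SNP-exposure effect is zero")
  beta <- G / g
  se <- if (second_order)
    sqrt(pair$se_outcome^2 / g^2 + G^2 * pair$se_exposure^2 / g^4)
  else pair$se_outcome / abs(g)
  mr_result("wald", beta, se, J = 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights `1 / sigma_Gamma^2`; equivalently the inverse-variance
#' meta-analysis of the per-SNP Wald ratios. The default multiplicative
#' random-effects model inflates the fixed-effect SE by
#' `max(1, sqrt(Q / (J - 1)))`, where `Q` is Cochran's heterogeneity
#' statistic about the fitted slope.
#'
#' @param pair a [harmonized_pair()] with `J >= 2` (a single SNP falls back
#'   to [wald_ratio()] with a warning).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return one-row MR result with `q` and `q_df`.
#' @export
mr_ivw <- function(pair, effects_model = c("multiplicative_random",
                                           "fixed")) {
  effects_model <- match.arg(effects_model)
  J <- nrow(pair)
  if (J < 2L) {
    warning("IVW needs at least 2 SNPs; falling back to Wald ratio")
    return(wald_ratio(pair))
  }
  w <- 1 / pair$se_outcome^2
  bx <- pair$beta_exposure; by <- pair$beta_outcome
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  df <- J - 1L
  se <- if (effects_model == "multiplicative_random")
    se_fixed * max(1, sqrt(q / df)) else se_fixed
  mr_result("ivw", beta, se, J, q = q, q_df = df)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects *with* an intercept,
#' weights `1 / sigma_Gamma^2`, after orienting every SNP so its exposure
#' effect is positive (flipping the sign of both members of a pair leaves
#' the model invariant). The intercept estimates the average directional
#' pleiotropic effect; the slope is the pleiotropy-adjusted causal effect,
#' consistent under the InSIDE assumption. SEs are inflated by
#' `max(1, sqrt(RSS_w / (J - 2)))`.
#'
#' @param pair a [harmonized_pair()] with `J >= 3`.
#' @return two-row MR result: methods `egger_slope` and `egger_intercept`.
#' @export
mr_egger <- function(pair) {
  J <- nrow(pair)
  if (J < 3L) stop("MR-Egger needs at least 3 SNPs")
  s <- sign(pair$beta_exposure); s[s == 0] <- 1
  x <- pair$beta_exposure * s
  y <- pair$beta_outcome * s
  w <- 1 / pair$se_outcome^2
  if (var(x) == 0) stop("all exposure effects identical: Egger unidentifiable")
  # weighted normal equations for y ~ a + b x
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  b <- (sw * swxy - swx * swy) / det
  a <- (swy * swxx - swx * swxy) / det
  res <- y - a - b * x
  sigma2 <- sum(w * res^2) / (J - 2L)
  infl <- max(1, sqrt(sigma2))
  se_b <- sqrt(sw / det) * infl
  se_a <- sqrt(swxx / det) * infl
  rbind(mr_result("egger_slope", b, se_b, J,
                  q = sum(w * res^2), q_df = J - 2L),
        mr_result("egger_intercept", a, se_a, J))
}

# Interpolated weighted quantile over cumulative-midpoint positions
# p_k = sum_{i<=k} w'_i - w'_k / 2 (weights normalized to 1).
.weighted_quantile <- function(b, w, probs) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  vapply(probs, function(q) {
    if (q <= p[1L]) b[1L]
    else if (q >= p[length(p)]) b[length(b)]
    else approx(p, b, xout = q, ties = "ordered")$y
  }, numeric(1))
}

.weighted_median_point <- function(ratios, weights) {
  .weighted_quantile(ratios, weights, 0.5)
}

.weighted_mode_point <- function(ratios, weights, phi = 1, grid_n = 512) {
  w <- weights / sum(weights)
  if (length(unique(ratios)) == 1L) return(ratios[1L])
  mu <- sum(w * ratios)
  sd_w <- sqrt(sum(w * (ratios - mu)^2))
  qs <- .weighted_quantile(ratios, w, c(0.25, 0.75))
  iqr_w <- qs[2L] - qs[1L]
  s <- min(sd_w, iqr_w / 1.349)
  if (s <= 0) s <- sd_w
  h <- phi * 0.9 * s * length(ratios)^(-1 / 5)
  if (h <= 0) return(ratios[which.max(w)])
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = grid_n)
  dens <- colSums(w * dnorm(outer(ratios, grid, "-") / h)) / h
  i <- which.max(dens)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  if (lo == hi) return(grid[i])
  optimize(function(x) sum(w * dnorm((x - ratios) / h)),
           c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

# Parametric bootstrap SE for ratio-based estimators: resample each SNP's
# effects from Normal(beta, se^2) in both samples, recompute ratios and
# first-order inverse-variance weights, and take the SD of the estimates.
.boot_se <- function(pair, point_fun, n_boot, seed) {
  if (is.na(n_boot) || n_boot <= 0L) return(NA_real_)
  J <- nrow(pair)
  with_local_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(J, pair$beta_exposure, pair$se_exposure)
      by <- rnorm(J, pair$beta_outcome, pair$se_outcome)
      point_fun(by / bx, bx^2 / pair$se_outcome^2)
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios and takes the value at cumulative weight
#' 0.5 (normalized inverse-variance weights, cumulative-midpoint linear
#' interpolation). Consistent when at least half the total weight comes
#' from valid instruments. SE by parametric bootstrap: both betas of every
#' SNP are resampled from their sampling distributions, the estimator
#' recomputed, and the SD over replicates reported.
#'
#' @param pair a [harmonized_pair()] with `J >= 3`.
#' @param n_boot bootstrap replicates (default 1000; 0 skips the SE).
#' @param seed seed for the bootstrap.
#' @return one-row MR result.
#' @export
mr_weighted_median <- function(pair, n_boot = 1000, seed = NULL) {
  if (nrow(pair) < 3L) stop("weighted median needs at least 3 SNPs")
  ratios <- pair$beta_outcome / pair$beta_exposure
  weights <- pair$beta_exposure^2 / pair$se_outcome^2  # 1 / var(Wald ratio)
  beta <- .weighted_median_point(ratios, weights)
  se <- .boot_se(pair, .weighted_median_point, n_boot, seed)
  mr_result("weighted_median", beta, se, nrow(pair), n_boot = n_boot)
}

#' Weighted mode estimator
#'
#' The mode of the weighted kernel density of the per-SNP Wald ratios
#' (Gaussian kernel, modified-Silverman bandwidth
#' `h = phi * 0.9 * min(SD_w, IQR_w / 1.349) * J^(-1/5)` on the weighted
#' ratios; 512-point grid with local refinement of the argmax). Consistent
#' when the largest homogeneous cluster of SNPs is valid. SE by the same
#' parametric bootstrap as [mr_weighted_median()].
#'
#' @param pair a [harmonized_pair()] with `J >= 3`.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000; 0 skips the SE).
#' @param seed seed for the bootstrap.
#' @param grid_n KDE grid size.
#' @return one-row MR result.
#' @export
mr_weighted_mode <- function(pair, phi = 1, n_boot = 1000, seed = NULL,
                             grid_n = 512) {
  if (nrow(pair) < 3L) stop("weighted mode needs at least 3 SNPs")
  ratios <- pair$beta_outcome / pair$beta_exposure
  weights <- pair$beta_exposure^2 / pair$se_outcome^2
  beta <- .weighted_mode_point(ratios, weights, phi = phi, grid_n = grid_n)
  se <- .boot_se(pair,
                 function(r, w) .weighted_mode_point(r, w, phi = phi,
                                                     grid_n = grid_n),
                 n_boot, seed)
  mr_result("weighted_mode", beta, se, nrow(pair), n_boot = n_boot)
}

#' Rescale an estimate to per-doubling of liability
#'
#' Multiplies beta, SE and both CI bounds by ln 2 = 0.693, converting
#' effects per log-odds unit of AD liability into effects per doubling of
#' liability (the recommended reporting scale for binary/liability
#' exposures). Refuses to scale twice.
#'
#' @param result an MR result or effect-estimate data.frame with a
#'   `scaled_by_ln2` column.
#' @return the rescaled result with `scaled_by_ln2 = TRUE`.
#' @export
scale_to_doubling <- function(result) {
  stopifnot(is.data.frame(result), "scaled_by_ln2" %in% names(result))
  scale_estimate_ln2(result)
}

#' Run the full MR estimator panel
#'
#' Harmonizes outcome summary statistics to the instrument, builds the
#' exposure-outcome pair, and runs the requested estimators, optionally for
#' both the full instrument and the instrument with the two APOE-defining
#' SNPs removed (to examine non-APOE-driven effects). All results are
#' returned on the per-doubling scale.
#'
#' @param instrument an [instrument_table()].
#' @param outcome outcome summary statistics data.frame.
#' @param methods subset of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"`, `"wald"`.
#' @param apoe_sets which instrument variants to run: `"with"`,
#'   `"without"`, or both (default).
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param seed bootstrap seed (each method/variant gets a derived stream).
#' @param ... passed to [harmonize()].
#' @return data.frame of MR results with an `apoe` column.
#' @export
run_mr_panel <- function(instrument, outcome,
                         methods = c("ivw", "egger", "weighted_median",
                                     "weighted_mode"),
                         apoe_sets = c("with", "without"),
                         n_boot = 1000, seed = NULL, ...) {
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median",
                                  "weighted_mode", "wald"),
                       several.ok = TRUE)
  apoe_sets <- match.arg(apoe_sets, c("with", "without"), several.ok = TRUE)
  out <- list()
  for (set in apoe_sets) {
    ins <- instrument
    if (set == "without") {
      ins <- ins[!ins$snp %in% apoe_ids_of(instrument), , drop = FALSE]
      if (nrow(ins) == 0L) stop("no non-APOE SNPs in instrument")
    }
    pair <- make_pair(ins, outcome, ...)
    for (i in seq_along(methods)) {
      m <- methods[i]
      sub_seed <- if (is.null(seed)) NULL
        else (seed + 101L * i + 7L * match(set, c("with", "without"))) %%
          .Machine$integer.max
      res <- switch(m,
        wald = wald_ratio(pair),
        ivw = if (nrow(pair) >= 2L) mr_ivw(pair) else wald_ratio(pair),
        egger = mr_egger(pair),
        weighted_median = mr_weighted_median(pair, n_boot = n_boot,
                                             seed = sub_seed),
        weighted_mode = mr_weighted_mode(pair, n_boot = n_boot,
                                         seed = sub_seed))
      res$apoe <- set
      out[[length(out) + 1L]] <- scale_to_doubling(res)
    }
  }
  do.call(rbind, out)
}
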
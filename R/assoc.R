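#' Ordinary least squares kernel
#'
#' Shared regression kernel for all individual-level models: OLS with an
#' intercept, listwise deletion of rows with any missing value, classical
#' standard errors from `sigma^2 (X'X)^-1`.
#'
#' @param y response vector.
#' @param design numeric matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @return list `coefficients`, `se`, `df_residual`, `sigma`, `n`.
#' @export
fit_ols <- function(y, design) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cc <- complete.cases(y, X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  X1 <- cbind("(Intercept)" = 1, X)
  n <- nrow(X1); p <- ncol(X1)
  if (n <= p) stop("too few complete observations (n <= p)")
  fit <- lm.fit(X1, y)
  if (fit$rank < p) stop("design matrix is rank deficient")
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- numeric(p)
  se[fit$qr$pivot] <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  names(se) <- colnames(X1)
  list(coefficients = fit$coefficients, se = se, df_residual = df,
       sigma = sqrt(sigma2), n = n)
}

effect_estimate <- function(beta, se, n, method, metabolite = NA_character_,
                            stratum = NA_character_, scaled_by_ln2 = FALSE) {
  data.frame(metabolite = metabolite, stratum = stratum, method = method,
             beta = beta, se = se,
             ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
             p = 2 * pnorm(-abs(beta / se)),
             n = n, scaled_by_ln2 = scaled_by_ln2,
             stringsAsFactors = FALSE)
}

scale_estimate_ln2 <- function(est) {
  if (any(est$scaled_by_ln2)) stop("estimate already scaled to per-doubling")
  for (col in c("beta", "se", "ci_low", "ci_high"))
    est[[col]] <- est[[col]] * log(2)
  est$scaled_by_ln2 <- TRUE
  est
}

.merge_pheno_grs <- function(cohort, grs, metabolite, covariates, timepoint) {
  ph <- cohort$phenotypes
  if (!is.null(timepoint)) ph <- ph[ph$timepoint == timepoint, , drop = FALSE]
  if (nrow(ph) == 0L) stop("no phenotype rows for timepoint ", timepoint)
  m <- match(ph$sample_id, grs$sample_id)
  ph$score <- grs$score[m]
  ph
}

#' GRS-metabolite association at one timepoint
#'
#' Linear regression of a (rank inverse-normal transformed) metabolite on
#' the AD genetic risk score, adjusted for age at metabolite assessment and
#' sex. Since the GRS is in log-odds of AD, the fitted slope is in SD units
#' per log-odds unit of liability; beta, SE and both CI bounds are then
#' multiplied by ln 2 = 0.693 so estimates read as SD-unit differences per
#' doubling of genetic liability.
#'
#' @param cohort a `synth_cohort` or compatible list with a long
#'   `phenotypes` table.
#' @param grs a GRS table from [compute_grs()].
#' @param metabolite metabolite column name (already transformed).
#' @param covariates adjustment columns present in the phenotype table
#'   (default age and sex).
#' @param timepoint phenotype timepoint to analyse (`NULL` = all rows).
#' @param min_n minimum analysable sample size (default 30).
#' @param scale multiply estimates by ln 2 (default TRUE).
#' @return one-row data.frame: metabolite, stratum, method, beta, se,
#'   ci_low, ci_high, p, n, scaled_by_ln2.
#' @export
grs_metabolite_assoc <- function(cohort, grs, metabolite,
                                 covariates = c("age", "sex"),
                                 timepoint = NULL, min_n = 30, scale = TRUE) {
  ph <- .merge_pheno_grs(cohort, grs, metabolite, covariates, timepoint)
  X <- as.matrix(ph[, c("score", covariates), drop = FALSE])
  y <- ph[[metabolite]]
  cc <- sum(complete.cases(y, X))
  if (cc < min_n) stop("stratum n (", cc, ") below minimum ", min_n)
  fit <- fit_ols(y, X)
  est <- effect_estimate(fit$coefficients[["score"]], fit$se[["score"]],
                         fit$n, method = "grs", metabolite = metabolite,
                         stratum = timepoint %||% "all")
  if (scale) est <- scale_estimate_ln2(est)
  est
}

#' Per-SNP metabolite GWAS within a stratum
#'
#' One OLS per instrument SNP of the (transformed) metabolite on
#' effect-allele dosage plus covariates, emitting per-SNP beta, se, eaf and
#' n in the standard summary-statistics schema — the SNP-outcome side of
#' the two-sample MR arm. Monomorphic SNPs in the stratum are emitted with
#' missing beta and logged.
#'
#' @param cohort a `synth_cohort` (or list with `dosages`, `snps`,
#'   `phenotypes`).
#' @param instrument an [instrument_table()].
#' @param metabolite metabolite column (transformed within the stratum).
#' @param sample_ids restrict to these samples (e.g. one age tertile);
#'   `NULL` = all.
#' @param covariates adjustment columns (default age, sex); extend with
#'   array/principal-component columns when present.
#' @param timepoint phenotype timepoint to use.
#' @return data.frame `snp`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `eaf`, `n`; attribute `"gwas_log"` lists skipped SNPs.
#' @export
snp_metabolite_gwas <- function(cohort, instrument, metabolite,
                                sample_ids = NULL,
                                covariates = c("age", "sex"),
                                timepoint = NULL) {
  ph <- cohort$phenotypes
  if (!is.null(timepoint)) ph <- ph[ph$timepoint == timepoint, , drop = FALSE]
  if (!is.null(sample_ids)) ph <- ph[ph$sample_id %in% sample_ids, ,
                                     drop = FALSE]
  snps <- intersect(instrument$snp, colnames(cohort$dosages))
  if (length(snps) == 0L) stop("no instrument SNPs in cohort")
  G <- cohort$dosages[ph$sample_id, snps, drop = FALSE]
  sn <- cohort$snps
  y <- ph[[metabolite]]
  Xc <- as.matrix(ph[, covariates, drop = FALSE])

  rows <- vector("list", length(snps))
  log <- list()
  for (k in seq_along(snps)) {
    g <- G[, k]
    cc <- complete.cases(y, g, Xc)
    ea <- sn$effect_allele[match(snps[k], sn$id)] %||% NA_character_
    oa <- sn$other_allele[match(snps[k], sn$id)] %||% NA_character_
    if (sum(cc) < ncol(Xc) + 3L || var(g[cc]) == 0) {
      rows[[k]] <- data.frame(snp = snps[k], effect_allele = ea,
                              other_allele = oa, beta = NA_real_,
                              se = NA_real_, eaf = mean(g, na.rm = TRUE) / 2,
                              n = sum(cc), stringsAsFactors = FALSE)
      log[[length(log) + 1L]] <- data.frame(
        snp = snps[k], reason = "monomorphic or insufficient data")
      next
    }
    fit <- fit_ols(y, cbind(dosage = g, Xc))
    rows[[k]] <- data.frame(snp = snps[k], effect_allele = ea,
                            other_allele = oa,
                            beta = fit$coefficients[["dosage"]],
                            se = fit$se[["dosage"]],
                            eaf = mean(g[cc]) / 2, n = fit$n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "gwas_log") <- if (length(log)) do.call(rbind, log) else NULL
  out
}

#' Check the GRS against a putative confounder
#'
#' A valid liability instrument should not associate with traits like BMI,
#' height, smoking or parental education; systematic associations would
#' signal pleiotropy or population structure. Continuous covariates are
#' regressed on the score by OLS, binary covariates by logistic regression.
#' Estimates are left unscaled.
#'
#' @param grs GRS table from [compute_grs()].
#' @param covariate numeric vector aligned with `grs` rows.
#' @param type `"continuous"` or `"binary"`.
#' @param label covariate name for the output row.
#' @return one-row effect-estimate data.frame (method
#'   `"confounder_check"`).
#' @export
confounder_check <- function(grs, covariate,
                             type = c("continuous", "binary"),
                             label = "covariate") {
  type <- match.arg(type)
  stopifnot(length(covariate) == nrow(grs))
  cc <- complete.cases(covariate, grs$score)
  if (sum(cc) < 30) stop("covariate observed for fewer than 30 samples")
  if (length(unique(covariate[cc])) < 2L) stop("constant covariate")
  if (type == "continuous") {
    fit <- fit_ols(covariate, cbind(score = grs$score))
    est <- effect_estimate(fit$coefficients[["score"]], fit$se[["score"]],
                           fit$n, method = "confounder_check",
                           metabolite = label)
  } else {
    if (!all(covariate[cc] %in% c(0, 1)))
      stop("binary covariate must be coded 0/1")
    fit <- glm(covariate[cc] ~ grs$score[cc], family = binomial())
    sm <- summary(fit)$coefficients
    est <- effect_estimate(sm[2L, 1L], sm[2L, 2L], sum(cc),
                           method = "confounder_check", metabolite = label)
  }
  est
}

#' APOE carrier contrast on a metabolite
#'
#' Mean difference in a (transformed) metabolite between epsilon4 carriers
#' (or epsilon2 carriers) and epsilon3 homozygotes, covariate-adjusted by
#' multivariable linear regression with a binary carriage indicator.
#' Carriers of the opposite epsilon allele are omitted, per the diplotype
#' grouping of [classify_apoe()]. Estimates are interpreted as mean
#' differences and are not ln2-scaled.
#'
#' @param cohort cohort with long `phenotypes`.
#' @param diplotypes output of [classify_apoe()].
#' @param contrast `"e4_vs_e3e3"` or `"e2_vs_e3e3"`.
#' @param metabolite metabolite column (transformed).
#' @param covariates adjustment columns (default age, sex).
#' @param timepoint phenotype timepoint.
#' @param min_group minimum size of both carrier and reference group.
#' @return one-row effect-estimate data.frame (method = contrast label).
#' @export
apoe_contrast <- function(cohort, diplotypes,
                          contrast = c("e4_vs_e3e3", "e2_vs_e3e3"),
                          metabolite, covariates = c("age", "sex"),
                          timepoint = NULL, min_group = 10) {
  contrast <- match.arg(contrast)
  carrier_grp <- if (contrast == "e4_vs_e3e3") "e4_carrier" else "e2_carrier"
  ph <- cohort$phenotypes
  if (!is.null(timepoint)) ph <- ph[ph$timepoint == timepoint, , drop = FALSE]
  grp <- diplotypes$group[match(ph$sample_id, diplotypes$sample_id)]
  keep <- grp %in% c(carrier_grp, "e3e3")
  ph <- ph[keep, , drop = FALSE]
  carrier <- as.numeric(grp[keep] == carrier_grp)
  if (sum(carrier == 1) < min_group) stop("empty or too-small contrast group")
  if (sum(carrier == 0) < min_group) stop("too-small reference group")
  fit <- fit_ols(ph[[metabolite]],
                 cbind(carrier = carrier,
                       as.matrix(ph[, covariates, drop = FALSE])))
  effect_estimate(fit$coefficients[["carrier"]], fit$se[["carrier"]], fit$n,
                  method = contrast, metabolite = metabolite,
                  stratum = timepoint %||% "all")
}
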
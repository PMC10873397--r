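APOE_SNPS <- c("rs429358", "rs7412")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.flip_alleles <- function(a) unname(.complement[toupper(a)])

.is_palindromic <- function(a1, a2) .flip_alleles(a1) == toupper(a2)

#' Construct an instrument table of AD-associated SNPs
#'
#' Validates and classes a table of instrument SNPs: one row per SNP with
#' its effect allele, other allele, external weight (log odds of AD per
#' effect allele, from a case-control GWAS meta-analysis) and the weight's
#' standard error. Two designated APOE SNP ids (default rs429358 and
#' rs7412, which jointly define the epsilon isoforms) can be dropped from
#' scoring with `include_apoe = FALSE` downstream.
#'
#' @param x data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta` (the weight), `se`; optional `eaf` (effect allele frequency,
#'   needed to align palindromic SNPs during harmonization).
#' @param apoe_ids ids of the two APOE-defining SNPs.
#' @return `x` with class `instrument_table` and attribute `apoe_ids`.
#' @export
instrument_table <- function(x, apoe_ids = APOE_SNPS) {
  stopifnot(is.data.frame(x),
            all(c("snp", "effect_allele", "other_allele", "beta", "se")
                %in% names(x)))
  if (anyDuplicated(x$snp)) stop("duplicate SNP ids in instrument table")
  al <- c(x$effect_allele, x$other_allele)
  if (!all(toupper(al) %in% names(.complement)))
    stop("alleles must be single bases A/C/G/T")
  if (any(toupper(x$effect_allele) == toupper(x$other_allele)))
    stop("effect and other allele must differ")
  if (!all(is.finite(x$beta))) stop("weights must be finite")
  if (is.null(x$eaf)) x$eaf <- NA_real_
  structure(x, class = c("instrument_table", "data.frame"),
            apoe_ids = apoe_ids)
}

apoe_ids_of <- function(instrument) {
  attr(instrument, "apoe_ids") %||% APOE_SNPS
}

#' Harmonize summary statistics to an instrument's effect alleles
#'
#' Aligns each summary-statistics row so its effect allele matches the
#' instrument's effect allele for the same SNP. Rows with swapped alleles
#' have `beta` sign-flipped and `eaf` mapped to `1 - eaf`; rows on the
#' opposite strand are base-complemented first. Palindromic SNPs (A/T or
#' C/G) are strand-ambiguous: under the default `"infer"` policy they are
#' aligned by comparing effect-allele frequencies when both frequencies are
#' informative (`|eaf - 0.5| > eaf_window` in both tables) and dropped
#' otherwise; policy `"drop"` removes them unconditionally. Rows whose
#' allele pair cannot be reconciled even after complementing are dropped
#' with a logged reason.
#'
#' Harmonization is idempotent: applying it to an already-aligned table
#' returns the table unchanged.
#'
#' @param instrument an [instrument_table()].
#' @param stats data.frame of summary statistics (`snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, optional `eaf`).
#' @param palindrome_policy `"infer"` (align by EAF, drop when
#'   uninformative) or `"drop"`.
#' @param eaf_window frequencies within this distance of 0.5 are treated as
#'   uninformative for palindromic alignment.
#' @return the harmonized subset of `stats`, rows in instrument order where
#'   present; attribute `"harmonization_log"` is a data.frame of per-SNP
#'   actions including dropped rows and reasons.
#' @export
harmonize <- function(instrument, stats,
                      palindrome_policy = c("infer", "drop"),
                      eaf_window = 0.08) {
  policy <- match.arg(palindrome_policy)
  stopifnot(is.data.frame(stats),
            all(c("snp", "effect_allele", "other_allele", "beta", "se")
                %in% names(stats)))
  if (is.null(stats$eaf)) stats$eaf <- NA_real_
  shared <- intersect(instrument$snp, stats$snp)
  if (length(shared) < 1L) stop("no shared SNPs between instrument and stats")

  keep <- list()
  log <- list()
  note <- function(snp, action) {
    log[[length(log) + 1L]] <<- data.frame(snp = snp, action = action,
                                           stringsAsFactors = FALSE)
  }

  for (id in shared) {
    ins <- instrument[instrument$snp == id, , drop = FALSE]
    row <- stats[stats$snp == id, , drop = FALSE][1L, , drop = FALSE]
    ie <- toupper(ins$effect_allele); io <- toupper(ins$other_allele)
    se_a <- toupper(row$effect_allele); so_a <- toupper(row$other_allele)

    swap <- function(r) {
      r$beta <- -r$beta
      r$eaf <- ifelse(is.na(r$eaf), NA_real_, 1 - r$eaf)
      tmp <- r$effect_allele; r$effect_allele <- r$other_allele
      r$other_allele <- tmp
      r
    }

    if (.is_palindromic(ie, io)) {
      if (policy == "drop") { note(id, "dropped: palindromic"); next }
      if (!setequal(c(se_a, so_a), c(ie, io))) {
        note(id, "dropped: irreconcilable alleles"); next
      }
      f_i <- ins$eaf; f_s <- row$eaf
      if (is.na(f_i) || is.na(f_s) ||
          abs(f_i - 0.5) <= eaf_window || abs(f_s - 0.5) <= eaf_window) {
        note(id, "dropped: palindromic, frequency uninformative"); next
      }
      if (se_a != ie) row <- swap(row)        # put nominal EA on instrument EA
      # same-strand reading vs strand-flipped reading differ by a swap;
      # choose the one whose frequency agrees in direction with the instrument
      if (sign(row$eaf - 0.5) != sign(f_i - 0.5)) {
        row <- swap(row)
        # restore allele labels to the instrument's (complement identity)
        row$effect_allele <- ins$effect_allele
        row$other_allele <- ins$other_allele
        note(id, "aligned: palindromic, strand-flipped by EAF")
      } else note(id, "aligned: palindromic by EAF")
      keep[[id]] <- row
      next
    }

    if (setequal(c(se_a, so_a), c(ie, io))) {
      if (se_a == ie) { note(id, "aligned"); keep[[id]] <- row }
      else { keep[[id]] <- swap(row); note(id, "aligned: alleles swapped") }
    } else if (setequal(.flip_alleles(c(se_a, so_a)), c(ie, io))) {
      row$effect_allele <- .flip_alleles(se_a)
      row$other_allele <- .flip_alleles(so_a)
      if (row$effect_allele == ie) { note(id, "aligned: strand complemented") }
      else { row <- swap(row); note(id, "aligned: complemented and swapped") }
      keep[[id]] <- row
    } else {
      note(id, "dropped: irreconcilable alleles")
    }
  }

  for (id in setdiff(stats$snp, instrument$snp))
    note(id, "dropped: not in instrument")

  if (length(keep) == 0L) stop("no rows retained after harmonization")
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  attr(out, "harmonization_log") <- do.call(rbind, log)
  out
}

#' Substitute proxy SNPs for instrument SNPs absent from a dataset
#'
#' When an instrument SNP is not typed in the target dataset, a
#' user-supplied high-LD proxy (e.g. found within 10,000 kb at r^2 >= 0.8)
#' replaces it, carrying the original SNP's weight unchanged. Proxies below
#' the r^2 threshold or beyond the distance limit are rejected and the SNP
#' left missing (the GRS missingness policy then applies).
#'
#' @param instrument an [instrument_table()].
#' @param available_ids SNP ids present in the target dataset.
#' @param proxies data.frame `original_id`, `proxy_id`, `r2`, `distance_kb`;
#'   may be `NULL`.
#' @param r2_threshold minimum LD r^2 (default 0.8).
#' @param max_distance_kb maximum distance (default 10,000 kb).
#' @return the instrument table with absent ids substituted where an
#'   acceptable proxy exists; attribute `"proxy_log"` lists substitutions
#'   and unresolved ids.
#' @export
apply_proxies <- function(instrument, available_ids, proxies = NULL,
                          r2_threshold = 0.8, max_distance_kb = 1e4) {
  absent <- setdiff(instrument$snp, available_ids)
  log <- list()
  if (!is.null(proxies) && length(absent) > 0L) {
    stopifnot(all(c("original_id", "proxy_id", "r2", "distance_kb")
                  %in% names(proxies)))
    if (any(proxies$original_id %in% available_ids))
      stop("proxies supplied for SNPs that are already available")
    for (id in absent) {
      p <- proxies[proxies$original_id == id, , drop = FALSE]
      if (nrow(p) == 0L) {
        warning("no proxy for absent SNP ", id, "; left missing")
        log[[id]] <- data.frame(original_id = id, proxy_id = NA_character_,
                                action = "missing: no proxy")
        next
      }
      p <- p[1L, ]
      if (p$r2 < r2_threshold || p$distance_kb > max_distance_kb) {
        warning("proxy for ", id, " rejected (r2 or distance); left missing")
        log[[id]] <- data.frame(original_id = id, proxy_id = p$proxy_id,
                                action = "missing: proxy rejected")
        next
      }
      instrument$snp[instrument$snp == id] <- p$proxy_id
      log[[id]] <- data.frame(original_id = id, proxy_id = p$proxy_id,
                              action = "substituted")
    }
  } else {
    for (id in absent) {
      warning("no proxy for absent SNP ", id, "; left missing")
      log[[id]] <- data.frame(original_id = id, proxy_id = NA_character_,
                              action = "missing: no proxy")
    }
  }
  attr(instrument, "proxy_log") <-
    if (length(log)) do.call(rbind, c(log, make.row.names = FALSE)) else NULL
  instrument
}

#' Compute weighted genetic risk scores
#'
#' Per-sample weighted sum of effect-allele dosages, weights being the
#' instrument's external log-odds ratios, so scores are in log-odds of AD.
#' Scores are computed for every sample with at least one observed
#' instrument SNP; samples with no observed SNP are excluded and reported.
#'
#' Missing-genotype policies:
#' \describe{
#'   \item{`rescale` (default)}{the observed weighted sum is rescaled by
#'     `sum(|w|) / sum(|w| over observed SNPs)`, keeping scores on a common
#'     scale across missingness patterns.}
#'   \item{`sum_observed`}{raw weighted sum over observed SNPs.}
#'   \item{`mean_impute`}{missing dosages imputed at `2 * eaf` from the
#'     instrument's allele frequencies.}
#' }
#'
#' @param dosages numeric matrix, samples x SNPs, effect-allele dosages in
#'   `[0, 2]` with `NA` for missing; or a `synth_cohort`, whose dosage
#'   matrix is used.
#' @param instrument an [instrument_table()] (after [apply_proxies()]).
#' @param missing_policy one of `"rescale"`, `"sum_observed"`,
#'   `"mean_impute"`.
#' @param include_apoe if `FALSE`, the two APOE-defining SNPs are dropped
#'   before scoring (the "without APOE" GRS variant).
#' @return data.frame `sample_id`, `score`, `n_snps_used`, `variant`;
#'   attribute `"excluded"` holds ids of samples with no observed SNP.
#' @export
compute_grs <- function(dosages, instrument,
                        missing_policy = c("rescale", "sum_observed",
                                           "mean_impute"),
                        include_apoe = TRUE) {
  policy <- match.arg(missing_policy)
  if (inherits(dosages, "synth_cohort")) dosages <- dosages$dosages
  stopifnot(is.matrix(dosages))
  snps <- intersect(instrument$snp, colnames(dosages))
  if (length(snps) == 0L)
    stop("no overlap between instrument and cohort SNPs")
  if (!include_apoe) {
    snps <- setdiff(snps, apoe_ids_of(instrument))
    if (length(snps) == 0L)
      stop("no non-APOE instrument SNPs present in cohort")
  }
  w <- instrument$beta[match(snps, instrument$snp)]
  G <- dosages[, snps, drop = FALSE]
  if (any(G < 0 | G > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  obs <- !is.na(G)
  n_used <- rowSums(obs)

  if (policy == "mean_impute") {
    eaf <- instrument$eaf[match(snps, instrument$snp)]
    if (anyNA(eaf) && any(!obs))
      stop("mean_impute policy requires instrument eaf for all SNPs")
    for (j in seq_along(snps)) G[!obs[, j], j] <- 2 * eaf[j]
    score <- drop(G %*% w)
  } else {
    G0 <- G; G0[!obs] <- 0
    raw <- drop(G0 %*% w)
    if (policy == "rescale") {
      wabs <- abs(w)
      denom <- drop(obs %*% wabs)
      score <- ifelse(denom > 0, raw * sum(wabs) / denom, NA_real_)
    } else score <- raw
  }

  ids <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  keep <- n_used >= 1L
  out <- data.frame(sample_id = ids[keep], score = score[keep],
                    n_snps_used = n_used[keep],
                    variant = if (include_apoe) "with_APOE" else "without_APOE",
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- ids[!keep]
  out
}

#' Classify APOE epsilon diplotypes from the two defining SNPs
#'
#' The epsilon-2/3/4 isoforms are haplotypes of rs429358 and rs7412:
#' epsilon4 carries C at rs429358, epsilon2 carries T at rs7412, epsilon3
#' carries neither. Given hard-called counts of the rs429358-C and rs7412-T
#' alleles, the standard lookup is
#' (0,0) e3/e3; (0,1) e2/e3; (0,2) e2/e2; (1,0) e3/e4; (2,0) e4/e4;
#' (1,1) e2/e4. Combinations (1,2), (2,1), (2,2) imply rare recombinant
#' haplotypes (e.g. epsilon1) and are flagged and excluded.
#'
#' Carrier groups for the contrasts: `e4_carrier` = e3/e4 or e4/e4
#' (excluding any e2 allele), `e2_carrier` = e2/e3 or e2/e2 (excluding any
#' e4 allele), `e3e3` the reference; e2/e4 heterozygotes are excluded from
#' both contrasts, since each contrast omits carriers of the opposite
#' allele.
#'
#' @param dosage_rs429358_C count of C alleles at rs429358 per sample;
#'   near-integer dosages are hard-called when within `hard_call_tol`.
#' @param dosage_rs7412_T count of T alleles at rs7412 per sample.
#' @param sample_id optional ids.
#' @param hard_call_tol rounding tolerance for hard calls (default 0.1);
#'   dosages further from an integer are unclassifiable.
#' @return data.frame `sample_id`, `diplotype`, `group` with
#'   `group` in `e4_carrier`, `e2_carrier`, `e3e3`, `excluded`.
#' @export
classify_apoe <- function(dosage_rs429358_C, dosage_rs7412_T,
                          sample_id = NULL, hard_call_tol = 0.1) {
  stopifnot(length(dosage_rs429358_C) == length(dosage_rs7412_T))
  n <- length(dosage_rs429358_C)
  sample_id <- sample_id %||% as.character(seq_len(n))

  hard <- function(d) {
    r <- round(d)
    r[is.na(d) | abs(d - r) > hard_call_tol | r < 0 | r > 2] <- NA_integer_
    as.integer(r)
  }
  c4 <- hard(dosage_rs429358_C)
  t2 <- hard(dosage_rs7412_T)

  dip_map <- c("0_0" = "e3/e3", "0_1" = "e2/e3", "0_2" = "e2/e2",
               "1_0" = "e3/e4", "2_0" = "e4/e4", "1_1" = "e2/e4",
               "1_2" = "rare", "2_1" = "rare", "2_2" = "rare")
  grp_map <- c("e3/e3" = "e3e3", "e2/e3" = "e2_carrier",
               "e2/e2" = "e2_carrier", "e3/e4" = "e4_carrier",
               "e4/e4" = "e4_carrier", "e2/e4" = "excluded",
               "rare" = "excluded")

  key <- paste(c4, t2, sep = "_")
  dip <- unname(dip_map[key])
  dip[is.na(c4) | is.na(t2)] <- "unclassifiable"
  grp <- unname(grp_map[dip])
  grp[dip == "unclassifiable"] <- "excluded"

  n_bad <- sum(dip %in% c("rare", "unclassifiable"))
  if (n_bad > 0)
    message(n_bad, " sample(s) with rare or unclassifiable APOE genotypes ",
            "set to group 'excluded'")
  data.frame(sample_id = sample_id, diplotype = dip, group = grp,
             stringsAsFactors = FALSE)
}
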
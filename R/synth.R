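# Synthetic cohorts with the generative structure the analysis assumes:
# HWE genotypes in linkage equilibrium except the APOE pair (drawn as
# haplotypes), an additive liability score, metabolites linear in liability
# with optional per-allele pleiotropy, age/sex covariates, MCAR genotype
# missingness.

#' Synthetic 25-SNP AD instrument table
#'
#' A deterministic synthetic stand-in for an external AD case-control GWAS
#' instrument: the two APOE-defining SNPs with field-typical log odds
#' ratios (rs429358-C +1.2, rs7412-T -0.47) plus 23 SNPs with small
#' weights, all with non-palindromic allele pairs and plausible effect
#' allele frequencies. The weights are synthetic calibration choices, not
#' estimates from any real GWAS.
#'
#' @param n_snps total number of SNPs including the APOE pair (>= 3).
#' @param seed seed for the deterministic draw (changing it yields a
#'   different but equally valid synthetic instrument).
#' @return an [instrument_table()].
#' @export
example_instrument <- function(n_snps = 25, seed = 42) {
  stopifnot(n_snps >= 3)
  n_other <- n_snps - 2L
  with_local_seed(seed, {
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    pick <- pairs[sample.int(4L, n_other, replace = TRUE), , drop = FALSE]
    df <- data.frame(
      snp = c(APOE_SNPS,
              sprintf("rs%07d", sample.int(9999999L, n_other))),
      effect_allele = c("C", "T", pick[, 1L]),
      other_allele = c("T", "C", pick[, 2L]),
      beta = c(1.2, -0.47, round(runif(n_other, 0.04, 0.16), 3)),
      se = c(0.02, 0.03, round(runif(n_other, 0.01, 0.03), 3)),
      eaf = c(0.15, 0.08, round(runif(n_other, 0.1, 0.5), 3)),
      stringsAsFactors = FALSE)
    instrument_table(df)
  })
}

default_timepoints <- function() {
  list(
    list(label = "age8",  age_mean = 8,  age_sd = 0.3),
    list(label = "age16", age_mean = 16, age_sd = 0.4),
    list(label = "age18", age_mean = 18, age_sd = 0.4),
    list(label = "age25", age_mean = 25, age_sd = 0.8),
    list(label = "adult", age_min = 39, age_max = 73)
  )
}

#' Specify a generative model for a synthetic cohort
#'
#' Collects and validates the parameters of the generative model:
#' per-SNP effect allele frequencies and liability weights `w_j`; the
#' liability effect `theta` of each metabolite (SD units per unit log-odds
#' of AD liability, the quantity the analysis estimates); optional
#' per-allele direct (pleiotropic) effects `alpha_j`; covariate effects;
#' residual noise; genotype missingness; and the timepoint age
#' distributions.
#'
#' The APOE pair is drawn as haplotypes with frequencies `apoe_hap_freq`
#' over (e2, e3, e4) so diplotype classification sees realistic joint
#' genotypes; defaults 0.08/0.77/0.15 match UK allele frequencies. All
#' other SNPs are independent Binomial(2, f) (Hardy-Weinberg, linkage
#' equilibrium).
#'
#' @param n_samples number of samples (>= 2).
#' @param snps data.frame `id`, `eaf`, `weight` (and optionally
#'   `effect_allele`, `other_allele`); defaults to [example_instrument()].
#' @param apoe_ids the two APOE SNP ids within `snps`.
#' @param theta named vector, metabolite -> effect per unit log-odds
#'   liability (SD units). Default one metabolite `"metab"` at 0.1.
#' @param pleiotropy named vector, SNP id -> direct per-allele metabolite
#'   effect `alpha_j` (applied to every metabolite); default none.
#' @param covariate_effects list per metabolite of
#'   `c(age_slope, sex_difference)`; a single unnamed numeric pair is
#'   recycled for all metabolites. Defaults `c(0.01, 0.2)`.
#' @param noise_sd residual SD (> 0), default 1.
#' @param missing_rate element-wise MCAR dosage missingness in `[0, 1)`.
#' @param timepoints list of `list(label, age_mean, age_sd)` or
#'   `list(label, age_min, age_max)`; defaults to four childhood/young-adult
#'   timepoints plus one adult timepoint spanning ages 39-73.
#' @param apoe_hap_freq haplotype frequencies, named `e2`, `e3`, `e4`.
#' @param seed integer seed; fixed seed gives byte-identical cohorts.
#'   `NULL` draws from the session's current RNG stream, so a caller can
#'   seed once and simulate several mutually independent objects.
#' @return a `generative_spec` list.
#' @export
generative_spec <- function(n_samples = 2000,
                            snps = NULL,
                            apoe_ids = APOE_SNPS,
                            theta = c(metab = 0.1),
                            pleiotropy = NULL,
                            covariate_effects = c(0.01, 0.2),
                            noise_sd = 1,
                            missing_rate = 0,
                            timepoints = default_timepoints(),
                            apoe_hap_freq = c(e2 = 0.08, e3 = 0.77, e4 = 0.15),
                            seed = 1L) {
  if (is.null(snps)) {
    ins <- example_instrument()
    snps <- data.frame(id = ins$snp, eaf = ins$eaf, weight = ins$beta,
                       effect_allele = ins$effect_allele,
                       other_allele = ins$other_allele,
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(snps), all(c("id", "eaf", "weight") %in% names(snps)))
  if (nrow(snps) == 0L) stop("spec must contain at least one SNP")
  if (any(snps$eaf <= 0 | snps$eaf >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1): higher rates would leave samples ",
         "with no observed genotype")
  stopifnot(length(theta) >= 1, !is.null(names(theta)))
  if (!is.null(pleiotropy) && !all(names(pleiotropy) %in% snps$id))
    stop("pleiotropy names must be SNP ids")
  if (!is.list(covariate_effects))
    covariate_effects <- stats::setNames(
      rep(list(covariate_effects), length(theta)), names(theta))
  hf <- apoe_hap_freq / sum(apoe_hap_freq)
  stopifnot(setequal(names(hf), c("e2", "e3", "e4")))
  structure(list(n_samples = as.integer(n_samples), snps = snps,
                 apoe_ids = apoe_ids, theta = theta,
                 pleiotropy = pleiotropy,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 timepoints = timepoints, apoe_hap_freq = hf,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "generative_spec")
}

draw_ages <- function(tp, n) {
  if (!is.null(tp$age_sd)) rnorm(n, tp$age_mean, tp$age_sd)
  else runif(n, tp$age_min, tp$age_max)
}

#' Simulate an individual-level cohort
#'
#' Draws genotypes, covariates and metabolites under a [generative_spec()]:
#' dosages Binomial(2, f_j) independently across SNPs, except the APOE pair
#' which is drawn as two haplotypes over (e2, e3, e4) — e4 contributes a C
#' at rs429358, e2 a T at rs7412. Liability is `L_i = sum_j w_j g_ij`; each
#' metabolite at each timepoint is
#' `theta * L_i + sum_j alpha_j g_ij + age * age_slope +
#'  sex * sex_difference + Normal(0, noise_sd^2)`.
#' MCAR missingness is applied element-wise to dosages; every sample is
#' guaranteed at least one observed SNP (samples fully masked by chance
#' have one genotype restored).
#'
#' @param spec a [generative_spec()].
#' @return a `synth_cohort`: list with `samples` (sample_id, sex),
#'   `snps` (the spec's SNP table), `dosages` (samples x SNPs, NA =
#'   missing), `phenotypes` (long: sample_id, timepoint, age, one column
#'   per metabolite, raw scale), and `truth` (liability vector and the
#'   generating parameters, for recovery tests).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    snps <- spec$snps
    J <- nrow(snps)
    ids <- sprintf("S%05d", seq_len(n))

    G <- matrix(NA_real_, n, J, dimnames = list(ids, snps$id))
    apoe_present <- spec$apoe_ids[spec$apoe_ids %in% snps$id]
    for (j in seq_len(J)) {
      if (snps$id[j] %in% apoe_present) next
      G[, j] <- rbinom(n, 2L, snps$eaf[j])
    }
    if (length(apoe_present) == 2L) {
      hf <- spec$apoe_hap_freq[c("e2", "e3", "e4")]
      h1 <- sample(names(hf), n, replace = TRUE, prob = hf)
      h2 <- sample(names(hf), n, replace = TRUE, prob = hf)
      G[, spec$apoe_ids[1L]] <- (h1 == "e4") + (h2 == "e4")  # rs429358 C
      G[, spec$apoe_ids[2L]] <- (h1 == "e2") + (h2 == "e2")  # rs7412 T
    } else if (length(apoe_present) == 1L) {
      j <- match(apoe_present, snps$id)
      G[, j] <- rbinom(n, 2L, snps$eaf[j])
    }

    w <- snps$weight
    L <- drop(G %*% w)
    alpha <- rep(0, J)
    if (!is.null(spec$pleiotropy))
      alpha[match(names(spec$pleiotropy), snps$id)] <- spec$pleiotropy
    direct <- drop(G %*% alpha)

    sex <- rbinom(n, 1L, 0.5)
    pheno <- list()
    for (tp in spec$timepoints) {
      age <- draw_ages(tp, n)
      df <- data.frame(sample_id = ids, timepoint = tp$label, age = age,
                       sex = sex, stringsAsFactors = FALSE)
      for (m in names(spec$theta)) {
        ce <- spec$covariate_effects[[m]] %||% c(0, 0)
        df[[m]] <- spec$theta[[m]] * L + direct + age * ce[1L] +
          sex * ce[2L] + rnorm(n, 0, spec$noise_sd)
      }
      pheno[[tp$label]] <- df
    }
    phenotypes <- do.call(rbind, c(pheno, make.row.names = FALSE))

    if (spec$missing_rate > 0) {
      mask <- matrix(runif(n * J) < spec$missing_rate, n, J)
      all_masked <- rowSums(!mask) == 0L
      if (any(all_masked))
        for (i in which(all_masked)) mask[i, sample.int(J, 1L)] <- FALSE
      G[mask] <- NA_real_
    }

    structure(list(samples = data.frame(sample_id = ids, sex = sex,
                                        stringsAsFactors = FALSE),
                   snps = snps, dosages = G, phenotypes = phenotypes,
                   truth = list(liability = L, theta = spec$theta,
                                pleiotropy = alpha, spec = spec)),
              class = "synth_cohort")
  })
}

#' Simulate paired two-sample GWAS summary statistics
#'
#' Generates exposure (SNP -> AD) and outcome (SNP -> metabolite) summary
#' statistics from non-overlapping samples of the generative model, for
#' exercising the two-sample MR estimators. Exposure betas are
#' `w_j + Normal(0, se_j^2)`, outcome betas
#' `theta * w_j + alpha_j + Normal(0, se_j^2)`, with GWAS-scale standard
#' errors `se_j = 1 / sqrt(2 f_j (1 - f_j) n)`. With `scramble_alleles =
#' TRUE` (default) the outcome table's alleles are emitted with random
#' effect/other orderings and strand flips so harmonization is exercised.
#'
#' @param spec a [generative_spec()].
#' @param n_exposure,n_outcome GWAS sample sizes (>= 2) for the SE scale.
#' @param seed seed; the two samples use derived, non-overlapping streams.
#' @param metabolite which metabolite in `spec$theta` to use (default
#'   first).
#' @param scramble_alleles randomize allele presentation in the outcome
#'   table.
#' @return list `exposure`, `outcome`: data.frames in the summary schema
#'   `snp`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `n`.
#' @export
simulate_summary_stats <- function(spec, n_exposure = 2e4, n_outcome = 2e4,
                                   seed = spec$seed,
                                   metabolite = names(spec$theta)[1L],
                                   scramble_alleles = TRUE) {
  stopifnot(inherits(spec, "generative_spec"))
  if (n_exposure < 2 || n_outcome < 2) stop("GWAS sample sizes must be >= 2")
  snps <- spec$snps
  if (is.null(snps$effect_allele)) {
    snps$effect_allele <- "A"; snps$other_allele <- "G"
  }
  theta <- spec$theta[[metabolite]]
  alpha <- rep(0, nrow(snps))
  if (!is.null(spec$pleiotropy))
    alpha[match(names(spec$pleiotropy), snps$id)] <- spec$pleiotropy

  se_of <- function(f, n) 1 / sqrt(2 * f * (1 - f) * n)
  with_local_seed(seed, {
    se_x <- se_of(snps$eaf, n_exposure)
    se_y <- se_of(snps$eaf, n_outcome)
    bx <- snps$weight + rnorm(nrow(snps), 0, se_x)
    by <- theta * snps$weight + alpha + rnorm(nrow(snps), 0, se_y)

    exposure <- data.frame(snp = snps$id,
                           effect_allele = snps$effect_allele,
                           other_allele = snps$other_allele,
                           beta = bx, se = se_x, eaf = snps$eaf,
                           n = n_exposure, stringsAsFactors = FALSE)
    outcome <- data.frame(snp = snps$id,
                          effect_allele = snps$effect_allele,
                          other_allele = snps$other_allele,
                          beta = by, se = se_y, eaf = snps$eaf,
                          n = n_outcome, stringsAsFactors = FALSE)
    if (scramble_alleles) {
      J <- nrow(outcome)
      do_swap <- runif(J) < 0.5
      do_flip <- runif(J) < 0.5
      pal <- .is_palindromic(outcome$effect_allele, outcome$other_allele)
      for (j in seq_len(J)) {
        if (do_swap[j]) {
          tmp <- outcome$effect_allele[j]
          outcome$effect_allele[j] <- outcome$other_allele[j]
          outcome$other_allele[j] <- tmp
          outcome$beta[j] <- -outcome$beta[j]
          outcome$eaf[j] <- 1 - outcome$eaf[j]
        }
        if (do_flip[j] && !pal[j]) {
          outcome$effect_allele[j] <- .flip_alleles(outcome$effect_allele[j])
          outcome$other_allele[j] <- .flip_alleles(outcome$other_allele[j])
        }
      }
    }
    list(exposure = exposure, outcome = outcome)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the dosage matrix (TSV, rows = samples, `NA` for missing), the
#' long phenotype table, and the SNP table to a directory.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dosages = file.path(dir, "dosages.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             snps = file.path(dir, "snps.tsv"))
  d <- data.frame(sample_id = rownames(cohort$dosages),
                  cohort$dosages, check.names = FALSE)
  write.table(d, paths["dosages"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$snps, paths["snps"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a dosage TSV written by [write_cohort()]
#' @param path TSV with a `sample_id` column and one column per SNP.
#' @return numeric matrix with sample ids as rownames.
#' @export
read_dosages <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  rownames(m) <- d$sample_id
  m
}
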
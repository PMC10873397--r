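#' Assign age tertiles
#'
#' Ranks samples by age and splits them into three contiguous strata of
#' near-equal size (sizes differ by at most one; the remainder goes to the
#' youngest strata first). Ties are broken by stable input order. Reported
#' bounds are the min/max observed age within each stratum.
#'
#' @param ages numeric vector, `n >= 3`.
#' @param labels stratum labels, youngest to oldest.
#' @return list with `assignment` (integer 1..3 per sample, in input
#'   order) and `strata` (data.frame label, n, age_min, age_max).
#' @export
assign_age_tertiles <- function(ages,
                                labels = c("youngest", "middle", "oldest")) {
  n <- length(ages)
  if (n < 3L) stop("need at least 3 samples to form tertiles")
  if (anyNA(ages)) stop("ages must be non-missing")
  sizes <- rep(n %/% 3L, 3L)
  rem <- n %% 3L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  o <- order(ages)                      # stable for ties
  grp_sorted <- rep.int(1:3, sizes)
  assignment <- integer(n)
  assignment[o] <- grp_sorted
  strata <- data.frame(
    label = labels,
    n = sizes,
    age_min = vapply(1:3, function(k) min(ages[assignment == k]), 0),
    age_max = vapply(1:3, function(k) max(ages[assignment == k]), 0),
    stringsAsFactors = FALSE)
  if (length(unique(ages)) == 1L)
    warning("all ages identical: tertile bounds coincide")
  list(assignment = assignment, strata = strata)
}

default_run_config <- function() {
  list(
    arms = c("grs", "mr", "apoe"),
    simulate = list(),          # generative_spec() arguments
    metabolites = NULL,         # default: all in spec theta
    grs_timepoints = NULL,      # default: all non-adult timepoints
    mr_timepoint = "adult",
    missing_policy = "rescale",
    palindrome_policy = "infer",
    ivw_model = "multiplicative_random",
    mr_methods = c("ivw", "egger", "weighted_median", "weighted_mode"),
    n_boot = 200,
    min_n = 30,
    min_group = 10,
    seed = 1L,
    out_dir = NULL
  )
}

#' Run the full life-course analysis pipeline
#'
#' Orchestrates the three analysis arms on a cohort:
#' \describe{
#'   \item{GRS arm}{per timepoint, rank-INT each metabolite and regress it
#'     on the with-APOE and without-APOE GRS, age- and sex-adjusted,
#'     ln2-scaled (the repeat-measures cohort design).}
#'   \item{MR arm}{at the adult timepoint, split samples into age
#'     tertiles, run a per-SNP metabolite GWAS within each tertile, and
#'     apply the MR estimator panel with and without the APOE SNPs (the
#'     age-stratified biobank design).}
#'   \item{APOE arm}{per stratum, epsilon4-carrier and epsilon2-carrier
#'     contrasts against epsilon3 homozygotes.}
#' }
#'
#' @param config a list (or path to a YAML file) overriding
#'   `default_run_config()`: arms, a `simulate` block of
#'   [generative_spec()] arguments (or `dosages`/`phenotypes`/`snps` paths
#'   to TSVs from [write_cohort()]), policies, seed, and optionally
#'   `out_dir` to write `results_grs.tsv`, `results_mr.tsv`,
#'   `results_apoe.tsv` and `provenance.json`.
#' @param cohort optionally, an already-simulated `synth_cohort` (overrides
#'   the `simulate`/paths blocks).
#' @param instrument optionally, an [instrument_table()]; defaults to the
#'   cohort's SNP table with the spec's weights.
#' @return list `results_grs`, `results_mr`, `results_apoe` (data.frames,
#'   `NULL` for arms not run), `provenance`, `log`.
#' @export
run_pipeline <- function(config = list(), cohort = NULL, instrument = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)

  if (is.null(cohort)) {
    if (!is.null(cfg$dosages)) {
      dos <- read_dosages(cfg$dosages)
      ph <- read.table(cfg$phenotypes, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      sn <- read.table(cfg$snps, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      cohort <- structure(list(
        samples = unique(ph[, c("sample_id", "sex")]),
        snps = sn, dosages = dos, phenotypes = ph, truth = NULL),
        class = "synth_cohort")
    } else {
      spec <- do.call(generative_spec,
                      utils::modifyList(list(seed = cfg$seed),
                                        cfg$simulate))
      cohort <- simulate_cohort(spec)
    }
  }
  if (is.null(instrument)) {
    sn <- cohort$snps
    instrument <- instrument_table(data.frame(
      snp = sn$id, effect_allele = sn$effect_allele %||% "A",
      other_allele = sn$other_allele %||% "G",
      beta = sn$weight, se = sn$se %||% abs(sn$weight) / 5,
      eaf = sn$eaf, stringsAsFactors = FALSE))
  }

  metabolites <- cfg$metabolites %||%
    setdiff(names(cohort$phenotypes),
            c("sample_id", "timepoint", "age", "sex"))
  tps <- unique(cohort$phenotypes$timepoint)
  grs_tps <- cfg$grs_timepoints %||% setdiff(tps, cfg$mr_timepoint)
  if (length(grs_tps) == 0L) grs_tps <- tps

  pheno_int <- transform_metabolites(cohort$phenotypes, metabolites)
  cohort_int <- cohort
  cohort_int$phenotypes <- pheno_int

  log <- list()
  note <- function(arm, stratum, metabolite, n, msg = "") {
    log[[length(log) + 1L]] <<- data.frame(
      arm = arm, stratum = stratum, metabolite = metabolite, n = n,
      note = msg, stringsAsFactors = FALSE)
  }

  res_grs <- res_mr <- res_apoe <- NULL

  run_arm <- function(arm, body) {
    tryCatch(body, error = function(e) {
      note(arm, "-", "-", 0L, paste("arm aborted:", conditionMessage(e)))
      NULL
    })
  }

  if ("grs" %in% cfg$arms) {
    res_grs <- run_arm("grs", {
      rows <- list()
      for (variant in c(TRUE, FALSE)) {
        grs <- compute_grs(cohort, instrument,
                           missing_policy = cfg$missing_policy,
                           include_apoe = variant)
        for (tp in grs_tps) for (m in metabolites) {
          est <- grs_metabolite_assoc(cohort_int, grs, m, timepoint = tp,
                                      min_n = cfg$min_n)
          est$arm <- "grs"
          est$apoe <- if (variant) "with" else "without"
          note("grs", tp, m, est$n)
          rows[[length(rows) + 1L]] <- est
        }
      }
      do.call(rbind, rows)
    })
  }

  if ("mr" %in% cfg$arms) {
    res_mr <- run_arm("mr", {
      ph_tp <- cohort$phenotypes[cohort$phenotypes$timepoint ==
                                   cfg$mr_timepoint, , drop = FALSE]
      if (nrow(ph_tp) == 0L)
        stop("no samples at MR timepoint ", cfg$mr_timepoint)
      tert <- assign_age_tertiles(ph_tp$age)
      rows <- list()
      for (k in 1:3) {
        ids <- ph_tp$sample_id[tert$assignment == k]
        lab <- tert$strata$label[k]
        # rank-INT within the stratum before the per-SNP GWAS
        strat_cohort <- cohort
        keep <- cohort$phenotypes$timepoint == cfg$mr_timepoint &
          cohort$phenotypes$sample_id %in% ids
        strat_ph <- cohort$phenotypes[keep, , drop = FALSE]
        strat_ph <- transform_metabolites(strat_ph, metabolites)
        strat_cohort$phenotypes <- strat_ph
        for (m in metabolites) {
          gw <- snp_metabolite_gwas(strat_cohort, instrument, m,
                                    timepoint = cfg$mr_timepoint)
          gw <- gw[!is.na(gw$beta), , drop = FALSE]
          panel <- run_mr_panel(instrument, gw, methods = cfg$mr_methods,
                                n_boot = cfg$n_boot,
                                seed = cfg$seed + 13L * k,
                                palindrome_policy = cfg$palindrome_policy)
          panel$arm <- "mr"
          panel$stratum <- lab
          panel$metabolite <- m
          note("mr", lab, m, length(ids))
          rows[[length(rows) + 1L]] <- panel
        }
      }
      do.call(rbind, rows)
    })
  }

  if ("apoe" %in% cfg$arms) {
    res_apoe <- run_arm("apoe", {
      dip <- classify_apoe(cohort$dosages[, "rs429358"],
                           cohort$dosages[, "rs7412"],
                           sample_id = rownames(cohort$dosages))
      rows <- list()
      for (tp in tps) for (m in metabolites)
        for (ct in c("e4_vs_e3e3", "e2_vs_e3e3")) {
          est <- tryCatch(
            apoe_contrast(cohort_int, dip, ct, m, timepoint = tp,
                          min_group = cfg$min_group),
            error = function(e) NULL)
          if (is.null(est)) {
            note("apoe", tp, m, 0L, paste(ct, "skipped"))
            next
          }
          est$arm <- "apoe"
          note("apoe", tp, m, est$n)
          rows[[length(rows) + 1L]] <- est
        }
      if (length(rows) == 0L) stop("no APOE contrasts estimable")
      do.call(rbind, rows)
    })
  }

  if (is.null(res_grs) && is.null(res_mr) && is.null(res_apoe))
    stop("pipeline produced no results")

  provenance <- list(
    package = "admetmr",
    version = as.character(utils::packageVersion("admetmr")),
    seed = cfg$seed,
    policies = list(missing = cfg$missing_policy,
                    palindromes = cfg$palindrome_policy,
                    ivw = cfg$ivw_model),
    arms = cfg$arms)

  out <- list(results_grs = res_grs, results_mr = res_mr,
              results_apoe = res_apoe, provenance = provenance,
              log = do.call(rbind, log))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("results_grs", "results_mr", "results_apoe"))
      if (!is.null(out[[nm]]))
        write.table(out[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
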
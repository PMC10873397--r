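mk_instrument <- function() {
  instrument_table(data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "C", "G", "A"),
    other_allele = c("G", "T", "C", "T"),   # rs3 C/G, rs4 A/T palindromic
    beta = c(0.1, 0.2, 0.15, 0.08),
    se = c(0.01, 0.02, 0.02, 0.01),
    eaf = c(0.3, 0.4, 0.2, 0.3), stringsAsFactors = FALSE))
}

test_that("harmonize flips swapped alleles and is idempotent", {
  ins <- mk_instrument()
  stats <- data.frame(snp = c("rs1", "rs2"),
                      effect_allele = c("G", "C"),
                      other_allele = c("A", "T"),
                      beta = c(0.2, -0.1), se = c(0.05, 0.05),
                      eaf = c(0.7, 0.4), stringsAsFactors = FALSE)
  h <- harmonize(ins, stats)
  r1 <- h[h$snp == "rs1", ]
  expect_equal(r1$beta, -0.2)          # sign symmetry under allele swap
  expect_equal(r1$effect_allele, "A")
  expect_equal(r1$eaf, 0.3)
  expect_equal(h[h$snp == "rs2", "beta"], -0.1)  # already aligned, untouched

  h2 <- harmonize(ins, h)
  strip_log <- function(d) { attr(d, "harmonization_log") <- NULL; d }
  expect_equal(strip_log(h2), strip_log(h))
})

test_that("harmonize complements strand-flipped rows", {
  ins <- mk_instrument()
  stats <- data.frame(snp = "rs1", effect_allele = "T", other_allele = "C",
                      beta = 0.3, se = 0.05, eaf = 0.3,
                      stringsAsFactors = FALSE)   # complement of A/G
  h <- harmonize(ins, stats)
  expect_equal(h$effect_allele, "A")
  expect_equal(h$beta, 0.3)

  # complemented AND swapped
  stats2 <- within(stats, { effect_allele <- "C"; other_allele <- "T" })
  h2 <- harmonize(ins, stats2)
  expect_equal(h2$beta, -0.3)
})

test_that("palindromic SNPs follow the EAF policy", {
  ins <- mk_instrument()
  pal <- function(eaf) data.frame(snp = "rs4", effect_allele = "A",
                                  other_allele = "T", beta = 0.5, se = 0.1,
                                  eaf = eaf, stringsAsFactors = FALSE)
  # frequency uninformative -> dropped (and only-row drop errors)
  expect_error(harmonize(ins, pal(0.5)), "no rows retained")
  # concordant informative frequency -> kept as-is
  h <- harmonize(ins, pal(0.3))
  expect_equal(h$beta, 0.5)
  # discordant frequency -> strand-flipped reading, sign reversed
  h2 <- harmonize(ins, pal(0.7))
  expect_equal(h2$beta, -0.5)
  expect_equal(h2$eaf, 0.3)
  # "drop" policy removes palindromic rows unconditionally
  expect_error(harmonize(ins, pal(0.3), palindrome_policy = "drop"),
               "no rows retained")
})

test_that("irreconcilable alleles are dropped with a logged reason", {
  ins <- mk_instrument()
  stats <- data.frame(snp = c("rs1", "rs2"),
                      effect_allele = c("A", "C"),
                      other_allele = c("C", "T"),  # rs1 A/C != A/G
                      beta = c(0.2, 0.1), se = c(0.05, 0.05),
                      eaf = c(0.3, 0.4), stringsAsFactors = FALSE)
  h <- harmonize(ins, stats)
  expect_equal(h$snp, "rs2")
  log <- attr(h, "harmonization_log")
  expect_match(log$action[log$snp == "rs1"], "irreconcilable")
  expect_error(harmonize(ins, stats[1, ]), "no rows retained")
})

test_that("proxy substitution carries weights and enforces thresholds", {
  ins <- mk_instrument()
  expect_equal(as.data.frame(apply_proxies(ins, ins$snp)),
               as.data.frame(ins))   # all available -> identity

  proxies <- data.frame(original_id = "rs2", proxy_id = "rs2p",
                        r2 = 0.9, distance_kb = 100)
  out <- apply_proxies(ins, c("rs1", "rs3", "rs4", "rs2p"), proxies)
  expect_true("rs2p" %in% out$snp)
  expect_equal(out$beta[out$snp == "rs2p"], 0.2)  # weight carried over
  expect_equal(nrow(out), 4)

  low <- data.frame(original_id = "rs2", proxy_id = "rs2p",
                    r2 = 0.5, distance_kb = 100)
  expect_warning(out2 <- apply_proxies(ins, c("rs1", "rs3", "rs4"), low),
                 "rejected")
  expect_true("rs2" %in% out2$snp)    # left missing, not substituted

  expect_warning(apply_proxies(ins, c("rs1", "rs3", "rs4")), "no proxy")
})

test_that("GRS is the weighted allele sum with the stated missingness policies", {
  ins <- instrument_table(data.frame(
    snp = c("s1", "s2"), effect_allele = c("A", "A"),
    other_allele = c("G", "G"), beta = c(0.1, 0.2), se = c(0.01, 0.01),
    eaf = c(0.3, 0.4)), apoe_ids = character(0))
  d <- matrix(c(2, 1, 2, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("i1", "i2"), c("s1", "s2")))
  g <- compute_grs(d, ins, "rescale")
  expect_equal(g$score, c(0.4, 0.2 * (0.3 / 0.1)))  # 0.4 and 0.6
  expect_equal(g$n_snps_used, c(2L, 1L))
  expect_equal(compute_grs(d, ins, "sum_observed")$score, c(0.4, 0.2))
  expect_equal(compute_grs(d, ins, "mean_impute")$score,
               c(0.4, 0.2 + 0.2 * 2 * 0.4))
})

test_that("GRS decomposes into APOE and non-APOE parts and is linear", {
  set.seed(41)
  ins <- test_instrument()
  spec <- generative_spec(n_samples = 300, snps = test_snp_table(ins),
                          timepoints = one_adult_timepoint, seed = 5)
  co <- simulate_cohort(spec)
  with_apoe <- compute_grs(co, ins, include_apoe = TRUE)
  without <- compute_grs(co, ins, include_apoe = FALSE)
  apoe_part <- co$dosages[, "rs429358"] * ins$beta[ins$snp == "rs429358"] +
    co$dosages[, "rs7412"] * ins$beta[ins$snp == "rs7412"]
  expect_equal(with_apoe$score - without$score, unname(apoe_part))

  ins2 <- ins; ins2$beta <- 2 * ins2$beta
  expect_equal(compute_grs(co, ins2)$score, 2 * with_apoe$score)

  shuffled <- ins[sample(nrow(ins)), ]
  expect_equal(compute_grs(co, shuffled)$score, with_apoe$score)
})

test_that("samples with no observed genotype are excluded from the GRS", {
  ins <- instrument_table(data.frame(
    snp = c("s1", "s2"), effect_allele = c("A", "A"),
    other_allele = c("G", "G"), beta = c(0.1, 0.2), se = c(0.01, 0.01)),
    apoe_ids = character(0))
  d <- matrix(c(1, 1, NA, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("ok", "empty"), c("s1", "s2")))
  g <- compute_grs(d, ins)
  expect_equal(g$sample_id, "ok")
  expect_equal(attr(g, "excluded"), "empty")
  expect_error(
    compute_grs(matrix(0, 2, 1, dimnames = list(NULL, "zz")), ins),
    "overlap")
})

test_that("APOE diplotype lookup matches the epsilon haplotype table", {
  cases <- data.frame(
    c4 = c(0, 0, 0, 1, 2, 1, 1, 2, 2),
    t2 = c(0, 1, 2, 0, 0, 1, 2, 1, 2),
    dip = c("e3/e3", "e2/e3", "e2/e2", "e3/e4", "e4/e4", "e2/e4",
            "rare", "rare", "rare"),
    grp = c("e3e3", "e2_carrier", "e2_carrier", "e4_carrier", "e4_carrier",
            "excluded", "excluded", "excluded", "excluded"))
  out <- classify_apoe(cases$c4, cases$t2)
  expect_equal(out$diplotype, cases$dip)
  expect_equal(out$group, cases$grp)
})

test_that("APOE hard-calling and grouping are a partition", {
  out <- classify_apoe(c(1.05, 1.3, NA), c(0, 0, 0))
  expect_equal(out$diplotype, c("e3/e4", "unclassifiable", "unclassifiable"))
  expect_equal(out$group[2:3], c("excluded", "excluded"))

  set.seed(51)
  dip <- classify_apoe(sample(0:2, 500, TRUE), sample(0:2, 500, TRUE))
  expect_true(all(dip$group %in% c("e4_carrier", "e2_carrier", "e3e3",
                                   "excluded")))
  # no sample in two groups by construction; e2/e4 goes to neither contrast
  expect_true(all(dip$group[dip$diplotype == "e2/e4"] == "excluded"))
})
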
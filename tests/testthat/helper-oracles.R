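# Independent oracles and small fixtures used across the suite.

# Random harmonized pair with GWAS-plausible magnitudes.
random_pair <- function(J, seed) {
  set.seed(seed)
  g <- runif(J, 0.03, 1.2) * sample(c(-1, 1), J, replace = TRUE)
  harmonized_pair(
    beta_exposure = g,
    se_exposure = runif(J, 0.005, 0.05),
    beta_outcome = 0.1 * g + rnorm(J, 0, 0.02),
    se_outcome = runif(J, 0.005, 0.05))
}

# IVW oracle: numeric minimization of the weighted residual sum of squares
# of the no-intercept model, independent of the closed form.
oracle_ivw <- function(pair) {
  w <- 1 / pair$se_outcome^2
  ss <- function(b) sum(w * (pair$beta_outcome - b * pair$beta_exposure)^2)
  wide <- max(abs(pair$beta_outcome / pair$beta_exposure)) + 1
  grid <- seq(-wide, wide, length.out = 4001)
  b0 <- grid[which.max(-vapply(grid, ss, 0))]
  step <- grid[2] - grid[1]
  optimize(ss, c(b0 - step, b0 + step), tol = 1e-12)$minimum
}

# Egger oracle: R's own weighted least squares via lm(), with the same
# orientation rule and the floored SE inflation applied on top.
oracle_egger <- function(pair) {
  s <- sign(pair$beta_exposure); s[s == 0] <- 1
  d <- data.frame(x = pair$beta_exposure * s, y = pair$beta_outcome * s,
                  w = 1 / pair$se_outcome^2)
  fit <- lm(y ~ x, data = d, weights = w)
  sm <- summary(fit)
  infl <- max(1, sm$sigma)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(coef(sm)[1, 2] / sm$sigma * infl),
       se_slope = unname(coef(sm)[2, 2] / sm$sigma * infl))
}

# Weighted-median oracle: plain transliteration of the cumulative-midpoint
# interpolation formula.
oracle_wmedian <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]; w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(b[1])
  J <- length(b)
  if (p[J] <= 0.5) return(b[J])
  k <- max(which(p < 0.5))
  b[k] + (0.5 - p[k]) / (p[k + 1] - p[k]) * (b[k + 1] - b[k])
}

# Weighted-mode oracle: exhaustive fine-grid argmax of the weighted KDE
# with the same modified-Silverman bandwidth.
oracle_wmode <- function(ratios, weights, phi = 1, grid_n = 20001) {
  w <- weights / sum(weights)
  mu <- sum(w * ratios)
  sd_w <- sqrt(sum(w * (ratios - mu)^2))
  qs <- oracle_wquant(ratios, w, c(0.25, 0.75))
  s <- min(sd_w, (qs[2] - qs[1]) / 1.349)
  if (s <= 0) s <- sd_w
  h <- phi * 0.9 * s * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratios) / h)), 0)
  list(mode = grid[which.max(dens)], resolution = grid[2] - grid[1])
}

oracle_wquant <- function(b, w, probs) {
  o <- order(b); b <- b[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  vapply(probs, function(q) {
    if (q <= p[1]) return(b[1])
    if (q >= p[length(p)]) return(b[length(b)])
    k <- max(which(p < q))
    b[k] + (q - p[k]) / (p[k + 1] - p[k]) * (b[k + 1] - b[k])
  }, 0)
}

# 25-SNP synthetic instrument shared by the simulation-based tests.
test_instrument <- function() example_instrument()

test_snp_table <- function(ins = test_instrument()) {
  data.frame(id = ins$snp, eaf = ins$eaf, weight = ins$beta,
             effect_allele = ins$effect_allele,
             other_allele = ins$other_allele, stringsAsFactors = FALSE)
}

one_adult_timepoint <- list(list(label = "adult", age_min = 39, age_max = 73))
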
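#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with non-zero counts in every sample) of the ratio between the
#' sample's count and the gene's geometric mean across samples. Factors are
#' not rescaled afterwards.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  check_counts(counts)
  use <- rowSums(counts == 0) == 0
  if (!any(use))
    stop("no gene with non-zero counts in all samples", call. = FALSE)
  loggm <- rowMeans(log(counts[use, , drop = FALSE]))
  sf <- apply(log(counts[use, , drop = FALSE]), 2,
              function(col) exp(stats::median(col - loggm)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factor estimation failed", call. = FALSE)
  sf
}

# Method-of-moments dispersion on normalized counts, pooled within conditions.
# Returns the raw (possibly negative) estimate alongside the group means.
moment_dispersion <- function(norm, iA, iB) {
  nA <- length(iA); nB <- length(iB)
  mA <- rowMeans(norm[, iA, drop = FALSE])
  mB <- rowMeans(norm[, iB, drop = FALSE])
  m <- rowMeans(norm)
  ss <- rowSums((norm[, iA, drop = FALSE] - mA)^2) +
    rowSums((norm[, iB, drop = FALSE] - mB)^2)
  s2 <- ss / (nA + nB - 2)
  raw <- ifelse(m > 0, (s2 - m) / m^2, NA_real_)
  list(m = m, mA = mA, mB = mB, raw = raw)
}

fit_dispersion_trend <- function(raw, m) {
  ok <- is.finite(raw) & m > 0
  # evaluate on a floored mean so all-zero genes get a finite trend value
  m_floor <- pmax(m, min(m[m > 0]))
  if (sum(ok) < 10) {
    # too few genes for a trend: fall back to a flat robust location
    a0 <- max(stats::median(raw[ok], na.rm = TRUE), 1e-8)
    return(list(value = rep(a0, length(m)), coef = c(a0, 0)))
  }
  fit <- suppressWarnings(MASS::rlm(raw[ok] ~ I(1 / m[ok]), maxit = 100))
  co <- stats::coef(fit)
  list(value = pmin(pmax(co[2] / m_floor + co[1], 1e-8), 100), coef = co)
}

# Spread (squared MAD) of log gene-wise estimates around the log trend,
# over genes with a positive gene-wise estimate.
log_residual_spread <- function(raw, trend) {
  a <- pmax(raw, 0)
  ok <- is.finite(a) & a > 0
  stats::mad(log(a[ok]) - log(trend[ok]))^2
}

#' Gene-wise, trend and shrunk negative-binomial dispersions
#'
#' Gene-wise dispersions are method-of-moments estimates
#' \code{max(0, (s2 - m) / m^2)} on size-factor-normalized counts with
#' variance pooled within conditions. A robust trend
#' \code{alpha(mu) = a1/mu + a0} is fitted across genes. Because the moment
#' estimator is biased at small replicate numbers, one parametric NB
#' resample is drawn under the fitted trend: the trend refitted on the
#' resample measures (i) the multiplicative bias of the trend, which is then
#' corrected, and (ii) the pure sampling spread of log gene-wise estimates.
#' The final estimate shrinks log gene-wise values toward the corrected log
#' trend with adaptive weight \code{prior_var / (prior_var + sampling_var)},
#' where \code{prior_var} is the excess of the observed spread over the
#' sampling spread — so for dispersion-homogeneous data the trend dominates,
#' while genuine gene-to-gene dispersion differences retain weight. All
#' values are floored at 1e-8.
#'
#' @param counts non-negative integer count matrix.
#' @param sf size factors from \code{\link{estimate_size_factors}}.
#' @param condition "A"/"B" labels per sample.
#' @param mc_seed seed for the internal calibration resample (the caller's
#'   RNG state is restored afterwards).
#' @return data.frame with columns \code{gene_id, genewise, trend, final};
#'   the shrinkage weight and trend coefficients are attached as attributes.
#' @export
estimate_dispersion <- function(counts, sf, condition, mc_seed = 1L) {
  check_counts(counts)
  condition <- check_condition(condition, ncol(counts))
  if (all(counts == 0)) stop("all-zero count matrix", call. = FALSE)
  norm <- sweep(counts, 2, sf, "/")
  iA <- which(condition == "A"); iB <- which(condition == "B")
  est <- moment_dispersion(norm, iA, iB)
  tr0 <- fit_dispersion_trend(est$raw, est$m)

  # parametric resample under the uncorrected trend
  old_state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(mc_seed))
  n <- nrow(counts)
  sim <- vapply(seq_along(sf), function(j)
    stats::rnbinom(n, mu = sf[j] * est$m, size = 1 / pmax(tr0$value, 1e-8)),
    numeric(n))
  if (is.null(old_state)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old_state, envir = globalenv())

  est_sim <- moment_dispersion(sweep(sim, 2, sf, "/"), iA, iB)
  tr_sim <- fit_dispersion_trend(est_sim$raw, est_sim$m)
  rho <- stats::median(tr_sim$value / tr0$value, na.rm = TRUE)
  trend <- pmax(tr0$value / max(rho, 0.2), 1e-8)

  samp_var <- log_residual_spread(est_sim$raw, tr0$value)
  obs_var <- log_residual_spread(est$raw, trend)
  if (!is.finite(samp_var) || samp_var <= 0) samp_var <- 1e-4
  prior_var <- max(obs_var - samp_var, 0)
  w <- prior_var / (prior_var + samp_var)

  genewise <- pmax(ifelse(is.finite(est$raw), est$raw, 0), 0)
  shrink_in <- pmax(genewise, trend * exp(-2 * sqrt(samp_var)), 1e-8)
  final <- pmax(exp(w * log(shrink_in) + (1 - w) * log(trend)), 1e-8)

  out <- data.frame(gene_id = rownames(counts), genewise = genewise,
                    trend = trend, final = final, stringsAsFactors = FALSE)
  attr(out, "shrink_weight") <- w
  attr(out, "trend_coef") <- tr0$coef
  attr(out, "trend_bias") <- rho
  out
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per gene, condition means are estimated on size-factor-normalized counts;
#' \code{log2fc = log2(mu_B / mu_A)} (condition B versus A). When one
#' condition's mean is zero, a pseudo-count of 0.5 normalized counts is
#' added to both means so exclusive genes get large finite fold changes. The
#' standard error comes from the delta method under the NB variance
#' \code{Var(K/sf) = q/sf + alpha*q^2} with the final shrunk dispersion, the
#' two-sided p-value from the standard normal, and adjusted p-values by
#' Benjamini-Hochberg. Genes with zero counts everywhere are reported with
#' \code{log2fc = 0, p = 1} and flagged in the \code{all_zero} column.
#'
#' @param counts non-negative integer count matrix.
#' @param sf size factors.
#' @param disp dispersion table from \code{\link{estimate_dispersion}}.
#' @param condition "A"/"B" labels per sample.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame with columns \code{gene_id, base_mean, log2fc, lfc_se,
#'   stat, pvalue, padj, significant, all_zero}.
#' @export
nb_wald_test <- function(counts, sf, disp, condition, alpha = 0.05) {
  check_counts(counts)
  condition <- check_condition(condition, ncol(counts))
  if (length(unique(condition)) != 2)
    stop("both conditions must be present", call. = FALSE)
  norm <- sweep(counts, 2, sf, "/")
  iA <- which(condition == "A"); iB <- which(condition == "B")
  nA <- length(iA); nB <- length(iB)
  qA <- rowMeans(norm[, iA, drop = FALSE])
  qB <- rowMeans(norm[, iB, drop = FALSE])
  base_mean <- rowMeans(norm)
  a_fin <- disp$final[match(rownames(counts), disp$gene_id)]

  all_zero <- qA == 0 & qB == 0
  zero_group <- (qA == 0) != (qB == 0)
  qA2 <- ifelse(zero_group, qA + 0.5, qA)
  qB2 <- ifelse(zero_group, qB + 0.5, qB)

  log2fc <- ifelse(all_zero, 0, log2(qB2 / qA2))
  invA <- sum(1 / sf[iA]); invB <- sum(1 / sf[iB])
  vlog <- function(q, n, inv) (q * inv / n^2 + a_fin * q^2 / n) /
    (q^2 * log(2)^2)
  se <- sqrt(vlog(qA2, nA, invA) + vlog(qB2, nB, invB))
  stat <- ifelse(all_zero | se == 0, 0, log2fc / se)
  pvalue <- ifelse(all_zero, 1, 2 * stats::pnorm(-abs(stat)))
  padj <- adjust_bh(pvalue)
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, lfc_se = ifelse(all_zero, NA_real_, se),
             stat = stat, pvalue = pvalue, padj = padj,
             significant = padj < alpha, all_zero = all_zero,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up procedure: sorted p-values are scaled by m/rank and a
#' running minimum is taken from the largest down, capped at 1. Output is
#' returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order as the input.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}
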
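#' Closed-form power for two-group RNA-seq differential expression
#'
#' Normal-approximation power for detecting a fold change \code{effect}
#' between two groups of \code{n} replicates each, given sequencing depth
#' (expected counts per gene) and biological coefficient of variation:
#' \deqn{power = \Phi\left(\sqrt{\frac{n \ln^2(effect)}
#'   {2 (1/depth + cv^2)}} - z_{1-\alpha/2}\right)}
#' The per-group variance of the log mean is \code{(1/depth + cv^2) / n},
#' i.e. shot noise plus biological variability. No multiple-testing
#' adjustment is applied inside the formula.
#'
#' @param depth expected counts per gene (> 0).
#' @param cv biological coefficient of variation (>= 0).
#' @param effect fold change (> 0, != 1 for non-degenerate power).
#' @param n replicates per group (> 0).
#' @param alpha two-sided test size (default 0.05).
#' @return power in (0, 1). Vectorized over all arguments.
#' @export
de_power <- function(depth, cv, effect, n, alpha = 0.05) {
  if (any(effect <= 0)) stop("effect must be positive", call. = FALSE)
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(cv < 0)) stop("cv must be non-negative", call. = FALSE)
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)",
                                         call. = FALSE)
  z_a <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(n * log(effect)^2 / (2 * (1 / depth + cv^2))) - z_a)
}

#' Smallest per-group sample size reaching a target power
#'
#' Returns the smallest integer \code{n} such that
#' \code{de_power(depth, cv, effect, n, alpha) >= power}.
#'
#' @inheritParams de_power
#' @param power target power in (alpha, 1).
#' @param n_max largest n considered before declaring the power unreachable.
#' @return integer sample size per group.
#' @export
de_sample_size <- function(depth, cv, effect, alpha = 0.05, power = 0.8,
                           n_max = 1e6L) {
  if (effect == 1) stop("effect must differ from 1", call. = FALSE)
  if (power <= alpha || power >= 1)
    stop("power must be in (alpha, 1)", call. = FALSE)
  z_a <- stats::qnorm(1 - alpha / 2)
  z_p <- stats::qnorm(power)
  n <- max(1, floor(2 * (z_a + z_p)^2 * (1 / depth + cv^2) / log(effect)^2))
  while (n > 1 && de_power(depth, cv, effect, n - 1, alpha) >= power)
    n <- n - 1
  while (de_power(depth, cv, effect, n, alpha) < power) {
    n <- n + 1
    if (n > n_max) stop("target power unreachable within n_max",
                        call. = FALSE)
  }
  as.integer(n)
}

#' Monte-Carlo power estimate for the two-group NB Wald test
#'
#' Simulation oracle for \code{\link{de_power}}, faithful to the closed
#' form's model: \code{depth} is the expected per-gene count at equal
#' expression and the fold change splits symmetrically, so the two groups
#' have means \code{depth * effect^(-1/2)} and \code{depth * effect^(1/2)}
#' (the same convention the count simulator uses for differential genes).
#' Each of \code{n_genes} independent genes is drawn NB with dispersion
#' \code{cv^2}; the log ratio of sample means is standardized by the design
#' standard error \code{sqrt(2 * (1/depth + cv^2) / n)} and compared to the
#' two-sided normal critical value.
#'
#' @inheritParams de_power
#' @param n_genes number of simulated genes (default 10000).
#' @param seed integer seed.
#' @return empirical power in [0, 1].
#' @export
de_power_mc <- function(depth, cv, effect, n, alpha = 0.05,
                        n_genes = 10000L, seed = 1L) {
  set.seed(as.integer(seed))
  draw <- function(mu) {
    if (cv > 0) matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / cv^2),
                       n_genes, n)
    else matrix(stats::rpois(n_genes * n, mu), n_genes, n)
  }
  mA <- pmax(rowMeans(draw(depth / sqrt(effect))), 0.5 / n)
  mB <- pmax(rowMeans(draw(depth * sqrt(effect))), 0.5 / n)
  se <- sqrt(2 * (1 / depth + cv^2) / n)
  z <- log(mB / mA) / se
  mean(abs(z) > stats::qnorm(1 - alpha / 2))
}
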
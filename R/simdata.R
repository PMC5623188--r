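#' Simulation configuration for a two-condition ganglion RNA-seq experiment
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' Defaults emulate the neuron-enriched DRG (condition A) versus trigeminal
#' (condition B) design: 6 vs 4 biological replicates, negative-binomial
#' counts with a shared dispersion, and a gene universe mixing commonly
#' expressed genes, twofold differentially expressed genes, genes exclusive
#' to one ganglion, glial contaminants carried in only by non-neuronal
#' admixture, and silent genes.
#'
#' @param n_genes number of genes to simulate.
#' @param n_reps_a,n_reps_b replicates per condition (each must be >= 2,
#'   the presence-call rule needs two replicates).
#' @param class_proportions named numeric vector over
#'   \code{common, de_up_a, de_up_b, exclusive_a, exclusive_b,
#'   glial_contaminant, silent}; non-negative, summing to 1.
#' @param baseline_mean_log_range range (natural-log scale) from which true
#'   baseline count means are drawn log-uniformly.
#' @param de_log2fc_magnitude true |log2 fold change| of the de classes.
#' @param dispersion shared NB dispersion alpha (variance = mu + alpha*mu^2);
#'   0 gives Poisson counts.
#' @param library_size_range range of library sizes, drawn log-uniformly;
#'   only the relative sizes matter downstream.
#' @param gene_length_range range (bp) of annotated gene lengths.
#' @param contamination_fraction fraction of condition-A counts originating
#'   from a glial expression profile, in [0, 1].
#' @param contamination_asymmetry multiplier applied to
#'   \code{contamination_fraction} in condition B. The two ganglia differ in
#'   their non-neuronal composition, so admixture is modelled as asymmetric;
#'   1 gives equal contamination on both sides.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_reps_a = 6L,
                       n_reps_b = 4L,
                       class_proportions = c(common = 0.70, de_up_a = 0.05,
                                             de_up_b = 0.05, exclusive_a = 0.03,
                                             exclusive_b = 0.03,
                                             glial_contaminant = 0.04,
                                             silent = 0.10),
                       baseline_mean_log_range = log(c(20, 2000)),
                       de_log2fc_magnitude = 1,
                       dispersion = 0.2,
                       library_size_range = c(8e5, 1.2e6),
                       gene_length_range = c(500L, 5000L),
                       contamination_fraction = 0,
                       contamination_asymmetry = 0.5,
                       seed = 1L) {
  classes <- c("common", "de_up_a", "de_up_b", "exclusive_a", "exclusive_b",
               "glial_contaminant", "silent")
  p <- class_proportions[classes]
  names(p) <- classes
  p[is.na(p)] <- 0
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must be non-negative and sum to 1", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (n_reps_a < 2 || n_reps_b < 2)
    stop("each condition needs at least 2 replicates", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop("contamination_fraction must be in [0, 1]", call. = FALSE)
  if (de_log2fc_magnitude <= 0)
    stop("de_log2fc_magnitude must be positive", call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes),
              n_reps_a = as.integer(n_reps_a), n_reps_b = as.integer(n_reps_b),
              class_proportions = p,
              baseline_mean_log_range = baseline_mean_log_range,
              de_log2fc_magnitude = de_log2fc_magnitude,
              dispersion = dispersion,
              library_size_range = library_size_range,
              gene_length_range = as.integer(gene_length_range),
              contamination_fraction = contamination_fraction,
              contamination_asymmetry = contamination_asymmetry,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Largest-remainder apportionment: class counts match proportions exactly.
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic two-condition experiment with ground truth
#'
#' Draws NB counts gene by gene. Genes are assigned to classes by the
#' largest-remainder method so truth counts match the configured proportions
#' exactly. Exclusive genes have literal zero mean in the off condition;
#' glial-contaminant genes have zero neuronal mean and enter only through the
#' admixture term; expected counts for gene g in sample j are
#' \code{s_j * ((1 - f_j) * mu_neuronal(g, cond_j) + f_j * mu_glial(g))}
#' where \code{s_j} is the relative library size and \code{f_j} the
#' condition's contamination fraction.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return a list of class \code{"sim_experiment"} with elements
#'   \code{counts} (integer matrix, genes x samples), \code{condition}
#'   (character vector "A"/"B" per sample), \code{annotation} (data.frame:
#'   gene_id, symbol, length_bp, family), \code{truth} (data.frame: gene_id,
#'   symbol, true_class, true_log2fc with B-vs-A orientation and +/-Inf for
#'   exclusives, neuronal), \code{reference} (character vector of gene ids)
#'   and \code{comparison} (ortholog FPKM table, concordant fraction 0.9).
#' @export
generate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_genes
  nA <- config$n_reps_a; nB <- config$n_reps_b
  counts_by_class <- largest_remainder(n, config$class_proportions)
  true_class <- rep(names(config$class_proportions), counts_by_class)

  gene_id <- sprintf("SIMG%05d", seq_len(n))
  symbol <- sprintf("Sim%04d", seq_len(n))
  length_bp <- as.integer(round(stats::runif(n, config$gene_length_range[1],
                                             config$gene_length_range[2])))
  family <- ifelse(true_class == "glial_contaminant", "glial", "")

  lo <- config$baseline_mean_log_range[1]
  hi <- config$baseline_mean_log_range[2]
  base_mu <- exp(stats::runif(n, lo, hi))
  # glial profiles from the upper half of the range: satellite-glia markers
  # are highly expressed, and must survive dilution by the admixture fraction
  glial <- true_class == "glial_contaminant"
  base_mu[glial] <- exp(stats::runif(sum(glial), (lo + hi) / 2, hi))

  mag <- config$de_log2fc_magnitude
  half <- 2^(mag / 2)
  mu_a <- base_mu; mu_b <- base_mu        # neuronal means per condition
  true_log2fc <- numeric(n)               # B vs A orientation
  cls <- true_class
  mu_a[cls == "de_up_a"] <- base_mu[cls == "de_up_a"] * half
  mu_b[cls == "de_up_a"] <- base_mu[cls == "de_up_a"] / half
  true_log2fc[cls == "de_up_a"] <- -mag
  mu_a[cls == "de_up_b"] <- base_mu[cls == "de_up_b"] / half
  mu_b[cls == "de_up_b"] <- base_mu[cls == "de_up_b"] * half
  true_log2fc[cls == "de_up_b"] <- mag
  mu_b[cls == "exclusive_a"] <- 0
  true_log2fc[cls == "exclusive_a"] <- -Inf
  mu_a[cls == "exclusive_b"] <- 0
  true_log2fc[cls == "exclusive_b"] <- Inf
  mu_a[cls == "silent" | glial] <- 0
  mu_b[cls == "silent" | glial] <- 0
  mu_glial <- ifelse(glial, base_mu, 0)

  lib <- exp(stats::runif(nA + nB, log(config$library_size_range[1]),
                          log(config$library_size_range[2])))
  s <- lib / mean(lib)
  condition <- rep(c("A", "B"), c(nA, nB))
  f <- ifelse(condition == "A", config$contamination_fraction,
              config$contamination_fraction * config$contamination_asymmetry)

  counts <- matrix(0L, n, nA + nB,
                   dimnames = list(gene_id,
                                   paste0(condition, "_",
                                          c(seq_len(nA), seq_len(nB)))))
  for (j in seq_len(nA + nB)) {
    mu_cond <- if (condition[j] == "A") mu_a else mu_b
    ev <- s[j] * ((1 - f[j]) * mu_cond + f[j] * mu_glial)
    counts[, j] <- if (config$dispersion > 0)
      stats::rnbinom(n, mu = ev, size = 1 / config$dispersion)
    else stats::rpois(n, ev)
  }

  truth <- data.frame(gene_id = gene_id, symbol = symbol,
                      true_class = true_class, true_log2fc = true_log2fc,
                      neuronal = !glial, stringsAsFactors = FALSE)
  annotation <- data.frame(gene_id = gene_id, symbol = symbol,
                           length_bp = length_bp, family = family,
                           stringsAsFactors = FALSE)
  out <- list(counts = counts, condition = condition,
              annotation = annotation, truth = truth,
              reference = generate_reference_presence(truth),
              comparison = generate_comparison(truth, 0.9,
                                               seed = config$seed + 1L),
              config = config)
  class(out) <- "sim_experiment"
  out
}

#' Reference presence set from a truth table
#'
#' Emulates a presence list derived from a pure-neuron (magnetically sorted)
#' reference dataset: it contains exactly the neuronal, non-silent genes, so
#' glial contaminants are absent by construction.
#'
#' @param truth truth table as produced by \code{\link{generate_counts}}.
#' @return character vector of gene ids.
#' @export
generate_reference_presence <- function(truth) {
  truth$gene_id[truth$neuronal & truth$true_class != "silent"]
}

#' Synthetic ortholog comparison dataset with configurable concordance
#'
#' Produces mean FPKM pairs for a second (e.g. human whole-ganglion) dataset
#' keyed by upper-cased symbol. For each truly differential or exclusive
#' gene the comparison ratio carries the same direction as the truth with
#' probability \code{concordant_fraction}, otherwise the opposite direction.
#' Non-differential genes get equal FPKM in both conditions (a tie, which
#' trend concordance counts as not same-trend); silent genes get zero.
#'
#' @param truth truth table.
#' @param concordant_fraction probability in [0, 1] that a differential
#'   gene's direction is reproduced.
#' @param seed integer seed.
#' @return data.frame with columns \code{ortholog_key, fpkm_a, fpkm_b}.
#' @export
generate_comparison <- function(truth, concordant_fraction, seed = 1L) {
  if (concordant_fraction < 0 || concordant_fraction > 1)
    stop("concordant_fraction must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(truth)
  base <- exp(stats::runif(n, log(1), log(100)))
  fpkm_a <- base
  fpkm_b <- base
  de <- truth$true_class %in% c("de_up_a", "de_up_b",
                                "exclusive_a", "exclusive_b")
  sgn <- sign(truth$true_log2fc)               # B vs A
  keep <- stats::runif(n) < concordant_fraction
  sgn[de & !keep] <- -sgn[de & !keep]
  fold <- ifelse(grepl("^exclusive", truth$true_class), 2^2, 2^1)
  fpkm_a[de] <- base[de] * fold[de]^(-sgn[de] / 2)
  fpkm_b[de] <- base[de] * fold[de]^(sgn[de] / 2)
  silent <- truth$true_class == "silent"
  fpkm_a[silent] <- 0; fpkm_b[silent] <- 0
  data.frame(ortholog_key = toupper(truth$symbol),
             fpkm_a = fpkm_a, fpkm_b = fpkm_b, stringsAsFactors = FALSE)
}

#' Write a simulated experiment to TSV files
#'
#' Writes counts, annotation, truth, reference presence list (one id per
#' line) and the comparison table into a directory using the pipeline's
#' tab-separated interchange formats.
#'
#' @param exp a \code{"sim_experiment"}.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_experiment <- function(exp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"),
             reference = file.path(dir, "reference_presence.txt"),
             comparison = file.path(dir, "comparison.tsv"),
             condition = file.path(dir, "conditions.tsv"))
  write_counts_tsv(exp$counts, paths["counts"])
  write_tsv(exp$annotation, paths["annotation"])
  write_tsv(exp$truth, paths["truth"])
  writeLines(exp$reference, paths["reference"])
  write_tsv(exp$comparison, paths["comparison"])
  write_tsv(data.frame(sample = colnames(exp$counts),
                       condition = exp$condition), paths["condition"])
  invisible(paths)
}
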
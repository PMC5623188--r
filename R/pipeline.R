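# --- TSV / JSON interchange --------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' Tab-separated, header row with sample names, first column \code{gene_id},
#' no quoting.
#'
#' @param counts matrix with gene ids as rownames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV with first column \code{gene_id} and one column per
#'   sample.
#' @return integer matrix with gene ids as rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read a gene annotation table
#'
#' @param path TSV with columns \code{gene_id, symbol, length_bp} and
#'   optionally \code{family}.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a reference presence set (one gene id per line)
#'
#' @param path text file path.
#' @return character vector of gene ids.
#' @export
read_reference_presence <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Read an ortholog comparison FPKM table
#'
#' @param path TSV with columns \code{ortholog_key, fpkm_a, fpkm_b}.
#' @return data.frame.
#' @export
read_comparison_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# --- validation --------------------------------------------------------------

#' Validate pipeline inputs
#'
#' Checks a count matrix, condition labels and annotation for structural
#' problems and returns machine-readable findings rather than raising
#' errors. Codes: \code{DUP_GENE} (duplicate gene id), \code{NEG_COUNT}
#' (negative entry), \code{NON_INTEGER} (non-integral entry),
#' \code{BAD_CONDITION} (labels missing, unknown, or a condition with fewer
#' than two replicates), \code{MISSING_LENGTH} (gene without annotated
#' length), \code{BAD_LENGTH} (length < 1).
#'
#' @param counts count matrix.
#' @param condition condition labels per sample.
#' @param annotation annotation data.frame.
#' @return data.frame with columns \code{code} and \code{message}; zero rows
#'   means valid.
#' @export
validate_inputs <- function(counts, condition, annotation) {
  findings <- list()
  add <- function(code, msg) findings[[length(findings) + 1]] <<-
    data.frame(code = code, message = msg, stringsAsFactors = FALSE)

  if (anyDuplicated(rownames(counts)))
    add("DUP_GENE", paste("duplicate gene ids in counts:",
        paste(unique(rownames(counts)[duplicated(rownames(counts))])[1:3],
              collapse = ", ")))
  if (anyDuplicated(annotation$gene_id))
    add("DUP_GENE", "duplicate gene ids in annotation")
  if (any(counts < 0)) add("NEG_COUNT", "negative count entries present")
  if (any(counts != round(counts)))
    add("NON_INTEGER", "non-integral count entries present")
  cond <- as.character(condition)
  if (length(cond) != ncol(counts))
    add("BAD_CONDITION", "number of condition labels != number of samples")
  else if (!all(cond %in% c("A", "B")))
    add("BAD_CONDITION", "condition labels must be 'A' or 'B'")
  else if (any(table(factor(cond, c("A", "B"))) < 2))
    add("BAD_CONDITION", "each condition needs at least 2 replicates")
  missing_len <- setdiff(rownames(counts), annotation$gene_id)
  if (length(missing_len))
    add("MISSING_LENGTH", paste("genes without annotated length:",
                                paste(utils::head(missing_len, 3),
                                      collapse = ", ")))
  if (any(annotation$length_bp < 1, na.rm = TRUE) ||
      any(is.na(annotation$length_bp)))
    add("BAD_LENGTH", "annotation length_bp must be >= 1")
  if (length(findings) == 0)
    data.frame(code = character(0), message = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, findings)
}

# --- orchestration -----------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Chains the stages: simulate (or load) -> validate -> FPKM -> presence
#' calls -> size factors -> dispersion -> NB Wald test -> classification ->
#' concordance, writes every stage output as TSV/JSON into \code{outdir} if
#' given, and returns a consolidated report. Deterministic given the seed.
#'
#' @param sim a \code{\link{sim_config}} to generate inputs, or NULL when
#'   real inputs are passed.
#' @param counts,condition,annotation,reference,comparison real inputs (used
#'   only when \code{sim} is NULL); \code{reference} and \code{comparison}
#'   are optional.
#' @param min_fpkm,min_replicates,strict_gt presence-call parameters.
#' @param alpha adjusted-p significance level.
#' @param fold_threshold fold threshold for trend concordance.
#' @param top_k number of top genes for presence agreement (capped at the
#'   gene count).
#' @param outdir output directory, or NULL to skip writing files.
#' @param seed integer seed (overrides the sim config's seed when
#'   simulating).
#' @return list of class \code{"ganglia_report"} with elements
#'   \code{detected, classification_summary, concordance, de, classification,
#'   calls, fpkm, parameters, version, timing_sec} (plus \code{truth} when
#'   simulated).
#' @export
run_pipeline <- function(sim = NULL, counts = NULL, condition = NULL,
                         annotation = NULL, reference = NULL,
                         comparison = NULL, min_fpkm = 1,
                         min_replicates = 2L, strict_gt = FALSE,
                         alpha = 0.05, fold_threshold = 2, top_k = 8000L,
                         outdir = NULL, seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(sim) && !is.null(counts))
    stop("supply either a sim config or real inputs, not both",
         call. = FALSE)
  truth <- NULL
  if (!is.null(sim)) {
    if (!is.null(seed)) sim$seed <- as.integer(seed)
    exp <- generate_counts(sim)
    counts <- exp$counts; condition <- exp$condition
    annotation <- exp$annotation; reference <- exp$reference
    comparison <- exp$comparison; truth <- exp$truth
  }
  if (is.null(counts) || is.null(condition) || is.null(annotation))
    stop("counts, condition and annotation are required", call. = FALSE)

  findings <- validate_inputs(counts, condition, annotation)
  if (nrow(findings) > 0)
    stop("input validation failed: ",
         paste(findings$code, findings$message, sep = ": ",
               collapse = "; "), call. = FALSE)

  fpkm <- compute_fpkm(counts, annotation)
  calls <- call_expressed(fpkm, condition, min_fpkm = min_fpkm,
                          min_replicates = min_replicates,
                          strict_gt = strict_gt)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, condition)
  de <- nb_wald_test(counts, sf, disp, condition, alpha = alpha)
  de$symbol <- annotation$symbol[match(de$gene_id, annotation$gene_id)]

  cls <- if (!is.null(reference))
    classify_genes(de, calls, reference)
  else classify_genes(de, calls, de$gene_id)
  summary <- summarize_classification(cls)

  concord <- NULL
  if (!is.null(comparison)) {
    de_sig <- de[de$significant & cls$category %in%
                   c("up_a", "up_b", "exclusive_a", "exclusive_b"), ]
    concord <- if (nrow(de_sig) > 0)
      trend_concordance(de_sig, comparison, fold_threshold = fold_threshold)
    else list(frac_same_trend = NA_real_, n_ge_fold_a = 0L,
              n_ge_fold_b = 0L, n_compared = 0L)
    mean_fpkm <- rowMeans(fpkm)
    names(mean_fpkm) <- rownames(fpkm)
    comp_idx <- match(toupper(annotation$symbol),
                      toupper(comparison$ortholog_key))
    comp_mean <- (comparison$fpkm_a[comp_idx] +
                    comparison$fpkm_b[comp_idx]) / 2
    other_present <- !is.na(comp_mean) & comp_mean >= min_fpkm
    names(other_present) <- rownames(fpkm)
    k <- min(as.integer(top_k), length(mean_fpkm))
    concord$frac_topk_present_both <-
      presence_agreement_topk(mean_fpkm, other_present, k)
    concord$top_k <- k
    ok <- !is.na(comp_mean)
    if (any(ok)) {
      concord$spearman_rho <- rank_correlation(mean_fpkm[ok], comp_mean[ok])
      comp_calls <- data.frame(gene_id = rownames(fpkm)[ok],
                               present_a = comparison$fpkm_a[comp_idx[ok]] >= min_fpkm,
                               present_b = comparison$fpkm_b[comp_idx[ok]] >= min_fpkm)
      comp_calls$detected <- comp_calls$present_a | comp_calls$present_b
      jp <- joint_presence_summary(calls[calls$gene_id %in% comp_calls$gene_id, ],
                                   comp_calls)
      concord$n_union_expressed <- jp$n_union
      concord$frac_equal_presence <- jp$frac_equal
    }
  }

  report <- list(detected = count_detected(calls),
                 classification_summary = summary,
                 concordance = concord,
                 de = de, classification = cls, calls = calls, fpkm = fpkm,
                 size_factors = sf, dispersion = disp, truth = truth,
                 parameters = list(min_fpkm = min_fpkm,
                                   min_replicates = min_replicates,
                                   strict_gt = strict_gt, alpha = alpha,
                                   fold_threshold = fold_threshold,
                                   top_k = top_k, seed = seed),
                 version = as.character(utils::packageVersion("gangliaDE")),
                 timing_sec = proc.time()[["elapsed"]] - t0)
  class(report) <- "ganglia_report"

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_counts_tsv(counts, file.path(outdir, "counts.tsv"))
    write_tsv(data.frame(gene_id = rownames(fpkm), round(fpkm, 6),
                         check.names = FALSE),
              file.path(outdir, "fpkm.tsv"))
    write_tsv(calls, file.path(outdir, "presence_calls.tsv"))
    write_tsv(de, file.path(outdir, "de_results.tsv"))
    write_tsv(cls, file.path(outdir, "classification.tsv"))
    jsonlite::write_json(
      list(detected = report$detected,
           classification_summary = summary,
           concordance = concord[setdiff(names(concord),
                                         c("de", "fpkm"))],
           parameters = report$parameters, version = report$version),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null")
  }
  report
}

#' @export
print.ganglia_report <- function(x, ...) {
  cat("gangliaDE pipeline report (v", x$version, ")\n", sep = "")
  cat("  genes detected in either condition:", x$detected, "\n")
  cm <- x$classification_summary$counts
  cat("  significant neuronal DE genes:",
      x$classification_summary$n_de_neuronal,
      sprintf("(up_a %d, up_b %d, exclusive_a %d, exclusive_b %d)\n",
              cm["up_a"], cm["up_b"], cm["exclusive_a"], cm["exclusive_b"]))
  cat("  significant genes excluded (not expressed / non-neuronal):",
      x$classification_summary$n_excluded, "\n")
  if (!is.null(x$concordance)) {
    cat(sprintf("  trend concordance: %.3f over %d mapped genes\n",
                x$concordance$frac_same_trend, x$concordance$n_compared))
    if (!is.null(x$concordance$spearman_rho))
      cat(sprintf("  Spearman rho vs comparison dataset: %.3f\n",
                  x$concordance$spearman_rho))
  }
  invisible(x)
}
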
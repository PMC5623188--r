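#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used for comparing
#' ranked expression profiles across datasets.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with at least 3 values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Presence agreement among the top-k expressed genes
#'
#' Takes the k genes with the highest mean FPKM in the primary dataset (ties
#' broken by identifier order) and returns the fraction called present in
#' the other dataset; genes missing from the other dataset count as absent.
#'
#' @param primary_mean_fpkm named numeric vector of per-gene mean FPKM in
#'   the primary dataset.
#' @param other_presence named logical vector of presence calls in the other
#'   dataset.
#' @param k number of top genes, 0 < k <= length(primary_mean_fpkm).
#' @return fraction in [0, 1].
#' @export
presence_agreement_topk <- function(primary_mean_fpkm, other_presence, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > length(primary_mean_fpkm))
    stop("k exceeds the number of genes", call. = FALSE)
  ord <- order(-primary_mean_fpkm, names(primary_mean_fpkm))
  top <- names(primary_mean_fpkm)[ord][seq_len(k)]
  status <- other_presence[top]
  status[is.na(status)] <- FALSE
  mean(status)
}

#' Joint presence summary over two datasets
#'
#' Over the shared key universe, counts the genes present in at least one
#' dataset (the union) and, within that union, the fraction whose presence
#' status matches between the datasets in both conditions
#' (\code{present_a} and \code{present_b} each agree).
#'
#' @param calls_x,calls_y presence-call data.frames with columns
#'   \code{gene_id, present_a, present_b, detected}.
#' @return list with \code{n_union} and \code{frac_equal}.
#' @export
joint_presence_summary <- function(calls_x, calls_y) {
  shared <- intersect(calls_x$gene_id, calls_y$gene_id)
  if (length(shared) == 0) stop("empty shared gene universe", call. = FALSE)
  x <- calls_x[match(shared, calls_x$gene_id), ]
  y <- calls_y[match(shared, calls_y$gene_id), ]
  in_union <- x$detected | y$detected
  equal <- x$present_a == y$present_a & x$present_b == y$present_b
  list(n_union = sum(in_union),
       frac_equal = if (any(in_union)) mean(equal[in_union]) else NA_real_)
}

#' Direction-of-trend concordance with an ortholog comparison dataset
#'
#' Maps differentially expressed genes to the comparison dataset by
#' upper-cased symbol. A mapped gene follows the same trend when the sign of
#' its log2 fold change (B vs A) equals the sign of the comparison log ratio
#' \code{log((fpkm_b + eps) / (fpkm_a + eps))}; a ratio of exactly 1
#' supports neither direction and counts as not same-trend. Among same-trend
#' genes, those whose comparison FPKM ratio reaches \code{fold_threshold}
#' are counted separately per direction.
#'
#' @param de differential-expression subset (significant genes), a
#'   data.frame with columns \code{symbol} and \code{log2fc}.
#' @param comparison data.frame with columns \code{ortholog_key, fpkm_a,
#'   fpkm_b}.
#' @param fold_threshold fold-change threshold >= 1 (default 2).
#' @param eps pseudo-FPKM offset keeping zero-FPKM genes finite
#'   (default 0.01).
#' @return list with \code{frac_same_trend}, \code{n_ge_fold_a},
#'   \code{n_ge_fold_b} and \code{n_compared}.
#' @export
trend_concordance <- function(de, comparison, fold_threshold = 2,
                              eps = 0.01) {
  if (fold_threshold < 1) stop("fold_threshold must be >= 1", call. = FALSE)
  key <- toupper(de$symbol)
  idx <- match(key, toupper(comparison$ortholog_key))
  mapped <- !is.na(idx)
  if (!any(mapped)) stop("no gene maps to the comparison dataset",
                         call. = FALSE)
  lfc <- de$log2fc[mapped]
  fa <- comparison$fpkm_a[idx[mapped]] + eps
  fb <- comparison$fpkm_b[idx[mapped]] + eps
  comp_lfc <- log2(fb / fa)
  same <- sign(lfc) == sign(comp_lfc) & comp_lfc != 0 & lfc != 0
  up_a <- same & lfc < 0
  up_b <- same & lfc > 0
  list(frac_same_trend = mean(same),
       n_ge_fold_a = sum(up_a & fa / fb >= fold_threshold),
       n_ge_fold_b = sum(up_b & fb / fa >= fold_threshold),
       n_compared = sum(mapped))
}

#' Row-standardized matrix for expression heatmaps
#'
#' Z-scores each row across columns (mean 0, sample standard deviation 1);
#' rows that are constant map to all zeros. Intended for matrices of average
#' log2 FPKM values (computed upstream with a 0.01 offset).
#'
#' @param mat numeric matrix with >= 2 columns (genes x datasets).
#' @return matrix of the same shape.
#' @export
standardized_heatmap_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 columns", call. = FALSE)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  z <- (mat - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}

#' Average log2 FPKM per condition
#'
#' Helper producing the per-gene, per-condition columns that feed
#' \code{\link{standardized_heatmap_matrix}}: mean FPKM within each
#' condition, offset by \code{eps} before taking log2.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param condition "A"/"B" labels per sample.
#' @param eps offset before log2 (default 0.01).
#' @return matrix with columns \code{A} and \code{B}.
#' @export
average_log2_fpkm <- function(fpkm, condition, eps = 0.01) {
  condition <- check_condition(condition, ncol(fpkm))
  cbind(A = log2(rowMeans(fpkm[, condition == "A", drop = FALSE]) + eps),
        B = log2(rowMeans(fpkm[, condition == "B", drop = FALSE]) + eps))
}
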
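#' FPKM from raw counts and gene lengths
#'
#' Fragments per kilobase of union-exon length per million assigned reads:
#' \code{fpkm[g, s] = counts[g, s] * 1e9 / (total_counts[s] * length_bp[g])}.
#' Each sample is normalized by its own total assigned counts; no
#' between-sample normalization or fragment-length correction is applied.
#' Genes present in the annotation but missing from the count matrix are
#' treated as zero counts everywhere, with a warning.
#'
#' @param counts non-negative integer matrix, genes x samples, rownames are
#'   gene ids.
#' @param annotation data.frame with columns \code{gene_id} and
#'   \code{length_bp}.
#' @return numeric matrix of FPKM values, rows ordered as the annotation.
#' @export
compute_fpkm <- function(counts, annotation) {
  check_counts(counts)
  if (!all(c("gene_id", "length_bp") %in% names(annotation)))
    stop("annotation needs gene_id and length_bp columns", call. = FALSE)
  if (anyDuplicated(annotation$gene_id))
    stop("duplicate gene_id in annotation", call. = FALSE)
  if (any(annotation$length_bp < 1))
    stop("length_bp must be >= 1", call. = FALSE)
  missing_len <- setdiff(rownames(counts), annotation$gene_id)
  if (length(missing_len))
    stop("no length for gene(s): ", paste(utils::head(missing_len, 5),
                                          collapse = ", "), call. = FALSE)
  extra <- setdiff(annotation$gene_id, rownames(counts))
  if (length(extra)) {
    warning(length(extra), " annotated gene(s) absent from counts; treated ",
            "as zero counts", call. = FALSE)
    zero <- matrix(0L, length(extra), ncol(counts),
                   dimnames = list(extra, colnames(counts)))
    counts <- rbind(counts, zero)
  }
  counts <- counts[annotation$gene_id, , drop = FALSE]
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  sweep(counts * 1e9 / annotation$length_bp, 2, totals, "/")
}

#' Replicate-based presence/absence calls
#'
#' A gene is called present in a condition if at least \code{min_replicates}
#' of that condition's samples reach the FPKM cut-off. The cut-off is
#' inclusive (\code{fpkm >= min_fpkm}) by default; \code{strict_gt = TRUE}
#' uses a strict inequality instead.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param condition character vector of "A"/"B" labels, one per column.
#' @param min_fpkm FPKM threshold (default 1).
#' @param min_replicates replicates required at or above threshold
#'   (default 2).
#' @param strict_gt use \code{>} instead of \code{>=}.
#' @return data.frame with columns \code{gene_id, present_a, present_b,
#'   detected}; thresholds recorded as attributes.
#' @export
call_expressed <- function(fpkm, condition, min_fpkm = 1,
                           min_replicates = 2L, strict_gt = FALSE) {
  condition <- check_condition(condition, ncol(fpkm))
  if (any(table(condition) < min_replicates))
    stop("each condition needs at least min_replicates samples",
         call. = FALSE)
  hit <- if (strict_gt) fpkm > min_fpkm else fpkm >= min_fpkm
  present_a <- rowSums(hit[, condition == "A", drop = FALSE]) >= min_replicates
  present_b <- rowSums(hit[, condition == "B", drop = FALSE]) >= min_replicates
  out <- data.frame(gene_id = rownames(fpkm),
                    present_a = unname(present_a),
                    present_b = unname(present_b),
                    detected = unname(present_a | present_b),
                    stringsAsFactors = FALSE)
  attr(out, "min_fpkm") <- min_fpkm
  attr(out, "min_replicates") <- as.integer(min_replicates)
  attr(out, "strict_gt") <- strict_gt
  out
}

#' Number of genes detected in either condition
#'
#' @param calls presence calls from \code{\link{call_expressed}}.
#' @return integer count of genes with \code{detected = TRUE}.
#' @export
count_detected <- function(calls) {
  sum(calls$detected)
}

# --- shared input checks -----------------------------------------------------

check_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)))
    stop("counts must be a matrix with gene ids as rownames", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integral", call. = FALSE)
  invisible(counts)
}

check_condition <- function(condition, n_samples) {
  condition <- as.character(condition)
  if (length(condition) != n_samples)
    stop("need one condition label per sample", call. = FALSE)
  if (!all(condition %in% c("A", "B")))
    stop("condition labels must be 'A' or 'B'", call. = FALSE)
  condition
}
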
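#' Classify genes into expression categories
#'
#' Partitions the gene universe using the decision order: (1) not
#' significant -> \code{common}; (2) significant but failing the presence
#' call in both conditions -> \code{not_expressed}; (3) significant but
#' absent from the pure-neuron reference set -> \code{non_neuronal};
#' (4) significant and present in exactly one condition -> exclusive for
#' that condition; (5) significant and present in both -> \code{up_a} if the
#' fold change favors condition A (log2fc, oriented B vs A, is negative),
#' else \code{up_b}. The order mirrors the analysis in which significant
#' genes are first screened by the expression cut-off and then by neuronal
#' origin before exclusivity is assessed.
#'
#' @param de differential-expression table from \code{\link{nb_wald_test}}.
#' @param calls presence calls from \code{\link{call_expressed}}.
#' @param reference character vector of gene ids expressed in a pure-neuron
#'   reference dataset (may be a subset of the universe).
#' @return data.frame with columns \code{gene_id, category, significant,
#'   present_a, present_b, in_reference}.
#' @export
classify_genes <- function(de, calls, reference) {
  if (!setequal(de$gene_id, calls$gene_id))
    stop("de and presence calls must cover the same gene universe",
         call. = FALSE)
  extra_ref <- setdiff(reference, de$gene_id)
  if (length(extra_ref) > 0 && length(extra_ref) == length(reference))
    stop("reference set shares no genes with the universe", call. = FALSE)
  idx <- match(de$gene_id, calls$gene_id)
  present_a <- calls$present_a[idx]
  present_b <- calls$present_b[idx]
  in_ref <- de$gene_id %in% reference
  sig <- de$significant

  category <- rep("common", nrow(de))
  detected <- present_a | present_b
  category[sig & !detected] <- "not_expressed"
  category[sig & detected & !in_ref] <- "non_neuronal"
  category[sig & in_ref & present_a & !present_b] <- "exclusive_a"
  category[sig & in_ref & !present_a & present_b] <- "exclusive_b"
  both <- sig & in_ref & present_a & present_b
  category[both & de$log2fc < 0] <- "up_a"
  category[both & de$log2fc >= 0] <- "up_b"

  data.frame(gene_id = de$gene_id, category = category, significant = sig,
             present_a = present_a, present_b = present_b,
             in_reference = in_ref, stringsAsFactors = FALSE)
}

#' Summarize a gene classification
#'
#' @param cls classification table from \code{\link{classify_genes}}.
#' @return list with per-category counts (\code{counts}), the number of
#'   differentially expressed neuronal genes \code{n_de_neuronal}
#'   (up + exclusive in either direction) and \code{n_excluded}
#'   (significant genes removed as not expressed or non-neuronal).
#' @export
summarize_classification <- function(cls) {
  levels <- c("up_a", "up_b", "exclusive_a", "exclusive_b", "common",
              "not_expressed", "non_neuronal")
  counts <- vapply(levels, function(l) sum(cls$category == l), integer(1))
  list(counts = counts,
       n_de_neuronal = unname(counts["up_a"] + counts["up_b"] +
                                counts["exclusive_a"] + counts["exclusive_b"]),
       n_excluded = unname(counts["not_expressed"] + counts["non_neuronal"]),
       n_genes = nrow(cls))
}

#' Count genes of a family by symbol prefix
#'
#' Matches the prefix case-insensitively and anchored at the start of the
#' symbol, so \code{"Hox"} matches \code{Hoxa7} but not \code{Shox2}.
#'
#' @param tbl data.frame with a \code{symbol} column.
#' @param family_prefix prefix string.
#' @return integer count.
#' @export
count_gene_family <- function(tbl, family_prefix) {
  if (nrow(tbl) == 0) return(0L)
  sum(startsWith(tolower(tbl$symbol), tolower(family_prefix)))
}

#' Read a table of ganglion-exclusive genes
#'
#' Reads a TSV with columns \code{gene_id, symbol, exclusive_drg,
#' exclusive_tg} (booleans). Every row must be flagged exclusive in exactly
#' one ganglion. The package ships such a table at
#' \code{system.file("extdata", "exclusive_genes.tsv", package =
#' "gangliaDE")}, listing the 24 genes found exclusively expressed in either
#' DRG or TG neurons.
#'
#' @param path path to the TSV file.
#' @return data.frame with logical exclusivity columns.
#' @export
read_exclusive_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "exclusive_drg", "exclusive_tg")
  if (!all(need %in% names(tbl)))
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  tbl$exclusive_drg <- as.logical(tbl$exclusive_drg)
  tbl$exclusive_tg <- as.logical(tbl$exclusive_tg)
  bad <- tbl$exclusive_drg == tbl$exclusive_tg
  if (any(bad | is.na(bad)))
    stop("row(s) flagged exclusive in both or neither ganglion: ",
         paste(tbl$symbol[bad | is.na(bad)], collapse = ", "), call. = FALSE)
  tbl
}

#' Interpret an exclusivity table as a classification
#'
#' Maps DRG-exclusive rows to \code{exclusive_a} and TG-exclusive rows to
#' \code{exclusive_b} so exclusivity tables can be summarized with
#' \code{\link{summarize_classification}}.
#'
#' @param tbl table from \code{\link{read_exclusive_table}}.
#' @return classification data.frame.
#' @export
exclusive_table_as_classification <- function(tbl) {
  data.frame(gene_id = tbl$gene_id,
             category = ifelse(tbl$exclusive_drg, "exclusive_a",
                               "exclusive_b"),
             significant = TRUE,
             present_a = tbl$exclusive_drg,
             present_b = tbl$exclusive_tg,
             in_reference = TRUE, stringsAsFactors = FALSE)
}
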
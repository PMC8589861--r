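#' Map copy-number segments onto genes
#'
#' Assigns each gene the DCN value of the segment it lies in. A gene fully
#' contained in one segment receives that segment's value; a gene spanning
#' several segments receives the overlap-length-weighted mean of their
#' values; a gene with no overlapping segment in a sample is missing (`NA`)
#' for that sample.
#'
#' @param segments Segment `data.frame` (`sample`, `chromosome`, `start`,
#'   `end`, `value`) in internal 0-based half-open coordinates.
#' @param annotation Gene annotation `data.frame` from
#'   [read_gene_annotation()].
#' @return Numeric genes-by-samples matrix of linear copy ratios with `NA`
#'   for uncovered genes; rownames are `gene_id`, colnames sample ids.
#' @export
map_segments_to_genes <- function(segments, annotation) {
  samples <- sort(unique(segments$sample))
  n_g <- nrow(annotation)
  n_s <- length(samples)
  out <- matrix(NA_real_, n_g, n_s, dimnames = list(annotation$gene_id, samples))
  if (nrow(segments) == 0L || n_g == 0L) return(out)
  # GRanges are 1-based inclusive; shift the half-open starts by +1
  gene_gr <- GenomicRanges::GRanges(annotation$chromosome,
                                    IRanges::IRanges(annotation$start + 1L,
                                                     annotation$end))
  seg_gr <- GenomicRanges::GRanges(segments$chromosome,
                                   IRanges::IRanges(segments$start + 1L,
                                                    segments$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(GenomicRanges::pintersect(gene_gr[qh], seg_gr[sh]))
  cell <- (match(segments$sample[sh], samples) - 1L) * n_g + qh
  wsum <- rowsum(as.numeric(w), cell)
  vsum <- rowsum(as.numeric(w) * segments$value[sh], cell)
  out[as.integer(rownames(wsum))] <- vsum / wsum
  out
}

#' Remove genes with sparse copy-number coverage
#'
#' Genes whose DCN value is present in strictly less than `min_fraction` of
#' the samples are excluded (the boundary case of exactly `min_fraction`
#' coverage is retained).
#'
#' @param mat Gene-level DCN matrix (genes x samples, `NA` = missing).
#' @param min_fraction Minimum covered fraction in `(0, 1]`; default 0.5.
#' @return List with `matrix` (retained genes) and `removed` (character
#'   vector of excluded gene ids).
#' @export
filter_low_coverage_genes <- function(mat, min_fraction = 0.5) {
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("filter_low_coverage_genes: empty matrix")
  }
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("min_fraction must be in (0, 1]")
  }
  covered <- rowSums(!is.na(mat))
  keep <- covered >= min_fraction * ncol(mat)
  list(matrix = mat[keep, , drop = FALSE],
       removed = rownames(mat)[!keep])
}

#' Deregulated-expression (DE) matrix
#'
#' Per-gene, per-tumor-sample log2 ratio of expression to the mean
#' expression over all non-tumor samples:
#' `DE[g, s] = log2((x_pt[g, s] + c) / (mean_nt(x_nt[g, ]) + c))`.
#' The pseudocount `c > 0` keeps the ratio finite at zero FPKM.
#'
#' @param expression_pt,expression_nt Nonnegative genes-by-samples matrices;
#'   every PT gene must be present in the NT table.
#' @param pseudocount Positive pseudocount `c`; default 1.
#' @return Genes-by-PT-samples matrix of finite log2 ratios.
#' @export
compute_de_matrix <- function(expression_pt, expression_nt, pseudocount = 1) {
  if (!(pseudocount > 0)) stop("pseudocount must be > 0")
  missing_genes <- setdiff(rownames(expression_pt), rownames(expression_nt))
  if (length(missing_genes) > 0L) {
    stop("gene(s) absent from the NT expression table: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  nt_mean <- rowMeans(expression_nt[rownames(expression_pt), , drop = FALSE])
  log2((expression_pt + pseudocount) / (nt_mean + pseudocount))
}

#' Somatic copy number alteration (SCNA) matrix
#'
#' Per-gene, per-tumor-sample log2 ratio of the gene-level DCN to the mean
#' gene-level DCN over the non-tumor samples (mean over non-missing NT
#' values). Missing PT values propagate; a gene with no non-missing NT value
#' is reported missing with a warning.
#'
#' @param gene_dcn_pt,gene_dcn_nt Gene-level linear copy-ratio matrices from
#'   [map_segments_to_genes()], sharing rownames.
#' @return Genes-by-PT-samples matrix of log2 copy ratios (`NA` = missing).
#' @export
compute_scna_matrix <- function(gene_dcn_pt, gene_dcn_nt) {
  missing_genes <- setdiff(rownames(gene_dcn_pt), rownames(gene_dcn_nt))
  if (length(missing_genes) > 0L) {
    stop("gene(s) absent from the NT DCN matrix: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  nt <- gene_dcn_nt[rownames(gene_dcn_pt), , drop = FALSE]
  nt_n <- rowSums(!is.na(nt))
  if (any(nt_n == 0L)) {
    warning(sum(nt_n == 0L), " gene(s) with no non-missing NT DCN value; reported missing")
  }
  nt_mean <- rowMeans(nt, na.rm = TRUE)
  nt_mean[nt_n == 0L] <- NA_real_
  log2(gene_dcn_pt / nt_mean)
}
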
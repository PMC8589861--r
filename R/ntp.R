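#' Gene-wise z-scoring
#'
#' Centers and scales each gene (row) to mean 0 and unit standard deviation
#' (denominator n - 1) across the cohort. Zero-variance genes are dropped
#' with a warning.
#'
#' @param mat Numeric genes-by-samples matrix.
#' @return The standardized matrix, possibly with fewer rows.
#' @export
standardize_genewise <- function(mat) {
  m <- rowMeans(mat)
  s <- sqrt(rowSums((mat - m)^2) / (ncol(mat) - 1))
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) dropped before z-scoring")
    mat <- mat[!zero, , drop = FALSE]
    m <- m[!zero]; s <- s[!zero]
  }
  (mat - m) / s
}

#' Cosine distance to a template
#'
#' `d = 1 - x . t / (||x|| ||t||)`, in `[0, 2]`.
#'
#' @param x Numeric vector (a sample's standardized signature values).
#' @param t Template direction vector of the same length (entries +-1).
#' @return Cosine distance.
#' @export
cosine_distance <- function(x, t) {
  if (length(x) != length(t)) stop("length mismatch")
  nx <- sqrt(sum(x * x)); nt <- sqrt(sum(t * t))
  if (nx == 0) stop("zero-norm sample vector")
  if (nt == 0) stop("zero-norm template vector")
  1 - sum(x * t) / (nx * nt)
}

#' Nearest Template Prediction of molecular subclass
#'
#' Assigns each sample to the subclass template with the smallest cosine
#' distance between the sample's z-scored signature-gene values and the
#' template's +-1 direction vector. Significance is assessed by resampling:
#' for each sample, `R` random gene sets of the winning signature's size are
#' drawn (uniformly, without replacement, from all measured genes,
#' independently per sample) and
#' `p = (1 + #{null distances <= observed}) / (R + 1)`. Benjamini-Hochberg
#' FDR is computed across samples over the winning-class p-values; a sample
#' is called to its nearest class when `fdr < fdr_thresh`, otherwise it is
#' reported `"unclassified"`.
#'
#' @param expression Genes-by-samples matrix. With
#'   `transform = "log2"` (default) values are taken as linear-scale
#'   abundances and log2(x + pseudocount)-transformed before z-scoring;
#'   use `transform = "none"` for matrices already on log scale.
#' @param templates Named list of per-class signatures (`gene_id`,
#'   `direction`), as from [read_templates()]. Signature genes absent from
#'   the matrix are dropped per class with a warning; at least 5 must
#'   remain or the class is dropped.
#' @param R Number of resampled gene sets (>= 1); default 1000.
#' @param fdr_thresh Call threshold on the BH FDR; default 0.05.
#' @param seed Optional integer seed for the resampling.
#' @param transform `"log2"` or `"none"`.
#' @param pseudocount Pseudocount for the log2 transform; default 1.
#' @return `data.frame` with `sample_id`, `nearest_class`, `distance`, `p`,
#'   `fdr`, `predicted_class` (the nearest class or `"unclassified"`).
#'   Per-class distances are attached as attribute `"distances"`.
#' @export
ntp_predict <- function(expression, templates, R = 1000, fdr_thresh = 0.05,
                        seed = NULL, transform = c("log2", "none"),
                        pseudocount = 1) {
  transform <- match.arg(transform)
  if (R < 1L) stop("R must be >= 1")
  if (length(templates) < 1L) stop("need at least one template class")
  mat <- if (transform == "log2") log2(expression + pseudocount) else expression
  Z <- standardize_genewise(mat)
  measured <- rownames(Z)
  sig <- list()
  for (cl in names(templates)) {
    tm <- templates[[cl]]
    present <- tm$gene_id %in% measured
    if (!all(present)) {
      warning(sum(!present), " signature gene(s) of class ", cl,
              " absent from the matrix; dropped")
      tm <- tm[present, , drop = FALSE]
    }
    if (nrow(tm) >= 5L) sig[[cl]] <- tm
    else warning("class ", cl, " dropped: fewer than 5 signature genes measured")
  }
  if (length(sig) == 0L) stop("all template classes dropped")
  n_samp <- ncol(Z)
  classes <- names(sig)
  D <- matrix(NA_real_, n_samp, length(classes),
              dimnames = list(colnames(Z), classes))
  for (j in seq_along(classes)) {
    tm <- sig[[j]]
    sub <- Z[tm$gene_id, , drop = FALSE]
    tvec <- tm$direction
    num <- as.vector(crossprod(sub, tvec))
    den <- sqrt(colSums(sub * sub)) * sqrt(sum(tvec * tvec))
    D[, j] <- 1 - num / den
  }
  win <- apply(D, 1L, which.min)
  d_obs <- D[cbind(seq_len(n_samp), win)]

  if (!is.null(seed)) set.seed(seed)
  p <- numeric(n_samp)
  n_genes <- length(measured)
  for (i in seq_len(n_samp)) {
    m <- nrow(sig[[win[i]]])
    tvec <- sig[[win[i]]]$direction
    idx <- replicate(R, sample.int(n_genes, m))
    Xnull <- matrix(Z[, i][idx], nrow = m)
    num <- as.vector(crossprod(Xnull, tvec))
    den <- sqrt(colSums(Xnull * Xnull)) * sqrt(m)
    d_null <- 1 - num / den
    p[i] <- (1 + sum(d_null <= d_obs[i])) / (R + 1)
  }
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(sample_id = colnames(Z),
             nearest_class = classes[win],
             distance = d_obs, p = p, fdr = fdr,
             predicted_class = ifelse(fdr < fdr_thresh, classes[win],
                                      "unclassified"),
             row.names = NULL, stringsAsFactors = FALSE) -> out
  attr(out, "distances") <- D
  out
}

#' Fisher's exact enrichment of predicted subclasses between groups
#'
#' For each predicted class, builds the 2x2 table of class membership
#' against group membership (high vs low) and reports the two-sided
#' Fisher's exact p-value and the sample odds ratio (with Haldane's +0.5
#' correction applied to all cells when any cell is zero).
#'
#' @param predictions Prediction table from [ntp_predict()].
#' @param group_high,group_low Disjoint character vectors of sample ids.
#' @param classes Optional class labels to tabulate; defaults to the
#'   nearest-class labels seen in `predictions`.
#' @return `data.frame` with `class`, the four counts, `odds_ratio`, `p`.
#' @export
fisher_enrichment <- function(predictions, group_high, group_low,
                              classes = NULL) {
  if (length(intersect(group_high, group_low)) > 0L) stop("groups overlap")
  if (is.null(classes)) classes <- sort(unique(predictions$nearest_class))
  pred <- predictions$predicted_class
  names(pred) <- predictions$sample_id
  out <- lapply(classes, function(cl) {
    a <- sum(pred[group_high] == cl, na.rm = TRUE)
    b <- length(group_high) - a
    c_ <- sum(pred[group_low] == cl, na.rm = TRUE)
    d <- length(group_low) - c_
    tab <- matrix(c(a, b, c_, d), 2L)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    cells <- c(a, b, c_, d)
    if (any(cells == 0L)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    data.frame(class = cl, in_class_high = a, not_class_high = b,
               in_class_low = c_, not_class_low = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
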
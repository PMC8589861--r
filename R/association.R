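# Welch's t statistic; zero-variance-in-both-groups yields t = 0 by convention
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  se2 <- stats::var(a) / na + stats::var(b) / nb
  if (!is.finite(se2) || se2 <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}

#' Permutation t-test for two groups
#'
#' Welch's t statistic on the observed labels, with a permutation p-value
#' over random relabellings. When the number of distinct label arrangements
#' `choose(n, n_a)` is at most `B`, all arrangements are enumerated and the
#' p-value is the exact fraction of arrangements with `|t*| >= |t|`
#' (the observed arrangement included). Otherwise `B` Monte Carlo shuffles
#' are drawn and the add-one estimate `(1 + #{|t*| >= |t|}) / (B + 1)` is
#' used, so the p-value is never exactly zero.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param B Maximum number of permutations (>= 1); default 9999.
#' @param seed Optional integer seed for the Monte Carlo shuffles.
#' @return List with `t` (observed Welch statistic), `p` (permutation
#'   p-value), `method` (`"exhaustive"` or `"monte-carlo"`) and `n_perm`.
#' @export
permutation_t_test <- function(values_a, values_b, B = 9999, seed = NULL) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (B < 1L) stop("B must be >= 1")
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pooled)
  t_obs <- welch_t(values_a, values_b)
  tol <- 1e-12 * max(1, abs(t_obs))
  if (choose(n, na) <= B) {
    splits <- utils::combn(n, na)
    t_star <- apply(splits, 2L, function(idx) welch_t(pooled[idx], pooled[-idx]))
    p <- mean(abs(t_star) >= abs(t_obs) - tol)
    list(t = t_obs, p = p, method = "exhaustive", n_perm = ncol(splits))
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (i in seq_len(B)) {
      idx <- sample.int(n, na)
      if (abs(welch_t(pooled[idx], pooled[-idx])) >= abs(t_obs) - tol) {
        count <- count + 1L
      }
    }
    list(t = t_obs, p = (1 + count) / (B + 1), method = "monte-carlo", n_perm = B)
  }
}

#' Genome-wide permutation t-test screen
#'
#' Vectorized Welch t permutation test applied to every row of a matrix,
#' using one shared permutation plan (the same label shuffles for all genes)
#' so a screen is reproducible from a single seed and runs as a handful of
#' matrix products. Exhaustive enumeration replaces Monte Carlo sampling
#' when all label arrangements fit within `B`.
#'
#' @param mat Numeric genes-by-samples matrix without missing values.
#' @param group_a,group_b Disjoint character vectors of column names.
#' @param B Number of permutations; default 9999.
#' @param seed Optional integer seed.
#' @return `data.frame` with `gene_id`, `t` and `perm_p`.
#' @export
permutation_de_screen <- function(mat, group_a, group_b, B = 9999, seed = NULL) {
  if (length(intersect(group_a, group_b)) > 0L) stop("groups overlap")
  miss <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(miss) > 0L) stop("sample(s) not in matrix: ", paste(utils::head(miss, 5L), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L) stop("each group needs at least 2 samples")
  if (anyNA(mat)) stop("matrix contains missing values")
  x <- mat[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  x2 <- x * x
  tot <- rowSums(x); tot2 <- rowSums(x2)

  t_for_plan <- function(P) {
    # P: n x k indicator of group-A membership per permutation
    sA <- x %*% P
    qA <- x2 %*% P
    mA <- sA / na
    mB <- (tot - sA) / nb
    vA <- (qA - na * mA * mA) / (na - 1)
    vB <- ((tot2 - qA) - nb * mB * mB) / (nb - 1)
    se2 <- vA / na + vB / nb
    tmat <- (mA - mB) / sqrt(pmax(se2, 0))
    tmat[!is.finite(tmat)] <- 0
    tmat
  }

  P_obs <- matrix(0, n, 1)
  P_obs[seq_len(na), 1] <- 1
  t_obs <- as.vector(t_for_plan(P_obs))
  tol <- 1e-12 * pmax(1, abs(t_obs))

  exhaustive <- choose(n, na) <= B
  if (exhaustive) {
    splits <- utils::combn(n, na)
    P <- matrix(0, n, ncol(splits))
    P[cbind(as.vector(splits), rep(seq_len(ncol(splits)), each = na))] <- 1
  } else {
    if (!is.null(seed)) set.seed(seed)
    P <- matrix(0, n, B)
    for (j in seq_len(B)) P[sample.int(n, na), j] <- 1
  }
  # chunk the permutation plan to bound memory on large screens
  count <- numeric(nrow(x))
  chunk <- max(1L, floor(2e7 / nrow(x)))
  for (j0 in seq(1L, ncol(P), by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, ncol(P))
    t_star <- t_for_plan(P[, jj, drop = FALSE])
    count <- count + rowSums(abs(t_star) >= abs(t_obs) - tol)
  }
  p <- if (exhaustive) count / ncol(P) else (1 + count) / (ncol(P) + 1)
  data.frame(gene_id = rownames(x), t = t_obs, perm_p = p,
             stringsAsFactors = FALSE)
}

#' Gene-wise Pearson correlation between DE and SCNA
#'
#' Pearson correlation of each gene's DE and SCNA values across the tumor
#' samples harboring both assays, with a two-sided p-value from the
#' t-transform on n - 2 degrees of freedom. Genes with fewer than 3 paired
#' finite observations, or zero variance on either axis, are reported
#' missing (the latter with a warning).
#'
#' @param de DE matrix (genes x PT samples), finite.
#' @param scna SCNA matrix (genes x PT samples), `NA` allowed.
#' @param samples Optional sample ids to use; default is the column
#'   intersection of the two matrices.
#' @return `data.frame` with `gene_id`, `n`, `cor_r`, `cor_p`.
#' @export
gene_wise_correlation <- function(de, scna, samples = NULL) {
  if (is.null(samples)) samples <- intersect(colnames(de), colnames(scna))
  if (length(samples) < 3L) stop("need at least 3 shared samples")
  genes <- intersect(rownames(de), rownames(scna))
  X <- de[genes, samples, drop = FALSE]
  Y <- scna[genes, samples, drop = FALSE]
  M <- is.finite(X) & is.finite(Y)
  X[!M] <- 0; Y[!M] <- 0
  n <- rowSums(M)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X * X); syy <- rowSums(Y * Y); sxy <- rowSums(X * Y)
  cov_ <- sxy - sx * sy / n
  vx <- sxx - sx * sx / n
  vy <- syy - sy * sy / n
  r <- cov_ / sqrt(vx * vy)
  degenerate <- n >= 3L & (vx <= 1e-12 * pmax(1, sxx) | vy <= 1e-12 * pmax(1, syy))
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero variance on an axis; correlation reported missing")
  }
  r[degenerate | n < 3L] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r * r, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[is.na(r)] <- NA_real_
  data.frame(gene_id = genes, n = n, cor_r = r, cor_p = pmin(p, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full DE / SCNA association screen
#'
#' Assembles per-gene association records: average DE fold change over the
#' tumor samples, permutation p-value of the NT-vs-PT expression test
#' (Welch t on log2-transformed abundance, shared permutation plan),
#' average SCNA fold change, and the DE-SCNA Pearson correlation over the
#' samples harboring both assays. BH-adjusted q-values are reported as
#' extra columns; the selection rule itself uses raw thresholds
#' (see [select_scna_dependent_genes()]).
#'
#' @param expression_pt,expression_nt FPKM-like matrices for the NT-vs-PT
#'   permutation test.
#' @param de DE matrix from [compute_de_matrix()].
#' @param scna SCNA matrix from [compute_scna_matrix()] (rows are matched to
#'   `de` by gene id; genes absent from `scna` get missing SCNA fields).
#' @param B Permutations for the NT-vs-PT test; default 1999 (resolves the
#'   0.005 threshold with add-one correction).
#' @param pseudocount Pseudocount for the log2 transform of expression.
#' @param seed Optional integer seed for the shared permutation plan.
#' @return `data.frame` with columns `gene_id`, `de_fc`, `perm_p`, `de_q`,
#'   `scna_fc`, `n_cor`, `cor_r`, `cor_p`, `cor_q`.
#' @export
association_screen <- function(expression_pt, expression_nt, de, scna,
                               B = 1999, pseudocount = 1, seed = NULL) {
  genes <- rownames(de)
  lg <- log2(cbind(expression_nt[genes, , drop = FALSE],
                   expression_pt[genes, , drop = FALSE]) + pseudocount)
  screen <- permutation_de_screen(lg,
                                  group_a = colnames(expression_pt),
                                  group_b = colnames(expression_nt),
                                  B = B, seed = seed)
  common <- intersect(genes, rownames(scna))
  cor_tab <- gene_wise_correlation(de[common, , drop = FALSE],
                                   scna[common, , drop = FALSE])
  idx <- match(genes, cor_tab$gene_id)
  scna_fc <- rowMeans(scna, na.rm = TRUE)[match(genes, rownames(scna))]
  out <- data.frame(gene_id = genes,
                    de_fc = rowMeans(de),
                    perm_p = screen$perm_p[match(genes, screen$gene_id)],
                    scna_fc = as.vector(scna_fc),
                    n_cor = cor_tab$n[idx],
                    cor_r = cor_tab$cor_r[idx],
                    cor_p = cor_tab$cor_p[idx],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$de_q <- stats::p.adjust(out$perm_p, method = "BH")
  out$cor_q <- stats::p.adjust(out$cor_p, method = "BH")
  out
}

#' Select copy-number-driven (SCNA-dependent) genes
#'
#' Applies the three-gate selection rule: (1) differential expression with
#' `|de_fc| > de_fc_thresh` and permutation `perm_p < de_p_thresh`;
#' (2) concordant copy-number change, `sign(scna_fc) == sign(de_fc)`;
#' (3) dosage correlation `cor_r > r_thresh` with `cor_p < r_p_thresh`
#' (signed r: dosage dependence is positive). Records with missing fields
#' are never selected.
#'
#' @param records Association records from [association_screen()].
#' @param de_fc_thresh,de_p_thresh,r_thresh,r_p_thresh Gate thresholds;
#'   defaults 0.3, 0.005, 0.5, 0.005.
#' @return The records with added logical `selected` and `direction`
#'   (`"up"`/`"down"`, the sign of `de_fc`) columns.
#' @export
select_scna_dependent_genes <- function(records, de_fc_thresh = 0.3,
                                        de_p_thresh = 0.005,
                                        r_thresh = 0.5, r_p_thresh = 0.005) {
  sel <- abs(records$de_fc) > de_fc_thresh &
    records$perm_p < de_p_thresh &
    sign(records$scna_fc) == sign(records$de_fc) &
    records$cor_r > r_thresh &
    records$cor_p < r_p_thresh
  sel[is.na(sel)] <- FALSE
  records$selected <- sel
  records$direction <- ifelse(records$de_fc > 0, "up", "down")
  records
}

#' Group-vs-group differential expression screen
#'
#' Compares log2 DE between two disjoint sample groups, gene by gene:
#' fold difference = mean(low) - mean(high), permutation p-value by the
#' shared-plan Welch t permutation test across group labels. Genes are
#' flagged `"up"` (higher in the low group) or `"down"` when
#' `|fold_difference| > fd_thresh` and `perm_p < p_thresh`.
#'
#' @param de DE matrix (genes x samples).
#' @param group_high,group_low Disjoint character vectors of sample ids.
#' @param B Permutations; default 9999.
#' @param p_thresh,fd_thresh Flagging thresholds; defaults 0.001 and 0.5.
#' @param seed Optional integer seed.
#' @param top_k Optional; also return the `top_k` flagged genes ranked by
#'   `perm_p` then `|fold_difference|` as attribute `"top"`.
#' @return `data.frame` with `gene_id`, `fold_difference`, `t`, `perm_p`,
#'   `flagged`, `direction`.
#' @export
group_differential_expression <- function(de, group_high, group_low,
                                          B = 9999, p_thresh = 0.001,
                                          fd_thresh = 0.5, seed = NULL,
                                          top_k = NULL) {
  screen <- permutation_de_screen(de, group_a = group_low,
                                  group_b = group_high, B = B, seed = seed)
  fd <- rowMeans(de[, group_low, drop = FALSE]) -
    rowMeans(de[, group_high, drop = FALSE])
  out <- data.frame(gene_id = screen$gene_id,
                    fold_difference = as.vector(fd[screen$gene_id]),
                    t = screen$t, perm_p = screen$perm_p,
                    stringsAsFactors = FALSE)
  out$flagged <- abs(out$fold_difference) > fd_thresh & out$perm_p < p_thresh
  out$direction <- ifelse(out$fold_difference > 0, "up", "down")
  if (!is.null(top_k)) {
    flagged <- out[out$flagged, , drop = FALSE]
    ord <- order(flagged$perm_p, -abs(flagged$fold_difference))
    attr(out, "top") <- utils::head(flagged[ord, , drop = FALSE], top_k)
  }
  out
}
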
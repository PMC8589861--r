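#' Stratify samples into upper and lower quartile groups
#'
#' Splits a cohort on a per-sample scalar (e.g. a gene's DCN or expression)
#' into a high group (top quartile) and a low group (bottom quartile), each
#' of size `k = round(N / 4)` with round-half-to-even — the unique rule
#' reproducing group sizes 94, 93 and 52 at cohort sizes 376, 371 and 210.
#' Ties are broken by ascending sample id for determinism.
#'
#' @param values Numeric per-sample scores.
#' @param sample_ids Sample identifiers, same length as `values`.
#' @param gene_id Optional label of the stratifying gene.
#' @return List of class `stratification` with `high`, `low`, `k`, `rule`.
#' @export
stratify_quartiles <- function(values, sample_ids, gene_id = NA_character_) {
  if (length(values) != length(sample_ids)) stop("length mismatch")
  if (length(values) < 4L) stop("need at least 4 samples")
  if (anyNA(values)) stop("missing stratification values")
  k <- round(length(values) / 4)
  low <- sample_ids[order(values, sample_ids)][seq_len(k)]
  high <- sample_ids[order(-values, sample_ids)][seq_len(k)]
  structure(list(gene_id = gene_id, high = high, low = low,
                 k = k, rule = "quartile"),
            class = "stratification")
}

#' Stratify samples by the median
#'
#' Samples strictly above the median form the high group; samples at or
#' below the median form the low group (exact-median samples go low, for
#' determinism). With an odd number of distinct values the groups differ in
#' size by one.
#'
#' @inheritParams stratify_quartiles
#' @return List of class `stratification` with `high`, `low`, `rule`.
#' @export
stratify_median <- function(values, sample_ids, gene_id = NA_character_) {
  if (length(values) != length(sample_ids)) stop("length mismatch")
  if (length(values) < 2L) stop("need at least 2 samples")
  if (anyNA(values)) stop("missing stratification values")
  med <- stats::median(values)
  ord <- order(values, sample_ids)
  high <- sample_ids[ord][values[ord] > med]
  low <- sample_ids[ord][values[ord] <= med]
  structure(list(gene_id = gene_id, high = high, low = low,
                 k = NA_integer_, rule = "median"),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("stratification (%s%s): high n = %d, low n = %d\n", x$rule,
              if (!is.na(x$gene_id)) paste0(" on ", x$gene_id) else "",
              length(x$high), length(x$low)))
  invisible(x)
}

#' Call per-gene gain/loss status
#'
#' Thresholds the log2 SCNA value of each gene in each sample: gain if
#' strictly greater than `threshold`, loss if strictly less than
#' `-threshold`, neutral otherwise; missing values propagate.
#'
#' @param scna SCNA matrix (log2 scale, genes x samples).
#' @param threshold Positive cut-off; default 0.2.
#' @return Character matrix with entries `"gain"`, `"loss"`, `"neutral"`
#'   or `NA`.
#' @export
call_gain_loss <- function(scna, threshold = 0.2) {
  if (!(threshold > 0)) stop("threshold must be > 0")
  status <- matrix(NA_character_, nrow(scna), ncol(scna), dimnames = dimnames(scna))
  status[scna > threshold] <- "gain"
  status[scna < -threshold] <- "loss"
  status[scna >= -threshold & scna <= threshold] <- "neutral"
  status
}

#' SCNA frequency profile of a sample group
#'
#' For each gene, the fraction of the group's informative (non-missing)
#' samples called gain, and the fraction called loss carried with a negative
#' sign so that losses plot below zero. Records are returned in genome
#' order (chromosome 1..22, X, Y, then start coordinate).
#'
#' @param status Gain/loss status matrix from [call_gain_loss()].
#' @param group Non-empty character vector of sample ids (columns of
#'   `status`).
#' @param annotation Gene annotation providing the genomic order.
#' @return `data.frame` with `gene_id`, `chromosome`, `start`, `freq_gain`,
#'   `freq_loss_signed`, `n_informative`, `missing`.
#' @export
scna_frequency_profile <- function(status, group, annotation) {
  if (length(group) == 0L) stop("empty group")
  miss <- setdiff(group, colnames(status))
  if (length(miss) > 0L) stop("sample(s) not in status matrix: ",
                              paste(utils::head(miss, 5L), collapse = ", "))
  genes <- intersect(annotation$gene_id, rownames(status))
  sub <- status[genes, group, drop = FALSE]
  n_inf <- rowSums(!is.na(sub))
  freq_gain <- rowSums(sub == "gain", na.rm = TRUE) / n_inf
  freq_loss <- -rowSums(sub == "loss", na.rm = TRUE) / n_inf
  freq_gain[n_inf == 0L] <- NA_real_
  freq_loss[n_inf == 0L] <- NA_real_
  ann <- annotation[match(genes, annotation$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = genes, chromosome = ann$chromosome,
                    start = ann$start,
                    freq_gain = freq_gain, freq_loss_signed = freq_loss,
                    n_informative = n_inf, missing = n_inf == 0L,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(chrom_rank(out$chromosome), out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential SCNA frequency landscape
#'
#' Gene-wise differences of gain and signed-loss frequencies between two
#' groups (low minus high); a gene is flagged when either difference
#' exceeds `min_diff` in absolute value.
#'
#' @param profile_low,profile_high Frequency profiles from
#'   [scna_frequency_profile()] over the same gene set.
#' @param min_diff Flagging threshold; default 0.2.
#' @return `data.frame` in genome order with per-group frequencies,
#'   `diff_gain`, `diff_loss` and `flagged`.
#' @export
differential_frequency <- function(profile_low, profile_high, min_diff = 0.2) {
  if (!setequal(profile_low$gene_id, profile_high$gene_id)) {
    stop("profiles cover different gene sets")
  }
  hi <- profile_high[match(profile_low$gene_id, profile_high$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = profile_low$gene_id,
                    chromosome = profile_low$chromosome,
                    start = profile_low$start,
                    gain_low = profile_low$freq_gain,
                    gain_high = hi$freq_gain,
                    loss_low = profile_low$freq_loss_signed,
                    loss_high = hi$freq_loss_signed,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$diff_gain <- out$gain_low - out$gain_high
  out$diff_loss <- out$loss_low - out$loss_high
  flagged <- abs(out$diff_gain) > min_diff | abs(out$diff_loss) > min_diff
  flagged[is.na(flagged)] <- FALSE
  out$flagged <- flagged
  out <- out[order(chrom_rank(out$chromosome), out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot an SCNA frequency landscape
#'
#' Frequency (gains above zero, signed losses below) against cumulative
#' genomic position, with chromosome boundaries drawn as vertical lines.
#'
#' @param profile Frequency profile from [scna_frequency_profile()].
#' @param file Optional PNG path; when given the plot is written there.
#' @param main Plot title.
#' @return Invisibly, the cumulative positions used.
#' @export
plot_scna_landscape <- function(profile, file = NULL, main = "SCNA frequency") {
  ord <- order(chrom_rank(profile$chromosome), profile$start)
  profile <- profile[ord, , drop = FALSE]
  chrom <- factor(profile$chromosome, levels = chrom_levels())
  chrom <- droplevels(chrom)
  sizes <- tapply(profile$start, chrom, max)
  offset <- c(0, cumsum(as.numeric(sizes)))[seq_along(levels(chrom))]
  names(offset) <- levels(chrom)
  pos <- profile$start + offset[as.character(chrom)]
  if (!is.null(file)) grDevices::png(file, width = 1200, height = 400)
  graphics::plot(pos, profile$freq_gain, type = "h", col = "firebrick",
                 ylim = c(-1, 1), xlab = "genomic position", ylab = "frequency",
                 main = main)
  graphics::lines(pos, profile$freq_loss_signed, type = "h", col = "navy")
  graphics::abline(h = 0)
  graphics::abline(v = offset[-1], lty = 1, col = "grey40")
  if (!is.null(file)) grDevices::dev.off()
  invisible(pos)
}
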
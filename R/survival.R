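#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; at tied times events
#' are counted before censorings (the standard convention). Computed with
#' the `survival` package.
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 death, 0 censored).
#' @return Object of class `km_curve`: `time` (grid beginning at 0), `surv`
#'   (estimates, `S(0) = 1`), `n_risk`, `n_event`, `n_censor`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (length(times) != length(events)) stop("length mismatch")
  if (any(times < 0)) stop("times must be nonnegative")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(length(times), fit$n.risk),
                 n_event = c(0, fit$n.event),
                 n_censor = c(0, fit$n.censor),
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, final S = %.3f\n",
              x$n, sum(x$n_event), x$surv[length(x$surv)]))
  invisible(x)
}

#' Median survival time from a KM curve
#' @param km A `km_curve`.
#' @return Smallest time with `S(t) <= 0.5`, or `NA` if never reached.
#' @export
km_median <- function(km) {
  below <- which(km$surv <= 0.5)
  if (length(below) == 0L) NA_real_ else km$time[min(below)]
}

#' Cox-Mantel (Mantel-Haenszel) log-rank test
#'
#' Two-group log-rank test: `(sum(O - E))^2 / sum(V)` referred to a
#' chi-square distribution with 1 degree of freedom. Computed with
#' `survival::survdiff`. With no events (or identical groups) the statistic
#' is 0 and p = 1.
#'
#' @param times_a,events_a,times_b,events_b Per-group times and indicators.
#' @return List with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("both groups need at least one subject")
  }
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  if (sum(events) == 0L) {
    return(list(statistic = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  stat <- as.numeric(sd$chisq)
  if (!is.finite(stat)) stat <- 0
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' One-covariate Cox fit with Breslow tie handling; hazard ratio with Wald
#' 95% confidence interval and p-value. Monotone partial likelihood
#' (perfect separation) is flagged and the confidence interval reported as
#' unbounded.
#'
#' @param times,events Follow-up times and event indicators.
#' @param covariate Numeric covariate with nonzero variance.
#' @param name Optional covariate label.
#' @return `data.frame` of class `cox_result` with `covariate`, `coef`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `n`, `n_event`, `separated`.
#' @export
cox_univariate <- function(times, events, covariate, name = "x") {
  if (length(times) != length(covariate)) stop("length mismatch")
  if (sum(events) < 1L) stop("no events")
  if (stats::var(covariate) <= 0) stop("constant covariate")
  separated <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (separated || abs(beta) > 15) {
    separated <- TRUE
    ci <- c(0, Inf)
  } else {
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(data.frame(covariate = name, coef = beta, hr = exp(beta),
                       ci_low = ci[1], ci_high = ci[2], p = p,
                       n = length(times), n_event = sum(events),
                       separated = separated, stringsAsFactors = FALSE),
            class = c("cox_result", "data.frame"))
}

#' Survival comparison between stratified groups
#'
#' Joins a clinical table to a [stratify_quartiles()] /
#' [stratify_median()] result, optionally after restricting the cohort by a
#' gene's DCN status (e.g. keeping only samples with log2 DCN at or above
#' -0.2 as copy-number wild type), and returns the per-group KM curves and
#' the log-rank test. Group samples without a clinical record are dropped
#' and counted.
#'
#' @param clinical Clinical `data.frame` (`sample_id`, `os_time`,
#'   `os_event`).
#' @param stratification A `stratification` object.
#' @param condition_values Optional named numeric vector of per-sample log2
#'   DCN values used as a pre-filter.
#' @param condition_threshold Retain samples with
#'   `condition_values >= condition_threshold` (default -0.2, the copy-loss
#'   call boundary); samples below it are excluded as deleted.
#' @return List with `km_high`, `km_low`, `logrank`, `n_high`, `n_low`,
#'   `n_dropped`.
#' @export
stratified_survival <- function(clinical, stratification,
                                condition_values = NULL,
                                condition_threshold = -0.2) {
  high <- stratification$high
  low <- stratification$low
  if (!is.null(condition_values)) {
    keep <- names(condition_values)[!is.na(condition_values) &
                                      condition_values >= condition_threshold]
    high <- intersect(high, keep)
    low <- intersect(low, keep)
  }
  cl <- clinical[match(c(high, low), clinical$sample_id), , drop = FALSE]
  known <- !is.na(cl$sample_id)
  n_dropped <- sum(!known)
  if (n_dropped > 0L) {
    message(n_dropped, " stratified sample(s) lack clinical records; dropped")
  }
  grp_high <- cl$sample_id %in% high & known
  grp_low <- cl$sample_id %in% low & known
  if (sum(grp_high) == 0L || sum(grp_low) == 0L) {
    stop("empty intersection of stratification groups and clinical records")
  }
  km_high <- km_estimate(cl$os_time[grp_high], cl$os_event[grp_high])
  km_low <- km_estimate(cl$os_time[grp_low], cl$os_event[grp_low])
  lr <- logrank_test(cl$os_time[grp_high], cl$os_event[grp_high],
                     cl$os_time[grp_low], cl$os_event[grp_low])
  list(km_high = km_high, km_low = km_low, logrank = lr,
       n_high = sum(grp_high), n_low = sum(grp_low), n_dropped = n_dropped)
}

#' Univariate Cox hazard table over a gene list
#'
#' One univariate Cox fit per gene, the covariate being the gene's
#' expression standardized to unit variance (hazard ratios are per standard
#' deviation). Duplicated genes collapse to one row; the table is sorted by
#' hazard ratio.
#'
#' @param clinical Clinical `data.frame`.
#' @param de DE (or expression) matrix, genes x samples.
#' @param genes Character vector of gene ids; all must be in `de`.
#' @return `data.frame` of per-gene Cox results sorted by `hr`.
#' @export
hazard_table <- function(clinical, de, genes) {
  genes <- unique(genes)
  missing_genes <- setdiff(genes, rownames(de))
  if (length(missing_genes) > 0L) {
    stop("gene(s) absent from the matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  samples <- intersect(clinical$sample_id, colnames(de))
  cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  rows <- lapply(genes, function(g) {
    z <- as.vector(scale(de[g, samples]))
    res <- cox_univariate(cl$os_time, cl$os_event, z, name = g)
    res
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "covariate"] <- "gene_id"
  out <- out[order(out$hr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot Kaplan-Meier curves for two groups
#'
#' @param km_high,km_low `km_curve` objects.
#' @param file Optional PNG path.
#' @param main Title.
#' @param labels Legend labels.
#' @export
plot_km_pair <- function(km_high, km_low, file = NULL,
                         main = "Overall survival",
                         labels = c("high", "low")) {
  if (!is.null(file)) grDevices::png(file, width = 600, height = 600)
  graphics::plot(km_high$time, km_high$surv, type = "s", col = "firebrick",
                 ylim = c(0, 1), xlab = "time", ylab = "survival fraction",
                 main = main, lwd = 2)
  graphics::lines(km_low$time, km_low$surv, type = "s", col = "navy", lwd = 2)
  graphics::legend("bottomleft", legend = labels, lwd = 2,
                   col = c("firebrick", "navy"), bty = "n")
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
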
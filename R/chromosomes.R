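#' Ordered human chromosome labels
#'
#' The fixed chromosome ordering used for every genome-ordered output:
#' autosomes 1-22 followed by X and Y. Input labels with or without a
#' `"chr"` prefix are accepted everywhere and normalized to this set.
#'
#' @return Character vector of the 24 ordered chromosome labels.
#' @export
chrom_levels <- function() {
  c(as.character(1:22), "X", "Y")
}

#' Normalize chromosome labels
#'
#' Strips any `"chr"` prefix and validates against [chrom_levels()].
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  bad <- setdiff(unique(x), chrom_levels())
  if (length(bad) > 0L) {
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  }
  x
}

# integer rank of a chromosome label in the fixed genome order
chrom_rank <- function(x) {
  match(normalize_chrom(x), chrom_levels())
}
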
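#' Read a SEG file of segmented copy number
#'
#' Reads tab-separated segmented DNA copy number (DCN) with required header
#' columns `sample`, `chromosome`, `start`, `end`, `value` (case-insensitive;
#' the common `Segment_Mean`-style headers are not guessed). Values are linear
#' copy ratios (> 0). Coordinates are converted from the input dialect to the
#' internal 0-based half-open convention, so a 1 bp segment written as
#' `start = 1, end = 1` in 1-based inclusive coordinates has internal span
#' `[0, 1)` and length 1.
#'
#' Segments belonging to one sample on one chromosome must not overlap; an
#' overlap raises a validation error naming the sample (downgraded to a
#' warning with `permissive = TRUE`, for real-world SEG exports that contain
#' duplicated or overlapping calls).
#'
#' @param path Path to the SEG file.
#' @param dialect Coordinate convention of the file: `"one-based-inclusive"`
#'   (the usual SEG convention, default) or `"zero-based-half-open"`.
#' @param permissive Logical; downgrade overlap errors to warnings.
#' @return A `data.frame` with columns `sample`, `chromosome`, `start`,
#'   `end`, `value` in internal coordinates.
#' @export
read_seg <- function(path, dialect = c("one-based-inclusive", "zero-based-half-open"),
                     permissive = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("sample", "chromosome", "start", "end", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("SEG format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[need]
  if (nrow(raw) == 0L) {
    return(empty_seg())
  }
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  value <- suppressWarnings(as.numeric(raw$value))
  if (dialect == "one-based-inclusive") start <- start - 1
  bad <- which(is.na(start) | is.na(end) | is.na(value) |
                 start != floor(start) | end != floor(end) |
                 start >= end | value <= 0 | raw$sample == "")
  if (length(bad) > 0L) {
    stop("SEG format error: malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  segs <- data.frame(sample = raw$sample,
                     chromosome = normalize_chrom(raw$chromosome),
                     start = as.integer(start), end = as.integer(end),
                     value = value, stringsAsFactors = FALSE)
  validate_seg_overlaps(segs, permissive = permissive)
  segs[order(segs$sample, chrom_rank(segs$chromosome), segs$start), , drop = FALSE]
}

empty_seg <- function() {
  data.frame(sample = character(), chromosome = character(),
             start = integer(), end = integer(), value = numeric(),
             stringsAsFactors = FALSE)
}

validate_seg_overlaps <- function(segs, permissive = FALSE) {
  key <- split(seq_len(nrow(segs)), paste(segs$sample, segs$chromosome, sep = "\r"))
  for (idx in key) {
    if (length(idx) < 2L) next
    o <- idx[order(segs$start[idx])]
    if (any(segs$start[o][-1L] < segs$end[o][-length(o)])) {
      msg <- paste0("overlapping segments for sample ", segs$sample[o][1L],
                    " on chromosome ", segs$chromosome[o][1L])
      if (permissive) warning(msg) else stop(msg)
    }
  }
  invisible(segs)
}

#' Write segments to a SEG file
#'
#' Inverse of [read_seg()]; internal 0-based half-open coordinates are
#' converted back to the requested dialect.
#'
#' @param segs Segment `data.frame` as returned by [read_seg()].
#' @param path Output path.
#' @inheritParams read_seg
#' @export
write_seg <- function(segs, path,
                      dialect = c("one-based-inclusive", "zero-based-half-open")) {
  dialect <- match.arg(dialect)
  out <- segs[c("sample", "chromosome", "start", "end", "value")]
  if (dialect == "one-based-inclusive") out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' TSV with a header; first column holds gene identifiers, remaining columns
#' one sample each. Values must be nonnegative finite abundances (FPKM-like).
#' Duplicate gene rows or duplicate sample columns are errors.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (ncol(raw) < 2L) stop("expression format error: need gene_id plus sample columns")
  genes <- as.character(raw[[1L]])
  if (anyDuplicated(genes)) {
    stop("expression validation error: duplicated gene_id ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- names(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("expression validation error: duplicated sample column ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  mat <- as.matrix(raw[-1L])
  if (!is.numeric(mat)) stop("expression validation error: non-numeric values")
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("expression validation error: missing or non-finite values")
  }
  if (any(mat < 0)) stop("expression validation error: negative values")
  dimnames(mat) <- list(genes, samples)
  mat
}

#' Read a general numeric gene-by-sample matrix
#'
#' Like [read_expression()] but without the nonnegativity constraint, for
#' derived matrices on the log2 scale (DE, SCNA, gene-level DCN) where
#' negative and missing (`NA`) entries are legitimate.
#'
#' @param path Path to the TSV file (first column gene ids, header row of
#'   sample ids).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (ncol(raw) < 2L) stop("matrix format error: need gene_id plus sample columns")
  genes <- as.character(raw[[1L]])
  if (anyDuplicated(genes)) stop("matrix validation error: duplicated gene_id")
  if (anyDuplicated(names(raw)[-1L])) stop("matrix validation error: duplicated sample column")
  mat <- as.matrix(raw[-1L])
  if (!is.numeric(mat)) stop("matrix validation error: non-numeric values")
  dimnames(mat) <- list(genes, names(raw)[-1L])
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @param id_column Name for the gene identifier column.
#' @export
write_expression <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene annotation
#'
#' Headerless five-column TSV: chromosome, start, end, gene_id, symbol, with
#' BED's 0-based half-open coordinates (kept as the internal convention).
#' Unknown chromosome labels, non-positive spans and duplicate gene ids are
#' errors. Strand, if present as a sixth column, is ignored: copy number and
#' expression are strand-agnostic here.
#'
#' @param path Path to the annotation file.
#' @return `data.frame` with columns `gene_id`, `symbol`, `chromosome`,
#'   `start`, `end`, sorted in genome order.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 5L) stop("annotation format error: need 5 columns (chrom, start, end, gene_id, symbol)")
  ann <- data.frame(gene_id = raw[[4L]], symbol = raw[[5L]],
                    chromosome = normalize_chrom(raw[[1L]]),
                    start = suppressWarnings(as.integer(raw[[2L]])),
                    end = suppressWarnings(as.integer(raw[[3L]])),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(ann$start) | is.na(ann$end) | ann$start >= ann$end)
  if (length(bad) > 0L) {
    stop("annotation validation error: start >= end (or unparsable) at line(s) ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ann$gene_id)) {
    stop("annotation validation error: duplicated gene_id ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  }
  ann[order(chrom_rank(ann$chromosome), ann$start), , drop = FALSE]
}

#' Write a gene annotation as BED-like TSV
#'
#' @param annotation Annotation `data.frame` from [read_gene_annotation()].
#' @param path Output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  out <- annotation[c("chromosome", "start", "end", "gene_id", "symbol")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a subclass template (signature) file
#'
#' TSV with header columns `class`, `gene_id`, `direction`; directions are
#' +1 (up in the class) or -1 (down). Every class must carry at least one
#' signature gene and a gene may appear once per class.
#'
#' @param path Path to the template TSV.
#' @return Named list (one element per class) of `data.frame`s with columns
#'   `gene_id` and `direction`.
#' @export
read_templates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character")
  names(raw) <- tolower(names(raw))
  need <- c("class", "gene_id", "direction")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("template format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  dir <- suppressWarnings(as.numeric(raw$direction))
  if (anyNA(dir) || !all(dir %in% c(-1, 1))) {
    stop("template validation error: direction must be +1 or -1")
  }
  if (any(raw$class == "") || any(raw$gene_id == "")) {
    stop("template validation error: empty class or gene_id")
  }
  tmpl <- lapply(split(data.frame(gene_id = raw$gene_id, direction = dir,
                                  stringsAsFactors = FALSE),
                       raw$class), function(d) {
    if (anyDuplicated(d$gene_id)) stop("template validation error: duplicated gene in a class")
    rownames(d) <- NULL
    d
  })
  if (length(tmpl) == 0L) stop("template validation error: no classes")
  tmpl
}

#' Write a template set to TSV
#'
#' @param templates Named list of per-class signature `data.frame`s
#'   (`gene_id`, `direction`).
#' @param path Output path.
#' @export
write_templates <- function(templates, path) {
  out <- do.call(rbind, lapply(names(templates), function(cl) {
    data.frame(class = cl, gene_id = templates[[cl]]$gene_id,
               direction = templates[[cl]]$direction, stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with header columns `sample_id`, `os_time` (nonnegative overall
#' survival time), `os_event` (0 censored / 1 death); extra covariate columns
#' are carried along untouched.
#'
#' @param path Path to the clinical TSV.
#' @return `data.frame` with at least `sample_id`, `os_time`, `os_event`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cl <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(need, names(cl))
  if (length(missing_cols) > 0L) {
    stop("clinical format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(cl$os_time)) || any(cl$os_time < 0)) {
    stop("clinical validation error: os_time must be nonnegative")
  }
  if (!all(cl$os_event %in% c(0, 1))) {
    stop("clinical validation error: os_event must be 0 or 1")
  }
  cl
}

#' Write a clinical table to TSV
#' @param clinical Clinical `data.frame`.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a validated cohort dataset
#'
#' Bundles paired tumor (PT) / non-tumor (NT) expression, segmented DCN,
#' annotation and clinical data into one object, recording the PT sample
#' intersection between the expression and DCN assays (the samples that
#' harbor both data types, on which DE-SCNA association is computed).
#' Samples present in only one assay are kept in that assay and logged, not
#' dropped. Every PT DCN sample must have a paired NT DCN sample through
#' `pairing`.
#'
#' @param expression_pt,expression_nt Genes-by-samples matrices (FPKM-like).
#' @param dcn_pt,dcn_nt Segment `data.frame`s as from [read_seg()].
#' @param annotation Gene annotation from [read_gene_annotation()].
#' @param clinical Optional clinical `data.frame`; rows for samples unknown
#'   to any assay are set aside with a warning.
#' @param pairing Named character vector mapping PT DCN sample ids to their
#'   matched NT DCN sample ids.
#' @return Object of class `cohort_dataset`.
#' @export
assemble_cohort <- function(expression_pt, expression_nt, dcn_pt, dcn_nt,
                            annotation, clinical = NULL, pairing) {
  pt_dcn_samples <- unique(dcn_pt$sample)
  nt_dcn_samples <- unique(dcn_nt$sample)
  unpaired <- setdiff(pt_dcn_samples, names(pairing))
  if (length(unpaired) > 0L) {
    stop("cohort validation error: PT DCN sample(s) without a pairing entry: ",
         paste(utils::head(unpaired, 5L), collapse = ", "))
  }
  bad_pair <- setdiff(pairing[pt_dcn_samples], nt_dcn_samples)
  if (length(bad_pair) > 0L) {
    stop("cohort validation error: paired NT DCN sample(s) absent: ",
         paste(utils::head(bad_pair, 5L), collapse = ", "))
  }
  both <- intersect(colnames(expression_pt), pt_dcn_samples)
  expr_only <- setdiff(colnames(expression_pt), pt_dcn_samples)
  dcn_only <- setdiff(pt_dcn_samples, colnames(expression_pt))
  message(sprintf("cohort: %d PT samples with both expression and DCN (%d expression-only, %d DCN-only)",
                  length(both), length(expr_only), length(dcn_only)))
  clinical_unmatched <- NULL
  if (!is.null(clinical)) {
    known <- union(colnames(expression_pt), pt_dcn_samples)
    unknown <- !(clinical$sample_id %in% known)
    if (any(unknown)) {
      warning(sum(unknown), " clinical row(s) for unknown samples kept aside")
      clinical_unmatched <- clinical[unknown, , drop = FALSE]
      clinical <- clinical[!unknown, , drop = FALSE]
    }
  }
  structure(list(expression_pt = expression_pt,
                 expression_nt = expression_nt,
                 dcn_pt = dcn_pt, dcn_nt = dcn_nt,
                 annotation = annotation, clinical = clinical,
                 clinical_unmatched = clinical_unmatched,
                 pairing = pairing,
                 samples_both = both,
                 samples_expression_only = expr_only,
                 samples_dcn_only = dcn_only),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset\n")
  cat(sprintf("  expression: %d genes x %d PT / %d NT samples\n",
              nrow(x$expression_pt), ncol(x$expression_pt), ncol(x$expression_nt)))
  cat(sprintf("  DCN: %d PT / %d NT samples (segments: %d / %d)\n",
              length(unique(x$dcn_pt$sample)), length(unique(x$dcn_nt$sample)),
              nrow(x$dcn_pt), nrow(x$dcn_nt)))
  cat(sprintf("  annotation: %d genes; intersection (expression & DCN): %d PT samples\n",
              nrow(x$annotation), length(x$samples_both)))
  if (!is.null(x$clinical)) cat(sprintf("  clinical: %d samples\n", nrow(x$clinical)))
  invisible(x)
}

#' Curated human mitoribosomal protein (MRP) gene set
#'
#' The 82 nuclear-encoded mitochondrial ribosomal protein genes bundled with
#' the package: 33 small-subunit (28S) genes, counting DAP3 (MRPS29), CHCHD1
#' (MRPS37), AURKAIP1 (MRPS38) and PTCD3 (MRPS39), and 49 large-subunit (39S)
#' genes, counting MRPL58 (ICT1). Used as the focal gene set when screening
#' for copy-number-driven genes.
#'
#' @return `data.frame` with columns `symbol` and `subunit` (`"SSU"`/`"LSU"`).
#' @export
mrp_genes <- function() {
  path <- system.file("extdata", "mrp_genes.tsv", package = "scnadriver",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
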
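#' Construct an OTU count table
#'
#' The universal community object of the package: a non-negative integer
#' matrix with samples as rows and OTUs as columns, both uniquely named.
#'
#' @param counts numeric matrix (samples x OTUs) of non-negative finite
#'   counts; dimnames are used when `sample_ids`/`otu_ids` are missing.
#' @param sample_ids,otu_ids optional character vectors of unique ids.
#' @return an object of class `otu_table` (a named integer matrix).
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  if (anyDuplicated(sample_ids)) stop_invalid("duplicate sample ids")
  if (anyDuplicated(otu_ids)) stop_invalid("duplicate OTU ids")
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop_invalid("id lengths do not match table dimensions")
  if (!all(is.finite(counts))) stop_invalid("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(apply(counts < 0, 1L, any))[1L]
    stop_invalid("negative count in row '", sample_ids[bad], "'")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sample_ids, otu_ids)
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

as_counts <- function(table) {
  m <- unclass(table)
  class(m) <- NULL
  m <- as.matrix(m)
  m
}

#' Read an OTU table from TSV or BIOM
#'
#' TSV layout follows the field convention: rows are OTUs, columns are
#' samples, first column holds OTU ids.  BIOM files are read with the
#' biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return an [otu_table] (samples x OTUs).
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_invalid("the biomformat package is required for BIOM files")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # OTUs x samples
    return(otu_table(t(m)))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, comment.char = "")
  otu_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_invalid("non-numeric counts in ", path)
  if (anyDuplicated(otu_ids))
    stop_invalid("duplicate OTU ids in ", path, ": ",
                 otu_ids[duplicated(otu_ids)][1L])
  if (any(m < 0)) {
    bad <- otu_ids[which(apply(m < 0, 1L, any))[1L]]
    stop_invalid("negative count in OTU row '", bad, "' of ", path)
  }
  rownames(m) <- otu_ids
  otu_table(t(m))
}

#' Write an OTU table
#'
#' @param table an [otu_table].
#' @param path output file.
#' @param format `"tsv"` (OTUs as rows) or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  m <- t(as_counts(table))  # OTUs x samples
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_invalid("the biomformat package is required for BIOM files")
    b <- biomformat::make_biom(m)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy every sample to a fixed depth
#'
#' Subsamples reads without replacement (hypergeometric marginals), the
#' standard normalization for unequal sequencing effort.  Samples with
#' fewer than `depth` reads are dropped with a warning.
#'
#' @param table an [otu_table].
#' @param depth target reads per sample (> 0).
#' @param seed optional integer seed.
#' @return an [otu_table] in which every retained sample sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (!is.numeric(depth) || depth <= 0) stop_invalid("depth must be > 0")
  depth <- as.integer(depth)
  m <- as_counts(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop_invalid("no sample reaches the rarefaction depth")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m)[!keep], collapse = ", "), call. = FALSE)
  m <- m[keep, , drop = FALSE]
  with_seed(seed, {
    out <- m
    for (i in seq_len(nrow(m))) {
      x <- m[i, ]
      if (sum(x) == depth) next
      pool <- rep.int(seq_along(x), x)
      drawn <- sample(pool, depth)
      out[i, ] <- tabulate(drawn, nbins = length(x))
    }
    otu_table(out, rownames(m), colnames(m))
  })
}

#' Filter OTUs by prevalence
#'
#' Keeps OTUs detected (count > 0) in strictly more than `min_fraction` of
#' the samples, the "more than 60\%" rule used before network construction.
#'
#' @param table an [otu_table].
#' @param min_fraction prevalence threshold in (0, 1]; strict inequality.
#' @return filtered [otu_table]; may have zero OTUs.
#' @export
filter_prevalence <- function(table, min_fraction) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop_invalid("min_fraction must be in (0, 1]")
  m <- as_counts(table)
  prev <- colMeans(m > 0)
  otu_table(m[, prev > min_fraction, drop = FALSE],
            rownames(m), colnames(m)[prev > min_fraction])
}

#' Convert counts to relative abundances
#'
#' @param table an [otu_table] with positive sample totals.
#' @return numeric matrix (samples x OTUs) with rows summing to 1.
#' @export
relative_abundance <- function(table) {
  m <- as_counts(table)
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop_invalid("zero-sum sample(s): ",
                 paste(rownames(m)[totals <= 0], collapse = ", "))
  sweep(m, 1L, totals, "/")
}
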
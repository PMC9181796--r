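#' FPKM quantification
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM[g, s] = counts[g, s] / ((length_bp[g] / 1e3) * (total[s] / 1e6))`,
#' where `total[s]` is the column sum of the supplied count matrix (the
#' only fragment total available once quantification starts from a count
#' table).
#'
#' @param cm a [count_matrix()].
#' @return Numeric matrix of FPKM values with the count matrix's dimnames
#'   and attribute `provenance = "fpkm"`.
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop("sample(s) with zero total counts: ",
         paste(zero, collapse = ", "), call. = FALSE)
  fpkm <- cm$counts /
    outer(cm$gene_lengths / 1e3, totals / 1e6)
  attr(fpkm, "provenance") <- "fpkm"
  fpkm
}

#' Within-group replicate correlation QC
#'
#' Pairwise Pearson correlation of `log10(FPKM + 1)` between replicates of
#' each sample group. A constant replicate vector has no defined
#' correlation; such pairs are reported as `NA` rather than raising.
#'
#' @param expr expression matrix (FPKM), genes x samples.
#' @param groups group label per column of `expr`.
#' @return Named list of per-group symmetric correlation matrices (unit
#'   diagonal), with a `summary` attribute holding the min/median/max
#'   off-diagonal correlation across groups.
#' @export
replicate_correlation <- function(expr, groups) {
  stopifnot(ncol(expr) == length(groups))
  lx <- log10(expr + 1)
  out <- list()
  offdiag <- numeric()
  for (g in unique(groups)) {
    sub <- lx[, groups == g, drop = FALSE]
    if (ncol(sub) < 2)
      stop("group ", g, " has fewer than 2 replicates", call. = FALSE)
    cc <- suppressWarnings(stats::cor(sub))  # constant column -> NA
    diag(cc) <- 1
    out[[g]] <- cc
    offdiag <- c(offdiag, cc[upper.tri(cc)])
  }
  defined <- offdiag[!is.na(offdiag)]
  attr(out, "summary") <- list(
    min = if (length(defined)) min(defined) else NA_real_,
    median = if (length(defined)) stats::median(defined) else NA_real_,
    max = if (length(defined)) max(defined) else NA_real_,
    n_undefined = sum(is.na(offdiag)))
  out
}

#' Write the replicate-correlation QC summary as JSON
#'
#' @param qc result of [replicate_correlation()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_qc_summary <- function(qc, path) {
  jsonlite::write_json(attr(qc, "summary"), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
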
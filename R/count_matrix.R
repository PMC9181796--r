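#' Count matrix with sample metadata and gene lengths
#'
#' Container tying together an integer genes-by-samples fragment-count
#' matrix, a sample sheet (sample, group, tissue, replicate) and a
#' per-gene transcript length in bp.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param samples data.frame with columns `sample`, `group` and
#'   `replicate`; a `tissue` column is derived from the group label when
#'   absent.
#' @param gene_lengths named positive integer vector (bp) covering every
#'   gene in `counts`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample names", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"

  req <- c("sample", "group", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!"tissue" %in% names(samples))
    samples$tissue <- group_tissue(samples$group)
  if (!setequal(samples$sample, colnames(counts)) ||
      anyDuplicated(samples$sample))
    stop("sample sheet does not match count-matrix columns", call. = FALSE)
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL

  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len))
    stop("gene lengths missing for: ",
         paste(utils::head(missing_len, 5), collapse = ", "),
         if (length(missing_len) > 5) ", ...", call. = FALSE)
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0) || anyNA(gene_lengths))
    stop("gene lengths must be positive", call. = FALSE)

  structure(list(counts = counts, samples = samples,
                 gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d groups)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$group))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Samples belonging to a group
#'
#' @param cm a [count_matrix()].
#' @param group a group label.
#' @return Character vector of sample names.
#' @export
group_samples <- function(cm, group) {
  cm$samples$sample[cm$samples$group == group]
}

#' Read and write pipeline tables
#'
#' TSV round-trip of the pipeline's file formats: a count table (first
#' column `gene_id`, one column per sample), a sample sheet
#' (`sample`, `tissue`, `group`/`condition`, `replicate`), a two-column
#' gene-length table (`gene_id`, `length`) and the simulator's truth
#' table.
#'
#' @param path file path.
#' @return `read_counts`: integer matrix; `read_sample_sheet`,
#'   `read_gene_lengths`, `read_truth`: data.frames (lengths as a named
#'   vector).
#' @name pipeline_io
NULL

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' @rdname pipeline_io
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- which(is.na(m) | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer count at gene %s, sample %s in %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path),
         call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname pipeline_io
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path)
  names(df)[names(df) == "condition"] <- "group"
  req <- c("sample", "group", "replicate")
  if (!all(req %in% names(df)))
    stop("sample sheet ", path, " needs columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  df
}

#' @rdname pipeline_io
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2)
    stop("gene-length table ", path, " needs two columns", call. = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' @rdname pipeline_io
#' @export
read_truth <- function(path) read_tsv_checked(path)

#' Write a simulated experiment to TSV files
#'
#' Writes the four round-trippable artefacts of [simulate_counts()]:
#' `counts.tsv`, `samples.tsv`, `gene_lengths.tsv` and `truth.tsv`.
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv",
                            "gene_lengths.tsv", "truth.tsv"))
  write_matrix_tsv(sim$counts$counts, paths[1])
  utils::write.table(sim$counts$samples, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(sim$counts$gene_lengths),
               length = unname(sim$counts$gene_lengths)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Validate pipeline inputs
#'
#' Cross-checks gene-id agreement between counts, lengths and annotations,
#' replicate counts, and count integrality, distinguishing fatal errors
#' from warnings (e.g. annotation genes absent from the count matrix,
#' which are dropped downstream).
#'
#' @param counts integer gene x sample matrix.
#' @param samples sample sheet data.frame.
#' @param gene_lengths named length vector.
#' @param annotations optional annotation data.frame
#'   (see [read_gmt()]).
#' @return data.frame of diagnostics with columns `level`
#'   ("error"/"warning") and `message`; zero rows when everything checks
#'   out.
#' @export
validate_inputs <- function(counts, samples, gene_lengths,
                            annotations = NULL) {
  diags <- list()
  note <- function(level, msg)
    diags[[length(diags) + 1L]] <<- data.frame(level = level, message = msg,
                                               stringsAsFactors = FALSE)

  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    note("error", sprintf("non-integer or negative count at gene %s, sample %s",
                          rownames(counts)[bad[1, 1]],
                          colnames(counts)[bad[1, 2]]))

  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len))
    note("error", paste("gene length missing for:",
                        paste(utils::head(missing_len, 5), collapse = ", ")))

  missing_samp <- setdiff(colnames(counts), samples$sample)
  if (length(missing_samp))
    note("error", paste("samples absent from sample sheet:",
                        paste(missing_samp, collapse = ", ")))

  reps <- table(samples$group[samples$sample %in% colnames(counts)])
  low <- names(reps)[reps < 2]
  if (length(low))
    note("error", paste("groups with fewer than 2 replicates:",
                        paste(low, collapse = ", ")))

  if (!is.null(annotations)) {
    extra <- setdiff(unique(annotations$gene_id), rownames(counts))
    if (length(extra))
      note("warning", sprintf(
        "%d annotation genes absent from the count matrix will be dropped",
        length(extra)))
  }

  if (length(diags)) do.call(rbind, diags) else
    data.frame(level = character(), message = character(),
               stringsAsFactors = FALSE)
}
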
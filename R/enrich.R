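#' Read term annotations from a GMT file
#'
#' One term per line: `term_id <tab> description <tab> gene1 <tab> gene2
#' ...`. Returns the long annotation table used by
#' [hypergeom_enrich()]. The description column is kept as `term_name`
#' (readers that return bare membership lists drop it).
#'
#' @param path GMT file path.
#' @param category annotation category assigned to every term in the file
#'   ("BP", "MF", "CC" or "pathway").
#' @return data.frame with columns `term_id`, `term_name`, `category`,
#'   `gene_id`.
#' @export
read_gmt <- function(path, category = "pathway") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d in %s: need term, description ",
                   i, path), "and at least one gene", call. = FALSE)
    data.frame(term_id = f[1], term_name = f[2], category = category,
               gene_id = unique(f[-(1:2)]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a two-column gene-to-term table
#'
#' @param path TSV with columns `gene_id` and `term_id` (optional
#'   `term_name`, `category`).
#' @param category default category when the file has none.
#' @return Annotation data.frame as in [read_gmt()].
#' @export
read_gene2term <- function(path, category = "pathway") {
  df <- read_tsv_checked(path)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("gene-to-term table ", path,
         " needs columns gene_id and term_id", call. = FALSE)
  if (!"term_name" %in% names(df)) df$term_name <- df$term_id
  if (!"category" %in% names(df)) df$category <- category
  df[, c("term_id", "term_name", "category", "gene_id")]
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term with `K` background genes annotated and `k` of the `n`
#' query genes annotated, the upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` over a background universe of `N` genes
#' (one-sided over-representation). BH adjustment is applied within each
#' annotation category separately by default, mirroring separate GO and
#' pathway analyses; set `adjust_by_category = FALSE` for a single global
#' adjustment.
#'
#' @param gene_set character vector of query genes; must be a subset of
#'   `background`.
#' @param background character vector, the gene universe.
#' @param annotations annotation data.frame ([read_gmt()] /
#'   [read_gene2term()]); genes absent from the background are dropped
#'   with a message.
#' @param enrich_fdr FDR threshold for the `enriched` flag (default 0.05).
#' @param adjust_by_category BH within category (default) or globally.
#' @return data.frame sorted by ascending `p` (ties by `term_id`):
#'   `term_id`, `term_name`, `category`, `k`, `K`, `n`, `N`, `p`, `fdr`,
#'   `enriched`.
#' @export
hypergeom_enrich <- function(gene_set, background, annotations,
                             enrich_fdr = 0.05,
                             adjust_by_category = TRUE) {
  background <- unique(as.character(background))
  gene_set <- unique(as.character(gene_set))
  stray <- setdiff(gene_set, background)
  if (length(stray))
    stop("gene set not contained in background: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ...", call. = FALSE)

  dropped <- !(annotations$gene_id %in% background)
  if (any(dropped)) {
    message(sprintf(
      "hypergeom_enrich: dropping %d annotation rows outside the background",
      sum(dropped)))
    annotations <- annotations[!dropped, , drop = FALSE]
  }
  if (!nrow(annotations))
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))

  N <- length(background)
  n <- length(gene_set)
  terms <- unique(annotations[, c("term_id", "term_name", "category")])
  memb <- split(annotations$gene_id, annotations$term_id)
  K <- vapply(memb, function(g) length(unique(g)), integer(1))
  k <- vapply(memb, function(g)
    length(intersect(unique(g), gene_set)), integer(1))
  terms$K <- K[terms$term_id]
  terms$k <- k[terms$term_id]
  terms$n <- n
  terms$N <- N
  terms$p <- stats::phyper(terms$k - 1, terms$K, N - terms$K, n,
                           lower.tail = FALSE)
  if (adjust_by_category) {
    terms$fdr <- NA_real_
    for (cat in unique(terms$category)) {
      idx <- terms$category == cat
      terms$fdr[idx] <- bh_adjust(terms$p[idx])
    }
  } else {
    terms$fdr <- bh_adjust(terms$p)
  }
  terms$enriched <- terms$fdr <= enrich_fdr
  terms <- terms[order(terms$p, terms$term_id), ]
  rownames(terms) <- NULL
  terms[, c("term_id", "term_name", "category", "k", "K", "n", "N",
            "p", "fdr", "enriched")]
}

#' Top enriched terms
#'
#' First `count` records by ascending p-value, ties broken by
#' lexicographic `term_id`.
#'
#' @param records result of [hypergeom_enrich()].
#' @param count number of terms to keep (e.g. 20 for GO, 10 for
#'   pathways).
#' @return Subset of `records` in selection order.
#' @export
top_terms <- function(records, count) {
  ord <- order(records$p, records$term_id)
  records[utils::head(ord, count), , drop = FALSE]
}

#' Direction score of a gene set
#'
#' The signed balance of up- versus down-regulated members used to colour
#' enrichment bubble plots: `(up - down) / total`, in \[-1, 1\].
#'
#' @param up_count,down_count numbers of up- and down-regulated genes.
#' @param total_count total genes considered; `up + down <= total`,
#'   `total > 0`.
#' @return Numeric score.
#' @export
direction_score <- function(up_count, down_count, total_count) {
  if (any(total_count <= 0))
    stop("total_count must be > 0", call. = FALSE)
  if (any(up_count + down_count > total_count))
    stop("up_count + down_count exceeds total_count", call. = FALSE)
  (up_count - down_count) / total_count
}

#' Term-gene edge list for network consumers
#'
#' Pairs each (optionally enriched-only) term with its query-set member
#' genes, replacing graph construction with a plain edge table.
#'
#' @param records result of [hypergeom_enrich()].
#' @param annotations the annotation data.frame used for the enrichment.
#' @param gene_set the query gene set.
#' @param enriched_only keep only terms flagged enriched (default TRUE).
#' @return data.frame with columns `term_id`, `gene_id`.
#' @export
enrichment_edges <- function(records, annotations, gene_set,
                             enriched_only = TRUE) {
  keep <- if (enriched_only) records$term_id[records$enriched] else
    records$term_id
  sub <- annotations[annotations$term_id %in% keep &
                     annotations$gene_id %in% gene_set, ]
  out <- unique(sub[, c("term_id", "gene_id")])
  rownames(out) <- NULL
  out
}
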
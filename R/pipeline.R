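#' Pipeline configuration
#'
#' One declarative object driving every stage: either a simulation design
#' (`simulate`) or input file paths (`counts`, `sample_sheet`,
#' `gene_lengths`), plus optional annotations, the contrast roster,
#' thresholds and the seed.
#'
#' @param simulate NULL, a [simulation_design()], or a named list of
#'   arguments for one.
#' @param counts,sample_sheet,gene_lengths input TSV paths (real-data
#'   mode).
#' @param annotations optional GMT path or annotation data.frame.
#' @param annotation_category category label when `annotations` is a GMT
#'   path.
#' @param contrasts named list with `root` and/or `shoot` contrast name
#'   vectors; defaults to [default_contrasts()].
#' @param thresholds a [deg_thresholds()] list.
#' @param precision decimals for rendered percentages.
#' @param seed integer seed; overrides the design's seed in simulation
#'   mode.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(simulate = NULL, counts = NULL,
                            sample_sheet = NULL, gene_lengths = NULL,
                            annotations = NULL,
                            annotation_category = "pathway",
                            contrasts = default_contrasts(),
                            thresholds = deg_thresholds(),
                            precision = 2, seed = 1L) {
  if (is.null(simulate) &&
      (is.null(counts) || is.null(sample_sheet) || is.null(gene_lengths)))
    stop("config needs either 'simulate' or all of counts/sample_sheet/",
         "gene_lengths", call. = FALSE)
  if (!is.null(simulate) && !inherits(simulate, "simulation_design"))
    simulate <- do.call(simulation_design, simulate)
  thresholds <- do.call(deg_thresholds, thresholds)
  structure(list(simulate = simulate, counts = counts,
                 sample_sheet = sample_sheet, gene_lengths = gene_lengths,
                 annotations = annotations,
                 annotation_category = annotation_category,
                 contrasts = contrasts, thresholds = thresholds,
                 precision = precision, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors [pipeline_config()]'s arguments; a `simulate` mapping
#' holds [simulation_design()] arguments, an `inputs` mapping holds the
#' file paths.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    simulate = y$simulate,
    counts = y$inputs$counts, sample_sheet = y$inputs$sample_sheet,
    gene_lengths = y$inputs$gene_lengths,
    annotations = y$inputs$annotations)
  if (!is.null(y$contrasts)) args$contrasts <- y$contrasts
  if (!is.null(y$thresholds)) args$thresholds <- y$thresholds
  if (!is.null(y$precision)) args$precision <- y$precision
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$annotation_category))
    args$annotation_category <- y$annotation_category
  do.call(pipeline_config, args)
}

stage_msg <- function(...) message("[splitSulfur] ", sprintf(...))

write_gene_list <- function(genes, dir, name) {
  path <- file.path(dir, paste0(name, ".txt"))
  writeLines(sort(genes), path)
  length(genes)
}

#' Run the full split-root pipeline
#'
#' simulate/load -> FPKM + replicate QC -> per-contrast NB Wald DE ->
#' root/shoot response classification -> tissue-common overlap ->
#' optional term enrichment -> report. All stage outputs are written
#' under `outdir`; every count in the report equals the length of a
#' materialised gene-list file under `outdir/gene_sets/`. Deterministic
#' given config and seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return The run report (named list), invisibly also written as
#'   `report.json` and `report.txt`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sets_dir <- file.path(outdir, "gene_sets")
  dir.create(sets_dir, showWarnings = FALSE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    design <- config$simulate
    design$seed <- config$seed
    stage_msg("simulating %d genes x %d groups x %d replicates (seed %d)",
              design$n_genes, length(design$groups), design$replicates,
              design$seed)
    sim <- simulate_counts(design)
    cm <- sim$counts
    truth <- sim$truth
    write_simulation(sim, file.path(outdir, "simulation"))
  } else {
    stage_msg("loading inputs")
    counts <- read_counts(config$counts)
    samples <- read_sample_sheet(config$sample_sheet)
    lengths <- read_gene_lengths(config$gene_lengths)
    diags <- validate_inputs(counts, samples, lengths)
    for (i in seq_len(nrow(diags)))
      stage_msg("%s: %s", diags$level[i], diags$message[i])
    if (any(diags$level == "error"))
      stop("input validation failed: ", diags$message[diags$level == "error"][1],
           call. = FALSE)
    cm <- count_matrix(counts, samples, lengths)
  }

  annotations <- config$annotations
  if (is.character(annotations))
    annotations <- read_gmt(annotations, config$annotation_category)

  stage_msg("computing FPKM and replicate QC")
  fpkm <- compute_fpkm(cm)
  write_matrix_tsv(fpkm, file.path(outdir, "fpkm.tsv"))
  qc <- replicate_correlation(fpkm, cm$samples$group)
  write_qc_summary(qc, file.path(outdir, "qc_summary.json"))

  roster <- unlist(config$contrasts, use.names = FALSE)
  groups_present <- unique(cm$samples$group)
  de <- list()
  pairs <- list()
  contrast_report <- list()
  for (ct in roster) {
    grp <- parse_contrast(ct)
    if (!all(grp %in% groups_present))
      stop("contrast ", ct, ": sample group(s) ",
           paste(setdiff(grp, groups_present), collapse = ", "),
           " missing from the data", call. = FALSE)
    res <- de_contrast(cm, ct, config$thresholds)
    de[[ct]] <- res
    pairs[[ct]] <- call_degs(res)
    safe <- gsub("/", "_vs_", ct, fixed = TRUE)
    utils::write.table(res, file.path(outdir, paste0("de_", safe, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    contrast_report[[ct]] <- list(
      up = write_gene_list(pairs[[ct]]$up, sets_dir,
                           paste0("deg_", safe, "_up")),
      down = write_gene_list(pairs[[ct]]$down, sets_dir,
                             paste0("deg_", safe, "_down")))
    stage_msg("contrast %s: %d up, %d down", ct,
              contrast_report[[ct]]$up, contrast_report[[ct]]$down)
  }

  report <- list(
    package = paste0("splitSulfur ",
                     as.character(utils::packageVersion("splitSulfur"))),
    seed = config$seed,
    thresholds = config$thresholds,
    n_genes = nrow(cm$counts),
    n_samples = ncol(cm$counts),
    qc = attr(qc, "summary"),
    contrasts = contrast_report)

  labels <- list()
  root_ct <- config$contrasts$root
  if (!is.null(root_ct) && length(root_ct) == 4L) {
    stage_msg("classifying root recovery responses")
    lab <- classify_root(pairs[[root_ct[1]]], pairs[[root_ct[2]]],
                         pairs[[root_ct[3]]], pairs[[root_ct[4]]])
    labels$root <- lab
    report$root <- label_report(lab, sets_dir, "root", config$precision)
  }
  shoot_ct <- config$contrasts$shoot
  if (!is.null(shoot_ct) && length(shoot_ct) == 3L) {
    stage_msg("classifying shoot recovery responses")
    lab <- classify_shoot(pairs[[shoot_ct[1]]], pairs[[shoot_ct[2]]],
                          pairs[[shoot_ct[3]]])
    labels$shoot <- lab
    report$shoot <- label_report(lab, sets_dir, "shoot", config$precision)
  }
  if (length(labels)) {
    all_lab <- do.call(rbind, labels)
    utils::write.table(all_lab, file.path(outdir, "response_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(root_ct) && !is.null(shoot_ct)) {
    ru <- pairs[[root_ct[1]]]; su <- pairs[[shoot_ct[1]]]
    report$tissue_common <- list(
      up = write_gene_list(intersect(ru$up, su$up), sets_dir,
                           "tissue_common_up"),
      down = write_gene_list(intersect(ru$down, su$down), sets_dir,
                             "tissue_common_down"))
  }

  if (!is.null(annotations) && length(labels)) {
    stage_msg("term enrichment over labelled gene sets")
    universe <- rownames(cm$counts)
    enr_report <- list()
    for (tis in names(labels)) {
      lab <- labels[[tis]]
      for (code in sort(unique(stats::na.omit(lab$gene_set_code)))) {
        gs <- lab$gene_id[!is.na(lab$gene_set_code) &
                          lab$gene_set_code == code]
        if (!length(gs)) next
        rec <- hypergeom_enrich(gs, universe, annotations,
                                enrich_fdr = config$thresholds$enrich_fdr)
        key <- paste0(tis, "_set_", code)
        utils::write.table(rec,
                           file.path(outdir, paste0("enrich_", key, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        edges <- enrichment_edges(rec, annotations, gs)
        utils::write.table(edges,
                           file.path(outdir, paste0("edges_", key, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        enr_report[[key]] <- sum(rec$enriched)
      }
    }
    report$enriched_terms <- enr_report
  }

  if (!is.null(truth))
    report$truth_class_counts <-
      as.list(table(truth$response_class[truth$tissue == "root"]))

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report), file.path(outdir, "report.txt"))
  stage_msg("done; report written to %s", file.path(outdir, "report.json"))
  invisible(report)
}

label_report <- function(lab, sets_dir, tissue, precision) {
  summ <- summarize_labels(lab, precision)
  for (i in seq_along(summ$sizes)) {
    key <- names(summ$sizes)[i]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    genes <- if (parts[3] %in% c("recovered", "unrecovered")) {
      sub <- lab[lab$direction == parts[2], ]
      if (parts[3] == "recovered")
        sub$gene_id[sub$label != "unrecovered"]
      else sub$gene_id[sub$label == "unrecovered"]
    } else {
      lab$gene_id[lab$direction == parts[2] &
                  !is.na(lab$gene_set_code) &
                  lab$gene_set_code == parts[3]]
    }
    write_gene_list(genes, sets_dir, gsub(".", "_", key, fixed = TRUE))
  }
  list(sizes = as.list(summ$sizes),
       fractions = lapply(summ$fractions, function(f)
         list(numerator = f$numerator, denominator = f$denominator,
              percentage = f$percentage, text = f$rounded_text)))
}

format_report <- function(report) {
  out <- c(report$package,
           sprintf("genes: %d  samples: %d  seed: %d",
                   report$n_genes, report$n_samples, report$seed),
           sprintf("replicate correlation (off-diagonal): min %.4f / median %.4f / max %.4f",
                   report$qc$min, report$qc$median, report$qc$max),
           "contrast DEG counts:")
  for (ct in names(report$contrasts))
    out <- c(out, sprintf("  %-14s up %6d  down %6d", ct,
                          report$contrasts[[ct]]$up,
                          report$contrasts[[ct]]$down))
  for (tis in intersect(c("root", "shoot"), names(report))) {
    out <- c(out, paste0(tis, " response classes:"))
    sz <- report[[tis]]$sizes
    for (key in names(sz))
      out <- c(out, sprintf("  %-24s %6d", key, sz[[key]]))
    for (key in names(report[[tis]]$fractions)) {
      f <- report[[tis]]$fractions[[key]]
      out <- c(out, sprintf("  %-24s %s (%d/%d)", key, f$text,
                            f$numerator, f$denominator))
    }
  }
  if (!is.null(report$tissue_common))
    out <- c(out, sprintf("tissue-common DEGs: %d up, %d down",
                          report$tissue_common$up,
                          report$tissue_common$down))
  out
}
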
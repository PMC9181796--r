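#' Sample-group vocabulary of the split-root sulfate-resupply design
#'
#' The experiment has nine sample groups: four shoot groups (control
#' `CK_Sh`, sulfate-deprived `S0_Sh`, homogeneous resupply `SR_Sh`, and the
#' shoot of the heterogeneously resupplied split-root plant `SP_Sh`) and
#' five root groups (`CK_R`, `S0_R`, whole-root resupply `SR_R`, the
#' resupplied split-root half `SPSR_R` and the still-deprived half
#' `SPS0_R`).
#'
#' @return Character vector of group labels, shoot groups first.
#' @export
split_root_groups <- function() {
  c(shoot_groups(), root_groups())
}

#' @rdname split_root_groups
#' @export
shoot_groups <- function() c("CK_Sh", "S0_Sh", "SR_Sh", "SP_Sh")

#' @rdname split_root_groups
#' @export
root_groups <- function() c("CK_R", "S0_R", "SR_R", "SPSR_R", "SPS0_R")

#' Tissue of a sample group
#'
#' @param group character vector of group labels.
#' @return "shoot" or "root" per element.
#' @export
group_tissue <- function(group) {
  ifelse(grepl("_Sh$", group), "shoot", "root")
}

#' Default contrast roster
#'
#' The deficiency contrast and the three (root) / two (shoot) resupply
#' contrasts, written in `"A/B"` notation (group A tested against
#' baseline B).
#'
#' @return Named list with `root` and `shoot` character vectors.
#' @export
default_contrasts <- function() {
  list(
    root  = c("S0_R/CK_R", "SR_R/S0_R", "SPSR_R/S0_R", "SPS0_R/S0_R"),
    shoot = c("S0_Sh/CK_Sh", "SR_Sh/S0_Sh", "SP_Sh/S0_Sh")
  )
}

#' Planted-class vocabulary
#'
#' Background plus up/down crossed with the five recovery behaviours
#' (local, systemic, both, none, unrecovered).
#'
#' @return Character vector of the eleven planted-class names.
#' @export
sim_classes <- function() {
  c("background",
    paste0("up_", c("local", "systemic", "both", "none", "unrecovered")),
    paste0("down_", c("local", "systemic", "both", "none", "unrecovered")))
}

#' Default planted-class proportions
#'
#' Fractions matching the root-tissue cardinalities of the motivating rice
#' sulfur study: out of 37,344 detected transcripts, 2,719 were induced and
#' 4,030 suppressed by sulfur deficiency, subdividing into 128/8/105/172
#' local/systemic/both/none up-recovered genes (plus 2,306 unrecovered) and
#' 28/7/85/1044 down mirrors (plus 2,866 unrecovered).
#'
#' @return Named numeric vector over [sim_classes()] summing to 1.
#' @export
default_class_proportions <- function() {
  n <- c(background = 30595,
         up_local = 128, up_systemic = 8, up_both = 105,
         up_none = 172, up_unrecovered = 2306,
         down_local = 28, down_systemic = 7, down_both = 85,
         down_none = 1044, down_unrecovered = 2866)
  n / sum(n)
}

#' Specify a split-root count simulation
#'
#' Bundles every knob of the synthetic-data generator: the design shape
#' (genes, replicates, groups), the planted-class mixture, the deficiency
#' effect size, the noise model and the random seed.
#'
#' @param n_genes number of simulated genes.
#' @param replicates replicates per sample group (>= 2).
#' @param groups ordered sample-group labels; defaults to the nine groups
#'   of the split-root design.
#' @param class_proportions named fractions over [sim_classes()]; must sum
#'   to 1 (within 1e-9). Defaults to [default_class_proportions()].
#' @param effect_log2fc planted absolute log2 fold change of the deficiency
#'   response (Delta > 0).
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param base_mean_log_range log10 bounds of the per-gene baseline mean,
#'   drawn log-uniformly.
#' @param libsize_cv coefficient of variation of per-sample library-size
#'   factors (log-normal, renormalised to geometric mean 1).
#' @param gene_length_range integer bounds (bp) of simulated gene lengths.
#' @param seed integer random seed.
#' @return A `simulation_design` object (validated list).
#' @seealso [plan_truth()], [simulate_counts()]
#' @export
simulation_design <- function(n_genes,
                              replicates = 3,
                              groups = split_root_groups(),
                              class_proportions = default_class_proportions(),
                              effect_log2fc = 3,
                              dispersion = 0.1,
                              base_mean_log_range = c(0.5, 3.5),
                              libsize_cv = 0.1,
                              gene_length_range = c(200L, 10000L),
                              seed = 1L) {
  design <- structure(
    list(n_genes = as.integer(n_genes),
         replicates = as.integer(replicates),
         groups = as.character(groups),
         class_proportions = class_proportions,
         effect_log2fc = effect_log2fc,
         dispersion = dispersion,
         base_mean_log_range = as.numeric(base_mean_log_range),
         libsize_cv = libsize_cv,
         gene_length_range = as.integer(gene_length_range),
         seed = as.integer(seed)),
    class = "simulation_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  with(design, {
    if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1L)
      stop("n_genes must be a positive integer", call. = FALSE)
    if (replicates < 2L)
      stop("replicates must be >= 2", call. = FALSE)
    if (anyDuplicated(groups))
      stop("duplicate group labels", call. = FALSE)
    bad <- setdiff(names(class_proportions), sim_classes())
    if (length(bad))
      stop("unknown planted classes: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(class_proportions < 0))
      stop("class proportions must be non-negative", call. = FALSE)
    if (abs(sum(class_proportions) - 1) > 1e-9)
      stop("class_proportions must sum to 1 (got ",
           format(sum(class_proportions)), ")", call. = FALSE)
    if (effect_log2fc <= 0)
      stop("effect_log2fc must be > 0", call. = FALSE)
    if (dispersion < 0)
      stop("dispersion must be >= 0", call. = FALSE)
    if (libsize_cv < 0)
      stop("libsize_cv must be >= 0", call. = FALSE)
    if (length(base_mean_log_range) != 2L ||
        diff(base_mean_log_range) < 0)
      stop("base_mean_log_range must be an increasing pair", call. = FALSE)
    if (length(gene_length_range) != 2L || any(gene_length_range < 1L) ||
        diff(gene_length_range) < 0)
      stop("gene_length_range must be a positive increasing pair",
           call. = FALSE)
  })
  invisible(design)
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Split-root simulation design\n")
  cat(sprintf("  %d genes x %d groups x %d replicates\n",
              x$n_genes, length(x$groups), x$replicates))
  cat(sprintf("  effect |log2FC| = %g, dispersion phi = %g, seed = %d\n",
              x$effect_log2fc, x$dispersion, x$seed))
  planted <- x$class_proportions[setdiff(names(x$class_proportions),
                                         "background")]
  cat(sprintf("  planted fraction = %.3g over %d classes\n",
              sum(planted), length(planted)))
  invisible(x)
}
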
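#' Plant ground-truth response classes
#'
#' Allocates genes to the planted classes of a [simulation_design()]:
#' per-class counts are `round(n_genes * proportion)` with the rounding
#' remainder absorbed by the background class (or, if background is absent
#' from the map, by the largest planted class), then classes are assigned
#' to gene ids by a seeded permutation.
#'
#' The returned truth table is long-format with one row per gene per
#' tissue. Root rows carry the planted recovery class
#' (local/systemic/both/none/unrecovered/background); shoot rows carry the
#' shoot analogue, where a class that recovers in either split-root half
#' (local, systemic or both) responds to heterogeneous resupply
#' (`hetero_responsive`), `none` recovers under homogeneous resupply only
#' (`homo_only`), and `unrecovered` stays unrecovered.
#'
#' @param design a [simulation_design()].
#' @return data.frame with columns `gene_id`, `tissue`, `direction`
#'   (up/down/none) and `response_class`.
#' @export
plan_truth <- function(design) {
  validate_design(design)
  set.seed(design$seed)
  props <- design$class_proportions
  n <- design$n_genes

  counts <- round(n * props)
  sink <- if ("background" %in% names(props)) "background" else
    names(which.max(props))
  counts[sink] <- counts[sink] + (n - sum(counts))
  if (counts[sink] < 0)
    stop("class proportions leave a negative remainder for ", sink,
         call. = FALSE)

  classes <- rep(names(counts), counts)
  classes <- classes[sample.int(n)]
  gene_id <- sprintf("gene_%06d", seq_len(n))

  direction <- ifelse(classes == "background", "none",
                      sub("_.*$", "", classes))
  root_class <- ifelse(classes == "background", "background",
                       sub("^(up|down)_", "", classes))
  shoot_class <- shoot_class_of(root_class)

  rbind(
    data.frame(gene_id = gene_id, tissue = "root", direction = direction,
               response_class = root_class, stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, tissue = "shoot", direction = direction,
               response_class = shoot_class, stringsAsFactors = FALSE)
  )
}

# Root recovery class -> shoot response vocabulary.
shoot_class_of <- function(root_class) {
  map <- c(local = "hetero_responsive", systemic = "hetero_responsive",
           both = "hetero_responsive", none = "homo_only",
           unrecovered = "unrecovered", background = "background")
  unname(map[root_class])
}

#' Expected group-mean factors of a planted gene
#'
#' Multiplicative factors applied to a gene's baseline mean in each sample
#' group, given its deficiency direction and recovery class. For an
#' up-regulated root gene with planted effect Delta the deficiency group
#' sits at `2^Delta`; whole-root resupply returns it to baseline (factor 1)
#' except for `unrecovered` genes; the two split-root halves return to
#' baseline or stay deficient according to the class (local: only the
#' resupplied half `SPSR_R` recovers; systemic: only the still-deprived
#' half `SPS0_R` recovers; both: both recover; none: neither). Down genes
#' mirror with `2^-Delta`; background genes sit at 1 everywhere.
#'
#' @param direction "up", "down" or "none".
#' @param response_class a root recovery class
#'   (local/systemic/both/none/unrecovered/background) or, for
#'   `tissue = "shoot"`, optionally the shoot vocabulary
#'   (hetero_responsive/homo_only/unrecovered/background).
#' @param effect_log2fc planted |log2 fold change| Delta.
#' @param tissue "root" or "shoot".
#' @return Named numeric vector of factors over that tissue's groups.
#' @export
expected_mean_pattern <- function(direction, response_class, effect_log2fc,
                                  tissue = c("root", "shoot")) {
  tissue <- match.arg(tissue)
  stopifnot(length(direction) == 1L, length(response_class) == 1L)
  if (!direction %in% c("up", "down", "none"))
    stop("unknown direction: ", direction, call. = FALSE)
  if (direction == "none" || response_class == "background") {
    if (!(direction == "none" && response_class == "background"))
      stop("direction 'none' and class 'background' must coincide",
           call. = FALSE)
    grp <- if (tissue == "root") root_groups() else shoot_groups()
    return(stats::setNames(rep(1, length(grp)), grp))
  }
  f <- 2^(if (direction == "up") effect_log2fc else -effect_log2fc)
  if (tissue == "root") {
    fac <- switch(response_class,
      local       = c(CK_R = 1, S0_R = f, SR_R = 1, SPSR_R = 1, SPS0_R = f),
      systemic    = c(CK_R = 1, S0_R = f, SR_R = 1, SPSR_R = f, SPS0_R = 1),
      both        = c(CK_R = 1, S0_R = f, SR_R = 1, SPSR_R = 1, SPS0_R = 1),
      none        = c(CK_R = 1, S0_R = f, SR_R = 1, SPSR_R = f, SPS0_R = f),
      unrecovered = c(CK_R = 1, S0_R = f, SR_R = f, SPSR_R = f, SPS0_R = f),
      stop("unknown response class: ", response_class, call. = FALSE))
  } else {
    cls <- if (response_class %in% c("local", "systemic", "both", "none",
                                     "unrecovered"))
      shoot_class_of(response_class) else response_class
    fac <- switch(cls,
      hetero_responsive = c(CK_Sh = 1, S0_Sh = f, SR_Sh = 1, SP_Sh = 1),
      homo_only         = c(CK_Sh = 1, S0_Sh = f, SR_Sh = 1, SP_Sh = f),
      unrecovered       = c(CK_Sh = 1, S0_Sh = f, SR_Sh = f, SP_Sh = f),
      stop("unknown response class: ", response_class, call. = FALSE))
  }
  fac
}

#' Simulate a split-root count matrix with planted truth
#'
#' Draws negative-binomial counts `NB(mean = baseline x pattern factor x
#' library factor, variance = mu + phi mu^2)` for every gene and sample of
#' the design; `phi = 0` degenerates to Poisson. Baseline means are
#' log-uniform over `base_mean_log_range`, library-size factors log-normal
#' with CV `libsize_cv` renormalised to geometric mean 1, gene lengths
#' uniform integers over `gene_length_range`. Fully reproducible from
#' `design$seed`.
#'
#' @param design a [simulation_design()].
#' @return List with elements `counts` (a [count_matrix()]) and `truth`
#'   (the [plan_truth()] table).
#' @export
simulate_counts <- function(design) {
  validate_design(design)
  truth <- plan_truth(design)  # seeds the RNG with design$seed

  n <- design$n_genes
  groups <- design$groups
  reps <- design$replicates
  gene_id <- unique(truth$gene_id)

  base <- 10^stats::runif(n, design$base_mean_log_range[1],
                          design$base_mean_log_range[2])
  lens <- sample(seq.int(design$gene_length_range[1],
                         design$gene_length_range[2]), n, replace = TRUE)

  samples <- data.frame(
    sample = paste(rep(groups, each = reps), seq_len(reps), sep = "_"),
    group = rep(groups, each = reps),
    tissue = group_tissue(rep(groups, each = reps)),
    replicate = rep(seq_len(reps), times = length(groups)),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  if (design$libsize_cv > 0) {
    sdlog <- sqrt(log(1 + design$libsize_cv^2))
    libfac <- stats::rlnorm(ns, meanlog = 0, sdlog = sdlog)
    libfac <- libfac / exp(mean(log(libfac)))
  } else {
    libfac <- rep(1, ns)
  }

  # genes x groups factor matrix via one pattern lookup per planted class
  root <- truth[truth$tissue == "root", ]
  shoot <- truth[truth$tissue == "shoot", ]
  key_root <- paste(root$direction, root$response_class)
  key_shoot <- paste(shoot$direction, shoot$response_class)
  fac <- matrix(1, nrow = n, ncol = length(groups),
                dimnames = list(gene_id, groups))
  for (k in unique(key_root)) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    pat <- expected_mean_pattern(parts[1], parts[2], design$effect_log2fc,
                                 tissue = "root")
    g <- intersect(names(pat), groups)
    fac[key_root == k, g] <- rep(pat[g], each = sum(key_root == k))
  }
  for (k in unique(key_shoot)) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    pat <- expected_mean_pattern(parts[1], parts[2], design$effect_log2fc,
                                 tissue = "shoot")
    g <- intersect(names(pat), groups)
    fac[key_shoot == k, g] <- rep(pat[g], each = sum(key_shoot == k))
  }

  mu <- fac[, samples$group, drop = FALSE] * outer(base, libfac)
  counts <- if (design$dispersion > 0) {
    matrix(stats::rnbinom(n * ns, mu = mu, size = 1 / design$dispersion),
           nrow = n)
  } else {
    matrix(stats::rpois(n * ns, lambda = mu), nrow = n)
  }
  dimnames(counts) <- list(gene_id, samples$sample)

  cm <- count_matrix(counts, samples,
                     stats::setNames(as.integer(lens), gene_id))
  list(counts = cm, truth = truth)
}
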
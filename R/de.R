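#' Median-of-ratios size factors
#'
#' Library-size normalisation factors for a set of samples: each sample's
#' factor is the median, over genes with all-positive counts, of the ratio
#' of its count to the gene's geometric mean across samples; factors are
#' then rescaled to geometric mean 1. When no gene has all-positive counts
#' the factors fall back to column-sum ratios (logged via `message()`).
#'
#' @param counts integer gene x sample matrix.
#' @param rescale rescale factors to geometric mean 1 (default TRUE).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, rescale = TRUE) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(counts[allpos, , drop = FALSE], 2,
                function(cn) stats::median(cn / exp(loggeo)))
  } else {
    message("size_factors: no gene with all-positive counts; ",
            "falling back to column-sum ratios")
    tot <- colSums(counts)
    if (any(tot == 0))
      stop("sample(s) with zero total counts: ",
           paste(colnames(counts)[tot == 0], collapse = ", "),
           call. = FALSE)
    sf <- tot / exp(mean(log(tot)))
  }
  if (rescale) sf <- sf / exp(mean(log(sf)))
  sf
}

#' Method-of-moments dispersion with shrinkage
#'
#' Per-gene negative-binomial dispersion from normalised counts of a
#' two-group contrast. The raw estimate pools the two groups' within-group
#' variance: `phi_raw = max(0, (s2 - m) / m^2)` with `m` the pooled
#' normalised mean and `s2` the pooled within-group sample variance. Each
#' gene is then shrunk towards the across-gene mean dispersion `phi_bar`:
#' `phi_hat = w * phi_bar + (1 - w) * phi_raw`. At few replicates the
#' gene-wise moment estimate is dominated by sampling noise, so the
#' default weight leans heavily on the pooled value (`shrink_weight =
#' 0.8`) and `phi_bar` is the untrimmed mean (trimming biases the centre
#' of the right-skewed `phi_raw` distribution downwards); both are
#' configurable. Genes with `m = 0` are untestable and get `phi_bar`.
#'
#' @param norm_counts normalised gene x sample matrix (both groups).
#' @param group_a,group_b column indices or names of the two groups.
#' @param shrink_weight weight w on the pooled dispersion, in \[0, 1\].
#' @param trim trim fraction for the across-gene mean of `phi_raw`.
#' @return data.frame with `phi_raw`, `phi_hat` and logical `testable`;
#'   attribute `phi_bar` holds the pooled dispersion.
#' @export
estimate_dispersion <- function(norm_counts, group_a, group_b,
                                shrink_weight = 0.8, trim = 0) {
  a <- norm_counts[, group_a, drop = FALSE]
  b <- norm_counts[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("both groups need >= 2 replicates", call. = FALSE)
  na <- ncol(a); nb <- ncol(b)
  va <- rowVars_(a); vb <- rowVars_(b)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  m <- rowMeans(cbind(a, b))
  testable <- m > 0
  phi_raw <- ifelse(testable, pmax(0, (s2 - m) / m^2), NA_real_)
  phi_bar <- if (any(testable))
    mean(phi_raw[testable], trim = trim) else 0
  phi_hat <- ifelse(testable,
                    shrink_weight * phi_bar + (1 - shrink_weight) * phi_raw,
                    phi_bar)
  out <- data.frame(phi_raw = phi_raw, phi_hat = phi_hat,
                    testable = testable)
  rownames(out) <- rownames(norm_counts)
  attr(out, "phi_bar") <- phi_bar
  out
}

rowVars_ <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Negative-binomial Wald test on group means
#'
#' For each gene, `log2fc = log2((mean_a + 0.5) / (mean_b + 0.5))` with a
#' delta-method standard error `SE^2 = (1/ln 2)^2 * [v(mu_a) / (n_a mu_a^2)
#' + v(mu_b) / (n_b mu_b^2)]`, `v(mu) = mu + phi mu^2` and `mu` the
#' pseudocounted group mean; `z = log2fc / SE` is referred to the standard
#' normal, two-sided. Genes with both raw means zero are untestable and
#' get `log2fc = 0`, `p = 1`.
#'
#' @param mean_a,mean_b normalised group means (vectors over genes).
#' @param dispersion per-gene dispersion phi (recycled if length 1).
#' @param n_a,n_b replicate counts of the two groups.
#' @return data.frame with `log2fc`, `se`, `z`, `p` and logical
#'   `testable`.
#' @export
wald_test <- function(mean_a, mean_b, dispersion, n_a, n_b) {
  stopifnot(length(mean_a) == length(mean_b))
  phi <- rep_len(dispersion, length(mean_a))
  mu_a <- mean_a + 0.5
  mu_b <- mean_b + 0.5
  log2fc <- log2(mu_a / mu_b)
  se2 <- (1 / log(2))^2 *
    ((mu_a + phi * mu_a^2) / (n_a * mu_a^2) +
     (mu_b + phi * mu_b^2) / (n_b * mu_b^2))
  se <- sqrt(se2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  testable <- mean_a > 0 | mean_b > 0
  log2fc[!testable] <- 0
  z[!testable] <- 0
  p[!testable] <- 1
  data.frame(log2fc = log2fc, se = se, z = z, p = p, testable = testable)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (`q_i = min_{j >= i} p_(j) m /
#' j`, clipped to 1, original order restored). Thin wrapper over
#' `stats::p.adjust(method = "BH")` so every module shares one
#' implementation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' DEG thresholds
#'
#' @param fc_min minimum absolute fold change (default 2).
#' @param p_max maximum raw p-value (default 0.05).
#' @param fdr_max maximum FDR (default 0.01).
#' @param enrich_fdr FDR cut-off for term enrichment (default 0.05).
#' @return Named list of thresholds.
#' @export
deg_thresholds <- function(fc_min = 2, p_max = 0.05, fdr_max = 0.01,
                           enrich_fdr = 0.05) {
  stopifnot(fc_min > 0, p_max > 0, fdr_max > 0, enrich_fdr > 0)
  list(fc_min = fc_min, p_max = p_max, fdr_max = fdr_max,
       enrich_fdr = enrich_fdr)
}

parse_contrast <- function(name) {
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || parts[1] == parts[2])
    stop("contrast must be of the form 'groupA/groupB' with distinct ",
         "groups: ", name, call. = FALSE)
  stats::setNames(parts, c("A", "B"))
}

#' Differential-expression test for one contrast
#'
#' Runs the full two-group pipeline on the samples of a contrast:
#' median-of-ratios [size_factors()], [estimate_dispersion()],
#' [wald_test()] and [bh_adjust()]. Genes with zero counts in every sample
#' of the contrast are excluded from the BH denominator (they are not
#' detected transcripts for this comparison) and reported with `p = 1`,
#' `fdr = 1`. Status is "up" when `log2fc >= log2(fc_min)`, `p < p_max`
#' and `fdr < fdr_max`; "down" symmetric; otherwise "ns".
#'
#' @param cm a [count_matrix()].
#' @param contrast contrast name `"groupA/groupB"` (e.g. `"S0_R/CK_R"`).
#' @param thresholds a [deg_thresholds()] list.
#' @param shrink_weight,trim passed to [estimate_dispersion()].
#' @return data.frame (one row per gene): `gene_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `dispersion`, `p`, `fdr`, `status`; attribute `contrast`.
#' @export
de_contrast <- function(cm, contrast, thresholds = deg_thresholds(),
                        shrink_weight = 0.8, trim = 0) {
  stopifnot(inherits(cm, "count_matrix"))
  grp <- parse_contrast(contrast)
  sa <- group_samples(cm, grp["A"])
  sb <- group_samples(cm, grp["B"])
  if (length(sa) < 2 || length(sb) < 2)
    stop("contrast ", contrast, ": missing sample group or fewer than 2 ",
         "replicates", call. = FALSE)
  sub <- cm$counts[, c(sa, sb), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")

  disp <- estimate_dispersion(norm, sa, sb, shrink_weight = shrink_weight,
                              trim = trim)
  mean_a <- rowMeans(norm[, sa, drop = FALSE])
  mean_b <- rowMeans(norm[, sb, drop = FALSE])
  wt <- wald_test(mean_a, mean_b, disp$phi_hat, length(sa), length(sb))

  detected <- rowSums(sub) > 0
  fdr <- rep(1, nrow(sub))
  fdr[detected] <- bh_adjust(wt$p[detected])

  lfc_min <- log2(thresholds$fc_min)
  status <- rep("ns", nrow(sub))
  sig <- wt$p < thresholds$p_max & fdr < thresholds$fdr_max & detected
  status[sig & wt$log2fc >= lfc_min] <- "up"
  status[sig & wt$log2fc <= -lfc_min] <- "down"

  out <- data.frame(gene_id = rownames(sub), mean_a = mean_a,
                    mean_b = mean_b, log2fc = wt$log2fc,
                    dispersion = disp$phi_hat, p = wt$p, fdr = fdr,
                    status = status, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "contrast") <- contrast
  out
}

#' Extract up/down DEG sets from contrast records
#'
#' @param records result of [de_contrast()] (or any data.frame with
#'   `gene_id` and `status`).
#' @param contrast contrast name; defaults to the records' attribute.
#' @return A `deg_sets` object: list with `contrast`, `up` and `down`
#'   character vectors (disjoint by construction).
#' @export
call_degs <- function(records, contrast = attr(records, "contrast")) {
  structure(list(contrast = contrast,
                 up = records$gene_id[records$status == "up"],
                 down = records$gene_id[records$status == "down"]),
            class = "deg_sets")
}

#' Construct a DEG-set pair directly
#'
#' @param up,down character vectors of gene ids; must be disjoint.
#' @param contrast contrast name.
#' @return A `deg_sets` object.
#' @export
deg_sets <- function(up, down, contrast = NA_character_) {
  if (length(intersect(up, down)))
    stop("up and down sets overlap: ",
         paste(utils::head(intersect(up, down), 5), collapse = ", "),
         call. = FALSE)
  structure(list(contrast = contrast, up = unique(as.character(up)),
                 down = unique(as.character(down))),
            class = "deg_sets")
}

#' @export
print.deg_sets <- function(x, ...) {
  cat(sprintf("DEG sets [%s]: %d up, %d down\n",
              x$contrast, length(x$up), length(x$down)))
  invisible(x)
}
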
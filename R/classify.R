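#' Recovered and unrecovered deficiency DEGs
#'
#' A deficiency-responsive gene counts as recovered when the full-resupply
#' contrast calls it significantly in the opposite direction:
#' `recovered_up = deficiency.up intersect resupply.down` (and mirrored for
#' down genes). The remainder of each deficiency set is unrecovered, so
#' recovered and unrecovered partition it.
#'
#' @param deficiency,resupply [deg_sets()] pairs computed on the same gene
#'   universe (e.g. `S0_R/CK_R` and `SR_R/S0_R`).
#' @return List with `recovered_up`, `recovered_down`, `unrecovered_up`,
#'   `unrecovered_down` character vectors.
#' @export
recovered_sets <- function(deficiency, resupply) {
  list(recovered_up = intersect(deficiency$up, resupply$down),
       recovered_down = intersect(deficiency$down, resupply$up),
       unrecovered_up = setdiff(deficiency$up, resupply$down),
       unrecovered_down = setdiff(deficiency$down, resupply$up))
}

root_code_map <- list(
  up = c(local = "A", systemic = "B", both = "C", none = "D"),
  down = c(local = "E", systemic = "F", both = "G", none = "H"))

shoot_code_map <- list(
  up = c(hetero_responsive = "A", homo_only = "B"),
  down = c(hetero_responsive = "C", homo_only = "D"))

label_rows <- function(tissue, direction, label, code, genes) {
  if (!length(genes)) return(NULL)
  data.frame(gene_id = unname(genes), tissue = tissue,
             direction = direction, gene_set_code = unname(code),
             label = label, stringsAsFactors = FALSE)
}

#' Classify root recovery as local, systemic, both or none
#'
#' The split-root classification: among deficiency DEGs recovered under
#' whole-root resupply (`R = S0_R/CK_R up` intersected with `SR_R/S0_R
#' down`, per direction), recovery in the two split-root halves decides
#' the class. Up branch (gene-set codes A-D):
#' \itemize{
#'   \item A, local: recovered only in the resupplied half
#'     (`R` ∩ `SPSR.down` − `SPS0.down`)
#'   \item B, systemic: recovered only in the still-deprived half
#'     (`R` ∩ `SPS0.down` − `SPSR.down`)
#'   \item C, both: recovered in both halves
#'   \item D, none: recovered in neither half
#' }
#' The down branch mirrors with all directions flipped (codes E-H).
#' Deficiency DEGs failing the whole-root recovery gate are labelled
#' `unrecovered` (the gate is applied before the split-half sets are
#' consulted).
#'
#' @param deficiency `S0_R/CK_R` [deg_sets()] pair.
#' @param resupply `SR_R/S0_R` pair.
#' @param spsr `SPSR_R/S0_R` pair (resupplied half).
#' @param sps0 `SPS0_R/S0_R` pair (still-deprived half).
#' @return A response-label table: data.frame with `gene_id`, `tissue`,
#'   `direction`, `gene_set_code` (A-H, NA for unrecovered) and `label`.
#' @export
classify_root <- function(deficiency, resupply, spsr, sps0) {
  rec <- recovered_sets(deficiency, resupply)
  one_branch <- function(direction) {
    if (direction == "up") {
      R <- rec$recovered_up; unrec <- rec$unrecovered_up
      half_sr <- spsr$down; half_s0 <- sps0$down
    } else {
      R <- rec$recovered_down; unrec <- rec$unrecovered_down
      half_sr <- spsr$up; half_s0 <- sps0$up
    }
    codes <- root_code_map[[direction]]
    rbind(
      label_rows("root", direction, "local", codes["local"],
                 setdiff(intersect(R, half_sr), half_s0)),
      label_rows("root", direction, "systemic", codes["systemic"],
                 setdiff(intersect(R, half_s0), half_sr)),
      label_rows("root", direction, "both", codes["both"],
                 intersect(R, intersect(half_sr, half_s0))),
      label_rows("root", direction, "none", codes["none"],
                 setdiff(setdiff(R, half_sr), half_s0)),
      label_rows("root", direction, "unrecovered", NA_character_, unrec))
  }
  out <- rbind(one_branch("up"), one_branch("down"))
  if (is.null(out))
    out <- data.frame(gene_id = character(), tissue = character(),
                      direction = character(), gene_set_code = character(),
                      label = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tissue") <- "root"
  out
}

#' Classify shoot response to homogeneous vs heterogeneous resupply
#'
#' Among shoot deficiency DEGs recovered under homogeneous resupply
#' (`R = S0_Sh/CK_Sh up` ∩ `SR_Sh/S0_Sh down`, per direction), genes also
#' recovered in the shoots of heterogeneously resupplied plants
#' (`SP_Sh/S0_Sh`) are `hetero_responsive` (codes A up / C down); the rest
#' recovered under homogeneous resupply only are `homo_only` (B / D).
#' Deficiency DEGs outside `R` are `unrecovered`.
#'
#' @param deficiency `S0_Sh/CK_Sh` [deg_sets()] pair.
#' @param resupply `SR_Sh/S0_Sh` pair (homogeneous).
#' @param sp `SP_Sh/S0_Sh` pair (heterogeneous).
#' @return Response-label table as in [classify_root()], tissue "shoot".
#' @export
classify_shoot <- function(deficiency, resupply, sp) {
  rec <- recovered_sets(deficiency, resupply)
  one_branch <- function(direction) {
    if (direction == "up") {
      R <- rec$recovered_up; unrec <- rec$unrecovered_up
      half <- sp$down
    } else {
      R <- rec$recovered_down; unrec <- rec$unrecovered_down
      half <- sp$up
    }
    codes <- shoot_code_map[[direction]]
    rbind(
      label_rows("shoot", direction, "hetero_responsive",
                 codes["hetero_responsive"], intersect(R, half)),
      label_rows("shoot", direction, "homo_only", codes["homo_only"],
                 setdiff(R, half)),
      label_rows("shoot", direction, "unrecovered", NA_character_, unrec))
  }
  out <- rbind(one_branch("up"), one_branch("down"))
  if (is.null(out))
    out <- data.frame(gene_id = character(), tissue = character(),
                      direction = character(), gene_set_code = character(),
                      label = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tissue") <- "shoot"
  out
}

#' Recovery fraction with half-up rounded rendering
#'
#' `percentage = 100 * numerator / denominator`, rendered half-up at the
#' requested number of decimals (the internal value stays unrounded).
#'
#' @param numerator,denominator non-negative integers,
#'   `denominator > 0`, `numerator <= denominator`.
#' @param precision decimals in the rendered text (default 2).
#' @return A `recovery_summary`: list with `numerator`, `denominator`,
#'   `percentage` and `rounded_text` (e.g. `"30.99%"`).
#' @export
recovery_fraction <- function(numerator, denominator, precision = 2) {
  if (denominator <= 0)
    stop("denominator must be > 0", call. = FALSE)
  if (numerator < 0 || numerator > denominator)
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  pct <- 100 * numerator / denominator
  structure(list(numerator = numerator, denominator = denominator,
                 percentage = pct,
                 rounded_text = paste0(round_half_up(pct, precision), "%")),
            class = "recovery_summary")
}

# Decimal half-up rounding rendered at fixed width ("30.99", "58.9").
round_half_up <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), floor(x * 10^digits + 0.5) / 10^digits)
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("%s (%d/%d)\n", x$rounded_text, x$numerator, x$denominator))
  invisible(x)
}

#' Summarise a response-label table
#'
#' Set sizes per (tissue, direction, gene-set code/label) plus recovery
#' fractions of each class within its direction's recovered set.
#'
#' @param labels a label table from [classify_root()] or
#'   [classify_shoot()].
#' @param precision decimals for rendered percentages.
#' @param tissue "root" or "shoot"; taken from the table's `tissue`
#'   attribute (set by the classifiers) when NULL.
#' @return Named list: `sizes` (named integer vector keyed like
#'   `"root.up.A"`, including zero-size classes), `fractions`
#'   (recovery_summary objects keyed the same way; class size over the
#'   direction's deficiency-recovered total, present when that total is
#'   positive).
#' @export
summarize_labels <- function(labels, precision = 2, tissue = NULL) {
  if (is.null(tissue)) tissue <- attr(labels, "tissue")
  if (is.null(tissue)) tissue <- unique(labels$tissue)
  stopifnot(length(tissue) == 1L)
  code_map <- if (tissue == "root") root_code_map else shoot_code_map
  sizes <- integer(); fractions <- list()
  for (dir in c("up", "down")) {
    sub <- labels[labels$tissue == tissue & labels$direction == dir, ]
    rec <- sub[sub$label != "unrecovered", ]
    key0 <- paste(tissue, dir, sep = ".")
    sizes[paste0(key0, ".unrecovered")] <- sum(sub$label == "unrecovered")
    sizes[paste0(key0, ".recovered")] <- nrow(rec)
    for (code in unname(code_map[[dir]])) {
      k <- sum(rec$gene_set_code == code)
      sizes[paste0(key0, ".", code)] <- k
      if (nrow(rec) > 0)
        fractions[[paste0(key0, ".", code)]] <-
          recovery_fraction(k, nrow(rec), precision)
    }
  }
  list(sizes = sizes, fractions = fractions)
}
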
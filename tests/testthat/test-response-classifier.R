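test_that("recovered/unrecovered partition the deficiency sets", {
  def <- deg_sets(up = c("g1", "g2"), down = "g9")
  res <- deg_sets(up = character(), down = c("g2", "g3"))
  rec <- recovered_sets(def, res)
  expect_equal(rec$recovered_up, "g2")
  expect_equal(rec$unrecovered_up, "g1")
  expect_equal(rec$recovered_down, character(0))
  expect_equal(rec$unrecovered_down, "g9")

  empty <- recovered_sets(deg_sets(character(), character()), res)
  expect_length(empty$recovered_up, 0)

  set.seed(31)
  uni <- paste0("g", 1:60)
  for (i in 1:10) {
    rec <- recovered_sets(random_pair(uni), random_pair(uni))
    expect_setequal(c(rec$recovered_up, rec$unrecovered_up),
                    intersect(uni, c(rec$recovered_up, rec$unrecovered_up)))
    expect_length(intersect(rec$recovered_up, rec$unrecovered_up), 0)
  }
})

test_that("a six-gene toy lands in exactly the defined root classes", {
  # g1 local, g2 systemic, g3 both, g4 none, g5 unrecovered, g6 untouched
  def  <- deg_sets(up = c("g1", "g2", "g3", "g4", "g5"), down = character())
  sr   <- deg_sets(up = character(), down = c("g1", "g2", "g3", "g4"))
  spsr <- deg_sets(up = character(), down = c("g1", "g3"))
  sps0 <- deg_sets(up = character(), down = c("g2", "g3"))
  lab <- classify_root(def, sr, spsr, sps0)
  got <- setNames(lab$label, lab$gene_id)
  expect_equal(got[c("g1", "g2", "g3", "g4", "g5")],
               c(g1 = "local", g2 = "systemic", g3 = "both",
                 g4 = "none", g5 = "unrecovered"))
  expect_false("g6" %in% lab$gene_id)
  codes <- setNames(lab$gene_set_code, lab$gene_id)
  expect_equal(unname(codes[c("g1", "g2", "g3", "g4")]),
               c("A", "B", "C", "D"))
  expect_true(is.na(codes["g5"]))
  # A-D partition the recovered set
  recovered <- lab$gene_id[lab$label != "unrecovered"]
  expect_setequal(recovered, c("g1", "g2", "g3", "g4"))
  expect_equal(anyDuplicated(lab$gene_id), 0L)
})

test_that("down-branch classes mirror with directions flipped", {
  def  <- deg_sets(up = character(), down = c("g1", "g2"))
  sr   <- deg_sets(up = c("g1", "g2"), down = character())
  spsr <- deg_sets(up = "g1", down = character())
  sps0 <- deg_sets(up = "g2", down = character())
  lab <- classify_root(def, sr, spsr, sps0)
  got <- setNames(paste(lab$label, lab$gene_set_code), lab$gene_id)
  expect_equal(unname(got["g1"]), "local E")
  expect_equal(unname(got["g2"]), "systemic F")
  expect_true(all(lab$direction == "down"))
})

test_that("root classes partition the recovered sets on random inputs", {
  set.seed(33)
  uni <- paste0("g", 1:200)
  for (i in 1:20) {
    def <- random_pair(uni, 0.3, 0.3)
    sr <- random_pair(uni, 0.3, 0.3)
    spsr <- random_pair(uni, 0.3, 0.3)
    sps0 <- random_pair(uni, 0.3, 0.3)
    lab <- classify_root(def, sr, spsr, sps0)
    expect_equal(anyDuplicated(lab$gene_id), 0L)
    rec <- recovered_sets(def, sr)
    up <- lab[lab$direction == "up" & lab$label != "unrecovered", ]
    expect_setequal(up$gene_id, rec$recovered_up)
    dn <- lab[lab$direction == "down" & lab$label != "unrecovered", ]
    expect_setequal(dn$gene_id, rec$recovered_down)
    # every deficiency DEG is labelled exactly once
    expect_setequal(lab$gene_id, c(def$up, def$down))
  }
})

test_that("exchanging the split-half inputs swaps local and systemic", {
  set.seed(35)
  uni <- paste0("g", 1:150)
  for (i in 1:10) {
    def <- random_pair(uni, 0.3, 0.3)
    sr <- random_pair(uni, 0.3, 0.3)
    spsr <- random_pair(uni, 0.3, 0.3)
    sps0 <- random_pair(uni, 0.3, 0.3)
    lab <- classify_root(def, sr, spsr, sps0)
    swp <- classify_root(def, sr, sps0, spsr)
    remap <- c(local = "systemic", systemic = "local", both = "both",
               none = "none", unrecovered = "unrecovered")
    lab$label <- unname(remap[lab$label])
    lab <- lab[order(lab$gene_id), c("gene_id", "direction", "label")]
    swp <- swp[order(swp$gene_id), c("gene_id", "direction", "label")]
    rownames(lab) <- rownames(swp) <- NULL
    expect_identical(swp, lab)
  }
})

test_that("classification ignores gene order and absent genes", {
  def  <- deg_sets(up = c("g2", "g1"), down = character())
  sr   <- deg_sets(up = character(), down = c("g1", "g2", "zzz_absent"))
  spsr <- deg_sets(up = character(), down = c("g1", "extra1"))
  sps0 <- deg_sets(up = character(), down = "extra2")
  lab1 <- classify_root(def, sr, spsr, sps0)
  def2 <- deg_sets(up = c("g1", "g2"), down = character())
  lab2 <- classify_root(def2, sr, spsr, sps0)
  ord <- function(x) x[order(x$gene_id), ]
  expect_equal(ord(lab1), ord(lab2), ignore_attr = TRUE)
  expect_setequal(lab1$gene_id, c("g1", "g2"))
})

test_that("shoot classification separates hetero from homo-only recovery", {
  def <- deg_sets(up = c("g1", "g2", "g3"), down = c("g4", "g5"))
  sr  <- deg_sets(up = c("g4", "g5"), down = c("g1", "g2"))
  sp  <- deg_sets(up = "g4", down = "g1")
  lab <- classify_shoot(def, sr, sp)
  got <- setNames(paste(lab$label, lab$gene_set_code), lab$gene_id)
  expect_equal(unname(got["g1"]), "hetero_responsive A")
  expect_equal(unname(got["g2"]), "homo_only B")
  expect_equal(unname(got["g3"]), "unrecovered NA")
  expect_equal(unname(got["g4"]), "hetero_responsive C")
  expect_equal(unname(got["g5"]), "homo_only D")

  # nothing recovered -> everything unrecovered
  lab0 <- classify_shoot(def, deg_sets(character(), character()), sp)
  expect_true(all(lab0$label == "unrecovered"))
  expect_setequal(lab0$gene_id, c(def$up, def$down))
})

test_that("recovery fractions render half-up at the requested precision", {
  expect_equal(recovery_fraction(128, 413)$rounded_text, "30.99%")
  expect_equal(recovery_fraction(28, 1164)$rounded_text, "2.41%")
  expect_equal(recovery_fraction(430, 1589)$rounded_text, "27.06%")
  expect_equal(recovery_fraction(0, 413)$rounded_text, "0.00%")
  expect_equal(recovery_fraction(129, 219, 1)$rounded_text, "58.9%")
  f <- recovery_fraction(128, 413)
  expect_equal(f$percentage, 100 * 128 / 413)
  expect_error(recovery_fraction(5, 0), "denominator")
  expect_error(recovery_fraction(7, 5), "numerator")
})

test_that("label summaries expose sizes and in-branch fractions", {
  def  <- deg_sets(up = c("g1", "g2", "g3", "g4", "g5"), down = character())
  sr   <- deg_sets(up = character(), down = c("g1", "g2", "g3", "g4"))
  spsr <- deg_sets(up = character(), down = c("g1", "g3"))
  sps0 <- deg_sets(up = character(), down = c("g2", "g3"))
  summ <- summarize_labels(classify_root(def, sr, spsr, sps0))
  expect_equal(unname(summ$sizes["root.up.recovered"]), 4L)
  expect_equal(unname(summ$sizes["root.up.A"]), 1L)
  expect_equal(summ$fractions[["root.up.A"]]$rounded_text, "25.00%")
})
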
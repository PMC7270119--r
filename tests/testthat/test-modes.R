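test_that("pairwise states threshold the three signed fold changes", {
  st <- pairwise_states(maternal = 100, hybrid = 100, paternal = 100)
  expect_identical(unlist(st[1, 1:3], use.names = FALSE),
                   c("equal", "equal", "equal"))
  st <- pairwise_states(maternal = 100, hybrid = 400, paternal = 150)
  expect_identical(unlist(st[1, 1:3], use.names = FALSE),
                   c("higher", "higher", "equal"))
  st <- pairwise_states(maternal = 10, hybrid = 100, paternal = 400)
  expect_identical(unlist(st[1, 1:3], use.names = FALSE),
                   c("higher", "lower", "lower"))
})

test_that("each canonical class pattern classifies as itself", {
  oracle <- class_pattern_oracle(L = 10, E = 4)
  for (cls in names(oracle)) {
    lv <- oracle[[cls]]
    res <- classify_12bin(maternal = lv[1], hybrid = lv[2], paternal = lv[3])
    expect_identical(res$class, cls)
    expect_identical(res$coarse_mode, coarse_mode_of_class(cls))
  }
})

test_that("worked classification examples land in the expected classes", {
  expect_identical(classify_12bin(100, 400, 150)$coarse_mode,
                   "transgressive_up")
  # hybrid at twice the low parent, half the high parent, near mid-parent
  res <- classify_12bin(400, 200, 100)
  expect_identical(res$class, "1")
  expect_identical(res$coarse_mode, "additive")
  expect_identical(classify_12bin(100, 100, 100)$class, "none")
  # intermediate but far from mid-parent: residual, not forced
  expect_identical(classify_12bin(160, 40, 10)$class, "none")
})

test_that("swapping parents permutes classes by the mirror map", {
  mirror <- c(`1` = "12", `12` = "1", `2` = "4", `4` = "2", `9` = "11",
              `11` = "9", `5` = "8", `8` = "5", `3` = "10", `10` = "3",
              `6` = "6", `7` = "7", none = "none")
  set.seed(2024)
  m <- 2^runif(1000, -2, 10)
  p <- 2^runif(1000, -2, 10)
  h <- 2^runif(1000, -2, 10)
  straight <- classify_12bin(m, h, p)
  swapped <- classify_12bin(p, h, m)
  expect_identical(swapped$class, unname(mirror[straight$class]))
  coarse_mirror <- c(additive = "additive", ELD_maternal = "ELD_paternal",
                     ELD_paternal = "ELD_maternal",
                     transgressive_up = "transgressive_up",
                     transgressive_down = "transgressive_down", none = "none")
  expect_identical(swapped$coarse_mode,
                   unname(coarse_mirror[straight$coarse_mode]))
})

test_that("class-to-coarse-mode mapping is a total partition", {
  cls <- c(as.character(1:12), "none")
  modes <- coarse_mode_of_class(cls)
  expect_identical(sort(cls[modes == "additive"]), c("1", "12"))
  expect_identical(sort(cls[modes == "ELD_paternal"]), c("11", "2"))
  expect_identical(sort(cls[modes == "ELD_maternal"]), c("4", "9"))
  expect_identical(sort(cls[modes == "transgressive_up"]), c("5", "6", "8"))
  expect_identical(sort(cls[modes == "transgressive_down"]),
                   c("10", "3", "7"))
  expect_error(coarse_mode_of_class("13"), "unknown class")
})

test_that("per-hybrid coarse rule matches its defining cases", {
  expect_identical(classify_per_hybrid_coarse(2.75, 2.69), "overdominance")
  expect_identical(classify_per_hybrid_coarse(2.15, 1.60), "dominance")
  expect_identical(classify_per_hybrid_coarse(1.23, 1.35), "additive")
  expect_identical(classify_per_hybrid_coarse(-2.96, -1.97), "dominance")
  expect_identical(classify_per_hybrid_coarse(2.5, -2.5), "discordant")
})

test_that("the published universal-DEG table is reproduced label by label", {
  fc <- universal_fc_fixture()
  lab <- label_universal_degs(fc)
  expect_identical(lab$labels$mode_hybrid1, fc$label_h1)
  expect_identical(lab$labels$mode_hybrid2, fc$label_h2)
  expect_equal(lab$n_overdominant_both, 9L)
  expect_equal(lab$n_up_both, 12L)
  expect_equal(lab$n_down_both, 16L)
  one <- label_universal_degs(data.frame(
    gene_id = "g", fc_h1_p1 = -4.33, fc_h1_p2 = -3.18,
    fc_h2_p1 = -1.92, fc_h2_p2 = -2.04))
  expect_identical(one$labels$mode_hybrid1, "overdominance")
  expect_identical(one$labels$mode_hybrid2, "dominance")
})

test_that("mode summary computes percentages over classified genes", {
  cl <- data.frame(
    cross_id = "A",
    class = c("1", "12", "4", rep("6", 7)),
    coarse_mode = c("additive", "additive", "ELD_maternal",
                    rep("transgressive_up", 7)),
    stringsAsFactors = FALSE)
  s <- mode_summary(cl)
  pooled <- s[s$cross_id == "pooled", ]
  expect_equal(pooled$pct_additive, 20)
  expect_equal(pooled$pct_dominance, 10)
  expect_equal(pooled$pct_overdominance, 70)
  expect_equal(pooled$pct_additive + pooled$pct_dominance +
                 pooled$pct_overdominance, 100, tolerance = 1e-10)

  all_none <- data.frame(cross_id = "A", class = "none", coarse_mode = "none",
                         stringsAsFactors = FALSE)
  s0 <- mode_summary(all_none)
  expect_equal(s0$n_classified, c(0L, 0L))
  expect_true(all(s0$pct_additive == 0 & s0$pct_overdominance == 0))
})
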
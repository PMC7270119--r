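test_that("signed fold change follows the symmetric ratio convention", {
  expect_identical(signed_fold_change(10, 10, 0.5), 1)
  expect_equal(signed_fold_change(8, 2, 0.01), 8.01 / 2.01)
  expect_equal(signed_fold_change(2, 8, 0.01), -8.01 / 2.01)
  expect_error(signed_fold_change(-1, 2), "non-negative")
  expect_error(signed_fold_change(1, 2, pseudocount = 0), "positive")

  set.seed(3)
  a <- runif(500, 0, 100); b <- runif(500, 0, 100)
  fc <- signed_fold_change(a, b)
  expect_true(all(abs(fc) >= 1))                         # never inside (-1, 1)
  expect_equal(signed_fold_change(b, a), ifelse(a == b, fc, -fc))
})

test_that("DEG calls use inclusive thresholds on both comparisons", {
  vals <- rbind(g_up = c(10, 40, 10), g_ns = c(10, 10, 10),
                g_mix = c(10, 25, 60), g_dn = c(40, 10, 30))
  colnames(vals) <- c("P1_A", "F1_A", "P2_A")
  expr <- expression_matrix(vals)
  calls <- call_degs(expr, trio_a())
  expect_equal(nrow(calls), 2L * nrow(vals))
  by_gene <- split(calls$call, calls$gene_id)
  expect_identical(unname(by_gene$g_up), c("up", "up"))
  expect_identical(unname(by_gene$g_ns), c("ns", "ns"))
  expect_identical(unname(by_gene$g_mix), c("up", "down"))
  expect_identical(unname(by_gene$g_dn), c("down", "down"))
  expect_error(call_degs(expr, trio_design("X", "nope", "P2_A", "F1_A")),
               "unknown genotype")
})

test_that("raising the up threshold never adds up calls", {
  set.seed(17)
  vals <- matrix(rexp(300, rate = 0.05), ncol = 3,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 c("P1_A", "F1_A", "P2_A")))
  expr <- expression_matrix(vals)
  ups <- sapply(c(1.5, 2, 3, 5), function(th)
    sum(call_degs(expr, trio_a(), up_threshold = th)$call == "up"))
  expect_true(all(diff(ups) <= 0))
})

test_that("common DEG sets require the same direction versus both parents", {
  # 3 genes up vs both, 2 down vs both, 5 mixed/ns
  vals <- rbind(
    u1 = c(5, 40, 5),  u2 = c(8, 40, 9),   u3 = c(10, 99, 12),
    d1 = c(40, 5, 40), d2 = c(33, 8, 20),
    m1 = c(5, 40, 40), m2 = c(40, 40, 5),  m3 = c(10, 11, 10),
    m4 = c(10, 25, 60), m5 = c(60, 25, 10))
  colnames(vals) <- c("P1_A", "F1_A", "P2_A")
  calls <- call_degs(expression_matrix(vals), trio_a())
  cm <- common_degs_per_cross(calls, trio_a())
  expect_identical(cm$common_up, c("u1", "u2", "u3"))
  expect_identical(cm$common_down, c("d1", "d2"))
})

test_that("universal, discordant and union sets follow set algebra", {
  s <- universal_degs(list(common_up = c("g1", "g2"), common_down = character(0)),
                      list(common_up = c("g2", "g3"), common_down = "g1"))
  expect_identical(s$universal_up, "g2")
  expect_identical(s$discordant, "g1")
  expect_equal(s$n_unique_union, 3L)
  expect_error(
    universal_degs(list(common_up = "g1", common_down = "g1"),
                   list(common_up = "x", common_down = "y")),
    "integrity")
})

test_that("inclusion-exclusion holds on random set instances", {
  set.seed(123)
  pool <- sprintf("g%04d", 1:400)
  for (i in 1:100) {
    a_all <- sample(pool, sample(10:120, 1))
    a_up <- sample(a_all, sample(0:length(a_all), 1))
    a_down <- setdiff(a_all, a_up)
    b_all <- sample(pool, sample(10:120, 1))
    b_up <- sample(b_all, sample(0:length(b_all), 1))
    b_down <- setdiff(b_all, b_up)
    s <- universal_degs(list(common_up = a_up, common_down = a_down),
                        list(common_up = b_up, common_down = b_down))
    expect_equal(s$n_unique_union,
                 length(a_all) + length(b_all) -
                   length(intersect(a_all, b_all)))
    expect_true(all(s$universal_up %in% a_up) && all(s$universal_up %in% b_up))
    expect_length(
      intersect(s$discordant, c(s$universal_up, s$universal_down)), 0)
  }
})

test_that("library correlation is a valid Pearson matrix on log2 scale", {
  vals <- rbind(g1 = c(1, 2, 8), g2 = c(4, 8, 2), g3 = c(16, 32, 1))
  colnames(vals) <- c("s1", "s2", "s3")
  expr <- expression_matrix(vals, pseudocount = 1e-9)
  r <- library_correlation(expr)
  expect_equal(diag(r), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(r, t(r))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  # s2 = 2 * s1 -> identical log2 profile up to a shift -> r = 1
  expect_equal(r["s1", "s2"], 1)
  # hand-computed Pearson on the log2 values of the anti-ordered pair
  l1 <- log2(vals[, "s1"] + 1e-9); l3 <- log2(vals[, "s3"] + 1e-9)
  expect_equal(r["s1", "s3"],
               sum((l1 - mean(l1)) * (l3 - mean(l3))) /
                 sqrt(sum((l1 - mean(l1))^2) * sum((l3 - mean(l3))^2)))

  flat <- rbind(g1 = c(1, 2), g2 = c(1, 4), g3 = c(1, 8))
  colnames(flat) <- c("zero_var", "ok")
  expect_warning(r2 <- library_correlation(expression_matrix(flat)),
                 "zero-variance")
  expect_true(is.na(r2["zero_var", "ok"]))
})
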
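make_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], genotype_id = r[[2]],
               ct_target = as.numeric(r[[3]]),
               ct_reference = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)))
}

test_that("2^-ddCt closed forms hold", {
  recs <- make_ct(list("g", "F1", 20, 18), list("g", "P1", 22, 20))
  expect_equal(relative_expression(recs, "g", "F1", "P1")$fold, 1)

  recs <- make_ct(list("g", "F1", 20, 19), list("g", "P1", 22, 20))
  r <- relative_expression(recs, "g", "F1", "P1")
  expect_equal(r$ddct, -1)
  expect_equal(r$fold, 2)

  recs <- make_ct(list("g", "F1", 20, 18), list("g", "P1", 23, 19))
  r <- relative_expression(recs, "g", "F1", "P1")
  expect_equal(r$ddct, -2)
  expect_equal(r$fold, 4)

  same <- relative_expression(recs, "g", "F1", "F1")
  expect_equal(same$fold, 1)
})

test_that("technical replicates are averaged on the Ct scale", {
  recs <- rbind(make_ct(list("g", "F1", 19, 18), list("g", "F1", 21, 18)),
                make_ct(list("g", "P1", 22, 20)))
  r <- relative_expression(recs, "g", "F1", "P1")
  expect_equal(r$delta_ct_sample, 2)  # mean(19, 21) - 18
  expect_equal(r$fold, 1)
})

test_that("fold reciprocity and Ct-shift invariance hold on random tables", {
  set.seed(7)
  for (i in 1:50) {
    recs <- make_ct(list("g", "s1", runif(1, 15, 30), runif(1, 15, 30)),
                    list("g", "s2", runif(1, 15, 30), runif(1, 15, 30)))
    f12 <- relative_expression(recs, "g", "s1", "s2")$fold
    f21 <- relative_expression(recs, "g", "s2", "s1")$fold
    expect_equal(f12 * f21, 1)

    shifted <- recs
    shift <- runif(1, -3, 3)   # added to BOTH target and reference of s1
    idx <- shifted$genotype_id == "s1"
    shifted$ct_target[idx] <- shifted$ct_target[idx] + shift
    shifted$ct_reference[idx] <- shifted$ct_reference[idx] + shift
    expect_equal(relative_expression(shifted, "g", "s1", "s2")$fold, f12)

    target_only <- recs
    target_only$ct_target[idx] <- target_only$ct_target[idx] + 1
    expect_equal(relative_expression(target_only, "g", "s1", "s2")$fold,
                 f12 / 2)
  }
})

test_that("missing records raise errors", {
  recs <- make_ct(list("g", "F1", 20, 18))
  expect_error(relative_expression(recs, "g", "F1", "P1"), "no Ct record")
  expect_error(relative_expression(recs, "other", "F1", "F1"), "no Ct record")
})

test_that("qPCR concordance scores direction agreement with RNA-Seq", {
  folds <- data.frame(gene_id = c("a", "b", "c"), fold = c(3.2, 2.0, 1.1))
  calls <- data.frame(gene_id = c("a", "b", "c"),
                      call = c("up", "down", "ns"))
  cc <- qpcr_concordance(folds, calls)
  expect_identical(cc$table$agree, c(TRUE, FALSE, TRUE))
  expect_equal(cc$agreement, 2 / 3)

  # 12-gene panel with fully concordant directions
  panel <- data.frame(gene_id = sprintf("g%02d", 1:12),
                      fold = rep(c(4, 0.25), 6))
  panel_calls <- data.frame(gene_id = panel$gene_id,
                            call = rep(c("up", "down"), 6))
  expect_equal(qpcr_concordance(panel, panel_calls)$agreement, 1)
  expect_error(qpcr_concordance(folds,
                                data.frame(gene_id = "zz", call = "up")),
               "no overlapping genes")
})
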
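mk_mat <- function(values, tissues = c("root", "leaf", "stem")) {
  m <- matrix(values, ncol = length(tissues), byrow = TRUE)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- tissues
  m
}

test_that("expression flags use inclusive thresholds", {
  m <- mk_mat(c(1.0, 1.0, 1.0,
                5.0, 1.9, 2.0,
                0.5, 9.0, 9.0))
  fl <- expression_flags(m)
  expect_true(fl$constitutive[["g1"]])     # exactly 1.0 everywhere
  expect_true(fl$constitutive[["g2"]])
  expect_false(fl$constitutive[["g3"]])
  expect_false("g2" %in% fl$expressed_sets$leaf)  # 1.9 < 2
  expect_true("g2" %in% fl$expressed_sets$stem)   # 2.0 >= 2
})

test_that("expression grouping orders groups by descending mean and is seeded", {
  m <- mk_mat(c(20, 20, 20, 6, 6, 6, 1, 1, 1))
  g <- group_expression(m, k = 3, seed = 2)
  mem <- attr(g, "membership")
  expect_equal(unname(mem[c("g1", "g2", "g3")]), c(1, 2, 3))
  expect_true(all(diff(g$mean_fpkm) < 0))

  flat <- mk_mat(rep(5, 9))
  expect_warning(g1 <- group_expression(flat, k = 3, seed = 1),
                 "single group")
  expect_equal(nrow(g1), 1)
  expect_error(group_expression(m, k = 5), "fewer genes")

  # determinism: same matrix + seed => same membership
  e <- generate_expression(small_config(seed = 91L))
  a <- attr(group_expression(e$mat, seed = 4), "membership")
  b <- attr(group_expression(e$mat, seed = 4), "membership")
  expect_identical(a, b)
})

test_that("planted three-level structure is recovered exactly", {
  e <- generate_expression(small_config(seed = 101L))
  g <- group_expression(e$mat, k = 3, seed = 1)
  mem <- attr(g, "membership")
  expect_identical(unname(mem[names(e$truth$groups)]),
                   unname(e$truth$groups))
  # planted tissue-specific gene appears only in its tissue's set
  fl <- expression_flags(e$mat)
  ts <- e$truth$tissue_specific
  typical <- c("root", "hypocotyl", "cotyledon", "true_leaf", "tendril")
  for (r in seq_len(nrow(ts))) {
    inset <- vapply(fl$expressed_sets[typical],
                    function(s) ts$gene_id[r] %in% s, logical(1))
    expect_identical(names(inset)[inset], ts$tissue[r])
  }
})

test_that("Venn regions follow exact set algebra and conserve the union", {
  A <- c("a", "b", "c"); B <- c("b", "c", "d"); C <- c("x")
  v <- venn_membership(list(A = A, B = B, C = C))
  expect_equal(sum(v$count), length(union(union(A, B), C)))
  expect_equal(v$count[v$region == "A&B"], 2)
  expect_equal(v$count[v$region == "C"], 1)
  expect_equal(v$count[v$region == "A&B&C"], 0)

  same <- venn_membership(list(X = A, Y = A))
  expect_equal(same$count[same$region == "X&Y"], 3)
  expect_equal(sum(same$count), 3)

  disj <- venn_membership(list(X = c("a"), Y = c("b")))
  expect_equal(disj$count[disj$region == "X&Y"], 0)
  expect_equal(sum(disj$count), 2)

  expect_error(venn_membership(list(A = A)), "2-5")
  expect_error(venn_membership(setNames(rep(list(A), 6), letters[1:6])),
               "2-5")
})

test_that("ddCt fold change, Welch test and calls follow the 2^-ddCt rule", {
  rec <- function(gene, cond, reps_target, reps_ref = rep(19, 3)) {
    data.frame(gene_id = gene, condition = cond,
               replicate = seq_along(reps_target),
               ct_target = reps_target, ct_reference = reps_ref)
  }
  # identical dCt -> fold 1, ns
  r <- rbind(rec("g", "control", c(25, 25.1, 24.9)),
             rec("g", "ABA", c(25, 25.1, 24.9)))
  out <- ddct_fold_change(r, "g", "ABA")
  expect_equal(out$fold_change, 1, tolerance = 1e-9)
  expect_identical(out$call, "ns")

  # target 1 cycle earlier with stable reference -> fold 2
  r2 <- rbind(rec("g", "control", c(25, 25.05, 24.95)),
              rec("g", "GA", c(24, 24.05, 23.95)))
  out2 <- ddct_fold_change(r2, "g", "GA")
  expect_equal(out2$fold_change, 2, tolerance = 1e-9)
  expect_identical(out2$call, "up")

  # shifting every Ct of a replicate group cancels in dCt
  r3 <- r2
  shift <- r3$condition == "GA"
  r3$ct_target[shift] <- r3$ct_target[shift] + 3
  r3$ct_reference[shift] <- r3$ct_reference[shift] + 3
  expect_equal(ddct_fold_change(r3, "g", "GA")$fold_change,
               out2$fold_change, tolerance = 1e-9)

  expect_error(ddct_fold_change(r2[r2$condition != "control", ], "g", "GA"),
               "control")
})

test_that("zero-noise qPCR recovers planted fold changes exactly", {
  cfg <- small_config(seed = 111L, ct_sd = 0)
  ids <- sprintf("G%02d", 1:5)
  q <- generate_qpcr(cfg, ids)
  fc <- ddct_all(q$records)
  for (i in seq_len(nrow(fc))) {
    planted <- q$truth$fold[fc$gene_id[i], fc$condition[i]]
    expect_equal(fc$fold_change[i], planted, tolerance = 1e-9)
    expected_call <- if (planted > 1) "up" else if (planted < 1) "down"
                     else "ns"
    expect_identical(fc$call[i], expected_call)
  }
})
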
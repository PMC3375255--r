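test_that("summary-statistic and raw-count t-tests agree exactly", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnbinom(4, size = 5, mu = 30)
    y <- rnbinom(6, size = 5, mu = 20)
    t1 <- pooled_t_test(x, y)
    t2 <- pooled_t_test(c(n = length(x), mean = mean(x), sd = sd(x)),
                        c(n = length(y), mean = mean(y), sd = sd(y)))
    expect_identical(t1$t, t2$t)
    expect_identical(t1$p, t2$p)
    expect_equal(t1$df, length(x) + length(y) - 2)
    # swapping the groups negates t and preserves p
    t3 <- pooled_t_test(y, x)
    expect_equal(t3$t, -t1$t)
    expect_identical(t3$p, t1$p)
  }
})

test_that("p-values match numeric integration of the t density", {
  cases <- list(c(10.25, 4.50, 0.50, 0.58), c(16, 5.1, 0, 0),
                c(11.28, 0.27, 12.32, 0.19), c(5, 2, 4.8, 2.1))
  for (cs in cases) {
    r <- pooled_t_test(c(n = 4, mean = cs[1], sd = cs[2]),
                       c(n = 4, mean = cs[3], sd = cs[4]))
    expect_equal(r$p, oracle_t_p(r$t, r$df), tolerance = 1e-4)
  }
})

test_that("degenerate and symmetric inputs are handled explicitly", {
  same <- pooled_t_test(c(n = 4, mean = 5, sd = 1), c(n = 4, mean = 5, sd = 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  zz_eq <- pooled_t_test(rep(3, 4), rep(3, 4))
  expect_equal(zz_eq$p, 1)
  expect_false(zz_eq$degenerate)
  zz <- pooled_t_test(rep(16, 4), rep(0, 4))
  expect_true(zz$degenerate)
  expect_equal(zz$t, Inf)
  expect_lte(zz$p, .Machine$double.xmin)
  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")
})

test_that("Welch option reproduces t.test and differs under variance imbalance", {
  set.seed(2)
  x <- c(10, 12, 9, 11); y <- c(3, 25, 1, 40)
  w <- pooled_t_test(x, y, welch = TRUE)
  ref <- stats::t.test(x, y)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p, ref$p.value)
  p <- pooled_t_test(x, y)
  refp <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(p$p, refp$p.value)
  expect_false(isTRUE(all.equal(w$p, p$p)))
})

test_that("BH adjustment is the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  # order-preserving, monotone step-up on a worked case:
  # sorted p (.001,.01,.04), m=3 -> (.003, .015, .04)
  expect_equal(bh_fdr(c(0.04, 0.001, 0.01)), c(0.04, 0.003, 0.015))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("Psi is the length-normalized density ratio with read filters", {
  expect_equal(estimate_psi(8, 2, 1, 1)$psi, 0.8)
  expect_equal(estimate_psi(20, 20, 2, 2)$psi, 0.5)
  # density normalization: 20 inclusion reads over 2 positions vs 10 over 1
  expect_equal(estimate_psi(20, 10, 2, 1)$psi, 0.5)
  z <- estimate_psi(0, 15, 1, 1)
  expect_equal(z$psi, 0)
  expect_false(z$passes_filter)          # needs >= 1 inclusion read
  expect_false(estimate_psi(5, 5, 1, 1)$passes_filter)  # sum must exceed 10
  expect_true(estimate_psi(6, 5, 1, 1)$passes_filter)
  expect_true(is.na(estimate_psi(0, 0, 1, 1)$psi))
  expect_error(estimate_psi(1, 1, 0, 1), "position")
})

test_that("RPKM follows the definition and fold change is scale-free", {
  expect_equal(rpkm_fold(1000, 1000, 1e7)$rpkm, 100)
  g <- rep(c("t", "c"), each = 2)
  r1 <- rpkm_fold(c(200, 220, 100, 110), 500, rep(1e6, 4), groups = g)
  r2 <- rpkm_fold(c(200, 220, 100, 110), 500, rep(2e6, 4), groups = g)
  expect_equal(r2$rpkm, r1$rpkm / 2)
  expect_equal(r1$fold, r2$fold)
  expect_equal(r1$fold, 2)
  ident <- rpkm_fold(c(5, 5, 5, 5), 100, rep(1e6, 4), groups = g)
  expect_equal(ident$fold, 1)
  zero <- rpkm_fold(c(5, 5, 0, 0), 100, rep(1e6, 4), groups = g)
  expect_true(is.na(zero$fold))
  expect_true(zero$induced_from_zero)
})

test_that("event testing annotates summaries, q-values and Psi", {
  ds <- make_dataset(small_sim_config(seed = 43))
  jt <- dataset_jt(ds)
  genes <- gene_models(ds$ref$annotation)
  ev <- filter_events(detect_exon_skipping(jt, genes), jt)
  tested <- test_all_events(ev, jt, genes = genes)
  expect_true(all(c("mean1", "sd1", "mean2", "sd2", "t", "df", "p", "q",
                    "psi1", "psi2", "delta_psi") %in% names(tested)))
  expect_true(all(diff(tested$p) >= 0))          # sorted by p
  expect_equal(tested$q, bh_fdr(tested$p))
  expect_true(all(tested$df == 6))
  # Psi lives in [0,1] and the skip with a planted group contrast moves it
  expect_true(all(tested$psi1 >= 0 & tested$psi1 <= 1, na.rm = TRUE))
  big <- tested[tested$gene_id == "GENE003", ]
  expect_gt(abs(big$delta_psi), 0.2)
  # constant groups flag the degenerate test
  j <- data.frame(chrom = "chrA", left_end = 100L, right_start = 300L)
  cj <- make_jt(j, matrix(c(16, 16, 16, 16, 0, 0, 0, 0), 1),
                groups = rep(c("t", "c"), each = 4))
  ev1 <- ev[1, ]; ev1$junction_key <- "chrA:100:300"
  class(ev1) <- c("splice_events", "data.frame")
  t1 <- test_all_events(ev1, cj)
  expect_true(t1$degenerate)
  expect_equal(t1$mean1, 16)
  expect_equal(t1$sd2, 0)
  # all-zero events are dropped with a message
  zj <- make_jt(j, matrix(0, 1, 8), groups = rep(c("t", "c"), each = 4))
  expect_message(tz <- test_all_events(ev1, zj), "zero counts")
  expect_equal(nrow(tz), 0)
})

test_that("a strong planted difference is detected with high power", {
  set.seed(7)
  hits <- 0
  for (i in 1:40) {
    x <- rnbinom(4, size = 10, mu = 200)
    y <- rnbinom(4, size = 10, mu = 20)
    if (pooled_t_test(x, y)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})
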
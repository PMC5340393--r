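test_that("pooled t test matches the textbook oracle and its symmetries", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  o <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742346, tolerance = 1e-6)
  expect_equal(r$p, 0.0213116, tolerance = 1e-5)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  expect_equal(r$log2fc, -3)
  expect_equal(r$df, 4)

  # identity: x == y
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # antisymmetry
  sw <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -r$t)
  expect_equal(sw$p, r$p)

  # degenerate zero-variance cases
  flat <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(c(flat$t, flat$p), c(0, 1))
  sep <- two_sample_t(c(5, 5, 5), c(1, 1, 1))
  expect_equal(sep$t, Inf)
  expect_equal(sep$p, 0)
  expect_error(two_sample_t(1, c(1, 2)), ">=2 values")
})

test_that("t statistic equals the closed form to 1e-10 on random data", {
  set.seed(91)
  for (i in 1:200) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    r <- two_sample_t(x, y)
    o <- oracle_pooled_t(x, y)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("stage-higher sets combine t tests with stage-unique peaks", {
  vals <- rbind(
    p1 = c(5, 5.1, 4.9, 1, 1.1, 0.9, 1, 0.9, 1.1),  # higher in s1
    p2 = c(1, 1.1, 0.9, 1, 0.9, 1.1, 1, 1.05, 0.95), # null
    p3 = c(2, 2, 2, NA, NA, NA, NA, NA, NA))          # unique to s1
  groups <- rep(c("s1", "s2", "s3"), each = 3)
  colnames(vals) <- paste(groups, 1:3, sep = ".")
  presence <- cbind(s1 = c(TRUE, TRUE, TRUE),
                    s2 = c(TRUE, TRUE, FALSE),
                    s3 = c(TRUE, TRUE, FALSE))
  rownames(presence) <- rownames(vals)
  sets <- call_stage_higher(vals, groups, presence)
  expect_setequal(sets$s1$id, c("p1", "p3"))
  expect_equal(sets$s1$provenance[sets$s1$id == "p1"], "t_test")
  expect_equal(sets$s1$provenance[sets$s1$id == "p3"], "stage_unique")
  expect_equal(nrow(sets$s2), 0)
  expect_equal(nrow(sets$s3), 0)
  # disjointness across stages
  ids <- unlist(lapply(sets, `[[`, "id"))
  expect_equal(anyDuplicated(ids), 0L)
  expect_error(call_stage_higher(vals[, 1:6], groups[1:6],
                                 presence[, 1:2]), ">=3 stages")
})

test_that("raising alpha only grows the stage-higher sets", {
  set.seed(92)
  n <- 60
  vals <- matrix(rnorm(9 * n, mean = rep(c(1, 0, 0), each = 3 * n) *
                         rep(stats::rbinom(n, 1, 0.4), 9), sd = 0.4),
                 nrow = n)
  groups <- rep(c("s1", "s2", "s3"), each = 3)
  rownames(vals) <- paste0("p", seq_len(n))
  colnames(vals) <- paste(groups, 1:3, sep = ".")
  presence <- matrix(TRUE, n, 3, dimnames = list(rownames(vals),
                                                 c("s1", "s2", "s3")))
  lo <- call_stage_higher(vals, groups, presence, alpha = 0.01)
  hi <- call_stage_higher(vals, groups, presence, alpha = 0.10)
  for (s in c("s1", "s2", "s3")) {
    expect_true(all(lo[[s]]$id %in% hi[[s]]$id))
  }
})

test_that("expression calls find planted direction and ignore flat genes", {
  set.seed(93)
  jitter <- function(x) x * 2^rnorm(3, 0, 0.05)
  fpkm <- rbind(g1 = c(jitter(100), jitter(1), jitter(1)),
                g2 = c(jitter(10), jitter(10), jitter(10)))
  groups <- rep(c("s1", "s2", "s3"), each = 3)
  colnames(fpkm) <- paste(groups, 1:3, sep = ".")
  res <- call_expression(fpkm, groups)
  expect_equal(res$higher$s1, "g1")
  expect_equal(res$lower$s2, character(0))
  expect_false("g2" %in% unlist(res$higher))
  # g1 is lower in neither s2 nor s3 alone (it must be below BOTH others)
  expect_false("g1" %in% res$lower$s2 && "g1" %in% res$lower$s3)
})

test_that("higher-methylation/lower-expression genes intersect correctly", {
  meth_sets <- list(
    s1 = data.frame(id = c("pk1", "pk2"), provenance = "t_test"),
    s2 = data.frame(id = character(0), provenance = character(0)),
    s3 = data.frame(id = character(0), provenance = character(0)))
  lower <- list(s1 = c("gA"), s2 = character(0), s3 = character(0))
  peak_genes <- c(pk1 = "gA", pk2 = "gB")
  out <- higher_meth_lower_expr(meth_sets, lower, peak_genes)
  expect_equal(out$s1, "gA")   # gB not lower-expressed -> excluded
  expect_equal(out$s2, character(0))
})

test_that("pairwise summary equals a direct recount of the call list", {
  set.seed(94)
  n <- 40
  vals <- matrix(rnorm(9 * n), nrow = n,
                 dimnames = list(paste0("pk", 1:n), NULL))
  groups <- rep(c("s1", "s2", "s3"), each = 3)
  calls <- pairwise_differential(vals, groups, alpha = 0.2)
  peak_genes <- stats::setNames(paste0("g", rep(1:20, 2)), rownames(vals))
  ex_vals <- matrix(rnorm(9 * 20), nrow = 20,
                    dimnames = list(paste0("g", 1:20), NULL))
  ex_calls <- pairwise_differential(ex_vals, groups, alpha = 0.2)
  tab <- summarize_differential(calls, ex_calls, peak_genes, 20, 20)
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    src <- if (row$measure == "methylation") calls else ex_calls
    sub <- src[paste(src$stage_a, "vs", src$stage_b) == row$comparison, ]
    if (row$measure == "methylation") {
      expect_equal(row$higher_in_a, length(unique(
        peak_genes[sub$id[sub$category == "higher_a"]])))
      expect_equal(row$higher_in_b, length(unique(
        peak_genes[sub$id[sub$category == "higher_b"]])))
    } else {
      expect_equal(row$higher_in_a, sum(sub$category == "higher_a"))
      expect_equal(row$higher_in_b, sum(sub$category == "higher_b"))
    }
    expect_equal(row$total, row$higher_in_a + row$higher_in_b)
    expect_equal(row$prop_a, row$higher_in_a / 20)
  }
})

test_that("null simulation keeps the per-pair false positive rate near alpha", {
  set.seed(95)
  n <- 2000
  vals <- matrix(rnorm(6 * n), nrow = n)
  p <- vapply(seq_len(n), function(i) {
    two_sample_t(vals[i, 1:3], vals[i, 4:6])$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.015)  # ~3 sigma at n = 2000
})
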
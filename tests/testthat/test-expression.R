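flat_ct <- function(gene_ct, ref_ct, reps = 3L) {
  dplyr::bind_rows(lapply(names(gene_ct), function(cond) {
    tibble::tibble(
      condition = cond,
      gene = rep(c("tgt", "gapdh"), each = reps),
      replicate = rep(seq_len(reps), 2L),
      ct = rep(c(gene_ct[[cond]], ref_ct), each = reps)
    )
  }))
}

test_that("2^-ddCt matches the closed form and pins the calibrator at 1", {
  ct <- flat_ct(c(control = 22, treated = 20), ref_ct = 18)
  res <- ddct_fold_change(ct, "gapdh", "control")
  treated <- res$summary[res$summary$condition == "treated", ]
  expect_equal(treated$ddct, -2)
  expect_equal(treated$fold, 4)
  expect_equal(res$summary$fold[res$summary$condition == "control"], 1)

  noisy <- generate_ct_table(ct_design(
    genes = "g", conditions = c("cal", "x"),
    folds = tibble::tibble(gene = "g", condition = "x", fold = 3),
    replicates = 4, sd = 0.3, seed = 7
  ))
  res2 <- ddct_fold_change(noisy, "gapdh", "cal")
  expect_identical(res2$summary$fold[res2$summary$condition == "cal"], 1)
})

test_that("missing reference measurements are reported by sample", {
  ct <- flat_ct(c(control = 22, treated = 20), ref_ct = 18)
  broken <- ct[!(ct$gene == "gapdh" & ct$condition == "treated"), ]
  expect_error(ddct_fold_change(broken, "gapdh", "control"), "treated",
               class = "sod_input_error")
})

test_that("the fold estimator is unbiased on the log scale", {
  true_fold <- 5.1
  errs <- vapply(1:200, function(s) {
    ct <- generate_ct_table(ct_design(
      genes = "g", conditions = c("cal", "x"),
      folds = tibble::tibble(gene = "g", condition = "x", fold = true_fold),
      replicates = 4, sd = 0.2, seed = s
    ))
    res <- ddct_fold_change(ct, "gapdh", "cal")
    log2(res$summary$fold[res$summary$condition == "x"])
  }, numeric(1))
  expect_lt(abs(mean(errs) - log2(true_fold)), 0.05)
})

test_that("LSD letters separate clear groups and share under equality", {
  clear <- tibble::tibble(
    group = rep(c("low", "mid", "high"), each = 3),
    value = c(1, 1.01, 0.99, 10, 10.1, 9.9, 100, 100.5, 99.5)
  )
  res <- lsd_letters(clear)
  expect_equal(sort(res$letters$letter), c("a", "b", "c"))

  same <- tibble::tibble(group = rep(c("g1", "g2", "g3"), each = 3),
                         value = rep(c(1, 1.2, 0.8), 3))
  res2 <- lsd_letters(same)
  expect_equal(unique(res2$letters$letter), "a")

  degenerate <- tibble::tibble(group = rep(c("g1", "g2"), each = 3),
                               value = rep(c(1, 2), each = 3))
  expect_error(lsd_letters(degenerate), class = "sod_variance_error")
})

test_that("two-group LSD reduces to the pooled-variance t-test", {
  df <- tibble::tibble(group = rep(c("g1", "g2"), each = 4),
                       value = c(1, 2, 1.5, 1.8, 3, 3.5, 2.9, 3.2))
  res <- lsd_letters(df)
  tt <- t.test(value ~ group, data = df, var.equal = TRUE)
  expect_equal(res$pairs$p, tt$p.value)
  expect_equal(res$letters$letter, c("a", "b"))
})

test_that("letters are consistent with the pairwise significance matrix", {
  set.seed(15)
  for (trial in 1:5) {
    df <- tibble::tibble(
      group = rep(paste0("g", 1:5), each = 3),
      value = rnorm(15, mean = rep(runif(5, 0, 3), each = 3), sd = 0.5)
    )
    res <- lsd_letters(df)
    lt <- setNames(res$letters$letter, res$letters$group)
    share <- function(a, b) {
      length(intersect(strsplit(lt[[a]], "")[[1]],
                       strsplit(lt[[b]], "")[[1]])) > 0
    }
    for (r in seq_len(nrow(res$pairs))) {
      p <- res$pairs[r, ]
      expect_equal(share(p$group1, p$group2), p$p >= res$alpha,
                   info = paste(trial, p$group1, p$group2))
    }
  }
})

test_that("Pearson correlation matches hand computations and affine laws", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(84 / 9),
               tolerance = 1e-6)
  x <- c(2.5, 1, 4, 3.3, 0.2)
  y <- c(1, 0.5, 2, 2.2, 0.4)
  expect_equal(pearson_correlation(2 * x + 1, y), pearson_correlation(x, y))
  expect_error(pearson_correlation(rep(1, 4), 1:4),
               class = "sod_variance_error")
})

test_that("karyogamy correlations use the recorded stage percentages", {
  k <- karyogamy_efficiency()
  expect_equal(k$efficiency, c(37.5, 30, 0.1))
  prop <- tibble::tibble(gene = "g", stage = k$stage,
                         expression = k$efficiency / 10)
  expect_equal(karyogamy_correlation(prop)$r, 1)
  two <- tibble::tibble(gene = "h", stage = k$stage,
                        expression = c(10, 8, 0.2))
  expect_equal(karyogamy_correlation(two)$r,
               cor(c(10, 8, 0.2), k$efficiency))
  expect_error(
    karyogamy_correlation(tibble::tibble(gene = "g", stage = c("egg", "x"),
                                         expression = c(1, 2))),
    class = "sod_input_error"
  )
  expect_error(
    karyogamy_correlation(tibble::tibble(gene = "g", stage = k$stage,
                                         expression = rep(2, 3))),
    class = "sod_variance_error"
  )
})

test_that("tidiers and plots expose the fitted results", {
  ct <- flat_ct(c(control = 22, treated = 20), ref_ct = 18)
  res <- ddct_fold_change(ct, "gapdh", "control")
  expect_equal(tidy(res), res$summary)
  expect_equal(glance(res)$reference_gene, "gapdh")
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(fx_mn1()), "ggplot")
})
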
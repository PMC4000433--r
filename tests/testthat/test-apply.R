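write_fixture_tsvs <- function(values, ann, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mat_path <- file.path(dir, "expr.tsv")
  ann_path <- file.path(dir, "ann.tsv")
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(values)),
                     tibble::as_tibble(values)),
    mat_path
  )
  readr::write_tsv(ann, ann_path)
  list(matrix = mat_path, annotation = ann_path)
}

small_fixture <- function() {
  values <- matrix(
    c(1.0, 1.1, 2.0, 2.2,
      0.5, 0.4, 0.5, 0.6,
      3.0, 3.1, 1.0, 0.9),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3", "s4"))
  )
  ann <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    category = c("t0", "t0", "t1", "t1"),
    category_order = c(1, 1, 2, 2)
  )
  list(values = values, ann = ann)
}

test_that("a small expression fixture round-trips through the TSV reader", {
  fx <- small_fixture()
  paths <- write_fixture_tsvs(fx$values, fx$ann)
  ds <- read_expression(paths$matrix, paths$annotation)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(ds$values, fx$values)
  expect_equal(ds$gene_ids, c("gA", "gB", "gC"))
  expect_equal(ds$categories, c("t0", "t1"))
  expect_equal(as.character(ds$samples$category), fx$ann$category)
})

test_that("the reader reports unknown samples, duplicates, and thin categories", {
  fx <- small_fixture()
  ann_bad <- dplyr::bind_rows(
    fx$ann,
    tibble::tibble(sample_id = "s99", category = "t1", category_order = 2)
  )
  paths <- write_fixture_tsvs(fx$values, ann_bad)
  expect_error(read_expression(paths$matrix, paths$annotation), "s99")

  vals_dup <- fx$values
  rownames(vals_dup) <- c("gA", "gA", "gC")
  paths2 <- write_fixture_tsvs(vals_dup, fx$ann)
  expect_error(read_expression(paths2$matrix, paths2$annotation), "Duplicate")

  ann_single <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    category = c("t0", "t0", "t1"),
    category_order = c(1, 1, 2)
  )
  paths3 <- write_fixture_tsvs(fx$values[, 1:3], ann_single)
  expect_error(read_expression(paths3$matrix, paths3$annotation),
               "fewer than 2 replicates")
})

test_that("contrast designs enumerate successive and baseline pairs", {
  cats <- c("0", "10", "30", "60", "100")
  succ <- contrast_design(cats, "successive")
  expect_equal(succ$ref, c("0", "10", "30", "60"))
  expect_equal(succ$alt, c("10", "30", "60", "100"))
  base <- contrast_design(cats, "baseline")
  expect_equal(base$ref, rep("0", 4))
  expect_equal(base$alt, c("10", "30", "60", "100"))
  expect_equal(nrow(base), length(cats) - 1L)
})

test_that("pooled t matches the closed-form textbook computation", {
  # A = (1,2,3) vs B = (4,5,6): pooled s^2 = 1, t = 3/sqrt(2/3), df = 4
  values <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:6)))
  ds <- expression_dataset(values, rep(c("a", "b"), each = 3))
  res <- compute_contrast_pvalues(ds, test = "pooled_t")
  t_expected <- 3 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_expected, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(-t_expected, 4), tolerance = 1e-6)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(res$statistic_sign, 1)
})

test_that("welch and pooled t agree with stats::t.test on random data", {
  set.seed(181)
  values <- matrix(rnorm(5 * 10, sd = rep(c(1, 3), each = 5)), 5, 10)
  rownames(values) <- paste0("g", 1:5)
  ds <- expression_dataset(values, rep(c("lo", "hi"), each = 5))
  for (test in c("welch_t", "pooled_t")) {
    res <- compute_contrast_pvalues(ds, test = test)
    for (g in 1:5) {
      tt <- stats::t.test(values[g, 6:10], values[g, 1:5],
                          var.equal = (test == "pooled_t"))
      row <- res[res$set_id == paste0("g", g), ]
      expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
      expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-10)
    }
  }
})

test_that("degenerate contrasts get p = 1 and no direction, with a warning", {
  values <- matrix(c(2, 2, 2, 2,   # constant, equal means
                     1, 1, 2, 2),  # constant but separated
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("flat", "step"), paste0("s", 1:4)))
  ds <- expression_dataset(values, c("a", "a", "b", "b"))
  expect_warning(res <- compute_contrast_pvalues(ds), "degenerate")
  flat <- res[res$set_id == "flat", ]
  expect_equal(flat$p_value, 1)
  expect_equal(flat$statistic_sign, 0)
  step <- res[res$set_id == "step", ]
  expect_equal(step$p_value, 0)
  expect_equal(step$statistic_sign, 1)
})

test_that("missing values leave a contrast testable only with 2+ replicates per side", {
  values <- matrix(rnorm(8), 2, 4,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  values[1, 1:3] <- NA  # one non-missing value on the 'a' side for g1
  ds <- expression_dataset(values, c("a", "a", "b", "b"))
  expect_warning(res <- compute_contrast_pvalues(ds), "degenerate")
  g1 <- res[res$set_id == "g1", ]
  expect_equal(g1$p_value, 1)
  expect_equal(g1$statistic_sign, 0)
})

test_that("gene lists are method-consistent: bonferroni = holm, hochberg a superset", {
  ds <- make_expression_fixture(n_genes = 60, reps = 4, n_signal = 25,
                                effect = 1.5, seed = 191)
  reports <- lapply(c("bonferroni", "holm", "hochberg"), function(meth) {
    analyze_expression(ds, mode = "baseline", method = meth, alpha = 0.05)
  })
  genes <- lapply(reports, function(r) r$genes$gene_id[r$genes$set_rejected])
  expect_setequal(genes[[1]], genes[[2]])
  expect_true(all(genes[[2]] %in% genes[[3]]))
  # per-gene significant-contrast counts are ordered genewise
  n_sig <- lapply(reports, function(r) r$genes$n_significant)
  expect_true(all(n_sig[[1]] <= n_sig[[2]]))
  expect_true(all(n_sig[[2]] <= n_sig[[3]]))
})

test_that("sensitivity table rows sum to the number of rejected genes", {
  ds <- make_expression_fixture(n_genes = 50, reps = 4, n_signal = 20,
                                effect = 2, seed = 201)
  rep <- analyze_expression(ds, mode = "successive", method = "holm")
  expect_equal(sum(rep$sensitivity$n_genes), sum(rep$genes$set_rejected))
  expect_equal(nrow(rep$sensitivity), nrow(rep$design))
})

test_that("induced genes are called induced and a no-signal dataset stays quiet", {
  ds <- make_expression_fixture(n_genes = 40, reps = 5, n_signal = 12,
                                effect = 4, seed = 211)
  rep <- analyze_expression(ds, mode = "baseline", method = "hochberg")
  called <- rep$genes[rep$genes$set_rejected, ]
  expect_gt(nrow(called), 0)
  expect_true(all(called$call == "induced"))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1)
  expect_s3_class(autoplot(rep), "ggplot")

  ds_null <- make_expression_fixture(n_genes = 40, reps = 5, n_signal = 0,
                                     seed = 221)
  rep_null <- analyze_expression(ds_null, mode = "baseline", method = "hochberg")
  expect_lte(sum(rep_null$genes$set_rejected), 2)
})

test_that("synthetic end-to-end analysis keeps the set-level OFDR near alpha", {
  # repeated small datasets with known truth; average OFDR of the calls
  set.seed(231)
  n_data <- 60
  ratios <- vapply(seq_len(n_data), function(i) {
    n_genes <- 60
    n_signal <- 20
    reps <- 4
    cats <- c("c1", "c2", "c3")
    vals <- matrix(rnorm(n_genes * length(cats) * reps), n_genes)
    rownames(vals) <- paste0("g", seq_len(n_genes))
    cat_of <- rep(cats, each = reps)
    up <- sample(n_genes, n_signal)
    for (g in up) {
      vals[g, ] <- vals[g, ] + 2.5 * (match(cat_of, cats) - 1)
    }
    ds <- expression_dataset(vals, cat_of, category_levels = cats)
    rep <- analyze_expression(ds, mode = "successive", method = "hochberg",
                              alpha = 0.05)
    false_rejected <- sum(rep$genes$set_rejected &
                            !(rep$genes$gene_id %in% paste0("g", up)))
    false_rejected / max(sum(rep$genes$set_rejected), 1)
  }, numeric(1))
  est <- mean(ratios)
  se <- sd(ratios) / sqrt(n_data)
  expect_lte(est, 0.05 + 3 * se)
})
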
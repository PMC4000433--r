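#' Build an expression dataset with ordered sample categories
#'
#' Wraps a genes-by-samples expression matrix and an ordered categorical
#' sample annotation (time points or dose levels) into the container used
#' by [compute_contrast_pvalues()] and [analyze_expression()]. Values are
#' assumed already normalized / log-scaled; no preprocessing is done.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). `NA`s are allowed and
#'   handled per contrast.
#' @param sample_category Vector of category labels, one per column of
#'   `values`, or a data frame with columns `sample_id`, `category` and
#'   optionally `category_order`.
#' @param category_levels Optional character vector giving the category
#'   order (low to high); defaults to the order of first appearance, or to
#'   `category_order` when given.
#'
#' @return An object of class `expression_dataset`: a list with `values`,
#'   `gene_ids`, `samples` (tibble `sample_id`, `category`) and
#'   `categories` (ordered levels).
#' @export
expression_dataset <- function(values, sample_category, category_levels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate gene ids in `values` rownames.")
  }
  if (any(is.infinite(values))) {
    abort("`values` must be finite (NA is allowed, Inf is not).")
  }
  if (is.data.frame(sample_category)) {
    ann <- sample_category
    if (!all(c("sample_id", "category") %in% names(ann))) {
      abort("Annotation must have columns `sample_id` and `category`.")
    }
    if (is.null(colnames(values))) {
      abort("`values` must have sample ids as colnames to match the annotation.")
    }
    missing_samples <- setdiff(ann$sample_id, colnames(values))
    if (length(missing_samples)) {
      abort(paste0(
        "Annotation references sample(s) absent from the matrix: ",
        paste(missing_samples, collapse = ", "), "."
      ))
    }
    values <- values[, as.character(ann$sample_id), drop = FALSE]
    if (is.null(category_levels) && "category_order" %in% names(ann)) {
      category_levels <- ann %>%
        distinct(.data$category, .data$category_order) %>%
        arrange(.data$category_order) %>%
        pull(.data$category) %>%
        as.character()
    }
    sample_category <- ann$category
  }
  if (length(sample_category) != ncol(values)) {
    abort("`sample_category` must have one entry per sample column.")
  }
  if (anyNA(sample_category)) abort("Missing category labels are not allowed.")
  if (is.null(category_levels)) category_levels <- unique(as.character(sample_category))
  category <- factor(as.character(sample_category), levels = category_levels,
                     ordered = TRUE)
  if (anyNA(category)) abort("`category_levels` does not cover all categories.")
  if (nlevels(category) < 2L) abort("At least 2 ordered categories are required.")
  reps <- table(category)
  if (any(reps < 2L)) {
    abort(paste0(
      "Categories with fewer than 2 replicates cannot be tested: ",
      paste(names(reps)[reps < 2L], collapse = ", "), "."
    ))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  }
  structure(
    list(
      values = values,
      gene_ids = rownames(values),
      samples = tibble(sample_id = colnames(values), category = category),
      categories = category_levels
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "Expression dataset: %d genes x %d samples\n",
    nrow(x$values), ncol(x$values)
  ))
  cat("  ordered categories:", paste(x$categories, collapse = " < "), "\n")
  print(table(x$samples$category))
  invisible(x)
}

#' Read an expression matrix and its ordered-category annotation
#'
#' Reads a tab-separated expression matrix (first column gene id, remaining
#' columns one sample each) and a sample annotation table with columns
#' `sample_id`, `category` and `category_order` (an integer or numeric rank
#' giving the category ordering, low to high).
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param annotation_path Path to the TSV sample annotation.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, annotation_path) {
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  if (ncol(mat_df) < 2L) abort("Expression matrix must have gene id + sample columns.")
  values <- as.matrix(mat_df[, -1L, drop = FALSE])
  if (!is.numeric(values)) abort("Expression values must be numeric.")
  rownames(values) <- as.character(mat_df[[1L]])
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE)
  expression_dataset(values, ann)
}

#' Contrast design over ordered categories
#'
#' Defines the individual hypotheses tested for every gene. With ordered
#' categories \eqn{c_1 < \dots < c_k}:
#' \describe{
#'   \item{successive}{each category against the previous one
#'     (\eqn{c_2} vs \eqn{c_1}, ..., \eqn{c_k} vs \eqn{c_{k-1}}) — the
#'     time-course design;}
#'   \item{baseline}{each later category against the first
#'     (\eqn{c_2} vs \eqn{c_1}, ..., \eqn{c_k} vs \eqn{c_1}) — the
#'     dose-response design with \eqn{c_1} as the zero dose.}
#' }
#' Both yield `q = k - 1` hypotheses per gene. Differences are always taken
#' as later minus earlier/baseline, so direction `+1` means induced.
#'
#' @param categories Character vector of ordered category labels (low to
#'   high), e.g. `dataset$categories`.
#' @param mode `"successive"` or `"baseline"`.
#' @return A tibble with columns `hypothesis_id`, `ref`, `alt`.
#' @export
contrast_design <- function(categories, mode = c("successive", "baseline")) {
  mode <- match.arg(mode)
  categories <- as.character(categories)
  k <- length(categories)
  if (k < 2L) abort("Need at least 2 categories.")
  ref <- if (mode == "successive") categories[-k] else rep(categories[1L], k - 1L)
  alt <- categories[-1L]
  tibble(
    hypothesis_id = paste0(alt, "_vs_", ref),
    ref = ref,
    alt = alt
  )
}

#' Per-gene per-contrast two-sample t-tests
#'
#' For every gene and every contrast of the design, computes a two-sided
#' two-sample t-test p-value for the difference in mean expression and the
#' sign of that difference (`alt` minus `ref`). `"welch_t"` (default) does
#' not assume equal variances (Welch-Satterthwaite degrees of freedom);
#' `"pooled_t"` uses the pooled-variance statistic.
#'
#' Degenerate cases are handled conservatively: a contrast with zero
#' variance on both sides and equal means, or with fewer than 2 non-missing
#' replicates on either side, gets `p = 1`, sign 0, and a warning.
#'
#' @param dataset An [expression_dataset()].
#' @param design A [contrast_design()] tibble (default: successive
#'   contrasts over the dataset's categories).
#' @param test `"welch_t"` or `"pooled_t"`.
#' @return A tibble in the long hypothesis-set format accepted by
#'   [hset_test()]: `set_id` (gene), `hypothesis_id` (contrast),
#'   `p_value`, `statistic_sign`, plus `statistic` and `df`.
#' @export
compute_contrast_pvalues <- function(dataset,
                                     design = contrast_design(dataset$categories),
                                     test = c("welch_t", "pooled_t")) {
  test <- match.arg(test)
  if (!inherits(dataset, "expression_dataset")) {
    abort("`dataset` must be an `expression_dataset`.")
  }
  vals <- dataset$values
  cat_of <- dataset$samples$category
  # per-category per-gene summaries, NA-aware
  cats <- unique(c(design$ref, design$alt))
  summ <- lapply(cats, function(cc) {
    sub <- vals[, cat_of == cc, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    mm <- rowMeans(sub, na.rm = TRUE)
    vv <- apply(sub, 1L, var, na.rm = TRUE)
    list(n = nn, mean = mm, var = vv)
  })
  names(summ) <- cats

  out <- purrr::pmap_dfr(design, function(hypothesis_id, ref, alt) {
    a <- summ[[ref]]
    b <- summ[[alt]]
    diff <- b$mean - a$mean
    ok <- a$n >= 2L & b$n >= 2L
    if (test == "welch_t") {
      se2 <- a$var / a$n + b$var / b$n
      df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
    } else {
      df <- a$n + b$n - 2
      sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
      se2 <- sp2 * (1 / a$n + 1 / b$n)
    }
    tstat <- diff / sqrt(se2)
    # zero variance on both sides: equal means -> no evidence (p = 1);
    # separated means -> infinitely strong evidence (p = 0)
    degen_equal <- ok & se2 == 0 & diff == 0
    degen_sep <- ok & se2 == 0 & diff != 0
    tstat[degen_equal] <- 0
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    p[degen_equal] <- 1
    p[degen_sep] <- 0
    p[!ok] <- 1
    sgn <- sign(diff)
    sgn[degen_equal | !ok] <- 0
    if (any(degen_equal) || any(!ok)) {
      warn(sprintf(
        "%d gene-contrast test(s) were degenerate (constant or insufficient data); p set to 1, sign to 0.",
        sum(degen_equal | !ok)
      ))
    }
    tibble(
      set_id = dataset$gene_ids,
      hypothesis_id = hypothesis_id,
      p_value = unname(p),
      statistic_sign = unname(sgn),
      statistic = unname(ifelse(degen_equal | !ok, 0, tstat)),
      df = unname(df)
    )
  })
  out %>% arrange(match(.data$set_id, dataset$gene_ids))
}

#' Set-level differential expression analysis over ordered categories
#'
#' End-to-end front-end: computes per-gene per-contrast t-tests, runs the
#' chosen hypothesis-set procedure at OFDR/mdFDR level `alpha`, and reports
#' per-gene calls and the dose-sensitivity distribution. A significant gene
#' is called `induced` when all its significant contrasts have direction
#' `+1`, `suppressed` when all are `-1`, and `mixed` otherwise;
#' non-significant genes are `none`.
#'
#' @inheritParams compute_contrast_pvalues
#' @param mode Contrast design: `"successive"` (each category vs the
#'   previous) or `"baseline"` (each category vs the first).
#' @param method Procedure passed to [hset_test()].
#' @param alpha Nominal OFDR/mdFDR level.
#' @return An object of class `gene_report`: a list with
#'   \describe{
#'     \item{genes}{tibble `gene_id`, `screening_p`, `set_rejected`,
#'       `n_significant`, `call`;}
#'     \item{contrasts}{tidy per-gene per-contrast tibble (tests, rejection
#'       flags, directions);}
#'     \item{sensitivity}{tibble counting rejected genes by their number of
#'       significant contrasts (1 ... q);}
#'     \item{fit}{the underlying [hset_test()] object;}
#'     \item{design, alpha, method, test}{the configuration.}
#'   }
#' @examples
#' sim <- simulate_timecourse(m = 40, m0 = 30, seed = 2)
#' # rows = time points in the simulated matrix; build a dataset with 3
#' # replicates per category by treating genes as features
#' @export
analyze_expression <- function(dataset, mode = c("successive", "baseline"),
                               method = c("hochberg", "holm", "bonferroni",
                                          "simple_bh"),
                               alpha = 0.05, test = c("welch_t", "pooled_t")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  test <- match.arg(test)
  design <- contrast_design(dataset$categories, mode)
  coll <- compute_contrast_pvalues(dataset, design, test)
  fit <- hset_test(coll, alpha = alpha, method = method)

  per_gene <- fit$hypotheses %>%
    group_by(.data$set_id) %>%
    summarise(
      n_significant = sum(.data$rejected),
      n_up = sum(.data$direction > 0),
      n_down = sum(.data$direction < 0)
    )
  genes <- fit$sets %>%
    rename(gene_id = "set_id") %>%
    left_join(per_gene, by = c(gene_id = "set_id")) %>%
    mutate(
      call = dplyr::case_when(
        .data$n_significant == 0L ~ "none",
        .data$n_up > 0L & .data$n_down == 0L ~ "induced",
        .data$n_down > 0L & .data$n_up == 0L ~ "suppressed",
        TRUE ~ "mixed"
      )
    ) %>%
    select("gene_id", "screening_p", "set_rejected", "n_significant", "call")

  q <- nrow(design)
  rejected_genes <- genes %>% filter(.data$set_rejected)
  sensitivity <- tibble(n_contrasts = seq_len(q)) %>%
    left_join(
      rejected_genes %>% count(n_contrasts = .data$n_significant),
      by = "n_contrasts"
    ) %>%
    mutate(n_genes = tidyr::replace_na(.data$n, 0L)) %>%
    select("n_contrasts", "n_genes")

  structure(
    list(
      genes = genes,
      contrasts = tidy(fit),
      sensitivity = sensitivity,
      fit = fit,
      design = design,
      alpha = alpha,
      method = method,
      test = test
    ),
    class = "gene_report"
  )
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf(
    "Ordered-category differential expression (%s, %s, alpha = %g)\n",
    x$method, x$test, x$alpha
  ))
  cat(sprintf(
    "  %d genes tested, %d significant (%d induced, %d suppressed, %d mixed)\n",
    nrow(x$genes), sum(x$genes$set_rejected),
    sum(x$genes$call == "induced"), sum(x$genes$call == "suppressed"),
    sum(x$genes$call == "mixed")
  ))
  cat("  significant contrasts per significant gene:\n")
  print(x$sensitivity)
  invisible(x)
}

#' @rdname analyze_expression
#' @param x A `gene_report`.
#' @param ... Unused.
#' @export
tidy.gene_report <- function(x, ...) x$genes

#' @rdname analyze_expression
#' @export
glance.gene_report <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_significant = sum(x$genes$set_rejected),
    n_induced = sum(x$genes$call == "induced"),
    n_suppressed = sum(x$genes$call == "suppressed"),
    n_mixed = sum(x$genes$call == "mixed"),
    n_individual_rejections = sum(x$contrasts$rejected),
    alpha = x$alpha,
    method = x$method,
    test = x$test
  )
}

#' @rdname analyze_expression
#' @param object A `gene_report`.
#' @export
autoplot.gene_report <- function(object, ...) {
  ggplot2::ggplot(object$sensitivity, ggplot2::aes(
    x = factor(.data$n_contrasts), y = .data$n_genes
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "number of significant contrasts",
      y = "number of significant genes",
      title = sprintf("Dose/time sensitivity (%s, alpha = %g)",
                      object$method, object$alpha)
    ) +
    ggplot2::theme_minimal()
}
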
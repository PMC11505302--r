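#' Log2-transform an expression matrix
#'
#' @param x an `expr_matrix` of raw or normalized counts.
#' @param pseudocount positive offset added before taking log2. Count data
#'   contain zeros, so the default of 1 keeps the transform defined; it is
#'   negligible at panel-typical expression levels (2^4 and up).
#' @return an `expr_matrix` with `scale_tag = "log2"`.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (!scale_tag(x) %in% c("raw_counts", "normalized"))
    stop("log2_transform expects raw or normalized counts, got scale_tag '",
         scale_tag(x), "'")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (any(unclass(x) < 0))
    stop("negative expression values cannot be log-transformed")
  expr_matrix(log2(unclass(x) + pseudocount), scale_tag = "log2")
}

#' Per-gene one-way ANOVA between diseased and naive groups
#'
#' Classical equal-variance one-way ANOVA on log2 expression, vectorized over
#' genes. With exactly two groups the F statistic equals the square of the
#' pooled-variance two-sample t statistic and p comes from F(1, n - 2).
#'
#' Genes with zero pooled within-group variance get p = 1 when the group
#' means are equal (no evidence of change) and p at the smallest positive
#' double when they differ (infinitely strong evidence; a warning is raised
#' so degenerate genes are visible in batch runs).
#'
#' @param x an `expr_matrix` with `scale_tag = "log2"`.
#' @param annotation a `sample_annotation` with >= 2 samples in each group.
#' @return data.frame: gene, mean_log2_naive, mean_log2_diseased, F, p_raw.
#' @export
anova_per_gene <- function(x, annotation) {
  if (!identical(scale_tag(x), "log2"))
    stop("anova_per_gene expects log2 expression (scale_tag 'log2')")
  ann <- annotation[annotation$sample_id %in% colnames(x), , drop = FALSE]
  idx_n <- ann$sample_id[ann$group == "naive"]
  idx_d <- ann$sample_id[ann$group == "diseased"]
  n1 <- length(idx_n); n2 <- length(idx_d)
  if (n1 < 2L || n2 < 2L)
    stop(sprintf("each group needs >= 2 samples (got %d naive, %d diseased)",
                 n1, n2))
  m <- unclass(x)
  xn <- m[, idx_n, drop = FALSE]
  xd <- m[, idx_d, drop = FALSE]
  mean_n <- rowMeans(xn)
  mean_d <- rowMeans(xd)
  ss_n <- rowSums((xn - mean_n)^2)
  ss_d <- rowSums((xd - mean_d)^2)
  df2 <- n1 + n2 - 2L
  pooled_var <- (ss_n + ss_d) / df2
  # between-group SS for 2 groups collapses to the harmonic-weighted mean gap
  ss_between <- (mean_d - mean_n)^2 / (1 / n1 + 1 / n2)
  F <- ss_between / pooled_var
  p <- stats::pf(F, 1, df2, lower.tail = FALSE)
  degen <- pooled_var == 0
  if (any(degen)) {
    eq <- degen & (mean_n == mean_d)
    F[eq] <- 0; p[eq] <- 1
    ne <- degen & (mean_n != mean_d)
    if (any(ne)) {
      warning(sum(ne), " gene(s) with zero within-group variance and unequal ",
              "means; p set to the smallest positive double")
      F[ne] <- Inf
      p[ne] <- .Machine$double.xmin
    }
  }
  data.frame(gene = rownames(m), mean_log2_naive = unname(mean_n),
             mean_log2_diseased = unname(mean_d), F = unname(F),
             p_raw = unname(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_raw numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_raw) {
  if (anyNA(p_raw) || any(p_raw < 0) || any(p_raw > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p_raw, method = "BH")
}

#' Fold change from group means on the log2 scale
#'
#' `log2fc = diseased - naive`. The signed fold change reports the linear
#' ratio when >= 1 and minus its reciprocal for down-regulation, so a
#' quartering of expression reads -4 rather than 0.25.
#'
#' @param mean_log2_naive,mean_log2_diseased finite group means (log2 units).
#' @return data.frame with columns log2fc and fold_change_signed.
#' @export
fold_change <- function(mean_log2_naive, mean_log2_diseased) {
  if (any(!is.finite(mean_log2_naive)) || any(!is.finite(mean_log2_diseased)))
    stop("group means must be finite")
  log2fc <- mean_log2_diseased - mean_log2_naive
  ratio <- 2^log2fc
  data.frame(log2fc = log2fc,
             fold_change_signed = ifelse(ratio >= 1, ratio, -1 / ratio))
}

new_de_table <- function(df, model_label, q_threshold, fc_threshold) {
  rownames(df) <- NULL
  structure(df, model_label = model_label, q_threshold = q_threshold,
            fc_threshold = fc_threshold, class = c("de_table", "data.frame"))
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table '%s': %d genes, %d DEGs (q < %g, fold change >= %g)\n",
              attr(x, "model_label"), nrow(x), sum(x$is_deg),
              attr(x, "q_threshold"), attr(x, "fc_threshold")))
  NextMethod()
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when its BH-adjusted p-value is strictly below
#' `q_threshold` and its fold change is at least `fc_threshold` in either
#' direction (`|log2fc| >= log2(fc_threshold)`, inclusive).
#'
#' @param table a `de_table` with `p_adj` populated.
#' @param q_threshold adjusted-p cutoff (strict `<`), default 0.1.
#' @param fc_threshold linear fold-change cutoff (inclusive `>=`), default 1.5.
#' @return the table with `is_deg` set and thresholds recorded; the DEG count
#'   and percent-of-panel are attached as attributes `deg_count` and
#'   `deg_percent`.
#' @export
call_degs <- function(table, q_threshold = 0.1, fc_threshold = 1.5) {
  if (is.null(table$p_adj) || anyNA(table$p_adj))
    stop("p_adj must be populated before calling DEGs")
  table$is_deg <- (table$p_adj < q_threshold) &
    (abs(table$log2fc) >= log2(fc_threshold))
  out <- new_de_table(as.data.frame(table),
                      model_label = attr(table, "model_label"),
                      q_threshold = q_threshold, fc_threshold = fc_threshold)
  attr(out, "deg_count") <- sum(out$is_deg)
  attr(out, "deg_percent") <- 100 * sum(out$is_deg) / nrow(out)
  out
}

#' Full per-gene differential-expression analysis for one model
#'
#' Runs log2 transform (if needed), per-gene one-way ANOVA between diseased
#' and naive groups, BH adjustment across the panel, fold-change computation,
#' and DEG calling.
#'
#' @param x an `expr_matrix` (counts, normalized, or already log2).
#' @param annotation a `sample_annotation` for the samples of one model.
#' @param model_label label recorded on the result (default: from annotation).
#' @param pseudocount log2-transform offset (ignored for log2 input).
#' @param q_threshold,fc_threshold DEG thresholds (see [call_degs()]).
#' @return a `de_table`: one row per gene with group means, log2fc, signed
#'   fold change, raw and BH-adjusted p, and the DEG flag.
#' @export
de_analysis <- function(x, annotation, model_label = NULL, pseudocount = 1,
                        q_threshold = 0.1, fc_threshold = 1.5) {
  if (is.null(model_label)) model_label <- annotation$model_label[1L]
  if (!identical(scale_tag(x), "log2"))
    x <- log2_transform(x, pseudocount = pseudocount)
  res <- anova_per_gene(x, annotation)
  fc <- fold_change(res$mean_log2_naive, res$mean_log2_diseased)
  df <- data.frame(gene = res$gene,
                   mean_log2_naive = res$mean_log2_naive,
                   mean_log2_diseased = res$mean_log2_diseased,
                   log2fc = fc$log2fc,
                   fold_change_signed = fc$fold_change_signed,
                   p_raw = res$p_raw,
                   p_adj = bh_adjust(res$p_raw),
                   is_deg = NA,
                   stringsAsFactors = FALSE)
  tab <- new_de_table(df, model_label = model_label,
                      q_threshold = q_threshold, fc_threshold = fc_threshold)
  call_degs(tab, q_threshold = q_threshold, fc_threshold = fc_threshold)
}

#' Compare DEG sets across models (Venn region counts)
#'
#' Enumerates all 2^k - 1 non-empty Venn regions over the models' DEG sets.
#' Region membership is exclusive: a gene counts in exactly one region, so
#' region counts sum to the size of the union.
#'
#' @param tables list of >= 2 `de_table` objects (or named list of character
#'   vectors of DEG symbols).
#' @return object of class `deg_comparison`: data.frame with one row per
#'   region; columns `region` (model names joined by `&`), `n_models`, and
#'   `count`; per-model DEG sets attached as attribute `deg_sets`.
#' @export
compare_deg_sets <- function(tables) {
  if (length(tables) < 2L)
    stop("need at least 2 DE tables to compare")
  sets <- lapply(tables, function(t) {
    if (inherits(t, "de_table")) t$gene[t$is_deg] else as.character(t)
  })
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(seq_along(tables), function(i) {
      lbl <- attr(tables[[i]], "model_label")
      if (is.null(lbl)) paste0("model", i) else lbl
    }, "")
  universes <- lapply(tables, function(t) {
    if (inherits(t, "de_table")) t$gene else NULL
  })
  universes <- Filter(Negate(is.null), universes)
  if (length(universes) > 1L &&
      !all(vapply(universes[-1L], function(u)
        setequal(u, universes[[1L]]), TRUE)))
    warning("DE tables have asymmetric gene universes; comparing DEG symbols as-is")
  k <- length(sets)
  union_genes <- unique(unlist(sets))
  membership <- vapply(sets, function(s) union_genes %in% s, logical(length(union_genes)))
  if (length(union_genes) == 1L) membership <- matrix(membership, nrow = 1L)
  # every non-empty sign pattern is one exclusive Venn region
  patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))[-(2^k), , drop = FALSE]
  colnames(patterns) <- names(sets)
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(membership, 1L, function(row) all(row == p)))
  })
  region <- apply(patterns, 1L, function(p) paste(names(sets)[p], collapse = " & "))
  res <- data.frame(region = region, n_models = rowSums(patterns),
                    count = counts, stringsAsFactors = FALSE)
  res <- res[order(-res$n_models, res$region), ]
  rownames(res) <- NULL
  structure(res, deg_sets = sets, class = c("deg_comparison", "data.frame"))
}

#' @export
print.deg_comparison <- function(x, ...) {
  cat(sprintf("deg_comparison over %d models; union of DEGs: %d\n",
              length(attr(x, "deg_sets")), sum(x$count)))
  NextMethod()
}
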
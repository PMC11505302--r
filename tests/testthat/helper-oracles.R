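# Independent oracles, deliberately written from textbook definitions and
# kept free of any code path they are used to check.

# Classical one-way ANOVA from raw sums of squares (two groups).
oracle_anova <- function(x_naive, x_diseased) {
  x <- c(x_naive, x_diseased)
  g <- rep(c(1, 2), c(length(x_naive), length(x_diseased)))
  grand <- mean(x)
  ss_between <- sum(tapply(x, g, length) * (tapply(x, g, mean) - grand)^2)
  ss_within <- sum((x - tapply(x, g, mean)[g])^2)
  df1 <- 1
  df2 <- length(x) - 2
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Pooled-variance two-sample t statistic.
oracle_pooled_t <- function(x_naive, x_diseased) {
  n1 <- length(x_naive); n2 <- length(x_diseased)
  sp2 <- ((n1 - 1) * stats::var(x_naive) + (n2 - 1) * stats::var(x_diseased)) /
    (n1 + n2 - 2)
  (mean(x_diseased) - mean(x_naive)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Benjamini-Hochberg step-up straight from the min-over-tail definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(j) m * p[ord[j]] / j, 0)
    q[ord[i]] <- min(1, min(tail_vals))
  }
  q
}

# Exhaustive Venn region counts by per-gene membership enumeration.
oracle_venn <- function(sets) {
  union_genes <- unique(unlist(sets))
  pat <- vapply(union_genes, function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, TRUE)), collapse = ""),
    "")
  table(factor(pat))
}

# Direct arithmetic for the normalized signed-rank product.
oracle_score <- function(r_mouse, r_human) {
  num <- 0; den <- 0
  for (i in seq_along(r_mouse)) {
    num <- num + r_mouse[i] * r_human[i]
    den <- den + abs(r_mouse[i]) * abs(r_human[i])
  }
  num / den
}

# DE table built directly from flags, bypassing the analysis path.
make_de_table_from_flags <- function(genes, deg, log2fc = NULL, label = "toy") {
  if (is.null(log2fc)) log2fc <- ifelse(deg, 2, 0.1)
  df <- data.frame(gene = genes, mean_log2_naive = 0,
                   mean_log2_diseased = log2fc, log2fc = log2fc,
                   fold_change_signed = ifelse(2^log2fc >= 1, 2^log2fc, -2^-log2fc),
                   p_raw = ifelse(deg, 1e-4, 0.9),
                   p_adj = ifelse(deg, 1e-3, 0.95), is_deg = deg)
  crossdeg:::new_de_table(df, label, 0.1, 1.5)
}

# Tiny expression fixture: genes x samples with distinct values.
make_tiny_matrix <- function(genes = c("Stat1", "Mx1", "Oas1a"),
                             samples = c("s1", "s2"),
                             scale_tag = "raw_counts") {
  m <- matrix(seq_len(length(genes) * length(samples)) * 10,
              nrow = length(genes), dimnames = list(genes, samples))
  expr_matrix(m, scale_tag = scale_tag)
}
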
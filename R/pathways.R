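#' Pathway-level DEG summary
#'
#' For each pathway, counts how many of its genes measured on the panel are
#' flagged DEG. The denominator is the intersection of the pathway with the
#' measured panel, not the full curated pathway — the convention behind
#' "x% (k/n)" reporting on targeted panels.
#'
#' @param table a `de_table` with `is_deg` populated.
#' @param sets a `gene_set_collection`.
#' @return data.frame of class `pathway_summary`: model, pathway,
#'   n_pathway_genes_measured, n_degs, percent (exact, 0-100; NA when no
#'   pathway gene is on the panel), percent_display (whole-percent string
#'   with the "(k/n)" fraction).
#' @export
pathway_deg_summary <- function(table, sets) {
  if (is.null(table$is_deg) || anyNA(table$is_deg))
    stop("DE table must have is_deg populated")
  panel <- table$gene
  deg <- table$gene[table$is_deg]
  rows <- lapply(names(sets), function(pw) {
    measured <- intersect(sets[[pw]], panel)
    n <- length(measured)
    k <- length(intersect(measured, deg))
    if (n == 0L)
      warning("pathway '", pw, "' has no genes on the measured panel")
    pct <- if (n > 0L) 100 * k / n else NA_real_
    data.frame(model = attr(table, "model_label"), pathway = pw,
               n_pathway_genes_measured = n, n_degs = k, percent = pct,
               percent_display = if (n > 0L)
                 sprintf("%d%% (%d/%d)", as.integer(round_half_up(pct, 0)), k, n)
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pathway_summary", "data.frame")
  out
}

#' Signed fold-change matrix for one pathway across models
#'
#' @param tables list of >= 1 `de_table` objects.
#' @param sets a `gene_set_collection`.
#' @param pathway_name pathway to extract.
#' @return numeric matrix, pathway genes (union over the panels that measure
#'   them) x models, of signed fold changes; NA where a gene is absent from
#'   a model's panel.
#' @export
pathway_fc_matrix <- function(tables, sets, pathway_name) {
  if (!pathway_name %in% names(sets))
    stop("unknown pathway '", pathway_name, "'; available: ",
         paste(names(sets), collapse = ", "))
  if (inherits(tables, "de_table")) tables <- list(tables)
  genes <- sets[[pathway_name]]
  measured <- genes[vapply(genes, function(g)
    any(vapply(tables, function(t) g %in% t$gene, TRUE)), TRUE)]
  labels <- vapply(seq_along(tables), function(i) {
    lbl <- attr(tables[[i]], "model_label")
    if (is.null(lbl)) paste0("model", i) else lbl
  }, "")
  m <- matrix(NA_real_, nrow = length(measured), ncol = length(tables),
              dimnames = list(measured, labels))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    hit <- intersect(measured, t$gene)
    m[hit, i] <- t$fold_change_signed[match(hit, t$gene)]
  }
  m
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
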
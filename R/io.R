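#' Construct an expression matrix
#'
#' An `expr_matrix` is a numeric gene-by-sample matrix with unique gene
#' symbols as row names, unique sample identifiers as column names, and a
#' `scale_tag` attribute recording whether the values are raw counts,
#' normalized counts, or log2-transformed expression.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene symbols (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @param scale_tag one of `"raw_counts"`, `"normalized"`, `"log2"`. Values
#'   must be finite, and non-negative unless `scale_tag = "log2"`.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values),
                        scale_tag = c("raw_counts", "normalized", "log2")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (row/column names)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("dimensions of values do not match gene_ids x sample_ids")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene symbols: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale_tag != "log2" && any(values < 0))
    stop("negative values are not allowed for scale_tag '", scale_tag, "'")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, scale_tag = scale_tag, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), scale_tag(x)))
  invisible(x)
}

#' Scale tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return character scalar.
#' @export
scale_tag <- function(x) attr(x, "scale_tag")

#' Read a gene-by-sample expression matrix from a delimited text file
#'
#' The first column holds gene symbols, the header row holds sample
#' identifiers, and the body is numeric. Duplicate gene symbols are rejected;
#' a non-numeric body cell is a parse error naming its row and column.
#'
#' @param path file path.
#' @param delimiter field delimiter, `"\t"` (default) or `","`.
#' @param scale_tag scale of the stored values (see [expr_matrix()]).
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   scale_tag = c("raw_counts", "normalized", "log2")) {
  scale_tag <- match.arg(scale_tag)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", na.strings = character())
  if (ncol(raw) < 2L)
    stop("expression matrix file needs a gene column plus >=1 sample column: ", path)
  genes <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell '%s' at gene '%s' (row %d), sample '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 bad[1L, 1L], colnames(body)[bad[1L, 2L]]))
  }
  if (anyNA(num))
    stop("missing values in expression matrix: ", path)
  expr_matrix(num, gene_ids = genes, sample_ids = colnames(body),
              scale_tag = scale_tag)
}

#' Write an expression matrix to TSV
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' Expects TSV columns `sample_id`, `group` (`naive` or `diseased`) and
#' `model_label`. If `matrix` is supplied, every annotated sample must be a
#' column of it.
#'
#' @param path file path.
#' @param matrix optional companion `expr_matrix` for cross-checking.
#' @return data.frame with columns sample_id, group, model_label.
#' @export
read_sample_annotation <- function(path, matrix = NULL) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  sample_annotation(ann$sample_id, ann$group, ann$model_label, matrix = matrix)
}

#' Construct a sample annotation
#' @param sample_id sample identifiers.
#' @param group group labels, `"naive"` or `"diseased"`.
#' @param model_label animal-model label (recycled if scalar).
#' @param matrix optional companion `expr_matrix`; annotated samples must be
#'   among its columns.
#' @return data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, group, model_label = "model", matrix = NULL) {
  if (is.null(sample_id) || is.null(group))
    stop("sample_id and group are required")
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in annotation")
  if (!all(group %in% c("naive", "diseased")))
    stop("group must be 'naive' or 'diseased'; got: ",
         paste(setdiff(unique(group), c("naive", "diseased")), collapse = ", "))
  if (!is.null(matrix)) {
    missing <- setdiff(sample_id, colnames(matrix))
    if (length(missing) > 0L)
      stop("annotated samples absent from expression matrix: ",
           paste(missing, collapse = ", "))
  }
  ann <- data.frame(sample_id = sample_id, group = group,
                    model_label = rep_len(as.character(model_label), length(sample_id)),
                    stringsAsFactors = FALSE)
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`. The
#' description column is discarded. Pathway names must be unique and every
#' set non-empty.
#'
#' @param path file path.
#' @return named list of character vectors of class `gene_set_collection`,
#'   with a `source` attribute.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list(), source = path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short) > 0L)
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1L]))
  names_ <- vapply(parts, `[[`, "", 1L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- names_
  gene_set_collection(sets, source = path)
}

#' Construct a gene-set collection
#' @param sets named list, pathway name -> character vector of gene symbols.
#' @param source free-text provenance tag.
#' @return `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (length(sets) > 0L) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set needs a name")
    if (anyDuplicated(names(sets)))
      stop("duplicate pathway name: ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    if (any(vapply(sets, length, 1L) == 0L))
      stop("empty gene set: ",
           paste(names(sets)[vapply(sets, length, 1L) == 0L], collapse = ", "))
    sets <- lapply(sets, as.character)
  }
  structure(sets, source = source, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (source: %s)\n",
              length(x), attr(x, "source")))
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a differential-expression profile
#'
#' A `de_profile` is a labelled map from gene symbol to log2 fold change
#' (one species/contrast), the unit compared across species.
#'
#' @param changes named numeric vector of finite log2 fold changes; names are
#'   unique gene symbols.
#' @param label free-text label (species, contrast, cell type).
#' @param pvals optional named numeric vector of raw p-values.
#' @return `de_profile` object.
#' @export
de_profile <- function(changes, label = "profile", pvals = NULL) {
  if (is.null(names(changes)) || any(!nzchar(names(changes))))
    stop("changes must be a named vector of log2 fold changes")
  if (anyDuplicated(names(changes)))
    stop("duplicate gene symbols in profile '", label, "'")
  if (any(!is.finite(changes)))
    stop("log2 fold changes must be finite")
  structure(list(label = label, changes = changes, pvals = pvals),
            class = "de_profile")
}

#' @export
print.de_profile <- function(x, ...) {
  cat(sprintf("de_profile '%s': %d genes\n", x$label, length(x$changes)))
  invisible(x)
}

#' Read a DE profile from TSV
#'
#' Expects columns `gene` and `log2fc`, with an optional `pval` column.
#'
#' @param path file path.
#' @param label profile label; defaults to the file name.
#' @return a `de_profile`.
#' @export
read_de_profile <- function(path, label = NULL) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc") %in% names(df)))
    stop("DE profile needs columns 'gene' and 'log2fc': ", path)
  changes <- stats::setNames(as.numeric(df$log2fc), df$gene)
  pv <- if ("pval" %in% names(df)) stats::setNames(as.numeric(df$pval), df$gene)
  de_profile(changes, label = label, pvals = pv)
}

#' Write a DE profile to TSV
#' @param profile a `de_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_profile <- function(profile, path) {
  df <- data.frame(gene = names(profile$changes), log2fc = unname(profile$changes))
  if (!is.null(profile$pvals)) df$pval <- unname(profile$pvals[df$gene])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Geometric-mean scaling normalization
#'
#' Scales every sample (column) so that the geometric mean of the reference
#' genes equals the across-sample mean of those per-sample geometric means.
#' A transparent stand-in for platform-specific count normalization; the
#' downstream statistics only require normalized counts.
#'
#' @param x an `expr_matrix` with `scale_tag = "raw_counts"`.
#' @param reference_genes optional character vector of genes to anchor the
#'   scaling (default: all genes). Must all be present in `x` and have
#'   strictly positive counts in every sample.
#' @return an `expr_matrix` with `scale_tag = "normalized"`.
#' @export
normalize_geomean <- function(x, reference_genes = NULL) {
  if (!scale_tag(x) %in% "raw_counts")
    stop("normalize_geomean expects raw counts (scale_tag 'raw_counts'), got '",
         scale_tag(x), "'")
  ref <- if (is.null(reference_genes)) rownames(x) else as.character(reference_genes)
  missing <- setdiff(ref, rownames(x))
  if (length(missing) > 0L)
    stop("reference genes absent from matrix: ", paste(missing, collapse = ", "))
  sub <- unclass(x)[ref, , drop = FALSE]
  if (any(sub == 0))
    stop("reference gene with a zero count; add a pseudocount before normalizing")
  gm <- exp(colMeans(log(sub)))         # per-sample geometric mean
  factors <- mean(gm) / gm
  out <- sweep(unclass(x), 2L, factors, `*`)
  expr_matrix(out, scale_tag = "normalized")
}

#' Write a differential-expression table to TSV
#'
#' Columns: gene, mean_log2_naive, mean_log2_diseased, log2fc,
#' fold_change_signed, p_raw, p_adj, is_deg. Numeric fields round-trip at
#' full double precision.
#'
#' @param table a `de_table` (see [de_analysis()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path) {
  stopifnot(inherits(table, "de_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "is_deg"
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table written by [write_de_table()]
#' @param path file path.
#' @param model_label model label; defaults to one stored in the companion
#'   column if present, else the file name.
#' @param q_threshold,fc_threshold thresholds recorded on the returned table.
#' @return a `de_table`.
#' @export
read_de_table <- function(path, model_label = NULL, q_threshold = 0.1,
                          fc_threshold = 1.5) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "mean_log2_naive", "mean_log2_diseased", "log2fc",
            "fold_change_signed", "p_raw", "p_adj", "is_deg")
  if (!all(need %in% names(df)))
    stop("DE table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(model_label))
    model_label <- if ("model_label" %in% names(df)) df$model_label[1L]
                   else tools::file_path_sans_ext(basename(path))
  df$is_deg <- as.logical(df$is_deg)
  new_de_table(df[need], model_label = model_label,
               q_threshold = q_threshold, fc_threshold = fc_threshold)
}
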
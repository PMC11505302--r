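#' Pair a mouse and a human DE profile on a shared gene universe
#'
#' The default ortholog rule maps symbols by case-insensitive equality
#' (mouse "Stat1" pairs with human "STAT1"), which covers the large majority
#' of one-to-one mouse/human orthologs on immunology panels. A user table
#' overrides the rule gene-by-gene. Genes without a counterpart are dropped
#' and their count reported in a message.
#'
#' @param mouse_profile,human_profile `de_profile` objects.
#' @param table optional data.frame with columns `mouse` and `human` mapping
#'   mouse symbols to human symbols. Each mouse symbol must map to at most
#'   one human symbol; many-to-one maps onto a human symbol are an error
#'   unless `collapse = "mean"`, which averages the mouse changes.
#' @param collapse `"error"` (default) or `"mean"` for many-to-one maps.
#' @return list with elements `mouse` and `human`: `de_profile`s re-indexed
#'   on the identical shared human-symbol universe; plus `n_dropped_mouse`
#'   and `n_dropped_human`.
#' @export
map_orthologs <- function(mouse_profile, human_profile, table = NULL,
                          collapse = c("error", "mean")) {
  collapse <- match.arg(collapse)
  if (length(mouse_profile$changes) == 0L || length(human_profile$changes) == 0L)
    stop("profiles must be non-empty")
  mouse_sym <- names(mouse_profile$changes)
  human_sym <- names(human_profile$changes)
  # start from the case rule, then let the user table override
  mapped <- toupper(mouse_sym)
  names(mapped) <- mouse_sym
  if (!is.null(table)) {
    if (!all(c("mouse", "human") %in% names(table)))
      stop("ortholog table needs columns 'mouse' and 'human'")
    if (anyDuplicated(table$mouse))
      stop("ortholog table maps a mouse symbol to more than one human symbol")
    hit <- mouse_sym %in% table$mouse
    mapped[hit] <- table$human[match(mouse_sym[hit], table$mouse)]
  }
  mouse_changes <- mouse_profile$changes
  names(mouse_changes) <- unname(mapped)
  if (anyDuplicated(names(mouse_changes))) {
    if (collapse == "error")
      stop("two mouse genes map to one human symbol: ",
           paste(unique(names(mouse_changes)[duplicated(names(mouse_changes))]),
                 collapse = ", "),
           "; use collapse = 'mean' to average them")
    mouse_changes <- tapply(mouse_changes, names(mouse_changes), mean)
    mouse_changes <- stats::setNames(as.numeric(mouse_changes), names(mouse_changes))
  }
  common <- intersect(names(mouse_changes), human_sym)
  if (length(common) == 0L)
    stop("no common genes between '", mouse_profile$label, "' and '",
         human_profile$label, "' after ortholog mapping")
  n_drop_m <- length(mouse_changes) - length(common)
  n_drop_h <- length(human_sym) - length(common)
  if (n_drop_m + n_drop_h > 0L)
    message(sprintf("ortholog mapping dropped %d mouse and %d human genes without counterparts",
                    n_drop_m, n_drop_h))
  list(mouse = de_profile(mouse_changes[common], label = mouse_profile$label),
       human = de_profile(human_profile$changes[common], label = human_profile$label),
       n_dropped_mouse = n_drop_m, n_dropped_human = n_drop_h)
}

#' Signed ranks of gene changes
#'
#' Ranks genes by |log2 fold change| ascending over the whole universe
#' (average ranks for ties) and attaches the sign of the change. A zero
#' change carries sign +. Ranking over the global universe, then subsetting
#' to a pathway, keeps a pathway's score sensitive to how large its changes
#' are relative to the rest of the transcriptional response.
#'
#' @param profile a `de_profile`.
#' @param universe character vector of genes to rank over (must all be in
#'   the profile); default: all profile genes.
#' @return object of class `signed_rank_profile`: list with `label`,
#'   `universe`, and `ranks` (named numeric; sign(change) * rank(|change|)).
#' @export
signed_ranks <- function(profile, universe = names(profile$changes)) {
  if (length(universe) == 0L)
    stop("empty gene universe")
  missing <- setdiff(universe, names(profile$changes))
  if (length(missing) > 0L)
    stop("universe genes absent from profile '", profile$label, "': ",
         paste(utils::head(missing, 5L), collapse = ", "))
  delta <- profile$changes[universe]
  r <- rank(abs(delta), ties.method = "average")
  sgn <- ifelse(delta < 0, -1, 1)   # zero change counts as +
  structure(list(label = profile$label, universe = universe,
                 ranks = stats::setNames(sgn * r, universe)),
            class = "signed_rank_profile")
}

#' @export
print.signed_rank_profile <- function(x, ...) {
  cat(sprintf("signed_rank_profile '%s': %d genes\n", x$label,
              length(x$ranks)))
  invisible(x)
}

#' Cross-species association score for a pathway
#'
#' The normalized signed-rank product: over the pathway genes G common to
#' both profiles,
#' \deqn{S = \frac{\sum_{g \in G} r_m(g)\, r_h(g)}{\sum_{g \in G} |r_m(g)|\,|r_h(g)|}}
#' where \eqn{r(g)} is the signed rank of gene g's change. S is bounded in
#' \[-1, 1\]: +1 when every gene pair changes in the same direction (the
#' animal model perfectly mimics the human profile), -1 when every pair is
#' opposite (perfect reversal), and values near 0 indicate no connectivity.
#'
#' @param mouse,human `signed_rank_profile` objects over the same universe.
#' @param pathway_genes character vector of gene symbols.
#' @return list with `score` (S) and `n_used` (|G|).
#' @export
association_score <- function(mouse, human, pathway_genes) {
  if (!setequal(mouse$universe, human$universe))
    stop("profiles must share a gene universe; run map_orthologs() first")
  G <- intersect(pathway_genes, mouse$universe)
  if (length(G) == 0L) {
    stop(if (length(pathway_genes) == 0L) "empty pathway"
         else "pathway has no genes in the common universe (not measured in both species)")
  }
  rm_ <- mouse$ranks[G]
  rh_ <- human$ranks[G]
  list(score = sum(rm_ * rh_) / sum(abs(rm_) * abs(rh_)), n_used = length(G))
}

#' Proportional directional concordance for a pathway
#'
#' The fraction of pathway genes whose direction of change agrees between
#' the two species, reported as "P (k/n)". Genes with an exactly zero change
#' in either profile carry no direction and are excluded from the
#' denominator (with a message).
#'
#' @param mouse,human `de_profile` objects on a shared universe.
#' @param pathway_genes character vector of gene symbols.
#' @return list: `k_concordant`, `n_used`, `proportional` (k/n), and
#'   `display` — the proportion rounded half-up to 2 decimals ("1.0" at
#'   unity) with the fraction, e.g. "0.77 (27/35)".
#' @export
proportional_association <- function(mouse, human, pathway_genes) {
  common <- intersect(names(mouse$changes), names(human$changes))
  G <- intersect(pathway_genes, common)
  if (length(G) == 0L)
    stop("pathway has no genes in the common universe")
  dm <- mouse$changes[G]
  dh <- human$changes[G]
  zero <- dm == 0 | dh == 0
  if (any(zero))
    message(sum(zero), " gene(s) with zero change excluded from the concordance denominator")
  dm <- dm[!zero]; dh <- dh[!zero]
  n <- length(dm)
  if (n == 0L)
    stop("no genes with a nonzero change in both species")
  k <- sum(sign(dm) == sign(dh))
  p <- k / n
  list(k_concordant = k, n_used = n, proportional = p,
       display = format_proportion(p, k, n))
}

format_proportion <- function(p, k, n) {
  num <- if (isTRUE(all.equal(p, 1)) || p == 1) "1.0"
         else sprintf("%.2f", round_half_up(p, 2))
  sprintf("%s (%d/%d)", num, k, n)
}

#' Cross-species association table over models, human contrasts and pathways
#'
#' For every (animal model, human contrast, pathway) combination, maps the
#' model's gene changes onto the human profile's symbol space, computes
#' signed ranks over the full common universe, and reports the normalized
#' rank-product association score together with the proportional
#' directional concordance. Pathways with no genes in a pair's common
#' universe are omitted (with a message).
#'
#' @param mouse_tables list of >= 1 `de_table` (or `de_profile`) objects,
#'   one per animal model.
#' @param human_profiles list of >= 1 `de_profile` objects (bulk tissue or
#'   per-cell-type contrasts).
#' @param sets a `gene_set_collection`.
#' @param ortholog_table optional mapping table (see [map_orthologs()]).
#' @param require_degs drop models whose `de_table` has zero DEGs (mirrors
#'   excluding models with no significant response from association
#'   analysis). Default FALSE.
#' @param rank_scope `"global"` (rank over the full common universe, then
#'   subset; default) or `"pathway"` (re-rank within each pathway; for
#'   sensitivity analysis).
#' @return data.frame of class `association_table`: model, human_contrast,
#'   pathway, n_common, n_used, score, k_concordant, proportional,
#'   proportional_display.
#' @export
association_table <- function(mouse_tables, human_profiles, sets,
                              ortholog_table = NULL, require_degs = FALSE,
                              rank_scope = c("global", "pathway")) {
  rank_scope <- match.arg(rank_scope)
  if (inherits(mouse_tables, c("de_table", "de_profile")))
    mouse_tables <- list(mouse_tables)
  if (inherits(human_profiles, "de_profile"))
    human_profiles <- list(human_profiles)
  mouse_profiles <- lapply(mouse_tables, function(t) {
    if (inherits(t, "de_profile")) return(t)
    if (require_degs && sum(t$is_deg) == 0L) return(NULL)
    de_profile(stats::setNames(t$log2fc, t$gene),
               label = attr(t, "model_label"))
  })
  dropped <- vapply(mouse_profiles, is.null, TRUE)
  if (any(dropped))
    message("dropping ", sum(dropped), " model(s) with zero DEGs from association analysis")
  mouse_profiles <- mouse_profiles[!dropped]
  if (length(mouse_profiles) == 0L)
    stop("no models left to associate")
  rows <- list()
  for (mp in mouse_profiles) {
    for (hp in human_profiles) {
      paired <- map_orthologs(mp, hp, table = ortholog_table)
      universe <- names(paired$mouse$changes)
      if (rank_scope == "global") {
        srm <- signed_ranks(paired$mouse)
        srh <- signed_ranks(paired$human)
      }
      for (pw in names(sets)) {
        G <- intersect(sets[[pw]], universe)
        if (length(G) == 0L) {
          message("pathway '", pw, "' has no common genes for ",
                  mp$label, " vs ", hp$label, "; omitted")
          next
        }
        if (rank_scope == "pathway") {
          srm <- signed_ranks(paired$mouse, universe = G)
          srh <- signed_ranks(paired$human, universe = G)
        }
        sc <- association_score(srm, srh, G)
        pa <- proportional_association(paired$mouse, paired$human, G)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mp$label, human_contrast = hp$label, pathway = pw,
          n_common = length(G), n_used = pa$n_used, score = sc$score,
          k_concordant = pa$k_concordant, proportional = pa$proportional,
          proportional_display = pa$display, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}
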
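#' Simulate a targeted-panel count matrix with planted fold changes
#'
#' Emulates a ~770-gene autoimmunity panel measured on two small groups of
#' mice (naive vs diseased). Per-gene baseline log2 means are drawn from
#' Uniform(4, 12); sample-level log2 expression adds Gaussian noise of SD
#' `noise_sd`; diseased samples are shifted by the planted log2 fold change;
#' counts are `round(2^x)` and therefore non-negative integers. The
#' generative model is Gaussian on the log2 scale — the same scale on which
#' the downstream ANOVA operates.
#'
#' All randomness flows through R's Mersenne-Twister stream seeded with
#' `seed`, so a (parameters, seed) pair reproduces the matrix bit-for-bit.
#'
#' @param n_genes panel size (default 770).
#' @param n_naive,n_diseased samples per group (>= 2 each).
#' @param effect_spec planted effects: `NULL` for an all-null panel, a
#'   numeric vector of length `n_genes` of true log2 fold changes, or a list
#'   `list(n_de =, log2fc =, prop_up = 0.5)` planting `n_de` genes (chosen by
#'   a seeded shuffle) at `± log2fc` with a fraction `prop_up` up-regulated.
#' @param noise_sd within-group SD on the log2 scale (> 0).
#' @param seed integer seed.
#' @param model_label label written into the sample annotation.
#' @return list with `matrix` (an `expr_matrix`, scale_tag `"normalized"`),
#'   `annotation` (a `sample_annotation`), and `truth` (data.frame: gene,
#'   true_log2fc, true_deg; parameters attached as attributes).
#' @export
simulate_panel_counts <- function(n_genes = 770, n_naive = 5, n_diseased = 7,
                                  effect_spec = NULL, noise_sd = 0.5,
                                  seed = 1, model_label = "simulated") {
  if (n_naive < 2L || n_diseased < 2L)
    stop("each group needs >= 2 samples")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  genes <- sprintf("G%04d", seq_len(n_genes))
  true_fc <- rep(0, n_genes)
  if (is.numeric(effect_spec)) {
    if (length(effect_spec) != n_genes)
      stop("numeric effect_spec must have length n_genes")
    true_fc <- effect_spec
  } else if (is.list(effect_spec)) {
    n_de <- effect_spec$n_de
    if (n_de > n_genes) stop("n_de exceeds n_genes")
    prop_up <- if (is.null(effect_spec$prop_up)) 0.5 else effect_spec$prop_up
    idx <- sample.int(n_genes, n_de)
    n_up <- round(prop_up * n_de)
    true_fc[idx] <- c(rep(effect_spec$log2fc, n_up),
                      rep(-effect_spec$log2fc, n_de - n_up))
  } else if (!is.null(effect_spec)) {
    stop("effect_spec must be NULL, a numeric vector, or a list(n_de, log2fc, prop_up)")
  }
  baseline <- stats::runif(n_genes, 4, 12)
  n_total <- n_naive + n_diseased
  shift <- cbind(matrix(0, n_genes, n_naive),
                 matrix(true_fc, n_genes, n_diseased))
  log2x <- baseline + shift +
    matrix(stats::rnorm(n_genes * n_total, sd = noise_sd), n_genes, n_total)
  counts <- round(2^log2x)
  sample_ids <- c(sprintf("naive_%02d", seq_len(n_naive)),
                  sprintf("diseased_%02d", seq_len(n_diseased)))
  dimnames(counts) <- list(genes, sample_ids)
  mat <- expr_matrix(counts, scale_tag = "normalized")
  ann <- sample_annotation(sample_ids,
                           c(rep("naive", n_naive), rep("diseased", n_diseased)),
                           model_label = model_label)
  truth <- data.frame(gene = genes, true_log2fc = true_fc,
                      true_deg = abs(true_fc) >= log2(1.5),
                      stringsAsFactors = FALSE)
  attr(truth, "seed") <- seed
  attr(truth, "n_naive") <- n_naive
  attr(truth, "n_diseased") <- n_diseased
  attr(truth, "noise_sd") <- noise_sd
  list(matrix = mat, annotation = ann, truth = truth)
}

#' Simulate paired mouse/human DE profiles with planted concordance
#'
#' Builds disjoint pathways of the given sizes and, for each pathway of size
#' n with concordance rho, makes exactly `round(rho * n)` genes
#' sign-concordant between the two species — a deterministic assignment
#' (the first `round(rho * n)` genes of a seeded shuffle), not a Bernoulli
#' draw, so downstream recovery of the planted proportion is exact. Change
#' magnitudes are drawn from `magnitude_dist` independently per species
#' (directional concordance is about signs only), and are strictly positive
#' so every gene carries a direction.
#'
#' @param pathway_sizes integer vector (> 0) of pathway sizes.
#' @param rho_per_pathway planted concordant fractions in \[0, 1\], recycled
#'   to `length(pathway_sizes)`.
#' @param magnitude_dist function(n) returning n positive magnitudes;
#'   default lognormal(meanlog 0, sdlog 1).
#' @param seed integer seed.
#' @return list with `mouse` and `human` (`de_profile`s on the same symbol
#'   universe), `sets` (a `gene_set_collection`), and `truth` (data.frame:
#'   gene, pathway, concordant; per-pathway rho as attribute `rho`).
#' @export
simulate_paired_profiles <- function(pathway_sizes,
                                     rho_per_pathway = 1,
                                     magnitude_dist = function(n)
                                       stats::rlnorm(n, meanlog = 0, sdlog = 1),
                                     seed = 1) {
  if (any(pathway_sizes < 1L))
    stop("pathway sizes must be >= 1")
  rho <- rep_len(rho_per_pathway, length(pathway_sizes))
  if (any(rho < 0 | rho > 1))
    stop("rho must lie in [0, 1]")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n_total <- sum(pathway_sizes)
  genes <- sprintf("GENE%04d", seq_len(n_total))
  pw_names <- sprintf("pathway_%02d", seq_along(pathway_sizes))
  pw_of <- rep(pw_names, pathway_sizes)
  sets <- split(genes, factor(pw_of, levels = pw_names))
  sets <- gene_set_collection(as.list(sets), source = "simulated")
  mouse_sign <- sample(c(-1, 1), n_total, replace = TRUE)
  concordant <- logical(n_total)
  for (i in seq_along(pathway_sizes)) {
    idx <- which(pw_of == pw_names[i])
    k <- round(rho[i] * length(idx))
    concordant[idx[sample.int(length(idx))][seq_len(k)]] <- TRUE
  }
  human_sign <- ifelse(concordant, mouse_sign, -mouse_sign)
  m_mag <- magnitude_dist(n_total)
  h_mag <- magnitude_dist(n_total)
  if (any(m_mag <= 0) || any(h_mag <= 0))
    stop("magnitude_dist must return strictly positive magnitudes")
  mouse <- de_profile(stats::setNames(mouse_sign * m_mag, genes),
                      label = "simulated mouse")
  human <- de_profile(stats::setNames(human_sign * h_mag, genes),
                      label = "simulated human")
  truth <- data.frame(gene = genes, pathway = pw_of, concordant = concordant,
                      stringsAsFactors = FALSE)
  attr(truth, "rho") <- stats::setNames(rho, pw_names)
  attr(truth, "seed") <- seed
  list(mouse = mouse, human = human, sets = sets, truth = truth)
}

#' Simulate replicate all-null panels for FDR calibration
#'
#' Generates `n_replicates` independent panels with no planted effects.
#' Replicate seeds are drawn deterministically from the master seed, so the
#' whole ensemble is reproducible and replicate i equals
#' `simulate_panel_counts()` run with the i-th derived seed and no effects.
#'
#' @param n_genes,n_naive,n_diseased,noise_sd as in [simulate_panel_counts()].
#' @param n_replicates number of replicate panels (>= 1).
#' @param seed master seed.
#' @return list with `replicates` (list of [simulate_panel_counts()] results)
#'   and `seeds` (the derived per-replicate seeds).
#' @export
simulate_null_panel <- function(n_genes = 770, n_naive = 5, n_diseased = 7,
                                noise_sd = 0.5, n_replicates = 1, seed = 1) {
  if (n_replicates < 1L)
    stop("n_replicates must be >= 1")
  seeds <- derive_seeds(seed, n_replicates)
  reps <- lapply(seeds, function(s)
    simulate_panel_counts(n_genes = n_genes, n_naive = n_naive,
                          n_diseased = n_diseased, effect_spec = NULL,
                          noise_sd = noise_sd, seed = s,
                          model_label = "null"))
  list(replicates = reps, seeds = seeds)
}

#' Derive replicate seeds from a master seed
#' @param seed master integer seed.
#' @param n number of seeds.
#' @return integer vector of n distinct seeds below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed, kind = "Mersenne-Twister")
  sample.int(.Machine$integer.max - 1L, n)
}
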
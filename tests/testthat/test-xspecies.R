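test_that("ortholog pairing maps case-insensitively and honors user overrides", {
  mouse <- de_profile(c(Stat1 = 2, Mx1 = -1, Uniquem = 0.5), label = "mouse")
  human <- de_profile(c(STAT1 = 1.5, MX1 = -0.5, ONLYHUM = 3), label = "human")
  expect_message(paired <- map_orthologs(mouse, human), "dropped 1 mouse and 1 human")
  expect_setequal(names(paired$mouse$changes), c("STAT1", "MX1"))
  expect_identical(names(paired$mouse$changes), names(paired$human$changes))
  expect_equal(paired$mouse$changes[["STAT1"]], 2)
  expect_equal(paired$human$changes[["STAT1"]], 1.5)

  tbl <- data.frame(mouse = "Uniquem", human = "ONLYHUM")
  paired2 <- suppressMessages(map_orthologs(mouse, human, table = tbl))
  expect_true("ONLYHUM" %in% names(paired2$mouse$changes))
  expect_equal(paired2$mouse$changes[["ONLYHUM"]], 0.5)
})

test_that("many-to-one ortholog maps error unless collapsed by mean", {
  mouse <- de_profile(c(Gm1 = 2, Gm2 = 4), label = "mouse")
  human <- de_profile(c(HG = 1), label = "human")
  tbl <- data.frame(mouse = c("Gm1", "Gm2"), human = c("HG", "HG"))
  expect_error(map_orthologs(mouse, human, table = tbl), "collapse")
  paired <- map_orthologs(mouse, human, table = tbl, collapse = "mean")
  expect_equal(paired$mouse$changes[["HG"]], 3)
  bad <- data.frame(mouse = c("Gm1", "Gm1"), human = c("HG", "HG2"))
  expect_error(map_orthologs(mouse, human, table = bad), "more than one")
})

test_that("signed ranks order |change| ascending with average ties and + for zero", {
  p <- de_profile(c(a = 0.5, b = -2, c = 1), label = "x")
  expect_equal(unname(signed_ranks(p)$ranks), c(1, -3, 2))
  p2 <- de_profile(c(a = 1, b = -1, c = 2), label = "x")
  expect_equal(unname(signed_ranks(p2)$ranks), c(1.5, -1.5, 3))
  p3 <- de_profile(c(a = 0, b = -0.5), label = "x")
  expect_equal(unname(signed_ranks(p3)$ranks), c(1, -2))  # zero carries +
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    delta <- round(rnorm(n), 1)   # rounding forces ties
    pr <- de_profile(setNames(delta, paste0("g", 1:n)), label = "x")
    r <- signed_ranks(pr)$ranks
    expect_equal(sort(unname(abs(r))), sort(rank(abs(delta), ties.method = "average")))
    expect_equal(unname(sign(r))[delta != 0], sign(delta)[delta != 0])
  }
  expect_error(signed_ranks(p, universe = character()), "empty")
  expect_error(signed_ranks(p, universe = c("a", "zz")), "absent")
})

test_that("association score hits +1/-1 at perfect mimicry/reversal and matches direct arithmetic", {
  mouse <- de_profile(c(a = 0.1, b = 0.2, c = -0.3, d = 0.4), label = "m")
  human <- de_profile(c(a = 0.2, b = 0.1, c = 0.3, d = -0.4), label = "h")
  sm <- signed_ranks(mouse); sh <- signed_ranks(human)
  expect_equal(unname(sm$ranks), c(1, 2, -3, 4))
  expect_equal(unname(sh$ranks), c(2, 1, 3, -4))
  got <- association_score(sm, sh, c("a", "b", "c", "d"))
  expect_equal(got$score, oracle_score(c(1, 2, -3, 4), c(2, 1, 3, -4)))
  expect_equal(got$score, -21 / 29)
  expect_equal(got$n_used, 4)

  set.seed(17)
  for (rep in 1:25) {
    n <- sample(3:60, 1)
    g <- paste0("g", 1:n)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    m2 <- de_profile(setNames(sgn * rlnorm(n), g), label = "m")
    conc <- de_profile(setNames(sgn * rexp(n) , g), label = "h")
    disc <- de_profile(setNames(-sgn * runif(n), g), label = "h")
    expect_equal(association_score(signed_ranks(m2), signed_ranks(conc), g)$score, 1)
    expect_equal(association_score(signed_ranks(m2), signed_ranks(disc), g)$score, -1)
  }
})

test_that("association score is bounded, antisymmetric, and rank-invariant", {
  set.seed(29)
  for (rep in 1:200) {
    n <- sample(3:50, 1)
    g <- paste0("g", 1:n)
    dm <- rnorm(n); dh <- rnorm(n)
    mouse <- de_profile(setNames(dm, g), label = "m")
    human <- de_profile(setNames(dh, g), label = "h")
    s <- association_score(signed_ranks(mouse), signed_ranks(human), g)$score
    expect_true(s >= -1 && s <= 1)
    # negating every human change negates the score exactly
    s_neg <- association_score(signed_ranks(mouse),
                               signed_ranks(de_profile(setNames(-dh, g), "h")),
                               g)$score
    expect_equal(s_neg, -s, tolerance = 1e-12)
    # a strictly increasing transform of |change| leaves the score unchanged
    warp <- de_profile(setNames(sign(dm) * (abs(dm)^3 + abs(dm)), g), "m")
    s_warp <- association_score(signed_ranks(warp), signed_ranks(human), g)$score
    expect_equal(s_warp, s, tolerance = 1e-12)
  }
})

test_that("random-sign profiles give association scores centered on zero", {
  set.seed(41)
  scores <- replicate(1000, {
    g <- paste0("g", 1:50)
    m <- de_profile(setNames(sample(c(-1, 1), 50, TRUE) * rlnorm(50), g), "m")
    h <- de_profile(setNames(sample(c(-1, 1), 50, TRUE) * rlnorm(50), g), "h")
    association_score(signed_ranks(m), signed_ranks(h), g)$score
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se)
})

test_that("proportional concordance counts sign agreements and excludes zero changes", {
  g <- paste0("g", 1:5)
  mouse <- de_profile(setNames(c(1, -1, 2, 0, 3), g), "m")
  human <- de_profile(setNames(c(2, 1, -4, 1, 5), g), "h")
  expect_message(pa <- proportional_association(mouse, human, g), "zero change")
  expect_equal(pa$n_used, 4)      # the zero-change gene drops out
  expect_equal(pa$k_concordant, 2)
  expect_equal(pa$proportional, 0.5)
  expect_identical(pa$display, "0.50 (2/4)")
  disc <- de_profile(setNames(-c(1, -1, 2, 1, 3), g), "h")
  expect_equal(proportional_association(mouse, disc, g[-4])$proportional, 0)
  expect_error(proportional_association(mouse, human, "zz"), "no genes")
  # antisymmetry: negating human changes maps P to 1 - P when no zeros
  set.seed(53)
  dm <- rnorm(20); dh <- rnorm(20)
  gg <- paste0("x", 1:20)
  p1 <- proportional_association(de_profile(setNames(dm, gg), "m"),
                                 de_profile(setNames(dh, gg), "h"), gg)
  p2 <- proportional_association(de_profile(setNames(dm, gg), "m"),
                                 de_profile(setNames(-dh, gg), "h"), gg)
  expect_equal(p2$proportional, 1 - p1$proportional)
})

test_that("association tables cover every model x contrast x pathway and match the single-pair ops", {
  sim <- simulate_paired_profiles(pathway_sizes = c(12, 8, 20),
                                  rho_per_pathway = c(0.8, 1, 0.4), seed = 77)
  sim2 <- simulate_paired_profiles(pathway_sizes = c(12, 8, 20),
                                   rho_per_pathway = c(0.5, 0.2, 0.9), seed = 78)
  mice <- list(sim$mouse, de_profile(sim2$mouse$changes, label = "mouse2"))
  humans <- list(sim$human, de_profile(sim2$human$changes, label = "human2"))
  tab <- suppressMessages(
    association_table(mice, humans, sim$sets))
  expect_equal(nrow(tab), 2 * 2 * 3)
  for (i in seq_len(nrow(tab))) {
    mp <- mice[[match(tab$model[i], vapply(mice, `[[`, "", "label"))]]
    hp <- humans[[match(tab$human_contrast[i], vapply(humans, `[[`, "", "label"))]]
    paired <- suppressMessages(map_orthologs(mp, hp))
    G <- intersect(sim$sets[[tab$pathway[i]]], names(paired$mouse$changes))
    sc <- association_score(signed_ranks(paired$mouse), signed_ranks(paired$human), G)
    pa <- proportional_association(paired$mouse, paired$human, G)
    expect_equal(tab$score[i], sc$score)
    expect_equal(tab$proportional[i], pa$proportional)
    expect_identical(tab$proportional_display[i], pa$display)
  }
  # a pathway absent from the shared universe is omitted with a message
  sets2 <- gene_set_collection(c(unclass(sim$sets), list(ghost = c("NOPE1", "NOPE2"))))
  expect_message(tab2 <- association_table(list(sim$mouse), list(sim$human), sets2),
                 "ghost.*omitted")
  expect_equal(nrow(tab2), 3)
})

test_that("models with zero DEGs are dropped only when require_degs is set", {
  genes <- sprintf("G%03d", 1:60)
  tab <- make_de_table_from_flags(genes, rep(FALSE, 60), label = "NZB/W")
  human <- de_profile(setNames(rnorm(length(genes)), toupper(genes)), "bulk")
  sets <- gene_set_collection(list(pw = genes[1:10]))
  kept <- suppressMessages(association_table(list(tab), list(human), sets))
  expect_equal(nrow(kept), 1)
  expect_error(suppressMessages(
    association_table(list(tab), list(human), sets, require_degs = TRUE)),
    "no models left")
})
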
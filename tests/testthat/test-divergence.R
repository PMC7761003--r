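fit_pairs <- function(h_lfc, h_p, m_lfc, m_p, crit = significance_criterion()) {
  n <- length(h_lfc)
  h_ids <- paste0("H", seq_len(n))
  m_ids <- paste0("m", seq_len(n))
  ortholog_divergence(
    make_deg(h_ids, h_lfc, h_p, h_p),
    make_deg(m_ids, m_lfc, m_p, m_p),
    data.frame(human_symbol = h_ids, mouse_symbol = m_ids),
    crit
  )
}

test_that("classification follows the sign product and significance pattern", {
  fit <- fit_pairs(h_lfc = c(1.0, 1.0, 1.0, 0.3),
                   h_p = c(0.01, 0.01, 0.01, 0.80),
                   m_lfc = c(0.5, -0.5, 2.0, 0.1),
                   m_p = c(0.02, 0.02, 0.80, 0.90))
  expect_identical(as.character(fit$table$class),
                   c("consistent", "opposite", "inconsistent", "not_regulated"))
  # zero log2fc in a both-significant pair is pathological: inconsistent
  expect_warning(
    zfit <- fit_pairs(0, 0.01, 1, 0.01),
    "zero log2FC")
  expect_identical(as.character(zfit$table$class), "inconsistent")
})

test_that("criterion presets threshold the intended field", {
  # significant by raw p only: nominal calls it, observational does not
  h <- make_deg("H1", 1, 0.01, 0.20)
  m <- make_deg("m1", 1, 0.02, 0.30)
  map <- data.frame(human_symbol = "H1", mouse_symbol = "m1")
  expect_identical(
    as.character(ortholog_divergence(h, m, map,
      significance_criterion("nominal"))$table$class), "consistent")
  expect_identical(
    as.character(ortholog_divergence(h, m, map,
      significance_criterion("observational"))$table$class), "not_regulated")
  # strict adds the |log2FC| > 0.4 floor
  h2 <- make_deg("H1", 0.3, 0.001, 0.001)
  m2 <- make_deg("m1", 0.5, 0.001, 0.001)
  expect_identical(
    as.character(ortholog_divergence(h2, m2, map,
      significance_criterion("strict"))$table$class), "inconsistent")
})

test_that("genes absent from one table are treated as not significant there", {
  h <- make_deg(c("H1", "H2"), c(1, 2), c(0.001, 0.001), c(0.01, 0.01))
  m <- make_deg("m1", 1, 0.001, 0.01)
  map <- data.frame(human_symbol = c("H1", "H2"),
                    mouse_symbol = c("m1", "m2"))
  fit <- ortholog_divergence(h, m, map)
  expect_identical(as.character(fit$table$class),
                   c("consistent", "inconsistent"))
})

test_that("divergence score is the absolute fold-change difference", {
  expect_equal(divergence_score(1.0, -0.5), 1.5)
  expect_equal(divergence_score(2.3, 2.3), 0)
  # opposite-sign pairs: score is the sum of magnitudes
  set.seed(4)
  a <- runif(20, 0.1, 3); b <- -runif(20, 0.1, 3)
  expect_equal(divergence_score(a, b), abs(a) + abs(b))
  expect_error(divergence_score(Inf, 1), "finite")
  expect_error(divergence_score(1, NA), "finite")
})

test_that("score bounds per class hold on fitted tables", {
  sim <- simulate_deg_pair(500, n_samples_per_group = 8, seed = 13)
  dh <- differential_expression(sim$human, sim$groups)
  dm <- differential_expression(sim$mouse, sim$groups)
  fit <- ortholog_divergence(dh, dm, sim$ortholog_map)
  tab <- fit$table
  opp <- tab[tab$class == "opposite", ]
  expect_true(all(opp$score >= pmax(abs(opp$human_log2fc),
                                    abs(opp$mouse_log2fc))))
  cons <- tab[tab$class == "consistent", ]
  expect_true(all(cons$score <= pmax(abs(cons$human_log2fc),
                                     abs(cons$mouse_log2fc)) + 1e-12))
  expect_true(all(is.na(tab$score[tab$class %in%
                                    c("inconsistent", "not_regulated")])))
})

test_that("species swap preserves every class label and score", {
  sim <- simulate_deg_pair(300, n_samples_per_group = 6, seed = 17)
  dh <- differential_expression(sim$human, sim$groups)
  dm <- differential_expression(sim$mouse, sim$groups)
  map <- sim$ortholog_map
  fwd <- ortholog_divergence(dh, dm, map)
  swapped_map <- data.frame(human_symbol = map$mouse_symbol,
                            mouse_symbol = map$human_symbol)
  rev <- ortholog_divergence(dm, dh, swapped_map)
  expect_identical(as.character(fwd$table$class), as.character(rev$table$class))
  expect_equal(fwd$table$score, rev$table$score)
  s1 <- summary(fwd); s2 <- summary(rev)
  expect_identical(s1$counts, s2$counts)
})

test_that("summary identities and printed percentages are exact", {
  s <- divergence_summary_from_counts(641, 883, 5525)
  expect_identical(s$commonly_regulated, 1524)
  expect_identical(s$regulated_in_either, 7049)
  expect_equal(s$pct_opposite, 12.53)
  expect_equal(s$pct_inconsistent, 78.38)
  expect_equal(s$pct_consistent, 9.09)

  s2 <- divergence_summary_from_counts(153, 51, 0)
  expect_identical(s2$commonly_regulated, 204)
  expect_equal(s2$pct_opposite_of_common, 25)

  empty <- divergence_summary_from_counts(0, 0, 0, not_regulated = 10)
  expect_equal(empty$pct_consistent, 0)
  expect_equal(empty$pct_opposite, 0)
  expect_equal(empty$pct_inconsistent, 0)

  # additivity holds on every fitted summary
  sim <- simulate_deg_pair(200, n_samples_per_group = 5, seed = 23)
  fit <- ortholog_divergence(differential_expression(sim$human, sim$groups),
                             differential_expression(sim$mouse, sim$groups),
                             sim$ortholog_map)
  fs <- summary(fit)
  expect_identical(fs$commonly_regulated,
                   unname(fs$counts[["consistent"]] + fs$counts[["opposite"]]))
  expect_identical(fs$regulated_in_either,
                   fs$commonly_regulated + unname(fs$counts[["inconsistent"]]))
  expect_identical(sum(fs$counts), fit$n_pairs)
})

test_that("fold-change correlation matches the direct-formula oracle", {
  n <- 10
  h <- c(0.5, -1.2, 2.0, 0.3, -0.7, 1.1, -2.2, 0.9, 1.7, -0.4)
  m <- c(0.6, -1.0, 1.5, 0.1, -0.9, 1.3, -1.8, 0.7, 2.0, -0.2)
  fit <- fit_pairs(h, rep(0.001, n), m, rep(0.001, n))
  fc <- fold_change_correlation(fit, "commonly_regulated")
  expect_equal(fc$r, oracle_pearson(h, m), tolerance = 1e-12)
  expect_identical(fc$n, 10L)
  # perfect concordance / anti-concordance
  lin <- fit_pairs(1:5 / 2, rep(0.001, 5), 1:5 / 2, rep(0.001, 5))
  expect_equal(fold_change_correlation(lin)$r, 1)
  anti <- fit_pairs(1:5 / 2, rep(0.001, 5), -(1:5) / 2, rep(0.001, 5))
  expect_equal(fold_change_correlation(anti)$r, -1)
  expect_error(fold_change_correlation(fit_pairs(c(1, 1, 1), rep(0.001, 3),
                                                 c(1, 2, 3), rep(0.001, 3))),
               "zero variance")
})

test_that("divergence-score comparison separates opposite from consistent", {
  sim <- simulate_deg_pair(1000, n_samples_per_group = 10, seed = 29)
  fit <- ortholog_divergence(differential_expression(sim$human, sim$groups),
                             differential_expression(sim$mouse, sim$groups),
                             sim$ortholog_map)
  cmp <- score_divergence_comparison(fit)
  # |a| + |b| >= ||a| - |b||: opposite pairs must diverge more on average
  expect_gt(cmp$opposite_mean, cmp$consistent_mean)
  expect_lt(cmp$pvalue, 0.0001)
  # identical score distributions give a large p
  # consistent pairs score {1, 2}; opposite pairs score {1, 2} as well
  same <- fit_pairs(c(2, 3, 0.5, 1), rep(0.001, 4),
                    c(1, 1, -0.5, -1), rep(0.001, 4))
  cmp2 <- score_divergence_comparison(same)
  expect_gt(cmp2$pvalue, 0.5)
})

test_that("planted class proportions are recovered within 3 points", {
  sim <- simulate_deg_pair(2000, n_samples_per_group = 20, seed = 31)
  fit <- ortholog_divergence(differential_expression(sim$human, sim$groups),
                             differential_expression(sim$mouse, sim$groups),
                             sim$ortholog_map,
                             significance_criterion("strict"))
  rec <- table(fit$table$class) / fit$n_pairs
  planted <- c(consistent = 0.10, opposite = 0.10, inconsistent = 0.20,
               not_regulated = 0.60)
  expect_true(all(abs(rec[names(planted)] - planted) <= 0.03))
})
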
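test_that("largest-remainder apportionment is exact and deterministic", {
  expect_identical(orthodiv:::largest_remainder(100, c(0.25, 0.25, 0.125, 0.125, 0.25)),
                   c(25L, 25L, 13L, 12L, 25L))
  expect_identical(orthodiv:::largest_remainder(7, c(1, 0, 0, 0, 0)),
                   c(7L, 0L, 0L, 0L, 0L))
  # property: sums exactly to n for random proportions
  set.seed(1)
  for (i in 1:25) {
    p <- runif(5); p <- p / sum(p)
    n <- sample(1:500, 1)
    counts <- orthodiv:::largest_remainder(n, p)
    expect_identical(sum(counts), n)
    expect_true(all(abs(counts - n * p) <= 1))
  }
  expect_error(orthodiv:::largest_remainder(10, c(0.5, 0.4)), "sum to 1")
})

test_that("simulate_deg_pair plants classes whose sign structure matches", {
  sim <- simulate_deg_pair(n_genes = 100,
                           props = c(0.25, 0.25, 0.125, 0.125, 0.25),
                           n_samples_per_group = 3, seed = 42)
  counts <- table(sim$truth$true_class)
  expect_equal(unname(counts[c("consistent", "opposite",
                               "inconsistent_human_only",
                               "inconsistent_mouse_only", "null")]),
               c(25L, 25L, 13L, 12L, 25L), ignore_attr = TRUE)
  with(sim$truth, {
    expect_true(all(human_lfc[true_class == "consistent"] *
                      mouse_lfc[true_class == "consistent"] > 0))
    expect_true(all(human_lfc[true_class == "opposite"] *
                      mouse_lfc[true_class == "opposite"] < 0))
    expect_true(all(mouse_lfc[true_class == "inconsistent_human_only"] == 0))
    expect_true(all(human_lfc[true_class == "inconsistent_mouse_only"] == 0))
    expect_true(all(human_lfc[true_class == "null"] == 0))
  })
  # all-consistent: every non-null gene has a positive sign product
  sim2 <- simulate_deg_pair(n_genes = 40, props = c(1, 0, 0, 0, 0),
                            n_samples_per_group = 2, seed = 1)
  expect_true(all(sim2$truth$human_lfc * sim2$truth$mouse_lfc > 0))
})

test_that("simulated counts are nonnegative integers and reproducible", {
  sim1 <- simulate_deg_pair(n_genes = 60, n_samples_per_group = 4, seed = 7)
  sim2 <- simulate_deg_pair(n_genes = 60, n_samples_per_group = 4, seed = 7)
  expect_identical(sim1, sim2)
  expect_true(is.integer(sim1$human) && all(sim1$human >= 0))
  expect_true(is.integer(sim1$mouse) && all(sim1$mouse >= 0))
  sim3 <- simulate_deg_pair(n_genes = 60, n_samples_per_group = 4, seed = 8)
  expect_false(identical(sim1$human, sim3$human))
})

test_that("group-mean log2 ratio converges to the planted fold change", {
  sim <- simulate_deg_pair(n_genes = 300, props = c(0.5, 0.5, 0, 0, 0),
                           lfc_magnitude_mean = 1, lfc_magnitude_sd = 0,
                           n_samples_per_group = 200, seed = 11)
  d <- differential_expression(sim$human, sim$groups)
  expect_lt(mean(abs(d$log2fc - sim$truth$human_lfc)), 0.1)
})

test_that("deg-pair generator rejects invalid configurations", {
  expect_error(simulate_deg_pair(100, props = c(0.5, 0.5, 0.5, 0, 0)),
               "sum to 1")
  expect_error(simulate_deg_pair(2, props = c(0.2, 0.2, 0.2, 0.2, 0.2),
                                 n_samples_per_group = 3),
               "smaller than")
})

test_that("coexpression generator plants disjoint modules with the stated geometry", {
  sim <- simulate_coexpression(n_lnc = 4, n_coding = 60, n_samples = 30,
                               module_size = 8, seed = 5)
  expect_identical(dim(sim$matrix), c(64L, 30L))
  expect_identical(nrow(sim$truth), 32L)
  # member sets are disjoint across lncs
  expect_false(anyDuplicated(sim$truth$coding_id) > 0)
  # noiseless limit: planted pairs correlate to ~1
  hi <- simulate_coexpression(n_lnc = 2, n_coding = 10, n_samples = 20,
                              module_size = 3, latent_correlation = 1,
                              noise_sd = 1e-8, seed = 2)
  for (k in seq_len(nrow(hi$truth))) {
    r <- cor(hi$matrix[hi$truth$lnc_id[k], ], hi$matrix[hi$truth$coding_id[k], ])
    expect_gt(r, 0.999)
  }
  expect_error(simulate_coexpression(5, 10, 20, module_size = 3),
               "exceeds n_coding")
})

test_that("zero latent correlation leaves planted pairs uncorrelated on average", {
  rs <- sapply(1:10, function(s) {
    sim <- simulate_coexpression(n_lnc = 1, n_coding = 5, n_samples = 100,
                                 module_size = 3, latent_correlation = 0,
                                 noise_sd = 1, seed = s)
    mean(apply(sim$matrix[sim$truth$coding_id, ], 1,
               cor, y = sim$matrix[sim$truth$lnc_id[1], ]))
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("sequence-pair generator honors substitution rate and labels", {
  same <- simulate_sequence_pairs(4, conserved_fraction = 0.5,
                                  length = 80, substitution_rate = 0, seed = 3)
  expect_identical(unname(same$query[1]), unname(same$subject[1]))
  expect_identical(same$truth$conserved, c(TRUE, TRUE, FALSE, FALSE))
  none <- simulate_sequence_pairs(6, conserved_fraction = 0, length = 60,
                                  seed = 4)
  expect_false(any(none$truth$conserved))
  # substituted copies differ at roughly the planted rate
  div <- simulate_sequence_pairs(10, conserved_fraction = 1, length = 500,
                                 substitution_rate = 0.1, seed = 5)
  mm <- mapply(function(q, s) {
    mean(strsplit(q, "")[[1]] != strsplit(s, "")[[1]])
  }, div$query, div$subject)
  expect_lt(abs(mean(mm) - 0.1), 0.02)
  expect_error(simulate_sequence_pairs(5, length = 40), ">= 60")
})

test_that("chimeric generator prefixes every row and errors on zero samples", {
  sim <- simulate_chimeric_counts(3, 2, 4, seed = 6)
  expect_identical(dim(sim$counts), c(5L, 4L))
  expect_identical(sum(startsWith(rownames(sim$counts), "human_")), 3L)
  expect_identical(sum(startsWith(rownames(sim$counts), "mouse_")), 2L)
  expect_error(simulate_chimeric_counts(3, 2, 0), "positive")
  expect_error(simulate_chimeric_counts(0, 2, 4), "positive")
})

test_that("generator streams are independent of one another", {
  # drawing from one generator must not perturb another under the same seed
  a <- simulate_deg_pair(30, n_samples_per_group = 2, seed = 99)
  invisible(simulate_chimeric_counts(5, 5, 3, seed = 99))
  b <- simulate_deg_pair(30, n_samples_per_group = 2, seed = 99)
  expect_identical(a, b)
})
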
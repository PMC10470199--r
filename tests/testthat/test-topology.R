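test_that("default 360-mer layout has the documented composition", {
  topo <- build_default()
  expect_equal(topo$n_beads, 360L)
  counts <- table(topo$types)
  expect_equal(unname(counts["METH"]), 117L)
  expect_equal(unname(counts["PRE"]), 4L)
  expect_equal(unname(counts["UNMETH"]), 239L)
  expect_true(all(topo$pre_indices >= 120 & topo$pre_indices <= 240))
  expect_false(any(topo$prc1_bound))
  expect_equal(nrow(topo$bonds), 359L)
  expect_equal(nrow(topo$angles), 358L)
  # 360 nucleosomes x 175 bp = 63 kb
  expect_equal(360 * 175 / 1000, 63)

  # controls: no PREs / no methylation
  no_pre <- build_default(pre_indices = integer(0))
  expect_equal(sum(no_pre$types == "PRE"), 0L)
  expect_equal(sum(no_pre$types == "METH"), 121L)
  no_meth <- build_default(methylated = FALSE)
  expect_equal(sum(no_meth$types == "METH"), 0L)
  expect_equal(sum(no_meth$types == "PRE"), 4L)

  expect_error(build_default(pre_indices = c(10L)), "methylated range")
})

test_that("PRE repositioning follows the fractional placement rule", {
  topo <- build_inv_en(c(0.02, 0.10, 0.90, 0.98))
  expect_equal(topo$pre_indices, c(122L, 132L, 228L, 238L))
  # fractions matching the default even spacing reproduce build_default
  frac <- (c(132, 156, 204, 228) - 120) / 120
  expect_equal(build_inv_en(frac)$pre_indices, build_default()$pre_indices)
  expect_error(build_inv_en(c(0.5, 0.4, 0.8, 0.9)), "increasing")
  expect_error(build_inv_en(c(0, 0.5, 0.8, 1.2)))
})

test_that("demethylation replaces the exact rounded count, PREs untouched", {
  topo <- build_default()
  expect_identical(demethylate(topo, 0, seed = 1)$types, topo$types)
  full <- demethylate(topo, 1, seed = 1)
  expect_equal(sum(full$types == "METH"), 0L)
  expect_equal(full$pre_indices, topo$pre_indices)

  half <- demethylate(topo, 0.5, seed = 7)
  expect_equal(sum(half$types == "METH"), 117L - 59L) # round half up
  expect_equal(sum(half$types == "PRE"), 4L)
  # deterministic given seed
  expect_identical(half$types, demethylate(topo, 0.5, seed = 7)$types)
  # quarter replacement: round(0.25 * 117 + 0.5) = 29
  expect_equal(sum(demethylate(topo, 0.25, seed = 3)$types == "METH"),
               117L - 29L)
})

test_that("PRC1 occupancy draws are Bernoulli(pb) per PRE", {
  topo <- build_default()
  expect_equal(sum(assign_prc1(topo, 0, seed = 1)$prc1_bound), 0L)
  expect_equal(sum(assign_prc1(topo, 1, seed = 1)$prc1_bound), 4L)
  # only PRE beads may be flagged
  b <- assign_prc1(topo, 1, seed = 1)
  expect_true(all(which(b$prc1_bound) %in% topo$pre_indices))

  # binomial oracle: mean bound fraction over many assignments within the
  # exact 99% binomial interval, and joint counts look Binomial(4, pb)
  pb <- 0.6
  n <- 10000
  set.seed(42)
  k <- vapply(seq_len(n), function(i)
    sum(assign_prc1(topo, pb)$prc1_bound), integer(1))
  ci <- qbinom(c(0.005, 0.995), n * 4, pb) / (n * 4)
  expect_gte(mean(k) / 4, ci[1])
  expect_lte(mean(k) / 4, ci[2])
  obs <- tabulate(k + 1L, nbins = 5L)
  expected <- dbinom(0:4, 4, pb) * n
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 4))
})

test_that("topology tables round-trip through the text format", {
  topo <- assign_prc1(build_default(n = 60, pre_indices = c(26L, 34L),
                                    methylated_range = c(21L, 40L)),
                      1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_identical(back$types, topo$types)
  expect_identical(back$prc1_bound, topo$prc1_bound)
  expect_identical(back$pre_indices, topo$pre_indices)
})
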
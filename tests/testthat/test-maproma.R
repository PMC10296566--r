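test_that("DAve and DCI equal the printed formulas on an exhaustive grid", {
  g <- expand.grid(x = 0:20, y = 0:20)
  expected_dave_vals <- ifelse(g$x + g$y == 0, 0,
                               ((g$x - g$y) / (g$x + g$y)) / 0.5)
  expect_equal(dave(g$x, g$y), expected_dave_vals)
  expect_equal(dci(g$x, g$y), (g$x + g$y) * (g$x - g$y) / 2)
  # hand-evaluated anchor points
  expect_equal(dave(5, 5), 0)
  expect_equal(dave(4, 0), 2)
  expect_equal(dave(3, 1), 1)
  expect_equal(dave(1, 3), -1)
  expect_equal(dci(5, 5), 0)
  expect_equal(dci(3, 1), 4)
  expect_equal(dci(4, 0), 8)
  expect_error(dave(-1, 2), "non-negative")
})

test_that("index properties: antisymmetry, bound, scale behaviour", {
  set.seed(1)
  x <- c(runif(300, 0, 50), 0, 0, 5)
  y <- c(runif(300, 0, 50), 0, 7, 0)
  expect_equal(dave(x, y), -dave(y, x), tolerance = 1e-12)
  expect_equal(dci(x, y), -dci(y, x), tolerance = 1e-12)
  expect_true(all(abs(dave(x, y)) <= 2 + 1e-12))
  # |DAve| = 2 iff exactly one side is zero
  at_bound <- abs(abs(dave(x, y)) - 2) < 1e-12
  expect_equal(at_bound, xor(x == 0, y == 0))
  for (c_ in c(0.5, 3)) {
    expect_equal(dave(c_ * x, c_ * y), dave(x, y), tolerance = 1e-9)
    expect_equal(dci(c_ * x, c_ * y), c_^2 * dci(x, y), tolerance = 1e-9)
  }
})

test_that("DEP calling applies both thresholds jointly with direction by sign", {
  m <- count_matrix(matrix(c(3, 1.05, 0.6, 4, 0,
                             1, 0.95, 0.4, 0, 0), ncol = 2,
                           dimnames = list(c("strong", "small_dave",
                                             "small_dci", "only_x", "absent"),
                                           c("X", "Y"))),
                    kind = "condition")
  calls <- compare_conditions(m, comparison_spec("t", "X", "Y"))
  expect_false("absent" %in% calls$protein)  # no evidence in either sample
  row <- function(p) calls[calls$protein == p, ]
  expect_equal(row("strong")$dave, 1.0)
  expect_equal(row("strong")$dci, 4.0)
  expect_true(row("strong")$is_dep)
  expect_equal(row("strong")$direction, "up_in_X")
  expect_false(row("small_dave")$is_dep)   # |DAve| = 0.1 < 0.2
  expect_false(row("small_dci")$is_dep)    # DAve 0.4 passes but DCI 0.1 < 2
  expect_true(row("only_x")$is_dep)        # DAve 2, DCI 8
  expect_error(compare_conditions(m, comparison_spec("bad", "X", "Z")),
               "not in matrix")
})

test_that("DEP calling matches the brute-force formula oracle on random matrices", {
  set.seed(7)
  for (trial in 1:25) {
    n <- 20
    m <- matrix(round(runif(2 * n, 0, 12), 2), ncol = 2,
                dimnames = list(sprintf("P%02d", 1:n), c("X", "Y")))
    m[sample(length(m), 8)] <- 0
    cm <- count_matrix(m, kind = "condition")
    got <- compare_conditions(cm, comparison_spec("t", "X", "Y"))
    want <- oracle_dep_calls(m, "X", "Y")
    expect_equal(got$protein, want$protein)
    expect_equal(got$dave, want$dave, tolerance = 1e-12)
    expect_equal(got$dci, want$dci, tolerance = 1e-12)
    expect_equal(got$is_dep, want$is_dep)
    expect_equal(got$direction, want$direction)
  }
})

test_that("common-trend mining keeps only consistently-signed DEPs", {
  mk <- function(p, dave, dep) data.frame(
    protein = p, x_apsm = 1, y_apsm = 1, dave = dave, dci = 99,
    is_dep = dep, direction = ifelse(dave > 0, "up_in_X",
                                     ifelse(dave < 0, "up_in_Y", "none")),
    stringsAsFactors = FALSE)
  c1 <- mk(c("A", "B", "C"), c(1, -1, 1), c(TRUE, TRUE, TRUE))
  c2 <- mk(c("A", "B", "C"), c(1, 1, -1), c(TRUE, TRUE, TRUE))
  tr <- common_trend(list(c1, c2))
  expect_equal(tr$up_in_X, "A")          # consistent in 2/2
  expect_equal(tr$up_in_Y, character(0)) # B flips sign, C flips sign
  tr1 <- common_trend(list(c1, c2), min_support = 1)
  expect_setequal(tr1$up_in_X, c("A", "B", "C"))
  expect_error(common_trend(list(c1)), "two comparisons")
})

test_that("the default design yields the 10 canonical comparisons", {
  specs <- comparison_family(bnct_design())
  expect_length(specs, 10)
  expect_equal(sum(grepl("^BPA\\+_vs_BPA-", names(specs))), 6)
  expect_equal(sum(grepl("^11.3Gy_vs_", names(specs))), 4)
  s <- specs[["BPA+_vs_BPA-_1.9Gy_24h"]]
  expect_equal(s$x_condition, "BPA+_1.9Gy_24h")
  expect_equal(s$y_condition, "BPA-_1.9Gy_24h")
  expect_equal(s$dave_threshold, 0.2)
  expect_equal(s$dci_threshold, 2.0)
  # dose contrasts compare the highest dose (X) with each lower dose
  s2 <- specs[["11.3Gy_vs_0Gy_BPA+_6h"]]
  expect_equal(s2$x_condition, "BPA+_11.3Gy_6h")
  expect_equal(s2$y_condition, "BPA+_0Gy_6h")
  # unmatched cells are warned about, empty design errors
  half <- bnct_design()
  half <- half[half$bpa == "plus" | half$dose_gy == 0, ]
  expect_warning(comparison_family(half), "unmatched")
  expect_error(comparison_family(half[0, ]), "no runs")
})

test_that("planted high-abundance proteins surface in the full-support trend set", {
  cfg <- tiny_config(n_human_proteins = 120L, depth_per_run = 6000,
                     n_dep = 12L, seed = 9L)
  sim <- simulate_experiment(cfg)
  counts <- aggregate_counts(sim$records, sim$design)
  hum <- rownames(counts)[attr(counts, "species") == "human"]
  norm_all <- normalize_runs(counts)
  apsm <- average_condition(count_matrix(unclass(norm_all)[hum, ], kind = "run"),
                            sim$design)
  specs <- comparison_family(sim$design)
  bpa <- specs[grepl("^BPA\\+_vs_BPA-", names(specs))]
  calls <- lapply(bpa, function(s) compare_conditions(apsm, s))
  trend <- common_trend(calls)
  dep <- sim$truth$dep_proteins
  hi <- dep$protein[dep$expected_apsm >= 20]
  expect_gt(length(hi), 0)
  expect_gte(mean(hi %in% trend$up_in_X), 0.9)
})
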
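test_that("F screen matches hand ANOVA anchors and handles degenerate proteins", {
  m <- count_matrix(matrix(c(1, 1, 1, 2, 1, 3, 1, 4, 1, 5, 1, 6), nrow = 2,
                           dimnames = list(c("flat", "sep"), paste0("r", 1:6))),
                    kind = "run")
  res <- f_screen(m, groups = rep(c("a", "b"), each = 3))
  flat <- res[res$protein == "flat", ]
  expect_equal(flat$f_ratio, 0)      # no between- or within-group variance
  expect_equal(flat$p_value, 1)
  expect_false(flat$retained)
  sep <- res[res$protein == "sep", ] # {1,2,3} vs {4,5,6}
  expect_equal(sep$f_ratio, 13.5)
  expect_equal(sep$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_true(sep$retained)
  # zero within-group variance with real separation -> infinite F, retained
  m2 <- count_matrix(matrix(c(1, 1, 1, 5, 5, 5), nrow = 1,
                            dimnames = list("step", paste0("r", 1:6))),
                     kind = "run")
  res2 <- f_screen(m2, groups = rep(c("a", "b"), each = 3))
  expect_equal(res2$f_ratio, Inf)
  expect_equal(res2$p_value, 0)
  expect_true(res2$retained)
})

test_that("F screen equals the aov oracle on random matrices", {
  set.seed(11)
  for (trial in 1:20) {
    k <- sample(2:6, 1)
    sizes <- sample(3:6, k, replace = TRUE)
    groups <- rep(letters[1:k], sizes)
    n <- length(groups)
    m <- matrix(rpois(8 * n, 6) + runif(8 * n), nrow = 8,
                dimnames = list(sprintf("P%d", 1:8), sprintf("r%02d", 1:n)))
    res <- f_screen(count_matrix(m, kind = "run"), groups = groups)
    for (p in rownames(m)) {
      want <- oracle_anova(m[p, ], groups)
      got <- res[res$protein == p, ]
      expect_equal(got$f_ratio, unname(want["f"]), tolerance = 1e-9)
      expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-9)
    }
  }
})

test_that("screen retention is monotone in its thresholds", {
  sim <- simulate_experiment(tiny_config(depth_per_run = 1000))
  m <- normalize_runs(aggregate_counts(sim$records, sim$design))
  strict <- f_screen(m, sim$design, f_min = 3, p_max = 0.01)
  loose <- f_screen(m, sim$design, f_min = 2, p_max = 0.05)
  expect_true(all(strict$protein[strict$retained] %in%
                    loose$protein[loose$retained]))
  # planted proteins are retained at a higher rate than nulls
  dep <- sim$truth$dep_proteins$protein
  rate_dep <- mean(loose$retained[loose$protein %in% dep])
  rate_null <- mean(loose$retained[!loose$protein %in% dep &
                                     grepl("^HS_", loose$protein)])
  expect_gt(rate_dep, rate_null)
})

test_that("Ward/Euclidean clustering is exact against the ESS oracle and deterministic", {
  # identical pair merges first at height 0
  m <- count_matrix(matrix(c(1, 2, 1, 2, 9, 9), nrow = 2,
                           dimnames = list(c("A", "B"), c("c1", "c2", "c3"))),
                    kind = "condition")
  hc <- cluster_profiles(m)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("c1", "c2"))
  # two well-separated groups split at the top
  m4 <- count_matrix(matrix(c(0, 0, 0.4, 0.2, 10, 9.8, 10.2, 10), nrow = 2,
                            dimnames = list(c("A", "B"),
                                            c("g1a", "g1b", "g2a", "g2b"))),
                     kind = "condition")
  top <- stats::cutree(cluster_profiles(m4), 2)
  expect_equal(top[["g1a"]], top[["g1b"]])
  expect_equal(top[["g2a"]], top[["g2b"]])
  expect_false(top[["g1a"]] == top[["g2a"]])
  # exhaustive-greedy oracle agreement on random 6-column matrices
  set.seed(3)
  for (trial in 1:10) {
    X <- matrix(rnorm(5 * 6), 5, 6,
                dimnames = list(paste0("P", 1:5), sample(letters[1:6])))
    cm <- count_matrix(abs(X), kind = "run")
    hc2 <- cluster_profiles(cm)
    orc <- oracle_ward(abs(X)[, order(colnames(X))])
    expect_equal(sort(hc2$height), sort(orc$heights), tolerance = 1e-8)
    got2 <- stats::cutree(hc2, 2)
    got_split <- vapply(split(names(got2), got2),
                        function(s) paste(sort(s), collapse = ","), "")
    want_split <- vapply(orc$split2,
                         function(s) paste(s, collapse = ","), "")
    expect_setequal(unname(got_split), unname(want_split))
  }
  # permutation invariance: shuffled columns give the same merge heights
  perm <- count_matrix(unclass(m4)[, c(3, 1, 4, 2)], kind = "condition")
  expect_equal(sort(cluster_profiles(perm)$height),
               sort(cluster_profiles(m4)$height), tolerance = 1e-12)
  m4na <- m4; m4na[1, 1] <- NA
  expect_error(cluster_profiles(m4na), "NaN/NA")
})

test_that("dendrogram exports as Newick readable by standard tree tools", {
  sim <- simulate_experiment(tiny_config(depth_per_run = 400))
  m <- normalize_runs(aggregate_counts(sim$records, sim$design))
  hc <- cluster_profiles(m)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, colnames(m))
})

test_that("PCA yields orthonormal components, full reconstruction, duplicates coincide", {
  set.seed(21)
  m <- count_matrix(matrix(abs(rnorm(40 * 6, 10, 4)), 40,
                           dimnames = list(sprintf("P%02d", 1:40),
                                           sprintf("c%d", 1:6))),
                    kind = "condition")
  pc <- pca_profiles(m)
  expect_true(all(diff(pc$explained) <= 1e-12))   # decreasing order
  expect_equal(sum(pc$explained), 1)
  rot <- pc$loadings
  expect_equal(t(rot) %*% rot, diag(ncol(rot)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # reconstruction from all components
  rec <- pc$scores %*% t(rot)
  centred <- scale(t(unclass(m)), center = TRUE, scale = FALSE)
  expect_lt(max(abs(rec - centred)), 1e-8)
  # two conditions -> one nontrivial component carrying all the variance
  pc2 <- pca_profiles(count_matrix(unclass(m)[, 1:2], kind = "condition"))
  expect_equal(pc2$explained[1], 1)
  # duplicated condition column -> coincident scores
  dup <- unclass(m); dup[, 2] <- dup[, 1]
  pcd <- pca_profiles(count_matrix(dup, kind = "condition"))
  expect_lt(max(abs(pcd$scores[1, ] - pcd$scores[2, ])), 1e-8)
})

test_that("selection combination is a union with provenance flags", {
  comb <- combine_selections(c("A", "B", "C"), c("D", "E"))
  expect_equal(nrow(comb), 5)
  nested <- combine_selections(c("A", "B", "C"), c("B"))
  expect_equal(nrow(nested), 3)
  expect_true(nested$from_dep[nested$protein == "B"])
  # inclusion-exclusion at the sizes of a typical screen/DEP combination
  screen <- sprintf("s%02d", 1:86)
  deps <- c(sprintf("s%02d", 1:16), sprintf("d%02d", 1:11)) # 27 with 16 shared
  expect_equal(nrow(combine_selections(screen, deps)), 97)
})
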
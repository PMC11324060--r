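# Morphological profile analysis: induction, activity, cluster assignment,
# embedding.

test_that("induction arithmetic is exact and length-checked", {
  v <- numeric(579)
  v[1:58] <- 4
  expect_equal(compute_induction(v), 100 * 58 / 579)
  expect_equal(round(compute_induction(v), 2), 10.02)
  expect_equal(compute_induction(numeric(579)), 0)
  v29 <- numeric(579); v29[1:29] <- -5
  expect_gte(compute_induction(v29), 5)
  expect_error(compute_induction(numeric(100)), "expected")
  # threshold is inclusive on |z|
  v1 <- numeric(579); v1[1] <- 3
  expect_equal(compute_induction(v1), 100 / 579)
})

test_that("induction is monotone in the significance threshold", {
  set.seed(42)
  v <- rnorm(579, sd = 2)
  ths <- seq(0.5, 6, by = 0.5)
  ind <- vapply(ths, function(t) compute_induction(v, t), numeric(1))
  expect_true(all(diff(ind) <= 0))
})

test_that("the activity boundary sits exactly at 5 percent", {
  expect_true(flag_active(5))
  expect_false(flag_active(4.99))
  expect_true(flag_active(16))
})

test_that("cluster assignment is correlation-based and scale-invariant", {
  gen <- make_profiles(n_active = 12L, n_clusters = 3L, seed = 3L)
  sp <- gen$subprofiles
  # a profile equal to a cluster's own subprofile: similarity 100
  v <- numeric(579)
  v[sp[[1]]$feature_subset] <- sp[[1]]$values
  a <- assign_cluster(v, sp)
  expect_identical(a$cluster, sp[[1]]$cluster_name)
  expect_equal(a$similarity[[sp[[1]]$cluster_name]], 100)
  # the negation of every subprofile: unassigned
  neg <- numeric(579)
  for (s in sp) neg[s$feature_subset] <- -s$values
  expect_true(is.na(assign_cluster(neg, sp)$cluster))
  # scaling a profile leaves assignments unchanged (Pearson)
  i <- 1L
  a1 <- assign_cluster(gen$profiles$mat[i, ], sp)
  a2 <- assign_cluster(2 * gen$profiles$mat[i, ], sp)
  expect_identical(a1$cluster, a2$cluster)
  expect_equal(a1$similarity, a2$similarity, tolerance = 1e-12)
  # constant restricted vector: undefined correlation, below threshold
  expect_true(is.na(assign_cluster(rep(1, 579), sp)$cluster))
})

test_that("planted clusters are recovered and novel profiles stay unassigned", {
  gen <- make_profiles(n_active = 50L, n_clusters = 3L, n_novel = 5L, seed = 1L)
  res <- analyze_profiles(gen$profiles, gen$subprofiles)
  expect_true(all(res$active))              # by construction
  member <- gen$truth$cluster != "novel"
  recovered <- res$cluster[member] == gen$truth$cluster[member]
  expect_gte(mean(recovered, na.rm = TRUE), 0.95)
  expect_false(anyNA(res$cluster[member]))
  expect_true(all(is.na(res$cluster[!member])))
})

test_that("profile tables round-trip through TSV", {
  gen <- make_profiles(n_active = 6L, n_clusters = 2L, n_novel = 1L, seed = 2L)
  f <- tempfile(fileext = ".tsv")
  write_profiles(gen$profiles, f)
  back <- read_profiles(f)
  expect_equal(back$meta$id, gen$profiles$meta$id)
  expect_equal(unname(back$mat), unname(gen$profiles$mat), tolerance = 1e-9)
  g <- tempfile(fileext = ".json")
  write_subprofiles(gen$subprofiles, g)
  back_sp <- read_subprofiles(g)
  expect_equal(back_sp, gen$subprofiles, tolerance = 1e-12)
})

test_that("the embedding is seeded-deterministic and separates clusters", {
  gen <- make_profiles(n_active = 40L, n_clusters = 2L, n_novel = 0L, seed = 5L)
  emb1 <- embed_profiles(gen$profiles$mat, seed = 9L)
  emb2 <- embed_profiles(gen$profiles$mat, seed = 9L)
  expect_identical(emb1, emb2)
  lab <- gen$truth$cluster
  xy <- as.matrix(emb1[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  same <- outer(lab, lab, "==") & upper.tri(d)
  diff <- outer(lab, lab, "!=") & upper.tri(d)
  expect_gt(mean(d[diff]), mean(d[same]))
  expect_error(embed_profiles(gen$profiles$mat[1, , drop = FALSE]), "at least 2")
})
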
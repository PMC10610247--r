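test_that("drug selection ranks by total with lexicographic ties at the cut", {
  rows <- tibble::tibble(
    drug_name = rep(c("beta", "alpha", "gamma"), times = c(5, 5, 3)),
    event_pt = "x", is_pruritus = FALSE, case_id = "c")
  expect_equal(select_drugs(rows, 0, Inf), c("alpha", "beta", "gamma"))
  expect_equal(select_drugs(rows, 0, 2), c("alpha", "beta"))
  expect_equal(select_drugs(rows, 3, Inf), c("alpha", "beta"))
  expect_error(select_drugs(rows, 100, Inf), "fewer than 2 drugs")
})

test_that("term selection on the packaged tally matches the printed counts", {
  tally <- pruritus_terms()
  expect_equal(nrow(tally), 37L)
  expect_length(select_pts(tally, 1), 29L)
  at50 <- select_pts(tally, 50)
  expect_length(at50, 17L)
  expect_equal(at50[1], "Pruritus")
  expect_equal(at50[17], "Lip Pruritus")
  expect_error(select_pts(tally, 1e9), "fewer than 2 terms")
})

test_that("lnROR matrix cells equal an independent per-cell recount", {
  gen <- synth_generate(synthetic_config(n_cases = 3000, seed = 12))
  built <- synth_cohort(gen)
  de <- make_analysis_set(built$cohort, "drug_event")
  drugs <- select_drugs(de, 0, 6)
  pts <- c("Pruritus", "Nausea", "Headache")
  rm_ <- build_ror_matrix(de, drugs, pts)
  expect_true(all(is.finite(rm_$values)))
  for (dg in drugs) {
    for (pt in pts) {
      a <- sum(de$drug_name == dg & de$event_pt == pt)
      b <- sum(de$drug_name == dg & de$event_pt != pt)
      cc <- sum(de$drug_name != dg & de$event_pt == pt)
      d <- sum(de$drug_name != dg & de$event_pt != pt)
      expect_equal(rm_$values[dg, pt], compute_ror(a, b, cc, d)$ln_ror,
                   tolerance = 1e-9)
    }
  }
})

test_that("a single planted pair stands out above the matrix median", {
  cfg <- synthetic_config(
    n_cases = 20000, seed = 3,
    drug_catalog = data.frame(drug = paste0("d", 1:4), p = 0.05),
    pt_catalog = data.frame(
      pt = c("Pruritus", "Eye Pruritus", "Nausea", "Headache"),
      p0 = c(0.02, 0.02, 0.35, 0.2),
      is_pruritus = c(TRUE, TRUE, FALSE, FALSE)),
    planted_effects = data.frame(drug = "d2", pt = "Eye Pruritus",
                                 multiplier = 6),
    duplicate_rate = 0, missing_date_rate = 0, out_of_window_rate = 0,
    indication_overlap_rate = 0)
  built <- synth_cohort(synth_generate(cfg))
  de <- make_analysis_set(built$cohort, "drug_event")
  rm_ <- build_ror_matrix(de, paste0("d", 1:4),
                          c("Pruritus", "Eye Pruritus"))
  expect_gt(rm_$values["d2", "Eye Pruritus"], stats::median(rm_$values))
})

test_that("covariance PCA matches an eigendecomposition oracle up to sign", {
  fix_signs <- function(v) {
    apply(v, 2, function(col) if (col[which.max(abs(col))] < 0) -col else col)
  }
  for (rep in 1:10) {
    set.seed(rep)
    X <- matrix(rnorm(20), 5, 4) %*% diag(c(3, 2, 1, 0.5))
    pca <- pca_covariance(X)
    ev <- eigen(stats::cov(X), symmetric = TRUE)
    keep <- seq_along(pca$eigenvalues)
    expect_equal(pca$eigenvalues, ev$values[keep], tolerance = 1e-8)
    expect_equal(unname(pca$loadings),
                 unname(fix_signs(ev$vectors[, keep, drop = FALSE])),
                 tolerance = 1e-8)
    expect_equal(sum(pca$contributions), 1, tolerance = 1e-9)
    expect_true(all(pca$eigenvalues >= -1e-12))
  }
})

test_that("all components reconstruct the centered matrix", {
  set.seed(2)
  X <- matrix(rnorm(60), 10, 6)
  pca <- pca_covariance(X)
  recon <- pca$scores %*% t(pca$loadings) +
    matrix(pca$center, 10, 6, byrow = TRUE)
  expect_equal(unname(recon), unname(X), tolerance = 1e-9)
})

test_that("a matrix with one varying column loads it all on PC1", {
  X <- cbind(a = c(1, 2, 3, 4), b = 5, c = 7)
  pca <- pca_covariance(X)
  expect_equal(pca$contributions[1], 1, tolerance = 1e-12)
  expect_error(pca_covariance(matrix(1, 4, 3)), "degenerate")
})

test_that("the loading sign convention makes the top element positive", {
  set.seed(30)
  X <- matrix(rnorm(48), 8, 6)
  pca <- pca_covariance(X)
  for (j in seq_len(ncol(pca$loadings))) {
    i <- which.max(abs(pca$loadings[, j]))
    expect_gt(pca$loadings[i, j], 0)
  }
})

test_that("Ward clustering matches the naive O(n^3) oracle on small inputs", {
  for (rep in 1:5) {
    set.seed(rep + 100)
    X <- matrix(rnorm(36), 12, 3)
    rownames(X) <- letters[1:12]
    pca <- list(scores = X)
    cl <- ward_cluster(pca, n_components = 3, k = 4)
    nw <- naive_ward(X)
    expect_equal(cl$height, nw$heights, tolerance = 1e-9)
    expect_equal(rand_index(cl$labels, naive_ward_cut(nw, 4)), 1)
  }
})

test_that("Ward merge heights are non-decreasing and k = n gives singletons", {
  set.seed(8)
  pca <- list(scores = matrix(rnorm(30), 10, 3))
  cl <- ward_cluster(pca, k = 10)
  expect_length(unique(cl$labels), 10L)
  cl2 <- ward_cluster(pca, k = 3)
  expect_true(all(diff(cl2$height) >= -1e-12))
  expect_error(ward_cluster(pca, k = 11), "exceeds")
})

test_that("two separated blobs are recovered exactly at k = 2", {
  set.seed(5)
  X <- rbind(matrix(rnorm(24, 0, 0.3), 8, 3),
             matrix(rnorm(24, 10, 0.3), 8, 3))
  truth <- rep(1:2, each = 8)
  cl <- ward_cluster(list(scores = X), k = 2)
  expect_equal(rand_index(cl$labels, truth), 1)
})

test_that("cluster signatures carry the mean-score signs, with symmetry", {
  scores <- rbind(matrix(1, 4, 3), matrix(-1, 4, 3))
  pca <- list(scores = scores)
  cl <- list(labels = rep(1:2, each = 4), n_components = 3)
  sig <- cluster_signatures(cl, pca)
  expect_equal(sig$sign[sig$cluster == 1], rep(1, 3))
  expect_equal(sig$sign[sig$cluster == 2], rep(-1, 3))
  mirrored <- cluster_signatures(cl, list(scores = -scores))
  expect_equal(mirrored$mean_score, -sig$mean_score)
})

test_that("the Rand index agrees with the adjusted-Rand cross-check at 1", {
  a <- rep(1:3, each = 4)
  expect_equal(rand_index(a, a), 1)
  b <- a
  b[1] <- 2
  expect_lt(rand_index(a, b), 1)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(a, a), 1)
  }
})
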
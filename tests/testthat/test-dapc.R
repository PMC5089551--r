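# well-conditioned clustered fixture shared by several blocks
lineage_fixture <- function(n_groups = 4, n = 20, div = 60, within = 25,
                            rate = 0.05, seed = 3) {
  comb <- full_panel()
  ld <- generate_lineage_dataset(n_groups, n, div, within,
                                 flat_mutation_model(comb, rate),
                                 default_founder(comb), seed = seed)
  X <- suppressWarnings(suppressMessages(
    encode_haplotypes(ld$haplotypes, single_copy_columns(comb))))
  list(X = X, labels = ld$labels)
}

test_that("encoding keeps single-copy loci and refuses multi-copy ones", {
  panel <- load_panel("YFILER")
  haps <- founder_table(c("s1", "s2", "s3"), panel)
  haps$DYS393 <- c(13, 14, 15)  # leave one column variable
  expect_error(encode_haplotypes(haps, c("DYS393", "DYS385a")),
               "multi-copy")
  expect_warning(X <- encode_haplotypes(haps, single_copy_columns(panel)),
                 "constant")
  expect_equal(colnames(X), "DYS393")
  # imputation by column mean
  haps$DYS393[2] <- NA
  expect_message(
    expect_warning(X2 <- encode_haplotypes(haps,
                                           single_copy_columns(panel))),
    "imputed")
  expect_equal(X2["s2", "DYS393"], mean(c(13, 15)))
})

test_that("well-separated groups reach membership ~1 on training data", {
  fx <- lineage_fixture(n_groups = 3, n = 10, div = 200, within = 3,
                        seed = 11)
  fit <- fit_dapc(fx$X, fx$labels)
  mm <- membership(fit, fx$X, fx$labels)
  expect_true(all(mm$amp > 0.99))
  expect_equal(unname(rowSums(mm$posterior)), rep(1, nrow(fx$X)),
               tolerance = 1e-9)
})

test_that("degenerate group sizes and mismatched features are refused", {
  fx <- lineage_fixture(n_groups = 3, n = 4, seed = 5)
  labs <- fx$labels
  labs[labs == labs[1]][-1] <- labs[5]  # leave one singleton group
  expect_error(fit_dapc(fx$X, labs), "single member")
  fit <- suppressWarnings(fit_dapc(fx$X, fx$labels))
  expect_error(membership(fit, fx$X[, -1]), "do not match")
  w <- capture_warnings(fit_dapc(fx$X, fx$labels, n_pc = 10000))
  expect_true(any(grepl("clipped", w)))
})

test_that("full-rank DAPC equals direct linear-discriminant posteriors", {
  fx <- lineage_fixture(n_groups = 4, n = 25, seed = 3)
  expect_equal(qr(scale(fx$X, scale = FALSE))$rank, ncol(fx$X))
  fit <- fit_dapc(fx$X, fx$labels, n_pc = ncol(fx$X))
  p1 <- membership(fit, fx$X)$posterior
  direct <- MASS::lda(fx$X, grouping = factor(fx$labels),
                      prior = rep(1 / 4, 4))
  p2 <- predict(direct, fx$X)$posterior
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("memberships are invariant under orthogonal feature rotation", {
  fx <- lineage_fixture(n_groups = 3, n = 15, seed = 19)
  Q <- qr.Q(qr(matrix(stats::rnorm(ncol(fx$X)^2), ncol(fx$X))))
  XR <- fx$X %*% Q
  colnames(XR) <- colnames(fx$X)
  attr(XR, "loci") <- colnames(XR)
  r <- ncol(fx$X)
  p1 <- membership(fit_dapc(fx$X, fx$labels, n_pc = r), fx$X)$posterior
  p2 <- membership(fit_dapc(XR, fx$labels, n_pc = r), XR)$posterior
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("fitting is deterministic: identical inputs, identical models", {
  fx <- lineage_fixture(n_groups = 3, n = 8, seed = 29)
  f1 <- fit_dapc(fx$X, fx$labels)
  f2 <- fit_dapc(fx$X, fx$labels)
  expect_identical(f1$rotation, f2$rotation)
  expect_identical(membership(f1, fx$X)$posterior,
                   membership(f2, fx$X)$posterior)
})

test_that("membership export is plot-ready and recomputes amp", {
  fx <- lineage_fixture(n_groups = 2, n = 4, div = 80, within = 10,
                        seed = 41)
  fit <- fit_dapc(fx$X, fx$labels)
  mm <- membership(fit, fx$X, fx$labels)
  out <- export_membership_plot(mm)
  expect_equal(nrow(out$assignments), nrow(fx$X) * 2)
  sums <- tapply(out$assignments$probability, out$assignments$sample_id, sum)
  expect_equal(as.vector(sums), rep(1, nrow(fx$X)), tolerance = 1e-9)
  # amp summary equals group-wise mean of true-group posteriors, recomputed
  for (g in unique(fx$labels)) {
    manual <- mean(mm$posterior[fx$labels == g, g])
    expect_equal(out$amp$amp[out$amp$group == g], manual)
  }
})

test_that("cross-validated membership is not optimistic on separable data", {
  fx <- lineage_fixture(n_groups = 3, n = 12, div = 200, within = 3,
                        seed = 53)
  cvm <- cv_membership(fx$X, fx$labels, folds = 5, seed = 1)
  expect_true(all(cvm$amp > 0.95))
  expect_equal(unname(rowSums(cvm$posterior)), rep(1, nrow(fx$X)),
               tolerance = 1e-9)
})
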
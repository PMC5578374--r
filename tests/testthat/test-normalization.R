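sim_bits <- function(seed = 21, ...) {
  sim <- simulate_profiles(seed = seed, ...)
  simulate_bitscores(sim$profile, seed = seed + 1000)
}

test_that("NPP reproduces the worked 2x2 pipeline", {
  bits <- bitscore_profile(matrix(c(100, 50, 80, 160), 2, 2, byrow = TRUE,
                                  dimnames = list(c("p1", "p2"), c("sA", "sB"))))
  norm <- npp_transform(bits, score_floor = 70, min_homologs = 1)
  # floor: (100,1)/(80,160); log2 row ratios: (0,-log2 100)/(-1,0);
  # two-row columns z-score to +-1/sqrt(2)
  s <- 1 / sqrt(2)
  expect_equal(unclass(norm),
               matrix(c(s, -s, -s, s), 2, 2,
                      dimnames = list(c("p1", "p2"), c("sA", "sB"))),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("NPP drops poorly conserved proteins and flags flat columns", {
  bits <- bitscore_profile(matrix(c(90, 90, 90,
                                    50, 60, 65,
                                    80, 100, 90), 3, 3, byrow = TRUE,
                                  dimnames = list(paste0("p", 1:3), paste0("s", 1:3))))
  expect_warning(norm <- npp_transform(bits, score_floor = 70, min_homologs = 1),
                 "zero spread")
  expect_equal(attr(norm, "dropped_proteins")$protein, "p2")
  expect_equal(attr(norm, "dropped_proteins")$reason, "poor conservation")
  expect_false("p2" %in% rownames(norm))
  # a column whose log-ratios all coincide has zero spread: zeroed, flagged
  bits2 <- bitscore_profile(matrix(c(90, 90, 80, 90), 2, 2, byrow = TRUE,
                                   dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  expect_warning(norm2 <- npp_transform(bits2, min_homologs = 1), "zero spread")
  expect_equal(attr(norm2, "degenerate_columns"), "s2")
  expect_equal(unname(unclass(norm2)[, "s2"]), c(0, 0))
  expect_error(npp_transform(bits, min_homologs = 4), "min_homologs 4")
})

test_that("NPP columns are z-scored and SVD rows unit-norm on simulated data", {
  bits <- sim_bits()
  npp <- npp_transform(bits)
  V <- unclass(npp)
  sds <- apply(V, 2, sd)
  expect_lt(max(abs(colMeans(V))), 1e-9)
  expect_lt(max(abs(sds[sds > 0] - 1)), 1e-9)

  sv <- svd_transform(bits, trim_fraction = 0.3)
  expect_lt(max(abs(sqrt(rowSums(unclass(sv)^2)) - 1)), 1e-9)
  # ceil(0.3 * 60) singular dimensions retained
  expect_equal(ncol(sv), 18L)
  expect_error(svd_transform(bits, trim_fraction = 0), "trim_fraction")
  expect_error(svd_transform(bits, trim_fraction = 1.2), "trim_fraction")
})

test_that("the SVD factorization reconstructs the scaled matrix", {
  bits <- sim_bits(seed = 5)
  sv <- svd_transform(bits, trim_fraction = 1)
  fac <- attr(sv, "factorization")
  P <- attr(sv, "scaled_input")
  recon <- fac$u %*% diag(fac$d) %*% t(fac$v)
  expect_lt(max(abs(recon - P)), 1e-9)
  expect_true(all(diff(fac$d) <= 1e-12))  # singular values descending
})

test_that("a rank-1 profile collapses onto its dominant singular dimension", {
  u <- c(1, 2, 3); v <- c(4, 2, 1)
  P <- outer(u, v)
  dimnames(P) <- list(paste0("p", 1:3), paste0("s", 1:3))
  # trimmed to the single non-zero singular dimension, every row maps to
  # the same unit point up to sign, so pairwise distances are 0 or 2
  sv <- svd_transform(bitscore_profile(P), score_floor = 0.5,
                      trim_fraction = 1 / 3, min_homologs = 1)
  V <- unclass(sv)
  expect_equal(ncol(V), 1L)
  expect_true(all(abs(abs(V) - 1) < 1e-9))
  D <- unclass(svd_score(sv))
  expect_true(all(abs(D) < 1e-9 | abs(D - 2) < 1e-9))
  # a reference SVD of the same instance agrees on the dominant column
  ref <- svd(P / apply(P, 1, max))
  expect_equal(abs(V[, 1]), abs(ref$u[, 1] / sqrt(rowSums(ref$u[, 1, drop = FALSE]^2))),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("raising min_homologs only ever shrinks the retained set", {
  bits <- sim_bits(seed = 9)
  prev <- rownames(npp_transform(bits, min_homologs = 1))
  for (k in c(5, 10, 20)) {
    cur <- rownames(npp_transform(bits, min_homologs = k))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("SVD distances are invariant to rotation of the species space", {
  bits <- sim_bits(seed = 13, n_background = 2, m_species = 12,
                   clade_block_sizes = c(6, 6))
  sv <- svd_transform(bits, score_floor = 60, trim_fraction = 1,
                      min_homologs = 1)
  d0 <- svd_score(sv)
  # rotate the row space of the floored/row-scaled matrix by a random
  # orthogonal map; with all dimensions kept the distances cannot change
  P <- attr(sv, "scaled_input")
  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(ncol(P)^2), ncol(P))))
  PR <- P %*% Q
  fac <- svd(PR)
  U <- fac$u / sqrt(rowSums(fac$u^2))
  rownames(U) <- rownames(P)
  d1 <- as.matrix(dist(U))
  expect_equal(unclass(d0)[rownames(U), rownames(U)], d1,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("scorers enforce the matching method and behave on identical rows", {
  bits <- sim_bits(seed = 31)
  npp <- npp_transform(bits)
  sv <- svd_transform(bits)
  expect_error(npp_score(sv), "NPP")
  expect_error(svd_score(npp), "SVD")
  cm <- npp_score(npp)
  expect_identical(attr(cm, "orientation"), "similarity")
  dm <- svd_score(sv)
  expect_identical(attr(dm, "orientation"), "distance")
  # unit-norm rows: squared distance is 2 - 2 * dot product
  V <- unclass(sv)
  i <- 1; j <- 2
  expect_equal(dm[i, j]^2, 2 - 2 * sum(V[i, ] * V[j, ]), tolerance = 1e-9)
  expect_true(all(dm <= 2 + 1e-9))
})
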
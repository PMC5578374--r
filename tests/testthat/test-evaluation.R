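toy_complexes <- function() {
  data.frame(
    complex_id = c("c1", "c1", "c1", "c2", "c2"),
    protein_id = c("P1", "P2", "P3", "P4", "P5"),
    localization = c("mito", "mito", "mito", "nucleus", "nucleus"),
    stringsAsFactors = FALSE)
}

test_that("positives are all intra-complex pairs", {
  ref <- build_reference(toy_complexes(), ratio = 1, seed = 1)
  keys <- sort(paste(ref$positives[, 1], ref$positives[, 2]))
  expect_equal(keys, c("P1 P2", "P1 P3", "P2 P3", "P4 P5"))
  expect_equal(nrow(ref$negatives), 4L)  # round(1 * 4)
})

test_that("negative sampling is seed-reproducible and seed-sensitive", {
  a <- build_reference(toy_complexes(), ratio = 1, seed = 7)
  b <- build_reference(toy_complexes(), ratio = 1, seed = 7)
  c <- build_reference(toy_complexes(), ratio = 0.5, seed = 8)
  expect_identical(a, b)
  expect_identical(a$positives, c$positives)
  expect_error(build_reference(toy_complexes(), ratio = 1), "seed")
})

test_that("negatives respect complex and localization exclusions", {
  cx <- rbind(toy_complexes(), data.frame(
    complex_id = "c3", protein_id = c("P1", "P6"), localization = "mito"))
  ref <- build_reference(cx, ratio = 1, seed = 3)
  neg_keys <- paste(ref$negatives[, 1], ref$negatives[, 2])
  pos_keys <- paste(ref$positives[, 1], ref$positives[, 2])
  expect_length(intersect(neg_keys, pos_keys), 0L)
  # P6's complex is mito-localized: no c1 member can be its negative partner
  banned <- paste(pmin(c("P1", "P2", "P3"), "P6"), pmax(c("P1", "P2", "P3"), "P6"))
  expect_length(intersect(neg_keys, banned), 0L)
  # the only eligible negatives pair {P4,P5} x {P1,P2,P3,P6}
  expect_true(all(grepl("P4|P5", neg_keys)))
})

test_that("over-requesting negatives and oversized complexes are handled", {
  expect_error(build_reference(toy_complexes(), ratio = 100, seed = 1),
               "eligible negative")
  cx <- rbind(toy_complexes(), data.frame(
    complex_id = "big", protein_id = sprintf("Q%02d", 1:41),
    localization = NA_character_))
  ref <- build_reference(cx, ratio = 1, seed = 2, max_subunits = 40)
  expect_equal(nrow(ref$positives), 4L)  # the 41-subunit complex is dropped
})

test_that("the hand-swept 4-pair curve gives AUC 0.75", {
  res <- evaluation_curve(list(pos = c(0.9, 0.7), neg = c(0.8, 0.1)),
                          list(positives = matrix("x", 1, 2),
                               negatives = matrix("y", 1, 2)))
  expect_equal(res$auc, 0.75)
  pts <- res$points
  expect_equal(pts$TP + pts$FN, rep(2L, nrow(pts)))
  expect_equal(pts$TN + pts$FP, rep(2L, nrow(pts)))
  expect_equal(pts$fpr[c(1, nrow(pts))], c(0, 1))
  expect_equal(pts$tpr[c(1, nrow(pts))], c(0, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  perfect <- evaluation_curve(list(pos = c(3, 2), neg = c(1, 0)),
                              list(positives = matrix("x", 1, 2),
                                   negatives = matrix("y", 1, 2)))
  expect_equal(perfect$auc, 1)
})

test_that("AUC equals the Mann-Whitney rank statistic without ties", {
  set.seed(5)
  for (rep in 1:25) {
    P <- sample(5:30, 1); N <- sample(5:30, 1)
    pos <- rnorm(P, mean = runif(1, 0, 2)); neg <- rnorm(N)
    res <- evaluation_curve(list(pos = pos, neg = neg),
                            list(positives = matrix("x", 1, 2),
                                 negatives = matrix("y", 1, 2)))
    W <- sum(outer(pos, neg, ">"))
    expect_equal(res$auc, W / (P * N), tolerance = 1e-9)
  }
})

test_that("label-free scores give a chance-level AUC", {
  set.seed(9)
  scores <- rnorm(400)
  res <- evaluation_curve(list(pos = scores[1:200], neg = scores[201:400]),
                          list(positives = matrix("x", 1, 2),
                               negatives = matrix("y", 1, 2)))
  expect_lt(abs(res$auc - 0.5), 0.1)  # ~3.5 SE of a null AUC at n=200
})

test_that("measure-matrix curves score distances by negation", {
  sim <- simulate_profiles(n_modules = 2, module_size = 4, n_background = 4,
                           m_species = 24, clade_block_sizes = c(12, 12),
                           flip_noise = 0.05, seed = 31)
  ref <- truth_to_reference(sim$truth, ratio = 1)$reference
  auc_sim <- evaluation_curve(pairwise_measure(sim$profile, "jaccard"), ref)$auc
  auc_dist <- evaluation_curve(pairwise_measure(sim$profile, "lp", p = 1), ref)$auc
  expect_gt(auc_sim, 0.5)
  expect_gt(auc_dist, 0.5)  # distance orientation flipped before sweeping
  expect_error(evaluation_curve(list(pos = numeric(), neg = numeric()),
                                list()), "no positives")
})

test_that("PPP curve points are monotone in T", {
  sim <- simulate_profiles(n_modules = 2, module_size = 4, n_background = 2,
                           m_species = 20, clade_block_sizes = c(10, 10),
                           flip_noise = 0.1, seed = 41)
  ref <- truth_to_reference(sim$truth, ratio = 1)$reference
  res <- ppp_curve(sim$profile, ref)
  expect_true(all(diff(res$points$tpr) >= 0))
  expect_true(all(diff(res$points$fpr) >= 0))
  expect_gte(res$auc, 0.5)
})

test_that("hit rate and gene-set coverage count set overlaps", {
  pred <- data.frame(protein_a = c("a", "a", "b"), protein_b = c("b", "c", "c"))
  class(pred) <- c("linkage_set", "data.frame")
  expect_equal(hit_rate(pred, rbind(c("a", "b"), c("c", "a"))), 1)
  expect_equal(hit_rate(pred, rbind(c("x", "y"))), 0)
  expect_equal(hit_rate(pred, rbind(c("b", "a"), c("a", "x"))), 0.5)
  expect_error(hit_rate(pred, matrix(character(), 0, 2)), "empty")

  sets <- list(s1 = rbind(c("a", "b"), c("b", "c")),
               s2 = rbind(c("a", "x"), c("c", "a")))
  cov <- geneset_coverage(pred, sets)
  expect_equal(cov$per_set$fraction, c(1, 0.5))
  expect_equal(cov$overall, 3 / 4)
})

test_that("AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  pos <- rnorm(40, 1); neg <- rnorm(60)
  ours <- evaluation_curve(list(pos = pos, neg = neg),
                           list(positives = matrix("x", 1, 2),
                                negatives = matrix("y", 1, 2)))$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})
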
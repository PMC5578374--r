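#' Build a labelled reference set from a protein-complex table
#'
#' Positives are all unordered pairs of proteins sharing a complex, pooled
#' over complexes (a size-k complex contributes k(k-1)/2 pairs).
#' Negatives are sampled uniformly without replacement, driven by `seed`,
#' from pairs (a, b) such that a and b share no complex, no complex of a
#' shares a subcellular-localization label with any complex of b, and the
#' pair is not a positive. The target count is `round(ratio * n_positives)`;
#' if fewer eligible pairs exist the call errors rather than silently
#' capping.
#'
#' @param complexes Data frame with columns `complex_id`, `protein_id` and
#'   optionally `localization` (per complex; `NA` imposes no constraint).
#' @param ratio Negatives per positive (default 10, the usual benchmark
#'   imbalance for complex-derived reference sets).
#' @param seed Integer seed for the negative sampler (required: negative
#'   sets must be reproducible).
#' @param max_subunits Drop complexes with more members than this before
#'   pairing (large complexes otherwise dominate the positives); `NULL`
#'   keeps all.
#' @return List of class `reference_set`: `positives` and `negatives`
#'   (2-column character matrices of canonically ordered pairs), `seed`,
#'   `ratio`.
#' @export
build_reference <- function(complexes, ratio = 10, seed, max_subunits = NULL) {
  stopifnot(is.data.frame(complexes), ratio > 0)
  if (missing(seed)) stop("a seed is required to sample negatives")
  cx <- data.frame(complex_id = as.character(complexes$complex_id),
                   protein_id = as.character(complexes$protein_id),
                   stringsAsFactors = FALSE)
  cx$localization <- if ("localization" %in% names(complexes)) {
    as.character(complexes$localization)
  } else NA_character_
  cx <- cx[!duplicated(cx[c("complex_id", "protein_id")]), , drop = FALSE]
  if (!is.null(max_subunits)) {
    sizes <- table(cx$complex_id)
    cx <- cx[cx$complex_id %in% names(sizes)[sizes <= max_subunits], , drop = FALSE]
  }
  members <- split(cx$protein_id, cx$complex_id)
  if (length(members) < 2L) stop("need at least 2 complexes")

  pos_list <- lapply(members, function(p) {
    p <- sort(unique(p))
    if (length(p) < 2L) return(NULL)
    t(utils::combn(p, 2L))
  })
  positives <- unique(do.call(rbind, pos_list))
  if (is.null(positives) || nrow(positives) == 0L) stop("no positive pairs")
  pos_keys <- pair_key(positives[, 1L], positives[, 2L])

  proteins <- sort(unique(cx$protein_id))
  cx_of <- split(cx$complex_id, cx$protein_id)
  loc_of_complex <- tapply(cx$localization, cx$complex_id,
                           function(l) unique(l[!is.na(l)]))
  loc_of <- lapply(cx_of, function(cids)
    unique(unlist(loc_of_complex[cids], use.names = FALSE)))

  all_pairs <- t(utils::combn(proteins, 2L))
  eligible <- vapply(seq_len(nrow(all_pairs)), function(r) {
    a <- all_pairs[r, 1L]; b <- all_pairs[r, 2L]
    if (length(intersect(cx_of[[a]], cx_of[[b]])) > 0L) return(FALSE)
    if (length(intersect(loc_of[[a]], loc_of[[b]])) > 0L) return(FALSE)
    TRUE
  }, logical(1L))
  candidates <- all_pairs[eligible &
                            !(pair_key(all_pairs[, 1L], all_pairs[, 2L]) %in% pos_keys),
                          , drop = FALSE]
  n_neg <- round(ratio * nrow(positives))
  if (nrow(candidates) < n_neg) {
    stop(sprintf("only %d eligible negative pairs for a request of %d (ratio %g)",
                 nrow(candidates), n_neg, ratio))
  }
  negatives <- with_seed(seed, {
    candidates[sample.int(nrow(candidates), n_neg), , drop = FALSE]
  })
  structure(list(positives = positives, negatives = negatives,
                 seed = seed, ratio = ratio),
            class = "reference_set")
}

# Similarity score per reference pair; pairs absent from the score matrix
# are assigned -Inf (scored as worst).
reference_scores <- function(scores, reference) {
  S <- as_similarity(scores)
  lookup <- function(pairs) {
    ok <- pairs[, 1L] %in% rownames(S) & pairs[, 2L] %in% rownames(S)
    out <- rep(-Inf, nrow(pairs))
    out[ok] <- S[pairs[ok, , drop = FALSE]]
    out[is.na(out)] <- -Inf
    out
  }
  list(pos = lookup(reference$positives), neg = lookup(reference$negatives))
}

#' Threshold-swept ROC and precision/recall curves
#'
#' Sweeps every distinct score of the reference pairs as a relaxed
#' threshold (ties flip together), computing at each threshold the
#' confusion counts over reference pairs only and deriving
#' FPR = 1 - TN/N, TPR = TP/P, precision = TP/(TP+FP) (undefined and
#' recorded as `NA` when nothing is predicted) and recall = TP/(TP+FN).
#' The AUC is the trapezoidal area under the achieved (FPR, TPR) points,
#' anchored at (0, 0) and (1, 1). Distance-oriented matrices (Lp, SVD,
#' Dollo) are negated before sweeping, so "relaxing" always means lowering
#' a similarity.
#'
#' @param scores A [measure_matrix()], or a precomputed list with numeric
#'   vectors `pos` and `neg` of per-pair similarity scores.
#' @param reference A [build_reference()] result.
#' @return List of class `curve_result`: `points` (data frame threshold,
#'   TP, FP, TN, FN, fpr, tpr, precision, recall) and `auc`.
#' @export
evaluation_curve <- function(scores, reference) {
  sc <- if (is.list(scores) && all(c("pos", "neg") %in% names(scores))) {
    scores
  } else {
    reference_scores(scores, reference)
  }
  P <- length(sc$pos); N <- length(sc$neg)
  if (P == 0L || N == 0L) stop("reference set has no positives or no negatives")
  labels <- c(rep(1L, P), rep(0L, N))
  s <- c(sc$pos, sc$neg)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; labels <- labels[ord]
  # threshold boundaries: after the last element of each tied score block
  block_end <- which(c(s[-1L] != s[-length(s)], TRUE))
  TP <- cumsum(labels)[block_end]
  FP <- block_end - TP
  points <- data.frame(
    threshold = s[block_end],
    TP = TP, FP = FP, TN = N - FP, FN = P - TP)
  # strictest sentinel: nothing predicted
  points <- rbind(data.frame(threshold = Inf, TP = 0L, FP = 0L, TN = N, FN = P),
                  points)
  points$fpr <- 1 - points$TN / N
  points$tpr <- points$TP / P
  points$precision <- ifelse(points$TP + points$FP > 0,
                             points$TP / (points$TP + points$FP), NA_real_)
  points$recall <- points$TP / (points$TP + points$FN)
  auc <- trapezoid_auc(points$fpr, points$tpr)
  structure(list(points = points, auc = auc), class = "curve_result")
}

trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord], 1)
  y <- c(0, tpr[ord], 1)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Top-rank sweep curve for PPP predictions
#'
#' Evaluates top-rank prediction against a reference set by sweeping the
#' threshold `T` from 1 to n-1. Because predicted link sets are nested in
#' `T`, the sweep is computed from a single prediction at the loosest
#' threshold: a pair is predicted at `T` when its best directed rank is at
#' most `T` (fallback links count at every `T`); reference pairs never
#' predicted score as worst.
#'
#' @param profile A [binary_profile()].
#' @param reference A [build_reference()] result.
#' @param rank_convention Passed to [ppp_predict()].
#' @return A `curve_result` (thresholds are `-T`, i.e. similarity
#'   orientation).
#' @export
ppp_curve <- function(profile, reference, rank_convention = "le") {
  n <- nrow(profile)
  links <- ppp_predict(profile, T = n - 1L, rank_convention = rank_convention)
  eff_rank <- ifelse(links$fallback, 1L, links$best_rank)
  sim <- stats::setNames(-as.numeric(eff_rank),
                         pair_key(links$protein_a, links$protein_b))
  lookup <- function(pairs) {
    v <- sim[pair_key(pairs[, 1L], pairs[, 2L])]
    v[is.na(v)] <- -Inf
    unname(v)
  }
  evaluation_curve(list(pos = lookup(reference$positives),
                        neg = lookup(reference$negatives)),
                   reference)
}

#' Hit rate of predicted linkages against an external pair list
#'
#' Fraction of an externally derived co-evolving pair list (e.g. from a
#' common-submatrix method) recovered among the predicted links:
#' `N_top / N_MMM`.
#'
#' @param predicted A `linkage_set` or 2-column pair matrix/data frame.
#' @param pairs 2-column matrix/data frame of unordered reference pairs.
#' @return Fraction in \[0, 1\].
#' @export
hit_rate <- function(predicted, pairs) {
  ref <- as_pair_keys(pairs)
  if (length(ref) == 0L) stop("reference pair list is empty")
  mean(ref %in% as_pair_keys(predicted))
}

#' Predicted coverage of gene-set edge lists
#'
#' For each named edge set, the fraction of its edges present among the
#' predicted links, plus the pooled overall fraction.
#'
#' @param predicted A `linkage_set` or 2-column pair matrix/data frame.
#' @param genesets Named list of 2-column pair matrices/data frames.
#' @return List with `per_set` (data frame set, n_edges, n_predicted,
#'   fraction) and `overall`.
#' @export
geneset_coverage <- function(predicted, genesets) {
  stopifnot(length(genesets) > 0L, !is.null(names(genesets)))
  pred <- as_pair_keys(predicted)
  per <- lapply(names(genesets), function(nm) {
    keys <- as_pair_keys(genesets[[nm]])
    data.frame(set = nm, n_edges = length(keys),
               n_predicted = sum(keys %in% pred),
               fraction = mean(keys %in% pred),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_set = per,
       overall = sum(per$n_predicted) / sum(per$n_edges))
}

as_pair_keys <- function(x) {
  if (inherits(x, "linkage_set")) {
    unique(pair_key(x$protein_a, x$protein_b))
  } else {
    x <- as.matrix(x)
    unique(pair_key(x[, 1L], x[, 2L]))
  }
}
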
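#' Co-occurrence measures on binary profile vectors
#'
#' Pairwise similarity and distance measures on presence/absence vectors
#' \eqn{X, Y \in \{0,1\}^n}:
#'
#' * `jaccard_similarity`: \eqn{|\{i : x_i = 1 \wedge y_i = 1\}| /
#'   |\{i : x_i = 1 \vee y_i = 1\}|}; defined as 0 when both vectors are
#'   all-zero (absent proteins share no evidence of co-evolution).
#' * `profile_pearson`: the sample Pearson correlation coefficient
#'   (\eqn{n-1} denominator). When either vector is constant the
#'   correlation is undefined and `NA` is returned; every consumer in this
#'   package treats that flag as "fails cor > 0".
#' * `mutual_information`: \eqn{\sum_x \sum_y p(x,y)\log_2 p(x,y)/(p(x)p(y))}
#'   over symbols \{0,1\} with empirical (frequency) probabilities and the
#'   convention \eqn{0 \log 0 = 0}. Reported in bits.
#' * `lp_distance`: \eqn{(\sum_i |x_i - y_i|^p)^{1/p}}; `p = 1` is the
#'   Hamming distance, `p = 2` the Euclidean distance.
#'
#' @param x,y Numeric 0/1 vectors of equal length.
#' @param p Norm order, `p >= 1`.
#' @return A single numeric value.
#' @examples
#' jaccard_similarity(c(1, 1, 0, 1), c(1, 0, 0, 1))  # 2/3
#' mutual_information(c(1, 1, 0, 0), c(0, 0, 1, 1))  # 1 bit
#' lp_distance(c(1, 1, 0, 0), c(0, 0, 1, 1), p = 2)  # 2
#' @name measures
NULL

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("profile vectors differ in length")
  if (length(x) < 1L) stop("profile vectors must be non-empty")
  invisible(TRUE)
}

#' @rdname measures
#' @export
jaccard_similarity <- function(x, y) {
  check_pair(x, y)
  union <- sum(x == 1 | y == 1)
  if (union == 0L) return(0)
  sum(x == 1 & y == 1) / union
}

#' @rdname measures
#' @export
profile_pearson <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  if (n < 2L) stop("Pearson correlation needs n >= 2")
  rx <- sum(x); ry <- sum(y)
  if (rx %in% c(0, n) || ry %in% c(0, n)) return(NA_real_)
  # on 0/1 data the sample correlation reduces to the phi coefficient;
  # the integer numerator keeps the sign of exact zeros exact, which the
  # strict cor > 0 prediction filter depends on
  num <- n * sum(x == 1 & y == 1) - rx * ry
  num / (sqrt(rx * (n - rx)) * sqrt(ry * (n - ry)))
}

#' @rdname measures
#' @export
mutual_information <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  # joint symbol counts over {0,1} x {0,1}
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- n - n11 - n10 - n01
  joint <- c(n00, n01, n10, n11) / n
  px <- c((n00 + n01) / n, (n10 + n11) / n)[c(1L, 1L, 2L, 2L)]
  py <- c((n00 + n10) / n, (n01 + n11) / n)[c(1L, 2L, 1L, 2L)]
  terms <- ifelse(joint > 0, joint * log2(joint / (px * py)), 0)
  max(sum(terms), 0)  # clamp away -0 from floating rounding
}

#' @rdname measures
#' @export
lp_distance <- function(x, y, p = 1) {
  check_pair(x, y)
  stopifnot(is.numeric(p), length(p) == 1L)
  if (p < 1) stop("lp_distance requires p >= 1")
  sum(abs(x - y)^p)^(1 / p)
}

#' Pairwise measure matrix over a binary profile
#'
#' Scores every unordered protein pair of a presence/absence profile with
#' one co-occurrence measure, returning a symmetric n x n matrix. The
#' computation is closed-form on pair count statistics (intersection,
#' row sums), so it scales to whole-proteome profiles without looping over
#' pairs.
#'
#' @param profile A [binary_profile()].
#' @param measure One of `"jaccard"`, `"pearson"`, `"mi"`, `"lp"`.
#' @param p Norm order when `measure = "lp"`.
#' @return A numeric matrix of class `measure_matrix` with attributes
#'   `measure` and `orientation` (`"similarity"` or `"distance"`).
#' @export
pairwise_measure <- function(profile, measure = c("jaccard", "pearson", "mi", "lp"),
                             p = 1) {
  measure <- match.arg(measure)
  X <- unclass(profile)
  if (nrow(X) < 2L) stop("pairwise scoring needs at least 2 proteins")
  m <- ncol(X)
  n11 <- tcrossprod(X)              # co-presence counts
  r <- rowSums(X)
  values <- switch(measure,
    jaccard = {
      union <- outer(r, r, "+") - n11
      out <- ifelse(union > 0, n11 / union, 0)
      out
    },
    pearson = {
      num <- m * n11 - outer(r, r)        # integer-exact phi numerator
      spread <- sqrt(r * (m - r))
      spread[spread == 0] <- NA_real_     # constant rows: undefined flag
      num / outer(spread, spread)
    },
    mi = {
      n10 <- outer(r, rep(0, length(r)), "+") - n11   # present in x only
      n01 <- t(n10)
      n00 <- m - n11 - n10 - n01
      px1 <- r / m
      mi_term <- function(nxy, pxv, pyv) {
        pj <- nxy / m
        ifelse(pj > 0, pj * log2(pj / (pxv * pyv)), 0)
      }
      PX1 <- outer(px1, rep(1, length(r)))
      PY1 <- t(PX1)
      out <- mi_term(n00, 1 - PX1, 1 - PY1) + mi_term(n01, 1 - PX1, PY1) +
        mi_term(n10, PX1, 1 - PY1) + mi_term(n11, PX1, PY1)
      pmax(out, 0)
    },
    lp = {
      mismatch <- outer(r, r, "+") - 2 * n11  # |x-y| is 0/1 on binary data
      mismatch^(1 / p)
    })
  dimnames(values) <- list(rownames(X), rownames(X))
  orientation <- if (measure == "lp") "distance" else "similarity"
  name <- if (measure == "lp") sprintf("lp(%g)", p) else measure
  measure_matrix(values, measure = name, orientation = orientation)
}

#' Measure matrix container
#'
#' A symmetric numeric matrix of pairwise scores with its measure name and
#' orientation. Distances are negated by consumers that need a similarity
#' ordering (larger = stronger link).
#'
#' @param values Symmetric numeric matrix with matching dimnames.
#' @param measure Measure name.
#' @param orientation `"similarity"` or `"distance"`.
#' @export
measure_matrix <- function(values, measure,
                           orientation = c("similarity", "distance")) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            identical(rownames(values), colnames(values)))
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-12) {
    stop("measure matrix is not symmetric (max asymmetry ", asym, ")")
  }
  structure(values, class = c("measure_matrix", class(matrix())),
            measure = measure, orientation = orientation)
}

# Similarity-oriented copy: distances (and Dollo distances) are negated so
# that larger always means a stronger predicted link.
as_similarity <- function(scores) {
  if (identical(attr(scores, "orientation"), "distance")) {
    out <- -unclass(scores)
    dimnames(out) <- dimnames(scores)
    out
  } else {
    unclass(scores)
  }
}

#' Write pairwise scores as long-form TSV
#'
#' @param scores A `measure_matrix`.
#' @param path Output file.
#' @export
write_pairs <- function(scores, path) {
  ids <- rownames(scores)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  df <- data.frame(protein_a = ids[idx[, 1L]], protein_b = ids[idx[, 2L]],
                   score = scores[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
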
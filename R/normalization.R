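#' NPP normalization of a bit-score profile
#'
#' Normalized phylogenetic profile (NPP) transform of a bit-score matrix
#' `P` (n proteins x m species):
#'
#' 1. Every bit score strictly below `score_floor` is replaced by 1.
#' 2. Proteins whose number of species with a raw bit score at or above
#'    `score_floor` is below `min_homologs` are dropped as poorly conserved.
#' 3. Each remaining entry becomes \eqn{\log_2(p_{ij}/p_{\max i})}, where
#'    \eqn{p_{\max i}} is the row maximum after step 1.
#' 4. Each species column is z-scored (\eqn{(p_{ij}-\mu_j)/\sigma_j},
#'    sample standard deviation). Columns with zero spread are set to 0 and
#'    recorded in the `degenerate_columns` attribute.
#'
#' Homolog counting in step 2 uses the raw scores, before the floor
#' replacement, so the sentinel value 1 can never be mistaken for a real
#' bit score.
#'
#' @param bits A [bitscore_profile()] with at least 2 proteins and species.
#' @param score_floor Bit-score floor; entries below it are treated as
#'   noise (default 70).
#' @param min_homologs Minimum number of species with a qualifying score
#'   for a protein to be retained (default 12).
#' @return A `normalized_profile` (method `"npp"`): numeric matrix of the
#'   retained proteins x all species, with attributes `method`,
#'   `dropped_proteins` (data frame protein/reason) and
#'   `degenerate_columns`.
#' @export
npp_transform <- function(bits, score_floor = 70, min_homologs = 12) {
  P <- unclass(bits)
  if (nrow(P) < 2L || ncol(P) < 2L) stop("NPP needs at least a 2 x 2 profile")
  conserved <- rowSums(P >= score_floor) >= min_homologs
  dropped <- data.frame(protein = rownames(P)[!conserved],
                        reason = rep("poor conservation", sum(!conserved)),
                        stringsAsFactors = FALSE)
  if (!any(conserved)) {
    stop(sprintf("all proteins dropped by the conservation filter (floor %g, min_homologs %d)",
                 score_floor, min_homologs))
  }
  P[P < score_floor] <- 1
  P <- P[conserved, , drop = FALSE]
  P <- log2(P / apply(P, 1L, max))
  mu <- colMeans(P)
  sdv <- apply(P, 2L, stats::sd)
  degenerate <- colnames(P)[sdv == 0]
  sdv[sdv == 0] <- Inf  # degenerate columns carry no signal; zero them
  P <- sweep(sweep(P, 2L, mu, "-"), 2L, sdv, "/")
  if (length(degenerate) > 0L) {
    warning(length(degenerate), " species column(s) with zero spread set to 0")
  }
  normalized_profile(P, method = "npp", dropped_proteins = dropped,
                     degenerate_columns = degenerate)
}

#' SVD normalization of a bit-score profile
#'
#' Truncated singular value decomposition transform of a bit-score matrix:
#'
#' 1. Every bit score strictly below `score_floor` is set to 0; all-zero
#'    rows are dropped (they cannot be row-scaled).
#' 2. Each row is scaled by its maximum (\eqn{p_{ij}/p_{\max i}}).
#' 3. The scaled matrix is factored as \eqn{P = U \Sigma V'}, singular
#'    values in decreasing order.
#' 4. The first `ceiling(trim_fraction * m)` columns of `U` are retained
#'    (capped at the matrix rank bound, `min(n, m)`).
#' 5. Poorly conserved proteins (fewer than `min_homologs` species with a
#'    raw score at or above `score_floor`) are dropped.
#' 6. Every retained row is scaled to unit Euclidean norm, so pairwise
#'    Euclidean distances between proteins lie in \[0, 2\].
#'
#' @param bits A [bitscore_profile()].
#' @param score_floor Bit-score floor (default 60).
#' @param trim_fraction Fraction of singular dimensions to keep, in (0, 1].
#'   Common settings are 1 (all) and 0.3 (top 30 percent).
#' @param min_homologs Conservation filter threshold (default 12).
#' @return A `normalized_profile` (method `"svd"`) whose columns are
#'   singular dimensions `sv1`, `sv2`, ...
#' @export
svd_transform <- function(bits, score_floor = 60, trim_fraction = 0.3,
                          min_homologs = 12) {
  P <- unclass(bits)
  if (nrow(P) < 2L || ncol(P) < 2L) stop("SVD needs at least a 2 x 2 profile")
  if (!is.numeric(trim_fraction) || trim_fraction <= 0 || trim_fraction > 1) {
    stop("trim_fraction must lie in (0, 1]")
  }
  raw <- P
  P[P < score_floor] <- 0
  nonzero <- rowSums(P) > 0
  conserved <- rowSums(raw >= score_floor) >= min_homologs
  dropped <- data.frame(
    protein = rownames(P)[!(nonzero & conserved)],
    reason = ifelse(!nonzero[!(nonzero & conserved)], "all scores below floor",
                    "poor conservation"),
    stringsAsFactors = FALSE)
  P <- P[nonzero, , drop = FALSE]
  if (nrow(P) == 0L) stop("degenerate profile: every bit score is below the floor")
  P <- P / apply(P, 1L, max)
  fac <- svd(P)
  k <- min(ceiling(trim_fraction * ncol(raw)), length(fac$d))
  U <- fac$u[, seq_len(k), drop = FALSE]
  rownames(U) <- rownames(P)
  colnames(U) <- paste0("sv", seq_len(k))
  keep <- conserved[rownames(U)]
  if (!any(keep)) {
    stop(sprintf("all proteins dropped by the conservation filter (floor %g, min_homologs %d)",
                 score_floor, min_homologs))
  }
  U <- U[keep, , drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  U <- U / norms
  normalized_profile(U, method = "svd", dropped_proteins = dropped,
                     degenerate_columns = character(),
                     factorization = fac, scaled_input = P)
}

normalized_profile <- function(values, method, dropped_proteins,
                               degenerate_columns = character(), ...) {
  structure(values, class = c("normalized_profile", class(matrix())),
            method = method, dropped_proteins = dropped_proteins,
            degenerate_columns = degenerate_columns, ...)
}

#' Score a normalized profile
#'
#' `npp_score` computes pairwise Pearson correlations between the rows of an
#' NPP-normalized profile (similarity orientation); `svd_score` computes
#' pairwise Euclidean distances between the unit-norm rows of an
#' SVD-normalized profile (distance orientation).
#'
#' @param norm A `normalized_profile` of the matching method.
#' @return A [measure_matrix()].
#' @export
npp_score <- function(norm) {
  if (!identical(attr(norm, "method"), "npp")) {
    stop("npp_score expects an NPP-normalized profile")
  }
  values <- suppressWarnings(stats::cor(t(unclass(norm))))
  measure_matrix(values, measure = "npp", orientation = "similarity")
}

#' @rdname npp_score
#' @export
svd_score <- function(norm) {
  if (!identical(attr(norm, "method"), "svd")) {
    stop("svd_score expects an SVD-normalized profile")
  }
  values <- as.matrix(stats::dist(unclass(norm)))
  measure_matrix(values, measure = "svd", orientation = "distance")
}

#' Write a normalized profile with a parameter sidecar
#'
#' Serializes the matrix as TSV (same layout as profiles) and a JSON
#' sidecar (`<path>.json`) recording the method, dropped proteins and any
#' degenerate columns.
#'
#' @param norm A `normalized_profile`.
#' @param path Output TSV path.
#' @export
write_normalized <- function(norm, path) {
  df <- data.frame(protein_id = rownames(norm), unclass(norm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(method = attr(norm, "method"),
               dropped_proteins = attr(norm, "dropped_proteins"),
               degenerate_columns = attr(norm, "degenerate_columns"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
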
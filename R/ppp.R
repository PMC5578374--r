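#' Rank linkage candidates for one query protein
#'
#' The per-protein candidate ordering behind top-rank linkage prediction:
#' all other proteins with strictly positive Pearson correlation to the
#' query (an undefined correlation from a constant profile counts as not
#' positive), ordered by decreasing Jaccard similarity, ties broken by
#' decreasing Pearson correlation and then lexicographic identifier so the
#' ordering is total and deterministic. Ranks are 1-based over this
#' filtered list.
#'
#' @param profile A [binary_profile()] with at least 2 proteins.
#' @param query Protein identifier present in the profile.
#' @return Data frame `candidate`, `jaccard`, `pearson`, `rank`, possibly
#'   empty when no candidate has positive correlation.
#' @export
ppp_rank <- function(profile, query) {
  if (!query %in% rownames(profile)) stop("query protein not in profile: ", query)
  J <- pairwise_measure(profile, "jaccard")
  C <- pairwise_measure(profile, "pearson")
  rank_one(rownames(profile), unclass(J), unclass(C), match(query, rownames(profile)))
}

rank_one <- function(ids, J, C, i) {
  j <- setdiff(seq_along(ids), i)
  cor_i <- C[i, j]
  keep <- !is.na(cor_i) & cor_i > 0
  j <- j[keep]
  ord <- order(-J[i, j], -C[i, j], ids[j], method = "radix")
  j <- j[ord]
  data.frame(candidate = ids[j], jaccard = J[i, j], pearson = C[i, j],
             rank = seq_along(j), row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict whole-proteome linkages by top-rank selection
#'
#' For every protein, candidates are filtered to strictly positive Pearson
#' correlation, ranked by decreasing Jaccard similarity (ties: decreasing
#' Pearson, then identifier), and the top `T` are selected. A protein whose
#' filtered list is empty still receives its single highest-Jaccard partner
#' regardless of correlation sign, flagged `fallback`, so no protein is
#' left solo at any threshold. Directed selections are then symmetrized:
#' each unordered pair appears once, carrying the minimum of its two
#' directed ranks.
#'
#' @param profile A [binary_profile()] with `n >= 2` proteins.
#' @param T Top-rank threshold, `1 <= T <= n - 1`.
#' @param rank_convention `"le"` (default) selects candidates with
#'   `rank <= T`, so `T` means "the top T partners"; `"lt"` selects
#'   `rank < T` strictly.
#' @return Data frame of class `linkage_set` with columns `protein_a`,
#'   `protein_b` (canonically ordered), `jaccard`, `pearson`, `best_rank`
#'   (`NA` for pure fallback links), `fallback`; attributes `T` and
#'   `rank_convention`.
#' @examples
#' prof <- binary_profile(matrix(
#'   c(1,1,1,1,0,0, 1,1,1,0,0,0, 0,0,1,1,1,1, 0,0,0,1,1,1),
#'   nrow = 4, byrow = TRUE,
#'   dimnames = list(c("A","B","C","D"), paste0("s", 1:6))))
#' ppp_predict(prof, T = 1)[, c("protein_a", "protein_b")]  # A-B and C-D
#' @export
ppp_predict <- function(profile, T, rank_convention = c("le", "lt")) {
  rank_convention <- match.arg(rank_convention)
  ids <- rownames(profile)
  n <- length(ids)
  if (n < 2L) stop("prediction needs at least 2 proteins")
  if (!is.numeric(T) || length(T) != 1L || T < 1 || T > n - 1L) {
    stop("T must lie in [1, n-1]")
  }
  J <- unclass(pairwise_measure(profile, "jaccard"))
  C <- unclass(pairwise_measure(profile, "pearson"))

  sel_a <- character(); sel_b <- character()
  sel_rank <- integer(); sel_fb <- logical()
  for (i in seq_len(n)) {
    cand <- rank_one(ids, J, C, i)
    picked <- if (rank_convention == "le") {
      cand[cand$rank <= T, , drop = FALSE]
    } else {
      cand[cand$rank < T, , drop = FALSE]
    }
    if (nrow(picked) > 0L) {
      sel_a <- c(sel_a, rep(ids[i], nrow(picked)))
      sel_b <- c(sel_b, picked$candidate)
      sel_rank <- c(sel_rank, picked$rank)
      sel_fb <- c(sel_fb, rep(FALSE, nrow(picked)))
    } else {
      # no positively correlated partner survives: keep the best-Jaccard
      # partner anyway so the protein is never solo
      j <- setdiff(seq_len(n), i)
      cor_key <- ifelse(is.na(C[i, j]), -Inf, C[i, j])
      best <- j[order(-J[i, j], -cor_key, ids[j], method = "radix")][1L]
      sel_a <- c(sel_a, ids[i]); sel_b <- c(sel_b, ids[best])
      sel_rank <- c(sel_rank, NA_integer_); sel_fb <- c(sel_fb, TRUE)
    }
  }

  key <- pair_key(sel_a, sel_b)
  agg_rank <- tapply(sel_rank, key, function(r)
    if (all(is.na(r))) NA_integer_ else min(r, na.rm = TRUE))
  agg_fb <- tapply(sel_fb, key, all)  # fallback only if never selected by rank
  first <- !duplicated(key)
  pa <- pmin(sel_a, sel_b)[first]; pb <- pmax(sel_a, sel_b)[first]
  k <- key[first]
  out <- data.frame(protein_a = pa, protein_b = pb,
                    jaccard = J[cbind(pa, pb)], pearson = C[cbind(pa, pb)],
                    best_rank = as.integer(agg_rank[k]),
                    fallback = as.logical(agg_fb[k]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$jaccard, out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("linkage_set", "data.frame"),
            T = T, rank_convention = rank_convention)
}

#' Write predicted linkages as TSV
#'
#' Columns: from, to, jaccard, cor, rank, fallback — jaccard sorted in
#' decreasing order.
#'
#' @param links A `linkage_set` from [ppp_predict()].
#' @param path Output file.
#' @export
write_linkages <- function(links, path) {
  df <- data.frame(from = links$protein_a, to = links$protein_b,
                   jaccard = links$jaccard, cor = links$pearson,
                   rank = links$best_rank, fallback = links$fallback)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
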
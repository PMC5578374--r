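# Independent literal-formula oracles. These deliberately re-derive every
# quantity from its printed definition with plain loops, so they share no
# code path with the package implementations they check.

oracle_jaccard <- function(x, y) {
  inter <- sum(x == 1 & y == 1)
  uni <- sum(x == 1 | y == 1)
  if (uni == 0) 0 else inter / uni
}

# Eq.-style sample correlation with the deviation products cleared of
# rounding: multiplying each deviation by n makes every term an integer
# on 0/1 data, so an exactly-zero correlation keeps its sign.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  if (sx == 0 || sy == 0) return(NA_real_)
  num <- sum((n * x - sum(x)) * (n * y - sum(y))) / n^2
  num / ((n - 1) * sx * sy)
}

oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in c(0, 1)) for (b in c(0, 1)) {
    pab <- sum(x == a & y == b) / n
    pa <- sum(x == a) / n
    pb <- sum(y == b) / n
    if (pab > 0) total <- total + pab * log2(pab / (pa * pb))
  }
  total
}

oracle_lp <- function(x, y, p) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i])^p
  s^(1 / p)
}

# Exhaustive minimum-loss Dollo search: enumerate every internal-state
# assignment consistent with the tips, keep those with at most one gain
# (a root in state 1 counts as the gain), and return the loss minimum and
# all assignments achieving it.
brute_dollo <- function(tree, tip_state) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  internal <- (n_tip + 1):n_node
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), length(internal))))
  best_loss <- Inf
  best <- list()
  for (g in seq_len(nrow(grid))) {
    state <- integer(n_node)
    state[seq_len(n_tip)] <- tip_state
    state[internal] <- grid[g, ]
    pa <- state[tree$edge[, 1]]
    ch <- state[tree$edge[, 2]]
    gains <- sum(pa == 0 & ch == 1) + (state[root] == 1)
    if (gains > 1) next
    if (gains == 0 && any(state == 1)) next
    losses <- sum(pa == 1 & ch == 0)
    if (losses < best_loss) {
      best_loss <- losses
      best <- list(state)
    } else if (losses == best_loss) {
      best <- c(best, list(state))
    }
  }
  list(min_loss = best_loss, states = best)
}

# Independent top-rank predictor: literal filter / sort / truncate / union.
brute_ppp <- function(X, T, convention = "le") {
  ids <- rownames(X)
  n <- nrow(X)
  links <- character()
  for (i in seq_len(n)) {
    jac <- cor <- numeric(0)
    cand <- character(0)
    for (j in seq_len(n)[-i]) {
      cand <- c(cand, ids[j])
      jac <- c(jac, oracle_jaccard(X[i, ], X[j, ]))
      cor <- c(cor, oracle_pearson(X[i, ], X[j, ]))
    }
    keep <- !is.na(cor) & cor > 0
    f_cand <- cand[keep]; f_jac <- jac[keep]; f_cor <- cor[keep]
    ord <- order(-f_jac, -f_cor, f_cand, method = "radix")
    ranked <- f_cand[ord]
    picked <- if (convention == "le") {
      utils::head(ranked, T)
    } else {
      utils::head(ranked, max(T - 1, 0))
    }
    if (length(picked) == 0) {
      cor_key <- ifelse(is.na(cor), -Inf, cor)
      picked <- cand[order(-jac, -cor_key, cand, method = "radix")][1]
    }
    links <- c(links, paste(pmin(ids[i], picked), pmax(ids[i], picked), sep = "|"))
  }
  sort(unique(links))
}

link_keys <- function(links) {
  sort(paste(links$protein_a, links$protein_b, sep = "|"))
}

random_profile <- function(n, m) {
  repeat {
    X <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m,
                dimnames = list(sprintf("p%02d", seq_len(n)),
                                sprintf("s%02d", seq_len(m))))
    if (all(rowSums(X) > 0)) return(binary_profile(X))
  }
}
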
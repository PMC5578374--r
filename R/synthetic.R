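#' Simulate a binary profile with planted co-evolving modules
#'
#' Generates a presence/absence profile whose rows fall into co-evolving
#' modules plus unstructured background. Species are partitioned into
#' clade blocks; each module draws one clade-structured base pattern (per
#' clade, a high or low presence probability is chosen, then species
#' entries are Bernoulli draws at that rate), so base patterns look like
#' real profiles: runs of presence within clades rather than i.i.d. noise.
#' Module members copy their base pattern with independent per-entry flips
#' at rate `flip_noise`; background proteins draw independent
#' clade-structured patterns of their own. Base patterns are guaranteed
#' pairwise distinct. All randomness flows from `seed`.
#'
#' @param n_modules Number of planted modules (default 3).
#' @param module_size Proteins per module (default 6, >= 2).
#' @param n_background Background proteins outside any module (default 6).
#' @param m_species Number of species (default 60).
#' @param clade_block_sizes Integer vector partitioning the species into
#'   clades (default six equal blocks).
#' @param presence_prob Length-2 numeric: presence probability of a
#'   species in a clade the pattern occupies vs one it does not (default
#'   c(0.95, 0.05)).
#' @param flip_noise Per-entry symmetric flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return List: `profile` (a [binary_profile()]) and `truth` (class
#'   `synthetic_truth`: `module` assignment protein -> module id or `NA`,
#'   `base_patterns`, `clade` species -> clade id, and all parameters).
#' @export
simulate_profiles <- function(n_modules = 3, module_size = 6, n_background = 6,
                              m_species = 60,
                              clade_block_sizes = NULL,
                              presence_prob = c(0.95, 0.05),
                              flip_noise = 0.1, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_modules >= 1, module_size >= 2, n_background >= 0, m_species >= 2,
            flip_noise >= 0, flip_noise < 0.5,
            length(presence_prob) == 2L, all(presence_prob > 0),
            all(presence_prob < 1), presence_prob[1L] > presence_prob[2L])
  if (is.null(clade_block_sizes)) {
    n_blocks <- min(6L, m_species)
    clade_block_sizes <- diff(round(seq(0, m_species, length.out = n_blocks + 1L)))
  }
  if (sum(clade_block_sizes) != m_species || any(clade_block_sizes < 1)) {
    stop("clade_block_sizes must be positive and sum to m_species")
  }
  species <- sprintf("s%03d", seq_len(m_species))
  clade <- rep(seq_along(clade_block_sizes), clade_block_sizes)
  names(clade) <- species

  with_seed(seed, {
    draw_pattern <- function() {
      # choose occupied clades, then Bernoulli presence per species
      occupied <- stats::rbinom(length(clade_block_sizes), 1L, 0.5)
      p <- presence_prob[2L - occupied[clade]]
      stats::rbinom(m_species, 1L, p)
    }
    base <- matrix(0L, nrow = n_modules, ncol = m_species)
    for (k in seq_len(n_modules)) {
      repeat {
        cand <- draw_pattern()
        distinct <- k == 1L ||
          !any(apply(base[seq_len(k - 1L), , drop = FALSE], 1L,
                     function(b) all(b == cand)))
        if (distinct && sum(cand) > 0L) break
      }
      base[k, ] <- cand
    }
    proteins <- c(sprintf("M%d_p%d", rep(seq_len(n_modules), each = module_size),
                          rep(seq_len(module_size), n_modules)),
                  if (n_background > 0L) sprintf("bg_p%d", seq_len(n_background)))
    module <- c(rep(seq_len(n_modules), each = module_size),
                rep(NA_integer_, n_background))
    names(module) <- proteins
    values <- matrix(0L, nrow = length(proteins), ncol = m_species,
                     dimnames = list(proteins, species))
    for (i in seq_along(proteins)) {
      row <- if (is.na(module[i])) draw_pattern() else base[module[i], ]
      if (flip_noise > 0) {
        flips <- stats::rbinom(m_species, 1L, flip_noise)
        row <- (row + flips) %% 2L
      }
      values[i, ] <- row
    }
    truth <- structure(
      list(module = module, base_patterns = base, clade = clade,
           flip_noise = flip_noise, presence_prob = presence_prob,
           seed = seed),
      class = "synthetic_truth")
    list(profile = binary_profile(values), truth = truth)
  })
}

#' Simulate bit scores conditional on a presence/absence profile
#'
#' Absent entries score 0; present entries draw from a normal distribution
#' truncated below at `floor` (inverse-CDF sampling), so the bit-score
#' floors of the NPP/SVD normalizations are exercised on realistic values.
#'
#' @param profile A [binary_profile()].
#' @param present_mean,present_sd Mean and SD of the present-score
#'   distribution (defaults 150 and 40, spanning typical BLAST bit scores
#'   on both sides of the 60/70 normalization floors).
#' @param floor Lower truncation bound (default 25, the practical minimum
#'   of a reported BLAST bit score).
#' @param seed Integer seed.
#' @return A [bitscore_profile()] of the same shape.
#' @export
simulate_bitscores <- function(profile, present_mean = 150, present_sd = 40,
                               floor = 25, seed) {
  if (missing(seed)) stop("a seed is required")
  if (present_mean <= 0) stop("present_mean must be positive")
  X <- unclass(profile)
  with_seed(seed, {
    idx <- which(X == 1)
    lo <- stats::pnorm(floor, present_mean, present_sd)
    u <- stats::runif(length(idx), min = lo, max = 1)
    scores <- stats::qnorm(u, present_mean, present_sd)
    V <- matrix(0, nrow = nrow(X), ncol = ncol(X), dimnames = dimnames(X))
    V[idx] <- scores
    bitscore_profile(V, taxon_group = attr(profile, "taxon_group"))
  })
}

#' Simulate a rooted species tree with monophyletic clades
#'
#' Builds a random rooted bifurcating tree over the given species by
#' random sequential coalescence, joining within each clade block first so
#' every clade is monophyletic, then joining the clade subtrees. Unit
#' branch lengths.
#'
#' @param species Character vector of leaf labels.
#' @param clade Optional named integer/character vector (species -> clade
#'   id, e.g. `truth$clade`); `NULL` treats all species as one pool.
#' @param seed Integer seed.
#' @return An ape `phylo` tree.
#' @export
simulate_tree <- function(species, clade = NULL, seed) {
  if (missing(seed)) stop("a seed is required")
  if (length(species) < 2L) stop("need at least 2 species")
  with_seed(seed, {
    coalesce <- function(parts) {
      while (length(parts) > 1L) {
        pick <- sample.int(length(parts), 2L)
        merged <- sprintf("(%s:1,%s:1)", parts[pick[1L]], parts[pick[2L]])
        parts <- c(parts[-pick], merged)
      }
      parts
    }
    parts <- if (is.null(clade)) {
      species
    } else {
      vapply(split(species, clade[species]), coalesce, "")
    }
    newick <- paste0(coalesce(parts), ";")
    read_species_tree(newick)
  })
}

#' Reference set and complex table from planted simulation truth
#'
#' Maps each planted module to a protein complex (localization label =
#' module id) and builds a labelled reference set via [build_reference()],
#' so predictions on the simulated profile can be scored against ground
#' truth. Background proteins belong to no complex and are eligible as
#' negative partners.
#'
#' @param truth A `synthetic_truth` from [simulate_profiles()].
#' @param ratio Negatives per positive (default 2; the planted-module
#'   cross-pair pool is far smaller than a proteome-scale negative space).
#' @param seed Integer seed for negative sampling (default: the truth's
#'   own seed).
#' @return List: `reference` (a `reference_set`) and `complexes` (the
#'   complex table data frame).
#' @export
truth_to_reference <- function(truth, ratio = 2, seed = truth$seed) {
  mod <- truth$module[!is.na(truth$module)]
  complexes <- data.frame(
    complex_id = paste0("module", mod),
    protein_id = names(mod),
    localization = paste0("module", mod),
    stringsAsFactors = FALSE)
  # build_reference draws negative candidates from table proteins only, so
  # background proteins enter as singleton complexes (no pairs, no
  # localization constraint)
  bg <- names(truth$module)[is.na(truth$module)]
  if (length(bg) > 0L) {
    complexes <- rbind(complexes, data.frame(
      complex_id = paste0("bg_", bg), protein_id = bg,
      localization = NA_character_, stringsAsFactors = FALSE))
  }
  list(reference = build_reference(complexes, ratio = ratio, seed = seed),
       complexes = complexes)
}
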
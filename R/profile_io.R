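#' Parse tabular homology search results
#'
#' Reads BLAST tabular output (`-outfmt 6`: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) and
#' resolves each subject sequence to a species through `species_map`. Hits
#' whose subject cannot be resolved are dropped and counted, not fatal:
#' proteome databases routinely contain entries absent from the taxon map.
#'
#' @param input Path to a tab-separated file, or a character vector of lines.
#' @param species_map Named character vector mapping subject identifiers (or
#'   their prefix before the first `:` or `|`) to species identifiers, or a
#'   data frame whose first two columns are subject id and species id.
#' @return A data frame with columns `query`, `species`, `evalue`, `bitscore`,
#'   one row per resolved hit, with attribute `n_unresolved` giving the count
#'   of dropped hits.
#' @examples
#' lines <- "q1\ts1\t90\t100\t5\t0\t1\t100\t1\t100\t1e-50\t180.3"
#' hits <- parse_blast_tab(lines, c(s1 = "hsa"))
#' hits$bitscore  # 180.3
#' @export
parse_blast_tab <- function(input, species_map) {
  if (length(input) == 1L && !grepl("\t", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- as.character(input)
  }
  lines <- lines[nzchar(lines)]
  map <- as_species_map(species_map)
  if (length(lines) == 0L) {
    out <- data.frame(query = character(), species = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_unresolved") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  arity <- lengths(fields)
  bad <- which(arity < 12L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BLAST tabular line %d: expected >= 12 fields, found %d",
                 bad[1L], arity[bad[1L]]))
  }
  query <- vapply(fields, `[[`, "", 1L)
  subject <- vapply(fields, `[[`, "", 2L)
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  bitscore <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
  bad <- which(is.na(evalue) | is.na(bitscore) | !nzchar(query) | !nzchar(subject))
  if (length(bad) > 0L) {
    stop(sprintf("malformed BLAST tabular line %d: e-value/bit-score fields do not parse",
                 bad[1L]))
  }
  species <- resolve_subject(subject, map)
  keep <- !is.na(species)
  out <- data.frame(query = query[keep], species = species[keep],
                    evalue = evalue[keep], bitscore = bitscore[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_unresolved") <- sum(!keep)
  if (any(!keep)) {
    message(sum(!keep), " hit(s) with unresolvable subject dropped")
  }
  out
}

as_species_map <- function(species_map) {
  if (is.data.frame(species_map)) {
    stats::setNames(as.character(species_map[[2L]]), as.character(species_map[[1L]]))
  } else {
    stopifnot(!is.null(names(species_map)))
    species_map
  }
}

# Resolve subject ids against the map: exact match first, then the prefix
# before ':' or '|' (KEGG- and NCBI-style subject identifiers).
resolve_subject <- function(subject, map) {
  out <- unname(map[subject])
  miss <- is.na(out)
  if (any(miss)) {
    prefix <- sub("[:|].*$", "", subject[miss])
    out[miss] <- unname(map[prefix])
  }
  out
}

#' Build a presence/absence phylogenetic profile
#'
#' A protein is marked present (1) in a species when at least one homology
#' hit for that protein in that species has an E-value at or below
#' `e_threshold`; otherwise 0. Proteins with no qualifying hit anywhere are
#' retained as all-zero rows and listed in the `empty_proteins` attribute so
#' downstream scorers can treat them explicitly.
#'
#' @param hits Data frame as returned by [parse_blast_tab()].
#' @param species Ordered character vector of species identifiers (the
#'   canonical column order), or a data frame whose first column is species
#'   id and optional second column a taxon-group label.
#' @param proteins Ordered character vector of protein identifiers (rows).
#' @param e_threshold Inclusive E-value cutoff (> 0). The web front ends of
#'   profiling tools typically expose 0.001, 0.0005 and 0.0001; 0.001 is the
#'   default.
#' @return A numeric 0/1 matrix of class `binary_profile` with proteins as
#'   row names and species as column names; attributes `taxon_group` (named
#'   vector or NULL) and `empty_proteins`.
#' @export
build_binary_profile <- function(hits, species, proteins, e_threshold = 0.001) {
  catalog <- as_species_catalog(species)
  check_profile_ids(proteins, catalog$species)
  stopifnot(is.numeric(e_threshold), length(e_threshold) == 1L, e_threshold > 0)
  values <- matrix(0, nrow = length(proteins), ncol = length(catalog$species),
                   dimnames = list(proteins, catalog$species))
  ok <- hits$evalue <= e_threshold &
    hits$query %in% proteins & hits$species %in% catalog$species
  if (any(ok)) {
    values[cbind(hits$query[ok], hits$species[ok])] <- 1
  }
  binary_profile(values, taxon_group = catalog$taxon_group)
}

#' Build a bit-score phylogenetic profile
#'
#' Entry (i, j) is the maximum BLAST bit score over all hits of protein i in
#' species j (the best-hit convention), 0 when the protein has no hit there.
#'
#' @inheritParams build_binary_profile
#' @return A non-negative numeric matrix of class `bitscore_profile`.
#' @export
build_bitscore_profile <- function(hits, species, proteins) {
  catalog <- as_species_catalog(species)
  check_profile_ids(proteins, catalog$species)
  values <- matrix(0, nrow = length(proteins), ncol = length(catalog$species),
                   dimnames = list(proteins, catalog$species))
  keep <- hits$query %in% proteins & hits$species %in% catalog$species
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) > 0L) {
    best <- tapply(h$bitscore, list(h$query, h$species), max)
    idx <- which(!is.na(best), arr.ind = TRUE)
    values[cbind(rownames(best)[idx[, 1L]], colnames(best)[idx[, 2L]])] <-
      best[idx]
  }
  bitscore_profile(values, taxon_group = catalog$taxon_group)
}

as_species_catalog <- function(species) {
  if (is.data.frame(species)) {
    ids <- as.character(species[[1L]])
    tg <- if (ncol(species) >= 2L) {
      stats::setNames(as.character(species[[2L]]), ids)
    } else NULL
    list(species = ids, taxon_group = tg)
  } else {
    list(species = as.character(species), taxon_group = NULL)
  }
}

check_profile_ids <- function(proteins, species) {
  if (length(proteins) == 0L) stop("protein list is empty")
  if (anyDuplicated(proteins)) stop("duplicate protein identifiers")
  if (length(species) == 0L) stop("species list is empty")
  if (anyDuplicated(species)) stop("duplicate species identifiers")
  invisible(TRUE)
}

#' Profile constructors
#'
#' Validating constructors for the two profile matrix classes. Rows are
#' proteins, columns are species; both dimensions must carry unique names.
#'
#' @param values Numeric matrix with protein row names and species column
#'   names; entries in \{0, 1\} for `binary_profile`, non-negative reals for
#'   `bitscore_profile`.
#' @param taxon_group Optional named character vector (species -> taxon
#'   group, e.g. Animals/Plants/Fungi/Protists/Bacteria/Archaea).
#' @return The matrix with class `binary_profile` or `bitscore_profile`,
#'   taxon-group attribute, and (binary only) an `empty_proteins` attribute
#'   naming all-zero rows.
#' @export
binary_profile <- function(values, taxon_group = NULL) {
  values <- validate_profile_matrix(values, taxon_group)
  if (!all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)))[1L]
    stop(sprintf("binary profile entry [%s, %s] is %s, not 0/1",
                 rownames(values)[(bad - 1L) %% nrow(values) + 1L],
                 colnames(values)[(bad - 1L) %/% nrow(values) + 1L],
                 values[bad]))
  }
  structure(values, class = c("binary_profile", "phylo_profile", class(matrix())),
            taxon_group = taxon_group,
            empty_proteins = rownames(values)[rowSums(values) == 0])
}

#' @rdname binary_profile
#' @export
bitscore_profile <- function(values, taxon_group = NULL) {
  values <- validate_profile_matrix(values, taxon_group)
  if (any(values < 0)) stop("bit scores must be non-negative")
  structure(values, class = c("bitscore_profile", "phylo_profile", class(matrix())),
            taxon_group = taxon_group)
}

validate_profile_matrix <- function(values, taxon_group) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if ((nrow(values) > 0L && is.null(rownames(values))) || is.null(colnames(values))) {
    stop("profile matrix needs protein row names and species column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate protein identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate species identifiers")
  if (anyNA(values)) stop("profile matrix contains missing values")
  if (!is.null(taxon_group)) {
    stopifnot(!is.null(names(taxon_group)))
  }
  values
}

#' Read and write profile matrices as TSV
#'
#' The on-disk format is UTF-8 TSV, no quoting: header row `protein_id`
#' followed by the species identifiers, then one row per protein. The
#' round trip `read_profile(write_profile(p))` is the identity.
#'
#' @param path File path.
#' @param type `"auto"` detects binary (all entries 0/1) vs bit-score;
#'   `"binary"` or `"bitscore"` enforce the respective contract.
#' @return For `read_profile`, a `binary_profile` or `bitscore_profile`.
#' @export
read_profile <- function(path, type = c("auto", "binary", "bitscore")) {
  type <- match.arg(type)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty profile file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "protein_id") {
    stop("profile TSV must start with a 'protein_id' header cell")
  }
  species <- header[-1L]
  body <- lines[-1L]
  if (length(body) == 0L) {
    warning("profile file has a header but no proteins")
    values <- matrix(numeric(), nrow = 0L, ncol = length(species),
                     dimnames = list(character(), species))
    return(if (type == "bitscore") bitscore_profile(values) else binary_profile(values))
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(cells) != length(header))) {
    stop("ragged row in profile TSV at line ",
         which(lengths(cells) != length(header))[1L] + 1L)
  }
  proteins <- vapply(cells, `[[`, "", 1L)
  values <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(cells, `[`, -1L))),
           nrow = length(body), ncol = length(species), byrow = TRUE,
           dimnames = list(proteins, species)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at protein '%s', species '%s'",
                 proteins[bad[1L]], species[bad[2L]]))
  }
  if (type == "binary" || (type == "auto" && all(values %in% c(0, 1)))) {
    binary_profile(values)
  } else {
    bitscore_profile(values)
  }
}

#' @rdname read_profile
#' @param profile A `binary_profile` or `bitscore_profile`.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("protein_id", colnames(profile)), collapse = "\t"), con)
  if (nrow(profile) > 0L) {
    body <- apply(unclass(profile), 1L, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE, digits = 15), collapse = "\t"))
    writeLines(paste(rownames(profile), body, sep = "\t"), con)
  }
  invisible(path)
}
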
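#' Core- and pan-genome accumulation curves
#'
#' For each of `n_orders` random genome orderings (or for every permutation
#' when `exhaustive = TRUE`), the pan curve at k counts orthogroups present
#' (copy number >= 1) in at least one of the first k genomes and the core
#' curve counts those present in all of them; the mean over orderings is
#' reported per k. Reproducible for a fixed seed, which is recorded in the
#' output.
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @param n_orders Number of random genome orderings to average over
#'   (default 100). Ignored when `exhaustive = TRUE`.
#' @param seed Integer seed for the orderings (default 42).
#' @param exhaustive Enumerate all G! orderings instead of sampling (only
#'   sensible for small G; refused above 8 genomes).
#' @return An `accumulation_curves` object: data frame with columns `k`,
#'   `pan_mean`, `core_mean` and attributes `n_orders` and `seed`.
#' @export
accumulation_curves <- function(matrix, n_orders = 100, seed = 42,
                                exhaustive = FALSE) {
  G <- ncol(matrix)
  if (G < 1) stop("need at least one genome")
  pres <- matrix >= 1
  orders <- if (exhaustive) {
    if (G > 8) stop("exhaustive enumeration limited to 8 genomes")
    all_permutations(G)
  } else {
    if (n_orders < 1) stop("n_orders must be >= 1")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    lapply(seq_len(n_orders), function(i) sample.int(G))
  }
  pan <- core <- matrix(0, nrow = length(orders), ncol = G)
  for (oi in seq_along(orders)) {
    ord <- orders[[oi]]
    seen_any <- rep(FALSE, nrow(pres))
    seen_all <- rep(TRUE, nrow(pres))
    for (k in seq_len(G)) {
      col <- pres[, ord[k]]
      seen_any <- seen_any | col
      seen_all <- seen_all & col
      pan[oi, k] <- sum(seen_any)
      core[oi, k] <- sum(seen_all)
    }
  }
  out <- data.frame(k = seq_len(G), pan_mean = colMeans(pan),
                    core_mean = colMeans(core))
  attr(out, "n_orders") <- length(orders)
  attr(out, "seed") <- if (exhaustive) NA_integer_ else seed
  class(out) <- c("accumulation_curves", "data.frame")
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Occupancy spectrum of the orthogroup set
#'
#' Histogram of orthogroups by the number of genomes in which they occur:
#' `counts[j]` is the number of orthogroups present (copy number >= 1) in
#' exactly j genomes. `counts[G]` is the core-genome size, `counts[1]` the
#' singleton count; the counts sum to the number of non-empty orthogroups.
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @return Named integer vector of length G (names "1".."G").
#' @export
occupancy_spectrum <- function(matrix) {
  if (nrow(matrix) == 0) stop("empty presence matrix")
  occ <- rowSums(matrix >= 1)
  G <- ncol(matrix)
  counts <- vapply(seq_len(G), function(j) sum(occ == j), 0L)
  stats::setNames(counts, as.character(seq_len(G)))
}

#' Venn partition of orthogroups over a genome subset
#'
#' Every orthogroup present in at least one genome of the subset is assigned
#' to exactly one region: the exact set of subset genomes that contain it.
#' The region counts therefore partition the union of the subset genomes'
#' orthogroups. Subsets of 2 to 6 genomes are supported (the classical
#' rendering limit; the counts themselves are exact for any size in range).
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @param genome_subset Character vector of 2-6 genome ids (columns of
#'   `matrix`).
#' @return Named integer vector; names are region signatures such as
#'   `"A&B"` (genome ids joined by `&` in `genome_subset` order), including
#'   zero-count regions.
#' @export
venn_partitions <- function(matrix, genome_subset) {
  n <- length(genome_subset)
  if (n < 2 || n > 6) stop("genome subset must contain between 2 and 6 genomes")
  if (!all(genome_subset %in% colnames(matrix)))
    stop("unknown genome id(s): ",
         paste(setdiff(genome_subset, colnames(matrix)), collapse = ", "))
  pres <- matrix[, genome_subset, drop = FALSE] >= 1
  sigs <- apply(pres, 1, function(r)
    paste(genome_subset[r], collapse = "&"))
  sigs <- sigs[nzchar(sigs)]
  # all 2^n - 1 possible regions, zeros included
  all_regions <- unlist(lapply(seq_len(n), function(k)
    utils::combn(genome_subset, k, FUN = paste, collapse = "&")))
  counts <- stats::setNames(integer(length(all_regions)), all_regions)
  tab <- table(sigs)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Orthogroups present in one genome set and absent from another
#'
#' Returns the orthogroups present (copy number >= 1) in every genome of
#' `include` and in none of `exclude`. A genome listed in both sets makes the
#' result empty by construction.
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @param include Non-empty character vector of genome ids that must all
#'   contain the group.
#' @param exclude Character vector of genome ids that must not (may be
#'   empty).
#' @param min_fraction Fraction of `include` genomes required to contain the
#'   group (default 1 = all; extension point for relaxed conservation
#'   queries).
#' @return Character vector of orthogroup ids, sorted.
#' @export
differential_query <- function(matrix, include, exclude = character(0),
                               min_fraction = 1) {
  if (!length(include)) stop("include set must not be empty")
  unknown <- setdiff(c(include, exclude), colnames(matrix))
  if (length(unknown)) stop("unknown genome id(s): ", paste(unknown, collapse = ", "))
  pres <- matrix >= 1
  in_ok <- rowSums(pres[, include, drop = FALSE]) >= min_fraction * length(include)
  ex_ok <- if (length(exclude))
    rowSums(pres[, exclude, drop = FALSE]) == 0 else TRUE
  sort(rownames(matrix)[in_ok & ex_ok])
}
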
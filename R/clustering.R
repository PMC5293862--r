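# Population metabolic profiles and UPGMA clustering.

#' Population metabolic profiles
#'
#' For every (population, peak), the median across the population's
#' genotypes of the genotype-level replicate medians. Profiles are
#' computed on the raw intensity scale by default, where presence/absence
#' contrast between populations dominates; set `log = TRUE` for
#' log-scale profiles.
#'
#' @param pe A [PeakExperiment].
#' @param log Use log-transformed intensities (default `FALSE`).
#' @param logOffset Offset for the log transform.
#' @return List with `matrix` (peaks x populations) and `sampleCount`
#'   (samples per population).
#' @export
populationProfiles <- function(pe, log = FALSE, logOffset = 1) {
  gm <- medianByGenotype(pe)
  Y <- if (log) .logT(gm$matrix, logOffset) else gm$matrix
  pop <- factor(gm$population)
  lev <- levels(pop)
  prof <- matrix(NA_real_, nrow(Y), length(lev),
                 dimnames = list(rownames(Y), lev))
  for (g in seq_along(lev))
    prof[, g] <- apply(Y[, pop == lev[g], drop = FALSE], 1L,
                       function(v) if (all(is.na(v))) NA_real_
                       else stats::median(v, na.rm = TRUE))
  cd <- colData(pe)
  cnt <- table(factor(cd$population[!cd$is_control], levels = lev))
  list(matrix = prof, sampleCount = as.integer(cnt),
       populations = lev)
}

#' UPGMA clustering of population profiles
#'
#' Average-linkage agglomeration on pairwise Euclidean distances between
#' population profile vectors, yielding an ultrametric rooted tree in
#' which two populations at distance `d` join at height `d/2`.
#'
#' @param profiles Output of [populationProfiles()], or a numeric matrix
#'   with populations as columns.
#' @param distance Distance metric passed to [stats::dist]
#'   (default `"euclidean"`).
#' @return List with `tree` (an [ape::phylo] rooted ultrametric tree with
#'   branch lengths), `hclust` (the merge structure), and `heights`
#'   (node heights on the UPGMA scale, i.e. half the merge distances).
#' @export
upgmaTree <- function(profiles, distance = "euclidean") {
  m <- if (is.list(profiles)) profiles$matrix else profiles
  m <- m[rowSums(is.na(m)) == 0L, , drop = FALSE]
  if (ncol(m) < 2L)
    stop("UPGMA needs >= 2 populations")
  d <- stats::dist(t(m), method = distance)
  hc <- stats::hclust(d, method = "average")
  tree <- ape::as.phylo(hc)  # halves heights: leaves join at d/2
  list(tree = tree, hclust = hc, heights = hc$height / 2)
}

#' Write a tree in Newick format
#'
#' @param upgma Output of [upgmaTree()] (or an `ape::phylo`).
#' @param file Path to write.
#' @return The file path, invisibly.
#' @export
writeNewick <- function(upgma, file) {
  tree <- if (inherits(upgma, "phylo")) upgma else upgma$tree
  ape::write.tree(tree, file = file)
  invisible(file)
}
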
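# Distance-based tree inference and tree-comparison metrics. The package
# deliberately uses a self-contained JC-corrected neighbor-joining engine so
# that critical-value calibration runs at desk scale; externally inferred
# trees (e.g. maximum-likelihood trees) can be substituted anywhere a tree is
# accepted.

#' Jukes--Cantor distance matrix
#'
#' Pairwise p-distances over shared non-missing sites, corrected with the JC
#' formula \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}\hat p)}. Saturated pairs
#' (\eqn{\hat p \ge 0.749}) are capped at \eqn{\hat p = 0.749} so that they
#' yield finite, large distances — calibration deliberately explores
#' saturation, where the correction would otherwise diverge.
#'
#' @param aln An [alignment()] object with at least 2 taxa.
#' @return A symmetric numeric matrix with taxon dimnames.
#' @export
jc_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "entsat_aln"))
  if (aln$n_taxa < 2L) stop("need at least 2 taxa")
  ch <- aln_chars(aln)
  ch[ch == "-"] <- "n"
  p <- as.matrix(ape::dist.dna(ape::as.DNAbin(ch), model = "raw",
                               pairwise.deletion = TRUE))
  if (any(!is.finite(p)))
    stop("some taxon pair shares no non-missing sites")
  p[p > 0.749] <- 0.749
  d <- -0.75 * log(1 - 4 * p / 3)
  diag(d) <- 0
  dimnames(d) <- list(aln$taxa, aln$taxa)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou--Nei criterion with Studier--Keppler
#' updates); negative estimated branch lengths are clamped to zero.
#'
#' @param dist Symmetric distance matrix with labels, `>= 3` taxa.
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(dist)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson--Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets of the
#' two (unrooted) trees; the normalized version divides by \eqn{2(n-3)}, its
#' maximum for binary trees, giving a value in `[0, 1]`. Rooted inputs are
#' unrooted before comparison.
#'
#' @param t1,t2 `phylo` objects over the same tip set, `n >= 4` tips.
#' @param normalized Logical; return the normalized distance.
#' @return A non-negative number (an even integer when `normalized = FALSE`).
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (length(t1$tip.label) < 4L) stop("need at least 4 tips")
  if (!setequal(t1$tip.label, t2$tip.label)) stop("tip sets differ")
  u1 <- ape::unroot(t1); u2 <- ape::unroot(t2)
  phangorn::RF.dist(u1, u2, normalize = normalized, check.labels = TRUE)
}

#' Proportional error in tree length
#'
#' `(estimated total length - true total length) / true total length`. A
#' signed value; estimates at least 50% longer or shorter than the truth
#' (|error| >= 0.5) define branch-length positives in the calibration.
#'
#' @param estimated,true `phylo` objects with branch lengths.
#' @return Signed proportional error.
#' @export
tree_length_error <- function(estimated, true) {
  lt <- sum(true$edge.length)
  if (!isTRUE(lt > 0)) stop("true tree length must be > 0")
  (sum(estimated$edge.length) - lt) / lt
}

#' Stemminess of a tree
#'
#' Proportion of total tree length contributed by internal branches,
#' internal/(internal + external).
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Value in `[0, 1)`.
#' @export
stemminess_of_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tot <- sum(tree$edge.length)
  if (!isTRUE(tot > 0)) stop("zero total tree length")
  ext <- external_edges(tree)
  sum(tree$edge.length[!ext]) / tot
}
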
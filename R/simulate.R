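# Tree construction and sequence-evolution simulation (JC and GTR+Gamma
# with a proportion of invariant sites). Trees are ape "phylo" objects.

#' Build a fully balanced or fully imbalanced tree topology
#'
#' Balanced trees are complete binary trees (taxon count must be a power of
#' two); imbalanced trees are caterpillars (each internal node subtends one
#' tip). These are the two extremes of tree shape used in the simulation
#' studies.
#'
#' @param n_taxa Number of tips, `>= 4`.
#' @param balanced Logical; `TRUE` for the complete binary tree.
#' @return A rooted binary `phylo` object without branch lengths; tips are
#'   labelled `t1 ... tn`.
#' @export
build_tree <- function(n_taxa, balanced = TRUE) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  if (balanced && abs(log2(n_taxa) - round(log2(n_taxa))) > 1e-9)
    stop("balanced trees require n_taxa to be a power of 2")
  tr <- ape::stree(n_taxa, type = if (balanced) "balanced" else "left")
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

# logical vector over edges: TRUE when the edge leads to a tip
external_edges <- function(tree) {
  tree$edge[, 2L] <= length(tree$tip.label)
}

#' Assign branch lengths from a mean length and a stemminess target
#'
#' All internal branches share one length and all external branches another,
#' chosen so that the realized mean branch length equals `mean_bl` exactly and
#' internal branches contribute a proportion `stemminess` of the total tree
#' length. Stemminess is the proportion
#' internal/(internal + external) of summed branch lengths; low values (short
#' internal branches relative to external ones) are a hard regime for
#' phylogenetic inference.
#'
#' @param tree A `phylo` object (rooted binary).
#' @param mean_bl Mean branch length in expected substitutions/site.
#' @param stemminess Target proportion in (0, 1).
#' @return The tree with `edge.length` set.
#' @export
assign_branch_lengths <- function(tree, mean_bl, stemminess) {
  stopifnot(mean_bl > 0, stemminess > 0, stemminess < 1)
  ext <- external_edges(tree)
  B <- nrow(tree$edge); B_ext <- sum(ext); B_int <- B - B_ext
  if (B_int == 0L) stop("tree has no internal branches")
  total <- mean_bl * B
  el <- numeric(B)
  el[!ext] <- stemminess * total / B_int
  el[ext] <- (1 - stemminess) * total / B_ext
  tree$edge.length <- el
  tree
}

#' Substitution model constructors
#'
#' `jc_model()` is the Jukes--Cantor model (equal rates, uniform base
#' frequencies). `gtr_model()` is a general time-reversible model with
#' gamma-distributed among-site rate variation; `sample_gtr_model()` draws the
#' six exchangeabilities from a symmetric Dirichlet with concentration
#' `alpha = 5` and uses continuous gamma rates with shape `alpha = 1`, the
#' configuration used to study inference under model underparameterization.
#' Rate matrices are scaled to a mean rate of 1 at stationarity, so branch
#' lengths are expected substitutions per site.
#'
#' @param p_invariant Proportion of sites held constant, in `[0, 1)`.
#' @param exchangeabilities Positive 6-vector (AC, AG, AT, CG, CT, GT).
#' @param base_freqs Stationary base frequency 4-vector.
#' @param gamma_shape Shape of the continuous gamma rate distribution, or
#'   `NULL` for equal rates.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet the
#'   exchangeabilities are drawn from.
#' @return An object of class `"entsat_model"`.
#' @name subst_models
NULL

#' @rdname subst_models
#' @export
jc_model <- function(p_invariant = 0) {
  structure(list(kind = "JC",
                 exchangeabilities = rep(1 / 6, 6L),
                 base_freqs = rep(0.25, 4L),
                 gamma_shape = NULL,
                 p_invariant = p_invariant),
            class = "entsat_model")
}

#' @rdname subst_models
#' @export
gtr_model <- function(exchangeabilities, base_freqs = rep(0.25, 4L),
                      gamma_shape = 1, p_invariant = 0) {
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities > 0),
            length(base_freqs) == 4L, all(base_freqs > 0))
  structure(list(kind = "GTRG",
                 exchangeabilities = exchangeabilities / sum(exchangeabilities),
                 base_freqs = base_freqs / sum(base_freqs),
                 gamma_shape = gamma_shape,
                 p_invariant = p_invariant),
            class = "entsat_model")
}

#' @rdname subst_models
#' @param seed Optional integer seed for reproducible draws.
#' @export
sample_gtr_model <- function(seed = NULL, dirichlet_alpha = 5, gamma_shape = 1,
                             base_freqs = rep(0.25, 4L), p_invariant = 0) {
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(6L, shape = dirichlet_alpha, rate = 1)
  gtr_model(g / sum(g), base_freqs = base_freqs, gamma_shape = gamma_shape,
            p_invariant = p_invariant)
}

# GTR rate matrix scaled to mean rate 1 at stationarity
model_Q <- function(model) {
  r <- model$exchangeabilities
  pi <- model$base_freqs
  Q <- matrix(0, 4L, 4L)
  Q[1, 2] <- r[1]; Q[1, 3] <- r[2]; Q[1, 4] <- r[3]
  Q[2, 3] <- r[4]; Q[2, 4] <- r[5]; Q[3, 4] <- r[6]
  Q <- Q + t(Q)
  Q <- Q * rep(pi, each = 4L)     # q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# eigendecomposition of a reversible Q via its symmetrized form
model_eigen <- function(model) {
  Q <- model_Q(model)
  pi <- model$base_freqs
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))       # diag(sp) Q diag(1/sp), symmetric
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(lambda = e$values,
       U = e$vectors / sp,          # diag(1/sp) E  -> rows scaled
       V = t(e$vectors * sp))       # t(E) diag(sp) as V = U^{-1}
}

#' Evolve nucleotide sequences along a tree
#'
#' Simulates sequences site-by-site down a tree under a reversible
#' substitution model. Root states are drawn from the stationary base
#' frequencies; along each branch of length `t`, per-site substitution
#' probabilities come from `expm(Q * t * r_s)` where `r_s` is the site's rate
#' multiplier. With a gamma shape set, each variable site receives an
#' independent continuous Gamma(shape, shape) multiplier (mean 1); a
#' Bernoulli(`p_invariant`) mask fixes sites as constant before simulation.
#'
#' @param tree A `phylo` object with non-negative branch lengths.
#' @param seq_len Number of sites.
#' @param model An `"entsat_model"` from [jc_model()], [gtr_model()] or
#'   [sample_gtr_model()].
#' @param seed Optional integer seed.
#' @return An [alignment()] object with rows in `tree$tip.label` order.
#' @export
evolve_sequences <- function(tree, seq_len, model, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), seq_len >= 1L, inherits(model, "entsat_model"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)

  rates <- if (!is.null(model$gamma_shape))
    stats::rgamma(seq_len, shape = model$gamma_shape, rate = model$gamma_shape)
  else rep(1, seq_len)
  if (model$p_invariant > 0)
    rates[stats::runif(seq_len) < model$p_invariant] <- 0

  eg <- model_eigen(model)
  pi <- model$base_freqs

  states <- matrix(NA_integer_, n_node, seq_len)
  root <- n_tip + 1L
  states[root, ] <- sample.int(4L, seq_len, replace = TRUE, prob = pi)

  # preorder traversal: reversed postorder guarantees parents precede children
  po <- stats::reorder(tree, "postorder")
  edges <- po$edge
  lens <- po$edge.length
  ord <- rev(seq_len(nrow(edges)))
  u <- stats::runif(nrow(edges) * seq_len)
  k <- 0L
  for (i in ord) {
    par <- edges[i, 1L]; child <- edges[i, 2L]
    bl <- lens[i]
    ps <- states[par, ]
    if (bl == 0) {
      states[child, ] <- ps
      k <- k + 1L
      next
    }
    E <- exp(outer(rates * bl, eg$lambda))       # S x 4
    M <- eg$U[ps, , drop = FALSE] * E            # rows: site-specific
    probs <- M %*% eg$V                          # S x 4 transition rows
    probs[probs < 0] <- 0
    probs <- probs / rowSums(probs)
    us <- u[(k * seq_len + 1L):((k + 1L) * seq_len)]
    c1 <- probs[, 1L]; c2 <- c1 + probs[, 2L]; c3 <- c2 + probs[, 3L]
    states[child, ] <- 1L + (us > c1) + (us > c2) + (us > c3)
    k <- k + 1L
  }
  alignment(states[seq_len(n_tip), , drop = FALSE], taxa = tree$tip.label)
}

#' Simulation configuration
#'
#' Bundles every knob of one simulated data set: tree shape and size, branch
#' lengths, stemminess, sequence length, substitution model and seed.
#'
#' @param n_taxa Number of tips (`>= 4`; powers of 2 when `balanced`).
#' @param seq_len Alignment length in sites.
#' @param mean_bl Mean branch length (expected substitutions/site).
#' @param stemminess Internal-branch proportion of total tree length, in (0,1).
#' @param balanced Logical tree-shape flag.
#' @param model An `"entsat_model"`.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `"entsat_config"`.
#' @export
sim_config <- function(n_taxa, seq_len, mean_bl, stemminess, balanced = TRUE,
                       model = jc_model(), seed = 1L) {
  stopifnot(n_taxa >= 4L, seq_len >= 1L, stemminess > 0, stemminess < 1)
  structure(list(n_taxa = n_taxa, seq_len = seq_len, mean_bl = mean_bl,
                 stemminess = stemminess, balanced = balanced, model = model,
                 seed = as.integer(seed)),
            class = "entsat_config")
}

#' Simulate one data set (true tree + alignment)
#'
#' Deterministic given the config's seed: builds the topology, assigns branch
#' lengths, and evolves sequences.
#'
#' @param config An [sim_config()] object.
#' @return List with `tree` (the true `phylo`) and `aln` (an [alignment()]).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "entsat_config"))
  set.seed(config$seed)
  tree <- build_tree(config$n_taxa, config$balanced)
  tree <- assign_branch_lengths(tree, config$mean_bl, config$stemminess)
  aln <- evolve_sequences(tree, config$seq_len, config$model)
  list(tree = tree, aln = aln)
}
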
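# Shared fixtures and independent oracles used across the suite.

# alignment from per-site columns (each a character vector over the taxa)
aln_cols <- function(..., taxa = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  if (is.null(taxa)) taxa <- paste0("s", seq_len(nrow(m)))
  alignment(m, taxa = taxa)
}

rand_simplex <- function() {
  g <- stats::rgamma(4L, 1, 1)
  g / sum(g)
}

# exhaustive-enumeration oracle for the multinomial entropy: sums -P log2 P
# over every count vector (x1..x4) with sum n
brute_multinomial_entropy <- function(n, p) {
  grid <- expand.grid(x1 = 0:n, x2 = 0:n, x3 = 0:n)
  grid$x4 <- n - rowSums(grid)
  grid <- grid[grid$x4 >= 0L, , drop = FALSE]
  P <- apply(grid, 1L, function(x) stats::dmultinom(x, n, p))
  P <- P[P > 0]
  -sum(P * log2(P))
}

# tips below every internal edge of a tree, by explicit traversal
tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  out <- list()
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2L]
    if (child <= n) next
    stack <- child
    tips <- integer(0L)
    while (length(stack) > 0L) {
      nd <- stack[[1L]]
      stack <- stack[-1L]
      kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
      tips <- c(tips, kids[kids <= n])
      stack <- c(stack, kids[kids > n])
    }
    out[[length(out) + 1L]] <- sort(tree$tip.label[tips])
  }
  out
}

# brute-force Robinson-Foulds: explicit symmetric difference of canonical
# non-trivial bipartitions; independent of the package's implementation
brute_rf <- function(t1, t2, normalized = FALSE) {
  t1 <- ape::unroot(t1)
  t2 <- ape::unroot(t2)
  all_tips <- sort(t1$tip.label)
  canon <- function(s) {
    comp <- setdiff(all_tips, s)
    a <- paste(s, collapse = "|")
    b <- paste(sort(comp), collapse = "|")
    if (a < b) paste(a, b, sep = "//") else paste(b, a, sep = "//")
  }
  splits <- function(tr) {
    ss <- tip_sets(tr)
    ss <- ss[vapply(ss, function(x)
      length(x) >= 2L && length(x) <= length(all_tips) - 2L, logical(1))]
    unique(vapply(ss, canon, character(1)))
  }
  s1 <- splits(t1)
  s2 <- splits(t2)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) d / (2 * (length(all_tips) - 3)) else d
}

# caterpillar tree with a given tip order, unit branch lengths
caterpillar <- function(labels) {
  nwk <- Reduce(function(a, b) paste0("(", a, ",", b, ")"), labels[-1L],
                labels[1L])
  ape::read.tree(text = paste0(nwk, ";"))
}

# synthetic calibration records (no simulation) for ROC / regression tests
synth_records <- function(n, stat, positive) {
  data.frame(n_taxa = rep(8L, n), seq_len = rep(500L, n),
             mean_bl = rep(0.1, n), stemminess = rep(0.5, n),
             balanced = rep(TRUE, n), model = rep("JC", n),
             p_invariant = rep(0, n), seed = seq_len(n),
             t_all = stat, t_inf = stat,
             n_informative = rep(100L, n), n_variable = rep(200L, n),
             rf_norm = as.numeric(positive), tl_error = ifelse(positive, 0.6, 0),
             not_testable = rep(FALSE, n), fail_reason = rep("", n),
             stringsAsFactors = FALSE)
}
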
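# Simulation studies that calibrate the saturation test: a randomized
# gradient over evolutionary scenarios scored with the internal NJ engine,
# ROC-based selection of critical values per (taxon count, length bin) cell,
# and the regression model predicting t_crit from sqrt(taxa) and sqrt(length).

# one simulation replicate -> one record row (never throws; failures are
# recorded with a reason so batch accounting matches the replicate count)
rec_one <- function(n_taxa, seq_len, mean_bl, stemminess, balanced,
                    model_kind, p_invariant, seed) {
  out <- list(n_taxa = n_taxa, seq_len = seq_len, mean_bl = mean_bl,
              stemminess = stemminess, balanced = balanced,
              model = model_kind, p_invariant = p_invariant, seed = seed,
              t_all = NA_real_, t_inf = NA_real_,
              n_informative = NA_integer_, n_variable = NA_integer_,
              rf_norm = NA_real_, tl_error = NA_real_,
              not_testable = FALSE, fail_reason = "")
  res <- tryCatch({
    set.seed(seed)
    tree <- assign_branch_lengths(build_tree(n_taxa, balanced), mean_bl, stemminess)
    model <- if (model_kind == "JC") jc_model(p_invariant)
             else sample_gtr_model(p_invariant = p_invariant)
    aln <- evolve_sequences(tree, seq_len, model)
    cm <- site_count_matrix(aln)
    out$n_variable <- sum(colSums(cm > 0L) >= 2L)
    out$n_informative <- sum(colSums(cm >= 2L) >= 2L)
    est <- nj_tree(jc_distance_matrix(aln))
    out$rf_norm <- rf_distance(est, tree, normalized = TRUE)
    out$tl_error <- tree_length_error(est, tree)
    out$t_all <- run_saturation_test(aln, "all_sites")$t_obs
    out$t_inf <- run_saturation_test(aln, "informative_sites")$t_obs
    out
  }, entsat_error = function(e) {
    out$not_testable <- TRUE
    out$fail_reason <- conditionMessage(e)
    out
  }, error = function(e) {
    out$not_testable <- TRUE
    out$fail_reason <- conditionMessage(e)
    out
  })
  res
}

records_frame <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Randomized gradient simulation experiment
#'
#' Draws `n_sims` evolutionary scenarios with mean branch length, stemminess,
#' sequence length and constant-site proportion sampled from uniform ranges;
#' the taxon count, tree shape (balanced/imbalanced) and generating model (JC
#' or GTR+Gamma) are sampled uniformly from their choices. Each scenario is
#' simulated, analysed with the internal JC-distance NJ engine, and scored:
#' normalized Robinson--Foulds distance and proportional tree-length error
#' against the true tree, plus both entropy t-statistics. Fully reproducible:
#' each replicate records its own seed.
#'
#' @param n_sims Number of replicates.
#' @param taxa_choices Taxon counts sampled uniformly (powers of 2).
#' @param ranges List with elements `mean_bl`, `stemminess`, `seq_len`,
#'   `p_const`, each a `c(min, max)` range.
#' @param models Generating models to sample from (`"JC"`, `"GTRG"`).
#' @param seed Master seed.
#' @return A data frame of simulation records, one row per replicate, with a
#'   `not_testable` flag and `fail_reason` for replicates whose statistics
#'   could not be computed (these are never dropped silently).
#' @export
run_gradient_experiment <- function(n_sims,
                                    taxa_choices = c(8L, 32L, 128L, 512L),
                                    ranges = list(mean_bl = c(0.01, 0.65),
                                                  stemminess = c(0.1, 0.9),
                                                  seq_len = c(250, 2000),
                                                  p_const = c(0, 0.8)),
                                    models = c("JC", "GTRG"),
                                    seed = 1L) {
  stopifnot(n_sims >= 1L)
  set.seed(seed)
  cfg <- data.frame(
    n_taxa = taxa_choices[sample.int(length(taxa_choices), n_sims, replace = TRUE)],
    seq_len = round(stats::runif(n_sims, ranges$seq_len[1], ranges$seq_len[2])),
    mean_bl = stats::runif(n_sims, ranges$mean_bl[1], ranges$mean_bl[2]),
    stemminess = stats::runif(n_sims, ranges$stemminess[1], ranges$stemminess[2]),
    balanced = stats::runif(n_sims) < 0.5,
    model = sample(models, n_sims, replace = TRUE),
    p_invariant = stats::runif(n_sims, ranges$p_const[1], ranges$p_const[2]),
    seed = sample.int(.Machine$integer.max - 1L, n_sims),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n_sims), function(i)
    rec_one(cfg$n_taxa[i], cfg$seq_len[i], cfg$mean_bl[i], cfg$stemminess[i],
            cfg$balanced[i], cfg$model[i], cfg$p_invariant[i], cfg$seed[i]))
  records_frame(rows)
}

#' Factorial simulation experiment
#'
#' Full crossing of the supplied factor levels with generating model
#' (JC, GTR+Gamma) and tree shape (balanced, imbalanced), `reps_per_cell`
#' replicates per cell, with the same per-replicate pipeline as
#' [run_gradient_experiment()].
#'
#' @param levels Named list of factor levels: `n_taxa`, `seq_len`, `mean_bl`,
#'   `stemminess`, `p_invariant`. Defaults are the factorial design used to
#'   study which data features drive inference error and the statistics.
#' @param reps_per_cell Replicates per design cell.
#' @param seed Master seed.
#' @return A data frame of simulation records (see
#'   [run_gradient_experiment()]).
#' @export
factorial_experiment <- function(levels = list(n_taxa = c(8L, 32L, 128L, 512L),
                                               seq_len = c(250L, 500L, 1500L),
                                               mean_bl = c(0.05, 0.25, 0.45, 0.65),
                                               stemminess = c(0.1, 0.5, 0.9),
                                               p_invariant = c(0, 0.25, 0.5, 0.75)),
                                 reps_per_cell = 100L, seed = 1L) {
  stopifnot(reps_per_cell >= 1L)
  set.seed(seed)
  cells <- expand.grid(n_taxa = levels$n_taxa, seq_len = levels$seq_len,
                       mean_bl = levels$mean_bl, stemminess = levels$stemminess,
                       p_invariant = levels$p_invariant,
                       model = c("JC", "GTRG"), balanced = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  cfg <- cells[rep(seq_len(nrow(cells)), each = reps_per_cell), , drop = FALSE]
  cfg$seed <- sample.int(.Machine$integer.max - 1L, nrow(cfg))
  rows <- lapply(seq_len(nrow(cfg)), function(i)
    rec_one(cfg$n_taxa[i], cfg$seq_len[i], cfg$mean_bl[i], cfg$stemminess[i],
            cfg$balanced[i], cfg$model[i], cfg$p_invariant[i], cfg$seed[i]))
  records_frame(rows)
}

#' ROC curve of a saturation statistic against inference error
#'
#' Positives are replicates where inference failed: a wrong topology
#' (`rf_norm > 0`) or a tree-length estimate off by at least 50%
#' (`|tl_error| >= 0.5`). The classifier flags a replicate saturated when its
#' statistic falls below a threshold; the curve traverses every distinct
#' observed statistic value. Not-testable replicates are excluded (their count
#' is reported as `n_excluded`).
#'
#' @param records Simulation records from [run_gradient_experiment()] or
#'   [factorial_experiment()].
#' @param statistic `"t_inf"` (informative sites) or `"t_all"`.
#' @param positives `"topology"` or `"tree_length"`.
#' @return An object of class `"entsat_roc"`: list with `thresholds`, `tpr`,
#'   `fpr`, `tp`, `fp`, counts `n_pos`/`n_neg`/`n_excluded`, `positives_def`,
#'   `statistic`, and the selected `chosen_tcrit` with `tpr_at_tcrit`,
#'   `fpr_at_tcrit` (see [select_tcrit()]).
#' @export
compute_roc <- function(records, statistic = c("t_inf", "t_all"),
                        positives = c("topology", "tree_length")) {
  statistic <- match.arg(statistic)
  positives <- match.arg(positives)
  stat <- records[[statistic]]
  ok <- !records$not_testable & !is.na(stat) &
    !is.na(if (positives == "topology") records$rf_norm else records$tl_error)
  n_excluded <- sum(!ok)
  stat <- stat[ok]
  pos <- if (positives == "topology") records$rf_norm[ok] > 0
         else abs(records$tl_error[ok]) >= 0.5
  if (!any(pos) || all(pos))
    stop("need at least one positive and one negative record")
  thr <- sort(unique(stat))
  # flag saturated when statistic < threshold
  tp <- vapply(thr, function(th) sum(stat < th & pos), numeric(1))
  fp <- vapply(thr, function(th) sum(stat < th & !pos), numeric(1))
  res <- list(thresholds = thr, tpr = tp / sum(pos), fpr = fp / sum(!pos),
              tp = tp, fp = fp, n_pos = sum(pos), n_neg = sum(!pos),
              n_excluded = n_excluded,
              positives_def = positives, statistic = statistic)
  class(res) <- "entsat_roc"
  sel <- select_tcrit(res)
  res$chosen_tcrit <- sel
  i <- match(sel, thr)
  res$tpr_at_tcrit <- res$tpr[i]
  res$fpr_at_tcrit <- res$fpr[i]
  res
}

#' Select the critical value from a ROC curve
#'
#' Returns the threshold maximizing the difference between the numbers of
#' true positives and false positives (TP - FP); ties are broken toward the
#' smallest threshold, the conservative choice that flags fewer loci.
#'
#' @param roc An `"entsat_roc"` object.
#' @return The chosen threshold.
#' @export
select_tcrit <- function(roc) {
  stopifnot(inherits(roc, "entsat_roc"))
  diff <- roc$tp - roc$fp
  roc$thresholds[which.max(diff)]
}

#' @export
print.entsat_roc <- function(x, ...) {
  cat(sprintf("ROC of %s vs %s positives: %d positives, %d negatives\n",
              x$statistic, x$positives_def, x$n_pos, x$n_neg))
  cat(sprintf("  chosen t_crit = %.4f (TPR %.3f, FPR %.3f); max(TPR-FPR) = %.3f\n",
              x$chosen_tcrit, x$tpr_at_tcrit, x$fpr_at_tcrit,
              max(x$tpr - x$fpr)))
  invisible(x)
}

#' Per-cell critical values over taxon counts and length bins
#'
#' Splits simulation records into cells by taxon count and equal-width
#' sequence-length bins, and selects the ROC-optimal critical value in each
#' cell. Cells lacking both positives and negatives are dropped with a
#' warning.
#'
#' @param records Simulation records.
#' @param statistic,positives Passed to [compute_roc()].
#' @param n_bins Number of equal-width length bins.
#' @param len_range Optional `c(min, max)` range for binning; defaults to the
#'   observed range of `seq_len`.
#' @return Data frame with columns `n_taxa`, `len_mid` (bin midpoint),
#'   `chosen_tcrit`, `tpr`, `fpr`, `n`; bin breaks in attribute `"breaks"`.
#' @export
crit_bins <- function(records, statistic = "t_inf", positives = "topology",
                      n_bins = 4L, len_range = NULL) {
  if (is.null(len_range)) len_range <- range(records$seq_len)
  breaks <- seq(len_range[1], len_range[2], length.out = n_bins + 1L)
  bin <- cut(records$seq_len, breaks, include.lowest = TRUE, labels = FALSE)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  out <- list()
  for (tx in sort(unique(records$n_taxa))) {
    for (b in seq_len(n_bins)) {
      sub <- records[records$n_taxa == tx & !is.na(bin) & bin == b, , drop = FALSE]
      if (nrow(sub) == 0L) next
      roc <- tryCatch(compute_roc(sub, statistic, positives), error = function(e) NULL)
      if (is.null(roc)) {
        warning(sprintf("cell n_taxa=%d, length bin %d is single-class; dropped", tx, b))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        n_taxa = tx, len_mid = mids[b], chosen_tcrit = roc$chosen_tcrit,
        tpr = roc$tpr_at_tcrit, fpr = roc$fpr_at_tcrit,
        n = roc$n_pos + roc$n_neg)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "breaks") <- breaks
  attr(res, "statistic") <- statistic
  attr(res, "positives") <- positives
  res
}

#' Fit the critical-value prediction model
#'
#' Ordinary least squares of the per-cell critical values on the square roots
#' of taxon count and sequence-length bin midpoint. The fitted surface
#' predicts `t_crit` for alignments of any size inside the calibration range;
#' each cell's true/false-positive rates are retained so screening can report
#' the expected error rates of its decisions.
#'
#' @param per_bin Per-cell table from [crit_bins()] (columns `n_taxa`,
#'   `len_mid`, `chosen_tcrit`, `tpr`, `fpr`), spanning at least 2 taxon
#'   counts and 2 length bins with >= 3 cells.
#' @return An object of class `"entsat_crit"`: coefficients (`intercept`,
#'   `coef_sqrt_taxa`, `coef_sqrt_len`), `adjusted_r2`, `calibration_range`,
#'   and the per-cell table `bins`.
#' @export
fit_crit_model <- function(per_bin) {
  need <- c("n_taxa", "len_mid", "chosen_tcrit", "tpr", "fpr")
  stopifnot(all(need %in% names(per_bin)))
  if (nrow(per_bin) < 3L || length(unique(per_bin$n_taxa)) < 2L ||
      length(unique(per_bin$len_mid)) < 2L)
    stop("need >= 3 cells spanning >= 2 taxon counts and >= 2 length bins")
  fit <- stats::lm(chosen_tcrit ~ I(sqrt(n_taxa)) + I(sqrt(len_mid)), data = per_bin)
  cf <- stats::coef(fit)
  br <- attr(per_bin, "breaks")
  len_range <- if (!is.null(br)) range(br) else range(per_bin$len_mid)
  structure(list(intercept = unname(cf[1L]),
                 coef_sqrt_taxa = unname(cf[2L]),
                 coef_sqrt_len = unname(cf[3L]),
                 adjusted_r2 = summary(fit)$adj.r.squared,
                 calibration_range = list(taxa = range(per_bin$n_taxa),
                                          len = len_range),
                 bins = as.data.frame(per_bin)),
            class = "entsat_crit")
}

#' Predict a critical value for an alignment size
#'
#' Point prediction from the fitted surface; the expected true/false-positive
#' rates are taken from the nearest calibration cell (in square-root
#' coordinates). Queries outside the calibration range are flagged as
#' extrapolations: predictions far beyond the calibrated taxon counts and
#' lengths carry excessive uncertainty.
#'
#' @param model An `"entsat_crit"` model.
#' @param n_taxa Taxon count of the alignment to be tested.
#' @param seq_len Number of sites used by the test (informative-site count in
#'   the default screening mode).
#' @return List with `t_crit`, `expected_tpr`, `expected_fpr`,
#'   `extrapolation` (logical).
#' @export
predict_tcrit <- function(model, n_taxa, seq_len) {
  stopifnot(inherits(model, "entsat_crit"))
  t_crit <- model$intercept + model$coef_sqrt_taxa * sqrt(n_taxa) +
    model$coef_sqrt_len * sqrt(seq_len)
  rng <- model$calibration_range
  extrap <- n_taxa < rng$taxa[1] || n_taxa > rng$taxa[2] ||
    seq_len < rng$len[1] || seq_len > rng$len[2]
  d <- (sqrt(model$bins$n_taxa) - sqrt(n_taxa))^2 +
    (sqrt(model$bins$len_mid) - sqrt(seq_len))^2
  i <- which.min(d)
  list(t_crit = unname(t_crit),
       expected_tpr = model$bins$tpr[i],
       expected_fpr = model$bins$fpr[i],
       extrapolation = extrap)
}

#' @export
print.entsat_crit <- function(x, ...) {
  cat("Critical-value model: t_crit =",
      sprintf("%.4f + %.4f*sqrt(taxa) + %.4f*sqrt(len)\n",
              x$intercept, x$coef_sqrt_taxa, x$coef_sqrt_len))
  cat(sprintf("  adjusted R^2 = %.3f over %d calibration cells\n",
              x$adjusted_r2, nrow(x$bins)))
  cat(sprintf("  calibrated for %d-%d taxa, lengths %.0f-%.0f\n",
              x$calibration_range$taxa[1], x$calibration_range$taxa[2],
              x$calibration_range$len[1], x$calibration_range$len[2]))
  invisible(x)
}

#' Calibrate a critical-value model from scratch
#'
#' Convenience pipeline: gradient experiment, per-cell ROC critical values,
#' regression fit. The default profile (taxa 8/32/128, lengths 250--1250 in 4
#' bins, ~1200 replicates) runs on a desktop in minutes; larger profiles
#' matching bigger data sets are a matter of widening `taxa_choices`,
#' `len_range` and `n_sims`.
#'
#' @param n_sims Number of gradient replicates.
#' @param taxa_choices Taxon counts to calibrate over.
#' @param len_range Sequence-length range, binned into `n_bins` bins.
#' @param n_bins Number of length bins.
#' @param statistic,positives Passed to [compute_roc()].
#' @param seed Master seed.
#' @return An `"entsat_crit"` model; the underlying records are attached as
#'   attribute `"records"`.
#' @export
calibrate_crit_model <- function(n_sims = 1200L, taxa_choices = c(8L, 32L, 128L),
                                 len_range = c(250, 1250), n_bins = 4L,
                                 statistic = "t_inf", positives = "topology",
                                 seed = 1L) {
  rec <- run_gradient_experiment(
    n_sims, taxa_choices = taxa_choices,
    ranges = list(mean_bl = c(0.01, 0.65), stemminess = c(0.1, 0.9),
                  seq_len = len_range, p_const = c(0, 0.8)),
    seed = seed)
  pb <- crit_bins(rec, statistic = statistic, positives = positives,
                  n_bins = n_bins, len_range = len_range)
  model <- fit_crit_model(pb)
  attr(model, "records") <- rec
  model
}

#' Serialize / deserialize a critical-value model
#'
#' Flat whitespace-delimited text format: scalar `key value` lines followed by
#' one `bin` line per calibration cell
#' (`bin n_taxa len_mid chosen_tcrit tpr fpr n`).
#'
#' @param model An `"entsat_crit"` model.
#' @param path File path.
#' @return `write_crit_model`: `path` invisibly; `read_crit_model`: the model.
#' @export
write_crit_model <- function(model, path) {
  stopifnot(inherits(model, "entsat_crit"))
  lines <- c(
    "# entsat critical-value model",
    paste("intercept", format(model$intercept, digits = 17)),
    paste("coef_sqrt_taxa", format(model$coef_sqrt_taxa, digits = 17)),
    paste("coef_sqrt_len", format(model$coef_sqrt_len, digits = 17)),
    paste("adjusted_r2", format(model$adjusted_r2, digits = 17)),
    paste("taxa_min", model$calibration_range$taxa[1]),
    paste("taxa_max", model$calibration_range$taxa[2]),
    paste("len_min", model$calibration_range$len[1]),
    paste("len_max", model$calibration_range$len[2]),
    vapply(seq_len(nrow(model$bins)), function(i)
      paste("bin", model$bins$n_taxa[i], model$bins$len_mid[i],
            format(model$bins$chosen_tcrit[i], digits = 17),
            format(model$bins$tpr[i], digits = 17),
            format(model$bins$fpr[i], digits = 17),
            model$bins$n[i]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_crit_model
#' @export
read_crit_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  kv <- list()
  bins <- list()
  for (tk in toks) {
    if (tk[1L] == "bin") {
      bins[[length(bins) + 1L]] <- data.frame(
        n_taxa = as.numeric(tk[2L]), len_mid = as.numeric(tk[3L]),
        chosen_tcrit = as.numeric(tk[4L]), tpr = as.numeric(tk[5L]),
        fpr = as.numeric(tk[6L]), n = as.numeric(tk[7L]))
    } else kv[[tk[1L]]] <- as.numeric(tk[2L])
  }
  structure(list(intercept = kv$intercept,
                 coef_sqrt_taxa = kv$coef_sqrt_taxa,
                 coef_sqrt_len = kv$coef_sqrt_len,
                 adjusted_r2 = kv$adjusted_r2,
                 calibration_range = list(taxa = c(kv$taxa_min, kv$taxa_max),
                                          len = c(kv$len_min, kv$len_max)),
                 bins = do.call(rbind, bins)),
            class = "entsat_crit")
}

#' The calibration model shipped with the package
#'
#' A critical-value model fitted once from the default desk-scale calibration
#' profile (taxa 8/32/128, sequence lengths 250--1250 in four bins, 1200
#' gradient replicates, informative-sites statistic, topology positives) and
#' stored as a plain-text file in the package. Suitable for screening typical
#' phylogenomic loci; recalibrate with [calibrate_crit_model()] for data far
#' outside this range.
#'
#' @return An `"entsat_crit"` model.
#' @export
default_crit_model <- function() {
  read_crit_model(system.file("extdata", "crit_model_default.txt",
                              package = "entsat", mustWork = TRUE))
}

#' Factor and interaction regression on simulation records
#'
#' Ordinary least squares of a chosen response on the six design factors
#' (taxon count, sequence length, true tree length, tree imbalance,
#' stemminess, generating model), the number of variable sites, and all
#' pairwise interactions of the six factors. P-values are adjusted for
#' multiple comparisons with the Benjamini--Hochberg false-discovery-rate
#' procedure. Aliased (collinear) terms are dropped with a warning.
#'
#' @param records Simulation records from [factorial_experiment()] (or the
#'   gradient experiment).
#' @param response One of `"rf_norm"`, `"tl_error"`, `"t_all"`, `"t_inf"`,
#'   or a numeric vector of length `nrow(records)`.
#' @return Data frame with columns `term`, `estimate`, `t_value`, `p_value`,
#'   `p_adj`, sorted by `|t_value|` decreasing.
#' @export
interaction_regression <- function(records,
                                   response = c("rf_norm", "tl_error", "t_all", "t_inf")) {
  if (is.character(response)) {
    response <- match.arg(response)
    y <- records[[response]]
  } else {
    stopifnot(length(response) == nrow(records))
    y <- response
  }
  df <- data.frame(
    y = y,
    taxa = records$n_taxa,
    len = records$seq_len,
    tree_length = records$mean_bl * (2 * records$n_taxa - 2),
    imbalance = factor(ifelse(records$balanced, "balanced", "imbalanced")),
    stemminess = records$stemminess,
    model = factor(records$model),
    n_variable = records$n_variable)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  # factors collapse to constants when a design arm is absent; drop them
  for (v in c("imbalance", "model"))
    if (length(unique(df[[v]])) < 2L) df[[v]] <- NULL
  main <- intersect(c("taxa", "len", "tree_length", "imbalance", "stemminess",
                      "model"), names(df))
  fml <- stats::as.formula(paste("y ~ (", paste(main, collapse = " + "),
                                 ")^2 + n_variable"))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    warning("dropping aliased terms: ",
            paste(names(stats::coef(fit))[aliased], collapse = ", "))
  out <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                    t_value = sm[, 3L], p_value = sm[, 4L],
                    stringsAsFactors = FALSE)
  out <- out[out$term != "(Intercept)", , drop = FALSE]
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(-abs(out$t_value)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
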
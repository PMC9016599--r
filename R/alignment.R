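# Alignment container and I/O.
#
# Internally an alignment is an integer matrix (taxa x sites) over 1:4
# coding A,C,G,T; every other symbol (IUPAC ambiguity codes, '-', '?', '.')
# is NA and excluded from all counts and frequencies.

NUC <- c("a", "c", "g", "t")

entsat_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "entsat_error")))
}

#' Construct an alignment object
#'
#' Builds the alignment container used by every statistic in the package: an
#' integer matrix over the nucleotide alphabet with `NA` for missing states
#' (gaps and ambiguity codes), plus the taxon labels.
#'
#' @param states Character or integer matrix, taxa in rows, sites in columns.
#'   Characters are parsed case-insensitively; anything outside `A,C,G,T`
#'   becomes missing.
#' @param taxa Character vector of unique, non-empty taxon labels; defaults to
#'   `rownames(states)`.
#' @return An object of class `"entsat_aln"` with elements `states`
#'   (integer matrix, codes 1--4 for A,C,G,T, `NA` missing), `taxa`,
#'   `n_taxa` and `n_sites`.
#' @examples
#' aln <- alignment(rbind(s1 = c("A", "C", "G", "T"), s2 = c("A", "C", "N", "-")))
#' aln$n_sites
#' @export
alignment <- function(states, taxa = rownames(states)) {
  if (is.character(states)) {
    dm <- dim(states)
    idx <- match(tolower(states), NUC)
    states <- matrix(as.integer(idx), dm[1L], dm[2L])
  }
  if (!is.matrix(states)) entsat_stop("entsat_malformed", "states must be a matrix")
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(states)))
  taxa <- as.character(taxa)
  if (nrow(states) != length(taxa))
    entsat_stop("entsat_malformed", "number of taxa does not match number of rows")
  if (anyDuplicated(taxa) > 0L)
    entsat_stop("entsat_duplicate_label", "duplicate taxon labels")
  if (any(!nzchar(taxa)))
    entsat_stop("entsat_duplicate_label", "empty taxon label")
  storage.mode(states) <- "integer"
  dimnames(states) <- NULL
  structure(
    list(states = states, taxa = taxa,
         n_taxa = nrow(states), n_sites = ncol(states)),
    class = "entsat_aln")
}

#' @export
print.entsat_aln <- function(x, ...) {
  cat("Nucleotide alignment:", x$n_taxa, "taxa x", x$n_sites, "sites\n")
  miss <- mean(is.na(x$states))
  cat(sprintf("  missing/ambiguous cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
`==.entsat_aln` <- function(e1, e2) {
  identical(e1$taxa, e2$taxa) && identical(e1$states, e2$states)
}

# character representation used by the writers; missing becomes '-'
aln_chars <- function(aln) {
  ch <- matrix("-", aln$n_taxa, aln$n_sites)
  ok <- !is.na(aln$states)
  ch[ok] <- NUC[aln$states[ok]]
  rownames(ch) <- aln$taxa
  ch
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna", "ffn")) return("fasta")
  if (ext %in% c("phy", "phylip")) return("phylip")
  if (ext %in% c("nex", "nexus", "nxs")) return("nexus")
  head <- readLines(path, n = 50L, warn = FALSE)
  head <- head[nzchar(trimws(head))]
  if (length(head) == 0L) entsat_stop("entsat_empty_input", "empty file")
  first <- trimws(head[1L])
  if (startsWith(first, ">")) return("fasta")
  if (grepl("^#NEXUS", first, ignore.case = TRUE)) return("nexus")
  if (grepl("^[0-9]+\\s+[0-9]+$", first)) return("phylip")
  entsat_stop("entsat_malformed", paste("cannot detect alignment format of", path))
}

#' Read a nucleotide alignment
#'
#' Reads FASTA, relaxed PHYLIP (whitespace-delimited labels of any length,
#' sequential or interleaved) or a NEXUS DATA block. `format = "auto"`
#' dispatches on the file extension, then on content sniffing.
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"fasta"`, `"phylip"`, `"nexus"`.
#' @return An [alignment()] object.
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) entsat_stop("entsat_empty_input", paste("no such file:", path))
  if (file.size(path) == 0L) entsat_stop("entsat_empty_input", paste("empty file:", path))
  if (format == "auto") format <- detect_format(path)
  recs <- switch(format,
    fasta = read_fasta_records(path),
    phylip = read_phylip_records(path),
    nexus = read_nexus_records(path))
  if (length(recs) == 0L) entsat_stop("entsat_empty_input", "no sequences found")
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    entsat_stop("entsat_malformed", "sequences have unequal lengths")
  nm <- names(recs)
  if (is.null(nm) || anyDuplicated(nm) > 0L || any(!nzchar(nm)))
    entsat_stop("entsat_duplicate_label", "duplicate or empty taxon labels")
  alignment(do.call(rbind, recs), taxa = nm)
}

read_fasta_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) entsat_stop("entsat_malformed", "no FASTA headers found")
  ends <- c(hdr[-1L] - 1L, length(lines))
  recs <- lapply(seq_along(hdr), function(i) {
    if (hdr[i] >= ends[i]) return(character(0L))
    seq <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    strsplit(gsub("\\s", "", seq), "")[[1L]]
  })
  names(recs) <- trimws(sub("^>\\s*", "", lines[hdr]))
  recs
}

read_phylip_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) entsat_stop("entsat_malformed", "truncated PHYLIP file")
  hdr <- scan(text = lines[1L], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) entsat_stop("entsat_malformed", "bad PHYLIP header")
  n <- hdr[1L]; s <- hdr[2L]
  body <- lines[-1L]
  # sequential, possibly line-wrapped: walk tokens, a label then sequence
  # chunks until s characters are accumulated
  toks <- unlist(strsplit(trimws(body), "\\s+"))
  recs <- vector("list", n); nm <- character(n)
  i <- 1L; ok <- TRUE
  for (r in seq_len(n)) {
    if (i > length(toks)) { ok <- FALSE; break }
    nm[r] <- toks[i]; i <- i + 1L
    acc <- character(0L)
    while (length(acc) < s && i <= length(toks)) {
      acc <- c(acc, strsplit(toks[i], "")[[1L]])
      i <- i + 1L
    }
    if (length(acc) != s) { ok <- FALSE; break }
    recs[[r]] <- acc
  }
  if (ok && i > length(toks)) {
    names(recs) <- nm
    return(recs)
  }
  # interleaved: first block of n lines carries labels, later blocks only chunks
  if (length(body) %% n != 0L)
    entsat_stop("entsat_malformed", "PHYLIP body is neither sequential nor interleaved")
  nblock <- length(body) %/% n
  nm <- character(n); acc <- replicate(n, character(0L), simplify = FALSE)
  for (b in seq_len(nblock)) {
    for (r in seq_len(n)) {
      tk <- strsplit(trimws(body[(b - 1L) * n + r]), "\\s+")[[1L]]
      if (b == 1L) { nm[r] <- tk[1L]; tk <- tk[-1L] }
      acc[[r]] <- c(acc[[r]], unlist(strsplit(tk, "")))
    }
  }
  if (any(lengths(acc) != s))
    entsat_stop("entsat_malformed", "PHYLIP sequence lengths disagree with header")
  names(acc) <- nm
  acc
}

read_nexus_records <- function(path) {
  x <- ape::read.nexus.data(path)
  lapply(x, as.character)
}

#' Write a nucleotide alignment
#'
#' Writes FASTA, relaxed sequential PHYLIP (full-length whitespace-delimited
#' labels, no 10-character truncation) or a NEXUS DATA block. Missing states
#' are written as `-`. Reading the file back reproduces the alignment exactly.
#'
#' @param aln An [alignment()] object.
#' @param path Output file path.
#' @param format One of `"fasta"`, `"phylip"`, `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "entsat_aln"))
  ch <- aln_chars(aln)
  seqs <- apply(ch, 1L, paste, collapse = "")
  con <- file(path, "w"); on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_len(aln$n_taxa)) {
      writeLines(paste0(">", aln$taxa[i]), con)
      writeLines(substring(seqs[i], seq(1L, aln$n_sites, 60L),
                           pmin(seq(1L, aln$n_sites, 60L) + 59L, aln$n_sites)), con)
    }
  } else if (format == "phylip") {
    writeLines(paste(aln$n_taxa, aln$n_sites), con)
    writeLines(paste(aln$taxa, seqs), con)
  } else {
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 paste0("  DIMENSIONS NTAX=", aln$n_taxa, " NCHAR=", aln$n_sites, ";"),
                 "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
                 "  MATRIX"), con)
    writeLines(paste0("    ", aln$taxa, "  ", seqs), con)
    writeLines(c("  ;", "END;"), con)
  }
  invisible(path)
}

#' Nucleotide counts at one alignment column
#'
#' @param aln An [alignment()] object.
#' @param site_index Column index (1-based).
#' @return A list with `counts`, a named integer 4-vector of A,C,G,T counts
#'   among non-missing states, and `n_obs`, their sum.
#' @export
site_counts <- function(aln, site_index) {
  stopifnot(inherits(aln, "entsat_aln"))
  if (length(site_index) != 1L || site_index < 1L || site_index > aln$n_sites)
    stop("site_index out of range")
  col <- aln$states[, site_index]
  counts <- tabulate(col, nbins = 4L)
  names(counts) <- c("A", "C", "G", "T")
  list(counts = counts, n_obs = sum(counts))
}

# 4 x n_sites matrix of per-column counts; workhorse behind the statistics
site_count_matrix <- function(aln, sites = NULL) {
  st <- aln$states
  if (!is.null(sites)) st <- st[, sites, drop = FALSE]
  ns <- ncol(st)
  if (ns == 0L) return(matrix(0L, 4L, 0L))
  m <- matrix(0L, 4L, ns)
  for (k in 1:4) m[k, ] <- as.integer(colSums(st == k, na.rm = TRUE))
  m
}

#' Classify parsimony-informative sites
#'
#' A site is parsimony-informative when at least two distinct nucleotides are
#' each present in at least two sequences; missing states are ignored. Only
#' these sites retain signal for (unweighted) parsimony and they are the basis
#' of the informative-sites saturation test.
#'
#' @param aln An [alignment()] object.
#' @return Logical vector of length `n_sites`.
#' @export
informative_mask <- function(aln) {
  stopifnot(inherits(aln, "entsat_aln"))
  cm <- site_count_matrix(aln)
  colSums(cm >= 2L) >= 2L
}

#' Overall base composition of an alignment
#'
#' Pools the non-missing cells of the selected columns into A,C,G,T
#' frequencies; these are the multinomial probabilities of the saturation
#' model. Also records the modal per-column number of observed states, the
#' taxon count at which the full-saturation entropy is evaluated.
#'
#' @param aln An [alignment()] object.
#' @param sites Optional site subset: logical or integer index vector.
#'   Default uses all sites.
#' @param source Label recorded on the result (`"all_sites"` or
#'   `"informative_sites"`); purely descriptive.
#' @return An object of class `"entsat_basecomp"`: list with `p` (named
#'   frequency 4-vector summing to 1), `source`, and `n_effective` (modal
#'   per-site count of non-missing states over the selection).
#' @export
base_frequencies <- function(aln, sites = NULL, source = "all_sites") {
  stopifnot(inherits(aln, "entsat_aln"))
  cm <- site_count_matrix(aln, sites)
  tot <- rowSums(cm)
  if (sum(tot) == 0L)
    entsat_stop("entsat_undefined_composition",
                "selected sites contain no non-missing states")
  nobs <- colSums(cm)
  nobs <- nobs[nobs > 0L]
  tb <- table(nobs)
  n_eff <- as.integer(names(tb)[which.max(tb)])
  structure(list(p = tot / sum(tot), source = source, n_effective = n_eff),
            class = "entsat_basecomp")
}
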
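# Substitution tolerance against a position-specific scoring matrix:
# PSI-BLAST ASCII parsing, the substitution score
# delta S = S(mutant) - S(wild type), and a Monte Carlo random-mutation-set
# null for the mean score. Negative delta S means the matrix tolerates the
# substitution less than the wild type residue; the empirical p-value is
# lower-tail.

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, then one row per
#' position with the position index, wild-type residue, 20 log-odds integers
#' (captured) and 20 weighted-percentage columns plus trailing statistics
#' (ignored). Positions are 1-based. Column order is taken from the letter
#' header line when present, else the canonical PSI-BLAST order.
#'
#' @param path Path to the ASCII PSSM file (or a character vector of lines
#'   via `text`).
#' @param text Optional character vector of lines, used instead of `path`.
#' @return A [pssm()] object.
#' @export
parse_pssm_ascii <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  col_order <- AA_ALPHABET
  data_rows <- integer()
  for (i in seq_along(lines)) {
    tk <- toks[[i]]
    if (length(tk) >= 20L && all(tk %in% AA_ALPHABET) &&
        length(data_rows) == 0L) {
      col_order <- tk[seq_len(20L)]  # letter header (first block = log-odds)
      if (anyDuplicated(col_order))
        col_order <- AA_ALPHABET
      next
    }
    if (length(tk) >= 2L && grepl("^[0-9]+$", tk[1L]) &&
        tk[2L] %in% AA_ALPHABET) {
      data_rows <- c(data_rows, i)
    }
  }
  if (!length(data_rows)) stop_parse("no PSSM rows found", line = 1L)
  L <- length(data_rows)
  wt <- character(L)
  scores <- matrix(0L, L, 20L)
  for (j in seq_along(data_rows)) {
    i <- data_rows[j]
    tk <- toks[[i]]
    if (length(tk) < 22L)
      stop_parse(sprintf("PSSM row has %d fields, expected >= 22",
                         length(tk)), line = i)
    idx <- as.integer(tk[1L])
    if (idx != j)
      stop_parse(sprintf("positions not consecutive (saw %d, expected %d)",
                         idx, j), line = i)
    wt[j] <- tk[2L]
    vals <- suppressWarnings(as.integer(tk[3:22]))
    if (anyNA(vals))
      stop_parse("non-integer log-odds value in PSSM row", line = i)
    scores[j, match(col_order, AA_ALPHABET)] <- vals
  }
  pssm(wt, scores)
}

#' Substitution score of one missense mutation
#'
#' `delta_s = scores[position, mut] - scores[position, wt]`. The supplied
#' wild-type residue must match the PSSM at that position, guarding against
#' misalignment between the mutation nomenclature and the matrix.
#'
#' @param x A [pssm()] object.
#' @param position 1-based residue position.
#' @param wt,mut Wild-type and mutant residues (single letters).
#' @return List of class `substitution_score`: `position`, `wt`, `mut`,
#'   `delta_s` (integer).
#' @export
delta_s <- function(x, position, wt, mut) {
  stopifnot(inherits(x, "pssm"))
  if (!is_count(position, 1) || position > x$length)
    stop_data(sprintf("position %s outside [1, %d]",
                      format(position), x$length))
  if (!mut %in% AA_ALPHABET)
    stop_data(sprintf("mutant residue '%s' not in the 20-letter alphabet",
                      mut))
  if (!identical(unname(wt), x$wild_type[position]))
    stop_data(sprintf(
      "wild-type mismatch at position %d: PSSM has %s, mutation says %s",
      position, x$wild_type[position], wt))
  ds <- x$scores[position, mut] - x$scores[position, wt]
  structure(list(position = as.integer(position), wt = wt, mut = mut,
                 delta_s = as.integer(ds)), class = "substitution_score")
}

#' @export
print.substitution_score <- function(x, ...) {
  cat(sprintf("p.%s%d%s: delta S = %d\n", x$wt, x$position, x$mut,
              x$delta_s))
  invisible(x)
}

#' Parse protein HGVS missense notation
#'
#' @param hgvs_p Strings like `"p.D73H"` (one-letter residues).
#' @return Data frame `wt`, `position`, `mut`.
#' @export
parse_hgvs_p <- function(hgvs_p) {
  m <- regmatches(hgvs_p, regexec("^p\\.([A-Z])([0-9]+)([A-Z])$", hgvs_p))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop_parse(sprintf("not a one-letter missense HGVS.p string: %s",
                       hgvs_p[bad][1L]))
  data.frame(wt = vapply(m, `[`, character(1), 2L),
             position = as.integer(vapply(m, `[`, character(1), 3L)),
             mut = vapply(m, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Mean substitution score of a mutation set
#'
#' @param x A [pssm()] object.
#' @param mutations Either a data frame with `position`, `wt`, `mut`, or a
#'   character vector of HGVS.p strings (`"p.D73H"`).
#' @return Arithmetic mean of the per-mutation `delta_s` values.
#' @export
mean_delta_s <- function(x, mutations) {
  if (is.character(mutations)) mutations <- parse_hgvs_p(mutations)
  if (NROW(mutations) == 0L) stop_data("empty mutation set")
  ds <- vapply(seq_len(nrow(mutations)), function(i)
    delta_s(x, mutations$position[i], mutations$wt[i],
            mutations$mut[i])$delta_s,
    integer(1))
  mean(ds)
}

#' Monte Carlo null distribution of mean substitution scores
#'
#' Draws `n_sets` sets of `set_size` random mutations -- position uniform on
#' 1..L, mutant residue uniform over the 19 alternatives to the wild type at
#' that position, independently with replacement within and across sets --
#' and records each set's mean substitution score. Deterministic under the
#' seed.
#'
#' @param x A [pssm()] object.
#' @param set_size Mutations per set (k >= 1).
#' @param n_sets Number of sets (>= 1).
#' @param seed Integer seed.
#' @return Object of class `tolerance_null`: `set_size`, `n_sets`, `samples`
#'   (numeric vector of set means), `seed`.
#' @export
sample_null <- function(x, set_size = 3L, n_sets = 10000L, seed = 1L) {
  stopifnot(inherits(x, "pssm"))
  if (!is_count(set_size, 1)) stop_config("set_size must be >= 1", "set_size")
  if (!is_count(n_sets, 1)) stop_config("n_sets must be >= 1", "n_sets")
  if (x$length < 1L) stop_data("empty PSSM")
  with_seed(seed, {
    total <- set_size * n_sets
    pos <- sample.int(x$length, total, replace = TRUE)
    wt_idx <- match(x$wild_type, AA_ALPHABET)[pos]
    r <- sample.int(19L, total, replace = TRUE)
    mut_idx <- r + (r >= wt_idx)
    ds <- x$scores[cbind(pos, mut_idx)] - x$scores[cbind(pos, wt_idx)]
    means <- rowMeans(matrix(ds, nrow = n_sets, ncol = set_size))
    structure(list(set_size = as.integer(set_size),
                   n_sets = as.integer(n_sets),
                   samples = means, seed = as.integer(seed)),
              class = "tolerance_null")
  })
}

#' @export
print.tolerance_null <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo null: %d sets of %d mutations; mean %.3f, sd %.3f\n",
    x$n_sets, x$set_size, mean(x$samples), stats::sd(x$samples)))
  invisible(x)
}

#' Exact expectation of a single random substitution score
#'
#' Full enumeration over all positions and all 19 alternative residues:
#' `sum_{p, a != wt(p)} delta_s(p, a) / (19 L)`. This is also the
#' expectation of a mean over any set size.
#'
#' @param x A [pssm()] object.
#' @return The exact expectation (numeric scalar).
#' @export
expected_delta_s <- function(x) {
  stopifnot(inherits(x, "pssm"))
  wt_idx <- match(x$wild_type, AA_ALPHABET)
  wt_scores <- x$scores[cbind(seq_len(x$length), wt_idx)]
  # sum over all 20 letters minus the wt cell, relative to wt
  row_sums <- rowSums(x$scores) - wt_scores
  sum(row_sums - 19 * wt_scores) / (19 * x$length)
}

#' Lower-tail empirical p-value against a Monte Carlo null
#'
#' Add-one (pseudo-count) estimate
#' `p = (1 + #\{samples <= observed\}) / (n_sets + 1)`; lower-tail because
#' negative mean scores indicate intolerant substitution sets.
#'
#' @param observed_mean Observed mean substitution score.
#' @param null A [sample_null()] result.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed_mean, null) {
  stopifnot(inherits(null, "tolerance_null"))
  if (!length(null$samples)) stop_data("empty null distribution")
  (1 + sum(null$samples <= observed_mean)) / (null$n_sets + 1)
}
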
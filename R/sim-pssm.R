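# Synthetic PSSM: conserved and unconserved positions, serialized in the
# PSI-BLAST ASCII matrix dialect.

#' Construct a PSSM object
#'
#' @param wild_type Character vector of wild-type residues (1-based
#'   positions), letters from the 20-residue alphabet.
#' @param scores Integer matrix, length(wild_type) rows by 20 columns in
#'   PSI-BLAST residue order (ARNDCQEGHILKMFPSTWYV).
#' @return An object of class `pssm` with fields `length`, `wild_type`,
#'   `scores`.
#' @export
pssm <- function(wild_type, scores) {
  wild_type <- as.character(wild_type)
  if (length(wild_type) == 1L && nchar(wild_type) > 1L)
    wild_type <- strsplit(wild_type, "", fixed = TRUE)[[1]]
  L <- length(wild_type)
  if (L < 1L) stop_config("PSSM length must be >= 1")
  if (!all(wild_type %in% AA_ALPHABET))
    stop_data("wild-type residues outside the 20-letter alphabet")
  scores <- as.matrix(scores)
  if (nrow(scores) != L || ncol(scores) != 20L)
    stop_data(sprintf("score matrix must be %d x 20", L))
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(seq_len(L), AA_ALPHABET)
  structure(list(length = L, wild_type = wild_type, scores = scores),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM:", x$length, "positions, wild type",
      paste0(utils::head(x$wild_type, 10), collapse = ""),
      if (x$length > 10) "...", "\n")
  invisible(x)
}

# Wild-type sequence stream shared between the PSSM generator and the
# pedigree annotation generator (same (length, fraction, seed) -> same
# sequence), so planted missense HGVS.p agrees with the PSSM fixture.
pssm_wild_type <- function(length, conserved_fraction, seed) {
  with_seed(seed, sample(AA_ALPHABET, length, replace = TRUE))
}

#' Simulate a PSSM with conserved and unconserved positions
#'
#' At conserved positions the wild-type residue scores high (the row maximum
#' by construction) and alternatives score low; at unconserved positions
#' scores are drawn independently near zero. Deterministic under the seed.
#'
#' @param length Number of positions (>= 1).
#' @param conserved_fraction Fraction of positions drawn as conserved.
#' @param seed Integer seed.
#' @return A [pssm()] object; conserved positions are recorded in the
#'   `conserved` attribute.
#' @export
simulate_pssm <- function(length, conserved_fraction = 0.5, seed = 1L) {
  if (!is_count(length, 1)) stop_config("length must be >= 1", "length")
  if (!is_fraction(conserved_fraction))
    stop_config("must be a fraction in [0,1]", "conserved_fraction")
  wt <- pssm_wild_type(length, conserved_fraction, seed)
  with_seed(child_seed(seed, 17L), {
    conserved <- stats::runif(length) < conserved_fraction
    scores <- matrix(sample(-4:2, length * 20L, replace = TRUE),
                     nrow = length, ncol = 20L)
    wt_idx <- match(wt, AA_ALPHABET)
    flat <- cbind(seq_len(length), wt_idx)
    # unconserved: wild type is unremarkable; conserved: clear row maximum
    scores[flat] <- sample(0:3, length, replace = TRUE)
    pen <- which(conserved)
    scores[cbind(pen, wt_idx[pen])] <- sample(6:9, length(pen), replace = TRUE)
    # deepen the penalty for substitutions at conserved positions
    for (i in pen) {
      alt <- setdiff(seq_len(20L), wt_idx[i])
      scores[i, alt] <- sample(-6:-1, 19L, replace = TRUE)
    }
    out <- pssm(wt, scores)
    attr(out, "conserved") <- conserved
    out
  })
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Reproduces the `-out_ascii_pssm` layout: two header lines, a 40-letter
#' column header, one row per position (index, residue, 20 log-odds
#' integers, 20 percentage columns, information content and relative
#' weight), and trailing K/lambda statistics. Byte-deterministic for a given
#' PSSM.
#'
#' @param x A [pssm()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pssm_ascii <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  wt_idx <- match(x$wild_type, AA_ALPHABET)
  pct <- matrix(0L, x$length, 20L)
  pct[cbind(seq_len(x$length), wt_idx)] <- 100L
  lines <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0(" ", paste(sprintf("%3s", c(AA_ALPHABET, AA_ALPHABET)),
                      collapse = " ")))
  rows <- vapply(seq_len(x$length), function(i) {
    paste0(sprintf("%5d %s ", i, x$wild_type[i]),
           paste(sprintf("%3d", x$scores[i, ]), collapse = " "), "  ",
           paste(sprintf("%3d", pct[i, ]), collapse = " "),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1))
  trailer <- c("", "                      K         Lambda",
               "Standard Ungapped    0.1397     0.3183",
               "Standard Gapped      0.0410     0.2670",
               "PSI Ungapped         0.1397     0.3183",
               "PSI Gapped           0.0410     0.2670")
  writeLines(c(lines, rows, trailer), path)
  invisible(path)
}
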
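# Allele-count algebra over population cohorts and Fisher exact burden
# testing.  Cohort subtraction derives a subset's counts from a superset and
# its complement (cancer = general - non-cancer; cancer-germline set = full -
# complement); the burden test compares allele counts between two cohorts.

check_counts_df <- function(x, what) {
  need <- c("variant_id", "ac", "an")
  if (!all(need %in% names(x)))
    stop_data(sprintf("%s needs columns: %s", what,
                      paste(need, collapse = ", ")))
  if (any(x$ac < 0 | x$an < 0 | x$ac > x$an))
    stop_data(sprintf("%s violates 0 <= ac <= an", what))
  if (anyDuplicated(x$variant_id))
    stop_data(sprintf("%s has duplicated variant ids", what))
  invisible(x)
}

#' Elementwise cohort subtraction
#'
#' Subtracts a complement cohort's allele counts and numbers from a superset
#' cohort, variant by variant, yielding the derived subset cohort (e.g.
#' cancer = general - non-cancer). Variants absent from the subtrahend are
#' treated as `ac = 0, an = 0` there. A negative difference is a
#' data-inconsistency error naming the variant; with `clamp = TRUE` it is
#' converted to 0 with a warning instead (real releases do contain subset
#' inconsistencies).
#'
#' @param minuend,subtrahend Count data frames (`variant_id`, `ac`, `an`).
#' @param cohort_name Name for the derived cohort (default
#'   `"<minuend> - <subtrahend>"` from their `cohort` columns when present).
#' @param clamp Convert negative differences to 0 with a warning.
#' @return Data frame `variant_id`, `cohort`, `ac`, `an` for every minuend
#'   variant.
#' @export
subtract_counts <- function(minuend, subtrahend, cohort_name = NULL,
                            clamp = FALSE) {
  check_counts_df(minuend, "minuend")
  check_counts_df(subtrahend, "subtrahend")
  if (is.null(cohort_name)) {
    a <- if ("cohort" %in% names(minuend)) minuend$cohort[1] else "minuend"
    b <- if ("cohort" %in% names(subtrahend)) subtrahend$cohort[1]
         else "subtrahend"
    cohort_name <- paste(a, "-", b)
  }
  m <- match(minuend$variant_id, subtrahend$variant_id)
  sub_ac <- ifelse(is.na(m), 0L, subtrahend$ac[m])
  sub_an <- ifelse(is.na(m), 0L, subtrahend$an[m])
  ac <- minuend$ac - sub_ac
  an <- minuend$an - sub_an
  neg <- ac < 0L | an < 0L
  if (any(neg)) {
    if (clamp) {
      warning(sprintf("clamped %d negative difference(s) to 0 (e.g. %s)",
                      sum(neg), minuend$variant_id[which(neg)[1L]]))
      ac <- pmax(ac, 0L)
      an <- pmax(an, 0L)
    } else {
      stop_data(sprintf(
        "negative count after subtraction for variant(s): %s",
        paste(utils::head(minuend$variant_id[neg], 5L), collapse = ", ")))
    }
  }
  data.frame(variant_id = minuend$variant_id, cohort = cohort_name,
             ac = as.integer(ac), an = as.integer(an),
             stringsAsFactors = FALSE)
}

#' Derive the cancer-germline variant set by table subtraction
#'
#' Subtracts the complement table (population minus the cancer cohort) from
#' the full table; ids with a positive derived allele count form the
#' cancer-germline set. Ids absent from the complement count as complement
#' `ac = 0`.
#'
#' @param full_table,complement_table Count data frames indexed by canonical
#'   variant id.
#' @param clamp Passed to [subtract_counts()].
#' @return Character vector of variant ids with derived `ac > 0`.
#' @export
derive_germline_subset <- function(full_table, complement_table,
                                   clamp = FALSE) {
  d <- subtract_counts(full_table, complement_table,
                       cohort_name = "germline-subset", clamp = clamp)
  d$variant_id[d$ac > 0L]
}

#' Keep variants passing quality filters in every source
#'
#' Retains the rows of variants whose `filter_status` is `"pass"` in every
#' source row present for that variant; a variant observed in a single
#' source only needs that one pass ("both" applies only when both sources
#' exist).
#'
#' @param rows Count data frame with `variant_id` and `filter_status`.
#' @return The subset of `rows` belonging to all-pass variants.
#' @export
quality_filter <- function(rows) {
  if (!"filter_status" %in% names(rows)) return(rows)
  ok <- as.logical(stats::ave(rows$filter_status == "pass", rows$variant_id,
                              FUN = function(z) all(z)))
  rows[ok, , drop = FALSE]
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by summation of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (the standard two-sided convention;
#' probabilities within one part in 1e7 of the observed one count as tied).
#' The odds ratio is the cross-product `ad/bc`, `+Inf` when `bc = 0` and
#' `ad > 0`.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as
#'   rows = carrier status, columns = cohort:
#'   `a` carriers in cohort A, `b` non-carriers in cohort A, `c` carriers in
#'   cohort B, `d` non-carriers in cohort B.
#' @return List with `odds_ratio`, `p` (two-sided), and `or_defined`
#'   (`FALSE` when a zero margin leaves the odds ratio undefined; then
#'   `p = 1`).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop_data("cells must be non-negative integers")
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || k == 0 || k == n) {
    return(list(odds_ratio = NA_real_, p = 1, or_defined = FALSE))
  }
  support <- max(0, k - r2):min(k, r1)
  probs <- stats::dhyper(support, r1, r2, k)
  observed <- probs[support == a]
  p <- min(1, sum(probs[probs <= observed * (1 + 1e-7)]))
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf
        else NaN
  list(odds_ratio = or, p = p, or_defined = TRUE)
}

#' Gene-level allele burden between two cohorts
#'
#' Aggregates a gene's variants within each cohort: carriers = sum of allele
#' counts over the gene's variants; trials = the cohort's maximum allele
#' number over those variants (call-rate-conservative: chromosomes are not
#' double-counted across variants). The resulting 2x2 table
#' (carriers / non-carriers x cohort A / cohort B) is tested with
#' [fisher_exact_2x2()]. Allele counts approximate carrier counts for rare
#' variants.
#'
#' @param ids Canonical variant ids of one gene.
#' @param table_a,table_b Count data frames (`variant_id`, `ac`, `an`) for
#'   the two cohorts.
#' @param gene Gene symbol carried through to the result.
#' @return List of class `burden_result`: `gene`, `table` (2x2 integer
#'   matrix), `odds_ratio`, `p`.
#' @export
gene_burden <- function(ids, table_a, table_b, gene = NA_character_) {
  agg <- function(tbl) {
    rows <- tbl[tbl$variant_id %in% ids, , drop = FALSE]
    if (nrow(rows) == 0L) return(c(carriers = 0L, trials = 0L))
    c(carriers = sum(rows$ac), trials = max(rows$an))
  }
  A <- agg(table_a)
  B <- agg(table_b)
  if (A[["carriers"]] > A[["trials"]] || B[["carriers"]] > B[["trials"]])
    stop_data(sprintf("gene %s: carriers exceed trials", gene))
  tab <- matrix(c(A[["carriers"]], A[["trials"]] - A[["carriers"]],
                  B[["carriers"]], B[["trials"]] - B[["carriers"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("cohort_a", "cohort_b"),
                                c("carriers", "non_carriers")))
  ft <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  structure(list(gene = gene, table = tab, odds_ratio = ft$odds_ratio,
                 p = ft$p, or_defined = ft$or_defined),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Gene burden:", x$gene, "\n")
  print(x$table)
  cat(sprintf("odds ratio = %s, two-sided Fisher p = %.4g\n",
              format(x$odds_ratio, digits = 4), x$p))
  invisible(x)
}

#' Burden scan over all genes
#'
#' Runs [gene_burden()] for every gene in the map and reports raw p-values
#' together with Benjamini-Hochberg adjusted q-values, ordered by p.
#'
#' @param gene_map Data frame `variant_id`, `gene` (e.g. annotation columns).
#' @param table_a,table_b Cohort count data frames.
#' @return Data frame `gene`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `q`.
#' @export
burden_scan <- function(gene_map, table_a, table_b) {
  genes <- unique(gene_map$gene)
  res <- lapply(genes, function(g) {
    ids <- gene_map$variant_id[gene_map$gene == g]
    br <- gene_burden(ids, table_a, table_b, gene = g)
    data.frame(gene = g, a = br$table[1, 1], b = br$table[1, 2],
               c = br$table[2, 1], d = br$table[2, 2],
               odds_ratio = br$odds_ratio, p = br$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
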
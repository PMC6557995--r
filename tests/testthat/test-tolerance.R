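# PSSM parsing and substitution-tolerance scoring.

test_that("parser recovers planted rows and reports bad rows by line", {
  # plant a row echoing a aspartate -> histidine substitution: D scores 6,
  # H scores -3, so delta S = -9
  wt <- c("M", "K", "L", "A", "G", "R", "D", "E")
  m <- toy_pssm(wt, overrides = list(list(7, "H", -3), list(7, "D", 6)))
  f <- tempfile()
  write_pssm_ascii(m, f)
  got <- parse_pssm_ascii(f)
  expect_equal(unname(got$scores[7, "H"]), -3L)
  expect_equal(unname(got$scores[7, "D"]), 6L)
  expect_identical(got$wild_type, wt)
  # truncate one data row -> parse error naming the line
  lines <- readLines(f)
  data_line <- grep("^\\s*7\\s+D", lines)
  lines[data_line] <- substr(lines[data_line], 1, 30)
  f2 <- tempfile()
  writeLines(lines, f2)
  expect_error(parse_pssm_ascii(f2), sprintf("line %d", data_line),
               class = "varcoseg_parse_error")
})

test_that("delta S is the mutant-minus-wild-type log-odds difference", {
  wt <- c("M", "K", "L", "A", "G", "R", "D", "E")
  m <- toy_pssm(wt, overrides = list(list(7, "H", -3), list(7, "D", 6)))
  expect_equal(delta_s(m, 7, "D", "H")$delta_s, -9L)
  # identity substitution scores zero at every position
  for (i in seq_along(wt))
    expect_equal(delta_s(m, i, wt[i], wt[i])$delta_s, 0L)
  expect_error(delta_s(m, 0, "M", "A"), class = "varcoseg_data_error")
  expect_error(delta_s(m, 7, "E", "H"), "mismatch",
               class = "varcoseg_data_error")
  expect_error(delta_s(m, 7, "D", "Z"), class = "varcoseg_data_error")
})

test_that("mean delta S averages per-mutation scores and parses HGVS", {
  # two substitutions scoring -3 and -1 average to -2
  wt <- rep("D", 80)
  m <- toy_pssm(wt, overrides = list(list(73, "H", -3), list(42, "Q", -1)))
  expect_equal(mean_delta_s(m, c("p.D73H", "p.D42Q")), -2)
  expect_equal(mean_delta_s(m, "p.D73H"), -3)
  expect_equal(mean_delta_s(m, data.frame(position = c(1, 2, 3), wt = "D",
                                          mut = "D")), 0)
  expect_error(mean_delta_s(m, data.frame()), class = "varcoseg_data_error")
  expect_error(mean_delta_s(m, "p.D73fs"), class = "varcoseg_parse_error")
})

test_that("row translation leaves delta S unchanged", {
  m <- simulate_pssm(25, 0.5, seed = 14)
  shifted <- m
  shifted$scores[10, ] <- shifted$scores[10, ] + 7L
  for (a in setdiff(varcoseg:::AA_ALPHABET, m$wild_type[10]))
    expect_equal(delta_s(shifted, 10, m$wild_type[10], a)$delta_s,
                 delta_s(m, 10, m$wild_type[10], a)$delta_s)
})

test_that("null sampling is deterministic, flat matrices give zero means", {
  flat <- toy_pssm(rep("A", 15))  # all scores equal
  nl <- sample_null(flat, set_size = 3, n_sets = 500, seed = 2)
  expect_true(all(nl$samples == 0))
  m <- simulate_pssm(40, 0.5, seed = 3)
  n1 <- sample_null(m, 3, 1000, seed = 9)
  n2 <- sample_null(m, 3, 1000, seed = 9)
  expect_identical(n1$samples, n2$samples)
})

test_that("null mean converges to the enumeration expectation", {
  m <- simulate_pssm(50, 0.4, seed = 21)
  nl <- sample_null(m, set_size = 3, n_sets = 10000, seed = 5)
  exact <- expected_delta_s(m)
  se <- stats::sd(nl$samples) / sqrt(nl$n_sets)
  expect_lt(abs(mean(nl$samples) - exact), 3 * se)
  # oracle cross-check of the expectation itself on a tiny matrix
  tiny <- simulate_pssm(4, 0.5, seed = 2)
  wt_idx <- match(tiny$wild_type, varcoseg:::AA_ALPHABET)
  acc <- 0
  for (p in 1:4) for (a in seq_len(20)) if (a != wt_idx[p])
    acc <- acc + tiny$scores[p, a] - tiny$scores[p, wt_idx[p]]
  expect_equal(expected_delta_s(tiny), acc / (19 * 4))
})

test_that("empirical p is the add-one lower-tail estimate and is monotone", {
  nl <- structure(list(set_size = 1L, n_sets = 5L,
                       samples = c(-3, -1, 0, 2, 4), seed = 1L),
                  class = "tolerance_null")
  expect_equal(empirical_p(-10, nl), 1 / 6)
  expect_equal(empirical_p(10, nl), 1)
  expect_equal(empirical_p(0, nl), 4 / 6)  # median of odd-sized null
  obs <- seq(-5, 5, by = 0.5)
  ps <- vapply(obs, empirical_p, numeric(1), null = nl)
  expect_false(is.unsorted(ps))
})
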
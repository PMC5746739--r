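make_raw <- function(frag, mid, sd = 0.001, ion_count = 1e6) {
  obs <- convolve_fragment(mid, frag)
  measurement_set(data.frame(
    fragment_id = frag$fragment_id, species = frag$amino_acid,
    carbons = paste(frag$carbons, collapse = ","), kind = "raw",
    index = paste0("M", seq_along(obs) - 1L), value = obs, sd = sd,
    ion_count = ion_count, stringsAsFactors = FALSE))
}

test_that("correction matrix of a bare fragment is the identity", {
  frag <- fragment_spec("bare", "X", 1:2, c(C = 0))
  M <- build_correction_matrix(frag)
  expect_equal(unname(M[1:3, ]), diag(3))
})

test_that("correction matrix column 0 equals the polynomial-expansion envelope", {
  frag <- fragment_spec("tb", "X", 1:3, c(C = 8, H = 19, O = 2, N = 1, Si = 1))
  # independent oracle: expand the generating polynomial by brute force over
  # per-atom isotope states, collecting mass-shift probabilities
  cst <- isotope_constants()
  env <- 1
  for (el in c(rep("C", 8), rep("H", 19), rep("O", 2), "N", "Si")) {
    d <- cst[[el]]
    new_env <- numeric(length(env) + length(d) - 1)
    for (i in seq_along(env)) {
      for (j in seq_along(d)) {
        new_env[i + j - 1] <- new_env[i + j - 1] + env[i] * d[j]
      }
    }
    env <- new_env
  }
  M <- build_correction_matrix(frag)
  k <- nrow(M) - 4L
  expect_equal(unname(M[seq_len(k + 1), 1]), env[seq_len(k + 1)],
               tolerance = 1e-12)
  expect_true(all(colSums(M) > 0.99 & colSums(M) <= 1 + 1e-12))
})

test_that("negative element counts are rejected", {
  expect_error(fragment_spec("x", "X", 1:2, c(C = 3, Si = -1)), "negative")
  expect_error(fragment_spec("x", "X", 1:2, c(Xx = 2)), "unknown element")
})

test_that("forward convolution then correction recovers backbone MIDs", {
  panel <- default_fragment_panel()
  set.seed(11)
  for (frag in panel) {
    n <- length(frag$carbons)
    for (k in 1:3) {
      mid <- runif(n + 1); mid <- mid / sum(mid)
      corr <- correct_natural_abundance(make_raw(frag, mid), panel)
      expect_lt(max(abs(corr$value - mid)), 1e-6)
      expect_identical(unique(corr$fragment_id), frag$fragment_id)
    }
  }
})

test_that("correcting a pure-M0 backbone yields M0 = 1 and empty spectra error", {
  panel <- default_fragment_panel()
  frag <- panel$Ala_M57
  corr <- correct_natural_abundance(make_raw(frag, c(1, 0, 0, 0)), panel)
  expect_equal(corr$value[1], 1, tolerance = 1e-3)
  raw0 <- make_raw(frag, c(1, 0, 0, 0))
  raw0$value <- 0
  expect_error(correct_natural_abundance(raw0, panel), "empty spectrum")
})

test_that("negative corrected entries are retained unless clamped", {
  panel <- default_fragment_panel()
  frag <- panel$Gly_M57
  raw <- make_raw(frag, c(0.98, 0.02, 0))
  # baseline correction ate most of the M1 channel: the deconvolved backbone
  # M1 goes negative and must be passed through as such
  raw$value[2] <- raw$value[2] - 0.05
  corr <- correct_natural_abundance(raw, panel)
  expect_true(any(corr$value < 0))
  expect_equal(sum(corr$value), 1, tolerance = 1e-9)
  clamped <- correct_natural_abundance(raw, panel, clamp = TRUE)
  expect_true(all(clamped$value >= 0))
  expect_equal(sum(clamped$value), 1, tolerance = 1e-9)
})

test_that("fractional enrichment follows its definition, unclamped", {
  expect_equal(fractional_enrichment(c(0.8, 0.2)), 0.2)
  expect_equal(fractional_enrichment(c(1, 0, 0, 0)), 0)
  expect_lt(fractional_enrichment(c(1.06, -0.08, 0.02, 0)), 0)
  # linearity: enrichment of a convex mixture is the mixture of enrichments
  set.seed(3)
  a <- runif(4); a <- a / sum(a); b <- runif(4); b <- b / sum(b)
  for (w in c(0, 0.3, 0.7, 1)) {
    expect_equal(fractional_enrichment(w * a + (1 - w) * b),
                 w * fractional_enrichment(a) +
                   (1 - w) * fractional_enrichment(b),
                 tolerance = 1e-12)
  }
})

test_that("ion-count QC removes only sub-threshold fragments", {
  ms <- measurement_set(data.frame(
    fragment_id = rep(c("f1", "f2", "f3"), each = 2), species = "X",
    carbons = "1", kind = "mid", index = rep(c("M0", "M1"), 3),
    value = 0.5, sd = 0.001,
    ion_count = rep(c(9e4, 1e5, 2e6), each = 2)))
  kept <- suppressMessages(filter_by_ion_count(ms, qc_rule(1e5)))
  expect_setequal(unique(kept$fragment_id), c("f2", "f3"))
  expect_identical(attr(kept, "removed"), "f1")
  empty <- measurement_set(ms[0, ])
  expect_equal(nrow(filter_by_ion_count(empty)), 0)
  all_kept <- filter_by_ion_count(ms, qc_rule(1e-6))
  expect_equal(nrow(all_kept), nrow(ms))
})

test_that("averaging measurement sets is the weighted per-isotopomer mean", {
  base <- measurement_set(data.frame(
    fragment_id = "f", species = "X", carbons = "1", kind = "mid",
    index = c("M0", "M1"), value = c(1, 0), sd = 0.001, ion_count = 1e6))
  other <- base; other$value <- c(0, 1)
  avg <- average_measurement_sets(list(base, other), c(0.5, 0.5))
  expect_equal(avg$value, c(0.5, 0.5))
  ident <- average_measurement_sets(list(base, other), c(1, 0))
  expect_equal(ident$value, base$value)
  bad <- other; bad$fragment_id <- "g"
  expect_error(average_measurement_sets(list(base, bad), c(0.5, 0.5)),
               "mismatched panels")
})
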
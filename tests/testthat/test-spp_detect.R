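# independent oracle: optimal two-cluster partition by exhaustive
# enumeration of all 2^n binary splits (not restricted to sorted cuts)
brute_force_split <- function(x) {
  n <- length(x)
  best <- Inf
  best_mask <- NULL
  for (mask in 1:(2^n - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    ss <- sum((x[sel] - mean(x[sel]))^2) + sum((x[!sel] - mean(x[!sel]))^2)
    if (ss < best - 1e-12) {
      best <- ss
      best_mask <- sel
    }
  }
  list(withinss = best, members = best_mask)
}

test_that("probe weights peak at the center and fall off symmetrically", {
  expect_equal(probe_weight(0), 1)
  expect_equal(probe_weight(12), 1 - (12 / 13)^2)
  expect_equal(probe_weight(-12), probe_weight(12))
  w <- probe_weight(0:12)
  expect_true(all(diff(w) < 0))
  expect_error(probe_weight(13), "outside the probe")
  # configurable length
  expect_equal(probe_weight(0, probe_length = 15), 1)
  expect_error(probe_weight(8, probe_length = 15), "outside")
})

test_that("position signals are threshold-gated weighted means", {
  # probe pA covers position 37 at its center (start 25), probe pB at
  # offset +12 (start 13); one AG probe for completeness
  design <- as_probe_design(data.frame(
    probe_id = c("pA", "pB", "ag1"),
    unigene_id = c("u1", "u1", NA), start = c(25L, 13L, NA),
    length = 25L, gc = 10L, antigenomic = c(0L, 0L, 1L)))
  manifest <- toy_manifest(2, 2)
  mat <- matrix(0, 3, 4, dimnames = list(design$probe_id, manifest$chip_id))
  mat["pA", ] <- 100
  mat["pB", ] <- 200
  mat["ag1", ] <- 1
  panel <- fake_panel(mat, design, manifest,
                      stats::setNames(rep(10, 4), manifest$chip_id))
  prof <- position_signals(panel, min_informative = 1)
  i37 <- which(prof$positions$position == 37)
  w12 <- probe_weight(12)
  expect_equal(unname(prof$signal[i37, 1]),
               (1 * 100 + w12 * 200) / (1 + w12), tolerance = 1e-12)
  # position 25: only pA's first base and pB center -> check single-probe rule
  i13 <- which(prof$positions$position == 13)  # covered by pB alone
  expect_equal(unname(prof$signal[i13, 1]), 200)

  # a probe below the chip threshold is excluded and the mean recomputed
  mat2 <- mat; mat2["pB", 1] <- 5
  panel2 <- fake_panel(mat2, design, manifest, panel$thresholds)
  prof2 <- position_signals(panel2, min_informative = 1)
  expect_equal(unname(prof2$signal[i37, 1]), 100)
  expect_equal(unname(prof2$informative[i37, 1]), 1)
  # and with min_informative = 2 that position/chip becomes undefined
  prof3 <- position_signals(panel2, min_informative = 2)
  expect_true(is.na(prof3$signal[i37, 1]))
  expect_false(is.na(prof3$signal[i37, 2]))
})

test_that("mode fitting is exact, deterministic and matches brute force", {
  f <- fit_modes(c(a = 100, b = 100, c = 300, d = 300))
  expect_equal(f$low_mean, 100)
  expect_equal(f$high_mean, 300)
  expect_equal(f$ratio, 3)
  expect_setequal(f$high_members, c("c", "d"))

  flat <- fit_modes(c(a = 5, b = 5, c = 5, d = 5))
  expect_equal(flat$ratio, 1)

  expect_null(fit_modes(c(1, 2, NA, NA, 3)))   # < 4 defined signals

  # oracle equivalence over random draws, several n
  withr::with_seed(99, {
    for (rep in 1:40) {
      n <- sample(4:10, 1)
      x <- c(rnorm(ceiling(n / 2), 100, 10), rnorm(floor(n / 2), 300, 40))
      x <- abs(x[sample(n)])
      names(x) <- paste0("c", seq_len(n))
      f <- fit_modes(x)
      o <- brute_force_split(x)
      expect_equal(f$withinss, o$withinss, tolerance = 1e-9)
    }
  })
})

test_that("chip allele calls respect the high mode and the no-call margin", {
  x <- c(c1 = 100, c2 = 110, c3 = 300, c4 = 310)
  f <- fit_modes(x)
  calls <- call_chip_allele(x, f)
  expect_equal(unname(calls), c("B", "B", "A", "A"))

  # a signal exactly at the midpoint is within the margin -> no call
  x2 <- c(x, c5 = f$midpoint)
  expect_equal(unname(call_chip_allele(x2, f)["c5"]), "-")
  # missing signal -> no call
  x3 <- c(x, c5 = NA)
  expect_equal(unname(call_chip_allele(x3, f)["c5"]), "-")
  # margin zero keeps midpoint-adjacent calls
  expect_equal(unname(call_chip_allele(c(c5 = f$midpoint + 1e-9), f,
                                       nocall_margin = 0)), "A")
  flat <- fit_modes(c(a = 1, b = 1, c = 1, d = 1))
  expect_error(call_chip_allele(c(a = 1), flat), "ratio > 1")
})

test_that("replicate summarization reproduces the published rule table", {
  # expected mapping written out independently of the implementation:
  # unanimous -> allele; two alleles + missing -> C/D; conflicts or a
  # single call -> I; all missing -> -
  expected <- function(calls) {
    nA <- sum(calls == "A"); nB <- sum(calls == "B")
    if (nA == 3) "A"
    else if (nB == 3) "B"
    else if (nA == 0 && nB == 0) "-"
    else if (nA > 0 && nB > 0) "I"
    else if (nB == 2) "C"
    else if (nA == 2) "D"
    else "I"
  }
  grid <- expand.grid(r1 = c("A", "B", "-"), r2 = c("A", "B", "-"),
                      r3 = c("A", "B", "-"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    triple <- unlist(grid[i, ])
    expect_equal(summarize_replicates(triple), expected(triple),
                 label = paste(triple, collapse = "/"))
  }
  # spot checks straight from the published list
  expect_equal(summarize_replicates(c("A", "A", "A")), "A")
  expect_equal(summarize_replicates(c("B", "B", "-")), "C")
  expect_equal(summarize_replicates(c("A", "A", "-")), "D")
  expect_equal(summarize_replicates(c("-", "-", "-")), "-")
  expect_equal(summarize_replicates(c("A", "B", "-")), "I")
  expect_equal(summarize_replicates(c("-", "-", "B")), "I")
  expect_error(summarize_replicates(c("A", "X", "B")), "invalid")
})

test_that("run assembly merges coherent adjacent positions and splits on gaps", {
  manifest <- toy_manifest(2, 2)   # 4 chips
  chips <- manifest$chip_id
  design <- as_probe_design(data.frame(
    probe_id = sprintf("p%02d", 1:40), unigene_id = "u1",
    start = seq(1L, 79L, 2L), length = 25L, gc = 10L, antigenomic = 0L))
  positions <- data.frame(unigene_id = "u1", position = 30:40,
                          stringsAsFactors = FALSE)
  profiles <- structure(list(
    positions = positions,
    tiling = as.data.frame(design),
    probe_above_fraction = stats::setNames(rep(1, 40), design$probe_id)),
    class = "position_profiles")

  part <- c("A", "A", "B", "B")
  calls <- matrix(rep(part, each = 11), nrow = 11,
                  dimnames = list(NULL, chips))
  ratios <- rep(2, 11)
  # three adjacent evaluable positions -> one marker spanning them
  r1 <- ratios; r1[4:11] <- NA
  c1 <- calls; c1[4:11, ] <- NA
  out <- assemble_spps(profiles, c1, r1, manifest,
                       min_ratio = 1.2, min_informative = 1, min_span = 1)
  expect_equal(n_spps(out), 1L)
  expect_equal(out$markers$start, 30L)
  expect_equal(out$markers$end, 32L)
  expect_equal(out$markers$span, 3L)
  expect_equal(unname(out$calls[1, ]), c("A", "B"))  # unanimous duplicates

  # a non-evaluable gap splits one polymorphic stretch into two markers
  r2 <- ratios; r2[6] <- NA
  c2 <- calls; c2[6, ] <- NA
  out2 <- assemble_spps(profiles, c2, r2, manifest,
                        min_ratio = 1.2, min_informative = 1, min_span = 1)
  expect_equal(n_spps(out2), 2L)
  expect_equal(out2$markers$start, c(30L, 36L))

  # a partition flip splits the run too
  c3 <- calls; c3[6:11, ] <- rep(c("B", "B", "A", "A"), each = 6)
  out3 <- assemble_spps(profiles, c3, ratios, manifest,
                        min_ratio = 1.2, min_informative = 1, min_span = 1)
  expect_equal(n_spps(out3), 2L)

  # filters are monotone: stronger settings emit no extra markers
  loose <- assemble_spps(profiles, c2, r2, manifest, 1.2, 1, 1)
  tight <- assemble_spps(profiles, c2, r2, manifest, 3, 1, 1)
  expect_lte(n_spps(tight), n_spps(loose))
})

test_that("detection is invariant to a common intensity scale factor", {
  sim <- small_sim()
  skip_scale <- preset_params("lowFDR-1.5")
  skip_scale$drop_multicopy <- FALSE
  res1 <- run_pipeline(sim$intensities, sim$design, sim$manifest,
                       params = skip_scale)
  res2 <- run_pipeline(sim$intensities * 2.5, sim$design, sim$manifest,
                       params = skip_scale)
  expect_equal(res1$spps$markers$spp_id, res2$spps$markers$spp_id)
  expect_equal(res1$spps$calls, res2$spps$calls)
})

test_that("raising detection stringency never adds markers", {
  run <- small_run()
  raw <- run$spps_raw
  n_at <- function(ratio, span, maxI) {
    p <- filter_params(min_ratio = ratio, min_span = span,
                       max_inconsistent_fraction = maxI)
    n_spps(apply_filters(raw, p))
  }
  for (span in c(2, 4))
    expect_true(all(diff(sapply(c(1.2, 1.5, 2.0), n_at,
                                span = span, maxI = 1)) <= 0))
  expect_lte(n_at(1.2, 4, 1), n_at(1.2, 2, 1))
  expect_lte(n_at(1.2, 4, 0), n_at(1.2, 4, 0.4))
})
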
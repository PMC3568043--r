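lines4 <- sprintf("L%02d", 1:4)

test_that("allele frequencies count A/D and B/C alleles over called lines", {
  calls <- rbind(c("A", "A", "B", "B"),
                 c("A", "A", "A", "A"),
                 c("A", "D", "C", "-"),
                 c("-", "-", "-", "-"))
  colnames(calls) <- lines4
  f <- allele_frequencies(toy_spp_set(calls))
  expect_equal(f$freq_A, c(0.5, 1, 2 / 3, NA))
  expect_equal(f$maf, c(0.5, 0, 1 / 3, NA))
  expect_equal(f$minor_count, c(2L, 0L, 1L, NA))
  expect_equal(f$minor_allele[1], "A")   # 0.5 tie reported with A minor

  # counting oracle on a random fixture
  lines <- sprintf("L%02d", 1:12)
  calls_big <- random_calls(80, lines, seed = 31,
                            symbols = c("A", "B", "C", "D", "I", "-"),
                            prob = c(.3, .3, .1, .1, .1, .1))
  f_big <- allele_frequencies(toy_spp_set(calls_big))
  for (i in c(1, 17, 80)) {
    nA <- sum(calls_big[i, ] %in% c("A", "D"))
    nB <- sum(calls_big[i, ] %in% c("B", "C"))
    expect_equal(f_big$freq_A[i], nA / (nA + nB))
  }
  # subset restriction
  f_sub <- allele_frequencies(toy_spp_set(calls), lines = c("L01", "L02"))
  expect_equal(f_sub$freq_A[1], 1)
  expect_error(allele_frequencies(toy_spp_set(calls), lines = "L99"),
               "unknown line")
})

test_that("unique allele counts attribute singletons to their carrier", {
  calls <- rbind(c("B", "A", "A", "A"),
                 c("B", "A", "A", "A"),
                 c("B", "A", "A", "A"),
                 c("A", "A", "B", "B"))
  colnames(calls) <- lines4
  u <- unique_allele_counts(toy_spp_set(calls))
  expect_equal(unname(u$per_line["L01"]), 3L)
  expect_equal(unname(u$per_line["L02"]), 0L)
  expect_equal(u$n_spp_with_unique, 3L)

  shared <- toy_spp_set(matrix("A", 5, 4, dimnames = list(NULL, lines4)))
  expect_equal(sum(unique_allele_counts(shared)$per_line), 0L)

  # oracle on a random fixture; also the sum-of-singletons invariant
  lines <- sprintf("L%02d", 1:20)
  calls_big <- random_calls(200, lines, seed = 77,
                            prob = c(0.85, 0.15))
  u_big <- unique_allele_counts(toy_spp_set(calls_big))
  brute <- stats::setNames(integer(20), lines)
  n_single <- 0L
  for (i in 1:200) {
    for (sym in c("A", "B")) {
      k <- which(calls_big[i, ] == sym)
      if (length(k) == 1L) brute[k] <- brute[k] + 1L
    }
    if (sum(calls_big[i, ] == "A") == 1L || sum(calls_big[i, ] == "B") == 1L)
      n_single <- n_single + 1L
  }
  expect_equal(u_big$per_line, brute)
  expect_equal(u_big$n_spp_with_unique, n_single)
  expect_equal(sum(u_big$per_line), n_single)  # each singleton counted once
})

test_that("group polymorphism Venn regions partition the evaluated set", {
  lines <- sprintf("L%02d", 1:9)
  groups <- list(g1 = lines[1:3], g2 = lines[4:6], g3 = lines[7:9])
  calls <- rbind(
    c("A", "B", "A",  "A", "A", "A",  "A", "A", "A"),  # poly in g1 only
    c("A", "B", "A",  "B", "A", "A",  "A", "A", "A"),  # g1 and g2
    c("A", "A", "A",  "B", "B", "B",  "A", "A", "A"),  # across, none within
    c("A", "B", "B",  "A", "B", "A",  "B", "A", "B"))  # all three
  colnames(calls) <- lines
  spps <- toy_spp_set(calls)
  venn <- group_polymorphism(spps, groups, min_minor_count_overall = 0)
  get <- function(r) venn$n_spp[venn$region == r]
  expect_equal(get("g1"), 1L)
  expect_equal(get("g1+g2"), 1L)
  expect_equal(get("none"), 1L)
  expect_equal(get("g1+g2+g3"), 1L)
  expect_equal(sum(venn$n_spp), n_spps(spps))

  # the overall minor-count threshold trims the evaluated set first
  venn2 <- group_polymorphism(spps, groups, min_minor_count_overall = 2)
  expect_equal(sum(venn2$n_spp),
               sum(allele_frequencies(spps)$minor_count > 2))

  # a single-line group is a structural zero
  g0 <- list(solo = lines[1], rest = lines[-1])
  venn3 <- group_polymorphism(spps, g0, min_minor_count_overall = 0)
  expect_equal(venn3$n_spp[venn3$region == "solo"], 0L)

  # brute-force set algebra on a random fixture
  calls_big <- random_calls(150, lines, seed = 41, prob = c(0.7, 0.3))
  spps_big <- toy_spp_set(calls_big)
  venn_big <- group_polymorphism(spps_big, groups,
                                 min_minor_count_overall = 1)
  memb <- attr(venn_big, "membership")
  keep <- allele_frequencies(spps_big)$minor_count > 1
  for (g in names(groups)) {
    poly_in <- apply(calls_big[keep, groups[[g]]], 1, function(r)
      any(r %in% c("A", "D")) && any(r %in% c("B", "C")))
    expect_equal(unname(memb[, g]), unname(poly_in))
  }
})

test_that("MAF matrix bins markers and conserves marginals", {
  lines <- sprintf("L%02d", 1:8)
  ga <- lines[1:4]; gb <- lines[5:8]
  calls <- rbind(c("A", "A", "A", "B",  "A", "A", "B", "B"))
  colnames(calls) <- lines
  m <- maf_matrix(toy_spp_set(calls), ga, gb)
  expect_equal(sum(m), 1)
  ba <- as.character(cut(0.25, seq(0, 0.5, 0.05), include.lowest = TRUE))
  bb <- as.character(cut(0.5, seq(0, 0.5, 0.05), include.lowest = TRUE))
  expect_equal(unname(m[ba, bb]), 1)

  calls_big <- random_calls(120, lines, seed = 55)
  m_big <- maf_matrix(toy_spp_set(calls_big), ga, gb)
  expect_equal(sum(m_big), 120)
  expect_equal(unname(attr(m_big, "marginal_a")), unname(rowSums(m_big)))
  expect_equal(unname(attr(m_big, "marginal_b")), unname(colSums(m_big)))
})

test_that("informative markers require strict MAF excess in every group", {
  lines <- sprintf("L%02d", 1:8)
  groups <- list(a = lines[1:4], b = lines[5:8])
  calls <- rbind(c("A", "A", "A", "B",  "A", "A", "B", "B"),  # 0.25 in a
                 c("A", "A", "B", "B",  "A", "A", "B", "B"))  # 0.5 both
  colnames(calls) <- lines
  res <- informative_markers(toy_spp_set(calls), groups)
  expect_equal(res$n, 1L)                    # exactly 0.25 excluded
  expect_equal(res$spp_id, "u1:100")
})

test_that("gene diversity closed forms and exclusions", {
  calls <- rbind(c("A", "A", "B", "B"),
                 c("A", "A", "A", "A"),
                 c("A", "B", "B", "B"),
                 c("A", "-", "-", "-"))
  colnames(calls) <- lines4
  g <- gene_diversity(toy_spp_set(calls))
  expect_equal(g$per_spp$he[1], 0.5)
  expect_equal(g$per_spp$he[2], 0)
  expect_equal(g$per_spp$he[3], 0.375)
  expect_true(is.na(g$per_spp$he[4]))
  expect_equal(g$n_excluded, 1L)
  expect_equal(g$mean_he, mean(c(0.5, 0, 0.375)))
  # bounded by 0.5 for biallelic markers, maximal at balance
  expect_true(all(g$per_spp$he <= 0.5, na.rm = TRUE))
})

test_that("unigene haplotypes group complete allele profiles", {
  calls <- rbind(c("A", "A", "A", "B"),
                 c("A", "A", "B", "B"))
  colnames(calls) <- lines4
  spps <- toy_spp_set(calls, unigene_id = c("u1", "u1"),
                      start = c(10L, 40L))
  haps <- unigene_haplotypes(spps)
  h <- haps$haplotypes
  expect_equal(nrow(h), 3L)                       # AA, AB, BB
  expect_setequal(h$profile, c("AA", "AB", "BB"))
  expect_equal(sort(h$frequency), c(0.25, 0.25, 0.5))
  expect_equal(sum(h$frequency), 1)

  # lines with missing calls are excluded and logged
  calls2 <- calls; calls2[2, "L01"] <- "-"
  haps2 <- unigene_haplotypes(toy_spp_set(calls2,
                                          unigene_id = c("u1", "u1"),
                                          start = c(10L, 40L)))
  expect_equal(haps2$excluded$line_id, "L01")
  expect_equal(sum(haps2$haplotypes$frequency), 1)  # renormalized over 3

  # single-SPP unigene: haplotypes are the alleles
  haps3 <- unigene_haplotypes(toy_spp_set(calls[1, , drop = FALSE]))
  expect_setequal(haps3$haplotypes$profile, c("A", "B"))
})

test_that("haplotype frequency matrix carries per-line frequencies", {
  lines <- sprintf("L%02d", 1:40)
  calls <- matrix("A", 1, 40, dimnames = list(NULL, lines))
  calls[1, 31:40] <- "B"                       # counts 30 / 10
  spps <- toy_spp_set(calls)
  hfm <- haplotype_frequency_matrix(unigene_haplotypes(spps))
  expect_equal(unname(hfm["L40", 1]), 0.25)
  expect_equal(unname(hfm["L01", 1]), 0.75)

  mono <- toy_spp_set(matrix("A", 1, 40, dimnames = list(NULL, lines)))
  hfm_mono <- haplotype_frequency_matrix(unigene_haplotypes(mono))
  expect_true(all(hfm_mono == 1))

  # conservation: sum over lines of cells equals sum of count^2 / n
  calls3 <- random_calls(3, lines, seed = 9)
  haps3 <- unigene_haplotypes(toy_spp_set(calls3,
                                          unigene_id = c("u1", "u2", "u3")))
  hfm3 <- haplotype_frequency_matrix(haps3)
  for (u in colnames(hfm3)) {
    counts <- haps3$haplotypes$count[haps3$haplotypes$unigene_id == u]
    expect_equal(sum(hfm3[, u]), sum(counts^2) / 40)
  }
  expect_true(all(hfm3 > 0 & hfm3 <= 1))
})

test_that("monomorphic region scan reports maximal cM runs", {
  lines <- sprintf("L%02d", 1:6)
  unis <- sprintf("u%02d", 1:10)
  calls <- matrix("A", 10, 6, dimnames = list(NULL, lines))
  calls[c(1, 2, 8, 9, 10), 1] <- "B"          # polymorphic rows
  spps <- toy_spp_set(calls, unigene_id = unis,
                      start = rep(10L, 10))
  map <- data.frame(unigene_id = unis, linkage_group = "P2",
                    cM = c(1, 2, 4, 5, 6, 7, 9, 11, 12, 13))
  runs <- monomorphic_region_scan(spps, map)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_spp, 5L)
  expect_equal(runs$start_cM, 4)
  expect_equal(runs$end_cM, 9)
  expect_equal(runs$extent_cM, 5)
  expect_equal(runs$n_unigene, 5L)

  # fully polymorphic chromosome: nothing to report
  poly <- toy_spp_set(rbind(matrix(rep(c("A", "B"), each = 3), 10, 6,
                                   byrow = TRUE,
                                   dimnames = list(NULL, lines))),
                      unigene_id = unis, start = rep(10L, 10))
  expect_equal(nrow(monomorphic_region_scan(poly, map)), 0L)

  # anchored query keeps only runs containing the anchor
  anchored <- monomorphic_region_scan(spps, map, anchor_unigene = "u04")
  expect_equal(nrow(anchored), 1L)
  expect_equal(nrow(monomorphic_region_scan(spps, map,
                                            anchor_unigene = "u01")), 0L)
})

test_that("Structure export dedups linked profiles within bins", {
  lines <- sprintf("L%02d", 1:5)
  calls <- rbind(c("A", "A", "B", "B", "A"),
                 c("A", "A", "B", "B", "A"),   # identical profile, same bin
                 c("A", "A", "B", "B", "A"),   # identical profile, bin 2
                 c("B", "A", "B", "A", "-"))
  colnames(calls) <- lines
  spps <- toy_spp_set(calls, unigene_id = c("u1", "u2", "u3", "u4"),
                      start = rep(10L, 4))
  map <- data.frame(unigene_id = c("u1", "u2", "u3", "u4"),
                    linkage_group = c("P1", "P1", "P1", "P2"),
                    cM = c(0, 3.5, 10, 0), bin = c("b1", "b1", "b2", "b3"))
  path <- tempfile()
  info <- export_structure_input(spps, map, path)
  expect_equal(nrow(info), 3L)                 # one of u1/u2 dropped
  expect_true("b2" %in% info$bin)              # same profile, other bin kept

  ln <- readLines(path)
  expect_equal(length(ln), 2 + 5)
  dist_row <- as.numeric(strsplit(ln[2], "\t")[[1]])
  expect_equal(dist_row, c(-1, 10, -1))        # new LG restarts at -1
  g1 <- strsplit(ln[3], "\t")[[1]]
  expect_equal(g1[1], "L01")
  expect_true(all(g1[-1] %in% c("0", "1", "-9")))
  l5 <- strsplit(ln[7], "\t")[[1]]
  expect_equal(l5[4], "-9")                    # missing call encoded -9

  diploid <- tempfile()
  export_structure_input(spps, map, diploid, diploid = TRUE)
  expect_equal(length(readLines(diploid)), 2 + 10)

  expect_error(export_structure_input(
    spps, map[0, ], tempfile()), "no markers")
})

test_that("PHYLIP restriction export recodes, thins and round-trips", {
  lines <- sprintf("L%02d", 1:4)
  calls <- rbind(c("A", "A", "B", "B"),
                 c("A", "B", "A", "B"),
                 c("B", "B", "A", "A"))
  colnames(calls) <- lines
  spps <- toy_spp_set(calls, unigene_id = c("u1", "u2", "u3"),
                      start = rep(10L, 3))
  path <- tempfile()
  mat <- export_phylip_restriction(spps, path)
  ln <- readLines(path)
  expect_match(ln[1], "^\\s*4\\s+3\\s*$")
  expect_equal(nchar(ln[2]), 10 + 3)
  back <- read_phylip_restriction(path)
  expect_equal(back, `colnames<-`(mat, NULL))
  expect_equal(unname(back["L01", ]), c("1", "1", "0"))

  # a marker whose minor allele is private to an excluded line drops out
  calls2 <- rbind(calls, c("B", "A", "A", "A"))
  spps2 <- toy_spp_set(calls2, unigene_id = c("u1", "u2", "u3", "u4"),
                       start = rep(10L, 4))
  mat2 <- export_phylip_restriction(spps2, tempfile(), exclude = "L01")
  expect_equal(ncol(mat2), 3L)   # u4's allele is private to L01: dropped
  expect_false("u4:10" %in% colnames(mat2))
  expect_equal(nrow(mat2), 3L)

  # within-unigene linked profiles are thinned to one representative
  calls3 <- rbind(calls[1, , drop = FALSE], calls[1, , drop = FALSE])
  spps3 <- toy_spp_set(calls3, unigene_id = c("u1", "u1"),
                       start = c(10L, 60L))
  expect_equal(ncol(export_phylip_restriction(spps3, tempfile())), 1L)

  # outgroup listed first; truncation collisions are an error
  mat4 <- export_phylip_restriction(spps, tempfile(), outgroup = "L03")
  expect_equal(rownames(mat4)[1], "L03")
  longnames <- c("SharedPrefix01", "SharedPrefix02", "X1", "X2")
  calls5 <- calls; colnames(calls5) <- longnames
  expect_error(export_phylip_restriction(toy_spp_set(calls5), tempfile()),
               "collide")
})
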
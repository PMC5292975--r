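test_that("pairwise LOD matches its closed form and is symmetric", {
  # n = 50 fully concordant lines
  gi <- rep(c(0L, 2L), 25)
  pl <- pairwise_lod(gi, gi)
  expect_equal(pl$lod, 50 * log10(2), tolerance = 1e-10)
  expect_equal(pl$r_hat, 0)
  # n = 100, k = 10
  gj <- gi2 <- rep(c(0L, 2L), 50)
  gj[1:10] <- 2L - gj[1:10]
  pl2 <- pairwise_lod(gi2, gj)
  expect_equal(pl2$lod, 10 * log10(0.2) + 90 * log10(1.8), tolerance = 1e-10)
  expect_equal(pl2$r_hat, 0.1)
  expect_equal(pairwise_lod(gj, gi2), pl2)
  # k = n/2: free recombination
  gk <- gi2; gk[seq(1, 100, 2)] <- 2L - gk[seq(1, 100, 2)]
  expect_equal(pairwise_lod(gi2, gk)$lod, 0)
  # hets and missing excluded; n = 0 flagged not thrown
  expect_equal(pairwise_lod(c(1L, NA), c(0L, 0L))$n, 0L)
  expect_true(is.na(pairwise_lod(c(1L, NA), c(0L, 0L))$lod))
})

test_that("pairwise_linkage agrees with per-pair pairwise_lod", {
  set.seed(3)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE,
                         prob = c(.4, .05, .4, .15)), 20, 10)
  g <- toy_geno(calls)
  pl <- pairwise_linkage(g)
  for (i in 1:9) for (j in (i + 1):10) {
    ref <- pairwise_lod(calls[, i], calls[, j])
    expect_equal(pl$n[i, j], ref$n)
    expect_equal(unname(pl$lod[i, j]), ref$lod)
  }
})

test_that("anchors are the zero-missing parent-discriminating markers", {
  gs <- small_genome()
  pop <- simulate_population(gs, n_lines = 40, n_markers = 300, seed = 71)
  # artifact-free: every marker qualifies
  expect_setequal(select_anchors(pop$geno), marker_info(pop$geno)$id)
  art <- artifact_spec(missing_rate = 0.4, missing_shape1 = 0.3,
                       error_rate = 0, n_misallocated = 0L,
                       inversion = NULL, distortion = NULL,
                       parent_missing = 0.3)
  obs <- inject_artifacts(pop$geno, pop$truth, art, seed = 72)$geno
  a <- select_anchors(obs)
  # brute-force recount of zero-missing columns
  x <- unclass(obs); pa <- parent_calls(obs)
  manual <- marker_info(obs)$id[colSums(is.na(x)) == 0 &
                                  !is.na(pa[1, ]) & !is.na(pa[2, ]) &
                                  pa[1, ] != pa[2, ] & pa[1, ] != 1 &
                                  pa[2, ] != 1]
  expect_setequal(a, manual)
  # a single missing RIL call excludes a marker
  x2 <- unclass(pop$geno)
  x2[1, 5] <- NA
  g2 <- geno_matrix(x2, marker_info(pop$geno),
                    parents = parent_calls(pop$geno), sort = FALSE)
  expect_false(marker_info(g2)$id[5] %in% select_anchors(g2))
})

test_that("linkage grouping recovers chromosomes and is order-invariant", {
  gs <- small_genome()
  pop <- simulate_population(gs, n_lines = 100, n_markers = 240, seed = 81,
                             marker_spacing = "even")
  gr <- cluster_groups(pop$geno, 10)
  expect_length(gr$members, 2L)
  split_chrom <- split(as.character(marker_info(pop$geno)$chrom), gr$group)
  for (memb in split_chrom) expect_length(unique(memb), 1L)
  # permuting marker input order leaves the partition unchanged
  perm <- sample(ncol(pop$geno))
  gr2 <- cluster_groups(pop$geno[, perm], 10)
  for (grp in gr$members)
    expect_true(any(vapply(gr2$members, setequal, TRUE, y = grp)))
  # threshold above every pairwise LOD: all singletons
  gr3 <- cluster_groups(pop$geno, 1e6)
  expect_equal(length(gr3$members), ncol(pop$geno))
})

test_that("misallocated anchors are flagged exactly, singletons never", {
  gs <- small_genome(n_chr = 3L)
  pop <- simulate_population(gs, n_lines = 100, n_markers = 360, seed = 91,
                             marker_spacing = "even")
  art <- artifact_spec(missing_rate = 0, error_rate = 0,
                       n_misallocated = 6L, inversion = NULL,
                       distortion = NULL, parent_missing = 0)
  out <- inject_artifacts(pop$geno, pop$truth, art, seed = 92)
  gr <- cluster_groups(out$geno, 10)
  flagged <- detect_misallocated(gr)
  expect_setequal(flagged, out$truth$artifacts$misallocated$id)
  # artifact-free data: nothing flagged
  expect_length(detect_misallocated(cluster_groups(pop$geno, 10)), 0L)
  # a chromosome represented by one marker is its own majority
  g1 <- toy_geno(cbind(rep(c(0L, 2L), 10), rep(c(0L, 2L), 10)),
                 chrom = c("1", "2"))
  gr1 <- cluster_groups(g1, 1e6)
  expect_length(detect_misallocated(gr1), 0L)
})

test_that("de novo ordering is brute-force optimal on small instances", {
  set.seed(7)
  for (rep in 1:25) {
    m <- sample(4:7, 1)
    d <- matrix(runif(m * m, 0.02, 0.5), m, m)
    d <- (d + t(d)) / 2; diag(d) <- 0
    ord <- order_denovo(d)
    expect_equal(gbsmap:::path_cost(d, ord), oracle_best_path(d),
                 tolerance = 1e-12)
  }
  # monotone distances: recovered order is the true order or its reverse
  m <- 5
  d <- abs(outer(1:m, 1:m, "-")) * 0.08
  ord <- order_denovo(d, pos = 1:m)
  expect_true(identical(ord, 1:m) || identical(ord, m:1))
  expect_equal(ord[1], 1L)  # orientation normalized by position
  expect_error(order_denovo(matrix(0.5, 3, 3)), "no linkage")
  expect_length(order_denovo(matrix(c(0, .1, .1, 0), 2), pos = c(5, 2)), 2L)
})

test_that("heuristic ordering matches the exact optimum above the DP limit", {
  set.seed(11)
  gs <- genome_spec(len_cM = 100, len_bp = 2e7, chrom = "1")
  pop <- simulate_population(gs, n_lines = 300, n_markers = 16, seed = 13,
                             marker_spacing = "even")
  r_hat <- pairwise_linkage(pop$geno)$r_hat
  ord <- order_denovo(r_hat, pos = marker_info(pop$geno)$pos)
  # at worst an equal-cost path: never worse than the generating order
  expect_lte(gbsmap:::path_cost(r_hat, ord),
             gbsmap:::path_cost(r_hat, 1:16) + 1e-9)
  expect_gt(cor(ord, 1:16, method = "spearman"), 0.99)
})

test_that("inversion detection reports planted reversed runs exactly", {
  ref <- paste0("m", 1:20)
  expect_equal(nrow(detect_inversions(ref, ref)), 0L)
  # one reversed block
  dn <- ref; dn[6:13] <- rev(dn[6:13])
  runs <- detect_inversions(ref, dn)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$type, "inversion")
  expect_setequal(runs$ids[[1L]], ref[6:13])
  # full reversal is orientation, not inversion
  runs2 <- detect_inversions(ref, rev(ref))
  expect_equal(runs2$type, "orientation")
  expect_equal(runs2$n, 20L)
  expect_error(detect_inversions(ref, ref[-1]), "same marker set")
})

test_that("a simulated inverted block is recovered from the de novo order", {
  gs <- genome_spec(len_cM = 106.7, len_bp = 35191472, chrom = "1",
                    landscape = list(data.frame(from = 0, to = 1, mult = 1)))
  pop <- simulate_population(gs, n_lines = 400, n_markers = 50, seed = 15,
                             marker_spacing = "even")
  art <- artifact_spec(missing_rate = 0, error_rate = 0,
                       n_misallocated = 0L,
                       inversion = list(chrom = "1", start_bp = 12e6,
                                        n_markers = 28L),
                       distortion = NULL, parent_missing = 0)
  out <- inject_artifacts(pop$geno, pop$truth, art, seed = 16)
  g <- out$geno
  r_hat <- pairwise_linkage(g)$r_hat
  ord <- order_denovo(r_hat, pos = marker_info(g)$pos)
  runs <- detect_inversions(marker_info(g)$id, marker_info(g)$id[ord])
  big <- runs[which.max(runs$n), ]
  expect_equal(big$n, 28L)
  expect_setequal(big$ids[[1L]], out$truth$artifacts$inverted)
})
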
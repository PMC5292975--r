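test_that("missing/MAF filter matches a brute-force per-column recount", {
  # hand cases: 95% missing dropped; 60:40 split kept at MAF 0.05
  calls <- rbind(matrix(NA_integer_, 19, 2), c(0L, 0L))
  calls[, 2] <- rep(c(0L, 0L, 0L, 2L, 2L), 4)
  g <- toy_geno(calls)
  v <- filter_missing_maf(g, max_missing = 0.9, min_maf = 0.05)$verdict
  expect_equal(v$status, c("dropped_missing", "kept"))
  expect_equal(unname(maf(g)[2]), 0.4)
  # random matrix vs recount
  set.seed(12)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 50 * 40, TRUE,
                         prob = c(.35, .05, .2, .4)), 50, 40)
  g <- toy_geno(calls)
  got <- filter_missing_maf(g, 0.3, 0.1)$verdict
  for (j in 1:40) {
    col <- calls[, j]
    miss <- mean(is.na(col))
    nA <- 2 * sum(col == 0, na.rm = TRUE) + sum(col == 1, na.rm = TRUE)
    nB <- 2 * sum(col == 2, na.rm = TRUE) + sum(col == 1, na.rm = TRUE)
    f <- if (nA + nB > 0) min(nA, nB) / (nA + nB) else NA
    want <- if (miss > 0.3) "dropped_missing"
    else if (is.na(f) || f < 0.1) "dropped_maf" else "kept"
    expect_equal(got$status[j], want)
  }
})

test_that("parental genotype inference orients, drops and completes", {
  # 10 lines, 4 markers: m1 oriented anchor; m2 unoriented in coupling
  # with m1 but coded flipped; m3 parents identical; m4 monomorphic
  calls <- cbind(c(0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L),
                 c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L),
                 c(0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L),
                 c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  pa <- rbind(c(0L, NA, 2L, 0L), c(2L, NA, 2L, 2L))
  mk <- data.frame(id = paste0("m", 1:4), chrom = "1",
                   pos = c(100, 200, 300, 400))
  g <- geno_matrix(calls, mk, parents = pa,
                   oriented = c(TRUE, FALSE, TRUE, TRUE))
  out <- infer_parental_genotypes(g)
  expect_equal(out$verdict$status,
               c("kept", "kept", "dropped_ambiguous_parent",
                 "dropped_monomorphic"))
  # m2 was re-phased: flipped to couple with m1
  expect_equal(unname(unclass(out$geno)[, "m2"]),
               c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L, 2L))
  expect_equal(out$n_flipped, 1L)
  # parent rows completed for kept markers
  expect_false(anyNA(parent_calls(out$geno)))
  # chromosome without any oriented marker: undecidable, not guessed
  g2 <- geno_matrix(calls[, 2, drop = FALSE],
                    mk[2, ], parents = pa[, 2, drop = FALSE],
                    oriented = FALSE)
  expect_warning(out2 <- infer_parental_genotypes(g2), "undecidable")
  expect_equal(out2$verdict$status, "dropped_ambiguous_parent")
})

test_that("fisher_exact_2x2 equals enumeration for all tables with n <= 30", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5))),
               2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(2, 2), c(2, 2))), 1)
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(2, 2))), "non-negative")
  # exhaustive sweep over every table with total n <= 30
  worst <- 0
  for (n in 0:30) for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
    d <- n - a - b - c
    p1 <- gbsmap:::fisher_p(a, b, c, d)
    p2 <- oracle_fisher(a, b, c, d)
    worst <- max(worst, abs(p1 - p2))
  }
  expect_lt(worst, 1e-10)
  # spot agreement with stats::fisher.test
  set.seed(4)
  for (k in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("anchor Fisher filter keeps coupled markers, drops shuffled ones", {
  gs <- small_genome()
  pop <- simulate_population(gs, n_lines = 109, n_markers = 500, seed = 21,
                             marker_spacing = "even")
  g <- pop$geno
  set.seed(22)
  anchors <- sort(sample(marker_info(g)$id, 120))
  # plant 40 permuted-genotype markers (decoupled from their neighbours)
  x <- unclass(g)
  non_anchor <- setdiff(marker_info(g)$id, anchors)
  planted <- sample(non_anchor, 40)
  for (id in planted) x[, id] <- sample(x[, id])
  gp <- geno_matrix(x, marker_info(g), parents = parent_calls(g), sort = FALSE)
  out <- anchor_fisher_filter(gp, anchors, 0.05)
  v <- out$verdict
  expect_true(all(v$status[v$id %in% anchors] == "kept"))
  # >= 95% of planted markers dropped
  expect_gte(mean(v$status[v$id %in% planted] == "dropped_fisher"), 0.95)
  # >= 99% of untouched markers kept (false-drop control)
  clean <- setdiff(non_anchor, planted)
  expect_gte(mean(v$status[v$id %in% clean] == "kept"), 0.99)
  # a copy of an anchor is maximally associated: kept
  x2 <- unclass(g)
  x2[, non_anchor[1]] <- x2[, anchors[5]]
  g2 <- geno_matrix(x2, marker_info(g), parents = parent_calls(g), sort = FALSE)
  v2 <- anchor_fisher_filter(g2, anchors, 0.05)$verdict
  expect_equal(v2$status[v2$id == non_anchor[1]], "kept")
  # chromosome without anchors passes untested with a warning
  a1 <- anchors[startsWith(anchors, "S1")]
  expect_warning(anchor_fisher_filter(gp, a1, 0.05), "no anchors")
})

test_that("sliding-window scores follow the stated arithmetic", {
  # one line; 25-marker window; central call differs from 20 of 24
  mkline <- function(center, flanks) {
    v <- c(flanks[1:12], center, flanks[13:24])
    rbind(c(rep(0L, 12), v, rep(0L, 12)))  # pad so the window is interior
  }
  flanks <- c(rep(2L, 20), rep(0L, 4))
  g <- toy_geno(mkline(0L, flanks))
  out <- sliding_window_clean(g, 25, 0.8, 12)
  expect_true(out$mask[1, 25])           # 20/24 = 0.833 > 0.8
  # all flanks agree: kept
  g2 <- toy_geno(mkline(0L, rep(0L, 24)))
  expect_false(any(sliding_window_clean(g2, 25, 0.8, 12)$mask))
  # 4 flanking missing, 17 of 20 differ: 0.85 removed
  flanks3 <- c(rep(2L, 17), rep(0L, 3), rep(NA, 4))
  g3 <- toy_geno(mkline(0L, flanks3))
  expect_true(sliding_window_clean(g3, 25, 0.8, 12)$mask[1, 25])
  # 19 of 24 differ: 0.79 kept
  flanks4 <- c(rep(2L, 19), rep(0L, 5))
  g4 <- toy_geno(mkline(0L, flanks4))
  expect_false(any(sliding_window_clean(g4, 25, 0.8, 12)$mask))
  expect_error(sliding_window_clean(g, 24), "odd")
  expect_error(sliding_window_clean(g, 1), "odd")
})

test_that("window cleaning is single-pass and spares chromosome ends", {
  gs <- genome_spec(len_cM = 90, len_bp = 2.5e7, chrom = "1")
  pop <- simulate_population(gs, n_lines = 30, n_markers = 300, seed = 31,
                             marker_spacing = "even")
  x <- unclass(pop$geno)
  # plant isolated flips at interior positions and at an end position
  set.seed(32)
  planted <- cbind(sample(30, 60, TRUE), sample(40:260, 60))
  planted <- planted[!duplicated(planted), , drop = FALSE]
  xp <- x
  for (i in seq_len(nrow(planted)))
    xp[planted[i, 1], planted[i, 2]] <- 2L - xp[planted[i, 1], planted[i, 2]]
  xp[1, 3] <- 2L - xp[1, 3]  # inside the uncorrectable end margin
  gp <- geno_matrix(xp, marker_info(pop$geno),
                    parents = parent_calls(pop$geno), sort = FALSE)
  out <- sliding_window_clean(gp, 25, 0.8, 12)
  hit <- out$mask[planted]
  flipped_is_error <- x[planted] != xp[planted]
  # planted isolated flips away from true breakpoints are removed
  expect_gte(mean(hit[flipped_is_error]), 0.95)
  expect_false(out$mask[1, 3])
  # score <= threshold cells are never altered
  kept <- !out$mask
  expect_identical(unclass(out$geno)[kept], xp[kept])
  # removal never cascades: re-running on the cleaned matrix removes the
  # few cells whose own windows changed, not a growing wave
  out2 <- sliding_window_clean(out$geno, 25, 0.8, 12)
  expect_lt(sum(out2$mask), sum(out$mask))
})

test_that("segregation distortion chi-square and Bonferroni flags", {
  calls <- rbind(matrix(rep(c(0L, 0L, 0L, 2L, 2L), 20), 100, 1),
                 NULL)
  g <- toy_geno(cbind(calls,
                      rep(c(0L, 2L), 50),
                      rep(NA_integer_, 100)))
  expect_message(sd_res <- segregation_distortion(g, 0.05), "without")
  expect_equal(sd_res$chisq[1], (60 - 40)^2 / 100)
  expect_equal(sd_res$p[1], pchisq(4, 1, lower.tail = FALSE))
  expect_equal(sd_res$chisq[2], 0)
  expect_equal(sd_res$p[3], 1)
  expect_equal(attr(sd_res, "cutoff"), 0.05 / 3)
  expect_false(any(sd_res$significant))
})
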
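# Shared small mapping dataset: two chromosomes, collapsed to bins with
# cM positions, plus helpers for planted-QTL phenotypes.
make_bins <- function(n_lines = 109, n_markers = 700, seed = 301,
                      cM = 90, n_chr = 2L) {
  gs <- small_genome(n_chr = n_chr, cM = cM)
  pop <- simulate_population(gs, n_lines = n_lines, n_markers = n_markers,
                             seed = seed)
  mp <- build_map(pop$geno)
  list(pop = pop, map = mp, bins = collapse_bins(pop$geno, mp))
}

test_that("genotype expectation interpolates between informative flanks", {
  dat <- make_bins(n_lines = 40, n_markers = 200, seed = 311)
  bm <- dat$bins
  sel <- bm$bins$chrom == "1"
  cm <- bm$bins$cM[sel]
  # at a genotyped bin the dosage is the observed +-1
  x0 <- genotype_expectation(bm, "1", cm[3])
  gb <- bm$geno[, sel][, 3]
  hom <- !is.na(gb) & gb != 1L
  expect_equal(unname(x0[hom, 1]), unname(ifelse(gb[hom] == 2L, 1, -1)))
  # matching flanks pull the midpoint dosage towards their sign
  x_all <- genotype_expectation(bm, "1", (cm[3] + cm[4]) / 2)
  g3 <- bm$geno[, sel][, 3]; g4 <- bm$geno[, sel][, 4]
  same <- !is.na(g3) & !is.na(g4) & g3 == g4 & g3 != 1L
  expect_true(all(abs(x_all[same, 1] - ifelse(g3[same] == 2L, 1, -1)) < 0.2))
  expect_error(genotype_expectation(bm, "1", max(cm) + 10), "outside")
})

test_that("two-flank dosage matches the conditional enumeration oracle", {
  # single line, two informative bins 20 cM apart with discordant calls
  bm <- list(bins = data.frame(bin = 1:2, chrom = "1",
                               representative = c("b1", "b2"),
                               start_bp = c(1, 2e6), end_bp = c(1e6, 3e6),
                               n_markers = 1L, cM = c(0, 20),
                               stringsAsFactors = FALSE),
             geno = matrix(c(0L, 2L), 1, 2,
                           dimnames = list("L1", c("b1", "b2"))),
             members = list("b1", "b2"))
  class(bm) <- "bin_map"
  pos <- 10
  x <- genotype_expectation(bm, "1", pos)[1, 1]
  # oracle: P(state) over the two-interval joint distribution with
  # RIL-scale switch probabilities
  Rfun <- function(d) { r <- tanh(d / 50) / 2; 2 * r / (1 + 2 * r) }
  RL <- Rfun(10); RR <- Rfun(10)
  pB <- (RL * (1 - RR)) / (RL * (1 - RR) + (1 - RL) * RR)
  expect_equal(x, 2 * pB - 1, tolerance = 1e-12)
  expect_equal(x, 0, tolerance = 1e-12)  # symmetric discordant flanks
  # asymmetric position
  x2 <- genotype_expectation(bm, "1", 5)[1, 1]
  RL <- Rfun(5); RR <- Rfun(15)
  pB2 <- (RL * (1 - RR)) / (RL * (1 - RR) + (1 - RL) * RR)
  expect_equal(x2, 2 * pB2 - 1, tolerance = 1e-12)
  expect_lt(x2, 0)
})

test_that("forward cofactor selection finds planted bins deterministically", {
  dat <- make_bins(seed = 321)
  bm <- dat$bins
  nb <- nrow(bm$bins)
  z <- ifelse(bm$geno == 2L, 1, ifelse(bm$geno == 0L, -1, 0))
  z[is.na(bm$geno)] <- 0
  target <- 11L
  y <- z[, target]  # exact single-bin phenotype
  cof <- select_cofactors(bm, y, k = 2)
  expect_equal(cof[1], target)
  # pure-noise phenotype: deterministic under the fixed tie-break
  set.seed(5); yn <- rnorm(nrow(bm$geno))
  expect_identical(select_cofactors(bm, yn, k = 3),
                   select_cofactors(bm, yn, k = 3))
  expect_warning(cof0 <- select_cofactors(bm, rep(1, nrow(bm$geno)), k = 2),
                 "constant")
  expect_length(cof0, 0L)
  # two strong additive QTLs on different chromosomes: both found, 20/20
  sel2 <- bm$bins$chrom == "2"
  t2 <- which(sel2)[5]
  # adjacent bins are nearly collinear, so require the selected pair to
  # tag the two planted regions (within 5 cM on the right chromosome)
  near <- function(j, tgt)
    bm$bins$chrom[j] == bm$bins$chrom[tgt] &
      abs(bm$bins$cM[j] - bm$bins$cM[tgt]) <= 5
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    y2 <- z[, target] + z[, t2] + rnorm(nrow(z), 0, sqrt(2 * (1 / 0.6 - 1)))
    cof <- select_cofactors(bm, y2, k = 2)
    any(near(cof, target)) && any(near(cof, t2))
  }, TRUE)
  expect_equal(mean(hits), 1)
})

test_that("CIM LOD curve is invariant to phenotype location and scale", {
  dat <- make_bins(n_lines = 60, n_markers = 300, seed = 331)
  bm <- dat$bins
  set.seed(6)
  y <- rnorm(60)
  cof <- select_cofactors(bm, y, k = 2)
  s1 <- cim_scan(bm, y, cof, step = 2)
  s2 <- cim_scan(bm, 100 + 5 * y, cof, step = 2)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
})

test_that("with no cofactors the scan equals a direct regression oracle", {
  dat <- make_bins(n_lines = 80, n_markers = 300, seed = 341)
  bm <- dat$bins
  set.seed(7)
  z <- ifelse(bm$geno == 2L, 1, ifelse(bm$geno == 0L, -1, 0))
  y <- z[, 4] * 0.8 + rnorm(80)
  sc <- cim_scan(bm, y, integer(0), step = 2)
  prep <- gbsmap:::cim_prepare(bm, step = 2)
  for (gi in sample(nrow(sc), 12)) {
    x <- prep$X[, gi]
    rss_full <- sum(lm.fit(cbind(1, x), y)$residuals^2)
    rss_red <- sum((y - mean(y))^2)
    expect_equal(sc$lod[gi], (80 / 2) * log10(rss_red / rss_full),
                 tolerance = 1e-8)
  }
})

test_that("an exact bin phenotype yields a capped peak with full PVE", {
  dat <- make_bins(n_lines = 50, n_markers = 250, seed = 351)
  bm <- dat$bins
  z <- ifelse(bm$geno == 2L, 1, ifelse(bm$geno == 0L, -1, 0))
  # pick a bin genotyped homozygous in every line so the fit is exact
  target <- which(colSums(is.na(bm$geno) | bm$geno == 1L) == 0)[1]
  y <- 2 * z[, target]
  expect_warning(sc <- cim_scan(bm, y, integer(0), step = 1, lod_cap = 50),
                 "capped")
  q <- summarize_qtl(sc, threshold = 3)
  hit <- q[q$chrom == bm$bins$chrom[target], ]
  expect_equal(hit$peak_cM, bm$bins$cM[target], tolerance = 1.01)
  expect_equal(hit$pve, 100, tolerance = 1e-6)
  expect_equal(hit$additive_effect, 2, tolerance = 1e-6)
  expect_equal(hit$lod, 50)
})

test_that("permutation threshold is deterministic and alpha = 1 is the min", {
  dat <- make_bins(n_lines = 50, n_markers = 200, seed = 361)
  bm <- dat$bins
  set.seed(8); y <- rnorm(50)
  t1 <- permutation_threshold(bm, y, k = 2, n_perm = 100, seed = 9, step = 2)
  t2 <- permutation_threshold(bm, y, k = 2, n_perm = 100, seed = 9, step = 2)
  expect_equal(as.numeric(t1), as.numeric(t2))
  tmin <- permutation_threshold(bm, y, k = 2, n_perm = 100, alpha = 1,
                                seed = 9, step = 2)
  expect_equal(as.numeric(tmin), min(attr(tmin, "max_lods")))
  expect_error(permutation_threshold(bm, y, n_perm = 10), "n_perm")
})

test_that("credible intervals collapse for spikes and widen for plateaus", {
  grid_bins <- data.frame(bin = 1:41, chrom = "1",
                          representative = paste0("b", 1:41),
                          start_bp = seq(1, 41) * 1e5,
                          end_bp = seq(1, 41) * 1e5 + 5e4,
                          n_markers = 1L, cM = seq(0, 40),
                          stringsAsFactors = FALSE)
  mk_scan <- function(lods) {
    sc <- data.frame(chrom = "1", pos_cM = seq(0, 40), lod = lods,
                     stringsAsFactors = FALSE)
    attr(sc, "effect") <- rep(1, 41); attr(sc, "pve") <- rep(10, 41)
    attr(sc, "bins") <- grid_bins; attr(sc, "n") <- 100
    class(sc) <- c("qtl_scan", "data.frame")
    sc
  }
  spike <- rep(0, 41); spike[21] <- 20
  q1 <- summarize_qtl(mk_scan(spike), threshold = 3)
  expect_equal(q1$ci_lo_cM, 20)
  expect_equal(q1$ci_hi_cM, 20)
  flat <- rep(10, 41)
  q2 <- summarize_qtl(mk_scan(flat), threshold = 3)
  expect_gte(q2$ci_hi_cM - q2$ci_lo_cM, 0.94 * 40)
  expect_lte(q2$ci_hi_cM - q2$ci_lo_cM, 40)
  # nothing above threshold: empty frame
  expect_equal(nrow(summarize_qtl(mk_scan(rep(0, 41)), threshold = 3)), 0L)
})

test_that("a planted 30 percent PVE QTL is localized within 5 cM", {
  hits <- 0L
  for (s in 1:10) {
    gs <- small_genome()
    pop <- simulate_population(gs, n_lines = 109, n_markers = 500,
                               seed = 400 + s)
    mp <- build_map(pop$geno)
    bm <- collapse_bins(pop$geno, mp)
    qtl <- data.frame(chrom = "1", pos_cM = 40, effect = 1)
    ph <- simulate_phenotypes(pop$truth, qtl, h2 = 0.30, seed = 500 + s)
    y <- ph[[2]]
    cof <- select_cofactors(bm, y, k = 3)
    sc <- cim_scan(bm, y, cof, window = 10, step = 1)
    pk <- sc[sc$chrom == "1", ]
    peak <- pk$pos_cM[which.max(pk$lod)]
    # the generating position is on the true map; compare on the
    # estimated map via the nearest true-position bin of chromosome 1
    sel1 <- bm$bins$chrom == "1"
    true_cm <- bm$bins$cM[sel1][which.min(abs(
      gbsmap:::bp_to_cm(gs, 1, bm$bins$start_bp[sel1]) - 40))]
    if (abs(peak - true_cm) <= 5) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("bin downsampling degrades interval width, validates fractions", {
  dat <- make_bins(n_lines = 109, n_markers = 600, seed = 371)
  bm <- dat$bins
  z <- ifelse(bm$geno == 2L, 1, ifelse(bm$geno == 0L, -1, 0))
  target <- which(bm$bins$chrom == "1")[10]
  set.seed(11)
  y <- z[, target] + rnorm(109, 0, sqrt(1 / 0.35 - 1))
  expect_error(density_downsample_experiment(bm, y, fractions = 1.5),
               "fractions")
  res <- density_downsample_experiment(bm, y, fractions = c(0.15, 0.5),
                                       k = 2, n_perm = 100, seed = 12,
                                       step = 2)
  full <- res[res$fraction == 1, ]
  expect_true(all(full$detected))
  sub <- res[res$fraction < 1 & res$detected, ]
  if (nrow(sub)) expect_true(all(sub$peak_shift_cM >= 0))
})
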
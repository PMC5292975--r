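# Bin genotypes enter Haley-Knott regression as expected allele dosages
# x in [-1, +1], with +1 = parent-B homozygote.  Hidden genotype
# probabilities between flanking informative bins use RIL-scale
# (riself-corrected) recombination fractions R(d) = 2r/(1+2r),
# r = kosambi_inv(d).

ril_switch_prob <- function(d_cM) {
  r <- kosambi_inv(d_cM)
  2 * r / (1 + 2 * r)
}

align_phenotype <- function(binmap, phenotype, trait = NULL) {
  if (is.data.frame(phenotype)) {
    if (is.null(trait)) trait <- setdiff(names(phenotype), "line")[1L]
    y <- phenotype[[trait]][match(rownames(binmap$geno), phenotype$line)]
  } else {
    y <- phenotype
    if (!is.null(names(y))) y <- y[rownames(binmap$geno)]
  }
  as.numeric(y)
}

#' Expected allele dosage at an arbitrary map position
#'
#' For each line, the conditional expectation `x = P(parent-B) -
#' P(parent-A)` of the hidden RIL genotype at `pos_cM`, given the nearest
#' informative (homozygous) flanking bins; at a genotyped bin x is +/-1.
#' Lines with no informative bin on the chromosome get x = 0.
#'
#' @param binmap a `bin_map` (from [collapse_bins()]) with bin cM
#'   positions.
#' @param chrom chromosome label.
#' @param pos_cM position(s) on the chromosome's map, cM.
#' @return matrix lines x positions of dosages in `[-1, 1]`.
#' @export
genotype_expectation <- function(binmap, chrom, pos_cM) {
  sel <- which(binmap$bins$chrom == as.character(chrom))
  if (!length(sel)) stop_gbs("no bins on chromosome ", chrom,
                             class = "gbsmap_validation_error")
  cm <- binmap$bins$cM[sel]
  if (anyNA(cm)) stop_gbs("bin map has no cM positions; pass a genetic map",
                          class = "gbsmap_validation_error")
  if (any(pos_cM < min(cm) - 1e-9) || any(pos_cM > max(cm) + 1e-9))
    stop_gbs("position outside the chromosome's map span",
             class = "gbsmap_validation_error")
  gb <- binmap$geno[, sel, drop = FALSE]
  z <- matrix(NA_real_, nrow(gb), ncol(gb))
  z[!is.na(gb) & gb == 0L] <- -1
  z[!is.na(gb) & gb == 2L] <- 1
  dosage_block(z, cm, pos_cM)
}

# z: lines x bins (+1/-1/NA), cm: bin positions, grid: query positions.
dosage_block <- function(z, cm, grid) {
  n <- nrow(z)
  out <- matrix(0, n, length(grid))
  for (l in seq_len(n)) {
    inf <- which(!is.na(z[l, ]))
    if (!length(inf)) next
    icm <- cm[inf]; ig <- z[l, inf]
    li <- findInterval(grid, icm)           # last informative at cm <= pos
    ri <- li + 1L
    has_l <- li >= 1L; has_r <- ri <= length(inf)
    pL <- rep(0.5, length(grid))
    RL <- ril_switch_prob(pmax(grid - icm[pmax(li, 1L)], 0))
    pL[has_l] <- ifelse(ig[pmax(li, 1L)][has_l] > 0,
                        1 - RL[has_l], RL[has_l])
    lB <- rep(0.5, length(grid))
    RR <- ril_switch_prob(pmax(icm[pmin(ri, length(inf))] - grid, 0))
    lB[has_r] <- ifelse(ig[pmin(ri, length(inf))][has_r] > 0,
                        1 - RR[has_r], RR[has_r])
    pB <- pL * lB / (pL * lB + (1 - pL) * (1 - lB))
    out[l, ] <- 2 * pB - 1
  }
  out
}

# Scan grid and precomputed dosages for a bin map; built once and shared
# by scans and permutations.
cim_prepare <- function(binmap, step = 1) {
  if (anyNA(binmap$bins$cM))
    stop_gbs("bin map has no cM positions; rebuild with collapse_bins(g, map)",
             class = "gbsmap_validation_error")
  chroms <- unique(binmap$bins$chrom)
  grid <- do.call(rbind, lapply(chroms, function(ch) {
    cm <- binmap$bins$cM[binmap$bins$chrom == ch]
    # step grid plus the bin positions themselves (as in scanone grids)
    pos <- sort(unique(c(cm, seq(min(cm), max(cm), by = step))))
    data.frame(chrom = ch, pos_cM = pos, stringsAsFactors = FALSE)
  }))
  z <- matrix(NA_real_, nrow(binmap$geno), ncol(binmap$geno))
  z[!is.na(binmap$geno) & binmap$geno == 0L] <- -1
  z[!is.na(binmap$geno) & binmap$geno == 2L] <- 1
  X <- matrix(0, nrow(z), nrow(grid))
  for (ch in chroms) {
    sel <- binmap$bins$chrom == ch
    gi <- grid$chrom == ch
    X[, gi] <- dosage_block(z[, sel, drop = FALSE], binmap$bins$cM[sel],
                            grid$pos_cM[gi])
  }
  zc <- z; zc[is.na(zc)] <- 0   # cofactor regressors: missing -> 0
  list(grid = grid, X = X, Z = zc,
       bin_chrom = binmap$bins$chrom, bin_cM = binmap$bins$cM,
       bins = binmap$bins)
}

#' Forward selection of CIM cofactor bins
#'
#' Repeatedly adds the bin whose inclusion most reduces the residual sum
#' of squares of a multiple regression of the phenotype on the chosen
#' bins (plus intercept), for `k` steps; ties break toward the
#' lower-index bin, making selection deterministic.
#'
#' @param binmap a `bin_map` with cM positions.
#' @param phenotype numeric vector (aligned with lines) or a phenotype
#'   data.frame with a `line` column.
#' @param k number of cofactors (2-5 in typical use).
#' @param trait trait column when `phenotype` is a data.frame.
#' @return integer vector of selected bin indices (possibly shorter than
#'   `k` when no candidate reduces the RSS); empty, with a warning, for a
#'   constant phenotype.
#' @export
select_cofactors <- function(binmap, phenotype, k = 3L, trait = NULL) {
  k <- check_count(k, "k", 1L)
  y <- align_phenotype(binmap, phenotype, trait)
  keep <- !is.na(y)
  prep <- if (is.list(binmap) && !is.null(binmap$Z)) binmap
  else cim_prepare(binmap)
  Z <- prep$Z[keep, , drop = FALSE]
  forward_select(Z, y[keep], k)
}

forward_select <- function(Z, y, k) {
  n <- length(y)
  if (stats::sd(y) == 0) {
    warning("constant phenotype; no cofactors selected")
    return(integer(0))
  }
  Q <- matrix(1 / sqrt(n), n, 1L)
  r <- y - Q %*% crossprod(Q, y)
  chosen <- integer(0)
  for (step in seq_len(min(k, ncol(Z)))) {
    Zp <- Z - Q %*% crossprod(Q, Z)
    den <- colSums(Zp^2)
    num <- drop(crossprod(Zp, r))^2
    gain <- ifelse(den > 1e-10, num / den, -Inf)
    gain[chosen] <- -Inf
    j <- which.max(gain)
    if (!is.finite(gain[j]) || gain[j] <= 1e-12) break
    qn <- Zp[, j] / sqrt(den[j])
    Q <- cbind(Q, qn)
    r <- r - qn * sum(qn * r)
    chosen <- c(chosen, j)
  }
  chosen
}

#' Composite interval mapping scan by Haley-Knott regression
#'
#' At each grid position (every `step` cM), the phenotype is regressed on
#' the expected allele dosage at that position plus all cofactor bins
#' except those within `window` cM on the same chromosome;
#' `LOD = (n/2) log10(RSS_reduced / RSS_full)` where the reduced model
#' omits the dosage term.  Lines with missing phenotype are dropped
#' listwise.
#'
#' @param binmap a `bin_map` with cM positions.
#' @param phenotype numeric vector or phenotype data.frame.
#' @param cofactors integer vector of cofactor bin indices (from
#'   [select_cofactors()]).
#' @param window cofactor exclusion window, cM (default 10).
#' @param step grid step, cM (default 1).
#' @param trait trait column when `phenotype` is a data.frame.
#' @param lod_cap LOD value reported when the full model fits exactly
#'   (RSS_full = 0).
#' @return object of class `qtl_scan`: data.frame(chrom, pos_cM, lod)
#'   with the inputs needed by [summarize_qtl()] attached as attributes.
#' @export
cim_scan <- function(binmap, phenotype, cofactors = integer(0),
                     window = 10, step = 1, trait = NULL, lod_cap = 100) {
  y <- align_phenotype(binmap, phenotype, trait)
  prep <- if (is.list(binmap) && !is.null(binmap$Z)) binmap
  else cim_prepare(binmap, step)
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n < 3L || stats::sd(y) == 0)
    stop_gbs("phenotype constant or nearly empty",
             class = "gbsmap_validation_error")
  X <- prep$X[keep, , drop = FALSE]
  Z <- prep$Z[keep, , drop = FALSE]
  grid <- prep$grid
  G <- nrow(grid)
  lod <- numeric(G)
  eff <- numeric(G)
  pve <- numeric(G)
  # positions sharing an active-cofactor set are scanned together
  active <- matrix(TRUE, G, length(cofactors))
  if (length(cofactors)) {
    for (c_i in seq_along(cofactors)) {
      b <- cofactors[c_i]
      active[, c_i] <- !(grid$chrom == prep$bin_chrom[b] &
                           abs(grid$pos_cM - prep$bin_cM[b]) <= window)
    }
  }
  key <- apply(active, 1L, paste, collapse = "")
  for (kk in unique(key)) {
    gi <- which(key == kk)
    cofs <- cofactors[active[gi[1L], ]]
    Q <- qr.Q(qr(cbind(1, Z[, cofs, drop = FALSE])))
    resid <- y - Q %*% crossprod(Q, y)
    rss_red <- sum(resid^2)
    Xg <- X[, gi, drop = FALSE]
    Xp <- Xg - Q %*% crossprod(Q, Xg)
    den <- colSums(Xp^2)
    num <- drop(crossprod(Xp, resid))
    gain <- ifelse(den > 1e-10, num^2 / den, 0)
    rss_full <- pmax(rss_red - gain, 0)
    l <- ifelse(rss_full <= rss_red * 1e-12, lod_cap,
                (n / 2) * log10(rss_red / rss_full))
    if (any(rss_full <= rss_red * 1e-12))
      warning("perfect fit at some positions; LOD capped at ", lod_cap)
    lod[gi] <- pmin(l, lod_cap)
    eff[gi] <- ifelse(den > 1e-10, num / den, 0)
    pve[gi] <- 100 * (1 - rss_full / rss_red)
  }
  out <- data.frame(chrom = grid$chrom, pos_cM = grid$pos_cM, lod = lod,
                    stringsAsFactors = FALSE)
  attr(out, "effect") <- eff
  attr(out, "pve") <- pve
  attr(out, "cofactors") <- cofactors
  attr(out, "n") <- n
  attr(out, "bins") <- prep$bins
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Shuffles the phenotype across lines, reselects cofactors and re-runs
#' the full scan per permutation, recording the genome-wide maximum LOD;
#' the threshold is the empirical `(1 - alpha)` quantile of those maxima.
#'
#' @inheritParams cim_scan
#' @param k cofactors reselected within each permutation.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha genome-wide false-positive level (default 0.05).
#' @param seed RNG seed.
#' @return threshold LOD (numeric scalar) with the permutation maxima in
#'   attribute `"max_lods"`.
#' @export
permutation_threshold <- function(binmap, phenotype, k = 3L,
                                  n_perm = 1000L, alpha = 0.05,
                                  window = 10, step = 1, seed = NULL,
                                  trait = NULL) {
  n_perm <- check_count(n_perm, "n_perm", 100L)
  check_fraction(alpha, "alpha")
  y <- align_phenotype(binmap, phenotype, trait)
  prep <- if (is.list(binmap) && !is.null(binmap$Z)) binmap
  else cim_prepare(binmap, step)
  keep <- !is.na(y)
  yk <- y[keep]
  prep_k <- prep
  prep_k$X <- prep$X[keep, , drop = FALSE]
  prep_k$Z <- prep$Z[keep, , drop = FALSE]
  maxl <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    yp <- sample(yk)
    cofs <- forward_select(prep_k$Z, yp, k)
    sc <- cim_scan(prep_k, yp, cofs, window = window, step = step)
    max(sc$lod)
  }, 0))
  thr <- unname(stats::quantile(maxl, 1 - alpha, type = 1))
  attr(thr, "max_lods") <- maxl
  thr
}

#' Summarize detected QTLs from a scan
#'
#' For every chromosome whose maximum LOD exceeds the threshold: the peak
#' position, a Bayes credible interval (the smallest grid span around the
#' peak containing at least `coverage` of the chromosome's normalized
#' `10^LOD` mass, grown greedily toward the heavier side), the additive
#' effect (partial regression coefficient on the dosage at the peak,
#' i.e. half the parental-class difference) and the PVE, plus nearest and
#' flanking bins by cM.
#'
#' @param scan a `qtl_scan`.
#' @param threshold LOD threshold (e.g. from [permutation_threshold()]).
#' @param coverage credible-interval coverage (default 0.95).
#' @return data.frame with one row per detected QTL (zero rows when none).
#' @export
summarize_qtl <- function(scan, threshold, coverage = 0.95) {
  check_fraction(coverage, "coverage")
  bins <- attr(scan, "bins")
  out <- list()
  for (ch in unique(scan$chrom)) {
    gi <- which(scan$chrom == ch)
    lods <- scan$lod[gi]
    if (max(lods) <= threshold) next
    # ties at the maximum (e.g. capped plateaus) break towards the
    # position with the largest PVE
    at_max <- which(lods >= max(lods) - 1e-12)
    pk_rel <- at_max[which.max(attr(scan, "pve")[gi][at_max])]
    pk <- gi[pk_rel]
    mass <- 10^(lods - max(lods))
    mass <- mass / sum(mass)
    lo <- hi <- pk_rel
    acc <- mass[lo]
    while (acc < coverage && (lo > 1L || hi < length(gi))) {
      ml <- if (lo > 1L) mass[lo - 1L] else -1
      mh <- if (hi < length(gi)) mass[hi + 1L] else -1
      if (ml >= mh) { lo <- lo - 1L; acc <- acc + ml }
      else { hi <- hi + 1L; acc <- acc + mh }
    }
    pk_cm <- scan$pos_cM[pk]
    bc <- bins[bins$chrom == ch, ]
    near <- bc$representative[which.min(abs(bc$cM - pk_cm))]
    fl_lo <- bc$representative[utils::tail(which(bc$cM <= pk_cm), 1L)]
    fl_hi <- bc$representative[utils::head(which(bc$cM >= pk_cm), 1L)]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, lod = max(lods), peak_cM = pk_cm,
      ci_lo_cM = scan$pos_cM[gi[lo]], ci_hi_cM = scan$pos_cM[gi[hi]],
      nearest_bin = near,
      flank_lo = if (length(fl_lo)) fl_lo else NA_character_,
      flank_hi = if (length(fl_hi)) fl_hi else NA_character_,
      additive_effect = attr(scan, "effect")[pk],
      pve = attr(scan, "pve")[pk], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), lod = numeric(0),
                      peak_cM = numeric(0), ci_lo_cM = numeric(0),
                      ci_hi_cM = numeric(0), nearest_bin = character(0),
                      flank_lo = character(0), flank_hi = character(0),
                      additive_effect = numeric(0), pve = numeric(0)))
  do.call(rbind, out)
}

subset_bin_map <- function(binmap, idx) {
  idx <- sort(idx)
  structure(list(bins = transform(binmap$bins[idx, ],
                                  bin = seq_along(idx)),
                 geno = binmap$geno[, idx, drop = FALSE],
                 members = binmap$members[idx]),
            class = "bin_map")
}

#' Marker-density downsampling experiment
#'
#' Randomly subsamples the recombination bins at each fraction, re-runs
#' cofactor selection, the CIM scan and the permutation threshold, and
#' compares the detected QTLs with the full-density scan: detection,
#' peak shift, credible-interval width and PVE.
#'
#' @inheritParams permutation_threshold
#' @param fractions bin fractions to test (default 0.1 and 0.2; a value
#'   of 1 reproduces the full scan).
#' @return data.frame(fraction, chrom, detected, peak_cM, peak_shift_cM,
#'   ci_width_cM, pve): one row per full-scan QTL per fraction (plus the
#'   full-density rows at fraction 1).
#' @export
density_downsample_experiment <- function(binmap, phenotype,
                                          fractions = c(0.1, 0.2),
                                          k = 3L, n_perm = 200L,
                                          alpha = 0.05, window = 10,
                                          step = 1, seed = NULL,
                                          trait = NULL) {
  if (any(fractions <= 0 | fractions > 1))
    stop_gbs("fractions must be in (0, 1]", class = "gbsmap_validation_error")
  nb <- nrow(binmap$bins)
  if (nb < 10L) stop_gbs("need >= 10 bins", class = "gbsmap_validation_error")
  run_one <- function(bm, sd_off) {
    prep <- cim_prepare(bm, step)
    cofs <- select_cofactors(prep, align_phenotype(bm, phenotype, trait), k)
    thr <- permutation_threshold(prep, align_phenotype(bm, phenotype, trait),
                                 k = k, n_perm = n_perm, alpha = alpha,
                                 window = window, step = step,
                                 seed = if (is.null(seed)) NULL else seed + sd_off)
    sc <- cim_scan(prep, align_phenotype(bm, phenotype, trait), cofs,
                   window = window, step = step)
    summarize_qtl(sc, thr)
  }
  full <- run_one(binmap, 0L)
  rows <- list()
  if (nrow(full))
    rows[[1L]] <- data.frame(fraction = 1, chrom = full$chrom,
                             detected = TRUE, peak_cM = full$peak_cM,
                             peak_shift_cM = 0,
                             ci_width_cM = full$ci_hi_cM - full$ci_lo_cM,
                             pve = full$pve, stringsAsFactors = FALSE)
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    idx <- with_seed(if (is.null(seed)) NULL else seed + 1000L * fi,
                     sample.int(nb, max(2L, round(f * nb))))
    res <- run_one(subset_bin_map(binmap, idx), 1000L * fi)
    for (qi in seq_len(nrow(full))) {
      hit <- res[res$chrom == full$chrom[qi], , drop = FALSE]
      det <- nrow(hit) > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, chrom = full$chrom[qi], detected = det,
        peak_cM = if (det) hit$peak_cM[1L] else NA_real_,
        peak_shift_cM = if (det) abs(hit$peak_cM[1L] - full$peak_cM[qi])
        else NA_real_,
        ci_width_cM = if (det) hit$ci_hi_cM[1L] - hit$ci_lo_cM[1L]
        else NA_real_,
        pve = if (det) hit$pve[1L] else NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
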
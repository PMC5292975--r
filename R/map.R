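#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a per-meiosis recombination fraction to a map
#' distance, `d = 25 ln((1 + 2r) / (1 - 2r))` cM; `kosambi_inv()` inverts
#' it, `r = tanh(d / 50) / 2`.  The round trip is exact to numerical
#' precision.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return numeric vector of distances (cM) / fractions.
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop_gbs("recombination fraction must be in [0, 0.5)",
             class = "gbsmap_validation_error")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop_gbs("map distance must be >= 0",
                           class = "gbsmap_validation_error")
  tanh(d / 50) / 2
}

#' Convert a RIL-observed recombinant fraction to a per-meiosis fraction
#'
#' For a selfed RIL population the recombinant fraction accumulated at
#' fixation is `R = 2r / (1 + 2r)`; this inverts it, `r = R / (2(1 - R))`,
#' capped at 0.4999.  Values of `R` above 0.5 (possible under sampling
#' noise) are clamped to 0.5 with a warning.
#'
#' @param R observed recombinant fraction(s) among RILs, in `[0, 0.5]`.
#' @return per-meiosis recombination fraction(s).
#' @export
riself_correct <- function(R) {
  if (any(R > 0.5, na.rm = TRUE)) {
    warning("observed recombinant fraction > 0.5 clamped to 0.5")
    R <- pmin(R, 0.5)
  }
  if (any(R < 0, na.rm = TRUE))
    stop_gbs("recombinant fraction must be >= 0",
             class = "gbsmap_validation_error")
  pmin(R / (2 * (1 - R)), 0.4999)
}

#' Expected observed recombinant fraction in a selfed RIL population
#'
#' Exact two-locus theory for single-seed descent: starting from an F1,
#' the joint haplotype-pair distribution is iterated through
#' `generation - 1` selfing rounds (16-state chain) and the recombinant
#' fraction is taken conditional on both loci being homozygous - the
#' lines actually informative for map estimation.  At F-infinity this
#' reduces to the classic riself relation `R = 2r/(1+2r)`; at finite
#' generations it is noticeably smaller (about 9.5 percent at F7 for
#' tight linkage), because recently created junctions are
#' disproportionately still heterozygous and hence invisible.
#'
#' @param r per-meiosis recombination fraction(s) in `[0, 0.5)`.
#' @param generation filial generation (>= 2), or `Inf` for the
#'   F-infinity riself relation.
#' @return expected observed recombinant fraction(s) among doubly
#'   homozygous lines.
#' @export
ril_observed_R <- function(r, generation = 7L) {
  if (is.infinite(generation)) return(2 * r / (1 + 2 * r))
  generation <- check_count(generation, "generation", 2L)
  vapply(r, function(ri) two_locus_R(ri, generation), 0)
}

# Haplotypes over two loci coded 1..4 = (A,A),(A,B),(B,A),(B,B);
# state = ordered haplotype pair (16 probabilities).
two_locus_R <- function(r, generation) {
  al <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  gam <- function(x, y) {
    # locus 1 from x or y with prob 1/2; locus 2 from the same parent
    # w.p. 1 - r, the other w.p. r
    g <- numeric(4L)
    for (p in list(c(x, y), c(y, x))) {
      a1 <- al[p[1L], 1L]
      g[al[, 1L] == a1 & al[, 2L] == al[p[1L], 2L]] <-
        g[al[, 1L] == a1 & al[, 2L] == al[p[1L], 2L]] + 0.5 * (1 - r)
      g[al[, 1L] == a1 & al[, 2L] == al[p[2L], 2L]] <-
        g[al[, 1L] == a1 & al[, 2L] == al[p[2L], 2L]] + 0.5 * r
    }
    g
  }
  P <- matrix(0, 4L, 4L)
  P[1L, 4L] <- 1
  for (t in seq_len(generation - 1L)) {
    Pn <- matrix(0, 4L, 4L)
    for (x in 1:4) for (y in 1:4) if (P[x, y] > 0) {
      g <- gam(x, y)
      Pn <- Pn + P[x, y] * outer(g, g)
    }
    P <- Pn
  }
  hom1 <- outer(al[, 1L], al[, 1L], "==")
  hom2 <- outer(al[, 2L], al[, 2L], "==")
  both <- hom1 & hom2
  disc <- both & outer(al[, 1L], al[, 1L], "+") != outer(al[, 2L], al[, 2L], "+")
  sum(P[both & disc]) / sum(P[both])
}

# Monotone-interpolated inverse of ril_observed_R on a fixed r grid.
ril_meiotic_r <- function(R, generation = 7L) {
  if (is.infinite(generation)) return(riself_correct(pmin(R, 0.5)))
  grid_r <- c(seq(0, 0.2, by = 0.005), seq(0.21, 0.4999, by = 0.01))
  grid_R <- ril_observed_R(grid_r, generation)
  pmin(stats::approx(grid_R, grid_r, xout = pmin(R, max(grid_R)),
                     rule = 2)$y, 0.4999)
}

#' Build a generation-aware Kosambi genetic map
#'
#' For each adjacent marker pair within a chromosome, the observed
#' recombinant fraction `R` is counted over doubly homozygous non-missing
#' lines, converted to a per-meiosis fraction by inverting the exact
#' selfed-RIL relation [ril_observed_R()] for the population's
#' generation (the classic riself formula is the `generation = Inf`
#' case), and converted to a cM distance by [kosambi()]; cumulative
#' positions start at 0 per chromosome.  Intervals with no informative
#' line get distance 0 with a warning.
#'
#' @param g a [geno_matrix()] with >= 2 markers per chromosome, ordered.
#' @param generation filial generation of the population (default 7);
#'   `Inf` applies the F-infinity riself correction.
#' @return object of class `genetic_map`: data.frame(id, chrom, pos_bp,
#'   cM, R, r, d) with per-chromosome summary in attribute `"summary"`
#'   (chrom, n_markers, length_cM, max_gap_cM) and total length in
#'   attribute `"total_cM"`.
#' @export
build_map <- function(g, generation = 7L) {
  mk <- marker_info(g)
  x <- unclass(g)
  a <- matrix(0, nrow(x), ncol(x))
  a[!is.na(x) & x == 0L] <- 1
  a[!is.na(x) & x == 2L] <- -1
  out <- vector("list", nlevels(mk$chrom))
  zero_info <- 0L
  for (ci in seq_along(levels(mk$chrom))) {
    ch <- levels(mk$chrom)[ci]
    jc <- which(mk$chrom == ch)
    if (length(jc) < 2L)
      stop_gbs("chromosome ", ch, " has < 2 markers",
               class = "gbsmap_validation_error")
    ac <- a[, jc, drop = FALSE]
    # missing-skip counting: per line, transitions are judged between
    # consecutive non-missing calls when both are homozygous, the
    # junction being attributed to the interval following the earlier
    # call.  Identical to strict adjacent-pair counting on complete
    # data, but junctions hidden behind missing cells (where imputation
    # abstains precisely because a breakpoint is ambiguous) stay
    # counted.  Pairs broken by a heterozygous call are dropped: the
    # finite-generation R(r) relation conditions on homozygosity, and
    # residual-het tracts are junction-enriched, so skipping hets would
    # bias the map upward.
    xc <- x[, jc, drop = FALSE]
    n <- k <- numeric(length(jc) - 1L)
    for (li in seq_len(nrow(ac))) {
      idx <- which(!is.na(xc[li, ]))
      if (length(idx) < 2L) next
      v1 <- ac[li, idx[-length(idx)]]
      v2 <- ac[li, idx[-1L]]
      use <- v1 != 0 & v2 != 0
      prev <- idx[-length(idx)][use]
      n[prev] <- n[prev] + 1
      k[prev] <- k[prev] + (v1[use] != v2[use])
    }
    R <- ifelse(n > 0, k / n, 0)
    zero_info <- zero_info + sum(n == 0)
    r <- if (is.infinite(generation)) suppressWarnings(riself_correct(R))
    else ril_meiotic_r(R, generation)
    d <- kosambi(r)
    out[[ci]] <- data.frame(id = mk$id[jc], chrom = ch, pos_bp = mk$pos[jc],
                            cM = cumsum(c(0, d)),
                            R = c(NA, R), r = c(NA, r), d = c(NA, d),
                            stringsAsFactors = FALSE)
  }
  if (zero_info > 0)
    warning(zero_info, " intervals without informative lines (distance 0)")
  map <- do.call(rbind, out)
  map$chrom <- factor(map$chrom, levels = levels(mk$chrom))
  summ <- do.call(rbind, lapply(out, function(df) data.frame(
    chrom = df$chrom[1L], n_markers = nrow(df),
    length_cM = max(df$cM), max_gap_cM = max(df$d, na.rm = TRUE),
    stringsAsFactors = FALSE)))
  attr(map, "summary") <- summ
  attr(map, "total_cM") <- sum(summ$length_cM)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("genetic_map: %d markers, %d chromosomes, %.1f cM total\n",
              nrow(x), nrow(s), attr(x, "total_cM")))
  print(s)
  invisible(x)
}

#' Count recombination breakpoints per line
#'
#' A breakpoint is a transition between successive non-missing homozygous
#' calls that differ; heterozygous and missing calls are skipped, the
#' transition being judged between the flanking homozygous calls.
#'
#' @param g a [geno_matrix()], ordered within chromosomes.
#' @return list(per_line = integer vector, total, mean).
#' @export
count_breakpoints <- function(g) {
  mk <- marker_info(g)
  x <- unclass(g)
  per_line <- integer(nrow(x))
  for (ch in levels(mk$chrom)) {
    jc <- which(mk$chrom == ch)
    xc <- x[, jc, drop = FALSE]
    for (l in seq_len(nrow(xc))) {
      v <- xc[l, ]
      v <- v[!is.na(v) & v != 1L]
      if (length(v) > 1L) per_line[l] <- per_line[l] + sum(diff(v) != 0L)
    }
  }
  names(per_line) <- rownames(x)
  list(per_line = per_line, total = sum(per_line), mean = mean(per_line))
}

#' Collapse markers into recombination bins
#'
#' Scans adjacent marker pairs within each chromosome and places a bin
#' boundary wherever at least one line shows a breakpoint between the two
#' markers (both calls non-missing, homozygous and different).  Markers
#' spanning a breakpoint whose position is undetermined (separated only
#' by missing or heterozygous calls) stay in one bin.  The bin genotype
#' of a line is the majority call over member markers (ties give
#' missing); the representative marker is the first member by position.
#'
#' @param g a [geno_matrix()], ordered, typically post-imputation.
#' @param map optional `genetic_map` supplying cM positions for the bins.
#' @return object of class `bin_map`: list with `bins` (data.frame: bin,
#'   chrom, representative, start_bp, end_bp, n_markers, cM) , `geno`
#'   (lines x bins matrix of consensus codes) and `members` (list of id
#'   vectors).
#' @export
collapse_bins <- function(g, map = NULL) {
  mk <- marker_info(g)
  x <- unclass(g)
  a <- matrix(0L, nrow(x), ncol(x))
  a[!is.na(x) & x == 0L] <- 1L
  a[!is.na(x) & x == 2L] <- -1L
  bin_of <- integer(ncol(x))
  nb <- 0L
  for (ch in levels(mk$chrom)) {
    jc <- which(mk$chrom == ch)
    ac <- a[, jc, drop = FALSE]
    if (length(jc) > 1L) {
      l <- ac[, -ncol(ac), drop = FALSE]; rgt <- ac[, -1L, drop = FALSE]
      boundary <- colSums(l * rgt == -1L) > 0L
    } else boundary <- logical(0)
    nb <- nb + 1L
    bin_of[jc] <- nb + c(0L, cumsum(boundary))
    nb <- max(bin_of[jc])
  }
  members <- split(mk$id, bin_of)
  idx <- split(seq_len(ncol(x)), bin_of)
  geno_bin <- matrix(NA_integer_, nrow(x), length(idx))
  for (b in seq_along(idx)) {
    ab <- a[, idx[[b]], drop = FALSE]
    n0 <- rowSums(ab == 1L); n2 <- rowSums(ab == -1L)
    nh <- rowSums(!is.na(x[, idx[[b]], drop = FALSE]) &
                    x[, idx[[b]], drop = FALSE] == 1L)
    top <- pmax(n0, n2, nh)
    code <- rep(NA_integer_, nrow(x))
    code[top > 0 & n0 == top & n2 < top & nh < top] <- 0L
    code[top > 0 & n2 == top & n0 < top & nh < top] <- 2L
    code[top > 0 & nh == top & n0 < top & n2 < top] <- 1L
    geno_bin[, b] <- code
  }
  rep_idx <- vapply(idx, function(j) j[which.min(mk$pos[j])], 0L)
  bins <- data.frame(bin = seq_along(idx),
                     chrom = as.character(mk$chrom[rep_idx]),
                     representative = mk$id[rep_idx],
                     start_bp = vapply(idx, function(j) min(mk$pos[j]), 0),
                     end_bp = vapply(idx, function(j) max(mk$pos[j]), 0),
                     n_markers = lengths(idx),
                     stringsAsFactors = FALSE)
  bins$cM <- if (!is.null(map)) map$cM[match(bins$representative, map$id)]
  else NA_real_
  rownames(bins) <- NULL
  colnames(geno_bin) <- bins$representative
  rownames(geno_bin) <- rownames(x)
  structure(list(bins = bins, geno = geno_bin, members = members),
            class = "bin_map")
}

#' @export
print.bin_map <- function(x, ...) {
  cat(sprintf("bin_map: %d bins over %d chromosomes (%d markers)\n",
              nrow(x$bins), length(unique(x$bins$chrom)),
              sum(x$bins$n_markers)))
  invisible(x)
}

#' Windowed recombination-rate track
#'
#' Slides a window of `span` bp along each chromosome and regresses the
#' genetic position (cM) of member markers on their physical position
#' (Mb) by ordinary least squares; the slope is the local recombination
#' rate in cM/Mb.  Windows with fewer than 3 markers or no physical
#' spread report no estimate.
#'
#' @param map a `genetic_map` from [build_map()].
#' @param span window span in bp (default 1e6).
#' @param step window step in bp (default `span`, i.e. non-overlapping).
#' @return data.frame(chrom, start_bp, end_bp, n_markers, rate_cM_per_Mb).
#' @export
windowed_recomb_rate <- function(map, span = 1e6, step = span) {
  if (span <= 0) stop_gbs("span must be > 0", class = "gbsmap_validation_error")
  out <- list()
  for (ch in levels(map$chrom)) {
    mc <- map[map$chrom == ch, ]
    if (!nrow(mc)) next
    starts <- seq(1, max(mc$pos_bp), by = step)
    for (s in starts) {
      e <- s + span - 1
      sel <- mc$pos_bp >= s & mc$pos_bp <= e
      n <- sum(sel)
      rate <- NA_real_
      if (n >= 3L && stats::sd(mc$pos_bp[sel]) > 0) {
        mb <- mc$pos_bp[sel] / 1e6
        fit <- stats::lm.fit(cbind(1, mb), mc$cM[sel])
        rate <- fit$coefficients[2L]
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = s, end_bp = e, n_markers = n,
        rate_cM_per_Mb = unname(rate), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
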
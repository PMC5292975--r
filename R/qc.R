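#' Missing-rate and minor-allele-frequency marker filter
#'
#' Drops markers whose missing fraction among RILs exceeds `max_missing`
#' (status `dropped_missing`) or whose MAF falls below `min_maf`
#' (status `dropped_maf`); MAF counts two allele copies per homozygote and
#' one of each per heterozygote.
#'
#' @param g a [geno_matrix()].
#' @param max_missing upper bound on the per-marker missing fraction.
#' @param min_maf lower bound on the minor allele frequency.
#' @return list(geno = filtered matrix, verdict = data.frame(id, status)).
#' @export
filter_missing_maf <- function(g, max_missing = 0.10, min_maf = 0.05) {
  check_fraction(max_missing, "max_missing")
  check_fraction(min_maf, "min_maf", hi = 0.5)
  miss <- missing_fraction(g)
  f <- maf(g)
  status <- rep("kept", ncol(g))
  status[!is.na(f) & f < min_maf] <- "dropped_maf"
  status[is.na(f)] <- "dropped_maf"
  status[miss > max_missing] <- "dropped_missing"
  verdict <- data.frame(id = marker_info(g)$id, status = status,
                        stringsAsFactors = FALSE)
  list(geno = g[, status == "kept"], verdict = verdict)
}

#' Determine parental genotypes and resolve marker orientation
#'
#' Completes the parent rows of a genotype matrix and fixes the 0/2 coding
#' of markers whose parental origin could not be read from the file.
#' Markers where both parents carry the same homozygous call are dropped
#' as `dropped_ambiguous_parent`; markers with only one homozygote class
#' segregating in the RILs are dropped as `dropped_monomorphic`.  For
#' markers where both parent calls are missing, the two RIL homozygote
#' classes are assigned to parents by linkage phase with the nearest
#' already-oriented marker on the same chromosome (concordance among
#' doubly homozygous lines); markers whose phase is undecidable (no
#' informative lines, exact 50:50 concordance, or no oriented marker on
#' the chromosome) are dropped rather than guessed.
#'
#' @param g a [geno_matrix()] with parent rows.
#' @return list(geno = oriented matrix of kept markers with completed
#'   parent rows, verdict = data.frame(id, status), n_flipped = markers
#'   whose coding was swapped).
#' @export
infer_parental_genotypes <- function(g) {
  pa <- parent_calls(g)
  if (is.null(pa)) stop_gbs("genotype matrix has no parent rows",
                            class = "gbsmap_validation_error")
  mk <- marker_info(g)
  x <- unclass(g)
  attr(x, "markers") <- attr(x, "parents") <- attr(x, "oriented") <- NULL
  oriented <- attr(g, "oriented")
  m <- ncol(x)
  status <- rep("kept", m)
  n0 <- colSums(x == 0L, na.rm = TRUE)
  n2 <- colSums(x == 2L, na.rm = TRUE)
  status[n0 == 0L | n2 == 0L] <- "dropped_monomorphic"
  both_obs <- !is.na(pa[1L, ]) & !is.na(pa[2L, ])
  ambig <- both_obs & pa[1L, ] == pa[2L, ]
  status[ambig & status == "kept"] <- "dropped_ambiguous_parent"
  # phase unoriented markers against the nearest oriented one
  flipped <- 0L
  hom <- !is.na(x) & x != 1L
  sgn <- matrix(0, nrow(x), m)
  sgn[hom] <- ifelse(x[hom] == 0L, 1, -1)
  for (ch in levels(mk$chrom)) {
    jc <- which(mk$chrom == ch)
    ref <- jc[oriented[jc] & status[jc] == "kept"]
    tofix <- jc[!oriented[jc] & status[jc] == "kept"]
    if (!length(tofix)) next
    if (!length(ref)) {
      status[tofix] <- "dropped_ambiguous_parent"
      warning("no oriented markers on chromosome ", ch,
              "; phase undecidable for ", length(tofix), " markers")
      next
    }
    for (j in tofix) {
      q <- ref[which.min(abs(mk$pos[ref] - mk$pos[j]))]
      s <- sum(sgn[, j] * sgn[, q])
      if (s == 0) { status[j] <- "dropped_ambiguous_parent"; next }
      if (s < 0) {
        x[, j] <- 2L - x[, j]
        flipped <- flipped + 1L
      }
      oriented[j] <- TRUE
    }
  }
  keep <- status == "kept"
  pa[1L, keep] <- 0L
  pa[2L, keep] <- 2L
  gout <- geno_matrix(x[, keep, drop = FALSE], mk[keep, , drop = FALSE],
                      parents = pa[, keep, drop = FALSE],
                      oriented = oriented[keep], sort = FALSE)
  list(geno = gout,
       verdict = data.frame(id = mk$id, status = status,
                            stringsAsFactors = FALSE),
       n_flipped = flipped)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the
#' probability of the observed table (within relative tolerance 1e-7).
#' A table with an empty row or column margin has p = 1.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_gbs("counts must be non-negative integers",
             class = "gbsmap_validation_error")
  fisher_p(tab[1L, 1L], tab[1L, 2L], tab[2L, 1L], tab[2L, 2L])
}

fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Anchor-based Fisher's-exact filter of error-prone markers
#'
#' Tests each non-anchor marker for dependence with its nearest four
#' anchors on the same chromosome (two upstream and two downstream by
#' physical position; ties broken toward the smaller position).  The 2x2
#' table counts parent-coded homozygous calls at marker and anchor over
#' lines non-missing and homozygous at both.  A marker is dropped
#' (`dropped_fisher`) when any of its available tests is non-significant
#' (p > alpha); chromosome-end markers with fewer than four anchors are
#' tested against those available.  Markers on a chromosome without any
#' anchor pass untested, with a warning.
#'
#' @param g a [geno_matrix()].
#' @param anchors character vector of anchor marker ids (subset of `g`'s
#'   markers).
#' @param alpha per-test significance level (default 0.05).
#' @return list(geno = matrix of retained markers (anchors included),
#'   verdict = data.frame(id, status, p_max)).
#' @export
anchor_fisher_filter <- function(g, anchors, alpha = 0.05) {
  check_fraction(alpha, "alpha")
  mk <- marker_info(g)
  is_anchor <- mk$id %in% anchors
  x <- unclass(g)
  attr(x, "markers") <- attr(x, "parents") <- attr(x, "oriented") <- NULL
  h0 <- (!is.na(x) & x == 0L) * 1
  h2 <- (!is.na(x) & x == 2L) * 1
  status <- rep("kept", ncol(x))
  p_max <- rep(NA_real_, ncol(x))
  for (ch in levels(mk$chrom)) {
    jc <- which(mk$chrom == ch)
    ja <- jc[is_anchor[jc]]
    jt <- jc[!is_anchor[jc]]
    if (!length(jt)) next
    if (!length(ja)) {
      warning("no anchors on chromosome ", ch, "; ",
              length(jt), " markers pass untested")
      next
    }
    apos <- mk$pos[ja]
    # counts of joint hom classes marker x anchor via crossproducts
    c00 <- crossprod(h0[, jt, drop = FALSE], h0[, ja, drop = FALSE])
    c02 <- crossprod(h0[, jt, drop = FALSE], h2[, ja, drop = FALSE])
    c20 <- crossprod(h2[, jt, drop = FALSE], h0[, ja, drop = FALSE])
    c22 <- crossprod(h2[, jt, drop = FALSE], h2[, ja, drop = FALSE])
    for (t in seq_along(jt)) {
      j <- jt[t]
      dpos <- apos - mk$pos[j]
      up <- utils::head(which(dpos < 0)[order(-dpos[dpos < 0])], 2L)
      dn <- utils::head(which(dpos >= 0)[order(dpos[dpos >= 0])], 2L)
      sel <- c(up, dn)
      if (!length(sel)) next
      pv <- vapply(sel, function(q)
        fisher_p(c00[t, q], c02[t, q], c20[t, q], c22[t, q]), 0)
      p_max[j] <- max(pv)
      if (any(pv > alpha)) status[j] <- "dropped_fisher"
    }
  }
  verdict <- data.frame(id = mk$id, status = status, p_max = p_max,
                        stringsAsFactors = FALSE)
  list(geno = g[, status == "kept"], verdict = verdict)
}

#' Sliding-window removal of spurious double recombinants
#'
#' For every line, a centered window of `window` markers slides along each
#' chromosome; the window score of the central call is the fraction of
#' non-missing flanking calls that differ from it.  Calls scoring above
#' `threshold` are set to missing.  All scores are computed on the
#' original matrix and removals applied afterwards (single pass, no
#' cascade).  Missing centers, windows with no non-missing flank, and the
#' first/last `end_skip` markers of each chromosome are skipped.
#'
#' @param g a [geno_matrix()] with markers ordered within chromosomes.
#' @param window window width in markers (odd, >= 3; default 25).
#' @param threshold removal threshold on the window score (default 0.8).
#' @param end_skip uncorrectable markers at each chromosome end
#'   (default 12).
#' @return list(geno = cleaned matrix, mask = logical lines x markers
#'   removal mask, removed_fraction = removed cells / non-missing cells).
#' @export
sliding_window_clean <- function(g, window = 25L, threshold = 0.8,
                                 end_skip = 12L) {
  if (window < 3L || window %% 2L == 0L)
    stop_gbs("window must be odd and >= 3", class = "gbsmap_validation_error")
  check_fraction(threshold, "threshold")
  end_skip <- check_count(end_skip, "end_skip")
  mk <- marker_info(g)
  x <- unclass(g)
  attr(x, "markers") <- attr(x, "parents") <- attr(x, "oriented") <- NULL
  k <- (window - 1L) %/% 2L
  mask <- matrix(FALSE, nrow(x), ncol(x))
  for (ch in levels(mk$chrom)) {
    jc <- which(mk$chrom == ch)
    mc <- length(jc)
    skip <- max(k, end_skip)
    if (mc < 2L * skip + 1L) next
    xc <- x[, jc, drop = FALSE]
    nm <- !is.na(xc)
    w_nm <- window_row_sums(nm * 1, k)
    same <- matrix(NA_real_, nrow(xc), mc)
    for (code in GENO_CODES) {
      wcode <- window_row_sums((nm & xc == code) * 1, k)
      sel <- nm & xc == code
      same[sel] <- wcode[sel] - 1
    }
    n_flank <- w_nm - 1
    score <- (n_flank - same) / n_flank
    rm_c <- !is.na(score) & n_flank > 0 & score > threshold
    rm_c[, c(seq_len(skip), (mc - skip + 1L):mc)] <- FALSE
    mask[, jc] <- rm_c
  }
  n_nonmiss <- sum(!is.na(x))
  x[mask] <- NA_integer_
  gout <- geno_matrix(x, mk, parents = parent_calls(g),
                      oriented = attr(g, "oriented"), sort = FALSE)
  list(geno = gout, mask = mask,
       removed_fraction = sum(mask) / max(1L, n_nonmiss))
}

#' Segregation-distortion scan
#'
#' Per-marker chi-square test (1 df) of the homozygote counts against the
#' 1:1 ratio expected in an advanced selfing generation; heterozygotes are
#' excluded.  Significance is declared at `alpha` after Bonferroni
#' correction for the number of tested markers.
#'
#' @param g a [geno_matrix()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame(id, chrom, n_a, n_b, chisq, p, significant); the
#'   Bonferroni cutoff is attached as attribute `"cutoff"`.
#' @export
segregation_distortion <- function(g, alpha = 0.05) {
  check_fraction(alpha, "alpha")
  x <- unclass(g)
  n_a <- colSums(x == 0L, na.rm = TRUE)
  n_b <- colSums(x == 2L, na.rm = TRUE)
  tot <- n_a + n_b
  chisq <- ifelse(tot > 0, (n_a - n_b)^2 / tot, NA_real_)
  p <- ifelse(tot > 0, stats::pchisq(chisq, df = 1, lower.tail = FALSE), 1)
  if (any(tot == 0))
    message("segregation_distortion: ", sum(tot == 0),
            " markers without homozygous calls (p set to 1)")
  cutoff <- alpha / ncol(x)
  out <- data.frame(id = marker_info(g)$id, chrom = marker_info(g)$chrom,
                    n_a = n_a, n_b = n_b, chisq = chisq, p = p,
                    significant = p < cutoff, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}
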
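#' Select anchor markers
#'
#' Anchors are the trusted backbone of the QC stages: markers genotyped in
#' every RIL and in both parents (zero missing data), biallelic, with the
#' parents carrying opposite homozygous calls.
#'
#' @param g a [geno_matrix()] with parent rows.
#' @return character vector of anchor marker ids (possibly empty).
#' @export
select_anchors <- function(g) {
  pa <- parent_calls(g)
  if (is.null(pa)) stop_gbs("genotype matrix has no parent rows",
                            class = "gbsmap_validation_error")
  x <- unclass(g)
  ok <- colSums(is.na(x)) == 0L &
    !is.na(pa[1L, ]) & !is.na(pa[2L, ]) &
    pa[1L, ] != 1L & pa[2L, ] != 1L & pa[1L, ] != pa[2L, ]
  marker_info(g)$id[ok]
}

#' Two-point linkage between a pair of markers
#'
#' Counts, over lines homozygous and non-missing at both markers, the
#' recombinant (discordant) fraction `R_hat = k/n` and the LOD score of
#' linkage against free recombination:
#' `LOD = k log10(2 R) + (n - k) log10(2 (1 - R))` (with `0 log 0 = 0`).
#' Heterozygous and missing calls are non-informative in a RIL cross and
#' are excluded.
#'
#' @param gi,gj integer call vectors of equal length (codes 0/1/2/NA).
#' @return list(n, k, r_hat, lod); `n = 0` yields `r_hat = NA`, `lod = NA`
#'   (undefined linkage, flagged rather than an error).
#' @export
pairwise_lod <- function(gi, gj) {
  if (length(gi) != length(gj))
    stop_gbs("call vectors differ in length", class = "gbsmap_validation_error")
  use <- !is.na(gi) & !is.na(gj) & gi != 1L & gj != 1L
  n <- sum(use)
  if (n == 0L) return(list(n = 0L, k = 0L, r_hat = NA_real_, lod = NA_real_))
  k <- sum(gi[use] != gj[use])
  r <- k / n
  lod <- xlog10(k, 2 * r) + xlog10(n - k, 2 * (1 - r))
  list(n = n, k = k, r_hat = r, lod = lod)
}

xlog10 <- function(a, x) ifelse(a == 0, 0, a * log10(x))

#' All pairwise linkage statistics of a marker set
#'
#' Vectorized two-point statistics ([pairwise_lod()]) for every marker
#' pair, computed by cross-products of the hom-coded matrix.
#' @param g a [geno_matrix()] (RIL rows only are used).
#' @return list of m x m matrices `n`, `k`, `r_hat`, `lod`.
#' @export
pairwise_linkage <- function(g) {
  x <- unclass(g)
  a <- matrix(0, nrow(x), ncol(x))
  a[!is.na(x) & x == 0L] <- 1
  a[!is.na(x) & x == 2L] <- -1
  n <- crossprod(abs(a))
  s <- crossprod(a)
  k <- (n - s) / 2
  r <- ifelse(n > 0, k / n, NA_real_)
  lod <- xlog10(k, 2 * r) + xlog10(n - k, 2 * (1 - r))
  lod[n == 0] <- NA_real_
  ids <- marker_info(g)$id
  dimnames(n) <- dimnames(k) <- dimnames(r) <- dimnames(lod) <-
    list(ids, ids)
  list(n = n, k = k, r_hat = r, lod = lod)
}

#' Cluster markers into linkage groups
#'
#' Single-linkage connected components of the graph whose edges join
#' marker pairs with pairwise LOD above `lod_threshold`.  The result is
#' invariant to marker input order.
#'
#' @param g a [geno_matrix()] restricted to the markers to cluster
#'   (typically the anchors).
#' @param lod_threshold edge threshold (default 10).
#' @return object of class `linkage_grouping`: list with `group` (named
#'   integer vector, group id per marker; groups numbered by size, largest
#'   first), `members` (list of id vectors) and `markers` (the marker
#'   metadata used).
#' @export
cluster_groups <- function(g, lod_threshold = 10) {
  pl <- pairwise_linkage(g)
  m <- ncol(pl$lod)
  adj <- !is.na(pl$lod) & pl$lod > lod_threshold
  # union-find over the edge list
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ed <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (e in seq_len(nrow(ed))) {
    ri <- find(ed[e, 1L]); rj <- find(ed[e, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  root <- vapply(seq_len(m), find, 0L)
  sizes <- table(root)
  ord <- order(-as.integer(sizes))
  relabel <- stats::setNames(seq_along(sizes), names(sizes)[ord])
  group <- unname(relabel[as.character(root)])
  ids <- marker_info(g)$id
  names(group) <- ids
  structure(list(group = group,
                 members = split(ids, group),
                 markers = marker_info(g)),
            class = "linkage_grouping")
}

#' Detect misallocated markers from a linkage grouping
#'
#' A marker is flagged when its linkage group differs from the majority
#' group of the chromosome it is physically assigned to.  A chromosome
#' represented by a single marker is its own majority and is never
#' flagged.
#'
#' @param grouping a `linkage_grouping` from [cluster_groups()].
#' @return character vector of flagged marker ids.
#' @export
detect_misallocated <- function(grouping) {
  mk <- grouping$markers
  grp <- grouping$group[mk$id]
  majority <- tapply(grp, as.character(mk$chrom), function(v)
    as.integer(names(which.max(table(v)))))
  mk$id[grp != majority[as.character(mk$chrom)]]
}

#' Order markers de novo from pairwise recombination fractions
#'
#' Seriation by objective: returns an order (approximately) minimizing the
#' sum of adjacent recombination fractions, by greedy nearest-neighbour
#' chaining from several starts followed by 2-opt refinement.  The
#' orientation is normalized so the first marker has the smaller physical
#' position.  On small instances (<= 8 markers) the result is checked
#' against brute force in the package's tests.
#'
#' @param r_hat symmetric matrix of pairwise recombination fractions.
#' @param pos physical positions of the markers (for orientation).
#' @return integer permutation of `seq_len(nrow(r_hat))`.
#' @export
order_denovo <- function(r_hat, pos = seq_len(nrow(r_hat))) {
  m <- nrow(r_hat)
  if (m < 2L) stop_gbs("need >= 2 markers to order",
                       class = "gbsmap_validation_error")
  d <- r_hat
  d[is.na(d)] <- 0.5
  diag(d) <- 0
  if (all(d[upper.tri(d)] >= 0.5 - 1e-12))
    stop_gbs("markers show no linkage (all R = 0.5); cannot order group",
             class = "gbsmap_validation_error")
  if (m == 2L) {
    ord <- 1:2
  } else if (m <= 12L) {
    ord <- hk_order(d)  # exact minimum-path seriation for small groups
  } else {
    starts <- unique(c(which.max(apply(d, 1L, sum)), 1L, m))
    best <- NULL; best_cost <- Inf
    for (s in starts) {
      ord <- nn_chain(d, s)
      ord <- two_opt(d, ord)
      cost <- path_cost(d, ord)
      if (cost < best_cost) { best <- ord; best_cost <- cost }
    }
    ord <- best
  }
  if (pos[ord[1L]] > pos[ord[length(ord)]]) ord <- rev(ord)
  ord
}

path_cost <- function(d, ord)
  sum(d[cbind(ord[-length(ord)], ord[-1L])])

# Held-Karp dynamic program over subsets: exact open-path seriation.
hk_order <- function(d) {
  m <- nrow(d)
  nset <- bitwShiftL(1L, m)
  cost <- matrix(Inf, nset, m)
  from <- matrix(NA_integer_, nset, m)
  for (j in 1:m) cost[bitwShiftL(1L, j - 1L) + 1L, j] <- 0
  for (s in seq_len(nset - 1L)) {
    for (j in 1:m) {
      if (!bitwAnd(s, bitwShiftL(1L, j - 1L)) || !is.finite(cost[s + 1L, j]))
        next
      for (k in 1:m) {
        if (bitwAnd(s, bitwShiftL(1L, k - 1L))) next
        s2 <- bitwOr(s, bitwShiftL(1L, k - 1L))
        nc <- cost[s + 1L, j] + d[j, k]
        if (nc < cost[s2 + 1L, k]) {
          cost[s2 + 1L, k] <- nc
          from[s2 + 1L, k] <- j
        }
      }
    }
  }
  full <- nset - 1L
  j <- which.min(cost[full + 1L, ])
  ord <- integer(m)
  s <- full
  for (i in m:1) {
    ord[i] <- j
    pj <- from[s + 1L, j]
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  ord
}

nn_chain <- function(d, start) {
  m <- nrow(d)
  ord <- integer(m); used <- logical(m)
  ord[1L] <- start; used[start] <- TRUE
  for (i in 2:m) {
    cand <- which(!used)
    nxt <- cand[which.min(d[ord[i - 1L], cand])]
    ord[i] <- nxt; used[nxt] <- TRUE
  }
  ord
}

two_opt <- function(d, ord, max_pass = 50L) {
  m <- length(ord)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        a <- if (i > 1L) d[ord[i - 1L], ord[j]] else 0
        b <- if (j < m) d[ord[i], ord[j + 1L]] else 0
        a0 <- if (i > 1L) d[ord[i - 1L], ord[i]] else 0
        b0 <- if (j < m) d[ord[j], ord[j + 1L]] else 0
        if (a + b < a0 + b0 - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

#' Detect inverted runs between a reference and a de novo marker order
#'
#' Reports maximal runs of markers that are contiguous in both orders but
#' reversed in one.  A run spanning the entire marker set reflects the
#' orientation ambiguity of a de novo map and is classed `"orientation"`;
#' shorter runs are classed `"inversion"`.  The de novo order's global
#' orientation is first normalized to the one agreeing best with the
#' reference.
#'
#' @param ref_order,denovo_order character vectors: the same marker ids in
#'   reference (physical) and de novo order.
#' @return data.frame(start, end, n, type, ids) with one row per run;
#'   `ids` is a list-column of member ids.  Zero rows when the orders
#'   agree.
#' @export
detect_inversions <- function(ref_order, denovo_order) {
  if (!setequal(ref_order, denovo_order))
    stop_gbs("orders must contain the same marker set",
             class = "gbsmap_validation_error")
  n <- length(ref_order)
  p_fwd <- match(ref_order, denovo_order)
  if (identical(p_fwd, n:1))
    return(data.frame(start = 1L, end = n, n = n, type = "orientation",
                      ids = I(list(ref_order))))
  # global orientation: align the de novo order with the reference
  p <- if (stats::cor(p_fwd, seq_len(n)) >= 0) p_fwd
  else match(ref_order, rev(denovo_order))
  runs <- reversed_runs(p)
  if (nrow(runs) == 0L) return(runs)
  runs$ids <- I(lapply(seq_len(nrow(runs)), function(k)
    ref_order[runs$start[k]:runs$end[k]]))
  runs
}

# Maximal runs where consecutive reference markers step backwards by one
# in the other order (i.e., a locally reversed block).
reversed_runs <- function(p) {
  dec <- diff(p) == -1L
  out <- data.frame(start = integer(0), end = integer(0), n = integer(0),
                    type = character(0))
  if (!any(dec)) return(out)
  r <- rle(dec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    out <- rbind(out, data.frame(start = starts[k], end = ends[k] + 1L,
                                 n = r$lengths[k] + 1L, type = "inversion"))
  }
  out
}
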
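#' Genotype matrix for a biparental RIL population
#'
#' The central container of the package: an integer matrix of genotype calls
#' with one row per RIL and one column per marker, coded by parental origin
#' (`0` = homozygous for the parent-A allele, `1` = heterozygous, `2` =
#' homozygous for the parent-B allele, `NA` = missing).  Marker metadata
#' (id, chromosome, physical bp position, alleles) travels alongside as the
#' `markers` attribute, and the two parental rows, when available, as the
#' `parents` attribute.
#'
#' Markers are stored sorted by chromosome then physical position unless
#' `sort = FALSE`; chromosome order follows the levels of
#' `markers$chrom`.  The `oriented` attribute flags, per marker, whether the
#' 0/2 coding is anchored to a known parental allele assignment (it is
#' `FALSE` for markers read from allele-level files where both parents were
#' missing; see [infer_parental_genotypes()]).
#'
#' @param calls integer matrix, lines x markers, values in {0, 1, 2, NA}.
#'   Row names are line identifiers.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, and
#'   optionally `allele_a`, `allele_b`.  `chrom` may be a factor whose level
#'   order declares the chromosome order.
#' @param parents optional 2 x markers integer matrix of parental calls
#'   (row 1 = parent A, row 2 = parent B), same coding.
#' @param oriented optional logical vector, one per marker; default all `TRUE`.
#' @param sort sort markers by chromosome then position (default `TRUE`).
#' @return An object of class `geno_matrix`.
#' @seealso [read_genotypes()], [simulate_population()]
#' @export
geno_matrix <- function(calls, markers, parents = NULL, oriented = NULL,
                        sort = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!is.data.frame(markers) || !all(c("id", "chrom", "pos") %in% names(markers)))
    stop_gbs("markers must be a data.frame with id, chrom, pos columns",
             class = "gbsmap_validation_error")
  if (nrow(markers) != ncol(calls))
    stop_gbs("marker table (", nrow(markers), ") and call matrix (",
             ncol(calls), " columns) disagree",
             class = "gbsmap_validation_error")
  if (anyDuplicated(markers$id))
    stop_gbs("duplicate marker ids: ",
             paste(utils::head(markers$id[duplicated(markers$id)], 3L),
                   collapse = ", "),
             class = "gbsmap_validation_error")
  if (any(markers$pos < 1))
    stop_gbs("physical positions must be >= 1 (1-based bp)",
             class = "gbsmap_validation_error")
  bad <- !(calls %in% GENO_CODES | is.na(calls))
  if (any(bad))
    stop_gbs("call codes must be 0/1/2/NA", class = "gbsmap_validation_error")
  if (!is.factor(markers$chrom))
    markers$chrom <- factor(markers$chrom, levels = unique(markers$chrom))
  if (is.null(oriented)) oriented <- rep(TRUE, nrow(markers))
  if (!is.null(parents)) {
    parents <- as.matrix(parents)
    storage.mode(parents) <- "integer"
    if (nrow(parents) != 2L || ncol(parents) != ncol(calls))
      stop_gbs("parents must be a 2 x n_markers matrix",
               class = "gbsmap_validation_error")
    if (is.null(rownames(parents))) rownames(parents) <- c("parentA", "parentB")
  }
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("RIL%03d", seq_len(nrow(calls)))
  if (sort) {
    ord <- order(as.integer(markers$chrom), markers$pos)
    calls <- calls[, ord, drop = FALSE]
    markers <- markers[ord, , drop = FALSE]
    oriented <- oriented[ord]
    if (!is.null(parents)) parents <- parents[, ord, drop = FALSE]
  }
  rownames(markers) <- NULL
  colnames(calls) <- markers$id
  if (!is.null(parents)) colnames(parents) <- markers$id
  structure(calls,
            markers = markers, parents = parents, oriented = oriented,
            class = c("geno_matrix", "matrix", "array"))
}

#' Marker metadata of a genotype matrix
#' @param g a `geno_matrix`.
#' @return data.frame with columns `id`, `chrom`, `pos`, alleles if present.
#' @export
marker_info <- function(g) attr(g, "markers")

#' Parental call rows of a genotype matrix
#' @param g a `geno_matrix`.
#' @return 2 x markers integer matrix, or `NULL` when no parents attached.
#' @export
parent_calls <- function(g) attr(g, "parents")

n_lines <- function(g) nrow(g)
n_markers <- function(g) ncol(g)

#' Subset a genotype matrix by lines and/or markers
#'
#' Keeps marker metadata, parent rows and orientation flags in sync.
#' Marker order is preserved as given by `j` (no re-sorting), so callers can
#' reorder columns deliberately.
#' @param x a `geno_matrix`.
#' @param i,j line / marker indices (any standard matrix index).
#' @param ... ignored.
#' @param drop ignored; result is always a `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  mk <- attr(x, "markers"); pa <- attr(x, "parents"); orf <- attr(x, "oriented")
  xm <- unclass(x)
  attr(xm, "markers") <- attr(xm, "parents") <- attr(xm, "oriented") <- NULL
  if (missing(i)) i <- seq_len(nrow(xm))
  if (missing(j)) j <- seq_len(ncol(xm))
  if (is.character(j)) j <- match(j, mk$id)
  if (is.logical(j)) j <- which(j)
  out <- xm[i, j, drop = FALSE]
  geno_matrix(out, mk[j, , drop = FALSE],
              parents = if (!is.null(pa)) pa[, j, drop = FALSE],
              oriented = orf[j], sort = FALSE)
}

#' @export
print.geno_matrix <- function(x, ...) {
  mk <- marker_info(x)
  cat(sprintf("geno_matrix: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x), ncol(x), nlevels(mk$chrom)))
  cat(sprintf("  missing: %.2f%%  het: %.2f%%  parents: %s\n",
              100 * mean(is.na(x)),
              100 * mean(x == 1L, na.rm = TRUE),
              if (is.null(parent_calls(x))) "absent" else
                paste(rownames(parent_calls(x)), collapse = " x ")))
  invisible(x)
}

#' Per-marker missing fraction among RIL lines
#' @param g a `geno_matrix`.
#' @return numeric vector in `[0, 1]`, one entry per marker.
#' @export
missing_fraction <- function(g) colMeans(is.na(unclass(g)))

#' Per-marker minor allele frequency among RIL lines
#'
#' Each homozygote contributes two copies of its allele and each
#' heterozygote one of each; missing calls are ignored.
#' @param g a `geno_matrix`.
#' @return numeric vector in `[0, 0.5]`; `NA` where no calls at all.
#' @export
maf <- function(g) {
  x <- unclass(g)
  nA <- colSums(2L * (x == 0L) + (x == 1L), na.rm = TRUE)
  nB <- colSums(2L * (x == 2L) + (x == 1L), na.rm = TRUE)
  tot <- nA + nB
  ifelse(tot == 0L, NA_real_, pmin(nA, nB) / tot)
}
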
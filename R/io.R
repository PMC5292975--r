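#' Read genotypes from HapMap-style, VCF or coded-CSV files
#'
#' All three readers return a [geno_matrix()] coded by parental origin.
#' For nucleotide-level formats (`hapmap`, `vcf`) the 0/2 orientation of
#' each marker is fixed by the parental samples named in `parents`
#' (parent A first): a marker whose parent calls are missing in the file is
#' coded by file allele order and flagged unoriented, to be resolved later
#' by [infer_parental_genotypes()].  The coded `csv` format stores call
#' codes directly and is always oriented.
#'
#' Unknown genotype symbols are mapped to missing with a reported count.
#'
#' @param path input file.
#' @param format one of `"hapmap"`, `"vcf"`, `"csv"`.
#' @param parents character(2): sample names of parent A and parent B, or
#'   `NULL` when the file has no parent samples.  Ignored for `csv`, which
#'   records its parents in a header comment.
#' @return A `geno_matrix` with markers sorted by chromosome and position.
#' @export
read_genotypes <- function(path, format = c("hapmap", "vcf", "csv"),
                           parents = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_gbs("file not found: ", path,
                                   class = "gbsmap_io_error")
  switch(format,
         hapmap = read_hapmap(path, parents),
         vcf = read_vcf_gt(path, parents),
         csv = read_geno_csv(path))
}

#' Write genotypes to HapMap-style, VCF or coded-CSV files
#'
#' Output is deterministic (fixed field order), so writing the same matrix
#' twice yields byte-identical files.  The VCF writer emits a minimal
#' GT-only VCF v4.2 body.
#'
#' @param g a [geno_matrix()].
#' @param path output file.
#' @param format one of `"hapmap"`, `"vcf"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("hapmap", "vcf", "csv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_gbs("directory does not exist: ", dir,
                                 class = "gbsmap_io_error")
  switch(format,
         hapmap = write_hapmap(g, path),
         vcf = write_vcf_gt(g, path),
         csv = write_geno_csv(g, path))
  invisible(path)
}

marker_alleles <- function(g) {
  mk <- marker_info(g)
  a <- if ("allele_a" %in% names(mk)) mk$allele_a else rep("A", nrow(mk))
  b <- if ("allele_b" %in% names(mk)) mk$allele_b else rep("B", nrow(mk))
  list(a = as.character(a), b = as.character(b))
}

code_to_diploid <- function(codes, a, b) {
  out <- rep("NN", length(codes))
  out[!is.na(codes) & codes == 0L] <- paste0(a, a)[!is.na(codes) & codes == 0L]
  out[!is.na(codes) & codes == 2L] <- paste0(b, b)[!is.na(codes) & codes == 2L]
  out[!is.na(codes) & codes == 1L] <- paste0(a, b)[!is.na(codes) & codes == 1L]
  out
}

# Decode diploid genotype strings ("AA", "AC", "NN", also single letters)
# against per-marker allele pairs; returns list(codes, n_unknown).
diploid_to_code <- function(gt, a, b) {
  gt <- toupper(gt)
  gt[nchar(gt) == 1L] <- paste0(gt[nchar(gt) == 1L], gt[nchar(gt) == 1L])
  x1 <- substr(gt, 1L, 1L); x2 <- substr(gt, 2L, 2L)
  miss <- gt %in% c("NN", "--", "..", "./.", "")
  codes <- rep(NA_integer_, length(gt))
  codes[x1 == a & x2 == a] <- 0L
  codes[x1 == b & x2 == b] <- 2L
  codes[(x1 == a & x2 == b) | (x1 == b & x2 == a)] <- 1L
  n_unknown <- sum(is.na(codes) & !miss)
  list(codes = codes, n_unknown = n_unknown)
}

# Orient per-marker coding by parental calls: where parent A (or B) carries
# a known homozygous call the 0/2 direction is fixed; where neither parent
# is informative the file allele order stands and the marker is unoriented.
orient_by_parents <- function(calls, pcalls) {
  flip <- pcalls[1L, ] == 2L | pcalls[2L, ] == 0L
  flip[is.na(flip)] <- FALSE
  conflict <- !is.na(pcalls[1L, ]) & !is.na(pcalls[2L, ]) &
    pcalls[1L, ] == pcalls[2L, ] & pcalls[1L, ] != 1L
  oriented <- (!is.na(pcalls[1L, ]) & pcalls[1L, ] != 1L) |
    (!is.na(pcalls[2L, ]) & pcalls[2L, ] != 1L)
  oriented[conflict] <- TRUE  # kept as-is; dropped later as ambiguous
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip]
    pcalls[, flip] <- 2L - pcalls[, flip]
  }
  list(calls = calls, parents = pcalls, oriented = oriented, flip = flip)
}

read_hapmap <- function(path, parents) {
  ln <- readLines(path)
  if (length(ln) < 1L) stop_gbs("empty file: ", path, class = "gbsmap_io_error")
  fields <- strsplit(ln, "\t", fixed = TRUE)
  hdr <- fields[[1L]]
  if (length(hdr) < 5L || hdr[1L] != "rs")
    stop_gbs("not a hapmap-style table (header must start with 'rs'): ", path,
             class = "gbsmap_format_error")
  nf <- lengths(fields)
  bad <- which(nf != length(hdr))[1L]
  if (!is.na(bad))
    stop_gbs("line ", bad, ": expected ", length(hdr), " fields, found ",
             nf[bad], class = "gbsmap_format_error")
  samples <- hdr[-(1:4)]
  if (length(fields) == 1L) {  # header-only file: no markers
    empty <- matrix(NA_integer_, length(samples), 0L,
                    dimnames = list(samples, NULL))
    mk0 <- data.frame(id = character(0), chrom = character(0),
                      pos = numeric(0), allele_a = character(0),
                      allele_b = character(0), stringsAsFactors = FALSE)
    return(assemble_allele_matrix(empty, samples, parents, mk0, 0L))
  }
  body <- do.call(rbind, fields[-1L])
  al <- strsplit(body[, 2L], "/", fixed = TRUE)
  a <- vapply(al, `[`, "", 1L); b <- vapply(al, `[`, "", 2L)
  gt <- body[, -(1:4), drop = FALSE]
  n_unknown <- 0L
  codes <- matrix(NA_integer_, ncol(gt), nrow(gt))  # samples x markers
  for (j in seq_len(nrow(gt))) {
    dec <- diploid_to_code(gt[j, ], a[j], b[j])
    codes[, j] <- dec$codes
    n_unknown <- n_unknown + dec$n_unknown
  }
  rownames(codes) <- samples
  assemble_allele_matrix(codes, samples, parents,
                         markers = data.frame(id = body[, 1L],
                                              chrom = body[, 3L],
                                              pos = as.numeric(body[, 4L]),
                                              allele_a = a, allele_b = b,
                                              stringsAsFactors = FALSE),
                         n_unknown = n_unknown)
}

assemble_allele_matrix <- function(codes, samples, parents, markers,
                                   n_unknown) {
  if (n_unknown > 0L)
    message("read_genotypes: ", n_unknown,
            " unrecognized genotype symbols set to missing")
  if (!is.null(parents)) {
    if (!all(parents %in% samples))
      stop_gbs("parent samples not found: ",
               paste(setdiff(parents, samples), collapse = ", "),
               class = "gbsmap_validation_error")
    pcalls <- codes[parents, , drop = FALSE]
    calls <- codes[setdiff(samples, parents), , drop = FALSE]
    o <- orient_by_parents(calls, pcalls)
    sw <- o$flip
    if (any(sw)) {  # keep allele columns in step with the flipped coding
      tmp <- markers$allele_a[sw]
      markers$allele_a[sw] <- markers$allele_b[sw]
      markers$allele_b[sw] <- tmp
    }
    geno_matrix(o$calls, markers, parents = o$parents, oriented = o$oriented)
  } else {
    geno_matrix(codes, markers,
                oriented = rep(FALSE, nrow(markers)))
  }
}

write_hapmap <- function(g, path) {
  al <- marker_alleles(g)
  mk <- marker_info(g)
  pa <- parent_calls(g)
  rows <- unclass(g)
  attr(rows, "markers") <- attr(rows, "parents") <- attr(rows, "oriented") <- NULL
  if (!is.null(pa)) rows <- rbind(pa, rows)
  gt <- apply(rows, 1L, code_to_diploid, a = al$a, b = al$b)  # markers x samples
  tab <- cbind(mk$id, paste0(al$a, "/", al$b), as.character(mk$chrom),
               format(mk$pos, scientific = FALSE, trim = TRUE),
               if (nrow(mk)) gt else NULL)
  hdr <- c("rs", "alleles", "chrom", "pos", rownames(rows))
  con <- file(path, "wb")  # binary mode: fixed "\n" on every platform
  on.exit(close(con))
  writeLines(c(paste(hdr, collapse = "\t"),
               if (nrow(mk)) apply(tab, 1L, paste, collapse = "\t")),
             con)
  invisible(path)
}

read_vcf_gt <- function(path, parents) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_gbs("VCF has no GT field: ", path,
                            class = "gbsmap_format_error")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, ncol(gt), nrow(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  vals <- known[gt]
  n_unknown <- sum(is.na(vals) & !(is.na(gt) | gt %in% c("./.", ".")))
  codes[] <- t(matrix(vals, nrow(gt), ncol(gt)))
  samples <- colnames(gt)
  rownames(codes) <- samples
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0("S", fix[noid, "CHROM"], "_", fix[noid, "POS"])
  assemble_allele_matrix(codes, samples, parents,
                         markers = data.frame(id = ids,
                                              chrom = fix[, "CHROM"],
                                              pos = as.numeric(fix[, "POS"]),
                                              allele_a = fix[, "REF"],
                                              allele_b = fix[, "ALT"],
                                              stringsAsFactors = FALSE),
                         n_unknown = n_unknown)
}

write_vcf_gt <- function(g, path) {
  al <- marker_alleles(g)
  mk <- marker_info(g)
  pa <- parent_calls(g)
  rows <- unclass(g)
  attr(rows, "markers") <- attr(rows, "parents") <- attr(rows, "oriented") <- NULL
  if (!is.null(pa)) rows <- rbind(pa, rows)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(mk), nrow(rows))
  ok <- !is.na(t(rows))
  gt[ok] <- gtmap[t(rows)[ok] + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gbsmap",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(rows)), collapse = "\t"))
  body <- cbind(as.character(mk$chrom),
                format(mk$pos, scientific = FALSE, trim = TRUE),
                mk$id, al$a, al$b, ".", ".", ".", "GT", gt)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, if (nrow(mk)) apply(body, 1L, paste, collapse = "\t")),
             con)
  invisible(path)
}

read_geno_csv <- function(path) {
  first <- readLines(path, n = 1L)
  pnames <- NULL
  if (startsWith(first, "#parents:"))
    pnames <- strsplit(sub("^#parents:\\s*", "", first), ",")[[1L]]
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop_gbs("coded CSV must have id, chrom, pos columns",
             class = "gbsmap_format_error")
  meta <- intersect(c("id", "chrom", "pos", "allele_a", "allele_b"),
                    names(tab))
  samples <- setdiff(names(tab), meta)
  codes <- t(as.matrix(tab[, samples, drop = FALSE]))
  storage.mode(codes) <- "integer"
  mk <- tab[, meta, drop = FALSE]
  if (!is.null(pnames)) {
    pcalls <- codes[pnames, , drop = FALSE]
    calls <- codes[setdiff(samples, pnames), , drop = FALSE]
    geno_matrix(calls, mk, parents = pcalls)
  } else geno_matrix(codes, mk)
}

write_geno_csv <- function(g, path) {
  mk <- marker_info(g)
  pa <- parent_calls(g)
  rows <- unclass(g)
  attr(rows, "markers") <- attr(rows, "parents") <- attr(rows, "oriented") <- NULL
  if (!is.null(pa)) rows <- rbind(pa, rows)
  tab <- cbind(mk[, intersect(c("id", "chrom", "pos", "allele_a", "allele_b"),
                              names(mk)), drop = FALSE],
               as.data.frame(t(rows)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(pa))
    writeLines(paste0("#parents: ", paste(rownames(pa), collapse = ",")), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' A CSV with a `line` column and one numeric column per trait.  Lines may
#' have missing trait values.
#' @param path file path.
#' @param pheno data.frame with a `line` column.
#' @return `read_phenotypes` returns a data.frame with `line` first.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"line" %in% names(tab))
    stop_gbs("phenotype CSV must have a 'line' column",
             class = "gbsmap_format_error")
  tab[, c("line", setdiff(names(tab), "line")), drop = FALSE]
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.csv(pheno, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
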
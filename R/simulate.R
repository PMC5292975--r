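#' Genome specification for the RIL simulator
#'
#' Per-chromosome genetic (cM) and physical (bp) lengths plus a
#' recombination landscape: a piecewise-constant rate multiplier along each
#' chromosome (normalized to average 1 over physical length) that shapes
#' where crossovers fall, creating suppressed pericentromeric regions and
#' recombination-hot chromosome ends as seen in compact plant genomes.
#'
#' The default genome emulates a 12-chromosome melon genome of 1,088 cM /
#' 353 Mb.
#'
#' @param len_cM numeric vector of per-chromosome genetic lengths, cM.
#' @param len_bp numeric vector of physical lengths, bp.
#' @param chrom chromosome labels.
#' @param landscape list, one element per chromosome, each a data.frame
#'   with columns `from`, `to` (physical fractions, tiling `[0, 1]`) and
#'   `mult` (> 0).  Multipliers are renormalized to average 1.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(len_cM = c(106.7, 79.5, 78.2, 114.9, 86.8, 100.4,
                                   96.3, 86.6, 89.2, 66.2, 105.3, 78.3),
                        len_bp = c(35191472, 26170228, 29150566, 32910366,
                                   28148921, 35697279, 26603112, 32490372,
                                   24104665, 24868054, 31233764, 26355078),
                        chrom = as.character(seq_along(len_cM)),
                        landscape = NULL) {
  if (length(len_cM) != length(len_bp) || length(len_cM) != length(chrom))
    stop_gbs("len_cM, len_bp and chrom must have equal length",
             class = "gbsmap_validation_error")
  if (any(len_cM <= 0) || any(len_bp <= 0))
    stop_gbs("chromosome lengths must be positive",
             class = "gbsmap_validation_error")
  if (is.null(landscape))
    landscape <- rep(list(default_landscape()), length(chrom))
  landscape <- lapply(landscape, function(ls) {
    w <- ls$to - ls$from
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-8 || any(ls$mult < 0))
      stop_gbs("landscape segments must tile [0,1] with mult >= 0",
               class = "gbsmap_validation_error")
    ls$mult <- ls$mult / sum(ls$mult * w)  # average to 1
    ls
  })
  structure(list(chrom = chrom, len_cM = len_cM, len_bp = len_bp,
                 landscape = landscape),
            class = "genome_spec")
}

# Suppressed center, hot ends; normalized by genome_spec().
default_landscape <- function() {
  data.frame(from = c(0, 0.08, 0.30, 0.70, 0.92),
             to   = c(0.08, 0.30, 0.70, 0.92, 1),
             mult = c(2.2, 1.4, 0.25, 1.4, 2.2))
}

# Piecewise-linear physical <-> genetic coordinate maps per chromosome.
landscape_nodes <- function(genome, i) {
  ls <- genome$landscape[[i]]
  bp <- c(ls$from, 1) * genome$len_bp[i]
  cm <- c(0, cumsum(ls$mult * (ls$to - ls$from))) * genome$len_cM[i]
  list(bp = bp, cM = cm)
}

bp_to_cm <- function(genome, i, pos_bp) {
  nd <- landscape_nodes(genome, i)
  stats::approx(nd$bp, nd$cM, xout = pos_bp, rule = 2)$y
}

cm_to_bp <- function(genome, i, pos_cm) {
  nd <- landscape_nodes(genome, i)
  stats::approx(nd$cM, nd$bp, xout = pos_cm, rule = 2, ties = "ordered")$y
}

# A haplotype along one chromosome: segment start positions `b` (cM,
# b[1] = 0) and parental origins `o` (0 = parent A, 1 = parent B).
hap_eval <- function(h, pos) h$o[findInterval(pos, h$b)]

# One meiotic gamete from a haplotype pair.  Crossover count ~
# Poisson(length in Morgans), positions uniform in genetic distance
# (no interference); the landscape enters through the cM <-> bp maps.
meiosis_gamete <- function(h1, h2, len_cM) {
  nco <- stats::rpois(1L, len_cM / 100)
  start <- sample.int(2L, 1L)
  if (nco == 0L) return(if (start == 1L) h1 else h2)
  xs <- sort(stats::runif(nco, 0, len_cM))
  b <- sort(unique(c(0, xs, h1$b, h2$b)))
  use1 <- (start - 1L + findInterval(b, xs)) %% 2L == 0L
  o <- ifelse(use1, hap_eval(h1, b), hap_eval(h2, b))
  keep <- c(TRUE, o[-1L] != o[-length(o)])
  list(b = b[keep], o = o[keep])
}

# Gamete under gametic viability selection at one locus: a gamete carrying
# the disfavored origin survives with probability 1 - s (rejection
# resampling).
meiosis_gamete_sel <- function(h1, h2, len_cM, locus_cM, s, disfavored = 1L) {
  repeat {
    g <- meiosis_gamete(h1, h2, len_cM)
    if (s <= 0 || hap_eval(g, locus_cM) != disfavored ||
        stats::runif(1L) >= s) return(g)
  }
}

#' Simulate an F-generation RIL population by single-seed descent
#'
#' Starting from a fully heterozygous F1, each line is selfed
#' `generation - 1` times, drawing two independent gametes per selfing.
#' Crossovers per chromosome per meiosis are Poisson with mean equal to
#' the genetic length in Morgans and are placed without interference;
#' the genome's recombination landscape shapes their physical positions.
#' Genotypes are read off the final haplotype pair at the marker
#' positions, coded 0 (parent-A homozygote) / 1 (het) / 2 (parent-B
#' homozygote).  Parent rows (fully inbred, no missing data) are attached.
#'
#' Optionally, gametic viability selection at one locus (see
#' [calibrate_viability()]) is applied in every selfing generation,
#' producing segregation distortion around the locus.
#'
#' @param genome a [genome_spec()].
#' @param n_lines number of RILs (default 109).
#' @param generation filial generation, >= 2 (default 7 = F7).
#' @param n_markers total marker count, allocated to chromosomes
#'   proportionally to physical length (default 23000).
#' @param seed RNG seed.
#' @param distortion optional list(chrom, pos_bp, s) applying viability
#'   selection of strength `s` against parent-B gametes at the locus.
#' @param marker_spacing `"uniform"` (random positions) or `"even"`
#'   (regular grid).
#' @return list with `geno` (a [geno_matrix()] of true genotypes with
#'   parent rows) and `truth` (a `sim_truth` ledger: haplotype mosaics,
#'   true marker table, genome, and empty artifact slots).
#' @export
simulate_population <- function(genome = genome_spec(), n_lines = 109L,
                                generation = 7L, n_markers = 23000L,
                                seed = NULL, distortion = NULL,
                                marker_spacing = c("uniform", "even")) {
  marker_spacing <- match.arg(marker_spacing)
  n_lines <- check_count(n_lines, "n_lines", 1L)
  generation <- check_count(generation, "generation", 2L)
  if (!inherits(genome, "genome_spec"))
    stop_gbs("genome must be a genome_spec", class = "gbsmap_validation_error")
  nchr <- length(genome$chrom)
  with_seed(seed, {
    # marker placement
    n_per <- pmax(2L, round(n_markers * genome$len_bp / sum(genome$len_bp)))
    mk <- do.call(rbind, lapply(seq_len(nchr), function(i) {
      pos <- if (marker_spacing == "even")
        round(seq(1, genome$len_bp[i], length.out = n_per[i]))
      else sort(sample.int(genome$len_bp[i], n_per[i]))
      pos <- unique(pos)
      data.frame(chrom = genome$chrom[i], pos = pos,
                 cM = bp_to_cm(genome, i, pos), stringsAsFactors = FALSE)
    }))
    mk$id <- paste0("S", mk$chrom, "_", mk$pos)
    nuc <- c("A", "C", "G", "T")
    mk$allele_a <- sample(nuc, nrow(mk), replace = TRUE)
    mk$allele_b <- vapply(mk$allele_a,
                          function(a) sample(setdiff(nuc, a), 1L), "")
    dis_i <- NULL; dis_cm <- NA_real_; dis_s <- 0
    if (!is.null(distortion)) {
      dis_i <- match(as.character(distortion$chrom), genome$chrom)
      if (is.na(dis_i)) stop_gbs("distortion chromosome not in genome",
                                 class = "gbsmap_validation_error")
      dis_cm <- bp_to_cm(genome, dis_i, distortion$pos_bp)
      dis_s <- distortion$s
    }
    # single-seed descent
    haps <- vector("list", n_lines)
    for (l in seq_len(n_lines)) {
      pair <- lapply(seq_len(nchr), function(i)
        list(h1 = list(b = 0, o = 0L), h2 = list(b = 0, o = 1L)))
      for (gen in seq_len(generation - 1L)) {
        pair <- lapply(seq_len(nchr), function(i) {
          L <- genome$len_cM[i]
          if (!is.null(dis_i) && i == dis_i && dis_s > 0) {
            g1 <- meiosis_gamete_sel(pair[[i]]$h1, pair[[i]]$h2, L, dis_cm, dis_s)
            g2 <- meiosis_gamete_sel(pair[[i]]$h1, pair[[i]]$h2, L, dis_cm, dis_s)
          } else {
            g1 <- meiosis_gamete(pair[[i]]$h1, pair[[i]]$h2, L)
            g2 <- meiosis_gamete(pair[[i]]$h1, pair[[i]]$h2, L)
          }
          list(h1 = g1, h2 = g2)
        })
      }
      haps[[l]] <- pair
    }
    # genotypes at markers
    calls <- matrix(NA_integer_, n_lines, nrow(mk))
    for (i in seq_len(nchr)) {
      j <- which(mk$chrom == genome$chrom[i])
      pos <- mk$cM[j]
      for (l in seq_len(n_lines)) {
        p <- haps[[l]][[i]]
        calls[l, j] <- hap_eval(p$h1, pos) + hap_eval(p$h2, pos)
      }
    }
    rownames(calls) <- sprintf("RIL%03d", seq_len(n_lines))
    parents <- rbind(parentA = rep(0L, nrow(mk)),
                     parentB = rep(2L, nrow(mk)))
    g <- geno_matrix(calls,
                     mk[, c("id", "chrom", "pos", "allele_a", "allele_b")],
                     parents = parents)
    truth <- structure(list(
      genome = genome, generation = generation,
      markers = mk[, c("id", "chrom", "pos", "cM")],
      haplotypes = haps, lines = rownames(calls),
      artifacts = list(errors = NULL, masked = NULL, misallocated = NULL,
                       inverted = NULL, flipped = NULL,
                       parent_masked = NULL,
                       distortion = if (is.null(distortion)) NULL else
                         c(distortion, list(pos_cM = dis_cm))),
      qtl = NULL), class = "sim_truth")
    list(geno = g, truth = truth)
  })
}

#' Mosaic segments of the simulated truth
#'
#' Expands the per-line haplotype pairs into a tidy segment table; segment
#' ends of each haplotype tile its chromosome exactly.
#' @param truth a `sim_truth`.
#' @return data.frame(line, chrom, hap, start_cM, end_cM, start_bp,
#'   end_bp, origin).
#' @export
truth_mosaic <- function(truth) {
  genome <- truth$genome
  out <- vector("list", 0L)
  for (l in seq_along(truth$haplotypes)) {
    for (i in seq_along(genome$chrom)) {
      for (hname in c("h1", "h2")) {
        h <- truth$haplotypes[[l]][[i]][[hname]]
        end <- c(h$b[-1L], genome$len_cM[i])
        out[[length(out) + 1L]] <- data.frame(
          line = truth$lines[l], chrom = genome$chrom[i], hap = hname,
          start_cM = h$b, end_cM = end,
          start_bp = cm_to_bp(genome, i, h$b),
          end_bp = cm_to_bp(genome, i, end),
          origin = h$o, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Count true junctions (haplotype breakpoints) per line
#' @param truth a `sim_truth`.
#' @return integer vector, one entry per line: total breakpoints across
#'   both haplotypes and all chromosomes.
#' @export
truth_junctions <- function(truth) {
  vapply(truth$haplotypes, function(pair)
    sum(vapply(pair, function(p)
      (length(p$h1$b) - 1L) + (length(p$h2$b) - 1L), 0L)), 0L)
}

#' Artifact specification for GBS-style corruption of simulated genotypes
#'
#' @param missing_rate mean per-site missing-call rate among RILs
#'   (default 0.445).
#' @param missing_shape1 beta shape1 of the per-site missing-rate
#'   distribution; small values give the strongly overdispersed site
#'   coverage typical of GBS, leaving a minority of sites with no missing
#'   calls at all (the anchor pool).
#' @param error_rate per-cell genotyping-error rate (default 0.002).
#' @param error_to_het probability that an erroneous homozygote is
#'   miscalled heterozygous rather than as the opposite homozygote.
#' @param n_misallocated markers assigned a false chromosome/position
#'   (default 54), sampled preferentially from low-recombination windows.
#' @param inversion list(chrom, start_bp, n_markers) whose reported marker
#'   order is reversed (default: 28 markers from 30,481,228 bp on
#'   chromosome 1), or `NULL`.
#' @param distortion list(chrom, pos_bp, target_freq) requesting viability
#'   selection calibrated so the favored parent-A allele reaches
#'   `target_freq` at the locus (default chromosome 6, 0.83), or `NULL`.
#' @param parent_missing per-call missing rate of the two parent rows
#'   (default 0.30, i.e. a 70 percent parental call rate).
#' @return list of class `artifact_spec`.
#' @export
artifact_spec <- function(missing_rate = 0.445, missing_shape1 = 0.35,
                          error_rate = 0.002, error_to_het = 0.3,
                          n_misallocated = 54L,
                          inversion = list(chrom = "1", start_bp = 30481228,
                                           n_markers = 28L),
                          distortion = list(chrom = "6", pos_bp = 17000000,
                                            target_freq = 0.83),
                          parent_missing = 0.30) {
  check_fraction(missing_rate, "missing_rate")
  check_fraction(error_rate, "error_rate")
  check_fraction(error_to_het, "error_to_het")
  check_fraction(parent_missing, "parent_missing")
  check_count(n_misallocated, "n_misallocated")
  if (missing_shape1 <= 0) stop_gbs("missing_shape1 must be > 0",
                                    class = "gbsmap_validation_error")
  structure(list(missing_rate = missing_rate,
                 missing_shape1 = missing_shape1,
                 error_rate = error_rate, error_to_het = error_to_het,
                 n_misallocated = as.integer(n_misallocated),
                 inversion = inversion, distortion = distortion,
                 parent_missing = parent_missing),
            class = "artifact_spec")
}

#' Inject GBS-style artifacts into a simulated genotype matrix
#'
#' Applies, in order: genotyping errors (code flips), beta-dispersed
#' per-site missingness, marker misallocation (false chromosome/position,
#' true genotype column kept), reversal of the reported order of one
#' marker block, parental missingness, and - for markers whose parents are
#' both masked - a random swap of the 0/2 coding with the marker flagged
#' unoriented, mimicking allele-level data whose parental phase is
#' unknown.  Every artifact is recorded exactly once in the returned
#' truth ledger.
#'
#' Segregation distortion is a breeding-time process (viability selection
#' during the selfing generations) and is therefore applied by
#' [simulate_population()], not here; use [simulate_gbs_dataset()] to get
#' both wired together.
#'
#' @param g true-genotype [geno_matrix()] with parent rows.
#' @param truth matching `sim_truth` from [simulate_population()].
#' @param art an [artifact_spec()].
#' @param seed RNG seed.
#' @return list(geno = observed matrix, truth = updated ledger).
#' @export
inject_artifacts <- function(g, truth, art = artifact_spec(), seed = NULL) {
  if (!inherits(art, "artifact_spec"))
    stop_gbs("art must be an artifact_spec", class = "gbsmap_validation_error")
  genome <- truth$genome
  with_seed(seed, {
    mk <- marker_info(g)
    calls <- unclass(g)
    attr(calls, "markers") <- attr(calls, "parents") <- attr(calls, "oriented") <- NULL
    pcalls <- parent_calls(g)
    n <- nrow(calls); m <- ncol(calls)
    led <- truth$artifacts
    # genotyping errors
    if (art$error_rate > 0) {
      idx <- which(stats::runif(n * m) < art$error_rate)
      if (length(idx)) {
        old <- calls[idx]
        new <- old
        hom <- old != 1L
        to_het <- hom & stats::runif(length(idx)) < art$error_to_het
        new[hom & !to_het] <- 2L - old[hom & !to_het]
        new[to_het] <- 1L
        new[!hom] <- sample(c(0L, 2L), sum(!hom), replace = TRUE)
        calls[idx] <- new
        led$errors <- data.frame(line = rownames(calls)[(idx - 1L) %% n + 1L],
                                 marker = mk$id[(idx - 1L) %/% n + 1L],
                                 true = old, observed = new,
                                 stringsAsFactors = FALSE)
      }
    }
    # beta-dispersed missingness
    if (art$missing_rate > 0) {
      a <- art$missing_shape1
      b <- a * (1 - art$missing_rate) / art$missing_rate
      site_rate <- stats::rbeta(m, a, b)
      mask <- matrix(stats::runif(n * m) <
                       matrix(site_rate, n, m, byrow = TRUE), n, m)
      calls[mask] <- NA_integer_
      led$masked <- mask
    }
    # inversion block fixed on the true marker table, so misallocation
    # cannot add or remove members
    inv_ids <- character(0)
    if (!is.null(art$inversion))
      inv_ids <- mk$id[inversion_block(mk, art$inversion)]
    # misallocated markers
    if (art$n_misallocated > 0L) {
      w <- landscape_weight(genome, mk)
      w[mk$id %in% inv_ids] <- 0
      pick <- sample.int(m, art$n_misallocated, prob = w)
      new_chr_i <- vapply(match(mk$chrom[pick], genome$chrom), function(ci)
        sample(setdiff(seq_along(genome$chrom), ci), 1L), 0L)
      new_pos <- vapply(new_chr_i, function(ci)
        sample.int(genome$len_bp[ci], 1L), 0L)
      led$misallocated <- data.frame(id = mk$id[pick],
                                     true_chrom = as.character(mk$chrom[pick]),
                                     true_pos = mk$pos[pick],
                                     obs_chrom = genome$chrom[new_chr_i],
                                     obs_pos = new_pos,
                                     stringsAsFactors = FALSE)
      mk$chrom <- as.character(mk$chrom)
      mk$chrom[pick] <- genome$chrom[new_chr_i]
      mk$pos[pick] <- new_pos
      mk$chrom <- factor(mk$chrom, levels = genome$chrom)
    }
    # inverted block: reflect reported positions within the block
    if (length(inv_ids) >= 2L) {
      blk <- match(inv_ids, mk$id)
      {
        lo <- min(mk$pos[blk]); hi <- max(mk$pos[blk])
        mk$pos[blk] <- lo + hi - mk$pos[blk]
        led$inverted <- mk$id[blk]
      }
    }
    # parent missingness and loss of orientation
    oriented <- rep(TRUE, m)
    if (art$parent_missing > 0 && !is.null(pcalls)) {
      pm <- matrix(stats::runif(2L * m) < art$parent_missing, 2L, m)
      pcalls[pm] <- NA_integer_
      led$parent_masked <- pm
      unor <- which(colSums(is.na(pcalls)) == 2L)
      oriented[unor] <- FALSE
      flip <- unor[stats::runif(length(unor)) < 0.5]
      if (length(flip)) {
        calls[, flip] <- 2L - calls[, flip]
        led$flipped <- mk$id[flip]
      }
    }
    truth$artifacts <- led
    gout <- geno_matrix(calls, mk, parents = pcalls, oriented = oriented)
    list(geno = gout, truth = truth)
  })
}

inversion_block <- function(mk, inv) {
  j <- which(as.character(mk$chrom) == as.character(inv$chrom) &
               mk$pos >= inv$start_bp)
  j <- j[order(mk$pos[j])]
  blk <- utils::head(j, inv$n_markers %||% length(j))
  ci <- which(as.character(mk$chrom) == as.character(inv$chrom))
  if (length(blk) && max(mk$pos[blk]) > max(mk$pos[ci]))
    stop_gbs("inversion block exceeds chromosome bounds",
             class = "gbsmap_validation_error")
  blk
}

# Sampling weight favoring markers in low-recombination landscape windows.
landscape_weight <- function(genome, mk) {
  w <- numeric(nrow(mk))
  for (i in seq_along(genome$chrom)) {
    j <- which(as.character(mk$chrom) == genome$chrom[i])
    ls <- genome$landscape[[i]]
    frac <- mk$pos[j] / genome$len_bp[i]
    seg <- findInterval(frac, c(ls$from, 1), rightmost.closed = TRUE)
    seg[seg < 1L] <- 1L; seg[seg > nrow(ls)] <- nrow(ls)
    w[j] <- 1 / (ls$mult[seg] + 0.05)^2
  }
  w
}

#' Calibrate the viability coefficient for a target allele frequency
#'
#' Finds, by bisection on the exact single-locus genotype recursion, the
#' gametic viability coefficient `s` (selection against parent-B gametes
#' in every selfing generation) such that the favored parent-A allele
#' reaches `target_freq` in the final generation.
#'
#' @param generation filial generation (>= 2).
#' @param target_freq desired final frequency of the favored allele, in
#'   `(0.5, 1)`.
#' @return list(s, freq): coefficient and the exact frequency it attains.
#' @export
calibrate_viability <- function(generation = 7L, target_freq = 0.83) {
  check_count(generation, "generation", 2L)
  check_fraction(target_freq, "target_freq", lo = 0.5, hi = 1)
  freq_at <- function(s) {
    p <- 1 / (2 - s)               # surviving gamete from a het is A w.p. p
    st <- c(AA = 0, Aa = 1, aa = 0)
    for (k in seq_len(generation - 1L)) {
      st <- c(AA = st["AA"] + st["Aa"] * p^2,
              Aa = st["Aa"] * 2 * p * (1 - p),
              aa = st["aa"] + st["Aa"] * (1 - p)^2)
      names(st) <- c("AA", "Aa", "aa")
    }
    unname(st["AA"] + st["Aa"] / 2)
  }
  lo <- 0; hi <- 0.999999
  if (freq_at(hi) < target_freq)
    stop_gbs("target frequency unattainable", class = "gbsmap_validation_error")
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (freq_at(mid) < target_freq) lo <- mid else hi <- mid
  }
  list(s = hi, freq = freq_at(hi))
}

#' Simulate a complete GBS dataset: population plus artifacts
#'
#' Convenience wrapper: calibrates the distortion viability coefficient,
#' simulates the population (with breeding-time selection), then injects
#' the observation-level artifacts.
#'
#' @inheritParams simulate_population
#' @param art an [artifact_spec()].
#' @return list(geno, truth) as from [inject_artifacts()].
#' @export
simulate_gbs_dataset <- function(genome = genome_spec(), n_lines = 109L,
                                 generation = 7L, n_markers = 23000L,
                                 art = artifact_spec(), seed = NULL) {
  dis <- NULL
  if (!is.null(art$distortion)) {
    cal <- calibrate_viability(generation, art$distortion$target_freq)
    dis <- list(chrom = art$distortion$chrom,
                pos_bp = art$distortion$pos_bp, s = cal$s)
  }
  seed2 <- if (is.null(seed)) NULL else (seed + 1L) %% .Machine$integer.max
  pop <- simulate_population(genome, n_lines, generation, n_markers,
                             seed = seed, distortion = dis)
  inject_artifacts(pop$geno, pop$truth, art, seed = seed2)
}

#' Simulate quantitative phenotypes from the true mosaic
#'
#' Phenotype = sum over QTLs of effect x z + Gaussian noise, where z is
#' the -1/0/+1 coding of parental origin at the QTL (+1 = parent-B
#' homozygote).  Supply either `noise_sd` or a target heritability `h2`
#' (noise variance scaled to the realized genetic variance).
#'
#' @param truth a `sim_truth`.
#' @param qtl data.frame with columns `chrom`, `pos_cM`, `effect`.
#' @param noise_sd residual standard deviation (>= 0).
#' @param h2 broad-sense heritability in `(0, 1]`; used when `noise_sd`
#'   is `NULL`.
#' @param seed RNG seed.
#' @param trait trait name for the output column.
#' @return data.frame(line, <trait>); realized per-QTL PVE is attached as
#'   attribute `"pve"` and recorded in the truth ledger when assigned back.
#' @export
simulate_phenotypes <- function(truth, qtl, noise_sd = NULL, h2 = NULL,
                                seed = NULL, trait = "trait1") {
  if (!is.null(noise_sd) && noise_sd < 0)
    stop_gbs("noise_sd must be >= 0", class = "gbsmap_validation_error")
  genome <- truth$genome
  ci <- match(as.character(qtl$chrom), genome$chrom)
  if (anyNA(ci) || any(qtl$pos_cM < 0) ||
      any(qtl$pos_cM > genome$len_cM[ci]))
    stop_gbs("QTL positions outside the genome",
             class = "gbsmap_validation_error")
  n <- length(truth$haplotypes)
  z <- matrix(0, n, nrow(qtl))
  for (k in seq_len(nrow(qtl))) {
    for (l in seq_len(n)) {
      p <- truth$haplotypes[[l]][[ci[k]]]
      z[l, k] <- hap_eval(p$h1, qtl$pos_cM[k]) +
        hap_eval(p$h2, qtl$pos_cM[k]) - 1
    }
  }
  gval <- drop(z %*% qtl$effect)
  if (is.null(noise_sd)) {
    if (is.null(h2)) stop_gbs("supply noise_sd or h2",
                              class = "gbsmap_validation_error")
    check_fraction(h2, "h2", lo = 1e-6, hi = 1)
    vg <- stats::var(gval)
    noise_sd <- sqrt(max(vg, 1e-12) * (1 - h2) / h2)
  }
  y <- with_seed(seed, gval + stats::rnorm(n, 0, noise_sd))
  vtot <- stats::var(y)
  pve <- vapply(seq_len(nrow(qtl)), function(k)
    100 * stats::var(z[, k] * qtl$effect[k]) / max(vtot, 1e-12), 0)
  out <- data.frame(line = truth$lines, y, stringsAsFactors = FALSE)
  names(out)[2L] <- trait
  attr(out, "pve") <- pve
  out
}
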
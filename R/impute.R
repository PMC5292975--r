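# Hidden-state order: 1 = parent-A homozygote, 2 = heterozygote,
# 3 = parent-B homozygote.  Observation codes 0/1/2 map to columns 1:3 of
# the emission lookup; missing observations emit 1 in every state.

hmm_emission_lookup <- function(error) {
  rbind(c(1 - error, error / 2, error / 2),
        c(error / 2, 1 - error, error / 2),
        c(error / 2, error / 2, 1 - error))
}

# Per-interval transition matrix: switch probability between the two
# homozygous states over map distance d is q = 2r/(1+2r) (riself scale,
# r = kosambi_inv(d)); the full 3-state chain is the reversible
# "redraw from the stationary distribution" kernel T = (1-rho) I +
# rho 1 pi', with stationary pi = ((1-h)/2, h, (1-h)/2) and rho = q/pi_B,
# so that T[A,B] = q exactly and the het state is entered in proportion
# to the residual-het level h.
hmm_transition <- function(d_cM, het) {
  r <- kosambi_inv(d_cM)
  q <- 2 * r / (1 + 2 * r)
  pi0 <- c((1 - het) / 2, het, (1 - het) / 2)
  rho <- pmin(q / pi0[3L], 0.999)
  list(rho = rho, pi = pi0)
}

#' Impute missing RIL genotypes with a three-state hidden Markov model
#'
#' Models each line's genotype sequence along a chromosome as a hidden
#' chain over {parent-A, heterozygous, parent-B} with distance-dependent
#' transitions (switch probability `2r/(1+2r)` between homozygous states,
#' where `r` is the Kosambi-inverse of the inter-marker distance) and a
#' symmetric genotyping-error emission model.  Posterior state
#' probabilities are computed by the forward-backward algorithm; missing
#' cells are filled with the maximum-posterior state's code when that
#' posterior reaches `tau`, and left missing otherwise.  Observed calls
#' are never overwritten.
#'
#' Inter-marker distances come from `map` (cM positions) when supplied,
#' otherwise from physical positions scaled by `cm_per_mb`.
#'
#' @param g a [geno_matrix()], markers ordered within chromosomes.
#' @param map optional `genetic_map` (from [build_map()]) with cM
#'   positions for `g`'s markers.
#' @param error emission (genotyping-error) rate, in (0, 0.5).
#' @param het residual-heterozygosity level of the hidden chain.
#' @param tau posterior call threshold in (0.5, 1].
#' @param cm_per_mb physical-to-genetic scale used when `map` is `NULL`.
#' @return list(geno = imputed matrix, report = per-chromosome
#'   data.frame(chrom, pre_missing, post_missing, non_imputed), posterior
#'   = lines x markers matrix of the called state's posterior, state =
#'   argmax state code matrix, skipped_lines = count of line/chromosome
#'   stretches with < 2 informative calls).
#' @export
impute_hmm <- function(g, map = NULL, error = 0.005, het = 0.015625,
                       tau = 0.95, cm_per_mb = 3.0) {
  if (error <= 0 || error >= 0.5)
    stop_gbs("error must be in (0, 0.5)", class = "gbsmap_validation_error")
  if (tau <= 0.5 || tau > 1)
    stop_gbs("tau must be in (0.5, 1]", class = "gbsmap_validation_error")
  mk <- marker_info(g)
  x <- unclass(g)
  attr(x, "markers") <- attr(x, "parents") <- attr(x, "oriented") <- NULL
  nl <- nrow(x)
  EM <- rbind(hmm_emission_lookup(error), c(1, 1, 1))  # row 4 = missing
  post_max <- matrix(NA_real_, nl, ncol(x))
  post_arg <- matrix(NA_integer_, nl, ncol(x))
  filled <- x
  skipped <- 0L
  report <- list()
  for (ch in levels(mk$chrom)) {
    jc <- which(mk$chrom == ch)
    mc <- length(jc)
    xc <- x[, jc, drop = FALSE]
    pre_missing <- mean(is.na(xc))
    n_obs <- rowSums(!is.na(xc))
    run <- n_obs >= 2L
    skipped <- skipped + sum(!run)
    if (mc >= 2L && any(run)) {
      xr <- xc[run, , drop = FALSE]
      L <- nrow(xr)
      if (!is.null(map)) {
        cm <- map$cM[match(mk$id[jc], map$id)]
        d <- pmax(diff(cm), 0)
      } else d <- pmax(diff(mk$pos[jc]), 0) / 1e6 * cm_per_mb
      tr <- hmm_transition(d, het)
      pi0 <- tr$pi; rho <- tr$rho
      obs_idx <- xr + 1L; obs_idx[is.na(obs_idx)] <- 4L
      # forward pass, scaled
      alphas <- array(0, c(mc, L, 3L))
      al <- matrix(pi0, L, 3L, byrow = TRUE) * EM[obs_idx[, 1L], , drop = FALSE]
      al <- al / rowSums(al)
      alphas[1L, , ] <- al
      for (t in 2:mc) {
        rh <- rho[t - 1L]
        # rowSums(al) == 1 after scaling, so the redraw term is just pi0
        al <- (1 - rh) * al + rh * matrix(pi0, L, 3L, byrow = TRUE)
        al <- al * EM[obs_idx[, t], , drop = FALSE]
        al <- al / rowSums(al)
        alphas[t, , ] <- al
      }
      # backward pass and posteriors
      be <- matrix(1, L, 3L)
      for (t in mc:1L) {
        po <- alphas[t, , , drop = TRUE]
        if (L == 1L) po <- matrix(po, 1L, 3L)
        po <- po * be
        po <- po / rowSums(po)
        amax <- max.col(po, ties.method = "first")
        post_arg[run, jc[t]] <- amax - 1L
        post_max[run, jc[t]] <- po[cbind(seq_len(L), amax)]
        if (t > 1L) {
          rh <- rho[t - 1L]
          be2 <- be * EM[obs_idx[, t], , drop = FALSE]
          be <- (1 - rh) * be2 + rh * outer(drop(be2 %*% pi0), rep(1, 3L))
          be <- be / rowSums(be)
        }
      }
      fill <- is.na(xc[run, , drop = FALSE]) &
        post_max[run, jc, drop = FALSE] >= tau
      sub <- filled[run, jc, drop = FALSE]
      sub[fill] <- post_arg[run, jc, drop = FALSE][fill]
      filled[run, jc] <- sub
    }
    post_missing <- mean(is.na(filled[, jc]))
    report[[ch]] <- data.frame(
      chrom = ch, pre_missing = pre_missing, post_missing = post_missing,
      non_imputed = if (pre_missing > 0) post_missing / pre_missing else 0,
      stringsAsFactors = FALSE)
  }
  gout <- geno_matrix(filled, mk, parents = parent_calls(g),
                      oriented = attr(g, "oriented"), sort = FALSE)
  list(geno = gout, report = do.call(rbind, report),
       posterior = post_max, state = post_arg, skipped_lines = skipped)
}

#' Masking-based evaluation of imputation accuracy
#'
#' Per replicate, a random `mask_fraction` of the observed homozygous
#' calls is set to missing, the matrix re-imputed, and accuracy computed
#' as the fraction of masked cells that received a call and were restored
#' to their original code; the non-imputed fraction is the share of
#' masked cells left missing.
#'
#' @param g a [geno_matrix()].
#' @param mask_fraction fraction of observed homozygous cells to mask per
#'   replicate, in (0, 1).
#' @param replicates number of replicates (default 10).
#' @param seed RNG seed.
#' @param ... passed to [impute_hmm()].
#' @return list(replicates = data.frame(rep, accuracy, non_imputed),
#'   mean_accuracy, sd_accuracy, mean_non_imputed, sd_non_imputed).
#' @export
evaluate_imputation <- function(g, mask_fraction = 0.05, replicates = 10L,
                                seed = NULL, ...) {
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop_gbs("mask_fraction must be in (0, 1)",
             class = "gbsmap_validation_error")
  replicates <- check_count(replicates, "replicates", 1L)
  x <- unclass(g)
  attr(x, "markers") <- attr(x, "parents") <- attr(x, "oriented") <- NULL
  hom_cells <- which(!is.na(x) & x != 1L)
  if (!length(hom_cells))
    stop_gbs("no homozygous calls to mask", class = "gbsmap_validation_error")
  with_seed(seed, {
    res <- lapply(seq_len(replicates), function(rep_i) {
      masked <- sample(hom_cells, max(1L, round(mask_fraction * length(hom_cells))))
      xm <- x
      xm[masked] <- NA_integer_
      gm <- geno_matrix(xm, marker_info(g), parents = parent_calls(g),
                        oriented = attr(g, "oriented"), sort = FALSE)
      imp <- impute_hmm(gm, ...)
      xi <- unclass(imp$geno)
      called <- !is.na(xi[masked])
      acc <- if (any(called))
        mean(xi[masked][called] == x[masked][called]) else NA_real_
      data.frame(rep = rep_i, accuracy = acc,
                 non_imputed = mean(!called))
    })
    tab <- do.call(rbind, res)
    list(replicates = tab,
         mean_accuracy = mean(tab$accuracy, na.rm = TRUE),
         sd_accuracy = stats::sd(tab$accuracy),
         mean_non_imputed = mean(tab$non_imputed),
         sd_non_imputed = stats::sd(tab$non_imputed))
  })
}
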
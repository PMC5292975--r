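# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, using factorial arithmetic only.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  supp <- max(0, k - n2):min(k, m)
  pr <- vapply(supp, function(x)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)), 0)
  p_obs <- pr[supp == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Brute-force optimal path cost over all permutations (small m); the
# permutation matrices are built once per size and cached.
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(m) {
  key <- as.character(m)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- matrix(1L, 1L, 1L)
  for (k in 2:m) {
    P <- do.call(rbind, lapply(0:(k - 1L), function(pos)
      cbind(P[, seq_len(pos), drop = FALSE], k,
            P[, pos + seq_len(k - 1L - pos), drop = FALSE])))
  }
  storage.mode(P) <- "integer"
  .perm_cache[[key]] <- P
  P
}

oracle_best_path <- function(d) {
  m <- nrow(d)
  P <- all_perms(m)
  cost <- numeric(nrow(P))
  for (j in seq_len(m - 1L))
    cost <- cost + d[cbind(P[, j], P[, j + 1L])]
  min(cost)
}

# Exhaustive-path HMM posterior for one line: sums over all 3^m hidden
# state paths with the same transition kernel and emissions as the
# package's imputer (reimplemented independently).
oracle_hmm_posterior <- function(obs, d_cM, error, het) {
  m <- length(obs)
  pi0 <- c((1 - het) / 2, het, (1 - het) / 2)
  emis <- rbind(c(1 - error, error / 2, error / 2),
                c(error / 2, 1 - error, error / 2),
                c(error / 2, error / 2, 1 - error))
  trans <- lapply(d_cM, function(d) {
    r <- tanh(d / 50) / 2
    q <- 2 * r / (1 + 2 * r)
    rho <- min(q / pi0[3], 0.999)
    (1 - rho) * diag(3) + rho * matrix(pi0, 3, 3, byrow = TRUE)
  })
  paths <- as.matrix(expand.grid(rep(list(1:3), m)))
  logp <- log(pi0[paths[, 1L]])
  for (t in seq_len(m)) {
    if (t > 1L) {
      tr <- trans[[t - 1L]]
      logp <- logp + log(tr[cbind(paths[, t - 1L], paths[, t])])
    }
    if (!is.na(obs[t])) logp <- logp + log(emis[paths[, t], obs[t] + 1L])
  }
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  post <- matrix(0, m, 3L)
  for (t in seq_len(m))
    for (s in 1:3) post[t, s] <- sum(w[paths[, t] == s])
  post
}

# Large-sample single-locus selfing simulation with gametic viability
# selection (vectorized; independent of the package's meiosis kernel).
oracle_distortion_freq <- function(s, generation, n = 10000L) {
  p <- 1 / (2 - s)                     # surviving gamete from a het is A
  geno <- rep(1L, n)                   # 0 = AA, 1 = Aa, 2 = aa
  for (gen in seq_len(generation - 1L)) {
    het <- geno == 1L
    nh <- sum(het)
    if (!nh) break
    g1 <- stats::rbinom(nh, 1L, 1 - p)  # 0 = A gamete
    g2 <- stats::rbinom(nh, 1L, 1 - p)
    geno[het] <- g1 + g2
  }
  mean(2 - geno) / 2
}

# Small hand-buildable genotype matrix.
toy_geno <- function(calls, chrom = NULL, pos = NULL, parents = TRUE) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  ids <- if (m) paste0("S", chrom, "_", pos) else character(0)
  mk <- data.frame(id = ids, chrom = chrom,
                   pos = pos, allele_a = rep("A", m), allele_b = rep("C", m),
                   stringsAsFactors = FALSE)
  pa <- if (parents) rbind(parentA = rep(0L, m), parentB = rep(2L, m))
  geno_matrix(calls, mk, parents = pa)
}

# Small two-chromosome genome for fast simulations.
small_genome <- function(n_chr = 2L, cM = 90, bp = 2.5e7)
  genome_spec(len_cM = rep(cM, n_chr), len_bp = rep(bp, n_chr),
              chrom = as.character(seq_len(n_chr)))

quiet_artifacts <- function(...)
  artifact_spec(missing_rate = 0, error_rate = 0, n_misallocated = 0L,
                inversion = NULL, distortion = NULL, parent_missing = 0, ...)
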
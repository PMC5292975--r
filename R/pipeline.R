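#' Run the full genotype QC / imputation / mapping / QTL pipeline
#'
#' Executes the stages in their canonical order: initial missing/MAF
#' filter, parental-genotype determination, anchor selection and linkage
#' grouping with removal of misallocated markers, the four-anchor
#' Fisher's-exact error filter, HMM imputation, sliding-window removal of
#' spurious double recombinants, the final missing/MAF filter, genetic-map
#' construction with segregation-distortion and breakpoint summaries, bin
#' collapsing and, when phenotypes are supplied, composite interval
#' mapping with a permutation threshold per trait.
#'
#' Marker bookkeeping is conserved at every stage: each input marker ends
#' as exactly one of retained or removed-with-reason, and
#' `markers_out = markers_in - removed` row by row in the summary.
#'
#' @param geno a [geno_matrix()] with parent rows.
#' @param phenotypes optional phenotype data.frame with a `line` column.
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return object of class `pipeline_result`: list with `summary` (per
#'   stage counts), `geno` (final matrix), `anchors`, `grouping`,
#'   `misallocated`, `imputation`, `window`, `map`, `breakpoints`,
#'   `distortion`, `bins`, `qtl` (per-trait list), and `config`.
#' @export
run_pipeline <- function(geno, phenotypes = NULL,
                         config = pipeline_config(), quiet = FALSE) {
  validate_config(config)
  if (is.null(parent_calls(geno)))
    stop_gbs("pipeline requires parent rows", class = "gbsmap_validation_error")
  say <- function(...) if (!quiet) message("[gbsmap] ", ...)
  summary_rows <- list()
  note <- function(stage, n_in, n_out, reason = "") {
    summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
      stage = stage, markers_in = n_in, markers_out = n_out,
      removed = n_in - n_out, reason = reason, stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_gbs("pipeline stage '", name, "' failed: ", conditionMessage(e),
               class = "gbsmap_stage_error"))
  }
  g <- geno

  n0 <- ncol(g)
  f1 <- stage("initial_filter",
              filter_missing_maf(g, max_missing = 0.90,
                                 min_maf = config$min_maf))
  g <- f1$geno
  note("initial_filter", n0, ncol(g), "missing>0.90 | maf<min")
  say("initial filter: ", n0, " -> ", ncol(g), " markers")

  n0 <- ncol(g)
  pg <- stage("parental_genotypes", infer_parental_genotypes(g))
  g <- pg$geno
  note("parental_genotypes", n0, ncol(g), "ambiguous | monomorphic")
  say("parental genotypes: ", n0, " -> ", ncol(g),
      " markers (", pg$n_flipped, " re-oriented)")

  anchors <- stage("anchor_selection", select_anchors(g))
  say("anchors: ", length(anchors), " zero-missing markers")
  grouping <- NULL
  mis <- character(0)
  if (length(anchors) >= 2L) {
    grouping <- stage("anchor_grouping",
                      cluster_groups(g[, marker_info(g)$id %in% anchors],
                                     config$anchor_lod))
    mis <- stage("misallocation", detect_misallocated(grouping))
  }
  n0 <- ncol(g)
  g <- g[, !(marker_info(g)$id %in% mis)]
  anchors <- setdiff(anchors, mis)
  note("misallocation", n0, ncol(g), "anchor in wrong linkage group")
  say("misallocated markers removed: ", length(mis))

  n0 <- ncol(g)
  ff <- stage("fisher_filter",
              anchor_fisher_filter(g, anchors, config$fisher_alpha))
  g <- ff$geno
  note("fisher_filter", n0, ncol(g), "independent of a flanking anchor")
  say("fisher filter: ", n0, " -> ", ncol(g), " markers")

  imp <- stage("imputation",
               impute_hmm(g, error = config$hmm_error, het = config$hmm_het,
                          tau = config$hmm_tau,
                          cm_per_mb = config$cm_per_mb))
  g <- imp$geno
  note("imputation", ncol(g), ncol(g), "")
  say(sprintf("imputation: missing %.1f%% -> %.2f%%",
              100 * mean(imp$report$pre_missing),
              100 * mean(imp$report$post_missing)))

  sw <- stage("sliding_window",
              sliding_window_clean(g, config$window_size,
                                   config$window_threshold, config$end_skip))
  g <- sw$geno
  note("sliding_window", ncol(g), ncol(g), "")
  say(sprintf("sliding window: %.3f%% of data points removed",
              100 * sw$removed_fraction))

  n0 <- ncol(g)
  f2 <- stage("final_filter",
              filter_missing_maf(g, config$max_missing, config$min_maf))
  g <- f2$geno
  note("final_filter", n0, ncol(g), "missing>max | maf<min")
  say("final filter: ", n0, " -> ", ncol(g), " markers")

  map <- stage("genetic_map", build_map(g))
  dist <- stage("distortion", segregation_distortion(g, config$distortion_alpha))
  bp <- stage("breakpoints", count_breakpoints(g))
  bins <- stage("bins", collapse_bins(g, map))
  say(sprintf("map: %.1f cM, %d bins, %.2f breakpoints/line",
              attr(map, "total_cM"), nrow(bins$bins), bp$mean))

  qtl <- NULL
  if (!is.null(phenotypes)) {
    traits <- setdiff(names(phenotypes), "line")
    qtl <- lapply(traits, function(tr) {
      stage(paste0("qtl_", tr), {
        cofs <- select_cofactors(bins, phenotypes, config$n_cofactors,
                                 trait = tr)
        thr <- permutation_threshold(bins, phenotypes,
                                     k = config$n_cofactors,
                                     n_perm = config$n_perm,
                                     alpha = config$perm_alpha,
                                     window = config$cim_window,
                                     step = config$cim_step,
                                     seed = config$seed, trait = tr)
        sc <- cim_scan(bins, phenotypes, cofs, window = config$cim_window,
                       step = config$cim_step, trait = tr)
        list(scan = sc, threshold = as.numeric(thr),
             qtl = summarize_qtl(sc, thr, config$ci_coverage))
      })
    })
    names(qtl) <- traits
    for (tr in traits)
      say("trait ", tr, ": ", nrow(qtl[[tr]]$qtl), " QTL(s) above LOD ",
          sprintf("%.2f", qtl[[tr]]$threshold))
  }
  structure(list(summary = do.call(rbind, summary_rows), geno = g,
                 anchors = anchors, grouping = grouping,
                 misallocated = mis, imputation = imp$report,
                 window = list(removed_fraction = sw$removed_fraction),
                 map = map, breakpoints = bp, distortion = dist,
                 bins = bins, qtl = qtl, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("gbsmap pipeline result\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("final: %d markers, %.1f cM, %d bins\n", ncol(x$geno),
              attr(x$map, "total_cM"), nrow(x$bins$bins)))
  invisible(x)
}
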
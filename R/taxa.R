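#' Generate seasonal taxon count tables with a taxonomy map
#'
#' Per-visit multinomial counts over a synthetic community whose expected
#' richness is higher in winter. The community has a core of always-present
#' taxa plus a seasonal block whose per-visit presence probability rises
#' smoothly from `base_occupancy` in mid summer to a winter ceiling solved so
#' that the expected number of present taxa in deep winter is
#' `winter_richness_boost` times the mid-summer expectation. Given presence,
#' relative abundances follow a fixed log-normal profile and read counts are
#' multinomial at the configured sequencing depth.
#'
#' @param design a [cohort_design()].
#' @param visits visit table; generated from `design` when missing.
#' @param n_taxa number of taxa (>= 2).
#' @param depth sequencing depth (reads per sample, > 0).
#' @param winter_richness_boost target winter/summer expected-richness ratio
#'   (1 = no seasonal effect).
#' @param frac_seasonal fraction of taxa in the seasonal block.
#' @param base_occupancy summer presence probability of seasonal taxa.
#' @param seed RNG seed (`NULL` = current stream).
#' @return list with `counts` (samples x taxa integer matrix, rownames =
#'   `sample_id`), `taxonomy` (`data.frame`: taxon, genus, family, order,
#'   class, phylum) and `visits`.
#' @export
generate_taxon_counts <- function(design, visits = NULL, n_taxa = 150,
                                  depth = 10000, winter_richness_boost = 1.5,
                                  frac_seasonal = 0.6, base_occupancy = 0.2,
                                  seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (n_taxa < 2) stopf("n_taxa must be >= 2")
  if (depth <= 0) stopf("depth must be positive")
  if (winter_richness_boost < 1) stopf("winter_richness_boost must be >= 1")
  if (is.null(visits)) visits <- generate_visits(design, seed = seed)
  n_seas <- round(frac_seasonal * n_taxa)
  n_core <- n_taxa - n_seas
  ## solve the winter occupancy ceiling from the requested richness ratio
  e_summer <- n_core + n_seas * base_occupancy
  q_max <- (winter_richness_boost * e_summer - n_core) / n_seas
  if (q_max > 1 + 1e-9)
    stopf("winter_richness_boost %.2f infeasible for this community (max %.2f)",
          winter_richness_boost, (n_core + n_seas) / e_summer)
  q_max <- min(q_max, 1)
  with_seed(if (is.null(seed)) NULL else seed + 2L, {
    abund <- stats::rlnorm(n_taxa, 0, 1.5)
    seasonal <- c(rep(FALSE, n_core), rep(TRUE, n_seas))
    w <- winterness(visits$day_of_year)
    counts <- matrix(0L, nrow(visits), n_taxa,
                     dimnames = list(visits$sample_id,
                                     sprintf("T%03d", seq_len(n_taxa))))
    for (i in seq_len(nrow(visits))) {
      q <- base_occupancy + (q_max - base_occupancy) * w[i]
      present <- !seasonal | stats::runif(n_taxa) < q
      if (!any(present)) present[which.max(abund)] <- TRUE
      counts[i, present] <- stats::rmultinom(1, depth, abund[present])
    }
    list(counts = counts, taxonomy = synthetic_taxonomy(n_taxa),
         visits = visits)
  })
}

## Deterministic synthetic lineage: genera grouped 5 per family, families 3
## per order, orders 2 per class, classes 2 per phylum.
synthetic_taxonomy <- function(n_taxa) {
  g <- seq_len(n_taxa)
  fam <- (g - 1) %/% 5 + 1
  ord <- (fam - 1) %/% 3 + 1
  cls <- (ord - 1) %/% 2 + 1
  phy <- (cls - 1) %/% 2 + 1
  data.frame(taxon = sprintf("T%03d", g), genus = sprintf("g%03d", g),
             family = sprintf("f%02d", fam), order = sprintf("o%02d", ord),
             class = sprintf("c%02d", cls), phylum = sprintf("p%02d", phy),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort in one call
#'
#' Convenience wrapper running [generate_visits()], [generate_features()] and
#' optionally [generate_taxon_counts()] under one seed.
#'
#' @param design a [cohort_design()].
#' @param specs feature specification list.
#' @param taxa logical; also generate taxon counts?
#' @param seed master seed (defaults to `design$seed`).
#' @param ... passed to [generate_taxon_counts()].
#' @return list with `visits`, `data`, `truth`, and (optionally) `counts`,
#'   `taxonomy`.
#' @export
simulate_cohort <- function(design, specs = default_feature_specs(),
                            taxa = TRUE, seed = design$seed, ...) {
  visits <- generate_visits(design, seed = seed)
  feats <- generate_features(design, specs, visits = visits, seed = seed)
  out <- list(visits = visits, data = feats$data, truth = feats$truth)
  if (taxa) {
    tc <- generate_taxon_counts(design, visits = visits, seed = seed, ...)
    out$counts <- tc$counts
    out$taxonomy <- tc$taxonomy
  }
  out
}
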
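# Synthetic cohorts with the statistical structure the analysis assumes:
# zero-inflated compositional genus counts under a planted case/control
# effect, plus a host-shifted four-arm transfer cohort.

#' Specification for synthetic cohorts
#'
#' Defines the taxonomy size, cohort sizes, abundance model and planted
#' effects used by [build_taxonomy()], [simulate_cohort()] and
#' [simulate_transfer_groups()]. Defaults emulate the clinical study
#' conditions: a 395-control cohort versus a ~110-patient arm, SILVA-style
#' six-rank lineages with a fraction of genera only resolved to family,
#' zero-inflated log-normal genus abundances, read depths of at least 1099,
#' and the seven reported case/control fold changes (23, 13, 7, 0.17, 0.27,
#' 0.32, 0.34) planted on arbitrary resolved genera.
#'
#' @param n_genera,n_families,n_orders,n_classes,n_phyla Taxonomy sizes
#'   (one kingdom, "Bacteria").
#' @param n_control,n_case Clinical cohort sizes (default 395 / 109).
#' @param control_label,case_label Group labels.
#' @param placeholder_fraction Fraction of genera left unresolved at genus
#'   rank (named `"(<family>)"`); at most one per family.
#' @param baseline_sdlog Log-sd of the per-genus baseline means (default
#'   1.5, a heavy-tailed but not single-taxon-dominated community).
#' @param sample_sdlog Log-sd of the per-sample dispersion around the genus
#'   baseline (default 0.35; between-subject variability beyond the
#'   zero-inflation process, which itself contributes most of the
#'   within-group variance at the default `zero_inflation`).
#' @param zero_inflation Probability that a genus drops to zero in a sample
#'   (applied before renormalisation), in `[0, 1)`.
#' @param depth_min,depth_max Per-sample read depth drawn uniformly;
#'   `depth_min` defaults to the 1099 minimum used for rarefaction.
#' @param effect_folds Multiplicative case-group fold changes planted on
#'   distinct resolved genera.
#' @param n_per_transfer_group Animals per transfer arm (default 8).
#' @param transfer_sample_sdlog Within-arm dispersion of the transfer
#'   cohort (default 0.3): controlled isogenic animals on a fixed diet are
#'   substantially more homogeneous than free-living human subjects.
#' @param transfer_zero_inflation Per-genus dropout probability in the
#'   transfer cohort (default 0.1): carriage of core taxa is far more
#'   uniform across co-housed animals than across human subjects.
#' @param host_shift_sdlog Log-sd of the genus-wise host-shift factor
#'   applied to every transfer-cohort sample.
#' @param host_absent_fraction Fraction of genera absent from the transfer
#'   cohort entirely (stresses feature alignment).
#' @param nfe_reversal,nfw_reversal Fraction of the planted log-fold-change
#'   reversed in the NFE / NFW arms, in `[0, 1]`: 1 restores the Normal
#'   profile, 0 leaves the full HFD effect. Defaults 0.8 (NFE) and 0 (NFW,
#'   whose effect-retention is thus 1.0).
#' @return A `taxrisk_synth_spec` list.
#' @export
synthetic_spec <- function(n_genera = 150L, n_families = 30L, n_orders = 15L,
                           n_classes = 8L, n_phyla = 5L,
                           n_control = 395L, n_case = 109L,
                           control_label = "HC", case_label = "IBD",
                           placeholder_fraction = 0.1,
                           baseline_sdlog = 1.5, sample_sdlog = 0.35,
                           zero_inflation = 0.3,
                           depth_min = 1099L, depth_max = 20000L,
                           effect_folds = c(23, 13, 7, 0.17, 0.27, 0.32, 0.34),
                           n_per_transfer_group = 8L,
                           transfer_sample_sdlog = 0.3,
                           transfer_zero_inflation = 0.1,
                           host_shift_sdlog = 0.3,
                           host_absent_fraction = 0.15,
                           nfe_reversal = 0.8, nfw_reversal = 0) {
  if (n_genera < 1L) stop("need at least one genus")
  if (any(effect_folds <= 0)) stop("fold changes must be positive")
  for (z in c(zero_inflation, transfer_zero_inflation)) {
    if (z < 0 || z >= 1) stop("zero_inflation must lie in [0, 1)")
  }
  if (depth_min < 1L || depth_max < depth_min) stop("invalid depth range")
  if (length(effect_folds) > n_genera) stop("more planted effects than genera")
  n_placeholder <- round(placeholder_fraction * n_genera)
  if (n_placeholder > n_families) {
    stop("placeholder_fraction too high: at most one placeholder per family")
  }
  for (r in c(nfe_reversal, nfw_reversal)) {
    if (r < 0 || r > 1) stop("reversal factors must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "taxrisk_synth_spec")
}

#' Build a random six-rank taxonomy
#'
#' Every genus receives a complete kingdom-to-genus lineage; each child
#' rank is attached to a uniformly random parent. A configured fraction of
#' genera are placeholder taxa named `"(<family>)"` (one per family at
#' most, so the placeholder count is exact).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return Lineage tibble (columns of [parse_lineage()]), one row per genus.
#' @export
build_taxonomy <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "taxrisk_synth_spec"))
  with_seed(seed, {
    pad <- function(stub, n) sprintf("%s%03d", stub, seq_len(n))
    phyla <- pad("Phylum", spec$n_phyla)
    classes <- pad("Class", spec$n_classes)
    orders <- pad("Order", spec$n_orders)
    families <- pad("Family", spec$n_families)
    genera <- pad("Genus", spec$n_genera)

    class_phylum <- sample(phyla, spec$n_classes, replace = TRUE)
    order_class <- sample(classes, spec$n_orders, replace = TRUE)
    family_order <- sample(orders, spec$n_families, replace = TRUE)
    genus_family <- sample(families, spec$n_genera, replace = TRUE)

    lin <- tibble::tibble(
      kingdom = "Bacteria",
      phylum = class_phylum[match(order_class[match(
        family_order[match(genus_family, families)], orders)], classes)],
      class = order_class[match(family_order[match(genus_family, families)], orders)],
      order = family_order[match(genus_family, families)],
      family = genus_family,
      genus = genera,
      resolved_rank = "genus",
      placeholder = FALSE
    )
    n_placeholder <- round(spec$placeholder_fraction * spec$n_genera)
    if (n_placeholder > 0L) {
      fams <- sample(families, n_placeholder)
      idx <- vapply(fams, function(f) which(lin$family == f)[1], integer(1))
      idx <- idx[!is.na(idx)]
      lin$genus[idx] <- paste0("(", lin$family[idx], ")")
      lin$placeholder[idx] <- TRUE
      lin$resolved_rank[idx] <- "family"
    }
    lin
  })
}

# planted effects: fold change per genus, on the first length(effect_folds)
# resolved genera (deterministic given the taxonomy)
planted_effects <- function(spec, taxonomy) {
  resolved <- taxonomy$genus[!taxonomy$placeholder]
  if (length(resolved) < length(spec$effect_folds)) {
    stop("not enough resolved genera to plant all effects")
  }
  tibble::tibble(genus = resolved[seq_along(spec$effect_folds)],
                 fold = spec$effect_folds)
}

# anchor planted genera at fixed modest shares of the baseline total mass:
# a multiplicative effect on a dominant taxon would saturate after
# renormalisation to the simplex, and tying markers to seed-dependent
# quantiles makes their relative abundance (hence the realised fold change)
# unstable across seeds. Up-regulated markers get the smaller shares so the
# case group's total-mass inflation, which compresses realised fold
# changes, stays below ~10%.
anchor_planted <- function(base_mean, taxonomy, truth) {
  if (nrow(truth) >= length(base_mean)) return(base_mean)  # nothing to anchor against
  up <- truth$fold > 1
  shares <- numeric(nrow(truth))
  if (any(up)) {
    s_up <- seq(0.0015, 0.0025, length.out = sum(up))
    shares[up] <- s_up[rank(-truth$fold[up], ties.method = "first")]
  }
  if (any(!up)) {
    s_dn <- seq(0.006, 0.009, length.out = sum(!up))
    shares[!up] <- s_dn[rank(truth$fold[!up], ties.method = "first")]
  }
  total <- sum(base_mean[-match(truth$genus, taxonomy$genus)])
  base_mean[match(truth$genus, taxonomy$genus)] <- shares * total
  base_mean
}

# one sample's genus relative-abundance vector, zero-inflated
draw_sample_probs <- function(base_mean, sdlog, pi0, max_attempts = 100L) {
  for (i in seq_len(max_attempts)) {
    a <- base_mean * stats::rlnorm(length(base_mean), 0, sdlog)
    a[stats::runif(length(a)) < pi0] <- 0
    if (sum(a) > 0) return(a / sum(a))
  }
  stop("all-genera-zero draw persisted after ", max_attempts, " attempts")
}

simulate_groups <- function(spec, taxonomy, group_sizes, group_fold,
                            base_mean, seed, sdlog = spec$sample_sdlog,
                            pi0 = spec$zero_inflation) {
  g <- nrow(taxonomy)
  with_seed(seed, {
    counts_list <- list()
    meta_list <- list()
    for (grp in names(group_sizes)) {
      n <- group_sizes[[grp]]
      mean_grp <- base_mean * group_fold[[grp]]
      rows <- matrix(0L, nrow = n, ncol = g)
      for (s in seq_len(n)) {
        p <- draw_sample_probs(mean_grp, sdlog, pi0)
        depth <- floor(stats::runif(1, spec$depth_min, spec$depth_max + 1))
        rows[s, ] <- stats::rmultinom(1, depth, p)[, 1]
      }
      rownames(rows) <- sprintf("%s_%03d", grp, seq_len(n))
      counts_list[[grp]] <- rows
      meta_list[[grp]] <- tibble::tibble(sample_id = rownames(rows), group = grp)
    }
    counts <- do.call(rbind, counts_list)
    colnames(counts) <- taxonomy$genus
    metadata <- dplyr::bind_rows(meta_list)
    metadata$group <- factor(metadata$group, levels = names(group_sizes))
    lineages <- tibble::add_column(taxonomy, otu_id = taxonomy$genus, .before = 1L)
    list(otu = otu_table(counts, lineages), metadata = metadata)
  })
}

#' Simulate a clinical case/control cohort
#'
#' Per sample, genus relative means are drawn log-normally around per-genus
#' baselines, case-group means are multiplied by the planted fold changes,
#' genera are zeroed with the configured probability, the vector is
#' renormalised and counts are drawn multinomially at the sample's depth.
#' Byte-identical given `spec` and `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param taxonomy Optional lineage tibble from [build_taxonomy()]; pass
#'   the same taxonomy to [simulate_transfer_groups()] when the transfer
#'   cohort must share feature names with this one. Defaults to
#'   `build_taxonomy(spec, seed)`.
#' @return List: `otu` (`taxrisk_otu`, one OTU per genus), `metadata`
#'   (tibble `sample_id`, `group`), `truth` (tibble `genus`, `fold` of the
#'   planted effects).
#' @export
simulate_cohort <- function(spec, seed = 1L,
                            taxonomy = build_taxonomy(spec, seed)) {
  stopifnot(inherits(spec, "taxrisk_synth_spec"))
  truth <- planted_effects(spec, taxonomy)
  base_mean <- with_seed(seed + 1L,
                         stats::rlnorm(nrow(taxonomy), 0, spec$baseline_sdlog))
  base_mean <- anchor_planted(base_mean, taxonomy, truth)
  case_fold <- rep(1, nrow(taxonomy))
  case_fold[match(truth$genus, taxonomy$genus)] <- truth$fold
  sizes <- stats::setNames(list(spec$n_control, spec$n_case),
                           c(spec$control_label, spec$case_label))
  folds <- stats::setNames(list(rep(1, nrow(taxonomy)), case_fold),
                           c(spec$control_label, spec$case_label))
  out <- simulate_groups(spec, taxonomy, sizes, folds, base_mean, seed + 2L)
  out$truth <- truth
  out
}

#' Simulate the four-arm transfer cohort
#'
#' Emulates the external-validation design: a Normal arm, a disease-
#' inducing HFD arm carrying the planted case-direction effects, and two
#' intervention arms (NFE, NFW) in which a reversal factor scales the
#' planted log-fold-changes back towards Normal. A genus-wise log-normal
#' host-shift factor (shared by all transfer samples) perturbs every
#' baseline, and a configured fraction of genera are absent from the
#' transfer cohort altogether, so scoring this cohort with a model trained
#' on [simulate_cohort()] output exercises genuine feature alignment.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param taxonomy Lineage tibble shared with the training cohort.
#' @return List: `otu`, `metadata` (groups Normal/HFD/NFE/NFW), `truth`.
#' @export
simulate_transfer_groups <- function(spec, seed = 1L,
                                     taxonomy = build_taxonomy(spec, seed)) {
  stopifnot(inherits(spec, "taxrisk_synth_spec"))
  truth <- planted_effects(spec, taxonomy)
  g <- nrow(taxonomy)
  base_mean <- with_seed(seed + 1L, stats::rlnorm(g, 0, spec$baseline_sdlog))
  base_mean <- anchor_planted(base_mean, taxonomy, truth)
  host <- with_seed(seed + 3L, {
    h <- stats::rlnorm(g, 0, spec$host_shift_sdlog)
    h[sample(g, round(spec$host_absent_fraction * g))] <- 0
    h
  })
  shifted <- base_mean * host

  fold_at <- function(reversal) {
    f <- rep(1, g)
    f[match(truth$genus, taxonomy$genus)] <- truth$fold^(1 - reversal)
    f
  }
  sizes <- stats::setNames(as.list(rep(spec$n_per_transfer_group, 4L)),
                           c("Normal", "HFD", "NFE", "NFW"))
  folds <- list(Normal = rep(1, g), HFD = fold_at(0),
                NFE = fold_at(spec$nfe_reversal), NFW = fold_at(spec$nfw_reversal))
  out <- simulate_groups(spec, taxonomy, sizes, folds, shifted, seed + 4L,
                         sdlog = spec$transfer_sample_sdlog,
                         pi0 = spec$transfer_zero_inflation)
  out$truth <- truth
  out
}
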
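# End-to-end pipeline: preprocess -> diversity -> differential abundance ->
# model training -> (optional) external cohort scoring, with a JSON manifest.

#' Pipeline configuration
#'
#' Collects the inputs and settings of [run_pipeline()]. Defaults mirror
#' the study protocol: rarefaction depth 1099, 30 cross-validation
#' iterations at a 7:3 split.
#'
#' @param otu Path to a QIIME-classic OTU table.
#' @param metadata Path to a two-column sample metadata TSV.
#' @param out_dir Output directory.
#' @param dialect Taxonomy dialect (see [parse_lineage()]).
#' @param depth Rarefaction depth for alpha diversity.
#' @param n_iter,train_frac Cross-validation settings.
#' @param seed Master seed for every stochastic stage.
#' @param design Differential-abundance design (see [diff_abundance()]).
#' @param external_otu,external_metadata Optional external cohort to score
#'   with the trained model.
#' @return A `taxrisk_config` list.
#' @export
run_config <- function(otu, metadata, out_dir, dialect = "auto",
                       depth = 1099L, n_iter = 30L, train_frac = 0.7,
                       seed = 1L, design = "two_group_t",
                       external_otu = NULL, external_metadata = NULL) {
  structure(list(otu = otu, metadata = metadata, out_dir = out_dir,
                 dialect = dialect, depth = depth, n_iter = n_iter,
                 train_frac = train_frac, seed = seed, design = design,
                 external_otu = external_otu,
                 external_metadata = external_metadata),
            class = "taxrisk_config")
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: read and validate inputs; taxonomic-accumulation preprocessing
#' (feature matrix written via [write_feature_matrix()]); alpha diversity
#' on counts rarefied to the configured depth plus Bray-Curtis/PCoA/
#' PERMANOVA at genus and phylum level; differential abundance for the
#' first two group levels; repeated random-split cross-validation of the
#' risk model with impurity importance; optional scoring of an external
#' cohort. Deterministic given the config; a `manifest.json` echoing the
#' resolved config, package version, input hashes and per-stage timing is
#' written last, so its presence marks a complete run.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "taxrisk_config"))
  for (f in c(config$otu, config$metadata, config$external_otu,
              config$external_metadata)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("taxrisk")),
                   config = config[setdiff(names(config), "out_dir")],
                   inputs = as.list(tools::md5sum(
                     unlist(config[c("otu", "metadata", "external_otu",
                                     "external_metadata")]))),
                   stages = list())
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  dat <- stage("read", {
    otu <- read_otu_table(config$otu, dialect = config$dialect)
    md <- check_metadata(read_metadata(config$metadata), rownames(otu$counts))
    list(otu = otu, md = md)
  })

  features <- stage("preprocess", {
    prof <- preprocess_otu(dat$otu)
    write_feature_matrix(prof, file.path(config$out_dir, "features.tsv"))
    prof
  })

  stage("diversity", {
    genus_counts <- collapse_to_genus(dat$otu)
    rare <- rarefy_counts(genus_counts, config$depth, seed = config$seed)
    write_tsv_plain(alpha_diversity(rare),
                    file.path(config$out_dir, "alpha_diversity.tsv"))
    for (rank in c("genus", "phylum")) {
      prof <- collapse_to_rank(genus_counts, rank)
      rel <- profile_tibble(profile_matrix(prof) / rowSums(profile_matrix(prof)))
      d <- bray_curtis(rel)
      write_tsv_plain(as.data.frame(as.matrix(d)),
                      file.path(config$out_dir, paste0("bray_curtis_", rank, ".tsv")))
      ord <- pcoa_ordination(d, n_axes = 2L)
      write_tsv_plain(ord$coordinates,
                      file.path(config$out_dir, paste0("pcoa_", rank, ".tsv")))
      pm <- permanova(d, dat$md$group, seed = config$seed)
      jsonlite::write_json(unclass(pm),
                           file.path(config$out_dir, paste0("permanova_", rank, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  })

  stage("diff", {
    genus_counts <- collapse_to_genus(dat$otu)
    for (rank in c("genus", "phylum")) {
      tab <- diff_abundance(genus_counts, dat$md, rank = rank,
                            design = config$design)
      write_tsv_plain(tab, file.path(config$out_dir, paste0("diff_", rank, ".tsv")))
    }
  })

  cv <- stage("train", {
    feats <- select_features(features)
    cv <- cross_validate_risk(feats, dat$md$group, n_iter = config$n_iter,
                              train_frac = config$train_frac,
                              base_seed = config$seed)
    write_tsv_plain(cv$iterations, file.path(config$out_dir, "cv_iterations.tsv"))
    jsonlite::write_json(as.list(cv$summary),
                         file.path(config$out_dir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv_plain(feature_importance(cv, "impurity"),
                    file.path(config$out_dir, "importance_impurity.tsv"))
    final <- fit_risk_model(feats, dat$md$group, seed = config$seed)
    save_risk_model(final, file.path(config$out_dir, "model"))
    list(cv = cv, final = final)
  })

  if (!is.null(config$external_otu)) {
    stage("score", {
      ext_otu <- read_otu_table(config$external_otu, dialect = config$dialect)
      ext_md <- check_metadata(read_metadata(config$external_metadata),
                               rownames(ext_otu$counts), min_groups = 1L)
      ext_prof <- preprocess_otu(ext_otu)
      sc <- score_cohort(cv$final, ext_prof, ext_md)
      write_tsv_plain(sc$scores, file.path(config$out_dir, "external_scores.tsv"))
      write_tsv_plain(sc$group_summary,
                      file.path(config$out_dir, "external_group_summary.tsv"))
      if (nrow(sc$pairwise)) {
        write_tsv_plain(sc$pairwise,
                        file.path(config$out_dir, "external_pairwise.tsv"))
      }
    })
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
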
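# Alpha diversity with rarefaction, Bray-Curtis beta diversity, PCoA and
# PERMANOVA.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Rarefy counts to a common read depth
#'
#' Subsamples each sample's reads uniformly without replacement to `depth`
#' reads (the classic rarefaction used before alpha-diversity comparison).
#' Samples with fewer than `depth` reads are dropped with a warning.
#'
#' @param counts Tibble with `sample_id` plus non-negative integer taxon
#'   count columns (e.g. from [collapse_to_genus()]).
#' @param depth Target depth; every retained row sums to exactly `depth`.
#' @param seed Integer seed; the draw is reproducible.
#' @return Tibble of rarefied counts (possibly fewer rows).
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  if (depth <= 0) stop("rarefaction depth must be positive")
  m <- profile_matrix(counts)
  keep <- rowSums(m) >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(m)[!keep], 5), collapse = ", "))
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no samples at or above depth ", depth)
  if (any(m != round(m))) stop("rarefaction requires integer counts")
  storage.mode(m) <- "integer"
  r <- with_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))  # integrality and depth validated above
  out <- profile_tibble(r, lineages = attr(counts, "lineages"))
  attr(out, "depth") <- depth
  attr(out, "seed") <- seed
  out
}

chao1_index <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Per-sample alpha diversity
#'
#' Computes observed taxa, Chao1 richness (`S_obs + F1^2/(2 F2)`, with the
#' `F2 = 0` fallback `S_obs + F1(F1-1)/2`), Shannon entropy (natural log)
#' and the Gini-Simpson index `1 - sum(p^2)`. Apply [rarefy_counts()] first
#' when comparing samples of unequal depth.
#'
#' @param counts Tibble with `sample_id` plus non-negative count columns.
#' @param simpson_variant `"gini"` (default, `1 - sum p^2`) or `"inverse"`
#'   (`1 / sum p^2`).
#' @return Tibble with one row per sample: `sample_id`, `observed`,
#'   `chao1`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(counts, simpson_variant = c("gini", "inverse")) {
  simpson_variant <- match.arg(simpson_variant)
  m <- profile_matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  p <- m / rowSums(m)
  shannon <- unname(-rowSums(ifelse(p > 0, p * log(p), 0)))
  sumsq <- unname(rowSums(p^2))
  tibble::tibble(
    sample_id = rownames(m),
    observed = unname(rowSums(m > 0)),
    chao1 = unname(apply(m, 1L, chao1_index)),
    shannon = shannon,
    simpson = if (simpson_variant == "gini") 1 - sumsq else 1 / sumsq
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y)`, computed on any
#' non-negative per-sample vectors over a shared feature set (counts or
#' relative abundances).
#'
#' @param profile Tibble with `sample_id` plus non-negative feature columns.
#' @return A [stats::dist] object labelled by sample ID.
#' @export
bray_curtis <- function(profile) {
  m <- profile_matrix(profile)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
  if (sum(rowSums(m) == 0) > 1L) {
    stop("Bray-Curtis is undefined between two all-zero samples")
  }
  s <- rowSums(m)
  # sum(min(x,y)) = (sx + sy - sum|x - y|) / 2, so BC = manhattan / (sx + sy)
  manh <- stats::dist(m, method = "manhattan")
  tot <- stats::as.dist(outer(s, s, `+`))
  out <- manh / tot
  attr(out, "Labels") <- rownames(m)
  out
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centred
#' `-0.5 * D^2` matrix; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. Negative eigenvalues are reported but their
#' axes are discarded.
#'
#' @param d A [stats::dist] object (e.g. from [bray_curtis()]).
#' @param n_axes Number of axes requested (>= 2); if fewer positive
#'   eigenvalues exist, fewer axes are returned with a warning.
#' @return An object of class `taxrisk_ordination`: list with `coordinates`
#'   (tibble, `sample_id` + `Axis1..k`), `eigenvalues` (all, decreasing)
#'   and `prop_explained` (per retained axis, relative to the positive
#'   eigenvalue total).
#' @export
pcoa_ordination <- function(d, n_axes = 2L) {
  stopifnot(inherits(d, "dist"), n_axes >= 2L)
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    warning("only ", k, " positive-eigenvalue axes available (", n_axes,
            " requested)")
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  if (is.null(rownames(coords))) rownames(coords) <- as.character(seq_len(n))
  structure(list(
    coordinates = profile_tibble(coords),
    eigenvalues = eig,
    prop_explained = eig[seq_len(k)] / sum(eig[pos])
  ), class = "taxrisk_ordination")
}

#' @export
print.taxrisk_ordination <- function(x, ...) {
  k <- ncol(x$coordinates) - 1L
  cat("<PCoA ordination> ", nrow(x$coordinates), " samples, ", k, " axes (",
      paste(sprintf("%.1f%%", 100 * x$prop_explained), collapse = ", "),
      " explained)\n", sep = "")
  invisible(x)
}

permanova_ss_within <- function(d2, groups) {
  ss <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss <- ss + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss
}

permanova_f <- function(d2, groups, ss_total = sum(d2[upper.tri(d2)]) / nrow(d2)) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_within <- permanova_ss_within(d2, groups)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA group-separation test
#'
#' Partitions the sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic by seeded label
#' permutation; `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param d A [stats::dist] object.
#' @param groups Group label per sample, in the order of `d`'s labels
#'   (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `taxrisk_permanova`: list with `f`, `p`,
#'   `df_among`, `df_within`, `ss_among`, `ss_within`, `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(d, "dist"))
  groups <- as.character(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups length must match distance size")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("group(s) of size 1: ", paste(names(tab)[tab < 2L], collapse = ", "))
  }
  if (n_perm < 99L) stop("n_perm must be at least 99")

  d2 <- as.matrix(d)^2
  a <- length(tab)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- permanova_ss_within(d2, groups)
  f_obs <- ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) permanova_f(d2, sample(groups), ss_total), numeric(1))
  })
  structure(list(
    f = f_obs,
    p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
    df_among = a - 1L,
    df_within = n - a,
    ss_among = ss_total - ss_within,
    ss_within = ss_within,
    n_perm = n_perm,
    seed = seed
  ), class = "taxrisk_permanova")
}

#' @export
print.taxrisk_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g on (%d, %d) df, p = %.4g (%d permutations)\n",
              x$f, x$df_among, x$df_within, x$p, x$n_perm))
  invisible(x)
}

#' Collapse a count or abundance table to an upper taxonomic rank
#'
#' Sums feature columns by their label at `rank` using the profile's
#' lineage attribute; used for phylum- or family-level diversity and
#' differential-abundance views.
#'
#' @param profile Tibble with `sample_id`, feature columns and a `lineages`
#'   attribute.
#' @param rank One of `"genus"`, `"family"`, `"order"`, `"class"`,
#'   `"phylum"`, `"kingdom"`.
#' @return Tibble with one column per distinct label at `rank`.
#' @export
collapse_to_rank <- function(profile, rank = "phylum") {
  rank <- match.arg(rank, RANKS)
  if (rank == "genus") return(profile)
  lin <- attr(profile, "lineages")
  if (is.null(lin)) stop("profile carries no lineage map")
  m <- profile_matrix(profile)
  labels <- lin[[rank]][match(colnames(m), lin$genus)]
  if (anyNA(labels)) stop("lineage missing for some features")
  profile_tibble(t(rowsum(t(m), group = labels)))
}
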
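# Preprocessing: genus collapsing, log2 scaling with per-sample
# normalisation, and hierarchical taxonomic accumulation.

UPPER_RANKS <- c("family", "order", "class", "phylum", "kingdom")

#' Default rank weights for taxonomic accumulation
#'
#' One weight per rank above genus (family, order, class, phylum, kingdom),
#' `k_i = 10^-(1+i)`, i.e. `1e-2 ... 1e-6`. The geometric decay keeps every
#' clade term strictly smaller than any genus-level difference it could mask
#' while still breaking ties between genera that share upper taxonomy.
#'
#' @return Named numeric vector of length 5.
#' @export
accumulation_weights <- function() {
  stats::setNames(10^-(2:6), UPPER_RANKS)
}

#' Collapse an OTU table to genus level
#'
#' Counts of OTUs sharing a genus label are summed per sample. Placeholder
#' genera (parenthesised fallback labels such as `"(Lachnospiraceae)"`) are
#' ordinary features here: all family-level OTUs of one family collapse into
#' one feature.
#'
#' @param x A `taxrisk_otu` object.
#' @return Tibble with `sample_id` plus one count column per genus, carrying
#'   a `lineages` attribute (one six-rank lineage per genus).
#' @export
collapse_to_genus <- function(x) {
  stopifnot(inherits(x, "taxrisk_otu"))
  lin <- x$lineages
  key <- apply(as.matrix(lin[, RANKS]), 1L, paste, collapse = "|")
  conflicts <- vapply(split(key, lin$genus),
                      function(k) length(unique(k)) > 1L, NA)
  if (any(conflicts)) {
    stop("OTUs share a genus label but disagree on upper ranks: ",
         paste(names(conflicts)[conflicts], collapse = ", "))
  }
  counts <- t(rowsum(t(x$counts), group = lin$genus))  # samples x genera
  genus_lin <- dplyr::distinct(lin[, c(RANKS, "placeholder")])
  genus_lin <- genus_lin[match(colnames(counts), genus_lin$genus), ]
  profile_tibble(counts, lineages = genus_lin)
}

#' Log2-scale and normalise genus counts to relative abundances
#'
#' Each count c becomes `log2(c + 1)` (so zero counts stay exactly zero,
#' damping the influence of zero inflation), then every sample's vector is
#' divided by its sum, giving per-sample genus values V_G that sum to one.
#'
#' @param genus_counts Tibble from [collapse_to_genus()] (or any
#'   `sample_id` + non-negative integer count columns with a `lineages`
#'   attribute).
#' @return Tibble of the same shape holding V_G, rows summing to 1.
#' @export
log_normalize <- function(genus_counts) {
  m <- profile_matrix(genus_counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("genus counts must be non-negative integers")
  }
  if (any(rowSums(m) == 0)) {
    stop("cannot normalise all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  lg <- log2(m + 1)
  v <- lg / rowSums(lg)
  profile_tibble(v, lineages = attr(genus_counts, "lineages"))
}

#' Hierarchical taxonomic accumulation
#'
#' Encodes each genus abundance together with its clade context: for each
#' sample and genus g,
#' \deqn{V_{ACC}(g) = V_G(g) + k_1 V_F + k_2 V_O + k_3 V_C + k_4 V_P + k_5 V_K}
#' where `V_F ... V_K` are the within-sample sums of V_G over all genera
#' sharing g's label at family, order, class, phylum and kingdom rank
#' (the clade sums include g itself) and `k_i = 10^-(1+i)`. Genera that the
#' reference database left unresolved still contribute their abundance to
#' the clade sums of their resolved ancestors, so imprecisely classified
#' reads weight the features of their verified upper taxonomy.
#'
#' @param profile Tibble of V_G values from [log_normalize()], with a
#'   `lineages` attribute mapping each genus feature to its full lineage.
#' @param weights Rank weights, see [accumulation_weights()].
#' @return Tibble with `sample_id` plus one accumulated value per genus;
#'   keeps the `lineages` attribute and gains class `tax_accumulated`.
#' @export
tax_accumulate <- function(profile, weights = accumulation_weights()) {
  stopifnot(length(weights) == 5L)
  v <- profile_matrix(profile)
  lin <- attr(profile, "lineages")
  if (is.null(lin)) stop("profile carries no lineage map")
  if (!all(colnames(v) %in% lin$genus)) {
    stop("lineage missing for feature(s): ",
         paste(utils::head(setdiff(colnames(v), lin$genus), 5), collapse = ", "))
  }
  lin <- lin[match(colnames(v), lin$genus), ]

  acc <- v
  for (i in seq_along(UPPER_RANKS)) {
    labels <- lin[[UPPER_RANKS[i]]]
    clade <- t(rowsum(t(v), group = labels))      # samples x distinct labels
    acc <- acc + weights[i] * clade[, labels, drop = FALSE]
  }
  dimnames(acc) <- dimnames(v)
  out <- profile_tibble(acc, lineages = lin)
  class(out) <- c("tax_accumulated", class(out))
  out
}

#' One-call preprocessing: OTU table to accumulated feature matrix
#'
#' Runs [collapse_to_genus()], [log_normalize()] and [tax_accumulate()].
#'
#' @param x A `taxrisk_otu` object.
#' @param weights Passed to [tax_accumulate()].
#' @return Accumulated profile tibble.
#' @export
preprocess_otu <- function(x, weights = accumulation_weights()) {
  tax_accumulate(log_normalize(collapse_to_genus(x)), weights = weights)
}
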
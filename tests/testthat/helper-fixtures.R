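# Fixture builders and independent oracles shared across tests.

# six-rank SILVA lineage string
silva_lineage <- function(p = "P", c = "C", o = "O", f = "F", g = "G",
                          k = "Bacteria", depth = 6L) {
  labs <- c(k, p, c, o, f, g)[seq_len(depth)]
  paste0("D_", seq_len(depth) - 1L, "__", labs, collapse = ";")
}

# in-memory OTU table from a counts matrix (samples x OTUs) and lineage strings
make_otu <- function(counts, lineage_strings) {
  lin <- parse_lineage(lineage_strings, dialect = "silva")
  lin <- tibble::add_column(lin, otu_id = colnames(counts), .before = 1L)
  otu_table(counts, lin)
}

# random valid OTU table for round-trip properties
random_otu <- function(n_samples = 4L, n_otus = 8L, seed = 1L) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_otus, 20) + 1L, n_samples, n_otus,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   paste0("otu", seq_len(n_otus))))
  fams <- paste0("Fam", sample(3L, n_otus, replace = TRUE))
  strs <- vapply(seq_len(n_otus), function(i) {
    silva_lineage(p = "Px", c = "Cx", o = "Ox", f = fams[i],
                  g = paste0("Genus", i))
  }, character(1))
  make_otu(counts, strs)
}

# brute-force accumulation oracle: explicit loops over samples, genera, ranks
accumulate_oracle <- function(v, lineages, weights = 10^-(2:6)) {
  ranks <- c("family", "order", "class", "phylum", "kingdom")
  out <- v
  for (s in seq_len(nrow(v))) {
    for (g in seq_len(ncol(v))) {
      gl <- lineages[lineages$genus == colnames(v)[g], ]
      for (r in seq_along(ranks)) {
        members <- lineages$genus[lineages[[ranks[r]]] == gl[[ranks[r]]]]
        clade_sum <- 0
        for (m in members) clade_sum <- clade_sum + v[s, m]
        out[s, g] <- out[s, g] + weights[r] * clade_sum
      }
    }
  }
  out
}

# random genus profile over a multi-family taxonomy, for oracle checks
random_profile <- function(n_samples = 20L, n_genera = 50L, seed = 1L) {
  set.seed(seed)
  fams <- paste0("F", sample(8L, n_genera, replace = TRUE))
  ords <- paste0("O", sample(4L, 8L, replace = TRUE))
  clss <- paste0("C", sample(3L, 4L, replace = TRUE))
  phyl <- paste0("P", sample(2L, 3L, replace = TRUE))
  lin <- tibble::tibble(
    kingdom = "Bacteria",
    phylum = phyl[match(clss[match(ords[match(fams, paste0("F", 1:8))],
                                   paste0("O", 1:4))], paste0("C", 1:3))],
    class = clss[match(ords[match(fams, paste0("F", 1:8))], paste0("O", 1:4))],
    order = ords[match(fams, paste0("F", 1:8))],
    family = fams,
    genus = paste0("G", seq_len(n_genera)),
    resolved_rank = "genus",
    placeholder = FALSE
  )
  raw <- matrix(rexp(n_samples * n_genera), n_samples, n_genera,
                dimnames = list(paste0("s", seq_len(n_samples)), lin$genus))
  raw[sample(length(raw), round(0.3 * length(raw)))] <- 0
  v <- raw / rowSums(raw)
  prof <- tibble::as_tibble(as.data.frame(v, check.names = FALSE))
  prof <- tibble::add_column(prof, sample_id = rownames(v), .before = 1L)
  attr(prof, "lineages") <- lin
  prof
}

# exhaustive two-sided Mann-Whitney p by direct permutation of raw values
mwu_brute_force <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- nx * length(y) / 2
  sets <- utils::combn(length(pooled), nx)
  u_all <- apply(sets, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# small clinical simulation used by several model tests
small_sim <- function(seed = 42L, n = 30L) {
  spec <- synthetic_spec(n_control = n, n_case = n, n_genera = 60L,
                         n_families = 12L, n_orders = 6L, n_classes = 4L,
                         n_phyla = 3L)
  simulate_cohort(spec, seed = seed)
}
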
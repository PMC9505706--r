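# Taxonomy data model and tabular I/O: QIIME-classic OTU tables, sample
# metadata, and feature matrices.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Parse semicolon-delimited taxonomy lineages
#'
#' Parses SILVA-style (`D_0__...;D_5__...`) or Greengenes-style
#' (`k__...;g__...`) lineage strings into a six-rank table
#' (kingdom through genus). Ranks left unassigned by the reference database
#' are filled with a fallback label: the deepest resolved name wrapped in
#' parentheses, e.g. a family-level OTU in Muribaculaceae becomes genus
#' `"(Muribaculaceae)"`. A seventh (species) field, if present, is ignored:
#' all downstream analysis is at genus level. Bracketed SILVA names such as
#' `"[Ruminococcus] gnavus group"` are genuine database labels and are kept
#' verbatim; only parenthesised labels mark unresolved genera.
#'
#' @param x Character vector of lineage strings.
#' @param dialect `"auto"` (detect from the first string's prefix),
#'   `"silva"`, or `"greengenes"`.
#' @return A tibble with one row per input: columns `kingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `resolved_rank` (deepest rank with
#'   a database-assigned name) and `placeholder` (`TRUE` when the genus is a
#'   parenthesised fallback label).
#' @examples
#' parse_lineage("D_0__Bacteria;D_1__Firmicutes;D_2__Bacilli;D_3__Lactobacillales;D_4__Lactobacillaceae;D_5__Lactobacillus")
#' parse_lineage("k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Muribaculaceae;g__")
#' @export
parse_lineage <- function(x, dialect = c("auto", "silva", "greengenes")) {
  dialect <- match.arg(dialect)
  if (length(x) == 0L) stop("no lineage strings supplied")
  if (any(is.na(x) | !nzchar(trimws(x)))) {
    stop("empty lineage string at position ",
         which(is.na(x) | !nzchar(trimws(x)))[1])
  }
  if (dialect == "auto") dialect <- detect_dialect(x[[1]])

  prefix_re <- switch(dialect,
    silva      = "^D_[0-6]__",
    greengenes = "^[kpcofgs]__"
  )

  parts <- strsplit(x, ";", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) > 7L) {
      stop("lineage has ", length(p), " fields; at most 7 supported")
    }
    p <- sub(prefix_re, "", p)
    p <- p[seq_len(min(length(p), 6L))]          # species dropped
    labs <- character(6L)
    labs[seq_along(p)] <- p
    resolved <- which(nzchar(labs) & !grepl("^\\(.*\\)$", labs))
    if (length(resolved) == 0L) {
      stop("lineage has no resolved rank: ", paste(p, collapse = ";"))
    }
    # fill each gap with the deepest resolved label above it
    for (i in seq_len(6L)) {
      if (!nzchar(labs[i])) {
        above <- resolved[resolved < i]
        labs[i] <- paste0("(", labs[max(above)], ")")
      }
    }
    list(labs = labs, resolved_rank = RANKS[max(resolved)])
  })

  out <- tibble::as_tibble(do.call(
    rbind.data.frame,
    c(lapply(rows, function(r) as.list(stats::setNames(r$labs, RANKS))),
      stringsAsFactors = FALSE)
  ))
  out$resolved_rank <- vapply(rows, `[[`, "", "resolved_rank")
  out$placeholder <- grepl("^\\(.*\\)$", out$genus)
  out
}

detect_dialect <- function(s) {
  if (grepl("^\\s*D_0__", s)) return("silva")
  if (grepl("^\\s*k__", s)) return("greengenes")
  stop("cannot detect taxonomy dialect from lineage: ", s,
       " (expected a 'D_0__' or 'k__' prefix; pass dialect= explicitly)")
}

#' Serialise parsed lineages back to strings
#'
#' Inverse of [parse_lineage()] up to fallback labels: placeholder ranks are
#' written as empty fields so that re-parsing reproduces an equal lineage
#' table.
#'
#' @param lineages Tibble as returned by [parse_lineage()].
#' @param dialect `"silva"` or `"greengenes"`.
#' @return Character vector of lineage strings.
#' @export
format_lineage <- function(lineages, dialect = c("silva", "greengenes")) {
  dialect <- match.arg(dialect)
  pre <- switch(dialect,
    silva      = paste0("D_", 0:5, "__"),
    greengenes = paste0(c("k", "p", "c", "o", "f", "g"), "__")
  )
  vapply(seq_len(nrow(lineages)), function(i) {
    labs <- unlist(lineages[i, RANKS], use.names = FALSE)
    labs[grepl("^\\(.*\\)$", labs)] <- ""
    keep <- max(which(nzchar(labs)))
    paste0(pre[seq_len(keep)], labs[seq_len(keep)], collapse = ";")
  }, character(1))
}

new_otu_table <- function(counts, lineages) {
  structure(list(counts = counts, lineages = lineages),
            class = "taxrisk_otu")
}

#' Construct an OTU table object
#'
#' Container for a validated sample-by-OTU count matrix plus one parsed
#' lineage per OTU. Rows of `counts` are samples everywhere in this package.
#'
#' @param counts Numeric matrix, samples x OTUs, with dimnames; entries
#'   must be non-negative integers (numeric storage with zero fractional
#'   part is accepted).
#' @param lineages Tibble with column `otu_id` plus the columns of
#'   [parse_lineage()], one row per OTU.
#' @return An object of class `taxrisk_otu`.
#' @export
otu_table <- function(counts, lineages) {
  validate_otu_table(new_otu_table(counts, lineages))
}

validate_otu_table <- function(x) {
  counts <- x$counts
  lin <- x$lineages
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample (row) and OTU (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU IDs")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integral")
  if (!all(colnames(counts) %in% lin$otu_id)) {
    stop("every OTU needs a lineage; missing: ",
         paste(utils::head(setdiff(colnames(counts), lin$otu_id), 3),
               collapse = ", "))
  }
  lin <- lin[match(colnames(counts), lin$otu_id), ]
  if (any(rowSums(counts) <= 0)) {
    stop("samples with zero read depth: ",
         paste(rownames(counts)[rowSums(counts) <= 0], collapse = ", "))
  }
  # one genus label -> one full lineage
  key <- apply(as.matrix(lin[, RANKS]), 1L, paste, collapse = "|")
  split_keys <- split(key, lin$genus)
  bad <- names(split_keys)[vapply(split_keys, function(k) length(unique(k)) > 1L, NA)]
  if (length(bad)) {
    stop("conflicting lineages for genus label(s): ", paste(bad, collapse = ", "))
  }
  x$counts <- counts
  x$lineages <- lin
  x
}

#' @export
print.taxrisk_otu <- function(x, ...) {
  cat("<taxrisk OTU table> ", nrow(x$counts), " samples x ",
      ncol(x$counts), " OTUs\n", sep = "")
  cat("  read depth: ", paste(range(rowSums(x$counts)), collapse = "-"),
      "; placeholder genera: ", sum(x$lineages$placeholder), "\n", sep = "")
  invisible(x)
}

#' @export
dim.taxrisk_otu <- function(x) dim(x$counts)

#' Read a QIIME-classic OTU table
#'
#' Reads the tab-separated format with OTUs as rows, samples as columns and
#' a trailing `taxonomy` (or `ConsensusLineage`) column holding the
#' semicolon-delimited lineage. Lines starting with `#` are treated as
#' comments; a final comment line containing tabs (the conventional
#' `#OTU ID ...` line) is taken as the header.
#'
#' @param path File path.
#' @param dialect Taxonomy dialect, see [parse_lineage()].
#' @return A `taxrisk_otu` object (samples x OTUs internally).
#' @export
read_otu_table <- function(path, dialect = c("auto", "silva", "greengenes")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (!length(lines)) stop("empty OTU table file: ", path)
  is_comment <- startsWith(lines, "#")
  header_idx <- NULL
  comment_idx <- which(is_comment)
  if (length(comment_idx)) {
    last <- comment_idx[length(comment_idx)]
    if (grepl("\t", lines[last])) header_idx <- last
  }
  if (is.null(header_idx)) header_idx <- which(!is_comment)[1]
  if (is.na(header_idx)) stop("no header line found in ", path)
  header <- strsplit(sub("^#", "", lines[header_idx]), "\t", fixed = TRUE)[[1]]
  data_idx <- which(!is_comment & seq_along(lines) > header_idx & nzchar(lines))
  if (!length(data_idx)) stop("no data rows in ", path)

  tax_col <- which(tolower(header) %in% c("taxonomy", "consensuslineage"))
  if (length(tax_col) != 1L) {
    stop("expected one 'taxonomy' or 'ConsensusLineage' column in header of ", path)
  }
  if (tax_col != length(header)) stop("taxonomy must be the last column in ", path)
  sample_ids <- header[-c(1L, tax_col)]

  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- data_idx[which(nf != length(header))[1]]
    stop("ragged row at line ", bad, " of ", path, ": expected ",
         length(header), " fields, found ", nf[which(nf != length(header))[1]])
  }
  m <- do.call(rbind, fields)
  otu_ids <- m[, 1L]
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU ID at line ",
         data_idx[which(duplicated(otu_ids))[1]], " of ", path)
  }
  raw <- m[, -c(1L, tax_col), drop = FALSE]
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(num)) {
    bad_row <- which(apply(is.na(num), 1L, any))[1]
    stop("non-numeric count at line ", data_idx[bad_row], " of ", path)
  }
  if (any(num < 0)) {
    bad_row <- which(apply(num < 0, 1L, any))[1]
    stop("negative count at line ", data_idx[bad_row], " of ", path)
  }
  if (any(num != round(num))) {
    bad_row <- which(apply(num != round(num), 1L, any))[1]
    stop("non-integral count at line ", data_idx[bad_row], " of ", path)
  }
  counts <- t(num)                              # samples x OTUs
  dimnames(counts) <- list(sample_ids, otu_ids)
  lineages <- parse_lineage(m[, tax_col], dialect = dialect)
  lineages <- tibble::add_column(lineages, otu_id = otu_ids, .before = 1L)
  otu_table(counts, lineages)
}

#' Write an OTU table in QIIME-classic format
#'
#' @param x A `taxrisk_otu` object.
#' @param path Output file path.
#' @param dialect Dialect used to serialise lineages.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, dialect = c("silva", "greengenes")) {
  dialect <- match.arg(dialect)
  counts <- t(x$counts)                          # back to OTUs x samples
  tax <- format_lineage(x$lineages, dialect = dialect)
  header <- paste(c("#OTU ID", colnames(counts), "taxonomy"), collapse = "\t")
  body <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(rownames(counts)[i],
            format(counts[i, ], scientific = FALSE, trim = TRUE),
            tax[i]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read sample metadata
#'
#' Two-column tab-separated file with a header: sample ID then group label.
#' Group levels are kept in first-appearance order.
#'
#' @param path File path.
#' @return Tibble with columns `sample_id` (character) and `group` (factor).
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("metadata needs at least two columns (sample_id, group)")
  if (nrow(df) == 0L) stop("metadata file has no rows: ", path)
  out <- tibble::tibble(sample_id = df[[1L]], group = df[[2L]])
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  }
  out$group <- factor(out$group, levels = unique(out$group))
  out
}

check_metadata <- function(metadata, sample_ids, min_groups = 2L) {
  missing <- setdiff(sample_ids, metadata$sample_id)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  md <- metadata[match(sample_ids, metadata$sample_id), ]
  md$group <- droplevels(md$group)
  if (nlevels(md$group) < min_groups) {
    stop("need at least ", min_groups, " groups, found ", nlevels(md$group))
  }
  md
}

#' Write a feature matrix (profile) as TSV
#'
#' Rows are samples, columns are genus features sorted lexicographically.
#' Values are printed with 15 significant digits so that a write/read
#' round trip through [read_feature_matrix()] is lossless to 1e-12.
#'
#' @param profile A profile tibble (`sample_id` column + numeric feature
#'   columns), e.g. from [tax_accumulate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(profile, path) {
  feats <- setdiff(names(profile), "sample_id")
  if (nrow(profile) == 0L || length(feats) == 0L) {
    stop("cannot write an empty profile")
  }
  feats <- sort(feats)
  header <- paste(c("sample_id", feats), collapse = "\t")
  body <- vapply(seq_len(nrow(profile)), function(i) {
    paste(c(profile$sample_id[i],
            sprintf("%.15g", unlist(profile[i, feats], use.names = FALSE))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path File path.
#' @return Tibble with `sample_id` plus numeric feature columns.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("feature matrix file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(fields) != length(header))) stop("ragged feature matrix: ", path)
  m <- do.call(rbind, fields)
  vals <- array(as.numeric(m[, -1L, drop = FALSE]), dim = c(nrow(m), length(header) - 1L))
  colnames(vals) <- header[-1L]
  out <- tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  tibble::add_column(out, sample_id = m[, 1L], .before = 1L)
}

# matrix view of a profile tibble: samples x features with dimnames
profile_matrix <- function(profile) {
  feats <- setdiff(names(profile), "sample_id")
  m <- as.matrix(profile[, feats, drop = FALSE])
  rownames(m) <- profile$sample_id
  m
}

profile_tibble <- function(m, lineages = NULL) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- tibble::add_column(out, sample_id = rownames(m), .before = 1L)
  if (!is.null(lineages)) attr(out, "lineages") <- lineages
  out
}
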
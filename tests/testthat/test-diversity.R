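counts_tbl <- function(m) {
  tibble::add_column(tibble::as_tibble(as.data.frame(m, check.names = FALSE)),
                     sample_id = rownames(m), .before = 1L)
}

test_that("rarefaction conserves the target depth exactly and is seeded", {
  m <- matrix(c(10L, 0L,
                60L, 40L), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  r <- rarefy_counts(counts_tbl(m), depth = 5, seed = 1)
  expect_equal(unname(rowSums(as.matrix(r[, -1]))), c(5, 5))
  expect_equal(unlist(r[r$sample_id == "a", -1], use.names = FALSE), c(5, 0))

  # depth equal to a sample's total leaves it unchanged
  r2 <- rarefy_counts(counts_tbl(m)[1, ], depth = 10, seed = 3)
  expect_equal(unlist(r2[1, -1], use.names = FALSE), c(10, 0))

  r3 <- rarefy_counts(counts_tbl(m), depth = 5, seed = 1)
  expect_identical(r, r3)
  expect_error(rarefy_counts(counts_tbl(m), depth = 0), "positive")
})

test_that("samples below the rarefaction depth are dropped with a warning", {
  m <- matrix(c(3L, 0L, 50L, 50L), 2, byrow = TRUE,
              dimnames = list(c("lo", "hi"), c("t1", "t2")))
  expect_warning(r <- rarefy_counts(counts_tbl(m), depth = 10, seed = 1),
                 "below depth")
  expect_equal(r$sample_id, "hi")
})

test_that("rarefied counts have the hypergeometric mean", {
  m <- matrix(c(50L, 50L), 1, dimnames = list("s", c("t1", "t2")))
  draws <- vapply(1:2000, function(s) {
    as.matrix(rarefy_counts(counts_tbl(m), depth = 10, seed = s)[, -1])[1, 1]
  }, numeric(1))
  expect_equal(mean(draws), 5, tolerance = 0.2 / 5)  # within +-0.2 of 5
})

test_that("alpha diversity matches closed forms", {
  uniform4 <- matrix(rep(5L, 4), 1, dimnames = list("u", paste0("t", 1:4)))
  a <- alpha_diversity(counts_tbl(uniform4))
  expect_equal(a$simpson, 0.75)
  expect_equal(a$shannon, log(4))
  expect_equal(a$observed, 4)

  single <- matrix(9L, 1, dimnames = list("s", "t1"))
  b <- alpha_diversity(counts_tbl(single))
  expect_equal(b$simpson, 0)
  expect_equal(b$shannon, 0)
  expect_equal(b$chao1, 1)

  # S_obs = 10 with 4 singletons and 2 doubletons: Chao1 = 10 + 16/4 = 14
  x <- matrix(c(rep(1L, 4), rep(2L, 2), rep(5L, 4)), 1,
              dimnames = list("s", paste0("t", 1:10)))
  expect_equal(alpha_diversity(counts_tbl(x))$chao1, 14)

  expect_error(alpha_diversity(counts_tbl(matrix(0L, 1, 2,
    dimnames = list("z", c("a", "b"))))), "all-zero")
})

test_that("alpha diversity is invariant to taxon order", {
  set.seed(8)
  m <- matrix(rpois(20, 4), 2, dimnames = list(c("a", "b"), paste0("t", 1:10)))
  m[1, 1] <- 1L  # ensure nonzero rows
  a1 <- alpha_diversity(counts_tbl(m))
  a2 <- alpha_diversity(counts_tbl(m[, sample(10)]))
  expect_equal(a1, a2)
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  m <- matrix(c(2, 2,
                1, 3,
                2, 2,
                0, 5), 4, byrow = TRUE,
              dimnames = list(c("x", "y", "x2", "z"), c("t1", "t2")))
  d <- bray_curtis(counts_tbl(m))
  dm <- as.matrix(d)
  expect_equal(dm["x", "y"], 0.25)      # 1 - 2*3/8
  expect_equal(dm["x", "x2"], 0)        # identical samples
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_equal(dm, t(dm))
  # disjoint supports
  disj <- matrix(c(5, 0, 0, 7), 2, byrow = TRUE,
                 dimnames = list(c("p", "q"), c("t1", "t2")))
  expect_equal(as.matrix(bray_curtis(counts_tbl(disj)))["p", "q"], 1)
  # independent implementation
  expect_equal(as.matrix(d), as.matrix(vegan::vegdist(m, "bray")),
               tolerance = 1e-12)
})

test_that("PCoA recovers exact low-dimensional configurations", {
  # points on a line: axis 1 recovers the spacing up to sign/offset
  pts <- c(0, 1, 3, 7)
  d <- stats::dist(pts)
  attr(d, "Labels") <- paste0("s", 1:4)
  ord <- suppressWarnings(pcoa_ordination(d, n_axes = 2))
  ax1 <- ord$coordinates$Axis1
  expect_equal(abs(cor(ax1, pts)), 1, tolerance = 1e-9)
  expect_equal(max(abs(stats::dist(ax1) - d)), 0, tolerance = 1e-9)

  # three equidistant points: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  ord3 <- suppressWarnings(pcoa_ordination(d3, n_axes = 2))
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # duplicated samples collapse onto each other
  dup <- stats::dist(c(0, 0, 5))
  ordd <- suppressWarnings(pcoa_ordination(dup, n_axes = 2))
  expect_equal(ordd$coordinates$Axis1[1], ordd$coordinates$Axis1[2])
})

test_that("PCoA warns when fewer positive axes exist than requested", {
  d <- stats::dist(c(0, 4))  # 2 points: one positive axis
  expect_warning(ord <- pcoa_ordination(d, n_axes = 2), "axes")
  expect_equal(ncol(ord$coordinates) - 1L, 1L)
})

test_that("PERMANOVA is maximal on separated clusters and matches vegan", {
  set.seed(2)
  m <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
             matrix(rnorm(20, 10, 0.05), 10, 2))
  rownames(m) <- paste0("s", 1:20)
  d <- stats::dist(m)
  g <- rep(c("A", "B"), each = 10)
  pm <- permanova(d, g, n_perm = 199, seed = 5)
  expect_equal(pm$p, 1 / 200)
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(pm$f, ad$F[1], tolerance = 1e-9)
})

test_that("PERMANOVA p matches brute-force exhaustive permutation at n = 6", {
  set.seed(11)
  m <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  d <- stats::dist(m)
  g <- rep(c("A", "B"), each = 3)
  d2 <- as.matrix(d)^2

  ss_w <- function(lab) {
    s <- 0
    for (gr in unique(lab)) {
      idx <- which(lab == gr)
      sub <- d2[idx, idx, drop = FALSE]
      s <- s + sum(sub[upper.tri(sub)]) / length(idx)
    }
    s
  }
  ss_t <- sum(d2[upper.tri(d2)]) / 6
  f_of <- function(lab) ((ss_t - ss_w(lab)) / 1) / (ss_w(lab) / 4)
  perms <- utils::combn(6, 3)
  f_all <- apply(perms, 2L, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"; f_of(lab)
  })
  exact_p <- mean(f_all >= f_of(g) - 1e-12)

  pm <- permanova(d, g, n_perm = 49999, seed = 1)
  # sampled permutation p converges on the exhaustive value; allow 3 MC sd
  expect_lt(abs(pm$p - exact_p), 3 * sqrt(exact_p * (1 - exact_p) / pm$n_perm))
})

test_that("identical data halves with duplicated labels give large p", {
  set.seed(3)
  half <- matrix(rnorm(16), 8, 2)
  m <- rbind(half, half)
  rownames(m) <- paste0("s", 1:16)
  d <- stats::dist(m)
  g <- rep(c("A", "B"), each = 8)[sample(16)]
  pm <- permanova(d, g, n_perm = 199, seed = 2)
  expect_gt(pm$p, 0.05)
})

test_that("PERMANOVA rejects degenerate designs", {
  d <- stats::dist(matrix(rnorm(8), 4, 2))
  expect_error(permanova(d, c("A", "A", "A", "B"), seed = 1), "size 1")
  expect_error(permanova(d, rep("A", 4), seed = 1), "two groups")
})

test_that("rank collapsing sums features by upper-rank label", {
  prof <- random_profile(n_samples = 4, n_genera = 30, seed = 2)
  lin <- attr(prof, "lineages")
  ph <- collapse_to_rank(prof, "phylum")
  v <- as.matrix(prof[, -1])
  for (pl in unique(lin$phylum)) {
    expect_equal(ph[[pl]],
                 unname(rowSums(v[, lin$genus[lin$phylum == pl], drop = FALSE])))
  }
  expect_equal(unname(rowSums(as.matrix(ph[, -1]))), rep(1, 4), tolerance = 1e-9)
})
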
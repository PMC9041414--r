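test_that("pairwise identity handles gaps exactly as specified", {
  expect_equal(pairwise_pid("ACGT", "ACGT"), 1.0)
  # single-gap column counts in the denominator and is non-identical
  expect_equal(pairwise_pid("A-CGT", "AACGT"), 0.8)
  # shared-gap columns are excluded entirely
  expect_equal(pairwise_pid("AC--G", "AC--G"), 1.0)
  # alternative convention: all gap columns excluded
  expect_equal(pairwise_pid("A-CGT", "AACGT", count_single_gaps = FALSE), 1.0)
  # ambiguity codes never match, even to themselves
  expect_equal(pairwise_pid("ANGT", "ANGT"), 3 / 4)
  expect_equal(pairwise_pid("ANGT", "ANGT", ambiguity_identical = TRUE), 1.0)
  expect_error(pairwise_pid("ACG", "ACGT"), "unequal")
  expect_error(pairwise_pid("--", "--"), "undefined")
})

test_that("pairwise identity is symmetric and invariant to shared-gap insertion", {
  set.seed(11)
  for (i in 1:20) {
    aln <- random_gapped_alignment(2, 60)
    a <- aln$seq[1]; b <- aln$seq[2]
    expect_equal(pairwise_pid(a, b), pairwise_pid(b, a))
    # insert the same gap columns into both sequences at the same spots
    pos <- sort(sample(60, 5))
    insert_gaps <- function(s) {
      ch <- strsplit(s, "")[[1]]
      out <- character(0)
      for (j in seq_along(ch)) {
        if (j %in% pos) out <- c(out, "-")
        out <- c(out, ch[j])
      }
      paste(out, collapse = "")
    }
    expect_equal(pairwise_pid(insert_gaps(a), insert_gaps(b)),
                 pairwise_pid(a, b))
  }
})

test_that("pid_matrix agrees with the brute-force column-loop oracle", {
  set.seed(101)
  for (rep in 1:10) {
    aln <- random_gapped_alignment(sample(3:8, 1), sample(40:200, 1))
    m <- pid_matrix(aln)
    expect_true(isSymmetric(m$values))
    expect_equal(unname(diag(m$values)), rep(1, nrow(aln)))
    for (i in seq_len(nrow(aln) - 1)) {
      for (j in (i + 1):nrow(aln)) {
        expect_equal(m$values[i, j], oracle_pid(aln$seq[i], aln$seq[j]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("pid_matrix has the right pair count and errors on all-gap pairs", {
  sim <- simulate_clade_alignment(n_clades = 2, members_per_clade = 5,
                                  seed = 5)
  m <- pid_matrix(sim$alignment)
  expect_equal(nrow(tidy(m)), choose(10, 2))
  bad <- as_alignment(tibble::tibble(id = c("a", "b"), seq = c("----", "----")))
  expect_error(pid_matrix(bad), "a, b")
})

test_that("group distributions have the expected pair counts", {
  sim <- simulate_clade_alignment(n_clades = 2, members_per_clade = 4,
                                  seed = 8)
  m <- pid_matrix(sim$alignment)
  between <- group_pni(m, sim$groups, "clade01", "clade02")
  expect_equal(between$n_pairs, 16L)
  within <- group_pni(m, sim$groups, "clade01", "clade01")
  expect_equal(within$n_pairs, 6L)
  expect_equal(stats::median(between$values), between$median)
  expect_error(group_pni(m, sim$groups, "clade01", "nope"), "unknown")
  # unbalanced groups: |A| = 3, |B| = 4 -> 12 pairs
  g2 <- sim$groups[-1, ]
  expect_equal(group_pni(m, g2, "clade01", "clade02")$n_pairs, 12L)
})

test_that("between-clade identity matches the Jukes-Cantor closed form", {
  d <- 0.25
  sims <- lapply(1:30, function(s) {
    simulate_clade_alignment(n_clades = 2, members_per_clade = 2,
                             d_w = 0, d_b = d, root_length = 600, seed = s)
  })
  meds <- vapply(sims, function(sim) {
    m <- pid_matrix(sim$alignment)
    group_pni(m, sim$groups, "clade01", "clade02")$median
  }, numeric(1))
  expected <- jc_expected_identity(d)
  se <- stats::sd(meds) / sqrt(length(meds))
  expect_lt(abs(mean(meds) - expected), 3 * se + 1e-3)
})

test_that("MIF is the median of inter-family means and is order-invariant", {
  # construct a matrix with three families at engineered mean identities
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2")
  fams <- tibble::tibble(id = ids, group = rep(c("A", "B", "C"), each = 2))
  v <- diag(1, 6); dimnames(v) <- list(ids, ids)
  v[ids[1:2], ids[3:4]] <- 0.80; v[ids[3:4], ids[1:2]] <- 0.80
  v[ids[1:2], ids[5:6]] <- 0.84; v[ids[5:6], ids[1:2]] <- 0.84
  v[ids[3:4], ids[5:6]] <- 0.90; v[ids[5:6], ids[3:4]] <- 0.90
  v[ids[1], ids[2]] <- v[ids[2], ids[1]] <- 0.99
  v[ids[3], ids[4]] <- v[ids[4], ids[3]] <- 0.99
  v[ids[5], ids[6]] <- v[ids[6], ids[5]] <- 0.99
  m <- structure(list(ids = ids, values = v), class = "pid_matrix")
  mif <- median_inter_family(m, fams)
  expect_equal(mif$mif, 0.84)
  expect_equal(c(mif$band_low, mif$band_high), c(0.80, 0.90))
  # permuting the family table leaves the statistic unchanged
  mif2 <- median_inter_family(m, fams[sample(6), ])
  expect_equal(mif2$mif, mif$mif)
  # two families: single pair mean, degenerate band
  mif3 <- median_inter_family(m, fams[1:4, ])
  expect_equal(mif3$mif, 0.80)
  expect_equal(mif3$band_low, mif3$band_high)
  expect_error(median_inter_family(m, fams[1:2, ]), "2 families")
})

test_that("rank placement follows the threshold ladder on the median", {
  thr <- rank_thresholds()
  sim <- simulate_clade_alignment(n_clades = 2, members_per_clade = 3,
                                  d_w = 0, d_b = 0, seed = 2)
  m <- pid_matrix(sim$alignment)
  call <- place_group(m, sim$groups, "clade01", "clade02", thr)
  expect_equal(call$rank_call, "same_genus")
  expect_equal(call$median_pni, 1.0)
  # planted expected identity midway between family and genus thresholds
  target <- (thr$family + thr$genus) / 2
  sim2 <- simulate_clade_alignment(
    n_clades = 2, members_per_clade = 3, d_w = 0.004,
    d_b = jc_divergence_for_identity(target), root_length = 1500, seed = 3)
  m2 <- pid_matrix(sim2$alignment)
  call2 <- place_group(m2, sim2$groups, "clade01", "clade02", thr)
  expect_equal(call2$rank_call, "same_family")
  # far below the order threshold
  sim3 <- simulate_clade_alignment(
    n_clades = 2, members_per_clade = 3, d_w = 0.004, d_b = 0.8,
    root_length = 1500, seed = 4)
  call3 <- place_group(pid_matrix(sim3$alignment), sim3$groups,
                       "clade01", "clade02", thr)
  expect_equal(call3$rank_call, "beyond_order")
  expect_equal(glance(call3)$rank_call, "beyond_order")
})

test_that("threshold constructor enforces ordering", {
  expect_error(rank_thresholds(genus = 0.8, family = 0.865), "thresholds")
  expect_s3_class(rank_thresholds(0.99, 0.9, 0.5), "rank_thresholds")
})

test_that("NJ recovers additive quartets and keeps clades monophyletic", {
  # additive quartet: true split ab|cd
  ids <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  # tree: a-1-x, b-2-x, x-3-y, c-1.5-y, d-2.5-y (scaled to identities)
  dm <- rbind(c(0, 3, 5.5, 6.5), c(3, 0, 6.5, 7.5),
              c(5.5, 6.5, 0, 4), c(6.5, 7.5, 4, 0)) / 100
  dimnames(dm) <- list(ids, ids)
  m <- structure(list(ids = ids, values = 1 - dm), class = "pid_matrix")
  tree <- build_nj_tree(m)
  true_tree <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(true_tree)), 0,
               ignore_attr = TRUE)
  expect_true(all(tree$edge.length >= 0))
  expect_error(build_nj_tree(structure(list(ids = ids[1:3],
                                            values = dm[1:3, 1:3]),
                                       class = "pid_matrix")), ">= 4 taxa")
  # simulated distant clades stay monophyletic
  sim <- simulate_clade_alignment(n_clades = 2, members_per_clade = 4,
                                  d_w = 0.01, d_b = 0.4, seed = 6)
  tr <- build_nj_tree(pid_matrix(sim$alignment))
  rooted <- ape::root(tr, outgroup = sim$groups$id[sim$groups$group ==
                                                     "clade02"],
                      resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted,
                                   sim$groups$id[sim$groups$group ==
                                                   "clade01"]))
})
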
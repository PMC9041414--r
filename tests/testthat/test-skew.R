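test_that("windowed skew obeys the 0/0 rule and hits its bounds", {
  allA <- tibble::tibble(id = "a", seq = strrep("A", 1000))
  prof <- windowed_gc_skew(allA, window = 100)
  expect_true(all(prof$skew == 0))
  expect_true(all(prof$cumulative == 0))
  gg <- tibble::tibble(id = "g", seq = paste0(strrep("G", 500),
                                              strrep("C", 500)))
  prof2 <- windowed_gc_skew(gg, window = 100)
  expect_equal(prof2$skew[1:5], rep(1, 5))
  expect_equal(prof2$skew[6:10], rep(-1, 5))
  expect_equal(prof2$cumulative, cumsum(prof2$skew))
  expect_error(windowed_gc_skew(allA, window = 600), "shorter")
  # final partial window retained
  prof3 <- windowed_gc_skew(tibble::tibble(id = "x", seq = strrep("G", 250)),
                            window = 100)
  expect_equal(nrow(prof3), 3L)
  expect_equal(prof3$end[3], 250L)
})

test_that("ori/ter are recovered within one window of the planted switch points", {
  sim <- simulate_skew_genome(length = 1e6, ori = 150000, ter = 650000,
                              strength = 0.2, seed = 41)
  prof <- windowed_gc_skew(sim$genome, window = 5000)
  pred <- predict_ori_ter(prof)
  expect_lt(abs(pred$ori_position - sim$truth$ori), 5000)
  expect_lt(abs(pred$ter_position - sim$truth$ter), 5000)
  expect_gt(pred$amplitude, 0)
  # per-arc mean skew close to the recorded expectation
  on_arc <- prof$midpoint > 150000 & prof$midpoint < 650000
  expect_lt(abs(mean(prof$skew[on_arc]) - sim$truth$expected_window_skew),
            0.02)
  expect_lt(abs(mean(prof$skew[!on_arc]) + sim$truth$expected_window_skew),
            0.02)
})

test_that("rotation shifts predictions by the rotation amount (mod length)", {
  sim <- simulate_skew_genome(length = 400000, ori = 100000, ter = 300000,
                              strength = 0.15, seed = 43)
  rot <- 100000
  s <- sim$genome$seq
  rotated <- tibble::tibble(id = "rot",
                            seq = paste0(substring(s, rot + 1),
                                         substring(s, 1, rot)))
  p1 <- predict_ori_ter(windowed_gc_skew(sim$genome, 5000))
  p2 <- predict_ori_ter(windowed_gc_skew(rotated, 5000))
  shift <- function(pos) ((pos - rot - 1) %% 400000) + 1
  expect_lt(min(abs(p2$ori_position - shift(p1$ori_position)),
                400000 - abs(p2$ori_position - shift(p1$ori_position))),
            5000 + 1)
  expect_lt(min(abs(p2$ter_position - shift(p1$ter_position)),
                400000 - abs(p2$ter_position - shift(p1$ter_position))),
            5000 + 1)
})

test_that("predictions are strand-symmetric under reverse complement", {
  # complementing negates the skew; reversing mirrors the axis and flips
  # the integration direction, negating again: the physical ori/ter loci
  # are therefore unchanged, i.e. predictions land on mirrored coordinates
  sim <- simulate_skew_genome(length = 400000, ori = 120000, ter = 290000,
                              strength = 0.15, seed = 47)
  p1 <- predict_ori_ter(windowed_gc_skew(sim$genome, 5000))
  rc <- tibble::tibble(id = "rc", seq = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sim$genome$seq))))
  p2 <- predict_ori_ter(windowed_gc_skew(rc, 5000))
  L <- 400000
  mirror <- function(pos) L - pos + 1
  expect_lt(abs(p2$ori_position - mirror(p1$ori_position)), 2 * 5000 + 1)
  expect_lt(abs(p2$ter_position - mirror(p1$ter_position)), 2 * 5000 + 1)
})

test_that("a structureless genome has a small cumulative amplitude", {
  sim <- simulate_skew_genome(length = 400000, ori = 100000, ter = 300000,
                              strength = 0.2, seed = 53)
  structured <- predict_ori_ter(windowed_gc_skew(sim$genome, 5000))
  set.seed(54)
  flat <- tibble::tibble(id = "flat",
                         seq = paste(sample(c("A", "C", "G", "T"), 400000,
                                            TRUE), collapse = ""))
  unstructured <- predict_ori_ter(windowed_gc_skew(flat, 5000))
  expect_lt(unstructured$amplitude, 0.1 * structured$amplitude)
})

test_that("dnaA proximity uses circular distance and validates input", {
  sim <- simulate_skew_genome(length = 400000, ori = 100000, ter = 300000,
                              strength = 0.2, seed = 59)
  pred <- predict_ori_ter(windowed_gc_skew(sim$genome, 5000))
  expect_lte(dnaa_proximity(pred, sim$annotations), 5000)
  # antipodal gene
  anti <- sim$annotations
  anti$start <- 300000L; anti$end <- 301349L
  expect_gt(dnaa_proximity(pred, anti), 190000)
  expect_error(dnaa_proximity(pred, anti[0, ]), "no annotation row")
  two <- dplyr::bind_rows(sim$annotations, sim$annotations)
  expect_error(dnaa_proximity(pred, two), "multiple")
})

test_that("coverage binning is exact and conserves total depth", {
  expect_equal(bin_coverage(rep(100, 12000), 5000)$mean_depth,
               c(100, 100, 100))
  b <- bin_coverage(rep(1, 12000), 5000)
  expect_equal(b$n_bases, c(5000L, 5000L, 2000L))
  # arithmetic-series check: depths 0..9999
  b2 <- bin_coverage(0:9999, 5000)
  expect_equal(b2$mean_depth, c(2499.5, 7499.5))
  # exact conservation on random tracks
  set.seed(61)
  for (i in 1:5) {
    depths <- stats::rpois(sample(7000:20000, 1), lambda = 40)
    bb <- bin_coverage(depths, 5000)
    expect_identical(sum(bb$total_depth), sum(as.numeric(depths)))
    expect_equal(sum(bb$mean_depth * bb$n_bases), sum(as.numeric(depths)))
  }
  expect_error(bin_coverage(numeric(0)), "empty")
  expect_error(bin_coverage(rep(1, 10), 0), "window")
  # data-frame input as from read_coverage_track
  tr <- tibble::tibble(pos = 1:6000, depth = rep(2, 6000))
  expect_equal(bin_coverage(tr, 5000)$mean_depth, c(2, 2))
})
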
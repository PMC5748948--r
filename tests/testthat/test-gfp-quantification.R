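make_image <- function(values) intensity_image(values)

test_that("compute_sweep counts pixels strictly above each threshold", {
  # empty signal
  sw0 <- compute_sweep(make_image(matrix(0, 10, 10)))
  expect_true(all(sw0$area == 0L))
  # single bright population: constant across the sweep
  m <- matrix(0, 10, 10); m[1:3, 1:10] <- 200
  sw1 <- compute_sweep(make_image(m))
  expect_true(all(sw1$area == 30L))
  # two populations: 100 px at 20, 50 px at 200
  m2 <- matrix(0, 20, 20)
  m2[seq_len(100)] <- 20
  m2[101:150] <- 200
  sw2 <- compute_sweep(make_image(m2))
  expect_true(all(sw2$area[1:20] == 150L))   # t = 0..19
  expect_true(all(sw2$area[21:51] == 50L))   # t = 20..50
})

test_that("compute_sweep equals the brute-force recount on random images", {
  set.seed(101)
  for (i in 1:8) {
    m <- matrix(sample(0:60, 16 * 16, TRUE), 16, 16)
    sw <- compute_sweep(intensity_image(m), t_max = 50L)
    expect_identical(sw$area, oracle_sweep(m, 50L))
    # monotone non-increasing, bounded by area(0)
    expect_true(all(diff(sw$area) <= 0L))
    expect_true(all(sw$area <= sw$area[1L]))
  }
})

test_that("select_threshold applies the stability-from-here-onward rule", {
  sweep_from <- function(area) structure(
    list(t = seq_along(area) - 1L, area = as.integer(area),
         t_max = length(area) - 1L, n_pixels = max(area)),
    class = "threshold_sweep")
  # flat curve: all decay zero -> threshold 1, flagged
  s1 <- select_threshold(sweep_from(rep(50L, 51)))
  expect_equal(s1$threshold, 1L)
  expect_true(s1$flat_curve)
  expect_false(s1$saturated)
  # step at t = 20: d(20) = 100/150 >= 0.10, zero after
  s2 <- select_threshold(sweep_from(c(rep(150L, 20), rep(50L, 31))))
  expect_equal(s2$threshold, 21L)
  expect_false(s2$flat_curve)
  # big early drop then sub-tolerance drift: d(1) = 0.70, d(t) = 0.001 after
  area3 <- c(1000L, 300L, 300L - (2:50 - 1L))
  s3 <- select_threshold(sweep_from(area3))
  expect_equal(s3$threshold, 2L)
  # never stabilizes: decay step at exactly t_max
  m <- matrix(0, 10, 10); m[1:3, 1] <- 50; m[1:5, 2] <- 200
  expect_warning(s4 <- select_threshold(compute_sweep(intensity_image(m))),
                 "never stabilized")
  expect_true(s4$saturated)
  expect_equal(s4$threshold, 50L)
  expect_false(s4$flat_curve)
  # contract errors
  expect_error(select_threshold(sweep_from(rep(0L, 51))), "empty signal")
  expect_error(select_threshold(sweep_from(rep(9L, 51)), tolerance = 1.2),
               "\\(0, 1\\)")
})

test_that("measure_gfp returns count above threshold and mean of counted pixels", {
  m <- matrix(0, 20, 20); m[seq_len(50)] <- 200
  g <- measure_gfp(intensity_image(m), 21)
  expect_equal(g$ngfp, 50L)
  expect_equal(g$gmv, 200)
  # nothing exceeds the scale maximum
  g255 <- measure_gfp(intensity_image(m), 255)
  expect_equal(g255$ngfp, 0L)
  expect_equal(g255$gmv, 0)
  # two equal populations
  m2 <- matrix(0, 10, 10); m2[1:10] <- 100; m2[11:20] <- 200
  g2 <- measure_gfp(intensity_image(m2), 50)
  expect_equal(g2$ngfp, 20L)
  expect_equal(g2$gmv, 150)
})

test_that("GMV invariant: threshold < GMV <= 255 whenever nGFP > 0", {
  set.seed(33)
  for (i in 1:20) {
    m <- matrix(sample(0:255, 100, TRUE), 10, 10)
    t <- sample(0:254, 1)
    g <- measure_gfp(intensity_image(m), t)
    if (g$ngfp > 0L) {
      expect_gt(g$gmv, t)
      expect_lte(g$gmv, 255)
    }
    expect_lte(g$ngfp, 100L)
  }
})

test_that("selected threshold is shift-equivariant on step phantoms", {
  # all-positive step phantom so the area(0) normalizer is the full frame
  base <- matrix(5, 40, 40)
  base[5:20, 5:30] <- 22          # autofluorescence-like block
  base[10:15, 10:20] <- 180       # mass
  t_base <- select_threshold(compute_sweep(intensity_image(base)))$threshold
  for (shift in c(3, 7, 12)) {
    t_s <- select_threshold(compute_sweep(intensity_image(base + shift)))$threshold
    expect_equal(t_s, t_base + shift)
  }
})

test_that("proliferation_index matches the displayed formula and classifies at 1", {
  spec <- pi_phantom_spec(5)
  r <- render_embryo(spec)
  rec0 <- embryo_record("e1", "0hpi", r$image)
  rec72 <- embryo_record("e1", "72hpi", r$image)
  pr <- proliferation_index(rec0, rec72)
  expect_identical(pr$pi, 1)
  expect_identical(pr$classification, "stable")

  # formula arithmetic on a constructed pair: (1000 * 120) / (500 * 100) = 2.4
  m0 <- matrix(0, 40, 40); m0[seq_len(500)] <- 100
  m72 <- matrix(0, 40, 40); m72[seq_len(1000)] <- 120
  pr2 <- proliferation_index(embryo_record("e2", "0hpi", intensity_image(m0)),
                             embryo_record("e2", "72hpi", intensity_image(m72)))
  expect_equal(pr2$pi, 2.4)
  expect_identical(pr2$classification, "proliferation")

  # blank 72 hpi image: zero numerator, death
  blank <- intensity_image(matrix(0, 40, 40))
  pr3 <- proliferation_index(embryo_record("e3", "0hpi", intensity_image(m0)),
                             embryo_record("e3", "72hpi", blank))
  expect_equal(pr3$pi, 0)
  expect_identical(pr3$classification, "death")
})

test_that("shared threshold is the max of the per-timepoint selections", {
  # 0 hpi has an autofluorescence shoulder at 20; 72 hpi at 35
  m0 <- matrix(0, 40, 40); m0[seq_len(400)] <- 20; m0[401:480] <- 200
  m72 <- matrix(0, 40, 40); m72[seq_len(400)] <- 35; m72[401:520] <- 210
  t0 <- select_threshold(compute_sweep(intensity_image(m0)))$threshold
  t72 <- select_threshold(compute_sweep(intensity_image(m72)))$threshold
  expect_equal(c(t0, t72), c(21L, 36L))
  pr <- proliferation_index(embryo_record("e", "0hpi", intensity_image(m0)),
                            embryo_record("e", "72hpi", intensity_image(m72)))
  expect_equal(pr$shared_threshold, 36L)
  expect_equal(pr$m0$threshold, 36L)
})

test_that("pairing and baseline errors are raised", {
  img <- render_embryo(pi_phantom_spec(9))$image
  blank <- intensity_image(matrix(0, 20, 20))
  expect_error(
    proliferation_index(embryo_record("a", "0hpi", img),
                        embryo_record("b", "72hpi", img)),
    "embryo_id mismatch")
  expect_error(
    proliferation_index(embryo_record("a", "0hpi", blank),
                        embryo_record("a", "72hpi", img)),
    "undefined baseline")
  expect_error(embryo_record("a", "48hpi", img), "0hpi")
})
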
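test_that("component counting matches a flood-fill oracle and EBImage", {
  set.seed(42)
  for (i in 1:30) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.15, 0.5)), 32, 32)
    expect_identical(count_components(m, 8), flood_fill_count(m, 8))
    expect_identical(count_components(m, 4), flood_fill_count(m, 4))
    # EBImage::bwlabel is 4-connected: an independent library oracle
    expect_identical(count_components(m, 4),
                     as.integer(max(EBImage::bwlabel(EBImage::Image(m)))))
  }
})

test_that("diagonal contact merges under 8- but not 4-connectivity", {
  m <- matrix(0L, 7, 7)
  m[3, 2:4] <- 1L; m[2:4, 3] <- 1L    # plus shape
  m[5, 4] <- 1L                       # touches (4, 3) only diagonally
  expect_identical(count_components(m, 8), 1L)
  expect_identical(count_components(m, 4), 2L)
  expect_identical(count_components(matrix(0L, 10, 10), 8), 0L)
  m2 <- matrix(0L, 10, 10); m2[2:4, 2:4] <- 1L; m2[7:9, 7:9] <- 1L
  expect_identical(count_components(m2, 8), 2L)
  expect_error(count_components(matrix(2L, 3, 3)), "binary")
})

test_that("component counts are invariant to translation and rotation", {
  set.seed(7)
  base <- matrix(0L, 40, 40)
  base[5:9, 5:9] <- 1L; base[20:22, 15:25] <- 1L; base[30, 30] <- 1L
  shifted <- matrix(0L, 40, 40)
  shifted[8:12, 3:7] <- 1L; shifted[23:25, 13:23] <- 1L; shifted[33, 28] <- 1L
  for (conn in c(4L, 8L)) {
    n0 <- count_components(base, conn)
    expect_identical(count_components(shifted, conn), n0)
    rot <- t(base)[ncol(base):1, ]          # 90-degree rotation
    expect_identical(count_components(rot, conn), n0)
    expect_lte(count_components(base, 8), count_components(base, 4))
  }
})

test_that("count MAE averages absolute errors", {
  expect_equal(count_mae(c(10, 20), c(12, 16)), 3.0)
  expect_equal(count_mae(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_equal(count_mae(7, 11), 4)
  rec <- cfu_records(NULL, c(10, 20), c(12, 16))
  expect_equal(count_mae(rec), 3.0)
  expect_error(count_mae(numeric(0), numeric(0)))
})

test_that("three-interval binning uses half-open food-safety intervals", {
  expect_identical(bin3(c(0, 39, 40, 299, 300, 1000)),
                   c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_true(all(diff(bin3(0:500)) >= 0))   # monotone in the count
})

test_that("equal-width bin schemes span [0, max) and extend to infinity", {
  sch <- make_equal_bins(400, 20)
  expect_equal(sch$edges, seq(0, 380, by = 20))
  expect_identical(assign_bin(c(0, 19, 20, 399, 400, 5000), sch),
                   c(0L, 0L, 1L, 19L, 19L, 19L))
  one <- make_equal_bins(50, 1)
  expect_equal(one$edges, 0)
  expect_identical(assign_bin(c(0, 1e6), one), c(0L, 0L))
  expect_true(all(diff(make_equal_bins(97, 13)$edges) > 0))
  expect_error(make_equal_bins(5, 10))
})

test_that("binned accuracy matches brute-force recomputation", {
  rec <- cfu_records(NULL, c(10, 50, 500), c(35, 299, 250))
  acc <- binned_accuracy(rec, bin3_scheme())
  expect_equal(acc$overall, 2 / 3)
  # per-bin accuracy groups by the TRUE bin
  expect_equal(acc$per_bin$accuracy[acc$per_bin$bin == 0], 1)
  expect_equal(acc$per_bin$accuracy[acc$per_bin$bin == 1], 0.5)
  expect_true(is.na(acc$per_bin$accuracy[acc$per_bin$bin == 2]))

  set.seed(3)
  for (i in 1:10) {
    pred <- rpois(40, 60); tru <- rpois(40, 60)
    sch <- make_equal_bins(200, 10)
    rec2 <- cfu_records(NULL, pred, tru)
    acc2 <- binned_accuracy(rec2, sch)
    # brute force: compare interval membership pair by pair
    member <- function(x) findInterval(x, c(sch$edges, Inf))
    expect_equal(acc2$overall, mean(member(pred) == member(tru)))
    for (b in acc2$per_bin$bin) {
      in_b <- member(tru) == b + 1
      if (any(in_b))
        expect_equal(acc2$per_bin$accuracy[acc2$per_bin$bin == b],
                     mean(member(pred)[in_b] == b + 1))
    }
    expect_gte(acc2$overall, 0); expect_lte(acc2$overall, 1)
  }
})

test_that("perfect predictions give zero MAE and unit accuracy", {
  rec <- cfu_records(NULL, c(3, 77, 420), c(3, 77, 420))
  expect_equal(count_mae(rec), 0)
  acc <- binned_accuracy(rec, bin3_scheme())
  expect_equal(acc$overall, 1)
  expect_true(all(acc$per_bin$accuracy[!is.na(acc$per_bin$accuracy)] == 1))
})

test_that("records carry bins consistent with their counts", {
  rec <- cfu_records(c("a", "b"), c(12, 310), c(45, 299))
  expect_identical(rec$predicted_bin3, bin3(rec$predicted_count))
  expect_identical(rec$true_bin3, bin3(rec$true_count))
  sch <- attr(rec, "fine_scheme")
  expect_identical(rec$true_bin_fine, assign_bin(rec$true_count, sch))
})
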
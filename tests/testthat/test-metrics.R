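# Evaluation metrics: overlap metrics by pixel enumeration, surface metrics
# against an all-pairs nearest-neighbour oracle, aggregation identities.

sq_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

test_that("dice / voe / ravd match pixel enumeration and conventions", {
  a <- sq_mask(5, 5, 2:4, 2:4)
  b <- sq_mask(5, 5, 2:4, 3:5) # shifted by one column: overlap 6 of 9
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 2 * 6 / 18, tolerance = 1e-12)
  expect_equal(dice(sq_mask(5, 5, 1, 1), sq_mask(5, 5, 5, 5)), 0)
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)

  expect_equal(voe(a, a), 0)
  expect_equal(voe(a, b), 1 - 6 / 12, tolerance = 1e-12)
  expect_equal(voe(sq_mask(5, 5, 1, 1), sq_mask(5, 5, 5, 5)), 1)
  expect_equal(voe(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)

  big <- sq_mask(6, 6, 1:5, 1:2) # 10 pixels
  expect_equal(ravd(big, big), 0)
  expect_equal(ravd(big, sq_mask(6, 6, 1:6, 1:2)), 0.2) # 12 pixels
  expect_equal(ravd(big, sq_mask(6, 6, 1:4, 1:2)), 0.2) # 8 pixels (unsigned)
  expect_warning(r <- ravd(matrix(FALSE, 2, 2), big[1:2, 1:2]), "undefined")
  expect_true(is.na(r))
  expect_error(dice(a, sq_mask(4, 4, 1, 1)), "share a shape")
})

test_that("dpc and dg follow the per-case and pooled definitions", {
  a9 <- sq_mask(5, 5, 2:4, 2:4)
  b9 <- sq_mask(5, 5, 2:4, 3:5) # dice 2/3
  a1 <- sq_mask(5, 5, 1, 1)
  cases <- list(list(a = a9, b = b9), list(a = a1, b = a1))
  expect_equal(dpc(cases), (2 / 3 + 1) / 2, tolerance = 1e-12)
  # pooled: 2 * (6 + 1) / (9 + 9 + 1 + 1) = 0.7
  expect_equal(dg(cases), 0.7, tolerance = 1e-12)
  one <- list(list(a = a9, b = b9))
  expect_equal(dpc(one), dg(one), tolerance = 1e-12)
  expect_error(dpc(list()), "at least one")
  # DG lies between the extreme per-case Dice values
  ds <- vapply(cases, function(cs) dice(cs$a, cs$b), 0)
  expect_gte(dg(cases), min(ds))
  expect_lte(dg(cases), max(ds))
})

test_that("assd / hd95: identical masks, single-pixel pairs, spacing", {
  a <- sq_mask(8, 8, 3:5, 3:5)
  expect_equal(assd(a, a), 0)
  expect_equal(hd95(a, a), 0)
  p1 <- sq_mask(8, 8, 2, 2)
  p2 <- sq_mask(8, 8, 2, 5) # 3 px apart
  expect_equal(assd(p1, p2), 3)
  expect_equal(hd95(p1, p2), 3)
  # anisotropic spacing scales physical distances
  bm1 <- binary_mask(p1, spacing = c(1, 2))
  bm2 <- binary_mask(p2, spacing = c(1, 2))
  expect_equal(assd(bm1, bm2), 6)
  expect_warning(r <- assd(a, matrix(FALSE, 8, 8)), "empty mask")
  expect_true(is.na(r))
})

test_that("surface metrics agree with the all-pairs oracle on 50 random masks", {
  set.seed(40)
  n_checked <- 0
  while (n_checked < 50) {
    a <- random_mask(16, 16, p = runif(1, 0.2, 0.5))
    b <- random_mask(16, 16, p = runif(1, 0.2, 0.5))
    if (!any(a) || !any(b)) next
    n_checked <- n_checked + 1
    sp <- sample(c(0.5, 0.7676, 1), 1)
    d_ab <- allpairs_directed(a, b, sp)
    d_ba <- allpairs_directed(b, a, sp)
    want_assd <- (mean(d_ab) + mean(d_ba)) / 2
    want_hd95 <- as.numeric(quantile(c(d_ab, d_ba), 0.95, type = 7))
    expect_lt(abs(assd(binary_mask(a, sp), binary_mask(b, sp)) - want_assd), 1e-9)
    expect_lt(abs(hd95(binary_mask(a, sp), binary_mask(b, sp)) - want_hd95), 1e-9)
  }
})

test_that("3D surface metrics use face-connectivity and 3D distances", {
  a <- array(FALSE, c(6, 6, 3))
  a[3:4, 3:4, 2] <- TRUE
  b <- array(FALSE, c(6, 6, 3))
  b[3:4, 3:4, 3] <- TRUE
  sp <- c(1, 1, 2.5)
  d_ab <- allpairs_directed(a, b, sp)
  d_ba <- allpairs_directed(b, a, sp)
  expect_equal(assd(binary_mask(a, sp), binary_mask(b, sp)),
               (mean(d_ab) + mean(d_ba)) / 2, tolerance = 1e-9)
})

test_that("metric symmetries and the dice/voe identity hold", {
  set.seed(41)
  for (i in 1:25) {
    a <- random_mask(12, 12)
    b <- random_mask(12, 12)
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(voe(a, b), voe(b, a))
    d <- dice(a, b)
    expect_equal(voe(a, b), 1 - d / (2 - d), tolerance = 1e-12)
    if (any(a) && any(b)) {
      expect_equal(assd(a, b), assd(b, a), tolerance = 1e-12)
      expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-12)
    }
  }
})

test_that("extract_class_masks follows the label convention", {
  lab <- matrix(0L, 3, 3)
  lab[1, 1] <- 1L
  lab[2, 2] <- 2L
  lv <- extract_class_masks(array(lab, c(3, 3)), "liver")
  tm <- extract_class_masks(array(lab, c(3, 3)), "tumor")
  expect_equal(sum(lv$data), 2) # tumor counts toward liver
  expect_equal(sum(tm$data), 1)
  zero <- array(0L, c(4, 4))
  expect_equal(sum(extract_class_masks(zero, "liver")$data), 0)
  expect_error(extract_class_masks(array(3L, c(2, 2)), "liver"), "values in")
})

test_that("metric_report aggregates per case and class", {
  set.seed(42)
  lab1 <- array(0L, c(2, 8, 8))
  lab1[, 3:6, 3:6] <- 1L
  lab1[, 4:5, 4:5] <- 2L
  lab2 <- lab1
  lab2[, , 1] <- 0L
  rep <- metric_report(list(lab1, lab1), list(lab1, lab2), spacing = 1)
  expect_equal(nrow(rep$per_case), 4L) # 2 cases x 2 classes
  expect_equal(rep$aggregate$dpc[rep$aggregate$class == "tumor"], 1)
  # dpc equals the mean of per-case dice
  for (cl in c("liver", "tumor")) {
    sub <- rep$per_case[rep$per_case$class == cl, ]
    expect_equal(mean(sub$dice), rep$aggregate$dpc[rep$aggregate$class == cl])
  }
  tmp <- tempfile(fileext = ".csv")
  tmpj <- tempfile(fileext = ".json")
  write_metric_report(rep, csv = tmp, json = tmpj)
  expect_true(file.exists(tmp) && file.exists(tmpj))
  back <- utils::read.csv(tmp)
  expect_true(all(c("per_case", "aggregate") %in% back$section))
})

test_that("ablation_deltas subtracts variant aggregates from the full model", {
  full <- data.frame(method = "full", dpc = 0.9, dg = 0.8)
  variants <- data.frame(method = c("v1", "v2"), dpc = c(0.85, 0.7),
                         dg = c(0.75, 0.6))
  d <- ablation_deltas(full, variants, metrics = c("dpc", "dg"))
  expect_equal(d$dpc, c(0.05, 0.2), tolerance = 1e-12)
  expect_equal(d$dg, c(0.05, 0.2), tolerance = 1e-12)
})
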
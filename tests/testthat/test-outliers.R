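subs_for <- function(values, window = "E1") {
  as_submissions(data.frame(
    code = sprintf("L%02dP1", seq_along(values)), window = window,
    exposure_kBqm3h = values, u_k1_kBqm3h = pmax(1, 0.05 * values)))
}

test_that("fences match a brute-force quartile evaluation and flag only true outliers", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  rep <- iqr_outliers(subs_for(v), default_windows()$E1)
  q <- unname(quantile(v, c(0.25, 0.75), type = 7))
  expect_equal(rep$q1, q[1])
  expect_equal(rep$q3, q[2])
  expect_equal(rep$iqr, q[2] - q[1])
  expect_equal(rep$lower_fence, q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(rep$upper_fence, q[2] + 1.5 * (q[2] - q[1]))
  flagged_brute <- sprintf("L%02dP1", which(v < rep$lower_fence |
                                              v > rep$upper_fence))
  expect_equal(rep$outlier_codes, flagged_brute)
  expect_equal(rep$outlier_codes, "L10P1")
})

test_that("a tight set has no outliers and a value exactly on a fence is kept", {
  rep <- iqr_outliers(subs_for(1:5), default_windows()$E1)
  expect_equal(rep$outlier_codes, character(0))
  # construct a value landing exactly on the upper fence: strictly-outside rule
  v <- c(10, 20, 30, 40)
  q <- unname(quantile(v, c(0.25, 0.75), type = 7))
  fence <- q[2] + 1.5 * (q[2] - q[1])
  rep2 <- iqr_outliers(subs_for(c(v, fence)), default_windows()$E1)
  expect_false(sprintf("L%02dP1", 5) %in% rep2$outlier_codes)
})

test_that("flagging is invariant under permutation and positive affine maps", {
  set.seed(11)
  for (r in 1:20) {
    v <- c(rlnorm(15, 6, 0.2), rlnorm(2, 6, 0.2) * 3)
    a <- runif(1, 0.5, 4)
    b <- runif(1, 0, 100)
    w <- default_windows()$E1
    f0 <- sort(iqr_outliers(subs_for(v), w)$outlier_codes)
    perm <- sample(length(v))
    sp <- as_submissions(data.frame(
      code = sprintf("L%02dP1", perm), window = "E1",
      exposure_kBqm3h = v[perm], u_k1_kBqm3h = 1))
    expect_equal(sort(iqr_outliers(sp, w)$outlier_codes), f0)
    expect_equal(sort(iqr_outliers(subs_for(a * v + b), w)$outlier_codes), f0)
  }
})

test_that("re-screening after removal flags nothing inside the original box", {
  set.seed(21)
  for (r in 1:20) {
    v <- c(rnorm(20, 100, 8), 200, 250)
    w <- default_windows()$E1
    first <- iqr_outliers(subs_for(v), w)
    keep <- setdiff(sprintf("L%02dP1", seq_along(v)), first$outlier_codes)
    v_keep <- v[sprintf("L%02dP1", seq_along(v)) %in% keep]
    second <- iqr_outliers(subs_for(v_keep), w)
    newly <- second$outlier_codes
    if (length(newly)) {
      vals <- v_keep[match(newly, sprintf("L%02dP1", seq_along(v_keep)))]
      expect_true(all(vals < first$q1 | vals > first$q3))
    } else {
      succeed()
    }
  }
})

test_that("fewer than four results is an insufficient-data error", {
  expect_error(iqr_outliers(subs_for(1:3), default_windows()$E1),
               "fewer than 4")
})

test_that("the contaminated groups of a default campaign are exactly the flagged codes", {
  camp <- cached_campaign(1)
  rep <- iqr_outliers(camp$submissions, camp$windows$E1)
  expect_setequal(rep$outlier_codes, camp$truth$contaminated_codes)
})

test_that("winsorisation keeps the all-results consensus between the plain mean and the cleaned consensus", {
  for (s in 1:10) {
    camp <- cached_campaign(s)
    rows <- camp$submissions[camp$submissions$window == "E1", ]
    rep <- iqr_outliers(camp$submissions, camp$windows$E1)
    if (length(rep$outlier_codes) == 0) next
    plain_mean <- mean(rows$exposure_kBqm3h)
    lo <- min(plain_mean, rep$e_ref_without_outliers)
    hi <- max(plain_mean, rep$e_ref_without_outliers)
    expect_gte(rep$e_ref_all, lo)
    expect_lte(rep$e_ref_all, hi)
  }
})

test_that("sensitivity check compares the two consensus variants at 2 combined sigma", {
  camp <- cached_campaign(1)
  rep <- iqr_outliers(camp$submissions, camp$windows$E1)
  expect_true(sensitivity_check(rep)) # mirrors the campaign-scale finding
  forced <- rep
  forced$e_ref_without_outliers <- rep$e_ref_all +
    10 * sqrt(rep$u_e_ref_all^2 + rep$u_e_ref_without_outliers^2)
  expect_false(sensitivity_check(forced))
  same <- rep
  same$e_ref_without_outliers <- rep$e_ref_all
  expect_true(sensitivity_check(same))
})
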
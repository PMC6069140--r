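test_that("the packaged published table is complete and well formed", {
  tab <- published_wsv_table()
  expect_equal(nrow(tab), 119)
  expect_equal(anyDuplicated(tab$api_name), 0)
  expect_true(all(tab$total_uf >= 100 & tab$total_uf <= 30000))
  expect_equal(sum(tab$rsc == 0.2), 1)
  expect_equal(tab$api_name[tab$rsc == 0.2], "Ibuprofen")
})

test_that("recomputation matches the published values for at least 115 of 119 rows", {
  report <- validate_published()
  expect_equal(report$n_records, 119)
  expect_gte(report$n_match, 115)
  expect_true(only_known_discrepancies(report))
  # frozen list and observed mismatches coincide exactly
  expect_setequal(report$discrepancies$api_name,
                  known_discrepancies()$table3$api_name)
})

test_that("spot-checked rows reproduce exactly", {
  report <- validate_published()
  rec <- report$records
  spot <- c("Gabapentin", "Digoxin", "Amoxicillin", "Ibuprofen",
            "Levothyroxine", "Demeclocycline", "Tetracycline", "Warfarin",
            "Metformin", "Ranitidine", "Lomefloxacin")
  expect_true(all(spot %in% rec$api_name))
  expect_true(all(rec$match[rec$api_name %in% spot]))
  gaba <- rec[rec$api_name == "Gabapentin", ]
  expect_identical(gaba$srfd_computed, 0.11)
  expect_identical(gaba$wsv_computed, 300)
  digo <- rec[rec$api_name == "Digoxin", ]
  expect_identical(digo$srfd_computed, 0.00000016)
  expect_identical(digo$wsv_computed, 0.0004)
})

test_that("a perturbed copy of the table is flagged", {
  tab <- published_wsv_table()
  tab$wsv_ug_L[tab$api_name == "Gabapentin"] <- 301
  report <- validate_published(tab)
  expect_true("Gabapentin" %in% report$discrepancies$api_name)
  expect_false(only_known_discrepancies(report))
})

test_that("schema violations name the offending row", {
  tab <- published_wsv_table()
  tab$ltd_mg_kg_d[5] <- -1
  expect_error(validate_published(tab), tab$api_name[5])
  tab2 <- published_wsv_table()
  tab2$total_uf[7] <- 200   # off the half-log lattice
  expect_error(validate_published(tab2), "lattice")
})

test_that("aggregate statistics reproduce the published ranges", {
  s <- aggregate_stats()
  expect_equal(s$n, 119)
  expect_equal(s$ltd_min, 0.0013)
  expect_equal(s$ltd_max, 25)
  expect_equal(s$wsv_min, 0.0004)
  expect_equal(s$total_uf_min, 100)
  expect_equal(s$total_uf_max, 30000)
  expect_equal(s$srfd_min, 0.00000016)
  expect_identical(aggregate_stats(published_wsv_table()[0, ]), list())
  one <- aggregate_stats(published_wsv_table()[1, ])
  expect_equal(one$ltd_min, one$ltd_max)
})

test_that("protection ratios reproduce the published comparison", {
  expect_equal(protection_ratio(100, 0.4), 250)
  expect_equal(protection_ratio(40, 0.9), 44)
  expect_equal(protection_ratio(5, 5), 1)
  expect_error(protection_ratio(-1, 5))
  hbg <- published_hbg_table()
  expect_equal(nrow(hbg), 6)
  consistent <- hbg[!hbg$inconsistent_as_printed, ]
  expect_equal(protection_ratio(consistent$hbg_ug_L, consistent$wsv_ug_L),
               consistent$protection_printed)
})

test_that("inconsistent published comparison rows are flagged, not repaired", {
  hbg <- published_hbg_table()
  flagged <- hbg$api_name[hbg$inconsistent_as_printed]
  expect_true(any(grepl("Acetaminophen", flagged)))
  expect_true("17a-Ethinylestradiol" %in% flagged)
  expect_true("Venlafaxine" %in% flagged)
  # the frozen file records a computed value for each flagged row
  kd <- known_discrepancies()
  expect_setequal(kd$table4$api_name, flagged)
  expect_true(all(is.finite(kd$table4$computed)))
})

test_that("detections are screened with strict exceedance and full accounting", {
  detections <- data.frame(
    analyte = c("Hydrochlorothiazide", "Gabapentin", "unknown-compound",
                "by-casrn"),
    casrn = c(NA, NA, NA, "66357-35-5"),   # ranitidine via CASRN
    concentration_ug_L = c(0.0571, 1, 0.5, 0.1),
    stringsAsFactors = FALSE)
  ctx <- contextualize_detections(detections)
  expect_equal(nrow(ctx$screened) + nrow(ctx$unmatched), nrow(detections))
  expect_equal(ctx$unmatched$analyte, "unknown-compound")

  hctz <- ctx$screened[ctx$screened$analyte == "Hydrochlorothiazide", ]
  expect_true(hctz$exceeds)
  expect_equal(hctz$ratio, 1.4)
  gaba <- ctx$screened[ctx$screened$analyte == "Gabapentin", ]
  expect_false(gaba$exceeds)
  expect_true("by-casrn" %in% ctx$screened$analyte)

  # a concentration exactly at the screening value does not exceed it
  at_wsv <- data.frame(analyte = "Gabapentin", concentration_ug_L = 300)
  ctx2 <- contextualize_detections(at_wsv)
  expect_false(ctx2$screened$exceeds)
  expect_equal(ctx2$screened$ratio, 1)

  bad <- data.frame(analyte = "Gabapentin", concentration_ug_L = -2)
  expect_error(contextualize_detections(bad), "nonnegative")
})
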
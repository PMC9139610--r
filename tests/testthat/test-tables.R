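test_that("the embedded summaries regenerate the published between-group F rows", {
  t1 <- between_group_table_from_summary(printed_summaries("rings"))
  expect_equal(t1$region_label, paste0("R", 1:5))
  expect_equal(round(t1$f_stat, 2), c(43.13, 23.16, 10.45, 7.72, 15.06))
  expect_equal(unique(t1$df_within), 43L)
  expect_true(all(t1$significant))

  t3 <- between_group_table_from_summary(printed_summaries("sectors"))
  expect_equal(round(t3$f_stat, 2), c(43.13, 16.78, 12.16, 12.88, 15.66))

  t5 <- between_group_table_from_summary(printed_summaries("etdrs"))
  named <- stats::setNames(round(t5$f_stat, 2), t5$region_label)
  expect_equal(named[["T 5-10"]], 17.92)
  expect_equal(named[["T 10-20"]], 18.9)
  expect_equal(named[["N 10-20"]], 19.74)
  expect_equal(named[["I 10-20"]], 16.24)
})

test_that("within-group tables use the study's degrees of freedom", {
  w_ctl <- within_group_table_from_summary(printed_summaries("rings"),
                                           "rings", "control")
  expect_equal(nrow(w_ctl), 10L)
  expect_equal(unique(w_ctl$df_within), 48L)
  r12 <- w_ctl[w_ctl$region_a == "R1" & w_ctl$region_b == "R2", ]
  expect_equal(round(r12$f_stat, 2), 170.33)
  w_case <- within_group_table_from_summary(printed_summaries("rings"),
                                            "rings", "case")
  expect_equal(unique(w_case$df_within), 38L)
  expect_equal(round(w_case$f_stat[w_case$region_a == "R1" &
                                     w_case$region_b == "R2"], 2), 67.19)
  # ETDRS adds the 10-20 vs 5-10 same-label column
  w_e <- within_group_table_from_summary(printed_summaries("etdrs"),
                                         "etdrs", "control")
  ecc <- w_e[w_e$comparison == "eccentricity", ]
  expect_equal(nrow(ecc), 4L)
  expect_equal(round(ecc$f_stat[ecc$region_a == "S 10-20"], 2), 249.35)
  # within-band pairs never cross eccentricity bands
  within <- w_e[w_e$comparison == "within", ]
  same_band <- mapply(function(a, b) {
    sub(".* ", "", a) == sub(".* ", "", b)
  }, within$region_a, within$region_b)
  expect_true(all(same_band))
})

test_that("a region lacking one group is an error from raw tables", {
  coh <- generate_cohort(cohort_spec(n_control = 3, n_case = 2, seed = 3))
  rad <- build_rad_table(coh, "rings")
  expect_error(between_group_table(rad[rad$group == "control", ], "rings"),
               "Both groups")
  expect_error(within_group_table(rad[rad$group == "control", ], "rings", "case"),
               "not present")
  # and the raw path agrees with the summary path on its own summaries
  bt <- between_group_table(rad, "rings")
  summ <- mfphnr:::.rad_to_summaries(rad, "rings")
  bt2 <- between_group_table_from_summary(summ)
  expect_equal(bt$f_stat, bt2$f_stat, tolerance = 1e-12)
})

test_that("region_means extracts the canonical fitting order", {
  y <- region_means(printed_summaries("sectors"), "sectors", "control")
  expect_equal(names(y), c("ST", "SN", "IN", "IT"))
  expect_equal(unname(y), c(7.208, 6.868, 6.888, 7.036))
  ye <- region_means(printed_summaries("etdrs"), "etdrs", "case", "10-20")
  expect_equal(unname(ye), c(6.357, 5.690, 5.657, 5.119))
  expect_error(region_means(printed_summaries("etdrs"), "etdrs", "case"),
               "ecc_band")
})

test_that("the printed-statistics ledger flags exactly the known misprints", {
  v <- verify_printed_statistics()
  # every between-group cell of the ring and sector tables agrees
  t13 <- v[grepl("^table [13] F", v$quantity), ]
  expect_equal(nrow(t13), 10L)
  expect_true(all(t13$agrees))
  # the six linear fits, the control exponential fit and the power n agree
  expect_true(all(v$agrees[grepl("linear r", v$quantity)]))
  expect_true(v$agrees[v$quantity == "ring exponential r^2" &
                         v$group == "control"])
  expect_true(v$agrees[v$quantity == "power analysis n per group"])
  # known internally inconsistent printed cells recompute differently:
  # the case-group exponential r^2 and a block of within-table misprints
  expect_false(v$agrees[v$quantity == "ring exponential r^2" &
                          v$group == "case"])
  t5 <- v[grepl("^table 5 F", v$quantity), ]
  expect_equal(sum(!t5$agrees), 1L)  # the printed Nasal 5-10 cell
  expect_false(t5$agrees[grepl("N 5-10", t5$quantity)])
  # overall: the ledger covers all printed quantities and most agree
  expect_equal(nrow(v), 19 + 20 + 12 + 24 + 8 + 8 + 1)
  expect_gte(sum(v$agrees), 70)
})
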
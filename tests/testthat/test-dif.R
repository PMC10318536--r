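test_that("identical residual distributions across levels give F ~ 0", {
  rm <- sim_rm(150, 911)
  p <- suppressWarnings(estimate_item_parameters(rm))
  # duplicate every person; factor = copy id -> identical residuals per level
  both <- response_matrix(rbind(unclass(rm), unclass(rm)), attr(rm, "item_max"))
  f <- rep(c("a", "b"), each = nrow(rm))
  rep <- suppressWarnings(dif_analysis(both, p, factors = data.frame(copy = f)))
  expect_lt(max(rep$F_main), 1e-10)
  expect_false(any(rep$uniform_dif))
})

test_that("injected uniform DIF is flagged on the seeded item (2 replicates)", {
  hits <- 0
  for (s in 1:2) {
    cfg <- pure_config(1000, 920 + s,
                       dif = list(item = 5L, factor = "gender",
                                  level = "male", shift = 0.5))
    rec <- simulate_dataset(cfg)
    rm <- to_response_matrix(rec)
    p <- suppressWarnings(estimate_item_parameters(rm))
    rep <- suppressWarnings(dif_analysis(rm, p, factors = data.frame(gender = rec$gender)))
    hits <- hits + rep$uniform_dif[rep$item == "BBS05"]
  }
  expect_equal(hits, 2)
})

test_that("the Bonferroni cut-off scales with items x factors x 2", {
  rec <- simulate_dataset(pure_config(300, 931))
  rm <- to_response_matrix(rec)
  p <- suppressWarnings(estimate_item_parameters(rm))
  rep <- suppressWarnings(dif_analysis(rm, p,
    factors = rec[, c("gender", "age", "duration", "course")]))
  expect_equal(attr(rep, "bonferroni_cutoff"), 0.05 / (14 * 4 * 2))
  expect_equal(nrow(rep), 14 * 4)
  # numeric factors are discretized, all rows produced
  expect_setequal(unique(rep$factor), c("gender", "age", "duration", "course"))
})

test_that("small factor levels are dropped with a warning", {
  rec <- simulate_dataset(pure_config(120, 941))
  rm <- to_response_matrix(rec)
  p <- suppressWarnings(estimate_item_parameters(rm))
  f <- as.character(rec$gender); f[1:3] <- "other"
  w <- testthat::capture_warnings(
    dif_analysis(rm, p, factors = data.frame(g = f), min_level_n = 10))
  expect_true(any(grepl("dropped", w)))
})

test_that("split impact: null is negligible, strong testlet DIF is not", {
  # null: no injected DIF, testlet-level split
  rec <- simulate_dataset(pure_config(1000, 951))
  trm <- build_testlets(to_response_matrix(rec), testlet_spec())
  pt <- suppressWarnings(estimate_item_parameters(trm))
  si <- suppressWarnings(dif_split_impact(trm, pt, item = 1, factor = rec$gender))
  expect_lt(si$d, 0.05)
  expect_true(si$negligible)
  # identical estimates pre/post: d exactly 0 (degenerate single-level guard)
  expect_error(dif_split_impact(trm, pt, item = 1, factor = rep("x", nrow(trm))),
               "two levels")
  # 1-logit uniform DIF on the high-information testlet
  dl <- bbsms:::default_item_locations()
  t1 <- bbsms:::DEFAULT_TESTLETS == 1
  dl2 <- dl; dl2[t1] <- dl2[t1] + 1; dl2 <- dl2 - mean(dl2)
  f_rec <- as.data.frame(simulate_dataset(pure_config(660, 952)))
  m_rec <- as.data.frame(simulate_dataset(pure_config(340, 953, item_locations = dl2)))
  f_rec$gender <- "female"; m_rec$gender <- "male"
  rec2 <- rbind(f_rec, m_rec); rec2$patient_id <- seq_len(nrow(rec2))
  trm2 <- build_testlets(to_response_matrix(as_bbs_records(rec2)), testlet_spec())
  pt2 <- suppressWarnings(estimate_item_parameters(trm2))
  si2 <- suppressWarnings(dif_split_impact(trm2, pt2, item = 1, factor = rec2$gender))
  expect_gte(si2$d, 0.2)
  expect_false(si2$negligible)
})
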
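# Dataset-level analyses: functional-group tables, cross-property
# correlation, substituent scans and optimization suggestions.

test_that("functional-group table equals brute-force aggregation", {
  fm <- fixture_small_model()
  data <- fm$data$test[1:30, ]
  catal <- load_fg_catalog()
  tab <- fg_attribution_table(fm$model, data, catalog = catal, min_count = 1L)

  # oracle: loop molecules x matches, attribute each occurrence separately
  vals <- list()
  for (i in seq_len(nrow(data))) {
    rec <- molecule_record(data$id[i], data$smiles[i])
    for (sub in functional_group_matches(rec, catal)) {
      row <- attribute(fm$model, rec, sub)
      vals[[sub$name]] <- c(vals[[sub$name]], row$attribution)
    }
  }
  expect_setequal(tab$fg_name, names(vals))
  for (g in tab$fg_name) {
    expect_equal(tab$mean_attribution[tab$fg_name == g], mean(vals[[g]]),
                 tolerance = 1e-10)
    expect_equal(tab$count[tab$fg_name == g], length(vals[[g]]))
  }
  # sorted by mean attribution
  expect_false(is.unsorted(tab$mean_attribution))
})

test_that("occurrence threshold excludes rare groups monotonically", {
  fm <- fixture_small_model()
  data <- fm$data$test[1:30, ]
  t1 <- fg_attribution_table(fm$model, data, min_count = 1L)
  t5 <- fg_attribution_table(fm$model, data, min_count = 5L)
  t10 <- fg_attribution_table(fm$model, data, min_count = 10L)
  expect_true(all(t5$fg_name %in% t1$fg_name))
  expect_true(all(t10$fg_name %in% t5$fg_name))
  expect_true(all(t10$count >= 10L))
  expect_false(any(t1$fg_name[t1$count < 5] %in% t5$fg_name))
})

test_that("zero-weight consensus gives all-zero group means", {
  model <- zero_weights(fixture_untrained_model(n_models = 1L))
  lib <- fixture_library()
  tab <- fg_attribution_table(model, data.frame(id = 1:10,
                                                smiles = lib$smiles[1:10]),
                              min_count = 1L)
  expect_true(all(tab$mean_attribution == 0))
})

test_that("cross-property correlation reproduces closed-form Spearman", {
  ta <- data.frame(fg_name = c("a", "b", "c", "d", "e"),
                   mean_attribution = c(0.5, 0.1, -0.2, 0.9, -0.7))
  self <- cross_property_correlation(ta, ta)
  expect_equal(self$rho, 1)
  flip <- ta; flip$mean_attribution <- -ta$mean_attribution
  expect_equal(cross_property_correlation(ta, flip)$rho, -1)

  # 5-row toy: hand-computed ranks a(4) b(3) c(2) d(5) e(1) vs
  # b-table ranks; rho = 1 - 6*sum(d^2)/(n(n^2-1))
  tb <- data.frame(fg_name = c("a", "b", "c", "d", "e"),
                   mean_attribution = c(0.3, 0.4, -0.1, 0.8, -0.9))
  ra <- rank(ta$mean_attribution); rb <- rank(tb$mean_attribution)
  rho_hand <- 1 - 6 * sum((ra - rb)^2) / (5 * 24)
  expect_equal(cross_property_correlation(ta, tb)$rho, rho_hand)

  expect_error(cross_property_correlation(ta[1:2, ], tb), "at least 3")
})

test_that("substituent scan grafts candidates at a terminal site", {
  fm <- fixture_small_model()
  catal <- load_fg_catalog()
  tab <- fg_attribution_table(fm$model, fm$data$test[1:30, ],
                              catalog = catal, min_count = 1L)
  # toluene-like fixture molecule: scan the methyl site
  smi <- "Cc1ccc(CCO)cc1"
  site <- functional_group_matches(smi, catal)
  site <- Filter(function(s) s$name == "methyl", site)[[1]]
  scan <- substituent_scan(fm$model, smi, site, tab, catal)
  expect_true(all(c("candidate", "smiles", "prediction",
                    "mean_attribution") %in% names(scan)))
  expect_gte(nrow(scan), 5L)
  # replacing methyl by methyl returns the canonical input
  self <- scan[scan$candidate == "methyl", ]
  expect_equal(self$smiles, canonical_smiles(smi))
  expect_equal(self$prediction, predict(fm$model, smi), tolerance = 1e-10)
  # every edited molecule parses
  for (s in scan$smiles) expect_s3_class(parse_smiles(s), "sme_mol")
})

test_that("substituent scan rejects multi-attachment sites", {
  fm <- fixture_small_model()
  tab <- data.frame(fg_name = "hydroxyl", mean_attribution = 1)
  # an in-chain ether is not a terminal group
  site <- substructure("FUNCTIONAL_GROUP", 1L, "ether")
  expect_error(suppressWarnings(substituent_scan(fm$model, "COC", site, tab)),
               "terminal|attachment|graft")
})

test_that("optimization suggestions follow the sign rules and ranking", {
  stats <- data.frame(
    fg_name = c("methyl", "hydroxyl", "nitro"),
    mean_attribution = c(0.4, -0.3, 0.1))
  # molecule contains methyl only
  sug <- optimization_suggestions("CCC", stats, direction = "decrease")
  expect_true(all(sug$expected_change == "decrease"))
  add <- sug[sug$strategy == "add_negative", ]
  expect_equal(add$candidate_fg, "hydroxyl")
  rem <- sug[sug$strategy == "remove_positive", ]
  expect_equal(rem$site_fg, "methyl")
  rep_ <- sug[sug$strategy == "replace_more_negative", ]
  expect_true(all(rep_$site_fg == "methyl"))
  # replace methyl(+0.4) by hydroxyl(-0.3): |delta| = 0.7 outranks
  # remove methyl (0.4)
  expect_equal(sug$strategy[1], "replace_more_negative")
  expect_equal(sug$score[1], 0.7)

  # molecule with no catalog groups -> only additions
  sug2 <- optimization_suggestions("C1CCCCC1", stats, direction = "decrease")
  expect_true(all(sug2$strategy == "add_negative"))

  # increase mirrors the signs
  sug3 <- optimization_suggestions("CCC", stats, direction = "increase")
  expect_true("nitro" %in%
                sug3$candidate_fg[sug3$strategy == "add_negative"])
})
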
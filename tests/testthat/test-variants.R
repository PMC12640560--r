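test_that("the variant family is exactly the six admissible combinations", {
  vs <- all_variants()
  expect_length(vs, 6)
  expect_error(variant_spec("DF", "native", "structure"), "inadmissible")
  for (id in names(vs))
    expect_equal(variant_id(parse_variant(id)), id)
  expect_setequal(names(vs),
                  c("DF-Native-Pathway", "DF-Normative-Pathway",
                    "VTA-Native-Pathway", "VTA-Native-Structure",
                    "VTA-Normative-Pathway", "VTA-Normative-Structure"))
})

test_that("single-factor contrasts enumerate exactly the one-factor pairs", {
  ct <- single_factor_contrasts()
  expect_equal(nrow(ct), 7)
  expect_equal(sum(ct$factor == "space"), 3)
  expect_equal(sum(ct$factor == "method"), 2)
  expect_equal(sum(ct$factor == "representation"), 2)
  # independent check: each listed pair differs in exactly one field
  for (i in seq_len(nrow(ct))) {
    a <- parse_variant(ct$variant_a[i])
    b <- parse_variant(ct$variant_b[i])
    ndiff <- (a$method != b$method) + (a$space != b$space) +
      (a$representation != b$representation)
    expect_equal(ndiff, 1)
  }
})

test_that("all four activation metrics are monotone in stimulation amplitude", {
  fx <- fixture_tiny_cohort()
  subj <- fx$cohort[[1]]
  # amplitude sweep on a fixed monopolar configuration
  sweep_settings <- enumerate_settings(subj$lead,
                                       list(monopolar = list(1L),
                                            amplitudes_mA = c(1, 2, 3, 4, 5)))
  s2 <- subj
  s2$settings <- sweep_settings
  opts <- tiny_opts()
  for (v in all_variants()) {
    act <- run_variant(s2, v, opts, fx$cache)
    for (tg in c("HDP", "CSBT")) {
      vals <- act$value[act$target == tg]
      expect_true(all(diff(vals) >= 0),
                  label = paste(variant_id(v), tg, "monotone"))
    }
  }
})

test_that("an identity warp makes normative and native variants agree", {
  fx <- fixture_tiny_cohort()
  subj <- fx$cohort[[2]]
  g <- subj$deformation$grid
  subj$deformation <- deformation_field(g, array(0, c(g$dim, 3)))
  subj$uid <- "identity-warp-case"
  opts <- tiny_opts()
  cache <- new.env(parent = emptyenv())
  for (pair in list(c("DF-Native-Pathway", "DF-Normative-Pathway"),
                    c("VTA-Native-Pathway", "VTA-Normative-Pathway"),
                    c("VTA-Native-Structure", "VTA-Normative-Structure"))) {
    a <- run_variant(subj, pair[1], opts, cache)
    b <- run_variant(subj, pair[2], opts, cache)
    if (grepl("Structure", pair[1])) {
      # native uses the vertex metric, normative the voxel metric: compare
      # only that both respond, not numerically
      expect_equal(nrow(a), nrow(b))
    } else {
      expect_equal(a$value, b$value, tolerance = 1e-6)
    }
  }
})

test_that("run_variant output is tidy, bounded and deterministic", {
  fx <- fixture_tiny_cohort()
  subj <- fx$cohort[[1]]
  act <- run_variant(subj, "VTA-Native-Pathway", tiny_opts(), fx$cache)
  expect_setequal(unique(act$target), c("HDP", "CSBT"))
  expect_equal(nrow(act), 2 * nrow(subj$settings))
  expect_true(all(act$value >= 0 & act$value <= 100))
  act2 <- run_variant(subj, "VTA-Native-Pathway", tiny_opts(), fx$cache)
  expect_identical(act, act2)
  # normative requires a deformation field
  s2 <- subj
  s2$deformation <- NULL
  s2$uid <- "no-warp"
  expect_error(run_variant(s2, "DF-Normative-Pathway", tiny_opts()),
               "deformation")
})

test_that("comparison reports carry medians, paired tests and exclusions", {
  fx <- fixture_tiny_cohort()
  acts <- run_cohort(fx$cohort,
                     all_variants()[c("DF-Native-Pathway",
                                      "VTA-Normative-Structure")],
                     tiny_opts(), fx$cache)
  rep <- compare_variants(
    acts, fx$cohort,
    contrasts = tibble::tibble(factor = "conventional",
                               variant_a = "DF-Native-Pathway",
                               variant_b = "VTA-Normative-Structure"))
  expect_s3_class(rep, "dbs_comparison")
  expect_true(all(rep$summary$median >= 0 & rep$summary$median <= 1))
  expect_equal(sort(unique(rep$tests$target)), c("CSBT", "HDP"))
  expect_identical(tidy(rep), rep$r2)
  expect_identical(glance(rep), rep$summary)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_error(
    compare_variants(acts, fx$cohort,
                     contrasts = tibble::tibble(variant_a = "DF-Native-Pathway",
                                                variant_b = "Nope")),
    "not present")
})

test_that("directional grouping restricts the settings analysed", {
  fx <- fixture_tiny_cohort()
  co <- fx$cohort
  has_dir <- vapply(co, function(s) any(s$settings$directional), logical(1))
  acts <- run_cohort(co, all_variants()["DF-Native-Pathway"], tiny_opts(),
                     fx$cache)
  if (any(has_dir)) {
    rep_d <- compare_variants(acts, co, contrasts = NULL,
                              group = "directional")
    expect_lte(sum(rep_d$r2$n_settings),
               sum(vapply(co, function(s) 2 * sum(s$settings$directional),
                          numeric(1))))
  }
  rep_n <- compare_variants(acts, co, contrasts = NULL,
                            group = "nondirectional")
  expect_true(all(rep_n$r2$n_settings <=
                    vapply(co, function(s) sum(!s$settings$directional),
                           numeric(1))[1] + 1e9))
})
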
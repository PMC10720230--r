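test_that("summarizePopulation counts diagnoses and the multimorbidity split", {
  co <- makeCohort(list(c("I10", "I63"), "K29", c("E11", "E78", "I10"), "N39"),
                   ages = c(45L, 45L, 50L, 50L),
                   sexes = c("male", "female", "male", "female"))
  s <- summarizePopulation(co)
  expect_equal(s$n_inpatients, 4L)
  expect_equal(s$n_diagnoses, 7L)
  expect_equal(s$per_capita, 7 / 4)
  expect_equal(s$multimorbidity_count, 2L)
  expect_equal(s$multimorbidity_pct, 50)
  expect_equal(s$single_pct + s$multimorbidity_pct, 100)
  expect_equal(unname(s$multimorbidity_by_sex["male"]), 100)
  expect_equal(unname(s$multimorbidity_by_sex["female"]), 0)
  expect_error(summarizePopulation(makeCohort(list())), "empty")
})

test_that("every record with one code means zero multimorbidity and per-capita 1", {
  co <- makeCohort(rep(list("I10"), 10))
  s <- summarizePopulation(co)
  expect_equal(s$multimorbidity_pct, 0)
  expect_equal(s$per_capita, 1)
})

test_that("per-capita by chapter sums to overall per-capita at each age", {
  co <- makeCohort(rep(list(c("I10", "I63")), 10), ages = rep(45L, 10))
  s <- summarizePopulation(co)
  expect_equal(s$per_capita, 2)
  byac <- s$per_capita_by_age_chapter
  expect_equal(sum(byac$per_capita[byac$chapter == 9]), 2)
  expect_equal(sum(byac$per_capita[byac$chapter != 9]), 0)
  # mixed chapters and ages: exact conservation
  set.seed(14)
  catalog <- c("A15", "C34", "E78", "I10", "J45", "K29", "M54", "N39")
  codes <- replicate(120, sample(catalog, sample(1:4, 1)), simplify = FALSE)
  ages <- sample(40:59, 120, replace = TRUE)
  co2 <- makeCohort(codes, ages = ages)
  s2 <- summarizePopulation(co2)
  byac2 <- s2$per_capita_by_age_chapter
  for (a in unique(byac2$age)) {
    total <- s2$per_capita_by_age$per_capita[s2$per_capita_by_age$age == a]
    expect_equal(sum(byac2$per_capita[byac2$age == a]), total)
  }
})

test_that("complexityRatio is the edge-count ratio", {
  a <- netFromEdges(randomEdges(10, 0.5, seed = 1))
  expect_equal(complexityRatio(a, a), 1)
  b <- netFromEdges(cbind("X00", "Y00"))
  expect_equal(complexityRatio(a, b), nEdges(a))
  empty <- buildNetwork(data.frame()[0, ])
  expect_error(complexityRatio(a, empty), "non-empty")
})

test_that("topKComorbidities ranks by frequency, then OR, then pair", {
  pats <- data.frame(code_i = c("A00", "B00", "C00", "D00"),
                     code_j = c("A01", "B01", "C01", "D01"),
                     frequency = c(5, 3, 3, 1),
                     odds_ratio = c(1.5, 2.0, 4.0, 9.0))
  top2 <- topKComorbidities(pats, k = 2)
  expect_equal(top2$code_i, c("A00", "C00"))  # freq 5, then the OR-4 tie-winner
  expect_equal(nrow(topKComorbidities(pats, k = 0)), 0L)
  expect_warning(all4 <- topKComorbidities(pats, k = 10), "only")
  expect_equal(nrow(all4), 4L)
})

test_that("overlapAnalysis is plain set algebra on canonical keys", {
  a <- data.frame(code_i = c("A00", "B00", "C00"), code_j = c("A01", "B01", "C01"))
  b <- data.frame(code_i = c("B00", "C00", "D00"), code_j = c("B01", "C01", "D01"))
  ov <- overlapAnalysis(a, b)
  expect_equal(ov$shared, c("B00+B01", "C00+C01"))
  expect_equal(ov$specific_a, "A00+A01")
  expect_equal(ov$specific_b, "D00+D01")
  # disjoint and identical lists
  expect_equal(overlapAnalysis(a[1, ], b[3, ])$shared, character(0))
  same <- overlapAnalysis(a, a)
  expect_equal(same$specific_a, character(0))
  expect_equal(same$specific_b, character(0))
  # plain character vectors (hub lists) work too
  expect_equal(overlapAnalysis(c("I10", "E78"), c("E78", "K29"))$shared, "E78")
})

test_that("runFullComparison on identical cohorts gives ratio 1 and full overlap", {
  dis <- setNames(rep(0.15, 8), sprintf("D%02d", 1:8))
  pairs <- data.frame(code_i = c("D01", "D03", "D05"),
                      code_j = c("D02", "D04", "D06"),
                      psi = c(6, 6, 6))
  gen <- generateCohort(syntheticCohortConfig(8000, dis, pairs, seed = 31))
  ca <- gen$cohort; ca@label <- "popA"
  cb <- gen$cohort; cb@label <- "popB"
  cmp <- suppressWarnings(runFullComparison(ca, cb, k_hubs = 4, k_top = 3))
  expect_equal(unname(cmp$complexity_ratios["overall"]), 1)
  expect_equal(cmp$top_overlap$overall$specific_a, character(0))
  expect_equal(cmp$hub_overlap$overall$specific_b, character(0))
  # ratio of selected edge counts matches a direct recount
  ea <- sum(cmp$reports$popA_overall$patterns$selected)
  eb <- sum(cmp$reports$popB_overall$patterns$selected)
  expect_equal(unname(cmp$complexity_ratios["overall"]), ea / eb)
})

test_that("runFullComparison writes a consistent, recountable artifact set", {
  dis <- setNames(rep(0.2, 6), sprintf("D%02d", 1:6))
  pairs <- data.frame(code_i = c("D01", "D03"), code_j = c("D02", "D04"),
                      psi = c(7, 5))
  a <- generateCohort(syntheticCohortConfig(6000, dis, pairs, seed = 41))$cohort
  a@label <- "popA"
  b <- generateCohort(syntheticCohortConfig(6000, dis, pairs[1, ], seed = 42))$cohort
  b@label <- "popB"
  dir <- withr::local_tempdir()
  cmp <- suppressWarnings(runFullComparison(a, b, k_hubs = 3, out_dir = dir))
  j <- jsonlite::read_json(file.path(dir, "comparison_report.json"),
                           simplifyVector = TRUE)
  # every reported number is recomputable from the exported tables
  pa <- read.csv(file.path(dir, "popA_overall_patterns.csv"))
  pb <- read.csv(file.path(dir, "popB_overall_patterns.csv"))
  expect_equal(j$complexity_ratios$overall,
               round(sum(pa$selected) / sum(pb$selected), 2))
  ea <- read.csv(file.path(dir, "popA_overall_edges.csv"))
  expect_equal(nrow(ea), sum(pa$selected))
  expect_equal(j$summaries$popA_overall$n_inpatients, nInpatients(a))
  expect_equal(j$summaries$popA_overall$multimorbidity_pct,
               round(summarizePopulation(a)$multimorbidity_pct, 2))
  # deterministic rerun: byte-identical report
  dir2 <- withr::local_tempdir()
  suppressWarnings(runFullComparison(a, b, k_hubs = 3, out_dir = dir2))
  expect_identical(readLines(file.path(dir, "comparison_report.json")),
                   readLines(file.path(dir2, "comparison_report.json")))
})
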
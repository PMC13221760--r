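makeRecords <- function(years = 2018:2023, perYear = 10) {
  do.call(rbind, lapply(years, function(y)
    data.frame(id = sprintf("h%03d@%d", seq_len(perYear), y),
               hybrid = sprintf("h%03d", seq_len(perYear)),
               year = y, stringsAsFactors = FALSE)))
}

test_that("leave-one-year-out builds one fold per year partitioning the data", {
  rec <- makeRecords()
  plan <- planLoyo(rec)
  expect_equal(length(folds(plan)), 6)
  tested <- unlist(lapply(folds(plan), `[[`, "test"))
  expect_setequal(tested, rec$id)
  expect_equal(anyDuplicated(tested), 0)
  for (f in folds(plan)) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), rec$id)
  }
  expect_equal(length(folds(planLoyo(makeRecords(2020:2021)))), 2)
  expect_error(planLoyo(makeRecords(2020)), "2 years")
})

test_that("rolling window advances one year at a time until the last year", {
  rec <- makeRecords()
  plan <- planRollingWindow(rec, window = 3)
  expect_equal(length(folds(plan)), 3)
  metas <- lapply(folds(plan), `[[`, "meta")
  expect_equal(vapply(metas, `[[`, numeric(1), "test_year"), c(2021, 2022, 2023))
  expect_equal(metas[[1]]$train_years, 2018:2020)
  expect_equal(length(folds(planRollingWindow(rec, window = 5))), 1)
  expect_error(planRollingWindow(rec, window = 6), "at least")
  expect_error(planRollingWindow(makeRecords(c(2018, 2020, 2021, 2022))),
               "consecutive")
  expect_silent(planRollingWindow(makeRecords(c(2018, 2020, 2021, 2022)),
                                  window = 2, allowGaps = TRUE))
})

test_that("repeated k-fold partitions are balanced, complete and seeded", {
  ids <- sprintf("x%02d", 1:11)
  plan <- planKfold(ids, k = 5, reps = 10, seed = 4)
  expect_equal(length(folds(plan)), 50)
  sizes <- vapply(folds(plan)[1:5], function(f) length(f$test), numeric(1))
  expect_setequal(sizes, c(3, 2, 2, 2, 2))
  for (r in 1:10) {
    rep_folds <- folds(plan)[((r - 1) * 5 + 1):(r * 5)]
    expect_setequal(unlist(lapply(rep_folds, `[[`, "test")), ids)
  }
  plan2 <- planKfold(ids, k = 5, reps = 10, seed = 4)
  expect_identical(folds(plan), folds(plan2))
  expect_error(planKfold(ids[1:3], k = 5), "fewer ids")
})

makeTesterData <- function() {
  lines <- sprintf("L%02d", 1:12)
  testers <- sprintf("T%02d", 1:10)
  ped <- expand.grid(parent1 = lines, parent2 = testers,
                     stringsAsFactors = FALSE)
  ped <- data.frame(hybrid = paste0(ped$parent1, "x", ped$parent2), ped)
  # testers T01..T10 evaluated in 2023; a subset also in 2020
  rec23 <- data.frame(hybrid = ped$hybrid, year = 2023L)
  rec20 <- data.frame(hybrid = ped$hybrid[ped$parent2 %in% c("T01", "T02")],
                      year = 2020L)
  rec <- rbind(rec20, rec23)
  rec$id <- paste0(rec$hybrid, "@", rec$year)
  list(ped = ped, rec = rec)
}

test_that("tester CV0 keeps held-out testers' earlier records in training", {
  d <- makeTesterData()
  plan <- planTesterCV0(d$ped, d$rec, testYear = 2023, frac = 0.2, reps = 10,
                        seed = 2)
  expect_equal(length(folds(plan)), 50)  # 5 disjoint groups x 10 reps
  tester <- setNames(d$ped$parent2, d$ped$hybrid)
  for (r in 1:2) {
    rep_folds <- folds(plan)[((r - 1) * 5 + 1):(r * 5)]
    groups <- lapply(rep_folds, function(f) f$meta$tester_group)
    expect_setequal(unlist(groups), sprintf("T%02d", 1:10))
    expect_equal(anyDuplicated(unlist(groups)), 0)
    for (f in rep_folds) {
      expect_length(intersect(f$train, f$test), 0)
      # all training records predate the test year
      expect_true(all(d$rec$year[match(f$train, d$rec$id)] < 2023))
      # the held-out testers' 2020 hybrids ARE in training when available
      held <- f$meta$tester_group
      early <- d$rec$id[d$rec$year == 2020 & tester[d$rec$hybrid] %in% held]
      expect_true(all(early %in% f$train))
    }
  }
})

test_that("tester CV00 excludes held-out testers across all years", {
  d <- makeTesterData()
  cv0 <- planTesterCV0(d$ped, d$rec, frac = 0.2, reps = 3, seed = 2)
  cv00 <- planTesterCV00(d$ped, d$rec, frac = 0.2, reps = 3, seed = 2)
  tester <- setNames(d$ped$parent2, d$ped$hybrid)
  for (i in seq_along(folds(cv00))) {
    f <- folds(cv00)[[i]]
    held <- f$meta$tester_group
    trainTesters <- tester[d$rec$hybrid[match(f$train, d$rec$id)]]
    expect_length(intersect(trainTesters, held), 0)
    # CV00 training is a subset of the matching CV0 training
    expect_true(all(f$train %in% folds(cv0)[[i]]$train))
    expect_identical(f$test, folds(cv0)[[i]]$test)
  }
})

test_that("tester schemes validate their inputs", {
  d <- makeTesterData()
  expect_error(planTesterCV0(d$ped, d$rec, testYear = 1999), "absent")
  ped2 <- d$ped[-1, ]
  expect_error(planTesterCV0(ped2, d$rec), "tester unknown")
  few <- d$rec[d$rec$hybrid %in% d$ped$hybrid[d$ped$parent2 %in%
                                                c("T01", "T02")], ]
  expect_error(planTesterCV0(d$ped, few, frac = 0.2), "at least 5 testers")
})
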
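.as_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "year") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicated record ids")
  records
}

#' Leave-one-year-out fold plan
#'
#' One fold per distinct year: the fold's test set is that year's records,
#' its training set all other years. Test sets partition the records.
#'
#' @param records data.frame with columns `id` (record id) and `year`.
#' @return a [FoldPlan-class] with scheme `"loyo"`.
#' @export
planLoyo <- function(records) {
  records <- .as_records(records)
  years <- sort(unique(records$year))
  if (length(years) < 2) stop("leave-one-year-out requires at least 2 years")
  folds <- lapply(years, function(yr) {
    list(train = records$id[records$year != yr],
         test = records$id[records$year == yr],
         meta = list(test_year = yr))
  })
  new("FoldPlan", scheme = "loyo", folds = folds)
}

#' Rolling-window fold plan
#'
#' A fixed window of `window` consecutive years trains, the following year
#' tests; the window advances one year at a time until the last year.
#'
#' @param records data.frame with `id` and `year`.
#' @param window training window length in years (default 3).
#' @param allowGaps tolerate missing calendar years in the sequence.
#' @return a [FoldPlan-class] with scheme `"rolling_window"`.
#' @export
planRollingWindow <- function(records, window = 3L, allowGaps = FALSE) {
  records <- .as_records(records)
  years <- sort(unique(records$year))
  if (!allowGaps && !all(diff(years) == 1))
    stop("years are not consecutive; use allowGaps = TRUE to permit gaps")
  if (length(years) < window + 1)
    stop("need at least window + 1 = ", window + 1, " years")
  starts <- seq_len(length(years) - window)
  folds <- lapply(starts, function(s) {
    trainYears <- years[s:(s + window - 1)]
    testYear <- years[s + window]
    list(train = records$id[records$year %in% trainYears],
         test = records$id[records$year == testYear],
         meta = list(train_years = trainYears, test_year = testYear))
  })
  new("FoldPlan", scheme = "rolling_window", folds = folds)
}

#' Repeated k-fold plan
#'
#' Per repetition, ids are randomly partitioned into k folds whose sizes
#' differ by at most one; each id is tested exactly once per repetition.
#'
#' @param ids record ids.
#' @param k folds per repetition (default 5).
#' @param reps repetitions (default 10).
#' @param seed integer seed; identical seeds give identical partitions.
#' @return a [FoldPlan-class] with scheme `"kfold"` and `k * reps` folds.
#' @export
planKfold <- function(ids, k = 5L, reps = 10L, seed = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated ids")
  n <- length(ids)
  if (n < k) stop("fewer ids than folds")
  set.seed(seed)
  folds <- list()
  for (r in seq_len(reps)) {
    assign <- rep_len(seq_len(k), n)[sample.int(n)]
    for (f in seq_len(k)) {
      folds[[length(folds) + 1L]] <-
        list(train = ids[assign != f], test = ids[assign == f],
             meta = list(repetition = r, fold = f, seed = seed))
    }
  }
  new("FoldPlan", scheme = "kfold", folds = folds)
}

.tester_groups <- function(testers, frac) {
  g <- ceiling(1 / frac)
  if (length(testers) < g)
    stop("need at least ", g, " testers in the test year for frac = ", frac)
  split(testers, rep_len(seq_len(g), length(testers)))
}

.plan_tester <- function(pedigree, records, testYear, frac, reps, seed,
                         excludeAcrossYears) {
  records <- .as_records(records)
  if (!"hybrid" %in% names(records)) stop("records need a 'hybrid' column")
  if (!testYear %in% records$year) stop("test year ", testYear, " absent")
  tester <- setNames(pedigree$parent2, pedigree$hybrid)
  testRecs <- records[records$year == testYear, ]
  unknown <- setdiff(unique(testRecs$hybrid), names(tester))
  if (length(unknown))
    stop("tester unknown for test-year hybrid(s): ",
         paste(head(unknown, 5), collapse = ", "))
  recTester <- tester[records$hybrid]
  yearTesters <- sort(unique(tester[testRecs$hybrid]))
  set.seed(seed)
  folds <- list()
  for (r in seq_len(reps)) {
    groups <- .tester_groups(sample(yearTesters), frac)
    for (g in seq_along(groups)) {
      held <- groups[[g]]
      testIds <- records$id[records$year == testYear & recTester %in% held]
      trainSel <- records$year < testYear
      if (excludeAcrossYears) trainSel <- trainSel & !(recTester %in% held)
      folds[[length(folds) + 1L]] <-
        list(train = records$id[trainSel], test = testIds,
             meta = list(repetition = r, tester_group = held,
                         test_year = testYear))
    }
  }
  folds
}

#' Tester CV0 fold plan: known testers in a new year
#'
#' Per repetition, the testers evaluated in `testYear` are partitioned into
#' `ceiling(1/frac)` disjoint groups. Each fold tests the `testYear` hybrids
#' whose tester is in the held-out group; training uses all records from
#' earlier years — including the held-out testers' own earlier hybrids
#' (the testers are "known"). Test-year hybrids with other testers are not
#' added to training.
#'
#' @param pedigree data.frame (hybrid, parent1, parent2); parent2 is the
#'   tester.
#' @param records data.frame with `id`, `hybrid`, `year`.
#' @param testYear year to predict (default 2023).
#' @param frac fraction of testers held out per fold (default 0.2).
#' @param reps repetitions (default 10).
#' @param seed integer seed.
#' @return a [FoldPlan-class] with scheme `"tester_cv0"`.
#' @export
planTesterCV0 <- function(pedigree, records, testYear = 2023L, frac = 0.2,
                          reps = 10L, seed = 1L) {
  folds <- .plan_tester(pedigree, records, testYear, frac, reps, seed,
                        excludeAcrossYears = FALSE)
  new("FoldPlan", scheme = "tester_cv0", folds = folds)
}

#' Tester CV00 fold plan: unknown testers in a new year
#'
#' As [planTesterCV0()], but every record (any year) whose tester is in the
#' held-out group is removed from training, so the held-out testers are
#' entirely unseen.
#'
#' @inheritParams planTesterCV0
#' @return a [FoldPlan-class] with scheme `"tester_cv00"`.
#' @export
planTesterCV00 <- function(pedigree, records, testYear = 2023L, frac = 0.2,
                           reps = 10L, seed = 1L) {
  folds <- .plan_tester(pedigree, records, testYear, frac, reps, seed,
                        excludeAcrossYears = TRUE)
  new("FoldPlan", scheme = "tester_cv00", folds = folds)
}
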
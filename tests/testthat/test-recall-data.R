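test_that("reading a delimited recall table maps rows to records and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,day,gender,years,item,value",
               "A,1,male,35,energy,1500",
               "A,2,male,35,energy,1800.5",
               "A,3,male,35,energy,1650"), path)
  schema <- c(person_id = "id", day_index = "day", sex = "gender",
              age = "years", component = "item", amount = "value")
  ds <- read_recalls(path, schema = schema)
  expect_s3_class(ds, "recall_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$amount, c(1500, 1800.5, 1650))
  expect_equal(ds$day_of_week[ds$day_index == 1], "Mon")
  expect_false(any(ds$is_weekend))

  out <- withr::local_tempfile(fileext = ".csv")
  write_recalls(ds, out)
  back <- read_recalls(out)
  expect_equal(as.data.frame(back), as.data.frame(ds))
})

test_that("malformed and invalid tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,day_index,sex,age,component,amount",
               "A,1,male,35,energy,-5"), path)
  expect_error(read_recalls(path), class = "recall_validation_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,day_index,sex,age,component,amount",
               "A,1,male,35,energy,abc",
               "A,2,male,35,energy,100"), path2)
  expect_error(read_recalls(path2), class = "recall_parse_error")

  expect_error(read_recalls(tempfile()), class = "recall_parse_error")
  expect_error(
    recall_dataset(data.frame(person_id = "A", day_index = 1, sex = "male",
                              age = 30)),
    class = "recall_parse_error")
})

test_that("exclusion filters drop implausible energy and incomplete persons", {
  mk <- function(pid, sex, energies) {
    data.frame(person_id = pid, day_index = seq_along(energies), sex = sex,
               age = 40, component = "energy", amount = energies,
               stringsAsFactors = FALSE)
  }
  ds <- recall_dataset(rbind(
    mk("man_high", "male", c(rep(2000, 27), 5000)),   # one day above 4200
    mk("woman_ok", "female", rep(2000, 28)),          # inside bounds
    mk("few", "male", rep(2000, 22)),                 # 22 recalls: excluded
    mk("just_enough", "male", rep(2000, 23))          # 23 recalls: retained
  ))
  res <- apply_exclusions(ds)
  kept <- unique(res$dataset$person_id)
  expect_setequal(kept, c("woman_ok", "just_enough"))
  expect_setequal(res$report$person_id, c("man_high", "few"))
  expect_equal(res$report$reason[res$report$person_id == "man_high"],
               "implausible_energy")
  # boundary values are plausible (range is inclusive)
  ds2 <- recall_dataset(mk("edge_man", "male", c(rep(600, 14), rep(4200, 14))))
  expect_equal(unique(apply_exclusions(ds2)$dataset$person_id), "edge_man")
  expect_error(apply_exclusions(recall_dataset(
    mk("A", "male", rep(10, 28)) |> transform(component = "iron"))),
    class = "config_error")
})

test_that("window extraction picks the first 2-weekday + 1-weekend run and honours availability", {
  ds <- toy_dataset(list(A = rep(100, 7)), days = 1:7)
  w <- extract_window(ds, "winter")
  expect_setequal(w$day_of_week, c("Thu", "Fri", "Sat"))

  # person missing Friday keeps the 2-day subset
  ds2 <- toy_dataset(list(A = rep(100, 6)), days = c(1:4, 6:7))
  w2 <- extract_window(ds2, "winter")
  expect_setequal(w2$day_of_week, c("Thu", "Sat"))

  # configured rule wraps Sunday into the same week's Monday and Tuesday
  w3 <- extract_window(ds, "winter", start_day = "Sun")
  expect_setequal(w3$day_of_week, c("Sun", "Mon", "Tue"))

  # output is always a subset of the person's days in that season
  expect_true(all(w$day_index %in% ds$day_index[ds$season == "winter"]))
  expect_lte(length(unique(w$day_index)), 3)

  # person with no recalls in the season is absent and logged
  ds3 <- toy_dataset(list(A = rep(100, 7), B = rep(50, 7)),
                     days = 1:7)
  ds3 <- recall_dataset(as.data.frame(ds3)[!(ds3$person_id == "B"), ])
  w4 <- extract_window(ds3, "winter")
  expect_false("B" %in% w4$person_id)
})

test_that("component descriptives handle degenerate variance structures", {
  # all persons constant at c > 0
  ds <- toy_dataset(list(A = rep(5, 4), B = rep(5, 4)))
  p <- describe_component(ds, "energy")
  expect_equal(p$cv_percent, 0)
  expect_equal(p$variance_ratio, 0)
  expect_equal(p$pct_zero, 0)

  # between-person signal only: VR 0
  ds2 <- toy_dataset(list(A = c(10, 10), B = c(20, 20)))
  p2 <- describe_component(ds2, "energy")
  expect_gt(p2$var_between, 0)
  expect_equal(p2$var_within, 0)
  expect_equal(p2$variance_ratio, 0)

  expect_error(describe_component(ds, "iron"), class = "lookup_error")
})

test_that("descriptives are invariant to record order and person relabeling", {
  sim <- sim_episodic()
  ds <- sim$dataset
  p1 <- describe_component(ds, "meats")

  shuffled <- as.data.frame(ds)[sample(nrow(ds)), ]
  p2 <- describe_component(recall_dataset(shuffled), "meats")
  expect_equal(p2[c("mean", "sd", "variance_ratio", "pct_zero", "spearman_r")],
               p1[c("mean", "sd", "variance_ratio", "pct_zero", "spearman_r")])

  relabeled <- as.data.frame(ds)
  relabeled$person_id <- paste0("X", relabeled$person_id)
  p3 <- describe_component(recall_dataset(relabeled), "meats")
  expect_equal(p3$percentiles, p1$percentiles)
  expect_equal(p3$variance_ratio, p1$variance_ratio)
})

test_that("the reference standard is the mean of all available recalls", {
  ds <- toy_dataset(list(A = rep(1500, 28), B = c(0, 0, 30, 30)),
                    days = 1:28)
  ds <- recall_dataset(as.data.frame(ds)[!(ds$person_id == "B" & ds$day_index > 4), ])
  tr <- true_usual_intake(ds, "energy")
  expect_equal(tr$estimate[tr$person_id == "A"], 1500)
  expect_equal(tr$estimate[tr$person_id == "B"], 15)

  # round-trips through the serialised form
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(mean(back$estimate), mean(tr$estimate))
})
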
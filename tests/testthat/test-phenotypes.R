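hd_fixture <- function(drinks, sexes) {
  completed <- unique(drinks[c("subject", "occasion")])
  sex <- data.frame(subject = names(sexes), sex = unname(sexes))
  assign_heavy_drinking(drinks, completed, sex)
}

test_that("heavy drinking classification follows the weekly-unit rule", {
  drinks <- data.frame(
    subject = c("m1", "m1", "m1", "f1", "f2", "f2", "f2", "f2", "f2"),
    occasion = c(1, 1, 1, 1, 1, 1, 1, 1, 1),
    beverage = c("beer/cider", "beer/cider", "beer/cider",
                 "white wine", "white wine", "spirits", "spirits",
                 "spirits", "spirits"),
    count = c(1, 1, 1, 2, 0, 2, 1, 1, 1))
  out <- hd_fixture(drinks, c(m1 = "male", f1 = "female", f2 = "female"))
  # male, 3 beers: daily 7.8, weekly 54.6 > 50 -> case
  expect_equal(as.character(out$status[out$subject == "m1"]), "case")
  expect_equal(out$max_weekly[out$subject == "m1"], 7 * 3 * 2.6)
  # female, 2 white wines: weekly 21 < 35 -> control
  expect_equal(as.character(out$status[out$subject == "f1"]), "control")
  # female, 5 spirits: weekly exactly 35 -> control ("exceeded" is strict)
  expect_equal(out$max_weekly[out$subject == "f2"], 35)
  expect_equal(as.character(out$status[out$subject == "f2"]), "control")
})

test_that("completion drives missing status; any exceeding occasion makes a case", {
  drinks <- data.frame(subject = c("a", "a"), occasion = c(1, 2),
                       beverage = "beer/cider", count = c(1, 4))
  completed <- data.frame(subject = c("a", "a", "b"), occasion = c(1, 2, 1))
  sex <- data.frame(subject = c("a", "b", "c"),
                    sex = c("male", "male", "female"))
  out <- assign_heavy_drinking(drinks, completed, sex)
  # occasion 2 (4 beers, weekly 72.8) exceeds even though occasion 1 did not
  expect_equal(as.character(out$status), c("case", "control", "missing"))
  expect_true(is.na(out$max_weekly[out$subject == "c"]))
  expect_error(
    assign_heavy_drinking(
      data.frame(subject = "a", occasion = 1, beverage = "mead", count = 1),
      completed, sex),
    "mead")
})

test_that("heavy drinking statuses partition subjects and are monotone in counts", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 30
    subj <- paste0("s", 1:n)
    sex <- data.frame(subject = subj,
                      sex = sample(c("male", "female"), n, replace = TRUE))
    done <- sample(subj, 20)
    drinks <- data.frame(
      subject = sample(done, 40, replace = TRUE), occasion = 1,
      beverage = sample(names(drink_unit_table()), 40, replace = TRUE),
      count = rpois(40, 2))
    completed <- data.frame(subject = done, occasion = 1)
    out <- assign_heavy_drinking(drinks, completed, sex)
    expect_equal(nrow(out), n)
    expect_false(any(is.na(out$status)))          # exactly one status each
    expect_setequal(out$subject[out$status == "missing"], setdiff(subj, done))
    # bump one random reported count: never case -> control
    before <- out$status[match(drinks$subject[1], out$subject)]
    drinks2 <- drinks
    drinks2$count[1] <- drinks2$count[1] + 5
    after <- assign_heavy_drinking(drinks2, completed, sex)
    after1 <- after$status[match(drinks$subject[1], after$subject)]
    if (before == "case") expect_equal(as.character(after1), "case")
  }
})

pd_fixture <- function(n = 1, ...) {
  base <- data.frame(subject = paste0("s", seq_len(n)), completed = TRUE,
                     dependent = "No", concerned = "No", addicted = "No",
                     failed_expectations = "Never", memory_blackout = "Never",
                     guilt = "Never", morning_drinking = "Never",
                     unable_to_stop = "Never", stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("problem drinking cases arise from Yes answers or monthly-plus frequencies", {
  expect_equal(as.character(assign_problem_drinking(
    pd_fixture(addicted = "Yes"))$status), "case")
  expect_equal(as.character(assign_problem_drinking(pd_fixture())$status),
               "control")
  expect_equal(as.character(assign_problem_drinking(
    pd_fixture(guilt = "Monthly"))$status), "case")
  expect_equal(as.character(assign_problem_drinking(
    pd_fixture(guilt = "Less than monthly"))$status), "control")
  expect_equal(as.character(assign_problem_drinking(
    pd_fixture(morning_drinking = "Daily or almost daily"))$status), "case")
  expect_equal(as.character(assign_problem_drinking(
    pd_fixture(completed = FALSE))$status), "missing")
  expect_error(assign_problem_drinking(pd_fixture(guilt = "Sometimes")),
               "unknown frequency")
})

test_that("problem drinking statuses partition subjects under random answers", {
  set.seed(77)
  lv <- c("Never", "Less than monthly", "Monthly", "Weekly",
          "Daily or almost daily")
  for (rep in 1:10) {
    n <- 50
    resp <- pd_fixture(n)
    resp$completed <- runif(n) < 0.8
    for (cc in c("dependent", "concerned", "addicted")) {
      resp[[cc]] <- sample(c("Yes", "No", NA), n, replace = TRUE,
                           prob = c(0.1, 0.8, 0.1))
    }
    for (cc in c("failed_expectations", "memory_blackout", "guilt",
                 "morning_drinking", "unable_to_stop")) {
      resp[[cc]] <- sample(c(lv, NA), n, replace = TRUE)
    }
    out <- assign_problem_drinking(resp)
    expect_equal(nrow(out), n)
    expect_false(any(is.na(out$status)))
    expect_true(all(out$status[!resp$completed] == "missing"))
    st <- phenotype_status(out)
    expect_identical(unname(is.na(st)), !resp$completed)
  }
})
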
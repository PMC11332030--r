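make_consistency_data <- function(n = 20, conditions = "c1", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(conditions, function(cond) {
    t1 <- runif(n, 0.1, 0.9)
    data.frame(participant = paste0("P", seq_len(n)), condition = cond,
               trial1 = t1, trial2 = t1)
  }))
}

test_that("zero-residual data flags nobody", {
  d <- make_consistency_data(20)
  d$trial2 <- d$trial1 + rnorm(20, 0, 1e-6)
  rep <- consistency_screen(d)
  expect_length(rep$flagged_participants, 0)
})

test_that("a constructed 10-sigma outlier (and only them) is flagged", {
  set.seed(2)
  n <- 20
  t1 <- runif(n, 0.1, 0.9)
  resid_sd <- 0.02
  t2 <- t1 + rnorm(n, 0, resid_sd)
  t2[7] <- t1[7] + 10 * resid_sd * 10   # displaced by 10x the residual SD
  d <- data.frame(participant = paste0("P", seq_len(n)), condition = "c1",
                  trial1 = t1, trial2 = t2)
  rep <- consistency_screen(d, level = 0.99)
  expect_equal(rep$flagged_participants, "P7")
})

test_that("flags are invariant to ordering and joint affine rescaling", {
  set.seed(3)
  n <- 24
  t1 <- runif(n)
  t2 <- 0.8 * t1 + rnorm(n, 0, 0.03)
  t2[5] <- t2[5] + 0.5
  d <- data.frame(participant = paste0("P", seq_len(n)), condition = "c1",
                  trial1 = t1, trial2 = t2)
  base <- consistency_screen(d)
  shuffled <- consistency_screen(d[sample(n), ])
  expect_setequal(base$flagged_participants,
                  shuffled$flagged_participants)
  d2 <- transform(d, trial1 = 10 * trial1 - 3, trial2 = 10 * trial2 - 3)
  expect_setequal(consistency_screen(d2)$flagged_participants,
                  base$flagged_participants)
})

test_that("widening the interval never adds flags", {
  set.seed(4)
  n <- 30
  t1 <- runif(n)
  t2 <- t1 + rnorm(n, 0, 0.05)
  d <- data.frame(participant = paste0("P", seq_len(n)), condition = "c1",
                  trial1 = t1, trial2 = t2)
  f90 <- consistency_screen(d, level = 0.90)$flagged_participants
  f99 <- consistency_screen(d, level = 0.99)$flagged_participants
  fhuge <- consistency_screen(d, level = 0.999999)$flagged_participants
  expect_true(all(f99 %in% f90))
  expect_true(all(fhuge %in% f99))
})

test_that("degenerate first-trial variance skips the condition", {
  d <- data.frame(participant = paste0("P", 1:5), condition = "c1",
                  trial1 = rep(0.5, 5), trial2 = runif(5))
  expect_warning(rep <- consistency_screen(d), "no variance")
  expect_length(rep$flagged_participants, 0)
})

make_responses <- function(acc_map, n_trials = 20) {
  # acc_map: named list participant -> named accuracy per cell
  cells <- expand.grid(stimulus = c("syllable", "tone"),
                       rate = c("slow", "fast"), stringsAsFactors = FALSE)
  do.call(rbind, lapply(names(acc_map), function(p) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      key <- paste(cells$stimulus[i], cells$rate[i], sep = "_")
      acc <- acc_map[[p]][[key]]
      if (is.null(acc)) return(NULL)
      n_ok <- round(acc * n_trials)
      data.frame(participant = p, stimulus = cells$stimulus[i],
                 rate = cells$rate[i],
                 correct = c(rep(TRUE, n_ok), rep(FALSE, n_trials - n_ok)))
    }))
  }))
}

test_that("chance screen excludes at-or-below-chance cells only", {
  all_cells <- function(a) setNames(as.list(rep(a, 4)),
                                    c("syllable_slow", "syllable_fast",
                                      "tone_slow", "tone_fast"))
  perfect <- all_cells(1.0)
  one_at_half <- perfect; one_at_half$tone_fast <- 0.5
  just_above <- perfect; just_above$tone_fast <- 0.55
  resp <- make_responses(list(P1 = perfect, P2 = one_at_half,
                              P3 = just_above))
  rep <- chance_screen(resp)
  expect_equal(rep$excluded, "P2")        # exactly 0.5 is "at or below"
  expect_length(rep$incomplete, 0)

  # missing cell -> incomplete, not excluded
  missing <- perfect; missing$tone_fast <- NULL
  rep2 <- chance_screen(make_responses(list(P1 = perfect, P4 = missing)))
  expect_equal(rep2$incomplete, "P4")
  expect_length(rep2$excluded, 0)
})

test_that("QC reports serialize to JSON", {
  d <- make_consistency_data(10)
  d$trial2 <- d$trial1 + rnorm(10, 0, 0.01)
  f <- withr::local_tempfile(fileext = ".json")
  write_qc_json(consistency_screen(d), f)
  x <- jsonlite::read_json(f)
  expect_equal(x$interval_level, 0.99)
})
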
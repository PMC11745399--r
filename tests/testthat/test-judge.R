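test_that("the prompt carries the record once, every criterion, and the JSON directive", {
  crit <- toy_criteria(c("population", "outcome"))
  record <- "Title: A study Abstract: Something quite specific."
  prompt <- build_prompt(record, crit)
  expect_equal(lengths(regmatches(prompt, gregexpr(record, prompt, fixed = TRUE))), 1L)
  expect_match(prompt, "population")
  expect_match(prompt, "outcome")
  expect_match(prompt, "JSON object")
  expect_match(prompt, "justification")

  # reordering criteria changes only the criterion block
  crit_rev <- toy_criteria(c("outcome", "population"))
  prompt_rev <- build_prompt(record, crit_rev)
  expect_false(identical(prompt, prompt_rev))
  expect_lt(regexpr("outcome", prompt_rev), regexpr("population", prompt_rev))

  expect_error(build_prompt(record, structure(data.frame(), class = c("criteria_set", "data.frame"))),
               class = "screenflow_config_error")
})

test_that("the shipped review configs load and the physiotherapy one lists 7 criteria", {
  dir <- system.file("extdata", "criteria", package = "screenflow")
  physio <- read_criteria(file.path(dir, "review1_physio.yaml"))
  expect_equal(nrow(physio), 7)
  prompt <- build_prompt("Title: t Abstract: a", physio)
  for (k in physio$key) expect_match(prompt, k, fixed = TRUE)
  neuro <- read_criteria(file.path(dir, "review2_neuro.yaml"))
  expect_equal(nrow(neuro), 5)
  digi <- read_criteria(file.path(dir, "review3_digihealth.yaml"))
  expect_equal(nrow(digi), 6)
})

test_that("the parser recovers JSON behind extraneous prose and normalizes string Booleans", {
  crit <- toy_criteria(c("population", "outcome"))
  raw <- paste0('Here is the output in the requested format: ',
                '{"population": {"value": "True", "justification": "looks right"}, ',
                '"outcome": {"value": false, "justification": "no costs"}}')
  v <- parse_verdicts(raw, crit)
  expect_true(v$population$value)
  expect_false(v$outcome$value)
  expect_equal(v$population$justification, "looks right")

  # bare Booleans and trailing prose also parse
  v2 <- parse_verdicts('{"population": true, "outcome": "False"} Hope that helps!', crit)
  expect_true(v2$population$value)
  expect_false(v2$outcome$value)
})

test_that("missing criteria are defaulted to false, never dropped", {
  crit <- toy_criteria(c("a", "b", "c"))
  v <- parse_verdicts('{"a": {"value": true, "justification": "x"}, "c": {"value": true, "justification": "y"}}', crit)
  expect_named(v, c("a", "b", "c"))
  expect_false(v$b$value)
  expect_match(v$b$justification, "defaulted")
})

test_that("parser totality: mutilated responses always yield a complete map or a parse error", {
  crit <- toy_criteria(c("alpha", "beta", "gamma"))
  base <- paste0('{"alpha": {"value": true, "justification": "j1"}, ',
                 '"beta": {"value": "False", "justification": "j2"}, ',
                 '"gamma": {"value": false, "justification": "j3"}}')
  set.seed(28)
  mutilate <- function(s) {
    op <- sample(4, 1)
    if (op == 1) paste0("Sure! Here you go: ", s)                       # prose prefix
    else if (op == 2) sub('"gamma".*$', "}", s)                          # drop a criterion
    else if (op == 3) gsub("true", '"True"', s, fixed = TRUE)            # string Booleans
    else paste0(substr(s, 1, nchar(s) - sample(5:20, 1)))                # truncation
  }
  for (i in 1:100) {
    mutant <- mutilate(base)
    out <- tryCatch(parse_verdicts(mutant, crit), screenflow_parse_error = function(e) "parse_error")
    if (identical(out, "parse_error")) succeed() else expect_named(out, crit$key)
  }
  expect_error(parse_verdicts("no structure here at all", crit),
               class = "screenflow_parse_error")
  expect_error(parse_verdicts("{broken json", crit), class = "screenflow_parse_error")
})

test_that("screening a record succeeds on the first attempt with a clean backend", {
  fx <- toy_simulation(n = 10)
  backend <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values)
  vs <- screen_record("rec-00001", fx$dataset$records$record_text[1],
                      fx$criteria, backend)
  expect_s3_class(vs, "verdict_set")
  expect_equal(vs$status, "ok")
  expect_equal(vs$attempts, 1L)
  expect_named(vs$verdicts, fx$criteria$key)
})

test_that("rate limits back off 2,4,8,16 seconds under an injected clock, then succeed", {
  fx <- toy_simulation(n = 10)
  backend <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values,
                          rate_limit_times = c("rec-00002" = 4L))
  slept <- numeric(0)
  vs <- screen_record("rec-00002", fx$dataset$records$record_text[2],
                      fx$criteria, backend, sleep_fn = function(s) slept <<- c(slept, s))
  expect_equal(vs$status, "ok")
  expect_equal(vs$attempts, 5L)
  expect_equal(slept, c(2, 4, 8, 16))
})

test_that("exhausted retries fail with class rate_limit; other errors fail immediately", {
  fx <- toy_simulation(n = 10)
  throttled <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values,
                            rate_limit_times = c("rec-00003" = 99L))
  slept <- numeric(0)
  vs <- screen_record("rec-00003", fx$dataset$records$record_text[3],
                      fx$criteria, throttled, sleep_fn = function(s) slept <<- c(slept, s))
  expect_equal(vs$status, "failed")
  expect_equal(vs$failure_class, "rate_limit")
  expect_equal(vs$attempts, 5L)
  expect_equal(slept, c(2, 4, 8, 16))

  hard <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values,
                       fail_ids = "rec-00004")
  vs2 <- screen_record("rec-00004", fx$dataset$records$record_text[4],
                       fx$criteria, hard, sleep_fn = function(s) stop("must not sleep"))
  expect_equal(vs2$status, "failed")
  expect_equal(vs2$failure_class, "other")
  expect_equal(vs2$attempts, 1L)

  garbled <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values,
                          garble_ids = "rec-00005")
  vs3 <- screen_record("rec-00005", fx$dataset$records$record_text[5],
                       fx$criteria, garbled)
  expect_equal(vs3$status, "failed")
  expect_equal(vs3$failure_class, "parse")
})

test_that("records can be screened through the exact-ID store", {
  fx <- toy_simulation(n = 10)
  idx <- embed_corpus(fx$dataset)
  backend <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values)
  vs <- screen_record("rec-00006", idx, fx$criteria, backend)
  expect_equal(vs$status, "ok")
  expect_error(screen_record("rec-99999", idx, fx$criteria, backend),
               class = "screenflow_not_found")
})

test_that("corpus screening partitions records into disjoint succeeded/missing sets", {
  fx <- toy_simulation(n = 10)
  clean <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values)
  res <- screen_corpus(fx$dataset, fx$criteria, clean)
  expect_length(res$succeeded, 10)
  expect_length(res$missing, 0)

  flaky <- mock_backend(fx$dataset, verdicts = fx$sim$matrix$values,
                        fail_ids = c("rec-00002", "rec-00007"))
  res2 <- screen_corpus(fx$dataset, fx$criteria, flaky)
  expect_length(res2$succeeded, 8)
  expect_length(res2$missing, 2)
  expect_length(intersect(names(res2$succeeded), names(res2$missing)), 0)
  expect_setequal(c(names(res2$succeeded), names(res2$missing)),
                  fx$dataset$records$record_id)
})

test_that("interrupted runs resume from the checkpoint and match a single pass", {
  fx <- toy_simulation(n = 50, seed = 5)
  make_backend <- function() mock_backend(fx$dataset, verdicts = fx$sim$matrix$values,
                                          fail_ids = c("rec-00013", "rec-00031"))
  oracle <- screen_corpus(fx$dataset, fx$criteria, make_backend())

  ckpt <- withr::local_tempdir()
  # simulate an interruption after 20 records by screening a truncated corpus
  partial <- fx$dataset
  partial$records <- partial$records[1:20, ]
  partial$preprocessed_total <- 20L
  screen_corpus(partial, fx$criteria, make_backend(), checkpoint_dir = ckpt,
                batch_size = 5)
  # disjointness holds in the persisted checkpoint itself
  state <- screenflow:::read_checkpoint(ckpt)
  expect_length(intersect(names(state$succeeded), names(state$missing)), 0)

  calls <- 0L
  inner <- make_backend()
  counting <- function(prompt) { calls <<- calls + 1L; inner(prompt) }
  resumed <- screen_corpus(fx$dataset, fx$criteria, counting,
                           checkpoint_dir = ckpt, batch_size = 5)
  # succeeded records from the first pass are not re-judged
  expect_lte(calls, 50 - length(state$succeeded) + length(state$missing))
  expect_setequal(names(resumed$succeeded), names(oracle$succeeded))
  expect_setequal(names(resumed$missing), names(oracle$missing))
  for (id in names(oracle$succeeded)) {
    expect_identical(resumed$succeeded[[id]]$verdicts, oracle$succeeded[[id]]$verdicts)
  }
})

test_that("a corrupt checkpoint refuses to resume and names the path", {
  fx <- toy_simulation(n = 10)
  ckpt <- withr::local_tempdir()
  writeLines(c('{"record_id": "rec-00001"', "not json at all"),
             file.path(ckpt, "checkpoint.jsonl"))
  err <- expect_error(
    screen_corpus(fx$dataset, fx$criteria,
                  mock_backend(fx$dataset, verdicts = fx$sim$matrix$values),
                  checkpoint_dir = ckpt),
    class = "screenflow_checkpoint_error")
  expect_match(conditionMessage(err), "checkpoint.jsonl", fixed = TRUE)
})

test_that("two full runs with the same mock backend produce identical verdict sets", {
  fx <- toy_simulation(n = 25, seed = 9)
  run <- function() {
    screen_corpus(fx$dataset, fx$criteria,
                  mock_backend(fx$dataset, verdicts = fx$sim$matrix$values,
                               prose_prefix = TRUE, string_booleans = TRUE))
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$succeeded, r2$succeeded)
  expect_identical(r1$missing, r2$missing)
})

test_that("verdicts persist as JSON lines and read back losslessly", {
  fx <- toy_simulation(n = 15, failure_rate = 0.2, seed = 12)
  res <- fx$sim$result
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_verdicts(res, path)
  back <- read_verdicts(path)
  expect_setequal(names(back$succeeded), names(res$succeeded))
  expect_setequal(names(back$missing), names(res$missing))
  id <- names(res$succeeded)[1]
  expect_identical(back$succeeded[[id]]$verdicts, res$succeeded[[id]]$verdicts)
})

test_that("configuration objects validate their invariants", {
  expect_error(judge_config(temperature = -1), class = "screenflow_config_error")
  expect_error(judge_config(top_p = 0), class = "screenflow_config_error")
  cfg <- judge_config()
  expect_equal(cfg$temperature, 0)
  expect_equal(cfg$top_p, 0.95)
  expect_equal(cfg$seed, 28L)
  expect_equal(cfg$context_window, 25000L)
  rp <- retry_policy()
  expect_equal(rp$max_attempts, 5L)
  expect_true(all(diff(rp$delay(1:4)) > 0))
  fx <- toy_simulation(n = 10)
  expect_error(screen_corpus(fx$dataset, fx$criteria, identity, concurrency_limit = 0),
               class = "screenflow_config_error")
})
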
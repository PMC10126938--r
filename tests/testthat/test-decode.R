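test_that("score aggregation sums per candidate within the budget", {
  codes <- rep(1:3, times = 2)
  reps <- rep(1:2, each = 3)
  scores <- c(0.9, 0.1, 0.1, 0.8, 0.2, 0.3)
  C1 <- aggregate_scores(scores, codes, reps, m = 1)
  expect_equal(unname(C1), c(0.9, 0.1, 0.1))
  expect_equal(unname(which.max(C1)), 1L)

  C2 <- aggregate_scores(c(0.6, 0.8), c(5, 5), c(1, 2), m = 2,
                         candidates = 5)
  expect_equal(unname(C2), 1.4)

  # all-equal scores tie; argmax falls to the lowest code index
  Ct <- aggregate_scores(rep(0.5, 6), codes, reps, m = 2)
  expect_equal(unname(which.max(Ct)), 1L)

  expect_error(aggregate_scores(scores, codes, reps, m = 1,
                                candidates = 1:4), "no flashes")
})

test_that("RCP character selection intersects row and column argmax", {
  rows <- c(0, 1, 0, 0, 0, 0)   # row 2
  cols <- c(0, 0, 0, 1, 0, 0)   # column 4
  expect_equal(select_character_rcp(rows, cols), "J")  # 10th symbol
  expect_equal(select_character_rcp(rep(1, 6), rep(1, 6)), "A")  # tie rule
  expect_equal(select_character_rcp(c(0, 0, 0, 0, 0, 1),
                                    c(0, 0, 0, 0, 0, 1)), "_")
  expect_error(select_character_rcp(rows[1:5], cols))
  expect_error(select_character_rcp(rows, cols, alphabet = LETTERS))
})

test_that("RSVP group selection is argmax with a deterministic tie rule", {
  expect_equal(select_group_rsvp(c(0, 0, 0, 0, 0, 0, 1, 0, 0)), 7L)
  expect_equal(select_group_rsvp(rep(1, 9)), 1L)
  expect_error(select_group_rsvp(rep(1, 8)))
})

test_that("perfect scores decode every character at every budget", {
  s <- make_rcp_session(n_characters = 4, n_repetitions = 6, snr_db = 0,
                        seed = 21)
  ep <- session_to_epochs(s, 0.3)
  scores <- as.numeric(ep$labels == 1L)
  dec <- decode_session(ep, scores, s$paradigm, s$truth,
                        budgets = c(1, 3, 6))
  expect_true(all(dec$accuracy_by_repetition$accuracy == 1))
  expect_true(all(dec$per_character == matrix(s$truth, 4, 3)))
})

test_that("selections are invariant to positive scaling and per-repetition shifts", {
  s <- make_rcp_session(n_characters = 3, n_repetitions = 5, snr_db = 0,
                        seed = 22)
  ep <- session_to_epochs(s, 0.3)
  scores <- stlfl:::with_seed(1, runif(length(ep$labels)))
  d1 <- decode_session(ep, scores, s$paradigm, s$truth)
  d2 <- decode_session(ep, 3.7 * scores, s$paradigm, s$truth)
  # constant added to every flash of a repetition adds equally to all
  # candidates of that repetition
  shift <- 0.9 * ep$repetition_index
  d3 <- decode_session(ep, scores + shift, s$paradigm, s$truth)
  expect_identical(d1$per_character, d2$per_character)
  expect_identical(d1$per_character, d3$per_character)
})

test_that("random scores decode at chance level", {
  p <- build_paradigm("RCP", n_repetitions = 5, seed = 31)
  n_char <- 400
  sched <- flash_schedule(p, n_char)
  truth <- stlfl:::with_seed(31, sample(p$alphabet, n_char, replace = TRUE))
  scores <- stlfl:::with_seed(32, rnorm(nrow(sched)))
  correct <- vapply(seq_len(n_char), function(ci) {
    idx <- which(sched$char_index == ci)
    rows <- idx[sched$code[idx] <= 6]
    cols <- idx[sched$code[idx] > 6]
    Cr <- aggregate_scores(scores[rows], sched$code[rows],
                           sched$repetition_index[rows], 5, 1:6)
    Cc <- aggregate_scores(scores[cols], sched$code[cols],
                           sched$repetition_index[cols], 5, 7:12)
    select_character_rcp(Cr, Cc, p$alphabet) == truth[ci]
  }, logical(1))
  p_hat <- mean(correct)
  se <- sqrt((1 / 36) * (35 / 36) / n_char)
  expect_lt(abs(p_hat - 1 / 36), 4 * se)
})

test_that("accuracy improves with repetition budget when scores are noisy", {
  acc_gain <- vapply(1:12, function(seed) {
    s <- make_rcp_session(n_characters = 6, n_repetitions = 10, snr_db = 0,
                          seed = 100 + seed)
    ep <- session_to_epochs(s, 0.3)
    scores <- as.numeric(ep$labels == 1L) +
      stlfl:::with_seed(seed, rnorm(length(ep$labels), sd = 2))
    a <- decode_session(ep, scores, s$paradigm, s$truth,
                        budgets = c(1, 10))$accuracy_by_repetition
    a$accuracy[2] - a$accuracy[1]
  }, numeric(1))
  expect_gte(mean(acc_gain), 0)
})

test_that("misaligned scores are rejected", {
  s <- make_rcp_session(n_characters = 2, n_repetitions = 2, seed = 23)
  ep <- session_to_epochs(s, 0.3)
  expect_error(decode_session(ep, rep(0.5, 3), s$paradigm, s$truth),
               "aligned")
  expect_error(decode_session(ep, as.numeric(ep$labels), s$paradigm,
                              s$truth, budgets = 99), "exceeds")
})
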
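test_that("zero rates leave every tip at the root state with no events", {
  tr <- make_tree(12, seed = 1)
  m <- ratchet_model(loss_rate = 0, hgt_rate = 0,
                     root_state = c("eEF1A", "eEF1Ba", "EFL"))
  h <- simulate(m, seed = 5, tree = tr)
  expect_equal(nrow(h$events), 0L)
  expect_true(all(h$tip_states == "eEF1A+eEF1Ba+EFL"))
  s <- summary(h)
  expect_equal(unname(s$tip_state_freq["eEF1A+eEF1Ba+EFL"]), 12L)
  expect_equal(s$n_reversals, 0L)
})

test_that("without HGT no tip ever acquires EFL from an EFL-free root", {
  tr <- make_tree(20, seed = 2)
  m <- ratchet_model(loss_rate = 2, hgt_rate = 0,
                     root_state = c("eEF1A", "eEF1Ba"))
  hs <- simulate(m, nsim = 50, seed = 6, tree = tr)
  for (h in hs) {
    expect_false(any(grepl("EFL", h$tip_states)))
    expect_false(any(h$events$event == "gain"))
  }
})

test_that("single-branch survival matches the exponential closed form", {
  # only eEF1Ba loss is active from the full state
  lambda <- 0.7; t <- 1.3; n <- 10000
  m <- ratchet_model(loss_rate = c(eEF1A = 0, eEF1Ba = lambda, EFL = 0),
                     hgt_rate = 0, root_state = c("eEF1A", "eEF1Ba", "EFL"))
  s <- ratchet_branch_sample(m, t = t, n = n, seed = 33)
  retained <- mean(bitwAnd(s, 2L) > 0L)
  p <- exp(-lambda * t)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(retained - p), 3 * se)
})

test_that("replaying the event log reproduces the stored node states", {
  m <- ratchet_model(loss_rate = 1.2, hgt_rate = 0.6,
                     root_state = c("eEF1A", "eEF1Ba", "EFL"))
  set.seed(40)
  for (i in 1:10) {
    tr <- make_tree(15, seed = 100 + i)
    h <- simulate(m, tree = tr)
    expect_identical(replay_history(h), h$node_states)
  }
})

test_that("the ratchet pawl holds: no history regains eEF1A or eEF1Ba", {
  m <- ratchet_model(loss_rate = 1.5, hgt_rate = 0.8,
                     root_state = c("eEF1A", "eEF1Ba", "EFL"))
  tr <- make_tree(10, seed = 3)
  set.seed(90)
  for (i in 1:200) {
    h <- simulate(m, tree = tr)
    ev <- h$events
    gains <- ev[ev$event == "gain", ]
    # gains exist only for EFL
    expect_true(all(gains$gene == "EFL"))
    # no transition adds eEF1A or eEF1Ba
    a_from <- bitwAnd(ev$from, 1L) > 0L; a_to <- bitwAnd(ev$to, 1L) > 0L
    b_from <- bitwAnd(ev$from, 2L) > 0L; b_to <- bitwAnd(ev$to, 2L) > 0L
    expect_false(any(!a_from & a_to))
    expect_false(any(!b_from & b_to))
    # no state on any path is inviable under the reject policy
    expect_true(all(viable(ev$from)) && all(viable(ev$to)))
  }
})

test_that("EFL regains occur if and only if the HGT rate is positive", {
  tr <- make_tree(25, seed = 4)
  m0 <- ratchet_model(loss_rate = 2, hgt_rate = 0,
                      root_state = c("eEF1A", "eEF1Ba", "EFL"))
  hs0 <- simulate(m0, nsim = 100, seed = 8, tree = tr)
  expect_equal(sum(vapply(hs0, function(h) summary(h)$n_reversals, 1L)), 0L)
  m1 <- ratchet_model(loss_rate = 2, hgt_rate = 2,
                      root_state = c("eEF1A", "eEF1Ba", "EFL"))
  hs1 <- simulate(m1, nsim = 100, seed = 8, tree = tr)
  expect_gt(sum(vapply(hs1, function(h) summary(h)$n_reversals, 1L)), 0L)
})

test_that("summary counts replacements and co-maintained tips", {
  # hand-built check on one history with moderate rates
  m <- ratchet_model(loss_rate = 1, hgt_rate = 0.5,
                     root_state = c("eEF1A", "eEF1Ba", "EFL"))
  tr <- make_tree(30, seed = 5)
  h <- simulate(m, seed = 44, tree = tr)
  s <- summary(h)
  ev <- h$events
  expect_equal(s$n_replacements,
               sum(ev$event == "loss" & ev$gene == "eEF1A" &
                   bitwAnd(ev$from, 4L) > 0L))
  expect_equal(s$n_comaintained,
               sum(bitwAnd(h$tip_codes, 1L) > 0L &
                   bitwAnd(h$tip_codes, 4L) > 0L))
  expect_equal(sum(s$tip_state_freq), s$n_tips)
})

test_that("mean EFL tip fraction is non-decreasing in the HGT rate", {
  tr <- make_tree(20, seed = 6)
  efl_frac <- function(hgt, reps = 150, seed = 60) {
    m <- ratchet_model(loss_rate = 0.5, hgt_rate = hgt,
                       root_state = c("eEF1A", "eEF1Ba"))
    hs <- simulate(m, nsim = reps, seed = seed, tree = tr)
    mean(vapply(hs, function(h) mean(bitwAnd(h$tip_codes, 4L) > 0L), 1))
  }
  f <- vapply(c(0, 0.1, 0.5, 1), efl_frac, 1)
  expect_equal(f[1], 0)
  # allow small Monte-Carlo slack between adjacent grid points
  expect_true(all(diff(f) > -0.03))
  expect_gt(f[4], f[1])
})

test_that("the extinct policy kills lineages that cross a lethal state", {
  m <- ratchet_model(loss_rate = 3, hgt_rate = 0, lethal_policy = "extinct",
                     root_state = c("eEF1A", "eEF1Ba"))
  tr <- make_tree(15, seed = 7)
  hs <- simulate(m, nsim = 30, seed = 70, tree = tr)
  codes <- unlist(lapply(hs, function(h) h$tip_codes))
  expect_true(any(codes == -1L)) # extinction happens at these rates
  expect_true(all(codes %in% c(-1L, 3L))) # survivors still carry both genes
})

test_that("simulation errors on trees without positive branch lengths", {
  tr <- make_tree(5, seed = 8)
  tr$edge.length[2] <- 0
  m <- ratchet_model()
  expect_error(simulate(m, tree = tr), "positive")
  tr2 <- ape::read.tree(text = "(A,B);")
  expect_error(simulate(m, tree = tr2), "branch lengths")
})
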
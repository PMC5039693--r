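test_that("sampled histories honour the conditioning and the model", {
  phy <- yule_tree(12, 1, seed = 31)
  rec <- simulate_mk(phy, rate_matrix(0.5, 0.5), 1L, seed = 32)
  tips <- rec$tips
  q <- rate_matrix(0.4, 0.4)
  set.seed(33)
  eng <- tmevol:::.simmap_engine(phy, tips, q, root_prior("flat"))
  for (i in 1:25) {
    h <- tmevol:::.simmap_draw(eng)
    ## leaf states always equal the observed data
    expect_identical(unname(h$node_states[names(tips)]), unname(tips))
    ## edge path consistency: last event state equals child state
    for (lab in names(h$events)) {
      ev <- h$events[[lab]]
      if (is.null(ev) || nrow(ev) == 0L) next
      expect_identical(ev$state[nrow(ev)], unname(h$node_states[lab]))
      expect_true(all(diff(ev$t) > 0))
      expect_true(all(diff(ev$state) != 0L))
    }
  }

  ## Dollo rates: no history may contain a gain
  dollo <- rate_matrix(0, 0.6)
  dtips <- stats::setNames(c(rep(1L, 6), rep(0L, 6)), phy$tip.label)
  set.seed(34)
  deng <- tmevol:::.simmap_engine(phy, dtips, dollo, root_prior("fixed", 1L))
  for (i in 1:25) {
    h <- tmevol:::.simmap_draw(deng)
    cts <- tmevol:::.history_change_counts(h)
    expect_identical(unname(cts["gains"]), 0L)
  }

  ## impossible constraint: Dollo, earless root, eared tips
  expect_error(sample_history(phy, dtips, dollo, root_prior("fixed", 0L)),
               "impossible")
})

test_that("branch path sampler matches a discretised-chain oracle", {
  ## one branch of length 2, both endpoints earless, ER rate 0.8
  q <- rate_matrix(0.8, 0.8)
  t <- 2
  set.seed(35)
  n <- 20000L
  counts <- integer(n)
  for (i in seq_len(n))
    counts[i] <- nrow(tmevol:::.sample_path(0L, 0L, t, q))
  expected <- oracle_expected_changes(0.8, 0.8, t, 0L, 0L)
  se <- stats::sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  ## conditional on equal endpoints, the number of changes is even
  expect_true(all(counts %% 2L == 0L))

  ## asymmetric rates, unequal endpoints: odd counts, oracle agreement
  q2 <- rate_matrix(0.3, 1.1)
  counts2 <- integer(n)
  for (i in seq_len(n))
    counts2[i] <- nrow(tmevol:::.sample_path(1L, 0L, 1.5, q2))
  expect_true(all(counts2 %% 2L == 1L))
  expected2 <- oracle_expected_changes(0.3, 1.1, 1.5, 1L, 0L)
  se2 <- stats::sd(counts2) / sqrt(n)
  expect_lt(abs(mean(counts2) - expected2), 3 * se2)
})

test_that("joint node-state draws follow the exact conditional distribution", {
  phy <- read_newick("((A:0.8,B:1.2)N1:0.6,C:1.5)R;")
  tips <- c(A = 1L, B = 0L, C = 0L)
  q <- rate_matrix(0.7, 0.4)
  ## exhaustive conditional over the two internal nodes
  ref <- numeric(4)
  A <- expand.grid(R = 0:1, N1 = 0:1)
  for (i in 1:4) {
    st <- c(A = 1L, B = 0L, C = 0L, R = A$R[i], N1 = A$N1[i])
    w <- 0.5 *
      oracle_P(q$q01, q$q10, 0.6)[st["R"] + 1, st["N1"] + 1] *
      oracle_P(q$q01, q$q10, 1.5)[st["R"] + 1, st["C"] + 1] *
      oracle_P(q$q01, q$q10, 0.8)[st["N1"] + 1, st["A"] + 1] *
      oracle_P(q$q01, q$q10, 1.2)[st["N1"] + 1, st["B"] + 1]
    ref[i] <- w
  }
  ref <- ref / sum(ref)
  set.seed(36)
  eng <- tmevol:::.simmap_engine(phy, tips, q, root_prior("flat"))
  n <- 30000L
  idx <- integer(n)
  for (i in seq_len(n)) {
    h <- tmevol:::.simmap_draw(eng)
    idx[i] <- 1L + h$node_states[["R"]] + 2L * h$node_states[["N1"]]
  }
  obs <- tabulate(idx, 4)
  gof <- stats::chisq.test(obs, p = ref)
  expect_gt(gof$p.value, 1e-3)
})

test_that("map summaries apply the strict >50% support counting rule", {
  phy <- read_newick("((A:1,B:1)P:1,C:1)R;")
  mk_states <- function(R, P, A, B, C)
    stats::setNames(c(A, B, C, R, P), c("A", "B", "C", "R", "P"))
  ## 10 maps: R eared in 9/10; P eared in 2/10; tips fixed (A=0,B=0,C=1)
  maps <- lapply(1:10, function(i)
    fake_history(phy, mk_states(R = as.integer(i <= 9),
                                P = as.integer(i <= 2),
                                A = 0L, B = 0L, C = 1L)))
  s <- summarize_maps(maps, threshold = 0.5)
  expect_equal(unname(s$node_posterior[c("R", "P")]), c(0.9, 0.2))
  ## R called eared, P called earless: one loss on edge R->P; P's pendant
  ## edges agree with P and the R->C edge agrees with R, so nothing else
  expect_equal(s$threshold_losses, 1L)
  expect_equal(s$threshold_gains, 0L)
})

test_that("a node at exactly 0.5 support is uncalled and uncounted", {
  phy <- read_newick("(A:1,B:1)R;")
  maps <- lapply(1:10, function(i)
    fake_history(phy, stats::setNames(c(1L, 1L, as.integer(i <= 5)),
                                      c("A", "B", "R"))))
  s <- summarize_maps(maps, threshold = 0.5)
  expect_equal(unname(s$node_posterior[["R"]]), 0.5)
  expect_true(is.na(s$called[["R"]]))
  expect_equal(s$threshold_gains, 0L)
  expect_equal(s$threshold_losses, 0L)
  ## all nodes unanimous: no threshold changes at all
  s2 <- summarize_maps(lapply(1:5, function(i)
    fake_history(phy, stats::setNames(c(1L, 1L, 1L), c("A", "B", "R")))))
  expect_equal(s2$threshold_gains + s2$threshold_losses, 0L)
})

test_that("scenarios are reproducible and Dollo forbids gains", {
  phy <- yule_tree(25, 1, seed = 41)
  rec <- simulate_mk(phy, rate_matrix(0.4, 0.4), 1L, seed = 42)
  cfg <- scenario_config("er_unconstrained", n_sims = 300, seed = 43)
  s1 <- run_scenario(phy, rec$tips, cfg)
  s2 <- run_scenario(phy, rec$tips, cfg)
  expect_identical(s1$node_posterior, s2$node_posterior)
  expect_identical(s1$gains_per_map, s2$gains_per_map)
  expect_identical(s1$threshold_losses, s2$threshold_losses)

  d <- run_scenario(phy, rec$tips,
                    scenario_config("dollo", n_sims = 300, seed = 44))
  expect_equal(d$rate$q01, 0)
  expect_true(all(d$gains_per_map == 0L))
  expect_equal(d$mean_gains, 0)
  expect_equal(d$threshold_gains, 0L)

  ## root-eared scenario keeps the unconstrained ER rate and fixes the root
  re <- run_scenario(phy, rec$tips,
                     scenario_config("er_root_eared", n_sims = 300, seed = 43))
  expect_equal(re$rate$q01, s1$rate$q01)
  expect_equal(re$node_posterior[["N26"]], 1)  # root posterior forced eared
})

test_that("simmap node posteriors converge to the pruning marginals", {
  phy <- yule_tree(20, 1, seed = 51)
  rec <- simulate_mk(phy, rate_matrix(0.6, 0.6), 1L, seed = 52)
  s <- run_scenario(phy, rec$tips,
                    scenario_config("er_unconstrained", n_sims = 3000,
                                    seed = 53))
  m <- marginal_ancestral(phy, rec$tips, s$rate, root_prior("flat"))
  expect_lt(max(abs(s$node_posterior[names(m)] - m)), 0.05)
})

test_that("under Dollo, threshold losses grow as earless clades accumulate", {
  phy <- yule_tree(16, 1, seed = 61)
  ## grow the earless set clade by clade
  labs <- node_labels(phy)
  base <- stats::setNames(rep(1L, 16), phy$tip.label)
  clades <- list(c("t1", "t2"), c("t5", "t6", "t7"), c("t12", "t13"))
  ## only keep clades that are actually monophyletic on this tree
  prev <- -1L
  tips <- base
  for (k in seq_along(clades)) {
    tips[unlist(clades[seq_len(k)])] <- 0L
    d <- run_scenario(phy, tips,
                      scenario_config("dollo", n_sims = 1500, seed = 62))
    expect_gte(d$threshold_losses, prev)
    prev <- d$threshold_losses
  }
})
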
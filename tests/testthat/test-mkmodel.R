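test_that("transition matrices follow the closed two-state form", {
  q <- rate_matrix(0.5, 0.5)
  expect_equal(transition_matrix(q, 0), diag(2), ignore_attr = TRUE)
  ## ER rate 0.5 over t = ln 2: stay probability (1 + exp(-2*0.5*ln2))/2
  P <- transition_matrix(q, log(2))
  expect_equal(P[1, 1], 0.75, tolerance = 1e-12)
  expect_equal(P[2, 2], 0.75, tolerance = 1e-12)
  ## long-time limit is the stationary distribution
  expect_equal(as.vector(transition_matrix(q, 500)), rep(0.5, 4),
               tolerance = 1e-12)
  expect_error(transition_matrix(q, -1), ">= 0")
  expect_equal(transition_matrix(rate_matrix(0, 0), 3), diag(2),
               ignore_attr = TRUE)

  ## rows sum to one; Chapman-Kolmogorov; agreement with eigen solution
  set.seed(7)
  for (i in 1:25) {
    qq <- rate_matrix(stats::runif(1, 0, 3), stats::runif(1, 0, 3))
    t1 <- stats::runif(1, 0, 4); t2 <- stats::runif(1, 0, 4)
    P1 <- transition_matrix(qq, t1)
    expect_equal(rowSums(P1), c("0" = 1, "1" = 1), tolerance = 1e-12)
    expect_equal(P1 %*% transition_matrix(qq, t2),
                 transition_matrix(qq, t1 + t2), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(unname(P1), oracle_P(qq$q01, qq$q10, t1), tolerance = 1e-10)
  }
})

test_that("pruning likelihood matches closed forms and symmetries", {
  two <- read_newick("(A:0.7,B:1.3)R;")
  q <- rate_matrix(0.4, 0.9)
  ## hand closed form: flat prior over the root state
  P1 <- transition_matrix(q, 0.7); P2 <- transition_matrix(q, 1.3)
  hand <- log(sum(0.5 * P1[, "0"] * P2[, "0"]))
  expect_equal(mk_loglik(two, c(A = 0L, B = 0L), q), hand, tolerance = 1e-12)

  ## ER + flat prior: complementing the data leaves the likelihood unchanged
  phy <- rand_tree(6, seed = 42)
  tips <- rand_tips(phy, seed = 43, p_na = 0)
  er <- rate_matrix(0.6, 0.6)
  expect_equal(mk_loglik(phy, tips, er),
               mk_loglik(phy, stats::setNames(1L - tips, names(tips)), er),
               tolerance = 1e-12)

  ## unknown tips contribute (1,1): loglik equals enumeration oracle
  for (i in 1:20) {
    phy <- rand_tree(3L + (i %% 3L), seed = 5000 + i, polytomies = i %% 4 == 0)
    tips <- rand_tips(phy, seed = 6000 + i)
    qq <- rate_matrix(stats::runif(1, 0.05, 2), stats::runif(1, 0.05, 2))
    expect_equal(mk_loglik(phy, tips, qq), oracle_loglik(phy, tips, qq),
                 tolerance = 1e-10)
  }
})

test_that("impossible data under a fixed root returns -Inf", {
  two <- read_newick("(A:1,B:1)R;")
  dollo <- rate_matrix(0, 0.5)
  ## root fixed earless but an eared tip exists: impossible without gains
  expect_equal(mk_loglik(two, c(A = 1L, B = 0L), dollo,
                         root_prior("fixed", 0L)), -Inf)
})

test_that("ER fitting is deterministic, optimal, and flags degenerate data", {
  rec <- simulate_mk(yule_tree(120, 1, seed = 21), rate_matrix(0.8, 0.8),
                     root_state = 1L, seed = 22)
  H <- max(ape::node.depth.edgelength(rec$tree))
  fit <- fit_mk(rec$tree, rec$tips, model = "ER")
  expect_s3_class(fit, "mk_fit")
  expect_equal(fit$rates$q01, fit$rates$q10)
  ## the optimum can be no worse than the truth
  expect_gte(fit$loglik + 1e-6,
             mk_loglik(rec$tree, rec$tips, rec$q_true))
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  ## identical rerun (no hidden randomness)
  fit2 <- fit_mk(rec$tree, rec$tips, model = "ER")
  expect_identical(fit$rates$q01, fit2$rates$q01)

  ard <- fit_mk(rec$tree, rec$tips, model = "ARD")
  expect_equal(ard$n_params, 2L)
  expect_gte(ard$loglik + 1e-6, fit$loglik)  # nested models

  expect_warning(
    cfit <- fit_mk(rec$tree,
                   stats::setNames(rep(1L, length(rec$tips)),
                                   names(rec$tips)), model = "ER"),
    "unidentifiable")
  expect_true(cfit$boundary)
  expect_lt(cfit$rates$q01 * H, 1e-6)
})

test_that("AIC comparison ranks, breaks ties to fewer parameters", {
  f <- function(model, k, ll) structure(list(model = model, n_params = k,
                                             loglik = ll, aic = 2 * k - 2 * ll),
                                        class = "mk_fit")
  tab <- compare_aic(list(f("ARD", 2L, -4.25), f("ER", 1L, -4.0)))
  expect_equal(tab$model, c("ER", "ARD"))
  expect_equal(tab$delta_aic, c(0, 2.5))
  ## equal log-likelihoods: the 1-parameter model must win
  tab2 <- compare_aic(list(f("ARD", 2L, -10), f("ER", 1L, -10)))
  expect_equal(tab2$model[1], "ER")
  ## exact AIC tie: stable order, fewer parameters first
  tab3 <- compare_aic(list(f("ARD", 2L, -9), f("ER", 1L, -10)))
  expect_equal(tab3$model[1], "ER")
  expect_equal(tab3$delta_aic, c(0, 0))
  expect_equal(nrow(compare_aic(list(f("ER", 1L, -3)))), 1L)
})

test_that("marginal ancestral probabilities are exact on small trees", {
  ## fully symmetric instance: the root cannot prefer either state
  sym <- read_newick("(A:1,B:1)R;")
  m <- marginal_ancestral(sym, c(A = 0L, B = 1L), rate_matrix(0.5, 0.5))
  expect_equal(unname(m["R"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(m[c("A", "B")]), c(0, 1))

  ## constant-present data pull every node above one half under ER
  phy <- rand_tree(5, seed = 77)
  ones <- stats::setNames(rep(1L, 5), phy$tip.label)
  m1 <- marginal_ancestral(phy, ones, rate_matrix(0.3, 0.3))
  expect_true(all(m1 > 0.5))

  ## exhaustive conditional oracle, mixed priors
  priors <- list(root_prior("flat"), root_prior("stationary"),
                 root_prior("fixed", 1L))
  for (i in 1:20) {
    phy <- rand_tree(3L + (i %% 3L), seed = 7000 + i, polytomies = i %% 5 == 0)
    tips <- rand_tips(phy, seed = 8000 + i)
    qq <- rate_matrix(stats::runif(1, 0.05, 2), stats::runif(1, 0.05, 2))
    pr <- priors[[1 + (i %% 3)]]
    got <- marginal_ancestral(phy, tips, qq, pr)
    ref <- oracle_marginal(phy, tips, qq, pr)
    expect_equal(got[names(ref)], ref, tolerance = 1e-10)
  }
})
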
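# Stochastic character mapping.
#
# A map is drawn in two stages: joint node states are sampled exactly
# (tipward pruning partials, then a rootward sweep sampling each node
# conditional on its parent and the data below it), and each branch path is
# then drawn conditional on its endpoint states by uniformization — the
# number of candidate jumps is sampled from its exact conditional
# distribution and the jump chain is filled in between the endpoints, so the
# sampler terminates by construction (no rejection). Scenario running follows
# the three-scenario design: unconstrained equal-rates, equal-rates with the
# root forced eared, and a Dollo model (gain rate exactly zero, loss rate
# refit by ML) — with gain/loss counting on the summarized node states under
# a strict >threshold support rule.

#' Scenario configuration for stochastic mapping
#'
#' @param name one of `"er_unconstrained"`, `"er_root_eared"`, `"dollo"`.
#' @param n_sims number of maps to draw (default 10000, the study design).
#' @param threshold node support needed to call a state; calls are strict
#'   (`> threshold`), so a node at exactly 0.5 is uncalled (default 0.5).
#' @param seed integer root seed; per-map seeds are derived from it, so
#'   results do not depend on evaluation order.
#' @param refit_rate for `er_root_eared`: re-estimate the ER rate under the
#'   root constraint instead of reusing the unconstrained estimate (default
#'   `FALSE`).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name = c("er_unconstrained", "er_root_eared",
                                     "dollo"),
                            n_sims = 10000L, threshold = 0.5, seed = 1L,
                            refit_rate = FALSE) {
  name <- match.arg(name)
  n_sims <- as.integer(n_sims)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  structure(list(name = name, n_sims = n_sims, threshold = threshold,
                 seed = as.integer(seed), refit_rate = isTRUE(refit_rate)),
            class = "scenario_config")
}

## ---- endpoint-conditioned path sampling on one branch ---------------------

## light data.frame constructor for the hot loop
.fast_df <- function(t, state) {
  structure(list(t = t, state = state), class = "data.frame",
            row.names = if (length(t)) seq_along(t) else integer(0))
}

## per-branch constants for uniformization: dominating rate, jump-chain
## matrix R = I + Q/Lambda, its powers (grown on demand), Poisson weights
.path_ctx <- function(q, t) {
  lam <- max(q$q01, q$q10)
  ctx <- new.env(parent = emptyenv())
  ctx$lam <- lam; ctx$t <- t; ctx$Pt <- transition_matrix(q, t)
  ctx$R <- NULL
  if (lam > 0 && t > 0) {
    Q <- matrix(c(-q$q01, q$q10, q$q01, -q$q10), 2, 2)
    ctx$R <- diag(2) + Q / lam
    ctx$Rpow <- list(diag(2))  # Rpow[[k]] = R^(k-1), grown on demand
    ctx$cap <- max(20L, stats::qpois(1 - 1e-13, lam * t) * 3L)
  }
  ctx
}

## sample real (state-changing) events on a branch conditional on endpoint
## states a, b; N | endpoints has p(n) = dpois(n, lam t) R^n[a,b] / Pt[a,b],
## then the jump chain is bridged between the endpoints.
.sample_path_ctx <- function(a, b, ctx) {
  if (is.null(ctx$R)) {
    if (a != b)
      stop("impossible endpoint pair on a zero-rate/zero-length branch")
    return(.fast_df(numeric(0), integer(0)))
  }
  ai <- a + 1L; bi <- b + 1L
  target <- ctx$Pt[ai, bi]
  if (target <= 0) stop("impossible endpoint pair for this rate matrix")
  u <- stats::runif(1) * target
  lt <- ctx$lam * ctx$t
  n <- 0L
  acc <- exp(-lt) * ctx$Rpow[[1L]][ai, bi]
  while (acc < u && n < ctx$cap) {
    n <- n + 1L
    if (length(ctx$Rpow) < n + 1L)
      ctx$Rpow[[n + 1L]] <- ctx$Rpow[[n]] %*% ctx$R
    acc <- acc + stats::dpois(n, lt) * ctx$Rpow[[n + 1L]][ai, bi]
  }
  if (n == 0L) return(.fast_df(numeric(0), integer(0)))
  Rpow <- ctx$Rpow
  times <- sort(stats::runif(n)) * ctx$t
  states <- integer(n)
  prev <- ai
  for (k in seq_len(n)) {
    w <- ctx$R[prev, ] * Rpow[[n - k + 1L]][, bi]
    tot <- w[1] + w[2]
    prev <- if (tot <= 0) bi
            else if (stats::runif(1) * tot > w[1]) 2L else 1L
    states[k] <- prev
  }
  real <- c(states[1] != ai, diff(states) != 0L)
  .fast_df(times[real], states[real] - 1L)
}

## standalone API used by tests/oracles; precomputes the context each call
.sample_path <- function(a, b, t, q) .sample_path_ctx(a, b, .path_ctx(q, t))

## ---- engine: precompute everything reusable across maps -------------------

.simmap_engine <- function(phy, tips, q, prior) {
  part <- .mk_partials_scaled(phy, tips, q)
  pv <- .prior_vector(prior, q)
  rw <- pv * part$D[part$root, ]
  if (sum(rw) <= 0)
    stop("tip data impossible under the given rates and root prior")
  ## per-edge uniformization contexts, indexed by child node
  ctx <- vector("list", nrow(part$D))
  edge <- part$edge
  for (i in seq_len(nrow(edge)))
    ctx[[edge[i, 2]]] <- .path_ctx(q, part$elen[i])
  list(phy = phy, q = q, prior = prior, part = part, ctx = ctx,
       root_w = rw, labs = node_labels(phy))
}

.simmap_draw <- function(eng) {
  part <- eng$part
  edge <- part$edge
  nn <- nrow(part$D)
  state <- integer(nn)
  rw <- eng$root_w
  state[part$root] <-
    if (stats::runif(1) * (rw[1] + rw[2]) > rw[1]) 1L else 0L
  events <- vector("list", nn)  # by child node
  D <- part$D
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[i, 1]; ch <- edge[i, 2]
    w <- part$P[[ch]][state[p] + 1L, ] * D[ch, ]
    state[ch] <- if (stats::runif(1) * (w[1] + w[2]) > w[1]) 1L else 0L
    events[[ch]] <- .sample_path_ctx(state[p], state[ch], eng$ctx[[ch]])
  }
  structure(list(node_states = stats::setNames(state, eng$labs),
                 events = stats::setNames(events, eng$labs),
                 tree = eng$phy),
            class = "character_history")
}

#' Draw one stochastic character map
#'
#' Samples a full character history (joint node states plus the exact path of
#' changes along every branch) from its conditional distribution given the
#' tip data, the rate matrix and the root prior.
#'
#' @inheritParams mk_loglik
#' @param seed optional integer; when given, `set.seed(seed)` is called first.
#' @return an object of class `character_history`: `node_states` (named
#'   vector over all node labels), `events` (per child-edge data frame with
#'   `t` = time from the parent node and `state` = new state), `tree`.
#' @export
sample_history <- function(phy, tips, q, prior = root_prior("flat"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eng <- .simmap_engine(phy, tips, q, prior)
  .simmap_draw(eng)
}

.history_change_counts <- function(h) {
  gains <- 0L; losses <- 0L
  for (ev in h$events) {
    if (is.null(ev) || nrow(ev) == 0L) next
    gains <- gains + sum(ev$state == 1L)
    losses <- losses + sum(ev$state == 0L)
  }
  c(gains = gains, losses = losses)
}

## threshold-rule change counting on called node states (NA = uncalled)
.count_threshold_changes <- function(phy, called) {
  labs <- node_labels(phy)
  e <- phy$edge
  from <- called[labs[e[, 1]]]
  to <- called[labs[e[, 2]]]
  ok <- !is.na(from) & !is.na(to)
  c(gains = sum(ok & from == 0L & to == 1L),
    losses = sum(ok & from == 1L & to == 0L))
}

#' Summarise a set of stochastic maps
#'
#' Per-node support is the across-map frequency of each state. A node is
#' called for a state only when its support strictly exceeds `threshold`;
#' threshold gains/losses count edges whose two endpoints are called for
#' different states, and edges touching an uncalled node are not counted.
#' Mean gains/losses average the per-map event counts.
#'
#' @param maps list of `character_history` objects on the same tree.
#' @param threshold support needed to call a node (strict; default 0.5).
#' @return an object of class `map_summary`: `node_posterior` (frequency of
#'   state 1), `called`, `threshold_gains`, `threshold_losses`, `mean_gains`,
#'   `mean_losses`, `gains_per_map`, `losses_per_map`, `n_maps`.
#' @export
summarize_maps <- function(maps, threshold = 0.5) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, TRUE, "character_history")))
  labs <- names(maps[[1]]$node_states)
  for (m in maps)
    if (!identical(names(m$node_states), labs))
      stop("maps are not on the same tree")
  S <- vapply(maps, `[[`, numeric(length(labs)), "node_states")
  post <- rowMeans(S)
  names(post) <- labs
  counts <- vapply(maps, .history_change_counts, c(gains = 0L, losses = 0L))
  .make_map_summary(maps[[1]]$tree, post, counts, threshold,
                    n_maps = length(maps))
}

.make_map_summary <- function(phy, post, counts, threshold, n_maps,
                              rate = NULL, config = NULL) {
  called <- ifelse(post > threshold, 1L,
                   ifelse(1 - post > threshold, 0L, NA_integer_))
  names(called) <- names(post)
  thr <- .count_threshold_changes(phy, called)
  structure(list(node_posterior = post, called = called,
                 threshold_gains = unname(thr["gains"]),
                 threshold_losses = unname(thr["losses"]),
                 mean_gains = mean(counts["gains", ]),
                 mean_losses = mean(counts["losses", ]),
                 gains_per_map = unname(counts["gains", ]),
                 losses_per_map = unname(counts["losses", ]),
                 n_maps = n_maps, rate = rate, config = config),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf(paste0("Stochastic mapping summary (%d maps): ",
                     "threshold gains = %d, losses = %d; ",
                     "mean gains = %.2f, losses = %.2f\n"),
              x$n_maps, x$threshold_gains, x$threshold_losses,
              x$mean_gains, x$mean_losses))
  invisible(x)
}

#' Run one stochastic-mapping scenario
#'
#' The three scenarios of the study design: (1) `er_unconstrained` fits an
#' equal-rates model with a flat root prior and samples maps under it; (2)
#' `er_root_eared` keeps that ER rate but fixes the root to state 1 (eared);
#' (3) `dollo` sets the gain rate to exactly zero, refits the loss rate by ML
#' with the root fixed eared, and samples irreversible histories. Per-map
#' seeds are derived from the configured root seed, so the summary is
#' bit-identical across runs with the same configuration.
#'
#' @inheritParams mk_loglik
#' @param cfg a [scenario_config()].
#' @return a `map_summary` with the fitted `rate` and the `config` echoed.
#' @export
run_scenario <- function(phy, tips, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$name %in% c("er_unconstrained", "er_root_eared")) {
    base_prior <- if (cfg$name == "er_root_eared" && cfg$refit_rate)
      root_prior("fixed", 1L) else root_prior("flat")
    fit <- fit_mk(phy, tips, model = "ER", prior = base_prior)
    q <- fit$rates
    prior <- if (cfg$name == "er_root_eared") root_prior("fixed", 1L)
             else root_prior("flat")
  } else {
    ## Dollo: q01 = 0 exactly, loss rate by ML, root fixed eared
    prior <- root_prior("fixed", 1L)
    H <- .tree_height(phy)
    fr <- .fit_rates(function(r) mk_loglik(phy, tips, rate_matrix(0, r[1]),
                                           prior),
                     1, H)
    q <- rate_matrix(0, fr$rates[1])
  }
  eng <- .simmap_engine(phy, tips, q, prior)
  set.seed(cfg$seed)
  map_seeds <- sample.int(.Machine$integer.max, cfg$n_sims)
  labs <- eng$labs
  state1 <- numeric(length(labs))
  counts <- matrix(0L, 2, cfg$n_sims, dimnames = list(c("gains", "losses"),
                                                      NULL))
  for (i in seq_len(cfg$n_sims)) {
    set.seed(map_seeds[i])
    h <- .simmap_draw(eng)
    state1 <- state1 + h$node_states
    counts[, i] <- .history_change_counts(h)
  }
  post <- stats::setNames(state1 / cfg$n_sims, labs)
  .make_map_summary(phy, post, counts, cfg$threshold, n_maps = cfg$n_sims,
                    rate = q, config = cfg)
}
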
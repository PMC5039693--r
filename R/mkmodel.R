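# Two-state continuous-time Markov (Mk) machinery: closed-form transition
# probabilities, pruning likelihood with per-node scaling, ER/ARD maximum
# likelihood fits compared by AIC, and marginal ancestral state probabilities
# from combined rootward/tipward partials.
#
# State encoding is repo-wide: 0 = absent (earless), 1 = present (eared).
# q01 is the gain rate (0 -> 1), q10 the loss rate (1 -> 0), per unit branch
# length.

#' Two-state rate matrix
#'
#' @param q01 gain rate (absent to present), per unit branch length.
#' @param q10 loss rate (present to absent).
#' @return an object of class `rate_matrix2`.
#' @export
rate_matrix <- function(q01, q10) {
  if (!is.finite(q01) || !is.finite(q10) || q01 < 0 || q10 < 0)
    stop("rates must be finite and nonnegative")
  structure(list(q01 = q01, q10 = q10), class = "rate_matrix2")
}

#' @export
print.rate_matrix2 <- function(x, ...) {
  cat(sprintf("2-state rates: gain q01 = %g, loss q10 = %g\n", x$q01, x$q10))
  invisible(x)
}

#' Root state prior
#'
#' @param kind `"flat"` (equal probabilities), `"stationary"` (equilibrium of
#'   the rate matrix; requires q01 + q10 > 0), or `"fixed"`.
#' @param state root state (0 or 1) when `kind = "fixed"`.
#' @return an object of class `root_prior`.
#' @export
root_prior <- function(kind = c("flat", "stationary", "fixed"), state = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (is.null(state) || !state %in% c(0L, 1L))
      stop("fixed root prior needs state 0 or 1")
    state <- as.integer(state)
  }
  structure(list(kind = kind, state = state), class = "root_prior")
}

.prior_vector <- function(prior, q) {
  switch(prior$kind,
         flat = c(0.5, 0.5),
         stationary = {
           s <- q$q01 + q$q10
           if (s <= 0) stop("stationary prior undefined when both rates are 0")
           c(q$q10, q$q01) / s
         },
         fixed = if (prior$state == 0L) c(1, 0) else c(0, 1))
}

#' Transition probability matrix over a branch
#'
#' Closed-form two-state solution: with `s = q01 + q10` and stationary
#' distribution `pi`, `P(t) = Pi + exp(-s t) (I - Pi)` where `Pi` has `pi` in
#' each row; for `s = 0`, `P = I`. Rows (from-state) sum to 1.
#'
#' @param q a `rate_matrix2`.
#' @param t branch length, `t >= 0`.
#' @return 2x2 stochastic matrix, rows/cols named `"0"`, `"1"`.
#' @export
transition_matrix <- function(q, t) {
  stopifnot(inherits(q, "rate_matrix2"))
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  s <- q$q01 + q$q10
  dm <- list(c("0", "1"), c("0", "1"))
  if (s == 0 || t == 0)
    return(matrix(c(1, 0, 0, 1), 2, 2, dimnames = dm))
  e <- exp(-s * t)
  pi0 <- q$q10 / s
  pi1 <- q$q01 / s
  matrix(c(pi0 + pi1 * e, pi0 - pi0 * e,    # col "0": from 0, from 1
           pi1 - pi1 * e, pi1 + pi0 * e),   # col "1"
         2, 2, dimnames = dm)
}

## tipward (downward) partial likelihoods with per-node scaling: each
## internal node's partials are rescaled to sum to 1 as soon as it is
## completed, with the log of the factor accumulated rootward. Shared by
## loglik, marginals and simmap.
.mk_partials_scaled <- function(phy, tips, q, strict = FALSE) {
  .require_branch_lengths(phy)
  allowed <- .tip_state_sets(phy, tips, strict = strict)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  children <- vector("list", nn)
  for (i in seq_len(nrow(edge)))
    children[[edge[i, 1]]] <- c(children[[edge[i, 1]]], i)
  D <- matrix(1, nn, 2)
  D[seq_len(ntip), ] <- ifelse(allowed, 1, 0)
  logscale <- numeric(nn)
  P <- vector("list", nn)
  node_order <- unique(edge[, 1])  # postorder of internal nodes
  for (v in node_order) {
    acc <- c(1, 1)
    ls <- 0
    for (i in children[[v]]) {
      ch <- edge[i, 2]
      Pe <- transition_matrix(q, elen[i])
      P[[ch]] <- Pe
      acc <- acc * as.vector(Pe %*% D[ch, ])
      ls <- ls + logscale[ch]
    }
    m <- sum(acc)
    if (m <= 0) {
      ## data impossible given constraints (e.g. Dollo with a gained tip)
      D[v, ] <- acc
      logscale[v] <- ls
    } else {
      D[v, ] <- acc / m
      logscale[v] <- ls + log(m)
    }
  }
  list(D = D, logscale = logscale, edge = edge, elen = elen, P = P,
       children = children, ntip = ntip, root = ntip + 1L)
}

#' Mk log-likelihood of tip data (pruning algorithm)
#'
#' Felsenstein pruning with per-node scaling; `NA` tips contribute the
#' partial likelihood `(1, 1)`; polytomies are handled natively.
#'
#' @param phy a labelled `phylo` with branch lengths.
#' @param tips named integer vector of tip states (`0`/`1`/`NA`).
#' @param q a `rate_matrix2`.
#' @param prior a `root_prior` (default flat).
#' @return the log-likelihood (`-Inf` if the data are impossible under the
#'   model, e.g. a Dollo constraint contradicted by the tips).
#' @export
mk_loglik <- function(phy, tips, q, prior = root_prior("flat")) {
  part <- .mk_partials_scaled(phy, tips, q)
  pv <- .prior_vector(prior, q)
  lik <- sum(pv * part$D[part$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + part$logscale[part$root]
}

## deterministic multistart maximisation over log-rates.
## fn takes a vector of rates (length k) and returns loglik.
.fit_rates <- function(fn, k, tree_height) {
  grid <- log(c(1e-3, 1e-2, 1e-1, 1, 10) / tree_height)
  starts <- if (k == 1) matrix(grid, ncol = 1) else
    as.matrix(expand.grid(grid, grid))
  lower <- log(1e-9 / tree_height)
  upper <- log(1e4 / tree_height)
  obj <- function(lp) -fn(exp(lp))
  vals <- apply(starts, 1, obj)
  ord <- order(vals)[seq_len(min(3, nrow(starts)))]
  best <- NULL
  for (i in ord) {
    o <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("rate optimisation failed to converge from every start")
  list(rates = exp(best$par), loglik = -best$value,
       convergence = best$convergence,
       at_lower = any(abs(best$par - lower) < 1e-6),
       at_upper = any(abs(best$par - upper) < 1e-6))
}

.tree_height <- function(phy) {
  .require_branch_lengths(phy)
  max(ape::node.depth.edgelength(phy))
}

#' Fit an ER or ARD Mk model by maximum likelihood
#'
#' Bounded quasi-Newton optimisation on the log-rate scale from a fixed
#' multistart grid spanning `1e-3` to `10` expected changes per tree height,
#' so the fit is deterministic. A constant character drives the rate to the
#' lower boundary and is flagged with a warning.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` (one rate, q01 = q10) or `"ARD"` (gain and loss rates
#'   free).
#' @return an object of class `mk_fit`: `rates` (`rate_matrix2`), `loglik`,
#'   `n_params`, `aic`, `model`, `prior`, `convergence`, `boundary`.
#' @export
fit_mk <- function(phy, tips, model = c("ER", "ARD"),
                   prior = root_prior("flat")) {
  model <- match.arg(model)
  obs <- tips[!is.na(tips)]
  if (length(unique(obs)) < 2L)
    warning("fewer than 2 distinct observed tip states; ",
            "rate is unidentifiable and will sit at the lower boundary")
  H <- .tree_height(phy)
  if (model == "ER") {
    fr <- .fit_rates(function(r) mk_loglik(phy, tips,
                                           rate_matrix(r[1], r[1]), prior),
                     1, H)
    q <- rate_matrix(fr$rates[1], fr$rates[1])
    k <- 1L
  } else {
    fr <- .fit_rates(function(r) mk_loglik(phy, tips,
                                           rate_matrix(r[1], r[2]), prior),
                     2, H)
    q <- rate_matrix(fr$rates[1], fr$rates[2])
    k <- 2L
  }
  structure(list(rates = q, loglik = fr$loglik, n_params = k,
                 aic = 2 * k - 2 * fr$loglik, model = model, prior = prior,
                 convergence = fr$convergence,
                 boundary = fr$at_lower || fr$at_upper),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("%s fit: q01 = %.6g, q10 = %.6g, lnL = %.4f, AIC = %.4f\n",
              x$model, x$rates$q01, x$rates$q10, x$loglik, x$aic))
  invisible(x)
}

#' Rank model fits by AIC
#'
#' @param fits list of `mk_fit` objects on identical data.
#' @return data frame sorted by AIC ascending (ties: fewer parameters first)
#'   with columns `model`, `n_params`, `loglik`, `aic`, `delta_aic`.
#' @export
compare_aic <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "mk_fit")))
  tab <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    n_params = vapply(fits, `[[`, 0L, "n_params"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aic = vapply(fits, `[[`, 0, "aic"))
  tab <- tab[order(tab$aic, tab$n_params), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}

#' Marginal ancestral state probabilities
#'
#' Standard marginal reconstruction: tipward partials from the pruning pass
#' are combined with rootward partials computed in a preorder sweep, giving
#' for every node the posterior probability of each state given all tip data,
#' the rates and the root prior. Tips with known state get probability 0/1.
#'
#' @inheritParams mk_loglik
#' @return named numeric vector over all node labels: `P(state = 1)`.
#' @export
marginal_ancestral <- function(phy, tips, q, prior = root_prior("flat")) {
  part <- .mk_partials_scaled(phy, tips, q)
  pv <- .prior_vector(prior, q)
  nn <- part$ntip + phy$Nnode
  D <- part$D
  ## U[v, ] = rootward partial: prior-weighted likelihood of everything
  ## outside subtree(v), as a function of the state at v (scaled per node)
  U <- matrix(NA_real_, nn, 2)
  U[part$root, ] <- pv
  edge <- part$edge
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[i, 1]; ch <- edge[i, 2]
    ## sibling contribution at p: product over other children of lifted D
    sib <- c(1, 1)
    for (j in part$children[[p]]) {
      sj <- edge[j, 2]
      if (sj == ch) next
      sib <- sib * as.vector(part$P[[sj]] %*% D[sj, ])
    }
    up_p <- U[p, ] * sib
    u <- as.vector(t(part$P[[ch]]) %*% up_p)
    m <- sum(u)
    U[ch, ] <- if (m > 0) u / m else u
  }
  post <- U * D
  tot <- rowSums(post)
  if (any(tot <= 0)) stop("data impossible under the given rates and prior")
  p1 <- post[, 2] / tot
  stats::setNames(p1, node_labels(phy))
}
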
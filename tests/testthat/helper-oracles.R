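# Independent brute-force oracles. These deliberately avoid the package's
# pruning/DP code paths: transition probabilities come from an eigen
# decomposition of the generator, likelihoods and parsimony scores from
# explicit enumeration over all ancestral assignments.

## random labelled tree, optionally with polytomies (short edges collapsed)
rand_tree <- function(n, seed, polytomies = FALSE) {
  set.seed(seed)
  phy <- ape::rtree(n)
  if (polytomies && n > 3) phy <- ape::di2multi(phy, tol = 0.25)
  tmevol:::.label_nodes(phy)
}

rand_tips <- function(phy, seed, p_na = 0.15) {
  set.seed(seed)
  n <- length(phy$tip.label)
  s <- sample(c(0L, 1L, NA_integer_), n, replace = TRUE,
              prob = c((1 - p_na) / 2, (1 - p_na) / 2, p_na))
  stats::setNames(s, phy$tip.label)
}

## 2-state transition matrix via eigen decomposition (independent of the
## package's closed form)
oracle_P <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  e <- eigen(Q)
  V <- e$vectors
  Re(V %*% diag(exp(e$values * t)) %*% solve(V))
}

## all full-state assignments compatible with the tips (free nodes = internal
## nodes plus unknown tips); returns a matrix, one row per assignment,
## columns in ape node order
.enum_assignments <- function(phy, tips) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  fixed <- rep(NA_integer_, nn)
  for (i in seq_len(ntip)) {
    s <- tips[[phy$tip.label[i]]]
    if (!is.null(s) && !is.na(s)) fixed[i] <- s
  }
  free <- which(is.na(fixed))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  out <- matrix(rep(fixed, each = nrow(grid)), nrow(grid), nn)
  out[, free] <- grid
  out
}

oracle_loglik <- function(phy, tips, q, prior = tmevol::root_prior("flat")) {
  pv <- switch(prior$kind,
               flat = c(0.5, 0.5),
               stationary = c(q$q10, q$q01) / (q$q01 + q$q10),
               fixed = if (prior$state == 0L) c(1, 0) else c(0, 1))
  A <- .enum_assignments(phy, tips)
  edge <- phy$edge
  Pe <- lapply(seq_len(nrow(edge)),
               function(i) oracle_P(q$q01, q$q10, phy$edge.length[i]))
  root <- length(phy$tip.label) + 1L
  tot <- 0
  for (r in seq_len(nrow(A))) {
    st <- A[r, ]
    w <- pv[st[root] + 1L]
    for (i in seq_len(nrow(edge)))
      w <- w * Pe[[i]][st[edge[i, 1]] + 1L, st[edge[i, 2]] + 1L]
    tot <- tot + w
  }
  log(tot)
}

oracle_marginal <- function(phy, tips, q, prior = tmevol::root_prior("flat")) {
  pv <- switch(prior$kind,
               flat = c(0.5, 0.5),
               stationary = c(q$q10, q$q01) / (q$q01 + q$q10),
               fixed = if (prior$state == 0L) c(1, 0) else c(0, 1))
  A <- .enum_assignments(phy, tips)
  edge <- phy$edge
  Pe <- lapply(seq_len(nrow(edge)),
               function(i) oracle_P(q$q01, q$q10, phy$edge.length[i]))
  root <- length(phy$tip.label) + 1L
  nn <- ncol(A)
  mass1 <- numeric(nn)
  tot <- 0
  for (r in seq_len(nrow(A))) {
    st <- A[r, ]
    w <- pv[st[root] + 1L]
    for (i in seq_len(nrow(edge)))
      w <- w * Pe[[i]][st[edge[i, 1]] + 1L, st[edge[i, 2]] + 1L]
    tot <- tot + w
    mass1 <- mass1 + w * st
  }
  stats::setNames(mass1 / tot, tmevol::node_labels(phy))
}

## exhaustive parsimony: min changes, per-node state sets over all optimal
## assignments, and min/max gains and losses across optimal assignments
oracle_parsimony <- function(phy, tips) {
  A <- .enum_assignments(phy, tips)
  edge <- phy$edge
  from <- edge[, 1]; to <- edge[, 2]
  changes <- apply(A, 1, function(st) sum(st[from] != st[to]))
  L <- min(changes)
  opt <- A[changes == L, , drop = FALSE]
  gains <- apply(opt, 1, function(st) sum(st[from] == 0L & st[to] == 1L))
  losses <- apply(opt, 1, function(st) sum(st[from] == 1L & st[to] == 0L))
  sets <- lapply(seq_len(ncol(opt)), function(j) sort(unique(opt[, j])))
  names(sets) <- tmevol::node_labels(phy)
  list(length = L, state_sets = sets,
       gains_range = c(min(gains), max(gains)),
       losses_range = c(min(losses), max(losses)))
}

## expected number of state changes on one branch, conditional on endpoints,
## from a finely discretised chain (step t/K)
oracle_expected_changes <- function(q01, q10, t, a, b, K = 10000L) {
  d <- t / K
  Pd <- oracle_P(q01, q10, d)
  ai <- a + 1L; bi <- b + 1L
  beta <- matrix(NA_real_, K + 1L, 2)  # beta[k+1, j] = P(end b | state j at k)
  beta[K + 1L, ] <- c(bi == 1L, bi == 2L)
  for (k in K:1) beta[k, ] <- Pd %*% beta[k + 1L, ]
  alpha <- c(ai == 1L, ai == 2L)
  total <- 0
  for (k in seq_len(K)) {
    ## joint P(X_{k-1} = i, X_k = j != i, X_K = b | X_0 = a), unnormalised
    total <- total + alpha[1] * Pd[1, 2] * beta[k + 1L, 2] +
                     alpha[2] * Pd[2, 1] * beta[k + 1L, 1]
    alpha <- as.vector(alpha %*% Pd)
  }
  total / beta[1L, ai]
}

## pectinate tree with k well-separated planted loss clades; eared backbone
planted_loss_tree <- function(k, nested = FALSE) {
  if (nested) {
    ## two eared lineages above the loss clade keep the root unambiguously
    ## eared, so the single loss must sit on the stem of C
    txt <- "(((x:1,(y:1,z:1)I:1)C:1,(o1:1,o2:1)O:1)A:1,o3:1)R;"
    phy <- tmevol::read_newick(txt)
    tips <- stats::setNames(c(0L, 0L, 0L, 1L, 1L, 1L),
                            c("x", "y", "z", "o1", "o2", "o3"))
    return(list(tree = phy, tips = tips, k = 1L))
  }
  core <- "e0:1"
  for (i in seq_len(k))
    core <- sprintf("(%s,((l%da:1,l%db:1):1,e%d:1):1):1", core, i, i, i)
  phy <- tmevol::read_newick(paste0("(", core, ",e999:2);"))
  tips <- stats::setNames(rep(1L, length(phy$tip.label)), phy$tip.label)
  tips[grep("^l", names(tips))] <- 0L
  list(tree = phy, tips = tips, k = k)
}

## hand-built stochastic map on a tree, for exercising the summary rules
fake_history <- function(phy, node_states) {
  labs <- tmevol::node_labels(phy)
  stopifnot(setequal(names(node_states), labs))
  ev <- stats::setNames(vector("list", length(labs)), labs)
  for (l in labs) ev[[l]] <- data.frame(t = numeric(0), state = integer(0))
  structure(list(node_states = node_states[labs], events = ev, tree = phy),
            class = "character_history")
}
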
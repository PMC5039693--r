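# Unordered parsimony for a binary character on a rooted tree.
#
# Sankoff dynamic programming over the postorder edge list, so polytomies are
# handled natively. Most-parsimonious-reconstruction (MPR) state sets come
# from a down-pass/up-pass (no enumeration). Directional bounds (minimum
# losses over all MPRs, minimum gains over all MPRs) use lexicographic cost
# pairs encoded exactly as integers: primary cost = number of changes,
# secondary = number of changes in the disfavoured direction, combined as
# primary * (E + 2) + secondary with E the edge count, so minimising the
# combined cost minimises changes first and the secondary count second, with
# no floating-point epsilon.

## tip label -> allowed-state matrix (ntip x 2, columns = states 0,1)
.tip_state_sets <- function(phy, tips, strict = TRUE) {
  ntip <- length(phy$tip.label)
  allowed <- matrix(TRUE, ntip, 2, dimnames = list(phy$tip.label, c("0", "1")))
  missing <- setdiff(phy$tip.label, names(tips))
  if (length(missing) && strict)
    stop("tips missing from the state map: ", paste(missing, collapse = ", "))
  for (i in seq_len(ntip)) {
    s <- unname(tips[phy$tip.label[i]])
    if (length(s) != 1L || is.na(s)) next
    if (!s %in% c(0L, 1L)) stop("tip state must be 0, 1 or NA")
    allowed[i, ] <- c(s == 0L, s == 1L)
  }
  allowed
}

## Sankoff down-pass: g[v, s] = min cost of subtree(v) given state s at v.
## cost is a 2x2 matrix, rows = parent state, cols = child state.
.sankoff_down <- function(phy, allowed, cost) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  g <- matrix(0, nn, 2)
  g[seq_len(ntip), ] <- ifelse(allowed, 0, Inf)
  m <- matrix(NA_real_, nn, 2)  # m[c, s] = min_t g[c, t] + cost[s, t]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    m[ch, 1] <- min(g[ch, 1] + cost[1, 1], g[ch, 2] + cost[1, 2])
    m[ch, 2] <- min(g[ch, 1] + cost[2, 1], g[ch, 2] + cost[2, 2])
    g[p, ] <- g[p, ] + m[ch, ]
  }
  list(g = g, m = m, edge = edge)
}

## up-pass: h[v, s] = min cost of everything outside subtree(v) given v = s
.sankoff_up <- function(down, phy, cost) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  h <- matrix(NA_real_, nn, 2)
  h[root, ] <- 0
  edge <- down$edge
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[i, 1]; ch <- edge[i, 2]
    rest <- h[p, ] + down$g[p, ] - down$m[ch, ]  # outside subtree(ch), by p state
    h[ch, 1] <- min(rest[1] + cost[1, 1], rest[2] + cost[2, 1])
    h[ch, 2] <- min(rest[1] + cost[1, 2], rest[2] + cost[2, 2])
  }
  h
}

## one optimal assignment under a cost matrix, greedy preorder traceback;
## ties broken toward state 0
.sankoff_traceback <- function(down, phy, cost) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  state <- integer(ntip + phy$Nnode)
  state[root] <- which.min(down$g[root, ]) - 1L
  edge <- down$edge
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    w <- down$g[ch, ] + cost[state[p] + 1L, ]
    state[ch] <- which.min(w) - 1L
  }
  state
}

.changes_of_assignment <- function(phy, state) {
  edge <- phy$edge
  labs <- node_labels(phy)
  from <- state[edge[, 1]]; to <- state[edge[, 2]]
  chg <- from != to
  data.frame(child = labs[edge[chg, 2]],
             direction = ifelse(to[chg] == 1L, "gain", "loss"),
             stringsAsFactors = FALSE)
}

#' Minimum number of changes (parsimony length)
#'
#' Sankoff generalisation of Fitch counting with unit costs; `NA` tips enter
#' with the full state set, polytomies are summed over directly.
#'
#' @param phy a labelled `phylo`.
#' @param tips named integer vector of tip states (`0`/`1`/`NA`).
#' @param strict error on tips absent from `tips` (default) instead of
#'   treating them as unknown.
#' @return integer: the minimum number of state changes over all ancestral
#'   assignments.
#' @export
fitch_length <- function(phy, tips, strict = TRUE) {
  allowed <- .tip_state_sets(phy, tips, strict)
  unit <- matrix(c(0, 1, 1, 0), 2, 2)
  down <- .sankoff_down(phy, allowed, unit)
  as.integer(min(down$g[length(phy$tip.label) + 1L, ]))
}

#' Summarise all most-parsimonious reconstructions
#'
#' Computes the parsimony length, the per-node MPR state sets (states realised
#' in at least one MPR, from the down/up passes), the `[min, max]` ranges of
#' gains and losses across MPRs (via lexicographic secondary costs), the
#' changes common to every MPR, and one concrete optimal assignment per
#' directional resolution.
#'
#' @inheritParams fitch_length
#' @return an object of class `parsimony_asr` with fields `length`,
#'   `state_sets`, `gains_range`, `losses_range`, `unambiguous_changes` and
#'   `resolutions` (per-resolution tallies and change lists).
#' @export
mpr_summary <- function(phy, tips, strict = TRUE) {
  allowed <- .tip_state_sets(phy, tips, strict)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  labs <- node_labels(phy)
  E <- nrow(phy$edge)
  unit <- matrix(c(0, 1, 1, 0), 2, 2)

  down <- .sankoff_down(phy, allowed, unit)
  L <- min(down$g[root, ])
  h <- .sankoff_up(down, phy, unit)
  total <- down$g + h
  in_set <- abs(total - L) < 0.5  # integer arithmetic; exact
  state_sets <- lapply(seq_len(nrow(in_set)), function(i)
    which(in_set[i, ]) - 1L)
  names(state_sets) <- labs

  ## lexicographic runs: secondary cost = losses (1->0) or gains (0->1)
  B <- E + 2
  cost_min_loss <- matrix(c(0, B + 1, B, 0), 2, 2)  # loss (row2,col1) costs B+1
  cost_min_gain <- matrix(c(0, B, B + 1, 0), 2, 2)
  res <- list()
  for (nm in c("min_losses", "min_gains")) {
    cost <- if (nm == "min_losses") cost_min_loss else cost_min_gain
    d <- .sankoff_down(phy, allowed, cost)
    st <- .sankoff_traceback(d, phy, cost)
    ch <- .changes_of_assignment(phy, st)
    res[[nm]] <- list(gains = sum(ch$direction == "gain"),
                      losses = sum(ch$direction == "loss"),
                      changes = ch,
                      node_states = stats::setNames(st, labs))
  }
  min_losses <- res$min_losses$losses
  min_gains <- res$min_gains$gains
  stopifnot(res$min_losses$gains + min_losses == L,
            min_gains + res$min_gains$losses == L)

  ## unambiguous changes: parent and child sets disjoint singletons
  sizes <- rowSums(in_set)
  e <- phy$edge
  unamb <- e[sizes[e[, 1]] == 1L & sizes[e[, 2]] == 1L, , drop = FALSE]
  if (nrow(unamb)) {
    ps <- apply(in_set[unamb[, 1], , drop = FALSE], 1, which) - 1L
    cs <- apply(in_set[unamb[, 2], , drop = FALSE], 1, which) - 1L
    keep <- ps != cs
    unambiguous <- data.frame(child = labs[unamb[keep, 2]],
                              direction = ifelse(cs[keep] == 1L, "gain",
                                                 "loss"),
                              stringsAsFactors = FALSE)
  } else {
    unambiguous <- data.frame(child = character(0), direction = character(0))
  }

  structure(list(length = as.integer(L),
                 state_sets = state_sets,
                 gains_range = c(min_gains, as.integer(L) - min_losses),
                 losses_range = c(min_losses, as.integer(L) - min_gains),
                 unambiguous_changes = unambiguous,
                 resolutions = res,
                 tree_labels = labs),
            class = "parsimony_asr")
}

#' @export
print.parsimony_asr <- function(x, ...) {
  cat("Parsimony reconstruction: length", x$length,
      "| gains in [", x$gains_range[1], ",", x$gains_range[2],
      "] | losses in [", x$losses_range[1], ",", x$losses_range[2], "]\n")
  cat(nrow(x$unambiguous_changes), "change(s) common to every MPR\n")
  invisible(x)
}

#' Tally gains and losses under an MPR resolution
#'
#' `min_losses` reports the reconstruction with the fewest losses (the
#' conservative "at least N losses" bound), `min_gains` the one with the
#' fewest gains, and `unambiguous_only` counts only changes shared by every
#' MPR. Under the first two, gains + losses equals the parsimony length.
#'
#' @param result a `parsimony_asr` from [mpr_summary()].
#' @param resolution one of `"min_gains"`, `"min_losses"`,
#'   `"unambiguous_only"`.
#' @return named integer vector `c(gains =, losses =)`.
#' @export
count_directed_changes <- function(result,
                                   resolution = c("min_losses", "min_gains",
                                                  "unambiguous_only")) {
  stopifnot(inherits(result, "parsimony_asr"))
  resolution <- match.arg(resolution)
  if (resolution == "unambiguous_only") {
    ch <- result$unambiguous_changes
    return(c(gains = sum(ch$direction == "gain"),
             losses = sum(ch$direction == "loss")))
  }
  r <- result$resolutions[[resolution]]
  c(gains = r$gains, losses = r$losses)
}
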
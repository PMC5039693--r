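# Synthetic data: Yule trees, forward-simulated binary Markov characters with
# recorded true change histories, and hierarchically dependent TM/TA/CO
# triples. These stand in for the study system (a published supermatrix tree
# plus a scored structure table), so every pipeline stage is testable without
# external downloads.

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed; the same seed reproduces the tree exactly.
#' @return a rooted, binary, ultrametric `phylo` with tips `t1..tN` and
#'   stable internal labels.
#' @export
yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  .label_nodes(phy)
}

## forward CTMC on one branch from a given state; returns events + end state
.forward_path <- function(start, t, q) {
  rates <- c(q$q01, q$q10)  # rate out of state 0, state 1
  st <- start
  now <- 0
  tt <- numeric(0); ss <- integer(0)
  repeat {
    r <- rates[st + 1L]
    if (r <= 0) break
    now <- now + stats::rexp(1, r)
    if (now >= t) break
    st <- 1L - st
    tt <- c(tt, now); ss <- c(ss, st)
  }
  list(events = data.frame(t = tt, state = ss), end = st)
}

#' Forward-simulate a binary Markov character on a tree
#'
#' Evolves a two-state continuous-time Markov character from `root_state`
#' down every branch, recording the full true change history.
#'
#' @param phy a labelled `phylo` with branch lengths.
#' @param q a `rate_matrix2` (true rates).
#' @param root_state state at the root (0 or 1).
#' @param seed integer seed.
#' @return an object of class `simulation_record`: `tree`, `tips` (named 0/1
#'   vector), `history` (a `character_history` holding the truth), `q_true`,
#'   `root_state`, `seed`.
#' @export
simulate_mk <- function(phy, q, root_state = 1L, seed = 1L) {
  .require_branch_lengths(phy)
  stopifnot(inherits(q, "rate_matrix2"), root_state %in% c(0L, 1L))
  set.seed(seed)
  labs <- node_labels(phy)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge; elen <- po$edge.length
  state <- integer(nn)
  state[ntip + 1L] <- as.integer(root_state)
  events <- vector("list", nn)
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[i, 1]; ch <- edge[i, 2]
    fp <- .forward_path(state[p], elen[i], q)
    state[ch] <- fp$end
    events[[ch]] <- fp$events
  }
  hist <- structure(list(node_states = stats::setNames(state, labs),
                         events = stats::setNames(events, labs),
                         tree = phy),
                    class = "character_history")
  structure(list(tree = phy,
                 tips = stats::setNames(state[seq_len(ntip)], phy$tip.label),
                 history = hist, q_true = q,
                 root_state = as.integer(root_state), seed = as.integer(seed)),
            class = "simulation_record")
}

#' Simulate hierarchically dependent TM/TA/CO triples
#'
#' The columella (the medial gate) evolves under its own Markov process;
#' the tympanic annulus and membrane evolve as latent Markov characters but
#' are expressed (present) only where the structure medial to them is
#' present: observed TA = latent TA AND CO; observed TM = latent TM AND
#' observed TA. Every generated row therefore satisfies the lateral-medial
#' dependency by construction and passes [complete_triple()] unchanged.
#'
#' @param phy a labelled `phylo` with branch lengths.
#' @param q_co rates for the columella process.
#' @param q_lateral rates for each latent lateral process (TA and TM).
#' @param seed integer seed.
#' @param root_eared start all processes in the present state (default) or
#'   all absent.
#' @return list with `matrix` (a completed `character_matrix`) and `truth`
#'   (the three true histories: `co`, `ta_latent`, `tm_latent`, plus the
#'   observed tip states).
#' @export
simulate_dependent_triple <- function(phy, q_co, q_lateral, seed = 1L,
                                      root_eared = TRUE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3L)
  root <- if (root_eared) 1L else 0L
  co <- simulate_mk(phy, q_co, root, seeds[1])
  ta <- simulate_mk(phy, q_lateral, root, seeds[2])
  tm <- simulate_mk(phy, q_lateral, root, seeds[3])
  ta_obs <- as.integer(ta$tips & co$tips)
  tm_obs <- as.integer(tm$tips & ta_obs)
  df <- data.frame(taxon = phy$tip.label,
                   tm = ifelse(tm_obs == 1L, "present", "absent"),
                   ta = ifelse(ta_obs == 1L, "present", "absent"),
                   co = ifelse(co$tips == 1L, "present", "absent"))
  list(matrix = character_matrix(df),
       truth = list(co = co, ta_latent = ta, tm_latent = tm,
                    ta_observed = stats::setNames(ta_obs, phy$tip.label),
                    tm_observed = stats::setNames(tm_obs, phy$tip.label),
                    seed = as.integer(seed)))
}
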
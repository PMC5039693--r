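# Tree I/O and node addressing.
#
# Trees are ordinary ape "phylo" objects. Every node (tip or internal) carries
# a unique label; internal nodes without a Newick label get one ("N<k>") when
# the tree is read or simulated. Labels are the stable node addresses used by
# every downstream module: ape's pruning keeps the labels of surviving nodes,
# so addresses never shift when taxa are dropped.

#' Node labels in ape numbering order
#'
#' Returns the vector of node addresses (tips first, then internal nodes) in
#' the order of ape's internal node numbering, so `node_labels(phy)[k]` is the
#' address of ape node `k`.
#'
#' @param phy a `phylo` object with complete node labels (see [read_newick()]).
#' @return character vector of length `Ntip + Nnode`.
#' @export
node_labels <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  c(phy$tip.label, phy$node.label)
}

## assign "N<k>" to internal nodes lacking a label; error on clashes
.label_nodes <- function(phy) {
  n_int <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  lab[is.na(lab)] <- ""
  need <- !nzchar(lab)
  lab[need] <- paste0("N", seq_len(n_int)[need] + length(phy$tip.label))
  phy$node.label <- lab
  all_lab <- c(phy$tip.label, lab)
  if (anyDuplicated(all_lab)) {
    stop("duplicate node labels: ",
         paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "))
  }
  phy
}

## strip bracketed comments ([...], incl. NHX annotations) outside quotes
.strip_comments <- function(text) {
  gsub("\\[[^]\\[]*\\]", "", text)
}

#' Read a rooted phylogeny from Newick text
#'
#' Parses a Newick string (or a file containing one), validates it, and
#' assigns stable labels to unlabelled internal nodes. Quoted labels are
#' allowed; underscores in unquoted labels are preserved verbatim. Bracketed
#' comments (including NHX annotations written by [write_annotated()]) are
#' stripped before parsing.
#'
#' @param text a Newick string, or the path of a file holding one.
#' @return a `phylo` object; branch lengths are absent if the input had none
#'   (likelihood operations will then refuse to run).
#' @export
read_newick <- function(text) {
  if (length(text) != 1L || !is.character(text) || !nzchar(trimws(text)))
    stop("empty Newick input")
  if (!grepl("\\(", text)) {
    if (!file.exists(text)) stop("empty Newick input (no '(' and no such file)")
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  ## balanced-parenthesis check with position of first offence
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_q <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_q <- !in_q
    if (in_q) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at character ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth,
                        " unclosed '(' at end of input")
  text <- .strip_comments(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: no tree found")
  unquote <- function(l) {
    q <- grepl("^'.*'$", l)
    l[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", l[q]))
    l
  }
  phy$tip.label <- unquote(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unquote(phy$node.label)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  if (any(!nzchar(phy$tip.label))) stop("empty leaf label")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length")
  if (phy$Nnode >= 1L) {
    root <- length(phy$tip.label) + 1L
    if (sum(phy$edge[, 1] == root) == 1L)
      warning("root has a single child (degree-1 root retained)")
  }
  .label_nodes(phy)
}

.require_branch_lengths <- function(phy) {
  if (is.null(phy$edge.length))
    stop("branch lengths required but absent from tree")
  invisible(phy)
}

#' Prune a tree to a set of taxa
#'
#' Keeps the requested tips, suppresses the resulting degree-2 internal nodes
#' (summing their branch lengths, so pairwise path lengths among kept taxa are
#' preserved), and reports which requested names were absent and which tips
#' were dropped. Node labels of surviving nodes are untouched.
#'
#' @param phy a `phylo` from [read_newick()].
#' @param keep character vector of taxon names to retain.
#' @return list with `tree` (pruned `phylo`) and `dropped` (tips removed).
#' @export
prune_to_taxa <- function(phy, keep) {
  stopifnot(inherits(phy, "phylo"))
  keep_in <- intersect(keep, phy$tip.label)
  if (length(keep_in) == 0L)
    stop("none of the requested taxa occur in the tree")
  dropped <- setdiff(phy$tip.label, keep_in)
  if (length(dropped) == 0L)
    return(list(tree = phy, dropped = character(0)))
  out <- ape::keep.tip(phy, keep_in)
  list(tree = out, dropped = dropped)
}

.quote_label <- function(lab) {
  ifelse(grepl("[ ()\\[\\]:;,']", lab),
         paste0("'", gsub("'", "''", lab), "'"),
         lab)
}

#' Write a tree with per-node annotations
#'
#' Serializes the tree as Newick with NHX-style comments
#' (`[&&NHX:key=value:...]`) attached to annotated nodes — a machine-readable
#' analogue of pie-chart figures. With no annotations the output is plain
#' Newick with internal labels. The output round-trips through
#' [read_newick()] without loss of topology or branch lengths.
#'
#' @param phy a labelled `phylo`.
#' @param annotations named list: node label -> named list/vector of
#'   key=value pairs. Unknown node labels are an error.
#' @param file optional path; when given the text is also written there.
#' @return the serialized tree, invisibly when `file` is given.
#' @export
write_annotated <- function(phy, annotations = list(), file = NULL) {
  stopifnot(inherits(phy, "phylo"))
  labs <- node_labels(phy)
  if (length(annotations)) {
    bad <- setdiff(names(annotations), labs)
    if (length(bad))
      stop("annotation on unknown node id: ", paste(bad, collapse = ", "))
  }
  ntip <- length(phy$tip.label)
  children <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1]]] <- c(children[[phy$edge[i, 1]]], phy$edge[i, 2])
  elen <- rep(NA_real_, ntip + phy$Nnode)
  if (!is.null(phy$edge.length)) elen[phy$edge[, 2]] <- phy$edge.length
  nhx <- function(lab) {
    a <- annotations[[lab]]
    if (is.null(a) || !length(a)) return("")
    kv <- paste0(names(a), "=", vapply(a, format, "", digits = 15))
    paste0("[&&NHX:", paste(kv, collapse = ":"), "]")
  }
  serialize <- function(node) {
    lab <- labs[node]
    core <- if (node <= ntip) {
      .quote_label(lab)
    } else {
      paste0("(", paste(vapply(children[[node]], serialize, ""),
                        collapse = ","), ")", .quote_label(lab))
    }
    out <- paste0(core, nhx(lab))
    if (!is.na(elen[node]))
      out <- paste0(out, ":", format(elen[node], digits = 15))
    out
  }
  root <- ntip + 1L
  txt <- paste0(serialize(root), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
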
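# End-to-end orchestration: load tree and character table, reconcile taxa,
# run per-structure parsimony reconstructions, ER/ARD model comparison, the
# three stochastic-mapping scenarios, and consolidate gains/losses into one
# report. Clade scoping is by MRCA of user-named anchor taxa, never by
# hardcoded taxonomy, so the pipeline runs on any tree.

.default_config <- function() {
  list(scope = list(anchors = NULL),
       parsimony = list(resolution = "min_losses"),
       mk = list(prior = "flat"),
       simmap = list(n_sims = 10000L, threshold = 0.5, seed = 1L))
}

.merge_config <- function(user) {
  cfg <- .default_config()
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  cfg
}

.input_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(unname(tools::md5sum(x)))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Count independent complete losses from a parsimony reconstruction
#'
#' The "lost at least N independent times" bound: the number of
#' present-to-absent edges in the most-parsimonious reconstruction with the
#' fewest losses. Nested losses inside an already-lost clade are not counted
#' because the reconstruction keeps the whole clade absent.
#'
#' @param result a `parsimony_asr` from [mpr_summary()], typically for the
#'   columella over the full tree.
#' @return integer lower bound on independent losses, with the contributing
#'   edges (child node labels) in attribute `"edges"`.
#' @export
count_independent_losses <- function(result) {
  stopifnot(inherits(result, "parsimony_asr"))
  ch <- result$resolutions$min_losses$changes
  loss <- ch[ch$direction == "loss", , drop = FALSE]
  structure(nrow(loss), edges = loss$child)
}

.parsimony_block <- function(phy, tips) {
  r <- mpr_summary(phy, tips, strict = FALSE)
  list(result = r,
       length = r$length,
       gains_range = r$gains_range,
       losses_range = r$losses_range,
       min_losses = as.list(count_directed_changes(r, "min_losses")),
       min_gains = as.list(count_directed_changes(r, "min_gains")),
       unambiguous = as.list(count_directed_changes(r, "unambiguous_only")))
}

#' Run the full tympanic-middle-ear analysis
#'
#' Reads a rooted tree and a TM/TA/CO character table, completes the coding
#' under the dependency rules, reconciles taxa (scored taxa absent from the
#' tree are dropped with a warning; unscored tips become unknown), and then:
#' reconstructs each structure by parsimony on the focal clade, counts
#' independent columella losses over the whole tree, compares ER vs ARD Mk
#' fits by AIC for ear (columella) presence, and runs the three
#' stochastic-mapping scenarios. All randomness derives from the configured
#' seed.
#'
#' @param tree a `phylo` or a Newick file path.
#' @param matrix a `character_matrix` or a TSV file path
#'   (see [read_character_table()]).
#' @param config nested list overriding the defaults: `scope$anchors` (two or
#'   more tip names whose MRCA bounds the focal clade; `NULL` = whole tree),
#'   `simmap$n_sims`, `simmap$threshold`, `simmap$seed`,
#'   `parsimony$resolution`.
#' @param out_dir optional directory; when given, writes `report.json`,
#'   per-structure `node_states_*.tsv`, per-scenario posterior TSVs and
#'   annotated trees there.
#' @return an `analysis_report` list; see the fields written to
#'   `report.json`.
#' @export
run_full_analysis <- function(tree, matrix, config = list(), out_dir = NULL) {
  cfg <- .merge_config(config)
  tree_hash <- .input_hash(tree)
  matrix_hash <- .input_hash(matrix)
  phy <- if (inherits(tree, "phylo")) tree else read_newick(tree)
  m <- if (inherits(matrix, "character_matrix")) matrix
       else read_character_table(matrix)

  extra <- setdiff(m$taxon, phy$tip.label)
  if (length(extra))
    warning(length(extra), " scored taxa absent from the tree were dropped")
  unscored <- setdiff(phy$tip.label, m$taxon)

  ## focal clade (e.g. a family) by MRCA of anchor taxa
  anchors <- cfg$scope$anchors
  scoped <- phy
  if (!is.null(anchors)) {
    bad <- setdiff(anchors, phy$tip.label)
    if (length(bad)) stop("anchor taxa not in tree: ",
                          paste(bad, collapse = ", "))
    mrca <- ape::getMRCA(phy, anchors)
    scoped <- ape::extract.clade(phy, mrca)
  }

  tip_map <- function(structure, tree_scope) {
    v <- extract_binary(m, structure)
    out <- stats::setNames(rep(NA_integer_, length(tree_scope$tip.label)),
                           tree_scope$tip.label)
    common <- intersect(names(v), tree_scope$tip.label)
    out[common] <- v[common]
    out
  }

  parsimony <- lapply(c(TM = "TM", TA = "TA", CO = "CO"), function(s)
    .parsimony_block(scoped, tip_map(s, scoped)))

  ## whole-tree columella reconstruction -> independent complete-loss bound
  co_full <- mpr_summary(phy, tip_map("CO", phy), strict = FALSE)
  full_losses <- count_independent_losses(co_full)

  ## Mk model selection on ear (columella) presence within the focal clade
  eared <- tip_map("CO", scoped)
  fit_er <- fit_mk(scoped, eared, model = "ER")
  fit_ard <- fit_mk(scoped, eared, model = "ARD")
  aic_table <- compare_aic(list(fit_er, fit_ard))

  scenarios <- list()
  seeds <- cfg$simmap$seed + 0:2
  names(seeds) <- c("er_unconstrained", "er_root_eared", "dollo")
  for (nm in names(seeds)) {
    sc <- scenario_config(nm, n_sims = cfg$simmap$n_sims,
                          threshold = cfg$simmap$threshold, seed = seeds[[nm]])
    scenarios[[nm]] <- run_scenario(scoped, eared, sc)
  }

  report <- structure(list(
    provenance = list(tree_hash = tree_hash, matrix_hash = matrix_hash,
                      n_tips = length(phy$tip.label),
                      n_tips_scoped = length(scoped$tip.label),
                      n_scored = nrow(m),
                      dropped_taxa = length(extra),
                      unscored_tips = length(unscored),
                      inconsistent_rows = nrow(attr(m, "inconsistent")),
                      seed = cfg$simmap$seed,
                      config = cfg,
                      version = as.character(utils::packageVersion("tmevol"))),
    parsimony = parsimony,
    full_tree_columella = list(length = co_full$length,
                               independent_losses = as.integer(full_losses),
                               loss_edges = attr(full_losses, "edges")),
    model_comparison = aic_table,
    scenarios = scenarios,
    trees = list(full = phy, scoped = scoped)),
    class = "analysis_report")

  if (!is.null(out_dir)) .write_report(report, parsimony, scenarios, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("TME analysis report\n")
  cat(sprintf("  tree: %d tips (%d in focal clade), %d scored taxa\n",
              x$provenance$n_tips, x$provenance$n_tips_scoped,
              x$provenance$n_scored))
  for (s in names(x$parsimony)) {
    p <- x$parsimony[[s]]
    cat(sprintf("  %s parsimony: length %d, gains [%d,%d], losses [%d,%d]\n",
                s, p$length, p$gains_range[1], p$gains_range[2],
                p$losses_range[1], p$losses_range[2]))
  }
  cat(sprintf("  whole-tree columella: lost at least %d independent times\n",
              x$full_tree_columella$independent_losses))
  cat(sprintf("  model selection: %s preferred (delta AIC %.2f)\n",
              x$model_comparison$model[1], x$model_comparison$delta_aic[2]))
  for (nm in names(x$scenarios)) {
    s <- x$scenarios[[nm]]
    cat(sprintf("  %s: %d gains, %d losses (threshold rule)\n",
                nm, s$threshold_gains, s$threshold_losses))
  }
  invisible(x)
}

.node_state_tsv <- function(result, phy, path) {
  labs <- node_labels(phy)
  sets <- vapply(result$state_sets[labs], paste, "", collapse = "|")
  utils::write.table(
    data.frame(node = labs, states = sets,
               is_leaf = labs %in% phy$tip.label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_report <- function(report, parsimony, scenarios, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scoped <- report$trees$scoped
  for (s in names(parsimony))
    .node_state_tsv(parsimony[[s]]$result, scoped,
                    file.path(out_dir, paste0("node_states_", s, ".tsv")))
  for (nm in names(scenarios)) {
    sm <- scenarios[[nm]]
    utils::write.table(
      data.frame(node = names(sm$node_posterior),
                 posterior_present = sm$node_posterior,
                 called = sm$called),
      file.path(out_dir, paste0("posterior_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- lapply(sm$node_posterior, function(p) list(p1 = signif(p, 6)))
    write_annotated(scoped, ann,
                    file = file.path(out_dir, paste0("annotated_", nm,
                                                     ".tre")))
  }
  json <- unclass(report)
  json$trees <- NULL
  json$parsimony <- lapply(json$parsimony, function(p) p[setdiff(names(p),
                                                                 "result")])
  json$scenarios <- lapply(json$scenarios, function(s)
    list(threshold_gains = s$threshold_gains,
         threshold_losses = s$threshold_losses,
         mean_gains = s$mean_gains, mean_losses = s$mean_losses,
         rate = list(q01 = s$rate$q01, q10 = s$rate$q10),
         n_maps = s$n_maps, seed = s$config$seed))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
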
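#' Robinson-Foulds distance between two trees
#'
#' The bipartition symmetric difference: the number of non-trivial splits
#' present in exactly one of the two unrooted topologies. Zero if and only
#' if the topologies are identical.
#'
#' @param a,b Trees as `phylo` objects, Newick strings, or paths to Newick
#'   files; leaf sets must match.
#' @return Integer distance.
#' @export
compare_trees <- function(a, b) {
  a <- as_tree(a); b <- as_tree(b)
  if (!setequal(a$tip.label, b$tip.label)) stop("trees have different leaf sets")
  sa <- unrooted_splits(a); sb <- unrooted_splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

as_tree <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1) {
    tr <- if (!grepl("\\(", x) && file.exists(x)) ape::read.tree(x)
          else ape::read.tree(text = x)
    # Newick convention: underscores in unquoted labels stand for spaces
    tr$tip.label <- gsub("_", " ", tr$tip.label)
    return(tr)
  }
  stop("cannot interpret input as a tree")
}

#' Replicate the full study analysis
#'
#' Runs the complete pipeline on the bundled microphthalmid matrix: two-step
#' heuristic search (random addition + TBR), branch collapse under both
#' conventions, ensemble CI/RI under both uninformative-character
#' conventions, strict consensus with outgroup rooting, and per-tree ACCTRAN
#' change mapping. Optionally writes `report.json`, `mpts.nwk`,
#' `consensus.nwk`, `characters.tsv` and `annotations.tsv` to a directory.
#'
#' @param config A [search_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `run_report`; see Details.
#' @details The report contains: `matrix` (dimensions and outgroup),
#'   `config` echo; `best_length`; `n_mpts` (named by collapse rule);
#'   `ci`/`ri` and `ci_excl`/`ri_excl` (all-characters and
#'   uninformative-excluded conventions, from the first tree);
#'   `consensus` (rooted strict consensus, Newick); `mpts` (collapsed trees
#'   under the configured rule, Newick); `annotations` (list of per-tree
#'   change tables); `diagnostics` (per-character m/s/g table).
#' @export
run_replication <- function(config = search_config(), out_dir = NULL) {
  m <- load_study_matrix()
  sr <- heuristic_search(m, config)
  coll <- list(
    min_length_zero = collapse_and_dedupe(sr$trees, m, "min_length_zero"),
    max_length_zero = collapse_and_dedupe(sr$trees, m, "max_length_zero"),
    none = collapse_and_dedupe(sr$trees, m, "none"))
  stats_all <- ensemble_indices(sr$trees[[1]], m, exclude_uninformative = FALSE)
  stats_ex <- ensemble_indices(sr$trees[[1]], m, exclude_uninformative = TRUE)
  mpts <- coll[[config$collapse_rule]]
  cons <- strict_consensus(mpts)
  cons_rooted <- root_with_outgroup(cons, m$outgroup)
  annot <- lapply(seq_along(sr$trees), function(i) {
    rooted <- root_with_outgroup(sr$trees[[i]], m$outgroup)
    rec <- acctran_reconstruct(rooted, m)
    cbind(tree = i, annotate_internodes(rooted, rec))
  })
  report <- structure(list(
    matrix = list(n_taxa = length(m$taxa), n_chars = ncol(m$cells),
                  outgroup = m$outgroup),
    config = unclass(config),
    best_length = sr$best_length,
    n_binary_trees = length(sr$trees),
    n_mpts = vapply(coll, length, 0L),
    ci = stats_all$ci, ri = stats_all$ri,
    ci_excl = stats_ex$ci, ri_excl = stats_ex$ri,
    replicates_hitting_best = sr$replicates_hitting_best,
    truncated = sr$truncated,
    consensus = ape::write.tree(cons_rooted),
    mpts = vapply(mpts, ape::write.tree, ""),
    annotations = annot,
    diagnostics = stats_all$per_char), class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- report[c("matrix", "config", "best_length", "n_binary_trees",
                     "n_mpts", "ci", "ri", "ci_excl", "ri_excl",
                     "replicates_hitting_best", "truncated", "consensus")]
    json$n_mpts <- as.list(json$n_mpts)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report$mpts, file.path(out_dir, "mpts.nwk"))
    writeLines(report$consensus, file.path(out_dir, "consensus.nwk"))
    write.table(report$diagnostics, file.path(out_dir, "characters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, report$annotations),
                file.path(out_dir, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("replication report\n")
  cat(sprintf("  matrix: %d taxa x %d characters (%d outgroup taxa)\n",
              x$matrix$n_taxa, x$matrix$n_chars, length(x$matrix$outgroup)))
  cat(sprintf("  best length: %d steps (%d binary trees)\n",
              x$best_length, x$n_binary_trees))
  cat(sprintf("  distinct MPTs: %s\n",
              paste(names(x$n_mpts), x$n_mpts, sep = "=", collapse = ", ")))
  cat(sprintf("  CI %.4f RI %.4f (all characters); CI %.4f RI %.4f (informative only)\n",
              x$ci, x$ri, x$ci_excl, x$ri_excl))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}
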
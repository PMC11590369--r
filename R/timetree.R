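#' Time-calibrated tree with node ages and sampled-ancestor flags
#'
#' A `time_tree` wraps an [ape::phylo] topology with absolute node ages in
#' Ma before present. Branch durations are always derived as
#' `age(parent) - age(child)`, never stored independently, so ages and
#' lengths cannot drift apart. A fossil tip sitting at the end of a
#' zero-length pendant branch is flagged as a sampled ancestor: it lies on
#' the ancestral lineage rather than beside it.
#'
#' @param phy A rooted `phylo` object. If `ages` is `NULL`, `phy$edge.length`
#'   is interpreted as durations in Ma and the youngest tip is placed at 0.
#' @param ages Optional numeric vector of node ages (Ma), indexed by ape node
#'   number (tips `1..Ntip`, then internal nodes). Overrides edge lengths.
#' @param calibrations Optional tibble with columns `taxon`, `min_age`,
#'   `max_age` giving stratigraphic age ranges for fossil tips.
#' @param sa_tol Pendant branches shorter than this (Ma) mark sampled
#'   ancestors.
#' @return An object of class `time_tree`.
#' @export
time_tree <- function(phy, ages = NULL, calibrations = NULL, sa_tol = 1e-8) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a phylo object")
  if (!ape::is.rooted(phy)) stop("`phy` must be rooted")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (is.null(ages)) {
    if (is.null(phy$edge.length)) stop("need `ages` or edge lengths on `phy`")
    if (any(phy$edge.length < 0)) stop("negative branch length")
    depth <- ape::node.depth.edgelength(phy)
    ages <- max(depth[seq_len(ntip)]) - depth
    ages[abs(ages) < sa_tol] <- 0
  }
  if (length(ages) != ntip + nnode) stop("`ages` must have one entry per node")
  obj <- structure(
    list(phy = phy, ages = as.numeric(ages), calibrations = calibrations),
    class = "time_tree"
  )
  obj$phy$edge.length <- branch_durations(obj)
  obj$sampled_ancestor <- detect_sampled_ancestors(obj, sa_tol)
  validate_time_tree(obj)
  obj
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf(
    "time_tree: %d tips (%d fossil, %d sampled ancestors), root age %.4g Ma\n",
    ape::Ntip(x$phy), sum(tip_ages(x) > 0), sum(x$sampled_ancestor),
    root_age(x)
  ))
  invisible(x)
}

#' @rdname time_tree
#' @param x,tree A `time_tree`.
#' @export
branch_durations <- function(tree) {
  e <- tree$phy$edge
  tree$ages[e[, 1]] - tree$ages[e[, 2]]
}

#' @rdname time_tree
#' @export
root_age <- function(tree) tree$ages[ape::Ntip(tree$phy) + 1L]

#' @rdname time_tree
#' @export
tip_ages <- function(tree) {
  stats::setNames(tree$ages[seq_len(ape::Ntip(tree$phy))], tree$phy$tip.label)
}

detect_sampled_ancestors <- function(tree, sa_tol = 1e-8) {
  ntip <- ape::Ntip(tree$phy)
  sa <- logical(ntip + tree$phy$Nnode)
  dur <- branch_durations(tree)
  tip_edges <- tree$phy$edge[, 2] <= ntip
  sa[tree$phy$edge[tip_edges, 2]] <- dur[tip_edges] <= sa_tol
  sa
}

#' Validate the age invariants of a time_tree
#'
#' Parent age must strictly exceed child age except across the zero-length
#' attachment branch of a sampled ancestor; all ages are non-negative.
#'
#' @param tree A `time_tree`.
#' @param tol Numerical slack in Ma.
#' @return `tree`, invisibly; errors describe the first violated invariant.
#' @export
validate_time_tree <- function(tree, tol = 1e-9) {
  if (any(tree$ages < -tol)) stop("negative node age")
  e <- tree$phy$edge
  dur <- branch_durations(tree)
  if (any(dur < -tol)) stop("parent younger than child")
  zero <- which(dur <= tol)
  bad <- zero[!(e[zero, 2] <= ape::Ntip(tree$phy))]
  if (length(bad)) stop("zero-length internal branch")
  invisible(tree)
}

#' @export
as.phylo.time_tree <- function(x, ...) x$phy

#' Read and write time trees
#'
#' Trees are serialized as Newick with durations (Ma) as branch lengths and
#' the root age carried in a `[&root_age=...]` metadata comment, so absolute
#' ages round-trip losslessly. `dialect = "nexus"` wraps the same string in a
#' TREES block. `annotate = FALSE` writes plain branch-length-only Newick for
#' interoperability.
#'
#' @param tree A `time_tree`.
#' @param path File path.
#' @param dialect `"newick"` or `"nexus"`.
#' @param annotate Include the root-age metadata comment?
#' @return `read_tree` returns a `time_tree`; `write_tree` returns `path`
#'   invisibly.
#' @export
write_tree <- function(tree, path, dialect = c("newick", "nexus"),
                       annotate = TRUE) {
  dialect <- match.arg(dialect)
  nwk <- ape::write.tree(tree$phy)
  if (annotate) {
    nwk <- sub(";$", sprintf("[&root_age=%.12g];", root_age(tree)), nwk)
  }
  lines <- switch(dialect,
    newick = nwk,
    nexus = c("#NEXUS", "BEGIN TREES;", paste0("  TREE tree1 = ", nwk),
              "END;")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path, dialect = c("newick", "nexus")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "nexus") {
    ln <- grep("=", lines, value = TRUE)[1]
    if (is.na(ln)) stop("no TREE statement found in NEXUS file")
    lines <- sub("^[^=]*=\\s*", "", ln)
  }
  txt <- paste(lines, collapse = "")
  ra <- NA_real_
  m <- regmatches(txt, regexpr("\\[&root_age=[-0-9.eE+]+\\]", txt))
  if (length(m)) ra <- as.numeric(sub("\\[&root_age=", "", sub("\\]", "", m)))
  plain <- gsub("\\[[^]]*\\]", "", txt)
  phy <- ape::read.tree(text = plain)
  if (is.null(phy)) stop("could not parse Newick string")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  depth <- ape::node.depth.edgelength(phy)
  if (is.na(ra)) ra <- max(depth[seq_len(ape::Ntip(phy))])
  time_tree(phy, ages = ra - depth)
}

#' Tidy per-node table of a time tree
#'
#' @param x A `time_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: node id, label (tips), age,
#'   parent id, branch duration, sampled-ancestor flag.
#' @export
tidy.time_tree <- function(x, ...) {
  ntip <- ape::Ntip(x$phy)
  n <- ntip + x$phy$Nnode
  parent <- rep(NA_integer_, n)
  parent[x$phy$edge[, 2]] <- x$phy$edge[, 1]
  tibble::tibble(
    node = seq_len(n),
    label = c(x$phy$tip.label, rep(NA_character_, x$phy$Nnode)),
    is_tip = seq_len(n) <= ntip,
    age = x$ages,
    parent = parent,
    duration = ifelse(is.na(parent), NA_real_, x$ages[parent] - x$ages),
    sampled_ancestor = x$sampled_ancestor
  )
}
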
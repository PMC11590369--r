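#' Highest posterior density interval
#'
#' Shortest contiguous window of sorted samples containing
#' `ceiling(mass * n)` points.
#'
#' @param samples Numeric vector.
#' @param mass Posterior mass (default 0.95).
#' @return `c(lower, upper)`; degenerate (zero-width, with a warning) when
#'   fewer than 2 samples.
#' @export
hpd <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 2) {
    warning("fewer than 2 samples: degenerate HPD")
    return(c(samples[1] %||% NA_real_, samples[1] %||% NA_real_))
  }
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  # shortest window covering exactly m order statistics
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Consensus trees from a posterior sample
#'
#' Majority-rule keeps splits with frequency > 0.5; `allcompat` (maximum
#' compatible / greedy consensus) then adds remaining splits in decreasing
#' frequency order whenever compatible with those already kept (frequency
#' ties broken by lexicographic split encoding). Node ages are summarized
#' (median and 95% HPD) over the samples that contain each clade.
#'
#' @param trees List of dated `phylo` objects (durations as edge lengths)
#'   on a common taxon set, or an `mcmc_trace`.
#' @param mode `"majrule"` or `"allcompat"`.
#' @param burnin Fraction discarded when an `mcmc_trace` is given.
#' @return A `consensus_tree`: `tree` (a [time_tree]), and `nodes`, a
#'   tibble with clade posterior probability, median age and HPD.
#' @export
consensus_tree <- function(trees, mode = c("majrule", "allcompat"),
                           burnin = 0) {
  mode <- match.arg(mode)
  if (inherits(trees, "mcmc_trace")) trees <- trace_trees(trees, burnin)
  if (!length(trees)) stop("no trees supplied")
  labs <- sort(trees[[1]]$tip.label)
  if (!all(vapply(trees, function(t) {
    identical(sort(t$tip.label), labs)
  }, logical(1)))) stop("taxon sets differ across trees")

  n <- length(trees)
  # clade age samples keyed by split
  ages_by_clade <- new.env(hash = TRUE)
  counts <- new.env(hash = TRUE)
  for (tr in trees) {
    ntip <- ape::Ntip(tr)
    depth <- ape::node.depth.edgelength(tr)
    nage <- max(depth[seq_len(ntip)]) - depth
    desc <- clade_descendants(tr)
    for (v in (ntip + 1L):(ntip + tr$Nnode)) {
      key <- paste(sort(tr$tip.label[desc[[v - ntip]]]), collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
      ages_by_clade[[key]] <- c(ages_by_clade[[key]], nage[v])
    }
  }
  freq <- unlist(as.list(counts)) / n
  ord <- order(-freq, names(freq))
  freq <- freq[ord]
  keep <- character(0)
  keep_sets <- list()
  for (key in names(freq)) {
    cl <- strsplit(key, "|", fixed = TRUE)[[1]]
    take <- freq[key] > 0.5 ||
      (mode == "allcompat" &&
         all(vapply(keep_sets, compatible_splits, logical(1), b = cl)))
    if (take) {
      keep <- c(keep, key)
      keep_sets <- c(keep_sets, list(cl))
    }
  }
  build_consensus(labs, keep, freq, ages_by_clade)
}

clade_descendants <- function(tr) {
  ntip <- ape::Ntip(tr)
  desc <- vector("list", tr$Nnode)
  for (ei in ape::postorder(tr)) {
    p <- tr$edge[ei, 1]; ch <- tr$edge[ei, 2]
    add <- if (ch <= ntip) ch else desc[[ch - ntip]]
    desc[[p - ntip]] <- c(desc[[p - ntip]], add)
  }
  desc
}

compatible_splits <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

build_consensus <- function(labs, keys, freq, ages_by_clade) {
  # order kept clades by size, largest first; nest them into a tree
  sets <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  root_key <- paste(labs, collapse = "|")
  if (!root_key %in% keys) {
    keys <- c(keys, root_key); sets <- c(sets, list(labs))
  }
  sz <- lengths(sets)
  ord <- order(-sz)
  keys <- keys[ord]; sets <- sets[ord]
  node_summary <- purrr::map_dfr(seq_along(keys), function(i) {
    a <- ages_by_clade[[keys[i]]]
    h <- if (length(a) >= 2) hpd(a) else c(a %||% NA_real_, a %||% NA_real_)
    tibble::tibble(
      clade = keys[i], size = length(sets[[i]]),
      pp = {
        f <- unname(freq[keys[i]])
        if (is.na(f)) 1 else min(1, f)
      },
      median_age = stats::median(a), hpd_lower = h[1], hpd_upper = h[2])
  })
  # recursive newick construction
  emit <- function(members, self_idx) {
    kids_idx <- c()
    claimed <- character(0)
    for (j in seq_along(keys)) {
      if (j == self_idx) next
      s <- sets[[j]]
      if (length(s) < length(members) && all(s %in% members) &&
          !any(s %in% claimed)) {
        kids_idx <- c(kids_idx, j); claimed <- c(claimed, s)
      }
    }
    singles <- setdiff(members, claimed)
    parts <- c(
      vapply(kids_idx, function(j) emit(sets[[j]], j), character(1)),
      singles
    )
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  root_idx <- which(keys == root_key)
  nwk <- paste0(emit(labs, root_idx), ";")
  phy <- ape::read.tree(text = nwk)
  # ages: per consensus node, median age of its clade
  ntip <- ape::Ntip(phy)
  desc <- clade_descendants(phy)
  ages <- numeric(ntip + phy$Nnode)
  med <- stats::setNames(node_summary$median_age, node_summary$clade)
  tip_age_med <- vapply(labs, function(l) {
    a <- ages_by_clade[[l]]
    if (is.null(a)) 0 else stats::median(a)
  }, numeric(1))
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    key <- paste(sort(phy$tip.label[desc[[v - ntip]]]), collapse = "|")
    ages[v] <- med[key]
  }
  ages[seq_len(ntip)] <- 0
  # enforce monotonicity for unresolved parts (parent at least child age)
  for (ei in ape::postorder(phy)) {
    p <- phy$edge[ei, 1]; ch <- phy$edge[ei, 2]
    if (ages[p] < ages[ch]) ages[p] <- ages[ch]
  }
  tt <- time_tree(phy, ages = ages)
  structure(list(tree = tt, nodes = node_summary),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("consensus_tree: %d tips, %d summarized clades\n",
              ape::Ntip(x$tree$phy), nrow(x$nodes)))
  invisible(x)
}

#' @export
tidy.consensus_tree <- function(x, ...) x$nodes

#' Age of a clade's most recent common ancestor across a posterior sample
#'
#' The MRCA of the named taxa is located in every sampled tree (whether or
#' not the clade is monophyletic there) and its age collected; the summary
#' is the sample median and 95% HPD.
#'
#' @param trees List of dated `phylo` (durations as edge lengths) or an
#'   `mcmc_trace`.
#' @param taxa Character vector (>= 2) defining the clade.
#' @param burnin Fraction discarded for an `mcmc_trace`.
#' @return One-row tibble: median age, HPD bounds, n.
#' @export
mrca_age_summary <- function(trees, taxa, burnin = 0) {
  if (inherits(trees, "mcmc_trace")) trees <- trace_trees(trees, burnin)
  ages <- vapply(trees, function(tr) {
    if (!all(taxa %in% tr$tip.label)) stop("unknown taxon in clade")
    ntip <- ape::Ntip(tr)
    node <- if (length(taxa) == 1L) {
      match(taxa, tr$tip.label)
    } else ape::getMRCA(tr, taxa)
    depth <- ape::node.depth.edgelength(tr)
    max(depth[seq_len(ntip)]) - depth[node]
  }, numeric(1))
  h <- hpd(ages)
  tibble::tibble(median_age = stats::median(ages),
                 hpd_lower = h[1], hpd_upper = h[2], n = length(ages))
}

#' Annotated node table and tree export for a consensus
#'
#' @param x A `consensus_tree`.
#' @param path File path for the annotated Newick (clade PP, median age and
#'   HPD as metadata comments on internal nodes).
#' @return `path`, invisibly.
#' @export
write_consensus <- function(x, path) {
  tt <- x$tree
  phy <- tt$phy
  ntip <- ape::Ntip(phy)
  desc <- clade_descendants(phy)
  lab <- vapply((ntip + 1L):(ntip + phy$Nnode), function(v) {
    key <- paste(sort(phy$tip.label[desc[[v - ntip]]]), collapse = "|")
    row <- x$nodes[x$nodes$clade == key, ]
    if (!nrow(row)) return("")
    sprintf("'[&pp=%.3f_age=%.4g_hpd=%.4g-%.4g]'",
            row$pp, row$median_age, row$hpd_lower, row$hpd_upper)
  }, character(1))
  phy$node.label <- lab
  nwk <- ape::write.tree(phy)
  writeLines(nwk, path)
  invisible(path)
}
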
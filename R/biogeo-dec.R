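#' Range state space for dispersal-extinction-cladogenesis models
#'
#' Enumerates all subsets of the area set up to `max_size` areas, plus the
#' empty (locally extinct) range, ordered by range size then
#' lexicographically by area index. Ranges are encoded as bitmasks.
#'
#' @param n_areas Number of areas.
#' @param max_size Largest allowed range size.
#' @return A `range_space` list with `masks`, `sizes`, `n_areas`.
#' @export
enumerate_ranges <- function(n_areas, max_size) {
  if (max_size < 1 || max_size > n_areas) stop("1 <= max_size <= n_areas")
  masks <- 0L
  for (sz in seq_len(max_size)) {
    combos <- utils::combn(n_areas, sz)
    m <- colSums(matrix(bitwShiftL(1L, combos - 1L), nrow = sz))
    masks <- c(masks, sort(as.integer(m)))
  }
  structure(list(masks = as.integer(masks),
                 sizes = vapply(masks, popcount, integer(1)),
                 n_areas = as.integer(n_areas),
                 index = stats::setNames(seq_along(masks),
                                         as.character(masks))),
            class = "range_space")
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

mask_areas <- function(mask, n_areas) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_areas) - 1L)) != 0L)
}

#' DEC model specification
#'
#' @param areas Character vector of area codes.
#' @param d Dispersal rate, per Ma per area pair.
#' @param e Local extinction rate, per Ma per area.
#' @param max_range_size Cap on ancestral range size (default 4).
#' @param connectivity Optional [connectivity_model]; full connectivity if
#'   `NULL`.
#' @param wide_vicariance Allow vicariant splits into two multi-area
#'   daughter ranges (the extended "classical vicariance"); default only
#'   single-area splits as in classical DEC.
#' @param root_prior `"uniform"` over non-empty states or `"stationary"`.
#' @return A `dec_model` list.
#' @export
dec_model <- function(areas, d = 0.1, e = 0.01,
                      max_range_size = min(4L, length(areas)),
                      connectivity = NULL, wide_vicariance = FALSE,
                      root_prior = c("uniform", "stationary")) {
  if (d < 0 || e < 0) stop("rates must be non-negative")
  structure(list(areas = areas, d = d, e = e,
                 max_range_size = as.integer(max_range_size),
                 connectivity = connectivity,
                 wide_vicariance = wide_vicariance,
                 root_prior = match.arg(root_prior),
                 space = enumerate_ranges(length(areas), max_range_size)),
            class = "dec_model")
}

#' Anagenetic DEC rate matrix
#'
#' Range expansion `R -> R + {a}` proceeds at rate `d` summed over source
#' areas `b` in `R` with connectivity `m[b, a] = 1`; contraction
#' `R -> R - {a}` at rate `e` per area, including extinction of single-area
#' ranges into the absorbing empty range.
#'
#' @param space A `range_space`.
#' @param d,e Dispersal and extinction rates.
#' @param conn Optional 0/1 connectivity matrix (from-row, to-column);
#'   `NULL` means fully connected.
#' @return Square rate matrix over the range states (rows sum to 0).
#' @export
dec_rate_matrix <- function(space, d, e, conn = NULL) {
  ns <- length(space$masks)
  na <- space$n_areas
  if (is.null(conn)) conn <- matrix(1, na, na)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    R <- space$masks[i]
    if (R == 0L) next  # empty range is absorbing
    occ <- mask_areas(R, na)
    # expansion
    if (space$sizes[i] < space$n_areas) {
      for (a in setdiff(seq_len(na), occ)) {
        tgt <- bitwOr(R, bitwShiftL(1L, a - 1L))
        j <- space$index[as.character(tgt)]
        if (!is.na(j)) {
          rate <- d * sum(conn[occ, a])
          Q[i, j] <- Q[i, j] + rate
        }
      }
    }
    # contraction
    for (a in occ) {
      tgt <- bitwAnd(R, bitwNot(bitwShiftL(1L, a - 1L)))
      j <- space$index[as.character(tgt)]
      Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Ordered cladogenetic event list per parent state: tibble-free list of
# matrices cbind(left, right, weight). Events are ordered pairs over the
# fixed (first child, second child) orientation.
clado_events <- function(model) {
  sp <- model$space
  na <- sp$n_areas
  lapply(seq_along(sp$masks), function(i) {
    R <- sp$masks[i]
    if (R == 0L) return(NULL)
    if (sp$sizes[i] == 1L) {
      return(cbind(left = i, right = i, weight = 1))
    }
    occ <- mask_areas(R, na)
    ev <- list()
    for (a in occ) {
      am <- bitwShiftL(1L, a - 1L)
      rest <- bitwAnd(R, bitwNot(am))
      ia <- sp$index[as.character(am)]
      ir <- sp$index[as.character(rest)]
      ifull <- i
      # subset sympatry (one daughter keeps the full range)
      ev[[length(ev) + 1L]] <- c(ia, ifull)
      ev[[length(ev) + 1L]] <- c(ifull, ia)
      # classical vicariance (single-area split)
      if (!is.na(ir)) {
        ev[[length(ev) + 1L]] <- c(ia, ir)
        ev[[length(ev) + 1L]] <- c(ir, ia)
      }
    }
    if (model$wide_vicariance && sp$sizes[i] >= 4L) {
      occm <- bitwShiftL(1L, occ - 1L)
      nsub <- 2^length(occ)
      for (b in seq_len(nsub - 2L)) {
        A <- sum(occm[bitwAnd(b, bitwShiftL(1L, seq_along(occ) - 1L)) != 0])
        B <- bitwAnd(R, bitwNot(as.integer(A)))
        if (popcount(A) >= 2L && popcount(B) >= 2L) {
          iA <- sp$index[as.character(as.integer(A))]
          iB <- sp$index[as.character(B)]
          if (!is.na(iA) && !is.na(iB)) ev[[length(ev) + 1L]] <- c(iA, iB)
        }
      }
    }
    ev <- unique(do.call(rbind, ev))
    cbind(left = ev[, 1], right = ev[, 2],
          weight = rep(1 / nrow(ev), nrow(ev)))
  })
}

# Per-branch propagator with epoch splitting: product of per-epoch matrix
# exponentials in chronological (old -> young) order.
dec_branch_propagator <- function(model, parent_age, child_age, Qcache) {
  cm <- model$connectivity
  if (is.null(cm) || length(Qcache) == 1L) {
    return(ape::matexpo(Qcache[[1]] * (parent_age - child_age)))
  }
  bounds <- sort(unique(c(
    parent_age, child_age,
    cm$epochs$start_ma[cm$epochs$start_ma < parent_age &
                         cm$epochs$start_ma > child_age])),
    decreasing = TRUE)
  P <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    mid <- (bounds[i] + bounds[i + 1L]) / 2
    ei <- epoch_index(cm, mid)
    Pi <- ape::matexpo(Qcache[[ei]] * (bounds[i] - bounds[i + 1L]))
    P <- if (is.null(P)) Pi else P %*% Pi
  }
  if (is.null(P)) diag(nrow(Qcache[[1]])) else P
}

epoch_index <- function(cm, age) {
  i <- findInterval(-age, -cm$epochs$start_ma)
  max(1L, min(length(cm$matrices), i))
}

dec_q_cache <- function(model) {
  cm <- model$connectivity
  if (is.null(cm)) {
    list(dec_rate_matrix(model$space, model$d, model$e, NULL))
  } else {
    lapply(cm$matrices, function(m) {
      dec_rate_matrix(model$space, model$d, model$e,
                      m[model$areas, model$areas, drop = FALSE])
    })
  }
}

dec_tip_index <- function(model, ranges, taxa) {
  rm_ <- range_masks(ranges)
  idx <- match(taxa, names(rm_))
  if (anyNA(idx)) stop(sprintf("taxon '%s' has no range",
                               taxa[which(is.na(idx))[1]]))
  st <- model$space$index[as.character(rm_[idx])]
  if (anyNA(st)) {
    stop(sprintf(
      "tip range of '%s' exceeds max_range_size %d; increase the cap",
      taxa[which(is.na(st))[1]], model$max_range_size))
  }
  st
}

# Down pass: conditional likelihood D[node, state] with per-node log scaling
# factors; propagators cached per edge.
dec_down_pass <- function(tree, model, tipstate, Qcache, clado) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  ns <- length(model$space$masks)
  D <- matrix(0, nn, ns)
  logsc <- numeric(nn)
  D[cbind(seq_len(ntip), tipstate)] <- 1
  po <- ape::postorder(phy)
  e <- phy$edge
  props <- vector("list", nrow(e))
  up <- matrix(0, nn, ns)  # child partial propagated to top of its branch
  children <- split(e[, 2], e[, 1])
  combine_node <- function(v) {
    kids <- children[[as.character(v)]]
    if (length(kids) != 2L) stop("tree must be strictly bifurcating")
    l <- up[kids[1], ]; r <- up[kids[2], ]
    dv <- numeric(ns)
    for (i in seq_len(ns)) {
      evs <- clado[[i]]
      if (is.null(evs)) next
      dv[i] <- sum(evs[, "weight"] * l[evs[, "left"]] * r[evs[, "right"]])
    }
    mx <- max(dv)
    if (mx > 0) { dv <- dv / mx } else mx <- 1
    D[v, ] <<- dv
    logsc[v] <<- log(mx) + sum(logsc[kids])
  }
  for (ei in po) {
    p <- e[ei, 1]; ch <- e[ei, 2]
    if (ch > ntip) combine_node(ch)  # postorder: ch's children are done
    P <- dec_branch_propagator(model, tree$ages[p], tree$ages[ch], Qcache)
    props[[ei]] <- P
    up[ch, ] <- as.vector(P %*% D[ch, ])
  }
  combine_node(ntip + 1L)  # root
  list(D = D, logsc = logsc, props = props, up = up, children = children)
}

dec_root_prior <- function(model, Qcache) {
  ns <- length(model$space$masks)
  if (model$root_prior == "uniform") {
    pi <- c(0, rep(1 / (ns - 1), ns - 1))
  } else {
    # quasi-stationary distribution of the oldest-epoch generator on
    # non-empty states
    Q <- Qcache[[1]][-1, -1, drop = FALSE]
    v <- abs(Re(eigen(t(Q))$vectors[, which.min(abs(Re(eigen(t(Q))$values)))]))
    pi <- c(0, v / sum(v))
  }
  pi
}

#' DEC log-likelihood of tip ranges on a dated tree
#'
#' Felsenstein pruning over range states with epoch-split branch
#' propagators (one matrix exponential per epoch segment) and cladogenetic
#' transition weights at internal nodes. Fossil tips enter as ordinary tips
#' at their ages; sampled-ancestor attachments have zero-duration branches
#' and identity propagators.
#'
#' @param tree A [time_tree].
#' @param ranges A [range_table] covering all tips.
#' @param model A [dec_model].
#' @return Log-likelihood.
#' @export
dec_log_likelihood <- function(tree, ranges, model) {
  tipstate <- dec_tip_index(model, ranges, tree$phy$tip.label)
  Qcache <- dec_q_cache(model)
  clado <- clado_events(model)
  dn <- dec_down_pass(tree, model, tipstate, Qcache, clado)
  root <- ape::Ntip(tree$phy) + 1L
  pi <- dec_root_prior(model, Qcache)
  L <- sum(pi * dn$D[root, ])
  if (L <= 0) return(-Inf)
  log(L) + dn$logsc[root]
}

#' Maximum-likelihood DEC fit
#'
#' Optimizes `(d, e)` on the log scale by Nelder-Mead.
#'
#' @inheritParams dec_log_likelihood
#' @param init Starting values `c(d, e)`.
#' @param lower_flag Rates below this are flagged as at-bound.
#' @return A `dec_fit` list: `d`, `e`, `loglik`, `model`, `at_bound`,
#'   `convergence`.
#' @export
fit_dec <- function(tree, ranges, model, init = c(0.05, 0.05),
                    lower_flag = 1e-6) {
  tipstate <- dec_tip_index(model, ranges, tree$phy$tip.label)
  clado <- clado_events(model)
  obj <- function(par) {
    m2 <- model
    m2$d <- exp(par[1]); m2$e <- exp(par[2])
    Qcache <- dec_q_cache(m2)
    dn <- dec_down_pass(tree, m2, tipstate, Qcache, clado)
    root <- ape::Ntip(tree$phy) + 1L
    L <- sum(dec_root_prior(m2, Qcache) * dn$D[root, ])
    if (L <= 0) return(1e10)
    -(log(L) + dn$logsc[root])
  }
  opt <- stats::optim(log(init), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-9))
  fit <- model
  fit$d <- exp(opt$par[1]); fit$e <- exp(opt$par[2])
  structure(list(d = fit$d, e = fit$e, loglik = -opt$value, model = fit,
                 at_bound = any(c(fit$d, fit$e) < lower_flag),
                 convergence = opt$convergence),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("DEC fit: d = %.5g, e = %.5g, lnL = %.4f%s\n", x$d, x$e,
              x$loglik, if (x$at_bound) " (rate at bound)" else ""))
  invisible(x)
}

#' @export
tidy.dec_fit <- function(x, ...) {
  tibble::tibble(term = c("dispersal", "extinction"),
                 estimate = c(x$d, x$e))
}

#' @export
glance.dec_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_states = length(x$model$space$masks),
                 at_bound = x$at_bound, convergence = x$convergence)
}

#' Marginal ancestral ranges under a fitted DEC model
#'
#' Up-down pass yielding, for every internal node, the marginal posterior
#' probability of each range state immediately after the cladogenetic event
#' at that node's parent (and, at the node itself, before its own split).
#'
#' @param tree A [time_tree].
#' @param ranges A [range_table].
#' @param model A fitted [dec_model] (or the `model` element of a
#'   [fit_dec] result).
#' @param keep_within_lnl Report, per node, all ranges whose probability is
#'   within `exp(-keep_within_lnl)` of the best.
#' @return Tibble: node, range (area-code string), probability, best flag.
#' @export
ancestral_ranges <- function(tree, ranges, model, keep_within_lnl = 2) {
  if (inherits(model, "dec_fit")) model <- model$model
  tipstate <- dec_tip_index(model, ranges, tree$phy$tip.label)
  Qcache <- dec_q_cache(model)
  clado <- clado_events(model)
  dn <- dec_down_pass(tree, model, tipstate, Qcache, clado)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  ns <- length(model$space$masks)
  root <- ntip + 1L
  pi <- dec_root_prior(model, Qcache)
  U <- matrix(0, nn, ns)  # outside partial at each node (before its split)
  U[root, ] <- pi
  e <- phy$edge
  preord <- rev(ape::postorder(phy))
  edge_of <- integer(nn); edge_of[e[, 2]] <- seq_len(nrow(e))
  for (ei in preord) {
    v <- e[ei, 1]; ch <- e[ei, 2]
    kids <- dn$children[[as.character(v)]]
    sib <- setdiff(kids, ch)
    sibvec <- dn$up[sib, ]
    # outside partial at the top of ch's branch, summing clado events
    topo <- numeric(ns)
    for (i in seq_len(ns)) {
      evs <- clado[[i]]
      if (is.null(evs) || U[v, i] == 0) next
      if (ch == kids[1]) {
        contrib <- evs[, "weight"] * sibvec[evs[, "right"]]
        topo[evs[, "left"]] <- topo[evs[, "left"]] + U[v, i] * contrib
      } else {
        contrib <- evs[, "weight"] * sibvec[evs[, "left"]]
        topo[evs[, "right"]] <- topo[evs[, "right"]] + U[v, i] * contrib
      }
    }
    mx <- max(topo)
    if (mx > 0) topo <- topo / mx
    U[ch, ] <- as.vector(topo %*% dn$props[[ei]])
  }
  purrr::map_dfr((ntip + 1L):nn, function(v) {
    post <- U[v, ] * dn$D[v, ]
    if (sum(post) <= 0) post <- rep(1 / ns, ns)
    post <- post / sum(post)
    best <- max(post)
    keep <- which(post >= best * exp(-keep_within_lnl) & post > 0)
    keep <- keep[order(post[keep], decreasing = TRUE)]
    tibble::tibble(
      node = v,
      range = vapply(keep, function(i) {
        paste(model$areas[mask_areas(model$space$masks[i],
                                     model$space$n_areas)], collapse = "+")
      }, character(1)),
      probability = post[keep],
      best = keep == keep[1]
    )
  })
}
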
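#' Simulate a fossilized birth-death tree
#'
#' Forward birth-death simulation from two lineages at the root age, with
#' Poisson fossilization at rate `psi` and extant sampling at `rho`. The
#' complete tree is pruned to the sampled tree: fossils with sampled
#' descendants become sampled ancestors (zero-length tips), other fossils
#' become pendant fossil tips. Retries until both root lineages carry
#' samples and the tip count falls in the requested window.
#'
#' @param p An [fbd_params].
#' @param root_age Age of the root, Ma.
#' @param seed Optional integer seed.
#' @param min_tips,max_tips Accepted sampled-tree size window.
#' @param calibration_jitter Range (Ma) of the uniform half-widths used to
#'   build stratigraphic windows around true fossil ages.
#' @param max_retries Resimulation cap before giving up.
#' @return A list with `tree` (a [time_tree] with fossil calibrations) and
#'   `truth` (manifest: parameters, true ages, seed).
#' @export
simulate_fbd_tree <- function(p, root_age, seed = NULL, min_tips = 3,
                              max_tips = Inf,
                              calibration_jitter = c(0.2, 1.5),
                              max_retries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    sub <- lapply(1:2, function(i) sim_lineage(root_age, p))
    sampled <- lapply(sub, prune_sampled, p = p)
    if (any(vapply(sampled, is.null, logical(1)))) next
    node <- list(type = "split", age = root_age, kids = sampled)
    ntips <- count_tips(node)
    if (ntips < min_tips || ntips > max_tips) next
    cnt <- new.env(); cnt$tip <- 0L
    nwk <- paste0(to_newick(node, root_age, cnt), ";")
    phy <- ape::read.tree(text = nwk)
    depth <- ape::node.depth.edgelength(phy)
    ages <- root_age - depth
    ages[abs(ages) < 1e-6] <- 0  # newick round-trip float noise
    fossil <- which(ages[seq_len(ape::Ntip(phy))] > 1e-9)
    cal <- NULL
    if (length(fossil)) {
      lo <- stats::runif(length(fossil), calibration_jitter[1],
                         calibration_jitter[2])
      hi <- stats::runif(length(fossil), calibration_jitter[1],
                         calibration_jitter[2])
      cal <- tibble::tibble(
        taxon = phy$tip.label[fossil],
        min_age = pmax(1e-3, ages[fossil] - lo),
        max_age = ages[fossil] + hi
      )
    }
    tt <- time_tree(phy, ages = ages, calibrations = cal)
    return(list(tree = tt,
                truth = list(params = unclass(p), root_age = root_age,
                             ages = ages, tip_labels = phy$tip.label,
                             seed = seed)))
  }
  stop("no acceptable tree after max_retries simulations")
}

# One complete lineage from start_age towards the present.
sim_lineage <- function(start_age, p) {
  tot <- p$lambda + p$mu + p$psi
  fossils <- numeric(0)
  age <- start_age
  repeat {
    age <- age - stats::rexp(1, tot)
    if (age <= 0) {
      return(list(type = "extant", fossils = fossils,
                  sampled = stats::runif(1) < p$rho))
    }
    u <- stats::runif(1)
    if (u < p$psi / tot) {
      fossils <- c(fossils, age)
    } else if (u < (p$psi + p$mu) / tot) {
      return(list(type = "dead", age = age, fossils = fossils))
    } else {
      return(list(type = "split", age = age, fossils = fossils,
                  kids = list(sim_lineage(age, p), sim_lineage(age, p))))
    }
  }
}

# Prune a complete lineage to its sampled representation: NULL if nothing
# below is sampled; otherwise a nested (split / tip / sa) structure with
# absolute ages.
prune_sampled <- function(lin, p) {
  base <- switch(lin$type,
    extant = if (lin$sampled) list(type = "tip", age = 0) else NULL,
    dead = NULL,
    split = {
      kids <- lapply(lin$kids, prune_sampled, p = p)
      keep <- !vapply(kids, is.null, logical(1))
      if (sum(keep) == 2L) {
        list(type = "split", age = lin$age, kids = kids)
      } else if (sum(keep) == 1L) kids[keep][[1]] else NULL
    }
  )
  for (a in sort(lin$fossils)) {  # youngest first; older fossils wrap later
    base <- if (is.null(base)) {
      list(type = "tip", age = a)
    } else {
      list(type = "sa", age = a, kids = list(base))
    }
  }
  base
}

count_tips <- function(node) {
  switch(node$type,
    tip = 1L,
    sa = 1L + count_tips(node$kids[[1]]),
    split = count_tips(node$kids[[1]]) + count_tips(node$kids[[2]])
  )
}

to_newick <- function(node, parent_age, cnt) {
  dur <- function(a) sprintf("%.15g", parent_age - a)
  switch(node$type,
    tip = {
      cnt$tip <- cnt$tip + 1L
      sprintf("t%d:%s", cnt$tip, dur(node$age))
    },
    sa = {
      inner <- to_newick(node$kids[[1]], node$age, cnt)
      cnt$tip <- cnt$tip + 1L
      sprintf("(%s,t%d:0):%s", inner, cnt$tip, dur(node$age))
    },
    split = sprintf("(%s,%s):%s",
                    to_newick(node$kids[[1]], node$age, cnt),
                    to_newick(node$kids[[2]], node$age, cnt),
                    dur(node$age))
  )
}

#' Simulate a clocked Mk character matrix on a time tree
#'
#' Root states are uniform; states evolve down the tree along effective
#' branch lengths `duration * base_rate * branch_rate`, each character
#' scaled by a continuous gamma(alpha, alpha) rate. Under variable-only
#' coding, constant characters are rejected and redrawn, reproducing the
#' ascertainment process the Mkv correction models.
#'
#' @param tree A [time_tree].
#' @param clock A [clock_config]; branch rates are drawn fresh.
#' @param n_chars Number of characters.
#' @param gamma_shape Among-character rate shape alpha.
#' @param state_counts Integer vector to sample character state counts
#'   from, or a single integer.
#' @param state_count_probs Sampling weights for `state_counts`. The
#'   default mixture (60/25/10/5% for 2/3/4/5 states) resembles published
#'   morphological matrices.
#' @param variable_only Reject constant characters?
#' @param seed Optional integer seed.
#' @param max_redraws Per-character rejection cap.
#' @return List: `matrix` (a [char_matrix]), `branch_rates`, `truth`
#'   (clock draw, alpha, per-character rates and state counts).
#' @export
simulate_characters <- function(tree, clock = clock_config("strict"),
                                n_chars = 100, gamma_shape = 1,
                                state_counts = c(2L, 3L, 4L, 5L),
                                state_count_probs = c(0.6, 0.25, 0.1, 0.05),
                                variable_only = TRUE, seed = NULL,
                                max_redraws = 1000) {
  if (!is.null(seed)) set.seed(seed)
  br <- draw_branch_rates(clock, tree)
  elen <- effective_lengths(tree, clock$base_rate, br)
  if (variable_only && all(elen <= 0)) {
    stop("all effective lengths are zero: every character would be constant")
  }
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  e <- phy$edge
  preord <- rev(ape::postorder(phy))
  ks <- if (length(state_counts) == 1L) {
    rep(as.integer(state_counts), n_chars)
  } else {
    sample(state_counts, n_chars, replace = TRUE, prob = state_count_probs)
  }
  crates <- stats::rgamma(n_chars, shape = gamma_shape, rate = gamma_shape)
  masks <- matrix(0L, ntip, n_chars)
  for (j in seq_len(n_chars)) {
    k <- ks[j]
    for (redraw in seq_len(max_redraws)) {
      # rejection redraws the whole character, including its gamma rate,
      # otherwise a near-zero-rate character can never become variable
      if (redraw > 1L) {
        crates[j] <- stats::rgamma(1, shape = gamma_shape,
                                   rate = gamma_shape)
      }
      st <- integer(ntip + phy$Nnode)
      st[ntip + 1L] <- sample.int(k, 1)
      for (ei in preord) {
        P <- mk_transition_matrix(k, elen[ei] * crates[j])
        st[e[ei, 2]] <- sample.int(k, 1, prob = P[st[e[ei, 1]], ])
      }
      tipst <- st[seq_len(ntip)]
      if (!variable_only || length(unique(tipst)) > 1L) break
      if (redraw == max_redraws) {
        stop(sprintf("character %d: constant after %d redraws", j,
                     max_redraws))
      }
    }
    masks[, j] <- bitwShiftL(1L, tipst - 1L)
  }
  cm <- char_matrix(masks, phy$tip.label, ks,
                    coding = if (variable_only) "variable" else "all")
  list(matrix = cm, branch_rates = br,
       truth = list(clock = unclass(clock), gamma_shape = gamma_shape,
                    char_rates = crates, state_counts = ks, seed = seed))
}

#' Simulate geographic ranges under DEC on a time tree
#'
#' Gillespie simulation of anagenetic dispersal/extinction along branches
#' (respecting the epoch-wise connectivity in force at each moment) with a
#' cladogenetic scenario drawn at every internal node. Lineages whose range
#' hits the empty set are recorded extinct; the whole simulation is redrawn
#' if any tip ends up rangeless.
#'
#' @param tree A [time_tree].
#' @param model A [dec_model].
#' @param seed Optional integer seed.
#' @param min_survivors Resimulate when fewer tips than this keep a range.
#' @param max_retries Resimulation cap.
#' @return List: `ranges` (a [range_table] over surviving tips), `tree`
#'   (the input tree pruned of extinct tips, if any), `dropped` (labels of
#'   range-extinct tips), `truth` (per-node true range masks on the
#'   original tree).
#' @export
simulate_ranges <- function(tree, model, seed = NULL, min_survivors = 3,
                            max_retries = 200) {
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  e <- phy$edge
  preord <- rev(ape::postorder(phy))
  sp <- model$space
  clado <- clado_events(model)
  nonempty <- which(sp$masks != 0L)
  for (try in seq_len(max_retries)) {
    st <- integer(nn)
    st[ntip + 1L] <- sample(nonempty, 1)
    picks <- vector("list", nn)  # one cladogenetic scenario per node
    ok <- TRUE
    for (ei in preord) {
      p <- e[ei, 1]; ch <- e[ei, 2]
      s <- st[p]
      if (sp$masks[s] == 0L) { st[ch] <- s; next }  # extinct stays extinct
      if (is.null(picks[[p]])) {
        evs <- clado[[s]]
        picks[[p]] <- evs[sample.int(nrow(evs), 1, prob = evs[, "weight"]), ]
      }
      pick <- picks[[p]]
      kids <- which(e[, 1] == p)
      s0 <- if (ei == kids[1]) pick[["left"]] else pick[["right"]]
      st[ch] <- gillespie_branch(s0, tree$ages[p], tree$ages[ch], model, sp)
    }
    alive <- which(sp$masks[st[seq_len(ntip)]] != 0L)
    if (!ok || length(alive) < min_survivors) next
    dropped <- phy$tip.label[setdiff(seq_len(ntip), alive)]
    out_tree <- tree
    if (length(dropped)) {
      warning(sprintf("%d lineage(s) went range-extinct and were dropped",
                      length(dropped)))
      phy2 <- ape::drop.tip(phy, dropped)
      keep_ages <- tree$ages[match(phy2$tip.label, phy$tip.label)]
      depth <- ape::node.depth.edgelength(phy2)
      # recompute ages from retained tip ages and durations
      off <- keep_ages[1] + depth[1]
      cal <- tree$calibrations
      new_ages <- off - depth
      new_ages[abs(new_ages) < 1e-6] <- 0  # float noise from pruning
      out_tree <- time_tree(phy2, ages = new_ages,
                            calibrations = if (is.null(cal)) NULL else {
                              cal[cal$taxon %in% phy2$tip.label, ]
                            })
    }
    presence <- t(vapply(alive, function(i) {
      as.integer(bitwAnd(sp$masks[st[i]],
                         bitwShiftL(1L, seq_along(model$areas) - 1L)) != 0L)
    }, integer(length(model$areas))))
    return(list(ranges = range_table(phy$tip.label[alive], presence,
                                     model$areas),
                tree = out_tree, dropped = dropped,
                truth = list(node_states = st, masks = sp$masks[st],
                             seed = seed)))
  }
  stop("range simulation failed: too many lineages went extinct")
}

# Gillespie walk over range states from age_top down to age_bottom.
gillespie_branch <- function(state, age_top, age_bottom, model, sp) {
  age <- age_top
  cm <- model$connectivity
  repeat {
    if (age <= age_bottom || sp$masks[state] == 0L) return(state)
    conn <- if (is.null(cm)) NULL else {
      connectivity_at(cm, age)[model$areas, model$areas, drop = FALSE]
    }
    # local rates out of the current state
    na <- sp$n_areas
    occ <- mask_areas(sp$masks[state], na)
    if (is.null(conn)) conn <- matrix(1, na, na)
    targets <- integer(0); rates <- numeric(0)
    if (length(occ) < model$max_range_size) {
      for (a in setdiff(seq_len(na), occ)) {
        rate <- model$d * sum(conn[occ, a])
        if (rate > 0) {
          targets <- c(targets,
                       sp$index[as.character(bitwOr(sp$masks[state],
                                                    bitwShiftL(1L, a - 1L)))])
          rates <- c(rates, rate)
        }
      }
    }
    for (a in occ) {
      targets <- c(targets,
                   sp$index[as.character(bitwAnd(sp$masks[state],
                              bitwNot(bitwShiftL(1L, a - 1L))))])
      rates <- c(rates, model$e)
    }
    tot <- sum(rates)
    if (tot <= 0) return(state)
    wait <- stats::rexp(1, tot)
    # epoch boundary between now and the event? re-draw from the boundary
    nb <- next_epoch_boundary(cm, age, age_bottom)
    if (!is.na(nb) && age - wait < nb) { age <- nb - 1e-12; next }
    if (age - wait <= age_bottom) return(state)
    age <- age - wait
    state <- sample(length(targets), 1, prob = rates / tot)
    state <- targets[state]
  }
}

next_epoch_boundary <- function(cm, age, age_bottom) {
  if (is.null(cm)) return(NA_real_)
  b <- cm$epochs$start_ma
  b <- b[b < age & b > age_bottom]
  if (!length(b)) NA_real_ else max(b)
}
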
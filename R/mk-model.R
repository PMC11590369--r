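#' Mk transition probability matrix
#'
#' The k-state symmetric (Jukes-Cantor-like) Markov model for discrete
#' morphology, normalized so that `t` is the expected number of
#' substitutions: `p_same(t) = 1/k + (k-1)/k exp(-k t / (k-1))`.
#'
#' @param k Number of states (>= 2).
#' @param t Expected substitutions (>= 0).
#' @return A `k x k` row-stochastic matrix.
#' @export
mk_transition_matrix <- function(k, t) {
  if (t < 0) stop("t must be >= 0")
  if (k < 2) stop("k must be >= 2")
  e <- exp(-k * t / (k - 1))
  p_diff <- (1 - e) / k
  m <- matrix(p_diff, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

#' Discrete-gamma rate categories
#'
#' Mean-of-quantile-bin construction (equal-probability categories, each
#' rate the conditional mean of its gamma quantile bin), renormalized so the
#' categories average to exactly 1.
#'
#' @param alpha Gamma shape (> 0); mean fixed at 1.
#' @param n Number of categories (>= 1).
#' @return Numeric vector of `n` rate multipliers with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, n = 4) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (n == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = n + 1), shape = alpha,
                     rate = alpha)
  # E[X | bin] via the incomplete-gamma identity for Gamma(alpha, alpha)
  cum <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- n * diff(cum)
  r / mean(r)
}

# Postorder edge traversal of a time_tree plus effective lengths.
postorder_edges <- function(tree, eff_len) {
  po <- ape::postorder(tree$phy)
  e <- tree$phy$edge
  list(parent = e[po, 1], child = e[po, 2], elen = eff_len[po])
}

#' Mk(v) log-likelihood of a character matrix
#'
#' Computes per-character log-likelihoods by Felsenstein pruning under the
#' symmetric Mk model with a discrete-gamma rate mixture and uniform root
#' frequencies. Ambiguity/polymorphism sets enter as indicator partials.
#' Under variable-only coding the ascertainment (Mkv) correction divides
#' each character's likelihood by `1 - P(constant pattern)`, where the
#' constant-pattern probability is computed with the same pruning engine per
#' state-count class.
#'
#' @param cmat A [char_matrix].
#' @param tree A [time_tree] whose taxa cover the matrix.
#' @param effective_lengths Per-edge expected substitutions, in the order of
#'   `tree$phy$edge`; defaults to branch durations (rate 1 per Ma).
#' @param gamma_shape Shape of the discrete-gamma mixture; `Inf` for a
#'   single rate.
#' @param n_categories Number of gamma categories (4 by default).
#' @param correct Apply the Mkv correction? Defaults to the matrix coding.
#' @param by_character Return the per-character vector instead of the sum.
#' @return Total log-likelihood (or a per-character vector).
#' @export
mk_loglik <- function(cmat, tree, effective_lengths = NULL,
                      gamma_shape = Inf, n_categories = 4,
                      correct = cmat$coding == "variable",
                      by_character = FALSE) {
  ntip <- ape::Ntip(tree$phy)
  if (is.null(effective_lengths)) effective_lengths <- branch_durations(tree)
  idx <- match(tree$phy$tip.label, cmat$taxa)
  if (anyNA(idx)) {
    stop(sprintf("taxon '%s' not in character matrix",
                 tree$phy$tip.label[which(is.na(idx))[1]]))
  }
  rates <- if (is.finite(gamma_shape)) {
    discrete_gamma_rates(gamma_shape, n_categories)
  } else 1
  po <- postorder_edges(tree, effective_lengths)
  root <- ntip + 1L
  nn <- ntip + tree$phy$Nnode
  nchar_ <- ncol(cmat$masks)
  masks <- cmat$masks[idx, , drop = FALSE]
  kvec <- cmat$state_count
  uks <- sort(unique(kvec))
  if (correct) {
    # append the constant patterns of every state-count class as extra
    # pseudo-characters, evaluated in the same pruning call
    const_cols <- do.call(cbind, lapply(uks, function(k) {
      matrix(bitwShiftL(1L, 0:(k - 1L)), nrow = ntip, ncol = k,
             byrow = TRUE)
    }))
    masks <- cbind(masks, const_cols)
    kvec <- c(kvec, rep(uks, uks))
  }
  ll_all <- mk_loglik_cpp(po$parent, po$child, po$elen, ntip, nn, root,
                          masks, as.integer(kvec), rates)
  out <- ll_all[seq_len(nchar_)]
  if (correct) {
    ll_const <- ll_all[-seq_len(nchar_)]
    class_of <- rep(uks, uks)
    for (k in uks) {
      p_const <- sum(exp(ll_const[class_of == k]))
      if (p_const >= 1) {
        stop(sprintf("Mkv correction denominator <= 0 for k = %d class", k))
      }
      out[cmat$state_count == k] <- out[cmat$state_count == k] -
        log1p(-p_const)
    }
  }
  if (by_character) out else sum(out)
}

#' @rdname mk_loglik
#' @param char Index of a single character column.
#' @export
character_log_likelihood <- function(cmat, tree, char,
                                     effective_lengths = NULL,
                                     gamma_shape = Inf, n_categories = 4) {
  sub <- char_matrix(cmat$masks[, char, drop = FALSE], cmat$taxa,
                     cmat$state_count[char], coding = "all")
  mk_loglik(sub, tree, effective_lengths, gamma_shape, n_categories,
            correct = FALSE)
}
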
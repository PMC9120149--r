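#' Branch-specific intron gain/loss rates on a rooted tree
#'
#' The model is a two-state (absent/present) Markov chain running down the
#' rooted species tree. Each branch carries its own transition
#' probabilities: `gain` = P(absent at parent -> present at child) and
#' `loss` = P(present -> absent); the root carries a prior probability of
#' presence. Parameterising branches by transition probabilities directly
#' (rather than rate x time) keeps the model usable on topology-only trees;
#' [estimate_rates()] offers a rate x length mode when branch lengths
#' exist.
#'
#' @param tree a rooted `phylo` (bifurcating, or with a multifurcating
#'   root).
#' @param gain,loss scalar recycled over branches, or a vector with one
#'   entry per node (indexed by ape node id, root entry ignored), or a
#'   vector named by child node id.
#' @param root_prior probability of presence at the root.
#' @return an object of class `branch_rates`.
#' @export
branch_rates <- function(tree, gain, loss, root_prior = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  expand <- function(x, what) {
    if (length(x) == 1L) {
      v <- rep(as.numeric(x), n_nodes)
    } else if (!is.null(names(x))) {
      v <- rep(NA_real_, n_nodes)
      v[as.integer(names(x))] <- as.numeric(x)
    } else if (length(x) == n_nodes) {
      v <- as.numeric(x)
    } else {
      stop(what, " must be scalar, node-named, or of length ", n_nodes)
    }
    v[root] <- NA_real_
    nonroot <- setdiff(seq_len(n_nodes), root)
    if (any(is.na(v[nonroot]))) stop(what, " missing for some branches")
    v
  }
  g <- expand(gain, "gain")
  l <- expand(loss, "loss")
  nonroot <- setdiff(seq_len(n_nodes), root)
  if (any(g[nonroot] < 0 | g[nonroot] >= 1)) stop("gain must be in [0, 1)")
  if (any(l[nonroot] < 0 | l[nonroot] > 1)) stop("loss must be in [0, 1]")
  if (root_prior < 0 || root_prior > 1) stop("root_prior must be in [0, 1]")
  structure(list(tree = tree, gain = g, loss = l,
                 root_prior = as.numeric(root_prior)),
            class = "branch_rates")
}

#' @export
print.branch_rates <- function(x, ...) {
  nonroot <- !is.na(x$gain)
  cat("branch_rates on a tree with", ape::Ntip(x$tree), "tips:\n")
  cat("  gain: [", format(min(x$gain[nonroot]), digits = 3), ",",
      format(max(x$gain[nonroot]), digits = 3), "]  loss: [",
      format(min(x$loss[nonroot]), digits = 3), ",",
      format(max(x$loss[nonroot]), digits = 3), "]  root prior:",
      format(x$root_prior, digits = 3), "\n")
  invisible(x)
}

# Encode presence patterns as an integer matrix (n_patterns x n_tips) in
# tip-label order: 1 present, 0 absent, NA missing.
encode_patterns <- function(patterns, tree) {
  tips <- tree$tip.label
  if (!is.matrix(patterns) && !is.data.frame(patterns)) {
    patterns <- matrix(patterns, nrow = 1,
                       dimnames = list(NULL, names(patterns)))
  }
  patterns <- as.matrix(patterns)
  if (is.null(colnames(patterns))) {
    if (ncol(patterns) != length(tips)) {
      stop("pattern has ", ncol(patterns), " states for ", length(tips),
           " tips and no species names")
    }
    colnames(patterns) <- tips
  }
  extra <- setdiff(colnames(patterns), tips)
  if (length(extra) > 0) {
    stop("species not on tree: ", paste(extra, collapse = ", "))
  }
  out <- matrix(NA_integer_, nrow(patterns), length(tips),
                dimnames = list(NULL, tips))
  for (sp in colnames(patterns)) {
    v <- patterns[, sp]
    code <- ifelse(v %in% c("1", 1), 1L, ifelse(v %in% c("0", 0), 0L,
                   NA_integer_))
    out[, sp] <- code
  }
  out
}

# Post-order pruning, vectorised over patterns. Returns per-node partial
# likelihood matrices (state absent / present), per-pattern log scaling
# factors, and per-edge lifted child contributions for reuse in the
# down pass. patmat: integer matrix from encode_patterns().
prune_up <- function(tree, patmat, gain, loss) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  npat <- nrow(patmat)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge

  up_a <- matrix(1, npat, n_nodes)
  up_p <- matrix(1, npat, n_nodes)
  for (i in seq_len(ntip)) {
    s <- patmat[, i]
    up_a[, i] <- ifelse(is.na(s), 1, 1 - s)
    up_p[, i] <- ifelse(is.na(s), 1, s)
  }
  logscale <- numeric(npat)
  lift_a <- matrix(NA_real_, npat, nrow(edge))
  lift_p <- matrix(NA_real_, npat, nrow(edge))
  rescaled <- rep(FALSE, n_nodes)

  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 1]; ch <- edge[e, 2]
    if (ch > ntip && !rescaled[ch]) {
      s <- up_a[, ch] + up_p[, ch]
      s[s == 0] <- 1          # impossible pattern: keep zeros, log L = -Inf
      up_a[, ch] <- up_a[, ch] / s
      up_p[, ch] <- up_p[, ch] / s
      logscale <- logscale + log(s * (up_a[, ch] + up_p[, ch] > 0))
      rescaled[ch] <- TRUE
    }
    g <- gain[ch]; l <- loss[ch]
    la <- (1 - g) * up_a[, ch] + g * up_p[, ch]
    lp <- l * up_a[, ch] + (1 - l) * up_p[, ch]
    lift_a[, e] <- la
    lift_p[, e] <- lp
    up_a[, v] <- up_a[, v] * la
    up_p[, v] <- up_p[, v] * lp
  }
  list(up_a = up_a, up_p = up_p, logscale = logscale, edge = edge,
       lift_a = lift_a, lift_p = lift_p)
}

# Log-likelihood per pattern given an up pass.
loglik_from_up <- function(up, root, root_prior) {
  lik <- (1 - root_prior) * up$up_a[, root] + root_prior * up$up_p[, root]
  ifelse(lik > 0, log(lik) + up$logscale, -Inf)
}

# Down (outside) pass; returns per-node posteriors and per-branch joint
# transition posteriors, vectorised over patterns.
prune_down <- function(tree, up, root_prior) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  npat <- nrow(up$up_a)
  edge <- up$edge

  down_a <- matrix(NA_real_, npat, n_nodes)
  down_p <- matrix(NA_real_, npat, n_nodes)
  down_a[, root] <- 1 - root_prior
  down_p[, root] <- root_prior

  kids <- split(seq_len(nrow(edge)), edge[, 1])
  gain <- attr(up, "gain"); loss <- attr(up, "loss")

  # preorder over edges = reverse postorder
  for (e in rev(seq_len(nrow(edge)))) {
    v <- edge[e, 1]; ch <- edge[e, 2]
    sib <- setdiff(kids[[as.character(v)]], e)
    Fa <- down_a[, v]; Fp <- down_p[, v]
    for (s in sib) {
      Fa <- Fa * up$lift_a[, s]
      Fp <- Fp * up$lift_p[, s]
    }
    g <- gain[ch]; l <- loss[ch]
    down_a[, ch] <- Fa * (1 - g) + Fp * l
    down_p[, ch] <- Fa * g + Fp * (1 - l)
    # rescale to dodge underflow; per-node normalisation absorbs this
    sc <- down_a[, ch] + down_p[, ch]
    sc[sc == 0] <- 1
    down_a[, ch] <- down_a[, ch] / sc
    down_p[, ch] <- down_p[, ch] / sc
  }
  list(down_a = down_a, down_p = down_p)
}

# Full posterior machinery for a set of patterns under given rates.
# Returns node presence posteriors and branch gain/loss posteriors
# (matrices n_patterns x n_nodes).
posterior_engine <- function(tree, patmat, rates) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  up <- prune_up(tree, patmat, rates$gain, rates$loss)
  attr(up, "gain") <- rates$gain
  attr(up, "loss") <- rates$loss
  ll <- loglik_from_up(up, root, rates$root_prior)
  if (any(!is.finite(ll))) {
    stop("zero total likelihood: pattern impossible under these rates")
  }
  dn <- prune_down(tree, up, rates$root_prior)

  node_prob <- matrix(NA_real_, nrow(patmat), n_nodes)
  for (v in seq_len(n_nodes)) {
    num <- up$up_p[, v] * dn$down_p[, v]
    den <- num + up$up_a[, v] * dn$down_a[, v]
    node_prob[, v] <- num / den
  }
  edge <- up$edge
  gain_post <- matrix(NA_real_, nrow(patmat), n_nodes)
  loss_post <- matrix(NA_real_, nrow(patmat), n_nodes)
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 1]; ch <- edge[e, 2]
    sib <- setdiff(kids[[as.character(v)]], e)
    Fa <- dn$down_a[, v]; Fp <- dn$down_p[, v]
    for (s in sib) {
      Fa <- Fa * up$lift_a[, s]
      Fp <- Fp * up$lift_p[, s]
    }
    g <- rates$gain[ch]; l <- rates$loss[ch]
    jaa <- Fa * (1 - g) * up$up_a[, ch]
    jap <- Fa * g * up$up_p[, ch]
    jpa <- Fp * l * up$up_a[, ch]
    jpp <- Fp * (1 - l) * up$up_p[, ch]
    tot <- jaa + jap + jpa + jpp
    gain_post[, ch] <- jap / tot
    loss_post[, ch] <- jpa / tot
  }
  list(node_prob = node_prob, branch_gain = gain_post,
       branch_loss = loss_post, loglik = ll)
}

#' Likelihood of one presence/absence pattern
#'
#' Computes the likelihood of an observed leaf pattern under the two-state
#' branch-specific gain/loss model by Felsenstein pruning. Missing leaves
#' (`"?"`/`NA`) contribute a partial likelihood of 1 in both states;
#' multifurcations are handled as products over children.
#'
#' @param pattern named character/numeric vector over tree tips with values
#'   `"1"`/`"0"`/`"?"` (or `1`/`0`/`NA`). Species absent from the pattern
#'   are treated as missing; species not on the tree are an error.
#' @param tree rooted `phylo`.
#' @param rates a [branch_rates()].
#' @param log return the log-likelihood.
#' @return numeric scalar.
#' @export
pattern_likelihood <- function(pattern, tree, rates, log = FALSE) {
  stopifnot(inherits(rates, "branch_rates"))
  patmat <- encode_patterns(pattern, tree)
  up <- prune_up(tree, patmat, rates$gain, rates$loss)
  ll <- loglik_from_up(up, ape::Ntip(tree) + 1L, rates$root_prior)
  if (log) ll else exp(ll)
}

#' Posterior ancestral intron presence for one pattern
#'
#' Runs the up-down (inside-outside) recursion to obtain, for every node,
#' P(intron present at the node | leaf pattern) and, for every branch, the
#' posterior probabilities of a gain (parent absent, child present) and a
#' loss (parent present, child absent) on that branch.
#'
#' @inheritParams pattern_likelihood
#' @return a list of class `posterior_presence` with `node_prob`,
#'   `branch_gain_prob`, `branch_loss_prob` (vectors indexed by ape node
#'   id; branch entries keyed by child node, root entry `NA`) and
#'   `loglik`.
#' @export
posterior_presence <- function(pattern, tree, rates) {
  stopifnot(inherits(rates, "branch_rates"))
  patmat <- encode_patterns(pattern, tree)
  eng <- posterior_engine(tree, patmat, rates)
  structure(list(node_prob = eng$node_prob[1, ],
                 branch_gain_prob = eng$branch_gain[1, ],
                 branch_loss_prob = eng$branch_loss[1, ],
                 loglik = eng$loglik[1]),
            class = "posterior_presence")
}

# Stack the rows of intron tables into one pattern matrix over the tree's
# species, with a bookkeeping data.frame of (og_id, column, phase).
patterns_from_tables <- function(tables, tree) {
  if (inherits(tables, "intron_table")) tables <- list(tables)
  mats <- list(); info <- list()
  for (tb in tables) {
    npos <- nrow(tb$positions)
    if (npos == 0L) next
    chars <- do.call(rbind, strsplit(tb$states, "", fixed = TRUE))
    rownames(chars) <- names(tb$states)
    m <- t(chars)  # positions x species
    colnames(m) <- names(tb$states)
    mats[[length(mats) + 1L]] <- m
    info[[length(info) + 1L]] <- data.frame(
      og_id = tb$og_id, column = tb$positions$column,
      phase = tb$positions$phase, stringsAsFactors = FALSE)
  }
  if (length(mats) == 0L) stop("no intron positions in the supplied tables")
  all_m <- do.call(rbind, lapply(mats, function(m) {
    out <- matrix("?", nrow(m), length(tree$tip.label),
                  dimnames = list(NULL, tree$tip.label))
    common <- intersect(colnames(m), tree$tip.label)
    out[, common] <- m[, common, drop = FALSE]
    out
  }))
  list(patmat = encode_patterns(all_m, tree),
       positions = do.call(rbind, info))
}

#' Maximum-likelihood estimation of branch gain/loss probabilities
#'
#' Maximises the observability-corrected log-likelihood
#' `sum(log L(pattern)) - N log(1 - P(all-absent))` over per-branch gain
#' and loss probabilities and the root prior. The correction conditions on
#' a position being present in at least one species, since positions absent
#' everywhere can never enter an intron table; unconditioned ML would bias
#' gain probabilities downwards.
#'
#' Optimisation is multi-start L-BFGS-B on logit-transformed parameters
#' (start seeds `1..n_starts`; the first start is a fixed moderate guess,
#' the rest random); the best likelihood wins, ties broken by the first
#' seed. The gradient is analytic, assembled from posterior branch
#' transition probabilities, so per-branch fits on trees with dozens of
#' branches remain fast.
#'
#' @param tables an [intron_table()] or list of them.
#' @param tree rooted `phylo` whose tip labels are species ids.
#' @param mode `"per_branch"` (default) fits one gain and one loss
#'   probability per branch; `"global"` fits a single gain and loss shared
#'   by all branches; `"global_rate"` fits global gain/loss rates with
#'   per-branch probabilities `1 - exp(-rate * branch_length)` (requires
#'   branch lengths).
#' @param n_starts number of optimisation starts.
#' @param max_iter L-BFGS-B iteration cap per start.
#' @return a [branch_rates()] with attributes `loglik`, `convergence`
#'   (TRUE when at least one start converged) and `n_patterns`.
#' @export
estimate_rates <- function(tables, tree,
                           mode = c("per_branch", "global", "global_rate"),
                           n_starts = 5L, max_iter = 200L) {
  mode <- match.arg(mode)
  pf <- patterns_from_tables(tables, tree)
  patmat <- pf$patmat
  if (nrow(patmat) == 0L) stop("no observed positions")
  # collapse to unique patterns with weights
  keystr <- apply(patmat, 1, function(r) paste(ifelse(is.na(r), "?", r),
                                               collapse = ""))
  uq <- !duplicated(keystr)
  w <- as.numeric(table(keystr)[keystr[uq]])
  upat <- patmat[uq, , drop = FALSE]
  N <- nrow(patmat)

  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  nonroot <- setdiff(seq_len(n_nodes), root)
  absent_pat <- matrix(0L, 1, ntip, dimnames = list(NULL, tree$tip.label))

  if (mode == "global_rate" && is.null(tree$edge.length)) {
    stop("mode 'global_rate' requires branch lengths")
  }
  blen <- rep(NA_real_, n_nodes)
  if (!is.null(tree$edge.length)) blen[tree$edge[, 2]] <- tree$edge.length

  par_to_rates <- function(par) {
    if (mode == "per_branch") {
      nb <- length(nonroot)
      g <- rep(NA_real_, n_nodes); l <- rep(NA_real_, n_nodes)
      g[nonroot] <- stats::plogis(par[seq_len(nb)])
      l[nonroot] <- stats::plogis(par[nb + seq_len(nb)])
      pi0 <- stats::plogis(par[2 * nb + 1])
    } else if (mode == "global") {
      g <- rep(stats::plogis(par[1]), n_nodes)
      l <- rep(stats::plogis(par[2]), n_nodes)
      g[root] <- NA; l[root] <- NA
      pi0 <- stats::plogis(par[3])
    } else {
      rg <- exp(par[1]); rl <- exp(par[2])
      g <- 1 - exp(-rg * blen)
      l <- 1 - exp(-rl * blen)
      pi0 <- stats::plogis(par[3])
    }
    list(gain = g, loss = l, root_prior = pi0)
  }

  negll <- function(par) {
    r <- par_to_rates(par)
    up <- prune_up(tree, upat, r$gain, r$loss)
    ll <- loglik_from_up(up, root, r$root_prior)
    up0 <- prune_up(tree, absent_pat, r$gain, r$loss)
    l0 <- loglik_from_up(up0, root, r$root_prior)
    p0 <- exp(l0)
    if (p0 >= 1) return(1e10)
    val <- sum(w * ll) - N * log1p(-p0)
    if (!is.finite(val)) return(1e10)
    -val
  }

  # analytic gradient from posterior branch/root statistics
  grad_stats <- function(r, pm, wt) {
    eng <- posterior_engine(tree, pm,
                            structure(list(tree = tree, gain = r$gain,
                                           loss = r$loss,
                                           root_prior = r$root_prior),
                                      class = "branch_rates"))
    # root occupancy
    node_root <- eng$node_prob[, root]
    list(gain_post = colSums(wt * eng$branch_gain),
         child_stay_a = colSums(wt * (1 - eng$node_prob - eng$branch_loss)),
         loss_post = colSums(wt * eng$branch_loss),
         child_stay_p = colSums(wt * (eng$node_prob - eng$branch_gain)),
         root_p = sum(wt * node_root), root_a = sum(wt * (1 - node_root)),
         loglik = sum(wt * eng$loglik))
  }
  dll_dpar <- function(r, pm, wt) {
    st <- grad_stats(r, pm, wt)
    # d logL / d g_c = E[gain]/g - E[parent a, child a]/(1-g)
    # E[parent a, child a] = E[child a] - E[loss]; child a = 1 - node_prob
    g <- r$gain; l <- r$loss
    dg <- st$gain_post / g - st$child_stay_a / (1 - g)
    dl <- st$loss_post / l - st$child_stay_p / (1 - l)
    dg[!is.finite(dg)] <- 0; dl[!is.finite(dl)] <- 0
    dpi <- st$root_p / r$root_prior - st$root_a / (1 - r$root_prior)
    list(dg = dg, dl = dl, dpi = dpi, loglik = st$loglik)
  }
  neggr <- function(par) {
    r <- par_to_rates(par)
    safe <- r
    eps <- 1e-12
    safe$gain <- pmin(pmax(r$gain, eps), 1 - eps)
    safe$loss <- pmin(pmax(r$loss, eps), 1 - eps)
    safe$root_prior <- min(max(r$root_prior, eps), 1 - eps)
    d_obs <- dll_dpar(safe, upat, w)
    d_abs <- dll_dpar(safe, absent_pat, 1)
    p0 <- exp(d_abs$loglik)
    corr <- N * p0 / (1 - p0)
    dg <- d_obs$dg + corr * d_abs$dg
    dl <- d_obs$dl + corr * d_abs$dl
    dpi <- d_obs$dpi + corr * d_abs$dpi
    if (mode == "per_branch") {
      jac_g <- safe$gain * (1 - safe$gain)
      jac_l <- safe$loss * (1 - safe$loss)
      grad <- c((dg * jac_g)[nonroot], (dl * jac_l)[nonroot],
                dpi * safe$root_prior * (1 - safe$root_prior))
    } else if (mode == "global") {
      gg <- safe$gain[nonroot][1]; ll_ <- safe$loss[nonroot][1]
      grad <- c(sum(dg[nonroot]) * gg * (1 - gg),
                sum(dl[nonroot]) * ll_ * (1 - ll_),
                dpi * safe$root_prior * (1 - safe$root_prior))
    } else {
      stop("internal: analytic gradient is not available for 'global_rate'")
    }
    -grad
  }
  use_analytic <- mode %in% c("per_branch", "global")

  n_par <- switch(mode,
                  per_branch = 2L * length(nonroot) + 1L,
                  global = 3L, global_rate = 3L)
  starts <- vector("list", n_starts)
  if (mode == "global_rate") {
    starts[[1]] <- c(log(0.1), log(0.5), stats::qlogis(0.5))
  } else {
    starts[[1]] <- c(rep(stats::qlogis(0.05), (n_par - 1) / 2),
                     rep(stats::qlogis(0.2), (n_par - 1) / 2),
                     stats::qlogis(0.5))
  }
  for (s in seq_len(n_starts)[-1]) {
    set.seed(s)
    if (mode == "global_rate") {
      starts[[s]] <- c(log(stats::runif(1, 0.01, 1)),
                       log(stats::runif(1, 0.05, 2)),
                       stats::qlogis(stats::runif(1, 0.2, 0.8)))
    } else {
      nb <- (n_par - 1) / 2
      starts[[s]] <- c(stats::qlogis(stats::runif(nb, 0.005, 0.3)),
                       stats::qlogis(stats::runif(nb, 0.05, 0.6)),
                       stats::qlogis(stats::runif(1, 0.2, 0.8)))
    }
  }

  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[[s]], fn = negll,
                   gr = if (use_analytic) neggr else NULL,
                   method = "L-BFGS-B",
                   lower = rep(-9, n_par), upper = rep(9, n_par),
                   control = list(maxit = max_iter, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) stop("rate estimation failed in all starts")
  if (!any_conv) {
    stop("rate estimation did not converge after ", n_starts,
         " restarts; best log-likelihood so far: ",
         format(-best$value, digits = 8))
  }
  r <- par_to_rates(best$par)
  out <- branch_rates(tree, r$gain, r$loss, r$root_prior)
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- any_conv
  attr(out, "n_patterns") <- N
  attr(out, "mode") <- mode
  out
}

#' Ancestral reconstruction over a set of intron tables
#'
#' Runs the posterior machinery for every intron position in `tables`
#' under `rates`, returning per-node presence posteriors and per-branch
#' gain/loss posteriors for all positions at once, together with the
#' all-absent pattern probability used for observability-corrected counts.
#'
#' @inheritParams estimate_rates
#' @param rates a [branch_rates()], e.g. from [estimate_rates()].
#' @return an object of class `intron_reconstruction`: list with
#'   `positions` (data.frame og_id/column/phase), `node_prob`,
#'   `branch_gain`, `branch_loss` (matrices positions x nodes),
#'   `p_all_absent`, `tree`, `rates`.
#' @export
reconstruct_introns <- function(tables, tree, rates) {
  stopifnot(inherits(rates, "branch_rates"))
  pf <- patterns_from_tables(tables, tree)
  eng <- posterior_engine(tree, pf$patmat, rates)
  absent_pat <- matrix(0L, 1, ape::Ntip(tree),
                       dimnames = list(NULL, tree$tip.label))
  eng0 <- tryCatch(posterior_engine(tree, absent_pat, rates),
                   error = function(e) NULL)
  if (is.null(eng0)) {  # all-absent impossible: every position observable
    eng0 <- list(loglik = -Inf,
                 node_prob = matrix(0, 1, ncol(eng$node_prob)))
  }
  p0 <- exp(eng0$loglik[1])
  structure(list(positions = pf$positions, node_prob = eng$node_prob,
                 branch_gain = eng$branch_gain,
                 branch_loss = eng$branch_loss,
                 p_all_absent = p0,
                 node_prob_unobserved = eng0$node_prob[1, ],
                 tree = tree, rates = rates),
            class = "intron_reconstruction")
}

#' Identify the LECA node of a species tree
#'
#' Under the Opimoda-Diphoda rooting the LECA node is the root; under the
#' unresolved-root topology it is the root of the multifurcation. Both are
#' the ape root node.
#'
#' @param tree rooted `phylo`.
#' @return the ape node id of the root.
#' @export
leca_node <- function(tree) ape::Ntip(tree) + 1L

#' Call LECA introns from posterior presence probabilities
#'
#' An intron position is called a LECA intron when its posterior presence
#' probability at the LECA node is at least `threshold` (default 0.5,
#' inclusive).
#'
#' @param post an `intron_reconstruction` (from [reconstruct_introns()]) or
#'   a single `posterior_presence`.
#' @param node ape node id of the LECA node; defaults to the tree root.
#' @param threshold calling threshold, inclusive.
#' @return for a reconstruction: a data.frame with `og_id`, `column`,
#'   `phase`, `leca_probability`, `is_leca`; for a single posterior: a
#'   one-row data.frame with `leca_probability` and `is_leca`.
#' @export
call_leca <- function(post, node = NULL, threshold = 0.5) {
  if (inherits(post, "intron_reconstruction")) {
    if (is.null(node)) node <- leca_node(post$tree)
    p <- post$node_prob[, node]
    out <- cbind(post$positions,
                 data.frame(leca_probability = p, is_leca = p >= threshold))
    rownames(out) <- NULL
    return(out)
  }
  if (inherits(post, "posterior_presence")) {
    if (is.null(node)) stop("node required for a single posterior")
    p <- post$node_prob[node]
    return(data.frame(leca_probability = p, is_leca = p >= threshold))
  }
  stop("unsupported input to call_leca")
}

#' Expected intron count at a node, including unobservable positions
#'
#' Positions absent from every sampled species never enter an intron
#' table, so the raw posterior sum undercounts ancestral introns. With
#' `P0 = P(all-absent pattern)`, the expected number of unobservable
#' positions behind `n` tabled ones is `n * P0 / (1 - P0)`, and each
#' contributes `P(node present | all-absent)` ancestral introns. The
#' estimator
#' `sum(posterior at node) + n * P0 / (1 - P0) * P(node | all-absent)`
#' is unbiased for the count over all positions that ever existed.
#'
#' @param recon an `intron_reconstruction`.
#' @param node ape node id; defaults to the root (LECA).
#' @return numeric scalar.
#' @export
node_intron_count <- function(recon, node = NULL) {
  stopifnot(inherits(recon, "intron_reconstruction"))
  if (is.null(node)) node <- leca_node(recon$tree)
  n_obs <- nrow(recon$node_prob)
  p0 <- recon$p_all_absent
  sum(recon$node_prob[, node]) +
    n_obs * p0 / (1 - p0) * recon$node_prob_unobserved[node]
}

#' Expected gains and losses per branch
#'
#' @param recon an `intron_reconstruction`.
#' @return data.frame with one row per branch (keyed by child node id and
#'   its label): expected numbers of gains and losses summed over
#'   positions.
#' @export
branch_event_counts <- function(recon) {
  stopifnot(inherits(recon, "intron_reconstruction"))
  tree <- recon$tree
  ntip <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep("", tree$Nnode))
  data.frame(node = child, label = labels[child],
             expected_gains = colSums(recon$branch_gain)[child],
             expected_losses = colSums(recon$branch_loss)[child],
             row.names = NULL)
}
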
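# Independent brute-force oracles used to validate the implementation.
# These enumerate over all ancestral-state assignments / all tables and
# never call the code paths they check.

# Sum the joint probability over every assignment of present/absent to
# internal nodes and missing leaves.
enum_likelihood <- function(pattern, tree, rates) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  obs <- rep(NA_integer_, n_nodes)
  for (i in seq_len(ntip)) {
    v <- pattern[[tree$tip.label[i]]]
    obs[i] <- if (is.null(v) || v %in% c("?", NA)) NA_integer_
              else if (v %in% c("1", 1)) 1L else 0L
  }
  free <- c(which(is.na(obs[seq_len(ntip)])), (ntip + 1L):n_nodes)
  total <- 0
  for (mask in 0:(2^length(free) - 1L)) {
    st <- obs
    st[free] <- as.integer(intToBits(mask))[seq_along(free)]
    p <- if (st[root] == 1L) rates$root_prior else 1 - rates$root_prior
    for (e in seq_len(nrow(tree$edge))) {
      v <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      g <- rates$gain[ch]; l <- rates$loss[ch]
      p <- p * if (st[v] == 0L) { if (st[ch] == 1L) g else 1 - g }
               else { if (st[ch] == 0L) l else 1 - l }
    }
    total <- total + p
  }
  total
}

# Joint-enumeration posteriors: node marginals and per-branch transition
# probabilities by Bayes' rule over the full joint distribution.
enum_posteriors <- function(pattern, tree, rates) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  obs <- rep(NA_integer_, n_nodes)
  for (i in seq_len(ntip)) {
    v <- pattern[[tree$tip.label[i]]]
    obs[i] <- if (is.null(v) || v %in% c("?", NA)) NA_integer_
              else if (v %in% c("1", 1)) 1L else 0L
  }
  free <- c(which(is.na(obs[seq_len(ntip)])), (ntip + 1L):n_nodes)
  node_p <- numeric(n_nodes)
  gain_p <- numeric(n_nodes)
  loss_p <- numeric(n_nodes)
  total <- 0
  for (mask in 0:(2^length(free) - 1L)) {
    st <- obs
    st[free] <- as.integer(intToBits(mask))[seq_along(free)]
    p <- if (st[root] == 1L) rates$root_prior else 1 - rates$root_prior
    for (e in seq_len(nrow(tree$edge))) {
      v <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      g <- rates$gain[ch]; l <- rates$loss[ch]
      p <- p * if (st[v] == 0L) { if (st[ch] == 1L) g else 1 - g }
               else { if (st[ch] == 0L) l else 1 - l }
    }
    total <- total + p
    node_p <- node_p + p * (st == 1L)
    for (e in seq_len(nrow(tree$edge))) {
      v <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (st[v] == 0L && st[ch] == 1L) gain_p[ch] <- gain_p[ch] + p
      if (st[v] == 1L && st[ch] == 0L) loss_p[ch] <- loss_p[ch] + p
    }
  }
  list(node_prob = node_p / total, branch_gain = gain_p / total,
       branch_loss = loss_p / total, lik = total)
}

# Random rooted tree with random per-branch rates and a random pattern.
random_instance <- function(n_leaves, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE)
  tree$tip.label <- paste0("t", seq_len(n_leaves))
  n_nodes <- n_leaves + tree$Nnode
  rates <- branch_rates(tree,
                        gain = stats::runif(n_nodes, 0.01, 0.5),
                        loss = stats::runif(n_nodes, 0.01, 0.8),
                        root_prior = stats::runif(1, 0.1, 0.9))
  pattern <- sample(c("1", "0", "?"), n_leaves, replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
  names(pattern) <- tree$tip.label
  list(tree = tree, rates = rates, pattern = pattern)
}

# Minimal-loss count for a single-gain (Dollo) character by exhaustive
# enumeration over internal-node states. The gain is either the root
# being present or exactly one absent->present edge.
dollo_min_losses <- function(tree, carrier_tips) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  st <- rep(0L, n_nodes)
  st[carrier_tips] <- 1L
  internal <- (ntip + 1L):n_nodes
  best <- Inf
  for (mask in 0:(2^length(internal) - 1L)) {
    st[internal] <- as.integer(intToBits(mask))[seq_along(internal)]
    gains <- as.integer(st[root] == 1L)
    losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      v <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (st[v] == 0L && st[ch] == 1L) gains <- gains + 1L
      if (st[v] == 1L && st[ch] == 0L) losses <- losses + 1L
    }
    if (gains == 1L && losses < best) best <- losses
  }
  best
}

# Two-sided Fisher p by direct hypergeometric enumeration with the
# probability-mass rule (standard 1e-7 relative tolerance on ties).
fisher_enum <- function(t) {
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(N, k), 0)
  pobs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Tiny GFF3 + FASTA fixture writer.
write_toy_gff <- function(dir, rows, contigs) {
  gff <- file.path(dir, "toy.gff3")
  fa <- file.path(dir, "toy.fa")
  writeLines(c("##gff-version 3", rows), gff)
  writeLines(unlist(lapply(names(contigs), function(n)
    c(paste0(">", n), contigs[[n]]))), fa)
  list(gff = gff, fa = fa)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
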
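## Independent oracles used to validate the package's own implementations.
## Everything here is written from the definitions, by different code paths
## than the implementations under test.

## all permutations of 1..n as rows
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

## double-loop betaMNTD between two named abundance vectors
brute_bmntd <- function(x, y, D, weighted = TRUE) {
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  fx <- if (weighted) x[px] / sum(x[px]) else
    stats::setNames(rep(1 / length(px), length(px)), px)
  fy <- if (weighted) y[py] / sum(y[py]) else
    stats::setNames(rep(1 / length(py), length(py)), py)
  s1 <- 0
  for (i in px) s1 <- s1 + fx[[i]] * min(D[i, py])
  s2 <- 0
  for (j in py) s2 <- s2 + fy[[j]] * min(D[j, px])
  0.5 * (s1 + s2)
}

## Faith PD by summing edges on the union of tip-to-root paths, minus the
## edges shared by every path (those above the MRCA)
brute_pd <- function(tips, tree) {
  if (length(tips) < 2) return(0)
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  elen <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n_tip + 1
  path_edges <- function(tip) {
    idx <- match(tip, tree$tip.label)
    out <- integer(0)
    while (idx != root) {
      out <- c(out, idx)   # identify edge by its child node
      idx <- parent[idx]
    }
    out
  }
  paths <- lapply(tips, path_edges)
  all_edges <- unique(unlist(paths))
  shared <- Reduce(intersect, paths)
  sum(elen[setdiff(all_edges, shared)])
}

## exact distribution of null assemblies for one sample under the
## abundance-based Raup-Crick null: sequential occupancy-weighted draws
## without replacement, then multinomial abundance filling
rc_null_distribution <- function(S, N, occ, abund) {
  n_taxa <- length(occ)
  seqs <- list()
  grow <- function(sel, p) {
    if (length(sel) == S) { seqs[[length(seqs) + 1]] <<- list(sel = sel, p = p); return() }
    left <- setdiff(which(occ > 0), sel)
    tot <- sum(occ[left])
    for (i in left) grow(c(sel, i), p * occ[i] / tot)
  }
  grow(integer(0), 1)
  ## compositions of N - S over the selected taxa
  compositions <- function(total, k) {
    if (k == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(a)
      cbind(a, compositions(total - a, k - 1))))
  }
  out_comm <- list(); out_p <- numeric(0)
  fills <- compositions(N - S, S)
  for (sq in seqs) {
    w <- abund[sq$sel]
    if (sum(w) <= 0) w <- rep(1, S)
    w <- w / sum(w)
    for (r in seq_len(nrow(fills))) {
      f <- fills[r, ]
      pf <- stats::dmultinom(f, prob = w)
      comm <- numeric(n_taxa)
      comm[sq$sel] <- 1 + f
      out_comm[[length(out_comm) + 1]] <- comm
      out_p <- c(out_p, sq$p * pf)
    }
  }
  list(comms = do.call(rbind, out_comm), p = out_p)
}

bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

## exact RC-bray for a two-sample table by full enumeration of both nulls
rc_exact <- function(counts) {
  occ <- colSums(counts > 0)
  abund <- colSums(counts)
  d1 <- rc_null_distribution(sum(counts[1, ] > 0), sum(counts[1, ]), occ, abund)
  d2 <- rc_null_distribution(sum(counts[2, ] > 0), sum(counts[2, ]), occ, abund)
  obs <- bray(counts[1, ], counts[2, ])
  p_lt <- 0; p_eq <- 0
  for (i in seq_along(d1$p)) for (j in seq_along(d2$p)) {
    b <- bray(d1$comms[i, ], d2$comms[j, ])
    pr <- d1$p[i] * d2$p[j]
    if (b < obs - 1e-10) p_lt <- p_lt + pr
    else if (abs(b - obs) <= 1e-10) p_eq <- p_eq + pr
  }
  list(rc = 2 * (p_lt + 0.5 * p_eq) - 1, p_lt = p_lt, p_eq = p_eq)
}

## small helper to build an otu_table from a plain matrix
tiny_table <- function(m, layer = NULL, domain = "bacteria") {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("OTU", seq_len(ncol(m)))
  if (is.null(layer)) layer <- rep("W", nrow(m))
  otu_table(m, domain = domain, layer = layer)
}
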
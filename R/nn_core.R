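# Dense reverse-mode primitives for the hybrid affinity networks.
#
# Each layer exposes a *_fwd function returning its output plus whatever
# the matching *_bwd function needs to push gradients back.  Parameters
# are plain R matrices/vectors held in nested named lists; gradients
# mirror that structure, and the Adam updater walks the tree.  Graphs are
# processed as one block-diagonal batch: node features of all molecules
# in a batch are stacked and per-graph structure (normalized adjacency,
# aggregation matrix, self-looped edge list, graph-id vector) is packed
# once per batch.  Everything is deterministic given the R RNG state.

glorot <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

lin_init <- function(n_in, n_out, w_scale = NULL) {
  W <- if (is.null(w_scale)) glorot(n_in, n_out) else
    matrix(stats::rnorm(n_in * n_out, 0, w_scale), n_in, n_out)
  list(W = W, b = numeric(n_out))
}

lin_fwd <- function(p, X) {
  out <- X %*% p$W
  out <- sweep(out, 2, p$b, "+")
  list(out = out, X = X)
}

lin_bwd <- function(p, cache, dOut) {
  list(grads = list(W = crossprod(cache$X, dOut), b = colSums(dOut)),
       dX = dOut %*% t(p$W))
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

relu_bwd <- function(cache, dOut) dOut * cache$mask

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p),
                 nrow = nrow(X), ncol = ncol(X))
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(cache, dOut) {
  if (is.null(cache$mask)) dOut else dOut * cache$mask
}

# ---- graph batching -------------------------------------------------------

# Pack a list of molecular_graph objects into one block-diagonal batch.
pack_graphs <- function(graphs) {
  sizes <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  N <- sum(sizes)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  graph_id <- rep(seq_along(graphs), sizes)
  edges <- do.call(rbind, c(lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e)) e + offsets[i] else matrix(integer(0), ncol = 2)
  }), list(matrix(integer(0), ncol = 2))))
  # normalized adjacency with self-loops (symmetric-normalized, as in the
  # standard graph-convolution propagation rule)
  A <- matrix(0, N, N)
  if (nrow(edges)) A[edges] <- 1
  Ahat <- A + diag(N)
  dinv <- 1 / sqrt(rowSums(Ahat))
  Ahat <- Ahat * tcrossprod(dinv)
  # sum aggregation with self term for isomorphism layers: (I + A)
  Aagg <- A + diag(N)
  # self-looped directed edges for attention layers
  edges_sl <- rbind(edges, cbind(seq_len(N), seq_len(N)))
  list(X = X, graph_id = graph_id, n_graphs = length(graphs),
       Ahat = Ahat, Aagg = Aagg, edges_sl = edges_sl, sizes = sizes)
}

# ---- graph convolution (normalized-adjacency propagation) -----------------

gcn_init <- function(n_in, n_out) lin_init(n_in, n_out)

gcn_fwd <- function(p, batch, H) {
  M <- batch$Ahat %*% H
  out <- sweep(M %*% p$W, 2, p$b, "+")
  list(out = out, M = M)
}

gcn_bwd <- function(p, cache, batch, dOut) {
  list(grads = list(W = crossprod(cache$M, dOut), b = colSums(dOut)),
       dX = batch$Ahat %*% (dOut %*% t(p$W)))  # Ahat is symmetric
}

# ---- graph isomorphism unit (sum aggregation + two-layer MLP) -------------

gin_init <- function(n_in, n_hidden) {
  list(fc1 = lin_init(n_in, n_hidden), fc2 = lin_init(n_hidden, n_hidden))
}

gin_fwd <- function(p, batch, H) {
  agg <- batch$Aagg %*% H
  l1 <- lin_fwd(p$fc1, agg)
  r1 <- relu_fwd(l1$out)
  l2 <- lin_fwd(p$fc2, r1$out)
  list(out = l2$out, l1 = l1, r1 = r1, l2 = l2)
}

gin_bwd <- function(p, cache, batch, dOut) {
  b2 <- lin_bwd(p$fc2, cache$l2, dOut)
  dr1 <- relu_bwd(cache$r1, b2$dX)
  b1 <- lin_bwd(p$fc1, cache$l1, dr1)
  list(grads = list(fc1 = b1$grads, fc2 = b2$grads),
       dX = batch$Aagg %*% b1$dX)  # Aagg is symmetric
}

# ---- graph attention layer ------------------------------------------------

gat_init <- function(n_in, n_out, heads) {
  list(W = glorot(n_in, n_out * heads),
       a_src = matrix(stats::runif(n_out * heads, -sqrt(3 / n_out),
                                   sqrt(3 / n_out)), n_out, heads),
       a_dst = matrix(stats::runif(n_out * heads, -sqrt(3 / n_out),
                                   sqrt(3 / n_out)), n_out, heads),
       b = numeric(n_out * heads),
       n_out = n_out, heads = heads)
}

segment_sum <- function(x, group, n_groups) {
  out <- if (is.matrix(x)) matrix(0, n_groups, ncol(x)) else numeric(n_groups)
  s <- rowsum(x, group)
  ids <- as.integer(rownames(s))
  if (is.matrix(x)) out[ids, ] <- s else out[ids] <- s
  out
}

gat_fwd <- function(p, batch, H) {
  edges <- batch$edges_sl
  src <- edges[, 1]; dst <- edges[, 2]
  N <- nrow(H)
  Z <- H %*% p$W
  C <- p$n_out
  heads <- p$heads
  out <- matrix(0, N, C * heads)
  hcache <- vector("list", heads)
  for (k in seq_len(heads)) {
    cols <- ((k - 1L) * C + 1L):(k * C)
    Zk <- Z[, cols, drop = FALSE]
    s_node_src <- as.vector(Zk %*% p$a_src[, k])
    s_node_dst <- as.vector(Zk %*% p$a_dst[, k])
    s <- s_node_src[src] + s_node_dst[dst]
    e <- ifelse(s > 0, s, 0.2 * s)  # leaky ReLU, slope 0.2
    mx <- as.vector(tapply(e, dst, max))  # dst ids 1..N all present (self-loops)
    ex <- exp(e - mx[dst])
    denom <- segment_sum(ex, dst, N)
    alpha <- ex / denom[dst]
    outk <- segment_sum(alpha * Zk[src, , drop = FALSE], dst, N)
    out[, cols] <- outk
    hcache[[k]] <- list(Zk = Zk, s = s, alpha = alpha)
  }
  out <- sweep(out, 2, p$b, "+")
  list(out = out, Z = Z, H = H, hcache = hcache)
}

gat_bwd <- function(p, cache, batch, dOut) {
  edges <- batch$edges_sl
  src <- edges[, 1]; dst <- edges[, 2]
  N <- nrow(cache$H)
  C <- p$n_out
  heads <- p$heads
  dZ <- matrix(0, N, C * heads)
  da_src <- matrix(0, C, heads)
  da_dst <- matrix(0, C, heads)
  for (k in seq_len(heads)) {
    cols <- ((k - 1L) * C + 1L):(k * C)
    hc <- cache$hcache[[k]]
    dOutk <- dOut[, cols, drop = FALSE]
    # through the weighted aggregation
    dalpha <- rowSums(dOutk[dst, , drop = FALSE] * hc$Zk[src, , drop = FALSE])
    dZk <- segment_sum(hc$alpha * dOutk[dst, , drop = FALSE], src, N)
    # through the per-target softmax
    S <- segment_sum(hc$alpha * dalpha, dst, N)
    de <- hc$alpha * (dalpha - S[dst])
    ds <- de * ifelse(hc$s > 0, 1, 0.2)
    da_src[, k] <- colSums(hc$Zk[src, , drop = FALSE] * ds)
    da_dst[, k] <- colSums(hc$Zk[dst, , drop = FALSE] * ds)
    ssum_src <- segment_sum(ds, src, N)
    ssum_dst <- segment_sum(ds, dst, N)
    dZk <- dZk + outer(ssum_src, p$a_src[, k]) + outer(ssum_dst, p$a_dst[, k])
    dZ[, cols] <- dZk
  }
  list(grads = list(W = crossprod(cache$H, dZ), a_src = da_src,
                    a_dst = da_dst, b = colSums(dOut)),
       dX = dZ %*% t(p$W))
}

# ---- global pooling -------------------------------------------------------

pool_fwd <- function(H, batch, type = c("max", "sum", "mean", "max_mean")) {
  type <- match.arg(type)
  gid <- batch$graph_id
  B <- batch$n_graphs
  if (type == "sum") {
    return(list(out = segment_sum(H, gid, B), type = type))
  }
  if (type == "mean") {
    return(list(out = segment_sum(H, gid, B) / batch$sizes, type = type))
  }
  # max (with argmax bookkeeping), possibly concatenated with mean
  idx <- split(seq_along(gid), gid)
  mx <- matrix(0, B, ncol(H))
  am <- matrix(0L, B, ncol(H))
  for (g in seq_len(B)) {
    rows <- idx[[g]]
    sub <- H[rows, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    am[g, ] <- rows[w]
    mx[g, ] <- sub[cbind(w, seq_len(ncol(H)))]
  }
  if (type == "max") {
    list(out = mx, type = type, am = am)
  } else {
    list(out = cbind(mx, segment_sum(H, gid, B) / batch$sizes),
         type = type, am = am)
  }
}

pool_bwd <- function(cache, batch, dOut, n_nodes) {
  gid <- batch$graph_id
  type <- cache$type
  C <- if (type == "max_mean") ncol(dOut) / 2L else ncol(dOut)
  dH <- matrix(0, n_nodes, C)
  if (type == "sum") return(dOut[gid, , drop = FALSE])
  if (type == "mean") return((dOut / batch$sizes)[gid, , drop = FALSE])
  dmax <- dOut[, seq_len(C), drop = FALSE]
  for (g in seq_len(nrow(dOut))) {
    dH[cbind(cache$am[g, ], seq_len(C))] <-
      dH[cbind(cache$am[g, ], seq_len(C))] + dmax[g, ]
  }
  if (type == "max_mean") {
    dmean <- dOut[, C + seq_len(C), drop = FALSE] / batch$sizes
    dH <- dH + dmean[gid, , drop = FALSE]
  }
  dH
}

# ---- 1D convolution over the protein feature vector -----------------------

conv1d_init <- function(n_filters, kernel) {
  list(W = glorot(kernel, n_filters) * 1, b = numeric(n_filters),
       kernel = kernel, n_filters = n_filters)
}

conv1d_fwd <- function(p, X) {
  B <- nrow(X); L <- ncol(X)
  k <- p$kernel
  if (L < k) stop("protein feature dimension ", L,
                  " shorter than convolution kernel ", k)
  T <- L - k + 1L
  Xc <- vapply(seq_len(k),
               function(j) as.vector(X[, j:(j + T - 1L), drop = FALSE]),
               numeric(B * T))
  Y <- Xc %*% p$W  # (B*T) x F
  Y <- sweep(Y, 2, p$b, "+")
  flat <- matrix(array(Y, dim = c(B, T, p$n_filters)), B, T * p$n_filters)
  list(out = flat, Xc = Xc, B = B, T = T, L = L)
}

conv1d_bwd <- function(p, cache, dOut) {
  B <- cache$B; T <- cache$T; k <- p$kernel
  dY <- matrix(array(dOut, dim = c(B, T, p$n_filters)), B * T, p$n_filters)
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(p$W)
  dX <- matrix(0, B, cache$L)
  for (j in seq_len(k)) {
    dX[, j:(j + T - 1L)] <- dX[, j:(j + T - 1L)] + matrix(dXc[, j], B, T)
  }
  list(grads = list(W = dW, b = db), dX = dX)
}

# ---- parameter-tree utilities and Adam ------------------------------------

is_param_leaf <- function(x) is.numeric(x)

# layer metadata stored alongside trainable arrays; never updated
.META_FIELDS <- c("n_out", "heads", "kernel", "n_filters")

tree_map <- function(f, tree) {
  if (is_param_leaf(tree)) return(f(tree))
  out <- tree
  for (nm in names(tree)) {
    if (nm %in% .META_FIELDS) next
    if (is_param_leaf(tree[[nm]]) || is.list(tree[[nm]])) {
      out[[nm]] <- tree_map(f, tree[[nm]])
    }
  }
  out
}

tree_map2 <- function(f, a, b) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- a
  for (nm in names(a)) {
    if (nm %in% .META_FIELDS) next
    if (is_param_leaf(a[[nm]]) || is.list(a[[nm]])) {
      out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    }
  }
  out
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  upd <- tree_map2(function(m, v) {
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  }, state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

tree_zero_like <- function(params) tree_map(function(x) x * 0, params)
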
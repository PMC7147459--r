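#' Configuration of a hybrid affinity model
#'
#' Defaults follow the published architecture: 128-dimensional branch
#' embeddings, mini-batch size 512 and learning rate 5e-5.  The protein
#' branch embedding defaults to 128 so that the fused representation is
#' 256 wide going into the 512-unit head layer; `protein_embed_dim = 256`
#' selects the alternative reading in which the protein branch maps to
#' 256 units (fused width 384).
#'
#' @param branch_kind Drug-branch architecture: `"gcn"`, `"gin"`,
#'   `"gat"` or `"gat_gcn"`.
#' @param protein_input_dim Width of the protein feature vector: 25, 625
#'   or 15625 for peptide orders 1-3.
#' @param embed_dim Drug-branch embedding width (128).
#' @param protein_embed_dim Protein-branch embedding width (128 or 256).
#' @param batch_size Mini-batch size (512).
#' @param learning_rate Adam learning rate (5e-5).
#' @param epochs Training epochs.
#' @param dropout Dropout probability on fully connected layers (0.2).
#' @param conv_filters,conv_kernel Protein-branch 1D convolution: number
#'   of filters (32) and kernel width (8).
#' @param pooling Global graph pooling; `NULL` picks the branch default
#'   (max for gcn/gat, sum for gin, concatenated max+mean for gat_gcn).
#' @param seed Integer seed for initialization and training randomness.
#' @return Object of class `model_config`.
#' @export
model_config <- function(branch_kind = c("gcn", "gin", "gat", "gat_gcn"),
                         protein_input_dim = 625,
                         embed_dim = 128,
                         protein_embed_dim = 128,
                         batch_size = 512,
                         learning_rate = 5e-5,
                         epochs = 30,
                         dropout = 0.2,
                         conv_filters = 32,
                         conv_kernel = 8,
                         pooling = NULL,
                         seed = 1) {
  branch_kind <- match.arg(branch_kind)
  if (!protein_input_dim %in% c(25, 625, 15625)) {
    stop("protein_input_dim must be 25, 625 or 15625 (peptide order 1-3)")
  }
  if (!protein_embed_dim %in% c(128, 256)) {
    stop("protein_embed_dim must be 128 or 256")
  }
  if (is.null(pooling)) {
    pooling <- switch(branch_kind, gcn = "max", gin = "sum", gat = "max",
                      gat_gcn = "max_mean")
  }
  pooling <- match.arg(pooling, c("max", "sum", "mean", "max_mean"))
  stopifnot(embed_dim >= 1, batch_size >= 1, learning_rate > 0,
            epochs >= 0, dropout >= 0, dropout < 1,
            conv_filters >= 1, conv_kernel >= 1)
  structure(list(branch_kind = branch_kind,
                 protein_input_dim = as.integer(protein_input_dim),
                 embed_dim = as.integer(embed_dim),
                 protein_embed_dim = as.integer(protein_embed_dim),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 dropout = dropout,
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pooling = pooling,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> ", x$branch_kind, " drug branch + 1D-conv protein branch\n",
      "  protein input ", x$protein_input_dim, " -> ", x$protein_embed_dim,
      "; drug embed ", x$embed_dim, "; pooling ", x$pooling, "\n",
      "  batch ", x$batch_size, ", lr ", x$learning_rate, ", epochs ",
      x$epochs, ", dropout ", x$dropout, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

.ATOM_DIM <- 78L

#' Build the drug graph branch
#'
#' Initializes the parameters of one of the four graph architectures.
#' All four map a molecular graph to an `embed_dim`-dimensional vector:
#' \itemize{
#'   \item `gcn`: three graph-convolution + ReLU units with output
#'     channels 78, 156, 312, global pooling, a 1024-unit fully connected
#'     layer, then the 128-dim output;
#'   \item `gin`: five isomorphism units, each a two-layer MLP of width
#'     32, global pooling, then the 128-dim output;
#'   \item `gat`: two attention layers (78 channels with 10 heads, then
#'     128 channels with 1 head), global pooling, then the 128-dim
#'     output;
#'   \item `gat_gcn`: an attention layer (78 channels, 10 heads) chained
#'     into a 780-channel graph convolution, global pooling, a 1500-unit
#'     fully connected layer, then the 128-dim output.
#' }
#'
#' @param kind One of `"gcn"`, `"gin"`, `"gat"`, `"gat_gcn"`.
#' @param embed_dim Output embedding width (default 128).
#' @param pooling Global pooling type (`NULL` = branch default, see
#'   [model_config()]).
#' @return List with `kind`, `pooling`, `widths` and initialized `params`.
#' @export
build_drug_branch <- function(kind = c("gcn", "gin", "gat", "gat_gcn"),
                              embed_dim = 128, pooling = NULL) {
  kind <- match.arg(kind)
  embed_dim <- as.integer(embed_dim)
  if (is.null(pooling)) {
    pooling <- switch(kind, gcn = "max", gin = "sum", gat = "max",
                      gat_gcn = "max_mean")
  }
  params <- switch(kind,
    gcn = list(gc1 = gcn_init(.ATOM_DIM, 78L),
               gc2 = gcn_init(78L, 156L),
               gc3 = gcn_init(156L, 312L),
               fc1 = lin_init(312L, 1024L),
               emb = lin_init(1024L, embed_dim)),
    gin = list(gin1 = gin_init(.ATOM_DIM, 32L),
               gin2 = gin_init(32L, 32L),
               gin3 = gin_init(32L, 32L),
               gin4 = gin_init(32L, 32L),
               gin5 = gin_init(32L, 32L),
               emb = lin_init(32L, embed_dim)),
    gat = list(gat1 = gat_init(.ATOM_DIM, 78L, 10L),
               gat2 = gat_init(780L, 128L, 1L),
               emb = lin_init(128L, embed_dim)),
    gat_gcn = list(gat1 = gat_init(.ATOM_DIM, 78L, 10L),
                   gc2 = gcn_init(780L, 780L),
                   fc1 = lin_init(780L * 2L, 1500L),
                   emb = lin_init(1500L, embed_dim))
  )
  widths <- switch(kind,
    gcn = c(78L, 156L, 312L, 1024L, embed_dim),
    gin = c(rep(32L, 5L), embed_dim),
    gat = c(780L, 128L, embed_dim),
    gat_gcn = c(780L, 780L, 1500L, embed_dim))
  list(kind = kind, pooling = pooling, widths = widths, params = params)
}

drug_branch_fwd <- function(kind, p, batch, pooling, dropout, train) {
  H <- batch$X
  if (kind == "gcn") {
    c1 <- gcn_fwd(p$gc1, batch, H);      r1 <- relu_fwd(c1$out)
    c2 <- gcn_fwd(p$gc2, batch, r1$out); r2 <- relu_fwd(c2$out)
    c3 <- gcn_fwd(p$gc3, batch, r2$out); r3 <- relu_fwd(c3$out)
    pl <- pool_fwd(r3$out, batch, pooling)
    f1 <- lin_fwd(p$fc1, pl$out); rf <- relu_fwd(f1$out)
    dp <- dropout_fwd(rf$out, dropout, train)
    em <- lin_fwd(p$emb, dp$out)
    list(out = em$out, cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                                    c3 = c3, r3 = r3, pl = pl, f1 = f1,
                                    rf = rf, dp = dp, em = em,
                                    n_nodes = nrow(H)))
  } else if (kind == "gin") {
    caches <- list()
    Hk <- H
    for (i in 1:5) {
      gi <- gin_fwd(p[[paste0("gin", i)]], batch, Hk)
      ri <- relu_fwd(gi$out)
      caches[[i]] <- list(g = gi, r = ri)
      Hk <- ri$out
    }
    pl <- pool_fwd(Hk, batch, pooling)
    em <- lin_fwd(p$emb, pl$out)
    list(out = em$out, cache = list(units = caches, pl = pl, em = em,
                                    n_nodes = nrow(H)))
  } else if (kind == "gat") {
    a1 <- gat_fwd(p$gat1, batch, H);      r1 <- relu_fwd(a1$out)
    a2 <- gat_fwd(p$gat2, batch, r1$out); r2 <- relu_fwd(a2$out)
    pl <- pool_fwd(r2$out, batch, pooling)
    em <- lin_fwd(p$emb, pl$out)
    list(out = em$out, cache = list(a1 = a1, r1 = r1, a2 = a2, r2 = r2,
                                    pl = pl, em = em, n_nodes = nrow(H)))
  } else {
    a1 <- gat_fwd(p$gat1, batch, H);      r1 <- relu_fwd(a1$out)
    c2 <- gcn_fwd(p$gc2, batch, r1$out);  r2 <- relu_fwd(c2$out)
    pl <- pool_fwd(r2$out, batch, pooling)
    f1 <- lin_fwd(p$fc1, pl$out); rf <- relu_fwd(f1$out)
    dp <- dropout_fwd(rf$out, dropout, train)
    em <- lin_fwd(p$emb, dp$out)
    list(out = em$out, cache = list(a1 = a1, r1 = r1, c2 = c2, r2 = r2,
                                    pl = pl, f1 = f1, rf = rf, dp = dp,
                                    em = em, n_nodes = nrow(H)))
  }
}

drug_branch_bwd <- function(kind, p, cache, batch, dEmb) {
  if (kind == "gcn") {
    bem <- lin_bwd(p$emb, cache$em, dEmb)
    ddp <- dropout_bwd(cache$dp, bem$dX)
    drf <- relu_bwd(cache$rf, ddp)
    bf1 <- lin_bwd(p$fc1, cache$f1, drf)
    dpl <- pool_bwd(cache$pl, batch, bf1$dX, cache$n_nodes)
    d3 <- relu_bwd(cache$r3, dpl);  b3 <- gcn_bwd(p$gc3, cache$c3, batch, d3)
    d2 <- relu_bwd(cache$r2, b3$dX); b2 <- gcn_bwd(p$gc2, cache$c2, batch, d2)
    d1 <- relu_bwd(cache$r1, b2$dX); b1 <- gcn_bwd(p$gc1, cache$c1, batch, d1)
    list(gc1 = b1$grads, gc2 = b2$grads, gc3 = b3$grads,
         fc1 = bf1$grads, emb = bem$grads)
  } else if (kind == "gin") {
    bem <- lin_bwd(p$emb, cache$em, dEmb)
    dH <- pool_bwd(cache$pl, batch, bem$dX, cache$n_nodes)
    grads <- list(emb = bem$grads)
    for (i in 5:1) {
      u <- cache$units[[i]]
      dGi <- relu_bwd(u$r, dH)
      bi <- gin_bwd(p[[paste0("gin", i)]], u$g, batch, dGi)
      grads[[paste0("gin", i)]] <- bi$grads
      dH <- bi$dX
    }
    grads
  } else if (kind == "gat") {
    bem <- lin_bwd(p$emb, cache$em, dEmb)
    dpl <- pool_bwd(cache$pl, batch, bem$dX, cache$n_nodes)
    d2 <- relu_bwd(cache$r2, dpl)
    b2 <- gat_bwd(p$gat2, cache$a2, batch, d2)
    d1 <- relu_bwd(cache$r1, b2$dX)
    b1 <- gat_bwd(p$gat1, cache$a1, batch, d1)
    list(gat1 = b1$grads, gat2 = b2$grads, emb = bem$grads)
  } else {
    bem <- lin_bwd(p$emb, cache$em, dEmb)
    ddp <- dropout_bwd(cache$dp, bem$dX)
    drf <- relu_bwd(cache$rf, ddp)
    bf1 <- lin_bwd(p$fc1, cache$f1, drf)
    dpl <- pool_bwd(cache$pl, batch, bf1$dX, cache$n_nodes)
    d2 <- relu_bwd(cache$r2, dpl)
    b2 <- gcn_bwd(p$gc2, cache$c2, batch, d2)
    d1 <- relu_bwd(cache$r1, b2$dX)
    b1 <- gat_bwd(p$gat1, cache$a1, batch, d1)
    list(gat1 = b1$grads, gc2 = b2$grads, fc1 = bf1$grads, emb = bem$grads)
  }
}

#' Build the protein convolution branch
#'
#' A single-channel 1D convolution (`conv_filters` filters of width
#' `conv_kernel`) slides over the word-frequency feature vector; the
#' flattened activation map is fully connected to the branch embedding.
#'
#' @param input_dim Protein feature width: 25, 625 or 15625.
#' @param embed_dim Branch embedding width (128, or 256 for the wide
#'   reading).
#' @param conv_filters,conv_kernel Convolution geometry.
#' @return List with `widths` and initialized `params`.
#' @export
build_protein_branch <- function(input_dim, embed_dim = 128,
                                 conv_filters = 32, conv_kernel = 8) {
  if (!input_dim %in% c(25, 625, 15625)) {
    stop("input_dim must be 25, 625 or 15625 (peptide order 1-3)")
  }
  T <- input_dim - conv_kernel + 1L
  params <- list(conv = conv1d_init(conv_filters, conv_kernel),
                 emb = lin_init(conv_filters * T, embed_dim))
  list(widths = c(conv_filters * T, embed_dim), params = params)
}

prot_branch_fwd <- function(p, X) {
  cv <- conv1d_fwd(p$conv, X)
  rc <- relu_fwd(cv$out)
  em <- lin_fwd(p$emb, rc$out)
  list(out = em$out, cache = list(cv = cv, rc = rc, em = em))
}

prot_branch_bwd <- function(p, cache, dEmb) {
  bem <- lin_bwd(p$emb, cache$em, dEmb)
  drc <- relu_bwd(cache$rc, bem$dX)
  bcv <- conv1d_bwd(p$conv, cache$cv, drc)
  list(grads = list(conv = bcv$grads, emb = bem$grads), dX = bcv$dX)
}

head_init <- function(in_dim) {
  list(fc1 = lin_init(in_dim, 512L),
       fc2 = lin_init(512L, 128L),
       out = lin_init(128L, 1L, w_scale = 0.01))
}

head_fwd <- function(p, Z, dropout, train) {
  f1 <- lin_fwd(p$fc1, Z); r1 <- relu_fwd(f1$out)
  d1 <- dropout_fwd(r1$out, dropout, train)
  f2 <- lin_fwd(p$fc2, d1$out); r2 <- relu_fwd(f2$out)
  d2 <- dropout_fwd(r2$out, dropout, train)
  fo <- lin_fwd(p$out, d2$out)
  list(out = as.vector(fo$out),
       cache = list(f1 = f1, r1 = r1, d1 = d1, f2 = f2, r2 = r2,
                    d2 = d2, fo = fo))
}

head_bwd <- function(p, cache, dPred) {
  bo <- lin_bwd(p$out, cache$fo, matrix(dPred, ncol = 1))
  dd2 <- dropout_bwd(cache$d2, bo$dX)
  dr2 <- relu_bwd(cache$r2, dd2)
  b2 <- lin_bwd(p$fc2, cache$f2, dr2)
  dd1 <- dropout_bwd(cache$d1, b2$dX)
  dr1 <- relu_bwd(cache$r1, dd1)
  b1 <- lin_bwd(p$fc1, cache$f1, dr1)
  list(grads = list(fc1 = b1$grads, fc2 = b2$grads, out = bo$grads),
       dZ = b1$dX)
}

#' Build the full hybrid affinity model
#'
#' Composes the drug graph branch, the protein convolution branch and the
#' fused regression head (fully connected layers of 512 and 128 units
#' followed by a single linear output).  Parameter initialization is
#' seeded from `config$seed`.
#'
#' @param config A [model_config()].
#' @return Object of class `dta_model` with elements `config` and
#'   `params`; pass to [train_dta()].
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(config$seed)
  drug <- build_drug_branch(config$branch_kind, config$embed_dim,
                            config$pooling)
  prot <- build_protein_branch(config$protein_input_dim,
                               config$protein_embed_dim,
                               config$conv_filters, config$conv_kernel)
  head <- head_init(config$embed_dim + config$protein_embed_dim)
  structure(list(config = config,
                 params = list(drug = drug$params, prot = prot$params,
                               head = head),
                 trained = FALSE),
            class = "dta_model")
}

#' @export
print.dta_model <- function(x, ...) {
  n_par <- 0
  count <- function(t) tree_map(function(a) { n_par <<- n_par + length(a); a }, t)
  invisible(count(x$params))
  cat("<dta_model> ", x$config$branch_kind, " branch, ",
      format(n_par, big.mark = ","), " parameters, ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Featurize an affinity dataset for the hybrid model
#'
#' Encodes the unique proteins as word-frequency peptide vectors and the
#' unique drugs as molecular graphs, and indexes every record against
#' them.  Word-frequency weights are fitted on the unique proteins of
#' `ds` unless `weights` is supplied; at prediction time always pass the
#' weights fitted on the training set.
#'
#' @param ds An [affinity_dataset()].
#' @param n Peptide order (ignored when `weights` given).
#' @param weights Optional [document_counts()] result from the training
#'   corpus.
#' @param alphabet A [peptide_alphabet()].
#' @param spec An [atom_feature_spec()].
#' @return Object of class `dta_features`.
#' @export
featurize_pairs <- function(ds, n = 2, weights = NULL,
                            alphabet = peptide_alphabet(),
                            spec = atom_feature_spec()) {
  stopifnot(inherits(ds, "affinity_dataset"))
  prot <- unique(data.frame(protein_id = ds$protein_id,
                            sequence = ds$sequence,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(prot$protein_id)) {
    stop("a protein_id maps to more than one sequence")
  }
  drug <- unique(data.frame(drug_id = ds$drug_id, smiles = ds$smiles,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(drug$drug_id)) {
    stop("a drug_id maps to more than one SMILES")
  }
  corpus <- stats::setNames(prot$sequence, prot$protein_id)
  if (is.null(weights)) weights <- document_counts(corpus, n, alphabet)
  prot_mat <- encode_corpus(corpus, weights = weights, alphabet = alphabet)
  gres <- graphs_from_table(drug, spec)
  if (nrow(gres$failures)) {
    stop("unparseable SMILES for drug(s): ",
         paste(gres$failures$drug_id, collapse = ", "))
  }
  structure(list(prot_mat = prot_mat,
                 graphs = gres$graphs,
                 drug_ix = match(ds$drug_id, names(gres$graphs)),
                 prot_ix = match(ds$protein_id, rownames(prot_mat)),
                 affinity = ds$affinity,
                 weights = weights,
                 units = attr(ds, "units")),
            class = "dta_features")
}

#' @export
print.dta_features <- function(x, ...) {
  cat("<dta_features> ", length(x$affinity), " pairs, ",
      length(x$graphs), " drugs, ", nrow(x$prot_mat), " proteins, ",
      "protein dim ", ncol(x$prot_mat), "\n", sep = "")
  invisible(x)
}

# Forward pass over one mini-batch of record indices.
.batch_forward <- function(params, config, feats, rows, train) {
  drug_ix <- feats$drug_ix[rows]
  prot_ix <- feats$prot_ix[rows]
  u_drugs <- sort(unique(drug_ix))
  u_prots <- sort(unique(prot_ix))
  gbatch <- pack_graphs(feats$graphs[u_drugs])
  Xp <- feats$prot_mat[u_prots, , drop = FALSE]
  dfw <- drug_branch_fwd(config$branch_kind, params$drug, gbatch,
                         config$pooling, config$dropout, train)
  pfw <- prot_branch_fwd(params$prot, Xp)
  dmap <- match(drug_ix, u_drugs)
  pmap <- match(prot_ix, u_prots)
  Z <- cbind(dfw$out[dmap, , drop = FALSE], pfw$out[pmap, , drop = FALSE])
  hfw <- head_fwd(params$head, Z, config$dropout, train)
  list(pred = hfw$out, gbatch = gbatch, dfw = dfw, pfw = pfw, hfw = hfw,
       dmap = dmap, pmap = pmap,
       n_u_drugs = length(u_drugs), n_u_prots = length(u_prots))
}

.batch_backward <- function(params, config, fw, dPred) {
  hbw <- head_bwd(params$head, fw$hfw$cache, dPred)
  ed <- config$embed_dim
  dZd <- hbw$dZ[, seq_len(ed), drop = FALSE]
  dZp <- hbw$dZ[, ed + seq_len(config$protein_embed_dim), drop = FALSE]
  dEmbD <- segment_sum(dZd, fw$dmap, fw$n_u_drugs)
  dEmbP <- segment_sum(dZp, fw$pmap, fw$n_u_prots)
  dgr <- drug_branch_bwd(config$branch_kind, params$drug, fw$dfw$cache,
                         fw$gbatch, dEmbD)
  pgr <- prot_branch_bwd(params$prot, fw$pfw$cache, dEmbP)
  list(drug = dgr, prot = pgr$grads, head = hbw$grads)
}

#' Train a hybrid affinity model
#'
#' Minimizes mean squared error by mini-batch Adam.  The linear output
#' bias is initialized to the mean training affinity so that the model
#' starts at the predict-the-mean baseline and training always measures
#' improvement over it.  All randomness (shuffling, dropout) derives from
#' `config$seed`, so runs are exactly reproducible.
#'
#' @param model A [build_model()] result.
#' @param feats A [featurize_pairs()] result; its protein feature width
#'   must equal `config$protein_input_dim`.
#' @param epochs Optional override of `config$epochs`.
#' @param verbose Print the per-epoch loss.
#' @return The trained `dta_model`, with a `history` data.frame
#'   (`epoch`, `loss`) attached.
#' @export
train_dta <- function(model, feats, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dta_model"), inherits(feats, "dta_features"))
  config <- model$config
  if (ncol(feats$prot_mat) != config$protein_input_dim) {
    stop("featurized protein dim ", ncol(feats$prot_mat),
         " does not match model protein_input_dim ", config$protein_input_dim)
  }
  if (length(feats$affinity) == 0L) stop("empty training set")
  if (is.null(epochs)) epochs <- config$epochs
  model$history <- data.frame(epoch = integer(0), loss = numeric(0))
  if (epochs == 0L) return(model)

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(config$seed + 1L)

  params <- model$params
  params$head$out$b[] <- mean(feats$affinity)
  state <- adam_init(params)
  n <- length(feats$affinity)
  y <- feats$affinity
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- perm[s:min(s + config$batch_size - 1L, n)]
      fw <- .batch_forward(params, config, feats, rows, train = TRUE)
      resid <- fw$pred - y[rows]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; lower the learning rate")
      }
      ep_loss <- ep_loss + loss * length(rows)
      grads <- .batch_backward(params, config, fw,
                               2 * resid / length(rows))
      step <- adam_step(params, grads, state, config$learning_rate)
      params <- step$params
      state <- step$state
    }
    model$history <- rbind(model$history,
                           data.frame(epoch = ep, loss = ep_loss / n))
    if (verbose) {
      message(sprintf("epoch %3d  training MSE %.5f", ep, ep_loss / n))
    }
  }
  model$params <- params
  model$trained <- TRUE
  model
}

#' Predict affinities for featurized pairs
#'
#' Deterministic evaluation-mode forward pass (no dropout); predictions
#' are independent of how the pairs are partitioned into batches.
#'
#' @param model A `dta_model` (trained or not).
#' @param feats A [featurize_pairs()] result built with the training-time
#'   peptide order/weights.
#' @param batch_size Evaluation batch size.
#' @return Numeric vector of predicted affinities, one per record of
#'   `feats`, in record order.
#' @export
predict_dta <- function(model, feats, batch_size = 512L) {
  stopifnot(inherits(model, "dta_model"), inherits(feats, "dta_features"))
  if (ncol(feats$prot_mat) != model$config$protein_input_dim) {
    stop("featurized protein dim ", ncol(feats$prot_mat),
         " does not match model protein_input_dim ",
         model$config$protein_input_dim)
  }
  n <- length(feats$affinity)
  pred <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    fw <- .batch_forward(model$params, model$config, feats, rows,
                         train = FALSE)
    pred[rows] <- fw$pred
  }
  pred
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration, the parameters and the
#' word-frequency corpus weights (when supplied) so that a reloaded model
#' can featurize and predict consistently.
#'
#' @param model A `dta_model`.
#' @param path Checkpoint path (RDS).
#' @param weights Optional [document_counts()] result to embed.
#' @export
save_model <- function(model, path, weights = NULL) {
  stopifnot(inherits(model, "dta_model"))
  saveRDS(list(model = model, weights = weights), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns a list with `model` and `weights`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$model, "dta_model"))
  obj
}
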